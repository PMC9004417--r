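#' Chi-square goodness-of-fit test for a two-haplotype clone
#'
#' If a heteroplasmic clone carries exactly two mitochondrial haplotypes,
#' the minor-allele read counts at its heteroplasmic sites should follow a
#' common binomial sampling distribution. The pooled minor fraction is the
#' read-weighted estimate `fbar = sum(minor) / sum(coverage)`; expected
#' minor counts at site i are `fbar * coverage_i`, and the statistic sums
#' `(obs - exp)^2 / exp` over minor and major read classes at every site,
#' with `m - 1` degrees of freedom (one parameter estimated). The p-value is
#' the upper tail of the chi-square distribution; large p means the binomial
#' (two-haplotype) model fits.
#'
#' @param minor_counts,coverages integer vectors over the clone's
#'   heteroplasmic sites.
#' @param clone_id optional label carried into the result.
#' @param min_sites minimum number of sites for the test (default 5);
#'   clones below it are flagged not testable.
#' @param support_threshold the clone is recorded as supporting the
#'   two-haplotype model when `p_value > support_threshold` (default 0.95,
#'   a literal reading of requiring very high probability of support for
#'   the null; many analyses will prefer the conventional 0.05).
#' @return one-row data.frame of class `two_hap_test` with columns
#'   `clone_id`, `n_sites`, `pooled_maf`, `chi2`, `df`, `p_value`,
#'   `supports_two_haplotypes`, `testable`.
#' @export
two_haplotype_test <- function(minor_counts, coverages, clone_id = NA_character_,
                               min_sites = 5L, support_threshold = 0.95) {
  stopifnot(length(minor_counts) == length(coverages))
  m <- length(minor_counts)
  res <- data.frame(clone_id = clone_id, n_sites = m,
                    pooled_maf = NA_real_, chi2 = NA_real_, df = NA_integer_,
                    p_value = NA_real_, supports_two_haplotypes = NA,
                    testable = FALSE, stringsAsFactors = FALSE)
  class(res) <- c("two_hap_test", "data.frame")
  if (m < min_sites) return(res)
  fbar <- sum(minor_counts) / sum(coverages)
  exp_minor <- fbar * coverages
  exp_major <- (1 - fbar) * coverages
  if (any(exp_minor == 0) || any(exp_major == 0))
    stop("degenerate expected count of 0 in two-haplotype test")
  obs_major <- coverages - minor_counts
  chi2 <- sum((minor_counts - exp_minor)^2 / exp_minor +
                (obs_major - exp_major)^2 / exp_major)
  df <- m - 1L
  p <- pchisq(chi2, df = df, lower.tail = FALSE)
  res$pooled_maf <- fbar
  res$chi2 <- chi2
  res$df <- df
  res$p_value <- p
  res$supports_two_haplotypes <- p > support_threshold
  res$testable <- TRUE
  res
}

#' Run the two-haplotype test for every clone in a call set
#'
#' @param sites a `het_sites` data.frame from [call_heteroplasmic_sites()].
#' @inheritParams two_haplotype_test
#' @return data.frame with one `two_hap_test` row per clone present in
#'   `sites`.
#' @export
test_all_clones <- function(sites, min_sites = 5L, support_threshold = 0.95) {
  clones <- unique(sites$clone_id)
  out <- do.call(rbind, lapply(clones, function(cl) {
    s <- sites[sites$clone_id == cl, , drop = FALSE]
    two_haplotype_test(s$minor_count, s$coverage, clone_id = cl,
                       min_sites = min_sites,
                       support_threshold = support_threshold)
  }))
  if (is.null(out)) out <- two_haplotype_test(integer(), integer())[0, ]
  rownames(out) <- NULL
  out
}

#' Majority-rule consensus sequence for one clone
#'
#' At each reference position the base with the highest read count is
#' emitted; ties go to the alphabetically earlier base, and positions with
#' coverage below `min_depth` (or absent from the table) are emitted as N.
#'
#' @param x an [allele_counts()] data.frame restricted to one clone.
#' @param reference_length length of the circular reference.
#' @param min_depth minimum coverage for a confident call (default 100).
#' @return a single consensus sequence string of length `reference_length`.
#' @export
build_consensus <- function(x, reference_length, min_depth = 100L) {
  stopifnot(inherits(x, "allele_counts"))
  if (length(unique(x$clone_id)) > 1L)
    stop("build_consensus expects records from a single clone")
  cons <- rep("N", reference_length)
  if (nrow(x) > 0L) {
    cnt <- as.matrix(as.data.frame(x)[BASES])
    maj <- BASES[max.col(cnt, ties.method = "first")]
    ok <- x$coverage >= min_depth & x$site <= reference_length
    cons[x$site[ok]] <- maj[ok]
  }
  paste(cons, collapse = "")
}

#' Phase a two-haplotype clone by allele frequency
#'
#' Alleles with the higher within-clone frequency are assigned to the major
#' haplotype, those with the lower frequency to the minor haplotype: the
#' major haplotype is the consensus itself, and the minor haplotype is the
#' consensus with every heteroplasmic site's minor allele substituted. The
#' two sequences differ exactly at the clone's heteroplasmic sites.
#'
#' @param clone_sites `het_sites` rows for one clone (may be empty, in
#'   which case major and minor coincide with the consensus).
#' @param consensus consensus sequence string for the clone.
#' @param test optional one-row result from [two_haplotype_test()]; if
#'   given and the clone does not support the two-haplotype model, phasing
#'   is refused.
#' @return list with elements `major` and `minor` (sequence strings).
#' @export
phase_by_frequency <- function(clone_sites, consensus, test = NULL) {
  if (!is.null(test)) {
    if (!isTRUE(test$testable) || !isTRUE(test$supports_two_haplotypes))
      stop("clone does not support the two-haplotype model; phasing refused")
  }
  if (nrow(clone_sites) > 0L &&
      length(unique(clone_sites$clone_id)) > 1L)
    stop("phase_by_frequency expects sites from a single clone")
  major <- strsplit(consensus, "", fixed = TRUE)[[1L]]
  minor <- major
  if (nrow(clone_sites) > 0L) {
    if (any(clone_sites$site > length(major)))
      stop("heteroplasmic site beyond consensus length")
    major[clone_sites$site] <- clone_sites$major_allele
    minor[clone_sites$site] <- clone_sites$minor_allele
  }
  list(major = paste(major, collapse = ""),
       minor = paste(minor, collapse = ""))
}

#' Pairwise p-distances between haplotypes
#'
#' Proportion of mismatching positions among positions where neither
#' sequence is N. Pairs with zero comparable positions are returned as NA.
#'
#' @param haps a [haplotype_set()].
#' @return symmetric numeric matrix with zero diagonal, labelled
#'   `clone|population|role`.
#' @export
pairwise_divergence <- function(haps) {
  stopifnot(inherits(haps, "haplotype_set"))
  n <- length(haps$seq)
  m <- matrix(0, n, n)
  labs <- paste(haps$info$clone_id, haps$info$population_id,
                haps$info$role, sep = "|")
  dimnames(m) <- list(labs, labs)
  if (n < 2L) return(m)
  chars <- do.call(rbind, strsplit(haps$seq, "", fixed = TRUE))
  valid <- chars != "N"
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      comp <- valid[i, ] & valid[j, ]
      nc <- sum(comp)
      m[i, j] <- m[j, i] <-
        if (nc == 0L) NA_real_ else sum(chars[i, comp] != chars[j, comp]) / nc
    }
  }
  m
}
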