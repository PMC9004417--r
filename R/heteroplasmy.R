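#' Parameters for the heteroplasmy filter cascade
#'
#' Defaults mirror a conservative high-depth calling recipe: the lower limit
#' of the 95% Wilson confidence interval of the minor-allele fraction must
#' reach 0.01, the site must be biallelic, the minor allele must be backed
#' by at least 5 reads, no candidate indel may lie within 3 bp, and the site
#' quality score must be at least 10.
#'
#' `allele_min_reads` and `allele_min_ci` define when a base with a nonzero
#' count is recognized as an allele at all: it needs both a minimum read
#' count and a Wilson lower bound of its own frequency reaching the 1%
#' credibility limit (below which sequencing error and true variation are
#' indistinguishable). Without the frequency condition, stray error reads
#' at depths of several thousand reads would routinely turn biallelic sites
#' into apparent triallelic ones. Both are definitional constants, not part
#' of the monotone filter cascade.
#'
#' @param min_ci_lower minimum Wilson lower bound on the minor-allele
#'   fraction (default 0.01).
#' @param max_alt_alleles maximum number of alternate (non-major) alleles;
#'   sites with more are removed (default 2, i.e. sites with more than two
#'   alternate alleles never pass; combined with the biallelic requirement
#'   below, emitted sites have exactly one alternate allele).
#' @param min_minor_reads minimum reads supporting the minor allele
#'   (default 5).
#' @param indel_flank_bp flank in bp within which a candidate indel
#'   disqualifies the site (default 3; the input flag is assumed to encode
#'   this window).
#' @param min_site_quality minimum per-site quality score (default 10).
#' @param ci_confidence two-sided confidence level of the Wilson interval
#'   (default 0.95).
#' @param allele_min_reads read support required to recognize a base as an
#'   allele (default 5).
#' @param allele_min_ci Wilson lower bound on a base's frequency required
#'   to recognize it as an allele (default 0.01).
#' @return list of class `het_call_params`.
#' @export
het_call_params <- function(min_ci_lower = 0.01, max_alt_alleles = 2L,
                            min_minor_reads = 5L, indel_flank_bp = 3L,
                            min_site_quality = 10, ci_confidence = 0.95,
                            allele_min_reads = 5L, allele_min_ci = 0.01) {
  p <- list(min_ci_lower = min_ci_lower,
            max_alt_alleles = as.integer(max_alt_alleles),
            min_minor_reads = as.integer(min_minor_reads),
            indel_flank_bp = as.integer(indel_flank_bp),
            min_site_quality = min_site_quality,
            ci_confidence = ci_confidence,
            allele_min_reads = as.integer(allele_min_reads),
            allele_min_ci = allele_min_ci)
  if (any(vapply(p, function(x) x < 0, TRUE)))
    stop("all thresholds must be non-negative")
  if (p$min_ci_lower >= 0.5) stop("min_ci_lower must be below 0.5")
  if (p$ci_confidence <= 0 || p$ci_confidence >= 1)
    stop("ci_confidence must be in (0, 1)")
  class(p) <- "het_call_params"
  p
}

#' Wilson score lower confidence bound for a binomial proportion
#'
#' Two-sided score interval of Wilson (1927); the lower limit is returned.
#' Stable at low counts, never exceeds the point estimate, and never drops
#' below 0. Vectorized over `minor_count` and `coverage`.
#'
#' @param minor_count number of successes (reads supporting the minor
#'   allele), `0 <= minor_count <= coverage`.
#' @param coverage number of trials (total reads); must be positive.
#' @param confidence two-sided confidence level (default 0.95).
#' @return lower bound(s) of the interval, in `[0, 1]`.
#' @export
ci_lower_bound <- function(minor_count, coverage, confidence = 0.95) {
  if (any(coverage <= 0)) stop("coverage must be positive")
  if (any(minor_count < 0) || any(minor_count > coverage))
    stop("minor_count must lie in [0, coverage]")
  z <- qnorm(1 - (1 - confidence) / 2)
  p <- minor_count / coverage
  n <- coverage
  centre <- (p + z^2 / (2 * n)) / (1 + z^2 / n)
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / (1 + z^2 / n)
  pmax(0, centre - half)
}

#' Call heteroplasmic sites per clone with the five-filter cascade
#'
#' A (clone, site) record is emitted iff all of the following hold:
#' exactly two alleles are recognized (see [het_call_params()] for the
#' recognition rule); the minor allele is supported by at least
#' `min_minor_reads` reads; the Wilson lower confidence bound of the
#' minor-allele fraction reaches `min_ci_lower`; no candidate indel lies
#' within the flanking window; and the site quality is at least
#' `min_site_quality`. Only single-base substitutions are considered.
#'
#' The minor allele is the base with the second-highest count; when minor
#' and major counts tie, the alphabetically later base is minor, so the
#' emitted minor-allele fraction never exceeds 0.5.
#'
#' @param x an [allele_counts()] data.frame (masks already applied).
#' @param params a [het_call_params()] list.
#' @return data.frame of class `het_sites` with columns `clone_id`,
#'   `population_id`, `site`, `major_allele`, `minor_allele`, `minor_count`,
#'   `coverage`, `maf`, `maf_ci_lower`.
#' @export
call_heteroplasmic_sites <- function(x, params = het_call_params()) {
  stopifnot(inherits(x, "allele_counts"), inherits(params, "het_call_params"))
  cnt <- as.matrix(as.data.frame(x)[BASES])
  n <- nrow(cnt)
  if (n == 0L) return(empty_het_sites())

  # major = largest count, ties to the alphabetically earlier base;
  # minor = second largest, ties to the alphabetically later base
  maj_idx <- max.col(cnt, ties.method = "first")
  cnt2 <- cnt
  cnt2[cbind(seq_len(n), maj_idx)] <- -1L
  min_idx <- max.col(cnt2, ties.method = "last")
  major_count <- cnt[cbind(seq_len(n), maj_idx)]
  minor_count <- cnt[cbind(seq_len(n), min_idx)]
  coverage <- x$coverage

  # allele recognition: enough reads AND a credibly non-error frequency
  recog <- cnt >= params$allele_min_reads
  if (any(recog)) {
    cv <- pmax(coverage, 1L)
    lows <- matrix(ci_lower_bound(as.vector(cnt), rep(cv, 4L),
                                  params$ci_confidence), ncol = 4L)
    recog <- recog & lows >= params$allele_min_ci
  }
  recog[cbind(seq_len(n), maj_idx)] <- cnt[cbind(seq_len(n), maj_idx)] > 0L
  n_alleles <- rowSums(recog)
  ok <- coverage > 0 &
    n_alleles == 2L &
    n_alleles - 1L <= params$max_alt_alleles &
    minor_count >= params$min_minor_reads &
    !x$indel_within_3bp &
    x$site_quality >= params$min_site_quality
  # CI bound evaluated only where coverage > 0
  ci_low <- rep(0, n)
  pos <- coverage > 0
  ci_low[pos] <- ci_lower_bound(minor_count[pos], coverage[pos],
                                params$ci_confidence)
  ok <- ok & ci_low >= params$min_ci_lower

  out <- data.frame(
    clone_id = x$clone_id[ok],
    population_id = x$population_id[ok],
    site = x$site[ok],
    major_allele = BASES[maj_idx[ok]],
    minor_allele = BASES[min_idx[ok]],
    minor_count = minor_count[ok],
    coverage = coverage[ok],
    maf = minor_count[ok] / coverage[ok],
    maf_ci_lower = ci_low[ok],
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("het_sites", "data.frame")
  out
}

empty_het_sites <- function() {
  out <- data.frame(clone_id = character(), population_id = character(),
                    site = integer(), major_allele = character(),
                    minor_allele = character(), minor_count = integer(),
                    coverage = integer(), maf = numeric(),
                    maf_ci_lower = numeric(), stringsAsFactors = FALSE)
  class(out) <- c("het_sites", "data.frame")
  out
}

#' Per-clone heteroplasmy summaries
#'
#' One row per clone: number of called heteroplasmic sites, mean
#' minor-allele fraction over those sites (NA for homoplasmic clones), and
#' the heteroplasmy status. Clones present in `all_clone_ids` but absent
#' from `sites` are reported homoplasmic.
#'
#' @param sites a `het_sites` data.frame from [call_heteroplasmic_sites()].
#' @param all_clone_ids character vector of every sequenced clone.
#' @return data.frame with columns `clone_id`, `n_het_sites`, `mean_maf`,
#'   `is_heteroplasmic`.
#' @export
summarize_clones <- function(sites, all_clone_ids) {
  all_clone_ids <- as.character(all_clone_ids)
  n <- setNames(integer(length(all_clone_ids)), all_clone_ids)
  mm <- setNames(rep(NA_real_, length(all_clone_ids)), all_clone_ids)
  if (nrow(sites) > 0L) {
    tab <- tapply(sites$maf, sites$clone_id, length)
    mus <- tapply(sites$maf, sites$clone_id, mean)
    known <- intersect(names(tab), all_clone_ids)
    n[known] <- as.integer(tab[known])
    mm[known] <- mus[known]
  }
  data.frame(clone_id = all_clone_ids,
             n_het_sites = as.integer(n),
             mean_maf = as.numeric(mm),
             is_heteroplasmic = n > 0L,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Population-level heteroplasmy summary
#'
#' Fraction of heteroplasmic clones, mean number of heteroplasmic sites per
#' heteroplasmic clone, and the population mean minor-allele fraction
#' (mean of per-clone means over heteroplasmic clones only).
#'
#' @param clone_summary output of [summarize_clones()].
#' @return one-row data.frame with `n_clones`, `n_heteroplasmic`,
#'   `frac_heteroplasmic`, `mean_sites_per_het_clone`, `mean_maf`.
#' @export
summarize_population <- function(clone_summary) {
  het <- clone_summary[clone_summary$is_heteroplasmic, , drop = FALSE]
  data.frame(
    n_clones = nrow(clone_summary),
    n_heteroplasmic = nrow(het),
    frac_heteroplasmic = if (nrow(clone_summary) > 0)
      nrow(het) / nrow(clone_summary) else NA_real_,
    mean_sites_per_het_clone = if (nrow(het) > 0)
      mean(het$n_het_sites) else NA_real_,
    mean_maf = if (nrow(het) > 0) mean(het$mean_maf) else NA_real_)
}

#' Sharing spectrum of heteroplasmic sites
#'
#' Histogram keyed by the number of clones sharing a heteroplasmic site
#' (singletons are sites found in just one clone). The spectrum is the
#' heteroplasmy analogue of a site-frequency spectrum.
#'
#' @param sites a `het_sites` data.frame, typically restricted to one
#'   population (or pooled per species).
#' @return data.frame with columns `n_clones_sharing` and `n_sites`,
#'   sorted by sharing count.
#' @export
shared_site_spectrum <- function(sites) {
  if (nrow(sites) == 0L)
    return(data.frame(n_clones_sharing = integer(), n_sites = integer()))
  sharing <- tapply(sites$clone_id, sites$site,
                    function(cl) length(unique(cl)))
  tab <- table(as.integer(sharing))
  data.frame(n_clones_sharing = as.integer(names(tab)),
             n_sites = as.integer(tab), row.names = NULL)
}

#' Count major/minor allele flips between clones
#'
#' A site is counted when the minor allele of at least one clone equals the
#' major allele of at least one other clone at the same position. Major
#' alleles default to those recorded in `sites` themselves; an optional
#' `majors` table (e.g. derived from all clones' consensus calls) widens the
#' comparison to clones that are homoplasmic at the site.
#'
#' @param sites a `het_sites` data.frame.
#' @param majors optional data.frame with columns `clone_id`, `site`,
#'   `major_allele`.
#' @return integer count of flipping sites.
#' @export
major_minor_flips <- function(sites, majors = NULL) {
  if (nrow(sites) == 0L) return(0L)
  if (is.null(majors))
    majors <- sites[c("clone_id", "site", "major_allele")]
  flips <- 0L
  for (s in unique(sites$site)) {
    mins <- sites[sites$site == s, , drop = FALSE]
    majs <- majors[majors$site == s, , drop = FALSE]
    hit <- FALSE
    for (i in seq_len(nrow(mins))) {
      other <- majs$clone_id != mins$clone_id[i]
      if (any(other & majs$major_allele == mins$minor_allele[i])) {
        hit <- TRUE
        break
      }
    }
    if (hit) flips <- flips + 1L
  }
  flips
}
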