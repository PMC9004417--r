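#' Character matrix view of a haplotype set
#' @param haps a [haplotype_set()].
#' @return matrix (haplotypes x positions) of single characters.
#' @export
hap_matrix <- function(haps) {
  stopifnot(inherits(haps, "haplotype_set"))
  do.call(rbind, strsplit(haps$seq, "", fixed = TRUE))
}

#' Shortest distance between two positions on a circular reference
#' @param i,j 1-based positions (vectorized).
#' @param L reference length.
#' @return `min(|i - j|, L - |i - j|)` in bp.
#' @export
circular_distance <- function(i, j, L) {
  d <- abs(i - j)
  pmin(d, L - d)
}

#' Identify biallelic columns in a haplotype panel
#'
#' A column is informative when, among non-N states, exactly two bases are
#' present and the minor base is carried by at least `min_minor_carriers`
#' haplotypes (filtering out singleton sequencing artefacts).
#'
#' @param mat character matrix from [hap_matrix()] (haplotypes x positions).
#' @param positions 1-based reference positions of the columns (default
#'   `1:ncol(mat)`).
#' @param min_minor_carriers minimum haplotypes carrying the minor allele
#'   (default 3).
#' @return list with `positions`, `major`, `minor`, `carriers`, and `X`, a
#'   haplotypes x sites matrix coded 0 (major), 1 (minor), NA (N).
#' @export
biallelic_columns <- function(mat, positions = NULL,
                              min_minor_carriers = 3L) {
  if (is.null(positions)) positions <- seq_len(ncol(mat))
  stopifnot(length(positions) == ncol(mat))
  counts <- vapply(BASES, function(b) colSums(mat == b),
                   numeric(ncol(mat)))
  counts <- matrix(counts, ncol = 4L,
                   dimnames = list(NULL, BASES))   # sites x bases
  n_alleles <- rowSums(counts > 0)
  # major = most frequent base (ties to the earlier base), minor = second
  # most frequent (ties to the later base)
  maj_idx <- max.col(counts, ties.method = "first")
  c2 <- counts
  c2[cbind(seq_len(nrow(c2)), maj_idx)] <- -1
  min_idx <- max.col(c2, ties.method = "last")
  carriers <- counts[cbind(seq_len(nrow(counts)), min_idx)]
  keep <- which(n_alleles == 2L & carriers >= min_minor_carriers)
  X <- matrix(integer(0), nrow = nrow(mat), ncol = 0L)
  if (length(keep) > 0L) {
    sub <- mat[, keep, drop = FALSE]
    minb <- matrix(BASES[min_idx[keep]], nrow = nrow(mat),
                   ncol = length(keep), byrow = TRUE)
    X <- matrix(as.integer(sub == minb), nrow = nrow(mat))
    X[sub == "N"] <- NA_integer_
  }
  list(positions = positions[keep], major = BASES[maj_idx[keep]],
       minor = BASES[min_idx[keep]], carriers = as.integer(carriers[keep]),
       X = X)
}

#' Observed two-locus gamete classes for a pair of biallelic sites
#'
#' Haplotypes with N (NA) at either site are excluded. Observing all four
#' combinations is a four-gamete-test violation, implying recombination or
#' recurrent mutation.
#'
#' @param x,y allele vectors over the haplotypes (any atomic coding; NA for
#'   missing).
#' @return character vector of the distinct observed gametes
#'   (`"x/y"` labels); the pair is skipped (error) when fewer than two
#'   haplotypes are informative.
#' @export
gamete_classes <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  if (sum(ok) < 2L) stop("fewer than 2 informative haplotypes for this pair")
  unique(paste(x[ok], y[ok], sep = "/"))
}

#' Pairwise two-locus statistics over all informative site pairs
#'
#' For every pair of biallelic columns, counts the observed gamete classes
#' and computes the linkage-disequilibrium measure
#' `r^2 = D^2 / (pA (1-pA) pB (1-pB))` with `D = pAB - pA pB` from the
#' haplotype frequencies. Distances are measured on the circle.
#'
#' @param bial output of [biallelic_columns()].
#' @param L circular reference length.
#' @return data.frame of class `pair_ld` with columns `site_i`, `site_j`,
#'   `distance`, `n_informative`, `n_gametes`, `r2` (NA when a column is
#'   monomorphic within the informative subset).
#' @export
pair_ld <- function(bial, L) {
  S <- ncol(bial$X)
  if (S < 2L)
    return(structure(data.frame(site_i = integer(), site_j = integer(),
                                distance = integer(),
                                n_informative = integer(),
                                n_gametes = integer(), r2 = numeric()),
                     class = c("pair_ld", "data.frame")))
  X <- bial$X
  M1 <- X; M1[is.na(M1)] <- 0L                      # minor indicator
  M0 <- 1L - X; M0[is.na(M0)] <- 0L                 # major indicator
  storage.mode(M1) <- "double"; storage.mode(M0) <- "double"
  n11 <- crossprod(M1)
  n10 <- crossprod(M1, M0)
  n01 <- crossprod(M0, M1)
  n00 <- crossprod(M0)
  nn <- n11 + n10 + n01 + n00
  gam <- (n11 > 0) + (n10 > 0) + (n01 > 0) + (n00 > 0)
  pA <- (n11 + n10) / nn
  pB <- (n11 + n01) / nn
  D <- n11 / nn - pA * pB
  denom <- pA * (1 - pA) * pB * (1 - pB)
  r2 <- ifelse(denom > 0, D^2 / denom, NA_real_)

  ut <- which(upper.tri(nn) & nn >= 2, arr.ind = TRUE)
  out <- data.frame(
    site_i = bial$positions[ut[, 1L]],
    site_j = bial$positions[ut[, 2L]],
    distance = circular_distance(bial$positions[ut[, 1L]],
                                 bial$positions[ut[, 2L]], L),
    n_informative = as.integer(nn[ut]),
    n_gametes = as.integer(gam[ut]),
    r2 = r2[ut])
  class(out) <- c("pair_ld", "data.frame")
  out
}

#' Fraction of informative site pairs compatible with no recombination
#'
#' F(D') is the number of pairs of informative sites passing the
#' four-gamete test (at most three gamete classes observed) divided by the
#' total pairs evaluated; `1 - F` is the violating fraction. Because the
#' orientation of this statistic is reported inconsistently in the
#' literature, both `F` and `1 - F` are returned.
#'
#' @param haps a [haplotype_set()] or character matrix of haplotypes.
#' @param L circular reference length (defaults to the set's length).
#' @param positions reference positions of the matrix columns.
#' @param min_minor_carriers carrier threshold for informative sites
#'   (default 3).
#' @return list with `F_compatible`, `F_violating`, `n_pairs`, and the
#'   pair-level `pairs` data.frame; `F_compatible` is NA when no pairs are
#'   eligible.
#' @export
fgt_fraction <- function(haps, L = NULL, positions = NULL,
                         min_minor_carriers = 3L) {
  mat <- if (inherits(haps, "haplotype_set")) hap_matrix(haps) else haps
  if (is.null(L))
    L <- if (inherits(haps, "haplotype_set")) haps$L else ncol(mat)
  bial <- biallelic_columns(mat, positions, min_minor_carriers)
  pairs <- pair_ld(bial, L)
  if (nrow(pairs) == 0L)
    return(list(F_compatible = NA_real_, F_violating = NA_real_,
                n_pairs = 0L, pairs = pairs))
  f <- mean(pairs$n_gametes <= 3L)
  list(F_compatible = f, F_violating = 1 - f, n_pairs = nrow(pairs),
       pairs = pairs)
}

#' Regression of four-gamete compatibility on circular distance
#'
#' Pairs are binned by circular distance (default 100-bp windows); the
#' compatible fraction per bin is regressed on the bin midpoint by ordinary
#' least squares. On a circular genome recombination between distant
#' markers generates four-gamete violations preferentially at long range,
#' so recombination is flagged when the slope is negative with a p-value
#' below `alpha`.
#'
#' @param pairs a `pair_ld` data.frame from [pair_ld()]/[fgt_fraction()].
#' @param bin_bp distance bin width in bp (default 100).
#' @param alpha significance level for the slope (default 0.05, two-sided).
#' @return list with `slope`, `intercept`, `pearson_r`, `p_value`,
#'   `recombination_flagged`, `n_bins`, and the per-bin data.frame `bins`;
#'   all NA when fewer than 3 bins are available.
#' @export
fd_vs_distance <- function(pairs, bin_bp = 100L, alpha = 0.05) {
  undefined <- list(slope = NA_real_, intercept = NA_real_,
                    pearson_r = NA_real_, p_value = NA_real_,
                    recombination_flagged = FALSE, n_bins = 0L,
                    bins = NULL)
  if (nrow(pairs) == 0L) return(undefined)
  bin <- (pairs$distance - 1L) %/% bin_bp
  mids <- (unique(sort(bin)) + 0.5) * bin_bp
  frac <- tapply(pairs$n_gametes <= 3L, bin, mean)
  bins <- data.frame(midpoint = mids, compatible_fraction = as.numeric(frac),
                     n_pairs = as.integer(table(bin)))
  if (nrow(bins) < 3L) { undefined$bins <- bins; return(undefined) }
  fit <- lm(compatible_fraction ~ midpoint, data = bins)
  sm <- suppressWarnings(summary(fit))$coefficients
  slope <- unname(coef(fit)[2L])
  p <- if (nrow(sm) == 2L && !is.nan(sm[2L, 4L])) sm[2L, 4L] else NA_real_
  r <- suppressWarnings(cor(bins$midpoint, bins$compatible_fraction))
  list(slope = slope, intercept = unname(coef(fit)[1L]),
       pearson_r = r, p_value = p,
       recombination_flagged = isTRUE(slope < 0 && !is.na(p) && p < alpha),
       n_bins = nrow(bins), bins = bins)
}

#' Linkage disequilibrium r-squared for one pair of biallelic sites
#'
#' Equal to the squared Pearson correlation of the allele indicators across
#' haplotypes.
#'
#' @param x,y allele vectors over haplotypes (NA for missing states).
#' @return r-squared in `[0, 1]`; NA when either site is monomorphic among
#'   the informative haplotypes.
#' @export
r2_pair <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 2L) stop("fewer than 2 informative haplotypes")
  xi <- as.integer(factor(x)) - 1L
  yi <- as.integer(factor(y)) - 1L
  if (length(unique(xi)) < 2L || length(unique(yi)) < 2L) return(NA_real_)
  pAB <- mean(xi == 1L & yi == 1L)
  pA <- mean(xi); pB <- mean(yi)
  (pAB - pA * pB)^2 / (pA * (1 - pA) * pB * (1 - pB))
}

#' Mean r-squared per distance bin with an OLS decay fit
#'
#' The decay of linkage disequilibrium with physical distance is summarized
#' by the mean `r^2` in distance bins (default 100-bp windows) and the
#' ordinary least-squares slope of the bin means on the bin midpoints, with
#' the slope's p-value from the t distribution on `bins - 2` degrees of
#' freedom.
#'
#' @inheritParams fd_vs_distance
#' @return list with `slope`, `intercept`, `p_value`, `n_bins` and per-bin
#'   data.frame `bins` (`midpoint`, `mean_r2`, `n_pairs`).
#' @export
r2_distance_profile <- function(pairs, bin_bp = 100L) {
  pairs <- pairs[!is.na(pairs$r2), , drop = FALSE]
  undefined <- list(slope = NA_real_, intercept = NA_real_,
                    p_value = NA_real_, n_bins = 0L, bins = NULL)
  if (nrow(pairs) == 0L) return(undefined)
  bin <- (pairs$distance - 1L) %/% bin_bp
  bins <- data.frame(midpoint = (unique(sort(bin)) + 0.5) * bin_bp,
                     mean_r2 = as.numeric(tapply(pairs$r2, bin, mean)),
                     n_pairs = as.integer(table(bin)))
  if (nrow(bins) < 3L) { undefined$bins <- bins; return(undefined) }
  fit <- lm(mean_r2 ~ midpoint, data = bins)
  sm <- suppressWarnings(summary(fit))$coefficients
  list(slope = unname(coef(fit)[2L]), intercept = unname(coef(fit)[1L]),
       p_value = if (nrow(sm) == 2L) sm[2L, 4L] else NA_real_,
       n_bins = nrow(bins), bins = bins)
}

#' Hudson-Kaplan minimum number of recombination events
#'
#' The classical lower bound Rm: every four-gamete-test violation between
#' ordered sites (i, j) requires at least one recombination event in the
#' open interval between them, and Rm is the maximum number of
#' non-overlapping violating intervals, computed by the standard interval
#' reduction (drop intervals containing another violating interval, then
#' greedily pick compatible intervals by right endpoint). Rm is defined on
#' a linear order, so the circular genome is cut at `cut_at` (positions are
#' rotated so the cut point comes first); on small panels Rm varies by at
#' most about one event across cut choices.
#'
#' @inheritParams fgt_fraction
#' @param cut_at position at which the circle is linearized (default 1).
#' @return integer Rm (0 iff no violations).
#' @export
hudson_kaplan_rm <- function(haps, L = NULL, positions = NULL,
                             min_minor_carriers = 3L, cut_at = 1L) {
  mat <- if (inherits(haps, "haplotype_set")) hap_matrix(haps) else haps
  if (is.null(L))
    L <- if (inherits(haps, "haplotype_set")) haps$L else ncol(mat)
  if (is.null(positions)) positions <- seq_len(ncol(mat))
  bial <- biallelic_columns(mat, positions, min_minor_carriers)
  if (ncol(bial$X) < 2L) return(0L)
  # linearize: order positions starting from the cut point
  lin <- ((bial$positions - cut_at) %% L)
  ord <- order(lin)
  X <- bial$X[, ord, drop = FALSE]
  S <- ncol(X)
  M1 <- X; M1[is.na(M1)] <- 0L
  M0 <- 1L - X; M0[is.na(M0)] <- 0L
  storage.mode(M1) <- "double"; storage.mode(M0) <- "double"
  gam <- (crossprod(M1) > 0) + (crossprod(M1, M0) > 0) +
    (crossprod(M0, M1) > 0) + (crossprod(M0) > 0)
  viol <- which(upper.tri(gam) & gam == 4L, arr.ind = TRUE)
  if (nrow(viol) == 0L) return(0L)
  rm_from_intervals(viol[, 1L], viol[, 2L])
}

# maximum number of disjoint violating open intervals (a, b), a < b in the
# linear site order; intervals sharing an endpoint do not overlap
rm_from_intervals <- function(a, b) {
  keep <- rep(TRUE, length(a))
  for (k in seq_along(a)) {
    inside <- a >= a[k] & b <= b[k] & !(a == a[k] & b == b[k])
    if (any(inside)) keep[k] <- FALSE
  }
  a <- a[keep]; b <- b[keep]
  ord <- order(b, a)
  a <- a[ord]; b <- b[ord]
  count <- 0L
  last_end <- -Inf
  for (k in seq_along(a)) {
    if (a[k] >= last_end) {
      count <- count + 1L
      last_end <- b[k]
    }
  }
  count
}
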