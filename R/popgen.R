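#' Per-site nucleotide diversity from allele frequencies
#'
#' Biallelic sites: `2pq`. Triallelic sites: `2(pq + pr + qr)`.
#' Monomorphic sites: 0. Sites with more than three alleles are rejected
#' (they are vanishingly rare in mitochondrial data and are excluded
#' upstream).
#'
#' @param freqs numeric vector of allele frequencies (length 1 to 3,
#'   summing to 1).
#' @return the per-site diversity (heterozygosity).
#' @export
site_pi <- function(freqs) {
  freqs <- freqs[freqs > 0]
  if (length(freqs) > 3L) stop("more than 3 alleles at a site")
  if (abs(sum(freqs) - 1) > 1e-8) stop("allele frequencies must sum to 1")
  1 - sum(freqs^2)
}

#' Between-population diversity Phi = H_t - H_s per site
#'
#' `H_t` is the total metapopulation heterozygosity computed from the
#' clone-number-weighted mean allele frequencies, and `H_s` is the
#' clone-number-weighted mean of the within-population heterozygosities.
#' Using the same weights in both components guarantees `Phi >= 0` at every
#' site (concavity of heterozygosity in the allele frequencies).
#'
#' @param p matrix of minor (or reference) allele frequencies with one row
#'   per population and one column per biallelic site.
#' @param weights per-population clone numbers (default equal).
#' @return list with per-site numeric vectors `H_t`, `H_s`, `phi`.
#' @export
phi_between <- function(p, weights = NULL) {
  p <- as.matrix(p)
  if (nrow(p) < 2L) stop("Phi requires at least 2 populations")
  if (is.null(weights)) weights <- rep(1, nrow(p))
  w <- weights / sum(weights)
  pbar <- colSums(p * w)
  H_t <- 2 * pbar * (1 - pbar)
  H_s <- colSums(2 * p * (1 - p) * w)
  list(H_t = H_t, H_s = H_s, phi = H_t - H_s)
}

#' Per-site F_ST and its average over retained biallelic sites
#'
#' Per-site `F_ST = (H_t - H_s) / H_t` with clone-number-weighted
#' components (see [phi_between()]). Sites whose metapopulation minor-allele
#' frequency does not exceed `maf_min` are excluded (the estimator is biased
#' at rare alleles), as are sites with `H_t = 0`. The overall estimate is
#' the unweighted mean of the per-site values.
#'
#' @inheritParams phi_between
#' @param maf_min metapopulation minor-allele-frequency threshold
#'   (default 0.1; sites with MAF <= `maf_min` are dropped).
#' @return list with `fst` (overall mean, NA when no site is retained),
#'   `n_sites` retained, and a per-site data.frame `sites`
#'   (`site`, `maf`, `H_t`, `H_s`, `fst`).
#' @export
fst_sites <- function(p, weights = NULL, maf_min = 0.1) {
  p <- as.matrix(p)
  comp <- phi_between(p, weights)
  if (is.null(weights)) weights <- rep(1, nrow(p))
  w <- weights / sum(weights)
  pbar <- colSums(p * w)
  maf <- pmin(pbar, 1 - pbar)
  keep <- maf > maf_min & comp$H_t > 0
  fst_site <- ifelse(comp$H_t > 0, comp$phi / comp$H_t, NA_real_)
  sites <- data.frame(site = seq_len(ncol(p)), maf = maf,
                      H_t = comp$H_t, H_s = comp$H_s, fst = fst_site)
  list(fst = if (any(keep)) mean(fst_site[keep]) else NA_real_,
       n_sites = sum(keep),
       sites = sites[keep, , drop = FALSE])
}

#' Effective population size from silent-site diversity
#'
#' For a haploid, uniparentally inherited genome at drift-mutation
#' equilibrium, `N_e = pi_s / (2 mu)`. The result is rounded to the nearest
#' integer. Monomorphic populations (`pi_s = 0`) yield `N_e = 0`.
#'
#' @param pi_s synonymous-site nucleotide diversity (>= 0).
#' @param mu mutation rate per site per generation (default 1.37e-7).
#' @return integer-valued `N_e` (vectorized over `pi_s`).
#' @export
effective_size <- function(pi_s, mu = 1.37e-7) {
  if (any(pi_s < 0)) stop("pi_s must be non-negative")
  if (mu <= 0) stop("mu must be positive")
  round(pi_s / (2 * mu))
}

#' Island-model effective number of migrants from F_ST
#'
#' Under the island model, `F_ST = 1 / (1 + 2 N_e m)` for a haploid genome
#' (the mitochondrion) and `F_ST = 1 / (1 + 4 N_e m)` for a diploid one, so
#' `N_e m = (1/F_ST - 1) / 2` or `/ 4` respectively.
#'
#' @param fst fixation index in `(0, 1]`.
#' @param model `"haploid"` or `"diploid"`.
#' @return `N_e m`, the effective number of migrants per generation; NA
#'   (with a warning) for `fst <= 0`, where gene flow is unbounded.
#' @export
nm_from_fst <- function(fst, model = c("haploid", "diploid")) {
  model <- match.arg(model)
  div <- if (model == "haploid") 2 else 4
  out <- ifelse(fst > 0 & fst <= 1, (1 / fst - 1) / div, NA_real_)
  if (anyNA(out))
    warning("fst outside (0, 1]: N_e m undefined (infinite gene flow)")
  out
}

#' Correlation between pairwise F_ST and geographic distance
#'
#' Standard Pearson correlation over population pairs with a two-sided
#' p-value (isolation by distance screen).
#'
#' @param fst,distance matched numeric vectors over population pairs.
#' @return list with `r`, `p_value`, `n`; both statistics NA when fewer
#'   than 3 pairs are available or either vector is constant.
#' @export
fst_distance_correlation <- function(fst, distance) {
  stopifnot(length(fst) == length(distance))
  ok <- !is.na(fst) & !is.na(distance)
  fst <- fst[ok]; distance <- distance[ok]
  if (length(fst) < 3L || stats::sd(fst) == 0 || stats::sd(distance) == 0)
    return(list(r = NA_real_, p_value = NA_real_, n = length(fst)))
  ct <- cor.test(fst, distance, method = "pearson")
  list(r = unname(ct$estimate), p_value = ct$p.value, n = length(fst))
}
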