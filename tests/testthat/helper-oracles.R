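# Independent oracles and small fixture builders used across test files.

# exact Clopper-Pearson lower bound (beta quantile form)
cp_lower <- function(x, n, conf = 0.95) {
  alpha <- 1 - conf
  ifelse(x == 0, 0, qbeta(alpha / 2, x, n - x + 1))
}

# build an allele_counts table from a counts matrix (one clone per row set)
make_counts <- function(mat, clone = "c1", pop = "p1",
                        sites = seq_len(nrow(mat)),
                        indel = FALSE, qual = 35) {
  allele_counts(data.frame(
    clone_id = clone, population_id = pop, site = sites,
    A = mat[, 1], C = mat[, 2], G = mat[, 3], T = mat[, 4],
    indel_within_3bp = indel, site_quality = qual,
    stringsAsFactors = FALSE))
}

# haplotype panel (character matrix) from strings of equal length
panel <- function(...) {
  do.call(rbind, strsplit(c(...), "", fixed = TRUE))
}

# independent translation route for codon oracles (seqinr, NCBI code 5)
translate5 <- function(codon) {
  seqinr::translate(strsplit(tolower(codon), "", fixed = TRUE)[[1]],
                    numcode = 5)
}

# enumeration oracle for modified Nei-Gojobori site counts: classify the
# three possible changes at each position, weight transitions by kappa
oracle_site_counts <- function(codon, kappa) {
  bases <- c("A", "C", "G", "T")
  purine <- c(A = TRUE, C = FALSE, G = TRUE, T = FALSE)
  cv <- strsplit(codon, "", fixed = TRUE)[[1]]
  aa0 <- translate5(codon)
  syn <- 0
  for (pos in 1:3) {
    alts <- setdiff(bases, cv[pos])
    w <- ifelse(purine[alts] == purine[cv[pos]], kappa, 1)
    w <- w / sum(w)
    for (k in seq_along(alts)) {
      mut <- cv; mut[pos] <- alts[k]
      aa1 <- translate5(paste(mut, collapse = ""))
      if (aa1 != "*" && aa1 == aa0) syn <- syn + unname(w[k])
    }
  }
  c(syn = syn, nonsyn = 3 - syn)
}

# brute-force maximum number of disjoint open intervals by weighted
# interval scheduling DP (weight 1): independent of the interval-reduction
# route used by hudson_kaplan_rm
oracle_max_disjoint <- function(a, b) {
  if (length(a) == 0) return(0L)
  ord <- order(b)
  a <- a[ord]; b <- b[ord]
  n <- length(a)
  f <- numeric(n + 1)
  for (k in seq_len(n)) {
    pred <- which(b <= a[k])
    best_pred <- if (length(pred) > 0) f[max(pred) + 1] else 0
    f[k + 1] <- max(f[k], 1 + best_pred)
  }
  as.integer(f[n + 1])
}

# all violating (four-gamete) pairs of a binary panel, as interval indices
violating_pairs <- function(X) {
  S <- ncol(X)
  out <- NULL
  if (S < 2) return(out)
  for (i in seq_len(S - 1)) {
    for (j in (i + 1):S) {
      ok <- !is.na(X[, i]) & !is.na(X[, j])
      g <- unique(paste(X[ok, i], X[ok, j]))
      if (length(g) == 4) out <- rbind(out, c(i, j))
    }
  }
  out
}

# random biallelic haplotype panel (characters A/C) for Rm and r2 oracles
random_panel <- function(n_haps, n_sites) {
  m <- matrix(sample(c("A", "C"), n_haps * n_sites, replace = TRUE,
                     prob = c(0.7, 0.3)), nrow = n_haps)
  m
}
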