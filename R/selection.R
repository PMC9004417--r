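# Codon-level machinery: modified Nei-Gojobori site counting with
# transition/transversion weighting, pathway-averaged differences,
# within-population pi_n/pi_s, between-population Phi_n/Phi_s, divergence
# d_n/d_s with Jukes-Cantor correction, and the neutrality index.

PURINES <- c("A", "G")

#' NCBI genetic code table as a named translation vector
#' @param code_id NCBI genetic-code id as a string (default `"5"`, the
#'   invertebrate mitochondrial code).
#' @return named character vector mapping codons to amino acids (`*` for
#'   stop).
#' @export
genetic_code <- function(code_id = "5") {
  Biostrings::getGeneticCode(code_id)
}

is_transition <- function(b1, b2) {
  (b1 %in% PURINES) == (b2 %in% PURINES)
}

#' Synonymous and nonsynonymous site counts for a codon
#'
#' Modified Nei-Gojobori counting: at each codon position the three
#' possible single-base changes are weighted by the
#' transition:transversion ratio `kappa` (transition weight `kappa`, each
#' transversion weight 1, normalized to sum to 1 per position). The
#' synonymous site count is the summed weight of synonymous changes;
#' changes creating a stop codon count as nonsynonymous. Site counts sum
#' to 3 for every codon, at every `kappa`; `kappa = 1` recovers the
#' unweighted Nei-Gojobori counts.
#'
#' @param codon 3-base string over `{A,C,G,T}`; must not be a stop codon.
#' @param kappa transition:transversion ratio (default 7.3).
#' @param code_id NCBI genetic-code id (default `"5"`).
#' @return list with `syn_sites` and `nonsyn_sites` (`syn + nonsyn = 3`).
#' @export
codon_site_counts <- function(codon, kappa = 7.3, code_id = "5") {
  gc <- genetic_code(code_id)
  codon <- toupper(codon)
  if (!codon %in% names(gc)) stop("invalid codon: ", codon)
  if (gc[[codon]] == "*") stop("stop codon in frame: ", codon)
  bases <- strsplit(codon, "", fixed = TRUE)[[1L]]
  syn <- 0
  for (pos in 1:3) {
    alts <- setdiff(BASES, bases[pos])
    w <- ifelse(vapply(alts, is_transition, TRUE, b2 = bases[pos]),
                kappa, 1)
    w <- w / sum(w)
    for (k in seq_along(alts)) {
      mut <- bases; mut[pos] <- alts[k]
      mutc <- paste(mut, collapse = "")
      if (gc[[mutc]] != "*" && gc[[mutc]] == gc[[codon]])
        syn <- syn + unname(w[k])
    }
  }
  list(syn_sites = syn, nonsyn_sites = 3 - syn)
}

#' Pathway-averaged synonymous/nonsynonymous differences between codons
#'
#' Codon pairs differing at one position are classified directly; pairs
#' differing at two or three positions are averaged over all mutational
#' pathways (orderings of the single-base steps) with equal pathway
#' weights. Pathways passing through a stop codon are excluded and the
#' remaining pathways reweighted; if every pathway is blocked (possible
#' only for multiply-substituted codon pairs), all pathways are used and
#' steps into or out of stop codons count as nonsynonymous.
#'
#' @param codon1,codon2 3-base strings over `{A,C,G,T}` (sense codons).
#' @param code_id NCBI genetic-code id (default `"5"`).
#' @return list with `syn_diffs` and `nonsyn_diffs`; they sum to the
#'   number of differing positions.
#' @export
codon_path_diffs <- function(codon1, codon2, code_id = "5") {
  gc <- genetic_code(code_id)
  codon1 <- toupper(codon1); codon2 <- toupper(codon2)
  b1 <- strsplit(codon1, "", fixed = TRUE)[[1L]]
  b2 <- strsplit(codon2, "", fixed = TRUE)[[1L]]
  diff_pos <- which(b1 != b2)
  nd <- length(diff_pos)
  if (nd == 0L) return(list(syn_diffs = 0, nonsyn_diffs = 0))

  paths <- perms(diff_pos)
  walk <- function(order_pos, count_stops) {
    cur <- b1
    syn <- 0; nonsyn <- 0
    for (pos in order_pos) {
      nxt <- cur; nxt[pos] <- b2[pos]
      c_cur <- paste(cur, collapse = ""); c_nxt <- paste(nxt, collapse = "")
      if (gc[[c_nxt]] == "*" || gc[[c_cur]] == "*") {
        if (!count_stops) return(NULL)
        nonsyn <- nonsyn + 1            # steps through stops: nonsynonymous
      } else if (gc[[c_nxt]] == gc[[c_cur]]) {
        syn <- syn + 1
      } else {
        nonsyn <- nonsyn + 1
      }
      cur <- nxt
    }
    c(syn, nonsyn)
  }
  res <- lapply(paths, walk, count_stops = FALSE)
  res <- res[!vapply(res, is.null, TRUE)]
  if (length(res) == 0L) res <- lapply(paths, walk, count_stops = TRUE)
  tot <- Reduce(`+`, res) / length(res)
  list(syn_diffs = tot[1L], nonsyn_diffs = tot[2L])
}

# all permutations of a small vector (at most 3 elements here)
perms <- function(v) {
  if (length(v) <= 1L) return(list(v))
  out <- list()
  for (k in seq_along(v))
    for (rest in perms(v[-k]))
      out[[length(out) + 1L]] <- c(v[k], rest)
  out
}

COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A", N = "N")

# character matrix of a gene's coding sequence, oriented 5'->3' in coding
# direction, for every haplotype row
extract_gene_chars <- function(mat, gene) {
  span <- gene$start:gene$end
  sub <- mat[, span, drop = FALSE]
  if (gene$strand == "-") {
    sub <- sub[, rev(seq_len(ncol(sub))), drop = FALSE]
    sub[] <- COMPLEMENT[sub]
  }
  if (gene$frame > 0L) sub <- sub[, -(seq_len(gene$frame)), drop = FALSE]
  if (ncol(sub) %% 3L != 0L) stop("gene span not divisible by 3")
  sub
}

# per-column majority base ignoring N; ties to the alphabetically earlier
# base; all-N columns yield N
column_consensus <- function(ch) {
  apply(ch, 2L, function(col) {
    col <- col[col != "N"]
    if (length(col) == 0L) return("N")
    tab <- table(col)
    names(tab)[which.max(tab)]
  })
}

# decompose a polymorphic coding column into unordered allele pairs,
# classify each pair as synonymous or not in the consensus codon context,
# and hand the pair (a, b, syn) to the caller
classify_column_pairs <- function(cons, col_idx, alleles, gc) {
  codon_idx <- (col_idx - 1L) %/% 3L
  pos_in <- (col_idx - 1L) %% 3L + 1L
  base_codon <- cons[(codon_idx * 3L + 1L):(codon_idx * 3L + 3L)]
  if (any(base_codon == "N")) return(NULL)
  pairs <- utils::combn(alleles, 2L)
  syn <- logical(ncol(pairs))
  for (k in seq_len(ncol(pairs))) {
    ca <- base_codon; ca[pos_in] <- pairs[1L, k]
    cb <- base_codon; cb[pos_in] <- pairs[2L, k]
    sa <- paste(ca, collapse = ""); sb <- paste(cb, collapse = "")
    aa_a <- gc[[sa]]; aa_b <- gc[[sb]]
    # a change into or out of a stop is never synonymous
    syn[k] <- aa_a != "*" && aa_b != "*" && aa_a == aa_b
  }
  list(pairs = pairs, syn = syn)
}

# summed syn/nonsyn site counts over in-frame consensus codons; stop or
# ambiguous consensus codons are skipped (terminal stops, low-depth spans)
gene_site_totals <- function(cons, kappa, code_id) {
  gc <- genetic_code(code_id)
  n_codons <- length(cons) %/% 3L
  S <- 0; N <- 0
  usable <- logical(n_codons)
  for (ci in seq_len(n_codons)) {
    codon <- cons[(3L * ci - 2L):(3L * ci)]
    cs <- paste(codon, collapse = "")
    if (any(codon == "N") || gc[[cs]] == "*") next
    counts <- codon_site_counts(cs, kappa, code_id)
    S <- S + counts$syn_sites
    N <- N + counts$nonsyn_sites
    usable[ci] <- TRUE
  }
  list(S = S, N = N, usable = usable)
}

#' Within-population pi_n and pi_s for one gene
#'
#' Per-site diversity (`2pq`, or `2(pq + pr + qr)` at triallelic sites) is
#' computed at every polymorphic coding position from the haplotype allele
#' frequencies, decomposed into unordered allele pairs, and each pair is
#' classified as synonymous or nonsynonymous in the context of the
#' population consensus codon. Class sums are normalized by the modified
#' Nei-Gojobori synonymous and nonsynonymous site totals of the consensus
#' coding sequence.
#'
#' @param haps a [haplotype_set()] for one population.
#' @param gene one row of a [gene_annotation()] (data.frame or list with
#'   `start`, `end`, `strand`, `frame`, `code`).
#' @param kappa transition:transversion ratio used in site counting
#'   (default 7.3).
#' @return list with `pi_n`, `pi_s`, `syn_sites`, `nonsyn_sites`.
#' @export
gene_pi_n_pi_s <- function(haps, gene, kappa = 7.3) {
  mat <- hap_matrix(haps)
  ch <- extract_gene_chars(mat, gene)
  cons <- column_consensus(ch)
  tot <- gene_site_totals(cons, kappa, gene$code)
  gc <- genetic_code(gene$code)
  syn_sum <- 0; nonsyn_sum <- 0
  for (j in seq_len(ncol(ch))) {
    if (!tot$usable[(j - 1L) %/% 3L + 1L]) next
    col <- ch[, j]
    col <- col[col != "N"]
    tab <- table(col)
    if (length(tab) < 2L) next
    if (length(tab) > 3L) stop("more than 3 alleles at coding position ", j)
    p <- as.numeric(tab) / sum(tab)
    cls <- classify_column_pairs(cons, j, names(tab), gc)
    if (is.null(cls)) next
    for (k in seq_along(cls$syn)) {
      contrib <- 2 * p[match(cls$pairs[1L, k], names(tab))] *
        p[match(cls$pairs[2L, k], names(tab))]
      if (cls$syn[k]) syn_sum <- syn_sum + contrib
      else nonsyn_sum <- nonsyn_sum + contrib
    }
  }
  list(pi_n = if (tot$N > 0) nonsyn_sum / tot$N else NA_real_,
       pi_s = if (tot$S > 0) syn_sum / tot$S else NA_real_,
       syn_sites = tot$S, nonsyn_sites = tot$N)
}

#' pi_n and pi_s for every annotated gene
#' @param haps a [haplotype_set()] for one population.
#' @param annotation a [gene_annotation()].
#' @inheritParams gene_pi_n_pi_s
#' @return data.frame with one row per gene: `gene_id`, `pi_n`, `pi_s`,
#'   `syn_sites`, `nonsyn_sites`.
#' @export
pi_n_pi_s_table <- function(haps, annotation, kappa = 7.3) {
  rows <- lapply(seq_len(nrow(annotation)), function(i) {
    g <- as.list(annotation[i, ])
    v <- gene_pi_n_pi_s(haps, g, kappa)
    data.frame(gene_id = g$gene_id, pi_n = v$pi_n, pi_s = v$pi_s,
               syn_sites = v$syn_sites, nonsyn_sites = v$nonsyn_sites,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Between-population Phi_n and Phi_s for one gene
#'
#' Per coding position, `Phi = H_t - H_s` is computed from the
#' clone-number-weighted population allele frequencies (see
#' [phi_between()]), decomposed into allele pairs, classified against the
#' pooled consensus codon, and normalized by the consensus synonymous and
#' nonsynonymous site totals (the same convention as [gene_pi_n_pi_s()]).
#'
#' @param haps_pops list of [haplotype_set()]s, one per population.
#' @param weights per-population clone numbers (default: sequences per
#'   population).
#' @inheritParams gene_pi_n_pi_s
#' @return list with `phi_n`, `phi_s`, `syn_sites`, `nonsyn_sites`.
#' @export
gene_phi_n_phi_s <- function(haps_pops, gene, kappa = 7.3, weights = NULL) {
  if (length(haps_pops) < 2L) stop("Phi requires at least 2 populations")
  mats <- lapply(haps_pops, function(h) extract_gene_chars(hap_matrix(h), gene))
  pooled <- do.call(rbind, mats)
  cons <- column_consensus(pooled)
  tot <- gene_site_totals(cons, kappa, gene$code)
  gc <- genetic_code(gene$code)
  if (is.null(weights)) weights <- vapply(haps_pops, length, 1L)
  w <- weights / sum(weights)
  syn_sum <- 0; nonsyn_sum <- 0
  for (j in seq_len(ncol(pooled))) {
    if (!tot$usable[(j - 1L) %/% 3L + 1L]) next
    pcol <- pooled[, j]
    alleles <- sort(unique(pcol[pcol != "N"]))
    if (length(alleles) < 2L) next
    if (length(alleles) > 3L) stop("more than 3 alleles at coding position ", j)
    # per-population frequencies of each allele
    freq <- vapply(mats, function(m) {
      col <- m[, j]; col <- col[col != "N"]
      if (length(col) == 0L) return(rep(NA_real_, length(alleles)))
      vapply(alleles, function(a) mean(col == a), 1)
    }, numeric(length(alleles)))
    freq <- matrix(freq, nrow = length(alleles))
    if (anyNA(freq)) next
    pbar <- as.numeric(freq %*% w)
    cls <- classify_column_pairs(cons, j, alleles, gc)
    if (is.null(cls)) next
    for (k in seq_along(cls$syn)) {
      ia <- match(cls$pairs[1L, k], alleles)
      ib <- match(cls$pairs[2L, k], alleles)
      contrib <- 2 * (pbar[ia] * pbar[ib] -
                        sum(w * freq[ia, ] * freq[ib, ]))
      if (cls$syn[k]) syn_sum <- syn_sum + contrib
      else nonsyn_sum <- nonsyn_sum + contrib
    }
  }
  list(phi_n = if (tot$N > 0) nonsyn_sum / tot$N else NA_real_,
       phi_s = if (tot$S > 0) syn_sum / tot$S else NA_real_,
       syn_sites = tot$S, nonsyn_sites = tot$N)
}

#' Jukes-Cantor multiple-hit correction
#' @param p proportion of differing sites (`p < 3/4`).
#' @return corrected distance `-(3/4) log(1 - 4p/3)`; NA (flagged by the
#'   caller) when `p >= 3/4`.
#' @export
jukes_cantor <- function(p) {
  ifelse(p < 0.75, -0.75 * log(1 - 4 * p / 3), NA_real_)
}

#' Per-gene divergence d_n and d_s between two aligned sequences
#'
#' Modified Nei-Gojobori divergence between an ingroup representative and
#' an outgroup: pathway-averaged synonymous/nonsynonymous differences
#' (see [codon_path_diffs()]) over site counts averaged between the two
#' sequences, with the Jukes-Cantor transform applied to the proportions.
#' Codons containing N (or a stop) in either sequence are excluded
#' codon-wise. Both the raw proportions and the corrected distances are
#' returned.
#'
#' @param seq_in,seq_out aligned full-length sequence strings (ingroup,
#'   outgroup).
#' @param annotation a [gene_annotation()].
#' @param kappa transition:transversion ratio (default 7.3).
#' @return data.frame with one row per gene: `gene_id`, `p_n`, `p_s`,
#'   `d_n`, `d_s`, `syn_sites`, `nonsyn_sites`, `undefined` (TRUE when a
#'   proportion reaches 3/4 and the correction breaks down).
#' @export
dn_ds <- function(seq_in, seq_out, annotation, kappa = 7.3) {
  mat <- rbind(strsplit(toupper(seq_in), "", fixed = TRUE)[[1L]],
               strsplit(toupper(seq_out), "", fixed = TRUE)[[1L]])
  if (ncol(mat) < max(annotation$end))
    stop("sequences shorter than annotated span")
  rows <- lapply(seq_len(nrow(annotation)), function(i) {
    g <- as.list(annotation[i, ])
    gc <- genetic_code(g$code)
    ch <- extract_gene_chars(mat, g)
    n_codons <- ncol(ch) %/% 3L
    S <- 0; N <- 0; Sd <- 0; Nd <- 0
    for (ci in seq_len(n_codons)) {
      idx <- (3L * ci - 2L):(3L * ci)
      c1 <- ch[1L, idx]; c2 <- ch[2L, idx]
      s1 <- paste(c1, collapse = ""); s2 <- paste(c2, collapse = "")
      if (any(c(c1, c2) == "N")) next
      if (gc[[s1]] == "*" || gc[[s2]] == "*") next
      cnt1 <- codon_site_counts(s1, kappa, g$code)
      cnt2 <- codon_site_counts(s2, kappa, g$code)
      S <- S + (cnt1$syn_sites + cnt2$syn_sites) / 2
      N <- N + (cnt1$nonsyn_sites + cnt2$nonsyn_sites) / 2
      d <- codon_path_diffs(s1, s2, g$code)
      Sd <- Sd + d$syn_diffs
      Nd <- Nd + d$nonsyn_diffs
    }
    p_s <- if (S > 0) Sd / S else NA_real_
    p_n <- if (N > 0) Nd / N else NA_real_
    data.frame(gene_id = g$gene_id, p_n = p_n, p_s = p_s,
               d_n = jukes_cantor(p_n), d_s = jukes_cantor(p_s),
               syn_sites = S, nonsyn_sites = N,
               undefined = (is.na(p_n) || is.na(p_s) ||
                              p_n >= 0.75 || p_s >= 0.75),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Ratio of means across genes with Delta-method variance
#'
#' The reported ratio is `mean(x) / mean(y)` (ratio of means, not mean of
#' ratios, to avoid extreme values from sampling variance in small
#' denominators). Its variance is the first-order Delta approximation
#' `R^2 [Var(xbar)/xbar^2 + Var(ybar)/ybar^2 - 2 Cov(xbar, ybar)/(xbar ybar)]`,
#' with the covariance term included when the per-gene values are paired.
#'
#' @param x,y per-gene numeric vectors (e.g. pi_n and pi_s).
#' @param use_cov include the covariance term (default TRUE when `x` and
#'   `y` are paired and of length > 1).
#' @return list with `ratio`, `variance`, `se`; all NA (flagged) when
#'   `mean(y) == 0`.
#' @export
mean_ratio_delta <- function(x, y, use_cov = TRUE) {
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  mx <- mean(x); my <- mean(y)
  if (n == 0L || my == 0)
    return(list(ratio = NA_real_, variance = NA_real_, se = NA_real_))
  R <- mx / my
  if (n < 2L) return(list(ratio = R, variance = NA_real_, se = NA_real_))
  vx <- stats::var(x) / n
  vy <- stats::var(y) / n
  cxy <- if (use_cov) stats::cov(x, y) / n else 0
  vr <- if (mx == 0) vx / my^2 else
    R^2 * (vx / mx^2 + vy / my^2 - 2 * cxy / (mx * my))
  vr <- max(vr, 0)
  list(ratio = R, variance = vr, se = sqrt(vr))
}

#' Neutrality index with Delta-method standard error
#'
#' `NI = (Pi_n / Pi_s) / (d_n / d_s)`, where `Pi_x = pi_x + Phi_x` is total
#' metapopulation diversity. `NI > 1` suggests purifying selection, `NI <
#' 1` positive selection at the divergence level. The standard error comes
#' from the first-order Delta method on the ratio of ratios, treating the
#' four inputs as independent unless covariances are supplied.
#'
#' @param Pi_n,Pi_s,d_n,d_s the four components (all must be positive for
#'   NI to be defined).
#' @param var_Pi_n,var_Pi_s,var_d_n,var_d_s sampling variances of the
#'   components (default 0).
#' @param cov_Pi,cov_d covariances of (Pi_n, Pi_s) and (d_n, d_s)
#'   (default 0).
#' @return list with `NI` and `se`; both NA (flagged, no error) when a
#'   denominator is zero.
#' @export
neutrality_index <- function(Pi_n, Pi_s, d_n, d_s,
                             var_Pi_n = 0, var_Pi_s = 0,
                             var_d_n = 0, var_d_s = 0,
                             cov_Pi = 0, cov_d = 0) {
  if (is.na(Pi_s) || is.na(d_s) || is.na(d_n) ||
      Pi_s <= 0 || d_s <= 0 || d_n <= 0)
    return(list(NI = NA_real_, se = NA_real_))
  NI <- (Pi_n / Pi_s) / (d_n / d_s)
  relvar <- function(v, m) if (m == 0) 0 else v / m^2
  rv <- relvar(var_Pi_n, Pi_n) + relvar(var_Pi_s, Pi_s) +
    relvar(var_d_n, d_n) + relvar(var_d_s, d_s) -
    2 * cov_Pi / (Pi_n * Pi_s) - 2 * cov_d / (d_n * d_s)
  rv <- max(rv, 0)
  list(NI = NI, se = sqrt(NI^2 * rv))
}
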