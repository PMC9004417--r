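# Ground-truthed synthetic data: populations of clones with known
# haplotypes, heteroplasmy, optional paternal-leakage and recombinant
# haplotypes, and binomially sampled read counts with sequencing error.

#' Configuration for the synthetic-data generator
#'
#' Defaults emulate high-depth clonal mitochondrial resequencing of
#' *Daphnia*-like populations: a 15,333-bp circular reference, two
#' populations of 60 clones, silent diversity around 0.01, most clones
#' heteroplasmic at minor fractions of a few percent, occasional deeply
#' divergent (paternal-leakage) minor haplotypes, coverage spanning
#' 100x-6,860x, and a sequencing error rate of 1e-3 per base.
#'
#' @param reference_length circular reference length L (default 15,333).
#' @param n_populations number of populations (default 2).
#' @param clones_per_population clones per population (default 60).
#' @param theta expected pairwise diversity per site (default 0.01).
#' @param heteroplasmy_prob probability that a clone carries a minor
#'   haplotype (default 0.7).
#' @param minor_fraction_range uniform range of the true minor-haplotype
#'   fraction (default `c(0.03, 0.18)`).
#' @param leakage_prob probability that a heteroplasmic clone's minor
#'   haplotype stems from paternal leakage (default 0.05).
#' @param leakage_divergence per-site divergence of a leakage haplotype
#'   from the clone's major haplotype (default 0.02).
#' @param endogenous_mean_sites endogenous minor haplotypes differ from the
#'   major at `1 + Poisson(endogenous_mean_sites)` sites (default 3).
#' @param n_recombinants number of clones whose major haplotype is replaced
#'   by a spliced recombinant (default 0; recombination is planted
#'   explicitly, never implicit).
#' @param breakpoints_per_recombinant breakpoints per recombinant on the
#'   circle (default 2; a circular exchange needs two breaks).
#' @param coverage_range log-uniform per-clone coverage range
#'   (default `c(100, 6860)`).
#' @param error_rate per-base sequencing error rate (default 0.001).
#' @param low_quality_fraction fraction of sites emitted with a low quality
#'   score to exercise the quality filter (default 0.01).
#' @param low_quality_score,base_quality_score emitted site quality scores
#'   (defaults 5 and 35).
#' @param indel_flag_fraction fraction of sites flagged as indel-adjacent
#'   (default 0.005).
#' @param nonsyn_scale acceptance probability for mutations that are
#'   nonsynonymous in the reference codon context (default 1 = neutral;
#'   values < 1 emulate purifying selection).
#' @param seed mandatory RNG seed; every source of randomness flows from
#'   it.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(reference_length = 15333L,
                       n_populations = 2L,
                       clones_per_population = 60L,
                       theta = 0.01,
                       heteroplasmy_prob = 0.7,
                       minor_fraction_range = c(0.03, 0.18),
                       leakage_prob = 0.05,
                       leakage_divergence = 0.02,
                       endogenous_mean_sites = 3,
                       n_recombinants = 0L,
                       breakpoints_per_recombinant = 2L,
                       coverage_range = c(100, 6860),
                       error_rate = 0.001,
                       low_quality_fraction = 0.01,
                       low_quality_score = 5,
                       base_quality_score = 35,
                       indel_flag_fraction = 0.005,
                       nonsyn_scale = 1,
                       seed) {
  if (missing(seed) || is.null(seed))
    stop("a seed is mandatory for reproducibility")
  cfg <- as.list(environment())
  cfg$reference_length <- as.integer(reference_length)
  cfg$n_populations <- as.integer(n_populations)
  cfg$clones_per_population <- as.integer(clones_per_population)
  cfg$n_recombinants <- as.integer(n_recombinants)
  cfg$breakpoints_per_recombinant <- as.integer(breakpoints_per_recombinant)
  if (cfg$reference_length <= 0) stop("reference_length must be positive")
  rates <- c(heteroplasmy_prob, leakage_prob, error_rate,
             low_quality_fraction, indel_flag_fraction, nonsyn_scale,
             minor_fraction_range)
  if (any(rates < 0 | rates > 1)) stop("all rates must lie in [0, 1]")
  if (theta < 0) stop("theta must be non-negative")
  if (theta == 0 && cfg$n_recombinants > 0)
    stop("theta = 0 with recombinants requested: nothing to recombine")
  if (leakage_prob > 0 && heteroplasmy_prob > 0 &&
      leakage_divergence * cfg$reference_length < 1)
    stop("leakage divergence incompatible with reference length ",
         "(expected differences < 1)")
  if (coverage_range[1L] <= 0 || coverage_range[2L] < coverage_range[1L])
    stop("invalid coverage_range")
  class(cfg) <- "sim_config"
  cfg
}

#' Default two-gene annotation for synthetic references
#'
#' Two protein-coding genes under the invertebrate mitochondrial code: one
#' on the plus strand, one on the minus strand, jointly covering about 78%
#' of the reference (the coding density of animal mitogenomes) and leaving
#' a noncoding tail that hosts the D-loop-like control region. Spans scale
#' with `L` so that small test references work identically.
#'
#' @param L reference length (default 15,333).
#' @return a [gene_annotation()].
#' @export
default_annotation <- function(L = 15333L) {
  stopifnot(L >= 120L)
  len <- as.integer(L * 0.39) %/% 3L * 3L
  s1 <- as.integer(L * 0.007) + 1L
  s2 <- as.integer(L * 0.42) + 1L
  gene_annotation(data.frame(
    gene_id = c("cds1", "cds2"),
    start = c(s1, s2),
    end = c(s1 + len - 1L, s2 + len - 1L),
    strand = c("+", "-"),
    frame = c(0L, 0L),
    code = c("5", "5"),
    stringsAsFactors = FALSE))
}

#' Default D-loop mask used by the synthetic pipeline
#' @param L reference length (default 15,333).
#' @return an [interval_mask()] covering sites 14645-15333 (scaled to the
#'   last ~4.5% of shorter references).
#' @export
default_dloop_mask <- function(L = 15333L) {
  if (L == 15333L) return(interval_mask(14645L, 15333L, "dloop"))
  interval_mask(max(1L, L - as.integer(0.045 * L)), L, "dloop")
}

# reference with random sense codons in coding spans (strand-aware) and
# uniform random bases elsewhere
random_reference <- function(L, annotation) {
  gc <- genetic_code("5")
  sense <- names(gc)[gc != "*"]
  ref <- sample(BASES, L, replace = TRUE)
  for (i in seq_len(nrow(annotation))) {
    g <- as.list(annotation[i, ])
    span <- g$start:g$end
    n_codons <- length(span) %/% 3L
    coding <- strsplit(paste(sample(sense, n_codons, replace = TRUE),
                             collapse = ""), "", fixed = TRUE)[[1L]]
    if (g$strand == "-")
      coding <- rev(unname(COMPLEMENT[coding]))
    ref[span[seq_along(coding)]] <- coding
  }
  ref
}

# classify a single-base change at a genome site: "syn", "nonsyn" or
# "noncoding", in the reference codon context (strand-aware)
classify_site_change <- function(ref, annotation, site, to) {
  for (i in seq_len(nrow(annotation))) {
    g <- as.list(annotation[i, ])
    if (site < g$start || site > g$end) next
    gc <- genetic_code(g$code)
    if (g$strand == "+") {
      idx <- site - g$start + 1L - g$frame
    } else {
      idx <- g$end - site + 1L - g$frame
    }
    if (idx < 1L) next
    codon_i <- (idx - 1L) %/% 3L
    pos_in <- (idx - 1L) %% 3L + 1L
    if (g$strand == "+") {
      csites <- g$start + g$frame + codon_i * 3L + 0:2
      codon <- ref[csites]
      mut <- codon; mut[pos_in] <- to
    } else {
      csites <- g$end - g$frame - codon_i * 3L - (0:2)
      codon <- unname(COMPLEMENT[ref[csites]])
      mut <- codon; mut[pos_in] <- unname(COMPLEMENT[to])
    }
    cs <- paste(codon, collapse = ""); ms <- paste(mut, collapse = "")
    if (gc[[cs]] == "*" || gc[[ms]] == "*") return("nonsyn")
    return(if (gc[[cs]] == gc[[ms]]) "syn" else "nonsyn")
  }
  "noncoding"
}

#' Simulate population haplotypes on random genealogies
#'
#' Per population, a random coalescent-shaped bifurcating tree
#' ([ape::rcoal()]) is drawn and mutations are placed on its branches as a
#' Poisson process calibrated so that the expected pairwise diversity per
#' site equals `theta` (branch lengths are in coalescent units, where a
#' random pair has expected divergence time 1, so the per-branch mutation
#' intensity is `theta/2 * L` per unit length). Mutated sites are uniform
#' on the circle with the derived base uniform among the three
#' alternatives; mutations that are nonsynonymous in the reference codon
#' context are retained with probability `nonsyn_scale`.
#'
#' @param config a [sim_config()].
#' @param annotation gene annotation used to lay out coding regions and tag
#'   mutations (default [default_annotation()]).
#' @param seed optional seed; when NULL the caller controls the RNG state.
#' @return list of class `mito_sim` with `config`, `annotation`,
#'   `reference` (character vector), `clones` (data.frame), `major`
#'   (clone x site character matrix) and `mutations` (data.frame with
#'   `population_id`, `site`, `from`, `to`, `class`).
#' @export
simulate_haplotypes <- function(config, annotation = NULL, seed = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (!is.null(seed)) set.seed(seed)
  L <- config$reference_length
  if (is.null(annotation)) annotation <- default_annotation(L)
  ref <- random_reference(L, annotation)
  n <- config$clones_per_population
  rate <- config$theta / 2 * L

  clones <- list(); major_rows <- list(); muts <- list()
  for (pop in seq_len(config$n_populations)) {
    pop_id <- sprintf("pop%d", pop)
    ids <- sprintf("%s_c%02d", pop_id, seq_len(n))
    seqs <- matrix(rep(ref, n), nrow = n, byrow = TRUE)
    if (n > 1L && rate > 0) {
      tree <- ape::rcoal(n)
      root <- n + 1L
      kids <- split(seq_len(nrow(tree$edge)), tree$edge[, 1L])
      # DFS from the root, accumulating mutations down each lineage
      apply_path <- function(node, acc) {
        if (node <= n) {
          for (m in acc) seqs[node, m$site] <<- m$to
          return(invisible())
        }
        for (e in kids[[as.character(node)]]) {
          child <- tree$edge[e, 2L]
          len <- tree$edge.length[e]
          acc2 <- acc
          n_mut <- rpois(1L, len * rate)
          if (n_mut > 0L) {
            for (k in seq_len(n_mut)) {
              site <- sample.int(L, 1L)
              # current base on this lineage at the site
              cur <- ref[site]
              for (m in acc2) if (m$site == site) cur <- m$to
              to <- sample(setdiff(BASES, cur), 1L)
              cls <- classify_site_change(ref, annotation, site, to)
              if (cls == "nonsyn" && config$nonsyn_scale < 1 &&
                  runif(1L) > config$nonsyn_scale) next
              acc2 <- c(acc2, list(list(site = site, to = to)))
              muts[[length(muts) + 1L]] <<- data.frame(
                population_id = pop_id, site = site, from = cur, to = to,
                class = cls, stringsAsFactors = FALSE)
            }
          }
          apply_path(child, acc2)
        }
      }
      apply_path(root, list())
    }
    clones[[pop]] <- data.frame(clone_id = ids, population_id = pop_id,
                                stringsAsFactors = FALSE)
    major_rows[[pop]] <- seqs
  }
  out <- list(config = config, annotation = annotation, reference = ref,
              clones = do.call(rbind, clones),
              major = do.call(rbind, major_rows),
              mutations = if (length(muts) > 0L) do.call(rbind, muts) else
                data.frame(population_id = character(), site = integer(),
                           from = character(), to = character(),
                           class = character(), stringsAsFactors = FALSE))
  rownames(out$major) <- out$clones$clone_id
  class(out) <- "mito_sim"
  out
}

#' Plant recombinant major haplotypes and heteroplasmic minor haplotypes
#'
#' First, `n_recombinants` clones have their major haplotype replaced by a
#' splice of two distinct major haplotypes from the same population, cut at
#' the configured number of breakpoints on the circle (segments alternate
#' between the parents). Then each clone independently becomes
#' heteroplasmic with probability `heteroplasmy_prob`: its minor haplotype
#' is either a paternal-leakage haplotype (divergence
#' `leakage_divergence`) or an endogenous near-copy of the major haplotype
#' (`1 + Poisson(endogenous_mean_sites)` substitutions), carried at a
#' minor fraction drawn from `minor_fraction_range`.
#'
#' @param sim a `mito_sim` from [simulate_haplotypes()].
#' @param seed optional seed; when NULL the caller controls the RNG state.
#' @return the `mito_sim` with added `minor` matrix (rows equal to the
#'   major haplotype for homoplasmic clones), updated `clones` columns
#'   (`is_het`, `minor_source`, `minor_fraction`), `het_sites` truth table
#'   and `breakpoints`.
#' @export
inject_heteroplasmy_and_recombinants <- function(sim, seed = NULL) {
  stopifnot(inherits(sim, "mito_sim"))
  if (!is.null(seed)) set.seed(seed)
  config <- sim$config
  L <- config$reference_length
  n_clones <- nrow(sim$clones)
  bp <- list()

  if (config$n_recombinants > 0L) {
    targets <- sample.int(n_clones, config$n_recombinants)
    for (t in targets) {
      pop <- sim$clones$population_id[t]
      pool <- setdiff(which(sim$clones$population_id == pop), t)
      if (length(pool) < 2L) stop("population too small to draw recombination parents")
      par <- sample(pool, 2L)
      cuts <- sort(sample.int(L, config$breakpoints_per_recombinant))
      child <- sim$major[par[1L], ]
      # alternate parent segments between successive cuts on the circle
      for (seg in seq_along(cuts)) {
        if (seg %% 2L == 1L) {
          from <- cuts[seg] + 1L
          to <- if (seg < length(cuts)) cuts[seg + 1L] else L
          if (from <= to)
            child[from:to] <- sim$major[par[2L], from:to]
        }
      }
      sim$major[t, ] <- child
      bp[[length(bp) + 1L]] <- data.frame(
        clone_id = sim$clones$clone_id[t],
        parent1 = sim$clones$clone_id[par[1L]],
        parent2 = sim$clones$clone_id[par[2L]],
        breakpoints = paste(cuts, collapse = ","),
        stringsAsFactors = FALSE)
    }
  }

  minor <- sim$major
  is_het <- runif(n_clones) < config$heteroplasmy_prob
  source <- ifelse(is_het,
                   ifelse(runif(n_clones) < config$leakage_prob,
                          "leakage", "endogenous"), "none")
  frac <- ifelse(is_het,
                 runif(n_clones, config$minor_fraction_range[1L],
                       config$minor_fraction_range[2L]), NA_real_)
  het_rows <- list()
  for (i in which(is_het)) {
    k <- if (source[i] == "leakage")
      max(1L, rbinom(1L, L, config$leakage_divergence))
    else 1L + rpois(1L, config$endogenous_mean_sites)
    sites <- sample.int(L, min(k, L))
    for (s in sites)
      minor[i, s] <- sample(setdiff(BASES, sim$major[i, s]), 1L)
    het_rows[[length(het_rows) + 1L]] <- data.frame(
      clone_id = sim$clones$clone_id[i], site = sites,
      major_base = sim$major[i, sites], minor_base = minor[i, sites],
      minor_fraction = frac[i], stringsAsFactors = FALSE)
  }
  sim$minor <- minor
  sim$clones$is_het <- is_het
  sim$clones$minor_source <- source
  sim$clones$minor_fraction <- frac
  sim$het_sites <- if (length(het_rows) > 0L) do.call(rbind, het_rows) else
    data.frame(clone_id = character(), site = integer(),
               major_base = character(), minor_base = character(),
               minor_fraction = numeric(), stringsAsFactors = FALSE)
  sim$breakpoints <- if (length(bp) > 0L) do.call(rbind, bp) else
    data.frame(clone_id = character(), parent1 = character(),
               parent2 = character(), breakpoints = character(),
               stringsAsFactors = FALSE)
  sim
}

#' Sample read counts from the simulated truth
#'
#' Coverage is drawn per clone on a log-uniform scale over
#' `coverage_range`, with per-site Poisson jitter. At a clone's
#' heteroplasmic sites, minor-haplotype reads are Binomial(coverage, f);
#' sequencing errors are drawn as Binomial(coverage, error_rate) and
#' scattered uniformly over the three bases other than the site's true
#' major base. Site qualities are high by default with a configurable
#' low-quality fraction, and a small fraction of sites carries the
#' indel-proximity flag, so that the quality and indel filters are
#' exercised.
#'
#' @param sim a `mito_sim` from [inject_heteroplasmy_and_recombinants()].
#' @param sites optional vector of reference positions to emit (default:
#'   all `1:L`).
#' @param seed optional seed; when NULL the caller controls the RNG state.
#' @return the `mito_sim` with an added [allele_counts()] data.frame
#'   `counts` and per-clone `coverage` column in `clones`.
#' @export
simulate_read_counts <- function(sim, sites = NULL, seed = NULL) {
  stopifnot(inherits(sim, "mito_sim"), !is.null(sim$minor))
  if (!is.null(seed)) set.seed(seed)
  config <- sim$config
  L <- config$reference_length
  if (is.null(sites)) sites <- seq_len(L)
  sites <- as.integer(sites)
  n_clones <- nrow(sim$clones)
  S <- length(sites)

  cov_clone <- exp(runif(n_clones, log(config$coverage_range[1L]),
                         log(config$coverage_range[2L])))
  sim$clones$coverage <- round(cov_clone)

  clone_rec <- rep(seq_len(n_clones), each = S)
  site_rec <- rep(sites, times = n_clones)
  n_rec <- length(clone_rec)

  cov <- rpois(n_rec, cov_clone[clone_rec])
  major_idx <- match(sim$major[cbind(clone_rec, site_rec)], BASES)
  minor_idx <- match(sim$minor[cbind(clone_rec, site_rec)], BASES)
  f <- ifelse(minor_idx != major_idx,
              sim$clones$minor_fraction[clone_rec], 0)
  f[is.na(f)] <- 0

  minor_n <- rbinom(n_rec, cov, f)
  err_n <- rbinom(n_rec, cov, config$error_rate)
  err_n <- pmin(err_n, cov - minor_n)
  major_n <- cov - minor_n - err_n
  e1 <- rbinom(n_rec, err_n, 1 / 3)
  e2 <- rbinom(n_rec, err_n - e1, 1 / 2)
  e3 <- err_n - e1 - e2

  counts <- matrix(0L, nrow = n_rec, ncol = 4L)
  others <- rbind(c(2L, 3L, 4L), c(1L, 3L, 4L), c(1L, 2L, 4L), c(1L, 2L, 3L))
  idx <- seq_len(n_rec)
  counts[cbind(idx, others[major_idx, 1L])] <- e1
  counts[cbind(idx, others[major_idx, 2L])] <- e2
  counts[cbind(idx, others[major_idx, 3L])] <- e3
  counts[cbind(idx, minor_idx)] <- counts[cbind(idx, minor_idx)] +
    as.integer(minor_n)
  counts[cbind(idx, major_idx)] <- counts[cbind(idx, major_idx)] +
    as.integer(major_n)

  df <- data.frame(
    clone_id = sim$clones$clone_id[clone_rec],
    population_id = sim$clones$population_id[clone_rec],
    site = site_rec,
    A = counts[, 1L], C = counts[, 2L], G = counts[, 3L], T = counts[, 4L],
    indel_within_3bp = runif(n_rec) < config$indel_flag_fraction,
    site_quality = ifelse(runif(n_rec) < config$low_quality_fraction,
                          config$low_quality_score,
                          config$base_quality_score),
    stringsAsFactors = FALSE)
  sim$counts <- allele_counts(df, reference_length = L)
  sim
}

#' One-call synthetic dataset with ground truth
#'
#' Seeds the RNG once from `config$seed` and runs
#' [simulate_haplotypes()], [inject_heteroplasmy_and_recombinants()] and
#' [simulate_read_counts()]. Output is byte-identical across runs with the
#' same config.
#'
#' @param config a [sim_config()].
#' @param annotation optional [gene_annotation()] (default
#'   [default_annotation()]).
#' @param sites optional positions at which read counts are emitted.
#' @return a `mito_sim` list with, in particular, `counts` (an
#'   [allele_counts()] table), `haplotypes` (a [haplotype_set()] of the
#'   true major and minor haplotypes), `het_sites`, `breakpoints`,
#'   `mutations`, `reference`, `annotation` and `mask` (the default
#'   D-loop mask).
#' @export
simulate_dataset <- function(config, annotation = NULL, sites = NULL) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  sim <- simulate_haplotypes(config, annotation = annotation)
  sim <- inject_heteroplasmy_and_recombinants(sim)
  sim <- simulate_read_counts(sim, sites = sites)
  major_seq <- apply(sim$major, 1L, paste, collapse = "")
  het <- sim$clones$is_het
  minor_seq <- apply(sim$minor[het, , drop = FALSE], 1L, paste,
                     collapse = "")
  sim$haplotypes <- haplotype_set(
    c(major_seq, minor_seq),
    clone_id = c(sim$clones$clone_id, sim$clones$clone_id[het]),
    population_id = c(sim$clones$population_id,
                      sim$clones$population_id[het]),
    role = c(rep("major", length(major_seq)),
             rep("minor", length(minor_seq))))
  sim$mask <- default_dloop_mask(config$reference_length)
  sim
}

#' Island-model allele frequencies via the Balding-Nichols distribution
#'
#' Per site, an ancestral frequency is drawn uniformly on
#' `ancestral_range` and deme frequencies are sampled independently from
#' `Beta(p (1-F)/F, (1-p)(1-F)/F)`, which has mean `p` and Wright's
#' `F_ST = F`. `F` may be given directly or through the migration
#' parameter `nem` (haploid island model, `F = 1 / (1 + 2 nem)`).
#'
#' @param n_populations number of demes (default 10).
#' @param n_sites number of biallelic sites (default 10,000).
#' @param fst target fixation index (used unless `nem` is given).
#' @param nem effective migrants per generation; overrides `fst`.
#' @param ancestral_range uniform range of ancestral allele frequencies
#'   (default `c(0.15, 0.85)`).
#' @param seed optional seed.
#' @return matrix of allele frequencies, one row per deme, one column per
#'   site.
#' @export
simulate_island_frequencies <- function(n_populations = 10L,
                                        n_sites = 10000L,
                                        fst = 0.16, nem = NULL,
                                        ancestral_range = c(0.15, 0.85),
                                        seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (!is.null(nem)) fst <- 1 / (1 + 2 * nem)
  stopifnot(fst > 0, fst < 1)
  a <- (1 - fst) / fst
  pbar <- runif(n_sites, ancestral_range[1L], ancestral_range[2L])
  matrix(rbeta(n_sites * n_populations,
               rep(pbar, each = n_populations) * a,
               rep(1 - pbar, each = n_populations) * a),
         nrow = n_populations)
}
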