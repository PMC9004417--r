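test_that("configuration guards its invariants", {
  expect_error(sim_config(), "seed is mandatory")
  expect_error(sim_config(theta = 0, n_recombinants = 2L, seed = 1),
               "nothing to recombine")
  expect_error(sim_config(reference_length = 40L, leakage_divergence = 0.02,
                          seed = 1), "leakage divergence")
  expect_error(sim_config(error_rate = 2, seed = 1), "rates")
  cfg <- sim_config(seed = 1)
  expect_equal(cfg$reference_length, 15333L)
  expect_equal(cfg$minor_fraction_range, c(0.03, 0.18))
  expect_equal(cfg$coverage_range, c(100, 6860))
})

test_that("a fixed seed reproduces the dataset byte-identically", {
  cfg <- sim_config(reference_length = 1500L, n_populations = 1L,
                    clones_per_population = 8L, n_recombinants = 1L,
                    seed = 99)
  a <- simulate_dataset(cfg)
  b <- simulate_dataset(cfg)
  expect_identical(a$counts, b$counts)
  expect_identical(a$major, b$major)
  expect_identical(a$minor, b$minor)
  expect_identical(a$het_sites, b$het_sites)
  expect_identical(a$breakpoints, b$breakpoints)
})

test_that("theta controls pairwise diversity; zero theta means identity", {
  cfg0 <- sim_config(reference_length = 1500L, n_populations = 1L,
                     clones_per_population = 6L, theta = 0,
                     heteroplasmy_prob = 0, seed = 2)
  s0 <- simulate_dataset(cfg0)
  expect_true(all(apply(s0$major, 1, identical, s0$major[1, ])))

  # mean pairwise p-distance ~ theta; column-frequency identity as oracle
  mean_pairwise <- function(m) {
    n <- nrow(m)
    mean(apply(m, 2, function(col) {
      tab <- table(col)
      1 - sum(tab * (tab - 1)) / (n * (n - 1))
    }))
  }
  set.seed(77)
  cfg <- sim_config(theta = 0.01, n_populations = 1L,
                    clones_per_population = 60L, heteroplasmy_prob = 0,
                    seed = 77)
  d <- replicate(50, mean_pairwise(simulate_haplotypes(cfg)$major))
  expect_equal(mean(d), 0.01, tolerance = 0.25)
})

test_that("minor haplotypes follow their configured source distributions", {
  cfg <- sim_config(reference_length = 15333L, n_populations = 1L,
                    clones_per_population = 20L, heteroplasmy_prob = 1,
                    leakage_prob = 1, seed = 5)
  set.seed(5)
  s <- inject_heteroplasmy_and_recombinants(simulate_haplotypes(cfg))
  ndiff <- vapply(seq_len(nrow(s$clones)), function(i)
    sum(s$major[i, ] != s$minor[i, ]), 1L)
  # Binomial(15333, 0.02): mean ~307, sd ~17; all clones within 5 sd
  expect_true(all(abs(ndiff - 15333 * 0.02) < 5 * sqrt(15333 * 0.02 * 0.98)))
  expect_true(all(s$clones$minor_fraction >= 0.03 &
                    s$clones$minor_fraction <= 0.18))

  cfg0 <- sim_config(reference_length = 1500L, n_populations = 1L,
                     clones_per_population = 10L, heteroplasmy_prob = 0,
                     seed = 6)
  set.seed(6)
  s0 <- inject_heteroplasmy_and_recombinants(simulate_haplotypes(cfg0))
  expect_identical(s0$major, s0$minor)
  expect_equal(nrow(s0$het_sites), 0L)
})

test_that("read counts concentrate on true bases and recover minor fractions", {
  # error-free homoplasmic clone: every read sits on the true base
  cfg <- sim_config(reference_length = 800L, n_populations = 1L,
                    clones_per_population = 4L, heteroplasmy_prob = 0,
                    error_rate = 0, seed = 8)
  sim <- simulate_dataset(cfg)
  cnt <- as.matrix(as.data.frame(sim$counts)[c("A", "C", "G", "T")])
  on_true <- cnt[cbind(seq_len(nrow(cnt)),
                       match(sim$major[cbind(
                         match(sim$counts$clone_id, sim$clones$clone_id),
                         sim$counts$site)], c("A", "C", "G", "T")))]
  expect_true(all(on_true == sim$counts$coverage))

  # f = 0.10 at fixed coverage 400 over 10,000 sites: tight mean recovery
  truth <- list(
    config = sim_config(reference_length = 10000L, n_populations = 1L,
                        clones_per_population = 1L,
                        coverage_range = c(400, 400), error_rate = 0,
                        seed = 9),
    clones = data.frame(clone_id = "c1", population_id = "p1",
                        is_het = TRUE, minor_source = "leakage",
                        minor_fraction = 0.10, stringsAsFactors = FALSE),
    major = matrix("A", 1, 10000), minor = matrix("C", 1, 10000))
  class(truth) <- "mito_sim"
  rc <- simulate_read_counts(truth, seed = 9)
  expect_equal(mean(rc$counts$C / rc$counts$coverage), 0.10,
               tolerance = 0.006 / 0.10)
})

test_that("the pipeline recovers planted heteroplasmy end to end", {
  cfg <- sim_config(reference_length = 3000L, n_populations = 2L,
                    clones_per_population = 15L, seed = 21)
  sim <- simulate_dataset(cfg)
  counts <- apply_site_mask(sim$counts, sim$mask)
  hs <- call_heteroplasmic_sites(counts)

  key <- function(d) paste(d$clone_id, d$site)
  truth <- merge(sim$het_sites, sim$clones[c("clone_id", "coverage")],
                 by = "clone_id")
  truth <- truth[!sites_in_mask(truth$site, sim$mask), ]
  # no false calls; detectable planted sites recovered
  expect_true(all(key(hs) %in% key(truth)))
  det <- truth[truth$minor_fraction >= 0.05 & truth$coverage >= 200, ]
  expect_gte(mean(key(det) %in% key(hs)), 0.9)

  # called minor fractions sit inside their binomial envelopes (99%)
  m <- merge(hs, truth, by = c("clone_id", "site"))
  env <- qnorm(0.995) * sqrt(m$minor_fraction * (1 - m$minor_fraction) /
                               m$coverage.x)
  expect_lte(mean(abs(m$maf - m$minor_fraction) > env), 0.03)

  # two-haplotype clones accepted at the conventional threshold
  th <- test_all_clones(hs, support_threshold = 0.05)
  th <- th[th$testable, ]
  expect_gt(mean(th$supports_two_haplotypes), 0.8)
})

test_that("mutation tagging agrees with an independent translation route", {
  cfg <- sim_config(reference_length = 1500L, n_populations = 1L,
                    clones_per_population = 12L, theta = 0.02,
                    heteroplasmy_prob = 0, nonsyn_scale = 0, seed = 33)
  set.seed(33)
  s <- simulate_haplotypes(cfg)
  # with nonsynonymous mutations suppressed, every haplotype encodes the
  # same proteins (Biostrings translation, genetic code 5)
  for (i in seq_len(nrow(s$annotation))) {
    g <- as.list(s$annotation[i, ])
    prots <- apply(s$major, 1, function(row) {
      cds <- paste(row[g$start:g$end], collapse = "")
      d <- Biostrings::DNAString(cds)
      if (g$strand == "-") d <- Biostrings::reverseComplement(d)
      as.character(Biostrings::translate(
        d, genetic.code = Biostrings::getGeneticCode("5")))
    })
    expect_length(unique(prots), 1L)
  }
  # and the within-population nonsynonymous diversity is exactly zero
  haps <- haplotype_set(apply(s$major, 1, paste, collapse = ""),
                        s$clones$clone_id, s$clones$population_id, "major")
  tab <- pi_n_pi_s_table(haps, s$annotation)
  expect_true(all(tab$pi_n == 0))
  expect_gt(sum(tab$pi_s), 0)
})

test_that("island-model frequencies carry the requested differentiation", {
  p <- simulate_island_frequencies(n_populations = 8L, n_sites = 4000L,
                                   fst = 0.25, seed = 14)
  expect_equal(dim(p), c(8L, 4000L))
  expect_true(all(p >= 0 & p <= 1))
  est <- fst_sites(p, maf_min = 0.1)$fst
  expect_equal(est, 0.25, tolerance = 0.25)
})
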