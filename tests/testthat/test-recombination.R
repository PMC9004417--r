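test_that("gamete classes distinguish compatible and violating pairs", {
  m <- panel("AC", "AG", "TC", "TG")     # all four gametes
  expect_length(gamete_classes(m[, 1], m[, 2]), 4L)
  expect_length(gamete_classes(m[1:3, 1], m[1:3, 2]), 3L)
  expect_length(gamete_classes(c("A", "A", "T"), c("C", "C", "G")), 2L)
  expect_error(gamete_classes("A", "C"), "fewer than 2")

  # removing haplotypes never increases the gamete count of any pair
  set.seed(6)
  for (rep in 1:25) {
    m <- random_panel(10, 2)
    g_full <- length(gamete_classes(m[, 1], m[, 2]))
    keep <- sample(10, 6)
    g_sub <- length(gamete_classes(m[keep, 1], m[keep, 2]))
    expect_lte(g_sub, g_full)
  }
})

test_that("FGT fraction spans its limits and is invariant to allele relabeling", {
  # no violations anywhere -> F = 1
  clean <- panel("AAAA", "AACC", "CCCC", "AAAA", "AACC", "CCCC")
  f1 <- fgt_fraction(clean, min_minor_carriers = 2L)
  expect_equal(f1$F_compatible, 1)

  # every pair violating -> F = 0
  dirty <- panel("AA", "AC", "CA", "CC", "AA", "AC", "CA", "CC")
  f0 <- fgt_fraction(dirty, min_minor_carriers = 2L)
  expect_equal(f0$F_compatible, 0)
  expect_equal(f0$F_violating, 1)

  # no eligible pairs -> undefined flag
  mono <- panel("AAAA", "AAAA", "AAAA")
  expect_true(is.na(fgt_fraction(mono)$F_compatible))

  # swapping the base labels of one column changes nothing
  set.seed(9)
  m <- random_panel(12, 8)
  swapped <- m
  swapped[, 3] <- chartr("AC", "CA", swapped[, 3])
  a <- fgt_fraction(m, min_minor_carriers = 2L)
  b <- fgt_fraction(swapped, min_minor_carriers = 2L)
  expect_equal(a$F_compatible, b$F_compatible)
  expect_equal(a$pairs$r2, b$pairs$r2)
})

test_that("r2 matches hand calculation and the squared indicator correlation", {
  # perfect association
  m <- panel("AC", "AC", "TG", "TG")
  expect_equal(r2_pair(m[, 1], m[, 2]), 1)
  # independence at equal gamete counts
  ind <- do.call(rbind, rep(list(c("A", "C"), c("A", "G"),
                                 c("T", "C"), c("T", "G")), 25))
  expect_equal(r2_pair(ind[, 1], ind[, 2]), 0)
  # AB=40, Ab=10, aB=10, ab=40: D = 0.15, r2 = 0.36
  gam <- rbind(matrix(rep(c("A", "C"), 40), ncol = 2, byrow = TRUE),
               matrix(rep(c("A", "G"), 10), ncol = 2, byrow = TRUE),
               matrix(rep(c("T", "C"), 10), ncol = 2, byrow = TRUE),
               matrix(rep(c("T", "G"), 40), ncol = 2, byrow = TRUE))
  expect_equal(r2_pair(gam[, 1], gam[, 2]), 0.36)

  # squared Pearson correlation of allele indicators, random panels
  set.seed(17)
  for (rep in 1:50) {
    m <- random_panel(sample(6:20, 1), 2)
    r2 <- r2_pair(m[, 1], m[, 2])
    xi <- as.integer(m[, 1] == "C"); yi <- as.integer(m[, 2] == "C")
    if (sd(xi) == 0 || sd(yi) == 0) {
      expect_true(is.na(r2))
    } else {
      expect_equal(r2, cor(xi, yi)^2)
    }
  }

  # monomorphic column -> NA, and pair_ld carries the same convention
  expect_true(is.na(r2_pair(rep("A", 6), c("C", "C", "G", "G", "C", "G"))))
})

test_that("distance regressions flag planted recombination, not clean panels", {
  # constant compatibility: zero slope, nothing flagged
  set.seed(23)
  clean <- data.frame(site_i = 1L, site_j = 2L,
                      distance = sample(1:2000, 400, replace = TRUE),
                      n_informative = 30L, n_gametes = 3L, r2 = 0.5)
  fd <- fd_vs_distance(clean)
  expect_equal(fd$slope, 0)
  expect_false(fd$recombination_flagged)

  # fewer than 3 bins -> undefined
  few <- clean[clean$distance <= 150, ]
  expect_true(is.na(fd_vs_distance(few)$slope))

  # planted recombinants at RAP-like scale produce a negative slope
  cfg <- sim_config(n_populations = 1L, clones_per_population = 60L,
                    n_recombinants = 15L, heteroplasmy_prob = 0, seed = 19)
  set.seed(19)
  s <- inject_heteroplasmy_and_recombinants(simulate_haplotypes(cfg))
  fg <- fgt_fraction(s$major, L = cfg$reference_length)
  fd <- fd_vs_distance(fg$pairs)
  expect_true(fd$recombination_flagged)
  expect_lt(fd$slope, 0)
  r2p <- r2_distance_profile(fg$pairs)
  expect_lt(r2p$slope, 0)            # LD decays with distance as well
})

test_that("circular distances fold around half the genome", {
  expect_equal(circular_distance(1, 15333, 15333), 1)
  expect_equal(circular_distance(100, 7766, 15333), 7666)
  d <- circular_distance(sample(15333, 50), sample(15333, 50), 15333)
  expect_true(all(d <= 15333 / 2))
})

test_that("Rm reproduces small known panels and tracks the DP oracle", {
  clean <- panel("AAAA", "AACC", "CCCC")
  expect_equal(hudson_kaplan_rm(clean, min_minor_carriers = 1L), 0L)

  one <- panel("AA", "AC", "CA", "CC")
  expect_equal(hudson_kaplan_rm(one, min_minor_carriers = 1L), 1L)

  # 000, 011, 101, 110: all three pairs violate -> two disjoint intervals
  three <- panel("AAA", "ACC", "CAC", "CCA")
  expect_equal(hudson_kaplan_rm(three, min_minor_carriers = 1L), 2L)

  set.seed(29)
  for (rep in 1:40) {
    m <- random_panel(sample(6:14, 1), sample(4:12, 1))
    bial <- biallelic_columns(m, min_minor_carriers = 1L)
    vp <- violating_pairs(bial$X)
    oracle <- if (is.null(vp)) 0L else oracle_max_disjoint(vp[, 1], vp[, 2])
    expect_equal(hudson_kaplan_rm(m, min_minor_carriers = 1L), oracle)
  }
})

test_that("Rm is stable within one event across circle cut points", {
  set.seed(37)
  for (rep in 1:10) {
    m <- random_panel(10, 8)
    rms <- vapply(c(1L, 3L, 5L, 7L),
                  function(cut) hudson_kaplan_rm(m, min_minor_carriers = 1L,
                                                 cut_at = cut),
                  integer(1))
    expect_lte(diff(range(rms)), 1L)
  }
})

test_that("planted recombinants put every FGT violation across a breakpoint", {
  cfg <- sim_config(reference_length = 8000L, n_populations = 1L,
                    clones_per_population = 40L, theta = 0.004,
                    n_recombinants = 1L, heteroplasmy_prob = 0, seed = 53)
  set.seed(53)
  s <- inject_heteroplasmy_and_recombinants(simulate_haplotypes(cfg))
  fg <- fgt_fraction(s$major, L = cfg$reference_length,
                     min_minor_carriers = 2L)
  viol <- fg$pairs[fg$pairs$n_gametes == 4L, ]
  expect_gt(nrow(viol), 0)
  cuts <- as.integer(strsplit(s$breakpoints$breakpoints, ",")[[1]])
  seg <- function(site) findInterval(site, cuts)   # parent segment index
  expect_true(all(seg(viol$site_i) != seg(viol$site_j)))
  expect_gte(hudson_kaplan_rm(s$major, L = cfg$reference_length,
                              min_minor_carriers = 2L), 1L)
})
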