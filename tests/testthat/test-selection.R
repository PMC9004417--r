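sense_codons_5 <- function() {
  gc <- genetic_code("5")
  names(gc)[gc != "*"]
}

test_that("codon site counts match the enumeration oracle at both kappas", {
  # fourfold-degenerate third position: one synonymous site at any kappa
  expect_equal(codon_site_counts("GGG", kappa = 7.3)$syn_sites, 1.0)
  expect_equal(codon_site_counts("GGG", kappa = 1)$syn_sites, 1.0)
  # Trp: only the third-position transition is synonymous under code 5
  expect_equal(codon_site_counts("TGG", kappa = 7.3)$syn_sites,
               7.3 / 9.3, tolerance = 1e-12)
  expect_error(codon_site_counts("TAA"), "stop codon")

  for (kappa in c(1, 7.3)) {
    for (codon in sense_codons_5()) {
      got <- codon_site_counts(codon, kappa = kappa)
      ora <- oracle_site_counts(codon, kappa)
      expect_equal(got$syn_sites, unname(ora["syn"]), tolerance = 1e-12)
      expect_equal(got$syn_sites + got$nonsyn_sites, 3)   # always 3 sites
    }
  }
})

test_that("pathway-averaged codon differences handle stops and multi-hits", {
  d0 <- codon_path_diffs("GGA", "GGA")
  expect_equal(d0$syn_diffs + d0$nonsyn_diffs, 0)
  d1 <- codon_path_diffs("GGA", "GGG")            # Gly/Gly
  expect_equal(d1$syn_diffs, 1)
  d1n <- codon_path_diffs("AAA", "AAC")           # Lys/Asn
  expect_equal(d1n$nonsyn_diffs, 1)
  expect_equal(codon_path_diffs("ATG", "ATA")$syn_diffs, 1)  # both Met (code 5)

  # TTT -> GTA: pathways (1 syn + 1 nonsyn) and (0 syn + 2 nonsyn)
  d2 <- codon_path_diffs("TTT", "GTA")
  expect_equal(d2$syn_diffs, 0.5)
  expect_equal(d2$nonsyn_diffs, 1.5)

  # TAC -> TTA: the pathway through the stop codon TAA is excluded
  d2s <- codon_path_diffs("TAC", "TTA")
  expect_equal(d2s$syn_diffs, 0)
  expect_equal(d2s$nonsyn_diffs, 2)

  # random pairs against an independent permutation + translation oracle
  set.seed(12)
  cods <- sense_codons_5()
  for (rep in 1:40) {
    c1 <- sample(cods, 1); c2 <- sample(cods, 1)
    got <- codon_path_diffs(c1, c2)
    dp <- which(strsplit(c1, "")[[1]] != strsplit(c2, "")[[1]])
    expect_equal(got$syn_diffs + got$nonsyn_diffs, length(dp))
    rev <- codon_path_diffs(c2, c1)
    expect_equal(got$syn_diffs, rev$syn_diffs, tolerance = 1e-12)
  }
})

toy_gene <- function(codons) {
  list(ann = gene_annotation(data.frame(
    gene_id = "g1", start = 1L, end = 3L * length(codons),
    strand = "+", frame = 0L, code = "5")),
    seq = paste(codons, collapse = ""))
}

test_that("gene pi_n/pi_s separates planted synonymous-only variation", {
  ref <- c("GGA", "CTT", "ATG", "AAA", "TCC", "GTT", "CCA", "ACG", "GCT",
           "CGA")
  g <- toy_gene(ref)
  mut <- ref; mut[1] <- "GGG"                        # fourfold third position
  haps <- haplotype_set(c(rep(g$seq, 2), rep(paste(mut, collapse = ""), 2)),
                        clone_id = paste0("c", 1:4), population_id = "p",
                        role = "major")
  v <- gene_pi_n_pi_s(haps, as.list(g$ann[1, ]))
  expect_equal(v$pi_n, 0)
  expect_gt(v$pi_s, 0)
  expect_equal(v$pi_s, 0.5 / v$syn_sites)            # p = q = 0.5 at one site
  expect_equal(v$syn_sites + v$nonsyn_sites, 30)

  mono <- haplotype_set(rep(g$seq, 4), paste0("c", 1:4), "p", "major")
  m <- gene_pi_n_pi_s(mono, as.list(g$ann[1, ]))
  expect_equal(m$pi_n, 0)
  expect_equal(m$pi_s, 0)
  expect_true(is.na(mean_ratio_delta(m$pi_n, m$pi_s)$ratio))  # undefined ratio

  tab <- pi_n_pi_s_table(haps, g$ann)
  expect_equal(tab$pi_s, v$pi_s)
})

test_that("gene Phi_n/Phi_s reflects between-population differentiation", {
  ref <- c("GGA", "CTT", "ATG", "AAA", "TCC", "GTT")
  g <- toy_gene(ref)
  syn_mut <- ref; syn_mut[1] <- "GGG"
  non_mut <- ref; non_mut[4] <- "AAC"                # Lys -> Asn
  pop1 <- haplotype_set(rep(g$seq, 4), paste0("a", 1:4), "p1", "major")
  pop2s <- haplotype_set(rep(paste(syn_mut, collapse = ""), 4),
                         paste0("b", 1:4), "p2", "major")
  pop2n <- haplotype_set(rep(paste(non_mut, collapse = ""), 4),
                         paste0("b", 1:4), "p2", "major")
  vs <- gene_phi_n_phi_s(list(pop1, pop2s), as.list(g$ann[1, ]))
  expect_gt(vs$phi_s, 0)
  expect_equal(vs$phi_n, 0)
  vn <- gene_phi_n_phi_s(list(pop1, pop2n), as.list(g$ann[1, ]))
  expect_gt(vn$phi_n, 0)
  expect_equal(vn$phi_s, 0)
  expect_error(gene_phi_n_phi_s(list(pop1), as.list(g$ann[1, ])),
               "at least 2 populations")
})

test_that("divergence applies Jukes-Cantor to pathway-averaged proportions", {
  # closed form: -(3/4) log(1 - 4 * 0.0745 / 3) = 0.078465
  expect_equal(jukes_cantor(0.0745), 0.078465, tolerance = 1e-4)
  expect_true(is.na(jukes_cantor(0.8)))

  ref <- c("GGA", "CTT", "ATG", "AAA", "TCC", "GTT", "CCA", "ACG")
  g <- toy_gene(ref)
  same <- dn_ds(g$seq, g$seq, g$ann)
  expect_equal(same$d_n, 0)
  expect_equal(same$d_s, 0)

  out <- ref; out[1] <- "GGC"; out[6] <- "GTA"       # fourfold third positions
  div <- dn_ds(g$seq, paste(out, collapse = ""), g$ann)
  expect_equal(div$d_n, 0)
  expect_gt(div$d_s, 0)
  expect_false(div$undefined)
  expect_gt(div$d_s, div$p_s)                         # correction expands p

  # codons with N are excluded codon-wise
  nseq <- sub("^GGA", "GNA", g$seq)
  dn <- dn_ds(nseq, g$seq, g$ann)
  expect_equal(dn$syn_sites, sum(vapply(ref[-1], function(cd)
    codon_site_counts(cd)$syn_sites, 1)))
})

test_that("Delta-method machinery reproduces hand-computed variances", {
  r <- mean_ratio_delta(c(2, 4), c(1, 3))
  expect_equal(r$ratio, 1.5)
  expect_equal(r$variance, 0.0625)
  expect_equal(r$se, 0.25)

  expect_equal(mean_ratio_delta(c(2, 2), c(1, 1))$se, 0)   # no variance
  expect_equal(mean_ratio_delta(c(1, 1), c(0.5, 2))$ratio, 0.8)  # ratio of means
  expect_true(is.na(mean_ratio_delta(c(1, 2), c(0, 0))$ratio))

  ni <- neutrality_index(0.131, 1, 0.106, 1)
  expect_equal(ni$NI, 1.236, tolerance = 5e-4)
  expect_equal(neutrality_index(0.2, 0.4, 0.1, 0.2)$NI, 1)  # neutral case
  expect_equal(neutrality_index(1, 1, 1, 1)$se, 0)
  expect_equal(neutrality_index(1, 1, 1, 1,
                                var_Pi_n = 0.01, var_Pi_s = 0.01,
                                var_d_n = 0.01, var_d_s = 0.01)$se, 0.2)
  expect_true(is.na(neutrality_index(0.1, 0, 0.1, 0.2)$NI))  # flagged, no error
})
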