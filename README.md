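# mitopop

Population genomics of animal mitochondrial genomes from per-clone
allele-count tables.

High-depth whole-genome resequencing of clonal isolates (for example
*Daphnia* panels sequenced at 100x–7,000x mitochondrial coverage) yields,
as a by-product, enough information to study mitochondrial variation at
every level: within individuals (heteroplasmy), between individuals,
between populations, and between species. `mitopop` implements that
analysis chain for researchers who already have pileup-style allele
counts per clone and site:

* **Heteroplasmy calling** — a five-filter cascade per (clone, site)
  record: Wilson 95% lower confidence bound of the minor-allele fraction
  ≥ 0.01, strictly biallelic site, ≥ 5 minor reads, no indel within 3 bp,
  site quality ≥ 10; plus Table-1-style clone and population summaries,
  sharing spectra, and major/minor flip counts.
* **Haplotype complexity and phasing** — a χ² goodness-of-fit test of
  minor-read counts against binomial sampling with pooled fraction
  f̄ = Σxᵢ/Σnᵢ and df = m − 1 (two haplotypes ⇒ binomial); clones passing
  are phased by allele frequency into a major and a minor haplotype.
* **Recombination screens** — four-gamete tests over informative site
  pairs, the compatible fraction F(D′) and mean r² = D²/(p_A q_A p_B q_B)
  regressed on circular distance in 100-bp bins, and the Hudson–Kaplan
  lower bound Rm on the number of recombination events.
* **Diversity and selection** — per-site π = 2pq (2(pq+pr+qr) when
  triallelic), between-population Φ = H_t − H_s, per-site
  F_ST = (H_t − H_s)/H_t averaged over biallelic sites with
  metapopulation MAF > 0.1, modified Nei–Gojobori d_n/d_s under the
  invertebrate mitochondrial code with transition:transversion weighting
  (κ = 7.3 by default) and Jukes–Cantor correction, the neutrality index
  NI = (Π_n/Π_s)/(d_n/d_s) with Delta-method standard errors, effective
  size N_e = π_s/2μ (μ = 1.37 × 10⁻⁷ by default), and island-model gene
  flow N_e m from F_ST.
* **A seeded synthetic-data generator** — populations of clones with
  known haplotypes, heteroplasmy (including divergent paternal-leakage
  minor haplotypes), planted recombinants, and binomial read counts with
  sequencing error, so that every stage can be validated against ground
  truth.

Inputs are plain files: allele counts as TSV, haplotypes as FASTA (with
`clone|population|role` headers), masks as BED, annotation as TSV or GFF3
CDS lines. Coordinates are 1-based inclusive on a circular reference.

## Worked example

```r
library(mitopop)

cfg <- sim_config(reference_length = 3000, n_populations = 2,
                  clones_per_population = 15, seed = 21)
sim <- simulate_dataset(cfg)

counts <- apply_site_mask(sim$counts, sim$mask)   # drop the D-loop
hs <- call_heteroplasmic_sites(counts)
summarize_population(summarize_clones(hs, sim$clones$clone_id))
#>   n_clones n_heteroplasmic frac_heteroplasmic mean_sites_per_het_clone
#> 1       30              20          0.6666667                      8.5
#>    mean_maf
#> 1 0.1024825
```

Twenty of thirty clones carry called heteroplasmic sites (the generator
plants them with probability 0.7), at a mean within-clone minor-allele
fraction of about 0.10 — the middle of the planted 0.03–0.18 range.

```r
th <- test_all_clones(hs, support_threshold = 0.05)
sum(th$testable); sum(th$supports_two_haplotypes[th$testable])
#> [1] 7
#> [1] 6
```

Seven clones have enough sites (≥ 5) for the two-haplotype test; six are
consistent with exactly two haplotypes at the conventional threshold.

```r
majors <- sim$haplotypes[sim$haplotypes$info$role == "major"]
pop1 <- majors[majors$info$population_id == "pop1"]
fg <- fgt_fraction(pop1)
fd <- fd_vs_distance(fg$pairs)
c(F = fg$F_compatible, slope = fd$slope, p = fd$p_value)
#>             F         slope             p
#>  9.960832e-01 -9.061094e-07  6.018877e-01
hudson_kaplan_rm(pop1)
#> [1] 2
```

99.6% of informative pairs pass the four-gamete test and the
compatibility-versus-distance slope is not significant: no recombination
is flagged in this recombination-free simulation (the residual Rm = 2
reflects recurrent mutation on a short 3-kb test reference, which the
four-gamete logic cannot distinguish from exchange).

```r
pt <- pi_n_pi_s_table(pop1, sim$annotation)
pt
#>   gene_id       pi_n       pi_s syn_sites nonsyn_sites
#> 1    cds1 0.01249449 0.01067035  373.2043     796.7957
#> 2    cds2 0.01810906 0.01181121  376.2903     793.7097
effective_size(mean(pt$pi_s))
#> [1] 41025
```

Under the neutral generator defaults π_n ≈ π_s ≈ θ = 0.01, and the
silent-site diversity converts to an effective number of mitochondria of
roughly 4 × 10⁴ at the default mutation rate.

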