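---
title: "Models and methods behind mitopop"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind mitopop}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mitopop)
```

## Scope

`mitopop` analyzes high-depth resequencing of animal mitochondrial genomes
across panels of clonal isolates. It answers four questions: which clones
carry more than one mitochondrial haplotype (heteroplasmy), whether a
heteroplasmic clone is consistent with exactly two haplotypes, whether
recombination is detectable among the pooled haplotypes of a population,
and how diversity, differentiation and selection are distributed within
and among populations. The pipeline deliberately starts at per-clone,
per-site allele-count tables; read trimming, mapping, variant calling and
assembly are upstream concerns handled by standard tools, and Numt and
control-region (D-loop) masks are *inputs*, because their discovery
depends on nuclear assemblies we do not touch.

## Heteroplasmy calling

At each (clone, site) record the major allele is the base with the highest
read count and the minor allele the second highest (ties assign the
alphabetically later base to the minor allele, so the minor-allele
fraction never exceeds 0.5). A record is called heteroplasmic only if all
of the following hold:

1. the lower limit of the two-sided 95% Wilson score interval of the
   minor-allele fraction is at least 0.01;
2. the site is biallelic (exactly two *recognized* alleles; see below);
3. the minor allele is supported by at least 5 reads;
4. no candidate indel lies within 3 bp;
5. the site quality score is at least 10.

The Wilson interval was chosen because it is stable at low counts and
never collapses to a zero-width interval at the boundaries; the exact
Clopper–Pearson interval, which is wider by construction, is used as an
oracle in the tests. The confidence level is a parameter
(`ci_confidence`), since reasonable pipelines differ here.

**Allele recognition.** Coverage in this kind of data spans nearly two
orders of magnitude (hundreds to thousands of reads). A fixed read-count
rule for deciding that a base "is an allele" is not coverage-robust: at
7,000x coverage and an error rate of 10^-3^, several stray error reads on
a third base are routine, and taking them at face value would reclassify
most truly biallelic sites as triallelic and discard them. `mitopop`
therefore recognizes a base as an allele only when it has at least
`allele_min_reads` reads **and** the Wilson lower bound of its own
frequency reaches `allele_min_ci` (default 0.01 — the same 1% limit below
which heteroplasmy and sequencing error cannot be told apart, which is the
rationale for filter 1). These two constants are definitional: they say
what an allele is, and they are deliberately *not* part of the filter
cascade. The cascade thresholds (`min_minor_reads`, `min_ci_lower`,
`min_site_quality`) are monotone — raising any of them can only remove
calls — and the test suite asserts exactly that. The recognition
constants are excluded from the monotonicity property because redefining
"allele" can legitimately merge a triallelic site into a biallelic one.

Only single-base substitutions are called; indel candidates are never
emitted. Quality scores are consumed as given — the package applies the
threshold but does not recalibrate.

## Two-haplotype test and phasing

If a clone carries exactly two haplotypes at minor fraction *f*, the
minor-read count at each of its *m* heteroplasmic sites is Binomial
(coverage~i~, *f*). The test pools a read-weighted estimate
$\bar f = \sum_i x_i / \sum_i n_i$ (read-weighting matches the fact that
expected minor counts are proportional to coverage), forms expected minor
and major counts per site, and sums the usual goodness-of-fit statistic
over both read classes. Degrees of freedom are $m - 1$: one parameter was
estimated from the data, which is the standard convention. The p-value is
the upper chi-square tail; a *large* p means the binomial (two-haplotype)
model fits.

The support threshold deserves a note. Requiring "probability of support
above 0.95" can be read as `p > 0.95` (literally: near-perfect fit
required) or as the conventional `p > 0.05` (fail to reject at 5%). Under
the null, p-values are uniform, so `p > 0.95` accepts only 5% of true
two-haplotype clones — a reading that makes sense only as a deliberately
conservative screen before phasing. The package implements the threshold
as a parameter with default 0.95 (the literal reading) and the test suite
exercises both; the synthetic end-to-end recovery checks use 0.05, under
which roughly 95% of true two-haplotype clones are accepted, as the
Monte-Carlo tests confirm.

Clones passing the test are phased by frequency: the major haplotype is
the clone consensus, and the minor haplotype substitutes every called
site's minor allele into the consensus. With 100–150-bp reads and several
kilobases between heteroplasmic sites, read-backed phasing is
uninformative, so no attempt is made; clones failing the test carry only
their major haplotype forward. Consensus building is majority-rule with N
below a configurable depth (default 100) and ties to the alphabetically
earlier base. Pairwise divergences are p-distances with N positions
excluded from both numerator and denominator.

## Recombination screens

All recombination statistics operate on pooled population haplotypes
restricted to biallelic sites whose minor allele is carried by at least 3
haplotypes (singletons and doubletons are too easily created by error),
with the D-loop masked upstream as a mutational hotspot.

*Four-gamete test.* A pair of biallelic sites showing all four allele
combinations requires either recombination or recurrent mutation.
`F(D')` is the fraction of informative pairs *compatible* with no
recombination (at most three gametes). Because published descriptions of
this statistic differ in orientation, both `F` and `1 - F` are reported.

*Distance profiles.* On a circular genome an exchange event needs two
breaks, and linkage disequilibrium is expected to decay roughly linearly
with distance up to the mean exchange-segment length. Distances are
therefore circular, `min(d, L - d)`. Pairs are binned into 100-bp
distance windows; the compatible fraction (and the mean r² for the LD
profile) per bin is regressed on the bin midpoint by ordinary least
squares, with the slope's p-value from the t distribution on
`bins - 2` degrees of freedom. Recombination is flagged when the
compatibility slope is negative at `alpha = 0.05`. Binned regression (not
pair-level) is used because pairs sharing a site are strongly dependent.

*r².* For two biallelic sites, `r² = D²/(p_A q_A p_B q_B)` with
`D = p_AB - p_A p_B` from haplotype frequencies — identically the squared
Pearson correlation of the allele indicators, which the tests verify
against `cor()` directly. The carrier threshold for r² pairs is "more
than 2" carriers, i.e. the same 3 as the FGT screen; both are parameters.

*Hudson–Kaplan bound.* Every violating pair defines an open interval that
must contain at least one recombination event; `Rm` is the maximum number
of disjoint such intervals, computed by the classical reduction (discard
intervals containing another violating interval, then select greedily by
right endpoint). The bound is defined on a linear order, so the circle is
cut at a configurable position (default 1); on small panels the tests
assert that the result varies by at most one event across cut choices. An
independent weighted-interval-scheduling dynamic program serves as the
oracle in the tests.

## Diversity, differentiation and selection

Per-site diversity is `2pq` at biallelic sites and `2(pq + pr + qr)` at
the rare triallelic ones (more than three alleles is rejected).
Between-population diversity is `Phi = H_t - H_s`, where `H_s` is the
clone-number-weighted mean of within-population heterozygosities and
`H_t` is the heterozygosity of the clone-number-weighted mean
frequencies. Using the *same* weights in both components makes
`Phi >= 0` a theorem (Jensen's inequality on the concave heterozygosity),
which the tests assert on random frequency tables; with unmatched weights
the sign guarantee would be lost. Per-site
`F_ST = (H_t - H_s)/H_t` uses the same components; sites with
metapopulation minor-allele frequency at or below 0.1 are excluded
(the estimator is noisy for rare alleles) and the overall value is the
unweighted mean over retained biallelic sites. Triallelic sites enter
diversity but are excluded from F~ST~ and LD statistics.

Synonymous/nonsynonymous accounting uses modified Nei–Gojobori counting
under the invertebrate mitochondrial code (NCBI table 5, in which TGA is
tryptophan and AGA/AGG are serine, leaving 62 sense codons): at each codon
position the three possible changes are weighted by the
transition:transversion ratio (default `kappa = 7.3`, appropriate for
this mitochondrial system), normalized to one site per position, so every
codon contributes exactly 3 sites and `kappa = 1` recovers the unweighted
method — both facts are checked codon-exhaustively against an independent
enumeration oracle. Changes creating a stop count as nonsynonymous in
site counting. For codon pairs differing at several positions,
differences are averaged over all mutational pathways with equal weights;
pathways through stop codons are excluded and the remainder reweighted
(if every pathway is blocked, all pathways are used with stop-passing
steps counted as nonsynonymous — a rare fallback for multiply-substituted
pairs). Divergence proportions are corrected with the Jukes–Cantor
transform `d = -(3/4) ln(1 - 4p/3)`; both raw proportions and corrected
distances are reported, and genes with `p >= 3/4` are flagged rather than
silently dropped. Within genes, polymorphic columns are decomposed into
unordered allele pairs classified against the consensus codon; stop or
ambiguous consensus codons (e.g. a terminal stop) are skipped.

Ratios are reported as *ratios of means* across genes — not means of
ratios — to avoid explosion when a denominator gene is nearly
monomorphic; the variance of a ratio uses the first-order Delta
approximation with the covariance term included whenever per-gene values
are paired. The neutrality index is
`NI = (Pi_n/Pi_s)/(d_n/d_s)` with `Pi = pi + Phi` the total
metapopulation diversity; `NI > 1` indicates purifying selection, `NI <
1` positive selection. Its standard error comes from the Delta method on
the ratio of ratios, treating polymorphism and divergence as independent
unless covariances are supplied.

Effective size is `N_e = pi_s / (2 mu)` with the mitochondrial mutation
rate default `mu = 1.37e-7` per site per generation, rounded to the
nearest integer; monomorphic populations report `N_e = 0` rather than NA.
Island-model gene flow inverts `F_ST = 1/(1 + 2 N_e m)` (haploid) or
`1/(1 + 4 N_e m)` (diploid).

## The synthetic-data generator

Because the raw study-scale sequencing data cannot be reproduced at desk
scale, every data-dependent claim is validated against a generator with
complete ground truth. Its defaults are fixed once to the study-like
regime and are not tuning knobs:

* reference length 15,333 bp, circular, with two protein-coding genes (one
  per strand) occupying ~78% of it and a D-loop-like masked tail;
* 2 populations x 60 clones (populations of sixty-odd clones are the
  typical sampling unit here; two populations are the minimum for the
  between-population statistics);
* `theta = 0.01` expected pairwise diversity — the mid-range of observed
  mitochondrial silent-site diversity in such data;
* heteroplasmy probability 0.7 per clone; minor fractions uniform on
  [0.03, 0.18]; endogenous minor haplotypes differ at `1 + Poisson(3)`
  sites; with probability 0.05 the minor haplotype is instead a
  paternal-leakage haplotype at 2% divergence (~307 differing sites);
* per-clone coverage log-uniform on [100, 6860] with per-site Poisson
  jitter; error rate 10^-3^ per base scattered uniformly over the three
  non-true bases; 1% of sites carry a low quality score and 0.5% an
  indel flag so the corresponding filters are exercised.

Haplotypes arise by placing Poisson mutations on a random
coalescent-shaped genealogy per population (`ape::rcoal`), calibrated so
a random pair of haplotypes diverges at rate `theta` per site; mutations
are tagged synonymous/nonsynonymous in the reference codon context, and a
`nonsyn_scale` knob can suppress nonsynonymous changes to emulate
purifying selection (the default is neutral, under which pi_n/pi_s
converges to 1 and silent diversity equals `theta` in expectation).
Recombinant haplotypes are planted explicitly — a splice of two same-
population haplotypes at two breakpoints on the circle — rather than
emerging from a coalescent with recombination, because the validation
needs countable, localizable events. All randomness flows from the single
mandatory seed; a fixed configuration reproduces its dataset
byte-identically.

What the generator does *not* emulate: read-level artefacts (mapping
bias, strand bias, index hopping), site-specific error spectra,
within-individual sorting dynamics, and Numt contamination. Passing the
recovery tests therefore demonstrates the statistical machinery is
correct under the declared sampling model, not that the upstream variant
calls of any particular sequencing pipeline are clean.

Two statistical readings in the recovery checks are worth making
explicit. First, calling sensitivity is measured over planted sites with
true minor fraction >= 0.05 and clone coverage >= 200 — the regime in
which detection is statistically possible under the 5-read and 1% rules;
below it, missing a site is the filter doing its job. Second, "minor
fractions fall inside the 99% binomial envelope" is asserted as "at most
3% of emitted sites fall outside", since with hundreds of sites roughly
1% must fall outside by construction.

## Worked example

```{r example, eval = FALSE}
cfg <- sim_config(reference_length = 3000, n_populations = 2,
                  clones_per_population = 15, seed = 21)
sim <- simulate_dataset(cfg)
counts <- apply_site_mask(sim$counts, sim$mask)
hs <- call_heteroplasmic_sites(counts)
summarize_population(summarize_clones(hs, sim$clones$clone_id))

majors <- sim$haplotypes[sim$haplotypes$info$role == "major"]
fg <- fgt_fraction(majors)
fd_vs_distance(fg$pairs)
hudson_kaplan_rm(majors)

pi_n_pi_s_table(majors[majors$info$population_id == "pop1"],
                sim$annotation)
```

## Numerical choices and edge cases

* Ties: consensus and major alleles break ties to the alphabetically
  earlier base, minor alleles to the later base — deterministic and
  mutually consistent.
* Zero coverage yields no call (never a division error); an expected
  count of zero in the two-haplotype test raises a degenerate-input
  error.
* Fewer than `min_sites` heteroplasmic sites marks a clone "not
  testable" rather than producing a meaningless p-value.
* Undefined statistics (no eligible pairs, monomorphic denominators,
  `F_ST <= 0` inversions, `p >= 3/4` corrections) are returned as flagged
  NA values, not exceptions, so tabulations over many genes or
  populations do not abort.
* BED masks are converted to the internal 1-based inclusive convention on
  read; wrap-around features are represented as two intervals.
* Problem sizes in the shipped tests — one default-scale synthetic
  dataset, 2,000-replicate null distributions, 200-replicate
  detection/false-positive rates, 10,000-site island-model panels —
  were chosen as the smallest sizes at which the Monte-Carlo standard
  errors are clearly inside the asserted bands.

## Known limitations

* No read-backed phasing and no reconstruction of more than two
  haplotypes per clone; such clones contribute only their major
  haplotype.
* The Hudson–Kaplan bound on a circle is computed after cutting at one
  position; a rotation-invariant circular bound is not attempted.
* Four-gamete violations — and hence Rm — count incompatibilities, which
  recurrent mutation also produces. On short references or at high
  diversity a nonzero Rm is expected even without any exchange; the
  distance-profile tests are the discriminating signal, since homoplasy
  has no distance dependence.
* Delta-method standard errors are first-order and can be optimistic for
  small gene counts or near-zero denominators.
* The quality column is taken at face value; recalibration belongs
  upstream.
* `F_ST` is the heterozygosity-partition form `(H_t - H_s)/H_t`; no
  small-sample allele-frequency correction is applied, which matters if
  per-population sample sizes are very small.
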