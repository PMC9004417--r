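Package: mitopop
Title: Mitochondrial Heteroplasmy, Recombination, and Population Genetics
    from Per-Clone Allele Counts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for population genomics of animal mitochondrial genomes
    sequenced at high depth across clonal isolates. Calls within-clone
    heteroplasmic sites from per-site allele-count tables with a five-filter
    cascade (Wilson confidence bound on the minor-allele fraction, biallelic
    restriction, minimum read support, indel proximity, and site quality),
    tests whether a heteroplasmic clone is consistent with exactly two
    haplotypes via a chi-square goodness-of-fit test against binomial read
    sampling, phases two-haplotype clones by allele frequency, and detects
    recombination among pooled haplotypes with four-gamete tests, linkage
    disequilibrium decay on a circular genome, and the Hudson-Kaplan lower
    bound on recombination events. Also computes nucleotide diversity at
    synonymous and nonsynonymous sites, between-population diversity, F_ST
    and island-model gene flow, divergence by the modified Nei-Gojobori
    method with transition-transversion weighting, the neutrality index with
    Delta-method standard errors, and effective population sizes from
    silent-site diversity. A seeded synthetic-data generator provides
    populations of clones with known haplotypes, heteroplasmy, and
    recombination so that every stage can be validated against ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    Biostrings,
    jsonlite,
    stats,
    utils
Suggests:
    seqinr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
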