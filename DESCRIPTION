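Package: cranecap
Title: Temporal Genetic Load, Inbreeding and Captive-Management Genomics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Statistics for genomic erosion in bottlenecked and captive-managed
    populations sampled at two time points: polarised deleterious-allele load
    counts, allele-frequency change and the Rxy ratio with delete-d jackknife,
    CADD-rank based decomposition of genetic load into realised and masked
    components with Mendelian cross prediction, runs-of-homozygosity (F_ROH)
    summaries with size and coalescence-age stratification, a per-bin
    empirical-Bayes moderated t-test for private low-heterozygosity regions,
    Waples inbreeding and variance effective sizes, and recursive pedigree
    kinship and inbreeding from studbooks. Includes a Wright-Fisher forward
    simulator with selection and dominance, a pedigree/gene-dropping simulator
    and an ROH/binned-heterozygosity generator so every statistic can be
    exercised and calibrated on synthetic data with known truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    vcfR,
    IRanges,
    GenomicRanges,
    yaml
Suggests:
    testthat (>= 3.0.0),
    limma,
    jsonlite
Config/testthat/edition: 3
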