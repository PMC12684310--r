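# cranecap

Statistics for **genomic erosion in bottlenecked, captive-managed
populations** sampled at two time points — the situation of a species such
as the whooping crane, which collapsed to ~20 individuals, was rescued by a
captive programme founded with ~35 wild-born birds, and recovered
demographically while its genomes kept eroding. The package is written for
conservation genomicists who already have genotypes, annotations, ROH calls
and a studbook, and need the bespoke statistics that connect them.

## What it computes

**Temporal load dynamics.** Sites are polarised by outgroup consensus
(every outgroup homozygous reference); derived alleles are counted per
sample and impact category (het + 2×hom), with MODERATE/HIGH counts
normalised by each sample's LOW total to cancel variant-discovery bias.
Frequency change is summarised per site (Δ = F_modern − F_historical, with
a two-sided sign test) and by the ratio

  R_xy = Σ F_m (1 − F_h) / Σ F_h (1 − F_m),

aggregated as a ratio of sums, normalised by the LOW-category ratio, with a
delete-1% jackknife (100 replicates) for the variance. R_xy < 1 for the
HIGH category is the signature of purging. Homozygous load is also split
inside/outside ROH and normalised by F_ROH and 1 − F_ROH.

**Score-based load decomposition.** PHRED-scaled deleteriousness scores are
inverted to rank proportions (10^(−score/10); score 20 ↔ 0.01), giving a
selection proxy s = 1/n_i and a score-binned dominance h. Per sample:
genetic load GL = Σ_hom s + Σ_het 0.5s, realised load RL = Σ_hom s +
Σ_het hs, masked load ML = Σ_het (0.5 − h)s, with GL = RL + ML exactly.
Hypothetical crosses get expected offspring components under exact
Mendelian segregation and are ranked by expected realised load.

**ROH and ROHbin.** F_ROH from merged intervals; tract age G = 100/(2 cM);
stratification by size (10 Mb) and generation bin. ROHbin compares binned
heterozygosity between wild and captive groups with an empirical-Bayes
moderated t-test (variances shrunk toward a method-of-moments scaled-F
prior) and calls significant bins as variation private to the group that
retains diversity there.

**Effective sizes.** Nef = 1/(2ΔF) from the F_ROH accumulation rate;
NeV from temporal allele-frequency change (Nei–Tajima standardised change
with full binomial sampling correction); and the
heterozygosity-loss-equivalent Ne that inverts (1 − 1/(2Ne))^t.

**Pedigree.** Recursive kinship and inbreeding from a studbook (founders
assumed unrelated), relatedness-degree classification, and Monte-Carlo gene
dropping as an independent cross-check.

**Synthetic data.** A Wright–Fisher forward simulator with selection and
dominance (decline → bottleneck of 20 → recovery; epoch samples of 16 and
37), a pedigree/gene-dropping simulator with a min-kinship pairing policy,
and an ROH/binned-heterozygosity generator with injectable private regions
— every statistic above is calibrated against these with known truth.

## Worked example

```r
library(cranecap)

# two-epoch simulation under the default bottleneck design
sim <- simulate_wf(sim_config(seed = 2024))
pol <- polarise(sim$genotypes, sim$outgroups)
ft  <- frequency_table(pol$genotypes, historical = "historical", modern = "wild")
jk_mod  <- jackknife_rxy(ft, "MODERATE", seed = 1)
jk_high <- jackknife_rxy(ft, "HIGH", seed = 1)
d       <- delta_frequency(ft, "HIGH")

nef(0.0794, c(rep(0.1031, 6), rep(0.1036, 19)), t = 4)$Nef
ne_from_het_loss(0.00296, 0.0008, t = 9.2)$Ne

ped <- pedigree(c("sire", "dam", "chick"), c(NA, NA, "sire"), c(NA, NA, "dam"))
kinship(ped)["sire", "chick"]
```

Output:

```
polarisation retained 4770/5300 sites (90.0%)
normalised Rxy MODERATE 1.004 (95% CI 0.907-1.100)
normalised Rxy HIGH     0.753 (95% CI 0.602-0.905)
HIGH mean delta-frequency -0.0069; sign-test p = 2.76e-06
Nef = 83.1
heterozygosity-loss-equivalent Ne = 3.77
parent-offspring kinship 0.25 (first_degree); self-kinship 0.50
```

Reading it: the neutral-ish MODERATE category shows no frequency shift
(normalised R_xy ≈ 1), while HIGH-impact variants are depleted in the
modern epoch (R_xy ≈ 0.75, CI below 1; negative mean Δ) — purging of
strongly deleterious, mostly recessive variation through the simulated
bottleneck. The Nef of 83 is the inbreeding effective size implied by mean
F_ROH rising from 7.94% (founders) to 10.35% (contemporary) over four
generations; the Ne of 3.8 is the ideal-population size whose neutral decay
would match a 70% heterozygosity loss over 9.2 generations.

A thin command-line front end over the same functions ships in
`inst/cli/cranecap.R` (subcommands `simulate`, `filter`, `load-counts`,
`rxy`, `cadd-load`, `crosses`, `roh`, `rohbin`, `ne`, `pedigree`).

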