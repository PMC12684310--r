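---
title: "Methods: temporal genetic load, inbreeding and captive-management statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: temporal genetic load, inbreeding and captive-management statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cranecap)
```

# Scope

`cranecap` implements the statistics used to quantify genomic erosion in a
bottlenecked, captive-managed population sampled at two time points
(museum-era and contemporary genomes). The motivating system is a large,
long-lived bird that collapsed to roughly 20 individuals, was rescued by a
captive breeding programme founded with ~35 wild-born birds, and has since
recovered while remaining genetically depauperate. Everything here applies to
any two-epoch resequencing design with a studbook: the inputs are polarised
genotype matrices with impact annotations, per-site deleteriousness scores,
ROH calls with binned heterozygosity, and a pedigree.

The package deliberately stops where standard tooling starts: genotype
calling, variant-effect annotation, ROH calling and demographic
reconstruction are consumed, not reimplemented.

# Temporal load dynamics

## Polarisation

Sites are polarised against an outgroup panel: a site is kept only when every
outgroup individual is homozygous reference with a called genotype
(`polarise()`). Any alternative allele in the focal samples is then derived
and treated as the putatively deleterious state. Requiring unanimity trades
site count for polarisation reliability — lineage-specific substitutions in a
single outgroup otherwise masquerade as ancestral states.

## Load counts and normalisation

`count_load()` counts derived alleles per sample and impact category
(`LOW`/`MODERATE`/`HIGH`, as produced by a variant-effect predictor):
heterozygotes contribute one allele, homozygotes two. Missing genotypes
contribute nothing, which is why the per-genotype depth window
(`apply_load_depth_window()`: minimum 5, maxima of twice the epoch's average
coverage — 20 modern, 16 historical by default) is applied as missingness
rather than site removal. Because historical DNA yields fewer confident
variant calls, MODERATE and HIGH counts are normalised by each sample's own
LOW-impact total (`normalise_load_counts()`); the LOW category acts as an
internal control for discovery power.

## Frequency change and Rxy

`frequency_table()` computes per-site derived-allele frequencies over
non-missing genotypes in each epoch. `delta_frequency()` reports per-site
`F_modern − F_historical`; `sign_binomial_test()` tests the direction of
change as a two-sided sign test on the nonzero deltas against
Binomial(n, 0.5). The frequency-weighted alternative (testing the summed
change) was considered and rejected: the sign construction is scale-free and
robust to a few high-frequency sites, and zero deltas are uninformative for
direction so they are dropped (all-zero input degenerates to p = 1 with a
warning).

`rxy()` computes

$$R_{xy} = \frac{\sum_i F_{m,i}\,(1 - F_{h,i})}{\sum_i F_{h,i}\,(1 - F_{m,i})}$$

as a ratio of sums across sites, not a mean of per-site ratios — per-site
ratios are undefined whenever a site is absent from one epoch, precisely the
sites a bottleneck produces. Values below 1 mean a relative deficit of that
category in the modern epoch. Category values are normalised by the LOW
ratio, so the normalised LOW value is 1 by construction and shared discovery
biases cancel.

`jackknife_rxy()` removes 1% of the focal-plus-reference sites per replicate,
100 replicates, partitioned by a seeded permutation (delete-d without
replacement). The reported variance is the delete-d estimate,
$(n-d)/d$ times the replicate variance, which targets the sampling variance
of the full statistic; the raw percentile spread of the replicates is also
returned but reflects only the 1% deletions.

`load_in_out_roh()` splits each sample's homozygous load by ROH membership
and normalises by $F_{ROH}$ and $1 - F_{ROH}$, the genome fractions the two
counts are drawn from. A sample with no ROH reports the inside count as
not-applicable rather than zero-divided.

# Score-based load decomposition

A PHRED-scaled deleteriousness score (CADD-style, computed on a model
species) is converted back to its rank proportion,
$n_i/N = 10^{-\mathrm{score}/10}$, with $N = 3{,}073{,}805{,}640$ candidate
mutations in the scoring (chicken) genome. The reciprocal rank $s = 1/n_i$
serves as a crude selection-coefficient proxy; it is used as-is, with no
re-normalisation, because any rescaling would be equally arbitrary and the
downstream comparisons are within-cohort. Dominance is assigned by score bin
— h = 0.3 below 10, 0.15 in [10, 20), 0.02 in [20, 30), 0 at 30 and above —
encoding the expectation that strongly deleterious mutations are more
recessive. The defining rule leaves the exact boundaries 10/20/30
unassigned; left-closed bins keep h monotone in the score and are recorded
here as the package's convention.

Per sample, over eligible scored sites (scored in all samples, alleles
matching, segregating — `eligible_scored_sites()`):

- genetic load $GL = \sum_{hom} s + \sum_{het} 0.5\,s$
- realised load $RL = \sum_{hom} s + \sum_{het} h\,s$
- masked load $ML = \sum_{het} (0.5 - h)\,s$

Sums (not per-site means) follow the formulas' additive form. The identity
$GL = RL + ML$ is algebraic ($0.5s = hs + (0.5-h)s$) and is enforced by test
on arbitrary inputs.

# Cross prediction

`expected_offspring_load()` takes the expectation of each load component
over the exact Mendelian offspring-genotype distribution per site and sums
across sites. Expectation — rather than sampled offspring — is the
reproducible per-cross summary; a seeded sampling mode
(`sample_offspring_load()`) exists for distribution plots. Sites missing in
either parent are dropped pairwise and counted. `rank_crosses()` sorts
candidate pairs by expected realised load (the declared optimality
criterion: minimise expected RL) and reports best-versus-worst reductions
within and between cross classes, plus best-overall versus the mean of the
k lowest-kinship pairs when a pedigree kinship matrix is supplied — the
quantity that measures what genotype-aware pairing adds over pedigree-only
management.

# ROH analysis

$F_{ROH}$ is the merged-interval fraction of the assayed genome
(`froh()`); BED input is 0-based half-open and all internal interval
arithmetic is half-open, with merging delegated to `IRanges`. The genome
length is a parameter, never hard-coded. Tract age uses
$G = 100 / (2\,\mathrm{cM})$ with cM from a genome-wide average
recombination rate (default 3.42 cM/Mb): an autozygous tract from an
ancestor $G$ generations back has expected genetic length $100/(2G)$ cM.
`stratify_roh()` assigns each tract to one size class (10 Mb threshold by
default) and one generation bin — defaults (0,2], (2,4], (4,8], (8,16],
(16,∞), a doubling scheme whose oldest informative class is 8–16
generations; the bins are configurable because other systems may warrant
different cut points. Class sums conserve the total by construction.

# ROHbin: the per-bin private-variation test

Heterozygosity per genome bin (1 Mb default; 500 kb and 250 kb supported)
is compared between two groups (wild vs captive) with an empirical-Bayes
moderated t-test. Per bin, the two-group residual variance $s_g^2$ on
$d_g$ degrees of freedom is shrunk toward a prior fitted across bins by
matching the first two moments of $\log s_g^2$ to the scaled-F marginal
(digamma/trigamma method of moments, with a Newton inversion of the
trigamma function):

$$\tilde s_g^2 = \frac{d_0 s_0^2 + d_g s_g^2}{d_0 + d_g},\qquad
t_g = \frac{\bar x_{g,1} - \bar x_{g,2}}{\tilde s_g \sqrt{1/n_1 + 1/n_2}}$$

on $d_0 + d_g$ degrees of freedom ($t_g^2$ is the two-group moderated F).
When the observed spread of log-variances does not exceed pure chi-square
sampling noise, $d_0$ is infinite and all bins share $s_0^2$. The fit is
validated against `limma::eBayes` in the test suite; the implementation
here is self-contained.

Decisions an ROH caller's output forces, recorded as explicit flags:

- **Transform.** Tests run on $\log_2(\mathrm{het} + c)$ with pseudocount
  $c$ = half the smallest positive observed value. Raw heterozygosity is
  right-skewed and near-zero inside ROH; the log transform makes the
  normal-theory machinery defensible. `log2_transform = FALSE` tests raw
  values.
- **Partial bins.** Terminal bins shorter than half the nominal size are
  excluded (their variance estimates are not exchangeable with full bins).
- **Multiplicity.** Raw p < 0.05 is the default call, matching the method's
  convention of treating each bin as a candidate region; a
  Benjamini–Hochberg flag exists but is off by default.

A significant bin with lower heterozygosity in one group is called private
variation of the *other* group (`call_private()`): the group retaining
diversity there is the one that holds something its counterpart lacks.

# Effective sizes

Three one-line estimators, kept deliberately separate because they answer
different questions:

- `nef()`: inbreeding effective size from the per-generation increase in
  mean $F_{ROH}$, $N_{ef} = 1/(2\Delta F)$. Contemporary samples pooled
  from several cohorts enter with individual weighting (each bird counts
  once), not cohort-mean weighting.
- `nev()`: variance effective size from temporal frequency change,
  $N_{eV} = t / (2(\bar F_c - \mathrm{corr}))$ with the Nei–Tajima
  standardised change $F_c = (p_1-p_2)^2 / (\bar p(1-\bar p))$ averaged
  over sites polymorphic in the pooled sample, and sampling correction
  $\mathrm{corr} = 1/(2n_1) + 1/(2n_2)$ for diploid sample sizes
  $n_1, n_2$. The correction uses both epochs' full binomial sampling
  variance; with anything less, the estimator is biased downward whenever
  samples are small — the parameter-recovery test (true N = 100, t = 4,
  samples of 16 and 37, 5,000 SNPs) only passes with the full correction,
  which is why it is the package default. Mean-of-$F_c$ (not a
  ratio-of-sums variant) is the declared aggregation.
- `ne_from_het_loss()`: the ideal-population size whose neutral decay
  $(1 - 1/(2N_e))^t$ reproduces an observed heterozygosity loss — a
  communication device ("this loss is what a population of Ne = 4 would
  experience"), not an estimator of the real Ne.

A note on the Nef-versus-NeV contrast: in a single panmictic Wright–Fisher
population the two have the same harmonic-mean expectation, so the
empirical pattern Nef ≪ NeV is not reproducible in that model. It arises
when relatedness accumulates at the scale of a small breeding group
(captive aviaries, a small wild flock) while allele frequencies drift at
the scale of the whole recovered population. The property test constructs
exactly that two-scale regime (breeding group of 25; recovered census of
150) and checks Nef < NeV in the majority of replicates.

# Pedigree kinship

`kinship()` runs the standard recursion in topological order
($\varphi(i,j) = (\varphi(s_i,j) + \varphi(d_i,j))/2$,
$\varphi(i,i) = (1 + F_i)/2$), assuming founders unrelated and non-inbred;
an unknown parent contributes zero (equivalently, each unknown side is a
unique founder). `inbreeding()` is the parents' kinship. The recursion is
cross-checked against Monte-Carlo gene dropping (`kinship_gene_drop()`),
which shares no code with it. Relatedness classes use upper-closed
intervals — (0, 0.0625] third degree or higher, (0.0625, 0.1875] second,
(0.1875, 0.375] first — so that boundary values stay in the class whose
expectation they match (0.0625 is exactly the first-cousin kinship).

# The synthetic-data generators

All calibration and recovery testing runs on three generators whose
defaults are fixed once and define the package's reference conditions.

**Wright–Fisher engine** (`simulate_wf()`, `wf_frequency_paths()`). Unlinked
sites; one generation = deterministic viability selection on Hardy–Weinberg
genotype frequencies (fitness 1, 1−hs, 1−s), recurrent ancestral→derived
mutation, binomial sampling of 2N gametes. Free recombination is a
deliberate simplification: none of the implemented statistics requires
intra-chromosomal LD, and unlinked sites make closed-form oracles (neutral
decay $(1-1/(2N))^t$, mutation–selection balance) exact. Defaults: a
trajectory of N = 200 (30 generations of standing variation), 100 (10
generations of decline), 20 (5-generation bottleneck), 150 (recovery);
historical sample of 16 at the last pre-collapse generation and modern
sample of 37 nine generations later, matching the two-epoch design; site
counts 3000/1500/800 for LOW/MODERATE/HIGH; selection coefficients 0 for
LOW, Gamma(0.5, scale 0.04) for MODERATE and Gamma(2, scale 0.2) for HIGH
(capped at 1); dominance $h = 0.5\,e^{-13 s}$, the standard negative s–h
relationship giving h ≈ 0.5 for neutral and h ≈ 0 for lethal variants. The
per-site mutation rate of 1e-4 is high for a nucleotide but appropriate for
the coarse-grained site model, where one simulated "site" stands for a
mutational target of many bases; initial frequencies draw from the neutral
SFS (P ∝ 1/i). Outgroups are emitted alongside, with 10% of sites carrying
a derived allele in one outgroup so the polarisation filter has something
to do. Under these defaults the bottleneck purges HIGH-category variants:
normalised HIGH Rxy < 1 in most replicates, the qualitative regime the
temporal analysis is designed to detect.

**Pedigree simulator** (`simulate_pedigree()`). Monogamous discrete
generations at constant census; `min_kinship` pairing greedily picks the
least-related available pair, breaking ties at random (deterministic
tie-breaking silently pairs whole families together, manufacturing double
first cousins — a bug the policy-contrast test caught), falling back with a
warning when every pair exceeds the kinship cap. Genotypes are gene-dropped
from founder haplotypes; because transmissions are dropped once as founder
labels and then translated to alleles, realised IBD and genotypes are
mutually consistent.

**ROH/bin generator** (`simulate_roh_and_bins()`). Tracts of a target age G
get exponential genetic lengths (mean $100/(2G)$ cM), converted at the
configured recombination rate and placed uniformly without overlap until
the target $F_{ROH}$ is met. Bin heterozygosity = baseline (1e-3/bp) ×
shared lognormal bin factor (sd 0.1; chromosomes genuinely vary along
their length) × per-sample lognormal noise (sd 0.25, the scale of
bin-level estimation error from a typical ROH caller) and is collapsed by
98% where a bin is more than half covered by ROH. Injected private regions
multiply one group's heterozygosity by 1 + effect in chosen bins and are
recorded as truth.

What these generators do *not* emulate — linkage and haplotype structure,
sequencing and alignment error, reference bias, ancient-DNA damage,
overlapping generations — bounds what passing tests show: the statistics
are correct and calibrated under their stated assumptions, not that those
assumptions hold in any particular sequencing dataset.

# Numerical and degenerate-input conventions

- Missing genotypes are `NA`, never dosage 0; every aggregation either
  skips and counts them or refuses to proceed.
- Coordinates: BED 0-based half-open, VCF 1-based; conversion happens at
  the boundary, all internal arithmetic is half-open.
- Division-by-zero paths are errors with the offending epoch/category
  named (Rxy denominator, zero-variance predictors, Ft ≤ F0, drift below
  sampling noise), except where the spec of the quantity defines a value
  (all-zero deltas → p = 1; F_ROH ∈ {0,1} → undefined side NA).
- Every stochastic function takes an explicit seed and refuses to run
  without one.

# Problem sizes

The shipped tests run the calibration studies at: 1,000 bins (type-I),
10,000 bins (KS uniformity, prior recovery), 20 replicates × 5,000 SNPs
(NeV recovery), 3,000 sites × 200 generations (neutral decay), and 7
replicates of the full two-epoch simulation (purging regime). These sizes
put Monte-Carlo error well inside the asserted bands while keeping the
whole suite near twenty seconds on one core; scaling them up changes no
conclusion, only the error bars.

# Known limitations

- The s-proxy from score ranks is ordinal at best; load components are
  comparable within a cohort scored the same way, not across scoring
  schemes.
- Pedigree kinship assumes founders unrelated and non-inbred; in a
  population founded after a bottleneck this understates true relatedness
  uniformly.
- The moderated test treats bins as exchangeable units; long-range
  autocorrelation in heterozygosity (real in any genome) makes raw p-values
  anticonservative at fine bin sizes — one reason the BH flag exists.
- `nev()` assumes the two samples are temporally distinct draws from one
  closed population; migration or sample mislabelling biases it upward.
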