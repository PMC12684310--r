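#' Polarise sites by outgroup consensus
#'
#' Keeps only sites at which every outgroup individual is homozygous
#' reference (dosage 0) with no missing genotype — the ancestral state is
#' then the reference allele and any alternative allele in the focal samples
#' is derived. Requiring consensus across all outgroups minimises
#' mispolarisation from lineage-specific substitutions.
#'
#' @param gm focal [genotype_matrix()].
#' @param outgroups [genotype_matrix()] of outgroup individuals over the same
#'   sites (matched on chrom:pos).
#' @return list with `genotypes` (gm restricted to retained sites), `mask`
#'   (logical over input sites) and `report` (retained, total, fraction).
#' @export
polarise <- function(gm, outgroups) {
  stopifnot(inherits(gm, "genotype_matrix"), inherits(outgroups, "genotype_matrix"))
  if (nrow(outgroups$geno) == 0) stop("zero outgroup individuals")
  key <- function(s) paste0(s$chrom, ":", s$pos)
  m <- match(key(gm$sites), key(outgroups$sites))
  if (anyNA(m)) {
    stop("site(s) absent from outgroup matrix: ",
         paste(key(gm$sites)[is.na(m)][1:min(5, sum(is.na(m)))], collapse = ", "))
  }
  og <- outgroups$geno[, m, drop = FALSE]
  mask <- unname(colSums(og == 0L) == nrow(og))  # NA genotypes fail too
  mask[is.na(mask)] <- FALSE
  report <- data.frame(
    retained = sum(mask), total = length(mask),
    fraction = sum(mask) / length(mask)
  )
  list(genotypes = subset_genotypes(gm, sites = mask), mask = mask,
       report = report)
}

#' Per-sample derived-allele load counts for one impact category
#'
#' Counts derived alleles per sample over the sites of one impact category:
#' heterozygous genotypes contribute one allele, homozygous-derived genotypes
#' two. Missing genotypes contribute nothing.
#'
#' @param gm polarised [genotype_matrix()].
#' @param category one of `LOW`, `MODERATE`, `HIGH`.
#' @return data.frame: `sample`, `category`, `het` (allele count from
#'   heterozygotes), `hom` (alleles from homozygotes, i.e. genotypes x 2),
#'   `total`, `n_sites`, `n_missing`.
#' @export
count_load <- function(gm, category) {
  stopifnot(inherits(gm, "genotype_matrix"), length(category) == 1)
  sel <- gm$sites$impact == category
  if (!any(sel)) warning("no sites in category ", category, "; counts are 0")
  g <- gm$geno[, sel, drop = FALSE]
  data.frame(
    sample = gm$samples$id,
    category = category,
    het = rowSums(g == 1L, na.rm = TRUE),
    hom = 2L * rowSums(g == 2L, na.rm = TRUE),
    total = rowSums(g, na.rm = TRUE),
    n_sites = sum(sel),
    n_missing = rowSums(is.na(g)),
    stringsAsFactors = FALSE
  )
}

#' Normalise moderate/high load counts by the low-impact total
#'
#' Dividing each sample's MODERATE and HIGH counts by its own total
#' LOW-impact allele count corrects for differences in variant-discovery
#' power (sequencing depth, DNA quality) between samples and epochs.
#'
#' @param counts data.frame rbind of [count_load()] results including the
#'   `LOW` category.
#' @return `counts` with columns `het_norm`, `hom_norm`, `total_norm` added
#'   (NA for the LOW rows of a sample whose LOW total is 0).
#' @export
normalise_load_counts <- function(counts) {
  low <- counts[counts$category == "LOW", c("sample", "total")]
  if (nrow(low) == 0) stop("LOW category counts required for normalisation")
  denom <- low$total[match(counts$sample, low$sample)]
  denom[denom == 0] <- NA_real_
  counts$het_norm <- counts$het / denom
  counts$hom_norm <- counts$hom / denom
  counts$total_norm <- counts$total / denom
  counts
}

#' Epoch allele-frequency table
#'
#' Derived-allele frequencies per site in two epochs, computed over
#' non-missing genotypes only. Cohort labels are mapped to epochs by the
#' caller.
#'
#' @param gm polarised [genotype_matrix()].
#' @param historical,modern character vectors of cohort labels forming each
#'   epoch.
#' @return data.frame (class `frequency_table`): `chrom`, `pos`, `impact`,
#'   `Fh`, `Fm` (epoch frequencies), `nh`, `nm` (called chromosome counts).
#' @export
frequency_table <- function(gm,
                            historical = "historical",
                            modern = c("founder_wildborn", "early_captive",
                                       "late_captive", "wild")) {
  stopifnot(inherits(gm, "genotype_matrix"))
  hi <- gm$samples$cohort %in% historical
  mi <- gm$samples$cohort %in% modern
  if (!any(hi) || !any(mi)) stop("both epochs need at least one sample")
  freq <- function(g) {
    n <- 2L * colSums(!is.na(g))
    list(f = colSums(g, na.rm = TRUE) / ifelse(n == 0, NA, n), n = n)
  }
  h <- freq(gm$geno[hi, , drop = FALSE])
  m <- freq(gm$geno[mi, , drop = FALSE])
  out <- data.frame(
    chrom = gm$sites$chrom, pos = gm$sites$pos, impact = gm$sites$impact,
    Fh = h$f, Fm = m$f, nh = h$n, nm = m$n,
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  class(out) <- c("frequency_table", "data.frame")
  out
}

#' Allele-frequency change between epochs for one category
#'
#' Delta frequency = F_modern - F_historical per site; sites uncallable
#' (zero called chromosomes) in either epoch are excluded and counted.
#'
#' @param ft a [frequency_table()].
#' @param category impact category to summarise.
#' @return list: `per_site` (data.frame with `delta`), `mean_delta`,
#'   `prop_positive` (fraction of sites with delta > 0), `n_used`,
#'   `n_excluded`.
#' @export
delta_frequency <- function(ft, category) {
  d <- ft[ft$impact == category, , drop = FALSE]
  usable <- d$nh > 0 & d$nm > 0
  d <- d[usable, , drop = FALSE]
  d$delta <- d$Fm - d$Fh
  list(
    per_site = d,
    mean_delta = mean(d$delta),
    prop_positive = mean(d$delta > 0),
    n_used = nrow(d),
    n_excluded = sum(!usable)
  )
}

#' Two-sided sign (binomial) test on frequency changes
#'
#' Tests whether positive and negative per-site frequency changes are equally
#' likely: among the nonzero deltas, the count of positive changes is compared
#' with Binomial(n, 0.5), two-sided. Zero deltas are uninformative for
#' direction and are dropped; if all deltas are zero the test degenerates to
#' p = 1 with a warning.
#'
#' @param deltas numeric vector of per-site frequency changes.
#' @return list: `p.value`, `n_positive`, `n_negative`, `n_zero`.
#' @export
sign_binomial_test <- function(deltas) {
  nz <- deltas[deltas != 0]
  n_pos <- sum(nz > 0)
  n <- length(nz)
  if (n == 0) {
    warning("all deltas are zero; p = 1")
    return(list(p.value = 1, n_positive = 0L, n_negative = 0L,
                n_zero = length(deltas)))
  }
  p <- stats::binom.test(n_pos, n, p = 0.5, alternative = "two.sided")$p.value
  list(p.value = p, n_positive = n_pos, n_negative = n - n_pos,
       n_zero = sum(deltas == 0))
}

# ratio-of-sums Rxy kernel over a frequency subtable
rxy_kernel <- function(Fm, Fh) {
  num <- sum(Fm * (1 - Fh))
  den <- sum(Fh * (1 - Fm))
  if (den == 0) stop("Rxy denominator is zero (historical epoch / category)")
  num / den
}

#' Rxy derived-allele frequency ratio between epochs
#'
#' Rxy = sum_sites Fm (1 - Fh) / sum_sites Fh (1 - Fm), aggregated as a
#' ratio of sums across sites (Do et al. convention; robust to sites fixed in
#' one epoch). Values below 1 indicate a relative frequency deficit of the
#' category in the modern epoch. The category value is normalised by the
#' same ratio computed on the putatively neutral low-impact category, so the
#' normalised LOW value is identically 1.
#'
#' @param ft a [frequency_table()]; only sites callable in both epochs are
#'   used.
#' @param category impact category of interest.
#' @param low_category reference category for normalisation.
#' @return list: `raw`, `raw_low`, `normalised`, `n_sites`.
#' @export
rxy <- function(ft, category, low_category = "LOW") {
  usable <- ft$nh > 0 & ft$nm > 0
  cat_tab <- ft[usable & ft$impact == category, , drop = FALSE]
  low_tab <- ft[usable & ft$impact == low_category, , drop = FALSE]
  if (nrow(cat_tab) == 0) stop("no usable sites in category ", category)
  if (nrow(low_tab) == 0) stop("no usable sites in category ", low_category)
  raw <- rxy_kernel(cat_tab$Fm, cat_tab$Fh)
  raw_low <- rxy_kernel(low_tab$Fm, low_tab$Fh)
  list(raw = raw, raw_low = raw_low, normalised = raw / raw_low,
       n_sites = nrow(cat_tab))
}

#' Delete-d jackknife for the normalised Rxy
#'
#' Sites of the focal category are partitioned into `blocks` blocks of
#' `frac` of the sites each by a seeded permutation; each replicate excludes
#' one block and recomputes the normalised Rxy. The variance is the standard
#' delete-d jackknife estimate, `(n - d) / d` times the variance of the
#' replicate values, which approximates the sampling variance of the full
#' estimate; a percentile interval of the replicates themselves is also
#' returned (note its width reflects the 1% deletions, not the sampling
#' distribution).
#'
#' @param ft a [frequency_table()].
#' @param category focal impact category.
#' @param low_category normalising category.
#' @param blocks number of jackknife replicates (default 100).
#' @param frac fraction of sites removed per replicate (default 0.01).
#' @param seed integer seed for the site permutation.
#' @return list: `estimate` (full-data normalised Rxy), `replicates`,
#'   `variance` (delete-d scaled), `se`, `ci` (normal-approximation 95%),
#'   `ci_percentile`, `blocks`.
#' @export
jackknife_rxy <- function(ft, category, low_category = "LOW",
                          blocks = 100, frac = 0.01, seed) {
  seed <- require_seed(seed)
  usable <- which(ft$nh > 0 & ft$nm > 0 &
                    ft$impact %in% c(category, low_category))
  n <- length(usable)
  d <- floor(frac * n)
  if (d < 1) stop("frac x sites < 1: too few sites (", n, ") for the jackknife")
  if (n < blocks) stop("need at least ", blocks, " sites; have ", n)
  set.seed(seed)
  perm <- sample(usable)
  full <- rxy(ft, category, low_category)$normalised
  reps <- vapply(seq_len(blocks), function(b) {
    drop_idx <- perm[((b - 1L) * d + 1L):(b * d)]
    rxy(ft[-drop_idx, , drop = FALSE], category, low_category)$normalised
  }, numeric(1))
  v_rep <- stats::var(reps)
  v_jack <- (n - d) / d * v_rep
  se <- sqrt(v_jack)
  list(
    estimate = full, replicates = reps, variance = v_jack, se = se,
    ci = full + c(-1, 1) * stats::qnorm(0.975) * se,
    ci_percentile = unname(stats::quantile(reps, c(0.025, 0.975))),
    blocks = blocks
  )
}

#' Homozygous load inside and outside runs of homozygosity
#'
#' Splits each sample's homozygous derived-allele load by ROH membership of
#' the site and normalises the two counts by the genome fractions they could
#' have come from: count-in / F_ROH and count-out / (1 - F_ROH). When a
#' sample has F_ROH of exactly 0 or 1 the undefined side is reported as NA.
#'
#' @param gm polarised [genotype_matrix()].
#' @param category impact category.
#' @param roh a [roh_set()].
#' @param genome_length total assayed genome length in bp.
#' @return data.frame per sample: `hom_in`, `hom_out` (raw allele counts;
#'   their sum is the total homozygous load), `froh`, `in_norm`, `out_norm`.
#' @export
load_in_out_roh <- function(gm, category, roh, genome_length) {
  stopifnot(inherits(gm, "genotype_matrix"))
  sel <- which(gm$sites$impact == category)
  sites_gr <- GenomicRanges::GRanges(
    gm$sites$chrom[sel],
    IRanges::IRanges(start = gm$sites$pos[sel], width = 1L)
  )
  out <- lapply(gm$samples$id, function(sid) {
    ri <- roh[roh$sample == sid, , drop = FALSE]
    inside <- rep(FALSE, length(sel))
    fr <- 0
    if (nrow(ri)) {
      roh_gr <- GenomicRanges::GRanges(
        ri$chrom, IRanges::IRanges(start = ri$start + 1L, end = ri$end)
      )
      inside <- IRanges::overlapsAny(sites_gr, roh_gr)
      fr <- sum(ri$end - ri$start) / genome_length
    }
    g <- gm$geno[gm$samples$id == sid, sel]
    hom_in <- 2L * sum(g[inside] == 2L, na.rm = TRUE)
    hom_out <- 2L * sum(g[!inside] == 2L, na.rm = TRUE)
    data.frame(
      sample = sid, category = category,
      hom_in = hom_in, hom_out = hom_out, froh = fr,
      in_norm = if (fr > 0) hom_in / fr else NA_real_,
      out_norm = if (fr < 1) hom_out / (1 - fr) else NA_real_,
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, out)
}
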