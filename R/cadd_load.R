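#' Invert the PHRED-scaled CADD transform to a rank proportion
#'
#' A CADD-style score is defined as `-10 * log10(n_i / N)`, the PHRED-scaled
#' rank of a candidate mutation among all `N` potential mutations in the
#' scoring genome. This inverts it: a score of 20 corresponds to a rank
#' proportion of 0.01.
#'
#' @param score numeric score(s) >= 0.
#' @return proportion(s) `n_i / N` in (0, 1].
#' @export
chcadd_to_proportion <- function(score) {
  if (any(score < 0)) stop("negative CADD score(s)")
  10^(-score / 10)
}

#' PHRED-scale a rank proportion back to a CADD-style score
#' @param p proportion(s) in (0, 1].
#' @return score(s); exact inverse of [chcadd_to_proportion()].
#' @export
proportion_to_chcadd <- function(p) {
  if (any(p <= 0 | p > 1)) stop("proportion must be in (0, 1]")
  -10 * log10(p)
}

# total candidate mutations across all chicken chromosomes (3 x each base)
CHICKEN_N_MUTATIONS <- 3073805640

#' Selection and dominance proxies from a CADD-style score
#'
#' The score is converted to its absolute rank `n_i = 10^(-score/10) * N`
#' among the `N` potential mutations of the scoring genome, and `s = 1 / n_i`
#' is used as a crude selection-coefficient proxy (higher score, smaller
#' rank, larger s). Dominance is assigned by score bin, encoding a negative
#' s-h relationship (highly deleterious mutations assumed more recessive):
#' h = 0.3 for scores in [0, 10), 0.15 for [10, 20), 0.02 for [20, 30) and 0
#' for scores >= 30. Scores exactly at 10, 20 or 30 fall in the upper
#' (more-deleterious, more-recessive) bin; the defining rule leaves them
#' unassigned, and left-closed bins keep h monotone in the score.
#'
#' @param score numeric score(s) >= 0.
#' @param N total candidate mutations of the scoring genome; the default is
#'   the chicken-genome total 3,073,805,640.
#' @return data.frame: `score`, `proportion`, `n_i`, `s`, `h`.
#' @export
assign_s_h <- function(score, N = CHICKEN_N_MUTATIONS) {
  p <- chcadd_to_proportion(score)
  n_i <- p * N
  h <- c(0.3, 0.15, 0.02, 0)[findInterval(score, c(0, 10, 20, 30))]
  data.frame(score = score, proportion = p, n_i = n_i, s = 1 / n_i, h = h)
}

#' Build the scored-site table used by the load decomposition
#'
#' @param cadd data.frame from [read_cadd()].
#' @param N total candidate mutations (see [assign_s_h()]).
#' @return data.frame (class `scored_sites`): chrom, pos, ref, alt, score,
#'   proportion, n_i, s, h.
#' @export
scored_sites <- function(cadd, N = CHICKEN_N_MUTATIONS) {
  sh <- assign_s_h(cadd$score, N = N)
  out <- cbind(cadd[, c("chrom", "pos", "ref", "alt", "score")],
               sh[, c("proportion", "n_i", "s", "h")])
  class(out) <- c("scored_sites", "data.frame")
  out
}

#' Restrict genotypes and scores to mutually eligible sites
#'
#' Eligibility mirrors the scored-load design: a site must carry a score,
#' match alleles between the score table and the genotype matrix, be
#' genotyped in every sample, and be segregating (not fixed for either
#' allele) across the samples.
#'
#' @param gm a [genotype_matrix()].
#' @param sites a [scored_sites()] table.
#' @return list: `genotypes` (subset gm), `sites` (matching scored subset),
#'   `report` (counts dropped per rule).
#' @export
eligible_scored_sites <- function(gm, sites) {
  key_g <- paste0(gm$sites$chrom, ":", gm$sites$pos)
  key_s <- paste0(sites$chrom, ":", sites$pos)
  m <- match(key_g, key_s)
  has_score <- !is.na(m)
  allele_ok <- has_score
  allele_ok[has_score] <- gm$sites$ancestral[has_score] == sites$ref[m[has_score]] &
    gm$sites$derived[has_score] == sites$alt[m[has_score]]
  complete <- colSums(is.na(gm$geno)) == 0
  dos <- colSums(gm$geno)
  segregating <- !is.na(dos) & dos > 0 & dos < 2L * nrow(gm$geno)
  keep <- allele_ok & complete & segregating
  report <- data.frame(
    sites_in = length(keep),
    no_score = sum(!has_score),
    allele_mismatch = sum(has_score & !allele_ok),
    incomplete = sum(allele_ok & !complete),
    fixed = sum(allele_ok & complete & !segregating),
    retained = sum(keep)
  )
  list(
    genotypes = subset_genotypes(gm, sites = keep),
    sites = sites[m[keep], , drop = FALSE],
    report = report
  )
}

#' Genetic, realised and masked load per sample
#'
#' Per sample, over scored sites with selection proxy `s` and dominance `h`:
#' genetic load GL = sum_hom s + sum_het 0.5 s (the diploid expectation under
#' random transmission), realised load RL = sum_hom s + sum_het h s (the
#' expressed portion), masked load ML = sum_het (0.5 - h) s (the hidden
#' portion). GL = RL + ML holds exactly since 0.5 s = h s + (0.5 - h) s.
#' Missing genotypes are skipped and counted.
#'
#' @param gm [genotype_matrix()] restricted to the scored sites (same order).
#' @param sites [scored_sites()] rows aligned with `gm`'s sites.
#' @return data.frame per sample: `GL`, `RL`, `ML`, `n_sites`, `n_missing`.
#' @export
load_components <- function(gm, sites) {
  stopifnot(inherits(gm, "genotype_matrix"), nrow(sites) == ncol(gm$geno))
  if (any(sites$h > 0.5)) stop("dominance h > 0.5 would make masked load negative")
  if (any(sites$h < 0)) stop("negative dominance h")
  g <- gm$geno
  hom <- g == 2L
  het <- g == 1L
  hom[is.na(hom)] <- FALSE
  het[is.na(het)] <- FALSE
  s <- sites$s
  h <- sites$h
  data.frame(
    sample = gm$samples$id,
    GL = as.vector(hom %*% s + het %*% (0.5 * s)),
    RL = as.vector(hom %*% s + het %*% (h * s)),
    ML = as.vector(het %*% ((0.5 - h) * s)),
    n_sites = ncol(g),
    n_missing = rowSums(is.na(g)),
    stringsAsFactors = FALSE
  )
}

# OLS of y on x returning slope, R^2 and the slope p-value
ols_summary <- function(y, x, component) {
  if (stats::var(x) == 0) stop("zero variance in predictor")
  if (stats::var(y) == 0) {
    # a constant response carries no signal: R^2 = 0 by convention
    return(data.frame(component = component, slope = 0, r.squared = 0,
                      p.value = NA_real_))
  }
  fit <- stats::lm(y ~ x)
  sm <- suppressWarnings(summary(fit))
  data.frame(
    component = component,
    slope = unname(stats::coef(fit)[2]),
    r.squared = sm$r.squared,
    p.value = sm$coefficients[2, 4]
  )
}

#' Regress load components on individual inbreeding (F_ROH)
#'
#' Ordinary least squares of each of GL, RL, ML on F_ROH across samples;
#' a non-significant fit indicates that realised load is not elevated in the
#' more inbred individuals.
#'
#' @param lc data.frame from [load_components()].
#' @param froh named numeric vector of per-sample F_ROH (names = sample ids).
#' @return data.frame: `component`, `slope`, `r.squared`, `p.value`.
#' @export
load_vs_froh <- function(lc, froh) {
  if (nrow(lc) < 3) stop("need at least 3 samples")
  x <- unname(froh[lc$sample])
  if (anyNA(x)) stop("F_ROH missing for sample(s): ",
                     paste(lc$sample[is.na(x)], collapse = ", "))
  do.call(rbind, lapply(c("GL", "RL", "ML"), function(cc)
    ols_summary(lc[[cc]], x, cc)))
}
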