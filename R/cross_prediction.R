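#' Mendelian offspring genotype distribution
#'
#' Exact transmission probabilities for the offspring dosage given two
#' parental dosages at a biallelic site (each parent transmits one allele,
#' heterozygotes with probability 1/2 each).
#'
#' @param g1,g2 parental derived-allele dosages in \{0, 1, 2\}.
#' @return numeric vector of length 3: P(offspring dosage = 0, 1, 2).
#' @export
offspring_genotype_dist <- function(g1, g2) {
  stopifnot(g1 %in% 0:2, g2 %in% 0:2)
  p1 <- g1 / 2  # P(transmit derived)
  p2 <- g2 / 2
  c(`0` = (1 - p1) * (1 - p2),
    `1` = p1 * (1 - p2) + (1 - p1) * p2,
    `2` = p1 * p2)
}

# expected per-site load contributions under the offspring distribution
site_expected_components <- function(p_dist, s, h) {
  e_hom <- p_dist[3]
  e_het <- p_dist[2]
  c(GL = e_hom * s + e_het * 0.5 * s,
    RL = e_hom * s + e_het * h * s,
    ML = e_het * (0.5 - h) * s)
}

#' Expected offspring load components for one pairing
#'
#' For each scored site genotyped in both parents, takes the expectation of
#' the genetic/realised/masked load contribution over the Mendelian
#' offspring genotype distribution and sums across sites. Sites with a
#' missing genotype in either parent are dropped pairwise and counted.
#'
#' @param g1,g2 parental dosage vectors over the scored sites (NA = missing).
#' @param sites [scored_sites()] rows aligned with the dosage vectors.
#' @return list: `GL`, `RL`, `ML` (expected sums; GL = RL + ML exactly),
#'   `n_sites_used`, `n_dropped`.
#' @export
expected_offspring_load <- function(g1, g2, sites) {
  stopifnot(length(g1) == length(g2), length(g1) == nrow(sites))
  use <- !is.na(g1) & !is.na(g2)
  if (!any(use)) stop("no shared genotyped sites between the parents")
  p1 <- g1[use] / 2
  p2 <- g2[use] / 2
  e_hom <- p1 * p2
  e_het <- p1 * (1 - p2) + (1 - p1) * p2
  s <- sites$s[use]
  h <- sites$h[use]
  list(
    GL = sum(e_hom * s + e_het * 0.5 * s),
    RL = sum(e_hom * s + e_het * h * s),
    ML = sum(e_het * (0.5 - h) * s),
    n_sites_used = sum(use),
    n_dropped = sum(!use)
  )
}

#' Sample offspring load components by simulated segregation
#'
#' Seeded sampling counterpart of [expected_offspring_load()] for
#' distribution plots: draws `n` offspring by Mendelian segregation and
#' returns their realised component values.
#'
#' @param g1,g2 parental dosage vectors.
#' @param sites [scored_sites()] rows aligned with the dosages.
#' @param n number of offspring to draw.
#' @param seed integer seed.
#' @return data.frame with `GL`, `RL`, `ML`, one row per offspring.
#' @export
sample_offspring_load <- function(g1, g2, sites, n = 100, seed) {
  seed <- require_seed(seed)
  set.seed(seed)
  use <- !is.na(g1) & !is.na(g2)
  if (!any(use)) stop("no shared genotyped sites between the parents")
  s <- sites$s[use]
  h <- sites$h[use]
  p1 <- g1[use] / 2
  p2 <- g2[use] / 2
  L <- sum(use)
  out <- matrix(0, n, 3, dimnames = list(NULL, c("GL", "RL", "ML")))
  for (k in seq_len(n)) {
    dos <- (stats::runif(L) < p1) + (stats::runif(L) < p2)
    hom <- dos == 2
    het <- dos == 1
    out[k, ] <- c(sum(s[hom]) + 0.5 * sum(s[het]),
                  sum(s[hom]) + sum(h[het] * s[het]),
                  sum((0.5 - h[het]) * s[het]))
  }
  as.data.frame(out)
}

#' Predict and rank hypothetical crosses by expected realised load
#'
#' Enumerates candidate parent pairs, classifies each cross from the parental
#' cohorts (`wild x wild`, `captive x captive`, `captive x wild`), computes
#' expected offspring load components under Mendelian segregation, and ranks
#' by expected realised load (ascending: best first). Reduction summaries
#' compare the best cross of one class against the worst of another
#' (`(worst - best) / worst`), and the best cross overall against the mean of
#' the `k` lowest-kinship pairs when a kinship matrix is supplied —
#' quantifying what genotype-informed pairing adds over pedigree-only
#' choices.
#'
#' @param gm [genotype_matrix()] over the scored sites (samples = candidate
#'   parents; cohort labels starting `wild` count as wild, everything else as
#'   captive).
#' @param sites [scored_sites()] aligned with `gm`'s sites.
#' @param pairs optional two-column matrix/data.frame of parent ids; default
#'   all unordered pairs (self-crosses excluded unless `allow_self`).
#' @param kinship_matrix optional pedigree kinship matrix for the top-k
#'   comparison.
#' @param k number of lowest-kinship pairs for that comparison.
#' @param allow_self include self-crosses.
#' @return list: `crosses` (ranked data.frame with class, E[GL/RL/ML],
#'   kinship when available) and `summary` (named reductions).
#' @export
rank_crosses <- function(gm, sites, pairs = NULL, kinship_matrix = NULL,
                         k = 5, allow_self = FALSE) {
  stopifnot(inherits(gm, "genotype_matrix"))
  ids <- gm$samples$id
  if (is.null(pairs)) {
    idx <- utils::combn(seq_along(ids), 2)
    pairs <- data.frame(p1 = ids[idx[1, ]], p2 = ids[idx[2, ]],
                        stringsAsFactors = FALSE)
  } else {
    pairs <- data.frame(p1 = as.character(pairs[[1]]),
                        p2 = as.character(pairs[[2]]),
                        stringsAsFactors = FALSE)
  }
  if (!allow_self) pairs <- pairs[pairs$p1 != pairs$p2, , drop = FALSE]
  if (nrow(pairs) < 2) stop("need at least 2 candidate pairs")
  is_wild <- function(sid) {
    startsWith(gm$samples$cohort[match(sid, ids)], "wild")
  }
  cls <- function(a, b) {
    w <- is_wild(a) + is_wild(b)
    c("captive x captive", "captive x wild", "wild x wild")[w + 1L]
  }
  rows <- lapply(seq_len(nrow(pairs)), function(r) {
    a <- pairs$p1[r]
    b <- pairs$p2[r]
    eo <- expected_offspring_load(gm$geno[match(a, ids), ],
                                  gm$geno[match(b, ids), ], sites)
    data.frame(p1 = a, p2 = b, class = cls(a, b),
               EGL = eo$GL, ERL = eo$RL, EML = eo$ML,
               n_sites = eo$n_sites_used,
               kinship = if (!is.null(kinship_matrix) &&
                             all(c(a, b) %in% rownames(kinship_matrix)))
                 kinship_matrix[a, b] else NA_real_,
               stringsAsFactors = FALSE)
  })
  crosses <- do.call(rbind, rows)
  crosses <- crosses[order(crosses$ERL), , drop = FALSE]
  rownames(crosses) <- NULL

  reduction <- function(best, worst) (worst - best) / worst
  best_of <- function(cl) {
    v <- crosses$ERL[crosses$class == cl]
    if (length(v)) min(v) else NA_real_
  }
  worst_of <- function(cl) {
    v <- crosses$ERL[crosses$class == cl]
    if (length(v)) max(v) else NA_real_
  }
  summary <- c(
    rl_reduction_cw_vs_worst_cc =
      reduction(best_of("captive x wild"), worst_of("captive x captive")),
    rl_reduction_cw_vs_worst_ww =
      reduction(best_of("captive x wild"), worst_of("wild x wild")),
    rl_reduction_best_vs_worst_overall =
      reduction(min(crosses$ERL), max(crosses$ERL))
  )
  if (any(!is.na(crosses$kinship))) {
    ranked_kin <- crosses[order(crosses$kinship), , drop = FALSE]
    topk <- utils::head(ranked_kin, k)
    summary <- c(summary,
                 rl_reduction_best_vs_topk_kinship =
                   reduction(min(crosses$ERL), mean(topk$ERL)))
  }
  list(crosses = crosses, summary = summary)
}

#' Regress expected offspring load on parental relatedness
#'
#' OLS of each expected component on relatedness across candidate crosses;
#' a positive realised-load slope means offspring of related pairs express
#' more load (masked load converted to realised load by inbreeding).
#'
#' @param crosses data.frame from [rank_crosses()] (or any table with
#'   `EGL`, `ERL`, `EML`).
#' @param relatedness numeric vector aligned with `crosses` rows (defaults to
#'   its `kinship` column).
#' @return data.frame: `component`, `slope`, `r.squared`, `p.value`.
#' @export
load_vs_relatedness <- function(crosses, relatedness = crosses$kinship) {
  if (nrow(crosses) < 3) stop("need at least 3 predictions")
  if (anyNA(relatedness)) stop("relatedness missing for some crosses")
  comp <- c(GL = "EGL", RL = "ERL", ML = "EML")
  do.call(rbind, lapply(names(comp), function(cc)
    ols_summary(crosses[[comp[[cc]]]], relatedness, cc)))
}
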