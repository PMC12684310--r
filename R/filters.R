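#' Apply per-genotype and per-site filters
#'
#' Genotypes failing the read-depth window or minimum genotype quality are set
#' to missing (the matrices must be present when the corresponding threshold
#' is enabled); sites whose genotyping rate then falls below the configured
#' minimum are dropped. Missingness introduced here is indistinguishable
#' downstream from missingness in the input — by design, since every
#' aggregation in this package handles missing genotypes explicitly.
#'
#' @param gm a [genotype_matrix()].
#' @param cfg a [run_config()]; `depth_min`/`depth_max` apply when `gm$depth`
#'   is present, `gq_min` when `gm$gq` is present, `genotyping_rate` always.
#' @return list with `genotypes` (filtered matrix; possibly 0 sites, with a
#'   warning) and `report` (one-row data.frame of per-filter counts; note
#'   `sites_kept + sites_dropped_rate = sites_in`).
#' @export
apply_site_filters <- function(gm, cfg = run_config()) {
  stopifnot(inherits(gm, "genotype_matrix"))
  geno <- gm$geno
  n_depth <- 0L
  n_gq <- 0L
  if (!is.null(gm$depth)) {
    fail <- !is.na(geno) & (is.na(gm$depth) | gm$depth < cfg$depth_min |
                              gm$depth > cfg$depth_max)
    n_depth <- sum(fail)
    geno[fail] <- NA_integer_
  }
  if (!is.null(gm$gq)) {
    fail <- !is.na(geno) & (is.na(gm$gq) | gm$gq < cfg$gq_min)
    n_gq <- sum(fail)
    geno[fail] <- NA_integer_
  }
  rate <- colMeans(!is.na(geno))
  keep <- rate >= cfg$genotyping_rate
  if (!any(keep)) warning("all sites removed by filters; returning empty matrix")
  out <- genotype_matrix(
    geno[, keep, drop = FALSE], gm$samples, gm$sites[keep, , drop = FALSE],
    depth = if (!is.null(gm$depth)) gm$depth[, keep, drop = FALSE],
    gq = if (!is.null(gm$gq)) gm$gq[, keep, drop = FALSE]
  )
  report <- data.frame(
    sites_in = ncol(gm$geno),
    genotypes_failed_depth = n_depth,
    genotypes_failed_gq = n_gq,
    sites_dropped_rate = sum(!keep),
    sites_kept = sum(keep)
  )
  list(genotypes = out, report = report)
}

#' Impose the load-analysis depth window as extra per-genotype missingness
#'
#' The load statistics use a stricter, epoch-specific depth window than the
#' general genotype filters: minimum 5 and a maximum of twice the average
#' coverage of the epoch (20 for modern, 16 for historical in the default
#' design). Genotypes outside the window for their sample's epoch are set to
#' missing; sites are not dropped here.
#'
#' @param gm a [genotype_matrix()] with a depth matrix.
#' @param epoch_of named character vector mapping cohort label to `"modern"`
#'   or `"historical"`.
#' @param depth_min minimum depth (applies to both epochs).
#' @param depth_max named numeric, maxima per epoch.
#' @return the genotype matrix with failing genotypes set to missing.
#' @export
apply_load_depth_window <- function(gm,
                                    epoch_of = c(historical = "historical",
                                                 founder_wildborn = "modern",
                                                 early_captive = "modern",
                                                 late_captive = "modern",
                                                 wild = "modern"),
                                    depth_min = 5,
                                    depth_max = c(modern = 20, historical = 16)) {
  stopifnot(inherits(gm, "genotype_matrix"))
  if (is.null(gm$depth)) stop("depth matrix required for the load depth window")
  epoch <- unname(epoch_of[gm$samples$cohort])
  if (anyNA(epoch)) {
    stop("cohort(s) without an epoch mapping: ",
         paste(unique(gm$samples$cohort[is.na(epoch)]), collapse = ", "))
  }
  dmax <- depth_max[epoch]
  geno <- gm$geno
  fail <- !is.na(geno) & (is.na(gm$depth) | gm$depth < depth_min |
                            gm$depth > dmax)
  geno[fail] <- NA_integer_
  genotype_matrix(geno, gm$samples, gm$sites, depth = gm$depth, gq = gm$gq)
}
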