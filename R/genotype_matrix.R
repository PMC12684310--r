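#' Genotype matrix with polarised sites and cohort labels
#'
#' The central container of the package: a samples-by-sites matrix of derived
#' allele dosages (0, 1, 2 or `NA` for missing) together with per-site
#' metadata (chromosome, 1-based position, ancestral/derived allele, predicted
#' impact category) and per-sample cohort labels. Optional per-genotype read
#' depth and genotype quality matrices support the site/genotype filters.
#'
#' @param geno integer matrix, samples in rows, sites in columns; values in
#'   \{0, 1, 2, NA\}. Dosage counts copies of the *derived* allele.
#' @param samples data.frame with columns `id` and `cohort`. Recognised cohort
#'   labels are `historical`, `founder_wildborn`, `early_captive`,
#'   `late_captive` and `wild`, but any label is accepted.
#' @param sites data.frame with columns `chrom`, `pos` (1-based), `ancestral`,
#'   `derived`, `impact` (one of `LOW`, `MODERATE`, `HIGH`, `NONE`).
#' @param depth,gq optional numeric matrices of the same shape as `geno`.
#'
#' @return an object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(geno, samples, sites, depth = NULL, gq = NULL) {
  geno <- as.matrix(geno)
  storage.mode(geno) <- "integer"
  samples <- as.data.frame(samples, stringsAsFactors = FALSE)
  sites <- as.data.frame(sites, stringsAsFactors = FALSE)
  stopifnot(
    all(c("id", "cohort") %in% names(samples)),
    all(c("chrom", "pos", "ancestral", "derived", "impact") %in% names(sites)),
    nrow(geno) == nrow(samples),
    ncol(geno) == nrow(sites)
  )
  bad <- !(geno %in% c(0L, 1L, 2L) | is.na(geno))
  if (any(bad)) {
    stop("genotype dosages must be 0, 1, 2 or NA; found: ",
         paste(unique(geno[bad]), collapse = ", "))
  }
  if (anyDuplicated(samples$id)) {
    stop("duplicated sample ids: ",
         paste(unique(samples$id[duplicated(samples$id)]), collapse = ", "))
  }
  ok_imp <- sites$impact %in% c("LOW", "MODERATE", "HIGH", "NONE")
  if (!all(ok_imp)) {
    stop("unknown impact label(s): ",
         paste(unique(sites$impact[!ok_imp]), collapse = ", "))
  }
  for (m in list(depth, gq)) {
    if (!is.null(m)) stopifnot(all(dim(m) == dim(geno)))
  }
  rownames(geno) <- samples$id
  colnames(geno) <- if (nrow(sites)) paste0(sites$chrom, ":", sites$pos)
  structure(
    list(geno = geno, samples = samples, sites = sites,
         depth = depth, gq = gq),
    class = "genotype_matrix"
  )
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat("genotype_matrix:", nrow(x$geno), "samples x", ncol(x$geno), "sites\n")
  cat("  cohorts:", paste(sprintf("%s (%d)", names(table(x$samples$cohort)),
                                  table(x$samples$cohort)), collapse = ", "), "\n")
  cat("  impact:", paste(sprintf("%s (%d)", names(table(x$sites$impact)),
                                 table(x$sites$impact)), collapse = ", "), "\n")
  miss <- mean(is.na(x$geno))
  cat(sprintf("  missing genotypes: %.1f%%\n", 100 * miss))
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$geno)

#' Subset a genotype matrix by samples and/or sites
#'
#' @param gm a [genotype_matrix()].
#' @param samples logical/integer/character index into samples.
#' @param sites logical/integer index into sites.
#' @return a `genotype_matrix` restricted to the selection.
#' @export
subset_genotypes <- function(gm, samples = NULL, sites = NULL) {
  stopifnot(inherits(gm, "genotype_matrix"))
  si <- if (is.null(samples)) seq_len(nrow(gm$geno)) else samples
  if (is.character(si)) si <- match(si, gm$samples$id)
  vi <- if (is.null(sites)) seq_len(ncol(gm$geno)) else sites
  genotype_matrix(
    gm$geno[si, vi, drop = FALSE],
    gm$samples[si, , drop = FALSE],
    gm$sites[vi, , drop = FALSE],
    depth = if (!is.null(gm$depth)) gm$depth[si, vi, drop = FALSE],
    gq = if (!is.null(gm$gq)) gm$gq[si, vi, drop = FALSE]
  )
}
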