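#' Read a genotype matrix from a VCF (or package TSV) file
#'
#' Dosages are computed relative to the declared derived allele, which for a
#' polarised VCF is the single ALT allele. Multiallelic records are rejected
#' by name rather than silently dropped: polarisation into one ancestral and
#' one derived allele is a precondition of every load statistic downstream.
#' Missing genotypes (`./.`) are preserved as `NA`, distinct from dosage 0.
#' FORMAT `DP` and `GQ` fields are honoured when present so that the
#' per-genotype filters in [apply_site_filters()] can act on them.
#'
#' The site impact category is taken from an `IMPACT=` key in the INFO column
#' (`NONE` when absent).
#'
#' @param path VCF file (plain text or bgzip).
#' @param cohort_map data.frame with columns `id`, `cohort` covering every
#'   sample in the file, or `NULL` to label every sample `unspecified`
#'   (sufficient for outgroup panels, which need no cohort).
#' @return a [genotype_matrix()].
#' @export
read_genotypes <- function(path, cohort_map = NULL) {
  if (!is.null(cohort_map)) {
    stopifnot(all(c("id", "cohort") %in% names(cohort_map)))
  }
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  multi <- grepl(",", fix$ALT)
  if (any(multi)) {
    stop("multiallelic site(s) not allowed: ",
         paste(paste0(fix$CHROM[multi], ":", fix$POS[multi]), collapse = ", "))
  }
  gt <- vcfR::extract.gt(v, element = "GT")
  sample_ids <- colnames(gt)
  if (is.null(cohort_map)) {
    cohort_map <- data.frame(id = sample_ids, cohort = "unspecified",
                             stringsAsFactors = FALSE)
  }
  missing_in_map <- setdiff(sample_ids, cohort_map$id)
  if (length(missing_in_map)) {
    stop("sample(s) absent from cohort_map: ",
         paste(missing_in_map, collapse = ", "))
  }
  # count derived (ALT) alleles; any genotype containing '.' is missing
  dos <- function(g) {
    out <- rep(NA_integer_, length(g))
    ok <- !is.na(g) & !grepl("\\.", g)
    alleles <- strsplit(gsub("\\|", "/", g[ok]), "/", fixed = FALSE)
    out[ok] <- vapply(alleles, function(a) sum(a == "1"), integer(1))
    out
  }
  geno <- t(matrix(dos(as.vector(gt)), nrow = nrow(gt)))  # samples x sites
  extract_num <- function(el) {
    if (!el %in% vcfR::vcf_field_names(v, tag = "FORMAT")$ID) return(NULL)
    m <- vcfR::extract.gt(v, element = el, as.numeric = TRUE)
    t(m)
  }
  depth <- extract_num("DP")
  gq <- extract_num("GQ")
  impact <- rep("NONE", nrow(fix))
  has <- grepl("IMPACT=", fix$INFO %||% "")
  impact[has] <- sub(".*IMPACT=([A-Z]+).*", "\\1", fix$INFO[has])
  sites <- data.frame(
    chrom = fix$CHROM, pos = as.integer(fix$POS),
    ancestral = fix$REF, derived = fix$ALT, impact = impact,
    stringsAsFactors = FALSE
  )
  samples <- data.frame(
    id = sample_ids,
    cohort = cohort_map$cohort[match(sample_ids, cohort_map$id)],
    stringsAsFactors = FALSE
  )
  genotype_matrix(geno, samples, sites, depth = depth, gq = gq)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a genotype matrix as a plain-text VCF
#'
#' Emits a minimal VCFv4.2 with GT (and DP/GQ when stored) so that
#' [read_genotypes()] round-trips the matrix exactly.
#'
#' @param gm a [genotype_matrix()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_genotype_vcf <- function(gm, path) {
  stopifnot(inherits(gm, "genotype_matrix"))
  has_dp <- !is.null(gm$depth)
  has_gq <- !is.null(gm$gq)
  fmt <- paste(c("GT", if (has_dp) "DP", if (has_gq) "GQ"), collapse = ":")
  hdr <- c(
    "##fileformat=VCFv4.2",
    "##source=cranecap",
    "##INFO=<ID=IMPACT,Number=1,Type=String,Description=\"Predicted impact category\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    if (has_dp) "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    if (has_gq) "##FORMAT=<ID=GQ,Number=1,Type=Integer,Description=\"Genotype quality\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", gm$samples$id), collapse = "\t")
  )
  gt_str <- c("0/0", "0/1", "1/1")
  rows <- vapply(seq_len(ncol(gm$geno)), function(j) {
    g <- gm$geno[, j]
    cells <- ifelse(is.na(g), "./.", gt_str[g + 1L])
    if (has_dp) cells <- paste(cells, ifelse(is.na(gm$depth[, j]), ".", gm$depth[, j]), sep = ":")
    if (has_gq) cells <- paste(cells, ifelse(is.na(gm$gq[, j]), ".", gm$gq[, j]), sep = ":")
    paste(c(gm$sites$chrom[j], gm$sites$pos[j], ".", gm$sites$ancestral[j],
            gm$sites$derived[j], ".", "PASS",
            paste0("IMPACT=", gm$sites$impact[j]), fmt, cells), collapse = "\t")
  }, character(1))
  writeLines(c(hdr, rows), path)
  invisible(path)
}

#' Read per-sample ROH intervals from BED
#'
#' BED is 0-based half-open; the 4th column carries the sample id. Intervals
#' are sorted and overlapping/adjacent intervals are merged per sample and
#' chromosome (with a warning, since a well-formed ROH caller output should
#' already be disjoint).
#'
#' @param path BED file with columns chrom, start, end, sample.
#' @return a data.frame (class `roh_set`) with columns
#'   `sample`, `chrom`, `start`, `end`, sorted, disjoint within sample.
#' @export
read_roh <- function(path) {
  bed <- utils::read.table(path, sep = "\t", header = FALSE,
                           stringsAsFactors = FALSE)
  if (ncol(bed) < 4) stop("ROH BED needs 4 columns: chrom, start, end, sample")
  names(bed)[1:4] <- c("chrom", "start", "end", "sample")
  if (any(bed$end <= bed$start)) stop("BED interval with end <= start")
  roh_set(bed[, c("sample", "chrom", "start", "end")])
}

#' Build a validated ROH set (sorted, merged per sample)
#'
#' @param df data.frame with columns `sample`, `chrom`, `start`, `end`
#'   (0-based half-open).
#' @return the merged, sorted `roh_set` data.frame.
#' @export
roh_set <- function(df) {
  stopifnot(all(c("sample", "chrom", "start", "end") %in% names(df)))
  if (nrow(df) == 0) {
    out <- data.frame(sample = character(), chrom = character(),
                      start = integer(), end = integer())
    class(out) <- c("roh_set", "data.frame")
    return(out)
  }
  pieces <- split(df, list(df$sample, df$chrom), drop = TRUE)
  merged_any <- FALSE
  out <- lapply(pieces, function(p) {
    ir <- IRanges::IRanges(start = p$start + 1L, end = p$end)  # to 1-based closed
    red <- IRanges::reduce(ir)
    if (length(red) < length(ir)) merged_any <<- TRUE
    data.frame(sample = p$sample[1], chrom = p$chrom[1],
               start = IRanges::start(red) - 1L, end = IRanges::end(red),
               stringsAsFactors = FALSE)
  })
  if (merged_any) warning("overlapping/adjacent ROH intervals were merged")
  out <- do.call(rbind, out)
  out <- out[order(out$sample, out$chrom, out$start), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("roh_set", "data.frame")
  out
}

#' Write an ROH set as BED
#' @param roh a [roh_set()].
#' @param path output BED path.
#' @return `path`, invisibly.
#' @export
write_roh_bed <- function(roh, path) {
  utils::write.table(roh[, c("chrom", "start", "end", "sample")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' Read binned heterozygosity (long TSV) into a bins-by-samples matrix
#'
#' Expected columns: `chrom`, `start`, `end`, `sample`, `het` — the per-bin
#' local heterozygosity estimates an ROH caller emits. All samples must cover
#' the same bins.
#'
#' @param path TSV with a header.
#' @return a `bin_het` object: list with `bins` (chrom, start, end) and
#'   `het` (matrix, bins x samples).
#' @export
read_bin_het <- function(path) {
  d <- utils::read.table(path, sep = "\t", header = TRUE,
                         stringsAsFactors = FALSE)
  need <- c("chrom", "start", "end", "sample", "het")
  if (!all(need %in% names(d))) {
    stop("bin-het TSV must have columns: ", paste(need, collapse = ", "))
  }
  bin_het(d)
}

#' Assemble a bin_het object from a long data.frame
#' @param d data.frame with chrom, start, end, sample, het.
#' @return a `bin_het` object (see [read_bin_het()]).
#' @export
bin_het <- function(d) {
  if (any(d$het < 0, na.rm = TRUE)) stop("negative heterozygosity value(s)")
  key <- paste(d$chrom, d$start, d$end, sep = ":")
  bins_key <- unique(key)
  samples <- unique(d$sample)
  het <- matrix(NA_real_, nrow = length(bins_key), ncol = length(samples),
                dimnames = list(bins_key, samples))
  het[cbind(match(key, bins_key), match(d$sample, samples))] <- d$het
  first <- !duplicated(key)
  bins <- data.frame(chrom = d$chrom[first], start = d$start[first],
                     end = d$end[first], stringsAsFactors = FALSE)
  structure(list(bins = bins, het = het), class = "bin_het")
}

#' Write a bin_het object as long TSV
#' @param bh a `bin_het` object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_bin_het <- function(bh, path) {
  long <- data.frame(
    chrom = rep(bh$bins$chrom, ncol(bh$het)),
    start = rep(bh$bins$start, ncol(bh$het)),
    end = rep(bh$bins$end, ncol(bh$het)),
    sample = rep(colnames(bh$het), each = nrow(bh$het)),
    het = as.vector(bh$het),
    stringsAsFactors = FALSE
  )
  utils::write.table(long, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a per-site deleteriousness (CADD-style) score table
#'
#' @param path TSV with header columns `chrom`, `pos`, `ref`, `alt`, `score`.
#' @return data.frame with those columns; `score` numeric and >= 0.
#' @export
read_cadd <- function(path) {
  d <- utils::read.table(path, sep = "\t", header = TRUE,
                         stringsAsFactors = FALSE, colClasses = "character")
  need <- c("chrom", "pos", "ref", "alt", "score")
  if (!all(need %in% names(d))) {
    stop("CADD TSV must have columns: ", paste(need, collapse = ", "))
  }
  score <- suppressWarnings(as.numeric(d$score))
  if (anyNA(score)) {
    # +1 for the header line
    stop("non-numeric CADD score at line(s): ",
         paste(which(is.na(score)) + 1L, collapse = ", "))
  }
  if (any(score < 0)) stop("negative CADD score(s)")
  data.frame(chrom = d$chrom, pos = as.integer(d$pos), ref = d$ref,
             alt = d$alt, score = score, stringsAsFactors = FALSE)
}

#' Write a CADD-style score table
#' @param d data.frame as returned by [read_cadd()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_cadd <- function(d, path) {
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a studbook pedigree from CSV
#'
#' Expected columns: `id`, `sire`, `dam`, `sex`, `cohort`; unknown parents as
#' empty string or `NA`. Cycles are reported with the offending path.
#'
#' @param path CSV with a header.
#' @return a [pedigree()] object.
#' @export
read_pedigree <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE,
                       colClasses = "character")
  need <- c("id", "sire", "dam")
  if (!all(need %in% names(d))) {
    stop("pedigree CSV must have columns: ", paste(need, collapse = ", "))
  }
  pedigree(id = d$id, sire = d$sire, dam = d$dam,
           sex = d$sex %||% NULL, cohort = d$cohort %||% NULL)
}

#' Write a pedigree as CSV
#' @param ped a [pedigree()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_pedigree <- function(ped, path) {
  d <- as.data.frame(ped)
  d$sire[is.na(d$sire)] <- ""
  d$dam[is.na(d$dam)] <- ""
  utils::write.csv(d, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a report table as TSV with a commented provenance header
#'
#' @param d data.frame.
#' @param path output path.
#' @param seed seed used for the run (or NA for deterministic steps).
#' @return `path`, invisibly.
#' @export
write_report_tsv <- function(d, path, seed = NA) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# cranecap %s; seed=%s",
                     as.character(utils::packageVersion("cranecap")),
                     as.character(seed)), con)
  utils::write.table(d, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
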