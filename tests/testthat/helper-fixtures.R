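# Fixture builders shared across the test files. Everything is generated in
# code; no data files.

# small genotype matrix with optional depth/GQ matrices
toy_gm <- function(geno, cohort = NULL, impact = NULL, depth = NULL, gq = NULL) {
  geno <- as.matrix(geno)
  n <- nrow(geno)
  L <- ncol(geno)
  genotype_matrix(
    geno,
    samples = data.frame(
      id = sprintf("s%02d", seq_len(n)),
      cohort = cohort %||% rep("wild", n)
    ),
    sites = data.frame(
      chrom = "chr1", pos = seq_len(L) * 100L,
      ancestral = "A", derived = "T",
      impact = impact %||% rep("LOW", L)
    ),
    depth = depth, gq = gq
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# frequency table straight from per-site epoch frequencies
toy_ft <- function(Fh, Fm, impact = "HIGH", nh = 32L, nm = 74L) {
  out <- data.frame(
    chrom = "chr1", pos = seq_along(Fh) * 100L, impact = impact,
    Fh = Fh, Fm = Fm, nh = nh, nm = nm, stringsAsFactors = FALSE
  )
  class(out) <- c("frequency_table", "data.frame")
  out
}

# HW diploid sample at given frequencies
draw_genotypes_test <- function(p, n) {
  matrix(stats::rbinom(n * length(p), 2L, rep(p, each = n)), nrow = n)
}

rbind_ft <- function(...) {
  out <- do.call(rbind, lapply(list(...), as.data.frame))
  class(out) <- c("frequency_table", "data.frame")
  out
}

# random pedigree: founders plus `extra` individuals with parents drawn from
# earlier individuals (valid DAG by construction)
random_pedigree <- function(n_founders, extra, seed) {
  set.seed(seed)
  id <- sprintf("I%03d", seq_len(n_founders + extra))
  sire <- rep(NA_character_, n_founders + extra)
  dam <- sire
  for (i in (n_founders + 1):(n_founders + extra)) {
    par <- sample(seq_len(i - 1), 2)
    sire[i] <- id[par[1]]
    dam[i] <- id[par[2]]
  }
  pedigree(id, sire, dam)
}

# write a VCF from raw lines
write_vcf_lines <- function(body, samples = c("s1", "s2", "s3")) {
  path <- tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t"),
    body
  ), path)
  path
}
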