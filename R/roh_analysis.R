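#' Fraction of the genome in runs of homozygosity
#'
#' F_ROH = total merged ROH length / assayed genome length. Intervals are
#' merged via [roh_set()] semantics before summing, so overlapping input
#' cannot inflate the fraction.
#'
#' @param roh a [roh_set()] (one or more samples).
#' @param genome_length assayed genome length in bp (> 0); may also be a
#'   named vector of chromosome lengths, in which case intervals beyond a
#'   chromosome end are an error.
#' @return named numeric vector of F_ROH per sample present in `roh`.
#' @export
froh <- function(roh, genome_length) {
  if (is.null(names(genome_length))) {
    total <- genome_length
    stopifnot(length(genome_length) == 1, genome_length > 0)
  } else {
    total <- sum(genome_length)
    lim <- genome_length[roh$chrom]
    if (anyNA(lim)) stop("interval on unknown chromosome: ",
                         paste(unique(roh$chrom[is.na(lim)]), collapse = ", "))
    if (any(roh$end > lim)) stop("interval beyond chromosome end")
  }
  lens <- tapply(roh$end - roh$start, roh$sample, sum)
  out <- as.vector(lens) / total
  names(out) <- names(lens)
  if (any(out > 1)) stop("F_ROH > 1: genome length smaller than ROH total")
  out
}

#' Expected coalescence age of an ROH of a given length
#'
#' An autozygous tract inherited from an ancestor G generations back has
#' expected genetic length 100 / (2 G) cM, so a tract of length `l` bp maps
#' to G = 100 / (2 * cM(l)) with cM(l) = Mb(l) * rate. Longer ROH are
#' younger; doubling the length halves G.
#'
#' @param length_bp tract length(s) in bp (> 0).
#' @param rec_rate_cM_per_Mb recombination rate (> 0); the package default is
#'   3.42 cM/Mb.
#' @return generations back to the common ancestor (numeric).
#' @export
roh_age <- function(length_bp, rec_rate_cM_per_Mb = 3.42) {
  if (any(length_bp <= 0)) stop("tract length must be positive")
  if (rec_rate_cM_per_Mb <= 0) stop("recombination rate must be positive")
  cm <- (length_bp / 1e6) * rec_rate_cM_per_Mb
  100 / (2 * cm)
}

#' Stratify F_ROH by tract size and coalescence-time bin
#'
#' Assigns every interval to exactly one size class (shorter vs at least
#' `size_threshold`) and one generation bin via [roh_age()], and reports the
#' per-class F_ROH. Class sums conserve the total by construction. Tracts
#' older than the last finite bin edge go to the open-ended last bin; the
#' default bins (0,2], (2,4], (4,8], (8,16], (16, Inf) follow the doubling
#' scheme in which the oldest informative class is 8-16 generations.
#'
#' @param roh a [roh_set()].
#' @param genome_length assayed genome length in bp.
#' @param rec_rate_cM_per_Mb recombination rate for the age conversion.
#' @param size_threshold size-class boundary in bp (default 10 Mb).
#' @param generation_bins increasing numeric vector of bin edges (left-open
#'   intervals; a final `Inf` is appended if absent).
#' @return list: `by_size` (data.frame sample x size class F_ROH),
#'   `by_age` (data.frame sample x generation bin F_ROH), `total` (named
#'   F_ROH vector).
#' @export
stratify_roh <- function(roh, genome_length, rec_rate_cM_per_Mb = 3.42,
                         size_threshold = 10e6,
                         generation_bins = c(0, 2, 4, 8, 16, Inf)) {
  if (is.unsorted(generation_bins, strictly = TRUE)) {
    stop("generation_bins must be strictly increasing")
  }
  if (!is.infinite(generation_bins[length(generation_bins)])) {
    generation_bins <- c(generation_bins, Inf)
  }
  len <- roh$end - roh$start
  size_class <- ifelse(len >= size_threshold,
                       sprintf(">=%.0fMb", size_threshold / 1e6),
                       sprintf("<%.0fMb", size_threshold / 1e6))
  g <- roh_age(len, rec_rate_cM_per_Mb)
  age_lab <- paste0("(", utils::head(generation_bins, -1), ",",
                    utils::tail(generation_bins, -1), "]")
  age_class <- age_lab[findInterval(g, generation_bins, left.open = TRUE,
                                    rightmost.closed = FALSE)]
  agg <- function(cls, levels) {
    tab <- tapply(len, list(roh$sample, factor(cls, levels = levels)), sum,
                  default = 0)
    as.data.frame(tab / genome_length)
  }
  list(
    by_size = agg(size_class, sort(unique(size_class))),
    by_age = agg(age_class, age_lab),
    total = froh(roh, genome_length)
  )
}
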