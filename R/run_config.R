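#' Analysis run configuration
#'
#' Bundles the constants and filter thresholds used across the pipeline.
#' Defaults follow the study design this package implements: a 3.42 cM/Mb
#' genome-wide recombination rate and a 13-year generation time (whooping
#' crane values from the literature), per-genotype read depth in [4, 50] and
#' genotype quality >= 30, and a 40% minimum per-site genotyping rate.
#'
#' @param seed integer seed; mandatory for any stochastic run.
#' @param bin_size heterozygosity bin width in bp (1 Mb default; 500 kb and
#'   250 kb are the supported alternatives for sensitivity checks).
#' @param alpha significance level for per-bin tests.
#' @param recombination_rate cM per Mb.
#' @param generation_time years per generation.
#' @param depth_min,depth_max per-genotype read-depth window (inclusive).
#' @param gq_min minimum genotype quality.
#' @param genotyping_rate minimum fraction of samples with a called genotype
#'   for a site to be kept.
#' @return a `run_config` list.
#' @export
run_config <- function(seed = NULL,
                       bin_size = 1e6,
                       alpha = 0.05,
                       recombination_rate = 3.42,
                       generation_time = 13,
                       depth_min = 4,
                       depth_max = 50,
                       gq_min = 30,
                       genotyping_rate = 0.4) {
  thr <- c(bin_size = bin_size, alpha = alpha,
           recombination_rate = recombination_rate,
           generation_time = generation_time,
           depth_min = depth_min, depth_max = depth_max, gq_min = gq_min,
           genotyping_rate = genotyping_rate)
  if (any(thr < 0)) {
    stop("negative threshold(s): ",
         paste(names(thr)[thr < 0], collapse = ", "))
  }
  if (!is.null(seed)) seed <- as.integer(seed)
  structure(
    list(seed = seed, bin_size = bin_size, alpha = alpha,
         recombination_rate = recombination_rate,
         generation_time = generation_time,
         depth_min = depth_min, depth_max = depth_max, gq_min = gq_min,
         genotyping_rate = genotyping_rate),
    class = "run_config"
  )
}

#' Read a run configuration from a YAML file
#'
#' Unknown keys are rejected so typos do not silently fall back to defaults.
#'
#' @param path YAML file whose keys match the arguments of [run_config()].
#' @return a `run_config`.
#' @export
read_run_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(run_config))
  bad <- setdiff(names(vals), known)
  if (length(bad)) {
    stop("unknown config key(s) in ", path, ": ", paste(bad, collapse = ", "))
  }
  do.call(run_config, vals)
}

# Require a seed before running anything stochastic.
require_seed <- function(cfg_or_seed) {
  seed <- if (inherits(cfg_or_seed, "run_config")) cfg_or_seed$seed else cfg_or_seed
  if (is.null(seed) || is.na(seed)) {
    stop("a seed is mandatory for stochastic operations; set it explicitly")
  }
  as.integer(seed)
}
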