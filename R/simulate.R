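#' Configuration for the two-epoch Wright-Fisher simulation
#'
#' The default configuration emulates the study design the analysis targets:
#' a long-standing moderate population that declines, collapses to ~20
#' diploid individuals, and recovers under protection; a historical sample
#' of 16 individuals drawn just before the collapse and a modern sample of
#' 37 drawn nine generations later. Sites are unlinked and grouped into the
#' three impact categories, with selection coefficients drawn per category
#' (LOW neutral; MODERATE weakly, HIGH strongly deleterious) and dominance
#' following a negative s-h relationship (strongly deleterious mutations
#' nearly recessive).
#'
#' @param N_trajectory data.frame with columns `gen`, `N`: step-wise diploid
#'   population sizes (N holds from its `gen` until the next breakpoint).
#' @param L named integer vector: site counts per impact category.
#' @param u per-site ancestral-to-derived mutation rate per generation
#'   (recurrent; no back mutation). The default 1e-4 reflects the
#'   coarse-grained site model (each site stands for a target of many bases).
#' @param s_dist named list of functions(n) drawing selection coefficients.
#' @param h_rule function(s) mapping s to dominance in [0, 0.5]; default
#'   `0.5 * exp(-13 * s)` (near-additive when neutral, recessive when
#'   strongly deleterious).
#' @param sample_plan data.frame with columns `cohort`, `n`, `gen`.
#' @param n_outgroups number of outgroup individuals to emit.
#' @param outgroup_disagreement fraction of sites at which one outgroup
#'   carries the derived allele (exercising the polarisation filter).
#' @param seed integer seed (mandatory).
#' @return a `sim_config` list.
#' @export
sim_config <- function(N_trajectory = data.frame(gen = c(0, 30, 40, 45),
                                                 N = c(200, 100, 20, 150)),
                       L = c(LOW = 3000, MODERATE = 1500, HIGH = 800),
                       u = 1e-4,
                       s_dist = list(
                         LOW = function(n) rep(0, n),
                         MODERATE = function(n) pmin(stats::rgamma(n, shape = 0.5, scale = 0.04), 1),
                         HIGH = function(n) pmin(stats::rgamma(n, shape = 2, scale = 0.2), 1)
                       ),
                       h_rule = function(s) 0.5 * exp(-13 * s),
                       sample_plan = data.frame(
                         cohort = c("historical", "wild"),
                         n = c(16, 37),
                         gen = c(39, 48)
                       ),
                       n_outgroups = 4,
                       outgroup_disagreement = 0.1,
                       seed = NULL) {
  stopifnot(all(c("gen", "N") %in% names(N_trajectory)),
            all(N_trajectory$N >= 2),
            !is.unsorted(N_trajectory$gen, strictly = TRUE),
            all(c("cohort", "n", "gen") %in% names(sample_plan)))
  if (max(sample_plan$gen) > 0 &&
      any(sample_plan$gen < min(N_trajectory$gen))) {
    stop("sampling generation outside the trajectory")
  }
  structure(
    list(N_trajectory = N_trajectory, L = L, u = u, s_dist = s_dist,
         h_rule = h_rule, sample_plan = sample_plan,
         n_outgroups = n_outgroups,
         outgroup_disagreement = outgroup_disagreement, seed = seed),
    class = "sim_config"
  )
}

# diploid N for generations 1..t_max from step-wise breakpoints
trajectory_N <- function(N_trajectory, t_max) {
  idx <- findInterval(seq_len(t_max), N_trajectory$gen)
  idx[idx == 0] <- 1
  N_trajectory$N[idx]
}

#' Wright-Fisher allele-frequency paths for unlinked sites
#'
#' One generation consists of deterministic viability selection on
#' Hardy-Weinberg genotype frequencies (fitness 1, 1-hs, 1-s for dosage
#' 0, 1, 2), recurrent ancestral-to-derived mutation, and binomial sampling
#' of 2N gametes (the diffusion-equivalent of multinomial reproduction under
#' random mating). Sites evolve independently (free recombination).
#'
#' @param p0 initial derived-allele frequencies (length L).
#' @param s,h selection and dominance coefficients (length L or scalar).
#' @param N_gen diploid population size for each generation 1..t.
#' @param u mutation rate (ancestral to derived).
#' @param seed integer seed.
#' @return matrix of frequencies, (t + 1) x L; row 1 is `p0`.
#' @export
wf_frequency_paths <- function(p0, s, h, N_gen, u = 0, seed) {
  seed <- require_seed(seed)
  set.seed(seed)
  L <- length(p0)
  if (length(s) == 1) s <- rep(s, L)
  if (length(h) == 1) h <- rep(h, L)
  stopifnot(all(s >= 0 & s <= 1), all(h >= 0 & h <= 0.5),
            all(p0 >= 0 & p0 <= 1))
  t_max <- length(N_gen)
  paths <- matrix(NA_real_, t_max + 1L, L)
  paths[1, ] <- p <- p0
  for (g in seq_len(t_max)) {
    q <- 1 - p
    w_bar <- p^2 * (1 - s) + 2 * p * q * (1 - h * s) + q^2
    p_sel <- (p^2 * (1 - s) + p * q * (1 - h * s)) / w_bar
    p_mut <- p_sel + u * (1 - p_sel)
    N2 <- 2L * N_gen[g]
    p <- stats::rbinom(L, N2, p_mut) / N2
    paths[g + 1L, ] <- p
  }
  paths
}

# draw n diploid genotypes at frequency p (HW, exchangeable individuals)
draw_genotypes <- function(p, n) {
  matrix(stats::rbinom(n * length(p), 2L, rep(p, each = n)), nrow = n)
}

#' Simulate a two-epoch population with selection and sample it
#'
#' Runs [wf_frequency_paths()] under the configured trajectory, draws the
#' planned diploid samples at their epochs, and emits the polarised
#' genotype matrix (with impact labels), an outgroup matrix for the
#' polarisation step and the full simulation truth.
#'
#' @param cfg a [sim_config()] with a seed.
#' @return list: `genotypes` ([genotype_matrix()], all epochs stacked with
#'   cohort labels), `outgroups` (genotype_matrix), `truth` (list: `sites`
#'   data.frame with true s, h, category; `paths` frequency matrix;
#'   `N_gen`; `sample_plan`).
#' @export
simulate_wf <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  seed <- require_seed(cfg$seed)
  set.seed(seed)
  L_tot <- sum(cfg$L)
  category <- rep(names(cfg$L), cfg$L)
  s <- unlist(lapply(names(cfg$L), function(k) cfg$s_dist[[k]](cfg$L[[k]])))
  h <- cfg$h_rule(s)
  h <- pmin(pmax(h, 0), 0.5)
  t_max <- max(cfg$sample_plan$gen)
  N_gen <- trajectory_N(cfg$N_trajectory, t_max)
  # neutral-SFS standing variation: P(count = i) proportional to 1/i
  n0 <- 2L * N_gen[1]
  counts <- sample(seq_len(n0 - 1L), L_tot, replace = TRUE,
                   prob = 1 / seq_len(n0 - 1L))
  p0 <- counts / n0
  paths <- wf_frequency_paths(p0, s, h, N_gen, u = cfg$u,
                              seed = sample.int(.Machine$integer.max, 1))
  sites <- data.frame(
    chrom = "chr1", pos = seq_len(L_tot) * 1000L,
    ancestral = "A", derived = "T", impact = category,
    stringsAsFactors = FALSE
  )
  geno <- NULL
  samples <- NULL
  for (r in seq_len(nrow(cfg$sample_plan))) {
    gen <- cfg$sample_plan$gen[r]
    n <- cfg$sample_plan$n[r]
    if (n > N_gen[max(gen, 1)]) {
      stop("sample n = ", n, " exceeds population size at generation ", gen)
    }
    g <- draw_genotypes(paths[gen + 1L, ], n)
    geno <- rbind(geno, g)
    samples <- rbind(samples, data.frame(
      id = sprintf("%s_%02d", cfg$sample_plan$cohort[r], seq_len(n)),
      cohort = cfg$sample_plan$cohort[r], stringsAsFactors = FALSE
    ))
  }
  gm <- genotype_matrix(geno, samples, sites)
  og <- matrix(0L, cfg$n_outgroups, L_tot)
  n_dis <- round(cfg$outgroup_disagreement * L_tot)
  if (n_dis > 0 && cfg$n_outgroups > 0) {
    dis_sites <- sample.int(L_tot, n_dis)
    og[cbind(sample.int(cfg$n_outgroups, n_dis, replace = TRUE), dis_sites)] <- 1L
  }
  outgroups <- genotype_matrix(
    og,
    data.frame(id = sprintf("outgroup_%d", seq_len(cfg$n_outgroups)),
               cohort = "outgroup", stringsAsFactors = FALSE),
    sites
  )
  list(
    genotypes = gm,
    outgroups = outgroups,
    truth = list(
      sites = data.frame(sites, s = s, h = h, stringsAsFactors = FALSE),
      paths = paths, N_gen = N_gen, sample_plan = cfg$sample_plan
    )
  )
}

#' Simulate a captive pedigree with gene-dropped genotypes
#'
#' Founds a captive population with `founders` unrelated wild-born birds and
#' breeds it for `generations` discrete generations of monogamous pairs,
#' keeping the census size constant. Under the `min_kinship` policy, pairs
#' are formed greedily by lowest pedigree kinship (recomputed each
#' generation, as a studbook manager would); `random` pairs uniformly. If
#' every available pair exceeds `kinship_cap`, the least-related pair is
#' used with a warning. Genotypes are gene-dropped from founder haplotypes
#' drawn at `founder_freq` per site.
#'
#' @param founders number of founders (>= 2).
#' @param generations breeding generations to simulate.
#' @param policy `"random"` or `"min_kinship"`.
#' @param seed integer seed.
#' @param n_sites number of unlinked sites to gene-drop.
#' @param founder_freq derived-allele frequency(ies) in the founders
#'   (scalar or length `n_sites`).
#' @param kinship_cap maximum tolerated pair kinship under `min_kinship`.
#' @return list: `pedigree` ([pedigree()]; cohorts `founder`, `gen1`, ...),
#'   `genotypes` ([genotype_matrix()] for all individuals), `truth` (list
#'   with founder-origin haplotype labels per individual).
#' @export
simulate_pedigree <- function(founders, generations, policy = c("min_kinship", "random"),
                              seed, n_sites = 200, founder_freq = 0.2,
                              kinship_cap = 0.125) {
  policy <- match.arg(policy)
  stopifnot(founders >= 2)
  seed <- require_seed(seed)
  set.seed(seed)
  id <- sprintf("F%03d", seq_len(founders))
  sire <- rep(NA_character_, founders)
  dam <- rep(NA_character_, founders)
  cohort <- rep("founder", founders)
  prev <- id
  counter <- 0L
  warned <- FALSE
  for (g in seq_len(generations)) {
    ped_now <- pedigree(id, sire, dam, cohort = cohort)
    phi <- kinship(ped_now)
    avail <- prev
    pairs <- list()
    while (length(avail) >= 2) {
      if (policy == "random") {
        pick <- sample(avail, 2)
      } else {
        sub <- phi[avail, avail, drop = FALSE]
        diag(sub) <- Inf
        # break ties at random: deterministic first-index picks would pair
        # whole families together and manufacture double first cousins
        best <- which(sub == min(sub), arr.ind = TRUE)
        best <- best[sample.int(nrow(best), 1), ]
        if (min(sub) > kinship_cap && !warned) {
          warning("all available pairs exceed the kinship cap; ",
                  "using the least-related pair")
          warned <- TRUE
        }
        pick <- c(avail[best[1]], avail[best[2]])
      }
      pairs[[length(pairs) + 1L]] <- pick
      avail <- setdiff(avail, pick)
    }
    n_off <- founders
    per_pair <- rep(floor(n_off / length(pairs)), length(pairs))
    rem <- n_off - sum(per_pair)
    if (rem > 0) per_pair[seq_len(rem)] <- per_pair[seq_len(rem)] + 1L
    new_ids <- character(0)
    for (k in seq_along(pairs)) {
      for (o in seq_len(per_pair[k])) {
        counter <- counter + 1L
        oid <- sprintf("G%d_%03d", g, counter)
        id <- c(id, oid)
        sire <- c(sire, pairs[[k]][1])
        dam <- c(dam, pairs[[k]][2])
        cohort <- c(cohort, paste0("gen", g))
        new_ids <- c(new_ids, oid)
      }
    }
    prev <- new_ids
  }
  ped <- pedigree(id, sire, dam, cohort = cohort)
  if (length(founder_freq) == 1) founder_freq <- rep(founder_freq, n_sites)
  drop_seed <- sample.int(.Machine$integer.max, 1)
  # drop founder-haplotype labels once, then translate labels to alleles so
  # that genotypes and IBD origins share the same transmissions
  origin <- gene_drop(ped, n_sites, drop_seed)
  n_labels <- max(origin$hap1, origin$hap2)
  allele <- matrix(stats::rbinom(n_labels * n_sites, 1L,
                                 rep(founder_freq, each = n_labels)),
                   nrow = n_labels)
  lookup <- function(lab) {
    matrix(allele[cbind(as.vector(lab),
                        rep(seq_len(n_sites), each = nrow(lab)))],
           nrow = nrow(lab), dimnames = dimnames(lab))
  }
  geno <- lookup(origin$hap1) + lookup(origin$hap2)
  storage.mode(geno) <- "integer"
  sites <- data.frame(
    chrom = "chr1", pos = seq_len(n_sites) * 1000L,
    ancestral = "A", derived = "T", impact = "NONE",
    stringsAsFactors = FALSE
  )
  gm <- genotype_matrix(geno, data.frame(id = ped$id, cohort = ped$cohort,
                                         stringsAsFactors = FALSE), sites)
  list(pedigree = ped, genotypes = gm,
       truth = list(origin_hap1 = origin$hap1, origin_hap2 = origin$hap2))
}

#' Simulate ROH profiles and binned heterozygosity
#'
#' Emulates an ROH caller's output on a genome of `genome_length` bp, one
#' chromosome, split into `bin_size` bins. Per sample, autozygous tracts of
#' target age `age_G` generations are drawn with exponential genetic length
#' (mean 100 / (2 age_G) cM, converted at `rec_rate_cM_per_Mb`) and placed
#' uniformly without overlap until the target F_ROH is reached. Bin
#' heterozygosity is `baseline_het` times a shared lognormal bin factor
#' (real genomes vary in diversity along the chromosome) times a per-sample
#' lognormal noise, collapsed to near zero (x 0.02) where the bin overlaps
#' an ROH by more than half. Optional private-region injections multiply
#' the heterozygosity of chosen bins by `1 + effect` for all members of one
#' group.
#'
#' @param samples data.frame with columns `id`, `group`, `target_froh`,
#'   `age_G`.
#' @param genome_length genome length in bp.
#' @param bin_size bin width in bp.
#' @param baseline_het baseline heterozygosity per bp.
#' @param rec_rate_cM_per_Mb recombination rate for the length conversion.
#' @param bin_sd,sample_sd standard deviations (natural-log scale) of the
#'   shared bin factor and the per-sample noise.
#' @param private_regions optional data.frame with columns `group`,
#'   `n_bins`, `effect`: for each row, `n_bins` bins are chosen and the
#'   heterozygosity of the named group's members is multiplied by
#'   `1 + effect` there (e.g. -0.8 for an 80% drop — variation private to
#'   the complementary group).
#' @param seed integer seed.
#' @return list: `roh` ([roh_set()]; samples with 0 target F_ROH absent),
#'   `bin_het` ([bin_het()]), `truth` (list: per-group injected bin indices,
#'   per-sample realised F_ROH).
#' @export
simulate_roh_and_bins <- function(samples,
                                  genome_length = 1e9,
                                  bin_size = 1e6,
                                  baseline_het = 1e-3,
                                  rec_rate_cM_per_Mb = 3.42,
                                  bin_sd = 0.1,
                                  sample_sd = 0.25,
                                  private_regions = NULL,
                                  seed) {
  stopifnot(all(c("id", "group", "target_froh", "age_G") %in% names(samples)))
  if (any(samples$target_froh > 1)) stop("target F_ROH > 1")
  seed <- require_seed(seed)
  set.seed(seed)
  n_bins <- floor(genome_length / bin_size)
  bins <- data.frame(chrom = "chr1",
                     start = (seq_len(n_bins) - 1) * bin_size,
                     end = seq_len(n_bins) * bin_size)
  bin_factor <- exp(stats::rnorm(n_bins, 0, bin_sd))
  het <- matrix(NA_real_, n_bins, nrow(samples),
                dimnames = list(NULL, samples$id))
  roh_rows <- list()
  realised <- numeric(nrow(samples))
  for (i in seq_len(nrow(samples))) {
    target <- samples$target_froh[i]
    tracts <- matrix(numeric(0), ncol = 2)
    if (target > 0) {
      mean_cM <- 100 / (2 * samples$age_G[i])
      need <- target * genome_length
      placed <- 0
      guard <- 0
      while (placed < need && guard < 1e5) {
        guard <- guard + 1
        len <- round(stats::rexp(1, rate = 1 / mean_cM) / rec_rate_cM_per_Mb * 1e6)
        if (len < 1 || len >= genome_length) next
        st <- floor(stats::runif(1, 0, genome_length - len))
        en <- st + len
        if (nrow(tracts) == 0 ||
            all(en <= tracts[, 1] | st >= tracts[, 2])) {
          tracts <- rbind(tracts, c(st, en))
          placed <- placed + len
        }
      }
      roh_rows[[samples$id[i]]] <- data.frame(
        sample = samples$id[i], chrom = "chr1",
        start = tracts[, 1], end = tracts[, 2], stringsAsFactors = FALSE
      )
    }
    realised[i] <- sum(tracts[, 2] - tracts[, 1]) / genome_length
    h <- baseline_het * bin_factor * exp(stats::rnorm(n_bins, 0, sample_sd))
    if (nrow(tracts)) {
      ir_bins <- IRanges::IRanges(bins$start + 1L, bins$end)
      ir_roh <- IRanges::IRanges(tracts[, 1] + 1L, tracts[, 2])
      ov <- IRanges::findOverlaps(ir_bins, ir_roh)
      cover <- tapply(
        IRanges::width(IRanges::pintersect(
          ir_bins[S4Vectors::queryHits(ov)], ir_roh[S4Vectors::subjectHits(ov)]
        )),
        S4Vectors::queryHits(ov), sum
      )
      covered_idx <- as.integer(names(cover))
      in_roh <- covered_idx[cover > bin_size / 2]
      h[in_roh] <- h[in_roh] * 0.02
    }
    het[, i] <- h
  }
  truth_private <- list()
  if (!is.null(private_regions)) {
    used <- integer(0)
    for (r in seq_len(nrow(private_regions))) {
      grp <- private_regions$group[r]
      pick <- sample(setdiff(seq_len(n_bins), used), private_regions$n_bins[r])
      used <- c(used, pick)
      members <- samples$id[samples$group == grp]
      het[pick, members] <- het[pick, members] * (1 + private_regions$effect[r])
      truth_private[[grp]] <- sort(pick)
    }
  }
  roh <- if (length(roh_rows)) roh_set(do.call(rbind, roh_rows)) else
    structure(data.frame(sample = character(), chrom = character(),
                         start = integer(), end = integer()),
              class = c("roh_set", "data.frame"))
  long <- data.frame(
    chrom = rep(bins$chrom, ncol(het)), start = rep(bins$start, ncol(het)),
    end = rep(bins$end, ncol(het)),
    sample = rep(colnames(het), each = n_bins), het = as.vector(het),
    stringsAsFactors = FALSE
  )
  list(roh = roh, bin_het = bin_het(long),
       truth = list(private_bins = truth_private,
                    froh = stats::setNames(realised, samples$id)))
}
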