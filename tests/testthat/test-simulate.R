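test_that("neutral heterozygosity decays like (1 - 1/(2N))^t", {
  N <- 50
  t <- 200
  L <- 3000  # unlinked sites are independent replicates of the decay
  p0 <- rep(0.5, L)
  paths <- wf_frequency_paths(p0, s = 0, h = 0.5, N_gen = rep(N, t), seed = 101)
  het <- function(p) mean(2 * p * (1 - p))
  ratio <- het(paths[t + 1, ]) / het(paths[1, ])
  expect_equal(ratio, (1 - 1 / (2 * N))^t, tolerance = 0.08)
})

test_that("a lethal recessive declines and never fixes", {
  paths <- wf_frequency_paths(rep(0.5, 200), s = 1, h = 0,
                              N_gen = rep(500, 100), u = 0, seed = 7)
  expect_true(all(paths[101, ] < 1))
  expect_lt(mean(paths[101, ]), 0.05)
})

test_that("the simulator is deterministic given a seed and demands one", {
  cfg <- sim_config(seed = 33, L = c(LOW = 100, MODERATE = 50, HIGH = 50))
  a <- simulate_wf(cfg)
  b <- simulate_wf(cfg)
  expect_identical(a$genotypes$geno, b$genotypes$geno)
  expect_identical(a$truth$paths, b$truth$paths)
  expect_error(simulate_wf(sim_config(seed = NULL)), "seed")
})

test_that("sampling more individuals than the population errors", {
  cfg <- sim_config(
    seed = 1,
    N_trajectory = data.frame(gen = 0, N = 20),
    sample_plan = data.frame(cohort = "wild", n = 25, gen = 5)
  )
  expect_error(simulate_wf(cfg), "exceeds population size")
})

test_that("min-kinship pairing curbs inbreeding relative to random pairing", {
  # pairing policy barely moves the mean *pairwise* kinship of the next
  # generation (allele flow is set by the parental pool), but it directly
  # controls which matings happen and hence offspring inbreeding
  stats_for <- function(sim) {
    phi <- kinship(sim$pedigree)
    g3 <- sim$pedigree$id[sim$pedigree$cohort == "gen3"]
    m <- phi[g3, g3]
    c(kin = mean(m[upper.tri(m, diag = TRUE)]),
      f = mean(inbreeding(sim$pedigree)[g3]))
  }
  res <- vapply(1:30, function(r) {
    mk <- suppressWarnings(
      simulate_pedigree(12, 3, "min_kinship", seed = 1000 + r, n_sites = 2))
    rnd <- simulate_pedigree(12, 3, "random", seed = 1000 + r, n_sites = 2)
    stats_for(rnd) - stats_for(mk)
  }, numeric(2))
  expect_gt(mean(res["f", ]), 0)        # strictly less inbreeding on average
  expect_gte(mean(res["kin", ]), 0)     # and no worse in mean kinship
})

test_that("pedigree simulation obeys basic inbreeding arithmetic", {
  # a single founder pair: generation-1 offspring are not inbred, but
  # generation-2 offspring of full sibs are
  sim <- suppressWarnings(
    simulate_pedigree(2, 2, "random", seed = 5, n_sites = 10)
  )
  f <- inbreeding(sim$pedigree)
  g1 <- sim$pedigree$cohort == "gen1"
  g2 <- sim$pedigree$cohort == "gen2"
  expect_true(all(f[g1] == 0))
  expect_true(all(f[g2] > 0))

  # a site fixed in the founders stays fixed in every descendant
  sim2 <- suppressWarnings(
    simulate_pedigree(6, 3, "min_kinship", seed = 8, n_sites = 40,
                      founder_freq = 1)
  )
  expect_true(all(sim2$genotypes$geno == 2L))
})

test_that("ROH tracts have the exponential length of their target age", {
  ss <- data.frame(id = sprintf("s%d", 1:10), group = "wild",
                   target_froh = 0.15, age_G = 1)
  sim <- simulate_roh_and_bins(ss, genome_length = 1e9, seed = 21)
  mean_bp <- mean(sim$roh$end - sim$roh$start)
  # age G = 1: mean genetic length 100/(2*1) = 50 cM = 50/3.42 Mb
  expect_equal(mean_bp, 50 / 3.42 * 1e6, tolerance = 0.15)
})

test_that("realised F_ROH tracks the target", {
  ss <- data.frame(id = sprintf("s%d", 1:10), group = "wild",
                   target_froh = 0.10, age_G = 4)
  sim <- simulate_roh_and_bins(ss, genome_length = 1e9, seed = 22)
  fr <- froh(sim$roh, 1e9)
  expect_equal(unname(mean(fr)), 0.10, tolerance = 0.08)
  expect_true(all(abs(fr - 0.10) < 0.03))
  expect_equal(sort(names(fr)), sort(ss$id))
  expect_error(
    simulate_roh_and_bins(data.frame(id = "x", group = "g", target_froh = 1.2,
                                     age_G = 2), seed = 1),
    "F_ROH > 1"
  )
})

test_that("injected private regions are the lowest-heterozygosity bins", {
  ss <- data.frame(id = sprintf("%s%d", rep(c("a", "b"), each = 5), 1:5),
                   group = rep(c("A", "B"), each = 5),
                   target_froh = 0, age_G = 4)
  sim <- simulate_roh_and_bins(
    ss, genome_length = 2e8,
    private_regions = data.frame(group = "A", n_bins = 20, effect = -0.8),
    seed = 30
  )
  a_mean <- rowMeans(sim$bin_het$het[, ss$id[ss$group == "A"]])
  lowest <- order(a_mean)[1:20]
  expect_setequal(lowest, sim$truth$private_bins$A)
})
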