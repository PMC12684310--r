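test_that("Mendelian offspring distributions are exact", {
  expect_equal(unname(offspring_genotype_dist(0, 0)), c(1, 0, 0))
  expect_equal(unname(offspring_genotype_dist(1, 1)), c(0.25, 0.5, 0.25))
  expect_equal(unname(offspring_genotype_dist(1, 2)), c(0, 0.5, 0.5))
  expect_equal(unname(offspring_genotype_dist(2, 2)), c(0, 0, 1))
  expect_equal(sum(offspring_genotype_dist(1, 0)), 1)
  expect_error(offspring_genotype_dist(3, 0))
})

test_that("expected offspring load matches enumeration of transmissions", {
  sites1 <- data.frame(s = 0.1, h = 0)
  eo <- expected_offspring_load(1L, 2L, sites1)
  expect_equal(eo$GL, 0.075)
  expect_equal(eo$RL, 0.05)
  expect_equal(eo$ML, 0.025)

  # both parents dosage 0 everywhere
  sitesL <- data.frame(s = runif(5, 0.01, 0.5), h = runif(5, 0, 0.5))
  z <- expected_offspring_load(rep(0L, 5), rep(0L, 5), sitesL)
  expect_equal(c(z$GL, z$RL, z$ML), c(0, 0, 0))

  # exhaustive oracle: average load over the four transmitted-allele
  # combinations per site, for every parental genotype pair
  enum_load <- function(g1, g2, s, h) {
    hap <- function(g) switch(as.character(g), "0" = c(0, 0),
                              "1" = c(0, 1), "2" = c(1, 1))
    combos <- expand.grid(a = hap(g1), b = hap(g2))
    gl <- rl <- ml <- 0
    for (k in seq_len(nrow(combos))) {
      dos <- combos$a[k] + combos$b[k]
      if (dos == 2) { gl <- gl + s; rl <- rl + s }
      if (dos == 1) {
        gl <- gl + 0.5 * s; rl <- rl + h * s; ml <- ml + (0.5 - h) * s
      }
    }
    c(GL = gl, RL = rl, ML = ml) / nrow(combos)
  }
  set.seed(4)
  for (g1 in 0:2) {
    for (g2 in 0:2) {
      s <- runif(1, 0.01, 1)
      h <- runif(1, 0, 0.5)
      eo2 <- expected_offspring_load(g1, g2, data.frame(s = s, h = h))
      ex <- enum_load(g1, g2, s, h)
      expect_equal(eo2$GL, unname(ex["GL"]))
      expect_equal(eo2$RL, unname(ex["RL"]))
      expect_equal(eo2$ML, unname(ex["ML"]))
    }
  }

  # selfing a single-het carrier (h = 0): expected realised load is s/4
  s <- 0.32
  self <- expected_offspring_load(1L, 1L, data.frame(s = s, h = 0))
  expect_equal(self$RL, 0.25 * s)

  # linearity: doubling s doubles the contribution; E[GL] = E[RL] + E[ML]
  set.seed(11)
  st <- data.frame(s = runif(20, 0.01, 0.5), h = runif(20, 0, 0.5))
  g1 <- sample(0:2, 20, TRUE); g2 <- sample(0:2, 20, TRUE)
  e1 <- expected_offspring_load(g1, g2, st)
  st2 <- st; st2$s <- 2 * st$s
  e2 <- expected_offspring_load(g1, g2, st2)
  expect_equal(e2$GL, 2 * e1$GL)
  expect_equal(e1$GL, e1$RL + e1$ML, tolerance = 1e-12)

  expect_error(expected_offspring_load(NA_integer_, 1L, sites1), "shared")
})

test_that("sampled offspring loads converge to the expectation", {
  set.seed(2)
  st <- data.frame(s = runif(30, 0.05, 0.5), h = runif(30, 0, 0.5))
  g1 <- sample(0:2, 30, TRUE); g2 <- sample(0:2, 30, TRUE)
  eo <- expected_offspring_load(g1, g2, st)
  sm <- sample_offspring_load(g1, g2, st, n = 4000, seed = 13)
  expect_equal(mean(sm$RL), eo$RL, tolerance = 0.05)
  expect_equal(mean(sm$GL), eo$GL, tolerance = 0.05)
})

test_that("cross ranking, class labels and reduction summaries", {
  # two wild, two captive parents over 4 scored sites
  geno <- rbind(w1 = c(0L, 0L, 1L, 0L),
                w2 = c(0L, 1L, 0L, 0L),
                c1 = c(2L, 2L, 1L, 1L),
                c2 = c(2L, 1L, 2L, 2L))
  gm <- genotype_matrix(
    geno,
    samples = data.frame(id = rownames(geno),
                         cohort = c("wild", "wild", "late_captive", "late_captive")),
    sites = data.frame(chrom = "chr1", pos = (1:4) * 100L, ancestral = "A",
                       derived = "T", impact = "NONE")
  )
  st <- data.frame(s = c(0.2, 0.1, 0.3, 0.15), h = c(0, 0.15, 0.02, 0.3))
  rc <- rank_crosses(gm, st)
  expect_equal(nrow(rc$crosses), 6)
  expect_true(!is.unsorted(rc$crosses$ERL))
  expect_setequal(unique(rc$crosses$class),
                  c("wild x wild", "captive x wild", "captive x captive"))
  # brute-force check of every pair's expectation
  ids <- rownames(geno)
  for (r in seq_len(nrow(rc$crosses))) {
    eo <- expected_offspring_load(geno[rc$crosses$p1[r], ],
                                  geno[rc$crosses$p2[r], ], st)
    expect_equal(rc$crosses$ERL[r], eo$RL)
  }
  # reduction arithmetic: two pairs at 0.5 and 0.9 -> 44.44%
  expect_equal(unname((0.9 - 0.5) / 0.9), 0.4444, tolerance = 1e-3)
  best_cw <- min(rc$crosses$ERL[rc$crosses$class == "captive x wild"])
  worst_cc <- max(rc$crosses$ERL[rc$crosses$class == "captive x captive"])
  expect_equal(unname(rc$summary["rl_reduction_cw_vs_worst_cc"]),
               (worst_cc - best_cw) / worst_cc)
  # identical pairs give zero best-vs-worst reduction
  gm_dup <- genotype_matrix(
    geno[c(1, 1, 1), ],
    samples = data.frame(id = c("a", "b", "c"), cohort = "wild"),
    sites = gm$sites
  )
  rc_dup <- rank_crosses(gm_dup, st)
  expect_equal(unname(rc_dup$summary["rl_reduction_best_vs_worst_overall"]), 0)
})

test_that("expected load rises with parental kinship in gene-dropped pedigrees", {
  hits <- vapply(1:12, function(r) {
    sim <- simulate_pedigree(8, 3, "random", seed = 600 + r, n_sites = 150,
                             founder_freq = 0.15)
    phi <- kinship(sim$pedigree)
    last <- sim$pedigree$id[sim$pedigree$cohort == "gen3"]
    gm <- subset_genotypes(sim$genotypes, samples = last)
    st <- data.frame(s = rep(0.2, 150), h = rep(0, 150))
    rc <- rank_crosses(gm, st, kinship_matrix = phi)
    fit <- load_vs_relatedness(rc$crosses)
    fit$slope[fit$component == "RL"] > 0
  }, logical(1))
  expect_gte(mean(hits), 0.75)
})

test_that("load-vs-relatedness regression is exact on linear toys", {
  crosses <- data.frame(EGL = c(1, 2, 3, 4), ERL = c(1, 2, 3, 4) * 0.6,
                        EML = c(1, 2, 3, 4) * 0.4,
                        kinship = c(0.1, 0.2, 0.3, 0.4))
  res <- load_vs_relatedness(crosses)
  expect_true(all(abs(res$r.squared - 1) < 1e-12))
  expect_error(load_vs_relatedness(transform(crosses, kinship = 0.2)),
               "zero variance")
})
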