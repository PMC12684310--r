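test_that("polarisation keeps only sites with unanimous 0/0 outgroups", {
  gm <- toy_gm(matrix(1L, 2, 4))
  og <- toy_gm(rbind(c(0L, 0L, 0L, NA), c(0L, 1L, 0L, 0L),
                     c(0L, 0L, 0L, 0L), c(0L, 0L, 0L, 0L)),
               cohort = rep("outgroup", 4))
  res <- polarise(gm, og)
  # site 2 has a heterozygous outgroup, site 4 a missing outgroup genotype
  expect_equal(res$mask, c(TRUE, FALSE, TRUE, FALSE))
  expect_equal(res$report$retained, 2)
  expect_error(polarise(gm, subset_genotypes(og, samples = integer(0))),
               "zero outgroup")
})

test_that("load counting matches its definition and a brute-force tally", {
  gm <- toy_gm(matrix(c(1L, 2L, 0L), 1, 3), impact = rep("HIGH", 3))
  lc <- count_load(gm, "HIGH")
  expect_equal(lc$het, 1)
  expect_equal(lc$hom, 2)
  expect_equal(lc$total, 3)

  # all-missing sample contributes zeros
  gm2 <- toy_gm(rbind(rep(NA_integer_, 3), c(2L, 2L, 1L)),
                impact = rep("MODERATE", 3))
  lc2 <- count_load(gm2, "MODERATE")
  expect_equal(lc2$total, c(0, 5))

  # 50-site random matrix vs an exhaustive per-genotype loop
  set.seed(14)
  geno <- matrix(sample(c(0:2, NA), 6 * 50, TRUE), 6, 50)
  imp <- sample(c("LOW", "MODERATE", "HIGH"), 50, TRUE)
  gm3 <- toy_gm(geno, impact = imp)
  for (cat in c("LOW", "MODERATE", "HIGH")) {
    got <- count_load(gm3, cat)
    for (i in 1:6) {
      het <- 0; hom <- 0
      for (j in which(imp == cat)) {
        g <- geno[i, j]
        if (!is.na(g)) {
          if (g == 1) het <- het + 1
          if (g == 2) hom <- hom + 2
        }
      }
      expect_equal(got$het[i], het)
      expect_equal(got$hom[i], hom)
      expect_equal(got$total[i], het + hom)
    }
  }
})

test_that("normalisation divides by the sample's LOW total", {
  gm <- toy_gm(rbind(c(1L, 1L, 2L, 1L), c(2L, 2L, 0L, 1L)),
               impact = c("LOW", "LOW", "HIGH", "HIGH"))
  counts <- rbind(count_load(gm, "LOW"), count_load(gm, "HIGH"))
  norm <- normalise_load_counts(counts)
  hi <- norm[norm$category == "HIGH", ]
  expect_equal(hi$total_norm, c(3 / 2, 1 / 4))
})

test_that("delta frequency arithmetic and exclusions", {
  ft <- toy_ft(Fh = c(0.1, 0.5), Fm = c(0.2, 0.4))
  d <- delta_frequency(ft, "HIGH")
  expect_equal(d$per_site$delta, c(0.1, -0.1))
  expect_equal(d$mean_delta, 0)
  expect_equal(d$prop_positive, 0.5)

  ft2 <- toy_ft(Fh = c(0.1, 0.2), Fm = c(0.1, 0.2))
  expect_equal(delta_frequency(ft2, "HIGH")$mean_delta, 0)

  ft3 <- toy_ft(Fh = c(0.1, 0.2), Fm = c(0.3, 0.2), nh = c(0L, 10L))
  d3 <- delta_frequency(ft3, "HIGH")
  expect_equal(d3$n_used, 1)
  expect_equal(d3$n_excluded, 1)
})

test_that("neutral drift with equal epochs gives mean delta near zero", {
  deltas <- vapply(1:10, function(r) {
    paths <- wf_frequency_paths(rep(0.3, 1500), s = 0, h = 0.5,
                                N_gen = rep(100, 8), seed = 400 + r)
    mean(paths[9, ] - paths[1, ])
  }, numeric(1))
  expect_equal(mean(deltas), 0, tolerance = 0.005)
})

test_that("the sign test is exact and calibrated", {
  expect_equal(sign_binomial_test(c(rep(0.1, 5), rep(-0.1, 5)))$p.value, 1)
  expect_equal(sign_binomial_test(rep(0.2, 10))$p.value, 2 * 0.5^10)
  expect_warning(res <- sign_binomial_test(c(0, 0)), "zero")
  expect_equal(res$p.value, 1)

  # null calibration: symmetric continuous deltas, exact binomial test is
  # valid (and if anything conservative)
  set.seed(77)
  pvals <- vapply(1:2000, function(i) {
    sign_binomial_test(stats::rnorm(101))$p.value
  }, numeric(1))
  rate <- mean(pvals < 0.05)
  expect_lt(rate, 0.065)
  expect_gt(rate, 0.02)
})

test_that("Rxy matches hand evaluation, brute force and symmetry", {
  ft <- rbind_ft(toy_ft(Fh = c(0.2, 0.4), Fm = c(0.1, 0.2), impact = "HIGH"),
                 toy_ft(Fh = 0.3, Fm = 0.3, impact = "LOW"))
  r <- rxy(ft, "HIGH")
  # (0.1*0.8 + 0.2*0.6) / (0.2*0.9 + 0.4*0.8) = 0.20 / 0.50
  expect_equal(r$raw, 0.4)
  expect_equal(r$raw_low, 1)
  expect_equal(r$normalised, 0.4)

  # identical epochs: Rxy exactly 1
  ft_eq <- toy_ft(Fh = c(0.1, 0.7), Fm = c(0.1, 0.7))
  expect_equal(rxy(rbind_ft(ft_eq, toy_ft(0.2, 0.2, "LOW")), "HIGH")$normalised, 1)

  # ratio-of-sums on a random table equals an independent per-site loop
  set.seed(3)
  Fh <- runif(40, 0.05, 0.95)
  Fm <- runif(40, 0.05, 0.95)
  num <- 0; den <- 0
  for (i in 1:40) {
    num <- num + Fm[i] * (1 - Fh[i])
    den <- den + Fh[i] * (1 - Fm[i])
  }
  ft_r <- rbind_ft(toy_ft(Fh, Fm, "HIGH"), toy_ft(0.5, 0.5, "LOW"))
  expect_equal(rxy(ft_r, "HIGH")$raw, num / den)

  # swapping the epochs gives the reciprocal of the raw ratio
  ft_s <- rbind_ft(toy_ft(Fm, Fh, "HIGH"), toy_ft(0.5, 0.5, "LOW"))
  expect_equal(rxy(ft_s, "HIGH")$raw, 1 / rxy(ft_r, "HIGH")$raw)

  # degenerate historical frequencies: named error
  ft_z <- rbind_ft(toy_ft(c(0, 0), c(0.5, 0.5), "HIGH"),
                   toy_ft(0.2, 0.2, "LOW"))
  expect_error(rxy(ft_z, "HIGH"), "denominator")
})

test_that("the delete-d jackknife behaves on degenerate and seeded input", {
  ft <- rbind_ft(toy_ft(rep(0.2, 200), rep(0.2, 200), "HIGH"),
                 toy_ft(rep(0.3, 200), rep(0.3, 200), "LOW"))
  jk <- jackknife_rxy(ft, "HIGH", seed = 5)
  expect_equal(jk$variance, 0)
  expect_equal(jk$estimate, 1)

  set.seed(10)
  ft2 <- rbind_ft(toy_ft(runif(300, 0.1, 0.9), runif(300, 0.1, 0.9), "HIGH"),
                  toy_ft(runif(300, 0.1, 0.9), runif(300, 0.1, 0.9), "LOW"))
  a <- jackknife_rxy(ft2, "HIGH", seed = 9)
  b <- jackknife_rxy(ft2, "HIGH", seed = 9)
  expect_identical(a$replicates, b$replicates)
  # 40 focal + 40 reference sites: too few for 100 one-percent blocks
  expect_error(jackknife_rxy(ft2[c(1:40, 301:340), ], "HIGH", seed = 1),
               "too few|at least")

  # scaled jackknife variance is the same order as a bootstrap over sites
  boot <- vapply(1:2000, function(i) {
    idx <- sample(nrow(ft2), replace = TRUE)
    rxy(ft2[idx, , drop = FALSE], "HIGH")$normalised
  }, numeric(1))
  ratio <- a$variance / stats::var(boot)
  expect_gt(ratio, 0.1)
  expect_lt(ratio, 10)
})

test_that("homozygous load splits by ROH membership and conserves totals", {
  # 20 hom sites: 10 inside a ROH covering the first 10 positions
  geno <- matrix(2L, 1, 20)
  gm <- toy_gm(geno, impact = rep("HIGH", 20))  # positions 100..2000
  roh <- roh_set(data.frame(sample = "s01", chrom = "chr1",
                            start = 0, end = 1000))
  res <- load_in_out_roh(gm, "HIGH", roh, genome_length = 10000)
  expect_equal(res$hom_in, 20)   # 10 genotypes x 2 alleles
  expect_equal(res$hom_out, 20)
  expect_equal(res$froh, 0.1)
  expect_equal(res$in_norm, 20 / 0.1)
  expect_equal(res$out_norm, 20 / 0.9)
  expect_equal(res$hom_in + res$hom_out, sum(count_load(gm, "HIGH")$hom))

  # no ROH: everything is outside, normalised by 1
  res2 <- load_in_out_roh(gm, "HIGH", roh[0, ], genome_length = 10000)
  expect_equal(res2$hom_in, 0)
  expect_equal(res2$out_norm, res2$hom_out)
  expect_true(is.na(res2$in_norm))
})
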