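test_that("the posterior variance is the weighted prior/observed blend", {
  # d0 = 4, s0^2 = 1, d_g = 4, s_g^2 = 2 -> (4*1 + 4*2)/8 = 1.5
  d0 <- 4; s0 <- 1; dg <- 4; s2 <- 2
  expect_equal((d0 * s0 + dg * s2) / (d0 + dg), 1.5)
  # the fitted prior reproduces that blend on its own output
  set.seed(1)
  s2v <- s0 * d0 / rchisq(5000, d0) * rchisq(5000, dg) / dg
  pr <- fit_variance_prior(s2v, dg)
  expect_equal(unname((pr$d0 * pr$s0_2 + dg * 2) / (pr$d0 + dg)),
               unname(pr$s2_post[which.min(abs(s2v - 2))]), tolerance = 0.05)
})

test_that("the prior fit recovers simulated hyperparameters", {
  set.seed(42)
  d0 <- 8; s0_2 <- 2; dg <- 10
  s2 <- s0_2 * d0 / rchisq(10000, d0) * rchisq(10000, dg) / dg
  pr <- fit_variance_prior(s2, dg)
  expect_equal(pr$d0, d0, tolerance = 0.15)
  expect_equal(pr$s0_2, s0_2, tolerance = 0.15)
})

test_that("identical variances give an infinite-d0 (fully pooled) prior", {
  pr <- fit_variance_prior(rep(2, 50), 4)
  expect_true(is.infinite(pr$d0))
  expect_equal(unname(pr$s2_post), rep(pr$s0_2, 50))
})

test_that("trigamma_inverse inverts trigamma across magnitudes", {
  y <- c(0.01, 0.5, 1, 5, 50)
  expect_equal(trigamma_inverse(trigamma(y)), y, tolerance = 1e-6)
})

test_that("moderated test is null-centred, order-invariant and labelled", {
  ss <- data.frame(id = sprintf("s%d", 1:12),
                   group = rep(c("wild", "captive"), each = 6),
                   target_froh = 0, age_G = 4)
  sim <- simulate_roh_and_bins(ss, genome_length = 3e8, seed = 51)
  groups <- setNames(ss$group, ss$id)
  res <- moderated_test(sim$bin_het, groups)
  expect_true(all(res$p.value >= 0 & res$p.value <= 1))
  expect_equal(res$F, res$t^2)

  # identical group means in every bin: t = 0, p = 1
  bh <- sim$bin_het
  bh$het[, 7:12] <- bh$het[, 1:6]
  res0 <- moderated_test(bh, groups)
  expect_true(all(res0$t == 0))
  expect_true(all(res0$p.value == 1))

  # invariance to bin order and to sample order within groups
  perm_bins <- sample(nrow(sim$bin_het$het))
  bh2 <- sim$bin_het
  bh2$bins <- bh2$bins[perm_bins, ]
  bh2$het <- bh2$het[perm_bins, ]
  res2 <- moderated_test(bh2, groups)
  expect_equal(res2$p.value[order(res2$start)], res$p.value[order(res$start)])
  bh3 <- sim$bin_het
  perm_s <- c(sample(1:6), sample(7:12))
  bh3$het <- bh3$het[, perm_s]
  res3 <- moderated_test(bh3, groups)
  expect_equal(res3$p.value, res$p.value)

  # direction labels: force one bin lower in wild
  bh4 <- sim$bin_het
  bh4$het[5, 1:6] <- bh4$het[5, 1:6] * 0.01
  res4 <- moderated_test(bh4, groups)
  expect_equal(res4$lower_in[5], "wild")
  expect_equal(res4$private_to[5], "captive")
})

test_that("null p-values are uniform and the test agrees with limma", {
  ss <- data.frame(id = sprintf("s%d", 1:20),
                   group = rep(c("wild", "captive"), each = 10),
                   target_froh = 0, age_G = 4)
  sim <- simulate_roh_and_bins(ss, genome_length = 1e9, bin_size = 1e5,
                               seed = 52)  # 10,000 null bins
  groups <- setNames(ss$group, ss$id)
  res <- moderated_test(sim$bin_het, groups)
  expect_gt(stats::ks.test(res$p.value, "punif")$p.value, 0.01)

  skip_if_not_installed("limma")
  x <- log2(sim$bin_het$het +
              attr(res, "transform")$pseudocount)
  design <- cbind(1, as.numeric(groups[colnames(x)] == "wild"))
  fit <- limma::eBayes(limma::lmFit(x, design))
  expect_equal(attr(res, "prior")$d0, fit$df.prior, tolerance = 0.01)
  expect_equal(attr(res, "prior")$s0_2, fit$s2.prior, tolerance = 0.01)
  expect_equal(res$p.value, fit$p.value[, 2], tolerance = 1e-8,
               ignore_attr = TRUE)
})

test_that("private-bin calling counts, sizes and directions", {
  res <- data.frame(
    chrom = "chr1", start = (0:999) * 1e6, end = (1:1000) * 1e6,
    p.value = c(rep(0.001, 51), runif(949, 0.2, 1)),
    private_to = c(rep("captive", 51), rep("wild", 949))
  )
  attr(res, "groups") <- c("wild", "captive")
  cp <- call_private(res, alpha = 0.05)
  expect_equal(cp$n_bins[cp$group == "captive"], 51)
  expect_equal(cp$fraction[cp$group == "captive"], 0.051)
  expect_equal(cp$mb[cp$group == "captive"], 51)
  expect_equal(cp$n_bins[cp$group == "wild"], 0)

  # no significant bins
  res2 <- res
  res2$p.value <- 0.5
  cp2 <- call_private(res2)
  expect_equal(cp2$fraction, c(0, 0))
})

test_that("partial terminal bins and underpowered bins are skipped", {
  d <- expand.grid(sample = sprintf("s%d", 1:6), bin = 1:20)
  d$chrom <- "chr1"
  d$start <- (d$bin - 1) * 1e6
  d$end <- pmin(d$bin * 1e6, 19.2e6)  # last bin only 200 kb
  set.seed(5)
  d$het <- runif(nrow(d), 1e-4, 1e-3)
  bh <- bin_het(d[, c("chrom", "start", "end", "sample", "het")])
  bh$het[3, 4:6] <- NA  # one group fully missing in bin 3
  groups <- setNames(rep(c("a", "b"), each = 3), sprintf("s%d", 1:6))
  res <- moderated_test(bh, groups)
  expect_equal(nrow(res), 18)
  expect_equal(attr(res, "skipped")$partial_bin, 1)
  expect_equal(attr(res, "skipped")$insufficient_samples, 1)
})
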