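#' Inverse of the trigamma function
#'
#' Solves `trigamma(y) = x` for `y > 0` by Newton iteration on a
#' monotone-convex transform, as needed by the method-of-moments fit of the
#' variance prior. Vectorised.
#'
#' @param x positive values.
#' @return y with `trigamma(y) = x`.
#' @export
trigamma_inverse <- function(x) {
  out <- x
  big <- x > 1e7
  out[big] <- 1 / sqrt(x[big])
  small <- x < 1e-6
  out[small] <- 1 / x[small]
  mid <- !(big | small)
  if (any(mid)) {
    y <- 0.5 + 1 / x[mid]
    for (i in 1:50) {
      tri <- trigamma(y)
      dif <- tri * (1 - tri / x[mid]) / psigamma(y, 2)
      y <- y + dif
      if (max(-dif / y) < 1e-8) break
    }
    out[mid] <- y
  }
  out
}

#' Fit the scaled inverse-chi-square variance prior (empirical Bayes)
#'
#' Under the hierarchical model s_g^2 | sigma_g^2 ~ sigma_g^2 chi^2_dg / dg
#' and 1/sigma_g^2 ~ chi^2_d0 / (d0 s0^2), the marginal distribution of
#' log s_g^2 is a shifted log-F. The prior degrees of freedom d0 and prior
#' variance s0^2 are estimated by matching the first two moments of
#' log s_g^2 (method of moments on the digamma/trigamma scale), and each
#' bin's variance is shrunk to the posterior
#' s~_g^2 = (d0 s0^2 + d_g s_g^2) / (d0 + d_g). When the observed spread of
#' the log variances is no larger than expected from chi-square sampling
#' alone, d0 is infinite and every s~_g^2 equals s0^2.
#'
#' @param s2 per-bin residual variances (> 0; zero variances are allowed and
#'   shrunk like any other value but do not enter the moment fit).
#' @param df residual degrees of freedom (scalar or per-bin vector).
#' @return list: `d0`, `s0_2`, `s2_post` (moderated variances), `df_total`
#'   (d0 + d_g, capped at 1e6 when d0 is infinite).
#' @export
fit_variance_prior <- function(s2, df) {
  if (length(df) == 1) df <- rep(df, length(s2))
  stopifnot(length(df) == length(s2), all(df > 0))
  pos <- s2 > 0
  if (sum(pos) < 10) stop("need >= 10 bins with positive variance")
  z <- log(s2[pos])
  e <- z - digamma(df[pos] / 2) + log(df[pos] / 2)
  emean <- mean(e)
  evar <- stats::var(e)
  t2 <- evar - mean(trigamma(df[pos] / 2))
  if (t2 > 0) {
    d0 <- 2 * trigamma_inverse(t2)
    s0_2 <- exp(emean + digamma(d0 / 2) - log(d0 / 2))
    s2_post <- (d0 * s0_2 + df * s2) / (d0 + df)
    df_total <- d0 + df
  } else {
    d0 <- Inf
    s0_2 <- exp(emean)
    s2_post <- rep(s0_2, length(s2))
    df_total <- rep(1e6, length(s2))
  }
  list(d0 = d0, s0_2 = s0_2, s2_post = s2_post, df_total = df_total)
}

#' Moderated two-group t-test on binned heterozygosity
#'
#' The per-bin private-variation test: heterozygosity values are
#' log2-transformed (with a pseudocount of half the smallest positive
#' observed value, unless supplied), per-bin two-group residual variances
#' are shrunk toward the empirical-Bayes prior fitted by
#' [fit_variance_prior()], and each bin is scored with the moderated
#' t-statistic t = (mean1 - mean2) / (s~ sqrt(1/n1 + 1/n2)) on d0 + d_g
#' degrees of freedom (the squared statistic is the moderated F for a
#' two-group comparison). Bins with fewer than 2 non-missing samples in
#' either group are skipped and reported, as are terminal partial bins
#' shorter than half the nominal bin size.
#'
#' @param bh a [bin_het()] object.
#' @param groups named character/factor mapping sample id to one of exactly
#'   two group labels (e.g. wild / captive).
#' @param log2_transform transform heterozygosity to log2(het + pseudocount)?
#' @param pseudocount pseudocount for the log transform; default half the
#'   smallest positive observed value.
#' @param trim_partial exclude bins shorter than 50% of the modal bin size.
#' @return data.frame (class `rohbin_result`), one row per tested bin:
#'   bin coordinates, group means (transformed scale), `logFC`
#'   (group1 - group2 on the log2 scale), `t`, `F`, `df_total`, `p.value`,
#'   `lower_in` (group with the smaller mean), `private_to` (the other
#'   group — the one retaining variation in that bin). Attributes:
#'   `prior` (the fitted [fit_variance_prior()] list), `groups` (level
#'   order), `transform`, `skipped` (bins dropped and why).
#' @export
moderated_test <- function(bh, groups, log2_transform = TRUE,
                           pseudocount = NULL, trim_partial = TRUE) {
  stopifnot(inherits(bh, "bin_het"))
  gvec <- groups[colnames(bh$het)]
  if (anyNA(gvec)) {
    stop("group label missing for sample(s): ",
         paste(colnames(bh$het)[is.na(gvec)], collapse = ", "))
  }
  lev <- unique(as.character(gvec))
  if (length(lev) != 2) stop("exactly two groups required; got: ",
                             paste(lev, collapse = ", "))
  het <- bh$het
  width <- bh$bins$end - bh$bins$start
  nominal <- as.numeric(names(sort(table(width), decreasing = TRUE))[1])
  partial <- trim_partial & width < 0.5 * nominal
  x <- het
  pc <- NA_real_
  if (log2_transform) {
    if (is.null(pseudocount)) {
      posv <- het[het > 0 & !is.na(het)]
      pseudocount <- if (length(posv)) min(posv) / 2 else 1e-9
    }
    pc <- pseudocount
    x <- log2(het + pseudocount)
  }
  i1 <- which(gvec == lev[1])
  i2 <- which(gvec == lev[2])
  n1 <- rowSums(!is.na(x[, i1, drop = FALSE]))
  n2 <- rowSums(!is.na(x[, i2, drop = FALSE]))
  testable <- n1 >= 2 & n2 >= 2 & !partial
  skipped <- data.frame(
    partial_bin = sum(partial),
    insufficient_samples = sum(!partial & (n1 < 2 | n2 < 2))
  )
  idx <- which(testable)
  m1 <- rowMeans(x[idx, i1, drop = FALSE], na.rm = TRUE)
  m2 <- rowMeans(x[idx, i2, drop = FALSE], na.rm = TRUE)
  rowvar <- function(m, mu) {
    rowSums((m - mu)^2, na.rm = TRUE)
  }
  ss <- rowvar(x[idx, i1, drop = FALSE], m1) + rowvar(x[idx, i2, drop = FALSE], m2)
  dg <- n1[idx] + n2[idx] - 2
  s2 <- ss / dg
  prior <- fit_variance_prior(s2, dg)
  se <- sqrt(prior$s2_post * (1 / n1[idx] + 1 / n2[idx]))
  tval <- (m1 - m2) / se
  p <- 2 * stats::pt(-abs(tval), df = prior$df_total)
  res <- data.frame(
    chrom = bh$bins$chrom[idx], start = bh$bins$start[idx],
    end = bh$bins$end[idx],
    mean_1 = m1, mean_2 = m2,
    logFC = if (log2_transform) m1 - m2 else log2(pmax(2^m1, 0) / pmax(2^m2, 0)),
    t = tval, F = tval^2, df_total = prior$df_total,
    p.value = p,
    lower_in = ifelse(m1 < m2, lev[1], lev[2]),
    private_to = ifelse(m1 < m2, lev[2], lev[1]),
    stringsAsFactors = FALSE
  )
  rownames(res) <- NULL
  attr(res, "prior") <- prior
  attr(res, "groups") <- lev
  attr(res, "transform") <- list(log2 = log2_transform, pseudocount = pc)
  attr(res, "skipped") <- skipped
  class(res) <- c("rohbin_result", "data.frame")
  res
}

#' Call private-variation bins per group
#'
#' Bins significantly different at `alpha` (raw p-values by default,
#' matching the p < 0.05 convention of the method; set `fdr` for a
#' Benjamini-Hochberg-adjusted call) are assigned to the group retaining
#' variation there (`private_to`): a bin with significantly lower
#' heterozygosity in one group is private variation of the other.
#'
#' @param results a [moderated_test()] result.
#' @param alpha significance level.
#' @param genome_length optional total genome length (bp) for the fraction;
#'   defaults to the summed length of the tested bins.
#' @param fdr apply Benjamini-Hochberg adjustment before thresholding.
#' @return data.frame per group: `group`, `n_bins`, `mb` (total private
#'   length in Mb), `fraction` of the genome. Attribute `bins`: list of the
#'   significant-bin data.frames per group.
#' @export
call_private <- function(results, alpha = 0.05, genome_length = NULL,
                         fdr = FALSE) {
  p <- if (fdr) stats::p.adjust(results$p.value, "BH") else results$p.value
  sig <- results[p < alpha, , drop = FALSE]
  glen <- genome_length %||% sum(results$end - results$start)
  groups <- attr(results, "groups")
  out <- do.call(rbind, lapply(groups, function(g) {
    b <- sig[sig$private_to == g, , drop = FALSE]
    tot <- sum(b$end - b$start)
    data.frame(group = g, n_bins = nrow(b), mb = tot / 1e6,
               fraction = tot / glen, stringsAsFactors = FALSE)
  }))
  attr(out, "bins") <- split(sig, sig$private_to)
  out
}

#' Write private bins as a BED file
#' @param results a [moderated_test()] result.
#' @param path output BED path.
#' @param alpha significance level.
#' @return `path`, invisibly.
#' @export
write_private_bed <- function(results, path, alpha = 0.05) {
  sig <- results[results$p.value < alpha, , drop = FALSE]
  utils::write.table(
    sig[, c("chrom", "start", "end", "private_to")], path,
    sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE
  )
  invisible(path)
}
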