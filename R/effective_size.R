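#' Inbreeding effective size from the rate of F_ROH increase
#'
#' Nef reflects the rate at which individuals become related: with mean
#' inbreeding F0 in the founder epoch and Ft in the contemporary epoch,
#' separated by t generations, the per-generation increase is
#' dF = (Ft - F0) / t and Nef = 1 / (2 dF). Vectors of per-individual F_ROH
#' are averaged with individual weighting (each sampled individual counts
#' once, regardless of cohort), which is how pooled contemporary samples
#' (e.g. late-captive plus wild) enter the estimate.
#'
#' @param F0 founder-epoch F_ROH (scalar mean or per-individual vector).
#' @param Ft contemporary-epoch F_ROH (scalar mean or per-individual vector).
#' @param t generations separating the epochs (>= 1).
#' @return list: `Nef`, `delta_F`, `F0`, `Ft`, `t`.
#' @export
nef <- function(F0, Ft, t) {
  stopifnot(t >= 1, all(F0 >= 0 & F0 <= 1), all(Ft >= 0 & Ft <= 1))
  F0 <- mean(F0)
  Ft <- mean(Ft)
  if (Ft <= F0) stop("no inbreeding accumulation: Ft <= F0")
  dF <- (Ft - F0) / t
  list(Nef = 1 / (2 * dF), delta_F = dF, F0 = F0, Ft = Ft, t = t)
}

#' Variance effective size from temporal allele-frequency change
#'
#' The temporal method of Waples (1989) with the Nei-Tajima standardised
#' frequency change: per usable SNP,
#' Fc = (p1 - p2)^2 / (pbar (1 - pbar)) with pbar the mean of the two epoch
#' frequencies; sites fixed in the pooled sample (pbar of 0 or 1) are
#' excluded. Averaging Fc over SNPs and subtracting the sampling
#' contribution 1/(2 n1) + 1/(2 n2) (the reciprocal harmonic mean of the
#' diploid sample sizes; equivalently 2/S with S the harmonic mean of the
#' allele counts 2 n) leaves the drift signal, and
#' NeV = t / (2 (Fc_mean - correction)).
#'
#' @param p1,p2 per-site derived-allele frequencies in the two epochs.
#' @param n1,n2 diploid sample sizes of the two epochs.
#' @param t generations between the epochs.
#' @return list: `NeV`, `F_mean` (mean Fc), `sampling_correction`, `S`
#'   (harmonic mean of allele counts), `n_sites` used.
#' @export
nev <- function(p1, p2, n1, n2, t) {
  stopifnot(length(p1) == length(p2), n1 > 0, n2 > 0, t >= 1)
  pbar <- (p1 + p2) / 2
  use <- pbar > 0 & pbar < 1
  if (!any(use)) stop("no usable (polymorphic) sites")
  Fc <- (p1[use] - p2[use])^2 / (pbar[use] * (1 - pbar[use]))
  F_mean <- mean(Fc)
  corr <- 1 / (2 * n1) + 1 / (2 * n2)
  S <- 2 / corr  # harmonic mean of the allele counts 2*n1, 2*n2
  if (F_mean <= corr) {
    stop("drift signal below sampling noise: mean Fc <= sampling correction")
  }
  list(NeV = t / (2 * (F_mean - corr)), F_mean = F_mean,
       sampling_correction = corr, S = S, n_sites = sum(use))
}

#' Effective size equivalent to an observed heterozygosity loss
#'
#' Inverts the neutral decay H_t = H_0 (1 - 1/(2 Ne))^t: an observed loss
#' from H0 to Ht over t generations is the erosion expected in an ideal
#' population of size Ne = 1 / (2 (1 - (Ht/H0)^(1/t))).
#'
#' @param H0,Ht genome-wide heterozygosity at the earlier/later epoch
#'   (0 < Ht < H0).
#' @param t generations elapsed (> 0).
#' @return list: `Ne`, `loss` (1 - Ht/H0), `t`.
#' @export
ne_from_het_loss <- function(H0, Ht, t) {
  stopifnot(H0 > 0, t > 0)
  if (Ht >= H0) stop("no heterozygosity loss: Ht >= H0")
  if (Ht <= 0) stop("Ht must be positive")
  ratio <- (Ht / H0)^(1 / t)
  list(Ne = 1 / (2 * (1 - ratio)), loss = 1 - Ht / H0, t = t)
}
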