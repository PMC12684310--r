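#' Studbook pedigree
#'
#' A validated pedigree: individuals with sire/dam links (either may be
#' unknown, in which case that side is treated as a unique, unrelated
#' founder), stored in topological order so that parents always precede
#' offspring. Cycles are rejected with the offending individuals listed.
#'
#' @param id character vector of unique individual ids.
#' @param sire,dam character vectors; `NA` or `""` for unknown.
#' @param sex,cohort optional per-individual labels.
#' @return an object of class `pedigree`.
#' @export
pedigree <- function(id, sire, dam, sex = NULL, cohort = NULL) {
  id <- as.character(id)
  norm <- function(x) {
    x <- as.character(x)
    x[is.na(x) | x == "" | x == "0"] <- NA_character_
    x
  }
  sire <- norm(sire)
  dam <- norm(dam)
  if (anyDuplicated(id)) {
    stop("duplicated pedigree id(s): ",
         paste(unique(id[duplicated(id)]), collapse = ", "))
  }
  for (p in list(sire = sire, dam = dam)) {
    unknown <- !is.na(p) & !(p %in% id)
    if (any(unknown)) {
      stop("parent id(s) not present in pedigree: ",
           paste(unique(p[unknown]), collapse = ", "))
    }
  }
  n <- length(id)
  si <- match(sire, id)
  di <- match(dam, id)
  # Kahn's algorithm; leftover nodes form the cycle(s)
  indeg <- integer(n)
  children <- vector("list", n)
  for (i in seq_len(n)) {
    for (p in c(si[i], di[i])) {
      if (!is.na(p)) {
        indeg[i] <- indeg[i] + 1L
        children[[p]] <- c(children[[p]], i)
      }
    }
  }
  queue <- which(indeg == 0L)
  topo <- integer(0)
  while (length(queue)) {
    v <- queue[1]
    queue <- queue[-1]
    topo <- c(topo, v)
    for (ch in children[[v]]) {
      indeg[ch] <- indeg[ch] - 1L
      if (indeg[ch] == 0L) queue <- c(queue, ch)
    }
  }
  if (length(topo) < n) {
    stop("pedigree contains a cycle involving: ",
         paste(id[setdiff(seq_len(n), topo)], collapse = ", "))
  }
  ord <- topo
  structure(
    list(id = id[ord], sire = sire[ord], dam = dam[ord],
         sex = if (!is.null(sex)) as.character(sex)[ord],
         cohort = if (!is.null(cohort)) as.character(cohort)[ord]),
    class = "pedigree"
  )
}

#' @export
print.pedigree <- function(x, ...) {
  founders <- is.na(x$sire) & is.na(x$dam)
  cat("pedigree:", length(x$id), "individuals,", sum(founders), "founders\n")
  invisible(x)
}

#' @export
as.data.frame.pedigree <- function(x, ...) {
  data.frame(id = x$id, sire = x$sire, dam = x$dam,
             sex = x$sex %||% NA_character_,
             cohort = x$cohort %||% NA_character_,
             stringsAsFactors = FALSE)
}

#' Recursive pedigree kinship matrix
#'
#' The kinship coefficient phi(i, j) is the probability that one allele drawn
#' at random from i and one from j are identical by descent. It is computed by
#' the standard recursion in topological order: for i below j,
#' phi(i, j) = (phi(sire_i, j) + phi(dam_i, j)) / 2 and
#' phi(i, i) = (1 + phi(sire_i, dam_i)) / 2, with an unknown parent
#' contributing 0. Founders are assumed unrelated and non-inbred, so a
#' parent-offspring pair has phi = 0.25 and the self-kinship of a non-inbred
#' individual ("selfing cross") is 0.5.
#'
#' @param ped a [pedigree()].
#' @return symmetric matrix of kinship coefficients with ids as dimnames;
#'   diagonal is `0.5 * (1 + F)`.
#' @export
kinship <- function(ped) {
  stopifnot(inherits(ped, "pedigree"))
  n <- length(ped$id)
  si <- match(ped$sire, ped$id)
  di <- match(ped$dam, ped$id)
  phi <- matrix(0, n, n, dimnames = list(ped$id, ped$id))
  for (i in seq_len(n)) {  # topological order: parents precede i
    s <- si[i]
    d <- di[i]
    if (i > 1) {
      js <- seq_len(i - 1L)
      v <- 0.5 * ((if (!is.na(s)) phi[s, js] else 0) +
                    (if (!is.na(d)) phi[d, js] else 0))
      phi[i, js] <- v
      phi[js, i] <- v
    }
    phi[i, i] <- 0.5 * (1 + (if (!is.na(s) && !is.na(d)) phi[s, d] else 0))
  }
  phi
}

#' Pedigree inbreeding coefficients
#'
#' F_i is the kinship of i's parents; any individual with an unknown parent
#' (including founders) gets F = 0.
#'
#' @param ped a [pedigree()].
#' @return named numeric vector of inbreeding coefficients.
#' @export
inbreeding <- function(ped) {
  phi <- kinship(ped)
  f <- 2 * diag(phi) - 1
  names(f) <- ped$id
  f
}

#' Classify a kinship coefficient into relatedness degrees
#'
#' Thresholds follow the standard kinship distribution values: unrelated at
#' 0; third-degree or higher for (0, 0.0625]; second-degree for
#' (0.0625, 0.1875]; first-degree for (0.1875, 0.375]. Each interval is
#' closed at its upper end, so a boundary value stays in the class whose
#' expectation it matches (e.g. 0.0625, the first-cousin expectation, is
#' third degree). Values in (0.375, 0.5] (possible for inbred pairs) are
#' labelled `beyond_first_degree`.
#'
#' @param theta kinship coefficient(s) in [0, 0.5].
#' @return character vector of categories.
#' @export
classify_relatedness <- function(theta) {
  if (any(theta < 0 | theta > 0.5)) stop("kinship out of range [0, 0.5]")
  cut_lab <- c("unrelated", "third_degree", "second_degree", "first_degree",
               "beyond_first_degree")
  idx <- findInterval(theta, c(0, 0.0625, 0.1875, 0.375), left.open = FALSE) + 1L
  # findInterval with left.open=FALSE puts boundary values in the upper bin
  idx[theta == 0] <- 1L
  idx[theta > 0 & theta <= 0.0625] <- 2L
  idx[theta > 0.0625 & theta <= 0.1875] <- 3L
  idx[theta > 0.1875 & theta <= 0.375] <- 4L
  idx[theta > 0.375] <- 5L
  cut_lab[idx]
}

#' Monte-Carlo gene dropping through a pedigree
#'
#' Drops founder alleles through the pedigree: each founder receives two
#' unique allele labels (or haplotypes supplied by the caller) and each
#' non-founder inherits one random allele from each parent, independently per
#' locus. Used both to simulate genotypes and as an independent estimator of
#' identity-by-descent probabilities.
#'
#' @param ped a [pedigree()].
#' @param n_loci number of independent loci to drop.
#' @param seed integer seed.
#' @param founder_alleles optional function(founder_index, n_loci) returning a
#'   2 x n_loci matrix of allele values; defaults to unique IBD labels.
#' @return list with `hap1`, `hap2`: individuals x loci matrices (rownames =
#'   ids, in pedigree order).
#' @export
gene_drop <- function(ped, n_loci, seed, founder_alleles = NULL) {
  seed <- require_seed(seed)
  set.seed(seed)
  n <- length(ped$id)
  si <- match(ped$sire, ped$id)
  di <- match(ped$dam, ped$id)
  hap1 <- matrix(NA_real_, n, n_loci, dimnames = list(ped$id, NULL))
  hap2 <- hap1
  lab <- 0
  for (i in seq_len(n)) {
    s <- si[i]
    d <- di[i]
    if (is.na(s)) {  # unknown sire side: unique founder alleles
      hap1[i, ] <- if (is.null(founder_alleles)) (lab <- lab + 1) else
        founder_alleles(i, n_loci)[1, ]
    } else {
      pick <- stats::runif(n_loci) < 0.5
      hap1[i, ] <- ifelse(pick, hap1[s, ], hap2[s, ])
    }
    if (is.na(d)) {
      hap2[i, ] <- if (is.null(founder_alleles)) (lab <- lab + 1) else
        founder_alleles(i, n_loci)[2, ]
    } else {
      pick <- stats::runif(n_loci) < 0.5
      hap2[i, ] <- ifelse(pick, hap1[d, ], hap2[d, ])
    }
  }
  list(hap1 = hap1, hap2 = hap2)
}

#' Monte-Carlo kinship estimate from gene dropping
#'
#' @param ped a [pedigree()].
#' @param n_loci number of independent drops.
#' @param seed integer seed.
#' @return matrix of IBD-sharing estimates comparable to [kinship()].
#' @export
kinship_gene_drop <- function(ped, n_loci = 1e4, seed = 1) {
  gd <- gene_drop(ped, n_loci, seed)
  n <- length(ped$id)
  phi <- matrix(0, n, n, dimnames = list(ped$id, ped$id))
  for (i in seq_len(n)) {
    for (j in seq_len(i)) {
      m <- (gd$hap1[i, ] == gd$hap1[j, ]) + (gd$hap1[i, ] == gd$hap2[j, ]) +
        (gd$hap2[i, ] == gd$hap1[j, ]) + (gd$hap2[i, ] == gd$hap2[j, ])
      if (i == j) m <- 2 + 2 * (gd$hap1[i, ] == gd$hap2[i, ])
      phi[i, j] <- phi[j, i] <- mean(m) / 4
    }
  }
  phi
}
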