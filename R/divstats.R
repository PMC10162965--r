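#' Per-locus alternate-allele frequency in one population
#'
#' `p = (number of alternate alleles) / (2 x non-missing individuals)`.
#'
#' @param gm a [genotype_matrix()]
#' @param individuals individual ids of the population (default: all).
#' @return numeric vector, one frequency per locus; `NA` where the locus has
#'   no calls in the population.
#' @export
allele_freq <- function(gm, individuals = colnames(gm$geno)) {
  if (!length(individuals)) stop("empty population")
  g <- gm$geno[, individuals, drop = FALSE]
  nn <- rowSums(!is.na(g))
  p <- rowSums(g, na.rm = TRUE) / (2 * nn)
  p[nn == 0] <- NA_real_
  stats::setNames(p, gm$loci$locus_id)
}

#' Observed and expected heterozygosity
#'
#' Per-locus observed heterozygosity (fraction of heterozygous calls) and
#' expected heterozygosity as unadjusted gene diversity `He = 2 p (1 - p)`,
#' with population means and standard deviations over loci.
#'
#' @inheritParams allele_freq
#' @return list with per-locus vectors `ho`, `he`, `p`, `n` (non-missing
#'   individuals) and scalar summaries `ho_mean`, `ho_sd`, `he_mean`,
#'   `he_sd`, `n_polymorphic`.
#' @export
heterozygosity <- function(gm, individuals = colnames(gm$geno)) {
  g <- gm$geno[, individuals, drop = FALSE]
  nn <- rowSums(!is.na(g))
  ho <- rowSums(g == 1, na.rm = TRUE) / nn
  ho[nn == 0] <- NA_real_
  p <- allele_freq(gm, individuals)
  he <- 2 * p * (1 - p)
  poly <- !is.na(p) & p > 0 & p < 1
  list(ho = ho, he = he, p = p, n = nn,
       ho_mean = mean(ho, na.rm = TRUE), ho_sd = stats::sd(ho, na.rm = TRUE),
       he_mean = mean(he, na.rm = TRUE), he_sd = stats::sd(he, na.rm = TRUE),
       n_polymorphic = sum(poly))
}

# Nei & Chesser small-sample gene diversity per locus:
#   Hs = n/(n-1) * (2p(1-p) - Ho/(2n))
nei_hs <- function(ho, p, n) {
  ifelse(n > 1, n / (n - 1) * (2 * p * (1 - p) - ho / (2 * n)), NA_real_)
}

#' Within-population inbreeding coefficient with bootstrap CI
#'
#' `F_IS = 1 - mean(Ho) / mean(Hs)` over polymorphic loci, where `Hs` is
#' Nei's small-sample-corrected gene diversity. The confidence interval is a
#' percentile bootstrap over loci.
#'
#' @inheritParams allele_freq
#' @param n_boot bootstrap replicates (default 100).
#' @param conf confidence level (default 0.95).
#' @param seed integer seed for the bootstrap.
#' @return list with `fis`, `ci` (length 2), `n_loci` used, `n_boot`.
#' @export
fis <- function(gm, individuals = colnames(gm$geno), n_boot = 100,
                conf = 0.95, seed = 1) {
  if (length(individuals) < 2) stop("need at least 2 individuals")
  h <- heterozygosity(gm, individuals)
  hs <- nei_hs(h$ho, h$p, h$n)
  use <- which(!is.na(h$ho) & !is.na(hs) & h$p > 0 & h$p < 1)
  if (!length(use)) {
    return(list(fis = NA_real_, ci = c(NA_real_, NA_real_),
                n_loci = 0L, n_boot = n_boot, note = "all loci monomorphic"))
  }
  ho <- h$ho[use]; hs <- hs[use]
  point <- 1 - mean(ho) / mean(hs)
  withr::local_seed(seed)
  reps <- vapply(seq_len(n_boot), function(b) {
    idx <- sample.int(length(use), replace = TRUE)
    1 - mean(ho[idx]) / mean(hs[idx])
  }, 0)
  alpha <- (1 - conf) / 2
  list(fis = point,
       ci = unname(stats::quantile(reps, c(alpha, 1 - alpha), na.rm = TRUE)),
       n_loci = length(use), n_boot = n_boot)
}

#' Per-population diversity summary
#'
#' One row per population: sample size, polymorphic-locus count, mean and sd
#' of observed/expected heterozygosity, inbreeding coefficient with
#' percentile-bootstrap CI.
#'
#' @param gm a [genotype_matrix()]
#' @param popmap a [pop_map()]
#' @param n_boot bootstrap replicates for the F_IS interval.
#' @param seed integer seed.
#' @return data frame of class `"diversity_summary"`.
#' @export
diversity_summary <- function(gm, popmap, n_boot = 100, seed = 1) {
  pops <- split_by_pop(gm, popmap)
  rows <- lapply(names(pops), function(p) {
    ids <- pops[[p]]
    h <- heterozygosity(gm, ids)
    f <- if (length(ids) >= 2) fis(gm, ids, n_boot = n_boot, seed = seed)
         else list(fis = NA_real_, ci = c(NA_real_, NA_real_))
    data.frame(population = p, n = length(ids),
               n_polymorphic = h$n_polymorphic,
               ho = h$ho_mean, ho_sd = h$ho_sd,
               he = h$he_mean, he_sd = h$he_sd,
               fis = f$fis, fis_lo = f$ci[1], fis_hi = f$ci[2],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("diversity_summary", "data.frame")
  out
}

# Weir & Cockerham (1984) per-locus variance components for r populations.
# n: r x L matrix of sample sizes (individuals with calls), p: r x L allele
# frequencies, h: r x L observed heterozygote frequencies.
wc_components <- function(n, p, h) {
  r <- nrow(n)
  nbar <- colMeans(n)
  nsum <- colSums(n)
  nc <- (nsum - colSums(n^2) / nsum) / (r - 1)
  pbar <- colSums(n * p) / nsum
  s2 <- colSums(n * sweep(p, 2, pbar)^2) / ((r - 1) * nbar)
  hbar <- colSums(n * h) / nsum
  a <- (nbar / nc) *
    (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4) / (nbar - 1))
  b <- (nbar / (nbar - 1)) *
    (pbar * (1 - pbar) - (r - 1) / r * s2 - (2 * nbar - 1) / (4 * nbar) * hbar)
  c_ <- hbar / 2
  list(a = a, b = b, c = c_)
}

#' Weir-Cockerham theta between two populations
#'
#' Multi-locus estimator of F_ST: per-locus variance components `a` (among
#' populations), `b` (among individuals within populations) and `c` (within
#' individuals) are summed over loci and `theta = sum(a) / sum(a + b + c)`
#' (ratio of sums). Loci that are monomorphic across both populations, or
#' with fewer than 2 calls in either, are skipped.
#'
#' @param gm a [genotype_matrix()]
#' @param ids_a,ids_b individual ids of the two populations.
#' @return list with `theta`, per-locus components `a`, `b`, `c`, and the
#'   logical vector `used` marking loci that entered the sums.
#' @export
fst_wc <- function(gm, ids_a, ids_b) {
  pops <- list(ids_a, ids_b)
  L <- n_loci(gm)
  n <- p <- h <- matrix(NA_real_, 2, L)
  for (k in 1:2) {
    g <- gm$geno[, pops[[k]], drop = FALSE]
    nn <- rowSums(!is.na(g))
    if (all(nn == 0)) stop("population ", k, " has no calls at any locus")
    n[k, ] <- nn
    p[k, ] <- rowSums(g, na.rm = TRUE) / (2 * pmax(nn, 1))
    h[k, ] <- rowSums(g == 1, na.rm = TRUE) / pmax(nn, 1)
  }
  usable <- colSums(n >= 2) == 2
  pbar_all <- colSums(n * p) / colSums(n)
  hbar_all <- colSums(n * h) / colSums(n)
  usable <- usable & !(pbar_all %in% c(0, 1) & hbar_all == 0)
  comp <- wc_components(n[, usable, drop = FALSE],
                        p[, usable, drop = FALSE],
                        h[, usable, drop = FALSE])
  theta <- sum(comp$a) / sum(comp$a + comp$b + comp$c)
  a <- b <- c_ <- rep(NA_real_, L)
  a[usable] <- comp$a; b[usable] <- comp$b; c_[usable] <- comp$c
  list(theta = theta, a = a, b = b, c = c_, used = usable)
}

# multi-population theta (ratio of sums across loci), used for the overall
# differentiation figure in reports
fst_wc_multi <- function(gm, popmap) {
  pops <- split_by_pop(gm, popmap)
  pops <- pops[lengths(pops) >= 2]
  r <- length(pops)
  if (r < 2) stop("need >= 2 populations with >= 2 individuals")
  L <- n_loci(gm)
  n <- p <- h <- matrix(NA_real_, r, L)
  for (k in seq_len(r)) {
    g <- gm$geno[, pops[[k]], drop = FALSE]
    nn <- rowSums(!is.na(g))
    n[k, ] <- nn
    p[k, ] <- rowSums(g, na.rm = TRUE) / (2 * pmax(nn, 1))
    h[k, ] <- rowSums(g == 1, na.rm = TRUE) / pmax(nn, 1)
  }
  usable <- colSums(n >= 2) == r
  pbar <- colSums(n * p) / colSums(n)
  hbar <- colSums(n * h) / colSums(n)
  usable <- usable & !(pbar %in% c(0, 1) & hbar == 0)
  comp <- wc_components(n[, usable, drop = FALSE], p[, usable, drop = FALSE],
                        h[, usable, drop = FALSE])
  sum(comp$a) / sum(comp$a + comp$b + comp$c)
}

#' Pairwise F_ST matrix with bootstrap CIs and permutation p-values
#'
#' Weir-Cockerham theta for every pair of populations. Uncertainty per cell:
#' a percentile bootstrap over loci (`n_boot` replicates) and a p-value from
#' permuting individuals between the pair (`n_perm` replicates; p = fraction
#' of permuted theta >= observed, with the +1 continuity correction).
#'
#' @param gm a [genotype_matrix()]
#' @param popmap a [pop_map()]; populations with a single individual are
#'   excluded with a warning.
#' @param n_boot bootstrap replicates (default 100).
#' @param n_perm permutation replicates for p-values (default 99; set 0 to
#'   skip).
#' @param conf confidence level.
#' @param seed integer seed.
#' @return object of class `"pairwise_fst"`: list of symmetric matrices
#'   `theta`, `lo`, `hi`, `p_value` plus `n_boot`, `n_perm`.
#' @export
pairwise_fst <- function(gm, popmap, n_boot = 100, n_perm = 99,
                         conf = 0.95, seed = 1) {
  pops <- split_by_pop(gm, popmap)
  small <- names(pops)[lengths(pops) < 2]
  if (length(small)) {
    warning("excluding population(s) of size < 2: ",
            paste(small, collapse = ", "))
    pops <- pops[lengths(pops) >= 2]
  }
  if (length(pops) < 2) stop("need at least 2 populations")
  nm <- names(pops)
  k <- length(nm)
  theta <- lo <- hi <- pv <- matrix(NA_real_, k, k, dimnames = list(nm, nm))
  withr::local_seed(seed)
  alpha <- (1 - conf) / 2
  for (i in seq_len(k - 1)) {
    for (j in (i + 1):k) {
      ids_a <- pops[[i]]; ids_b <- pops[[j]]
      res <- fst_wc(gm, ids_a, ids_b)
      th <- res$theta
      use <- which(res$used)
      boot <- vapply(seq_len(n_boot), function(b) {
        idx <- use[sample.int(length(use), replace = TRUE)]
        sum(res$a[idx]) / sum(res$a[idx] + res$b[idx] + res$c[idx])
      }, 0)
      ci <- stats::quantile(boot, c(alpha, 1 - alpha), na.rm = TRUE)
      p <- NA_real_
      if (n_perm > 0) {
        all_ids <- c(ids_a, ids_b)
        na <- length(ids_a)
        perm <- vapply(seq_len(n_perm), function(b) {
          sh <- sample(all_ids)
          fst_wc(gm, sh[seq_len(na)], sh[-seq_len(na)])$theta
        }, 0)
        p <- (sum(perm >= th) + 1) / (n_perm + 1)
      }
      theta[i, j] <- theta[j, i] <- th
      lo[i, j] <- lo[j, i] <- ci[1]
      hi[i, j] <- hi[j, i] <- ci[2]
      pv[i, j] <- pv[j, i] <- p
    }
  }
  structure(list(theta = theta, lo = lo, hi = hi, p_value = pv,
                 n_boot = n_boot, n_perm = n_perm),
            class = "pairwise_fst")
}

#' @export
print.pairwise_fst <- function(x, digits = 3, ...) {
  cat("Pairwise Weir-Cockerham F_ST (theta)\n")
  print(round(x$theta, digits))
  cat(sprintf("bootstrap reps: %d; permutation reps: %d\n",
              x$n_boot, x$n_perm))
  invisible(x)
}

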