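#' Composite-disequilibrium r-squared for one locus pair
#'
#' The squared Burrows composite-disequilibrium correlation for unphased
#' diploids, the per-pair statistic of the single-sample LD method: over
#' the jointly non-missing individuals,
#' `Delta = (S/(S-1)) * (mean(x y)/2 - 2 p_x p_y)` and
#' `r2 = Delta^2 / ((p_x(1-p_x) + D_x)(p_y(1-p_y) + D_y))`,
#' where `D` is the within-locus Hardy-Weinberg disequilibrium
#' (`freq(hom alt) - p^2`). This is the statistic whose no-LD sampling
#' expectation the published calibration curves ([expected_sample_r2()])
#' describe. `method = "pearson"` gives the plain squared Pearson
#' correlation of the dosage vectors instead (slightly smaller null
#' expectation; not matched to the calibration).
#'
#' @param x,y integer dosage vectors (`0/1/2/NA`) of equal length.
#' @param method `"burrows"` (default) or `"pearson"`.
#' @return list with `r2` and `s` (number of jointly complete
#'   individuals); `r2` is `NA` when fewer than 5 individuals are complete
#'   or either locus has zero variance after pairwise deletion.
#' @export
pair_r2 <- function(x, y, method = c("burrows", "pearson")) {
  method <- match.arg(method)
  ok <- !is.na(x) & !is.na(y)
  s <- sum(ok)
  if (s < 5) return(list(r2 = NA_real_, s = s))
  x <- x[ok]; y <- y[ok]
  if (stats::var(x) == 0 || stats::var(y) == 0) {
    return(list(r2 = NA_real_, s = s))
  }
  if (method == "pearson") {
    return(list(r2 = stats::cor(x, y)^2, s = s))
  }
  px <- mean(x) / 2; py <- mean(y) / 2
  delta <- (mean(x * y) / 2 - 2 * px * py) * s / (s - 1)
  dx <- mean(x == 2) - px^2
  dy <- mean(y == 2) - py^2
  den <- (px * (1 - px) + dx) * (py * (1 - py) + dy)
  if (den <= 0) return(list(r2 = NA_real_, s = s))
  list(r2 = delta^2 / den, s = s)
}

#' Expected sample r-squared under no true LD
#'
#' The finite-sample expectation of the squared genotype correlation for
#' independent loci, from the published calibration of the bias-corrected
#' single-sample LD method (Waples 2006; as used by NeEstimator v2):
#' for `S >= 30`, `E[r2] = 1/S + 3.19/S^2`; for `S < 30`,
#' `E[r2] = 0.0018 + 0.907/S + 4.44/S^2`. The sampling bias depends only on
#' the number of individuals sampled, so the same curve applies to both
#' mating systems; the mating system enters in [ne_from_r2()].
#'
#' @param s sample size (number of individuals; may be a non-integer
#'   harmonic mean).
#' @param mating `"random"` or `"monogamy"` (same expectation; kept for a
#'   uniform interface).
#' @return expected r-squared.
#' @export
expected_sample_r2 <- function(s, mating = c("random", "monogamy")) {
  mating <- match.arg(mating)
  if (s < 2) stop("sample size must be >= 2")
  if (s >= 30) 1 / s + 3.19 / s^2 else 0.0018 + 0.907 / s + 4.44 / s^2
}

#' Effective population size from adjusted r-squared
#'
#' Inverts the calibrated drift relationship between the bias-adjusted
#' r-squared and `Ne` (Waples 2006; NeEstimator v2 constants):
#' \describe{
#'   \item{random mating, `S >= 30`}{`Ne = (1/3 + sqrt(1/9 - 2.76 r2)) / (2 r2)`}
#'   \item{random mating, `S < 30`}{`Ne = (0.308 + sqrt(0.308^2 - 2.08 r2)) / (2 r2)`}
#'   \item{monogamy, `S >= 30`}{`Ne = (2/3 + sqrt(4/9 - 7.2 r2)) / (2 r2)`}
#'   \item{monogamy, `S < 30`}{`Ne = (0.618 + sqrt(0.618^2 - 5.24 r2)) / (2 r2)`}
#' }
#' A non-positive adjusted r-squared or a negative discriminant means no
#' detectable drift signal and returns `Inf`.
#'
#' @param r2_adj adjusted r-squared (mean observed r2 minus
#'   [expected_sample_r2()]).
#' @param mating `"random"` or `"monogamy"`.
#' @param s sample size used to pick the calibration branch (default large).
#' @return point estimate of Ne (possibly `Inf`).
#' @export
ne_from_r2 <- function(r2_adj, mating = c("random", "monogamy"), s = Inf) {
  mating <- match.arg(mating)
  if (is.na(r2_adj)) return(NA_real_)
  if (r2_adj <= 0) return(Inf)
  cc <- if (mating == "random") {
    if (s >= 30) c(1 / 3, 2.76) else c(0.308, 2.08)
  } else {
    if (s >= 30) c(2 / 3, 7.2) else c(0.618, 5.24)
  }
  disc <- cc[1]^2 - cc[2] * r2_adj
  if (disc < 0) return(Inf)
  (cc[1] + sqrt(disc)) / (2 * r2_adj)
}

# mean Burrows composite r2 over all locus pairs, weighted by pair sample
# size, plus the harmonic-mean S and pair count. Vectorised complete-data
# path; masked-crossprod pairwise-deletion path when calls are missing.
mean_pair_r2 <- function(geno_li) {
  x <- t(geno_li)                       # individuals x loci
  keep <- colSums(!is.na(x)) >= 5 &
    apply(x, 2, function(v) stats::var(v, na.rm = TRUE) > 0)
  x <- x[, keep, drop = FALSE]
  L <- ncol(x)
  if (L < 2) stop("fewer than 2 usable polymorphic loci")
  up <- upper.tri(matrix(0, L, L))
  if (!anyNA(x)) {
    S <- nrow(x)
    px <- colMeans(x) / 2
    dx <- colMeans(x == 2) - px^2
    vx <- px * (1 - px) + dx            # = half the MLE dosage variance
    delta <- (crossprod(x) / S / 2 - 2 * tcrossprod(px)) * S / (S - 1)
    r2m <- delta^2 / tcrossprod(vx)
    r2 <- r2m[up]
    s <- rep(S, length(r2))
    bad <- !is.finite(r2)
    r2 <- r2[!bad]; s <- s[!bad]
  } else {
    m <- !is.na(x)
    x0 <- x; x0[!m] <- 0
    h0 <- (x == 2); h0[!m] <- FALSE
    mm <- m * 1
    cnt <- crossprod(mm)                 # pair sample sizes
    sx <- crossprod(x0, mm)              # sum of x over jointly observed
    sxy <- crossprod(x0)                 # sum of x*y over jointly observed
    shom <- crossprod(h0 * 1, mm)        # hom-alt counts over joint sets
    S <- cnt
    px <- sx / (2 * S)
    py <- t(px)
    delta <- (sxy / S / 2 - 2 * px * py) * S / (S - 1)
    dx <- shom / S - px^2
    vx <- px * (1 - px) + dx
    den <- vx * t(vx)
    r2m <- delta^2 / den
    r2 <- r2m[up]
    s <- S[up]
    bad <- !is.finite(r2) | s < 5
    r2 <- r2[!bad]; s <- s[!bad]
  }
  if (!length(r2)) stop("no usable locus pairs")
  list(r2_mean = sum(r2 * s) / sum(s),
       s_harmonic = length(s) / sum(1 / s),
       n_pairs = length(r2), n_loci = L)
}

#' Single-sample LD estimate of local effective population size
#'
#' Implements the bias-corrected LD method: rare alleles below `pcrit` are
#' screened out within the focal population, all locus pairs' squared
#' genotype correlations are averaged (weighted by pair sample size), the
#' sampling expectation at the harmonic-mean sample size is subtracted, and
#' the adjusted r-squared is inverted to `Ne` under the chosen mating
#' system. Confidence intervals come from a delete-one-individual jackknife
#' on the adjusted r-squared, mapped through the Ne formula.
#'
#' @param gm a [genotype_matrix()].
#' @param individuals ids of the focal population's sample.
#' @param pcrit minor-allele-frequency screening floor (the study's values
#'   are 0.02 and 0.05).
#' @param mating `"random"` or `"monogamy"`.
#' @param exclude ids to drop before estimation (e.g. known immigrants,
#'   which bias Ne upward).
#' @param ci compute the jackknife CI (default TRUE; the jackknife re-runs
#'   the pair sums once per individual).
#' @param conf confidence level.
#' @return object of class `"ne_estimate"`.
#' @export
estimate_ne <- function(gm, individuals = colnames(gm$geno), pcrit = 0.02,
                        mating = c("random", "monogamy"), exclude = NULL,
                        ci = TRUE, conf = 0.95) {
  mating <- match.arg(mating)
  individuals <- setdiff(individuals, exclude)
  if (length(individuals) < 10) stop("need >= 10 individuals after exclusions")
  sub <- gm[, individuals]
  sub <- filter_maf(sub, pcrit = pcrit)
  if (n_loci(sub) < 2) stop("fewer than 2 polymorphic loci after screening")
  est <- mean_pair_r2(sub$geno)
  er2 <- expected_sample_r2(est$s_harmonic, mating)
  r2_adj <- est$r2_mean - er2
  ne <- ne_from_r2(r2_adj, mating, s = est$s_harmonic)
  ci_lo <- ci_hi <- NA_real_
  if (ci) {
    n <- length(individuals)
    jack <- vapply(seq_len(n), function(j) {
      e <- mean_pair_r2(sub$geno[, -j, drop = FALSE])
      e$r2_mean - expected_sample_r2(e$s_harmonic, mating)
    }, 0)
    jbar <- mean(jack)
    jvar <- (n - 1) / n * sum((jack - jbar)^2)
    z <- stats::qnorm(1 - (1 - conf) / 2)
    r2_lo <- r2_adj - z * sqrt(jvar)
    r2_hi <- r2_adj + z * sqrt(jvar)
    # higher r2 -> smaller Ne, so the CI endpoints swap
    ci_lo <- ne_from_r2(r2_hi, mating, s = est$s_harmonic)
    ci_hi <- ne_from_r2(r2_lo, mating, s = est$s_harmonic)
  }
  structure(list(mating = mating, pcrit = pcrit,
                 n_individuals = length(individuals),
                 n_loci = est$n_loci, n_pairs = est$n_pairs,
                 s_harmonic = est$s_harmonic,
                 r2_mean = est$r2_mean, r2_expected = er2, r2_adj = r2_adj,
                 ne = ne, ci = c(ci_lo, ci_hi), conf = conf),
            class = "ne_estimate")
}

#' @export
print.ne_estimate <- function(x, ...) {
  cat(sprintf("LD Ne estimate (%s mating, Pcrit = %g)\n", x$mating, x$pcrit))
  cat(sprintf("  S = %d individuals, %d loci, %d pairs (harmonic-mean S %.1f)\n",
              x$n_individuals, x$n_loci, x$n_pairs, x$s_harmonic))
  cat(sprintf("  mean r2 = %.6f, E[r2|S] = %.6f, adjusted = %.6f\n",
              x$r2_mean, x$r2_expected, x$r2_adj))
  cat(sprintf("  Ne = %.1f", x$ne))
  if (!anyNA(x$ci)) {
    cat(sprintf("  (%g%% CI %.1f-%.1f)", 100 * x$conf, x$ci[1], x$ci[2]))
  }
  cat("\n")
  invisible(x)
}

#' Table of Ne estimates over populations, mating systems and Pcrit values
#'
#' @param gm a [genotype_matrix()]
#' @param popmap a [pop_map()]
#' @param pops population labels to estimate (default: all with >= 10
#'   individuals).
#' @param pcrit numeric vector of screening values.
#' @param mating character vector of mating systems.
#' @param exclude ids excluded everywhere (e.g. identified migrants).
#' @param ci compute jackknife CIs.
#' @return data frame, one row per (population, mating, pcrit).
#' @export
ne_table <- function(gm, popmap, pops = NULL, pcrit = c(0.05, 0.02),
                     mating = c("random", "monogamy"), exclude = NULL,
                     ci = TRUE) {
  groups <- split_by_pop(gm, popmap)
  groups <- lapply(groups, setdiff, y = exclude)
  if (is.null(pops)) pops <- names(groups)[lengths(groups) >= 10]
  rows <- list()
  for (p in pops) {
    for (m in mating) {
      for (pc in pcrit) {
        e <- estimate_ne(gm, groups[[p]], pcrit = pc, mating = m, ci = ci)
        rows[[length(rows) + 1L]] <- data.frame(
          population = p, mating = m, pcrit = pc,
          n = e$n_individuals, n_loci = e$n_loci,
          r2_mean = e$r2_mean, r2_adj = e$r2_adj,
          ne = e$ne, ci_lo = e$ci[1], ci_hi = e$ci[2],
          stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, rows)
}
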