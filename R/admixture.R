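#' Admixture-model Gibbs sampler for population structure
#'
#' Bayesian clustering of individuals into `K` clusters with admixture:
#' each individual `i` has membership proportions `q_i` (Dirichlet prior
#' with parameter `alpha`), each cluster `k` has per-locus alternate-allele
#' frequencies `p_kl`, and every allele copy is drawn by first picking an
#' origin cluster from `q_i`, then the allele from `p_kl`. The sampler
#' alternates:
#' \enumerate{
#'   \item origin assignments `Z` of each allele copy (categorical,
#'     conditioned on `Q` and `P`);
#'   \item cluster frequencies `P`: under `freq_model = "independent"`, a
#'     conjugate Beta(1 + alt, 1 + ref) update; under `"correlated"`, the
#'     F-model — `p_kl ~ Beta(p_l^A (1-F_k)/F_k, (1-p_l^A)(1-F_k)/F_k)`
#'     around an ancestral frequency `p^A` — with conjugate `P` updates and
#'     Metropolis updates for `p^A` (uniform prior) and the per-cluster
#'     drift `F_k` (half-normal-style prior with mean 0.01, following the
#'     original model description);
#'   \item memberships `q_i ~ Dirichlet(alpha + counts)`;
#'   \item optionally (`alpha_prior = "cluster"`) cluster-specific `alpha_k`
#'     by Metropolis steps, the unbalanced-sampling-robust alternative
#'     ancestry prior.
#' }
#'
#' The model evidence is estimated, as in the standard implementation of
#' this model, by `ln P(X|K) = mean(lnL) - var(lnL)/2` over post-burn-in
#' iterations.
#'
#' @param gm a [genotype_matrix()] of biallelic loci.
#' @param K number of clusters (>= 1).
#' @param burnin,iters burn-in and retained MCMC iterations. Defaults are
#'   desk-scale (2000/5000); production-scale runs simply raise them.
#' @param alpha initial (or fixed) Dirichlet parameter; default `1/K`, the
#'   recommended choice for unbalanced samples.
#' @param freq_model `"correlated"` (F-model, default) or `"independent"`.
#' @param alpha_prior `"fixed"` or `"cluster"` (per-cluster alpha updated by
#'   Metropolis).
#' @param seed integer seed.
#' @param thin keep every `thin`-th retained iteration for the Q average
#'   (default 5).
#' @return object of class `"q_matrix"`: list with `q` (posterior-mean
#'   memberships, rows sum to 1), `K`, `lnp` (estimated `ln P(X|K)`),
#'   `lnl_trace` (per-retained-iteration log-likelihood), `seed`, `alpha`
#'   (final), `freq_model`.
#' @export
admixture_gibbs <- function(gm, K, burnin = 2000, iters = 5000,
                            alpha = 1 / K,
                            freq_model = c("correlated", "independent"),
                            alpha_prior = c("fixed", "cluster"),
                            seed = 1, thin = 5) {
  freq_model <- match.arg(freq_model)
  alpha_prior <- match.arg(alpha_prior)
  if (K < 1) stop("K must be >= 1")
  if (iters < 100) warning("iters < 100; estimates will be unstable")
  g <- t(gm$geno)                      # individuals x loci
  N <- nrow(g); L <- ncol(g)
  M <- !is.na(g)
  if (!any(M)) stop("no genotype calls")
  g0 <- g; g0[!M] <- 0L
  A1 <- (g0 >= 1) * 1                  # allele of copy 1
  A2 <- (g0 >= 2) * 1                  # allele of copy 2
  A1i <- A1; storage.mode(A1i) <- "integer"
  A2i <- A2; storage.mode(A2i) <- "integer"
  Mnum <- M * 1
  het_const <- sum(g0[M] == 1) * log(2)
  withr::local_seed(seed)

  clamp <- function(x, eps = 1e-9) pmin(pmax(x, eps), 1 - eps)
  # init
  pA <- clamp(colSums(g0) / pmax(2 * colSums(Mnum), 1))
  P <- matrix(rep(pA, each = K), K, L) +
    matrix(stats::rnorm(K * L, 0, 0.01), K, L)
  P <- clamp(P)
  Fk <- rep(0.05, K)
  alpha_k <- rep(alpha, K)
  Q <- matrix(stats::rgamma(N * K, 1), N, K)
  Q <- Q / rowSums(Q)

  lnl_of <- function(Q, P) {
    pi_ <- clamp(Q %*% P)
    sum((g0 * log(pi_) + (2 - g0) * log(1 - pi_)) * Mnum) + het_const
  }

  n_keep <- 0L
  q_sum <- matrix(0, N, K)
  lnl_trace <- numeric(iters)
  total <- burnin + iters
  f_prior_sd <- 0.05; f_prior_mean <- 0.01

  for (it in seq_len(total)) {
    if (K == 1L) {
      nik <- cbind(rowSums(Mnum * 2))
      alt_k <- rbind(colSums((A1 + A2) * Mnum))
      tot_k <- rbind(colSums(2 * Mnum))
    } else {
      cnt <- .gibbs_origin_counts(Q, P, A1i, A2i, M)
      nik <- cnt$nik
      alt_k <- cnt$alt_k
      tot_k <- cnt$tot_k
    }
    ref_k <- tot_k - alt_k

    # P update (conjugate given prior)
    if (freq_model == "independent") {
      pa_shape <- 1 + alt_k
      pb_shape <- 1 + ref_k
    } else {
      prior_a <- matrix(rep(pA, each = K), K, L) * (1 - Fk) / Fk
      prior_b <- matrix(rep(1 - pA, each = K), K, L) * (1 - Fk) / Fk
      pa_shape <- prior_a + alt_k
      pb_shape <- prior_b + ref_k
    }
    P <- clamp(matrix(stats::rbeta(K * L, pa_shape, pb_shape), K, L))

    if (freq_model == "correlated") {
      # Metropolis on ancestral frequencies pA (uniform prior)
      prop <- clamp(pA + stats::rnorm(L, 0, 0.05), 1e-4)
      lr <- beta_logdens_cols(P, prop, Fk) - beta_logdens_cols(P, pA, Fk)
      acc <- log(stats::runif(L)) < lr
      pA[acc] <- prop[acc]
      # Metropolis on per-cluster drift Fk (truncated-normal prior, mean 0.01)
      for (k in seq_len(K)) {
        fprop <- Fk[k] + stats::rnorm(1, 0, 0.01)
        if (fprop <= 1e-4 || fprop >= 0.99) next
        lr <- sum(beta_logdens_row(P[k, ], pA, fprop)) -
          sum(beta_logdens_row(P[k, ], pA, Fk[k])) +
          (-(fprop - f_prior_mean)^2 + (Fk[k] - f_prior_mean)^2) /
            (2 * f_prior_sd^2)
        if (log(stats::runif(1)) < lr) Fk[k] <- fprop
      }
    }

    # Q update
    Q <- matrix(stats::rgamma(N * K,
                              shape = sweep(nik, 2, alpha_k, `+`)), N, K)
    Q <- Q / pmax(rowSums(Q), 1e-300)

    if (alpha_prior == "cluster" && K > 1) {
      lq <- log(clamp(Q))
      for (k in seq_len(K)) {
        aprop <- alpha_k[k] + stats::rnorm(1, 0, 0.05)
        if (aprop <= 0.001 || aprop > 10) next
        a_new <- alpha_k; a_new[k] <- aprop
        lr <- dirichlet_loglik(lq, a_new) - dirichlet_loglik(lq, alpha_k)
        if (log(stats::runif(1)) < lr) alpha_k[k] <- aprop
      }
    }

    if (it > burnin) {
      idx <- it - burnin
      lnl_trace[idx] <- lnl_of(Q, P)
      if (idx %% thin == 0L) {
        q_sum <- q_sum + Q
        n_keep <- n_keep + 1L
      }
    }
  }

  qbar <- q_sum / n_keep
  qbar <- qbar / rowSums(qbar)
  dimnames(qbar) <- list(rownames(g), paste0("q", seq_len(K)))
  lnp <- mean(lnl_trace) - stats::var(lnl_trace) / 2
  structure(list(q = qbar, K = K, lnp = lnp, lnl_trace = lnl_trace,
                 seed = seed, alpha = alpha_k, freq_model = freq_model),
            class = "q_matrix")
}

# sum over clusters of Beta log-density of P[, l] given ancestral pa[l], F
beta_logdens_cols <- function(P, pa, Fk) {
  K <- nrow(P)
  out <- 0
  for (k in seq_len(K)) {
    a <- pa * (1 - Fk[k]) / Fk[k]
    b <- (1 - pa) * (1 - Fk[k]) / Fk[k]
    out <- out + stats::dbeta(P[k, ], a, b, log = TRUE)
  }
  out
}

beta_logdens_row <- function(p_row, pa, f) {
  a <- pa * (1 - f) / f
  b <- (1 - pa) * (1 - f) / f
  stats::dbeta(p_row, a, b, log = TRUE)
}

# log-likelihood of all rows of log-Q under Dirichlet(alpha)
dirichlet_loglik <- function(lq, alpha) {
  n <- nrow(lq)
  n * (lgamma(sum(alpha)) - sum(lgamma(alpha))) +
    sum(lq %*% (alpha - 1))
}

#' Run the admixture sampler over a K grid with replicates
#'
#' Convenience wrapper producing everything [evanno_delta_k()] and
#' [align_runs()] need: `n_reps` independently seeded runs for each K in
#' `k_grid`.
#'
#' @inheritParams admixture_gibbs
#' @param k_grid integer vector of K values (consecutive for delta-K).
#' @param n_reps replicate runs per K.
#' @param seed base seed; run seeds are derived deterministically from it.
#' @param ... passed to [admixture_gibbs()].
#' @return list with `runs` (list of lists of `q_matrix` by K), `lnp`
#'   (replicates x K matrix), `delta_k` (when the grid allows), and
#'   `aligned` (per K, the [align_runs()] average).
#' @export
structure_scan <- function(gm, k_grid = 1:5, n_reps = 5, seed = 1, ...) {
  runs <- vector("list", length(k_grid))
  names(runs) <- as.character(k_grid)
  lnp <- matrix(NA_real_, n_reps, length(k_grid),
                dimnames = list(NULL, as.character(k_grid)))
  for (ki in seq_along(k_grid)) {
    K <- k_grid[ki]
    runs[[ki]] <- lapply(seq_len(n_reps), function(r) {
      run_seed <- as.integer((as.numeric(seed) + 1000 * ki + r) %% 2147483647)
      admixture_gibbs(gm, K = K, seed = run_seed, ...)
    })
    lnp[, ki] <- vapply(runs[[ki]], function(x) x$lnp, 0)
  }
  dk <- if (length(k_grid) >= 3 && all(diff(k_grid) == 1) && n_reps >= 2) {
    evanno_delta_k(lnp)
  }
  aligned <- lapply(runs, align_runs)
  list(runs = runs, lnp = lnp, delta_k = dk, aligned = aligned)
}
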