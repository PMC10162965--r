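#' Principal coordinates analysis of SNP genotypes
#'
#' Missing dosages are imputed with the locus mean, individuals are rows,
#' columns (loci) are centred, and classical multidimensional scaling
#' (Gower double-centring + eigendecomposition of Euclidean distances) is
#' applied. Percent variance per axis is computed over positive eigenvalues
#' only; negative eigenvalues are reported but carry no variance share.
#'
#' @param gm a [genotype_matrix()]
#' @param n_axes number of axes to retain (default 2).
#' @return object of class `"pcoa_result"`: list with `coords` (individuals
#'   x axes), `eig` (all eigenvalues, non-increasing), `percent_var`
#'   (per retained axis).
#' @export
pcoa <- function(gm, n_axes = 2) {
  x <- impute_dosage(gm)
  if (nrow(x) < 2) stop("need at least 2 individuals")
  x <- scale(x, center = TRUE, scale = FALSE)
  d <- stats::dist(x)
  k <- min(n_axes, nrow(x) - 1)
  mds <- stats::cmdscale(d, k = k, eig = TRUE)
  eig <- mds$eig
  pos <- sum(eig[eig > 0])
  pv <- 100 * pmax(eig[seq_len(k)], 0) / pos
  coords <- mds$points
  colnames(coords) <- paste0("axis", seq_len(ncol(coords)))
  structure(list(coords = coords, eig = eig, percent_var = pv),
            class = "pcoa_result")
}

#' @export
print.pcoa_result <- function(x, ...) {
  cat(sprintf("PCoA: %d individuals, %d retained axes\n",
              nrow(x$coords), ncol(x$coords)))
  cat("percent variance:", paste(sprintf("%.1f", x$percent_var),
                                 collapse = ", "), "\n")
  invisible(x)
}

# loci x individuals -> individuals x loci numeric matrix with per-locus
# mean imputation; errors if an individual has no data at all
impute_dosage <- function(gm) {
  g <- t(gm$geno)
  if (any(rowSums(!is.na(g)) == 0)) {
    stop("individual(s) with all loci missing: ",
         paste(rownames(g)[rowSums(!is.na(g)) == 0], collapse = ", "))
  }
  mu <- colMeans(g, na.rm = TRUE)
  mu[is.nan(mu)] <- 0
  idx <- which(is.na(g))
  if (length(idx)) g[idx] <- mu[(idx - 1) %/% nrow(g) + 1]
  g
}

#' Select the number of genetic clusters by k-means + BIC
#'
#' Dosages are reduced to `n_pca` principal components; k-means (with
#' multiple restarts) is run for `K = 1..k_max`; each solution is scored by
#' `BIC(K) = n log(WSS_K / n) + K log(n)` and the minimiser is returned.
#'
#' @param gm a [genotype_matrix()]
#' @param k_max largest number of clusters considered (default 8).
#' @param n_pca number of principal components retained (default
#'   `min(n/2, 40)`: enough dimensions that splitting unstructured noise
#'   cannot pay for the `K log(n)` penalty).
#' @param n_start k-means restarts per K (default 10).
#' @param seed integer seed.
#' @return object of class `"bic_clusters"`: list with data frame `table`
#'   (K, WSS, BIC), `best_k`, and `cluster` (assignment at `best_k`).
#' @export
find_clusters_bic <- function(gm, k_max = 8, n_pca = NULL, n_start = 10,
                              seed = 1) {
  x <- impute_dosage(gm)
  n <- nrow(x)
  if (k_max >= n) stop("k_max must be smaller than the number of individuals")
  n_pca <- n_pca %||% min(floor(n / 2), 40)
  pc <- stats::prcomp(x, center = TRUE, scale. = FALSE)
  n_pca <- min(n_pca, ncol(pc$x))
  y <- pc$x[, seq_len(n_pca), drop = FALSE]
  withr::local_seed(seed)
  rows <- vector("list", k_max)
  fits <- vector("list", k_max)
  for (K in seq_len(k_max)) {
    if (K == 1) {
      wss <- sum(scale(y, scale = FALSE)^2)
      fits[[K]] <- rep(1L, n)
    } else {
      km <- stats::kmeans(y, centers = K, nstart = n_start, iter.max = 50)
      wss <- km$tot.withinss
      fits[[K]] <- km$cluster
    }
    rows[[K]] <- data.frame(K = K, wss = wss,
                            bic = n * log(wss / n) + K * log(n))
  }
  tab <- do.call(rbind, rows)
  best <- tab$K[which.min(tab$bic)]
  structure(list(table = tab, best_k = best, cluster = fits[[best]]),
            class = "bic_clusters")
}

#' @export
print.bic_clusters <- function(x, ...) {
  cat("k-means / BIC cluster selection\n")
  print(transform(x$table, bic = round(bic, 2), wss = signif(wss, 5)),
        row.names = FALSE)
  cat("best K:", x$best_k, "\n")
  invisible(x)
}

#' Discriminant analysis of principal components (DAPC)
#'
#' Dosages are reduced to `n_pca` principal components, then a canonical
#' (linear) discriminant analysis maximises between-group relative to
#' within-group variance. Per-individual membership probabilities come from
#' the Gaussian class densities on the discriminant axes.
#'
#' @param gm a [genotype_matrix()]
#' @param groups factor/character of group labels, one per individual (in
#'   `colnames(gm$geno)` order), or a named vector.
#' @param n_pca principal components retained (default `min(n/3, 40)`, a
#'   common guard against overfitting the discriminant space).
#' @param n_da discriminant axes retained; clipped to `n_groups - 1` with a
#'   warning.
#' @return object of class `"dapc_result"`: list with `coords` (individuals
#'   x discriminant axes), `posterior` (individuals x groups, rows sum to
#'   1), `assigned` (max-posterior group), `groups`.
#' @export
dapc <- function(gm, groups, n_pca = NULL, n_da = NULL) {
  ids <- colnames(gm$geno)
  if (!is.null(names(groups))) groups <- groups[ids]
  groups <- factor(groups)
  if (nlevels(groups) < 2) stop("need at least 2 groups")
  if (any(table(groups) < 2)) stop("every group needs at least 2 members")
  x <- impute_dosage(gm)
  n <- nrow(x)
  n_pca <- n_pca %||% min(floor(n / 3), 40)
  pc <- stats::prcomp(x, center = TRUE, scale. = FALSE)
  n_pca <- min(n_pca, ncol(pc$x))
  y <- pc$x[, seq_len(n_pca), drop = FALSE]
  max_da <- nlevels(groups) - 1
  n_da <- n_da %||% max_da
  if (n_da > max_da) {
    warning("n_da clipped to number of groups - 1 (", max_da, ")")
    n_da <- max_da
  }
  fit <- tryCatch(MASS::lda(y, grouping = groups), error = function(e) {
    if (!grepl("constant within groups", conditionMessage(e))) stop(e)
    # perfectly separated groups collapse the within-group variance;
    # regularise with a deterministic hair of noise
    jit <- withr::with_seed(1, matrix(stats::rnorm(length(y)), nrow(y)))
    y <<- y + jit * 1e-3 * max(stats::sd(y), 1e-12)
    MASS::lda(y, grouping = groups)
  })
  pred <- stats::predict(fit, y)
  coords <- pred$x[, seq_len(min(n_da, ncol(pred$x))), drop = FALSE]
  structure(list(coords = coords, posterior = pred$posterior,
                 assigned = as.character(pred$class), groups = groups),
            class = "dapc_result")
}

#' @export
print.dapc_result <- function(x, ...) {
  cat(sprintf("DAPC: %d individuals, %d groups, %d discriminant axes\n",
              nrow(x$coords), nlevels(x$groups), ncol(x$coords)))
  acc <- mean(x$assigned == as.character(x$groups))
  cat(sprintf("reassignment to own group: %.1f%%\n", 100 * acc))
  invisible(x)
}

#' Evanno delta-K table from replicate admixture runs
#'
#' Given estimated log model evidence `ln P(X|K)` for a grid of K values
#' with several replicate runs each, computes per K the mean and sd over
#' runs, the first difference `L'(K) = mean L(K) - mean L(K-1)`, the
#' absolute second difference `|L''(K)| = |L(K+1) - 2 L(K) + L(K-1)|`, and
#' `deltaK(K) = |L''(K)| / sd(L(K))`. Endpoints of the grid have no deltaK;
#' a zero sd leaves deltaK undefined (`NaN`) at that K.
#'
#' @param runs matrix of `ln P(X|K)` values, replicates in rows and one
#'   column per K (column names give K, else `1..ncol`); or a data frame
#'   with columns `K` and `lnp`.
#' @return data frame of class `"delta_k_table"`: K, mean_lnp, sd_lnp,
#'   first difference `lprime`, `lsecond`, `delta_k`.
#' @export
evanno_delta_k <- function(runs) {
  if (is.data.frame(runs) && all(c("K", "lnp") %in% names(runs))) {
    ks <- sort(unique(runs$K))
    m <- vapply(ks, function(k) mean(runs$lnp[runs$K == k]), 0)
    s <- vapply(ks, function(k) stats::sd(runs$lnp[runs$K == k]), 0)
    nrep <- min(table(runs$K))
  } else {
    runs <- as.matrix(runs)
    ks <- as.integer(colnames(runs) %||% seq_len(ncol(runs)))
    m <- colMeans(runs)
    s <- apply(runs, 2, stats::sd)
    nrep <- nrow(runs)
  }
  if (length(ks) < 3) stop("need at least 3 consecutive K values")
  if (any(diff(ks) != 1)) stop("K grid must be consecutive")
  if (nrep < 2) stop("need at least 2 replicates per K")
  nk <- length(ks)
  lprime <- c(NA, diff(m))
  lsecond <- rep(NA_real_, nk)
  interior <- 2:(nk - 1)
  lsecond[interior] <- abs(m[interior + 1] - 2 * m[interior] + m[interior - 1])
  delta_k <- ifelse(s > 0, lsecond / s, NaN)
  out <- data.frame(K = ks, mean_lnp = m, sd_lnp = s, lprime = lprime,
                    lsecond = lsecond, delta_k = delta_k)
  class(out) <- c("delta_k_table", "data.frame")
  out
}

#' Best K under the Evanno criterion
#' @param dk a [evanno_delta_k()] table
#' @return the interior K maximising delta-K.
#' @export
best_k_evanno <- function(dk) {
  ok <- which(is.finite(dk$delta_k))
  if (!length(ok)) stop("delta-K undefined everywhere")
  dk$K[ok[which.max(dk$delta_k[ok])]]
}

#' Align and average replicate admixture runs (CLUMPP-style)
#'
#' Cluster labels are arbitrary in each run. Every run's columns are
#' permuted to best match the first run (the permutation maximising
#' `trace(Q' t(Q_ref))` over all K! permutations, i.e. the optimal label
#' assignment), then the aligned matrices are averaged element-wise and rows
#' renormalised to sum to 1.
#'
#' @param qmatrices list of [q_matrix] objects or plain individuals-x-K
#'   matrices with identical row sets and K.
#' @return the averaged Q matrix (class `"q_matrix"`), with attribute
#'   `"permutations"` recording each run's column order.
#' @export
align_runs <- function(qmatrices) {
  qs <- lapply(qmatrices, function(q) if (inherits(q, "q_matrix")) q$q else q)
  K <- unique(vapply(qs, ncol, 0L))
  if (length(K) != 1) stop("runs have mismatched K")
  ids <- rownames(qs[[1]])
  if (!all(vapply(qs, function(q) identical(rownames(q), ids), TRUE))) {
    stop("runs have mismatched individuals")
  }
  ref <- qs[[1]]
  perms <- perm_enum(K)
  used <- vector("list", length(qs))
  aligned <- lapply(seq_along(qs), function(i) {
    q <- qs[[i]]
    scores <- vapply(perms, function(pp) sum(q[, pp] * ref), 0)
    best <- perms[[which.max(scores)]]
    used[[i]] <<- best
    q[, best, drop = FALSE]
  })
  avg <- Reduce(`+`, aligned) / length(aligned)
  avg <- avg / rowSums(avg)
  colnames(avg) <- paste0("q", seq_len(K))
  structure(list(q = avg, K = K, n_runs = length(qs)),
            class = "q_matrix", permutations = used)
}

# all permutations of 1..k (k <= 9 is plenty for admixture alignment)
perm_enum <- function(k) {
  if (k == 1) return(list(1L))
  smaller <- perm_enum(k - 1L)
  out <- vector("list", k * length(smaller))
  i <- 1L
  for (p in smaller) {
    for (pos in seq_len(k)) {
      out[[i]] <- append(p, k, after = pos - 1L)
      i <- i + 1L
    }
  }
  out
}

#' @export
print.q_matrix <- function(x, ...) {
  cat(sprintf("q_matrix: %d individuals x K = %d", nrow(x$q), x$K))
  if (!is.null(x$n_runs)) cat(sprintf(" (average of %d runs)", x$n_runs))
  cat("\n")
  if (!is.null(x$lnp)) cat(sprintf("ln P(X|K) = %.2f\n", x$lnp))
  invisible(x)
}
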