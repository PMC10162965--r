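test_that("pcoa gives identical coordinates to duplicated individuals", {
  sim <- three_cluster_sim(seed = 2, n_loci = 60, n = 8)
  gm <- sim$gm
  dup <- gm$geno
  dup <- cbind(dup, dup[, 1, drop = FALSE])
  colnames(dup)[ncol(dup)] <- "copy"
  gmd <- genotype_matrix(dup)
  pc <- pcoa(gmd)
  i <- match(colnames(dup)[1], rownames(pc$coords))
  j <- match("copy", rownames(pc$coords))
  expect_equal(pc$coords[i, ], pc$coords[j, ], tolerance = 1e-8)
  # percent variance = eigenvalue / sum positive eigenvalues
  pos <- sum(pc$eig[pc$eig > 0])
  expect_equal(pc$percent_var[1], 100 * pc$eig[1] / pos)
  expect_lte(sum(pc$percent_var), 100)
})

test_that("pcoa separates F-model clusters", {
  sim <- three_cluster_sim(seed = 13, n_loci = 200, n = 15)
  pc <- pcoa(sim$gm)
  km <- stats::kmeans(pc$coords, centers = 3, nstart = 20)
  truth <- factor(sim$popmap$assignments[rownames(pc$coords)])
  tab <- table(truth, km$cluster)
  agreement <- sum(apply(tab, 1, max)) / sum(tab)
  expect_gte(agreement, 0.95)
})

test_that("BIC selects one cluster for homogeneous data and the true K for
           clustered data", {
  picks1 <- sapply(1:5, function(s) {
    sim <- simulate_fmodel(
      sim_config(labels = "A", sample_sizes = 45, F_drift = 0.05,
                 n_loci = 200), seed = s)
    find_clusters_bic(sim$gm, k_max = 5, seed = s)$best_k
  })
  expect_gte(sum(picks1 == 1), 4)
  picks3 <- sapply(1:5, function(s) {
    sim <- three_cluster_sim(seed = 50 + s, n_loci = 200, n = 15)
    find_clusters_bic(sim$gm, k_max = 6, seed = s)$best_k
  })
  expect_gte(sum(picks3 == 3), 4)
  # K column increasing, WSS non-increasing
  sim <- three_cluster_sim(seed = 77, n_loci = 100, n = 10)
  tab <- find_clusters_bic(sim$gm, k_max = 5, seed = 1)$table
  expect_true(all(diff(tab$K) == 1))
  expect_true(all(diff(tab$wss) <= 1e-8))
  expect_error(find_clusters_bic(sim$gm, k_max = 30), "k_max")
})

test_that("dapc separates fixed-difference groups and is calibrated under
           label permutation", {
  # perfect separation
  geno <- cbind(matrix(0L, 30, 12), matrix(2L, 30, 12))
  colnames(geno) <- paste0("i", 1:24)
  gm <- genotype_matrix(geno)
  grp <- rep(c("a", "b"), each = 12)
  d <- dapc(gm, grp, n_pca = 5)
  expect_true(all(d$posterior[cbind(1:24, match(grp, colnames(d$posterior)))]
                  > 0.99))
  # random labels on one population: mean own-group membership near chance
  withr::local_seed(31)
  geno2 <- matrix(rbinom(150 * 40, 2, 0.4), 150, 40)
  colnames(geno2) <- paste0("i", 1:40)
  gm2 <- genotype_matrix(geno2)
  grp2 <- sample(rep(c("a", "b"), each = 20))
  d2 <- dapc(gm2, grp2, n_pca = 5)
  own <- d2$posterior[cbind(1:40, match(grp2, colnames(d2$posterior)))]
  expect_lt(mean(own), 0.75)
  # n_da clipping warns
  expect_warning(dapc(gm, grp, n_pca = 5, n_da = 5), "clipped")
})

test_that("dapc recovers the three simulated clusters", {
  sim <- three_cluster_sim(seed = 19, n_loci = 200, n = 15)
  d <- dapc(sim$gm, sim$popmap$assignments)
  acc <- mean(d$assigned == as.character(d$groups))
  expect_gte(acc, 0.95)
  expect_equal(unname(rowSums(d$posterior)), rep(1, 45), tolerance = 1e-9)
})

test_that("evanno delta-K reproduces hand arithmetic and flags endpoints", {
  m <- rbind(c(-100, -80, -75, -74), c(-100, -80, -75, -74))
  # inject spread so sd = 1 at every K
  runs <- rbind(m[1, ] - 0.5 * sqrt(2), m[1, ] + 0.5 * sqrt(2))
  colnames(runs) <- 1:4
  dk <- evanno_delta_k(runs)
  expect_equal(dk$delta_k[2], 15, tolerance = 1e-9)
  expect_equal(dk$delta_k[3], 4, tolerance = 1e-9)
  expect_true(is.na(dk$delta_k[1]) && is.na(dk$delta_k[4]))
  # linear mean lnP: delta-K identically 0 inside
  lin <- rbind(c(-30, -20, -10, 0) + 0.1, c(-30, -20, -10, 0) - 0.1)
  colnames(lin) <- 1:4
  dklin <- evanno_delta_k(lin)
  expect_equal(dklin$delta_k[2:3], c(0, 0), tolerance = 1e-9)
  # zero sd leaves delta-K undefined, flagged as NaN
  colnames(m) <- 1:4
  expect_true(is.nan(evanno_delta_k(m)$delta_k[2]))
  expect_error(evanno_delta_k(m[, 1:2]), "3 consecutive")
})

test_that("align_runs undoes label switching and averages", {
  withr::local_seed(8)
  q <- matrix(stats::rgamma(30 * 3, 1), 30, 3)
  q <- q / rowSums(q)
  rownames(q) <- paste0("i", 1:30)
  swapped <- q[, c(3, 1, 2)]
  avg <- align_runs(list(q, swapped))
  expect_equal(unname(avg$q), unname(q), tolerance = 1e-12)
  # identical runs: identity
  same <- align_runs(list(q, q, q))
  expect_equal(unname(same$q), unname(q), tolerance = 1e-12)
  expect_error(align_runs(list(q, q[, 1:2])), "mismatched K")
  # averaging noisy replicates gets closer to truth than single runs
  hits <- 0
  for (trial in 1:10) {
    noisy <- lapply(1:10, function(r) {
      qn <- q + matrix(stats::rgamma(90, 0.5), 30, 3) * 0.25
      qn <- qn / rowSums(qn)
      qn[, sample(3)]
    })
    avgn <- align_runs(noisy)$q
    # undo any global permutation before comparing to truth
    perms <- list(1:3, c(1, 3, 2), c(2, 1, 3), c(2, 3, 1),
                  c(3, 1, 2), c(3, 2, 1))
    dist_to <- function(qq) {
      min(vapply(perms, function(p) sqrt(sum((qq[, p] - q)^2)), 0))
    }
    d_avg <- dist_to(avgn)
    d_single <- vapply(noisy, dist_to, 0)
    if (d_avg < min(d_single)) hits <- hits + 1
  }
  expect_gte(hits, 8)
})

test_that("admixture sampler: K = 1 gives unit memberships; fixed
           differences give clean K = 2 assignment", {
  sim <- three_cluster_sim(seed = 3, n_loci = 40, n = 8)
  q1 <- admixture_gibbs(sim$gm, K = 1, burnin = 50, iters = 200, seed = 1)
  expect_true(all(q1$q == 1))
  expect_true(all(is.finite(q1$lnl_trace)))
  # 2 pops, 200 fixed-difference loci
  geno <- cbind(matrix(0L, 200, 12), matrix(2L, 200, 12))
  colnames(geno) <- paste0("i", 1:24)
  gm <- genotype_matrix(geno)
  q2 <- admixture_gibbs(gm, K = 2, burnin = 300, iters = 700, seed = 5)
  expect_true(all(apply(q2$q, 1, max) > 0.99))
  grp <- apply(q2$q, 1, which.max)
  expect_equal(length(unique(grp[1:12])), 1L)
  expect_true(grp[1] != grp[24])
  # rows always sum to 1
  expect_equal(unname(rowSums(q2$q)), rep(1, 24), tolerance = 1e-9)
})

test_that("admixture sampler recovers a 50/50 admixed individual", {
  withr::local_seed(60)
  L <- 300
  pA <- runif(L, 0.05, 0.95)
  f <- 0.3
  p1 <- rbeta(L, pA * (1 - f) / f, (1 - pA) * (1 - f) / f)
  p2 <- rbeta(L, pA * (1 - f) / f, (1 - pA) * (1 - f) / f)
  n <- 15
  geno <- cbind(matrix(rbinom(L * n, 2, p1), L),
                matrix(rbinom(L * n, 2, p2), L),
                # admixed: one allele copy from each parent pool
                rbinom(L, 1, p1) + rbinom(L, 1, p2))
  colnames(geno) <- c(paste0("a", 1:n), paste0("b", 1:n), "adm")
  gm <- genotype_matrix(geno)
  qs <- lapply(1:3, function(s) {
    admixture_gibbs(gm, K = 2, burnin = 1000, iters = 2000, seed = s)
  })
  est <- vapply(qs, function(q) max(q$q["adm", ]), 0)
  # posterior mean membership of the admixed bird stays near 0.5
  expect_true(all(est < 0.6 + 0.1))
  expect_true(all(est >= 0.5 - 0.1))
})

test_that("admixture runs are reproducible under a fixed seed", {
  sim <- three_cluster_sim(seed = 3, n_loci = 50, n = 8)
  a <- admixture_gibbs(sim$gm, K = 2, burnin = 100, iters = 200, seed = 9)
  b <- admixture_gibbs(sim$gm, K = 2, burnin = 100, iters = 200, seed = 9)
  expect_identical(a$q, b$q)
  expect_identical(a$lnp, b$lnp)
})
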