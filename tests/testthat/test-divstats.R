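test_that("allele frequency and heterozygosity match hand counts", {
  geno <- matrix(c(0L, 1L, 2L, NA,
                   0L, 1L, 1L, 2L), 2, byrow = TRUE,
                 dimnames = list(NULL, paste0("i", 1:4)))
  gm <- genotype_matrix(geno)
  p <- allele_freq(gm)
  expect_equal(unname(p), c(0.5, 0.5))
  h <- heterozygosity(gm)
  expect_equal(unname(h$ho), c(1 / 3, 0.5))
  expect_equal(unname(h$he), c(0.5, 0.5))
  # all-missing locus flagged NA
  gm2 <- genotype_matrix(rbind(geno, NA))
  expect_true(is.na(allele_freq(gm2)[3]))
  expect_error(allele_freq(gm, character(0)), "empty")
})

test_that("monomorphic loci have zero diversity", {
  gm <- genotype_matrix(matrix(c(0L, 0L, 0L), 1))
  h <- heterozygosity(gm)
  expect_equal(unname(h$ho), 0)
  expect_equal(unname(h$he), 0)
  expect_equal(h$n_polymorphic, 0L)
})

test_that("F_IS closed forms: HWE gives 0, all-heterozygote gives -1", {
  # all heterozygotes at p = 0.5 across many loci
  gm <- genotype_matrix(matrix(1L, 50, 20))
  f <- fis(gm, n_boot = 20)
  expect_equal(f$fis, -1, tolerance = 1e-12)
  # Ho == Hs exactly requires Ho = Hs = n/(n-1)(2p(1-p) - Ho/2n)
  # simulate HWE and check F_IS is near 0
  withr::local_seed(42)
  geno <- matrix(rbinom(400 * 60, 2, 0.5), 400, 60)
  f0 <- fis(genotype_matrix(geno), n_boot = 50)
  expect_lt(abs(f0$fis), 0.02)
  expect_true(f0$ci[1] <= f0$ci[2])
  # all-monomorphic input is flagged, not an error
  gmono <- genotype_matrix(matrix(0L, 5, 4))
  expect_true(is.na(fis(gmono)$fis))
})

test_that("theta matches the ANOVA variance-component oracle exactly", {
  withr::local_seed(17)
  for (rep in 1:25) {
    n1 <- sample(5:20, 1); n2 <- sample(5:20, 1)
    L <- sample(1:4, 1)
    geno <- cbind(
      matrix(rbinom(L * n1, 2, runif(L, 0.05, 0.95)), L),
      matrix(rbinom(L * n2, 2, runif(L, 0.05, 0.95)), L))
    colnames(geno) <- paste0("i", seq_len(n1 + n2))
    gm <- genotype_matrix(geno)
    a <- paste0("i", 1:n1)
    b <- paste0("i", (n1 + 1):(n1 + n2))
    res <- fst_wc(gm, a, b)
    if (!any(res$used)) next
    expect_equal(res$theta, fst_anova_oracle(gm, a, b), tolerance = 1e-10)
  }
})

test_that("theta limits: no differentiation near 0, fixed difference near 1", {
  withr::local_seed(5)
  geno <- matrix(rbinom(200 * 100, 2, 0.5), 200, 100)
  colnames(geno) <- paste0("i", 1:100)
  gm <- genotype_matrix(geno)
  th <- fst_wc(gm, paste0("i", 1:50), paste0("i", 51:100))$theta
  expect_lt(abs(th), 0.01)
  fixed <- genotype_matrix(
    cbind(matrix(0L, 10, 30), matrix(2L, 10, 30)),
    individual_ids = paste0("i", 1:60))
  thf <- fst_wc(fixed, paste0("i", 1:30), paste0("i", 31:60))$theta
  expect_gt(thf, 0.95)
})

test_that("theta is invariant to allele relabelling and orderings", {
  sim <- three_cluster_sim(seed = 21, n_loci = 80, n = 12)
  ids <- split(names(sim$popmap$assignments), sim$popmap$assignments)
  th <- fst_wc(sim$gm, ids$A, ids$B)$theta
  flipped <- sim$gm
  flipped$geno <- 2L - flipped$geno
  expect_equal(fst_wc(flipped, ids$A, ids$B)$theta, th, tolerance = 1e-12)
  # locus and individual order invariance of Ho/He
  h1 <- heterozygosity(sim$gm, ids$A)
  perm <- sim$gm[sample(n_loci(sim$gm)), sample(n_ind(sim$gm))]
  h2 <- heterozygosity(perm, sample(ids$A))
  expect_equal(h2$ho_mean, h1$ho_mean)
  expect_equal(h2$he_mean, h1$he_mean)
})

test_that("pairwise theta recovers the configured F-model divergence", {
  # Weir-Cockerham theta is calibrated for the island model: populations
  # drifted to F from a common ancestor should give theta ~= F
  thetas <- sapply(1:10, function(s) {
    sim <- simulate_fmodel(
      sim_config(labels = c("A", "B"), sample_sizes = c(30, 30),
                 F_drift = c(0.2, 0.2), n_loci = 300), seed = 100 + s)
    ids <- split(names(sim$popmap$assignments), sim$popmap$assignments)
    fst_wc(sim$gm, ids$A, ids$B)$theta
  })
  expect_equal(mean(thetas), 0.2, tolerance = 0.1)
  # and realised theta increases with configured F
  mean_theta_at <- function(f) {
    mean(sapply(1:5, function(s) {
      sim <- simulate_fmodel(
        sim_config(labels = c("A", "B"), sample_sizes = c(25, 25),
                   F_drift = c(f, f), n_loci = 150), seed = 200 + s)
      ids <- split(names(sim$popmap$assignments), sim$popmap$assignments)
      fst_wc(sim$gm, ids$A, ids$B)$theta
    }))
  }
  grid <- c(0.02, 0.05, 0.1, 0.2, 0.3)
  realised <- vapply(grid, mean_theta_at, 0)
  expect_true(all(diff(realised) > 0))
})

test_that("pairwise_fst returns a symmetric matrix with sane p-values", {
  sim <- three_cluster_sim(seed = 31, n_loci = 60, n = 10)
  pf <- pairwise_fst(sim$gm, sim$popmap, n_boot = 30, n_perm = 19, seed = 2)
  expect_true(isSymmetric(pf$theta))
  expect_true(all(is.na(diag(pf$theta))))
  offdiag <- pf$p_value[upper.tri(pf$p_value)]
  expect_true(all(offdiag >= 0 & offdiag <= 1))
  # strong divergence should be significant at the permutation floor
  expect_true(all(offdiag <= 0.1))
  # duplicated population: theta approx 0, p approx 1
  geno <- sim$gm$geno[, 1:10]
  colnames(geno) <- paste0("x", 1:10)
  dup <- cbind(sim$gm$geno[, 1:10], geno)
  gmd <- genotype_matrix(dup)
  pm <- pop_map(stats::setNames(rep(c("P1", "P2"), each = 10),
                                colnames(dup)))
  pfd <- suppressWarnings(pairwise_fst(gmd, pm, n_boot = 20, n_perm = 19,
                                       seed = 3))
  # duplicated samples are not independent draws, so theta sits at the
  # estimator's small-sample floor just below 0
  expect_lt(abs(pfd$theta["P1", "P2"]), 0.06)
  expect_gt(pfd$p_value["P1", "P2"], 0.5)
})

test_that("size-1 populations are excluded from pairwise theta with warning", {
  sim <- three_cluster_sim(seed = 41, n_loci = 40, n = 8)
  pm <- sim$popmap
  pm$assignments[1] <- "Lonely"
  pm <- pop_map(pm$assignments)
  expect_warning(pf <- pairwise_fst(sim$gm, pm, n_boot = 10, n_perm = 0),
                 "size")
  expect_false("Lonely" %in% rownames(pf$theta))
})
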