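test_that("generators are pure functions of (config, seed)", {
  cfg <- sim_config(labels = c("A", "B"), sample_sizes = c(10, 10),
                    F_drift = c(0.1, 0.1), n_loci = 50,
                    missing_rate = 0.05)
  a <- simulate_fmodel(cfg, seed = 7)
  b <- simulate_fmodel(cfg, seed = 7)
  expect_identical(a$gm$geno, b$gm$geno)
  expect_identical(a$gm$loci, b$gm$loci)
  expect_identical(a$truth$p_pop, b$truth$p_pop)
  cfgw <- sim_config("A", 10, census_n = 30, n_loci = 40)
  w1 <- simulate_wf(cfgw, generations = 10, seed = 3)
  w2 <- simulate_wf(cfgw, generations = 10, seed = 3)
  expect_identical(w1$gm$geno, w2$gm$geno)
})

test_that("F = 0 collapses to the ancestral frequencies and theta near 0", {
  cfg <- sim_config(labels = c("A", "B"), sample_sizes = c(40, 40),
                    F_drift = c(0, 0), n_loci = 300)
  sim <- simulate_fmodel(cfg, seed = 5)
  expect_equal(sim$truth$p_pop["A", ], sim$truth$p_ancestral)
  ids <- split(names(sim$popmap$assignments), sim$popmap$assignments)
  expect_lt(abs(fst_wc(sim$gm, ids$A, ids$B)$theta), 0.01)
})

test_that("sample allele frequencies track the simulated truth", {
  sim <- simulate_fmodel(
    sim_config(labels = "A", sample_sizes = 50, F_drift = 0.1,
               n_loci = 200), seed = 13)
  p_hat <- allele_freq(sim$gm)
  p_true <- sim$truth$p_pop["A", ]
  se <- sqrt(p_true * (1 - p_true) / (2 * 50))
  z <- (p_hat - p_true) / se
  # about 99.7% of loci within 3 binomial SEs
  expect_gt(mean(abs(z) < 3), 0.98)
})

test_that("realised theta increases with configured F across a grid", {
  grid <- c(0.02, 0.05, 0.1, 0.15, 0.25)
  realised <- vapply(grid, function(f) {
    mean(sapply(1:4, function(s) {
      sim <- simulate_fmodel(
        sim_config(labels = c("A", "B"), sample_sizes = c(20, 20),
                   F_drift = c(f, f), n_loci = 120), seed = 600 + s)
      ids <- split(names(sim$popmap$assignments), sim$popmap$assignments)
      fst_wc(sim$gm, ids$A, ids$B)$theta
    }))
  }, 0)
  expect_equal(stats::cor(grid, realised, method = "spearman"), 1)
})

test_that("wright-fisher conserves census size and mean frequency", {
  cfg <- sim_config("A", sample_sizes = 50, census_n = 50, n_loci = 500)
  sim <- simulate_wf(cfg, generations = 20, seed = 2)
  expect_equal(n_ind(sim$gm), 50L)
  p_end <- allele_freq(sim$gm)
  # martingale: mean frequency change across many replicate loci near 0
  expect_equal(mean(p_end), mean(sim$truth$p_initial), tolerance = 0.02)
})

test_that("migrant injection relabels exactly n individuals and records
           truth", {
  sim <- simulate_fmodel(
    sim_config(labels = c("Src", "Dst"), sample_sizes = c(20, 25),
               F_drift = c(0.2, 0.2), n_loci = 100), seed = 3)
  out <- inject_migrants(sim, "Src", "Dst", 6)
  expect_equal(length(out$truth$migrants), 6L)
  expect_true(all(out$popmap$assignments[out$truth$migrants] == "Dst"))
  expect_equal(length(out$truth$migrants) /
                 sum(out$popmap$assignments == "Dst"), 0.24)
  # untouched individuals keep their genotypes
  keep <- setdiff(colnames(sim$gm$geno), out$truth$migrants)
  expect_identical(out$gm$geno[, keep], sim$gm$geno[, keep])
  # n = 0 is the identity
  same <- inject_migrants(sim, "Src", "Dst", 0)
  expect_identical(same$gm$geno, sim$gm$geno)
})

test_that("technical replicates produce calibrated repeatability", {
  sim <- simulate_fmodel(
    sim_config(labels = "A", sample_sizes = 60, F_drift = 0.05,
               n_loci = 400), seed = 8)
  withr::local_seed(1)
  clean <- add_technical_replicates(sim$gm, error_rate = 0)
  expect_true(all(clean$loci$repeatability == 1))
  noisy <- add_technical_replicates(sim$gm, error_rate = 0.05)
  expect_equal(mean(noisy$loci$repeatability), 0.95, tolerance = 0.01)
  # filtering at 0.95 then keeps exactly the loci at/above threshold
  kept <- filter_repeatability(noisy, 0.95)
  expect_equal(n_loci(kept), sum(noisy$loci$repeatability >= 0.95))
})

test_that("the study-shaped preset carries its design quantities", {
  cfg <- preset_pardalote(n_loci = 60)
  expect_equal(cfg$sample_sizes, c(79, 25, 113, 16, 12, 3))
  expect_equal(length(cfg$labels), 6L)
  mig <- attr(cfg, "migration")
  expect_equal(mig$n, 6)
  sim <- simulate_fmodel(cfg, seed = 1)
  sim <- inject_migrants(sim, mig$from, mig$to, mig$n)
  expect_equal(n_ind(sim$gm), sum(cfg$sample_sizes))
  expect_equal(length(sim$truth$migrants), 6L)
})
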