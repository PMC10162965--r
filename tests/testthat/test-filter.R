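test_that("repeatability filter thresholds at >= and logs counts", {
  gm <- tiny_gm()
  out <- filter_repeatability(gm, 0.95)
  expect_equal(n_loci(out), 2L)
  expect_equal(out$loci$locus_id, c("L1", "L2"))
  expect_equal(n_loci(filter_repeatability(gm, 0)), 3L)
  log <- filter_log(out)
  expect_equal(log$loci_before, 3L)
  expect_equal(log$loci_after, 2L)
  gm$loci$repeatability <- NA_real_
  expect_error(filter_repeatability(gm), "repeatability")
})

test_that("monomorphic filter drops fixed and all-missing loci", {
  geno <- matrix(c(0L, 0L, 0L,
                   0L, 1L, 0L,
                   NA, NA, NA,
                   2L, 2L, 2L), 4, byrow = TRUE)
  gm <- genotype_matrix(geno)
  out <- filter_monomorphic(gm)
  expect_equal(out$loci$locus_id, "L2")
})

test_that("spiked monomorphic loci are removed exactly", {
  sim <- simulate_fmodel(
    sim_config(labels = "A", sample_sizes = 30, F_drift = 0.05,
               n_loci = 100, n_monomorphic = 10), seed = 5)
  before <- n_loci(sim$gm)
  out <- filter_monomorphic(sim$gm)
  # the 10 spiked all-zero loci must go; drifted loci may fix by chance too
  spiked <- 101:110
  expect_false(any(spiked %in% match(out$loci$locus_id,
                                     sim$gm$loci$locus_id)))
  expect_lte(n_loci(out), before - 10)
})

test_that("locus call-rate filter keeps the boundary and matches a recount", {
  geno <- matrix(1L, 2, 20)
  geno[1, 1] <- NA  # call rate exactly 0.95
  geno[2, 1:2] <- NA
  gm <- genotype_matrix(rbind(geno, 1L))
  out <- filter_locus_callrate(gm, 0.95)
  expect_true("L1" %in% out$loci$locus_id)
  expect_false("L2" %in% out$loci$locus_id)
  expect_equal(n_loci(filter_locus_callrate(gm, 1.0)), 1L)

  sim <- simulate_fmodel(
    sim_config(labels = "A", sample_sizes = 25, F_drift = 0.05,
               n_loci = 200, missing_rate = 0.08), seed = 2)
  out <- filter_locus_callrate(sim$gm, 0.95)
  brute <- rowMeans(!is.na(sim$gm$geno)) >= 0.95
  expect_equal(out$loci$locus_id, sim$gm$loci$locus_id[brute])
})

test_that("secondaries keep the highest-PIC SNP per clone, first on ties", {
  expect_equal(pic(0.5), 0.375)
  expect_equal(pic(0.1), 0.1638)
  # clone C1: p = 0.5 (PIC 0.375) vs p = 0.125 at 4 individuals
  geno <- matrix(c(0L, 1L, 1L, 2L,
                   0L, 0L, 0L, 1L,
                   1L, 1L, 0L, 0L), 3, byrow = TRUE)
  gm <- genotype_matrix(geno, clone_id = c("C1", "C1", "C2"))
  out <- filter_secondaries(gm)
  expect_equal(out$loci$locus_id, c("L1", "L3"))
  expect_false(anyDuplicated(out$loci$clone_id) > 0)
  # exact PIC tie: first-listed wins
  geno2 <- matrix(c(0L, 1L, 1L, 2L,
                    2L, 1L, 1L, 0L), 2, byrow = TRUE)
  gm2 <- genotype_matrix(geno2, clone_id = c("C", "C"))
  expect_equal(filter_secondaries(gm2)$loci$locus_id, "L1")
  # all-singleton clones: identity
  gm3 <- genotype_matrix(geno2, clone_id = c("C1", "C2"))
  expect_equal(n_loci(filter_secondaries(gm3)), 2L)
})

test_that("individual call-rate filter drops high-missingness individuals", {
  geno <- matrix(1L, 20, 3, dimnames = list(NULL, c("a", "b", "c")))
  geno[1:3, 2] <- NA  # b has call rate 0.85
  gm <- genotype_matrix(geno)
  out <- filter_individual_callrate(gm, 0.90)
  expect_equal(colnames(out$geno), c("a", "c"))
  expect_equal(n_ind(filter_individual_callrate(gm, 0)), 3L)
})

test_that("hamming distance is the mismatch fraction over compared length", {
  expect_equal(hamming_distance("ACGT", "ACGA"), 0.25)
  expect_equal(hamming_distance("ACGT", "ACGT"), 0)
  expect_equal(hamming_distance("ACGTAC", "ACGT"), 0)  # shorter length
  expect_error(hamming_distance("", "ACGT"), "empty")
  # random 69-mers have expected distance 0.75
  withr::local_seed(1)
  tags <- replicate(200, paste(sample(c("A", "C", "G", "T"), 69,
                                      replace = TRUE), collapse = ""))
  d <- mean(sapply(1:100, function(i) {
    hamming_distance(tags[2 * i - 1], tags[2 * i])
  }))
  expect_equal(d, 0.75, tolerance = 0.03)
})

test_that("hamming filter drops the lower-call-rate twin and is near-identity on random tags", {
  sim <- three_cluster_sim(seed = 8, n_loci = 60, n = 10)
  gm <- sim$gm
  # duplicate the first tag into locus 2; make locus 2 the lower call rate
  gm$loci$tag_seq[2] <- gm$loci$tag_seq[1]
  gm$geno[2, 1:3] <- NA
  out <- filter_hamming(gm, min_dist = 0.2)
  expect_false("L2" %in% out$loci$locus_id)
  expect_true("L1" %in% out$loci$locus_id)
  # distinct random 64-mers at min_dist 0.2: nothing else should drop
  expect_equal(n_loci(out), 59L)
})

test_that("maf screen drops rare alleles and matches a brute-force recount", {
  geno <- matrix(0L, 2, 50)
  geno[1, 1] <- 1L   # p = 0.01
  geno[2, 1:5] <- 1L # p = 0.05
  gm <- genotype_matrix(geno)
  out <- filter_maf(gm, pcrit = 0.02)
  expect_equal(out$loci$locus_id, "L2")
  sim <- three_cluster_sim(seed = 3, n_loci = 150, n = 15)
  out <- filter_maf(sim$gm, pcrit = 0.1)
  p <- allele_freq(sim$gm)
  brute <- !is.na(p) & pmin(p, 1 - p) >= 0.1
  expect_equal(out$loci$locus_id, sim$gm$loci$locus_id[brute])
  expect_equal(n_loci(filter_maf(sim$gm, pcrit = 0)),
               sum(rowSums(!is.na(sim$gm$geno)) > 0))
})

test_that("ld filter removes duplicated loci and leaves independents alone", {
  sim <- three_cluster_sim(seed = 9, n_loci = 50, n = 20)
  gm <- sim$gm
  gm$geno[2, ] <- gm$geno[1, ]  # r2 = 1 pair
  out <- filter_ld(gm, sim$popmap, r2_max = 0.8)
  expect_equal(n_loci(out), 49L)
  expect_true(xor("L1" %in% out$loci$locus_id,
                  "L2" %in% out$loci$locus_id))
  expect_equal(n_loci(filter_ld(gm, sim$popmap, r2_max = 1)), 50L)
})

test_that("every filter is idempotent and cascade counts are monotone", {
  sim <- simulate_fmodel(
    sim_config(labels = c("A", "B"), sample_sizes = c(15, 15),
               F_drift = c(0.1, 0.1), n_loci = 80, missing_rate = 0.05,
               n_monomorphic = 5, n_lowcall = 5), seed = 6)
  gm <- sim$gm
  filters <- list(
    function(x) filter_repeatability(x, 0.95),
    filter_monomorphic,
    function(x) filter_locus_callrate(x, 0.9),
    filter_secondaries,
    function(x) filter_individual_callrate(x, 0.9),
    function(x) filter_hamming(x, 0.2),
    function(x) filter_maf(x, pcrit = 0.05))
  for (f in filters) {
    once <- f(gm)
    twice <- f(once)
    expect_identical(twice$geno, once$geno)
    expect_identical(twice$loci$locus_id, once$loci$locus_id)
  }
  out <- filter_cascade(gm)
  log <- filter_log(out)
  expect_equal(log$step, c("repeatability", "monomorphic", "locus_callrate",
                           "secondaries", "individual_callrate", "hamming"))
  expect_true(all(diff(c(log$loci_before[1], log$loci_after)) <= 0))
  expect_true(all(log$loci_after <= log$loci_before))
  expect_true(all(log$individuals_after <= log$individuals_before))
})
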