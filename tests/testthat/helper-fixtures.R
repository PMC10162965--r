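# small deterministic fixtures shared across test files

# hand-built 3-locus x 4-individual matrix with one missing call
tiny_gm <- function() {
  geno <- matrix(c(0L, 1L, 2L, 1L,
                   0L, 0L, NA, 2L,
                   2L, 2L, 2L, 2L),
                 nrow = 3, byrow = TRUE,
                 dimnames = list(c("L1", "L2", "L3"),
                                 c("i1", "i2", "i3", "i4")))
  genotype_matrix(geno,
                  clone_id = c("C1", "C1", "C2"),
                  tag_seq = c("ACGTACGT", "ACGTACGA", "TTTTCCCC"),
                  repeatability = c(1, 0.96, 0.9))
}

tiny_popmap <- function() {
  pop_map(c(i1 = "A", i2 = "A", i3 = "B", i4 = "B"))
}

# three-cluster F-model fixture used by the structure/assignment tests
three_cluster_sim <- function(seed = 11, n_loci = 150, n = 20, f = 0.2) {
  simulate_fmodel(
    sim_config(labels = c("A", "B", "C"), sample_sizes = rep(n, 3),
               F_drift = rep(f, 3), n_loci = n_loci),
    seed = seed)
}

# independent oracle for Weir-Cockerham theta: allele-level nested ANOVA
# (populations / individuals within populations / alleles within
# individuals) with method-of-moments variance components. Distinct code
# path from the package's closed-form a/b/c components.
fst_anova_oracle <- function(gm, ids_a, ids_b) {
  pops <- list(A = ids_a, B = ids_b)
  num <- den <- 0
  for (l in seq_len(n_loci(gm))) {
    dat <- do.call(rbind, lapply(names(pops), function(p) {
      g <- gm$geno[l, pops[[p]]]
      g <- g[!is.na(g)]
      if (!length(g)) return(NULL)
      data.frame(pop = p, ind = paste0(p, seq_along(g)),
                 a1 = as.integer(g >= 1), a2 = as.integer(g >= 2))
    }))
    if (is.null(dat)) next
    ni <- table(dat$pop)
    if (length(ni) < 2 || any(ni < 2)) next
    y <- c(dat$a1, dat$a2)
    if (stats::var(y) == 0) next
    longd <- data.frame(y = y, pop = factor(rep(dat$pop, 2)),
                        ind = factor(rep(dat$ind, 2)))
    fit <- stats::aov(y ~ pop + Error(ind), data = longd)
    ms <- summary(fit)
    tab_ind <- ms[["Error: ind"]][[1]]
    tab_win <- ms[["Error: Within"]][[1]]
    msp <- tab_ind[match("pop", trimws(rownames(tab_ind))), "Mean Sq"]
    msi <- tab_ind[match("Residuals", trimws(rownames(tab_ind))), "Mean Sq"]
    msg <- tab_win[match("Residuals", trimws(rownames(tab_win))), "Mean Sq"]
    r <- length(ni)
    nsum <- sum(ni)
    nc <- (nsum - sum(ni^2) / nsum) / (r - 1)
    s2_g <- msg
    s2_i <- (msi - msg) / 2
    s2_p <- (msp - msi) / (2 * nc)
    num <- num + s2_p
    den <- den + s2_p + s2_i + s2_g
  }
  num / den
}

# exhaustive rarefaction oracle: average allele count over all
# combinations of g copies drawn from the pool (N <= 12)
rarefied_ar_bruteforce <- function(allele_counts, g) {
  pool <- rep(seq_along(allele_counts), allele_counts)
  combos <- utils::combn(length(pool), g)
  mean(apply(combos, 2, function(idx) length(unique(pool[idx]))))
}

# brute-force maximum coverage for the reserve-selection oracle
coverage_bruteforce <- function(presence, k) {
  combos <- utils::combn(ncol(presence), k)
  best <- 0
  for (ci in seq_len(ncol(combos))) {
    best <- max(best, sum(rowSums(presence[, combos[, ci], drop = FALSE]) > 0))
  }
  best
}
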