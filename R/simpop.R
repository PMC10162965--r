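#' Simulation configuration
#'
#' Describes a set of island populations to simulate: labels, sampled
#' individuals per population, per-population drift (the F of the
#' Balding-Nichols F-model, or the census size for the forward
#' Wright-Fisher simulator), plus panel-level nuisance parameters.
#'
#' @param labels character population labels.
#' @param sample_sizes integer individuals sampled per population.
#' @param F_drift per-population divergence F in `[0, 1)` (F-model).
#' @param census_n per-population census size (Wright-Fisher).
#' @param n_loci number of biallelic SNP loci.
#' @param missing_rate fraction of calls set missing at random.
#' @param error_rate technical-replicate genotype error rate.
#' @param mating `"random"` or `"monogamy"` (Wright-Fisher only).
#' @param n_monomorphic,n_lowcall extra spiked-in monomorphic and
#'   low-call-rate loci (for filter tests).
#' @param tag_length length of the simulated trimmed sequence tags.
#' @return list of class `"sim_config"`.
#' @export
sim_config <- function(labels, sample_sizes, F_drift = NULL, census_n = NULL,
                       n_loci = 1000, missing_rate = 0, error_rate = 0,
                       mating = c("random", "monogamy"),
                       n_monomorphic = 0, n_lowcall = 0, tag_length = 64) {
  mating <- match.arg(mating)
  stopifnot(length(labels) == length(sample_sizes), all(sample_sizes > 0))
  if (!is.null(F_drift)) {
    stopifnot(length(F_drift) == length(labels), all(F_drift >= 0),
              all(F_drift < 1))
  }
  if (!is.null(census_n)) stopifnot(all(census_n > 0))
  structure(list(labels = labels, sample_sizes = sample_sizes,
                 F_drift = F_drift, census_n = census_n, n_loci = n_loci,
                 missing_rate = missing_rate, error_rate = error_rate,
                 mating = mating, n_monomorphic = n_monomorphic,
                 n_lowcall = n_lowcall, tag_length = tag_length),
            class = "sim_config")
}

#' Study-shaped simulation preset
#'
#' Six populations with the study's sample sizes (79, 25, 113, 16, 12, 3)
#' in three genetic clusters: one strongly drifted isolate (the Maria
#' Island analogue, F = 0.2) and two weakly diverged southern clusters
#' (F = 0.03-0.06), with one-way migration from the large cluster into the
#' 25-bird peninsula analogue at the observed 24% rate (6 of 25 sampled
#' birds are immigrants).
#'
#' @param n_loci panel size (default 1000 for desk-scale work).
#' @param missing_rate,error_rate nuisance rates (defaults 0.02 and 0.01,
#'   typical of reduced-representation panels passing QC).
#' @return a [sim_config()], with attribute `"migration"` describing the
#'   injected migrant flow.
#' @export
preset_pardalote <- function(n_loci = 1000, missing_rate = 0.02,
                             error_rate = 0.01) {
  cfg <- sim_config(
    labels = c("Maria", "Tinderbox", "NorthBruny", "SouthBruny",
               "Partridge", "Southport"),
    sample_sizes = c(79, 25, 113, 16, 12, 3),
    F_drift = c(0.20, 0.03, 0.03, 0.05, 0.06, 0.05),
    n_loci = n_loci, missing_rate = missing_rate, error_rate = error_rate)
  attr(cfg, "migration") <- list(from = "NorthBruny", to = "Tinderbox", n = 6)
  cfg
}

random_tags <- function(n, len) {
  bases <- c("A", "C", "G", "T")
  vapply(seq_len(n), function(i) {
    paste(sample(bases, len, replace = TRUE), collapse = "")
  }, "")
}

attach_panel_metadata <- function(geno, cfg, pop_labels) {
  L <- nrow(geno)
  gm <- genotype_matrix(
    geno,
    locus_ids = paste0("L", seq_len(L)),
    individual_ids = colnames(geno),
    clone_id = paste0("C", seq_len(L)),
    tag_seq = random_tags(L, cfg$tag_length),
    repeatability = rep(1, L))
  gm
}

apply_missingness <- function(gm, rate) {
  if (rate <= 0) return(recompute_call_rate(gm))
  idx <- which(stats::runif(length(gm$geno)) < rate)
  gm$geno[idx] <- NA_integer_
  recompute_call_rate(gm)
}

#' Simulate SNP data under the Balding-Nichols F-model
#'
#' Ancestral frequencies `p_A ~ Uniform(0.05, 0.95)`; population
#' frequencies `p_k ~ Beta(p_A (1-F_k)/F_k, (1-p_A)(1-F_k)/F_k)` (with
#' `p_k = p_A` when `F_k = 0`); genotypes `Binomial(2, p_k)`. Optional
#' spiked monomorphic and low-call-rate loci exercise the QC filters;
#' random missingness is applied last. No linkage disequilibrium is
#' generated beyond that induced by structure, which matches the
#' assumptions of the structure/assignment/rarefaction stages.
#'
#' @param cfg a [sim_config()] with `F_drift` set.
#' @param seed integer seed; the run is a pure function of `(cfg, seed)`.
#' @return list with `gm` (a [genotype_matrix()]), `popmap` (a
#'   [pop_map()]), and `truth` (class `"sim_truth"`: ancestral and
#'   per-population frequencies, F values, migrant identities - empty
#'   here -, the seed).
#' @export
simulate_fmodel <- function(cfg, seed = 1) {
  if (is.null(cfg$F_drift)) stop("cfg$F_drift must be set for the F-model")
  withr::local_seed(seed)
  L <- cfg$n_loci
  npop <- length(cfg$labels)
  pA <- stats::runif(L, 0.05, 0.95)
  pk <- matrix(NA_real_, npop, L, dimnames = list(cfg$labels, NULL))
  for (k in seq_len(npop)) {
    f <- cfg$F_drift[k]
    pk[k, ] <- if (f == 0) pA else {
      stats::rbeta(L, pA * (1 - f) / f, (1 - pA) * (1 - f) / f)
    }
  }
  ids <- unlist(lapply(seq_len(npop), function(k) {
    sprintf("%s_%02d", cfg$labels[k], seq_len(cfg$sample_sizes[k]))
  }))
  pops <- rep(cfg$labels, cfg$sample_sizes)
  geno <- matrix(NA_integer_, L, length(ids),
                 dimnames = list(NULL, ids))
  col <- 1L
  for (k in seq_len(npop)) {
    nk <- cfg$sample_sizes[k]
    geno[, col:(col + nk - 1L)] <-
      matrix(stats::rbinom(L * nk, 2, pk[k, ]), L, nk)
    col <- col + nk
  }
  # spiked pathological loci for filter tests
  extra_mono <- cfg$n_monomorphic
  extra_low <- cfg$n_lowcall
  if (extra_mono > 0) {
    mono <- matrix(0L, extra_mono, length(ids))
    geno <- rbind(geno, mono)
  }
  if (extra_low > 0) {
    lowp <- stats::runif(extra_low, 0.2, 0.8)
    low <- matrix(stats::rbinom(extra_low * length(ids), 2, lowp),
                  extra_low, length(ids))
    drop <- matrix(stats::runif(extra_low * length(ids)) < 0.3,
                   extra_low, length(ids))
    low[drop] <- NA_integer_
    geno <- rbind(geno, low)
  }
  rownames(geno) <- NULL
  gm <- attach_panel_metadata(geno, cfg, pops)
  gm <- apply_missingness(gm, cfg$missing_rate)
  popmap <- pop_map(stats::setNames(pops, ids))
  truth <- structure(list(model = "fmodel", p_ancestral = pA,
                          p_pop = pk, F_drift = cfg$F_drift,
                          migrants = character(),
                          migrant_sources = character(),
                          seed = seed, n_spiked_monomorphic = extra_mono,
                          n_spiked_lowcall = extra_low),
                     class = "sim_truth")
  list(gm = gm, popmap = popmap, truth = truth)
}

#' Simulate one population forward in time (Wright-Fisher)
#'
#' Discrete non-overlapping generations at constant diploid census size
#' `N`, unlinked biallelic loci, no mutation. Under random mating each
#' offspring draws two (distinct) parents uniformly; under monogamy the
#' population is paired into `N/2` permanent couples each generation and
#' every offspring draws its parents from one random couple. Drift builds
#' the inter-locus LD that the single-sample Ne estimator reads out. Loci
#' that fix are retained (monomorphic) for filter realism.
#'
#' @param cfg a [sim_config()] with a single population and `census_n`
#'   set.
#' @param generations generations to run (default 50; LD among unlinked
#'   loci equilibrates within a few tens of generations).
#' @param seed integer seed.
#' @return list with `gm` (sampled individuals), `popmap`, and `truth`
#'   (contains `ne_true = N`).
#' @export
simulate_wf <- function(cfg, generations = 50, seed = 1) {
  if (is.null(cfg$census_n)) stop("cfg$census_n must be set for Wright-Fisher")
  if (length(cfg$labels) != 1) stop("simulate_wf runs one population")
  withr::local_seed(seed)
  N <- cfg$census_n[1]
  S <- cfg$sample_sizes[1]
  if (S > N) stop("sample size exceeds census size")
  L <- cfg$n_loci
  p0 <- stats::runif(L, 0.1, 0.9)
  # two haplotype matrices, N x L, entries 0/1
  H1 <- matrix(stats::rbinom(N * L, 1, rep(p0, each = N)), N, L)
  H2 <- matrix(stats::rbinom(N * L, 1, rep(p0, each = N)), N, L)
  for (gen in seq_len(generations)) {
    if (cfg$mating == "monogamy") {
      perm <- sample.int(N)
      half <- N %/% 2
      couple <- sample.int(half, N, replace = TRUE)
      mothers <- perm[couple]
      fathers <- perm[half + couple]
    } else {
      mothers <- sample.int(N, N, replace = TRUE)
      fathers <- sample.int(N, N, replace = TRUE)
    }
    pick_m <- matrix(stats::runif(N * L) < 0.5, N, L)
    pick_f <- matrix(stats::runif(N * L) < 0.5, N, L)
    new1 <- ifelse(pick_m, H1[mothers, , drop = FALSE],
                   H2[mothers, , drop = FALSE])
    new2 <- ifelse(pick_f, H1[fathers, , drop = FALSE],
                   H2[fathers, , drop = FALSE])
    H1 <- new1; H2 <- new2
  }
  take <- sample.int(N, S)
  geno <- t(H1[take, , drop = FALSE] + H2[take, , drop = FALSE])
  storage.mode(geno) <- "integer"
  ids <- sprintf("%s_%03d", cfg$labels[1], seq_len(S))
  colnames(geno) <- ids
  gm <- attach_panel_metadata(geno, cfg, rep(cfg$labels[1], S))
  gm <- apply_missingness(gm, cfg$missing_rate)
  popmap <- pop_map(stats::setNames(rep(cfg$labels[1], S), ids))
  truth <- structure(list(model = "wf", ne_true = N, generations = generations,
                          p_initial = p0, mating = cfg$mating,
                          migrants = character(), seed = seed),
                     class = "sim_truth")
  list(gm = gm, popmap = popmap, truth = truth)
}

#' Inject known migrants into a simulated sample
#'
#' Replaces `n` individuals sampled in `to_pop` with genotypes freshly
#' drawn from `from_pop`'s true allele frequencies, keeping the sample
#' size of `to_pop` unchanged; their identities are recorded in the truth
#' object so assignment results can be scored exactly.
#'
#' @param sim a [simulate_fmodel()] result.
#' @param from_pop,to_pop population labels.
#' @param n number of migrants (0 is a no-op).
#' @return `sim` with modified `gm` and updated `truth$migrants` /
#'   `truth$migrant_sources`.
#' @export
inject_migrants <- function(sim, from_pop, to_pop, n) {
  if (n == 0) return(sim)
  truth <- sim$truth
  if (truth$model != "fmodel") stop("migrant injection needs F-model truth")
  ids <- names(sim$popmap$assignments)[sim$popmap$assignments == to_pop]
  if (n > length(ids)) stop("more migrants than individuals in ", to_pop)
  targets <- utils::tail(ids, n)
  pf <- truth$p_pop[from_pop, ]
  L_model <- length(pf)
  for (id in targets) {
    sim$gm$geno[seq_len(L_model), id] <-
      stats::rbinom(L_model, 2, pf)
  }
  sim$gm <- recompute_call_rate(sim$gm)
  sim$truth$migrants <- c(truth$migrants, targets)
  sim$truth$migrant_sources <- c(truth$migrant_sources,
                                 stats::setNames(rep(from_pop, n), targets))
  sim
}

#' Simulate technical replicates and per-locus repeatability
#'
#' Re-genotypes a random 30% of individuals with symmetric genotype-flip
#' errors at `error_rate` per call, then records per-locus repeatability
#' (the fraction of concordant replicate pairs) in the locus metadata, as
#' reduced-representation providers report it.
#'
#' @param gm a [genotype_matrix()].
#' @param error_rate per-call flip probability in `[0, 0.5]`.
#' @param replicate_fraction fraction of individuals re-genotyped
#'   (default 0.3).
#' @return `gm` with `loci$repeatability` filled in; the replicate calls
#'   are attached as attribute `"replicates"` (list of `ids`, `geno`).
#' @export
add_technical_replicates <- function(gm, error_rate,
                                     replicate_fraction = 0.3) {
  stopifnot(error_rate >= 0, error_rate <= 0.5)
  n <- n_ind(gm)
  n_rep <- max(2L, round(replicate_fraction * n))
  ids <- sample(colnames(gm$geno), n_rep)
  orig <- gm$geno[, ids, drop = FALSE]
  rep_g <- orig
  flip <- which(!is.na(rep_g) & stats::runif(length(rep_g)) < error_rate)
  if (length(flip)) {
    cur <- rep_g[flip]
    rep_g[flip] <- vapply(cur, function(g) {
      sample(setdiff(0:2, g), 1)
    }, 0L)
  }
  both <- !is.na(orig) & !is.na(rep_g)
  agree <- rowSums(both & (orig == rep_g))
  total <- rowSums(both)
  gm$loci$repeatability <- ifelse(total > 0, agree / total, 1)
  attr(gm, "replicates") <- list(ids = ids, geno = rep_g)
  gm
}
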