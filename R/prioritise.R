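#' Rarefied allele count for one locus in one population
#'
#' Expected number of distinct alleles in a random subsample of `g` gene
#' copies, by hypergeometric inclusion probabilities:
#' `AR = sum_a [1 - C(N - N_a, g) / C(N, g)]` where `N_a` is the copy count
#' of allele `a` and `N = sum(N_a)`. Computed on the log-gamma scale so it
#' is stable for large `N`.
#'
#' @param allele_counts integer vector of allele copy counts at the locus
#'   (for a biallelic SNP: `c(ref copies, alt copies)`).
#' @param g number of gene copies to rarefy to; must satisfy
#'   `1 <= g <= sum(allele_counts)`.
#' @return expected allele count in `[1, length(allele_counts)]` (for loci
#'   with at least one copy).
#' @export
rarefied_ar <- function(allele_counts, g) {
  N <- sum(allele_counts)
  if (g > N) stop("g (", g, ") exceeds total gene copies (", N, ")")
  if (g < 1) stop("g must be >= 1")
  # P(allele absent from subsample) = C(N - Na, g) / C(N, g)
  absent <- ifelse(N - allele_counts < g, 0,
                   exp(lchoose(N - allele_counts, g) - lchoose(N, g)))
  sum((1 - absent)[allele_counts > 0])
}

# per-locus ref/alt copy counts for a set of individuals: 2 x L matrix
allele_copy_counts <- function(gm, individuals) {
  g <- gm$geno[, individuals, drop = FALSE]
  nn <- rowSums(!is.na(g))
  alt <- rowSums(g, na.rm = TRUE)
  rbind(ref = 2 * nn - alt, alt = alt)
}

#' Rarefied allelic richness per population, totals and contributions
#'
#' Mean allelic richness per locus for a standardised sample of
#' `n_std_individuals` diploids (`g = 2 x n_std_individuals` gene copies)
#' in each population, the total richness `AR(t)` over the pooled
#' populations, the leave-one-population-out totals `AR(-i)` and the
#' contribution of each population
#' `CT_i = (AR(t) - AR(-i)) / (AR(t) - 1)` (see [contribution()]).
#'
#' At loci where missing data leaves a population with fewer than `g`
#' copies, all samples are rarefied at the per-locus minimum copy count
#' across included populations, keeping the comparison standardised; loci
#' where some population has no copies at all are skipped.
#'
#' @param gm a [genotype_matrix()]
#' @param popmap a [pop_map()]
#' @param n_std_individuals standardised sample size in individuals
#'   (default 25, i.e. 50 gene copies). Populations smaller than this are
#'   excluded with a warning.
#' @return object of class `"rarefaction_result"`: list with `g`, data
#'   frame `per_population` (population, mean AR, sd over loci, AR(-i),
#'   contribution), scalars `ar_total`, `n_loci`.
#' @export
population_ar <- function(gm, popmap, n_std_individuals = 25) {
  pops <- split_by_pop(gm, popmap)
  small <- names(pops)[lengths(pops) < n_std_individuals]
  if (length(small)) {
    warning("excluding population(s) smaller than the standardised sample: ",
            paste(small, collapse = ", "))
    pops <- pops[lengths(pops) >= n_std_individuals]
  }
  if (length(pops) < 2) stop("need >= 2 populations of standard size")
  g_std <- 2L * n_std_individuals
  nm <- names(pops)
  counts <- lapply(pops, function(ids) allele_copy_counts(gm, ids))
  tot_per_pop <- vapply(counts, colSums, numeric(n_loci(gm)))  # L x pops
  g_locus <- pmin(g_std, apply(tot_per_pop, 1, min))
  use <- which(g_locus >= 1)
  if (!length(use)) stop("no loci with data in every population")
  pooled <- Reduce(`+`, counts)
  ar_pop <- matrix(NA_real_, length(use), length(nm),
                   dimnames = list(NULL, nm))
  ar_tot <- ar_minus <- matrix(NA_real_, length(use), length(nm),
                               dimnames = list(NULL, nm))
  ar_t <- numeric(length(use))
  for (r in seq_along(use)) {
    l <- use[r]
    gl <- g_locus[l]
    for (j in seq_along(nm)) {
      ar_pop[r, j] <- rarefied_ar(counts[[j]][, l], gl)
      ar_minus[r, j] <- rarefied_ar(pooled[, l] - counts[[j]][, l], gl)
    }
    ar_t[r] <- rarefied_ar(pooled[, l], gl)
  }
  ar_total <- mean(ar_t)
  per_pop <- data.frame(
    population = nm,
    mean_ar = colMeans(ar_pop),
    sd_ar = apply(ar_pop, 2, stats::sd),
    ar_without = colMeans(ar_minus),
    stringsAsFactors = FALSE)
  per_pop$contribution <- vapply(per_pop$ar_without, contribution,
                                 0, ar_total = ar_total)
  structure(list(g = g_std, per_population = per_pop, ar_total = ar_total,
                 n_loci = length(use)),
            class = "rarefaction_result")
}

#' @export
print.rarefaction_result <- function(x, ...) {
  cat(sprintf("Rarefied allelic richness (g = %d gene copies, %d loci)\n",
              x$g, x$n_loci))
  df <- x$per_population
  df$mean_ar <- sprintf("%.2f +/- %.2f", df$mean_ar, df$sd_ar)
  df$contribution <- sprintf("%.3f", df$contribution)
  print(df[, c("population", "mean_ar", "contribution")], row.names = FALSE)
  cat(sprintf("total AR(t) = %.3f\n", x$ar_total))
  invisible(x)
}

#' Contribution of a population to total allelic richness
#'
#' `CT_i = (AR(t) - AR(-i)) / (AR(t) - 1)`: the proportional loss of
#' standardised allelic richness (above the 1-allele floor) if population
#' `i` went extinct.
#'
#' @param ar_total total rarefied richness `AR(t)` over all populations;
#'   must exceed 1 (an all-monomorphic panel has no defined contribution).
#' @param ar_without `AR(-i)`, richness with population `i` removed.
#' @return the contribution `CT_i`.
#' @export
contribution <- function(ar_total, ar_without) {
  if (ar_total <= 1) stop("AR(t) must exceed 1 (panel all monomorphic)")
  (ar_total - ar_without) / (ar_total - 1)
}

#' Allele-by-population presence matrix
#'
#' Each biallelic locus contributes two candidate alleles; an allele is
#' present in a population when at least one copy was observed there.
#'
#' @param gm a [genotype_matrix()]
#' @param pops named list of individual-id vectors (e.g. from a
#'   [pop_map()]).
#' @return logical matrix, `2 * n_loci` rows (ref/alt per locus) by
#'   populations.
#' @export
allele_presence <- function(gm, pops) {
  pres <- vapply(pops, function(ids) {
    cc <- allele_copy_counts(gm, ids)
    c(cc["ref", ] > 0, cc["alt", ] > 0)
  }, logical(2L * n_loci(gm)))
  rownames(pres) <- c(paste0(gm$loci$locus_id, ".ref"),
                      paste0(gm$loci$locus_id, ".alt"))
  pres
}

#' Optimal population network for allele representation
#'
#' Exact maximum-coverage search: over all subsets of `k` populations,
#' maximise the number of alleles present in at least one selected
#' population (each population has equal unit cost). Ties are broken by the
#' higher sum of within-population allele frequencies over covered alleles,
#' then lexicographically by population order.
#'
#' @param presence logical allele x population matrix (see
#'   [allele_presence()]).
#' @param k number of populations to protect.
#' @param freq optional numeric matrix of the same shape with
#'   within-population allele frequencies, used only for tie-breaking.
#' @return object of class `"prioritisation_solution"`: list with `k`,
#'   `selected` (population names), `n_covered`, `proportion` of all
#'   represented alleles covered.
#' @export
optimise_representation <- function(presence, k, freq = NULL) {
  npop <- ncol(presence)
  if (k < 1 || k > npop) stop("k must be between 1 and ", npop)
  present_any <- rowSums(presence) > 0
  total <- sum(present_any)
  combos <- utils::combn(npop, k)
  best <- NULL
  for (ci in seq_len(ncol(combos))) {
    sel <- combos[, ci]
    covered <- rowSums(presence[, sel, drop = FALSE]) > 0
    ncov <- sum(covered)
    tie <- if (!is.null(freq)) sum(freq[covered, sel]) else 0
    cand <- list(sel = sel, ncov = ncov, tie = tie)
    if (is.null(best) || cand$ncov > best$ncov ||
        (cand$ncov == best$ncov && cand$tie > best$tie)) {
      best <- cand
    }
  }
  structure(list(k = k,
                 selected = colnames(presence)[best$sel] %||% best$sel,
                 n_covered = best$ncov,
                 n_total = total,
                 proportion = best$ncov / total),
            class = "prioritisation_solution")
}

#' @export
print.prioritisation_solution <- function(x, ...) {
  cat(sprintf("protect %d population(s): %s\n", x$k,
              paste(x$selected, collapse = ", ")))
  cat(sprintf("alleles covered: %d / %d (%.1f%%)\n",
              x$n_covered, x$n_total, 100 * x$proportion))
  invisible(x)
}

#' Full prioritisation table over protection scenarios
#'
#' Combines [population_ar()] with [optimise_representation()] for
#' scenarios protecting `1..max(scenarios)` populations.
#'
#' @param gm a [genotype_matrix()]
#' @param popmap a [pop_map()]
#' @param n_std_individuals standardised sample size for rarefaction.
#' @param scenarios integer vector of protection-scenario sizes.
#' @return list with `richness` (a [population_ar()] result) and
#'   `solutions` (one [optimise_representation()] result per scenario).
#' @export
prioritise <- function(gm, popmap, n_std_individuals = 25,
                       scenarios = 1:4) {
  rich <- population_ar(gm, popmap, n_std_individuals)
  pops <- split_by_pop(gm, popmap)
  pops <- pops[rich$per_population$population]
  pres <- allele_presence(gm, pops)
  freqm <- vapply(pops, function(ids) {
    cc <- allele_copy_counts(gm, ids)
    tot <- pmax(colSums(cc), 1)
    c(cc["ref", ] / tot, cc["alt", ] / tot)
  }, numeric(nrow(pres)))
  scenarios <- scenarios[scenarios <= ncol(pres)]
  sols <- lapply(scenarios, function(k) {
    optimise_representation(pres, k, freq = freqm)
  })
  names(sols) <- paste0("k", scenarios)
  list(richness = rich, solutions = sols)
}
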