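#' Leave-one-out self-assignment to source populations
#'
#' For every individual, each candidate collection's allele frequencies are
#' estimated as posterior means under a per-allele Dirichlet prior (weight
#' `prior_weight`, default 1/2 per allele for biallelic loci) from the
#' collection's allele counts - excluding the focal individual when scoring
#' its own collection (the leave-one-out step, which removes the upward
#' bias of self-inclusion). The genotype log-likelihood assumes
#' Hardy-Weinberg proportions per locus (`p^2`, `2pq`, `q^2`), summed over
#' the individual's non-missing loci; likelihoods are normalised across
#' collections and summed over each reporting unit's member collections to
#' give unit posteriors.
#'
#' Collections with fewer than `min_size` individuals are excluded as
#' candidate sources (their members are still assigned, among the remaining
#' candidates).
#'
#' @param gm a [genotype_matrix()]
#' @param popmap a [pop_map()]; reporting units come from
#'   `popmap$reporting_units`.
#' @param prior_weight Dirichlet prior weight per allele (default 0.5).
#' @param min_size minimum candidate-collection size (default 2).
#' @return object of class `"assignment_result"`: data frame `table` (one
#'   row per individual: collection of origin, top unit, top posterior),
#'   matrix `unit_posterior` (individuals x units), matrix `log_likelihood`
#'   (individuals x collections).
#' @export
loo_self_assign <- function(gm, popmap, prior_weight = 0.5, min_size = 2) {
  pops <- split_by_pop(gm, popmap)
  small <- names(pops)[lengths(pops) < min_size]
  if (length(small)) {
    warning("collection(s) excluded as candidates (too few samples): ",
            paste(small, collapse = ", "))
  }
  cand <- setdiff(names(pops), small)
  if (length(cand) < 2) stop("need >= 2 candidate collections")
  g <- gm$geno
  ids <- colnames(g)
  L <- nrow(g)
  # per-collection alt/total copy counts per locus
  alt <- tot <- matrix(0, L, length(cand), dimnames = list(NULL, cand))
  for (k in cand) {
    sub <- g[, pops[[k]], drop = FALSE]
    alt[, k] <- rowSums(sub, na.rm = TRUE)
    tot[, k] <- 2 * rowSums(!is.na(sub))
  }
  ll <- matrix(NA_real_, length(ids), length(cand),
               dimnames = list(ids, cand))
  origin <- popmap$assignments[ids]
  for (i in seq_along(ids)) {
    gi <- g[, i]
    obs <- !is.na(gi)
    for (k in cand) {
      a <- alt[, k]; t_ <- tot[, k]
      if (origin[i] == k) {
        a <- a - ifelse(obs, gi, 0)
        t_ <- t_ - ifelse(obs, 2, 0)
      }
      p <- (a + prior_weight) / (t_ + 2 * prior_weight)
      ll[i, k] <- sum((gi * log(p) + (2 - gi) * log(1 - p) +
                         (gi == 1) * log(2))[obs])
    }
  }
  # scaled likelihood across collections (flat prior over collections)
  scaled <- exp(ll - apply(ll, 1, max))
  scaled <- scaled / rowSums(scaled)
  units <- popmap$reporting_units[cand]
  unit_names <- unique(unname(units))
  up <- vapply(unit_names, function(u) {
    rowSums(scaled[, cand[units == u], drop = FALSE])
  }, numeric(length(ids)))
  colnames(up) <- unit_names
  top <- unit_names[max.col(up, ties.method = "first")]
  tab <- data.frame(individual = ids,
                    collection = unname(origin),
                    sampled_unit = unname(popmap$reporting_units[origin]),
                    top_unit = top,
                    posterior = up[cbind(seq_along(ids),
                                         match(top, unit_names))],
                    stringsAsFactors = FALSE)
  structure(list(table = tab, unit_posterior = up, log_likelihood = ll,
                 prior_weight = prior_weight, excluded = small),
            class = "assignment_result")
}

#' @export
print.assignment_result <- function(x, ...) {
  tab <- x$table
  home <- mean(tab$top_unit == tab$sampled_unit, na.rm = TRUE)
  cat(sprintf("LOO self-assignment: %d individuals, %d candidate collections\n",
              nrow(tab), ncol(x$log_likelihood)))
  cat(sprintf("assigned to home unit: %.1f%%\n", 100 * home))
  if (length(x$excluded)) {
    cat("excluded candidates:", paste(x$excluded, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Count migrants and immigration rates from an assignment result
#'
#' An individual sampled in population A but assigned (top reporting unit,
#' posterior at or above `threshold`) to a different unit B counts as a
#' migrant B -> A; the immigration rate into A is migrants / sample size of
#' A. Individuals whose own sampling unit was not a candidate are skipped.
#'
#' @param ar a [loo_self_assign()] result.
#' @param popmap the [pop_map()] used to build it.
#' @param threshold minimum posterior for calling a migrant (default 0.9).
#' @return list with `migrants` (data frame: individual, sampled
#'   population, source unit, posterior) and `rates` (data frame per
#'   destination population: sample size, migrant count, immigration
#'   rate).
#' @export
count_migrants <- function(ar, popmap, threshold = 0.9) {
  tab <- ar$table
  known <- !is.na(tab$sampled_unit) &
    tab$sampled_unit %in% colnames(ar$unit_posterior)
  mig <- tab[known & tab$top_unit != tab$sampled_unit &
               tab$posterior >= threshold, , drop = FALSE]
  migrants <- data.frame(individual = mig$individual,
                         sampled_pop = mig$collection,
                         source_unit = mig$top_unit,
                         posterior = mig$posterior,
                         stringsAsFactors = FALSE)
  pops <- sort(unique(tab$collection[known]))
  rates <- do.call(rbind, lapply(pops, function(p) {
    n <- sum(tab$collection == p & known)
    m <- sum(migrants$sampled_pop == p)
    data.frame(population = p, n = n, migrants = m,
               immigration_rate = m / n, stringsAsFactors = FALSE)
  }))
  list(migrants = migrants, rates = rates, threshold = threshold)
}
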