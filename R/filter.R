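#' SNP quality-control filters
#'
#' Each filter is a pure function `genotype_matrix -> genotype_matrix` that
#' appends one entry to the filter log carried in `attr(gm, "filter_log")`
#' (see [filter_log()]). Thresholds retain at the boundary (`>=`), matching
#' the behaviour of the standard reduced-representation QC toolchain.
#'
#' @name snp_filters
NULL

log_step <- function(gm_out, gm_in, name, params = list()) {
  log <- attr(gm_in, "filter_log") %||%
    data.frame(step = character(), parameters = character(),
               loci_before = integer(), loci_after = integer(),
               individuals_before = integer(), individuals_after = integer(),
               stringsAsFactors = FALSE)
  par_str <- if (length(params)) {
    paste(names(params), vapply(params, format, ""), sep = "=", collapse = ",")
  } else ""
  log <- rbind(log, data.frame(
    step = name, parameters = par_str,
    loci_before = n_loci(gm_in), loci_after = n_loci(gm_out),
    individuals_before = n_ind(gm_in), individuals_after = n_ind(gm_out),
    stringsAsFactors = FALSE))
  attr(gm_out, "filter_log") <- log
  gm_out
}

#' Retrieve the filter log of a genotype matrix
#'
#' @param gm a [genotype_matrix()] that has passed through one or more
#'   filters.
#' @return data frame with one row per filter step: name, parameters, and
#'   locus/individual counts before and after. Counts are monotonically
#'   non-increasing down the cascade.
#' @export
filter_log <- function(gm) {
  attr(gm, "filter_log") %||%
    data.frame(step = character(), parameters = character(),
               loci_before = integer(), loci_after = integer(),
               individuals_before = integer(), individuals_after = integer(),
               stringsAsFactors = FALSE)
}

keep_loci <- function(gm, keep) {
  out <- gm[which(keep), ]
  attr(out, "filter_log") <- attr(gm, "filter_log")
  out
}

#' @describeIn snp_filters retain loci whose technical-replicate
#'   repeatability is at least `min_rep`. Errors if repeatability metadata is
#'   absent.
#' @param gm a [genotype_matrix()]
#' @param min_rep minimum repeatability fraction in `[0, 1]`
#' @export
filter_repeatability <- function(gm, min_rep = 0.95) {
  rep <- gm$loci$repeatability
  if (anyNA(rep)) {
    stop("repeatability metadata absent for some loci; compute it from ",
         "technical replicates (see add_technical_replicates) or skip this filter")
  }
  log_step(keep_loci(gm, rep >= min_rep), gm,
           "repeatability", list(min_rep = min_rep))
}

#' @describeIn snp_filters drop loci whose non-missing calls are all
#'   identical homozygotes (all 0 or all 2); an all-missing locus is
#'   vacuously monomorphic and is dropped too. A locus with any heterozygote
#'   is polymorphic.
#' @export
filter_monomorphic <- function(gm) {
  g <- gm$geno
  poly <- rowSums(g == 1, na.rm = TRUE) > 0 |
    (rowSums(g == 0, na.rm = TRUE) > 0 & rowSums(g == 2, na.rm = TRUE) > 0)
  log_step(keep_loci(gm, poly), gm, "monomorphic", list())
}

#' @describeIn snp_filters retain loci genotyped in at least `min_cr` of
#'   individuals. The rate is recomputed from the calls, not taken from
#'   metadata.
#' @param min_cr minimum call-rate fraction in `[0, 1]`
#' @export
filter_locus_callrate <- function(gm, min_cr = 0.95) {
  cr <- rowMeans(!is.na(gm$geno))
  log_step(keep_loci(gm, cr >= min_cr), gm,
           "locus_callrate", list(min_cr = min_cr))
}

#' Polymorphic information content of a biallelic locus
#'
#' `PIC = 1 - (p^2 + q^2) - 2 p^2 q^2` for allele frequency `p` (`q = 1-p`);
#' maximised (0.375) at `p = 0.5`.
#'
#' @param p alternate-allele frequency in `[0, 1]` (vectorised).
#' @return numeric PIC value(s).
#' @export
pic <- function(p) {
  q <- 1 - p
  1 - (p^2 + q^2) - 2 * p^2 * q^2
}

#' @describeIn snp_filters keep one SNP per clone (sequence tag): the one
#'   with the highest polymorphic information content, ties broken by file
#'   order. Requires `clone_id` metadata.
#' @export
filter_secondaries <- function(gm) {
  clone <- gm$loci$clone_id
  if (anyNA(clone)) stop("clone_id metadata absent; cannot resolve secondaries")
  g <- gm$geno
  nn <- rowSums(!is.na(g))
  p <- rowSums(g, na.rm = TRUE) / (2 * pmax(nn, 1))
  score <- pic(p)
  score[nn == 0] <- -Inf
  keep <- rep(FALSE, n_loci(gm))
  best <- tapply(seq_along(score), clone, function(idx) {
    idx[which.max(score[idx])]  # which.max takes the first on ties
  })
  keep[unlist(best)] <- TRUE
  log_step(keep_loci(gm, keep), gm, "secondaries", list())
}

#' @describeIn snp_filters retain individuals whose per-individual call rate
#'   is at least `min_cr`.
#' @export
filter_individual_callrate <- function(gm, min_cr = 0.90) {
  cr <- individual_call_rate(gm)
  out <- gm[, cr >= min_cr]
  attr(out, "filter_log") <- attr(gm, "filter_log")
  log_step(out, gm, "individual_callrate", list(min_cr = min_cr))
}

#' Proportional Hamming distance between two sequence tags
#'
#' Fraction of mismatching positions. Tags of unequal length are compared
#' over the shorter length so the result is always defined and in `[0, 1]`.
#'
#' @param tag_a,tag_b non-empty strings over `A/C/G/T`.
#' @return mismatch fraction in `[0, 1]`.
#' @export
hamming_distance <- function(tag_a, tag_b) {
  if (!nzchar(tag_a) || !nzchar(tag_b)) stop("empty sequence tag")
  n <- min(nchar(tag_a), nchar(tag_b))
  a <- utf8ToInt(substr(tag_a, 1, n))
  b <- utf8ToInt(substr(tag_b, 1, n))
  sum(a != b) / n
}

# all pairwise proportional Hamming distances; fast path for equal lengths
tag_distance_matrix <- function(tags) {
  L <- length(tags)
  d <- matrix(0, L, L)
  lens <- nchar(tags)
  if (L >= 2 && length(unique(lens)) == 1) {
    m <- matrix(unlist(lapply(tags, utf8ToInt)), nrow = lens[1])
    for (i in seq_len(L - 1)) {
      js <- (i + 1):L
      mm <- colSums(m[, js, drop = FALSE] != m[, i]) / lens[1]
      d[i, js] <- mm
      d[js, i] <- mm
    }
  } else {
    for (i in seq_len(max(L - 1, 0))) {
      for (j in (i + 1):L) {
        d[i, j] <- d[j, i] <- hamming_distance(tags[i], tags[j])
      }
    }
  }
  d
}

#' @describeIn snp_filters drop loci whose trimmed sequence tags are too
#'   similar: for every pair at proportional Hamming distance below
#'   `min_dist` the locus with the lower call rate is dropped (ties: the
#'   later-listed locus), iterating until no pair violates. Requires
#'   `tag_seq` metadata.
#' @param min_dist minimum allowed proportional Hamming distance (default
#'   0.2).
#' @export
filter_hamming <- function(gm, min_dist = 0.2) {
  tags <- gm$loci$tag_seq
  if (anyNA(tags)) stop("tag_seq metadata absent; cannot filter on Hamming distance")
  d <- tag_distance_matrix(tags)
  cr <- rowMeans(!is.na(gm$geno))
  alive <- rep(TRUE, n_loci(gm))
  repeat {
    idx <- which(alive)
    if (length(idx) < 2) break
    sub <- d[idx, idx, drop = FALSE]
    viol <- which(upper.tri(sub) & sub < min_dist, arr.ind = TRUE)
    if (!nrow(viol)) break
    # resolve the closest pair first, then re-scan
    ord <- order(sub[viol])
    i <- idx[viol[ord[1], 1]]
    j <- idx[viol[ord[1], 2]]
    drop <- if (cr[i] < cr[j]) i else if (cr[j] < cr[i]) j else max(i, j)
    alive[drop] <- FALSE
  }
  log_step(keep_loci(gm, alive), gm, "hamming", list(min_dist = min_dist))
}

#' @describeIn snp_filters drop loci whose minor-allele frequency within the
#'   given individuals is below `pcrit` (used to screen rare alleles before
#'   LD-based Ne estimation).
#' @param individuals character vector of individual ids defining the
#'   population the frequency is computed in (default: all).
#' @param pcrit minor-allele-frequency floor.
#' @export
filter_maf <- function(gm, individuals = colnames(gm$geno), pcrit = 0.02) {
  g <- gm$geno[, individuals, drop = FALSE]
  nn <- rowSums(!is.na(g))
  p <- rowSums(g, na.rm = TRUE) / (2 * pmax(nn, 1))
  maf <- pmin(p, 1 - p)
  keep <- nn > 0 & maf >= pcrit
  log_step(keep_loci(gm, keep), gm, "maf",
           list(pcrit = pcrit, n_individuals = length(individuals)))
}

#' @describeIn snp_filters prune loci in linkage disequilibrium: the squared
#'   genotype correlation ([pair_r2()]) is computed within each population
#'   and averaged across populations; for each pair whose mean r-squared
#'   exceeds `r2_max` the locus with the lower call rate is dropped.
#' @param popmap a [pop_map()]; populations with fewer than 2 genotyped
#'   individuals are ignored.
#' @param r2_max maximum tolerated mean squared correlation.
#' @export
filter_ld <- function(gm, popmap, r2_max = 0.8) {
  if (r2_max >= 1) return(log_step(gm, gm, "ld", list(r2_max = r2_max)))
  pops <- split_by_pop(gm, popmap)
  pops <- pops[lengths(pops) >= 2]
  if (!length(pops)) stop("need at least one population with >= 2 individuals")
  L <- n_loci(gm)
  acc <- matrix(0, L, L)
  cnt <- matrix(0L, L, L)
  for (ids in pops) {
    x <- t(gm$geno[, ids, drop = FALSE])
    r <- suppressWarnings(stats::cor(x, use = "pairwise.complete.obs"))
    ok <- !is.na(r)
    acc[ok] <- acc[ok] + r[ok]^2
    cnt <- cnt + ok
  }
  mean_r2 <- acc / pmax(cnt, 1L)
  mean_r2[cnt == 0L] <- 0
  cr <- rowMeans(!is.na(gm$geno))
  alive <- rep(TRUE, L)
  viol <- which(upper.tri(mean_r2) & mean_r2 > r2_max, arr.ind = TRUE)
  if (nrow(viol)) {
    ord <- order(mean_r2[viol], decreasing = TRUE)
    for (k in ord) {
      i <- viol[k, 1]; j <- viol[k, 2]
      if (!alive[i] || !alive[j]) next
      drop <- if (cr[i] < cr[j]) i else if (cr[j] < cr[i]) j else max(i, j)
      alive[drop] <- FALSE
    }
  }
  log_step(keep_loci(gm, alive), gm, "ld", list(r2_max = r2_max))
}

#' Run the standard QC filter cascade
#'
#' Applies, in order: repeatability, monomorphic, locus call rate, secondary
#' SNPs, individual call rate, Hamming distance on sequence tags. Steps whose
#' metadata is unavailable can be switched off.
#'
#' @param gm a [genotype_matrix()]
#' @param min_rep,min_locus_cr,min_ind_cr,min_hamming thresholds for the
#'   respective steps; set a threshold to `NULL` to skip that step.
#' @param secondaries logical, run the one-SNP-per-clone step.
#' @return the filtered [genotype_matrix()]; inspect [filter_log()] for
#'   per-step retention counts.
#' @export
filter_cascade <- function(gm, min_rep = 0.95, min_locus_cr = 0.95,
                           secondaries = TRUE, min_ind_cr = 0.90,
                           min_hamming = 0.2) {
  if (!is.null(min_rep)) gm <- filter_repeatability(gm, min_rep)
  gm <- filter_monomorphic(gm)
  if (!is.null(min_locus_cr)) gm <- filter_locus_callrate(gm, min_locus_cr)
  if (secondaries) gm <- filter_secondaries(gm)
  if (!is.null(min_ind_cr)) gm <- filter_individual_callrate(gm, min_ind_cr)
  if (!is.null(min_hamming)) gm <- filter_hamming(gm, min_hamming)
  gm
}
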