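#' Construct a genotype matrix object
#'
#' The central container of the package: a loci-by-individuals matrix of
#' allele dosages (the count of the alternate allele, so 0 = homozygous
#' reference, 1 = heterozygous, 2 = homozygous alternate, `NA` = missing
#' call), together with per-locus metadata carried through the filtering
#' cascade.
#'
#' @param geno integer matrix, loci in rows and individuals in columns,
#'   entries in `{0, 1, 2, NA}`. Row and column names, when present, seed
#'   `locus_ids` / `individual_ids`.
#' @param locus_ids,individual_ids character identifiers; defaults come from
#'   `dimnames(geno)` or are generated (`L1..`, `ind1..`).
#' @param clone_id character, identifier of the sequence tag (clone) the SNP
#'   was called from; several "secondary" SNPs may share one clone.
#' @param tag_seq character, trimmed sequence tag over `A/C/G/T` (typically
#'   20--69 bp), `NA` when unknown.
#' @param repeatability numeric in `[0, 1]`, per-locus concordance across
#'   technical replicates, `NA` when no replicates were run.
#' @param call_rate numeric in `[0, 1]`; when `NULL` it is recomputed as the
#'   fraction of non-missing calls per locus.
#'
#' @return An object of class `"genotype_matrix"`: a list with elements
#'   `geno` (integer matrix) and `loci` (data frame of per-locus metadata).
#' @export
genotype_matrix <- function(geno, locus_ids = NULL, individual_ids = NULL,
                            clone_id = NULL, tag_seq = NULL,
                            repeatability = NULL, call_rate = NULL) {
  geno <- as.matrix(geno)
  storage.mode(geno) <- "integer"
  bad <- !is.na(geno) & !(geno %in% 0:2)
  if (any(bad)) {
    stop("genotype codes must be 0, 1, 2 or NA; found ",
         paste(unique(geno[bad]), collapse = ", "))
  }
  L <- nrow(geno)
  n <- ncol(geno)
  locus_ids <- locus_ids %||% rownames(geno) %||% paste0("L", seq_len(L))
  individual_ids <- individual_ids %||% colnames(geno) %||%
    paste0("ind", seq_len(n))
  if (anyDuplicated(locus_ids)) stop("duplicate locus ids")
  if (anyDuplicated(individual_ids)) stop("duplicate individual ids")
  if (length(locus_ids) != L) stop("locus_ids length != number of loci")
  if (length(individual_ids) != n) stop("individual_ids length != n individuals")
  dimnames(geno) <- list(locus_ids, individual_ids)

  rep_len1 <- function(x, default) {
    if (is.null(x)) rep(default, L) else {
      stopifnot(length(x) == L)
      x
    }
  }
  cr <- if (is.null(call_rate)) rowMeans(!is.na(geno)) else {
    stopifnot(length(call_rate) == L)
    as.numeric(call_rate)
  }
  loci <- data.frame(
    locus_id = as.character(locus_ids),
    clone_id = as.character(rep_len1(clone_id, NA_character_)),
    tag_seq = as.character(rep_len1(tag_seq, NA_character_)),
    call_rate = cr,
    repeatability = as.numeric(rep_len1(repeatability, NA_real_)),
    stringsAsFactors = FALSE
  )
  structure(list(geno = geno, loci = loci), class = "genotype_matrix")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d loci x %d individuals\n",
              n_loci(x), n_ind(x)))
  miss <- mean(is.na(x$geno))
  cat(sprintf("  missing calls: %.2f%%; mean locus call rate %.3f\n",
              100 * miss, mean(x$loci$call_rate)))
  if (any(!is.na(x$loci$repeatability))) {
    cat(sprintf("  repeatability: mean %.3f\n",
                mean(x$loci$repeatability, na.rm = TRUE)))
  }
  has_tag <- sum(!is.na(x$loci$tag_seq))
  cat(sprintf("  sequence tags present for %d loci\n", has_tag))
  invisible(x)
}

#' Number of loci / individuals
#' @param gm a [genotype_matrix()]
#' @return integer count.
#' @export
n_loci <- function(gm) nrow(gm$geno)

#' @rdname n_loci
#' @export
n_ind <- function(gm) ncol(gm$geno)

#' @export
dim.genotype_matrix <- function(x) dim(x$geno)

#' Subset a genotype matrix by loci and/or individuals
#'
#' Metadata rows follow the locus subset; call rate is *not* recomputed
#' (use [recompute_call_rate()] after dropping individuals if needed).
#'
#' @param x a `genotype_matrix`
#' @param i locus index (integer, logical or locus id)
#' @param j individual index (integer, logical or individual id)
#' @param ... unused
#' @export
`[.genotype_matrix` <- function(x, i, j, ...) {
  if (missing(i)) i <- seq_len(n_loci(x))
  if (missing(j)) j <- seq_len(n_ind(x))
  if (is.character(i)) i <- match(i, x$loci$locus_id)
  geno <- x$geno[i, j, drop = FALSE]
  loci <- x$loci[i, , drop = FALSE]
  rownames(loci) <- NULL
  structure(list(geno = geno, loci = loci), class = "genotype_matrix")
}

#' Recompute per-locus call rate from the genotype calls
#' @param gm a [genotype_matrix()]
#' @return `gm` with `loci$call_rate` replaced by the observed non-missing
#'   fraction per locus.
#' @export
recompute_call_rate <- function(gm) {
  gm$loci$call_rate <- rowMeans(!is.na(gm$geno))
  gm
}

#' Per-individual call rate
#' @param gm a [genotype_matrix()]
#' @return named numeric vector, fraction of non-missing loci per individual.
#' @export
individual_call_rate <- function(gm) colMeans(!is.na(gm$geno))

#' Population map: individual to population (and reporting unit) labels
#'
#' @param assignments named character vector or two-column data frame mapping
#'   individual id to population label.
#' @param reporting_units optional named character vector mapping population
#'   label to reporting-unit label; defaults to each population being its own
#'   unit.
#' @return An object of class `"pop_map"`: list with `assignments` (named
#'   character) and `reporting_units` (named character).
#' @export
pop_map <- function(assignments, reporting_units = NULL) {
  if (is.data.frame(assignments)) {
    a <- as.character(assignments[[2]])
    names(a) <- as.character(assignments[[1]])
    assignments <- a
  }
  if (is.null(names(assignments)) || anyDuplicated(names(assignments))) {
    stop("assignments must be uniquely named by individual id")
  }
  pops <- sort(unique(unname(assignments)))
  if (is.null(reporting_units)) {
    reporting_units <- stats::setNames(pops, pops)
  } else {
    missing_pop <- setdiff(pops, names(reporting_units))
    if (length(missing_pop)) {
      stop("populations without a reporting unit: ",
           paste(missing_pop, collapse = ", "))
    }
    reporting_units <- reporting_units[pops]
  }
  structure(list(assignments = assignments,
                 reporting_units = reporting_units),
            class = "pop_map")
}

#' @export
print.pop_map <- function(x, ...) {
  tab <- table(x$assignments)
  cat(sprintf("pop_map: %d individuals, %d populations, %d reporting units\n",
              length(x$assignments), length(tab),
              length(unique(x$reporting_units))))
  for (p in names(tab)) {
    cat(sprintf("  %s (unit %s): n = %d\n", p, x$reporting_units[[p]], tab[[p]]))
  }
  invisible(x)
}

#' Individuals belonging to one population
#' @param gm a [genotype_matrix()]
#' @param popmap a [pop_map()]
#' @param pop population label
#' @return character vector of individual ids present in `gm`.
#' @export
pop_individuals <- function(gm, popmap, pop) {
  ids <- names(popmap$assignments)[popmap$assignments == pop]
  intersect(colnames(gm$geno), ids)
}

# internal: split the columns of gm by population, in gm column order
split_by_pop <- function(gm, popmap) {
  labs <- popmap$assignments[colnames(gm$geno)]
  if (anyNA(labs)) {
    stop("individuals missing from population map: ",
         paste(colnames(gm$geno)[is.na(labs)], collapse = ", "))
  }
  split(colnames(gm$geno), labs)
}
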