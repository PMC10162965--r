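#' Read a genotype matrix from disk
#'
#' Three on-disk layouts are supported:
#' \describe{
#'   \item{`dart_csv`}{the provider-style single-row-per-SNP report written by
#'     [write_genotypes()]: locus-metadata columns (`CloneID`, `AlleleID`,
#'     `TrimmedSequence`, `CallRate`, `RepAvg`) followed by one column per
#'     individual holding allele dosages.}
#'   \item{`matrix_csv`}{a plain CSV with locus ids in the first column and
#'     one column per individual; `NA` or empty cells are missing calls.}
#'   \item{`vcf`}{a VCF whose `GT` field is converted to alternate-allele
#'     dosage. Only biallelic SNP records are imported; multiallelic records
#'     are skipped (a message reports how many). Half-missing genotypes
#'     (e.g. `./0`) are treated as missing because their dosage is undefined.}
#' }
#'
#' @param path file path.
#' @param format one of `"dart_csv"`, `"matrix_csv"`, `"vcf"`.
#' @return a [genotype_matrix()]. Call rate is taken from file metadata when
#'   present, otherwise recomputed from the calls; repeatability and tag
#'   sequence are `NA` when the format does not carry them.
#' @export
read_genotypes <- function(path, format = c("dart_csv", "matrix_csv", "vcf")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  switch(format,
         dart_csv = read_dart_csv(path),
         matrix_csv = read_matrix_csv(path),
         vcf = read_vcf_genotypes(path))
}

dart_meta_cols <- c("AlleleID", "CloneID", "TrimmedSequence", "CallRate", "RepAvg")

read_dart_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  missing_cols <- setdiff(dart_meta_cols, names(df))
  if (length(missing_cols)) {
    stop("not a dart_csv file (missing columns ",
         paste(missing_cols, collapse = ", "), "): ", path)
  }
  ind_cols <- setdiff(names(df), dart_meta_cols)
  if (!length(ind_cols)) stop("dart_csv has no individual columns: ", path)
  geno <- as.matrix(df[, ind_cols, drop = FALSE])
  suppressWarnings(storage.mode(geno) <- "integer")
  check_parsed_dosages(geno, df[, ind_cols, drop = FALSE], path)
  genotype_matrix(geno,
                  locus_ids = df$AlleleID,
                  individual_ids = ind_cols,
                  clone_id = df$CloneID,
                  tag_seq = ifelse(df$TrimmedSequence == "", NA, df$TrimmedSequence),
                  call_rate = df$CallRate,
                  repeatability = df$RepAvg)
}

read_matrix_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  geno <- as.matrix(df[, -1, drop = FALSE])
  suppressWarnings(storage.mode(geno) <- "integer")
  check_parsed_dosages(geno, df[, -1, drop = FALSE], path)
  genotype_matrix(geno, locus_ids = as.character(df[[1]]),
                  individual_ids = colnames(df)[-1])
}

# raise a parse error (with row number) where a cell was non-numeric garbage
# rather than a declared missing value
check_parsed_dosages <- function(geno, raw, path) {
  raw <- as.matrix(raw)
  garbage <- is.na(geno) & !(is.na(raw) | raw %in% c("", "NA"))
  if (any(garbage)) {
    row <- which(apply(garbage, 1, any))[1]
    stop(sprintf("malformed genotype value in %s at data row %d", path, row))
  }
}

read_vcf_genotypes <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  ref <- fix[, "REF"]
  alt <- fix[, "ALT"]
  biallelic_snp <- !is.na(alt) & nchar(ref) == 1 & nchar(alt) == 1 &
    !grepl(",", alt, fixed = TRUE)
  n_skip <- sum(!biallelic_snp)
  if (n_skip > 0) {
    message(n_skip, " non-biallelic-SNP record(s) skipped")
  }
  if (!any(biallelic_snp)) stop("no biallelic SNP records in ", path)
  gt <- vcfR::extract.gt(v, element = "GT")[biallelic_snp, , drop = FALSE]
  fix <- fix[biallelic_snp, , drop = FALSE]
  ids <- fix[, "ID"]
  no_id <- is.na(ids) | ids == "."
  ids[no_id] <- paste0(fix[no_id, "CHROM"], "_", fix[no_id, "POS"])
  # dosage from unphased or phased GT; any missing allele makes the call NA
  a1 <- substr(gt, 1, 1)
  a2 <- substr(gt, 3, 3)
  dose <- suppressWarnings(as.integer(a1) + as.integer(a2))
  dose[a1 == "." | a2 == "." | is.na(gt)] <- NA_integer_
  geno <- matrix(dose, nrow = nrow(gt), ncol = ncol(gt),
                 dimnames = list(ids, colnames(gt)))
  genotype_matrix(geno)
}

#' Write a genotype matrix to disk
#'
#' @param gm a [genotype_matrix()].
#' @param path output file.
#' @param format `"dart_csv"` (metadata columns + one column per individual)
#'   or `"matrix_csv"` (ids + dosages only; metadata is dropped).
#' @return `path`, invisibly.
#' @export
write_genotypes <- function(gm, path, format = c("dart_csv", "matrix_csv")) {
  format <- match.arg(format)
  geno <- gm$geno
  if (format == "dart_csv") {
    df <- data.frame(
      AlleleID = gm$loci$locus_id,
      CloneID = gm$loci$clone_id,
      TrimmedSequence = ifelse(is.na(gm$loci$tag_seq), "", gm$loci$tag_seq),
      CallRate = gm$loci$call_rate,
      RepAvg = gm$loci$repeatability,
      check.names = FALSE, stringsAsFactors = FALSE
    )
    df <- cbind(df, as.data.frame(geno, check.names = FALSE))
  } else {
    df <- data.frame(locus_id = gm$loci$locus_id, check.names = FALSE)
    df <- cbind(df, as.data.frame(geno, check.names = FALSE))
  }
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE, na = "NA")
  invisible(path)
}

#' Read an individual-to-population map
#'
#' Tab-separated, two columns (individual, population) or three (individual,
#' population, reporting unit), with or without a header line (a header is
#' detected when the first field of line one is `individual`). With two
#' columns the reporting unit defaults to the population itself.
#'
#' @param path TSV file path.
#' @return a [pop_map()].
#' @export
read_popmap <- function(path) {
  first <- readLines(path, n = 1)
  header <- grepl("^individual\\b", first)
  df <- utils::read.table(path, sep = "\t", header = header,
                          stringsAsFactors = FALSE,
                          col.names = if (!header) {
                            nf <- length(strsplit(first, "\t")[[1]])
                            c("individual", "population", "reporting_unit")[seq_len(nf)]
                          })
  if (ncol(df) < 2) stop("popmap needs at least two columns: ", path)
  dup <- duplicated(df[[1]])
  if (any(dup)) {
    conflict <- tapply(df[[2]], df[[1]], function(p) length(unique(p)) > 1)
    if (any(conflict)) {
      stop("individual(s) listed with conflicting populations: ",
           paste(names(conflict)[conflict], collapse = ", "))
    }
    df <- df[!dup, , drop = FALSE]
  }
  assignments <- stats::setNames(as.character(df[[2]]), as.character(df[[1]]))
  units <- NULL
  if (ncol(df) >= 3) {
    per_pop <- tapply(as.character(df[[3]]), df[[2]],
                      function(u) unique(u))
    if (any(lengths(per_pop) > 1)) {
      stop("population mapped to more than one reporting unit")
    }
    units <- stats::setNames(vapply(per_pop, `[[`, "", 1), names(per_pop))
  }
  pop_map(assignments, units)
}

#' Write a population map as TSV
#' @param popmap a [pop_map()]
#' @param path output file
#' @return `path`, invisibly.
#' @export
write_popmap <- function(popmap, path) {
  df <- data.frame(individual = names(popmap$assignments),
                   population = unname(popmap$assignments),
                   reporting_unit = unname(
                     popmap$reporting_units[popmap$assignments]),
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
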