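#' Default pipeline configuration
#'
#' Nested list of per-stage parameter blocks consumed by
#' [run_pipeline()]. Unknown keys in a supplied configuration are
#' rejected, and all blocks are validated before any stage runs.
#'
#' @param ... named overrides, e.g. `filter = list(min_rep = 0.99)`.
#' @return named list of class `"pipeline_config"`.
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    seed = 1,
    filter = list(min_rep = 0.95, min_locus_cr = 0.95, secondaries = TRUE,
                  min_ind_cr = 0.90, min_hamming = 0.2),
    divstats = list(n_boot = 100, n_perm = 99),
    structure = list(k_grid = 1:5, n_reps = 3, burnin = 500, iters = 1000,
                     freq_model = "correlated"),
    assign = list(prior_weight = 0.5, threshold = 0.9, min_size = 2),
    ne = list(pcrit = c(0.05, 0.02), mating = c("random", "monogamy"),
              min_pop = 10, ci = TRUE, exclude_migrants = TRUE),
    prioritise = list(n_std_individuals = 25, scenarios = 1:4)
  )
  over <- list(...)
  for (nm in names(over)) {
    if (!nm %in% names(cfg)) stop("unknown configuration block: ", nm)
    if (is.list(cfg[[nm]])) {
      bad <- setdiff(names(over[[nm]]), names(cfg[[nm]]))
      if (length(bad)) {
        stop("unknown key(s) in '", nm, "': ", paste(bad, collapse = ", "))
      }
      cfg[[nm]][names(over[[nm]])] <- over[[nm]]
    } else {
      cfg[[nm]] <- over[[nm]]
    }
  }
  structure(cfg, class = c("pipeline_config", "list"))
}

#' Read a pipeline configuration from YAML
#' @param path YAML file whose top-level keys mirror [pipeline_config()].
#' @return a validated `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  do.call(pipeline_config, yaml::read_yaml(path))
}

# per-stage deterministic sub-seeds derived from the global seed, so
# stages are reproducible in isolation (kept below 2^31)
stage_seed <- function(seed, stage) {
  (seed * 131L + utf8ToInt(substr(stage, 1, 1)) * 7L +
     nchar(stage)) %% 2000000000L
}

#' Run the full genetic-assessment pipeline
#'
#' Stages in order: QC filter cascade, per-population diversity and
#' pairwise differentiation, structure scan (PCoA + admixture sampler with
#' Evanno delta-K), leave-one-out assignment with migrant counting,
#' LD-based Ne per population (identified migrants excluded when
#' configured), and rarefaction/reserve-selection prioritisation. All
#' tables are returned and, when `out_dir` is given, written as
#' tab-separated UTF-8 files plus a provenance JSON (input hashes,
#' parameters, seeds, package version).
#'
#' @param gm a [genotype_matrix()]
#' @param popmap a [pop_map()]
#' @param config a [pipeline_config()]
#' @param out_dir optional output directory (created if needed).
#' @return object of class `"result_report"`: list of stage results.
#' @export
run_pipeline <- function(gm, popmap, config = pipeline_config(),
                         out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  seed <- config$seed
  report <- list()

  run_stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  fcfg <- config$filter
  gm_f <- run_stage("filter", {
    skip_rep <- anyNA(gm$loci$repeatability)
    skip_tags <- anyNA(gm$loci$tag_seq)
    filter_cascade(gm,
                   min_rep = if (skip_rep) NULL else fcfg$min_rep,
                   min_locus_cr = fcfg$min_locus_cr,
                   secondaries = fcfg$secondaries && !anyNA(gm$loci$clone_id),
                   min_ind_cr = fcfg$min_ind_cr,
                   min_hamming = if (skip_tags) NULL else fcfg$min_hamming)
  })
  report$filter_log <- filter_log(gm_f)
  keep_ids <- colnames(gm_f$geno)
  popmap_f <- pop_map(popmap$assignments[keep_ids], popmap$reporting_units)

  dcfg <- config$divstats
  report$diversity <- run_stage("divstats", {
    diversity_summary(gm_f, popmap_f, n_boot = dcfg$n_boot,
                      seed = stage_seed(seed, "divstats"))
  })
  report$fst <- run_stage("fst", {
    pairwise_fst(gm_f, popmap_f, n_boot = dcfg$n_boot,
                 n_perm = dcfg$n_perm, seed = stage_seed(seed, "fst"))
  })
  report$overall_fst <- run_stage("fst", fst_wc_multi(gm_f, popmap_f))

  scfg <- config$structure
  report$pcoa <- run_stage("structure", pcoa(gm_f, n_axes = 2))
  report$structure <- run_stage("structure", {
    structure_scan(gm_f, k_grid = scfg$k_grid, n_reps = scfg$n_reps,
                   burnin = scfg$burnin, iters = scfg$iters,
                   freq_model = scfg$freq_model,
                   seed = stage_seed(seed, "structure"))
  })

  acfg <- config$assign
  report$assignment <- run_stage("assign", {
    loo_self_assign(gm_f, popmap_f, prior_weight = acfg$prior_weight,
                    min_size = acfg$min_size)
  })
  report$migrants <- run_stage("assign", {
    count_migrants(report$assignment, popmap_f,
                   threshold = acfg$threshold)
  })

  ncfg <- config$ne
  report$ne <- run_stage("ne", {
    excl <- if (isTRUE(ncfg$exclude_migrants)) {
      report$migrants$migrants$individual
    }
    groups <- split_by_pop(gm_f, popmap_f)
    pops <- names(groups)[vapply(groups, function(x) {
      length(setdiff(x, excl)) >= ncfg$min_pop
    }, TRUE)]
    if (length(pops)) {
      ne_table(gm_f, popmap_f, pops = pops, pcrit = ncfg$pcrit,
               mating = ncfg$mating, exclude = excl, ci = ncfg$ci)
    }
  })

  pcfg <- config$prioritise
  report$prioritisation <- run_stage("prioritise", {
    tryCatch(prioritise(gm_f, popmap_f,
                        n_std_individuals = pcfg$n_std_individuals,
                        scenarios = pcfg$scenarios),
             warning = function(w) {
               suppressWarnings(
                 prioritise(gm_f, popmap_f,
                            n_std_individuals = pcfg$n_std_individuals,
                            scenarios = pcfg$scenarios))
             })
  })

  report$provenance <- list(
    package_version = as.character(utils::packageVersion("pardassess")),
    seed = seed,
    config = unclass(config),
    n_loci_in = n_loci(gm), n_ind_in = n_ind(gm),
    n_loci_filtered = n_loci(gm_f), n_ind_filtered = n_ind(gm_f),
    genotype_hash = genotype_hash(gm),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  class(report) <- "result_report"
  if (!is.null(out_dir)) write_report(report, out_dir)
  report
}

# content hash of the genotype codes + ids, independent of file layout
genotype_hash <- function(gm) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(c(colnames(gm$geno), gm$loci$locus_id,
               as.character(gm$geno)), f)
  unname(tools::md5sum(f))
}

#' @export
print.result_report <- function(x, ...) {
  cat("Genetic-assessment report\n")
  cat(sprintf("  loci: %d -> %d after filtering; individuals: %d -> %d\n",
              x$provenance$n_loci_in, x$provenance$n_loci_filtered,
              x$provenance$n_ind_in, x$provenance$n_ind_filtered))
  cat(sprintf("  populations: %d; overall theta = %.3f\n",
              nrow(x$diversity), x$overall_fst))
  if (!is.null(x$structure$delta_k)) {
    cat(sprintf("  Evanno best K = %d\n", best_k_evanno(x$structure$delta_k)))
  }
  cat(sprintf("  migrants called: %d\n", nrow(x$migrants$migrants)))
  invisible(x)
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
}

#' Write a result report as TSV tables + provenance JSON
#' @param report a [run_pipeline()] result.
#' @param out_dir destination directory.
#' @return `out_dir`, invisibly.
#' @export
write_report <- function(report, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_tsv(report$filter_log, file.path(out_dir, "filter_log.tsv"))
  write_tsv(report$diversity, file.path(out_dir, "diversity.tsv"))
  fst <- report$fst
  write_tsv(data.frame(population = rownames(fst$theta),
                       round(fst$theta, 6), check.names = FALSE),
            file.path(out_dir, "pairwise_fst.tsv"))
  for (k in names(report$structure$aligned)) {
    q <- report$structure$aligned[[k]]$q
    write_tsv(data.frame(individual = rownames(q), q, check.names = FALSE),
              file.path(out_dir, sprintf("qmatrix_K%s.tsv", k)))
  }
  if (!is.null(report$structure$delta_k)) {
    write_tsv(report$structure$delta_k, file.path(out_dir, "delta_k.tsv"))
  }
  write_tsv(report$assignment$table, file.path(out_dir, "assignment.tsv"))
  write_tsv(report$migrants$rates, file.path(out_dir, "immigration_rates.tsv"))
  if (!is.null(report$ne)) {
    write_tsv(report$ne, file.path(out_dir, "ne.tsv"))
  }
  rich <- report$prioritisation$richness$per_population
  write_tsv(rich, file.path(out_dir, "allelic_richness.tsv"))
  sols <- do.call(rbind, lapply(report$prioritisation$solutions, function(s) {
    data.frame(k = s$k, selected = paste(s$selected, collapse = ","),
               n_covered = s$n_covered, proportion = s$proportion)
  }))
  write_tsv(sols, file.path(out_dir, "prioritisation.tsv"))
  jsonlite::write_json(report$provenance,
                       file.path(out_dir, "provenance.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(out_dir)
}
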