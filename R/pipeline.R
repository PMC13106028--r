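#' Build a pipeline configuration
#'
#' Collects the thresholds and seeds for an end-to-end run on synthetic
#' data: simulation settings, per-cohort minor-allele-count filters
#' (visit-based cohorts default to MAC > 20, EHR-style cohorts to
#' MAC > 40, matching the differing sequencing-panel depths the two
#' record styles emulate), the single-variant significance threshold
#' (5e-8), the gene-test Bonferroni settings (0.05 over 20000 tests) and
#' the rare-variant MAF cut-off (0.01).
#'
#' @param sim a \code{\link{sim_config}}.
#' @param pheno a \code{\link{pheno_params}}.
#' @param sv_alpha single-variant significance threshold. Default 5e-8.
#' @param gene_n_tests,gene_alpha Bonferroni settings for gene tests.
#' @param mac_min per-cohort MAC thresholds (recycled).
#' @param maf_max rare-variant MAF cut-off. Default 0.01.
#' @param seed global seed; expanded into per-stage substreams through
#'   the simulation config.
#' @return list of class \code{pipeline_config}.
#' @export
pipeline_config <- function(sim = sim_config(seed = seed),
                            pheno = pheno_params(),
                            sv_alpha = 5e-8,
                            gene_n_tests = 20000, gene_alpha = 0.05,
                            mac_min = NULL,
                            maf_max = 0.01,
                            seed = 1L) {
  if (is.null(mac_min))
    mac_min <- ifelse(sim$visit_style == "ehr_style", 40L, 20L)
  stopifnot(sv_alpha > 0, gene_n_tests > 0, gene_alpha > 0, maf_max > 0)
  structure(list(sim = sim, pheno = pheno, sv_alpha = sv_alpha,
                 gene_n_tests = gene_n_tests, gene_alpha = gene_alpha,
                 mac_min = rep_len(mac_min, sim$n_cohorts),
                 maf_max = maf_max, seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Load a pipeline configuration from a YAML file
#'
#' Flat YAML keys mirror the \code{\link{pipeline_config}} and
#' \code{\link{sim_config}} arguments (simulation keys under \code{sim:},
#' thresholds at top level).
#'
#' @param path YAML file path.
#' @return a \code{pipeline_config}.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  sim_args <- y$sim %||% list()
  if (!is.null(y$seed) && is.null(sim_args$seed))
    sim_args$seed <- y$seed
  sim <- do.call(sim_config, sim_args)
  pipeline_config(sim = sim,
                  sv_alpha = y$sv_alpha %||% 5e-8,
                  gene_n_tests = y$gene_n_tests %||% 20000,
                  gene_alpha = y$gene_alpha %||% 0.05,
                  mac_min = y$mac_min,
                  maf_max = y$maf_max %||% 0.01,
                  seed = y$seed %||% 1L)
}

#' Run the full synthetic pipeline
#'
#' Executes the stages in dependency order: simulate the multi-cohort
#' study, phenotype every cohort with the classifier matching its record
#' style, run per-cohort single-variant association, meta-analyse across
#' cohorts, run per-cohort gene burden tests and combine them with
#' Fisher's method, and write a cohort-accounting report. All tabular
#' outputs are TSVs under \code{out_dir}; a JSON manifest records the
#' seed, thresholds and per-stage row counts. Reruns with the same
#' configuration reproduce identical outputs.
#'
#' @param config a \code{\link{pipeline_config}}.
#' @param out_dir output directory (created).
#' @param write_plots write QQ/Manhattan PDFs per cohort and for the
#'   meta-analysis. Default FALSE.
#' @return invisibly, a list with every stage's in-memory result and the
#'   manifest.
#' @export
run_pipeline <- function(config, out_dir, write_plots = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(package = "copdwl",
                   version = as.character(utils::packageVersion("copdwl")),
                   seed = config$seed,
                   sv_alpha = config$sv_alpha,
                   gene_threshold = config$gene_alpha / config$gene_n_tests,
                   timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
                   stages = list())

  study <- simulate_study(config$sim)
  assoc_tables <- list()
  gene_tables <- list()
  pheno_tables <- list()
  for (ci in seq_along(study$cohorts)) {
    co <- study$cohorts[[ci]]
    cdir <- file.path(out_dir, co$name)
    write_cohort(co, study$masks, cdir)

    mode <- if (co$style == "ehr_style") "ehr" else "visits"
    heights <- setNames(co$truth$height_m, co$truth$participant_id)
    ph <- phenotype_cohort(co$weights, config$pheno, mode = mode,
                           heights = heights)
    write.table(ph$calls, file.path(cdir, "phenotype.tsv"), sep = "\t",
                row.names = FALSE, quote = FALSE)
    if (!is.null(ph$cleaning))
      write.table(ph$cleaning, file.path(cdir, "cleaning_report.tsv"),
                  sep = "\t", row.names = FALSE, quote = FALSE)
    pheno_tables[[co$name]] <- ph$calls

    usable <- ph$calls[ph$calls$status %in% c("case", "control"), ]
    phen <- data.frame(participant_id = usable$participant_id,
                       status = usable$status)
    ar <- run_assoc(co$genotypes, phen, co$covariates,
                    mac_min = config$mac_min[ci])
    ar_ok <- ar[ar$converged, , drop = FALSE]
    write_assoc(ar_ok, file.path(cdir, "assoc.tsv"))
    if (write_plots)
      qq_manhattan_report(ar_ok, config$sv_alpha,
                          prefix = file.path(cdir, "assoc"))
    assoc_tables[[co$name]] <- ar_ok

    gt <- run_gene_tests(co$genotypes, study$masks, phen, co$covariates,
                         maf_max = config$maf_max)
    write.table(gt, file.path(cdir, "gene_tests.tsv"), sep = "\t",
                row.names = FALSE, quote = FALSE)
    gene_tables[[co$name]] <- gt

    manifest$stages[[co$name]] <- list(
      participants = nrow(co$covariates),
      phenotype_rows = nrow(ph$calls),
      cases = sum(ph$calls$status == "case"),
      assoc_rows = nrow(ar_ok),
      gene_rows = nrow(gt))
  }

  meta <- run_meta(assoc_tables)
  write_meta(meta, file.path(out_dir, "meta.tsv"))
  if (write_plots)
    qq_manhattan_report(meta, config$sv_alpha,
                        prefix = file.path(out_dir, "meta"))
  meta_hits <- meta[meta$p < config$sv_alpha, , drop = FALSE]
  write_meta(meta_hits, file.path(out_dir, "meta_hits.tsv"))

  combined <- combine_gene_results(gene_tables)
  write.table(combined, file.path(out_dir, "gene_combined.tsv"),
              sep = "\t", row.names = FALSE, quote = FALSE)
  sig <- gene_significance(combined, config$gene_n_tests,
                           config$gene_alpha)

  acct <- cohort_accounting()
  write.table(acct$wl_pct, file.path(out_dir, "cohort_report.tsv"),
              sep = "\t", row.names = FALSE, quote = FALSE)

  manifest$stages$meta <- list(variants = nrow(meta),
                               hits = nrow(meta_hits))
  manifest$stages$gene_combined <- list(genes = nrow(combined),
                                        hits = nrow(sig$hits),
                                        threshold = sig$threshold)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(list(study = study, phenotypes = pheno_tables,
                 assoc = assoc_tables, meta = meta,
                 meta_hits = meta_hits, gene = gene_tables,
                 gene_combined = combined, gene_sig = sig,
                 accounting = acct, manifest = manifest))
}
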