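#' Pipeline configuration
#'
#' Assembles and validates the configuration for [run_pipeline()]. Either a
#' simulated experiment (default) or file inputs (catalog, sample sheet and
#' FASTQ reads) drive the run.
#'
#' @param out_dir Output directory (created if needed).
#' @param seed Master seed, recorded in every output header.
#' @param simulate Simulate the experiment (`TRUE`) or read `reads_fastq`,
#'   `catalog_tsv`, `sample_sheet_tsv` from disk.
#' @param sim List of [sim_params()] overrides for simulation mode.
#' @param depth_per_sample Expected reads per library in simulation mode.
#' @param n_bio,n_tech Design of the simulated experiment.
#' @param simulate_read_level Also emit raw reads and demultiplex them
#'   (end-to-end mode) instead of using the simulated counts directly.
#' @param per_base_error Read-level substitution rate in end-to-end mode.
#' @param reads_fastq,catalog_tsv,sample_sheet_tsv,gene_sets_gmt Input paths
#'   for file mode (GMT optional in both modes).
#' @param control_ids Control strains removed before analysis.
#' @param min_total Low-count row filter threshold.
#' @param max_barcode_dist,max_index_dist Demultiplexing cutoffs.
#' @param bottom_frac Variance-partition bottom filter.
#' @param prior_df,fdr Test constants.
#' @param run_design_eval Also run the design-evaluation engine.
#' @param designs,grid_step Design-evaluation settings.
#' @param spline_df,spline_df_sets Smoothing degrees of freedom.
#' @return A list of class `barseq_config`.
#' @export
barseq_config <- function(out_dir = tempfile("barseq_run_"), seed = 1L,
                          simulate = TRUE, sim = list(),
                          depth_per_sample = 2e5, n_bio = 4L, n_tech = 2L,
                          simulate_read_level = FALSE, per_base_error = 0.01,
                          reads_fastq = NULL, catalog_tsv = NULL,
                          sample_sheet_tsv = NULL, gene_sets_gmt = NULL,
                          control_ids = character(0), min_total = 100,
                          max_barcode_dist = 2L, max_index_dist = 1L,
                          bottom_frac = 0.1, prior_df = 10, fdr = 0.05,
                          run_design_eval = FALSE,
                          designs = c("2x4x2", "2x3x2", "2x2x2", "2x4x1"),
                          grid_step = 0.05, spline_df = 20,
                          spline_df_sets = 15) {
  cfg <- as.list(environment())
  stopifnot(cfg$min_total >= 0, cfg$bottom_frac >= 0, cfg$bottom_frac < 1,
            cfg$fdr > 0, cfg$fdr < 1, cfg$grid_step > 0, cfg$grid_step <= 1,
            cfg$prior_df >= 0)
  if (!cfg$simulate) {
    for (f in c("reads_fastq", "catalog_tsv", "sample_sheet_tsv")) {
      if (is.null(cfg[[f]])) abort(sprintf("file mode requires `%s`", f))
      if (!file.exists(cfg[[f]])) {
        abort(sprintf("input file not found: %s", cfg[[f]]))
      }
    }
  }
  if (!is.null(cfg$gene_sets_gmt) && !file.exists(cfg$gene_sets_gmt)) {
    abort(sprintf("input file not found: %s", cfg$gene_sets_gmt))
  }
  structure(cfg, class = "barseq_config")
}

#' Read or write a pipeline configuration as YAML
#'
#' @param path YAML file path.
#' @param config A `barseq_config` object.
#' @return `read_config()` returns a validated `barseq_config`.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) abort(sprintf("config file not found: %s", path))
  do.call(barseq_config, yaml::read_yaml(path))
}

#' @rdname read_config
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

tsv_with_header <- function(x, path, config) {
  hdr <- sprintf("# barseqr %s | seed %d | config %s",
                 as.character(packageVersion("barseqr")),
                 config$seed, rlang::hash(unclass(config)))
  writeLines(hdr, path)
  readr::write_tsv(x, path, append = TRUE, col_names = TRUE)
  invisible(path)
}

#' Run the full Bar-seq pipeline
#'
#' Orchestrates simulate (or load) -> demultiplex -> filter -> collapse ->
#' exact NB test -> variance partition -> enrichment -> design evaluation,
#' writing TSV outputs (each with a version/seed/config-hash header) and
#' returning a machine-readable run report of per-stage record counts.
#'
#' @param config A [barseq_config()] object.
#' @return Invisibly, a list with `report` (tibble), `test`, `variance`,
#'   `enrichment`, `design_eval` and the output directory.
#' @export
run_pipeline <- function(config = barseq_config()) {
  stopifnot(inherits(config, "barseq_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  report <- list()
  note <- function(stage, n) {
    report[[length(report) + 1]] <<- tibble(stage = stage, records = n)
  }

  if (config$simulate) {
    params <- do.call(sim_params, modifyList(list(seed = config$seed),
                                             config$sim))
    pool <- simulate_pool(params)
    samples <- make_sample_sheet(n_bio = config$n_bio,
                                 n_tech = config$n_tech,
                                 seed = derive_seed(config$seed, 2))
    counts <- simulate_counts(pool$effects, samples,
                              depth_per_sample = config$depth_per_sample,
                              dispersion = params$dispersion,
                              seed = derive_seed(config$seed, 3))
    write_barcode_catalog(pool$catalog, file.path(config$out_dir,
                                                  "catalog.tsv"))
    readr::write_tsv(pool$effects, file.path(config$out_dir,
                                             "true_effects.tsv"))
    write_sample_sheet(samples, file.path(config$out_dir, "samples.tsv"))
    note("simulate_pool", nrow(pool$catalog))
    if (config$simulate_read_level) {
      reads <- simulate_reads(counts, pool$catalog, samples,
                              read_sim_params(per_base_error =
                                                config$per_base_error),
                              seed = derive_seed(config$seed, 4))
      note("simulate_reads", nrow(reads))
      dmx <- demultiplex(reads, samples, pool$catalog,
                         max_barcode_dist = config$max_barcode_dist,
                         max_index_dist = config$max_index_dist)
      counts <- dmx$counts
      tsv_with_header(dmx$stats, file.path(config$out_dir,
                                           "mapping_stats.tsv"), config)
      note("demultiplex_mapped", dmx$stats$mapped_d2)
    }
  } else {
    catalog <- read_barcode_catalog(config$catalog_tsv)
    samples <- read_sample_sheet(config$sample_sheet_tsv)
    reads <- read_fastq(config$reads_fastq)
    note("reads_in", nrow(reads))
    dmx <- demultiplex(reads, samples, catalog,
                       max_barcode_dist = config$max_barcode_dist,
                       max_index_dist = config$max_index_dist)
    counts <- dmx$counts
    tsv_with_header(dmx$stats, file.path(config$out_dir,
                                         "mapping_stats.tsv"), config)
    note("demultiplex_mapped", dmx$stats$mapped_d2)
  }
  tsv_with_header(counts, file.path(config$out_dir, "counts_raw.tsv"),
                  config)
  note("counts_rows_in", nrow(counts))

  counts <- filter_low_count(counts, min_total = config$min_total)
  note("counts_rows_filtered", nrow(counts))
  if (length(config$control_ids) > 0) {
    counts <- remove_control(counts, config$control_ids)
    note("counts_rows_after_control", nrow(counts))
  }
  t24 <- subset_samples(counts, samples, .data$time != "t0")
  coll <- collapse_tags_and_technical(t24$counts, t24$samples)
  stopifnot(sum(as_count_matrix(coll$counts)) ==
              sum(as_count_matrix(t24$counts)))  # conservation
  tsv_with_header(coll$counts, file.path(config$out_dir, "collapsed.tsv"),
                  config)
  note("mutants_collapsed", nrow(coll$counts))

  fit <- nb_fit(coll$counts, coll$samples, groups = "treatment",
                prior_df = config$prior_df)
  test <- exact_nb_test(fit)
  tsv_with_header(test, file.path(config$out_dir, "test_results.tsv"),
                  config)
  note("tests_run", nrow(test))
  note("significant_mutants", sum(test$q_value <= config$fdr))

  x <- preprocess_for_variance(t24$counts, bottom_frac = config$bottom_frac)
  vp <- partition_variance(x, t24$samples)
  tsv_with_header(vp, file.path(config$out_dir, "variance.tsv"), config)

  enrichment <- NULL
  if (!is.null(config$gene_sets_gmt)) {
    sets <- read_gmt(config$gene_sets_gmt) |>
      filter_gene_sets(universe = test$mutant_id)
    enrichment <- wilcoxon_enrichment(test, sets, fdr = config$fdr)
    tsv_with_header(enrichment |> select(-dplyr::any_of("members")),
                    file.path(config$out_dir, "enrichment.tsv"), config)
    note("sets_tested", nrow(enrichment))
  }

  de <- NULL
  if (config$run_design_eval) {
    de <- run_design_evaluation(t24$counts, t24$samples,
                                designs = config$designs,
                                grid = make_fraction_grid(config$grid_step),
                                seed = derive_seed(config$seed, 5),
                                fdr = config$fdr,
                                prior_df = config$prior_df,
                                df = config$spline_df,
                                df_sets = config$spline_df_sets)
    tsv_with_header(de$points, file.path(config$out_dir,
                                         "design_eval_points.tsv"), config)
    tsv_with_header(de$curves, file.path(config$out_dir,
                                         "design_eval_curves.tsv"), config)
    note("design_eval_points", nrow(de$points))
  }

  report <- bind_rows(report)
  tsv_with_header(report, file.path(config$out_dir, "run_report.tsv"),
                  config)
  invisible(list(report = report, test = test, variance = vp,
                 enrichment = enrichment, design_eval = de,
                 out_dir = config$out_dir))
}
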