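#' Experimental design specification
#'
#' A Bar-seq design is written treatments x biological replicates x technical
#' replicates, e.g. `2x4x2`. Differential testing needs at least two
#' biological replicates.
#'
#' @param n_bio Biological replicates (>= 2).
#' @param n_tech Technical replicates (>= 1).
#' @param n_treatments Treatments (default 2).
#' @return A list of class `design_spec` with a `label`.
#' @export
design_spec <- function(n_bio, n_tech, n_treatments = 2L) {
  stopifnot(n_bio >= 2, n_tech >= 1, n_treatments >= 1)
  structure(list(n_treatments = as.integer(n_treatments),
                 n_bio = as.integer(n_bio), n_tech = as.integer(n_tech),
                 label = sprintf("%dx%dx%d", n_treatments, n_bio, n_tech)),
            class = "design_spec")
}

parse_design <- function(x) {
  if (inherits(x, "design_spec")) return(x)
  parts <- as.integer(strsplit(tolower(x), "x", fixed = TRUE)[[1]])
  if (length(parts) != 3 || any(is.na(parts))) {
    abort(sprintf("cannot parse design '%s'; expected e.g. '2x4x2'", x))
  }
  design_spec(parts[2], parts[3], parts[1])
}

#' Sequencing-efficiency arithmetic for a pooled screen
#'
#' Converts a per-condition read budget into per-mutant and per-library
#' coverage, and an index inventory into the number of conditions that fit
#' on one sequencing lane.
#'
#' @param reads_per_condition Mapped reads available per condition.
#' @param n_mutants Mutants in the pool.
#' @param n_bio_reps Biological replicates per condition.
#' @param n_indices Available uniquely indexed adaptors.
#' @return One-row tibble: `reads_per_mutant_per_condition`,
#'   `reads_per_replicate_library` (both rounded to whole reads),
#'   `conditions_per_lane`.
#' @export
design_efficiency <- function(reads_per_condition = 6e6, n_mutants = 4295,
                              n_bio_reps = 4, n_indices = 120) {
  tibble(
    reads_per_mutant_per_condition = round(reads_per_condition / n_mutants),
    reads_per_replicate_library = round(reads_per_condition / n_mutants /
                                          n_bio_reps),
    conditions_per_lane = floor(n_indices / n_bio_reps))
}

#' Enumerate replicate combinations of a reduced design
#'
#' All ways of realising a target design inside a full experiment: choose
#' `n_bio` of the available biological replicates (the same choice applied to
#' both treatments) crossed with a globally shared choice of `n_tech` of the
#' available technical replicates. For a full 2x4x2 experiment this yields
#' 1, 2, 4, 8, 6 and 12 combinations for the 2x4x2, 2x4x1, 2x3x2, 2x3x1,
#' 2x2x2 and 2x2x1 designs.
#'
#' @param samples Sample sheet of the full experiment (t24 samples).
#' @param design Target design (`design_spec` or label string).
#' @return A tibble with `combination` id and a list-column `sample_ids`.
#' @export
enumerate_replicate_subsets <- function(samples, design) {
  design <- parse_design(design)
  check_sample_sheet(samples)
  bio_levels <- sort(unique(samples$bio_rep))
  tech_levels <- sort(unique(samples$tech_rep))
  if (design$n_bio > length(bio_levels) ||
      design$n_tech > length(tech_levels)) {
    abort("target design exceeds the full experiment")
  }
  bio_sets <- combn(bio_levels, design$n_bio, simplify = FALSE)
  tech_sets <- combn(tech_levels, design$n_tech, simplify = FALSE)
  combos <- tidyr::expand_grid(bio = bio_sets, tech = tech_sets)
  ids <- purrr::map2(combos$bio, combos$tech, function(bs, ts) {
    samples$sample_id[samples$bio_rep %in% bs & samples$tech_rep %in% ts]
  })
  tibble(combination = seq_len(nrow(combos)), sample_ids = ids)
}

#' The canonical read-subsampling fraction grid
#'
#' @param step Grid step (default 0.0025, i.e. 0.25%).
#' @return Fractions `step, 2 step, ..., 1`; with the default step, exactly
#'   400 evenly spaced fractions from 0.25% to 100%.
#' @export
make_fraction_grid <- function(step = 0.0025) {
  stopifnot(step > 0, step <= 1)
  seq_len(round(1 / step)) * step
}

#' Binomial subsampling of a count matrix
#'
#' Each cell is independently thinned as `Binom(X, p)`, which is
#' distributionally equivalent to sampling a fraction `p` of the sequenced
#' reads before mapping.
#'
#' @param counts Wide count table.
#' @param p Retention fraction in `[0, 1]`.
#' @param seed Optional seed.
#' @return The thinned count table (same shape; `S <= X` elementwise).
#' @export
subsample_counts <- function(counts, p, seed = NULL) {
  if (!is.numeric(p) || length(p) != 1 || is.na(p) || p < 0 || p > 1) {
    abort("`p` must be a single fraction in [0, 1]")
  }
  check_count_table(counts)
  cols <- count_sample_cols(counts)
  m <- as_count_matrix(counts)
  thin <- function() matrix(rbinom(length(m), as.integer(m), p), nrow(m))
  s <- if (is.null(seed)) thin() else withr::with_seed(seed, thin())
  counts[cols] <- as_tibble(setNames(as.data.frame(s), cols))
  counts
}

# Collapse + fit + test, the shared analysis core for the gold standard and
# for every subsample. Returns NULL if the data are degenerate (e.g. an
# all-zero library after extreme thinning).
analyze_experiment <- function(counts, samples, pair = NULL, prior_df = 10,
                               gene_sets = NULL, fdr = 0.05) {
  coll <- collapse_tags_and_technical(counts, samples)
  test <- tryCatch({
    fit <- nb_fit(coll$counts, coll$samples, groups = "treatment",
                  prior_df = prior_df)
    exact_nb_test(fit, pair = pair)
  }, error = function(e) NULL)
  if (is.null(test)) return(NULL)
  sets <- NULL
  if (!is.null(gene_sets)) {
    sets <- wilcoxon_enrichment(test, gene_sets, fdr = fdr)
  }
  list(test = test, sets = sets)
}

#' Gold-standard results from the complete experiment
#'
#' Analyses the full dataset and freezes its significant set, per-mutant log
#' fold changes, and effect-size strata, against which subsampled designs
#' are scored.
#'
#' @param counts Full (mutant, tag) x sample count table (filtered, t24).
#' @param samples Matching sample sheet.
#' @param gene_sets Optional filtered gene-set tibble.
#' @param fdr Significance threshold (default 0.05).
#' @param pair Group pair passed to [exact_nb_test()].
#' @param prior_df Dispersion shrinkage prior.
#' @param fc_thresholds Fold-change strata (default none, 1.5-fold, 2-fold);
#'   strata are nested.
#' @return A list of class `barseq_gold` with `test`, `sets`, `significant`,
#'   and `strata` (a named list of mutant-id vectors).
#' @export
gold_standard <- function(counts, samples, gene_sets = NULL, fdr = 0.05,
                          pair = NULL, prior_df = 10,
                          fc_thresholds = c(all = 1, fc1.5 = 1.5, fc2 = 2)) {
  res <- analyze_experiment(counts, samples, pair = pair,
                            prior_df = prior_df, gene_sets = gene_sets,
                            fdr = fdr)
  if (is.null(res)) abort("full-experiment analysis failed")
  sig <- res$test$mutant_id[res$test$q_value <= fdr]
  strata <- lapply(fc_thresholds, function(th) {
    keep <- abs(res$test$logFC) >= log2(th)
    intersect(sig, res$test$mutant_id[keep])
  })
  structure(list(test = res$test, sets = res$sets, significant = sig,
                 strata = strata, fdr = fdr, pair = attr(res$test, "pair")),
            class = "barseq_gold")
}

#' Score one subsampled dataset against the gold standard
#'
#' Re-runs the full analysis stack (collapse, TMM, dispersion, exact test,
#' q-values, optional enrichment) on a thinned count matrix and computes the
#' four design metrics: the number of significant mutants, power (fraction
#' of the gold significant set recovered), the mean squared error of the log
#' fold changes against the gold values, the number of significant gene
#' sets, and the empirical FDR (fraction of subsample-significant mutants
#' absent from the gold significant set; `NA` when nothing is significant).
#'
#' @param counts Subsampled (mutant, tag) x sample table, columns already
#'   restricted to the evaluated design.
#' @param samples Sample sheet.
#' @param gold A [gold_standard()] object.
#' @param gene_sets Optional filtered gene sets.
#' @param prior_df Dispersion shrinkage prior.
#' @return A one-row tibble of metrics (plus per-stratum power columns).
#' @export
evaluate_subsample <- function(counts, samples, gold, gene_sets = NULL,
                               prior_df = 10) {
  stopifnot(inherits(gold, "barseq_gold"))
  res <- analyze_experiment(counts, samples, pair = gold$pair,
                            prior_df = prior_df, gene_sets = gene_sets,
                            fdr = gold$fdr)
  if (is.null(res)) {
    return(tibble(n_significant = 0L, power = 0, mse_logfc = NA_real_,
                  n_significant_gene_sets = NA_integer_,
                  empirical_fdr = NA_real_,
                  power_all = 0, power_fc1.5 = NA_real_,
                  power_fc2 = NA_real_))
  }
  sig <- res$test$mutant_id[res$test$q_value <= gold$fdr]
  common <- dplyr::inner_join(res$test[, c("mutant_id", "logFC")],
                              gold$test[, c("mutant_id", "logFC")],
                              by = "mutant_id", suffix = c("_sub", "_gold"))
  strata_power <- power_by_effect_size(res$test, gold)
  tibble(
    n_significant = length(sig),
    power = if (length(gold$significant) > 0) {
      mean(gold$significant %in% sig)
    } else NA_real_,
    mse_logfc = mean((common$logFC_sub - common$logFC_gold)^2),
    n_significant_gene_sets = if (is.null(res$sets)) NA_integer_
                              else sum(res$sets$significant, na.rm = TRUE),
    empirical_fdr = if (length(sig) > 0) mean(!sig %in% gold$significant)
                    else NA_real_,
    power_all = strata_power$power[strata_power$stratum == "all"],
    power_fc1.5 = strata_power$power[strata_power$stratum == "fc1.5"],
    power_fc2 = strata_power$power[strata_power$stratum == "fc2"])
}

#' Recovery of the gold significant set, stratified by effect size
#'
#' For each gold stratum (all gold-significant mutants, and those whose full
#' experiment fold change exceeds each threshold), the fraction recovered as
#' significant in a subsample's results. Empty strata give `NA`, not 0.
#'
#' @param test A `barseq_test` tibble for the subsample.
#' @param gold A [gold_standard()] object.
#' @return A tibble with `stratum`, `n_gold`, `power`.
#' @export
power_by_effect_size <- function(test, gold) {
  sig <- test$mutant_id[test$q_value <= gold$fdr]
  purrr::imap(gold$strata, function(ids, nm) {
    tibble(stratum = nm, n_gold = length(ids),
           power = if (length(ids) > 0) mean(ids %in% sig) else NA_real_)
  }) |> bind_rows()
}

#' Natural-cubic-spline smoothing of raw metric points
#'
#' Least-squares fit of a natural cubic spline basis in the subsampling
#' fraction (knots at quantiles), pooling the raw points of all replicate
#' combinations of a design, evaluated on a prediction grid.
#'
#' @param points Tibble with `fraction` and `value` columns (`NA` values are
#'   dropped).
#' @param df Spline degrees of freedom (20 for power, accuracy and FDR;
#'   15 for gene-set counts, which are noisier).
#' @param grid Fractions at which to evaluate the fit (default the observed
#'   fractions).
#' @return Tibble with `fraction` and smoothed `value`.
#' @export
smooth_curves <- function(points, df = 20, grid = NULL) {
  pts <- points |> filter(!is.na(.data$value), !is.na(.data$fraction))
  if (nrow(pts) < df + 1) {
    abort(sprintf("need at least df + 1 = %d points, got %d", df + 1,
                  nrow(pts)))
  }
  if (is.null(grid)) grid <- sort(unique(pts$fraction))
  basis <- splines::ns(pts$fraction, df = df)
  fit <- lm(pts$value ~ basis)
  pred <- cbind(1, predict(basis, grid)) %*% stats::coef(fit)
  tibble(fraction = grid, value = as.vector(pred))
}

#' Evaluate replication and read-depth designs by subsampling
#'
#' The complete design-evaluation engine: analyse the full experiment as the
#' gold standard, then for every target design, every replicate combination
#' and every fraction of the grid, binomially thin the corresponding
#' columns, re-run the analysis, score the four metrics, and smooth each
#' metric per design with a natural cubic spline (`df` for power, accuracy
#' and FDR; `df_sets` for gene-set counts). Each (design, combination,
#' fraction) draw has its own deterministic seed stream.
#'
#' @param counts Full (mutant, tag) x sample table (t24, pre-filtered).
#' @param samples Matching sample sheet.
#' @param designs Character labels (e.g. `c("2x4x2", "2x3x2")`) or
#'   `design_spec` list.
#' @param grid Fraction grid (default [make_fraction_grid()]).
#' @param seed Master seed.
#' @param gene_sets Optional filtered gene sets.
#' @param fdr Significance threshold.
#' @param prior_df Dispersion shrinkage prior.
#' @param df,df_sets Spline degrees of freedom for smoothing.
#' @return An object of class `barseq_design_eval` with `points` (raw
#'   per-combination metrics, including the realised
#'   `reads_per_condition`), `curves` (smoothed metric curves per design)
#'   and `gold`.
#' @export
run_design_evaluation <- function(counts, samples,
                                  designs = c("2x4x2", "2x3x2", "2x2x2",
                                              "2x4x1", "2x3x1", "2x2x1"),
                                  grid = make_fraction_grid(), seed = 1L,
                                  gene_sets = NULL, fdr = 0.05,
                                  prior_df = 10, df = 20, df_sets = 15) {
  check_count_table(counts)
  check_sample_sheet(samples)
  gold <- gold_standard(counts, samples, gene_sets = gene_sets, fdr = fdr,
                        prior_df = prior_df)
  key_cols <- count_key_cols(counts)
  n_trt <- length(unique(samples$treatment))
  points <- purrr::imap(designs, function(dsn, d_idx) {
    dsn <- parse_design(dsn)
    combos <- enumerate_replicate_subsets(samples, dsn)
    purrr::map(seq_len(nrow(combos)), function(ci) {
      ids <- combos$sample_ids[[ci]]
      sub_counts <- counts[, c(key_cols, ids)]
      sub_samples <- samples[samples$sample_id %in% ids, ]
      purrr::map(seq_along(grid), function(gi) {
        p <- grid[gi]
        s <- subsample_counts(sub_counts, p,
                              seed = derive_seed(seed, d_idx, ci, gi))
        met <- evaluate_subsample(s, sub_samples, gold,
                                  gene_sets = gene_sets,
                                  prior_df = prior_df)
        bind_cols(tibble(design = dsn$label, combination = ci, fraction = p,
                         reads_per_condition =
                           sum(as_count_matrix(s)) / n_trt),
                  met)
      }) |> bind_rows()
    }) |> bind_rows()
  }) |> bind_rows()

  metric_cols <- c("n_significant", "power", "mse_logfc",
                   "n_significant_gene_sets", "empirical_fdr",
                   "power_all", "power_fc1.5", "power_fc2")
  curves <- purrr::map(unique(points$design), function(dsn) {
    pts_d <- points[points$design == dsn, ]
    purrr::map(metric_cols, function(mc) {
      raw <- tibble(fraction = pts_d$fraction, value = pts_d[[mc]])
      use_df <- if (mc == "n_significant_gene_sets") df_sets else df
      use_df <- min(use_df, max(1, length(unique(raw$fraction[
        !is.na(raw$value)])) - 1))
      sm <- tryCatch(smooth_curves(raw, df = use_df, grid = grid),
                     error = function(e) NULL)
      if (is.null(sm)) return(NULL)
      tibble(design = dsn, metric = mc, fraction = sm$fraction,
             value = sm$value)
    }) |> bind_rows()
  }) |> bind_rows()

  structure(list(points = points, curves = curves, gold = gold,
                 designs = vapply(designs,
                                  function(d) parse_design(d)$label, ""),
                 grid = grid, seed = seed),
            class = "barseq_design_eval")
}

#' @export
print.barseq_design_eval <- function(x, ...) {
  cat("Bar-seq design evaluation\n")
  cat(sprintf("  designs: %s\n", paste(x$designs, collapse = ", ")))
  cat(sprintf("  %d raw points over %d fractions; gold significant set: %d\n",
              nrow(x$points), length(x$grid), length(x$gold$significant)))
  invisible(x)
}

#' Tidy a design evaluation
#'
#' @param x A `barseq_design_eval` object.
#' @param type `"points"` (raw per-combination metrics) or `"curves"`
#'   (smoothed).
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.barseq_design_eval <- function(x, type = c("points", "curves"), ...) {
  type <- match.arg(type)
  x[[type]]
}
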