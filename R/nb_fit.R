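#' Fit the negative-binomial model to a collapsed count matrix
#'
#' The full normalisation-plus-dispersion stack used before exact testing:
#' TMM normalisation factors and effective library sizes, library-size
#' equalisation by quantile-matched pseudo-counts, common dispersion by
#' conditional maximum likelihood, and shrunken per-mutant dispersions under
#' a weighted-likelihood prior.
#'
#' @param counts Collapsed mutant x biological-replicate count table (see
#'   [collapse_tags_and_technical()]) or matrix.
#' @param samples Sample sheet for the collapsed columns (needs `sample_id`
#'   and the grouping column), or `NULL` if `groups` is given directly.
#' @param groups Either the name of a sample-sheet column (default
#'   `"treatment"`) or a vector of group labels per count column.
#' @param prior_df Prior degrees of freedom for dispersion shrinkage
#'   (default 10); `0` disables shrinkage toward the common value.
#' @param dispersion Optional fixed common dispersion; skips estimation
#'   (tagwise values are then also fixed at it).
#' @param lib_sizes Optional effective library sizes, overriding
#'   raw size x TMM (e.g. equal sizes for a controlled comparison).
#' @return An object of class `nb_fit`.
#' @export
nb_fit <- function(counts, samples = NULL, groups = "treatment",
                   prior_df = 10, dispersion = NULL, lib_sizes = NULL) {
  m <- if (is.matrix(counts)) counts else as_count_matrix(counts)
  if (length(groups) == 1 && is.character(groups) && !is.null(samples)) {
    idx <- match(colnames(m), samples$sample_id)
    if (any(is.na(idx))) abort("count columns missing from sample sheet")
    groups <- samples[[groups]][idx]
  }
  groups <- as.factor(groups)
  if (length(groups) != ncol(m)) {
    abort("`groups` must supply one label per sample column")
  }
  if (is.null(lib_sizes)) {
    factors <- tmm_factors(m)
    lib <- colSums(m) * factors
  } else {
    factors <- rep(1, ncol(m))
    lib <- rep_len(lib_sizes, ncol(m))
  }
  if (is.null(dispersion)) {
    phi_common <- estimate_common_dispersion(m, groups, lib_sizes = lib)
    phi_tagwise <- estimate_tagwise_dispersion(m, groups, phi_common,
                                               prior_df = prior_df,
                                               lib_sizes = lib)
  } else {
    phi_common <- dispersion
    phi_tagwise <- rep(dispersion, nrow(m))
  }
  eq <- equalize_libraries(m, groups, lib, phi_common)
  structure(list(counts = m, groups = groups, tmm_factors = factors,
                 lib_sizes = lib, pseudo = eq$pseudo,
                 pseudo_lib = eq$pseudo_lib, phi_common = phi_common,
                 phi_tagwise = phi_tagwise, prior_df = prior_df),
            class = "nb_fit")
}

#' @export
print.nb_fit <- function(x, ...) {
  cat("Negative-binomial Bar-seq fit\n")
  cat(sprintf("  %d mutants x %d samples, groups: %s\n",
              nrow(x$counts), ncol(x$counts),
              paste(levels(x$groups), collapse = ", ")))
  cat(sprintf("  common dispersion %.4g; tagwise range [%.4g, %.4g] (prior df %g)\n",
              x$phi_common, min(x$phi_tagwise), max(x$phi_tagwise),
              x$prior_df))
  invisible(x)
}

#' Tidy a negative-binomial fit
#'
#' @param x An [nb_fit()] object.
#' @param ... Unused.
#' @return One row per mutant: `mutant_id`, `mean_count`, `phi_tagwise`.
#' @export
tidy.nb_fit <- function(x, ...) {
  tibble(mutant_id = rownames(x$counts),
         mean_count = rowMeans(x$counts),
         phi_tagwise = x$phi_tagwise)
}

#' Glance at a negative-binomial fit
#'
#' @param x An [nb_fit()] object.
#' @param ... Unused.
#' @return A one-row tibble summarising the fit.
#' @export
glance.nb_fit <- function(x, ...) {
  tibble(n_mutants = nrow(x$counts), n_samples = ncol(x$counts),
         n_groups = length(levels(x$groups)),
         phi_common = x$phi_common,
         phi_tagwise_median = median(x$phi_tagwise),
         prior_df = x$prior_df)
}
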