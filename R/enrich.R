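#' Filter gene sets against the detected universe
#'
#' Intersects every set with the detected mutant ids and drops sets with
#' fewer than `min_size` detected members (a set with exactly `min_size` is
#' kept).
#'
#' @param sets Gene-set tibble from [read_gmt()] (`set_id`, `description`,
#'   list-column `members`).
#' @param universe Character vector of detected mutant ids.
#' @param min_size Minimum detected members (default 4).
#' @return The filtered tibble, members restricted to the universe, with an
#'   `n_detected` column.
#' @export
filter_gene_sets <- function(sets, universe, min_size = 4) {
  if (length(universe) == 0) abort("universe is empty")
  out <- sets |>
    mutate(members = lapply(.data$members, intersect, y = universe),
           n_detected = lengths(.data$members)) |>
    filter(.data$n_detected >= min_size)
  out
}

#' Wilcoxon rank-sum gene-set enrichment on log fold changes
#'
#' For each gene set, compares the estimated log2 fold changes of in-set
#' mutants against all other tested mutants with a two-sided Wilcoxon
#' rank-sum test (exact enumeration for in-set sizes up to
#' `exact_threshold` when there are no ties, normal approximation with tie
#' and continuity correction otherwise), then attaches Storey q-values
#' across sets and flags significance at `fdr`.
#'
#' @param logfc Tibble with `mutant_id` and `logFC` columns (e.g. a
#'   [exact_nb_test()] result).
#' @param sets Gene-set tibble (pre-filter with [filter_gene_sets()]).
#' @param fdr Significance threshold on q-values (default 0.05).
#' @param alternative Sidedness passed to the rank-sum test.
#' @param exact_threshold Largest in-set size for which the exact
#'   distribution is used (default 10).
#' @return A tibble with `set_id`, `n_detected`, `direction` (sign of the
#'   in-set median shift), `p_value`, `q_value`, `significant`.
#' @export
wilcoxon_enrichment <- function(logfc, sets, fdr = 0.05,
                                alternative = "two.sided",
                                exact_threshold = 10) {
  stopifnot(all(c("mutant_id", "logFC") %in% names(logfc)))
  vals <- setNames(logfc$logFC, logfc$mutant_id)
  rows <- purrr::map(seq_len(nrow(sets)), function(i) {
    ms <- intersect(sets$members[[i]], names(vals))
    inside <- vals[ms]
    outside <- vals[setdiff(names(vals), ms)]
    if (length(outside) == 0) {
      abort(sprintf("gene set %s covers the whole universe", sets$set_id[i]))
    }
    if (length(inside) == 0) {
      return(tibble(set_id = sets$set_id[i], n_detected = 0L,
                    direction = NA_real_, p_value = NA_real_))
    }
    exact <- length(inside) <= exact_threshold
    wt <- suppressWarnings(
      wilcox.test(inside, outside, alternative = alternative, exact = exact,
                  correct = TRUE))
    tibble(set_id = sets$set_id[i], n_detected = length(inside),
           direction = sign(median(inside) - median(outside)),
           p_value = wt$p.value)
  })
  out <- bind_rows(rows)
  ok <- !is.na(out$p_value)
  out$q_value <- NA_real_
  if (any(ok)) out$q_value[ok] <- storey_qvalues(out$p_value[ok])
  out$significant <- !is.na(out$q_value) & out$q_value <= fdr
  out
}
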