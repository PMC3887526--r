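#' Remove low-count rows
#'
#' Drops (mutant, tag) rows whose total across all sample columns is below
#' `min_total`. Such rows are typically spurious matches created by
#' sequencing error. The boundary is strict: a row totalling exactly
#' `min_total` is kept.
#'
#' @param counts A wide count table.
#' @param min_total Minimum row total to keep (default 100).
#' @return The filtered count table, with the removed rows (and their totals)
#'   attached as attribute `"removed"`.
#' @export
filter_low_count <- function(counts, min_total = 100) {
  check_count_table(counts)
  totals <- rowSums(as_count_matrix(counts))
  keep <- totals >= min_total
  out <- counts[keep, , drop = FALSE]
  removed <- counts[!keep, count_key_cols(counts), drop = FALSE]
  removed$total <- unname(totals[!keep])
  attr(out, "removed") <- removed
  out
}

#' Remove control strains
#'
#' Drops every row belonging to the listed control mutants (for example a
#' highly abundant neutral deletion replicated on every source plate, which
#' can dominate the read pool). Warns, rather than fails, if a control id is
#' absent.
#'
#' @param counts A wide count table.
#' @param control_ids Character vector of mutant ids to drop.
#' @return The count table without the control rows.
#' @export
remove_control <- function(counts, control_ids) {
  check_count_table(counts)
  absent <- setdiff(control_ids, counts$mutant_id)
  if (length(absent) > 0) {
    warn(paste0("control id(s) not present: ", paste(absent, collapse = ", ")))
  }
  counts[!counts$mutant_id %in% control_ids, , drop = FALSE]
}

#' Collapse tags and technical replicates
#'
#' Sums UPTAG and DNTAG counts and all technical replicates within each
#' biological replicate, yielding the mutant x (treatment, biological
#' replicate) matrix used for differential-abundance testing. Summing (rather
#' than averaging) combines the two semi-redundant barcode measurements while
#' remaining robust to loss of one barcode, and is the appropriate way to
#' pool technical replicates of count data. The grand total is conserved
#' exactly.
#'
#' @param counts A (mutant, tag) x sample count table.
#' @param samples Sample sheet covering every count column.
#' @return A list with `counts` (mutant x collapsed-sample table, columns
#'   named `treatment_bioRep`) and `samples` (collapsed sheet with
#'   `sample_id`, `treatment`, `time`, `bio_rep`).
#' @export
collapse_tags_and_technical <- function(counts, samples) {
  check_count_table(counts)
  check_sample_sheet(samples)
  samp_cols <- count_sample_cols(counts)
  meta <- samples[match(samp_cols, samples$sample_id), ]
  if (any(is.na(meta$sample_id)) || any(is.na(meta$bio_rep))) {
    abort("every count column needs sample-sheet metadata with bio_rep")
  }
  if (!"time" %in% names(meta)) meta$time <- "t24"
  group <- paste(meta$treatment, meta$bio_rep, sep = "_")
  m <- as_count_matrix(counts)
  collapsed <- t(rowsum(t(m), group = group, reorder = FALSE))
  # sum over tags within mutant
  by_mut <- rowsum(collapsed, group = counts$mutant_id, reorder = FALSE)
  out_samples <- meta |>
    distinct(.data$treatment, .data$time, .data$bio_rep) |>
    mutate(sample_id = paste(.data$treatment, .data$bio_rep, sep = "_")) |>
    select("sample_id", "treatment", "time", "bio_rep")
  out <- bind_cols(tibble(mutant_id = rownames(by_mut)),
                   as_tibble(by_mut[, out_samples$sample_id, drop = FALSE]))
  list(counts = out, samples = out_samples)
}

#' UPTAG/DNTAG divergence report
#'
#' For each mutant, the ratio of the larger to the smaller tag total across
#' all samples (with a pseudocount of 1 added to both totals for reporting
#' only, so mutants with a fully lost tag get a finite ratio), plus how many
#' mutants fall within two-fold and beyond ten- and hundred-fold divergence.
#'
#' @param counts A (mutant, tag) x sample count table.
#' @return A list with `ratios` (tibble: `mutant_id`, `uptag_total`,
#'   `dntag_total`, `ratio`) and `summary` (counts of mutants
#'   `within_2fold`, `over_2fold`, `over_10fold`, `over_100fold`).
#' @export
tag_divergence <- function(counts) {
  check_count_table(counts)
  if (!"tag" %in% names(counts)) abort("counts must carry a tag column")
  totals <- tibble(mutant_id = counts$mutant_id, tag = counts$tag,
                   total = rowSums(as_count_matrix(counts))) |>
    tidyr::pivot_wider(names_from = "tag", values_from = "total",
                       values_fill = 0)
  for (tg in c("UPTAG", "DNTAG")) if (!tg %in% names(totals)) totals[[tg]] <- 0
  ratios <- totals |>
    mutate(ratio = pmax(.data$UPTAG + 1, .data$DNTAG + 1) /
                   pmin(.data$UPTAG + 1, .data$DNTAG + 1)) |>
    rename(uptag_total = "UPTAG", dntag_total = "DNTAG")
  list(ratios = ratios,
       summary = tibble(within_2fold = sum(ratios$ratio <= 2),
                        over_2fold = sum(ratios$ratio > 2),
                        over_10fold = sum(ratios$ratio > 10),
                        over_100fold = sum(ratios$ratio > 100)))
}

#' Restrict a count table and sheet to selected samples
#'
#' Convenience metadata filter, e.g. to exclude unselected time-zero samples
#' from differential testing.
#'
#' @param counts A wide count table.
#' @param samples Sample sheet.
#' @param keep Logical expression on the sample sheet columns.
#' @return A list with filtered `counts` and `samples`.
#' @export
subset_samples <- function(counts, samples, keep) {
  keep_q <- rlang::enquo(keep)
  sel <- samples |> filter(!!keep_q)
  cols <- intersect(count_sample_cols(counts), sel$sample_id)
  list(counts = counts[, c(count_key_cols(counts), cols)],
       samples = sel[sel$sample_id %in% cols, ])
}
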