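#' Levenshtein edit distance
#'
#' Standard unit-cost edit distance (substitution, insertion, deletion)
#' between pairs of sequences. Vectorised with recycling.
#'
#' @param a,b Character vectors of sequences.
#' @return Integer vector of distances.
#' @examples
#' levenshtein("ACGT", c("ACGT", "ACGA", "AGT"))
#' @export
levenshtein <- function(a, b) {
  stopifnot(is.character(a), is.character(b))
  if (length(a) == 0 || length(b) == 0) return(integer(0))
  lv_dist_cpp(a, b)
}

# Nearest-unique assignment: the unique strictly-nearest reference within
# `max_dist` wins; a tie at the minimum distance is discarded as ambiguous.
nearest_unique <- function(queries, refs, max_dist) {
  res <- lv_nearest_cpp(queries, refs, as.integer(max_dist))
  tibble(index = ifelse(res$tie, NA_integer_, res$index),
         dist = res$dist,
         status = dplyr::case_when(
           is.na(res$index) ~ "no_hit",
           res$tie ~ "ambiguous",
           TRUE ~ "assigned"))
}

#' Match barcode regions against a catalogue
#'
#' Assigns each read's barcode region to the unique nearest catalogue barcode
#' within `max_dist` edits. Reads matching two or more barcodes equally well
#' at the minimum distance are discarded as ambiguous; a unique strictly
#' nearer candidate wins even when other candidates lie within the cutoff.
#'
#' @param barcodes Character vector of observed barcode regions.
#' @param catalog Catalogue tibble (`mutant_id`, `uptag`, `dntag`).
#' @param max_dist Maximum Levenshtein distance (default 2).
#' @param tags Which tag sequences to search: `"both"`, `"UPTAG"` or
#'   `"DNTAG"`.
#' @return A tibble with `mutant_id`, `tag`, `dist`, `status`
#'   (`assigned` / `ambiguous` / `no_hit`); `mutant_id` is `NA` unless
#'   `status == "assigned"`.
#' @export
match_barcode <- function(barcodes, catalog, max_dist = 2L,
                          tags = c("both", "UPTAG", "DNTAG")) {
  tags <- match.arg(tags)
  if (nrow(catalog) == 0) abort("catalog is empty")
  refs <- switch(tags,
    both = c(catalog$uptag, catalog$dntag),
    UPTAG = catalog$uptag,
    DNTAG = catalog$dntag)
  ref_mut <- switch(tags,
    both = rep(catalog$mutant_id, 2),
    catalog$mutant_id)
  ref_tag <- switch(tags,
    both = rep(c("UPTAG", "DNTAG"), each = nrow(catalog)),
    UPTAG = rep("UPTAG", nrow(catalog)),
    DNTAG = rep("DNTAG", nrow(catalog)))
  hit <- nearest_unique(barcodes, refs, max_dist)
  tibble(mutant_id = ifelse(hit$status == "assigned", ref_mut[hit$index],
                            NA_character_),
         tag = ifelse(hit$status == "assigned", ref_tag[hit$index],
                      NA_character_),
         dist = hit$dist, status = hit$status)
}

#' Match sample-index regions against a sample sheet
#'
#' Same nearest-unique rule as [match_barcode()] with a default cutoff of 1,
#' the appropriate tolerance for 5-bp indices designed at pairwise distance
#' >= 2.
#'
#' @param indices Character vector of observed index regions.
#' @param sheet Sample sheet with `sample_id` and `index` columns.
#' @param max_dist Maximum Levenshtein distance (default 1).
#' @return A tibble with `sample_id`, `dist`, `status`.
#' @export
match_index <- function(indices, sheet, max_dist = 1L) {
  if (nrow(sheet) == 0) abort("sample sheet is empty")
  hit <- nearest_unique(indices, sheet$index, max_dist)
  tibble(sample_id = ifelse(hit$status == "assigned",
                            sheet$sample_id[hit$index], NA_character_),
         dist = hit$dist, status = hit$status)
}

#' Demultiplex reads into a (mutant, tag) x sample count matrix
#'
#' Implements fixed-layout demultiplexing: the 5-bp sample index is matched
#' within 1 edit, the 15-bp constant priming region decides UPTAG vs DNTAG
#' (nearest constant within 2 edits), and the 20-bp barcode region is matched
#' against the corresponding catalogue tags within `max_barcode_dist` edits.
#' Every read increments at most one cell; ties discard the read.
#'
#' @param reads A tibble with a `sequence` column (e.g. from [read_fastq()]
#'   or [simulate_reads()]), or a path to a FASTQ file.
#' @param sheet Sample sheet tibble.
#' @param catalog Barcode catalogue tibble.
#' @param max_barcode_dist,max_index_dist Levenshtein cutoffs (defaults 2
#'   and 1).
#' @param layout Read layout, see [read_layout()].
#' @return A list with `counts` (wide count table over all
#'   (mutant, tag) x sample cells, zero-filled) and `stats`, a one-row tibble
#'   with `total`, cumulative `mapped_d0`/`mapped_d1`/`mapped_d2` (reads
#'   assigned with barcode distance <= 0, 1, 2), `ambiguous`, `no_hit`,
#'   `bad_constant`, `bad_index` and `too_short`. Categories are mutually
#'   exclusive and sum to `total` (with `mapped_d2` counting all assigned
#'   reads).
#' @export
demultiplex <- function(reads, sheet, catalog,
                        max_barcode_dist = 2L, max_index_dist = 1L,
                        layout = read_layout()) {
  if (is.character(reads) && length(reads) == 1) reads <- read_fastq(reads)
  check_sample_sheet(sheet)
  seqs <- reads$sequence
  n_total <- length(seqs)
  lay <- layout
  bc_end <- lay$barcode_start + lay$barcode_len - 1L

  empty_counts <- tidyr::expand_grid(mutant_id = catalog$mutant_id,
                                     tag = c("UPTAG", "DNTAG"))
  zero <- matrix(0L, nrow(empty_counts), nrow(sheet),
                 dimnames = list(NULL, sheet$sample_id))
  finish <- function(cells, stats) {
    if (nrow(cells) > 0) {
      key <- match(paste(cells$mutant_id, cells$tag),
                   paste(empty_counts$mutant_id, empty_counts$tag))
      col <- match(cells$sample_id, sheet$sample_id)
      zero[cbind(key, col)] <- cells$n  # cells are pre-aggregated, pairs unique
    }
    list(counts = bind_cols(empty_counts, as_tibble(zero)), stats = stats)
  }
  stats0 <- tibble(total = n_total, mapped_d0 = 0L, mapped_d1 = 0L,
                   mapped_d2 = 0L, ambiguous = 0L, no_hit = 0L,
                   bad_constant = 0L, bad_index = 0L, too_short = 0L)
  if (n_total == 0) return(finish(tibble(), stats0))

  too_short <- nchar(seqs) < bc_end
  use <- seqs[!too_short]
  idx_region <- substr(use, lay$index_start, lay$index_start + lay$index_len - 1L)
  con_region <- substr(use, lay$constant_start,
                       lay$constant_start + lay$constant_len - 1L)
  bc_region <- substr(use, lay$barcode_start, bc_end)

  idx_hit <- match_index(idx_region, sheet, max_index_dist)
  bad_index <- idx_hit$status != "assigned"

  # tag type from the constant region: nearest of the two constants within 2
  con_hit <- nearest_unique(con_region, c(lay$up_constant, lay$dn_constant), 2L)
  bad_constant <- !bad_index & con_hit$status != "assigned"
  live <- !bad_index & !bad_constant

  mutant <- rep(NA_character_, length(use))
  tag <- rep(NA_character_, length(use))
  bdist <- rep(NA_integer_, length(use))
  bstatus <- rep(NA_character_, length(use))
  for (tg in c("UPTAG", "DNTAG")) {
    sel <- live & con_hit$index == match(tg, c("UPTAG", "DNTAG"))
    if (!any(sel)) next
    # fast path: exact string match, unique by catalogue construction
    refcol <- if (tg == "UPTAG") catalog$uptag else catalog$dntag
    ex <- match(bc_region[sel], refcol)
    hitrows <- which(sel)
    exact <- !is.na(ex)
    mutant[hitrows[exact]] <- catalog$mutant_id[ex[exact]]
    tag[hitrows[exact]] <- tg
    bdist[hitrows[exact]] <- 0L
    bstatus[hitrows[exact]] <- "assigned"
    if (any(!exact)) {
      mh <- match_barcode(bc_region[hitrows[!exact]], catalog,
                          max_dist = max_barcode_dist, tags = tg)
      mutant[hitrows[!exact]] <- mh$mutant_id
      tag[hitrows[!exact]] <- mh$tag
      bdist[hitrows[!exact]] <- mh$dist
      bstatus[hitrows[!exact]] <- mh$status
    }
  }
  assigned <- live & !is.na(bstatus) & bstatus == "assigned"
  stats <- tibble(
    total = n_total,
    mapped_d0 = sum(assigned & bdist == 0L),
    mapped_d1 = sum(assigned & bdist <= 1L),
    mapped_d2 = sum(assigned),
    ambiguous = sum(live & !is.na(bstatus) & bstatus == "ambiguous"),
    no_hit = sum(live & !is.na(bstatus) & bstatus == "no_hit"),
    bad_constant = sum(bad_constant),
    bad_index = sum(bad_index),
    too_short = sum(too_short))
  cells <- tibble(mutant_id = mutant[assigned], tag = tag[assigned],
                  sample_id = idx_hit$sample_id[assigned]) |>
    dplyr::count(.data$mutant_id, .data$tag, .data$sample_id, name = "n")
  finish(cells, stats)
}
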