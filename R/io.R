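#' Read and write Bar-seq tables and reads
#'
#' Plain-text interchange: tab-separated tables for the barcode catalogue
#' (`mutant_id`, `uptag`, `dntag`), the sample sheet (`sample_id`, `index`,
#' `treatment`, `time`, `bio_rep`, `tech_rep`), count matrices
#' (key columns then one column per sample), and GMT gene sets
#' (`set_id <tab> description <tab> member...`). FASTQ I/O goes through
#' Biostrings. Lines starting with `#` in TSV files are treated as comments.
#'
#' @param path File path.
#' @param x Object to write.
#' @name barseq-io
NULL

#' @rdname barseq-io
#' @export
read_barcode_catalog <- function(path) {
  cat <- readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                         col_types = readr::cols(.default = "c"))
  need <- c("mutant_id", "uptag", "dntag")
  if (!all(need %in% names(cat))) {
    abort("catalog must have columns mutant_id, uptag, dntag")
  }
  if (anyDuplicated(cat$mutant_id)) abort("catalog mutant_ids must be unique")
  bad <- grepl("[^ACGT]", c(cat$uptag, cat$dntag))
  if (any(bad) || any(!nzchar(c(cat$uptag, cat$dntag)))) {
    abort("catalog barcodes must be non-empty uppercase ACGT")
  }
  cat[, need]
}

#' @rdname barseq-io
#' @export
write_barcode_catalog <- function(x, path) {
  readr::write_tsv(x, path)
  invisible(path)
}

#' @rdname barseq-io
#' @export
read_sample_sheet <- function(path) {
  sheet <- readr::read_tsv(path, comment = "#", show_col_types = FALSE)
  check_sample_sheet(sheet, required = c("sample_id", "index", "treatment",
                                         "bio_rep", "tech_rep"))
  if (!"time" %in% names(sheet)) sheet$time <- "t24"
  # sample indices must be unambiguous under distance-1 matching
  if (nrow(sheet) > 1) {
    pairs <- combn(sheet$index, 2)
    d <- lv_dist_cpp(pairs[1, ], pairs[2, ])
    if (any(d < 2)) warn("sample indices closer than Levenshtein distance 2")
  }
  as_tibble(sheet)
}

#' @rdname barseq-io
#' @export
write_sample_sheet <- function(x, path) {
  readr::write_tsv(x, path)
  invisible(path)
}

#' @rdname barseq-io
#' @export
read_count_table <- function(path) {
  counts <- readr::read_tsv(path, comment = "#", show_col_types = FALSE)
  check_count_table(counts)
  counts
}

#' @rdname barseq-io
#' @export
write_count_table <- function(x, path) {
  readr::write_tsv(x, path)
  invisible(path)
}

#' @rdname barseq-io
#' @export
read_fastq <- function(path) {
  seqs <- tryCatch(
    Biostrings::readDNAStringSet(path, format = "fastq"),
    error = function(e) abort(paste0("malformed FASTQ at ", path, ": ",
                                     conditionMessage(e))))
  tibble(read_id = names(seqs), sequence = unname(as.character(seqs)))
}

#' @rdname barseq-io
#' @export
write_fastq <- function(x, path) {
  seqs <- Biostrings::DNAStringSet(x$sequence)
  names(seqs) <- x$read_id
  quals <- Biostrings::BStringSet(strrep("I", nchar(x$sequence)))
  Biostrings::writeXStringSet(seqs, path, format = "fastq", qualities = quals)
  invisible(path)
}

#' @rdname barseq-io
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) < 3)
  if (length(bad) > 0) {
    abort(sprintf("GMT line %d has fewer than 3 fields", bad[1]))
  }
  tibble(set_id = vapply(parts, `[[`, "", 1),
         description = vapply(parts, `[[`, "", 2),
         members = lapply(parts, function(p) unique(p[-(1:2)])))
}

#' @rdname barseq-io
#' @export
write_gmt <- function(x, path) {
  lines <- vapply(seq_len(nrow(x)), function(i) {
    paste(c(x$set_id[i], x$description[i], x$members[[i]]), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}
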