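#' Preprocess counts for variance partitioning
#'
#' Adds 1 to every count, scales each column by its TMM-derived effective
#' library size so per-library read depth is not itself a source of
#' variation, log-transforms, and drops the bottom `bottom_frac` of mutants
#' ranked by total raw count (low counts have a disproportionate effect on
#' the technical component). Exactly `floor(bottom_frac * n)` rows are
#' dropped.
#'
#' @param counts Wide count table or matrix.
#' @param bottom_frac Fraction of lowest-total mutants to drop (default 0.1).
#' @return A real-valued matrix (rows = retained mutants).
#' @export
preprocess_for_variance <- function(counts, bottom_frac = 0.1) {
  m <- if (is.matrix(counts)) counts else as_count_matrix(counts)
  if (ncol(m) < 2) abort("variance preprocessing needs >= 2 samples")
  eff <- effective_lib_sizes(m)
  x <- log(sweep(m + 1, 2, eff, "/"))
  n_drop <- floor(bottom_frac * nrow(m))
  if (n_drop > 0) {
    totals <- rowSums(m)
    keep <- order(totals, decreasing = TRUE)[seq_len(nrow(m) - n_drop)]
    x <- x[sort(keep), , drop = FALSE]
  }
  x
}

#' Eigen-R2: fraction of variance explained by a factor
#'
#' Row-centres the matrix, takes its singular value decomposition, regresses
#' each right singular vector (eigen-row) on the factor's indicator design,
#' and returns the eigenvalue-weighted average of the per-eigen-row
#' coefficients of determination: `sum_j lambda_j R2_j / sum_j lambda_j`.
#' All eigen-rows with an eigenvalue share above machine tolerance are
#' retained.
#'
#' @param x Real matrix (features x samples).
#' @param fac Factor (or coercible) of length `ncol(x)`.
#' @return R-squared in `[0, 1]`.
#' @export
eigen_r2 <- function(x, fac) {
  if (ncol(x) < 2) abort("eigen_r2 needs >= 2 columns")
  fac <- as.factor(fac)
  if (length(fac) != ncol(x)) abort("factor length must match column count")
  xc <- x - rowMeans(x)
  sv <- svd(xc)
  lambda <- sv$d^2
  keep <- lambda / sum(lambda) > 1e-12
  if (!any(keep)) return(0)
  lambda <- lambda[keep]
  v <- sv$v[, keep, drop = FALSE]
  design <- model.matrix(~fac)
  qr_d <- qr(design)
  r2 <- vapply(seq_len(ncol(v)), function(j) {
    y <- v[, j]
    tss <- sum((y - mean(y))^2)
    if (tss < 1e-300) return(0)
    res <- qr.resid(qr_d, y)
    max(0, 1 - sum(res^2) / tss)
  }, 0.0)
  sum(lambda * r2) / sum(lambda)
}

#' Partition variance into treatment, biological and technical components
#'
#' Computes `R2_T = eigen_r2(x, treatment)` and `R2_B = eigen_r2(x,
#' replicate-within-treatment)`. Because the biological factor (one level per
#' independent culture) nests the treatment factor, its design spans the
#' treatment design and `R2_B >= R2_T` by construction. The reported shares
#' are treatment `R2_T`, biological `R2_B - R2_T`, and technical `1 - R2_B`,
#' which sum to 1 exactly.
#'
#' @param x Preprocessed matrix from [preprocess_for_variance()].
#' @param samples Sample sheet rows matching the columns of `x` (needs
#'   `treatment` and `bio_rep`).
#' @return A one-row tibble of class `barseq_variance` with `r2_treatment`,
#'   `r2_biological`, and component shares `treatment`, `biological`,
#'   `technical`.
#' @export
partition_variance <- function(x, samples) {
  check_sample_sheet(samples, required = c("sample_id", "treatment",
                                           "bio_rep"))
  meta <- samples[match(colnames(x), samples$sample_id), ]
  if (any(is.na(meta$sample_id))) abort("columns of x missing from samples")
  trt <- as.factor(meta$treatment)
  bio <- interaction(meta$treatment, meta$bio_rep, drop = TRUE)
  r2_t <- eigen_r2(x, trt)
  r2_b <- eigen_r2(x, bio)
  out <- tibble(r2_treatment = r2_t, r2_biological = r2_b,
                treatment = r2_t, biological = r2_b - r2_t,
                technical = 1 - r2_b)
  class(out) <- c("barseq_variance", class(out))
  out
}
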