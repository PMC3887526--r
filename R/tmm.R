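#' Trimmed mean of M-values (TMM) normalisation factors
#'
#' Computes a relative scaling factor per sample from a doubly trimmed,
#' precision-weighted mean of per-mutant log2 count ratios (M-values) against
#' a reference sample, correcting for composition bias between libraries.
#' Rows with a zero in either sample are excluded; by default 30% of
#' M-values (15% each tail) and 5% of A-values (2.5% each tail) are trimmed,
#' weights are the inverse delta-method binomial variances, and the returned
#' factors are rescaled to have geometric mean exactly 1.
#'
#' @param counts A wide count table or numeric matrix (rows = mutants,
#'   columns = samples).
#' @param reference Optional reference column name or index. By default the
#'   sample whose upper-quartile count fraction is closest to the mean upper
#'   quartile is used.
#' @param logratio_trim,sum_trim Total trim fractions for M and A values.
#' @param do_weighting Weight M-values by inverse approximate variance.
#' @return Named numeric vector of factors (geometric mean 1). Effective
#'   library size = raw library size x factor.
#' @export
tmm_factors <- function(counts, reference = NULL,
                        logratio_trim = 0.3, sum_trim = 0.05,
                        do_weighting = TRUE) {
  m <- if (is.matrix(counts)) counts else as_count_matrix(counts)
  if (ncol(m) < 2) abort("TMM needs at least two samples")
  lib <- colSums(m)
  if (any(lib == 0)) abort("all-zero sample column")
  if (is.null(reference)) {
    uq <- apply(m, 2, function(x) quantile(x, 0.75)) / lib
    reference <- which.min(abs(uq - mean(uq)))
  } else if (is.character(reference)) {
    reference <- match(reference, colnames(m))
    if (is.na(reference)) abort("reference sample not found")
  }
  ref <- m[, reference]
  nref <- lib[reference]
  one_factor <- function(obs, nobs) {
    fin <- obs > 0 & ref > 0
    o <- obs[fin]; r <- ref[fin]
    if (length(o) == 0) return(1)
    M <- log2((o / nobs) / (r / nref))
    A <- 0.5 * log2((o / nobs) * (r / nref))
    w <- (nobs - o) / (nobs * o) + (nref - r) / (nref * r)
    if (max(abs(M)) < 1e-6) return(1)  # identical composition
    # trim fractions are per tail, following the canonical TMM definition
    n <- length(M)
    loL <- floor(n * logratio_trim) + 1
    hiL <- n + 1 - loL
    loS <- floor(n * sum_trim) + 1
    hiS <- n + 1 - loS
    keep <- rank(M) >= loL & rank(M) <= hiL & rank(A) >= loS & rank(A) <= hiS
    if (!any(keep)) return(1)
    f <- if (do_weighting) {
      sum(M[keep] / w[keep]) / sum(1 / w[keep])
    } else {
      mean(M[keep])
    }
    if (!is.finite(f)) f <- 0
    2^f
  }
  f <- vapply(seq_len(ncol(m)), function(j) one_factor(m[, j], lib[j]), 0.0)
  f <- f / exp(mean(log(f)))
  names(f) <- colnames(m)
  f
}

#' Effective library sizes
#'
#' @param counts A wide count table or matrix.
#' @param factors Optional precomputed TMM factors.
#' @return Named vector of raw library size x TMM factor.
#' @export
effective_lib_sizes <- function(counts, factors = NULL) {
  m <- if (is.matrix(counts)) counts else as_count_matrix(counts)
  if (is.null(factors)) factors <- tmm_factors(m)
  colSums(m) * factors
}
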