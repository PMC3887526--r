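#' Storey q-values
#'
#' Estimates the null proportion pi0 by smoothing
#' `pi0(lambda) = #\{p > lambda\} / (m (1 - lambda))` over a lambda grid with
#' a cubic smoothing spline and taking the fitted value at the largest
#' lambda, clipped to (0, 1]. The q-value of each p-value is then
#' `min over t >= p of pi0 * m * t / #\{p <= t\}`, which is monotone
#' non-decreasing in p. Forcing `pi0 = 1` reproduces Benjamini-Hochberg
#' adjusted p-values exactly.
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @param lambda Grid for pi0 estimation (default 0.05 to 0.95 by 0.05).
#' @param pi0 Optional fixed null proportion overriding the estimate.
#' @return Numeric vector of q-values, same order as `p`.
#' @export
storey_qvalues <- function(p, lambda = seq(0.05, 0.95, 0.05), pi0 = NULL) {
  if (any(is.na(p)) || any(p < 0) || any(p > 1)) {
    abort("p-values must lie in [0, 1]")
  }
  m <- length(p)
  if (m == 0) return(numeric(0))
  if (is.null(pi0)) pi0 <- estimate_pi0(p, lambda)
  o <- order(p)
  q <- pi0 * m * p[o] / seq_len(m)
  q <- rev(cummin(rev(pmin(q, 1))))
  out <- numeric(m)
  out[o] <- q
  out
}

#' @rdname storey_qvalues
#' @export
estimate_pi0 <- function(p, lambda = seq(0.05, 0.95, 0.05)) {
  m <- length(p)
  pi0_l <- vapply(lambda, function(l) mean(p > l) / (1 - l), 0.0)
  pi0 <- if (length(lambda) >= 4 && length(unique(pi0_l)) > 1) {
    fit <- smooth.spline(lambda, pi0_l, df = 3)
    predict(fit, x = max(lambda))$y
  } else {
    pi0_l[length(lambda)]
  }
  min(max(pi0, 1e-8), 1)
}
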