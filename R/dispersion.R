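# Quantile-to-quantile matching of NB counts between library sizes, via a
# gamma approximation with matched mean and variance, averaging the lower-
# and upper-tail transforms. With equal input and output means the transform
# is the identity.
q2q_gamma <- function(y, mu_in, mu_out, phi) {
  out <- numeric(length(y))
  pos <- mu_in > 0 & mu_out > 0
  if (!any(pos)) return(out)
  y <- y[pos]; mi <- mu_in[pos]; mo <- mu_out[pos]
  vi <- mi + phi * mi^2
  vo <- mo + phi * mo^2
  shi <- mi^2 / vi; sci <- vi / mi
  sho <- mo^2 / vo; sco <- vo / mo
  p_lo <- pgamma(y, shape = shi, scale = sci)
  p_hi <- pgamma(y, shape = shi, scale = sci, lower.tail = FALSE)
  q_lo <- qgamma(p_lo, shape = sho, scale = sco)
  q_hi <- qgamma(p_hi, shape = sho, scale = sco, lower.tail = FALSE)
  # far in a tail one of the transforms saturates; fall back to the other,
  # and to plain rescaling if both do
  q_lo[!is.finite(q_lo)] <- q_hi[!is.finite(q_lo)]
  q_hi[!is.finite(q_hi)] <- q_lo[!is.finite(q_hi)]
  res <- (q_lo + q_hi) / 2
  bad <- !is.finite(res)
  res[bad] <- y[bad] * mo[bad] / mi[bad]
  out[pos] <- res
  out
}

#' Equalise library sizes by quantile-matched pseudo-counts
#'
#' Maps every count to the quantile-matched value it would have had in a
#' library of the geometric-mean effective size, assuming NB variation with
#' dispersion `phi` around group-specific expected proportions. The
#' conditional-likelihood machinery below assumes exchangeable replicates,
#' which holds only after this equalisation.
#'
#' @param m Count matrix (mutants x samples).
#' @param groups Factor of group membership per column.
#' @param lib_sizes Effective library sizes (raw x TMM by default).
#' @param phi NB dispersion used for the quantile matching.
#' @return List with `pseudo` (matrix), `pseudo_lib` (scalar common size).
#' @export
equalize_libraries <- function(m, groups, lib_sizes = NULL, phi = 0.01) {
  groups <- as.factor(groups)
  if (is.null(lib_sizes)) lib_sizes <- effective_lib_sizes(m)
  n_star <- exp(mean(log(lib_sizes)))
  pseudo <- matrix(0, nrow(m), ncol(m), dimnames = dimnames(m))
  for (k in levels(groups)) {
    j <- which(groups == k)
    p_g <- rowSums(m[, j, drop = FALSE]) / sum(lib_sizes[j])
    for (jj in j) {
      pseudo[, jj] <- q2q_gamma(m[, jj], lib_sizes[jj] * p_g, n_star * p_g, phi)
    }
  }
  list(pseudo = pseudo, pseudo_lib = n_star)
}

# Conditional (on group totals) NB log-likelihood per mutant, summed over
# groups, for equal-library counts. `phi` may be a scalar or one value per
# mutant. Terms constant in phi are dropped.
cond_loglik_by_gene <- function(pseudo, groups, phi) {
  groups <- as.factor(groups)
  r <- 1 / pmax(phi, 1e-10)
  ll <- rowSums(lgamma(pseudo + r)) - ncol(pseudo) * lgamma(r)
  for (k in levels(groups)) {
    j <- which(groups == k)
    nk <- length(j)
    z <- rowSums(pseudo[, j, drop = FALSE])
    ll <- ll + lgamma(nk * r) - lgamma(z + nk * r)
  }
  ll
}

check_replication <- function(groups) {
  groups <- as.factor(groups)
  if (all(table(groups) < 2)) {
    abort(paste("dispersion estimation requires at least two biological",
                "replicates in at least one group"))
  }
  invisible(groups)
}

#' Estimate the common NB dispersion by conditional maximum likelihood
#'
#' Maximises the conditional log-likelihood (conditioning on per-mutant group
#' totals) summed over mutants, on library-size-equalised pseudo-counts. The
#' equalisation and the maximisation are alternated twice, starting from
#' phi = 0.01; the optimum is searched on log10(phi) over [1e-8, 10] to a
#' relative tolerance of 1e-6.
#'
#' @param counts Wide count table or matrix.
#' @param groups Group label per sample column.
#' @param lib_sizes Optional effective library sizes.
#' @return Scalar dispersion estimate `phi_common`.
#' @export
estimate_common_dispersion <- function(counts, groups, lib_sizes = NULL) {
  m <- if (is.matrix(counts)) counts else as_count_matrix(counts)
  groups <- check_replication(groups)
  if (is.null(lib_sizes)) lib_sizes <- effective_lib_sizes(m)
  phi <- 0.01
  for (it in 1:2) {
    eq <- equalize_libraries(m, groups, lib_sizes, phi)
    obj <- function(lp) {
      v <- sum(cond_loglik_by_gene(eq$pseudo, groups, 10^lp))
      if (!is.finite(v)) -1e300 else v
    }
    opt <- optimize(obj, interval = c(-8, 1), maximum = TRUE, tol = 1e-7)
    phi <- 10^opt$maximum
  }
  phi
}

#' Estimate shrunken per-mutant (tagwise) dispersions
#'
#' Maximises, per mutant, the weighted conditional log-likelihood
#' `ll_g(phi) + prior_n * mean_g(ll_g(phi))`, where the common component's
#' weight `prior_n = prior_df / df_residual` carries `prior_df` prior degrees
#' of freedom. `prior_df = 0` gives unshrunken per-mutant estimates;
#' `prior_df = Inf`-like values pin every mutant to the common dispersion.
#' The per-mutant maximisation is a vectorised golden-section search on
#' log10(phi) over [1e-8, 10].
#'
#' @param counts Wide count table or matrix.
#' @param groups Group label per sample column.
#' @param phi_common Common dispersion (used for pseudo-count equalisation).
#' @param prior_df Prior degrees of freedom (default 10).
#' @param lib_sizes Optional effective library sizes.
#' @return Numeric vector of per-mutant dispersions.
#' @export
estimate_tagwise_dispersion <- function(counts, groups, phi_common,
                                        prior_df = 10, lib_sizes = NULL) {
  m <- if (is.matrix(counts)) counts else as_count_matrix(counts)
  groups <- check_replication(groups)
  if (is.null(lib_sizes)) lib_sizes <- effective_lib_sizes(m)
  eq <- equalize_libraries(m, groups, lib_sizes, phi_common)
  pseudo <- eq$pseudo
  df_resid <- ncol(m) - length(unique(groups))
  prior_n <- if (df_resid > 0) prior_df / df_resid else prior_df
  G <- nrow(m)
  # average conditional log-likelihood profile, spline-interpolated in
  # log10(phi) so it can be evaluated at per-mutant candidate dispersions
  grid <- seq(-8, 1, length.out = 41)
  lbar_grid <- vapply(grid, function(lp) {
    mean(cond_loglik_by_gene(pseudo, groups, 10^lp))
  }, 0.0)
  lbar <- stats::splinefun(grid, lbar_grid, method = "natural")
  wll <- function(lphi) {
    v <- cond_loglik_by_gene(pseudo, groups, 10^lphi) + prior_n * lbar(lphi)
    v[!is.finite(v)] <- -1e300
    v
  }
  # vectorised golden-section: each mutant keeps its own bracket
  gr <- (sqrt(5) - 1) / 2
  a <- rep(-8, G); b <- rep(1, G)
  c1 <- b - gr * (b - a); d1 <- a + gr * (b - a)
  fc <- wll(c1); fd <- wll(d1)
  for (it in 1:45) {
    left <- fc > fd
    b[left] <- d1[left]; d1[left] <- c1[left]; fd[left] <- fc[left]
    c1[left] <- b[left] - gr * (b[left] - a[left])
    a[!left] <- c1[!left]; c1[!left] <- d1[!left]; fc[!left] <- fd[!left]
    d1[!left] <- a[!left] + gr * (b[!left] - a[!left])
    fresh <- wll(ifelse(left, c1, d1))
    fc[left] <- fresh[left]
    fd[!left] <- fresh[!left]
  }
  10^((a + b) / 2)
}
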