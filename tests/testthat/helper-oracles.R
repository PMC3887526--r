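# Independent oracles, kept deliberately naive and separate from the package
# implementations they check.

# Full dynamic-programming edit distance in plain R.
lv_oracle <- function(a, b) {
  a <- strsplit(a, "")[[1]]
  b <- strsplit(b, "")[[1]]
  n <- length(a); m <- length(b)
  D <- matrix(0L, n + 1, m + 1)
  D[, 1] <- 0:n
  D[1, ] <- 0:m
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      D[i + 1, j + 1] <- min(D[i, j] + (a[i] != b[j]),
                             D[i, j + 1] + 1L,
                             D[i + 1, j] + 1L)
    }
  }
  D[n + 1, m + 1]
}

# Brute-force conditional NB enumeration for the two-group exact test:
# explicit log-pmf from the gamma-function form, looped outcome by outcome.
nb_exact_oracle <- function(y1, y2, n1, n2, phi) {
  s <- y1 + y2
  m <- s / (n1 + n2)
  lpmf <- function(k, n) {
    if (phi < 1e-10) return(dpois(k, n * m, log = TRUE))
    r <- n / phi
    mu <- n * m
    lgamma(k + r) - lgamma(r) - lfactorial(k) +
      r * log(r / (r + mu)) + k * log(mu / (r + mu))
  }
  lp <- vapply(0:s, function(k) lpmf(k, n1) + lpmf(s - k, n2), 0.0)
  pr <- exp(lp - max(lp))
  sum(pr[pr <= pr[y1 + 1] * (1 + 1e-12)]) / sum(pr)
}

# Straightforward transcription of the doubly trimmed weighted mean-of-M
# formula for a single sample against a reference.
tmm_oracle_one <- function(obs, ref) {
  no <- sum(obs); nr <- sum(ref)
  fin <- obs > 0 & ref > 0
  o <- obs[fin]; r <- ref[fin]
  M <- log2((o / no) / (r / nr))
  A <- 0.5 * log2((o / no) * (r / nr))
  w <- (no - o) / (no * o) + (nr - r) / (nr * r)
  if (max(abs(M)) < 1e-6) return(1)
  n <- length(M)
  loL <- floor(n * 0.3) + 1; hiL <- n + 1 - loL
  loS <- floor(n * 0.05) + 1; hiS <- n + 1 - loS
  keep <- rank(M) >= loL & rank(M) <= hiL & rank(A) >= loS & rank(A) <= hiS
  2^(sum(M[keep] / w[keep]) / sum(1 / w[keep]))
}

# Average per-row one-way ANOVA R-squared (direct, no SVD).
anova_r2_oracle <- function(x, fac) {
  fac <- as.factor(fac)
  mean(apply(x, 1, function(y) {
    tss <- sum((y - mean(y))^2)
    if (tss == 0) return(0)
    fitted <- ave(y, fac)
    1 - sum((y - fitted)^2) / tss
  }))
}

# Exact two-sided rank-sum p by full enumeration of in-set rank assignments.
wilcox_enum_oracle <- function(inside, outside) {
  vals <- c(inside, outside)
  stopifnot(!anyDuplicated(vals))
  k <- length(inside)
  rks <- rank(vals)
  obs <- sum(rks[seq_len(k)])
  all_sets <- combn(length(vals), k)
  sums <- colSums(matrix(rank(vals)[all_sets], nrow = k))
  mu <- mean(sums)
  min(1, mean(abs(sums - mu) >= abs(obs - mu) - 1e-9))
}
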