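test_that("TMM factors satisfy their contract and match the formula oracle", {
  withr::with_seed(3, {
    base <- rpois(500, rlnorm(500, 4, 1))
    m <- cbind(s1 = base, s2 = base)
  })
  f <- tmm_factors(counts_from_matrix(m))
  expect_equal(unname(f), c(1, 1))  # identical columns
  # one column doubled, no differential rows: factors compensate the depth
  m2 <- cbind(s1 = base, s2 = 2L * base)
  f2 <- tmm_factors(m2, reference = 1)
  expect_equal(exp(mean(log(f2))), 1, tolerance = 1e-12)
  expect_equal(unname(f2[2] / f2[1]),
               unname(tmm_oracle_one(m2[, 2], m2[, 1])), tolerance = 1e-10)
  # doubling is pure depth, so normalised means agree
  eff <- colSums(m2) * f2
  expect_equal(mean(m2[, 1] / eff[1]), mean(m2[, 2] / eff[2]),
               tolerance = 1e-12)
  # random composition-biased data against the oracle
  withr::with_seed(4, {
    m3 <- cbind(a = rpois(400, rlnorm(400, 3, 1)),
                b = rpois(400, rlnorm(400, 3.5, 1)))
  })
  f3 <- tmm_factors(m3, reference = 1)
  expect_equal(unname(f3[2] / f3[1]), unname(tmm_oracle_one(m3[, 2], m3[, 1])),
               tolerance = 1e-10)
  expect_error(tmm_factors(cbind(a = c(0, 0), b = c(1, 2))), "all-zero")
})

test_that("TMM agrees with the reference implementation in edgeR", {
  withr::with_seed(5, {
    m <- matrix(rpois(3000, rlnorm(3000, 3, 1.2)), ncol = 6,
                dimnames = list(NULL, paste0("s", 1:6)))
  })
  ours <- tmm_factors(m)
  theirs <- edgeR::calcNormFactors(m, method = "TMM")
  expect_equal(unname(ours), unname(theirs), tolerance = 1e-6)
})

test_that("library equalisation is the identity at equal sizes", {
  withr::with_seed(6, m <- matrix(rpois(200, 50), 50, 4,
                                  dimnames = list(NULL, paste0("s", 1:4))))
  eq <- equalize_libraries(m, groups = rep("g", 4),
                           lib_sizes = rep(1000, 4), phi = 0.1)
  expect_equal(eq$pseudo, m, ignore_attr = TRUE, tolerance = 1e-8)
})

test_that("common dispersion is recovered across regimes", {
  sim_nb <- function(phi, seed, G = 2000, n = 4) {
    withr::with_seed(seed, {
      mu <- rlnorm(G, 4, 1)
      m <- sapply(seq_len(2 * n), function(j) {
        if (phi == 0) rpois(G, mu) else {
          rnbinom(G, mu = mu, size = 1 / phi)
        }
      })
      colnames(m) <- paste0("s", seq_len(2 * n))
      m
    })
  }
  grp <- rep(c("a", "b"), each = 4)
  # Poisson data: estimate collapses toward zero
  expect_lte(estimate_common_dispersion(sim_nb(0, 11), grp), 0.01)
  # phi = 0.1 recovered
  phi_hat <- estimate_common_dispersion(sim_nb(0.1, 12), grp)
  expect_gte(phi_hat, 0.07)
  expect_lte(phi_hat, 0.13)
  # constant replicate columns: lower boundary
  m_const <- matrix(rep(c(10, 20, 40, 80), each = 4), 4, 4, byrow = TRUE,
                    dimnames = list(NULL, paste0("s", 1:4)))
  expect_lt(estimate_common_dispersion(m_const, rep(c("a", "b"), each = 2),
                                       lib_sizes = rep(1e4, 4)), 1e-6)
  # no replication anywhere is an explicit failure
  expect_error(estimate_common_dispersion(m_const, letters[1:4]),
               "two biological replicates")
})

test_that("tagwise dispersion shrinks toward the common value", {
  withr::with_seed(21, {
    G <- 500
    mu <- rlnorm(G, 4, 0.5)
    m <- sapply(1:8, function(j) rnbinom(G, mu = mu, size = 10))
    colnames(m) <- paste0("s", 1:8)
    # one mutant with grossly inflated within-group variance
    m[1, ] <- c(10, 400, 80, 900, 15, 380, 70, 1000)
  })
  grp <- rep(c("a", "b"), each = 4)
  lib <- rep(exp(mean(log(colSums(m)))), 8)
  phi_c <- estimate_common_dispersion(m, grp, lib_sizes = lib)
  tw0 <- estimate_tagwise_dispersion(m, grp, phi_c, prior_df = 0,
                                     lib_sizes = lib)
  tw10 <- estimate_tagwise_dispersion(m, grp, phi_c, prior_df = 10,
                                      lib_sizes = lib)
  twInf <- estimate_tagwise_dispersion(m, grp, phi_c, prior_df = 1e9,
                                       lib_sizes = lib)
  # infinite prior pins every mutant to the common value
  expect_equal(twInf, rep(phi_c, G), tolerance = 0.05)
  # the noisy mutant stands out without shrinkage
  expect_gt(tw0[1], phi_c)
  # shrinkage strictly reduces spread
  expect_lt(sd(log10(tw10)), sd(log10(tw0)))
})

test_that("exact test matches enumeration and honours scale sensitivity", {
  # perfectly null configuration
  m <- matrix(c(50, 50, 50, 50), 1,
              dimnames = list("g", paste0("s", 1:4)))
  fit <- nb_fit(m, groups = rep(c("a", "b"), each = 2), dispersion = 0.1,
                lib_sizes = rep(1e4, 4))
  res <- exact_nb_test(fit)
  expect_equal(res$p_value, 1)
  expect_equal(res$logFC, 0)
  # random small instances against the brute-force oracle
  withr::with_seed(31, {
    for (i in 1:80) {
      y1 <- sample(0:120, 1); y2 <- sample(0:(200 - y1), 1)
      n1 <- sample(2:4, 1); n2 <- sample(2:4, 1)
      phi <- sample(c(0, 0.01, 0.1, 0.6), 1)
      expect_equal(exact_nb_pvals(y1, y2, n1, n2, phi),
                   nb_exact_oracle(y1, y2, n1, n2, phi), tolerance = 1e-10)
    }
  })
  # read-depth sensitivity: scaling a fixed split strictly lowers p
  p_small <- exact_nb_pvals(30, 60, 2, 2, 0.05)
  p_big <- exact_nb_pvals(300, 600, 2, 2, 0.05)
  expect_lt(p_big, p_small)
})

test_that("q-values respect the Storey construction", {
  expect_equal(storey_qvalues(rep(1, 10)), rep(1, 10))
  withr::with_seed(41, p <- runif(300)^1.5)
  expect_equal(storey_qvalues(p, pi0 = 1), p.adjust(p, "BH"))
  # monotone in p
  q <- storey_qvalues(p)
  expect_true(all(diff(q[order(p)]) >= -1e-12))
  # pure null: pi0 close to 1
  withr::with_seed(42, pn <- runif(5000))
  expect_gte(estimate_pi0(pn), 0.9)
  expect_lte(estimate_pi0(pn), 1)
  expect_error(storey_qvalues(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("the full fit pipeline controls error and recovers effects", {
  sim <- sim_experiment(n_mutants = 800, depth = 1e5, frac_affected = 0.1,
                        seed = 55, tag_dropout = 0.2)
  coll <- collapse_tags_and_technical(sim$counts, sim$sheet)
  fit <- nb_fit(coll$counts, coll$samples)
  res <- exact_nb_test(fit)
  truth <- sim$pool$effects
  j <- dplyr::inner_join(res, truth, by = "mutant_id")
  # logFC recovery slope near 1 for well-measured mutants
  tot <- rowSums(as_count_matrix(coll$counts))
  big <- j[tot[match(j$mutant_id, coll$counts$mutant_id)] > 1000, ]
  slope <- coef(lm(logFC ~ log2fc, data = big))[2]
  expect_equal(unname(slope), 1, tolerance = 0.1)
  # discoveries are mostly true
  sig <- j$mutant_id[j$q_value <= 0.05]
  if (length(sig) >= 10) {
    expect_lte(mean(j$log2fc[j$mutant_id %in% sig] == 0), 0.2)
  }
  # tidy/glance surfaces
  expect_equal(nrow(tidy(fit)), nrow(coll$counts))
  expect_equal(nrow(glance(fit)), 1)
  expect_s3_class(autoplot(res), "ggplot")
})
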