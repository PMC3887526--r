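test_that("pool simulation honours degenerate fractions and determinism", {
  p0 <- sim_params(n_mutants = 30, frac_affected = 0, seed = 3)
  pool0 <- simulate_pool(p0)
  expect_true(all(pool0$effects$log2fc == 0))
  expect_equal(sum(pool0$effects$baseline), 1)
  # same seed twice: identical catalog and effects
  pool0b <- simulate_pool(p0)
  expect_identical(pool0, pool0b)
  # effects identical with and without catalog generation
  expect_identical(pool0$effects,
                   simulate_pool(p0, with_catalog = FALSE)$effects)
  # catalog separation: every pairwise distance at least 5
  bc <- c(pool0$catalog$uptag, pool0$catalog$dntag)
  prs <- combn(seq_along(bc), 2)
  expect_gte(min(levenshtein(bc[prs[1, ]], bc[prs[2, ]])), 5)
  # impossible packing fails explicitly
  expect_error(generate_separated_barcodes_cpp(300L, 4L, 3L, 5000L),
               "could not place")
})

test_that("per-mutant experiment totals span three log-decades as intended", {
  # abundance-distribution check in isolation: no tag dropout, spread and
  # depth chosen to centre totals at 1e4
  p <- sim_params(n_mutants = 4295, baseline_sdlog = 0.85,
                  tag_dropout_prob = 0, seed = 31)
  pool <- simulate_pool(p, with_catalog = FALSE)
  sheet <- make_sample_sheet(n_bio = 4, n_tech = 2, seed = 32)
  cnt <- simulate_counts(pool$effects, sheet, depth_per_sample = 3.85e6,
                         dispersion = 0.1, seed = 33)
  totals <- rowsum(rowSums(as_count_matrix(cnt)), cnt$mutant_id)
  q <- quantile(totals, c(0.01, 0.99))
  expect_gte(q[[1]], 1e3)
  expect_lte(q[[2]], 1e5)
})

test_that("count simulation has the promised moment structure", {
  eff <- simulate_pool(sim_params(n_mutants = 200, frac_affected = 0,
                                  tag_dropout_prob = 0, seed = 41),
                       with_catalog = FALSE)$effects
  # phi = 0: counts across biological replicates are Poisson
  sheet <- make_sample_sheet(n_bio = 40, n_tech = 1, seed = 42)
  cnt <- simulate_counts(eff, sheet, depth_per_sample = 1e4,
                         dispersion = 0, seed = 43)
  m <- as_count_matrix(cnt)
  ratio <- apply(m, 1, var) / rowMeans(m)
  expect_equal(mean(ratio), 1, tolerance = 0.05)
  # phi = 0.3: clearly overdispersed
  cnt2 <- simulate_counts(eff, sheet, depth_per_sample = 1e4,
                          dispersion = 0.3, seed = 44)
  m2 <- as_count_matrix(cnt2)
  expect_gt(mean(apply(m2, 1, var) / rowMeans(m2)), 2)
  # depth 0: all zeros
  z <- simulate_counts(eff, tiny_sheet(), depth_per_sample = 0, seed = 45)
  expect_true(all(as_count_matrix(z) == 0))
  # column sums track the nominal depth
  big <- simulate_pool(sim_params(n_mutants = 4295, seed = 46),
                       with_catalog = FALSE)$effects
  cb <- simulate_counts(big, tiny_sheet(), depth_per_sample = 1e6,
                        dispersion = 0.1, seed = 47)
  expect_true(all(abs(colSums(as_count_matrix(cb)) - 1e6) / 1e6 < 0.05))
})

test_that("technical variance is smaller than biological variance", {
  eff <- simulate_pool(sim_params(n_mutants = 300, frac_affected = 0,
                                  tag_dropout_prob = 0, seed = 51),
                       with_catalog = FALSE)$effects
  sheet <- make_sample_sheet(treatments = "YPD", n_bio = 6, n_tech = 4,
                             seed = 52)
  cnt <- simulate_counts(eff, sheet, depth_per_sample = 5e4,
                         dispersion = 0.2, seed = 53)
  m <- as_count_matrix(cnt)
  meta <- sheet[match(colnames(m), sheet$sample_id), ]
  # within biological replicate (across tech reps) vs across bio replicates
  tech_var <- sapply(unique(meta$bio_rep), function(b) {
    apply(m[, meta$bio_rep == b, drop = FALSE], 1, var)
  })
  bio_means <- sapply(unique(meta$bio_rep), function(b) {
    rowMeans(m[, meta$bio_rep == b, drop = FALSE])
  })
  expect_lt(mean(tech_var), mean(apply(bio_means, 1, var)))
})

test_that("read simulation emits sum(counts) reads with binomial error load", {
  cat1 <- tibble::tibble(mutant_id = "geneA",
                         uptag = "ACGTACGTACGTACGTACGT",
                         dntag = "TGCATGCATGCATGCATGCA")
  sheet1 <- tiny_sheet()[1, ]
  n_reads <- 4000
  cnt <- tibble::tibble(mutant_id = "geneA", tag = "UPTAG",
                        YPD_1_1 = n_reads)
  # zero counts, zero output
  z <- simulate_reads(dplyr::mutate(cnt, YPD_1_1 = 0), cat1, sheet1)
  expect_equal(nrow(z), 0)
  # substitution load in the barcode region matches the binomial tail
  e <- 0.05
  reads <- simulate_reads(cnt, cat1, sheet1,
                          read_sim_params(per_base_error = e), seed = 61)
  expect_equal(nrow(reads), n_reads)
  bc <- substr(reads$sequence, 21, 40)
  nsub <- vapply(strsplit(bc, ""), function(ch) {
    sum(ch != strsplit(cat1$uptag, "")[[1]])
  }, 0L)
  frac3 <- mean(nsub >= 3)
  expected <- pbinom(2, 20, e, lower.tail = FALSE)
  expect_equal(frac3, expected, tolerance = 4 * sqrt(expected / n_reads) /
                 expected)
  # unknown sample column fails
  expect_error(simulate_reads(dplyr::rename(cnt, bogus = YPD_1_1), cat1,
                              sheet1), "absent from sheet")
})
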