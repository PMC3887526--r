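test_that("levenshtein matches a full DP oracle on random sequences", {
  expect_equal(levenshtein("ACGT", "ACGT"), 0L)
  expect_equal(levenshtein("ACGT", "ACGA"), 1L)
  expect_equal(levenshtein("GTCCACGAGG", "GTCACGAGGT"),
               lv_oracle("GTCCACGAGG", "GTCACGAGGT"))
  withr::with_seed(11, {
    for (i in 1:60) {
      a <- paste(sample(c("A", "C", "G", "T"), sample(3:25, 1),
                        replace = TRUE), collapse = "")
      b <- paste(sample(c("A", "C", "G", "T"), sample(3:25, 1),
                        replace = TRUE), collapse = "")
      expect_equal(levenshtein(a, b), lv_oracle(a, b))
      expect_equal(levenshtein(a, b), levenshtein(b, a))  # symmetry
    }
  })
})

test_that("barcode matching follows the nearest-unique rule", {
  cat <- tiny_catalog()
  # exact hit
  hit <- match_barcode(cat$uptag[2], cat)
  expect_equal(hit$mutant_id, "geneB")
  expect_equal(hit$tag, "UPTAG")
  expect_equal(hit$dist, 0L)
  # beyond the cutoff: 3 substitutions from geneA's uptag, far from others
  far <- "TTGTACGTACGTACGTACGA"
  expect_gte(min(levenshtein(far, c(cat$uptag, cat$dntag))), 3)
  expect_equal(match_barcode(far, cat)$status, "no_hit")
  # a unique strictly nearer candidate wins even with others inside cutoff
  cat2 <- tibble::tibble(mutant_id = c("x", "y"),
                         uptag = c("AAAAAAAAAAAAAAAAAAAA",
                                   "AAAAAAAAAAAAAAAAAACC"),
                         dntag = c("GGGGGGGGGGGGGGGGGGGG",
                                   "CCCCCCCCCCCCCCCCCCCC"))
  q <- "AAAAAAAAAAAAAAAAAAAC"  # dist 1 to x's uptag, dist 1 to y's uptag
  expect_equal(lv_oracle(q, cat2$uptag[1]), 1)
  expect_equal(lv_oracle(q, cat2$uptag[2]), 1)
  expect_equal(match_barcode(q, cat2)$status, "ambiguous")
  q2 <- "AAAAAAAAAAAAAAAAAAAA"  # dist 0 to x, dist 2 to y: x wins
  expect_equal(match_barcode(q2, cat2)$mutant_id, "x")
  # equal-distance tie at distance 2, verified by the oracle, is discarded
  tie <- "AAAAAAAAAAAAAAAAACCC"
  expect_equal(lv_oracle(tie, cat2$uptag[1]), 3)  # not x
  expect_equal(lv_oracle(tie, cat2$uptag[2]), 1)
  expect_equal(match_barcode(tie, cat2)$mutant_id, "y")
})

test_that("index matching uses cutoff 1 and discards deliberate ties", {
  sheet <- tiny_sheet()
  expect_equal(match_index("AAAAA", sheet)$sample_id, "YPD_1_1")
  expect_equal(match_index("AAAAC", sheet)$sample_id, "YPD_1_1")  # 1 sub
  expect_equal(match_index("AACCA", sheet)$status, "no_hit")      # 2 subs
  # a sheet violating the >= 2 separation invariant, built on purpose
  bad <- tibble::tibble(sample_id = c("s1", "s2"),
                        index = c("AAAAA", "AAAAT"),
                        treatment = "x", time = "t24",
                        bio_rep = 1:2, tech_rep = 1)
  q <- "AAAAG"  # distance 1 from both
  expect_equal(lv_oracle(q, "AAAAA"), 1)
  expect_equal(lv_oracle(q, "AAAAT"), 1)
  expect_equal(match_index(q, bad)$status, "ambiguous")
})

test_that("demultiplexing conserves reads and fills all cells", {
  cat <- tiny_catalog(); sheet <- tiny_sheet()
  # zero reads
  z <- demultiplex(tibble::tibble(read_id = character(0),
                                  sequence = character(0)), sheet, cat)
  expect_equal(sum(as_count_matrix(z$counts)), 0)
  expect_equal(z$stats$total, 0L)
  expect_equal(nrow(z$counts), 6)  # 3 mutants x 2 tags
  # a hand-built read set: good reads, an errored read, garbage, short read
  lay <- read_layout()
  mk <- function(index, constant, bc) paste0(index, constant, bc)
  reads <- tibble::tibble(sequence = c(
    mk("AAAAA", lay$up_constant, cat$uptag[1]),          # geneA UPTAG YPD_1_1
    mk("AAAAA", lay$up_constant, cat$uptag[1]),
    mk("GGGGG", lay$dn_constant, cat$dntag[3]),          # geneC DNTAG YPGal_1
    mk("CCCCC", lay$up_constant,
       sub("^AC", "GC", cat$uptag[2])),                  # 1 error, mappable
    mk("AAAAA", lay$up_constant, strrep("N", 20)),       # no hit
    mk("TATAT", lay$up_constant, cat$uptag[1]),          # bad index (>=2 subs)
    mk("AAAAA", strrep("T", 15), cat$uptag[1]),          # bad constant
    "ACGT"))                                             # too short
  reads$read_id <- sprintf("r%d", seq_len(nrow(reads)))
  res <- demultiplex(reads, sheet, cat)
  st <- res$stats
  expect_equal(st$mapped_d2 + st$ambiguous + st$no_hit + st$bad_constant +
                 st$bad_index + st$too_short, st$total)
  expect_equal(st$total, 8L)
  expect_equal(st$mapped_d2, 4L)
  expect_equal(st$too_short, 1L)
  expect_equal(st$bad_index, 1L)
  expect_equal(st$bad_constant, 1L)
  expect_true(st$mapped_d0 <= st$mapped_d1 & st$mapped_d1 <= st$mapped_d2)
  expect_equal(sum(as_count_matrix(res$counts)), st$mapped_d2)
  m <- as_count_matrix(res$counts)
  expect_equal(m["geneA:UPTAG", "YPD_1_1"], 2)
  expect_equal(m["geneC:DNTAG", "YPGal_1_1"], 1)
})

test_that("assignment is independent of read and catalogue order", {
  p <- sim_params(n_mutants = 40, seed = 5, tag_dropout_prob = 0)
  pool <- simulate_pool(p)
  sheet <- make_sample_sheet(n_bio = 2, n_tech = 1, seed = 6)
  cnt <- simulate_counts(pool$effects, sheet, depth_per_sample = 500,
                         dispersion = 0.1, seed = 7)
  reads <- simulate_reads(cnt, pool$catalog, sheet,
                          read_sim_params(per_base_error = 0.05), seed = 8)
  a <- demultiplex(reads, sheet, pool$catalog)
  b <- demultiplex(reads[rev(seq_len(nrow(reads))), ], sheet, pool$catalog)
  cat_rev <- pool$catalog[rev(seq_len(nrow(pool$catalog))), ]
  c3 <- demultiplex(reads, sheet, cat_rev)
  key <- function(x) dplyr::arrange(x$counts, mutant_id, tag)
  expect_equal(as_count_matrix(key(a)), as_count_matrix(key(b)))
  expect_equal(as_count_matrix(key(a)), as_count_matrix(key(c3)))
  expect_equal(a$stats, b$stats)
})

test_that("error-free simulated reads reproduce the source matrix exactly", {
  p <- sim_params(n_mutants = 60, seed = 21, tag_dropout_prob = 0.2)
  pool <- simulate_pool(p)
  sheet <- make_sample_sheet(n_bio = 2, n_tech = 2, seed = 22)
  cnt <- simulate_counts(pool$effects, sheet, depth_per_sample = 3000,
                         dispersion = 0.1, seed = 23)
  reads <- simulate_reads(cnt, pool$catalog, sheet,
                          read_sim_params(per_base_error = 0), seed = 24)
  res <- demultiplex(reads, sheet, pool$catalog)
  m1 <- as_count_matrix(dplyr::arrange(cnt, mutant_id, tag))
  m2 <- as_count_matrix(dplyr::arrange(res$counts, mutant_id, tag))
  expect_identical(m1, m2[, colnames(m1)])
  expect_equal(res$stats$mapped_d0, sum(m1))
})

test_that("FASTQ round trips through files", {
  reads <- tibble::tibble(read_id = c("r1", "r2"),
                          sequence = c("ACGTACGT", "GGGTTTAA"))
  fp <- withr::local_tempfile(fileext = ".fastq")
  write_fastq(reads, fp)
  back <- read_fastq(fp)
  expect_equal(back, reads)
  bad <- withr::local_tempfile(fileext = ".fastq")
  writeLines(c("@r1", "ACGT", "oops"), bad)
  expect_error(read_fastq(bad), "malformed FASTQ")
})
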