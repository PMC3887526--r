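# Shared fixture builders. Everything is generated in code at test time.

tiny_catalog <- function() {
  tibble::tibble(
    mutant_id = c("geneA", "geneB", "geneC"),
    uptag = c("ACGTACGTACGTACGTACGT",
              "TTTTGGGGCCCCAAAATTTT",
              "GACGACGACGACGACGACGA"),
    dntag = c("TGCATGCATGCATGCATGCA",
              "CCCCAAAATTTTGGGGCCCC",
              "AGTCAGTCAGTCAGTCAGTC"))
}

tiny_sheet <- function() {
  tibble::tibble(
    sample_id = c("YPD_1_1", "YPD_2_1", "YPGal_1_1", "YPGal_2_1"),
    index = c("AAAAA", "CCCCC", "GGGGG", "TTTTT"),
    treatment = rep(c("YPD", "YPGal"), each = 2),
    time = "t24",
    bio_rep = c(1, 2, 1, 2),
    tech_rep = 1)
}

# A small simulated experiment, counts only (no barcode sequences).
sim_experiment <- function(n_mutants = 300, n_bio = 4, n_tech = 2,
                           depth = 2e4, dispersion = 0.1,
                           frac_affected = 0.1, effect = 1,
                           tag_dropout = 0, seed = 1) {
  p <- sim_params(n_mutants = n_mutants, frac_affected = frac_affected,
                  effect_sdlog2 = effect, effect_model = "point",
                  dispersion = dispersion, tag_dropout_prob = tag_dropout,
                  seed = seed)
  pool <- simulate_pool(p, with_catalog = FALSE)
  sheet <- make_sample_sheet(n_bio = n_bio, n_tech = n_tech,
                             seed = seed + 1000)
  counts <- simulate_counts(pool$effects, sheet, depth_per_sample = depth,
                            dispersion = dispersion, seed = seed + 2000)
  list(pool = pool, sheet = sheet, counts = counts)
}

# Wide count table from a plain matrix (mutant rows).
counts_from_matrix <- function(m, tags = NULL) {
  stopifnot(!is.null(colnames(m)))
  key <- tibble::tibble(mutant_id = if (is.null(rownames(m))) {
    sprintf("m%03d", seq_len(nrow(m)))
  } else rownames(m))
  if (!is.null(tags)) key$tag <- tags
  dplyr::bind_cols(key, tibble::as_tibble(m))
}

# Log-scale expression-like matrix with exact realised variance shares
# (a, b, 1 - a - b) for treatment, biological culture and technical noise:
# 2 treatments x 3 cultures x n_tech libraries, culture effects centred
# within treatment so they cannot masquerade as treatment signal.
variance_mixture_fixture <- function(a, b, seed, G = 1500, n_tech = 8) {
  trts <- rep(c("A", "B"), each = 3 * n_tech)
  bio <- rep(rep(1:3, each = n_tech), 2)
  cultures <- paste(trts, bio)
  n <- length(trts)
  rowvar_total <- function(z) mean(apply(z, 1, var))
  withr::with_seed(seed, {
    Tm <- outer(rnorm(G), ifelse(trts == "A", -1, 1))
    u <- matrix(rnorm(G * 6), G, 6, dimnames = list(NULL, unique(cultures)))
    u[, 1:3] <- u[, 1:3] - rowMeans(u[, 1:3])
    u[, 4:6] <- u[, 4:6] - rowMeans(u[, 4:6])
    Bm <- u[, cultures]
    Em <- matrix(rnorm(G * n), G, n)
    x <- sqrt(a / rowvar_total(Tm)) * Tm +
         sqrt(b / rowvar_total(Bm)) * Bm +
         sqrt((1 - a - b) / rowvar_total(Em)) * Em
    colnames(x) <- paste(trts, bio, rep(1:n_tech, 6), sep = "_")
  })
  samp <- tibble::tibble(sample_id = colnames(x), index = "AAAAA",
                         treatment = trts, time = "t24", bio_rep = bio,
                         tech_rep = rep(1:n_tech, 6))
  list(x = x, samples = samp)
}
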