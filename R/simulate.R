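#' Simulation parameters for a synthetic Bar-seq pool
#'
#' Bundles the generative settings used by [simulate_pool()]. Defaults emulate
#' the prototrophic yeast deletion collection screen this package targets:
#' 4295 mutants whose per-mutant read totals are approximately log-normal and
#' span roughly three orders of magnitude, biological replicates that are
#' overdispersed relative to Poisson, and a sizeable minority of mutants with
#' one unusable (dropped-out) barcode.
#'
#' @param n_mutants Number of mutants in the pool.
#' @param baseline_meanlog,baseline_sdlog Log-normal parameters of per-mutant
#'   baseline abundance (relative scale; baselines are normalised to sum to 1,
#'   so `baseline_meanlog` only shifts the overall scale). `baseline_sdlog = 1`
#'   gives a 1st-99th percentile span of about two orders of magnitude.
#' @param dispersion Negative-binomial dispersion phi (Var = mu + phi mu^2)
#'   of biological replication; 0 recovers Poisson.
#' @param frac_affected Fraction of mutants with a nonzero true log2
#'   fold change between treatments.
#' @param effect_sdlog2 Standard deviation of true log2 fold changes under
#'   `effect_model = "normal"`, or the fixed |log2FC| under `"point"` (random
#'   sign).
#' @param effect_model `"normal"` or `"point"` effect-size distribution.
#' @param tag_dropout_prob Probability that a mutant's UPTAG or DNTAG is
#'   unusable; a dropped tag keeps a residual relative abundance of
#'   10^-3..10^-2 of its nominal share rather than hard zero.
#' @param seed Integer RNG seed; all simulator draws are reproducible from it.
#' @return A list of class `sim_params`.
#' @export
sim_params <- function(n_mutants = 4295,
                       baseline_meanlog = 0,
                       baseline_sdlog = 1,
                       dispersion = 0.1,
                       frac_affected = 0.1,
                       effect_sdlog2 = 1,
                       effect_model = c("normal", "point"),
                       tag_dropout_prob = 0.25,
                       seed = 1L) {
  effect_model <- match.arg(effect_model)
  stopifnot(n_mutants >= 1, baseline_sdlog >= 0, dispersion >= 0,
            frac_affected >= 0, frac_affected <= 1,
            tag_dropout_prob >= 0, tag_dropout_prob <= 1,
            effect_sdlog2 >= 0)
  structure(list(n_mutants = as.integer(n_mutants),
                 baseline_meanlog = baseline_meanlog,
                 baseline_sdlog = baseline_sdlog,
                 dispersion = dispersion,
                 frac_affected = frac_affected,
                 effect_sdlog2 = effect_sdlog2,
                 effect_model = effect_model,
                 tag_dropout_prob = tag_dropout_prob,
                 seed = as.integer(seed)),
            class = "sim_params")
}

#' Read-simulation parameters
#'
#' @param read_length Total read length; must cover the
#'   index + constant-region + barcode layout (40 bp by default).
#' @param per_base_error Per-base substitution probability.
#' @param index_length,barcode_length Layout constants (5 and 20 bp).
#' @return A list of class `read_sim_params`.
#' @export
read_sim_params <- function(read_length = 40L,
                            per_base_error = 0.01,
                            index_length = 5L,
                            barcode_length = 20L) {
  stopifnot(read_length >= 30, per_base_error >= 0, per_base_error <= 1)
  structure(list(read_length = as.integer(read_length),
                 per_base_error = per_base_error,
                 index_length = as.integer(index_length),
                 barcode_length = as.integer(barcode_length)),
            class = "read_sim_params")
}

#' Fixed read layout of a two-step PCR Bar-seq library
#'
#' Reads are laid out as a 5-bp sample index, a 15-bp constant priming region
#' that distinguishes UPTAG from DNTAG libraries, and the 20-bp molecular
#' barcode. The constant sequences are the tag-specific priming regions of the
#' indexed amplification primers.
#'
#' @return A list with offsets and the two constant-region sequences.
#' @export
read_layout <- function() {
  list(index_start = 1L, index_len = 5L,
       constant_start = 6L, constant_len = 15L,
       barcode_start = 21L, barcode_len = 20L,
       up_constant = "GTCCACGAGGTCTCT",
       dn_constant = "GTGTCGGTCTCGTAG")
}

#' Simulate a barcode catalogue and ground-truth effects
#'
#' Generates `n_mutants` mutants, each with distinct 20-bp UPTAG and DNTAG
#' barcodes placed at pairwise Levenshtein distance >= 5 (so that up to two
#' substitutions can never make two catalogue entries ambiguous), log-normal
#' baseline relative abundances normalised to the simplex, a random
#' `frac_affected` subset with nonzero true log2 fold changes, and
#' per-(mutant, tag) dropout factors.
#'
#' @param params A [sim_params()] object.
#' @param with_catalog Generate barcode sequences (`TRUE`, default). Placing
#'   thousands of barcodes at guaranteed separation is the slow part of pool
#'   simulation; count-level studies that never touch raw reads can set this
#'   to `FALSE` and receive `catalog = NULL`. Effects are drawn before
#'   barcodes, so they are identical for the same seed either way.
#' @return A list with elements `catalog` (tibble: `mutant_id`, `uptag`,
#'   `dntag`) and `effects` (tibble: `mutant_id`, `baseline`, `log2fc`,
#'   `up_factor`, `dn_factor`). Unaffected mutants have `log2fc` exactly 0;
#'   baselines sum to 1.
#' @export
simulate_pool <- function(params = sim_params(), with_catalog = TRUE) {
  stopifnot(inherits(params, "sim_params"))
  n <- params$n_mutants
  withr::with_seed(params$seed, {
    baseline <- rlnorm(n, params$baseline_meanlog, params$baseline_sdlog)
    baseline <- baseline / sum(baseline)
    log2fc <- numeric(n)
    n_aff <- round(params$frac_affected * n)
    if (n_aff > 0) {
      aff <- sample.int(n, n_aff)
      log2fc[aff] <- if (params$effect_model == "normal") {
        rnorm(n_aff, 0, params$effect_sdlog2)
      } else {
        sample(c(-1, 1), n_aff, replace = TRUE) * params$effect_sdlog2
      }
    }
    drop_up <- runif(n) < params$tag_dropout_prob
    drop_dn <- runif(n) < params$tag_dropout_prob
    up_factor <- ifelse(drop_up, 10^-runif(n, 2, 3), 1)
    dn_factor <- ifelse(drop_dn, 10^-runif(n, 2, 3), 1)
    bc <- if (with_catalog) {
      generate_separated_barcodes_cpp(2L * n, 20L, 5L,
                                      max_tries = 200L * n + 10000L)
    }
  })
  ids <- sprintf("mut%05d", seq_len(n))
  list(catalog = if (with_catalog) tibble(mutant_id = ids,
                                          uptag = bc[seq_len(n)],
                                          dntag = bc[n + seq_len(n)]),
       effects = tibble(mutant_id = ids,
                        baseline = baseline,
                        log2fc = log2fc,
                        up_factor = up_factor,
                        dn_factor = dn_factor))
}

#' Build a sample sheet for a treatments x bio-reps x tech-reps design
#'
#' @param treatments Character vector of treatment labels (default the
#'   glucose/galactose pair of the motivating screen).
#' @param n_bio,n_tech Numbers of biological and technical replicates.
#' @param t0_samples Number of additional unselected time-zero samples
#'   (each with `n_tech` technical replicates); 0 for none.
#' @param seed Seed used to draw the 5-bp sample indices (pairwise
#'   Levenshtein distance >= 2).
#' @return A sample-sheet tibble with columns `sample_id`, `index`,
#'   `treatment`, `time`, `bio_rep`, `tech_rep`.
#' @export
make_sample_sheet <- function(treatments = c("YPD", "YPGal"),
                              n_bio = 4L, n_tech = 2L,
                              t0_samples = 0L, seed = 1L) {
  stopifnot(length(treatments) >= 1, n_bio >= 1, n_tech >= 1)
  grid <- tidyr::expand_grid(treatment = treatments,
                             bio_rep = seq_len(n_bio),
                             tech_rep = seq_len(n_tech)) |>
    mutate(time = "t24")
  if (t0_samples > 0) {
    grid <- bind_rows(grid,
                      tidyr::expand_grid(treatment = "t0",
                                         bio_rep = seq_len(t0_samples),
                                         tech_rep = seq_len(n_tech)) |>
                        mutate(time = "t0"))
  }
  n <- nrow(grid)
  idx <- withr::with_seed(seed,
    generate_separated_barcodes_cpp(n, 5L, 2L, max_tries = 2000L * n))
  grid |>
    mutate(sample_id = paste(.data$treatment, .data$bio_rep, .data$tech_rep,
                             sep = "_"),
           index = idx) |>
    select("sample_id", "index", "treatment", "time", "bio_rep", "tech_rep")
}

#' Simulate a (mutant, tag) x sample count matrix
#'
#' For each biological replicate a latent relative-abundance vector is drawn
#' with a gamma perturbation of the expected abundances (mean
#' baseline x 2^(log2fc x treatment indicator), variance phi mu^2), so each
#' technical replicate — an independent Poisson resampling of the shared
#' latent abundance at the library depth — is marginally negative binomial
#' with dispersion `dispersion`, technical variance is strictly smaller than
#' biological variance, and time-zero samples carry no treatment effect.
#'
#' @param effects The `effects` tibble from [simulate_pool()].
#' @param samples A sample sheet from [make_sample_sheet()].
#' @param depth_per_sample Expected sequenced reads per sample library
#'   (both tags combined). The default matches a lane of ~112 million mapped
#'   reads spread over 16 samples.
#' @param dispersion Biological NB dispersion phi >= 0.
#' @param affected_treatment Treatment label carrying the effect; defaults to
#'   the last non-t0 treatment in `samples`.
#' @param seed Optional seed for reproducibility.
#' @return A wide count table with key columns `mutant_id`, `tag` and one
#'   integer column per sample.
#' @export
simulate_counts <- function(effects, samples, depth_per_sample = 7e6,
                            dispersion = 0.1, affected_treatment = NULL,
                            seed = NULL) {
  check_sample_sheet(samples)
  if (depth_per_sample < 0) abort("`depth_per_sample` must be non-negative.")
  if (dispersion < 0) abort("`dispersion` must be >= 0.")
  trts <- setdiff(unique(samples$treatment), "t0")
  if (is.null(affected_treatment)) affected_treatment <- trts[length(trts)]
  n <- nrow(effects)

  draw <- function() {
    # per-(mutant, tag) expected relative weights per condition
    weight_for <- function(is_affected) {
      w <- effects$baseline * 2^(effects$log2fc * is_affected)
      wt <- cbind(UPTAG = w / 2 * effects$up_factor,
                  DNTAG = w / 2 * effects$dn_factor)
      wt / sum(wt)
    }
    bio <- distinct(samples, .data$treatment, .data$bio_rep)
    lam <- vector("list", nrow(bio))
    for (b in seq_len(nrow(bio))) {
      wt <- weight_for(as.integer(bio$treatment[b] == affected_treatment))
      if (dispersion < 1e-12) {
        g <- rep(1, n)
      } else {
        g <- rgamma(n, shape = 1 / dispersion, rate = 1 / dispersion)
      }
      lam[[b]] <- wt * g  # shared biological perturbation across both tags
    }
    names(lam) <- paste(bio$treatment, bio$bio_rep)
    cols <- lapply(seq_len(nrow(samples)), function(j) {
      l <- lam[[paste(samples$treatment[j], samples$bio_rep[j])]]
      rpois(2L * n, depth_per_sample * as.vector(l))
    })
    mat <- do.call(cbind, cols)
    colnames(mat) <- samples$sample_id
    mat
  }
  mat <- if (is.null(seed)) draw() else withr::with_seed(seed, draw())
  bind_cols(tibble(mutant_id = rep(effects$mutant_id, 2L),
                   tag = rep(c("UPTAG", "DNTAG"), each = n)),
            as_tibble(mat))
}

#' Simulate raw reads from a count matrix
#'
#' Emits exactly `sum(counts)` reads. Each read is the sample's 5-bp index,
#' the tag-specific 15-bp constant priming region, and the mutant's 20-bp
#' barcode, with i.i.d. substitution errors at `per_base_error` across the
#' whole read. Qualities are a constant placeholder (the analysis ignores
#' them).
#'
#' @param counts A (mutant, tag) x sample count table.
#' @param catalog Barcode catalogue tibble (`mutant_id`, `uptag`, `dntag`).
#' @param samples Sample sheet covering every count column.
#' @param rp A [read_sim_params()] object.
#' @param seed Optional seed.
#' @return A tibble with columns `read_id` and `sequence`.
#' @export
simulate_reads <- function(counts, catalog, samples, rp = read_sim_params(),
                           seed = NULL) {
  check_count_table(counts)
  check_sample_sheet(samples)
  lay <- read_layout()
  if (rp$read_length < lay$barcode_start + lay$barcode_len - 1L) {
    abort("`read_length` must cover the barcode region (>= 40 bp).")
  }
  samp_cols <- count_sample_cols(counts)
  missing <- setdiff(samp_cols, samples$sample_id)
  if (length(missing) > 0) {
    abort(paste0("samples absent from sheet: ", paste(missing, collapse = ", ")))
  }
  long <- tidyr::pivot_longer(counts, all_of(samp_cols),
                              names_to = "sample_id", values_to = "count") |>
    filter(.data$count > 0) |>
    left_join(samples[, c("sample_id", "index")], by = "sample_id") |>
    left_join(catalog, by = "mutant_id") |>
    mutate(barcode = ifelse(.data$tag == "UPTAG", .data$uptag, .data$dntag),
           constant = ifelse(.data$tag == "UPTAG", lay$up_constant,
                             lay$dn_constant))
  if (any(is.na(long$barcode))) abort("count rows missing from catalog.")
  pad <- strrep("A", rp$read_length - (lay$barcode_start + lay$barcode_len - 1L))
  seqs <- if (nrow(long) == 0) character(0) else {
    rep(paste0(long$index, long$constant, long$barcode, pad),
        as.integer(long$count))
  }
  inject <- function(seqs) {
    if (rp$per_base_error <= 0 || length(seqs) == 0) return(seqs)
    w <- rp$read_length
    n_err <- rbinom(length(seqs), w, rp$per_base_error)
    hit <- which(n_err > 0)
    for (i in hit) {
      ch <- strsplit(seqs[i], "", fixed = TRUE)[[1]]
      pos <- sample.int(w, n_err[i])
      for (p in pos) ch[p] <- sample(setdiff(c("A", "C", "G", "T"), ch[p]), 1)
      seqs[i] <- paste(ch, collapse = "")
    }
    seqs
  }
  seqs <- if (is.null(seed)) inject(seqs) else withr::with_seed(seed, inject(seqs))
  tibble(read_id = if (length(seqs)) sprintf("read%07d", seq_along(seqs))
                   else character(0),
         sequence = seqs)
}
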