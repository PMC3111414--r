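#' Simulation configuration
#'
#' Parameters of the synthetic time-course generator. Defaults mirror the
#' sampling design the pipeline targets: one sample every 4 h over 48 h
#' (13 time points, endpoints inclusive), half the genes cycling, a
#' dawn/dusk-biased phase distribution, and lognormal multiplicative noise.
#'
#' @param n_genes Number of genes.
#' @param frac_cycling Fraction of genes with a planted rhythm.
#' @param phase_density `"uniform"` or `"bimodal_dawn_dusk"` (mixture of two
#'   wrapped normals centred at `bimodal_centers` with sd
#'   `bimodal_sd_h`).
#' @param amplitude_range Length-2 positive vector: range of the
#'   peak-over-trough fold change of planted cyclers.
#' @param noise_sd SD of the additive Gaussian noise on log expression
#'   (i.e. multiplicative lognormal noise).
#' @param sampling_interval_h Hours between samples (default 4).
#' @param segment_length_h Length of one segment in hours (default 48).
#' @param damp_freerun Amplitude multiplier applied when simulating a
#'   free-running (circadian) segment, in `[0, 1]`.
#' @param shape Planted waveform shape (default `"cosine"`).
#' @param bimodal_centers,bimodal_sd_h Centres (h) and sd (h) of the
#'   bimodal phase mixture.
#' @param seed Integer seed.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_genes = 2000, frac_cycling = 0.5,
                       phase_density = c("bimodal_dawn_dusk", "uniform"),
                       amplitude_range = c(2, 8), noise_sd = 0.15,
                       sampling_interval_h = 4, segment_length_h = 48,
                       damp_freerun = 0.5, shape = "cosine",
                       bimodal_centers = c(10, 22), bimodal_sd_h = 2,
                       seed = 1) {
  phase_density <- match.arg(phase_density)
  shape <- match.arg(shape, MODEL_SHAPES)
  if (n_genes <= 0) stop("n_genes must be positive")
  if (frac_cycling < 0 || frac_cycling > 1) stop("frac_cycling in [0,1]")
  if (noise_sd < 0) stop("noise_sd must be non-negative")
  if (any(amplitude_range <= 1)) stop("amplitude fold range must exceed 1")
  if (damp_freerun < 0 || damp_freerun > 1) stop("damp_freerun in [0,1]")
  ratio <- segment_length_h / sampling_interval_h
  if (abs(ratio - round(ratio)) > 1e-9)
    stop("sampling_interval_h must divide segment_length_h")
  structure(list(n_genes = as.integer(n_genes), frac_cycling = frac_cycling,
                 phase_density = phase_density,
                 amplitude_range = amplitude_range, noise_sd = noise_sd,
                 sampling_interval_h = sampling_interval_h,
                 segment_length_h = segment_length_h,
                 damp_freerun = damp_freerun, shape = shape,
                 bimodal_centers = bimodal_centers,
                 bimodal_sd_h = bimodal_sd_h, seed = as.integer(seed)),
            class = "sim_config")
}

# wrapped draw of phases in [0, 24)
.draw_phases <- function(n, config) {
  if (config$phase_density == "uniform") {
    stats::runif(n, 0, 24)
  } else {
    centre <- sample(config$bimodal_centers, n, replace = TRUE)
    (centre + stats::rnorm(n, 0, config$bimodal_sd_h)) %% 24
  }
}

#' Simulate a rhythmic expression time course
#'
#' Generates a genes x time-points matrix with known ground truth. Planted
#' cyclers follow the configured waveform (default: 24-h cosine) at a
#' gene-specific phase; the waveform enters the expression linearly,
#'
#' \deqn{x_g(t) = b_g (1 + a_g w(t; \phi_g)) e^{\epsilon}, \quad
#'       \epsilon \sim N(0, \sigma^2),}
#'
#' where the relative amplitude `a` is set from the drawn peak/trough fold
#' `F` as `a = (F-1)/(F+1)`, so the noiseless series is exactly an affine
#' transform of the waveform. Non-cyclers are lognormal noise around a
#' gene-specific baseline. A free-running segment multiplies `a` by
#' `damp_freerun`, emulating the damped amplitude of clock-driven rhythms
#' once external cycles are removed.
#'
#' @param config A [sim_config()].
#' @param segment `"driven"` or `"freerun"`.
#' @return A list with `matrix` (a [timecourse_matrix()]) and `truth`
#'   (data.frame of class `synthetic_truth`: `gene_id`, `is_cycling`,
#'   `true_phase_h`, `true_shape`, `amplitude_fold`, `baseline`).
#' @export
simulate_timecourse <- function(config, segment = c("driven", "freerun")) {
  stopifnot(inherits(config, "sim_config"))
  segment <- match.arg(segment)
  times_h <- seq(0, config$segment_length_h, by = config$sampling_interval_h)
  n <- config$n_genes
  n_cyc <- round(config$frac_cycling * n)
  withr::with_seed(config$seed, {
    gene_ids <- sprintf("g%04d", seq_len(n))
    is_cyc <- seq_len(n) <= n_cyc
    phases <- rep(NA_real_, n)
    phases[is_cyc] <- .draw_phases(n_cyc, config)
    folds <- rep(NA_real_, n)
    folds[is_cyc] <- stats::runif(n_cyc, config$amplitude_range[1],
                                  config$amplitude_range[2])
    baseline <- exp(stats::rnorm(n, mean = 6, sd = 1))

    a <- (folds - 1) / (folds + 1)
    if (segment == "freerun") a <- a * config$damp_freerun
    vals <- matrix(baseline, nrow = n, ncol = length(times_h))
    if (n_cyc > 0) {
      spike_w <- config$sampling_interval_h
      w <- t(vapply(which(is_cyc), function(i) {
        model_waveform(config$shape, times_h, phases[i],
                       spike_width_h = spike_w)
      }, numeric(length(times_h))))
      vals[is_cyc, ] <- baseline[is_cyc] * (1 + a[is_cyc] * w)
    }
    if (config$noise_sd > 0)
      vals <- vals * exp(matrix(stats::rnorm(length(vals), 0,
                                             config$noise_sd),
                                nrow = n))
    truth <- data.frame(gene_id = gene_ids, is_cycling = is_cyc,
                        true_phase_h = phases,
                        true_shape = ifelse(is_cyc, config$shape,
                                            NA_character_),
                        amplitude_fold = folds, baseline = baseline,
                        stringsAsFactors = FALSE)
    class(truth) <- c("synthetic_truth", "data.frame")
    cond <- if (segment == "driven") "SIM_DRIVEN" else "SIM_FREERUN"
    list(matrix = timecourse_matrix(vals, times_h, gene_ids, cond),
         truth = truth)
  })
}

REVCOMP <- c(A = "T", C = "G", G = "C", T = "A", N = "N")

.revcomp <- function(word) {
  paste(rev(REVCOMP[strsplit(word, "")[[1]]]), collapse = "")
}

#' Simulate promoter sequences with planted phase-specific motifs
#'
#' Gives every gene a random promoter of `promoter_len` bases with the
#' stated GC content. For genes whose true phase bin (`floor(true_phase_h)`)
#' matches a planted motif's bin, the motif word is overwritten at a random
#' position with probability `plant_prob`. Insertions are recorded in the
#' returned truth table.
#'
#' @param truth A `synthetic_truth` data.frame (from [simulate_timecourse()]).
#' @param motifs Data.frame with columns `word` (DNA string, length 3-8) and
#'   `phase_bin` (integer 0-23). May be empty.
#' @param promoter_len Promoter length in bases (default 500).
#' @param plant_prob Probability a matching gene receives the insertion.
#' @param bg_gc Background GC fraction of the random sequence.
#' @param seed Integer seed.
#' @return A list with `promoters` (named character vector, one sequence per
#'   gene) and `planted` (data.frame `gene_id`, `word`, `position`).
#' @export
simulate_promoters <- function(truth, motifs = NULL, promoter_len = 500,
                               plant_prob = 0.8, bg_gc = 0.5, seed = 1) {
  stopifnot(inherits(truth, "data.frame"))
  if (is.null(motifs))
    motifs <- data.frame(word = character(), phase_bin = integer())
  if (nrow(motifs) > 0) {
    wl <- nchar(motifs$word)
    if (any(wl < 3 | wl > 8)) stop("planted motif words must be 3-8 bases")
    if (any(wl > promoter_len)) stop("promoter_len shorter than a motif")
    if (any(grepl("[^ACGT]", motifs$word))) stop("motif words must be ACGT")
  }
  if (bg_gc < 0 || bg_gc > 1) stop("bg_gc in [0,1]")
  n <- nrow(truth)
  withr::with_seed(seed, {
    probs <- c(A = (1 - bg_gc) / 2, C = bg_gc / 2,
               G = bg_gc / 2, T = (1 - bg_gc) / 2)
    seqs <- vapply(seq_len(n), function(i) {
      paste(sample(names(probs), promoter_len, replace = TRUE, prob = probs),
            collapse = "")
    }, character(1))
    names(seqs) <- truth$gene_id
    planted <- data.frame(gene_id = character(), word = character(),
                          position = integer())
    if (nrow(motifs) > 0) {
      bins <- floor(truth$true_phase_h %% 24)
      for (m in seq_len(nrow(motifs))) {
        word <- motifs$word[m]
        hit <- which(!is.na(bins) & bins == motifs$phase_bin[m])
        take <- hit[stats::runif(length(hit)) < plant_prob]
        for (i in take) {
          pos <- sample.int(promoter_len - nchar(word) + 1L, 1L)
          substr(seqs[i], pos, pos + nchar(word) - 1L) <- word
          planted <- rbind(planted,
                           data.frame(gene_id = truth$gene_id[i],
                                      word = word, position = pos))
        }
      }
    }
    list(promoters = seqs, planted = planted)
  })
}

#' Simulate an ortholog trio of species with phase jitter
#'
#' Draws `n_orthologs` ortholog trios. Each trio shares a base phase; each
#' species' true phase adds independent wrapped-normal jitter
#' (`phase_jitter_sd_h`). A fraction `frac_cycling_all` of trios cycle in
#' all three species; the rest are non-cycling noise genes everywhere.
#' Expression matrices are generated per species with the cosine machinery
#' of [simulate_timecourse()].
#'
#' @param n_orthologs Number of trios (may be 0).
#' @param phase_jitter_sd_h SD (h) of the per-species phase jitter.
#' @param frac_cycling_all Fraction of trios cycling in every species.
#' @param seed Integer seed.
#' @param species Labels for the three species.
#' @param config Base [sim_config()] reused for amplitudes/noise per species.
#' @return A list with `matrices` (named list of `timecourse_matrix`),
#'   `truths` (named list of truth tables), and `orthologs` (data.frame of
#'   ID triples, one column per species).
#' @export
simulate_species_trio <- function(n_orthologs = 300, phase_jitter_sd_h = 1,
                                  frac_cycling_all = 0.7, seed = 1,
                                  species = c("spA", "spB", "spC"),
                                  config = sim_config()) {
  if (phase_jitter_sd_h < 0) stop("phase_jitter_sd_h must be >= 0")
  stopifnot(length(species) == 3)
  times_h <- seq(0, config$segment_length_h, by = config$sampling_interval_h)
  n <- as.integer(n_orthologs)
  n_cyc <- round(frac_cycling_all * n)
  withr::with_seed(seed, {
    base_phase <- .draw_phases(n, config)
    is_cyc <- seq_len(n) <= n_cyc
    ortho <- as.data.frame(stats::setNames(
      lapply(species, function(sp) sprintf("%s_%04d", sp, seq_len(n))),
      species))
    out_m <- list(); out_t <- list()
    for (sp in species) {
      phases <- (base_phase + stats::rnorm(n, 0, phase_jitter_sd_h)) %% 24
      phases[!is_cyc] <- NA_real_
      folds <- stats::runif(n, config$amplitude_range[1],
                            config$amplitude_range[2])
      folds[!is_cyc] <- NA_real_
      baseline <- exp(stats::rnorm(n, 6, 1))
      a <- (folds - 1) / (folds + 1)
      vals <- matrix(baseline, nrow = max(n, 1L), ncol = length(times_h))
      if (n == 0) vals <- matrix(numeric(0), 0, length(times_h))
      if (n_cyc > 0) {
        w <- t(vapply(which(is_cyc), function(i) {
          model_waveform(config$shape, times_h, phases[i],
                         spike_width_h = config$sampling_interval_h)
        }, numeric(length(times_h))))
        vals[is_cyc, ] <- baseline[is_cyc] * (1 + a[is_cyc] * w)
      }
      if (config$noise_sd > 0 && n > 0)
        vals <- vals * exp(matrix(stats::rnorm(length(vals), 0,
                                               config$noise_sd),
                                  nrow = n))
      truth <- data.frame(gene_id = ortho[[sp]], is_cycling = is_cyc,
                          true_phase_h = phases,
                          true_shape = ifelse(is_cyc, config$shape,
                                              NA_character_),
                          amplitude_fold = folds, baseline = baseline,
                          stringsAsFactors = FALSE)
      class(truth) <- c("synthetic_truth", "data.frame")
      out_m[[sp]] <- timecourse_matrix(vals, times_h, ortho[[sp]],
                                       paste0("SIM_", sp))
      out_t[[sp]] <- truth
    }
    list(matrices = out_m, truths = out_t, orthologs = ortho)
  })
}

#' Synthetic similarity hit tables for a planted ortholog table
#'
#' Builds 12-column tabular hit files (standard BLAST outfmt-6 column
#' order) in which every planted ortholog pair is each other's top-scoring
#' hit and decoy hits score lower, so reciprocal-best-hit prediction can be
#' exercised without an aligner. Scores are synthetic.
#'
#' @param orthologs Data.frame of ID triples (or pairs), one column per
#'   species, as from [simulate_species_trio()].
#' @param seed Integer seed for decoy generation.
#' @param n_decoys Decoy hits added per query.
#' @return Named list of hit-table data.frames, one per ordered species pair
#'   (`"A_vs_B"` etc.), each in outfmt-6 column order.
#' @export
simulate_hit_tables <- function(orthologs, seed = 1, n_decoys = 2) {
  species <- names(orthologs)
  stopifnot(length(species) >= 2)
  n <- nrow(orthologs)
  withr::with_seed(seed, {
    out <- list()
    for (i in seq_along(species)) for (j in seq_along(species)) {
      if (i == j) next
      q <- orthologs[[species[i]]]; s <- orthologs[[species[j]]]
      top <- stats::runif(n, 200, 500)
      rows <- data.frame(qseqid = q, sseqid = s,
                         pident = stats::runif(n, 70, 100),
                         length = 300L, mismatch = 10L, gapopen = 1L,
                         qstart = 1L, qend = 300L, sstart = 1L, send = 300L,
                         evalue = 10^(-top / 10), bitscore = top)
      if (n_decoys > 0 && n > 1) {
        dq <- rep(q, each = n_decoys)
        ds <- vapply(seq_along(dq), function(k) {
          sample(s[s != s[(k - 1) %/% n_decoys + 1]], 1L)
        }, character(1))
        dscore <- stats::runif(length(dq), 50,
                               rep(top, each = n_decoys) - 10)
        rows <- rbind(rows,
                      data.frame(qseqid = dq, sseqid = ds,
                                 pident = stats::runif(length(dq), 50, 90),
                                 length = 250L, mismatch = 40L, gapopen = 3L,
                                 qstart = 1L, qend = 250L, sstart = 1L,
                                 send = 250L, evalue = 10^(-dscore / 10),
                                 bitscore = dscore))
      }
      out[[paste(species[i], "vs", species[j], sep = "_")]] <- rows
    }
    out
  })
}
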