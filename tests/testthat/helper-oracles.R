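# Independent brute-force oracles. These deliberately avoid the package's
# vectorised code paths: plain loops, stats::cor on single vectors, and
# base string matching only.

# exhaustive scan: best (shape, phase, r) over every pattern in a library.
# Exact ties (to float tolerance; e.g. phase-shifted sawtooths whose
# discontinuity stays between samples are affine shifts of each other)
# resolve by the stated rule: cosine first, then lower phase, then shape.
oracle_best_pattern <- function(values, library, tol = 1e-9) {
  r <- vapply(seq_len(nrow(library$patterns)), function(j) {
    suppressWarnings(stats::cor(values, library$samples[, j]))
  }, numeric(1))
  if (all(is.na(r))) return(list(shape = NA, phase_h = NA, r = NA))
  cand <- which(r >= max(r, na.rm = TRUE) - tol)
  p <- library$patterns[cand, ]
  pick <- cand[order(p$shape != "cosine", p$phase_h, p$shape)[1]]
  list(shape = library$patterns$shape[pick],
       phase_h = library$patterns$phase_h[pick], r = r[pick])
}

oracle_revcomp <- function(word) {
  map <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  paste(rev(map[strsplit(word, "")[[1]]]), collapse = "")
}

# naive substring containment with optional reverse complement
oracle_contains <- function(seqs, word, both_strands = TRUE) {
  hit <- grepl(word, seqs, fixed = TRUE)
  if (both_strands) hit <- hit | grepl(oracle_revcomp(word), seqs,
                                       fixed = TRUE)
  hit
}

# double-argmax reciprocal best hits from a dense score matrix
# rows = species A genes, cols = species B genes
oracle_rbh_from_scores <- function(scores) {
  pairs <- list()
  for (i in seq_len(nrow(scores))) {
    j <- which.max(scores[i, ])
    if (which.max(scores[, j]) == i)
      pairs[[length(pairs) + 1]] <- c(rownames(scores)[i],
                                      colnames(scores)[j])
  }
  if (length(pairs) == 0)
    return(data.frame(id_a = character(), id_b = character()))
  out <- as.data.frame(do.call(rbind, pairs), stringsAsFactors = FALSE)
  names(out) <- c("id_a", "id_b")
  out[order(out$id_a), ]
}

# hit-table pair (both directions) from a dense score matrix
hit_tables_from_scores <- function(scores) {
  long <- expand.grid(q = rownames(scores), s = colnames(scores),
                      stringsAsFactors = FALSE)
  long$score <- scores[cbind(long$q, long$s)]
  mk <- function(q, s, sc) {
    data.frame(qseqid = q, sseqid = s, pident = 90, length = 100,
               mismatch = 5, gapopen = 1, qstart = 1, qend = 100,
               sstart = 1, send = 100, evalue = 10^(-sc / 10),
               bitscore = sc, stringsAsFactors = FALSE)
  }
  list(ab = mk(long$q, long$s, long$score),
       ba = mk(long$s, long$q, long$score))
}

# exhaustive set algebra for 3 sets
oracle_venn3 <- function(a, b, c) {
  list(
    abc = length(intersect(intersect(a, b), c)),
    ab = length(intersect(a, b)),
    ac = length(intersect(a, c)),
    bc = length(intersect(b, c)),
    union = length(union(union(a, b), c)))
}

# seeded mixture fixture shared by rhythm tests
mixture_fixture <- function(n_genes = 200, noise_sd = 0.15, seed = 42,
                            frac_cycling = 0.5) {
  cfg <- sim_config(n_genes = n_genes, frac_cycling = frac_cycling,
                    noise_sd = noise_sd, seed = seed)
  simulate_timecourse(cfg)
}

# truth table + matrix for a phase-18 regulon (genes dispersed over bins
# 17-19) embedded in a uniform-phase population; used by motif tests
regulon_fixture <- function(n_total = 1000, n_regulon = 300, centre_bin = 18,
                            noise_sd = 0.15, seed = 1) {
  cfg <- sim_config(n_genes = n_total, frac_cycling = 1,
                    phase_density = "uniform",
                    amplitude_range = c(4, 4.0001), noise_sd = noise_sd,
                    seed = seed)
  sim <- simulate_timecourse(cfg)
  tr <- sim$truth
  tm <- sim$matrix
  bins <- centre_bin + c(-1, 0, 1)
  set.seed(seed + 7000)
  tr$true_phase_h[seq_len(n_regulon)] <-
    rep(bins, each = ceiling(n_regulon / 3))[seq_len(n_regulon)] +
    runif(n_regulon)
  for (i in seq_len(n_regulon)) {
    a <- (tr$amplitude_fold[i] - 1) / (tr$amplitude_fold[i] + 1)
    w <- cos(2 * pi * (tm$times_h - tr$true_phase_h[i]) / 24)
    tm$values[i, ] <- tr$baseline[i] * (1 + a * w) *
      exp(rnorm(length(tm$times_h), 0, noise_sd))
  }
  list(matrix = tm, truth = tr, regulon_bins = bins)
}
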