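# calls table with given phases, all cycling
calls_at <- function(gene_ids, phases) {
  df <- data.frame(gene_id = gene_ids, condition = "c", shape = "cosine",
                   phase_h = phases, r = 0.9, p = NA_real_, fdr = NA_real_,
                   is_cycling = TRUE)
  class(df) <- c("cycling_calls", "data.frame")
  df
}

test_that("word Z-score matches its closed form and degenerate rules", {
  # n=100 foreground all containing the word, background rate 0.1:
  # Z = (100 - 10) / sqrt(100 * 0.1 * 0.9) = 30
  set.seed(2)
  bg_ids <- sprintf("g%04d", 1:1000)
  seqs <- vapply(bg_ids, function(i) {
    paste(sample(c("A", "T"), 40, TRUE), collapse = "")
  }, character(1))
  word <- "CGCGCGC"  # absent from A/T background
  fg <- bg_ids[1:100]
  seqs[fg] <- paste0(substr(seqs[fg], 1, 33), word)
  # plant in exactly 90 background-only genes => phat = (100+90)/1000
  seqs[bg_ids[101:190]] <- paste0(substr(seqs[bg_ids[101:190]], 1, 33), word)
  ps <- promoter_set(seqs)
  k <- 100; n <- 100; phat <- 190 / 1000
  want <- (k - n * phat) / sqrt(n * phat * (1 - phat))
  expect_equal(word_zscore(word, fg, bg_ids, ps), want)
  # degenerate background rates give Z = 0
  expect_equal(word_zscore("CCCCCCCC", fg, bg_ids, ps), 0)  # phat = 0
  ps1 <- promoter_set(c(a = "TTACGTTT", b = "AACGTAAA", c = "CACGTCCC"))
  expect_equal(word_zscore("ACGT", c("a", "b"), c("a", "b", "c"), ps1),
               0)                                           # phat = 1
  expect_error(word_zscore(word, fg, character(0), ps), "background")
  expect_error(word_zscore(word, c(fg, "zzz"), bg_ids, ps), "subset")
})

test_that("null foreground draws give |Z| <= 3 in >= 99% of draws", {
  set.seed(31)
  bg_ids <- sprintf("g%04d", 1:600)
  seqs <- vapply(bg_ids, function(i) {
    paste(sample(c("A", "C", "G", "T"), 300, TRUE), collapse = "")
  }, character(1))
  ps <- promoter_set(seqs)
  word <- "ACGTA"
  hit <- contains_word(ps, word)
  phat <- mean(hit)
  expect_gt(phat, 0.2)  # common enough for the normal approximation
  expect_lt(phat, 0.8)
  z <- vapply(1:1000, function(i) {
    fg <- sample(bg_ids, 50)
    (sum(hit[fg]) - 50 * phat) / sqrt(50 * phat * (1 - phat))
  }, numeric(1))
  expect_gte(mean(abs(z) <= 3), 0.99)
  # and the package's zscore against a fixed random foreground agrees
  set.seed(32)
  fg <- sample(bg_ids, 50)
  expect_equal(word_zscore(word, fg, bg_ids, ps),
               (sum(hit[fg]) - 50 * phat) / sqrt(50 * phat * (1 - phat)))
})

test_that("profiles have 24 bins and planted motifs peak at their bin", {
  sim <- simulate_timecourse(sim_config(n_genes = 600, frac_cycling = 1,
                                        phase_density = "uniform",
                                        noise_sd = 0, seed = 41))
  tr <- sim$truth
  prom <- simulate_promoters(tr, data.frame(word = "ATGGGCC",
                                            phase_bin = 18L),
                             plant_prob = 0.8, seed = 42)
  ps <- promoter_set(prom$promoters, 500)
  calls <- calls_at(tr$gene_id, floor(tr$true_phase_h))
  prof <- zscore_profile("ATGGGCC", calls, ps)
  expect_length(prof$z, 24)
  expect_equal(unname(which.max(prof$z)) - 1L, 18L)
  # no cycling genes at all -> flat zero profile
  none <- calls; none$is_cycling <- FALSE
  prof0 <- zscore_profile("ATGGGCC", none, ps)
  expect_equal(unname(prof0$z), rep(0, 24))
  expect_false(prof0$significant)
})

test_that("consecutive-bin rule honours threshold, runs and wraparound", {
  z <- rep(0, 24)
  z[6:8] <- 2.33  # exactly at threshold, three consecutive
  expect_true(significant_profile(z))
  z2 <- rep(0, 24); z2[c(6, 8)] <- 5  # gap breaks the run
  expect_false(significant_profile(z2))
  z3 <- rep(0, 24); z3[c(24, 1, 2)] <- 3  # bins 23, 0, 1 wrap
  expect_true(significant_profile(z3))
  expect_false(significant_profile(z3, circular = FALSE))
  z4 <- rep(0, 24); z4[6:8] <- 2.32  # just below threshold
  expect_false(significant_profile(z4))
  expect_true(significant_profile(rep(3, 24)))
  expect_error(significant_profile(z, run_length = 25), "24")
})

test_that("profile phase matches planted bins and rejects flat profiles", {
  z <- cos(2 * pi * (0:23 - 8) / 24)
  expect_equal(profile_phase(z), 8)
  expect_error(profile_phase(rep(1.5, 24)), "constant")
  prof <- structure(list(word = "AAA", z = rep(0, 24), significant = FALSE),
                    class = "zprofile")
  expect_error(profile_phase(prof), "non-significant")
})

test_that("word and reverse complement give identical profiles", {
  sim <- simulate_timecourse(sim_config(n_genes = 300, frac_cycling = 1,
                                        phase_density = "uniform",
                                        noise_sd = 0, seed = 51))
  tr <- sim$truth
  prom <- simulate_promoters(tr, data.frame(word = "GATCGA", phase_bin = 6L),
                             plant_prob = 0.9, seed = 52)
  ps <- promoter_set(prom$promoters, 500)
  calls <- calls_at(tr$gene_id, floor(tr$true_phase_h))
  p1 <- zscore_profile("GATCGA", calls, ps)
  p2 <- zscore_profile("TCGATC", calls, ps)  # reverse complement
  expect_equal(p1$z, p2$z, ignore_attr = TRUE)
})

test_that("scan_all_words finds the planted word among significant hits", {
  fix <- regulon_fixture(n_total = 700, n_regulon = 240, seed = 61)
  lib <- build_model_library(fix$matrix$times_h)
  calls <- call_cycling(fix$matrix, lib)
  prom <- simulate_promoters(fix$truth,
                             data.frame(word = "ATGGGCC",
                                        phase_bin = fix$regulon_bins),
                             plant_prob = 0.8, seed = 62)
  ps <- promoter_set(prom$promoters, 500)
  scan <- scan_all_words(calls, ps, k_min = 7, k_max = 7)
  hit <- scan[scan$word == "ATGGGCC", ]
  expect_true(hit$significant)
  expect_lte(circular_phase_distance(hit$peak_phase_h, 18), 2)
  # the planted word's profile from the scan equals the per-word route
  z_scan <- attr(scan, "z")["ATGGGCC", ]
  z_single <- zscore_profile("ATGGGCC", calls, ps)$z
  expect_equal(unname(z_scan), unname(z_single))
})

test_that("scan respects alphabet bounds and empty inputs", {
  set.seed(71)
  seqs <- vapply(1:50, function(i) {
    paste(sample(c("A", "C", "G", "T"), 60, TRUE), collapse = "")
  }, character(1))
  names(seqs) <- sprintf("s%02d", 1:50)
  ps <- promoter_set(seqs)
  calls <- calls_at(names(seqs), sample(0:23, 50, TRUE))
  scan <- scan_all_words(calls, ps, k_min = 3, k_max = 3)
  expect_lte(nrow(scan), 64)
  expect_true(all(nchar(scan$word) == 3))
  empty <- promoter_set(character(0))
  expect_equal(nrow(scan_all_words(calls, empty, 3, 3)), 0)
  expect_error(scan_all_words(calls, ps, 5, 3), "k_min")
  expect_error(scan_all_words(calls, ps, 0, 3), "guard")
})

test_that("scan null calibration: no planting keeps tail near nominal", {
  set.seed(81)
  n <- 960  # ~40 cycling genes per 1-h bin
  seqs <- vapply(1:n, function(i) {
    paste(sample(c("A", "C", "G", "T"), 500, TRUE), collapse = "")
  }, character(1))
  names(seqs) <- sprintf("g%03d", 1:n)
  ps <- promoter_set(seqs)
  calls <- calls_at(names(seqs), runif(n, 0, 24))
  scan <- scan_all_words(calls, ps, k_min = 5, k_max = 5,
                         both_strands = FALSE)
  z <- attr(scan, "z")
  phat <- vapply(rownames(z), function(w) {
    mean(contains_word(ps, w, both_strands = FALSE))
  }, numeric(1))
  zz <- z[phat >= 0.2 & phat <= 0.8, ]
  expect_gt(nrow(zz), 100)
  tail_frac <- mean(zz >= 2.33)
  nominal <- pnorm(2.33, lower.tail = FALSE)  # ~0.0099
  # slack: Monte-Carlo error plus binomial discreteness of ~40-gene bins
  expect_lt(abs(tail_frac - nominal), 0.01)
})

test_that("conserved elements require significance and phase agreement", {
  mk_tab <- function(words, sig, phase) {
    data.frame(word = words, k = nchar(words), max_z = 5,
               max_z_bin = phase, significant = sig, peak_phase_h = phase)
  }
  a <- mk_tab(c("ATGGGCC", "GATAAG", "CCCTTT"), c(TRUE, TRUE, FALSE),
              c(18, 6, 3))
  b <- mk_tab(c("ATGGGCC", "GATAAG"), c(TRUE, TRUE), c(17, 18))
  out <- conserved_elements(list(spA = a, spB = b), window_h = 3)
  expect_true(out$conserved[out$word == "ATGGGCC"])   # phases 18 vs 17
  expect_false(out$conserved[out$word == "GATAAG"])   # phases 6 vs 18
  expect_false("CCCTTT" %in% out$word)                # not significant in A
  expect_error(conserved_elements(list(spA = a)), "2 species")
})
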