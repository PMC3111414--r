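toy_hits <- function(q, s, score) {
  data.frame(qseqid = q, sseqid = s, pident = 90, length = 100,
             mismatch = 5, gapopen = 1, qstart = 1, qend = 100,
             sstart = 1, send = 100, evalue = 10^(-score / 10),
             bitscore = score, stringsAsFactors = FALSE)
}

test_that("reciprocal best hits follow the mutual-best rule", {
  ab <- toy_hits(c("a1", "a1", "a2"), c("b1", "b2", "b1"), c(100, 80, 60))
  ba <- toy_hits(c("b1", "b2"), c("a1", "a1"), c(90, 50))
  got <- reciprocal_best_hits(ab, ba)
  expect_equal(got, data.frame(id_a = "a1", id_b = "b1"))
  # a1's best is b1 but b1's best is a2 -> no pair for a1 (a2-b1 remain
  # mutual best)
  ba2 <- toy_hits(c("b1", "b1"), c("a1", "a2"), c(70, 95))
  got2 <- reciprocal_best_hits(ab, ba2)
  expect_false("a1" %in% got2$id_a)
  expect_equal(got2$id_a, "a2")
  expect_equal(nrow(reciprocal_best_hits(ab[0, ], ba)), 0)
})

test_that("multiple HSPs collapse to the max-score row before ranking", {
  ab <- toy_hits(c("a1", "a1", "a1"), c("b1", "b1", "b2"), c(40, 95, 90))
  ba <- toy_hits(c("b1", "b2"), c("a1", "a1"), c(80, 70))
  got <- reciprocal_best_hits(ab, ba)
  expect_equal(got$id_b, "b1")  # b1's best HSP (95) beats b2 (90)
})

test_that("RBH pairs equal brute-force double argmax on random scores", {
  set.seed(17)
  scores <- matrix(runif(50 * 50, 10, 100), 50, 50,
                   dimnames = list(sprintf("a%02d", 1:50),
                                   sprintf("b%02d", 1:50)))
  ht <- hit_tables_from_scores(scores)
  got <- reciprocal_best_hits(ht$ab, ht$ba)
  want <- oracle_rbh_from_scores(scores)
  expect_equal(got$id_a, want$id_a)
  expect_equal(got$id_b, want$id_b)
  # symmetry: swapping directions transposes the pairing
  rev <- reciprocal_best_hits(ht$ba, ht$ab)
  expect_setequal(paste(rev$id_b, rev$id_a), paste(got$id_a, got$id_b))
  # each gene appears at most once
  expect_false(anyDuplicated(got$id_a) > 0)
  expect_false(anyDuplicated(got$id_b) > 0)
})

test_that("three-way orthologs require all three mutual relations", {
  ab <- data.frame(id_a = "a1", id_b = "b1")
  ac <- data.frame(id_a = "a1", id_b = "c1")
  bc_good <- data.frame(id_a = "b1", id_b = "c1")
  bc_bad <- data.frame(id_a = "b1", id_b = "c2")
  expect_equal(nrow(three_way_orthologs(ab, ac, bc_good)), 1)
  expect_equal(nrow(three_way_orthologs(ab, ac, bc_bad)), 0)
})

test_that("planted ortholog trios are recovered exactly from hit tables", {
  trio <- simulate_species_trio(n_orthologs = 40, phase_jitter_sd_h = 1,
                                seed = 19)
  hits <- simulate_hit_tables(trio$orthologs, seed = 20)
  ab <- reciprocal_best_hits(hits$spA_vs_spB, hits$spB_vs_spA)
  ac <- reciprocal_best_hits(hits$spA_vs_spC, hits$spC_vs_spA)
  bc <- reciprocal_best_hits(hits$spB_vs_spC, hits$spC_vs_spB)
  triples <- three_way_orthologs(ab, ac, bc)
  expect_equal(nrow(triples), 40)
  ord <- order(triples$id_a)
  expect_equal(triples$id_a[ord], sort(trio$orthologs$spA))
  planted <- trio$orthologs[order(trio$orthologs$spA), ]
  expect_equal(triples$id_b[ord], planted$spB)
  expect_equal(triples$id_c[ord], planted$spC)
})

test_that("circular phase distance is symmetric, bounded and triangular", {
  expect_equal(circular_phase_distance(1, 23), 2)
  expect_equal(circular_phase_distance(0, 12), 12)
  expect_equal(circular_phase_distance(7.5, 7.5), 0)
  expect_error(circular_phase_distance(25, 1), "24")
  grid <- 0:23
  for (a in grid) for (b in grid) {
    expect_equal(circular_phase_distance(a, b),
                 circular_phase_distance(b, a))
    expect_lte(circular_phase_distance(a, b), 12)
    for (cc in c(5, 17)) {
      expect_lte(circular_phase_distance(a, b),
                 circular_phase_distance(a, cc) +
                   circular_phase_distance(cc, b) + 1e-12)
    }
  }
})

calls_for_truth <- function(truth) {
  df <- data.frame(gene_id = truth$gene_id, condition = "c",
                   shape = "cosine", phase_h = truth$true_phase_h %% 24,
                   r = ifelse(truth$is_cycling, 0.95, 0.1),
                   p = NA_real_, fdr = NA_real_,
                   is_cycling = truth$is_cycling)
  class(df) <- c("cycling_calls", "data.frame")
  df
}

test_that("zero-jitter trios are fully concordant with diagonal mass", {
  trio <- simulate_species_trio(n_orthologs = 60, phase_jitter_sd_h = 0,
                                frac_cycling_all = 1, seed = 23)
  calls <- lapply(trio$truths, calls_for_truth)
  pc <- phase_concordance(trio$orthologs, calls, window_h = 3)
  expect_equal(pc$n_cycling_all, 60)
  expect_equal(pc$frac_within_window, 1)
  m <- pc$matrices[[1]]
  expect_equal(sum(m), 60)
  expect_equal(sum(diag(m)), 60)
  # window 12 always captures everything
  expect_equal(phase_concordance(trio$orthologs, calls,
                                 window_h = 12)$frac_within_window, 1)
})

test_that("uniform 1-h-grid phases hit the exact pairwise null 7/24", {
  # exact: |d| <= 3 on the 24-point circle covers 7 of 24 offsets
  set.seed(29)
  n <- 10000
  ids <- sprintf("o%05d", 1:n)
  pairs <- data.frame(s1 = paste0(ids, "x"), s2 = paste0(ids, "y"))
  mk <- function(g) {
    df <- data.frame(gene_id = g, condition = "c", shape = "cosine",
                     phase_h = sample(0:23, n, TRUE), r = 0.9,
                     p = NA_real_, fdr = NA_real_, is_cycling = TRUE)
    class(df) <- c("cycling_calls", "data.frame")
    df
  }
  calls <- list(s1 = mk(pairs$s1), s2 = mk(pairs$s2))
  pc <- phase_concordance(pairs, calls, window_h = 3)
  p0 <- 7 / 24
  se <- sqrt(p0 * (1 - p0) / n)
  expect_lt(abs(pc$frac_within_window - p0), 4 * se)
  expect_equal(sum(pc$matrices[[1]]), n)
})

test_that("concordance decreases monotonically with phase jitter", {
  fracs <- vapply(c(0, 1, 2, 4, 8), function(sd_h) {
    trio <- simulate_species_trio(n_orthologs = 400,
                                  phase_jitter_sd_h = sd_h,
                                  frac_cycling_all = 1, seed = 37)
    calls <- lapply(trio$truths, calls_for_truth)
    phase_concordance(trio$orthologs, calls)$frac_within_window
  }, numeric(1))
  expect_true(all(diff(fracs) < 0))
  expect_equal(fracs[1], 1)
})

test_that("non-cycling orthologs are excluded; empty case flagged", {
  trio <- simulate_species_trio(n_orthologs = 40, phase_jitter_sd_h = 1,
                                frac_cycling_all = 0.5, seed = 41)
  calls <- lapply(trio$truths, calls_for_truth)
  pc <- phase_concordance(trio$orthologs, calls)
  expect_equal(pc$n_cycling_all, 20)
  none <- lapply(calls, function(x) { x$is_cycling <- FALSE; x })
  pc0 <- phase_concordance(trio$orthologs, none)
  expect_equal(pc0$n_cycling_all, 0)
  expect_true(is.na(pc0$frac_within_window))
  expect_equal(sum(pc0$matrices[[1]]), 0)
})

test_that("hypergeometric set enrichment matches exact oracles", {
  universe <- sprintf("g%03d", 1:200)
  fam <- data.frame(gene_id = universe,
                    family = rep(c("X", "Y", "Z", "none"), c(10, 40, 20, 130)))
  # member set = all 10 family-X genes plus 10 others
  members <- c(universe[1:10], universe[51:60])
  out <- set_enrichment(members, universe, fam)
  want_x <- phyper(10 - 1, 10, 190, 20, lower.tail = FALSE)
  expect_equal(out$p[out$family == "X"], want_x)
  expect_lt(out$p[out$family == "X"], 1e-6)
  # family fully outside the member set, small draw -> p near 1
  out1 <- set_enrichment(universe[11], universe, fam)
  expect_equal(out1$p[out1$family == "X"], 1)  # zero family members drawn
  expect_equal(out1$p[out1$family == "Z"],
               phyper(-1, 20, 180, 1, lower.tail = FALSE))
  # BH adjustment comes from stats::p.adjust
  expect_equal(out$p_adj, p.adjust(out$p, "BH"))
  expect_error(set_enrichment("not_in_universe", universe, fam), "subset")
})

test_that("random member draws give roughly uniform enrichment p-values", {
  universe <- sprintf("g%03d", 1:200)
  fam <- data.frame(gene_id = universe, family = rep("F", 200)[1:200])
  fam$family[1:50] <- "X"
  set.seed(43)
  ps <- vapply(1:400, function(i) {
    m <- sample(universe, 40)
    out <- set_enrichment(m, universe, fam)
    out$p[out$family == "X"]
  }, numeric(1))
  # discrete p-values are super-uniform; check both tails loosely
  expect_gt(mean(ps > 0.5), 0.35)
  expect_lt(mean(ps < 0.05), 0.08)
})

test_that("hit tables round-trip through the tabular reader", {
  dir <- withr::local_tempdir()
  tab <- toy_hits(c("a1", "a2"), c("b1", "b2"), c(100, 90))
  path <- file.path(dir, "hits.tsv")
  write.table(tab, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  got <- read_hit_table(path)
  expect_equal(got$qseqid, tab$qseqid)
  expect_equal(got$bitscore, tab$bitscore)
})
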