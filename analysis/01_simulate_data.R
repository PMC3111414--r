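#!/usr/bin/env Rscript
# Stage 1: generate the synthetic study data with planted ground truth.
#
# Emulates the sampling design of a multi-condition diurnal/circadian
# time-course experiment: three driven (diurnal) conditions and one
# free-running (circadian) segment, each sampled every 4 h over 48 h
# (13 time points); promoter sets with phase-specifically planted motifs;
# and a three-species ortholog trio with 1-h phase jitter.

suppressMessages(library(dielscan))

out <- "results/data"
dir.create(out, showWarnings = FALSE, recursive = TRUE)
seed <- 20260925L

## Three diurnal conditions over a shared gene universe. The generator
## plants cyclers as the first half of the universe, so the same genes
## cycle under every condition (with independent phases/noise) -- a strong
## cross-condition overlap, as real diurnal conditions show. The first
## condition also gets a free-running segment with damped amplitude.
conditions <- c(LDHH = 1L, LDHC = 2L, LLHC = 3L)
for (cond in names(conditions)) {
  cfg <- sim_config(n_genes = 2000, frac_cycling = 0.5,
                    phase_density = "bimodal_dawn_dusk",
                    noise_sd = 0.15, damp_freerun = 0.4,
                    seed = seed + conditions[[cond]])
  sim <- simulate_timecourse(cfg, segment = "driven")
  sim$matrix$condition <- cond
  write_timecourse(sim$matrix, file.path(out, paste0(cond, ".tsv")),
                   seed = cfg$seed, config = cfg)
  write.table(sim$truth, file.path(out, paste0("truth_", cond, ".tsv")),
              sep = "\t", quote = FALSE, row.names = FALSE)
  if (cond == "LDHH") {
    fr <- simulate_timecourse(cfg, segment = "freerun")
    fr$matrix$condition <- "LL_LDHH"
    write_timecourse(fr$matrix, file.path(out, "LL_LDHH.tsv"),
                     seed = cfg$seed, config = cfg)
  }
  message(cond, ": ", sum(sim$truth$is_cycling), " / 2000 genes planted cycling")
}

## Promoters for the LDHH universe: a PBX-like midnight element planted in
## a phase-18 regulon (bins 17-19) and a GATA-like morning element in a
## phase-6 regulon (bins 5-7).
cfg <- sim_config(n_genes = 2000, frac_cycling = 0.5,
                  phase_density = "bimodal_dawn_dusk", noise_sd = 0.15,
                  seed = seed + 1L)
sim <- simulate_timecourse(cfg)
motifs <- data.frame(word = c(rep("ATGGGCC", 3), rep("GGATAA", 3)),
                     phase_bin = c(17:19, 5:7))
prom <- simulate_promoters(sim$truth, motifs, promoter_len = 500,
                           plant_prob = 0.8, seed = seed + 10L)
write_promoters_fasta(promoter_set(prom$promoters, 500),
                      file.path(out, "promoters_LDHH.fa"))
write.table(prom$planted, file.path(out, "planted_motifs.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
message("promoters: ", length(prom$promoters), " x 500 bp; ",
        nrow(prom$planted), " motif insertions")

## Three-species ortholog trio (500 trios, 80% cycling everywhere, 1-h
## wrapped-normal phase jitter) with BLAST-like hit tables.
trio <- simulate_species_trio(n_orthologs = 500, phase_jitter_sd_h = 1,
                              frac_cycling_all = 0.8, seed = seed + 20L,
                              config = sim_config(noise_sd = 0.1))
for (sp in names(trio$matrices)) {
  write_timecourse(trio$matrices[[sp]],
                   file.path(out, paste0("trio_", sp, ".tsv")),
                   seed = seed + 20L)
  write.table(trio$truths[[sp]],
              file.path(out, paste0("trio_truth_", sp, ".tsv")),
              sep = "\t", quote = FALSE, row.names = FALSE)
}
write.table(trio$orthologs, file.path(out, "trio_orthologs.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
hits <- simulate_hit_tables(trio$orthologs, seed = seed + 21L)
for (nm in names(hits)) {
  write.table(hits[[nm]], file.path(out, paste0("hits_", nm, ".tsv")),
              sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
}
message("trio: 500 ortholog triples across ", length(trio$matrices),
        " species; hit tables written")
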