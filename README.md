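# dielscan

Model-based analysis of diurnal and circadian transcriptomes: rhythm
detection with phase calling and permutation FDR, phase-specific promoter
element discovery, and cross-species ortholog phase concordance — with a
synthetic-data generator that plants known rhythms, motifs and ortholog
trios so every stage can be validated against ground truth.

It is written for transcriptome time courses of the classic diurnal design:
samples every 4 h over 48 h (13 time points per segment), under driven
(photocycle/thermocycle) and free-running (constant) conditions.

## What it computes

**Rhythm detection.** Every gene's expression series is correlated against
a library of phased model waveforms — five shapes (cosine, box, spike, two
asymmetric sawtooths) × 24 integer phases, 24-h period. The best pattern
gives the gene its model and phase of peak expression (hours after dawn);
genes with Pearson *r* ≥ 0.75 are called cycling. Correlation is
amplitude- and offset-invariant. A permutation null (each gene's time
points shuffled independently) yields the FDR at the cutoff and per-gene
empirical p-values; both the conventional raw estimate and a
π₀-calibrated estimate are reported.

**Promoter elements.** For each DNA word of length 3–8 in the 500-bp
upstream promoters, a 24-bin enrichment profile is computed: per phase bin,

    Z = (k − n·p̂) / sqrt(n·p̂·(1 − p̂))

where *n* is the number of cycling genes called at that phase, *k* how many
of their promoters contain the word (either strand), and *p̂* the
containment fraction among all promoters. Words with ≥ 3 consecutive bins
at Z ≥ 2.33 (one-sided p = 0.01) are significant; a significant profile's
phase comes from matching it against 24-point cosines, and elements whose
profiles are significant in every species with phases within 3 h are called
conserved.

**Orthologs.** Reciprocal best hits from pairwise tabular similarity files
(BLAST outfmt-6 column order), three-way mutual orthologs, 24×24
phase-combination matrices, and the fraction of ortholog groups phased
within 3 h of each other on the 24-h circle (uniform-null reference:
7/24 ≈ 0.29 for a pair). Gene-family enrichment is hypergeometric with BH
adjustment.

## Worked example

```r
library(dielscan)

# 2,000 genes, half cycling with dawn/dusk-biased phases, lognormal noise
cfg <- sim_config(n_genes = 2000, frac_cycling = 0.5, seed = 101)
sim <- simulate_timecourse(cfg)

rep1 <- run_condition(run_config(sim$matrix, condition = "LDHH",
                                 n_perm = 10, seed = 101))
#> [LDHH] 2000 genes on 13 time points; 120 model patterns
#> [LDHH] 1044 cycling at r >= 0.75 (52.2%); permutation FDR 0.0872

rep1$phase_histogram   # counts per 1-h phase bin, summing to 1044
```

The report says 1,044 of 2,000 genes pass *r* ≥ 0.75 — the 1,000 planted
cyclers plus ~4% false discoveries, matching the raw permutation FDR
estimate of ~8.7% (which counts null passers over all genes and is
therefore conservative by ~2× when half the genes truly cycle; the
calibrated estimate `fdr_at_cutoff_pi0` from `permutation_fdr()` lands at
~4.3%). The phase histogram is bimodal with modes a few hours before dawn
and dusk, as planted.

The full four-stage analysis lives in `analysis/`:

```sh
Rscript analysis/01_simulate_data.R       # fixtures with planted truth
Rscript analysis/02_rhythm_detection.R    # cycling calls per condition
Rscript analysis/03_promoter_elements.R   # word Z-profiles, conserved elements
Rscript analysis/04_ortholog_concordance.R # RBH, triples, concordance
```

Each script states what it found and writes its tables under `results/`.
Representative output from a full run:

```
 condition n_genes n_cycling cycling_pct perm_fdr_pct
      LDHH    2000      1045        52.2         8.41
   LL_LDHH    2000       810        40.5        10.88   # damped free-run
ATGGGCC: max Z = 15.2 at bin 19; significant = TRUE; profile phase = 19 h
500 three-way mutual orthologs; 100% of planted trios recovered
phase_concordance: 400 ortholog groups cycling in all species; 93% within 3 h
```

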