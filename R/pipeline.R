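#' Configuration for a pipeline run
#'
#' Bundles the knobs of a per-condition or cross-species run. Paths are
#' validated when given; in-memory objects (a `timecourse_matrix`, hit-table
#' data.frames) may be supplied instead of paths.
#'
#' @param matrix Path to an expression TSV, or a `timecourse_matrix`.
#' @param condition Condition label.
#' @param r_cutoff Correlation cutoff for cycling calls.
#' @param shapes Model shapes for the library.
#' @param n_perm Permutations for the FDR estimate (0 skips permutation).
#' @param seed Integer seed (mandatory).
#' @param promoters Optional `promoter_set` or FASTA path.
#' @param k_min,k_max Promoter word length range.
#' @param z_threshold,run_length Profile significance rule.
#' @param window_h Cross-species phase concordance window (h).
#' @param out_dir Output directory (created on demand); NULL disables
#'   file output.
#' @return A list of class `run_config`.
#' @export
run_config <- function(matrix, condition = "cond", r_cutoff = 0.75,
                       shapes = MODEL_SHAPES, n_perm = 10, seed,
                       promoters = NULL, k_min = 3, k_max = 8,
                       z_threshold = 2.33, run_length = 3, window_h = 3,
                       out_dir = NULL) {
  if (missing(seed)) stop("seed is mandatory")
  if (is.character(matrix) && !file.exists(matrix))
    stop("matrix file not found: ", matrix)
  if (is.character(promoters) && !file.exists(promoters))
    stop("promoter file not found: ", promoters)
  structure(list(matrix = matrix, condition = condition,
                 r_cutoff = r_cutoff, shapes = shapes, n_perm = n_perm,
                 seed = as.integer(seed), promoters = promoters,
                 k_min = k_min, k_max = k_max, z_threshold = z_threshold,
                 run_length = run_length, window_h = window_h,
                 out_dir = out_dir),
            class = "run_config")
}

.load_matrix <- function(config) {
  m <- config$matrix
  if (is.character(m)) m <- read_timecourse(m, config$condition)
  stopifnot(inherits(m, "timecourse_matrix"))
  if (nrow(m$values) == 0) stop("empty expression matrix")
  m
}

.load_promoters <- function(x) {
  if (is.null(x)) return(NULL)
  if (inherits(x, "promoter_set")) x else promoter_set(x)
}

#' Run the per-condition rhythm analysis
#'
#' Loads one condition's expression matrix, builds the model library on its
#' time grid, calls cycling genes at the configured cutoff, estimates the
#' permutation FDR, and summarises the cycling fraction and the phase
#' histogram. When `out_dir` is set, writes `calls_<condition>.tsv` and
#' `phase_histogram_<condition>.tsv` with provenance headers. Stage counts
#' (genes in, filtered, cycling) are reported with `message()`.
#'
#' @param config A [run_config()].
#' @return A list of class `condition_report`: `condition`, `calls`,
#'   `n_genes`, `n_cycling`, `cycling_fraction`, `fdr_at_cutoff`,
#'   `phase_histogram`, `library`, `seed`.
#' @export
run_condition <- function(config) {
  stopifnot(inherits(config, "run_config"))
  m <- .load_matrix(config)
  lib <- build_model_library(m$times_h, shapes = config$shapes)
  message("[", config$condition, "] ", nrow(m$values), " genes on ",
          length(m$times_h), " time points; ", nrow(lib$patterns),
          " model patterns")
  calls <- call_cycling(m, lib, r_cutoff = config$r_cutoff)
  fdr <- NA_real_
  if (config$n_perm > 0) {
    perm <- permutation_fdr(m, lib, r_cutoff = config$r_cutoff,
                            n_perm = config$n_perm, seed = config$seed,
                            calls = calls)
    calls <- perm$calls
    fdr <- perm$fdr_at_cutoff
  }
  n_cyc <- sum(calls$is_cycling)
  message("[", config$condition, "] ", n_cyc, " cycling at r >= ",
          config$r_cutoff, " (", round(100 * n_cyc / nrow(calls), 1),
          "%); permutation FDR ",
          if (is.na(fdr)) "not estimated" else round(fdr, 4))
  hist <- phase_histogram(calls)
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    write_calls(calls, file.path(config$out_dir,
                                 paste0("calls_", config$condition, ".tsv")),
                seed = config$seed, config = config)
    .write_tsv(data.frame(phase_bin = names(hist), n_cycling = hist),
               file.path(config$out_dir,
                         paste0("phase_histogram_", config$condition,
                                ".tsv")),
               seed = config$seed, config = config)
  }
  structure(list(condition = config$condition, calls = calls,
                 n_genes = nrow(calls), n_cycling = n_cyc,
                 cycling_fraction = n_cyc / nrow(calls),
                 fdr_at_cutoff = fdr, phase_histogram = hist,
                 library = lib, seed = config$seed),
            class = "condition_report")
}

#' @export
print.condition_report <- function(x, ...) {
  cat("condition_report [", x$condition, "]: ", x$n_cycling, "/",
      x$n_genes, " cycling (", round(100 * x$cycling_fraction, 1),
      "%), permutation FDR ",
      if (is.na(x$fdr_at_cutoff)) "NA" else round(x$fdr_at_cutoff, 4),
      "\n", sep = "")
  invisible(x)
}

#' Run the cross-species analysis
#'
#' Runs [run_condition()] per species, then (when hit tables are supplied)
#' predicts reciprocal-best-hit orthologs, three-way mutual orthologs if
#' three species are given, and phase concordance; and (when promoters are
#' supplied) scans promoter words per species and calls conserved elements.
#' Missing hit tables skip the orthology stage with a warning; the element
#' scan still runs.
#'
#' @param configs Named list of [run_config()], one per species (>= 2).
#' @param hit_tables Named list of hit-table data.frames (or paths), keyed
#'   `"<spA>_vs_<spB>"` for every ordered species pair, as produced by
#'   [simulate_hit_tables()]. NULL skips orthology.
#' @param out_dir Output directory; NULL disables file output.
#' @return A list of class `cross_species_report`: `reports` (per-species
#'   `condition_report`s), `pairs` (RBH tables per species pair), `triples`
#'   (if 3 species), `concordance` (a `phase_concordance` or NULL),
#'   `elements` (conserved-element table or NULL).
#' @export
run_cross_species <- function(configs, hit_tables = NULL, out_dir = NULL) {
  species <- names(configs)
  if (length(species) < 2) stop("need >= 2 species")
  reports <- lapply(configs, run_condition)
  calls_by_species <- lapply(reports, `[[`, "calls")

  pairs <- NULL; triples <- NULL; concord <- NULL
  if (is.null(hit_tables)) {
    warning("no hit tables supplied; skipping orthology stage")
  } else {
    hit_tables <- lapply(hit_tables, function(h) {
      if (is.character(h)) read_hit_table(h) else h
    })
    combos <- utils::combn(species, 2, simplify = FALSE)
    pairs <- lapply(combos, function(pr) {
      ab <- hit_tables[[paste(pr[1], "vs", pr[2], sep = "_")]]
      ba <- hit_tables[[paste(pr[2], "vs", pr[1], sep = "_")]]
      if (is.null(ab) || is.null(ba))
        stop("missing hit tables for pair ", pr[1], "/", pr[2])
      reciprocal_best_hits(ab, ba)
    })
    names(pairs) <- vapply(combos, paste, character(1), collapse = "_vs_")
    if (length(species) == 3) {
      triples <- three_way_orthologs(pairs[[1]],
                                     stats::setNames(pairs[[2]],
                                                     c("id_a", "id_b")),
                                     stats::setNames(pairs[[3]],
                                                     c("id_a", "id_b")))
      names(triples) <- species
      message(nrow(triples), " three-way mutual ortholog triples")
      concord <- phase_concordance(triples, calls_by_species,
                                   window_h = configs[[1]]$window_h)
    } else {
      pr2 <- stats::setNames(pairs[[1]], species[1:2])
      concord <- phase_concordance(pr2, calls_by_species,
                                   window_h = configs[[1]]$window_h)
    }
    message(concord$n_cycling_all, " ortholog groups cycling in all ",
            "species; ",
            round(100 * concord$frac_within_window, 1),
            "% phased within ", concord$window_h, " h")
  }

  elements <- NULL
  have_prom <- !vapply(lapply(configs, `[[`, "promoters"), is.null,
                       logical(1))
  if (all(have_prom)) {
    scans <- lapply(species, function(sp) {
      scan_all_words(calls_by_species[[sp]],
                     .load_promoters(configs[[sp]]$promoters),
                     k_min = configs[[sp]]$k_min,
                     k_max = configs[[sp]]$k_max,
                     z_threshold = configs[[sp]]$z_threshold,
                     run_length = configs[[sp]]$run_length)
    })
    names(scans) <- species
    elements <- conserved_elements(scans,
                                   window_h = configs[[1]]$window_h)
    message(sum(elements$conserved), " conserved promoter element(s)")
  }

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    seed <- configs[[1]]$seed
    if (!is.null(triples))
      .write_tsv(triples, file.path(out_dir, "ortholog_triples.tsv"),
                 seed = seed, config = configs)
    if (!is.null(concord)) {
      for (nm in names(concord$matrices))
        .write_tsv(as.data.frame(concord$matrices[[nm]]),
                   file.path(out_dir, paste0("concordance_", nm, ".tsv")),
                   seed = seed, config = configs)
    }
    if (!is.null(elements))
      .write_tsv(elements, file.path(out_dir, "conserved_elements.tsv"),
                 seed = seed, config = configs)
  }
  structure(list(reports = reports, pairs = pairs, triples = triples,
                 concordance = concord, elements = elements),
            class = "cross_species_report")
}
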