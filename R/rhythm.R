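#' Time-course expression matrix
#'
#' Light wrapper around a genes x times numeric matrix carrying the sampling
#' grid and a condition label. Times must be strictly increasing and evenly
#' spaced; rows with missing values are dropped at construction with a
#' message (counts of dropped rows are part of the run log).
#'
#' @param values Numeric matrix, genes in rows, time points in columns.
#' @param times_h Sampling hours, one per column.
#' @param gene_ids Row identifiers; defaults to rownames(values).
#' @param condition Condition label (e.g. "LDHH", "LL_LDHH").
#' @return An object of class `timecourse_matrix`.
#' @export
timecourse_matrix <- function(values, times_h, gene_ids = rownames(values),
                              condition = "unspecified") {
  values <- as.matrix(values)
  if (is.null(gene_ids)) stop("gene_ids required (or rownames on values)")
  stopifnot(length(gene_ids) == nrow(values),
            length(times_h) == ncol(values))
  if (is.unsorted(times_h, strictly = TRUE))
    stop("times_h must be strictly increasing")
  if (length(times_h) > 2) {
    dt <- diff(times_h)
    if (max(dt) - min(dt) > 1e-8) stop("times_h must be evenly spaced")
  }
  if (anyDuplicated(gene_ids)) stop("gene_ids must be unique")
  keep <- stats::complete.cases(values)
  if (!all(keep)) {
    message("dropping ", sum(!keep), " gene(s) with missing values")
    values <- values[keep, , drop = FALSE]
    gene_ids <- gene_ids[keep]
  }
  rownames(values) <- gene_ids
  structure(list(values = values, times_h = times_h,
                 gene_ids = gene_ids, condition = condition),
            class = "timecourse_matrix")
}

#' @export
print.timecourse_matrix <- function(x, ...) {
  cat("timecourse_matrix [", x$condition, "]: ", nrow(x$values), " genes x ",
      length(x$times_h), " time points (",
      x$times_h[1], "-", x$times_h[length(x$times_h)], " h)\n", sep = "")
  invisible(x)
}

# correlation of every column of `values_t` (times x genes) against every
# library pattern; returns genes x patterns matrix. Constant genes give NA.
.pattern_cor <- function(values_t, library) {
  suppressWarnings(stats::cor(values_t, library$samples))
}

#' Correlate one gene against the model library
#'
#' Computes the Pearson correlation of an expression series against every
#' pattern in the library and returns the best match. Pearson correlation is
#' invariant to the scale and offset of the series, so detection does not
#' depend on absolute expression level. Ties in r resolve to the library's
#' deterministic order (cosine first, then lower phase, then shape label).
#'
#' @param values Numeric expression vector on the library's time grid.
#' @param library A `model_library` from [build_model_library()].
#' @return A list with `shape`, `phase_h` and `r`. For a constant input
#'   vector the correlation is undefined and `r` is `NA`.
#' @export
correlate_gene <- function(values, library) {
  stopifnot(length(values) == length(library$times_h))
  if (diff(range(values)) == 0)
    return(list(shape = NA_character_, phase_h = NA_real_, r = NA_real_))
  r <- as.vector(.pattern_cor(matrix(values, ncol = 1), library))
  # ties within float tolerance resolve to the library order (cosine
  # first, then lower phase): distinct patterns can sample identically
  best <- which.max(r >= max(r, na.rm = TRUE) - 1e-9)
  list(shape = library$patterns$shape[best],
       phase_h = library$patterns$phase_h[best], r = r[best])
}

#' Call cycling genes against a model library
#'
#' For every gene, finds the best-matching model pattern by Pearson
#' correlation and flags the gene as cycling when r meets the cutoff
#' (default 0.75, the threshold corresponding to roughly 5% FDR by
#' permutation on these designs). Permutation p-values and FDR columns are
#' `NA` until filled in by [permutation_fdr()].
#'
#' Genes with constant series get `r = NA` and are never called cycling. An
#' optional variance filter drops near-flat genes before matching.
#'
#' @param matrix_tc A `timecourse_matrix`.
#' @param library A `model_library` on the same time grid.
#' @param r_cutoff Correlation cutoff for the cycling call.
#' @param min_var Minimum per-gene variance; genes below are reported with
#'   `r = NA` (filtered, not cycling). Default 0 keeps all non-constant genes.
#' @return A data.frame of class `cycling_calls` with columns `gene_id`,
#'   `condition`, `shape`, `phase_h`, `r`, `p`, `fdr`, `is_cycling`.
#' @export
call_cycling <- function(matrix_tc, library, r_cutoff = 0.75, min_var = 0) {
  stopifnot(inherits(matrix_tc, "timecourse_matrix"),
            inherits(library, "model_library"))
  if (length(matrix_tc$times_h) != length(library$times_h) ||
      any(abs(matrix_tc$times_h - library$times_h) > 1e-8))
    stop("matrix and model library are on different time grids")

  vals <- matrix_tc$values
  v <- apply(vals, 1L, stats::var)
  usable <- v > min_var & v > 0
  n <- nrow(vals)
  shape <- rep(NA_character_, n); phase <- rep(NA_real_, n)
  r <- rep(NA_real_, n)
  if (any(usable)) {
    cors <- .pattern_cor(t(vals[usable, , drop = FALSE]), library)
    rmax <- cors[cbind(seq_len(nrow(cors)),
                       max.col(cors, ties.method = "first"))]
    # tolerance-based argmax: float-level ties resolve to library order
    best <- max.col(-1 * (cors < rmax - 1e-9), ties.method = "first")
    shape[usable] <- library$patterns$shape[best]
    phase[usable] <- library$patterns$phase_h[best]
    r[usable] <- rmax
  }
  calls <- data.frame(
    gene_id = matrix_tc$gene_ids, condition = matrix_tc$condition,
    shape = shape, phase_h = phase, r = r,
    p = NA_real_, fdr = NA_real_,
    is_cycling = !is.na(r) & r >= r_cutoff,
    stringsAsFactors = FALSE)
  attr(calls, "r_cutoff") <- r_cutoff
  class(calls) <- c("cycling_calls", "data.frame")
  calls
}

#' Permutation FDR for cycling calls
#'
#' Builds an empirical null by shuffling every gene's time points
#' independently `n_perm` times, re-running the best-model scan on each
#' shuffled matrix, and pooling the null best-r values across genes and
#' permutations. Reports:
#' \itemize{
#'   \item `fdr_at_cutoff`: mean over permutations of the number of null
#'     genes reaching the cutoff divided by the observed number reaching it
#'     (floored at 1).
#'   \item per-gene add-one empirical p-values against the pooled null:
#'     `p = (1 + #null >= r) / (1 + #null)`.
#'   \item per-gene FDR evaluated at each gene's own r.
#' }
#'
#' @param matrix_tc A `timecourse_matrix`.
#' @param library A `model_library` on the same grid.
#' @param r_cutoff Correlation cutoff at which the headline FDR is reported.
#' @param n_perm Number of permutations (default 10).
#' @param seed Integer seed for the shuffle stream.
#' @param calls Optional precomputed [call_cycling()] result to annotate;
#'   computed internally if missing.
#'
#' @details The raw estimator counts null passers over *all* genes, so when
#' a substantial fraction of genes truly cycle it overestimates the FDR by
#' roughly `1/pi0` (the reciprocal of the truly-null fraction). The
#' calibrated estimate `fdr_at_cutoff_pi0` multiplies by a Storey-type
#' plug-in `pi0` estimated from the fraction of observed best-r values
#' below the null median: `pi0 = min(1, mean(r_obs <= median(null)) / 0.5)`.
#'
#' @return A list with `fdr_at_cutoff` (raw permutation estimate),
#'   `fdr_at_cutoff_pi0` (pi0-calibrated estimate), `pi0`, `fdr_per_perm`
#'   (one raw value per permutation, for Monte-Carlo error), `per_gene_p`
#'   (named vector), `null_r` (pooled null best-r values) and `calls`
#'   (annotated data.frame).
#' @export
permutation_fdr <- function(matrix_tc, library, r_cutoff = 0.75,
                            n_perm = 10, seed = 1, calls = NULL) {
  if (n_perm < 1) stop("n_perm must be >= 1")
  if (is.null(calls)) calls <- call_cycling(matrix_tc, library, r_cutoff)
  vals <- matrix_tc$values
  nt <- ncol(vals)

  null_best <- withr::with_seed(seed, {
    vapply(seq_len(n_perm), function(i) {
      shuf <- t(apply(vals, 1L, sample, size = nt))
      cors <- .pattern_cor(t(shuf), library)
      suppressWarnings(apply(cors, 1L, max))
    }, numeric(nrow(vals)))
  })
  null_best <- matrix(null_best, nrow = nrow(vals))  # genes x perms

  n_obs <- sum(calls$is_cycling)
  fdr_per_perm <- apply(null_best, 2L, function(nb) {
    sum(nb >= r_cutoff, na.rm = TRUE) / max(1L, n_obs)
  })
  fdr_at_cutoff <- mean(fdr_per_perm)

  pooled <- sort(as.vector(null_best[!is.na(null_best)]))
  n_null <- length(pooled)
  # #null >= r via position in the sorted pooled null
  ge_count <- function(r) n_null - findInterval(r - 1e-12, pooled)
  obs_r <- calls$r
  p <- rep(NA_real_, length(obs_r))
  ok <- !is.na(obs_r)
  p[ok] <- (1 + ge_count(obs_r[ok])) / (1 + n_null)

  # FDR at each gene's own r: E[#null >= r]/#obs >= r
  fdr_gene <- rep(NA_real_, length(obs_r))
  if (any(ok)) {
    n_ge_obs <- vapply(obs_r[ok], function(r) sum(obs_r >= r, na.rm = TRUE),
                       integer(1))
    fdr_gene[ok] <- pmin(1, (ge_count(obs_r[ok]) / n_perm) /
                              pmax(1L, n_ge_obs))
  }
  calls$p <- p
  calls$fdr <- fdr_gene
  names(p) <- calls$gene_id

  null_med <- stats::median(pooled)
  pi0 <- min(1, mean(obs_r <= null_med, na.rm = TRUE) / 0.5)
  list(fdr_at_cutoff = fdr_at_cutoff,
       fdr_at_cutoff_pi0 = pi0 * fdr_at_cutoff, pi0 = pi0,
       fdr_per_perm = fdr_per_perm,
       per_gene_p = p, null_r = pooled, calls = calls)
}

#' Collapse probe-level calls to gene models
#'
#' Arrays carry several probe sets per gene model; the gene inherits the
#' call of its best-correlated probe. Ties on r resolve to the lower phase,
#' then the first probe in input order. Probes absent from the mapping are
#' dropped with a message.
#'
#' @param calls A `cycling_calls` data.frame keyed by probe IDs.
#' @param probe_to_gene Data.frame with columns `probe_id`, `gene_id` (or a
#'   named character vector probe -> gene).
#' @return A `cycling_calls` data.frame with one row per gene model.
#' @export
collapse_probes_to_genes <- function(calls, probe_to_gene) {
  if (is.character(probe_to_gene))
    probe_to_gene <- data.frame(probe_id = names(probe_to_gene),
                                gene_id = unname(probe_to_gene))
  stopifnot(all(c("probe_id", "gene_id") %in% names(probe_to_gene)))
  if (nrow(probe_to_gene) == 0L) stop("empty probe-to-gene mapping")
  idx <- match(calls$gene_id, probe_to_gene$probe_id)
  if (anyNA(idx))
    message("dropping ", sum(is.na(idx)), " unmapped probe(s)")
  keep <- !is.na(idx)
  out <- calls[keep, , drop = FALSE]
  gene <- probe_to_gene$gene_id[idx[keep]]
  # best probe: max r, then lower phase, then input order
  ord <- order(gene, -out$r, out$phase_h, na.last = TRUE)
  out <- out[ord, , drop = FALSE]
  gene <- gene[ord]
  first <- !duplicated(gene)
  out <- out[first, , drop = FALSE]
  out$gene_id <- gene[first]
  rownames(out) <- NULL
  class(out) <- c("cycling_calls", "data.frame")
  out
}

#' Phase histogram of cycling genes
#'
#' Counts cycling genes per phase bin over the 24-h day. Bin width defaults
#' to 1 h (24 bins); any width dividing 24 is allowed. Counts sum to the
#' number of cycling genes.
#'
#' @param calls A `cycling_calls` data.frame.
#' @param bin_width_h Bin width in hours; must divide 24.
#' @return Named integer vector of counts; names are bin start hours.
#' @export
phase_histogram <- function(calls, bin_width_h = 1) {
  if (bin_width_h <= 0 || abs(24 / bin_width_h - round(24 / bin_width_h)) > 1e-9)
    stop("bin_width_h must divide 24")
  n_bins <- as.integer(round(24 / bin_width_h))
  starts <- (seq_len(n_bins) - 1L) * bin_width_h
  ph <- calls$phase_h[calls$is_cycling]
  bin <- floor((ph %% 24) / bin_width_h)
  counts <- tabulate(bin + 1L, nbins = n_bins)
  names(counts) <- starts
  counts
}

#' Overlap of cycling gene sets across conditions
#'
#' Computes all pairwise and higher-order intersection sizes, the exclusive
#' (Venn region) counts, and the union ("cycling under at least one
#' condition") for two or more conditions.
#'
#' @param sets Named list of character vectors (cycling gene IDs per
#'   condition).
#' @return A list with `union_size`, `intersections` (named sizes for every
#'   non-empty condition combination, e.g. `"A&B"`), and `exclusive_regions`
#'   (Venn region counts: genes in exactly that combination).
#' @export
condition_overlap <- function(sets) {
  if (length(sets) < 2L) stop("need at least 2 condition sets")
  if (is.null(names(sets)) || any(!nzchar(names(sets))))
    stop("sets must be named")
  sets <- lapply(sets, unique)
  universe <- unique(unlist(sets))
  member <- vapply(sets, function(s) universe %in% s,
                   logical(length(universe)))
  member <- matrix(member, nrow = length(universe),
                   dimnames = list(NULL, names(sets)))
  combos <- unlist(lapply(seq_along(sets), function(k) {
    utils::combn(names(sets), k, simplify = FALSE)
  }), recursive = FALSE)
  inter <- vapply(combos, function(cs) {
    sum(rowSums(member[, cs, drop = FALSE]) == length(cs))
  }, integer(1))
  names(inter) <- vapply(combos, paste, character(1), collapse = "&")
  sig <- apply(member, 1L, function(m) paste(names(sets)[m], collapse = "&"))
  excl <- table(sig)
  list(union_size = length(universe),
       intersections = inter,
       exclusive_regions = stats::setNames(as.integer(excl), names(excl)))
}
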