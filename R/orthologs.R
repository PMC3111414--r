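#' Read a tabular similarity hit file
#'
#' Reads a 12-column tab-separated hit table (standard BLAST outfmt-6
#' column order: qseqid, sseqid, pident, length, mismatch, gapopen, qstart,
#' qend, sstart, send, evalue, bitscore). Extra columns are ignored;
#' '#'-prefixed comment lines are skipped.
#'
#' @param path Path to the file.
#' @return Data.frame with the 12 named columns.
#' @export
read_hit_table <- function(path) {
  cols <- c("qseqid", "sseqid", "pident", "length", "mismatch", "gapopen",
            "qstart", "qend", "sstart", "send", "evalue", "bitscore")
  tab <- utils::read.table(path, sep = "\t", comment.char = "#",
                           stringsAsFactors = FALSE)
  if (ncol(tab) < 12) stop("hit table must have >= 12 columns")
  tab <- tab[, 1:12]
  names(tab) <- cols
  tab
}

# best subject per query: max bitscore, ties by min evalue then subject ID;
# multiple HSPs to the same subject collapse to their max-bitscore row first
.best_hits <- function(tab) {
  if (nrow(tab) == 0)
    return(data.frame(qseqid = character(), sseqid = character()))
  ord <- order(tab$qseqid, tab$sseqid, -tab$bitscore, tab$evalue)
  tab <- tab[ord, ]
  tab <- tab[!duplicated(tab[c("qseqid", "sseqid")]), ]
  ord <- order(tab$qseqid, -tab$bitscore, tab$evalue, tab$sseqid)
  tab <- tab[ord, ]
  tab[!duplicated(tab$qseqid), c("qseqid", "sseqid")]
}

#' Reciprocal best hits between two species
#'
#' A pair (a, b) is reported when b is a's best hit in the A-vs-B table and
#' a is b's best hit in the B-vs-A table. "Best" means maximum bit score,
#' with ties broken by minimum e-value and then lexicographic subject ID;
#' multiple HSPs between the same pair keep their maximum-bit-score row.
#'
#' @param ab Hit table (data.frame as from [read_hit_table()]) of species A
#'   queried against species B.
#' @param ba Hit table of B queried against A.
#' @return Data.frame with columns `id_a`, `id_b`, one row per RBH pair,
#'   sorted by `id_a`.
#' @export
reciprocal_best_hits <- function(ab, ba) {
  best_ab <- .best_hits(ab)
  best_ba <- .best_hits(ba)
  if (nrow(best_ab) == 0 || nrow(best_ba) == 0)
    return(data.frame(id_a = character(), id_b = character()))
  back <- best_ba$sseqid[match(best_ab$sseqid, best_ba$qseqid)]
  keep <- !is.na(back) & back == best_ab$qseqid
  out <- data.frame(id_a = best_ab$qseqid[keep],
                    id_b = best_ab$sseqid[keep],
                    stringsAsFactors = FALSE)
  out[order(out$id_a), , drop = FALSE]
}

#' Three-way mutual orthologs
#'
#' A triple (a, b, c) is reported when all three pairwise reciprocal best
#' hit relations hold: (a,b), (a,c) and (b,c).
#'
#' @param pairs_ab,pairs_ac,pairs_bc RBH pair tables from
#'   [reciprocal_best_hits()] (columns `id_a`, `id_b` meaning the
#'   respective species pair).
#' @return Data.frame with columns `id_a`, `id_b`, `id_c`.
#' @export
three_way_orthologs <- function(pairs_ab, pairs_ac, pairs_bc) {
  m <- merge(stats::setNames(pairs_ab, c("id_a", "id_b")),
             stats::setNames(pairs_ac, c("id_a", "id_c")), by = "id_a")
  if (nrow(m) == 0)
    return(data.frame(id_a = character(), id_b = character(),
                      id_c = character()))
  bc <- paste(pairs_bc[[1]], pairs_bc[[2]], sep = "\r")
  keep <- paste(m$id_b, m$id_c, sep = "\r") %in% bc
  out <- m[keep, c("id_a", "id_b", "id_c"), drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Circular distance between two phases
#'
#' Shortest distance around the 24-h circle, in hours; always in `[0, 12]`.
#'
#' @param p1,p2 Phases in hours, each in `[0, 24)`. Vectorised.
#' @return Circular distance(s) in hours.
#' @export
circular_phase_distance <- function(p1, p2) {
  if (any(p1 < 0 | p1 >= 24 | p2 < 0 | p2 >= 24, na.rm = TRUE))
    stop("phases must lie in [0, 24)")
  d <- abs(p1 - p2)
  pmin(d, 24 - d)
}

#' Cross-species phase concordance of orthologs
#'
#' Restricts ortholog triples (or pairs) to those cycling in every supplied
#' species, tabulates the 24 x 24 matrix of phase-bin combinations for each
#' species pair, and reports the fraction of ortholog groups whose maximum
#' pairwise circular phase distance is within `window_h` hours.
#'
#' @param triples Data.frame of ortholog IDs, one column per species
#'   (column order defines the species order; 2 or 3 columns).
#' @param calls_by_species Named list of `cycling_calls`, names matching
#'   `names(triples)`.
#' @param window_h Concordance window in hours (default 3).
#' @return A list of class `phase_concordance`: `n_cycling_all` (groups
#'   cycling in all species), `frac_within_window` (NA if no qualifying
#'   group), `window_h`, `matrices` (named list of 24 x 24 count matrices
#'   per species pair; each sums to `n_cycling_all`), `distances` (max
#'   pairwise circular distance per qualifying group).
#' @export
phase_concordance <- function(triples, calls_by_species, window_h = 3) {
  species <- names(triples)
  stopifnot(length(species) >= 2,
            all(species %in% names(calls_by_species)))
  phase_of <- lapply(species, function(sp) {
    calls <- calls_by_species[[sp]]
    ph <- ifelse(calls$is_cycling, calls$phase_h, NA_real_)
    ph[match(triples[[sp]], calls$gene_id)]
  })
  names(phase_of) <- species
  pm <- do.call(cbind, phase_of)
  all_cyc <- stats::complete.cases(pm)
  pm <- pm[all_cyc, , drop = FALSE]
  n <- nrow(pm)

  pairs <- utils::combn(species, 2, simplify = FALSE)
  mats <- lapply(pairs, function(pr) {
    m <- matrix(0L, 24, 24, dimnames = list(0:23, 0:23))
    if (n > 0) {
      b1 <- floor(pm[, pr[1]] %% 24); b2 <- floor(pm[, pr[2]] %% 24)
      for (i in seq_len(n)) m[b1[i] + 1L, b2[i] + 1L] <-
          m[b1[i] + 1L, b2[i] + 1L] + 1L
    }
    m
  })
  names(mats) <- vapply(pairs, paste, character(1), collapse = "_vs_")
  dists <- if (n > 0) {
    apply(pm, 1L, function(ph) {
      max(utils::combn(ph, 2,
                       function(p) circular_phase_distance(p[1], p[2])))
    })
  } else numeric(0)
  structure(list(n_cycling_all = n,
                 frac_within_window = if (n > 0) mean(dists <= window_h)
                                      else NA_real_,
                 window_h = window_h, matrices = mats, distances = dists),
            class = "phase_concordance")
}

#' @export
print.phase_concordance <- function(x, ...) {
  cat("phase_concordance:", x$n_cycling_all,
      "ortholog groups cycling in all species;",
      if (is.na(x$frac_within_window)) "fraction within window undefined"
      else paste0(round(100 * x$frac_within_window, 1), "% within ",
                  x$window_h, " h"), "\n")
  invisible(x)
}

#' Hypergeometric set enrichment by family
#'
#' For each family label, tests whether the member set is enriched for that
#' family relative to the universe (hypergeometric upper tail, i.e.
#' one-sided Fisher), with Benjamini-Hochberg adjusted p-values alongside.
#' Families with no genes in the universe are skipped.
#'
#' @param member_set Character vector of gene IDs (subset of universe).
#' @param universe Character vector of gene IDs.
#' @param family_map Data.frame with columns `gene_id`, `family` (or a named
#'   character vector gene -> family).
#' @return Data.frame with `family`, `n_family` (in universe), `n_member`
#'   (family genes in the member set), `expected`, `p`, `p_adj`, sorted by p.
#' @export
set_enrichment <- function(member_set, universe, family_map) {
  if (is.character(family_map))
    family_map <- data.frame(gene_id = names(family_map),
                             family = unname(family_map))
  member_set <- unique(member_set); universe <- unique(universe)
  if (!all(member_set %in% universe))
    stop("member_set must be a subset of universe")
  fam <- family_map[family_map$gene_id %in% universe, ]
  if (nrow(fam) == 0)
    return(data.frame(family = character(), n_family = integer(),
                      n_member = integer(), expected = numeric(),
                      p = numeric(), p_adj = numeric()))
  n_draw <- length(member_set)
  n_univ <- length(universe)
  fams <- sort(unique(fam$family))
  n_family <- vapply(fams, function(f) {
    length(unique(fam$gene_id[fam$family == f]))
  }, integer(1))
  n_member <- vapply(fams, function(f) {
    sum(member_set %in% fam$gene_id[fam$family == f])
  }, integer(1))
  # upper tail including the observed count
  p <- stats::phyper(n_member - 1, n_family, n_univ - n_family, n_draw,
                     lower.tail = FALSE)
  out <- data.frame(family = fams, n_family = n_family,
                    n_member = n_member,
                    expected = n_draw * n_family / n_univ,
                    p = p, p_adj = stats::p.adjust(p, method = "BH"),
                    row.names = NULL, stringsAsFactors = FALSE)
  out[order(out$p), , drop = FALSE]
}
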