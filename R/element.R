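#' Enrichment Z-score of a word in a foreground gene set
#'
#' Presence/absence enrichment of a DNA word among foreground promoters
#' against the background containment rate. With n foreground genes, k of
#' whose promoters contain the word, and background containment fraction
#' p-hat,
#'
#' \deqn{Z = \frac{k - n \hat p}{\sqrt{n \hat p (1 - \hat p)}}.}
#'
#' If the background rate is degenerate (p-hat 0 or 1) the Z-score is
#' defined as 0. Presence/absence is the default statistic because
#' overlapping occurrences of a word within one promoter are not
#' independent; a total-occurrence mode (background-standardised mean
#' count) is available behind `mode = "occurrence"`.
#'
#' @param word DNA word, length 3-8.
#' @param foreground Character vector of foreground gene IDs (subset of
#'   background).
#' @param background Character vector of background gene IDs; all must have
#'   promoters.
#' @param promoters A `promoter_set`.
#' @param both_strands Match the reverse complement too (default TRUE).
#' @param mode `"presence"` (default) or `"occurrence"`.
#' @return A single Z-score.
#' @export
word_zscore <- function(word, foreground, background, promoters,
                        both_strands = TRUE,
                        mode = c("presence", "occurrence")) {
  mode <- match.arg(mode)
  if (length(background) == 0) stop("empty background")
  if (length(foreground) == 0) stop("empty foreground")
  if (!all(foreground %in% background))
    stop("foreground must be a subset of background")
  seqs <- promoters$sequences
  miss <- setdiff(background, names(seqs))
  if (length(miss)) stop("background genes without promoters: ",
                         paste(utils::head(miss, 3), collapse = ", "))
  n <- length(foreground)
  if (mode == "presence") {
    hit <- contains_word(promoters, word, both_strands)[background]
    k <- sum(hit[foreground])
    phat <- mean(hit)
    if (phat <= 0 || phat >= 1) return(0)
    (k - n * phat) / sqrt(n * phat * (1 - phat))
  } else {
    ss <- Biostrings::DNAStringSet(seqs[background])
    cnt <- Biostrings::vcountPattern(toupper(word), ss, fixed = TRUE)
    if (both_strands && .revcomp(word) != toupper(word))
      cnt <- cnt + Biostrings::vcountPattern(.revcomp(toupper(word)), ss,
                                             fixed = TRUE)
    names(cnt) <- background
    s <- stats::sd(cnt)
    if (s == 0) return(0)
    (sum(cnt[foreground]) - n * mean(cnt)) / (s * sqrt(n))
  }
}

# phase-bin indicator matrix (background genes x 24) from cycling calls
.bin_indicator <- function(calls, background) {
  bins <- matrix(0, nrow = length(background), ncol = 24,
                 dimnames = list(background, 0:23))
  cyc <- calls[calls$is_cycling & calls$gene_id %in% background, ]
  if (nrow(cyc) > 0) {
    b <- floor(cyc$phase_h %% 24)
    bins[cbind(match(cyc$gene_id, background), b + 1L)] <- 1
  }
  bins
}

#' 24-bin enrichment Z-score profile of one word
#'
#' For each one-hour phase bin, the foreground is the set of cycling genes
#' called at that phase and the background is every gene with a promoter;
#' [word_zscore()] is evaluated per bin, giving a length-24 profile. Bins
#' with no cycling genes score 0 and are flagged in `empty_bins`.
#'
#' @param word DNA word, length 3-8.
#' @param calls A `cycling_calls` data.frame with phases.
#' @param promoters A `promoter_set` covering the call universe (calls for
#'   genes without promoters are dropped with a message).
#' @param both_strands Match the reverse complement too.
#' @param z_threshold,run_length Significance rule parameters (see
#'   [significant_profile()]).
#' @return An object of class `zprofile`: `word`, `z` (named numeric,
#'   length 24), `significant`, `peak_phase_h` (NA unless significant),
#'   `empty_bins`, `n_foreground` (per-bin counts).
#' @export
zscore_profile <- function(word, calls, promoters, both_strands = TRUE,
                           z_threshold = 2.33, run_length = 3) {
  background <- names(promoters$sequences)
  if (length(background) == 0) stop("empty promoter set")
  uncovered <- sum(!(calls$gene_id %in% background))
  if (uncovered > 0)
    message("dropping ", uncovered, " call(s) without promoters")
  bins <- .bin_indicator(calls, background)
  n_fg <- colSums(bins)
  hit <- as.numeric(contains_word(promoters, word, both_strands)[background])
  phat <- mean(hit)
  k <- as.vector(crossprod(hit, bins))
  z <- if (phat <= 0 || phat >= 1) rep(0, 24) else
    (k - n_fg * phat) / sqrt(pmax(n_fg, 1) * phat * (1 - phat))
  z[n_fg == 0] <- 0
  names(z) <- 0:23
  .finish_profile(word, z, n_fg, z_threshold, run_length)
}

.finish_profile <- function(word, z, n_fg, z_threshold, run_length) {
  sig <- significant_profile(z, z_threshold, run_length)
  prof <- structure(list(word = word, z = z, significant = sig,
                         peak_phase_h = NA_real_,
                         empty_bins = which(n_fg == 0) - 1L,
                         n_foreground = n_fg),
                    class = "zprofile")
  if (sig && diff(range(z)) > 0)
    prof$peak_phase_h <- profile_phase(prof)
  prof
}

#' @export
print.zprofile <- function(x, ...) {
  cat("zprofile ", x$word, ": max Z = ", round(max(x$z), 2),
      " at bin ", which.max(x$z) - 1L,
      if (x$significant) paste0("; significant, profile phase ",
                                x$peak_phase_h, " h")
      else "; not significant", "\n", sep = "")
  invisible(x)
}

#' Consecutive-bin significance rule for a Z-score profile
#'
#' A profile is significant when at least `run_length` consecutive phase
#' bins all reach `z_threshold`. The default threshold 2.33 is the
#' one-sided standard-normal quantile at p = 0.01; the default run length
#' is 3 bins. By default runs may wrap across midnight (bin 23 is adjacent
#' to bin 0), since phase is circular.
#'
#' @param profile A `zprofile` or a numeric vector of 24 Z-scores.
#' @param z_threshold Per-bin significance threshold.
#' @param run_length Required number of consecutive significant bins.
#' @param circular Allow the run to wrap 23 -> 0 (default TRUE).
#' @return Logical flag.
#' @export
significant_profile <- function(profile, z_threshold = 2.33,
                                run_length = 3, circular = TRUE) {
  z <- if (inherits(profile, "zprofile")) profile$z else profile
  stopifnot(length(z) == 24)
  if (run_length > 24) stop("run_length cannot exceed 24 bins")
  if (run_length < 1) stop("run_length must be >= 1")
  s <- z >= z_threshold
  if (all(s)) return(TRUE)
  if (circular && run_length > 1) s <- c(s, s[seq_len(run_length - 1)])
  r <- rle(s)
  any(r$values & r$lengths >= run_length)
}

#' Phase of a significant Z-score profile
#'
#' Treats the 24-bin profile as a time series on a 1-h grid and
#' pattern-matches it against phased cosines (via [correlate_gene()]),
#' returning the best-matching cosine phase. Defined only for significant
#' profiles.
#'
#' @param profile A `zprofile`, or a numeric vector of 24 Z-scores (assumed
#'   significant by the caller when a bare vector is given).
#' @return Profile phase in hours (0-23).
#' @export
profile_phase <- function(profile) {
  if (inherits(profile, "zprofile")) {
    if (!profile$significant)
      stop("profile phase is undefined for a non-significant profile")
    z <- profile$z
  } else z <- profile
  stopifnot(length(z) == 24)
  if (diff(range(z)) == 0) stop("constant profile has no phase")
  lib <- build_model_library(0:23, shapes = "cosine")
  correlate_gene(z, lib)$phase_h
}

#' Scan all 3-8-mer words for phase-specific promoter enrichment
#'
#' Enumerates every DNA word of each length in `k_min:k_max` that occurs in
#' at least one background promoter, and computes its 24-bin Z-score
#' profile in a single counting pass per word length
#' (`Biostrings::oligonucleotideFrequency`). Returns a table of per-word
#' summaries with the full Z matrix attached.
#'
#' @param calls A `cycling_calls` data.frame.
#' @param promoters A `promoter_set`.
#' @param k_min,k_max Word length range (within the guard 1-12; the
#'   pipeline default is 3-8).
#' @param both_strands Count a promoter as containing the word if either
#'   strand matches.
#' @param z_threshold,run_length Significance rule parameters.
#' @return A data.frame of class `zprofile_table`: `word`, `k`, `max_z`,
#'   `max_z_bin`, `significant`, `peak_phase_h`; the words x 24 Z matrix is
#'   in `attr(, "z")`.
#' @export
scan_all_words <- function(calls, promoters, k_min = 3, k_max = 8,
                           both_strands = TRUE, z_threshold = 2.33,
                           run_length = 3) {
  if (k_min > k_max) stop("k_min must be <= k_max")
  if (k_min < 1 || k_max > 12) stop("word lengths outside guard [1, 12]")
  background <- names(promoters$sequences)
  empty <- data.frame(word = character(), k = integer(), max_z = numeric(),
                      max_z_bin = integer(), significant = logical(),
                      peak_phase_h = numeric())
  if (length(background) == 0) {
    attr(empty, "z") <- matrix(numeric(0), 0, 24)
    class(empty) <- c("zprofile_table", "data.frame")
    return(empty)
  }
  ss <- Biostrings::DNAStringSet(promoters$sequences)
  bins <- .bin_indicator(calls, background)
  n_fg <- colSums(bins)

  res <- list()
  for (k in k_min:k_max) {
    cnt <- Biostrings::oligonucleotideFrequency(ss, width = k)
    pres <- cnt > 0
    if (both_strands) {
      rc <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAStringSet(colnames(pres))))
      pres <- pres | pres[, rc, drop = FALSE]
    }
    storage.mode(pres) <- "double"
    phat <- colMeans(pres)
    keep <- phat > 0
    if (!any(keep)) next
    pres <- pres[, keep, drop = FALSE]; phat <- phat[keep]
    kmat <- crossprod(pres, bins)             # words x 24
    z <- (kmat - outer(phat, n_fg)) /
      sqrt(outer(phat * (1 - phat), pmax(n_fg, 1)))
    z[phat >= 1, ] <- 0
    z[, n_fg == 0] <- 0
    res[[as.character(k)]] <- z
  }
  if (length(res) == 0) {
    attr(empty, "z") <- matrix(numeric(0), 0, 24)
    class(empty) <- c("zprofile_table", "data.frame")
    return(empty)
  }
  zall <- do.call(rbind, res)
  colnames(zall) <- 0:23
  sig <- apply(zall, 1L, significant_profile, z_threshold = z_threshold,
               run_length = run_length)
  peak <- rep(NA_real_, nrow(zall))
  if (any(sig)) {
    nonconst <- apply(zall, 1L, function(v) diff(range(v)) > 0)
    idx <- which(sig & nonconst)
    peak[idx] <- vapply(idx, function(i) profile_phase(zall[i, ]),
                        numeric(1))
  }
  out <- data.frame(word = rownames(zall), k = nchar(rownames(zall)),
                    max_z = apply(zall, 1L, max),
                    max_z_bin = apply(zall, 1L, which.max) - 1L,
                    significant = sig, peak_phase_h = peak,
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "z") <- zall
  class(out) <- c("zprofile_table", "data.frame")
  out
}

#' Cross-species conserved promoter elements
#'
#' A word is a conserved element when its Z-score profile is significant in
#' every species and the profile phases agree pairwise within `window_h`
#' hours of circular distance.
#'
#' @param profiles_by_species Named list (one entry per species, >= 2) of
#'   `zprofile_table`s from [scan_all_words()], or lists of `zprofile`s.
#' @param window_h Phase concordance window in hours (default 3).
#' @return Data.frame with `word`, one `phase_<species>` column per
#'   species, `max_pairwise_distance_h`, `conserved`. Rows cover words
#'   significant in every species.
#' @export
conserved_elements <- function(profiles_by_species, window_h = 3) {
  if (length(profiles_by_species) < 2) stop("need >= 2 species")
  species <- names(profiles_by_species)
  tabs <- lapply(profiles_by_species, function(p) {
    if (inherits(p, "data.frame")) p
    else data.frame(word = vapply(p, `[[`, character(1), "word"),
                    significant = vapply(p, `[[`, logical(1), "significant"),
                    peak_phase_h = vapply(p, `[[`, numeric(1),
                                          "peak_phase_h"))
  })
  nonempty <- vapply(tabs, nrow, integer(1)) > 0
  if (!all(nonempty)) {
    message("excluding species with no profiles: ",
            paste(species[!nonempty], collapse = ", "))
    tabs <- tabs[nonempty]; species <- species[nonempty]
    if (length(tabs) < 2) stop("fewer than 2 species with profiles")
  }
  sig_words <- Reduce(intersect, lapply(tabs, function(t) {
    t$word[t$significant]
  }))
  if (length(sig_words) == 0) {
    out <- data.frame(word = character())
    for (sp in species) out[[paste0("phase_", sp)]] <- numeric()
    out$max_pairwise_distance_h <- numeric()
    out$conserved <- logical()
    return(out)
  }
  phases <- vapply(tabs, function(t) {
    t$peak_phase_h[match(sig_words, t$word)]
  }, numeric(length(sig_words)))
  phases <- matrix(phases, nrow = length(sig_words),
                   dimnames = list(NULL, species))
  maxd <- apply(phases, 1L, function(ph) {
    max(utils::combn(ph, 2, function(p) circular_phase_distance(p[1], p[2])))
  })
  out <- data.frame(word = sig_words, stringsAsFactors = FALSE)
  for (sp in species) out[[paste0("phase_", sp)]] <- phases[, sp]
  out$max_pairwise_distance_h <- maxd
  out$conserved <- maxd <= window_h
  out
}
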