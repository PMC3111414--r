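#' Phased model waveforms
#'
#' Idealized 24-h waveforms used as templates for rhythm detection. Each
#' shape is parameterised by the phase `phase_h` (hours after dawn) at which
#' the waveform peaks; all have a fixed 24-h period.
#'
#' Shapes:
#' \describe{
#'   \item{cosine}{`cos(2*pi*(t - phase)/24)`.}
#'   \item{box}{1 on the half-day `[phase, phase + 12)` (mod 24), else 0.}
#'   \item{spike}{1 on `[phase, phase + width)` (mod 24), else 0, where
#'     `width` is the sampling interval of the grid.}
#'   \item{asym_rise}{sawtooth rising linearly over 24 h to a peak at
#'     `phase`, then dropping sharply.}
#'   \item{asym_fall}{sawtooth peaking at `phase`, then falling linearly
#'     over 24 h (sharp rise).}
#' }
#'
#' @param times_h Numeric vector of sampling times in hours.
#' @param phase_h Peak phase in hours, in `[0, 24)`.
#' @param spike_width_h Width of the spike shape in hours.
#' @return Numeric vector of waveform values at `times_h`.
#' @keywords internal
#' @name waveforms
NULL

MODEL_SHAPES <- c("cosine", "box", "spike", "asym_rise", "asym_fall")
PERIOD_H <- 24

#' @rdname waveforms
model_waveform <- function(shape, times_h, phase_h, spike_width_h = 4) {
  t24 <- times_h %% PERIOD_H
  rel <- (t24 - phase_h) %% PERIOD_H
  switch(shape,
    cosine = cos(2 * pi * (times_h - phase_h) / PERIOD_H),
    box = as.numeric(rel < 12),
    spike = as.numeric(rel < spike_width_h),
    # rises over the full period to peak exactly at phase_h, sharp drop
    asym_rise = (PERIOD_H - ((phase_h - t24) %% PERIOD_H)) / PERIOD_H,
    # peaks at phase_h, then falls linearly; sharp rise at the peak
    asym_fall = (PERIOD_H - rel) / PERIOD_H,
    stop("unknown model shape: ", shape)
  )
}

#' Build a library of phased model patterns
#'
#' Constructs every (shape, phase) combination sampled on a common time
#' grid. Patterns whose sampled values are constant on the grid (possible on
#' pathological grids, e.g. a spike falling between samples) are excluded
#' with a warning, since Pearson correlation is undefined against them.
#'
#' Patterns are ordered so that ties in correlation resolve
#' deterministically: cosine shapes first, then by ascending phase, then by
#' shape label.
#'
#' @param times_h Sampling grid in hours (strictly increasing, >= 2 points).
#' @param shapes Character vector of shapes to enable (subset of
#'   `c("cosine", "box", "spike", "asym_rise", "asym_fall")`).
#' @param phases Integer phases in hours, default `0:23`.
#' @return An object of class `model_library`: a list with `patterns`
#'   (data.frame of shape and phase_h), `samples` (matrix, one column per
#'   pattern), and `times_h`.
#' @examples
#' lib <- build_model_library(seq(0, 48, by = 4))
#' nrow(lib$patterns)  # 5 shapes x 24 phases = 120
#' @export
build_model_library <- function(times_h, shapes = MODEL_SHAPES,
                                phases = 0:23) {
  stopifnot(length(times_h) >= 2, !is.unsorted(times_h, strictly = TRUE))
  shapes <- match.arg(shapes, MODEL_SHAPES, several.ok = TRUE)
  if (length(shapes) == 0L) stop("at least one model shape required")
  if (any(phases < 0 | phases >= 24)) stop("phases must lie in [0, 24)")
  spike_w <- min(diff(times_h))

  grid <- expand.grid(phase_h = sort(unique(phases)), shape = shapes,
                      stringsAsFactors = FALSE)
  # tie-break order: cosine first, then lower phase, then shape label
  grid <- grid[order(grid$shape != "cosine", grid$phase_h, grid$shape), ]
  samples <- mapply(function(sh, ph) {
    model_waveform(sh, times_h, ph, spike_width_h = spike_w)
  }, grid$shape, grid$phase_h)
  colnames(samples) <- paste(grid$shape, grid$phase_h, sep = "_")

  const <- apply(samples, 2L, function(v) diff(range(v)) < 1e-12)
  if (any(const)) {
    warning(sum(const), " constant sampled pattern(s) excluded: ",
            paste(colnames(samples)[const], collapse = ", "))
    samples <- samples[, !const, drop = FALSE]
    grid <- grid[!const, , drop = FALSE]
  }
  if (nrow(grid) == 0L) stop("no usable model patterns on this grid")

  structure(
    list(patterns = data.frame(shape = grid$shape, phase_h = grid$phase_h,
                               row.names = NULL),
         samples = samples, times_h = times_h),
    class = "model_library")
}

#' @export
print.model_library <- function(x, ...) {
  cat("model_library:", nrow(x$patterns), "patterns (",
      paste(unique(x$patterns$shape), collapse = ", "), ") on",
      length(x$times_h), "time points\n")
  invisible(x)
}
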