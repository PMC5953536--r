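# Fluorescence trace extraction, neuropil correction, and per-trial
# delta-F/F0 computation.

#' Extract per-ROI fluorescence traces
#'
#' For each ROI (and its neuropil annulus), the trace value at frame `t` is
#' the mean of the frame over the ROI's (annulus's) pixels.
#'
#' @param movie a registered [movie_stack()].
#' @param rois a `roi_set` from [detect_rois()] (or any list with elements
#'   `rois` and `neuropil` of linear pixel-index vectors).
#' @return A list with `roi` and `neuropil`, each an `n_rois x T` matrix.
#' @export
extract_traces <- function(movie, rois) {
  movie <- .as_movie(movie)
  d <- dim(movie$frames)
  if (any(lengths(rois$rois) == 0)) stop("empty ROI in roi set")
  if (max(unlist(rois$rois), 0) > d[2] * d[3])
    stop("ROI pixels fall outside the frame")
  n <- length(rois$rois)
  f_roi <- matrix(0, n, d[1])
  f_np <- matrix(0, n, d[1])
  for (t in seq_len(d[1])) {
    frame <- movie$frames[t, , ]
    for (i in seq_len(n)) {
      f_roi[i, t] <- mean(frame[rois$rois[[i]]])
      np <- rois$neuropil[[i]]
      f_np[i, t] <- if (length(np)) mean(frame[np]) else 0
    }
  }
  list(roi = f_roi, neuropil = f_np)
}

#' Neuropil correction
#'
#' Subtracts a fixed fraction of the annulus signal from the somatic trace:
#' `corrected = F - r * F_np`, with the standard correction index
#' `r = 0.7`.
#'
#' @param f somatic trace (vector, or `n x T` matrix of traces).
#' @param f_np neuropil trace(s), same shape as `f`.
#' @param r correction index in `[0, 1]`.
#' @return Corrected trace(s), same shape as `f`.
#' @examples
#' neuropil_correct(1.0, 0.5)  # 1.0 - 0.7 * 0.5 = 0.65
#' @export
neuropil_correct <- function(f, f_np, r = 0.7) {
  if (r < 0 || r > 1) stop("`r` must lie in [0, 1]")
  if (length(f) != length(f_np))
    stop("somatic and neuropil traces differ in length")
  f - r * f_np
}

#' Per-trial delta-F/F0 responses from one corrected trace
#'
#' For each trial-table row, `F0` is the mean trace over the blank (OFF)
#' window and `F` the mean over the stimulus (ON) window; the response is
#' `(F - F0) / F0`. A non-positive baseline aborts with the offending
#' trial named, rather than silently propagating degenerate ratios.
#'
#' @param trace corrected fluorescence trace (length >= the last ON frame).
#' @param trial_table a [make_trial_table()]-format table.
#' @return A data.frame with columns `trial`, `stimulus`, `f0`, `f`, `dff`.
#' @export
compute_dff <- function(trace, trial_table) {
  validate_trial_table(trial_table)
  if (max(trial_table$on_end) > length(trace))
    stop("trial windows extend beyond the trace")
  n <- nrow(trial_table)
  f0 <- f <- numeric(n)
  for (r in seq_len(n)) {
    f0[r] <- mean(trace[.window_frames(trial_table[r, ], "off")])
    f[r] <- mean(trace[.window_frames(trial_table[r, ], "on")])
    if (f0[r] <= 0)
      stop(sprintf(
        "non-positive baseline F0 = %.4g in trial %d (stimulus %d)",
        f0[r], trial_table$trial[r], trial_table$stimulus[r]))
  }
  data.frame(trial = trial_table$trial, stimulus = trial_table$stimulus,
             f0 = f0, f = f, dff = (f - f0) / f0)
}

#' Movie + ROIs to response tensor
#'
#' Convenience wrapper running [extract_traces()], [neuropil_correct()] and
#' [compute_dff()] for every ROI and assembling the
#' trials x stimuli x neurons response tensor.
#'
#' @param movie a registered [movie_stack()].
#' @param rois a `roi_set`.
#' @param trial_table a [make_trial_table()]-format table.
#' @param r neuropil-correction index (default 0.7).
#' @return A [response_tensor()] of dimension
#'   `max(trial) x max(stimulus) x n_rois`.
#' @export
extract_response_tensor <- function(movie, rois, trial_table, r = 0.7) {
  validate_trial_table(trial_table)
  traces <- extract_traces(movie, rois)
  n <- nrow(traces$roi)
  R <- max(trial_table$trial); S <- max(trial_table$stimulus)
  x <- array(NA_real_, c(R, S, n))
  for (i in seq_len(n)) {
    corrected <- neuropil_correct(traces$roi[i, ], traces$neuropil[i, ], r)
    df <- compute_dff(corrected, trial_table)
    x[cbind(df$trial, df$stimulus, i)] <- df$dff
  }
  if (anyNA(x))
    stop("trial table does not cover the full trial x stimulus grid")
  response_tensor(x)
}
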