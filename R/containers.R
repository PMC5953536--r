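# Core data containers: movie stacks, trial tables, response tensors,
# and their plain-text on-disk formats.

#' Construct a movie stack
#'
#' A movie stack is a `T x H x W` array of non-negative fluorescence values
#' (arbitrary units) together with its acquisition frame rate.
#'
#' @param frames numeric array with dimensions `T x H x W` (frames, rows,
#'   columns), all values finite.
#' @param frame_rate acquisition rate in frames per second.
#' @return An object of class `movie_stack`: a list with elements `frames`
#'   and `frame_rate`.
#' @examples
#' mov <- movie_stack(array(1, c(4, 8, 8)))
#' dim(mov$frames)
#' @export
movie_stack <- function(frames, frame_rate = 8) {
  if (!is.array(frames) || length(dim(frames)) != 3L)
    stop("`frames` must be a T x H x W array")
  if (dim(frames)[1] < 1L) stop("movie must contain at least one frame")
  if (!all(is.finite(frames))) stop("movie contains non-finite values")
  if (!is.numeric(frame_rate) || frame_rate <= 0)
    stop("`frame_rate` must be positive")
  structure(list(frames = frames, frame_rate = frame_rate),
            class = "movie_stack")
}

#' @export
print.movie_stack <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("movie_stack: %d frames of %d x %d px at %g fps\n",
              d[1], d[2], d[3], x$frame_rate))
  invisible(x)
}

.as_movie <- function(movie) {
  if (inherits(movie, "movie_stack")) return(movie)
  if (is.array(movie) && length(dim(movie)) == 3L) return(movie_stack(movie))
  stop("expected a movie_stack or a T x H x W array")
}

#' Build a trial table
#'
#' The trial table maps each stimulus presentation to its blank (OFF) and
#' stimulus (ON) frame windows. Frame indices are 0-based and windows are
#' half-open (`start` inclusive, `end` exclusive), matching the on-disk CSV
#' format. The default layout presents every stimulus once per repeat, in
#' stimulus order, with 1 s blank followed by 1 s stimulus at 8 fps
#' (8 OFF + 8 ON frames per presentation).
#'
#' @param n_stimuli number of distinct stimuli.
#' @param n_trials number of repeats of the whole stimulus set.
#' @param frames_off,frames_on frames per blank / stimulus period.
#' @return A `data.frame` with columns `trial`, `stimulus`, `off_start`,
#'   `off_end`, `on_start`, `on_end`.
#' @examples
#' head(make_trial_table(3, 2))
#' @export
make_trial_table <- function(n_stimuli, n_trials = 3, frames_off = 8,
                             frames_on = 8) {
  if (n_stimuli < 1 || n_trials < 1) stop("need at least one stimulus and trial")
  if (frames_off < 1 || frames_on < 1) stop("windows must contain >= 1 frame")
  per <- frames_off + frames_on
  idx <- 0L
  rows <- vector("list", n_stimuli * n_trials)
  for (tr in seq_len(n_trials)) {
    for (s in seq_len(n_stimuli)) {
      start <- idx * per
      rows[[idx + 1L]] <- data.frame(
        trial = tr, stimulus = s,
        off_start = start, off_end = start + frames_off,
        on_start = start + frames_off, on_end = start + per)
      idx <- idx + 1L
    }
  }
  tt <- do.call(rbind, rows)
  validate_trial_table(tt)
  tt
}

#' Validate a trial table
#'
#' Checks the schema and the window invariants: integer 0-based half-open
#' windows, OFF before ON, non-overlapping within a trial row.
#'
#' @param trial_table data.frame as produced by [make_trial_table()].
#' @return The table, invisibly; signals an error describing the first
#'   violation otherwise.
#' @export
validate_trial_table <- function(trial_table) {
  need <- c("trial", "stimulus", "off_start", "off_end", "on_start", "on_end")
  miss <- setdiff(need, names(trial_table))
  if (length(miss))
    stop("trial table is missing columns: ", paste(miss, collapse = ", "))
  w <- trial_table[, c("off_start", "off_end", "on_start", "on_end")]
  if (!all(vapply(w, is.numeric, TRUE)) || !all(unlist(w) == round(unlist(w))))
    stop("window columns must be integer frame indices")
  if (any(w$off_start < 0)) stop("negative frame index in trial table")
  if (any(w$off_end <= w$off_start) || any(w$on_end <= w$on_start))
    stop("empty frame window in trial table")
  if (any(w$on_start < w$off_end))
    stop("OFF window must precede and not overlap the ON window")
  if (anyDuplicated(trial_table[, c("trial", "stimulus")]))
    stop("duplicate (trial, stimulus) presentation in trial table")
  invisible(trial_table)
}

#' Read / write trial tables as CSV
#'
#' @param path file path.
#' @return `read_trial_table` returns a validated data.frame.
#' @rdname trial_table_io
#' @export
read_trial_table <- function(path) {
  tt <- utils::read.csv(path)
  validate_trial_table(tt)
  tt
}

#' @param trial_table table to write.
#' @rdname trial_table_io
#' @export
write_trial_table <- function(trial_table, path) {
  validate_trial_table(trial_table)
  utils::write.csv(trial_table, path, row.names = FALSE)
  invisible(path)
}

# 1-based inclusive frame indices for one table row's window
.window_frames <- function(row, which = c("on", "off")) {
  which <- match.arg(which)
  a <- row[[paste0(which, "_start")]]
  b <- row[[paste0(which, "_end")]]
  seq.int(a + 1L, b)
}

#' Construct a response tensor
#'
#' A response tensor holds delta-F/F0 responses as a
#' `trials x stimuli x neurons` array. Most analysis functions accept either
#' this class or a bare 3-D array.
#'
#' @param values numeric array `R x S x N`, all finite.
#' @return The array with class `response_tensor`.
#' @examples
#' x <- response_tensor(array(0, c(3, 5, 4)))
#' dim(x)
#' @export
response_tensor <- function(values) {
  if (!is.array(values) || length(dim(values)) != 3L)
    stop("`values` must be a trials x stimuli x neurons array")
  if (!all(is.finite(values))) stop("response tensor contains non-finite values")
  structure(values, class = c("response_tensor", "array"))
}

.as_tensor <- function(x) {
  if (inherits(x, "response_tensor")) return(unclass(x))
  if (is.array(x) && length(dim(x)) == 3L) {
    if (!all(is.finite(x))) stop("response tensor contains non-finite values")
    return(x)
  }
  stop("expected a response_tensor or a 3-D array (trials x stimuli x neurons)")
}

#' @export
print.response_tensor <- function(x, ...) {
  d <- dim(x)
  cat(sprintf("response_tensor: %d trials x %d stimuli x %d neurons\n",
              d[1], d[2], d[3]))
  cat(sprintf("  delta-F/F0 range [%.3g, %.3g]\n", min(x), max(x)))
  invisible(x)
}

#' Read / write a response tensor as long-format CSV
#'
#' The on-disk format is a long table with columns `trial`, `stimulus`,
#' `neuron` (1-based integer ids) and `dff`.
#'
#' @param tensor a response tensor (or 3-D array).
#' @param path file path.
#' @rdname tensor_io
#' @export
write_tensor_csv <- function(tensor, path) {
  x <- .as_tensor(tensor)
  d <- dim(x)
  idx <- arrayInd(seq_along(x), d)
  df <- data.frame(trial = idx[, 1], stimulus = idx[, 2], neuron = idx[, 3],
                   dff = as.vector(x))
  df <- df[order(df$trial, df$stimulus, df$neuron), ]
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname tensor_io
#' @export
read_tensor_csv <- function(path) {
  df <- utils::read.csv(path)
  need <- c("trial", "stimulus", "neuron", "dff")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("tensor CSV is missing columns: ", paste(miss, collapse = ", "))
  d <- c(max(df$trial), max(df$stimulus), max(df$neuron))
  if (nrow(df) != prod(d))
    stop("tensor CSV is not a complete trial x stimulus x neuron grid")
  x <- array(NA_real_, d)
  x[cbind(df$trial, df$stimulus, df$neuron)] <- df$dff
  response_tensor(x)
}

#' Read / write multi-page TIFF movies
#'
#' Movies are stored as 32-bit multi-page TIFF, one page per frame. The TIFF
#' payload is normalized to `[0, 1]`; the intensity scale and frame rate are
#' kept in a small JSON sidecar (`<path>.json`) so raw fluorescence units
#' round-trip.
#'
#' @param movie a [movie_stack()].
#' @param path file path.
#' @param scale full-scale intensity mapped to 1.0 in the TIFF; by default
#'   the smallest power of two not below the movie maximum.
#' @param frame_rate frame rate to use when the sidecar is absent.
#' @rdname movie_io
#' @export
write_movie_tiff <- function(movie, path, scale = NULL) {
  movie <- .as_movie(movie)
  if (min(movie$frames) < 0) stop("movie contains negative intensities")
  if (is.null(scale))
    scale <- 2^max(0, ceiling(log2(max(movie$frames, 1e-12))))
  n <- dim(movie$frames)[1]
  pages <- lapply(seq_len(n), function(i) movie$frames[i, , ] / scale)
  tiff::writeTIFF(pages, path, bits.per.sample = 32L, reduce = FALSE)
  jsonlite::write_json(list(scale = scale, frame_rate = movie$frame_rate),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname movie_io
#' @export
read_movie_tiff <- function(path, frame_rate = 8) {
  scale <- 1
  sidecar <- paste0(path, ".json")
  if (file.exists(sidecar)) {
    meta <- jsonlite::read_json(sidecar)
    scale <- meta$scale
    frame_rate <- meta$frame_rate
  }
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  frames <- array(0, c(length(pages), dim(pages[[1]])[1], dim(pages[[1]])[2]))
  for (i in seq_along(pages)) frames[i, , ] <- pages[[i]] * scale
  movie_stack(frames, frame_rate = frame_rate)
}
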