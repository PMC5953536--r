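# Ground-truth simulator: sparse tuning matrices, noisy trial tensors, and
# small fluorescence movies with planted ROIs, neuropil and rigid motion.

#' Generate a sparse ground-truth tuning matrix
#'
#' Builds an `S x N` non-negative matrix of mean delta-F/F0 responses in
#' which each stimulus strongly drives exactly `k_strong` neurons and all
#' other responses are weak. Strong responders are assigned by chunking
#' concatenated random permutations of the neuron set, so per-stimulus
#' subsets are random while every neuron is guaranteed a strong response to
#' at least one stimulus whenever `S * k_strong >= N` (flat-tuned "orphan"
#' neurons would otherwise make half-max sparseness counts meaningless).
#' Strong amplitudes are jittered uniformly in
#' `[amp_strong, 1.25 * amp_strong]`; weak responses are half-normal with
#' scale `weak_scale`.
#'
#' @param n_stimuli,n_neurons matrix dimensions S and N.
#' @param k_strong number of strong responders per stimulus.
#' @param amp_strong minimum strong-response amplitude (delta-F/F0 units).
#' @param weak_scale half-normal scale of weak background responses; `0`
#'   gives exact zeros off the strong set.
#' @param seed integer seed; fully determines the output.
#' @return An object of class `tuning_matrix`: a list with `values`
#'   (`S x N` matrix), `strong` (logical `S x N` ground-truth mask),
#'   `k_strong`, `amp_strong`, `weak_scale`, `seed`.
#' @examples
#' tm <- generate_tuning_matrix(20, 10, k_strong = 1, seed = 1)
#' rowSums(tm$strong)
#' @export
generate_tuning_matrix <- function(n_stimuli, n_neurons, k_strong = 1,
                                   amp_strong = 1, weak_scale = 0.05,
                                   seed = 1) {
  if (k_strong < 1 || k_strong > n_neurons)
    stop("`k_strong` must be between 1 and `n_neurons`")
  if (amp_strong <= 0) stop("`amp_strong` must be positive")
  if (weak_scale < 0) stop("`weak_scale` must be non-negative")
  S <- as.integer(n_stimuli); N <- as.integer(n_neurons)
  k <- as.integer(k_strong)
  withr_seed(seed, {
    # balanced assignment: chunk concatenated permutations of 1..N
    need <- S * k
    pool <- integer(0)
    while (length(pool) < need) pool <- c(pool, sample.int(N))
    strong <- matrix(FALSE, S, N)
    for (s in seq_len(S)) {
      chunk <- pool[((s - 1L) * k + 1L):(s * k)]
      dup <- duplicated(chunk)
      if (any(dup)) { # permutation boundary may duplicate within a chunk
        repl <- sample(setdiff(seq_len(N), chunk), sum(dup))
        chunk[dup] <- repl
      }
      strong[s, chunk] <- TRUE
    }
    values <- matrix(abs(stats::rnorm(S * N)) * weak_scale, S, N)
    n_strong <- sum(strong)
    values[strong] <- amp_strong * (1 + 0.25 * stats::runif(n_strong))
    structure(list(values = values, strong = strong, k_strong = k,
                   amp_strong = amp_strong, weak_scale = weak_scale,
                   seed = seed),
              class = "tuning_matrix")
  })
}

#' @export
print.tuning_matrix <- function(x, ...) {
  cat(sprintf(paste0("tuning_matrix: %d stimuli x %d neurons, ",
                     "k_strong = %d (amp >= %g, weak scale %g)\n"),
              nrow(x$values), ncol(x$values), x$k_strong, x$amp_strong,
              x$weak_scale))
  invisible(x)
}

.as_tuning <- function(tuning) {
  if (inherits(tuning, "tuning_matrix")) return(tuning$values)
  if (is.matrix(tuning)) return(tuning)
  stop("expected a tuning_matrix or an S x N matrix")
}

# evaluate `expr` under a temporary RNG state seeded with `seed`;
# NULL seed runs in the caller's RNG stream
withr_seed <- function(seed, expr) {
  if (is.null(seed)) expr else withr::with_seed(seed, expr)
}

#' Generate a noisy trial response tensor from a tuning matrix
#'
#' Each trial equals the tuning matrix plus independent Gaussian noise, then
#' (by default) floored at zero so that the tensor stays in the non-negative
#' range of delta-F/F0 responses.
#'
#' @param tuning a [generate_tuning_matrix()] result or `S x N` matrix.
#' @param n_trials number of trials (repeats of the stimulus set).
#' @param noise_sd trial-noise standard deviation (delta-F/F0 units).
#' @param seed integer seed; fully determines the output.
#' @param floor_at_zero floor noisy responses at 0 (default `TRUE`).
#' @return A list with `responses` (a [response_tensor()], `n_trials x S x N`)
#'   and `ground_truth` (tuning object and generator parameters).
#' @examples
#' tm <- generate_tuning_matrix(10, 5, seed = 1)
#' sim <- generate_response_tensor(tm, n_trials = 3, noise_sd = 0.1, seed = 2)
#' dim(sim$responses)
#' @export
generate_response_tensor <- function(tuning, n_trials = 3, noise_sd = 0.1,
                                     seed = 1, floor_at_zero = TRUE) {
  if (n_trials < 1) stop("`n_trials` must be >= 1")
  if (noise_sd < 0) stop("`noise_sd` must be non-negative")
  tm <- .as_tuning(tuning)
  S <- nrow(tm); N <- ncol(tm); R <- as.integer(n_trials)
  x <- withr_seed(seed, {
    out <- array(0, c(R, S, N))
    for (t in seq_len(R)) {
      trial <- tm + matrix(stats::rnorm(S * N, sd = noise_sd), S, N)
      if (floor_at_zero) trial[trial < 0] <- 0
      out[t, , ] <- trial
    }
    out
  })
  list(responses = response_tensor(x),
       ground_truth = list(tuning = tuning, n_trials = R, noise_sd = noise_sd,
                           floor_at_zero = floor_at_zero, seed = seed))
}

#' Lay out non-overlapping disc ROIs on an imaging frame
#'
#' Places `n_rois` discs of the given radius on a regular grid inside an
#' `height x width` frame, leaving `margin` pixels free at the borders (so
#' that motion correction and neuropil annuli stay inside the frame).
#'
#' @param n_rois number of cell bodies to plant.
#' @param height,width frame size in pixels.
#' @param radius disc radius in pixels (a radius of 3 px gives a 29-pixel
#'   soma; 4 px gives 49 pixels).
#' @param margin border kept free of ROI pixels.
#' @param spacing center-to-center grid spacing; defaults to
#'   `2 * radius + 12` which leaves room for a neuropil annulus between
#'   neighbours.
#' @return An object of class `roi_layout`: list with `height`, `width` and
#'   `rois`, a list of linear pixel-index vectors (column-major, as used by
#'   R matrices).
#' @examples
#' lay <- roi_layout(4, 64, 64, radius = 3)
#' lengths(lay$rois)
#' @export
roi_layout <- function(n_rois, height, width, radius = 4, margin = 10,
                       spacing = 2 * radius + 12) {
  if (n_rois < 1) stop("`n_rois` must be >= 1")
  if (spacing < 2 * radius + 1)
    stop("`spacing` too small: planted ROIs would overlap")
  centers_y <- seq(margin + radius + 1, height - margin - radius, by = spacing)
  centers_x <- seq(margin + radius + 1, width - margin - radius, by = spacing)
  if (length(centers_y) * length(centers_x) < n_rois)
    stop(sprintf("frame %d x %d fits only %d ROIs at radius %d, need %d",
                 height, width, length(centers_y) * length(centers_x),
                 radius, n_rois))
  grid <- expand.grid(y = centers_y, x = centers_x)
  rois <- vector("list", n_rois)
  for (i in seq_len(n_rois)) {
    cy <- grid$y[i]; cx <- grid$x[i]
    yy <- (cy - radius):(cy + radius)
    xx <- (cx - radius):(cx + radius)
    px <- expand.grid(y = yy, x = xx)
    keep <- (px$y - cy)^2 + (px$x - cx)^2 <= radius^2
    rois[[i]] <- sort((px$x[keep] - 1L) * height + px$y[keep])
  }
  if (anyDuplicated(unlist(rois))) stop("planted ROIs overlap")
  structure(list(height = height, width = width, rois = rois),
            class = "roi_layout")
}

#' Render a synthetic fluorescence movie with planted ground truth
#'
#' Builds a `T x H x W` movie from per-trial delta-F/F0 targets: background
#' pixels carry the neuropil trace, each planted ROI carries
#' `f0 * (1 + dff)` plus a fraction `neuropil_r` of the neuropil trace
#' (so that annulus-based correction at the same index recovers the planted
#' responses exactly), and each frame can be rigidly translated and
#' corrupted with Gaussian noise.
#'
#' @param responses per-trial delta-F/F0 targets: a `R x S x N` tensor from
#'   [generate_response_tensor()] (its `responses` element) or a
#'   `tuning_matrix` (targets identical across trials).
#' @param layout a [roi_layout()] with `N` ROIs.
#' @param trial_table a [make_trial_table()] table with `R` trials and `S`
#'   stimuli.
#' @param f0 per-ROI baseline fluorescence (scalar or length-`N` vector).
#' @param neuropil_level mean neuropil fluorescence.
#' @param neuropil_r fraction of the neuropil signal contaminating ROI
#'   pixels (matched by the extraction-side correction index).
#' @param neuropil_fluct_sd per-frame fractional fluctuation of the neuropil
#'   trace.
#' @param frame_noise_sd per-pixel Gaussian noise SD, in fluorescence units.
#' @param shifts optional `T x 2` matrix (or data.frame) of planted integer
#'   translations `(dy, dx)` applied to each frame; `NULL` for none.
#' @param frame_rate frames per second.
#' @param seed integer seed for the noise and neuropil fluctuation.
#' @return A [movie_stack()] of `max(on_end)` frames.
#' @examples
#' tm <- generate_tuning_matrix(4, 4, seed = 1, weak_scale = 0)
#' lay <- roi_layout(4, 64, 64, radius = 3)
#' tt <- make_trial_table(4, 1)
#' mov <- generate_movie(tm, lay, tt)
#' dim(mov$frames)
#' @export
generate_movie <- function(responses, layout, trial_table, f0 = 100,
                           neuropil_level = 30, neuropil_r = 0.7,
                           neuropil_fluct_sd = 0, frame_noise_sd = 0,
                           shifts = NULL, frame_rate = 8, seed = 1) {
  validate_trial_table(trial_table)
  if (!inherits(layout, "roi_layout")) stop("`layout` must be a roi_layout")
  if (inherits(responses, "tuning_matrix") || is.matrix(responses)) {
    tm <- .as_tuning(responses)
    R <- max(trial_table$trial)
    x <- array(0, c(R, nrow(tm), ncol(tm)))
    for (t in seq_len(R)) x[t, , ] <- tm
  } else {
    x <- .as_tensor(responses)
  }
  R <- dim(x)[1]; S <- dim(x)[2]; N <- dim(x)[3]
  if (length(layout$rois) != N)
    stop(sprintf("layout has %d ROIs but responses have %d neurons",
                 length(layout$rois), N))
  if (max(trial_table$trial) > R || max(trial_table$stimulus) > S)
    stop("trial table refers to trials/stimuli outside the response tensor")
  H <- layout$height; W <- layout$width
  if (max(unlist(layout$rois)) > H * W) stop("planted ROI outside the frame")
  f0 <- rep_len(f0, N)
  if (any(f0 <= 0)) stop("`f0` must be positive")
  n_frames <- max(trial_table$on_end)
  if (!is.null(shifts)) {
    shifts <- as.matrix(shifts)
    if (nrow(shifts) != n_frames || ncol(shifts) != 2)
      stop("`shifts` must be a T x 2 matrix of (dy, dx)")
    if (any(shifts != round(shifts))) stop("planted shifts must be integer")
  }
  # per-frame ON state: stimulus shown (0 = none), per trial row
  frame_trial <- integer(n_frames)   # row of trial_table owning the ON window
  for (r in seq_len(nrow(trial_table))) {
    on <- .window_frames(trial_table[r, ], "on")
    if (max(on) > n_frames) stop("trial window beyond movie length")
    frame_trial[on] <- r
  }
  withr_seed(seed, {
    np <- neuropil_level *
      (1 + stats::rnorm(n_frames, sd = neuropil_fluct_sd))
    np <- pmax(np, 0)
    frames <- array(0, c(n_frames, H, W))
    for (f in seq_len(n_frames)) {
      img <- matrix(np[f], H, W)
      r <- frame_trial[f]
      for (i in seq_len(N)) {
        dff <- if (r > 0)
          x[trial_table$trial[r], trial_table$stimulus[r], i] else 0
        img[layout$rois[[i]]] <- f0[i] * (1 + dff) + neuropil_r * np[f]
      }
      if (frame_noise_sd > 0)
        img <- img + matrix(stats::rnorm(H * W, sd = frame_noise_sd), H, W)
      if (!is.null(shifts) && any(shifts[f, ] != 0))
        img <- shift_image(img, shifts[f, 1], shifts[f, 2], fill = np[f])
      img[img < 0] <- 0
      frames[f, , ] <- img
    }
    movie_stack(frames, frame_rate = frame_rate)
  })
}
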