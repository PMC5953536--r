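# S-way nearest-centroid stimulus decoding with leave-one-trial-out
# cross-validation, and top-only / top-excluded response thresholding in
# absolute and peak-relative modes.

#' Train a nearest-centroid model with one trial held out
#'
#' The centroid matrix is the element-wise mean of all trials except the
#' held-out one (e.g. with three trials and trial 1 held out,
#' `C = (X2 + X3) / 2`).
#'
#' @param tensor a [response_tensor()] with at least two trials.
#' @param held_out_trial index of the trial excluded from training.
#' @return An object of class `centroid_model`: list with `centroids`
#'   (`S x N` matrix) and `held_out_trial`.
#' @export
train_centroids <- function(tensor, held_out_trial) {
  x <- .as_tensor(tensor)
  R <- dim(x)[1]
  if (R < 2) stop("cannot cross-validate with a single trial")
  if (held_out_trial < 1 || held_out_trial > R)
    stop("`held_out_trial` out of range")
  rest <- x[-held_out_trial, , , drop = FALSE]
  centroids <- if (dim(rest)[1] == 1L) rest[1, , ] else colMeans(rest)
  structure(list(centroids = centroids, held_out_trial = held_out_trial),
            class = "centroid_model")
}

#' Predict stimulus identity by nearest centroid
#'
#' Assigns each population response vector to the stimulus whose centroid
#' row is nearest in Euclidean distance; distance ties are broken towards
#' the smallest stimulus index.
#'
#' @param x an `N`-vector (one population response) or an `M x N` matrix of
#'   responses in rows.
#' @param model a [train_centroids()] model.
#' @return Integer stimulus index (or vector of `M` indices).
#' @export
predict_stimulus <- function(x, model) {
  C <- model$centroids
  if (is.null(dim(x))) x <- matrix(x, 1)
  if (ncol(x) != ncol(C))
    stop("response vector length does not match the number of neurons")
  d2 <- outer(rowSums(x^2), rowSums(C^2), "+") - 2 * tcrossprod(x, C)
  # squared distances can dip microscopically below the true value; snap
  # near-ties to a common level so index tie-breaking is exact
  d2 <- round(d2, 9)
  max.col(-d2, ties.method = "first")
}

#' Cross-validated nearest-centroid decoding accuracy
#'
#' Leave-one-trial-out cross-validation: for each trial, a centroid model
#' is trained on the remaining trials and every stimulus row of the
#' held-out trial is decoded; the reported accuracy is the mean over
#' trials of the per-trial fraction of correctly decoded stimuli.
#'
#' @param tensor a [response_tensor()] with at least two trials.
#' @return Decoding accuracy in `[0, 1]`, with attribute `per_trial`.
#' @export
cross_validated_accuracy <- function(tensor) {
  x <- .as_tensor(tensor)
  R <- dim(x)[1]; S <- dim(x)[2]
  if (R < 2) stop("cannot cross-validate with a single trial")
  per_trial <- vapply(seq_len(R), function(t) {
    model <- train_centroids(x, t)
    pred <- predict_stimulus(x[t, , ], model)
    mean(pred == seq_len(S))
  }, 0)
  structure(mean(per_trial), per_trial = per_trial)
}

#' The standard percentage grid for thresholded decoding
#'
#' @return The 29-point grid `0, 0.1, ..., 0.9, 1, 2, ..., 10, 20, ..., 90,
#'   99` (percent).
#' @export
decoding_percentages <- function() {
  c(seq(0, 0.9, by = 0.1), 1:10, seq(20, 90, by = 10), 99)
}

#' Keep or remove the top p% of responses
#'
#' Ranks all `R * S * N` tensor entries pooled across trials, stimuli and
#' neurons and either keeps only the largest `p%` (`top_only`, zeroing the
#' rest) or zeroes exactly those (`top_excluded`, keeping the rest). The
#' kept sets of the two variants are exact complements at every `p`.
#' Exactly `ceiling(p/100 * R*S*N)` entries form the top set; ties at the
#' cut value are resolved by a stable order (neuron, then stimulus, then
#' trial index).
#'
#' In `absolute` mode entries are ranked by raw delta-F/F0 value — the view
#' that downstream neurons see absolute signal strengths. In `relative`
#' mode entries are ranked by value divided by that neuron's peak
#' (maximum trial-mean over stimuli, computed on the input tensor), the
#' variant comparable with the per-neuron half-maximum sparseness measure;
#' entries of neurons with non-positive peaks rank last.
#'
#' @param tensor a [response_tensor()].
#' @param p percentage in `[0, 100]`.
#' @param keep `"top_only"` or `"top_excluded"`.
#' @param mode `"absolute"` (default) or `"relative"`.
#' @return The thresholded [response_tensor()]; `top_only` at `p = 100` and
#'   `top_excluded` at `p = 0` return the input unchanged.
#' @export
threshold_responses <- function(tensor, p,
                                keep = c("top_only", "top_excluded"),
                                mode = c("absolute", "relative")) {
  keep <- match.arg(keep)
  mode <- match.arg(mode)
  if (p < 0 || p > 100) stop("`p` must lie in [0, 100]")
  x <- .as_tensor(tensor)
  d <- dim(x)
  n <- length(x)
  m <- ceiling(p / 100 * n)
  rank_vals <- as.vector(x)
  if (mode == "relative") {
    peaks <- as.numeric(neuron_peaks(x))
    norm <- rep(peaks, each = d[1] * d[2])
    rank_vals <- ifelse(norm > 0, rank_vals / norm, -Inf)
  }
  idx <- arrayInd(seq_len(n), d)  # trial, stimulus, neuron
  ord <- order(-rank_vals, idx[, 3], idx[, 2], idx[, 1])
  top <- ord[seq_len(m)]
  out <- x
  if (keep == "top_only") {
    if (m < n) out[ord[(m + 1):n]] <- 0
  } else {
    if (m > 0) out[top] <- 0
  }
  response_tensor(out)
}

#' Decoding accuracy as a function of the response threshold
#'
#' Evaluates [cross_validated_accuracy()] on thresholded versions of the
#' tensor over a grid of percentages. Thresholding is applied to the whole
#' tensor before the cross-validation split, so training and test data are
#' thresholded alike. The untouched-data accuracy is returned as the
#' `full_accuracy` reference (the highest achievable decoding performance).
#'
#' @param tensor a [response_tensor()] with at least two trials.
#' @param percentages grid of percentages (default [decoding_percentages()]).
#' @param keep `"top_only"` or `"top_excluded"`.
#' @param mode `"absolute"` or `"relative"`, see [threshold_responses()].
#' @return An object of class `decoding_curve`: list with `curve`
#'   (data.frame `percentage`, `accuracy`), `full_accuracy`, `keep`,
#'   `mode`.
#' @export
decoding_curve <- function(tensor, percentages = decoding_percentages(),
                           keep = c("top_only", "top_excluded"),
                           mode = c("absolute", "relative")) {
  keep <- match.arg(keep)
  mode <- match.arg(mode)
  if (any(percentages < 0 | percentages > 100))
    stop("`percentages` must lie in [0, 100]")
  x <- .as_tensor(tensor)
  full <- as.numeric(cross_validated_accuracy(x))
  acc <- vapply(percentages, function(p) {
    as.numeric(cross_validated_accuracy(
      threshold_responses(x, p, keep = keep, mode = mode)))
  }, 0)
  structure(list(curve = data.frame(percentage = percentages,
                                    accuracy = acc),
                 full_accuracy = full, keep = keep, mode = mode),
            class = "decoding_curve")
}

#' @export
print.decoding_curve <- function(x, ...) {
  cat(sprintf("decoding_curve (%s, %s mode): full accuracy %.3f\n",
              x$keep, x$mode, x$full_accuracy))
  print(utils::head(x$curve, 12))
  if (nrow(x$curve) > 12) cat(sprintf("  ... %d more rows\n",
                                      nrow(x$curve) - 12))
  invisible(x)
}

#' Plot a decoding curve
#'
#' Accuracy against the percentage of strongest responses kept (red,
#' `top_only`) or removed (blue, `top_excluded`), with the full-data
#' reference accuracy as a dashed line.
#'
#' @param x a `decoding_curve` (further curves can be overlaid with
#'   `add = TRUE`).
#' @param add overlay on an existing plot.
#' @param ... passed to [graphics::lines()].
#' @export
plot.decoding_curve <- function(x, add = FALSE, ...) {
  col <- if (x$keep == "top_only") "red" else "blue"
  if (!add) {
    graphics::plot(NA, xlim = range(x$curve$percentage), ylim = c(0, 1),
                   xlab = "% of top responses", ylab = "decoding accuracy")
    graphics::abline(h = x$full_accuracy, lty = 2, col = "grey40")
  }
  graphics::lines(x$curve$percentage, x$curve$accuracy, type = "b",
                  pch = 4, col = col, ...)
  invisible(x)
}

#' Write a decoding curve as CSV (+ JSON summary)
#'
#' @param curve a `decoding_curve`.
#' @param csv_path destination for the `(keep, mode, percentage, accuracy)`
#'   table.
#' @param json_path optional JSON with `full_accuracy` and the accuracy at
#'   `p = 0.5` if that percentage is on the grid.
#' @export
write_decoding_curve <- function(curve, csv_path, json_path = NULL) {
  stopifnot(inherits(curve, "decoding_curve"))
  df <- cbind(keep = curve$keep, mode = curve$mode, curve$curve)
  utils::write.csv(df, csv_path, row.names = FALSE)
  if (!is.null(json_path)) {
    at05 <- curve$curve$accuracy[curve$curve$percentage == 0.5]
    jsonlite::write_json(
      list(full_accuracy = curve$full_accuracy, keep = curve$keep,
           mode = curve$mode,
           accuracy_at_0.5 = if (length(at05)) at05 else NULL),
      json_path, auto_unbox = TRUE, digits = NA)
  }
  invisible(csv_path)
}
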