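# Per-neuron reliability of sparse strong responses: ROC/AUC of ON vs OFF
# stimulus classes from single-trial responses, tested against a
# label-shuffle null.

#' Split stimuli into ON and OFF classes at half-maximum
#'
#' ON stimuli are those whose mean response strictly exceeds `thresh_frac`
#' times the maximum mean response; the peak stimulus is therefore always
#' ON.
#'
#' @param mean_responses vector of per-stimulus mean responses (length >= 2).
#' @param thresh_frac fraction of the maximum (default 0.5).
#' @return Logical vector, `TRUE` for ON stimuli.
#' @export
classify_on_off <- function(mean_responses, thresh_frac = 0.5) {
  if (length(mean_responses) < 2) stop("need at least two stimuli")
  mean_responses > thresh_frac * max(mean_responses)
}

#' ROC AUC by the rank-sum formulation
#'
#' The probability that a randomly chosen positive-class value exceeds a
#' randomly chosen negative-class value, with ties counting one half
#' (equivalent to the Mann-Whitney U statistic normalized by `n1 * n0`).
#'
#' @param values numeric response values.
#' @param labels logical (or 0/1) class labels, `TRUE` = positive (ON).
#' @return AUC in `[0, 1]`.
#' @examples
#' roc_auc(c(3, 1, 2, 0), c(TRUE, TRUE, FALSE, FALSE))  # 0.75
#' @export
roc_auc <- function(values, labels) {
  labels <- as.logical(labels)
  if (length(values) != length(labels))
    stop("`values` and `labels` differ in length")
  n1 <- sum(labels); n0 <- sum(!labels)
  if (n1 == 0 || n0 == 0)
    stop("AUC undefined: one class is empty")
  r <- rank(values)
  (sum(r[labels]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# test statistic of the shuffle test: AUC of ON vs OFF classes defined at
# half-maximum of the per-stimulus means, applied identically to observed
# and shuffled data; 0.5 when the OFF class is empty (no separable classes)
.onoff_auc <- function(values_rs, n_trials, n_stimuli, thresh_frac) {
  means <- colMeans(matrix(values_rs, n_trials, n_stimuli))
  on <- means > thresh_frac * max(means)
  if (all(on)) return(0.5)
  labels <- rep(on, each = n_trials)
  roc_auc(values_rs, labels)
}

#' Shuffle test of single-neuron response reliability
#'
#' Tests whether a neuron's sparse strong responses are reliable across
#' trials. The observed statistic is the ROC AUC for classifying ON versus
#' OFF stimuli (split at `thresh_frac` of the maximum mean response) from
#' single-trial responses. Under the null that strong responses are
#' spurious single-trial events, responses are exchangeable across
#' (trial, stimulus) slots: each shuffle permutes all `R * S` pooled
#' single-trial responses against the stimulus labels, recomputes the
#' per-stimulus means, the maximum, and the half-maximum threshold,
#' reclassifies ON/OFF, and recomputes the AUC. The p-value is the
#' fraction of shuffles whose AUC reaches (>=) the observed AUC, by
#' default with the permutation-test `(1 + b) / (1 + n)` convention so
#' that p is never exactly zero.
#'
#' @param trial_responses `R x S` matrix of single-trial responses for one
#'   neuron (trials in rows).
#' @param n_shuffles number of label shuffles (default 1000).
#' @param thresh_frac ON/OFF threshold as a fraction of the maximum mean.
#' @param seed optional integer seed for the shuffles.
#' @param add_one use the `(1 + b) / (1 + n)` convention (default `TRUE`);
#'   `FALSE` gives the plain fraction `b / n`.
#' @return An object of class `reliability_result`: list with `auc`,
#'   `shuffle_aucs`, `p_value`, `on_class` (ON stimulus indices),
#'   `n_shuffles`.
#' @export
shuffle_test <- function(trial_responses, n_shuffles = 1000,
                         thresh_frac = 0.5, seed = NULL, add_one = TRUE) {
  m <- as.matrix(trial_responses)
  R <- nrow(m); S <- ncol(m)
  if (R < 2) stop("need at least two trials")
  if (S < 2) stop("need at least two stimuli")
  v <- as.vector(m)  # column-major: trials vary fastest, matching rep(each=R)
  if (length(unique(v)) == 1L) {
    warning("all responses identical; reliability undefined, p = 1")
    return(structure(list(auc = 0.5,
                          shuffle_aucs = rep(0.5, n_shuffles),
                          p_value = 1, on_class = seq_len(S),
                          n_shuffles = n_shuffles),
                     class = "reliability_result"))
  }
  means <- colMeans(m)
  on <- classify_on_off(means, thresh_frac)
  obs <- .onoff_auc(v, R, S, thresh_frac)
  sh <- withr_seed(seed, {
    vapply(seq_len(n_shuffles), function(i)
      .onoff_auc(v[sample.int(R * S)], R, S, thresh_frac), 0)
  })
  b <- sum(sh >= obs)
  p <- if (add_one) (1 + b) / (1 + n_shuffles) else b / n_shuffles
  structure(list(auc = obs, shuffle_aucs = sh, p_value = p,
                 on_class = which(on), n_shuffles = n_shuffles),
            class = "reliability_result")
}

#' @export
print.reliability_result <- function(x, ...) {
  cat(sprintf(
    "reliability_result: AUC %.3f, p = %.4g (%d shuffles, %d ON stimuli)\n",
    x$auc, x$p_value, x$n_shuffles, length(x$on_class)))
  invisible(x)
}

#' Population-level reliability summary
#'
#' Runs [shuffle_test()] on every neuron of a response tensor and reports
#' the fraction of neurons whose sparse strong responses are reliable at
#' the given significance level.
#'
#' @param tensor a [response_tensor()] with at least two trials.
#' @param n_shuffles shuffles per neuron (default 1000).
#' @param thresh_frac ON/OFF threshold fraction (default 0.5).
#' @param alpha per-neuron significance level (default 0.01; no correction
#'   across neurons, matching the per-neuron criterion).
#' @param seed integer seed; the per-neuron shuffles are drawn from one
#'   seeded stream so results are reproducible.
#' @param add_one p-value convention, see [shuffle_test()].
#' @return An object of class `reliability_summary`: list with `per_neuron`
#'   (data.frame: `neuron`, `auc`, `p_value`, `n_on`), `fraction_reliable`,
#'   `alpha`, `n_shuffles`.
#' @export
reliability_summary <- function(tensor, n_shuffles = 1000, thresh_frac = 0.5,
                                alpha = 0.01, seed = 1, add_one = TRUE) {
  x <- .as_tensor(tensor)
  N <- dim(x)[3]
  res <- withr_seed(seed, {
    lapply(seq_len(N), function(i)
      shuffle_test(x[, , i], n_shuffles = n_shuffles,
                   thresh_frac = thresh_frac, seed = NULL,
                   add_one = add_one))
  })
  per_neuron <- data.frame(
    neuron = seq_len(N),
    auc = vapply(res, `[[`, 0, "auc"),
    p_value = vapply(res, `[[`, 0, "p_value"),
    n_on = vapply(res, function(r) length(r$on_class), 0L))
  structure(list(per_neuron = per_neuron,
                 fraction_reliable = mean(per_neuron$p_value < alpha),
                 alpha = alpha, n_shuffles = n_shuffles),
            class = "reliability_summary")
}

#' @export
print.reliability_summary <- function(x, ...) {
  cat(sprintf(
    "reliability_summary: %.1f%% of %d neurons reliable (p < %g, %d shuffles)\n",
    100 * x$fraction_reliable, nrow(x$per_neuron), x$alpha, x$n_shuffles))
  invisible(x)
}

#' Write a reliability summary (per-neuron CSV + JSON overview)
#'
#' @param summary a [reliability_summary()].
#' @param csv_path per-neuron table destination.
#' @param json_path overview destination (fraction reliable, alpha,
#'   shuffles).
#' @export
write_reliability_summary <- function(summary, csv_path, json_path = NULL) {
  stopifnot(inherits(summary, "reliability_summary"))
  utils::write.csv(summary$per_neuron, csv_path, row.names = FALSE)
  if (!is.null(json_path))
    jsonlite::write_json(
      list(fraction_reliable = summary$fraction_reliable,
           alpha = summary$alpha, n_shuffles = summary$n_shuffles),
      json_path, auto_unbox = TRUE, digits = NA)
  invisible(csv_path)
}
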