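# Half-maximum population and life-time sparseness, plus the classical
# Treves-Rolls measure for comparison.

# trial-mean S x N response matrix (dims preserved for S or N equal 1)
.trial_means <- function(tensor) {
  x <- .as_tensor(tensor)
  d <- dim(x)
  m <- colMeans(x)
  if (!is.matrix(m)) m <- matrix(m, d[2], d[3])
  m
}

#' Per-neuron peak responses
#'
#' For each neuron, the maximum over stimuli of its trial-mean response.
#' Neurons whose peak is not positive cannot define a half-maximum
#' threshold; they are flagged via the `excluded` attribute and skipped by
#' the sparseness counts.
#'
#' @param tensor a [response_tensor()] (or 3-D array).
#' @return Numeric vector of length N with attribute `excluded` (integer
#'   indices of neurons with non-positive peaks).
#' @export
neuron_peaks <- function(tensor) {
  m <- .trial_means(tensor)
  peaks <- apply(m, 2, max)
  structure(peaks, excluded = which(peaks <= 0))
}

#' Half-maximum population sparseness
#'
#' For each stimulus, the number (and fraction) of neurons whose trial-mean
#' response to it strictly exceeds `thresh_frac` times that neuron's own
#' peak response. With the default `thresh_frac = 0.5` this is the
#' "fraction of neurons above their half-maximum" population-sparseness
#' measure. Neurons with non-positive peaks are excluded from both counts
#' and the denominator.
#'
#' @param tensor a [response_tensor()].
#' @param thresh_frac threshold as a fraction of each neuron's peak,
#'   strictly between 0 and 1.
#' @return A list with `counts` (length S), `fraction` (`counts`
#'   divided by the number of included neurons), `n_neurons` (denominator),
#'   and `excluded` (indices of excluded neurons).
#' @export
population_sparseness <- function(tensor, thresh_frac = 0.5) {
  if (thresh_frac <= 0 || thresh_frac >= 1)
    stop("`thresh_frac` must lie strictly between 0 and 1")
  m <- .trial_means(tensor)
  peaks <- neuron_peaks(tensor)
  excl <- attr(peaks, "excluded")
  keep <- setdiff(seq_len(ncol(m)), excl)
  above <- m[, keep, drop = FALSE] >
    matrix(thresh_frac * peaks[keep], nrow(m), length(keep), byrow = TRUE)
  counts <- rowSums(above)
  list(counts = counts, fraction = counts / length(keep),
       n_neurons = length(keep), excluded = excl)
}

#' Half-maximum life-time sparseness
#'
#' For each neuron, the number (and fraction) of stimuli whose trial-mean
#' response strictly exceeds `thresh_frac` times the neuron's peak — the
#' half-height width of its tuning curve over the stimulus set. Neurons
#' with non-positive peaks get `NA` counts.
#'
#' @inheritParams population_sparseness
#' @return A list with `counts` (length N, `NA` for excluded neurons),
#'   `fraction` (`counts / S`), `n_stimuli`, and `excluded`.
#' @export
lifetime_sparseness <- function(tensor, thresh_frac = 0.5) {
  if (thresh_frac <= 0 || thresh_frac >= 1)
    stop("`thresh_frac` must lie strictly between 0 and 1")
  m <- .trial_means(tensor)
  peaks <- neuron_peaks(tensor)
  excl <- attr(peaks, "excluded")
  counts <- colSums(m > matrix(thresh_frac * peaks, nrow(m), ncol(m),
                               byrow = TRUE))
  counts[excl] <- NA_integer_
  list(counts = counts, fraction = counts / nrow(m), n_stimuli = nrow(m),
       excluded = excl)
}

#' Classical (Treves-Rolls) sparseness of a response vector
#'
#' Computes `a = (sum(r)/n)^2 / (sum(r^2)/n)` and reports the normalized
#' sparseness `(1 - a) / (1 - 1/n)`, which is 0 for a flat vector and 1
#' for a one-hot vector. Provided for comparison with the half-maximum
#' measure; it is sensitive to baseline noise in calcium signals, which is
#' why the half-maximum measure is the primary statistic. Negative entries
#' are floored at zero (with a message) for this measure only.
#'
#' @param x non-negative response vector of length >= 2.
#' @return Sparseness in `[0, 1]`, or `NA` for an all-zero vector.
#' @examples
#' classic_sparseness(c(1, 0, 0, 0))  # 1
#' classic_sparseness(c(1, 1, 1, 1))  # 0
#' @export
classic_sparseness <- function(x) {
  if (length(x) < 2) stop("need at least two responses")
  if (any(x < 0)) {
    message(sprintf(
      "classic_sparseness: flooring %d negative response(s) at 0",
      sum(x < 0)))
    x[x < 0] <- 0
  }
  if (all(x == 0)) return(NA_real_)
  n <- length(x)
  a <- mean(x)^2 / mean(x^2)
  (1 - a) / (1 - 1 / n)
}

#' Full sparseness summary of a response tensor
#'
#' Bundles the half-maximum population and life-time statistics with their
#' means and the per-neuron peaks.
#'
#' @inheritParams population_sparseness
#' @return An object of class `sparseness_summary`: list with
#'   `per_stimulus_counts`, `per_stimulus_fraction`, `per_neuron_counts`,
#'   `per_neuron_fraction`, `mean_population_sparseness`,
#'   `mean_lifetime_sparseness` (both fractions in `[0, 1]`),
#'   `neuron_peaks`, `excluded_neurons`, `n_neurons`, `n_stimuli`,
#'   `thresh_frac`.
#' @export
sparseness_summary <- function(tensor, thresh_frac = 0.5) {
  pop <- population_sparseness(tensor, thresh_frac)
  lt <- lifetime_sparseness(tensor, thresh_frac)
  peaks <- neuron_peaks(tensor)
  structure(list(
    per_stimulus_counts = pop$counts,
    per_stimulus_fraction = pop$fraction,
    per_neuron_counts = lt$counts,
    per_neuron_fraction = lt$fraction,
    mean_population_sparseness = mean(pop$fraction),
    mean_lifetime_sparseness = mean(lt$fraction, na.rm = TRUE),
    neuron_peaks = as.numeric(peaks),
    excluded_neurons = pop$excluded,
    n_neurons = pop$n_neurons,
    n_stimuli = lt$n_stimuli,
    thresh_frac = thresh_frac), class = "sparseness_summary")
}

#' @export
print.sparseness_summary <- function(x, ...) {
  cat(sprintf("sparseness_summary (threshold %.0f%% of peak):\n",
              100 * x$thresh_frac))
  cat(sprintf(
    "  population sparseness: %.3g%% of %d neurons (mean %.2f cells/stimulus)\n",
    100 * x$mean_population_sparseness, x$n_neurons,
    mean(x$per_stimulus_counts)))
  cat(sprintf(
    "  life-time sparseness:  %.3g%% of %d stimuli (mean %.2f stimuli/neuron)\n",
    100 * x$mean_lifetime_sparseness, x$n_stimuli,
    mean(x$per_neuron_counts, na.rm = TRUE)))
  if (length(x$excluded_neurons))
    cat(sprintf("  excluded neurons (non-positive peak): %d\n",
                length(x$excluded_neurons)))
  invisible(x)
}

#' Write a sparseness summary to JSON plus count histograms to CSV
#'
#' @param summary a [sparseness_summary()].
#' @param json_path output JSON file.
#' @param hist_path optional CSV of integer-count histograms (per-stimulus
#'   and per-neuron).
#' @export
write_sparseness_summary <- function(summary, json_path, hist_path = NULL) {
  stopifnot(inherits(summary, "sparseness_summary"))
  jsonlite::write_json(unclass(summary), json_path, auto_unbox = TRUE,
                       digits = NA)
  if (!is.null(hist_path)) {
    tab <- function(cnt, what) {
      t <- table(factor(cnt, levels = 0:max(cnt, 0, na.rm = TRUE)))
      data.frame(measure = what, count = as.integer(names(t)),
                 frequency = as.integer(t))
    }
    utils::write.csv(
      rbind(tab(summary$per_stimulus_counts, "population"),
            tab(summary$per_neuron_counts[!is.na(summary$per_neuron_counts)],
                "lifetime")),
      hist_path, row.names = FALSE)
  }
  invisible(json_path)
}
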