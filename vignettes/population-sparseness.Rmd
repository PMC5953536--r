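---
title: "Measuring population sparseness in two-photon calcium imaging"
author: "popsparse"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring population sparseness in two-photon calcium imaging}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(popsparse)
```

## The scientific problem

Two-photon calcium imaging can record hundreds to thousands of cortical
neurons simultaneously while a large battery of stimuli is presented. With
such data one can measure *population sparseness* directly — for a given
stimulus, what fraction of the imaged population responds strongly? — rather
than inferring it from single-neuron (life-time) sparseness as
extracellular studies had to. `popsparse` implements this analysis for the
standard experimental structure: a stimulus set presented in a small number
of complete repeats (trials), each presentation consisting of a blank (OFF)
period followed by a stimulus (ON) period, at a frame rate of about 8 fps
(1 s OFF + 1 s ON = 8 + 8 frames per presentation by default).

The central statistic is deliberately simple. For neuron $j$ let
$m_{sj}$ be its trial-mean $\Delta F/F_0$ response to stimulus $s$ and
$P_j = \max_s m_{sj}$ its peak. Then

* **population sparseness** of stimulus $s$ is
  $\#\{j : m_{sj} > \tfrac12 P_j\} / N$, and
* **life-time sparseness** of neuron $j$ is
  $\#\{s : m_{sj} > \tfrac12 P_j\} / S$.

The half-maximum form is robust to the two dominant nuisances of calcium
signals — uncertain baselines and compressive nonlinearity at low rates —
which strongly affect moment-based measures such as the Treves–Rolls
index (included as `classic_sparseness()` for comparison). Both counts use
a strict `>` at the threshold (ties at exactly half-peak do not count), and
both are invariant to rescaling any single neuron's responses, since each
neuron is compared only with its own peak. The two counts satisfy an exact
pair-counting identity ($\sum_s \text{count}(s) = \sum_j \text{count}(j)$),
which the test suite checks on random tensors.

Neurons whose peak is not positive cannot define a half-maximum threshold;
they are excluded from numerator and denominator alike and reported in the
summary, rather than contributing degenerate counts.

## From movies to the response tensor

The imaging stages mirror standard practice for response-based
segmentation:

1. **Template and registration.** The template is the mean of the leading
   frames (`build_template()`, classically 1000 frames). Each frame is
   aligned by exhaustive search over integer translations within
   `max_shift`, maximizing the normalized cross-correlation (Pearson
   correlation on the overlap region). Candidates are scanned in order of
   increasing shift magnitude and only a strictly larger correlation
   replaces the incumbent, which makes the zero shift the default and
   registration idempotent. Vacated edge pixels are filled with template
   values so differential images stay unbiased at the borders. Constant
   (zero-variance) frames get shift (0, 0) with a warning.
2. **Differential images.** For each stimulus, the mean of all ON frames
   across its trials minus the mean of the corresponding OFF frames.
3. **Band-pass.** A difference of Gaussians: the image blurred at the small
   scale minus the image blurred at the large scale. The classic sizes "5
   and 50 pixels" are interpreted as Gaussian $\sigma$ values — the
   conventional one-parameter specification — and both are configurable;
   for the desk-scale synthetic frames used in the tests (~100 px frames,
   somata of radius 4–5 px) the matched choice is $\sigma = 2$ and
   $\sigma = 20$. Kernels are normalized and truncated at $3\sigma$ with
   replicate-edge padding; the implementation is an explicit separable
   convolution so that boundary behaviour is exactly reproducible by a
   direct-convolution oracle. The filtered images are used *only* for ROI
   detection; every response measurement reads raw data.
4. **ROI segmentation.** Pixels above `mean + 3 sd` of the (filtered)
   differential image are kept; connected components (8-connectivity by
   default, 4 available) with more than 25 pixels become candidate ROIs.
   Because detection runs per stimulus, the same cell reappears across
   differential images: candidates whose pixel overlap exceeds half of the
   smaller candidate are merged (union), others are kept distinct. The
   merge rule is a documented package choice — how per-stimulus detections
   were consolidated into a final cell list is generally not specified in
   this class of analysis. Any residual sub-threshold overlap is assigned
   to the earlier ROI so the final pixel sets are pairwise disjoint. Note
   that with filtering on, the ">25 pixels" rule acts on the *filtered*
   component footprint: a very bright sub-25-pixel source can still exceed
   25 pixels after blurring. The size rule is exact on unfiltered images
   (`bandpass = FALSE`), which is how the rejection behaviour is tested.
5. **Neuropil annuli and traces.** Each ROI receives a Chebyshev ring
   starting 2 px outside the ROI, 4 px wide, excluding all ROI pixels
   (geometry configurable). Traces are per-frame pixel means;
   `F_corr = F − 0.7 F_np` applies the standard correction index before
   $\Delta F/F_0$ (the conventional order). Per trial,
   $F_0$ is the mean over the full OFF window and $F$ the mean over the
   full ON window — the exact ON sub-window is not critical and both
   window definitions are configurable. A non-positive $F_0$ aborts with
   the trial named: silently propagating degenerate ratios would corrupt
   the sparseness counts downstream.

## Reliability: shuffle ROC test

Sparse strong responses could in principle be single-trial artefacts. Per
neuron, stimuli with mean response above half the maximum mean form the ON
class; the ROC AUC measures how well single-trial responses separate ON
from OFF. The null distribution is built by shuffling all $R \times S$
single-trial responses against the stimulus labels (pooled, not
within-trial), and — for a strict comparison — recomputing the maximum,
the half-max threshold and the classes for every shuffle before computing
its AUC. The test statistic is defined identically for observed and
shuffled data; in the degenerate case where every stimulus lands in the ON
class the statistic is defined as 0.5 (no separable classes), keeping the
permutation test exact. The p-value uses the standard
$(1 + b)/(1 + n_\text{shuffles})$ convention so it is never exactly zero;
the plain fraction is available via `add_one = FALSE`. 1000 shuffles and a
per-neuron criterion of $p < 0.01$ are the defaults; no multiplicity
correction is applied across neurons, matching the per-neuron reporting
convention. Calibration under an exchangeable null (type-I rate at
$\alpha = 0.01$ over 1000 simulated untuned neurons) is part of the test
suite.

## Decoding: nearest centroid with response thresholding

With $R$ trials, matrices $X^{(t)}$ ($S \times N$) hold each trial's
responses. For held-out trial $t$ the centroid matrix $C^{(t)}$ is the
mean of the other trials; each row of $X^{(t)}$ is assigned to the
stimulus with the nearest centroid row in Euclidean distance, distance
ties going to the smallest stimulus index (squared distances are snapped
at $10^{-9}$ before the argmin so that exact geometric ties are not
broken by floating-point noise). Accuracy is the mean over trials of the
per-trial fraction correct.

The thresholding experiments pool all $R \cdot S \cdot N$ entries and
either keep (*top only*) or zero (*top excluded*) the largest $p\%$,
applied to the whole tensor before the cross-validation split. Exactly
$\lceil p\% \cdot RSN \rceil$ entries form the top set; ties at the cut are
resolved by a stable order (neuron, then stimulus, then trial), which makes
the kept sets of the two variants exact complements at every $p$ — an
invariant the tests check across the full percentage grid, the standard
29-point list from 0 to 99. Pooling is across trials, stimuli *and*
neurons: a single pooled ranking is the reading under which "the top 0.5%
of responses" is directly comparable to the population-sparseness
fraction. The *relative* mode ranks entries by value divided by the
neuron's peak (maximum trial-mean), mirroring the per-neuron half-maximum
convention of the sparseness measure; entries of neurons with non-positive
peaks rank last. An alternative reading — a fixed per-neuron cutoff at a
fraction of peak — would not keep the two curve families complementary and
was not adopted.

## The synthetic-data generator

No public recordings accompany this class of experiment, so the generator
is a first-class, tested module that emulates the statistical structure
the analysis assumes:

* **Tuning.** Each stimulus strongly drives exactly `k_strong` neurons
  (default 1 at the desk scale of $S = N = 200$; the full-scale structure
  is ~2250 stimuli × ~1000 neurons with ~0.5% strong responders). Strong
  amplitudes are jittered uniformly in $[1, 1.25] \times$ `amp_strong`
  ($\Delta F/F_0 \approx 1$, a typical strong calcium response); weak
  background responses are half-normal with scale 0.05 so the matrix is
  non-negative like $\Delta F/F_0$ data. Strong responders are assigned by
  chunking concatenated random permutations of the neuron set: subsets per
  stimulus remain random, but every neuron is guaranteed at least one
  strong stimulus whenever $S \cdot k \ge N$. A fully independent uniform
  draw would leave a $(1 - k/N)^S$ fraction of neurons with no strong
  stimulus; such flat-tuned neurons have weak, noise-defined peaks and
  would dominate the half-max counts, destroying the exact
  ground-truth-recovery property ($k/N$ population sparseness on noiseless
  data) that makes the generator useful as an oracle.
* **Trials.** Additive Gaussian noise (default SD 0.1 in $\Delta F/F_0$
  units — moderate trial-to-trial variability) with an optional floor at
  zero (on by default). The floor slightly biases means upward near zero,
  so convergence-of-means properties are checked with the floor off.
* **Movies.** Background pixels carry the neuropil trace; ROI pixels carry
  $F_0 (1 + \Delta F/F_0)$ plus `neuropil_r` times the neuropil trace, so
  annulus-based correction at the matching index recovers the planted
  responses *exactly* — the end-to-end closure property the acceptance
  tests exploit (relative error below $10^{-6}$ on noiseless movies).
  Planted integer shifts, per-frame neuropil fluctuation and pixel noise
  are available. Movies round-trip through 32-bit multi-page TIFF with a
  JSON sidecar carrying the intensity scale and frame rate.

What the generator does *not* emulate: calcium-indicator kinetics (rise and
decay times, saturation), spike-to-fluorescence transforms, bleaching,
correlated (shared) trial noise, non-rigid tissue deformation, and overlap
between cell bodies. Tests passing on this generator therefore validate
the *analysis* — counting rules, test calibration, decoder mechanics,
pixel arithmetic — not the biological fidelity of any particular recording.

## Problem sizes and numerical choices

The test suite and the acceptance script run at desk scale: $S = N = 200$
with 3 trials for the statistics and decoding (about $1.2 \times 10^5$
tensor entries), 2250-way decoding with 60 stimulus-independent neurons for
the chance-level check, 1000 simulated null neurons at $S = 40$ for the
calibration of the shuffle test, and a $128 \times 128$ px movie of 3200
frames (20 stimuli × 10 repeats, 20 planted somata of radius 5 px) for the
imaging closure. These sizes were chosen so the whole suite completes in a
few minutes while every statistic retains enough resolution to be
meaningful; all of them scale up by argument.

Other numerical decisions, in one place: tensors are dense base-R arrays
(trials × stimuli × neurons); tensor files are long-format CSV; the ROC
AUC uses midranks (ties count $\tfrac12$); the differential-image mean is
computed over all ON/OFF frames pooled across a stimulus's trials;
per-image detection statistics (mean, sd) are taken over all pixels of
that image; random draws are isolated with `withr::with_seed` so that a
seed argument fully determines each function's output without disturbing
the caller's RNG stream.

## Limitations

* Registration is translation-only at integer precision, by design; there
  is no non-rigid or sub-pixel mode.
* The ROI merge rule (50% of the smaller component) is a reasonable
  default, not a canonical procedure; distinct touching cells that respond
  to the same stimulus can merge if their filtered footprints overlap
  heavily.
* The half-max counts depend on each neuron's peak being well estimated;
  with very few trials a noisy peak inflates the threshold. The
  reliability module exists precisely to flag neurons whose strong
  responses are not trial-stable.
* At desk scale the decoder saturates (accuracy 1.0) under the default
  generator; the thresholding experiments remain informative through the
  *top excluded* branch, which collapses once the strong tail is removed.
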