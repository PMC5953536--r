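# Shared fixture builders: small synthetic movies with planted ground truth.

# one planted blob (disc) movie: S stimuli, each driving one ROI
tiny_movie_fixture <- function(n_stimuli = 4, n_neurons = 4, n_trials = 2,
                               side = 96, radius = 4, seed = 1,
                               weak_scale = 0, shifts = NULL, ...) {
  tm <- generate_tuning_matrix(n_stimuli, n_neurons, k_strong = 1,
                               weak_scale = weak_scale, seed = seed)
  lay <- roi_layout(n_neurons, side, side, radius = radius)
  tt <- make_trial_table(n_stimuli, n_trials)
  mov <- generate_movie(tm, lay, tt, shifts = shifts, seed = seed + 1, ...)
  list(tuning = tm, layout = lay, trial_table = tt, movie = mov)
}

# detection settings matched to the desk-scale synthetic frames (somata of
# radius ~4 px in ~100 px frames, vs the default sigmas meant for
# 1024 px fields)
desk_detect <- function(diffs, ...) {
  detect_rois(diffs, low_size = 2, high_size = 20, ...)
}
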