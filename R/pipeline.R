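# Configuration-driven end-to-end runs: simulate -> preprocess -> extract ->
# sparseness -> reliability -> decode, with a reproducibility manifest.

.pipeline_defaults <- function() {
  list(
    seed = 1,
    stages = c("simulate", "sparseness", "reliability", "decode"),
    # synthetic-data scale (desk scale by default; full scale ~2250 x 1000
    # is reached by raising n_stimuli / n_neurons)
    n_stimuli = 200, n_neurons = 200, n_trials = 3, k_strong = 1,
    amp_strong = 1, weak_scale = 0.05, noise_sd = 0.1,
    simulate_movie = FALSE,
    movie_height = 128, movie_width = 128, movie_f0 = 100,
    movie_neuropil_level = 30, movie_roi_radius = 4,
    frames_off = 8, frames_on = 8, frame_rate = 8,
    # inputs (used instead of simulation when set)
    movie_tiff = NULL, trial_table_csv = NULL, tensor_csv = NULL,
    # preprocessing
    max_shift = 5, template_frames = 1000, low_size = 5, high_size = 50,
    z_thresh = 3, min_pixels = 25, connectivity = 8,
    # extraction
    neuropil_r = 0.7,
    # statistics
    thresh_frac = 0.5, n_shuffles = 1000, alpha = 0.01,
    percentages = decoding_percentages(), decode_mode = "absolute")
}

#' Build a validated pipeline configuration
#'
#' Starts from the package defaults (the standard analysis parameters:
#' `z_thresh = 3`, `min_pixels = 25`, band-pass sigmas 5/50 px,
#' `neuropil_r = 0.7`, half-maximum threshold, 1000 shuffles, the 29-point
#' percentage grid) and overrides the named fields. Unknown keys are
#' rejected so that typos cannot silently fall back to defaults.
#'
#' @param ... named overrides of default fields.
#' @return An object of class `pipeline_config` (a named list).
#' @examples
#' cfg <- pipeline_config(n_stimuli = 50, n_neurons = 50, seed = 7)
#' cfg$z_thresh
#' @export
pipeline_config <- function(...) {
  cfg <- .pipeline_defaults()
  over <- list(...)
  if (length(over) && (is.null(names(over)) || any(names(over) == "")))
    stop("all configuration overrides must be named")
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown))
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  cfg[names(over)] <- over
  bad_stage <- setdiff(cfg$stages,
                       c("simulate", "preprocess", "extract", "sparseness",
                         "reliability", "decode"))
  if (length(bad_stage))
    stop("unknown stage(s): ", paste(bad_stage, collapse = ", "))
  structure(cfg, class = "pipeline_config")
}

#' Read / write a pipeline configuration (YAML or JSON)
#'
#' The format is chosen by extension (`.yaml`/`.yml` or `.json`); every
#' parameter round-trips losslessly and unknown keys are rejected on read.
#'
#' @param path file path.
#' @rdname pipeline_config_io
#' @export
read_pipeline_config <- function(path) {
  raw <- if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path)
  else jsonlite::read_json(path, simplifyVector = TRUE)
  null_keys <- names(.pipeline_defaults())[
    vapply(.pipeline_defaults(), is.null, TRUE)]
  raw[setdiff(null_keys, names(raw))] <- NULL
  do.call(pipeline_config, raw)
}

#' @param config a [pipeline_config()].
#' @rdname pipeline_config_io
#' @export
write_pipeline_config <- function(config, path) {
  stopifnot(inherits(config, "pipeline_config"))
  x <- unclass(config)
  x <- x[!vapply(x, is.null, TRUE)]
  if (grepl("\\.ya?ml$", path)) yaml::write_yaml(x, path)
  else jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Validate pipeline inputs
#'
#' Checks that referenced input files exist and are readable, that the
#' trial table satisfies its schema, and that dimensions are mutually
#' consistent. A non-empty issue list blocks [run_pipeline()].
#'
#' @param config a [pipeline_config()].
#' @return Character vector of issues (empty when everything is valid).
#' @export
validate_inputs <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  issues <- character(0)
  note <- function(msg) issues <<- c(issues, msg)
  tt <- NULL
  if (!is.null(config$trial_table_csv)) {
    if (!file.exists(config$trial_table_csv))
      note(sprintf("trial table not found: %s", config$trial_table_csv))
    else tt <- tryCatch(read_trial_table(config$trial_table_csv),
                        error = function(e) {
                          note(sprintf("trial table invalid: %s",
                                       conditionMessage(e)))
                          NULL
                        })
  }
  if (!is.null(config$movie_tiff)) {
    if (!file.exists(config$movie_tiff))
      note(sprintf("movie not found: %s", config$movie_tiff))
    else {
      mov <- tryCatch(read_movie_tiff(config$movie_tiff),
                      error = function(e) {
                        note(sprintf("movie unreadable: %s",
                                     conditionMessage(e)))
                        NULL
                      })
      if (!is.null(mov) && !is.null(tt) &&
          max(tt$on_end) > dim(mov$frames)[1])
        note("trial table windows extend beyond the movie")
    }
    if (is.null(config$trial_table_csv))
      note("movie input requires `trial_table_csv`")
  }
  if (!is.null(config$tensor_csv)) {
    if (!file.exists(config$tensor_csv))
      note(sprintf("tensor not found: %s", config$tensor_csv))
    else {
      x <- tryCatch(read_tensor_csv(config$tensor_csv),
                    error = function(e) {
                      note(sprintf("tensor invalid: %s",
                                   conditionMessage(e)))
                      NULL
                    })
      if (!is.null(x) && !is.null(tt) &&
          (dim(x)[1] < max(tt$trial) || dim(x)[2] < max(tt$stimulus)))
        note("tensor dimensions do not cover the trial table")
    }
  }
  issues
}

#' Run the analysis pipeline
#'
#' Executes the requested stages in order, writing each stage's artifacts
#' into `output_dir` together with a manifest (parameters, seed, file
#' checksums). Inputs come either from the synthetic generator
#' (`simulate` stage) or from the files named in the configuration.
#' All randomness flows from `config$seed`, split per stage, so a rerun
#' with the same configuration reproduces every artifact bit-for-bit.
#'
#' @param config a [pipeline_config()].
#' @param output_dir directory for artifacts (created if needed).
#' @return The manifest, invisibly (a list; also written as
#'   `manifest.json`).
#' @export
run_pipeline <- function(config, output_dir) {
  stopifnot(inherits(config, "pipeline_config"))
  issues <- validate_inputs(config)
  if (length(issues))
    stop("invalid pipeline inputs:\n  ", paste(issues, collapse = "\n  "))
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  stages <- config$stages
  artifacts <- character(0)
  timings <- list()
  out <- function(name) file.path(output_dir, name)
  emit <- function(name) artifacts <<- c(artifacts, out(name))
  stage_seed <- function(k) config$seed + 1000L * k

  tensor <- NULL
  trial_table <- NULL
  movie <- NULL
  rois <- NULL

  if (!is.null(config$tensor_csv)) tensor <- read_tensor_csv(config$tensor_csv)
  if (!is.null(config$trial_table_csv))
    trial_table <- read_trial_table(config$trial_table_csv)
  if (!is.null(config$movie_tiff)) movie <- read_movie_tiff(config$movie_tiff)

  run_stage <- function(name, fun) {
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(fun(), error = function(e)
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
    timings[[name]] <<- round(proc.time()[["elapsed"]] - t0, 3)
    res
  }

  if ("simulate" %in% stages) {
    run_stage("simulate", function() {
      tuning <- generate_tuning_matrix(
        config$n_stimuli, config$n_neurons, k_strong = config$k_strong,
        amp_strong = config$amp_strong, weak_scale = config$weak_scale,
        seed = stage_seed(1))
      sim <- generate_response_tensor(
        tuning, n_trials = config$n_trials, noise_sd = config$noise_sd,
        seed = stage_seed(2))
      trial_table <<- make_trial_table(config$n_stimuli, config$n_trials,
                                       config$frames_off, config$frames_on)
      write_trial_table(trial_table, out("trial_table.csv"))
      emit("trial_table.csv")
      if (config$simulate_movie) {
        layout <- roi_layout(config$n_neurons, config$movie_height,
                             config$movie_width,
                             radius = config$movie_roi_radius)
        movie <<- generate_movie(
          sim$responses, layout, trial_table, f0 = config$movie_f0,
          neuropil_level = config$movie_neuropil_level,
          neuropil_r = config$neuropil_r, frame_rate = config$frame_rate,
          seed = stage_seed(3))
        write_movie_tiff(movie, out("movie.tif"))
        emit("movie.tif"); emit("movie.tif.json")
      } else {
        tensor <<- sim$responses
        write_tensor_csv(tensor, out("responses.csv"))
        emit("responses.csv")
      }
      jsonlite::write_json(
        list(k_strong = config$k_strong, amp_strong = config$amp_strong,
             weak_scale = config$weak_scale, noise_sd = config$noise_sd,
             strong_per_neuron = colSums(tuning$strong), seed = config$seed),
        out("ground_truth.json"), auto_unbox = TRUE, digits = NA)
      emit("ground_truth.json")
    })
  }

  if ("preprocess" %in% stages) {
    run_stage("preprocess", function() {
      if (is.null(movie) || is.null(trial_table))
        stop("preprocess needs a movie and a trial table")
      template <- build_template(
        movie, min(config$template_frames, dim(movie$frames)[1]))
      reg <- register_frames(movie, template, max_shift = config$max_shift)
      movie <<- reg$movie
      utils::write.csv(reg$shifts, out("shifts.csv"), row.names = FALSE)
      emit("shifts.csv")
      diffs <- lapply(sort(unique(trial_table$stimulus)), function(s)
        differential_image(movie, trial_table, s))
      rois <<- detect_rois(diffs, z_thresh = config$z_thresh,
                           min_pixels = config$min_pixels,
                           connectivity = config$connectivity,
                           low_size = config$low_size,
                           high_size = config$high_size)
      write_roi_set(rois, out("rois.tif"))
      emit("rois.tif"); emit("rois.tif.json")
    })
  }

  if ("extract" %in% stages) {
    run_stage("extract", function() {
      if (is.null(movie) || is.null(rois) || is.null(trial_table))
        stop("extract needs a registered movie, ROIs and a trial table")
      tensor <<- extract_response_tensor(movie, rois, trial_table,
                                         r = config$neuropil_r)
      write_tensor_csv(tensor, out("responses.csv"))
      emit("responses.csv")
    })
  }

  need_tensor <- function(stage) {
    if (is.null(tensor))
      stop(sprintf("stage '%s' needs a response tensor %s", stage,
                   "(run simulate/extract or set `tensor_csv`)"),
           call. = FALSE)
  }

  if ("sparseness" %in% stages) {
    run_stage("sparseness", function() {
      need_tensor("sparseness")
      sp <- sparseness_summary(tensor, thresh_frac = config$thresh_frac)
      write_sparseness_summary(sp, out("sparseness.json"),
                               out("sparseness_hist.csv"))
      emit("sparseness.json"); emit("sparseness_hist.csv")
    })
  }

  if ("reliability" %in% stages) {
    run_stage("reliability", function() {
      need_tensor("reliability")
      rel <- reliability_summary(tensor, n_shuffles = config$n_shuffles,
                                 thresh_frac = config$thresh_frac,
                                 alpha = config$alpha,
                                 seed = stage_seed(4))
      write_reliability_summary(rel, out("reliability.csv"),
                                out("reliability.json"))
      emit("reliability.csv"); emit("reliability.json")
    })
  }

  if ("decode" %in% stages) {
    run_stage("decode", function() {
      need_tensor("decode")
      for (keep in c("top_only", "top_excluded")) {
        curve <- decoding_curve(tensor, percentages = config$percentages,
                                keep = keep, mode = config$decode_mode)
        write_decoding_curve(curve,
                             out(sprintf("decoding_%s.csv", keep)),
                             out(sprintf("decoding_%s.json", keep)))
        emit(sprintf("decoding_%s.csv", keep))
        emit(sprintf("decoding_%s.json", keep))
      }
    })
  }

  manifest <- list(
    package = "popsparse",
    version = as.character(utils::packageVersion("popsparse")),
    config = unclass(config)[!vapply(unclass(config), is.null, TRUE)],
    stages_run = stages,
    timings_s = timings,
    checksums = as.list(tools::md5sum(artifacts)))
  jsonlite::write_json(manifest, file.path(output_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
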