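# Synthetic ABR generator.
#
# A sweep is modelled as a sum of Gaussian bumps, one per characteristic wave
# (I--V), plus broadband Gaussian noise, a slow sinusoidal baseline drift and
# an optional late-window artifact emulating myogenic interference after
# 8 ms. Waves II and IV are generated for morphological realism (fused IV-V
# complexes) but never annotated; clinical marks cover I, III and V only.

#' Wave template
#'
#' Generative parameters of one characteristic wave. Latencies are drawn as
#' Gaussian jitter around `mean_latency`, amplitudes around `mean_amplitude`
#' (floored at zero), and the wave is present with probability
#' `presence_prob`.
#'
#' @param wave_id One of `"I"`, `"II"`, `"III"`, `"IV"`, `"V"`.
#' @param mean_latency Mean peak latency in ms, in (0, 8).
#' @param latency_sd Latency jitter SD in ms.
#' @param mean_amplitude Mean peak amplitude in uV.
#' @param amplitude_sd Amplitude SD in uV.
#' @param width Gaussian-bump SD in ms.
#' @param presence_prob Probability the wave is present at all.
#' @return An object of class `"wave_template"`.
#' @export
wave_template <- function(wave_id, mean_latency, latency_sd, mean_amplitude,
                          amplitude_sd, width, presence_prob = 1) {
  wave_id <- match.arg(wave_id, c("I", "II", "III", "IV", "V"))
  stopifnot(mean_latency > 0, mean_latency < 8, latency_sd >= 0,
            amplitude_sd >= 0, width > 0,
            presence_prob >= 0, presence_prob <= 1)
  structure(
    list(wave_id = wave_id, mean_latency = mean_latency,
         latency_sd = latency_sd, mean_amplitude = mean_amplitude,
         amplitude_sd = amplitude_sd, width = width,
         presence_prob = presence_prob),
    class = "wave_template"
  )
}

validate_templates <- function(templates) {
  stopifnot(length(templates) >= 1L)
  ids <- vapply(templates, function(t) t$wave_id, character(1))
  ord <- order(match(ids, c("I", "II", "III", "IV", "V")))
  templates <- templates[ord]
  lat <- vapply(templates, function(t) t$mean_latency, numeric(1))
  if (length(lat) > 1L && any(diff(lat) <= 0)) {
    stop("template mean latencies must strictly increase with wave order")
  }
  templates
}

#' Default wave templates
#'
#' Five-wave click-ABR morphology at high stimulus level (96 dB nHL), with
#' latency means around 1.6, 2.8, 3.9, 5.1 and 5.7 ms, widths 0.25-0.45 ms
#' and amplitudes 0.1-0.5 uV, taken from standard adult click-ABR audiology
#' ranges. The `"abnormal"` class draws lower amplitudes, larger latency
#' jitter and higher wave-absence probability, emulating recordings where
#' waves I and III are not obvious.
#'
#' @param subject_class `"normal"` or `"abnormal"`.
#' @param latency_sd Latency jitter SD in ms for the normal class.
#' @return List of [wave_template()] objects ordered I..V.
#' @export
default_wave_templates <- function(subject_class = c("normal", "abnormal"),
                                   latency_sd = 0.08) {
  subject_class <- match.arg(subject_class)
  base <- list(
    wave_template("I",   1.6, latency_sd, 0.30, 0.05, 0.25, 1),
    wave_template("II",  2.8, latency_sd, 0.12, 0.04, 0.30, 0.8),
    wave_template("III", 3.9, latency_sd, 0.30, 0.05, 0.30, 1),
    wave_template("IV",  5.1, latency_sd, 0.15, 0.05, 0.35, 0.8),
    wave_template("V",   5.7, latency_sd, 0.50, 0.08, 0.45, 1)
  )
  if (subject_class == "abnormal") {
    presence <- c(I = 0.55, II = 0.4, III = 0.7, IV = 0.5, V = 0.9)
    base <- lapply(base, function(tp) {
      wave_template(tp$wave_id, tp$mean_latency,
                    latency_sd = tp$latency_sd * 2,
                    mean_amplitude = tp$mean_amplitude * 0.45,
                    amplitude_sd = tp$amplitude_sd,
                    width = tp$width,
                    presence_prob = unname(presence[tp$wave_id]))
    })
  }
  base
}

#' Noise specification
#'
#' @param baseline_sd Broadband Gaussian noise SD in uV.
#' @param drift_amplitude Amplitude of the slow sinusoidal baseline drift, uV.
#' @param drift_period Drift period in ms.
#' @param late_artifact_prob Probability that a sweep carries a late-window
#'   artifact (amplified potentials after 8 ms).
#' @param late_artifact_gain Multiplicative gain applied to samples after
#'   8 ms when the artifact is present.
#' @return An object of class `"noise_spec"`.
#' @export
noise_spec <- function(baseline_sd = 0.05, drift_amplitude = 0.03,
                       drift_period = 30, late_artifact_prob = 0.3,
                       late_artifact_gain = 3) {
  stopifnot(baseline_sd >= 0, drift_amplitude >= 0, drift_period > 0,
            late_artifact_prob >= 0, late_artifact_prob <= 1,
            late_artifact_gain >= 0)
  structure(
    list(baseline_sd = baseline_sd, drift_amplitude = drift_amplitude,
         drift_period = drift_period, late_artifact_prob = late_artifact_prob,
         late_artifact_gain = late_artifact_gain),
    class = "noise_spec"
  )
}

#' Simulator configuration
#'
#' Bundles wave templates per class, the noise model and the annotation
#' visibility floor. Two presets are shipped: `"easy"` (all-normal morphology,
#' low noise, small jitter; used for qualitative architecture comparisons
#' where training variance must be small) and `"clinical-like"` (default
#' templates, more noise and jitter, abnormal class enabled).
#'
#' @param preset `"easy"` or `"clinical-like"`, or `NULL` to pass every part
#'   explicitly.
#' @param templates_normal,templates_abnormal Lists of [wave_template()].
#' @param noise A [noise_spec()].
#' @param visibility_floor Minimum realized amplitude (uV) for a wave to be
#'   annotated; dimmer waves are generated but left unmarked, emulating
#'   "not obvious" waves.
#' @param grid An [abr_grid()].
#' @return An object of class `"abr_sim_config"`.
#' @export
abr_sim_config <- function(preset = NULL,
                           templates_normal = default_wave_templates("normal"),
                           templates_abnormal = default_wave_templates("abnormal"),
                           noise = noise_spec(),
                           visibility_floor = 0.05,
                           grid = abr_grid()) {
  if (!is.null(preset)) {
    preset <- match.arg(preset, c("easy", "clinical-like"))
    if (preset == "easy") {
      templates_normal <- default_wave_templates("normal", latency_sd = 0.05)
      templates_normal <- lapply(templates_normal, function(tp) {
        tp$presence_prob <- if (tp$wave_id %in% c("I", "III", "V")) 1 else 0.9
        tp
      })
      noise <- noise_spec(baseline_sd = 0.02, drift_amplitude = 0.01,
                          late_artifact_prob = 0.2)
    } else {
      noise <- noise_spec(baseline_sd = 0.08, drift_amplitude = 0.04,
                          late_artifact_prob = 0.4)
    }
  }
  structure(
    list(templates_normal = validate_templates(templates_normal),
         templates_abnormal = validate_templates(templates_abnormal),
         noise = noise, visibility_floor = visibility_floor, grid = grid,
         preset = if (is.null(preset)) "custom" else preset),
    class = "abr_sim_config"
  )
}

# Draw noise for a full-length sweep using the current RNG state.
draw_noise <- function(noise, grid) {
  t <- grid_time(grid, seq_len(grid$n_samples))
  out <- numeric(grid$n_samples)
  if (noise$baseline_sd > 0) {
    out <- out + stats::rnorm(grid$n_samples, 0, noise$baseline_sd)
  } else {
    # keep the RNG stream aligned across noise settings
    stats::rnorm(grid$n_samples)
  }
  phase <- stats::runif(1, 0, noise$drift_period)
  if (noise$drift_amplitude > 0) {
    out <- out + noise$drift_amplitude *
      sin(2 * pi * (t - phase) / noise$drift_period)
  }
  out
}

#' Simulate one ABR sweep
#'
#' Draws wave presence, amplitudes and jittered latencies from the templates,
#' snaps each realized latency to the acquisition grid, sums Gaussian bumps
#' centred at the snapped latencies, and adds noise. Waves I/III/V whose
#' realized amplitude reaches the visibility floor are annotated at their
#' snapped latency, so every annotation is exactly on-grid.
#'
#' Uses R's current RNG state; seed with `set.seed()` (or use
#' [simulate_dataset()], which derives per-sweep seeds).
#'
#' @param templates List of [wave_template()], ordered I..V.
#' @param noise A [noise_spec()].
#' @param subject_class `"normal"` or `"abnormal"` (stored on the recording).
#' @param grid An [abr_grid()].
#' @param visibility_floor Minimum annotated amplitude in uV.
#' @return List with elements `recording` ([abr_recording()]) and
#'   `annotation` ([wave_annotation()]).
#' @export
simulate_recording <- function(templates, noise = noise_spec(),
                               subject_class = "normal", grid = abr_grid(),
                               visibility_floor = 0.05) {
  templates <- validate_templates(templates)
  k <- length(templates)
  present <- stats::runif(k) < vapply(templates, `[[`, numeric(1), "presence_prob")
  amp <- pmax(0, stats::rnorm(
    k,
    vapply(templates, `[[`, numeric(1), "mean_amplitude"),
    vapply(templates, `[[`, numeric(1), "amplitude_sd")
  ))
  lat <- stats::rnorm(
    k,
    vapply(templates, `[[`, numeric(1), "mean_latency"),
    vapply(templates, `[[`, numeric(1), "latency_sd")
  )
  lat <- pmin(pmax(lat, 0.3), 7.7)
  # enforce strict ordering by pushing each wave at least one sample after
  # its predecessor (jitter rarely violates this with default SDs)
  if (k > 1L) for (j in 2:k) lat[j] <- max(lat[j], lat[j - 1] + grid$dt)
  # snap to grid so annotations land exactly on sample times
  lat <- grid_time(grid, grid_index(grid, lat))

  t <- grid_time(grid, seq_len(grid$n_samples))
  clean <- numeric(grid$n_samples)
  for (j in seq_len(k)) {
    if (present[j] && amp[j] > 0) {
      w <- templates[[j]]$width
      clean <- clean + amp[j] * exp(-0.5 * ((t - lat[j]) / w)^2)
    }
  }
  pot <- clean + draw_noise(noise, grid)
  if (stats::runif(1) < noise$late_artifact_prob) {
    late <- t > 8
    pot[late] <- pot[late] * noise$late_artifact_gain
  }

  # A clinician marks the visible peak of the composite waveform, which
  # overlapping neighbours (the fused IV-V complex) can shift away from a
  # wave's own bump centre: annotate the local maximum of the clean
  # composite within +/- 0.5 ms of the realized centre.
  half <- as.integer(round(0.5 / grid$dt))
  ids <- vapply(templates, `[[`, character(1), "wave_id")
  ann <- numeric(0)
  for (wv in c("I", "III", "V")) {
    j <- match(wv, ids)
    if (!is.na(j) && present[j] && amp[j] >= visibility_floor) {
      ci <- grid_index(grid, lat[j])
      nb <- max(1L, ci - half):min(grid$n_samples, ci + half)
      lat_ann <- grid_time(grid, nb[which.max(clean[nb])])
      # keep annotations strictly increasing and inside the window
      if (length(ann) > 0L) lat_ann <- max(lat_ann, ann[length(ann)] + grid$dt)
      ann[wv] <- min(max(lat_ann, 0), 8)
    }
  }
  list(
    recording = abr_recording(pot, grid, subject_class),
    annotation = wave_annotation(ann)
  )
}

#' Simulate an annotated ABR dataset
#'
#' Per-sweep seeds are derived deterministically from the master seed, so the
#' dataset is reproducible and individual sweeps can be regenerated in
#' isolation.
#'
#' @param n Number of sweeps.
#' @param class_mix Fraction of abnormal-hearing subjects; the default mirrors
#'   a clinical composition of 433 abnormal among 614.
#' @param config An [abr_sim_config()].
#' @param seed Master integer seed.
#' @param stratified If `TRUE`, the abnormal count is exactly
#'   `round(n * class_mix)`; otherwise each sweep is abnormal independently
#'   with probability `class_mix`.
#' @return A list of class `"abr_dataset"`; each element has `recording` and
#'   `annotation`.
#' @export
simulate_dataset <- function(n, class_mix = 433 / 614,
                             config = abr_sim_config("clinical-like"),
                             seed = 1L, stratified = FALSE) {
  stopifnot(n >= 1L, class_mix >= 0, class_mix <= 1,
            inherits(config, "abr_sim_config"))
  set.seed(seed)
  sweep_seeds <- sample.int(.Machine$integer.max - 1L, n)
  if (stratified) {
    n_ab <- round(n * class_mix)
    classes <- sample(rep(c("abnormal", "normal"), c(n_ab, n - n_ab)))
  } else {
    classes <- ifelse(stats::runif(n) < class_mix, "abnormal", "normal")
  }
  out <- vector("list", n)
  for (i in seq_len(n)) {
    set.seed(sweep_seeds[i])
    tpl <- if (classes[i] == "abnormal") config$templates_abnormal
           else config$templates_normal
    out[[i]] <- simulate_recording(tpl, config$noise, classes[i],
                                   config$grid, config$visibility_floor)
  }
  structure(out, class = "abr_dataset", seed = seed, config = config)
}

#' @export
print.abr_dataset <- function(x, ...) {
  cls <- vapply(x, function(s) s$recording$subject_class, character(1))
  cat(sprintf("ABR dataset: %d sweeps (%d normal, %d abnormal), seed %s\n",
              length(x), sum(cls == "normal"), sum(cls == "abnormal"),
              format(attr(x, "seed"))))
  invisible(x)
}

#' Add interference noise to a recording
#'
#' Returns a new recording with an additive, seed-reproducible noise
#' component (broadband Gaussian + sinusoidal drift); the input is untouched.
#' Used by the wavelet-preprocessing comparison, where both pipeline arms
#' consume identically corrupted data.
#'
#' @param recording An [abr_recording()].
#' @param noise A [noise_spec()] (its late-artifact fields are ignored here;
#'   only additive components are injected).
#' @param seed Optional integer seed; if `NULL` the current RNG state is used.
#' @return A new [abr_recording()].
#' @export
add_interference_noise <- function(recording, noise, seed = NULL) {
  stopifnot(inherits(recording, "abr_recording"), inherits(noise, "noise_spec"))
  if (!is.null(seed)) set.seed(seed)
  add <- draw_noise(noise, recording$grid)
  abr_recording(recording$potentials + add, recording$grid,
                recording$subject_class, recording$stimulus_level)
}
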