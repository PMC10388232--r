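#' Parameters of the synthetic vertical-GRF stance curve
#'
#' Describes the canonical two-peak ("M"-shaped) vertical ground-reaction
#' force of one stance phase: a loading-response peak, a mid-stance valley
#' and a push-off peak at fixed fractions of stance, scaled by body weight,
#' plus the recording characteristics of the force plate (Gaussian sensor
#' noise, quantization to the plate resolution, saturation limits).
#'
#' Defaults follow canonical vertical-GRF morphology (peaks of 1.15 and
#' 1.10 BW at 25% and 75% of stance, a 0.75 BW valley at mid-stance) and a
#' plate with 0.3 N resolution saturating at 3500 N compression / 900 N
#' tension.
#'
#' @param body_weight Body weight in newtons.
#' @param stance_duration Stance duration in seconds.
#' @param sample_rate Sampling rate in Hz.
#' @param peak1_amp,valley_amp,peak2_amp Loading-response peak, mid-stance
#'   valley and push-off peak amplitudes in body-weight (BW) units.
#' @param peak1_time_frac,valley_time_frac,peak2_time_frac Locations of the
#'   three control points as fractions of stance; must be strictly
#'   increasing within (0, 1).
#' @param phase_width_frac Width (as a fraction of stance) of the smooth
#'   phase windows used by the impairment model.
#' @param noise_sd Standard deviation of additive Gaussian sensor noise in
#'   BW units.
#' @param quantization_step Plate resolution in newtons; 0 disables
#'   quantization.
#' @param clip_compression,clip_tension Saturation limits in newtons
#'   (tension is negative).
#' @param seed Integer seed for the trial's noise stream.
#' @return A validated list of class `gait_params`.
#' @export
gait_params <- function(body_weight = 700,
                        stance_duration = 1.025,
                        sample_rate = 1000,
                        peak1_amp = 1.15, valley_amp = 0.75, peak2_amp = 1.10,
                        peak1_time_frac = 0.25, valley_time_frac = 0.50,
                        peak2_time_frac = 0.75,
                        phase_width_frac = 0.12,
                        noise_sd = 0.01,
                        quantization_step = 0.3,
                        clip_compression = 3500, clip_tension = -900,
                        seed = 1L) {
  p <- list(body_weight = body_weight, stance_duration = stance_duration,
            sample_rate = sample_rate, peak1_amp = peak1_amp,
            valley_amp = valley_amp, peak2_amp = peak2_amp,
            peak1_time_frac = peak1_time_frac,
            valley_time_frac = valley_time_frac,
            peak2_time_frac = peak2_time_frac,
            phase_width_frac = phase_width_frac, noise_sd = noise_sd,
            quantization_step = quantization_step,
            clip_compression = clip_compression, clip_tension = clip_tension,
            seed = as.integer(seed))
  with(p, {
    stopifnot(body_weight > 0, stance_duration > 0, sample_rate > 0,
              peak1_amp > 0, valley_amp > 0, peak2_amp > 0,
              0 < peak1_time_frac, peak1_time_frac < valley_time_frac,
              valley_time_frac < peak2_time_frac, peak2_time_frac < 1,
              phase_width_frac > 0, noise_sd >= 0, quantization_step >= 0,
              clip_compression > 0, clip_tension < 0)
  })
  class(p) <- "gait_params"
  p
}

#' Phase-attenuation profile of an impaired gait
#'
#' An impaired stance misses or weakens the loading-response, mid-stance
#' and push-off phases while heel strike and toe-off are still performed;
#' each attenuation in `[0, 1]` flattens the corresponding phase of the
#' healthy curve toward a low featureless arch (0 = healthy, 1 = phase
#' fully flattened; see [impaired_step()]).
#'
#' @param loading_response,mid_stance,push_off Per-phase attenuations in
#'   `[0, 1]`.
#' @param severity Convenience scalar applying the same attenuation to all
#'   three phases (overrides the individual arguments).
#' @return A list of class `impairment_profile`.
#' @export
impairment_profile <- function(loading_response = 0, mid_stance = 0,
                               push_off = 0, severity = NULL) {
  if (!is.null(severity)) {
    stopifnot(severity >= 0, severity <= 1)
    loading_response <- mid_stance <- push_off <- severity
  }
  stopifnot(loading_response >= 0, loading_response <= 1,
            mid_stance >= 0, mid_stance <= 1,
            push_off >= 0, push_off <= 1)
  structure(list(loading_response = loading_response,
                 mid_stance = mid_stance, push_off = push_off),
            class = "impairment_profile")
}

# C1 interpolation through knots with zero slope at every knot: each segment
# is the cubic smooth-step between its endpoint values, so curve extrema sit
# exactly on the knots.
hermite_flat <- function(s, xs, ys) {
  seg <- findInterval(s, xs, rightmost.closed = TRUE, all.inside = TRUE)
  x0 <- xs[seg]; x1 <- xs[seg + 1L]
  u <- (s - x0) / (x1 - x0)
  ys[seg] + (ys[seg + 1L] - ys[seg]) * (3 * u^2 - 2 * u^3)
}

stance_grid <- function(params) {
  len <- round(params$stance_duration * params$sample_rate)
  seq(0, 1, length.out = len)
}

#' Healthy stance-phase force curve
#'
#' Noiseless vertical GRF of one healthy step: zero at heel-strike onset and
#' toe-off, rising to the loading-response peak, dipping to the mid-stance
#' valley and rising again to the push-off peak, at the control points of
#' `params`. The curve passes exactly through the three control amplitudes.
#'
#' @param params A [gait_params] object.
#' @return Numeric vector of forces in newtons, of length
#'   `round(stance_duration * sample_rate)`.
#' @examples
#' f <- healthy_step(gait_params(body_weight = 700))
#' max(f)  # 1.15 BW = 805 N
#' @export
healthy_step <- function(params) {
  stopifnot(inherits(params, "gait_params"))
  s <- stance_grid(params)
  xs <- c(0, params$peak1_time_frac, params$valley_time_frac,
          params$peak2_time_frac, 1)
  ys <- c(0, params$peak1_amp, params$valley_amp, params$peak2_amp, 0)
  params$body_weight * hermite_flat(s, xs, ys)
}

# featureless low arch a fully impaired stance collapses onto: a single
# hump at half the healthy mid-stance load, heel strike and toe-off intact
baseline_arch <- function(s, params) {
  params$body_weight * 0.5 * params$valley_amp *
    hermite_flat(s, c(0, 0.5, 1), c(0, 1, 0))
}

# blended attenuation weight in [0, 1] from the three phase windows:
# raised-cosine tapers of half-width phase_width_frac around each control
# point; with the default geometry the windows cannot overlap, so the
# weight is exactly linear in each attenuation (no saturation)
impairment_weight <- function(s, params, impairment) {
  g <- function(center) {
    u <- abs(s - center) / params$phase_width_frac
    ifelse(u < 1, cos(pi * u / 2)^2, 0)
  }
  pmin(1, impairment$loading_response * g(params$peak1_time_frac)
        + impairment$mid_stance * g(params$valley_time_frac)
        + impairment$push_off * g(params$peak2_time_frac))
}

#' Impaired stance-phase force curve
#'
#' The healthy curve with its loading-response, mid-stance and push-off
#' phases attenuated through smooth (Gaussian) phase windows centered on
#' the control points: within each window the deviation of the healthy
#' curve from a low featureless arch is multiplicatively reduced by the
#' phase's attenuation. Zero attenuation reproduces [healthy_step()]
#' exactly; full attenuation of all phases flattens the curve onto the
#' arch, so heel strike and toe-off are still performed while the distinct
#' loading-response / mid-stance / push-off structure disappears — and the
#' foot still bears load, so the step remains a single detectable contact.
#'
#' @param params A [gait_params] object.
#' @param impairment An [impairment_profile].
#' @return Numeric vector of forces in newtons.
#' @export
impaired_step <- function(params, impairment) {
  stopifnot(inherits(params, "gait_params"),
            inherits(impairment, "impairment_profile"))
  s <- stance_grid(params)
  healthy <- healthy_step(params)
  w <- impairment_weight(s, params, impairment)
  healthy - w * (healthy - baseline_arch(s, params))
}

quantize_clip <- function(force, params) {
  q <- params$quantization_step
  if (q > 0) {
    force <- round(force / q) * q
    lo <- ceiling(params$clip_tension / q) * q
    hi <- floor(params$clip_compression / q) * q
  } else {
    lo <- params$clip_tension
    hi <- params$clip_compression
  }
  pmin(pmax(force, lo), hi)
}

# evaluate code under a temporary RNG state seeded with `seed`
with_local_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Built-in healthy reference step, ready for scoring
#'
#' The noiseless healthy stance curve restricted to its contact support
#' (samples above `threshold_fraction` of the peak) and expressed in
#' body-weight units — i.e. processed exactly like a measured step coming
#' out of [detect_steps()] and [normalize_amplitude()], so reference and
#' measurement are compared on the same footing.
#'
#' @param params A [gait_params] object.
#' @param threshold_fraction Contact threshold, matching the one used for
#'   step detection.
#' @return Numeric vector of dimensionless (BW) samples.
#' @export
reference_step <- function(params = gait_params(), threshold_fraction = 0.05) {
  f <- healthy_step(params)
  f[f > threshold_fraction * max(f)] / params$body_weight
}

#' Simulate a multi-step force-plate trial
#'
#' Concatenates `n_steps` stance curves separated (and flanked) by
#' zero-force baseline, then applies the plate model: additive Gaussian
#' sensor noise (`noise_sd` x body weight), quantization to the plate
#' resolution and saturation clipping. Ground-truth step windows are
#' recorded from the noiseless curve using the same relative contact
#' threshold that step detection defaults to (force above
#' `contact_fraction` of the trial peak).
#'
#' @param params A [gait_params]; its `seed` drives the noise stream.
#' @param impairment An [impairment_profile]; default healthy.
#' @param n_steps Number of steps in the trial.
#' @param inter_step_gap Baseline duration between steps, in seconds.
#' @param contact_fraction Relative threshold defining the ground-truth
#'   contact windows.
#' @param foot_label,subject_id Passed to the output signal.
#' @return A list of class `synthetic_trial`: `signal` (a [force_signal]),
#'   `true_step_windows` (2-column matrix of 0-based half-open sample
#'   windows), `params`, `impairment`, `seed`.
#' @export
synth_trial <- function(params, impairment = impairment_profile(),
                        n_steps = 10L, inter_step_gap = 0.5,
                        contact_fraction = 0.05,
                        foot_label = "unknown", subject_id = "") {
  stopifnot(inherits(params, "gait_params"), n_steps >= 1,
            inter_step_gap >= 0)
  step <- impaired_step(params, impairment)
  step_len <- length(step)
  gap_len <- round(inter_step_gap * params$sample_rate)
  total <- n_steps * step_len + (n_steps + 1L) * gap_len
  ideal <- numeric(total)
  starts <- gap_len + (seq_len(n_steps) - 1L) * (step_len + gap_len)  # 0-based
  for (s0 in starts) ideal[(s0 + 1L):(s0 + step_len)] <- step

  peak <- max(ideal)
  windows <- matrix(NA_integer_, nrow = n_steps, ncol = 2,
                    dimnames = list(NULL, c("start", "end")))
  for (i in seq_len(n_steps)) {
    rng <- (starts[i] + 1L):(starts[i] + step_len)
    above <- which(ideal[rng] > contact_fraction * peak)
    windows[i, ] <- c(starts[i] + above[1] - 1L, starts[i] + above[length(above)])
  }

  force <- with_local_seed(params$seed, {
    ideal + stats::rnorm(total, sd = params$noise_sd * params$body_weight)
  })
  force <- quantize_clip(force, params)
  signal <- force_signal(time = (seq_len(total) - 1L) / params$sample_rate,
                         force = force, sample_rate = params$sample_rate,
                         foot_label = foot_label, subject_id = subject_id)
  structure(list(signal = signal, true_step_windows = windows,
                 params = params, impairment = impairment,
                 seed = params$seed),
            class = "synthetic_trial")
}

#' Simulate a before/after pair of trials for one subject
#'
#' Generates two trials sharing the physiological parameters but with
#' different impairment severities and independent noise streams derived
#' from `seed`. Stance durations default to a slower pre-treatment gait
#' (1.18 s before vs 1.01 s after, against a 1.025 s reference), so the
#' compared sequences naturally differ in length.
#'
#' @param params A [gait_params] (reference-condition parameters).
#' @param severity_before,severity_after Impairment severities in `[0, 1]`.
#' @param n_steps Steps per trial.
#' @param seed Integer master seed for the pair.
#' @param stance_before,stance_after Stance durations (s) for the two
#'   conditions.
#' @param ... Further arguments passed to [synth_trial()].
#' @return A list with elements `before` and `after` (each a
#'   `synthetic_trial`) plus the true severities.
#' @export
synth_subject_pair <- function(params = gait_params(),
                               severity_before, severity_after,
                               n_steps = 10L, seed = 1L,
                               stance_before = 1.18, stance_after = 1.01,
                               ...) {
  sub_seeds <- with_local_seed(as.integer(seed),
                               sample.int(.Machine$integer.max - 1L, 2L))
  p_before <- params
  p_before$stance_duration <- stance_before
  p_before$seed <- sub_seeds[1]
  p_after <- params
  p_after$stance_duration <- stance_after
  p_after$seed <- sub_seeds[2]
  list(
    before = synth_trial(p_before,
                         impairment_profile(severity = severity_before),
                         n_steps = n_steps, ...),
    after = synth_trial(p_after,
                        impairment_profile(severity = severity_after),
                        n_steps = n_steps, ...),
    severity_before = severity_before,
    severity_after = severity_after
  )
}
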