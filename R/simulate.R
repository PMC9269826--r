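# Synthetic multi-channel rPPG signal generator.
#
# Emulates what the pipeline assumes about real recordings: a cardiac
# sinusoid riding on per-channel DC baselines, additive Gaussian sensor
# noise, an optional linear illumination trend, variable frame rates
# (3-30 fps) with timestamp jitter, a face-to-camera distance profile,
# and an oxygenation-dependent IR/red level obtained by inverting the
# ratiometric SpO2 relation so the forward pipeline recovers the
# configured trajectory.

#' Simulation configuration
#'
#' Defaults are the package's reference study conditions: 60 s at a
#' nominal 30 fps for both streams, 1 ms timestamp jitter, constant
#' 72 BPM / 97 % SpO2, colour baselines (R 120, G 90, B 70 camera units)
#' with cardiac amplitudes (R 1.5, G 2.0, B 1.0, IR 1.5; green carries
#' the strongest pulse), noise sd 0.2 (10 % of the green amplitude), no
#' trend, and a constant 0.5 m distance.
#'
#' @param duration_s recording length in seconds.
#' @param fps_colour,fps_ir nominal frame rates (3-30).
#' @param fps_colour_per_second,fps_ir_per_second optional integer
#'   vectors (length `duration_s`) of per-second frame counts, modelling
#'   frame drops; override the nominal rate.
#' @param jitter_ms timestamp jitter standard deviation (ms).
#' @param hr heart-rate trajectory: `list(type = "constant", value =)`,
#'   `list(type = "ramp", from =, to =)` or
#'   `list(type = "walk", start =, sd =)` (bounded random walk), BPM,
#'   within \[39, 200\].
#' @param spo2 SpO2 trajectory: `list(type = "constant", value =)` or
#'   `list(type = "ramp", from =, to =)`, percent, within \[70, 100\].
#' @param baseline named list of colour DC levels (`R`, `G`, `B`); the IR
#'   baseline is derived from the SpO2 trajectory.
#' @param amplitude named list of cardiac amplitudes (`R`, `G`, `B`,
#'   `IR`), intensity units; at least one must be positive.
#' @param noise_sd additive Gaussian noise sd, intensity units.
#' @param trend_slope linear trend, intensity units per second.
#' @param distance `list(type = "constant", value =)` or
#'   `list(type = "ramp", from =, to =)`, metres.
#' @param state recording-state label for the generated store.
#' @param seed integer seed; every random element (jitter, walk, noise)
#'   is drawn from a stream seeded by it.
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(duration_s = 60, fps_colour = 30, fps_ir = 30,
                       fps_colour_per_second = NULL,
                       fps_ir_per_second = NULL,
                       jitter_ms = 1,
                       hr = list(type = "constant", value = 72),
                       spo2 = list(type = "constant", value = 97),
                       baseline = list(R = 120, G = 90, B = 70),
                       amplitude = list(R = 1.5, G = 2.0, B = 1.0,
                                        IR = 1.5),
                       noise_sd = 0.2, trend_slope = 0,
                       distance = list(type = "constant", value = 0.5),
                       state = "resting1", seed = 1L) {
  if (duration_s < 1) stop_validation("duration_s must be >= 1")
  for (fps in c(fps_colour, fps_ir)) {
    if (fps < 3 || fps > 30) stop_validation("fps must be in [3, 30]")
  }
  hr_pts <- switch(hr$type,
                   constant = hr$value,
                   ramp = c(hr$from, hr$to),
                   walk = hr$start,
                   stop_validation("unknown hr trajectory type: ", hr$type))
  if (any(hr_pts < 39 | hr_pts > 200)) {
    stop_validation("HR trajectory must stay within [39, 200] BPM")
  }
  spo2_pts <- switch(spo2$type,
                     constant = spo2$value,
                     ramp = c(spo2$from, spo2$to),
                     stop_validation("unknown spo2 trajectory type: ",
                                     spo2$type))
  if (any(spo2_pts < 70 | spo2_pts > 100)) {
    stop_validation("SpO2 trajectory must stay within [70, 100] %")
  }
  if (all(unlist(amplitude) <= 0)) {
    stop_validation("at least one channel amplitude must be positive")
  }
  structure(list(duration_s = duration_s, fps_colour = fps_colour,
                 fps_ir = fps_ir,
                 fps_colour_per_second = fps_colour_per_second,
                 fps_ir_per_second = fps_ir_per_second,
                 jitter_ms = jitter_ms, hr = hr, spo2 = spo2,
                 baseline = baseline, amplitude = amplitude,
                 noise_sd = noise_sd, trend_slope = trend_slope,
                 distance = distance, state = state,
                 seed = as.integer(seed)),
            class = "sim_config")
}

# Per-second trajectory values for seconds 0 .. n-1 (walk draws from the
# current RNG stream).
trajectory_values <- function(traj, n, lower, upper) {
  switch(traj$type,
    constant = rep(traj$value, n),
    ramp = seq(traj$from, traj$to, length.out = n),
    walk = {
      steps <- rnorm(n - 1, 0, traj$sd)
      pmin(pmax(cumsum(c(traj$start, steps)), lower), upper)
    }
  )
}

#' Generate a per-second ground-truth trace
#'
#' Deterministic given the config seed; stands in for a contact
#' pulse-oximeter reference.
#'
#' @param config a [sim_config()].
#' @return a `ground_truth_trace` of `duration_s` seconds.
#' @export
generate_ground_truth <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  n <- config$duration_s
  with_local_seed(config$seed, {
    hr <- trajectory_values(config$hr, n, 39, 200)
    spo2 <- trajectory_values(config$spo2, n, 70, 100)
    ground_truth_trace(seq.int(0L, n - 1L), hr, spo2)
  })
}

# Frame timestamps (ms) for one stream: per-second counts, even spacing
# within each second, Gaussian jitter clamped inside the second.
stream_timestamps <- function(duration_s, nominal_fps, per_second,
                              jitter_ms) {
  counts <- if (is.null(per_second)) {
    rep(as.integer(nominal_fps), duration_s)
  } else {
    if (length(per_second) != duration_s) {
      stop_validation("per-second fps override must have length duration_s")
    }
    as.integer(per_second)
  }
  ts <- numeric(0)
  for (k in seq_len(duration_s) - 1L) {
    n <- counts[k + 1L]
    if (n == 0L) next
    base <- k * 1000 + (seq_len(n) - 1) * 1000 / n
    jit <- rnorm(n, 0, jitter_ms)
    t <- pmin(pmax(base + jit, k * 1000), k * 1000 + 999.5)
    ts <- c(ts, sort(t))
  }
  # enforce strict monotonicity against pathological jitter collisions
  for (i in seq_along(ts)[-1]) {
    if (ts[i] <= ts[i - 1]) ts[i] <- ts[i - 1] + 1e-6
  }
  ts
}

#' Generate a synthetic region store
#'
#' Every channel value is
#' `baseline + amplitude * sin(2*pi*phase(t)) + trend_slope * t + noise`
#' with `phase(t)` the integral of the instantaneous cardiac frequency
#' `HR(t) / 60`. The grey channel is derived from the generated noisy R,
#' G, B exactly as the reader would derive it. The red and IR DC levels
#' are coupled, per second, by algebraically inverting the ratiometric
#' SpO2 relation at the systolic peak (baseline plus amplitude, scaled by
#' the configured distance), so that the forward SpO2 computation
#' recovers the configured trajectory. All five face regions carry the
#' same underlying pulse with independent noise realisations.
#'
#' @param truth a `ground_truth_trace` (typically from
#'   [generate_ground_truth()]).
#' @param config a [sim_config()].
#' @param table haemoglobin [load_extinction_table()].
#' @param params [spo2_params()] used for the encoding.
#' @return a validated `region_store`.
#' @export
generate_region_store <- function(truth, config,
                                  table = load_extinction_table(),
                                  params = spo2_params()) {
  stopifnot(inherits(truth, "ground_truth_trace"),
            inherits(config, "sim_config"))
  dur <- config$duration_s
  if (length(truth$seconds) < dur) {
    stop_validation("ground truth shorter than configured duration")
  }

  dist_at <- function(t_ms) {
    d <- config$distance
    switch(d$type,
           constant = rep(d$value, length(t_ms)),
           ramp = d$from + (d$to - d$from) * (t_ms / 1000) / dur,
           stop_validation("unknown distance type: ", d$type))
  }
  # validate invertibility on the per-second targets first, so an
  # out-of-range trajectory surfaces as a configuration error
  invisible(ratio_for_spo2(truth$spo2_pct[seq_len(dur)], table, params))
  # smooth per-frame target: a stepped DC level would inject a spurious
  # 1 Hz comb into the IR spectrum
  spo2_at <- function(t_ms) {
    approx(x = truth$seconds[seq_len(dur)] + 0.5,
           y = truth$spo2_pct[seq_len(dur)],
           xout = t_ms / 1000, rule = 2)$y
  }
  K_at <- function(t_ms) {
    ratio_for_spo2(spo2_at(t_ms), table, params) * params$scaling *
      (table$ir_oxy / table$red_oxy)
  }

  with_local_seed(config$seed, {
    ts_col <- stream_timestamps(dur, config$fps_colour,
                                config$fps_colour_per_second,
                                config$jitter_ms)
    ts_ir <- stream_timestamps(dur, config$fps_ir,
                               config$fps_ir_per_second,
                               config$jitter_ms)
    if (length(ts_col) < 2L || length(ts_ir) < 2L) {
      stop_validation("configuration yields too few frames")
    }

    # cardiac phase on a fine grid, then interpolated to frame times
    grid <- seq(0, dur, by = 0.004)
    hr_inst <- approx(x = truth$seconds[seq_len(dur)] + 0.5,
                      y = truth$hr_bpm[seq_len(dur)],
                      xout = grid, rule = 2)$y
    f_inst <- hr_inst / 60
    phase_grid <- c(0, cumsum((f_inst[-1] + f_inst[-length(f_inst)]) / 2 *
                                diff(grid)))
    phase_at <- function(t_ms) {
      approx(grid, phase_grid, xout = t_ms / 1000, rule = 2)$y
    }
    pulse_col <- sin(2 * pi * phase_at(ts_col))
    pulse_ir <- sin(2 * pi * phase_at(ts_ir))
    trend_col <- config$trend_slope * ts_col / 1000
    trend_ir <- config$trend_slope * ts_ir / 1000

    red_peak <- config$baseline$R + config$amplitude$R
    b_ir_col <- K_at(ts_ir) * red_peak / dist_at(ts_ir) -
      config$amplitude$IR
    if (any(b_ir_col <= 0)) {
      stop_validation("SpO2/distance configuration gives non-positive ",
                      "IR baseline")
    }

    regions <- list()
    for (rg in REGION_LABELS) {
      noisy <- function(clean) clean + rnorm(length(clean), 0,
                                             config$noise_sd)
      rv <- noisy(config$baseline$R + config$amplitude$R * pulse_col +
                    trend_col)
      gv <- noisy(config$baseline$G + config$amplitude$G * pulse_col +
                    trend_col)
      bv <- noisy(config$baseline$B + config$amplitude$B * pulse_col +
                    trend_col)
      iv <- noisy(b_ir_col + config$amplitude$IR * pulse_ir + trend_ir)
      regions[[rg]] <- list(
        R = channel_series("R", ts_col, rv),
        G = channel_series("G", ts_col, gv),
        B = channel_series("B", ts_col, bv),
        Gy = channel_series("Gy", ts_col, compute_grey(rv, gv, bv)),
        IR = channel_series("IR", ts_ir, iv)
      )
    }
    distance <- list(timestamps = ts_col, metres = dist_at(ts_col))
    region_store(regions, distance,
                 participant_id = sprintf("SIM-%d", config$seed),
                 state = config$state)
  })
}
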