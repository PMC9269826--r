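# Sliding-window orchestration: align -> preprocess -> separate ->
# spectrum -> peak/SNR -> HR, plus the grey/raw SpO2 pathway and the
# reliability gate.

#' Pipeline configuration
#'
#' Defaults are the method's operating point: 15 s windows slid by 1 s,
#' cardiac band 0.66-3.33 Hz, SNR threshold 5.0, deviation acceptance
#' factor 0.18, fps-adaptive pre-processing, FastICA applied once on the
#' joint five-channel matrix, and last-second ground-truth alignment.
#'
#' @param window_s window length, seconds.
#' @param step_s sliding step, seconds (0 < step <= window).
#' @param band cardiac passband `(low, high)` in Hz.
#' @param snr_threshold minimum SNR for a new estimate to be accepted.
#' @param deviation_factor maximum relative change between consecutive
#'   accepted estimates (0-1).
#' @param preprocess `"auto"` (technique 6, or 7 below 15 fps) or a fixed
#'   technique id 1-7.
#' @param separation a [separation_spec()].
#' @param spo2 a [spo2_params()].
#' @param gt_alignment `"last"` or `"average"` (see
#'   [align_ground_truth()]).
#' @param seed integer seed forwarded to stochastic separation methods.
#' @return an object of class `pipeline_config`.
#' @export
pipeline_config <- function(window_s = 15, step_s = 1,
                            band = c(0.66, 3.33), snr_threshold = 5.0,
                            deviation_factor = 0.18, preprocess = "auto",
                            separation = separation_spec(seed = seed),
                            spo2 = spo2_params(),
                            gt_alignment = "last", seed = 1L) {
  if (!(step_s > 0 && step_s <= window_s)) {
    stop_validation("need 0 < step_s <= window_s")
  }
  if (!(band[1] < band[2])) stop_validation("band[1] must be < band[2]")
  if (snr_threshold <= 0) stop_validation("snr_threshold must be > 0")
  if (!(deviation_factor > 0 && deviation_factor < 1)) {
    stop_validation("deviation_factor must be in (0, 1)")
  }
  if (!identical(preprocess, "auto") && !preprocess %in% 1:7) {
    stop_validation("preprocess must be 'auto' or a technique id 1-7")
  }
  if (!gt_alignment %in% c("last", "average")) {
    stop_validation("gt_alignment must be 'last' or 'average'")
  }
  structure(list(window_s = window_s, step_s = step_s, band = band,
                 snr_threshold = snr_threshold,
                 deviation_factor = deviation_factor,
                 preprocess = preprocess, separation = separation,
                 spo2 = spo2, gt_alignment = gt_alignment,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Sliding-window bounds
#'
#' Windows `[k*step, k*step + window]` for
#' `k = 0 .. floor((duration - window) / step)`.
#'
#' @param duration_s recording length, seconds (>= `window_s`).
#' @param window_s window length, seconds.
#' @param step_s step, seconds.
#' @return data frame with columns `start_s`, `end_s`.
#' @export
slide <- function(duration_s, window_s = 15, step_s = 1) {
  if (duration_s < window_s) {
    stop_validation("recording shorter than one window")
  }
  starts <- seq(0, duration_s - window_s, by = step_s)
  data.frame(start_s = starts, end_s = starts + window_s)
}

#' Reliability gate for a new vital-sign measurement
#'
#' The first measurement is accepted unconditionally. Afterwards a new
#' measurement is rejected — and the previous values held, flagged
#' `accepted = FALSE` — when its SNR falls below the threshold or when
#' either vital deviates from the previously held value by more than the
#' deviation factor (relative change). Vital signs change gradually; a
#' stable 60 BPM does not leap to 144 BPM for one second.
#'
#' @param new_hr,new_spo2 newly measured values (may be `NA` when the
#'   window produced no estimate, which always holds the previous value).
#' @param snr SNR of the new measurement.
#' @param previous `NULL` or the previous estimate (list with `hr_bpm`,
#'   `spo2_pct`).
#' @param cfg a [pipeline_config()].
#' @return list with `hr_bpm`, `spo2_pct`, `snr`, `accepted`.
#' @export
reliability_gate <- function(new_hr, new_spo2, snr, previous, cfg) {
  if (is.null(previous) || is.na(previous$hr_bpm)) {
    return(list(hr_bpm = new_hr, spo2_pct = new_spo2, snr = snr,
                accepted = TRUE))
  }
  hold <- function() list(hr_bpm = previous$hr_bpm,
                          spo2_pct = previous$spo2_pct, snr = snr,
                          accepted = FALSE)
  if (is.na(new_hr) || is.na(snr) || snr < cfg$snr_threshold) {
    return(hold())
  }
  dev_hr <- abs(new_hr - previous$hr_bpm) / previous$hr_bpm
  if (dev_hr > cfg$deviation_factor) return(hold())
  if (!is.na(new_spo2) && !is.na(previous$spo2_pct) &&
      previous$spo2_pct > 0) {
    dev_spo2 <- abs(new_spo2 - previous$spo2_pct) / previous$spo2_pct
    if (dev_spo2 > cfg$deviation_factor) return(hold())
  }
  if (is.na(new_spo2)) new_spo2 <- previous$spo2_pct
  list(hr_bpm = new_hr, spo2_pct = new_spo2, snr = snr, accepted = TRUE)
}

# Per-second frame counts of every stream in the store, cached once.
store_fps_tables <- function(store) {
  out <- list()
  for (rg in names(store$regions)) {
    chans <- store$regions[[rg]]
    col_ch <- intersect(COLOUR_CHANNELS, names(chans))
    if (length(col_ch)) {
      out[[paste0(rg, ":colour")]] <-
        estimate_fps(chans[[col_ch[1]]]$timestamps)
    }
    if ("IR" %in% names(chans)) {
      out[[paste0(rg, ":IR")]] <- estimate_fps(chans$IR$timestamps)
    }
  }
  out
}

# Minimum per-second frame count across all streams over full seconds
# [start_s, end_s).
window_fps <- function(fps_tables, start_s, end_s) {
  secs <- seq.int(start_s + 1L, end_s)      # 1-based second indices
  mins <- vapply(fps_tables, function(tab) {
    have <- secs[secs <= length(tab)]
    if (!length(have)) return(NA_real_)
    min(tab[have])
  }, numeric(1))
  mins <- mins[!is.na(mins)]
  if (!length(mins)) return(NA_real_)
  min(mins)
}

#' Run the full pipeline over a recording
#'
#' For every sliding window: estimate the window's frame rate (minimum
#' per-second count across streams), select the pre-processing technique
#' (fps-adaptive under `preprocess = "auto"`), then per region align the
#' channels onto the colour grid, pre-process every row, extract
#' candidate components with the configured separation method, score
#' each candidate's dominant in-band spectral peak by SNR, and select
#' the best candidate across all regions for HR. SpO2 is computed from
#' the winning region's raw grey pulse waveform with raw red/IR and
#' distance at the pulse peaks. The reliability gate compares each
#' window against the previously held estimate. Regions with too few
#' samples are skipped (with a message); a window with no usable
#' candidate inherits the previous estimate, flagged not-accepted.
#'
#' @param store a validated `region_store`.
#' @param cfg a [pipeline_config()].
#' @param verbose emit per-window messages for skipped regions.
#' @return data frame of per-window estimates with columns
#'   `window_end_s`, `hr_bpm`, `spo2_pct`, `snr`, `region`, `provenance`,
#'   `accepted`, `technique`, `fps`.
#' @export
process_participant <- function(store, cfg = pipeline_config(),
                                verbose = FALSE) {
  validate_region_store(store)
  stopifnot(inherits(cfg, "pipeline_config"))
  max_ts <- max(vapply(store$regions, function(chans) {
    max(vapply(chans, function(cs) max(cs$timestamps), numeric(1)))
  }, numeric(1)))
  duration_s <- floor(max_ts / 1000) + 1L
  windows <- slide(duration_s, cfg$window_s, cfg$step_s)
  fps_tables <- store_fps_tables(store)
  table <- load_extinction_table()

  previous <- NULL
  rows <- vector("list", nrow(windows))
  for (w in seq_len(nrow(windows))) {
    bounds <- c(windows$start_s[w], windows$end_s[w]) * 1000
    fps_w <- window_fps(fps_tables, windows$start_s[w], windows$end_s[w])
    technique <- if (identical(cfg$preprocess, "auto")) {
      if (is.na(fps_w) || fps_w <= 0) 7L else select_technique_auto(fps_w)
    } else {
      as.integer(cfg$preprocess)
    }

    candidates <- list()
    aligned <- list()
    for (rg in intersect(REGION_LABELS, names(store$regions))) {
      M <- tryCatch(align_channels(store$regions[[rg]], bounds),
                    error = function(e) {
                      if (verbose) message("window ", w, ": skipping ",
                                           rg, ": ", conditionMessage(e))
                      NULL
                    })
      if (is.null(M)) next
      aligned[[rg]] <- M
      grid_ts <- attr(M, "timestamps")
      fs_in <- attr(M, "fs")
      proc <- lapply(seq_len(nrow(M)), function(i) {
        apply_technique(M[i, ], grid_ts, technique)
      })
      P <- do.call(rbind, proc)
      rownames(P) <- rownames(M)
      fs_eff <- fs_in * ncol(P) / ncol(M)
      cands <- tryCatch(separate(P, cfg$separation),
                        error = function(e) {
                          if (verbose) message("window ", w,
                                               ": separation failed for ",
                                               rg, ": ",
                                               conditionMessage(e))
                          list()
                        })
      for (cand in cands) {
        spec <- tryCatch(
          bandpass(magnitude_spectrum(cand$values, fs_eff),
                   cfg$band[1], cfg$band[2]),
          error = function(e) NULL)
        if (is.null(spec)) next
        pk <- tryCatch(dominant_peak(spec), error = function(e) NULL)
        if (is.null(pk)) next
        prov <- if (cand$method %in% c("none")) {
          cand$source
        } else {
          paste0(cand$method, ":", cand$index)
        }
        candidates[[length(candidates) + 1L]] <-
          vital_candidate(rg, prov, pk$frequency, pk$magnitude,
                          snr(spec, pk$magnitude))
      }
    }

    if (length(candidates)) {
      best <- select_best(candidates)
      new_hr <- best$hr_bpm
      best_snr <- best$snr
      sp <- tryCatch({
        M <- aligned[[best$region]]
        chans <- store$regions[[best$region]]
        spo2_window(M["Gy", ], attr(M, "timestamps"), chans$R, chans$IR,
                    store$distance, table, cfg$spo2, cfg$band)$spo2_pct
      }, error = function(e) NA_real_)
      gated <- reliability_gate(new_hr, sp, best_snr, previous, cfg)
      region <- best$region
      prov <- best$provenance
    } else {
      gated <- reliability_gate(NA_real_, NA_real_, NA_real_, previous,
                                cfg)
      region <- NA_character_
      prov <- NA_character_
    }
    previous <- gated
    rows[[w]] <- data.frame(
      window_end_s = windows$end_s[w], hr_bpm = gated$hr_bpm,
      spo2_pct = gated$spo2_pct, snr = gated$snr, region = region,
      provenance = prov, accepted = gated$accepted,
      technique = technique, fps = fps_w, stringsAsFactors = FALSE
    )
  }
  do.call(rbind, rows)
}
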