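# Region-store data model and file I/O, plus the small acquisition-side
# operations (grey channel, spatial pooling, fps estimation, colour->IR
# box mapping).

#' Construct a channel series
#'
#' A single region/channel signal: spatially pooled pixel intensity per
#' frame with millisecond timestamps.
#'
#' @param channel one of `"R"`, `"G"`, `"B"`, `"Gy"`, `"IR"`.
#' @param timestamps numeric vector, milliseconds since acquisition start,
#'   strictly increasing.
#' @param values numeric vector of pooled intensities (arbitrary camera
#'   units), same length as `timestamps`, all finite.
#' @return an object of class `channel_series`.
#' @export
channel_series <- function(channel, timestamps, values) {
  if (!is.character(channel) || length(channel) != 1L ||
      !channel %in% CHANNEL_LABELS) {
    stop_validation("unknown channel label: ", channel)
  }
  timestamps <- as.numeric(timestamps)
  values <- as.numeric(values)
  if (length(timestamps) != length(values)) {
    stop_validation("channel ", channel,
                    ": timestamps and values differ in length")
  }
  if (length(timestamps) > 1L && any(diff(timestamps) <= 0)) {
    stop_validation("channel ", channel,
                    ": timestamps must be strictly increasing")
  }
  if (any(!is.finite(values))) {
    stop_validation("channel ", channel, ": values must be finite")
  }
  structure(list(channel = channel, timestamps = timestamps,
                 values = values),
            class = "channel_series")
}

#' Construct a region store
#'
#' Container for one participant/state recording: per-region, per-channel
#' pooled intensity series plus a timestamped face-to-camera distance
#' trace. Colour-stream channels (R, G, B, Gy) of a region must share one
#' timestamp vector; IR may run on its own clock.
#'
#' @param regions named list: region label (`forehead`, `right_cheek`,
#'   `left_cheek`, `cheeks_nose`, `lips`) -> named list of
#'   [channel_series()] keyed by channel.
#' @param distance list with numeric `timestamps` (ms) and `metres`
#'   (face-to-camera distance, 0 < d < 10).
#' @param participant_id,state identification labels; `state` is one of
#'   `"resting1"`, `"resting2"`, `"active"`.
#' @return an object of class `region_store`.
#' @export
region_store <- function(regions, distance,
                         participant_id = "unknown", state = "resting1") {
  store <- structure(
    list(participant_id = participant_id, state = state,
         regions = regions, distance = distance),
    class = "region_store"
  )
  validate_region_store(store)
}

#' Validate a region store
#'
#' Checks all structural invariants: known region and channel labels, at
#' least one channel per region, strictly increasing timestamps, shared
#' colour-stream timestamps within a region, finite values and distance
#' in (0, 10) metres.
#'
#' @param store a `region_store`.
#' @return `store`, invisibly-validated (errors otherwise).
#' @export
validate_region_store <- function(store) {
  if (!inherits(store, "region_store")) {
    stop_validation("not a region_store")
  }
  if (!store$state %in% c("resting1", "resting2", "active")) {
    stop_validation("unknown state label: ", store$state)
  }
  if (length(store$regions) == 0L) {
    stop_validation("region store has no regions")
  }
  bad_region <- setdiff(names(store$regions), REGION_LABELS)
  if (length(bad_region)) {
    stop_validation("unknown region label: ", bad_region[1])
  }
  for (rg in names(store$regions)) {
    chans <- store$regions[[rg]]
    if (length(chans) == 0L) {
      stop_validation("region ", rg, " has no channels")
    }
    colour_ts <- NULL
    for (ch in names(chans)) {
      cs <- chans[[ch]]
      if (!inherits(cs, "channel_series") || cs$channel != ch) {
        stop_validation("region ", rg, ": malformed series for ", ch)
      }
      # re-check monotonicity in case fields were edited after construction
      if (length(cs$timestamps) > 1L && any(diff(cs$timestamps) <= 0)) {
        stop_validation("region ", rg, "/", ch,
                        ": timestamps must be strictly increasing")
      }
      if (ch %in% COLOUR_CHANNELS) {
        if (is.null(colour_ts)) {
          colour_ts <- cs$timestamps
        } else if (!isTRUE(all.equal(colour_ts, cs$timestamps,
                                     tolerance = 0))) {
          stop_validation("region ", rg,
                          ": colour channels must share one timestamp vector")
        }
      }
    }
  }
  d <- store$distance
  if (!is.null(d) && length(d$metres)) {
    if (length(d$metres) != length(d$timestamps)) {
      stop_validation("distance timestamps/values differ in length")
    }
    if (any(!is.finite(d$metres)) || any(d$metres <= 0) ||
        any(d$metres >= 10)) {
      stop_validation("distance must be in (0, 10) metres")
    }
  }
  store
}

#' @export
print.region_store <- function(x, ...) {
  cat("<region_store> participant", x$participant_id,
      "state", x$state, "\n")
  for (rg in names(x$regions)) {
    chans <- x$regions[[rg]]
    n <- vapply(chans, function(cs) length(cs$values), integer(1))
    cat("  ", rg, ": ", paste0(names(chans), "[", n, "]",
                               collapse = " "), "\n", sep = "")
  }
  cat("  distance samples:", length(x$distance$metres), "\n")
  invisible(x)
}

#' Write a region store to a long-format CSV
#'
#' One row per (region, channel, frame) with columns
#' `region,channel,timestamp_ms,value,distance_m`. Distance is written on
#' colour rows whose timestamp matches a distance sample; other rows have
#' an empty distance field. Values are printed with 15 significant digits
#' so a write/read round trip is lossless at double precision.
#'
#' @param store a validated `region_store`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_region_store <- function(store, path) {
  validate_region_store(store)
  rows <- list()
  dist_ts <- store$distance$timestamps
  dist_m <- store$distance$metres
  for (rg in names(store$regions)) {
    for (ch in intersect(CHANNEL_LABELS, names(store$regions[[rg]]))) {
      cs <- store$regions[[rg]][[ch]]
      dcol <- rep(NA_real_, length(cs$timestamps))
      if (ch %in% COLOUR_CHANNELS && length(dist_ts)) {
        hit <- match(cs$timestamps, dist_ts)
        dcol[!is.na(hit)] <- dist_m[hit[!is.na(hit)]]
      }
      rows[[length(rows) + 1L]] <- data.frame(
        region = rg, channel = ch,
        timestamp_ms = cs$timestamps, value = cs$values,
        distance_m = dcol, stringsAsFactors = FALSE
      )
    }
  }
  df <- do.call(rbind, rows)
  num <- function(v) ifelse(is.na(v), "", sprintf("%.15g", v))
  out <- data.frame(region = df$region, channel = df$channel,
                    timestamp_ms = num(df$timestamp_ms),
                    value = num(df$value),
                    distance_m = num(df$distance_m),
                    stringsAsFactors = FALSE)
  tryCatch(
    write.csv(out, path, row.names = FALSE, quote = FALSE),
    error = function(e) stop("cannot write region store: ",
                             conditionMessage(e))
  )
  invisible(path)
}

#' Read a region store from a long-format CSV
#'
#' Inverse of [write_region_store()]. Grey (`Gy`) rows may be omitted in
#' input files: when a region has R, G and B on a shared clock but no Gy,
#' the reader synthesizes Gy via [compute_grey()]. The distance trace is
#' collected from all rows with a non-empty `distance_m`.
#'
#' @param path input CSV path.
#' @param participant_id,state labels to attach (the file format does not
#'   carry them).
#' @return a validated `region_store`.
#' @export
read_region_store <- function(path, participant_id = "unknown",
                              state = "resting1") {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- read.csv(path, stringsAsFactors = FALSE,
                 colClasses = c(region = "character",
                                channel = "character"))
  required <- c("region", "channel", "timestamp_ms", "value", "distance_m")
  missing_col <- setdiff(required, names(df))
  if (length(missing_col)) {
    stop_format("region-store file missing column: ",
                paste(missing_col, collapse = ", "))
  }
  df$timestamp_ms <- as.numeric(df$timestamp_ms)
  df$value <- as.numeric(df$value)
  df$distance_m <- suppressWarnings(as.numeric(df$distance_m))
  bad_ch <- setdiff(unique(df$channel), CHANNEL_LABELS)
  if (length(bad_ch)) {
    stop_validation("unknown channel label: ", bad_ch[1])
  }
  regions <- list()
  for (rg in unique(df$region)) {
    sub <- df[df$region == rg, , drop = FALSE]
    chans <- list()
    for (ch in intersect(CHANNEL_LABELS, unique(sub$channel))) {
      rowset <- sub[sub$channel == ch, , drop = FALSE]
      chans[[ch]] <- channel_series(ch, rowset$timestamp_ms, rowset$value)
    }
    if (!"Gy" %in% names(chans) && all(c("R", "G", "B") %in% names(chans))) {
      chans[["Gy"]] <- channel_series(
        "Gy", chans$R$timestamps,
        compute_grey(chans$R$values, chans$G$values, chans$B$values)
      )
    }
    regions[[rg]] <- chans
  }
  with_dist <- df[!is.na(df$distance_m), , drop = FALSE]
  with_dist <- with_dist[!duplicated(with_dist$timestamp_ms), , drop = FALSE]
  with_dist <- with_dist[order(with_dist$timestamp_ms), , drop = FALSE]
  distance <- list(timestamps = with_dist$timestamp_ms,
                   metres = with_dist$distance_m)
  region_store(regions, distance, participant_id = participant_id,
               state = state)
}

#' Read a per-second ground-truth trace
#'
#' CSV with columns `second,hr_bpm,spo2_pct`; seconds must be contiguous
#' from 0, HR in \[30, 220\] BPM and SpO2 in \[50, 100\] %.
#'
#' @param path input CSV path.
#' @return an object of class `ground_truth_trace`.
#' @export
read_ground_truth <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- read.csv(path, stringsAsFactors = FALSE)
  missing_col <- setdiff(c("second", "hr_bpm", "spo2_pct"), names(df))
  if (length(missing_col)) {
    stop_format("ground-truth file missing column: ",
                paste(missing_col, collapse = ", "))
  }
  ground_truth_trace(df$second, df$hr_bpm, df$spo2_pct)
}

#' Construct a ground-truth trace
#'
#' @param seconds integer second index, contiguous from 0.
#' @param hr_bpm reference heart rate per second, \[30, 220\] BPM.
#' @param spo2_pct reference SpO2 per second, \[50, 100\] %.
#' @return an object of class `ground_truth_trace`.
#' @export
ground_truth_trace <- function(seconds, hr_bpm, spo2_pct) {
  seconds <- as.integer(seconds)
  n <- length(seconds)
  if (n == 0L || !identical(seconds, seq.int(0L, n - 1L))) {
    stop_validation("ground-truth seconds must be contiguous from 0")
  }
  if (length(hr_bpm) != n || length(spo2_pct) != n) {
    stop_validation("ground-truth column lengths differ")
  }
  if (any(hr_bpm < 30 | hr_bpm > 220)) {
    stop_validation("ground-truth HR outside [30, 220] BPM")
  }
  if (any(spo2_pct < 50 | spo2_pct > 100)) {
    stop_validation("ground-truth SpO2 outside [50, 100] %")
  }
  structure(list(seconds = seconds, hr_bpm = as.numeric(hr_bpm),
                 spo2_pct = as.numeric(spo2_pct)),
            class = "ground_truth_trace")
}

#' Write a ground-truth trace to CSV
#'
#' @param gt a `ground_truth_trace`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_ground_truth <- function(gt, path) {
  stopifnot(inherits(gt, "ground_truth_trace"))
  write.csv(data.frame(second = gt$seconds, hr_bpm = gt$hr_bpm,
                       spo2_pct = gt$spo2_pct),
            path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Grey channel from R, G, B intensities
#'
#' The grey (Gy) channel is the plain average `(r + g + b) / 3` in double
#' precision, computed per frame.
#'
#' @param r,g,b finite intensities (vectorised).
#' @return grey intensity.
#' @export
compute_grey <- function(r, g, b) {
  if (any(!is.finite(r)) || any(!is.finite(g)) || any(!is.finite(b))) {
    stop_validation("compute_grey requires finite inputs")
  }
  (r + g + b) / 3
}

#' Spatially pool a pixel patch
#'
#' Averages all pixels of a region-of-interest patch into one intensity,
#' suppressing per-pixel noise.
#'
#' @param pixels non-empty numeric matrix (or array) of intensities.
#' @return scalar mean intensity.
#' @export
spatial_pool <- function(pixels) {
  if (length(pixels) == 0L) stop_validation("empty pixel patch")
  mean(as.numeric(pixels))
}

#' Per-second frame counts from timestamps
#'
#' `fps[k]` is the number of timestamps `t` with
#' `k*1000 <= t < (k+1)*1000`, for `k` from 0 up to the second containing
#' the last timestamp. The counts always sum to the number of samples.
#'
#' @param timestamps millisecond timestamps, non-decreasing.
#' @return integer vector of per-second counts (length 0 for empty input).
#' @export
estimate_fps <- function(timestamps) {
  if (length(timestamps) == 0L) return(integer(0))
  if (any(diff(timestamps) < 0)) {
    stop_validation("timestamps must be monotonic")
  }
  sec <- floor(timestamps / 1000)
  tabulate(sec + 1L, nbins = max(sec) + 1L)
}

#' Map a colour-frame bounding box into IR-frame pixels
#'
#' The colour and IR sensors share the scene but differ in resolution;
#' a face box found in the colour frame is carried to the IR frame by
#' dividing each coordinate by the width ratio `colour_w / ir_w` or height
#' ratio `colour_h / ir_h`, flooring to integer pixels, and clipping
#' inside the IR frame.
#'
#' @param box numeric `(x, y, w, h)` in colour pixels.
#' @param colour_dims `(width, height)` of the colour frame; default
#'   1920 x 1080.
#' @param ir_dims `(width, height)` of the IR frame; default 512 x 424.
#' @return integer `(x, y, w, h)` in IR pixels.
#' @export
map_colour_box_to_ir <- function(box, colour_dims = c(1920, 1080),
                                 ir_dims = c(512, 424)) {
  stopifnot(length(box) == 4, length(colour_dims) == 2, length(ir_dims) == 2)
  x <- box[1]; y <- box[2]; w <- box[3]; h <- box[4]
  if (x < 0 || y < 0 || w < 0 || h < 0 ||
      x + w > colour_dims[1] || y + h > colour_dims[2]) {
    stop_validation("box outside colour frame")
  }
  rw <- colour_dims[1] / ir_dims[1]
  rh <- colour_dims[2] / ir_dims[2]
  out <- floor(c(x / rw, y / rh, w / rw, h / rh))
  out[1] <- min(max(out[1], 0), ir_dims[1])
  out[2] <- min(max(out[2], 0), ir_dims[2])
  out[3] <- min(out[3], ir_dims[1] - out[1])
  out[4] <- min(out[4], ir_dims[2] - out[2])
  as.integer(out)
}
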