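# Ground-truth alignment and the evaluation metrics (mean difference,
# mean absolute difference, population SD of the error, RMSE, Pearson r).

#' Align a per-second ground truth to sliding windows
#'
#' `method = "last"` takes the ground-truth value at each window's final
#' second (the default: against a moving reference the freshest value
#' compares slightly better); `method = "average"` takes the mean over
#' the window's seconds.
#'
#' @param gt a `ground_truth_trace`.
#' @param windows data frame from [slide()] (`start_s`, `end_s`).
#' @param method `"last"` or `"average"`.
#' @return data frame with per-window `hr_ref` and `spo2_ref`.
#' @export
align_ground_truth <- function(gt, windows, method = "last") {
  stopifnot(inherits(gt, "ground_truth_trace"))
  if (!method %in% c("last", "average")) {
    stop_validation("method must be 'last' or 'average'")
  }
  if (max(windows$end_s) > length(gt$seconds)) {
    stop_validation("ground truth shorter than the recording")
  }
  if (method == "last") {
    idx <- windows$end_s                # second end-1, 1-based
    data.frame(hr_ref = gt$hr_bpm[idx], spo2_ref = gt$spo2_pct[idx])
  } else {
    refs <- t(vapply(seq_len(nrow(windows)), function(i) {
      secs <- (windows$start_s[i] + 1):windows$end_s[i]
      c(mean(gt$hr_bpm[secs]), mean(gt$spo2_pct[secs]))
    }, numeric(2)))
    data.frame(hr_ref = refs[, 1], spo2_ref = refs[, 2])
  }
}

#' Error metrics between reference and estimated vitals
#'
#' With error `e = reference - estimate`: mean difference `mean(e)`, mean
#' absolute difference `mean(|e|)`, standard deviation of the error in
#' population form (divisor N), RMSE `sqrt(mean(e^2))`, and the Pearson
#' product-moment correlation between reference and estimate. These
#' satisfy `rmse^2 = mean_diff^2 + sd_error^2`.
#'
#' @param reference,estimates equal-length numeric vectors (length >= 1;
#'   >= 2 with non-zero variance for `pearson_r`, otherwise `NA`).
#' @param vital label, `"HR"` or `"SpO2"`.
#' @param labels optional named list of grouping labels carried through
#'   to the report (state, algorithm, technique, ...).
#' @return an object of class `metric_report` (also a one-row data frame
#'   via [as.data.frame()]).
#' @export
compute_metrics <- function(reference, estimates, vital = "HR",
                            labels = list()) {
  n <- length(reference)
  if (n == 0L || length(estimates) != n) {
    stop_validation("reference and estimates must be equal length >= 1")
  }
  keep <- !is.na(reference) & !is.na(estimates)
  reference <- reference[keep]
  estimates <- estimates[keep]
  n <- length(reference)
  if (n == 0L) stop_validation("no comparable (non-missing) pairs")
  e <- reference - estimates
  r <- if (n >= 2 && sd(reference) > 0 && sd(estimates) > 0) {
    cor(reference, estimates)
  } else {
    NA_real_
  }
  structure(list(vital = vital, n = n,
                 mean_diff = mean(e),
                 mean_abs_diff = mean(abs(e)),
                 sd_error = sqrt(mean((e - mean(e))^2)),
                 rmse = sqrt(mean(e^2)),
                 pearson_r = r,
                 labels = labels),
            class = "metric_report")
}

#' @export
print.metric_report <- function(x, ...) {
  cat(sprintf(
    "<metric_report> %s (n = %d): mean diff %.3f, |diff| %.3f, sd %.3f, RMSE %.3f, r %s\n",
    x$vital, x$n, x$mean_diff, x$mean_abs_diff, x$sd_error, x$rmse,
    ifelse(is.na(x$pearson_r), "NA", sprintf("%.3f", x$pearson_r))))
  invisible(x)
}

#' @export
as.data.frame.metric_report <- function(x, ...) {
  base <- data.frame(vital = x$vital, n = x$n, mean_diff = x$mean_diff,
                     mean_abs_diff = x$mean_abs_diff,
                     sd_error = x$sd_error, rmse = x$rmse,
                     pearson_r = x$pearson_r, stringsAsFactors = FALSE)
  for (nm in names(x$labels)) base[[nm]] <- x$labels[[nm]]
  base
}

#' Evaluate a pipeline run against ground truth
#'
#' Convenience wrapper: aligns the ground truth to the estimate windows
#' and computes HR and SpO2 metric reports.
#'
#' @param estimates data frame from [process_participant()].
#' @param gt a `ground_truth_trace`.
#' @param method ground-truth alignment, `"last"` or `"average"`.
#' @param labels grouping labels carried into the reports.
#' @return list with `hr` and `spo2` `metric_report`s.
#' @export
evaluate_estimates <- function(estimates, gt, method = "last",
                               labels = list()) {
  # first window starts at second 0, so its end equals the window length
  windows <- data.frame(start_s = estimates$window_end_s -
                          estimates$window_end_s[1],
                        end_s = estimates$window_end_s)
  refs <- align_ground_truth(gt, windows, method)
  list(hr = compute_metrics(refs$hr_ref, estimates$hr_bpm, "HR", labels),
       spo2 = compute_metrics(refs$spo2_ref, estimates$spo2_pct, "SpO2",
                              labels))
}

#' Technique-by-separation grid evaluation
#'
#' Runs the pipeline once per (technique, separation method) cell over
#' one or more stores and tabulates HR and SpO2 metric reports. Failed
#' cells are recorded with `NA` metrics and the run continues.
#'
#' @param stores a `region_store` or list of them.
#' @param gts matching `ground_truth_trace` or list of them.
#' @param techniques technique ids (subset of 1-7, or `"auto"`).
#' @param methods separation method labels.
#' @param cfg base [pipeline_config()]; each cell overrides `preprocess`
#'   and `separation$method`.
#' @param path optional CSV output path.
#' @return data frame, one row per (cell, vital).
#' @export
grid_report <- function(stores, gts, techniques = c(6, 2),
                        methods = c("fastica", "none"),
                        cfg = pipeline_config(), path = NULL) {
  if (inherits(stores, "region_store")) stores <- list(stores)
  if (inherits(gts, "ground_truth_trace")) gts <- list(gts)
  stopifnot(length(stores) == length(gts), length(stores) >= 1)
  rows <- list()
  for (tech in techniques) {
    for (method in methods) {
      cell_cfg <- cfg
      cell_cfg$preprocess <- tech
      cell_cfg$separation <- separation_spec(
        method, cfg$separation$repeats, cfg$separation$mode,
        cfg$separation$seed)
      hr_ref <- hr_est <- sp_ref <- sp_est <- numeric(0)
      states <- character(0)
      ok <- TRUE
      for (i in seq_along(stores)) {
        res <- tryCatch({
          est <- process_participant(stores[[i]], cell_cfg)
          w <- data.frame(start_s = est$window_end_s - cfg$window_s,
                         end_s = est$window_end_s)
          refs <- align_ground_truth(gts[[i]], w, cfg$gt_alignment)
          list(est = est, refs = refs)
        }, error = function(e) NULL)
        if (is.null(res)) {
          ok <- FALSE
          next
        }
        hr_ref <- c(hr_ref, res$refs$hr_ref)
        hr_est <- c(hr_est, res$est$hr_bpm)
        sp_ref <- c(sp_ref, res$refs$spo2_ref)
        sp_est <- c(sp_est, res$est$spo2_pct)
        states <- c(states, stores[[i]]$state)
      }
      state_lab <- paste(unique(states), collapse = "+")
      for (vital in c("HR", "SpO2")) {
        rep <- if (length(hr_ref)) {
          if (vital == "HR") {
            compute_metrics(hr_ref, hr_est, "HR")
          } else {
            compute_metrics(sp_ref, sp_est, "SpO2")
          }
        } else {
          NULL
        }
        rows[[length(rows) + 1L]] <- data.frame(
          technique = as.character(tech), method = method, vital = vital,
          state = state_lab,
          n = if (is.null(rep)) NA_integer_ else rep$n,
          mean_diff = if (is.null(rep)) NA_real_ else rep$mean_diff,
          mean_abs_diff = if (is.null(rep)) NA_real_ else
            rep$mean_abs_diff,
          sd_error = if (is.null(rep)) NA_real_ else rep$sd_error,
          rmse = if (is.null(rep)) NA_real_ else rep$rmse,
          pearson_r = if (is.null(rep)) NA_real_ else rep$pearson_r,
          complete = ok, stringsAsFactors = FALSE
        )
      }
    }
  }
  out <- do.call(rbind, rows)
  if (!is.null(path)) write.csv(out, path, row.names = FALSE)
  out
}
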