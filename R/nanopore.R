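# Solid-state nanopore HA sizing: event detection on ionic-current traces,
# event-area -> molecular-weight mapping, polydispersity summaries.
#
# Analysis settings mirror the acquisition convention for HA in high-salt
# buffer: detection threshold 5 sigma below baseline on a 5 kHz-filtered
# trace, event durations restricted to 25 us - 2.5 ms, and a minimum of 500
# events for a dataset to pass QC.

#' Construct an ionic-current trace
#'
#' @param samples numeric vector of current samples, pA.
#' @param sampling_hz sampling rate, Hz.
#' @param voltage_mv applied bias, mV (metadata).
#' @param acq_filter_hz acquisition-filter corner, Hz (metadata).
#' @param source free-text source id.
#' @return object of class `current_trace`.
#' @export
current_trace <- function(samples, sampling_hz, voltage_mv = NA_real_,
                          acq_filter_hz = NA_real_, source = "") {
  stopifnot_scalar_pos(sampling_hz, "sampling_hz")
  if (!length(samples)) stop("trace must be nonempty", call. = FALSE)
  structure(list(samples = as.numeric(samples), sampling_hz = sampling_hz,
                 voltage_mv = voltage_mv, acq_filter_hz = acq_filter_hz,
                 source = source),
            class = "current_trace")
}

#' @export
print.current_trace <- function(x, ...) {
  cat(sprintf("current_trace: %d samples @ %g kHz (%.3f s), source '%s'\n",
              length(x$samples), x$sampling_hz / 1000,
              length(x$samples) / x$sampling_hz, x$source))
  invisible(x)
}

#' Detection parameters for nanopore event analysis
#'
#' @param threshold_sigma detection threshold in units of baseline noise sd
#'   (default 5).
#' @param min_duration_s,max_duration_s accepted event-duration window
#'   (defaults 25 us and 2.5 ms).
#' @param analysis_lowpass_hz corner of the additional zero-phase analysis
#'   low-pass (default 5000); `Inf` disables it.
#' @param boundary_fraction fraction of the detection threshold at which event
#'   boundaries are placed for area integration (default 0.2, i.e. the 1-sigma
#'   return for a 5-sigma threshold).
#' @param abs_floor_pa optional absolute detection floor (pA below baseline)
#'   used when the noise estimate is zero; `NA` means error in that case.
#' @return object of class `detection_params`.
#' @export
detection_params <- function(threshold_sigma = 5, min_duration_s = 25e-6,
                             max_duration_s = 2.5e-3,
                             analysis_lowpass_hz = 5000,
                             boundary_fraction = 0.2,
                             abs_floor_pa = NA_real_) {
  stopifnot_scalar_pos(threshold_sigma, "threshold_sigma")
  stopifnot_scalar_pos(min_duration_s, "min_duration_s")
  if (max_duration_s <= min_duration_s) {
    stop("need min_duration_s < max_duration_s", call. = FALSE)
  }
  stopifnot_fraction(boundary_fraction, "boundary_fraction")
  structure(list(threshold_sigma = threshold_sigma,
                 min_duration_s = min_duration_s,
                 max_duration_s = max_duration_s,
                 analysis_lowpass_hz = analysis_lowpass_hz,
                 boundary_fraction = boundary_fraction,
                 abs_floor_pa = abs_floor_pa),
            class = "detection_params")
}

#' Zero-phase low-pass filter of a trace
#'
#' Applies [fft_lowpass()] (Gaussian response, unit DC gain, no phase shift)
#' to the trace samples.
#'
#' @param trace a [current_trace()].
#' @param corner_hz corner frequency, Hz; `Inf` returns the trace unchanged.
#' @return a filtered [current_trace()].
#' @export
lowpass <- function(trace, corner_hz) {
  stopifnot(inherits(trace, "current_trace"))
  if (!is.finite(corner_hz) || corner_hz >= trace$sampling_hz / 2) return(trace)
  trace$samples <- fft_lowpass(trace$samples, trace$sampling_hz, corner_hz)
  trace
}

#' Estimate baseline current and noise of a trace
#'
#' Baseline is the median of the (analysis-filtered) trace; noise sigma is the
#' MAD scaled to the normal sd (x 1.4826), both recomputed on samples outside
#' provisional events (two-pass) so deep translocation dips do not contaminate
#' the estimates.
#'
#' @param trace a [current_trace()].
#' @param analysis_lowpass_hz analysis filter corner applied before
#'   estimation; `Inf` for none.
#' @return list with `baseline_pa` and `sigma_pa`.
#' @export
estimate_baseline <- function(trace, analysis_lowpass_hz = 5000) {
  stopifnot(inherits(trace, "current_trace"))
  if (length(trace$samples) / trace$sampling_hz < 0.01) {
    stop("trace shorter than 10 ms: baseline not estimable", call. = FALSE)
  }
  x <- lowpass(trace, analysis_lowpass_hz)$samples
  b <- stats::median(x)
  s <- stats::mad(x, center = b)
  if (s > 0) {  # second pass excluding provisional events (dips beyond 4 sigma)
    keep <- x > b - 4 * s
    if (sum(keep) > 100L) {
      b <- stats::median(x[keep])
      s <- stats::mad(x[keep], center = b)
    }
  }
  list(baseline_pa = b, sigma_pa = s)
}

#' Detect translocation events in an ionic-current trace
#'
#' The trace is low-pass filtered (zero phase), baseline and noise sigma are
#' estimated robustly, and events are maximal excursions dropping at least
#' `threshold_sigma * sigma` below baseline. Each excursion's integration
#' window extends outward to the `boundary_fraction`-of-threshold return
#' crossing; its duration is measured between the half-depth (FWHM) crossings,
#' which a zero-phase filter leaves at the true edges while the outer
#' crossings smear outward. Events with FWHM duration outside
#' `[min_duration_s, max_duration_s]` are discarded. Area is the integral of
#' (baseline - filtered current) over the extended window.
#'
#' @param trace a [current_trace()].
#' @param params a [detection_params()].
#' @return data.frame of class `nanopore_events` with columns `onset_s`,
#'   `duration_s`, `mean_depth_pa`, `area_pa_s`, sorted by onset,
#'   non-overlapping. Attributes `baseline_pa` and `sigma_pa` record the
#'   estimates used.
#' @export
detect_events <- function(trace, params = detection_params()) {
  stopifnot(inherits(trace, "current_trace"), inherits(params, "detection_params"))
  fs <- trace$sampling_hz
  filt <- lowpass(trace, params$analysis_lowpass_hz)$samples
  est <- estimate_baseline(trace, params$analysis_lowpass_hz)
  b <- est$baseline_pa; s <- est$sigma_pa
  thr_depth <- params$threshold_sigma * s
  if (thr_depth <= 0) {
    if (is.na(params$abs_floor_pa)) {
      stop("zero noise estimate and no `abs_floor_pa` configured", call. = FALSE)
    }
    thr_depth <- params$abs_floor_pa
  }
  empty <- data.frame(onset_s = numeric(0), duration_s = numeric(0),
                      mean_depth_pa = numeric(0), area_pa_s = numeric(0))
  # candidate windows: runs below the boundary return level that contain at
  # least one sample below the full threshold
  depth <- b - filt
  runs <- true_runs(depth > params$boundary_fraction * thr_depth)
  if (nrow(runs)) {
    # keep only candidate windows containing a supra-threshold sample
    deep <- cumsum(depth > thr_depth)
    has_deep <- deep[runs$end] - deep[runs$start] + (depth[runs$start] > thr_depth) > 0
    runs <- runs[has_deep, , drop = FALSE]
  }
  out <- empty
  if (nrow(runs)) {
    keep <- logical(nrow(runs))
    dur <- dep <- area <- onset <- numeric(nrow(runs))
    for (k in seq_len(nrow(runs))) {
      i <- runs$start[k]:runs$end[k]
      d <- depth[i]
      peak <- max(d)
      if (peak < thr_depth) next
      # FWHM duration: first/last crossing of half the peak depth
      above <- which(d >= peak / 2)
      n_half <- above[length(above)] - above[1L] + 1L
      dur[k] <- n_half / fs
      if (dur[k] < params$min_duration_s || dur[k] > params$max_duration_s) next
      onset[k] <- (i[above[1L]] - 1L) / fs
      area[k] <- sum(d) / fs
      dep[k] <- area[k] / dur[k]
      keep[k] <- TRUE
    }
    out <- data.frame(onset_s = onset[keep], duration_s = dur[keep],
                      mean_depth_pa = dep[keep], area_pa_s = area[keep])
  }
  out <- out[order(out$onset_s), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "baseline_pa") <- b
  attr(out, "sigma_pa") <- s
  class(out) <- c("nanopore_events", "data.frame")
  out
}

#' Map event areas to molecular weights through a calibration curve
#'
#' @param events a `nanopore_events` data.frame (from [detect_events()]) or
#'   any data.frame with an `area_pa_s` column.
#' @param cal a [calibration_curve()].
#' @param above_range `"exclude"` (default) or `"clamp"` areas above the
#'   calibrated range to its top molecular weight.
#' @return the events with added columns `mw_kda` and `flag`
#'   (`"ok"`, `"below-calibration"` (sub-50 kDa territory, excluded from
#'   summaries), `"above-calibration"`).
#' @export
map_mw <- function(events, cal, above_range = c("exclude", "clamp")) {
  above_range <- match.arg(above_range)
  stopifnot(inherits(cal, "calibration_curve"), "area_pa_s" %in% names(events))
  a <- events$area_pa_s
  flag <- rep("ok", length(a))
  flag[a < cal$valid_range[1L]] <- "below-calibration"
  flag[a > cal$valid_range[2L]] <- "above-calibration"
  mw <- cal_area_to_mw(cal, a)
  if (above_range == "clamp") {
    mw[flag == "above-calibration"] <- max(cal$points$mw_kda)
  }
  events$mw_kda <- mw
  events$flag <- flag
  events
}

#' Summarize HA polydispersity from per-event molecular weights
#'
#' The weighted-average molecular mass is the mass-weighted mean
#' `Mw = sum(m_i^2) / sum(m_i)` (the polymer-science Mw); the number-average
#' `Mn = mean(m_i)` is reported alongside. `fraction_below` uses strict
#' inequality (`MW < cutoff`).
#'
#' @param mw_kda numeric vector of per-event molecular weights (kDa), already
#'   restricted to in-calibration events.
#' @param min_events QC minimum event count (default 500).
#' @param cutoffs_kda cutoffs for `fraction_below` (default 50 and 300 kDa).
#' @param breaks_kda histogram bin edges, kDa; default 20 log-spaced bins over
#'   the data range.
#' @return object of class `polydispersity_result`: `mw_kda_per_event`,
#'   `n_events`, `weighted_avg_mw_kda`, `number_avg_mw_kda`, `fraction_below`
#'   (named numeric), `histogram` (data.frame `lower_kda`, `upper_kda`,
#'   `fraction`), `qc_pass`.
#' @export
summarize_polydispersity <- function(mw_kda, min_events = 500L,
                                     cutoffs_kda = c(50, 300),
                                     breaks_kda = NULL) {
  mw <- mw_kda[is.finite(mw_kda)]
  if (!length(mw)) stop("no molecular weights to summarize", call. = FALSE)
  if (any(mw <= 0)) stop("molecular weights must be positive", call. = FALSE)
  if (is.null(breaks_kda)) {
    rng <- range(mw)
    if (rng[1L] == rng[2L]) rng <- rng * c(0.9, 1.1)
    breaks_kda <- exp(seq(log(rng[1L]), log(rng[2L]), length.out = 21L))
  }
  breaks_kda[1L] <- min(breaks_kda[1L], min(mw))
  breaks_kda[length(breaks_kda)] <- max(breaks_kda[length(breaks_kda)], max(mw))
  h <- graphics::hist(mw, breaks = breaks_kda, plot = FALSE)
  fb <- vapply(cutoffs_kda, function(cc) mean(mw < cc), numeric(1L))
  names(fb) <- as.character(cutoffs_kda)
  structure(list(
    mw_kda_per_event = mw,
    n_events = length(mw),
    weighted_avg_mw_kda = sum(mw^2) / sum(mw),
    number_avg_mw_kda = mean(mw),
    fraction_below = fb,
    histogram = data.frame(lower_kda = h$breaks[-length(h$breaks)],
                           upper_kda = h$breaks[-1L],
                           fraction = h$counts / length(mw)),
    qc_pass = length(mw) >= min_events
  ), class = "polydispersity_result")
}

#' @export
print.polydispersity_result <- function(x, ...) {
  cat(sprintf("polydispersity: n = %d events (QC %s)\n", x$n_events,
              if (x$qc_pass) "pass" else "FAIL"))
  cat(sprintf("  mass-weighted Mw = %.1f kDa, number-average Mn = %.1f kDa\n",
              x$weighted_avg_mw_kda, x$number_avg_mw_kda))
  for (nm in names(x$fraction_below)) {
    cat(sprintf("  fraction < %s kDa: %.3f\n", nm, x$fraction_below[[nm]]))
  }
  invisible(x)
}

#' Run the full sizing pipeline on a trace
#'
#' Convenience wrapper: [detect_events()], [map_mw()] (events flagged outside
#' the calibrated range are excluded), [summarize_polydispersity()].
#'
#' @param trace a [current_trace()].
#' @param cal a [calibration_curve()].
#' @param params a [detection_params()].
#' @param min_events QC minimum (default 500).
#' @return list with `events` (mapped data.frame) and `polydispersity`.
#' @export
size_trace <- function(trace, cal, params = detection_params(),
                       min_events = 500L) {
  ev <- map_mw(detect_events(trace, params), cal)
  ok <- ev$flag == "ok"
  list(events = ev,
       polydispersity = summarize_polydispersity(ev$mw_kda[ok],
                                                 min_events = min_events))
}
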