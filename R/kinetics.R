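# Cumulus-expansion endpoints and time-lapse morphokinetics.
#
# Endpoints: pre/post COC area and cumulus-layer thickness (mean of the
# 3, 6, 9, 12 o'clock measurements), subjective expansion score 0-4, and the
# post-minus-pre differences used for difference-between-differences testing
# when baselines differ between groups. Morphokinetics: expansion distance
# measured hourly over a 16 h observation, converted to velocities
# (distance difference / elapsed time, um/min) per 1 h interval, per 4 h
# window, and overall.

#' Construct an expansion record
#'
#' @param coc_id,mouse_id identifiers.
#' @param group age group, one of `"young"`, `"mid"`, `"old"`.
#' @param pre_area_mm2,post_area_mm2 COC areas, mm^2.
#' @param pre_thickness_um,post_thickness_um numeric length-4 vectors: cumulus
#'   layer thickness at the 3, 6, 9 and 12 o'clock positions, um.
#' @param score subjective expansion score, integer 0-4.
#' @return object of class `expansion_record`.
#' @export
expansion_record <- function(coc_id, mouse_id, group,
                             pre_area_mm2, post_area_mm2,
                             pre_thickness_um, post_thickness_um,
                             score = NA_integer_) {
  group <- match.arg(group, c("young", "mid", "old"))
  stopifnot_scalar_pos(pre_area_mm2, "pre_area_mm2")
  stopifnot_scalar_pos(post_area_mm2, "post_area_mm2")
  if (length(pre_thickness_um) != 4L || length(post_thickness_um) != 4L) {
    stop("thickness needs exactly 4 measurements per timepoint", call. = FALSE)
  }
  if (!is.na(score) && !(score %in% 0:4)) {
    stop("score must be an integer in 0..4", call. = FALSE)
  }
  structure(list(coc_id = coc_id, mouse_id = mouse_id, group = group,
                 pre_area_mm2 = pre_area_mm2, post_area_mm2 = post_area_mm2,
                 pre_thickness_um = as.numeric(pre_thickness_um),
                 post_thickness_um = as.numeric(post_thickness_um),
                 score = as.integer(score)),
            class = "expansion_record")
}

#' Construct an expansion distance series
#'
#' @param times_h strictly increasing observation times, h.
#' @param distances_um cumulus edge expansion distances, um. The series may
#'   truncate early (e.g. when the cumulus layer expands beyond the well).
#' @param coc_id,mouse_id identifiers.
#' @return object of class `distance_series`.
#' @export
distance_series <- function(times_h, distances_um, coc_id = "coc1",
                            mouse_id = "m1") {
  if (length(times_h) != length(distances_um)) {
    stop("times and distances must have equal length", call. = FALSE)
  }
  if (any(diff(times_h) <= 0)) {
    stop("times must be strictly increasing", call. = FALSE)
  }
  if (any(!is.finite(distances_um))) {
    stop("distances must be finite", call. = FALSE)
  }
  structure(list(times_h = as.numeric(times_h),
                 distances_um = as.numeric(distances_um),
                 coc_id = coc_id, mouse_id = mouse_id),
            class = "distance_series")
}

#' Expansion velocity between two time points
#'
#' `(distance at 2nd time point - distance at 1st) / (time at 2nd - time at
#' 1st)`, in um/min. Negative values (retraction) are returned unchanged.
#'
#' @param d1,d2 distances, um.
#' @param t1,t2 times, minutes; `t2 > t1`.
#' @return velocity, um/min.
#' @export
velocity <- function(d1, d2, t1, t2) {
  if (any(t2 <= t1)) stop("t2 must be greater than t1", call. = FALSE)
  (d2 - d1) / (t2 - t1)
}

# the four canonical 4 h windows of hourly-interval velocities; interval i
# covers (i-1, i] h, so window "1-4 h" holds intervals ending at 1..4 h.
.v4_windows <- list(`1-4 h` = c(0, 4), `5-8 h` = c(4, 8),
                    `9-12 h` = c(8, 12), `13-16 h` = c(12, 16))

#' Velocity profile of an expansion distance series
#'
#' Hourly velocities are difference quotients over consecutive observations
#' (um/min, computed over the actual elapsed gap when frames are missing).
#' 4 h-window velocities are means of the member hourly velocities (windows
#' 1-4, 5-8, 9-12, 13-16 h; windows with no data are omitted); a
#' direct-endpoint quotient per window is available via
#' `window_method = "endpoint"`. The overall rate is (last - first distance) /
#' total elapsed minutes.
#'
#' @param series a [distance_series()].
#' @param window_method `"mean-of-hourly"` (default) or `"endpoint"`.
#' @return object of class `velocity_profile`: `v1h` (data.frame `t_start_h`,
#'   `t_end_h`, `v_um_min`), `v4h` (named numeric), `overall_rate_um_min`,
#'   `peak_window`.
#' @export
profile <- function(series, window_method = c("mean-of-hourly", "endpoint")) {
  stopifnot(inherits(series, "distance_series"))
  window_method <- match.arg(window_method)
  t <- series$times_h; d <- series$distances_um
  if (length(t) < 2L) stop("need at least two time points", call. = FALSE)
  n <- length(t)
  v1 <- data.frame(t_start_h = t[-n], t_end_h = t[-1L],
                   v_um_min = velocity(d[-n], d[-1L], 60 * t[-n], 60 * t[-1L]))
  v4 <- vapply(.v4_windows, function(w) {
    inside <- v1$t_end_h > w[1L] & v1$t_end_h <= w[2L]
    if (!any(inside)) return(NA_real_)
    if (window_method == "mean-of-hourly") {
      mean(v1$v_um_min[inside])
    } else {
      i0 <- which(inside)[1L]; i1 <- which(inside)[sum(inside)]
      velocity(d[i0], d[i1 + 1L], 60 * v1$t_start_h[i0], 60 * v1$t_end_h[i1])
    }
  }, numeric(1L))
  v4 <- v4[!is.na(v4)]
  structure(list(
    v1h = v1,
    v4h = v4,
    overall_rate_um_min = velocity(d[1L], d[n], 60 * t[1L], 60 * t[n]),
    peak_window = if (length(v4)) names(v4)[which.max(v4)] else NA_character_,
    coc_id = series$coc_id, mouse_id = series$mouse_id
  ), class = "velocity_profile")
}

#' @export
print.velocity_profile <- function(x, ...) {
  cat(sprintf("velocity_profile [%s]: overall %.4f um/min, peak window %s\n",
              x$coc_id, x$overall_rate_um_min, x$peak_window))
  for (nm in names(x$v4h)) cat(sprintf("  %s: %.4f um/min\n", nm, x$v4h[[nm]]))
  invisible(x)
}

#' Post-minus-pre expansion deltas
#'
#' Computes the differences fed into difference-between-differences testing:
#' `post - pre` area and `mean(post thickness) - mean(pre thickness)` over the
#' four clock positions.
#'
#' @param rec an [expansion_record()].
#' @return list with `delta_area_mm2` and `delta_thickness_um`.
#' @export
expansion_deltas <- function(rec) {
  stopifnot(inherits(rec, "expansion_record"))
  list(delta_area_mm2 = rec$post_area_mm2 - rec$pre_area_mm2,
       delta_thickness_um = mean(rec$post_thickness_um) - mean(rec$pre_thickness_um))
}

#' Compare expansion deltas between two groups
#'
#' Applies [expansion_deltas()] per record and then the normality-gated
#' two-group rule ([choose_two_group_test()]): Shapiro-Wilk on each group at
#' alpha 0.05 decides between Student's t-test and Mann-Whitney U.
#'
#' @param records list of [expansion_record()]s spanning exactly two groups.
#' @param metric `"area"`, `"thickness"`, or `"score"`.
#' @return a `test_result` (see [choose_two_group_test()]).
#' @export
compare_groups <- function(records, metric = c("area", "thickness", "score")) {
  metric <- match.arg(metric)
  stopifnot(length(records) > 0L,
            all(vapply(records, inherits, logical(1L), "expansion_record")))
  grp <- vapply(records, `[[`, character(1L), "group")
  val <- vapply(records, function(r) {
    switch(metric,
           area = expansion_deltas(r)$delta_area_mm2,
           thickness = expansion_deltas(r)$delta_thickness_um,
           score = as.numeric(r$score))
  }, numeric(1L))
  groups <- unique(grp)
  if (length(groups) != 2L) {
    stop("compare_groups needs exactly two groups", call. = FALSE)
  }
  x <- val[grp == groups[1L]]; y <- val[grp == groups[2L]]
  if (!length(x) || !length(y)) stop("a group is empty", call. = FALSE)
  choose_two_group_test(x, y)
}

#' Read a long-format distance-series CSV
#'
#' Columns: `coc_id`, `mouse_id` (optional), `time_h`, `distance_um`.
#'
#' @param path CSV path.
#' @return named list of [distance_series()] objects, one per `coc_id`.
#' @export
read_distance_series_csv <- function(path) {
  d <- utils::read.csv(path)
  stopifnot(all(c("coc_id", "time_h", "distance_um") %in% names(d)))
  out <- lapply(split(d, d$coc_id), function(s) {
    s <- s[order(s$time_h), ]
    distance_series(s$time_h, s$distance_um, coc_id = s$coc_id[1L],
                    mouse_id = if ("mouse_id" %in% names(s)) s$mouse_id[1L] else NA)
  })
  out
}
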