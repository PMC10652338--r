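# Event-area -> molecular-weight calibration.
#
# The calibration curve relating the event charge deficit (area of the current
# dip, pA*s) to hyaluronan molecular weight is instrument-specific and is
# supplied as data (an ordered table of (area, MW) points). The mapping is
# piecewise linear in log-log coordinates; a pure power-law fit through the
# points is available as an option.

#' Construct an area-to-molecular-weight calibration curve
#'
#' @param area_pa_s numeric vector of event areas (pA*s), strictly increasing.
#' @param mw_kda matching molecular weights (kDa), strictly increasing.
#' @param form `"loglog"` (piecewise log-log linear interpolation, default) or
#'   `"powerlaw"` (least-squares power law `MW = k * A^p` through the points).
#' @return object of class `calibration_curve` with elements `points`
#'   (data.frame `area_pa_s`, `mw_kda`), `valid_range` (range of areas), and
#'   `form`.
#' @details The low end of the curve must sit at >= 50 kDa: solid-state
#'   nanopores cannot reliably identify HA molecules below ~50 kDa, so areas
#'   below the calibrated range are flagged rather than extrapolated.
#' @export
calibration_curve <- function(area_pa_s, mw_kda, form = c("loglog", "powerlaw")) {
  form <- match.arg(form)
  if (length(area_pa_s) < 2L || length(area_pa_s) != length(mw_kda)) {
    stop("calibration needs >= 2 matched (area, mw) points", call. = FALSE)
  }
  if (any(area_pa_s <= 0) || any(mw_kda <= 0)) {
    stop("calibration areas and molecular weights must be positive", call. = FALSE)
  }
  if (any(diff(area_pa_s) <= 0) || any(diff(mw_kda) <= 0)) {
    stop("calibration must be strictly increasing in both coordinates", call. = FALSE)
  }
  if (mw_kda[1L] < 50 - 1e-6) {
    stop("calibration lower end must be >= 50 kDa (sub-50 kDa HA is not resolvable)",
         call. = FALSE)
  }
  obj <- list(
    points = data.frame(area_pa_s = as.numeric(area_pa_s),
                        mw_kda = as.numeric(mw_kda)),
    valid_range = range(area_pa_s),
    form = form
  )
  if (form == "powerlaw") {
    fit <- stats::lm(log(mw_kda) ~ log(area_pa_s))
    obj$powerlaw <- c(k = exp(unname(stats::coef(fit)[1L])),
                      p = unname(stats::coef(fit)[2L]))
  }
  class(obj) <- "calibration_curve"
  obj
}

#' @export
print.calibration_curve <- function(x, ...) {
  cat(sprintf("calibration_curve (%s): %d points, area %.3g-%.3g pA*s, MW %.3g-%.3g kDa\n",
              x$form, nrow(x$points), x$valid_range[1L], x$valid_range[2L],
              min(x$points$mw_kda), max(x$points$mw_kda)))
  invisible(x)
}

#' Read/write a calibration curve as CSV
#'
#' CSV columns: `area_pa_s`, `mw_kda`.
#' @param path file path.
#' @param form passed to [calibration_curve()].
#' @return a `calibration_curve`.
#' @export
read_calibration_csv <- function(path, form = "loglog") {
  d <- utils::read.csv(path)
  calibration_curve(d$area_pa_s, d$mw_kda, form = form)
}

#' @rdname read_calibration_csv
#' @param cal a `calibration_curve`.
#' @export
write_calibration_csv <- function(cal, path) {
  utils::write.csv(cal$points, path, row.names = FALSE)
  invisible(path)
}

# forward map: area -> MW. Out-of-range areas return NA (callers flag them).
cal_area_to_mw <- function(cal, area_pa_s) {
  out <- rep(NA_real_, length(area_pa_s))
  ok <- is.finite(area_pa_s) & area_pa_s >= cal$valid_range[1L] &
    area_pa_s <= cal$valid_range[2L]
  if (!any(ok)) return(out)
  if (cal$form == "powerlaw") {
    out[ok] <- cal$powerlaw[["k"]] * area_pa_s[ok]^cal$powerlaw[["p"]]
  } else {
    out[ok] <- exp(stats::approx(log(cal$points$area_pa_s), log(cal$points$mw_kda),
                                 xout = log(area_pa_s[ok]))$y)
  }
  out
}

# inverse map: MW -> area, used by the trace generator.
cal_mw_to_area <- function(cal, mw_kda) {
  if (cal$form == "powerlaw") {
    return((mw_kda / cal$powerlaw[["k"]])^(1 / cal$powerlaw[["p"]]))
  }
  if (any(mw_kda < min(cal$points$mw_kda) | mw_kda > max(cal$points$mw_kda))) {
    stop("molecular weight outside the calibrated range", call. = FALSE)
  }
  exp(stats::approx(log(cal$points$mw_kda), log(cal$points$area_pa_s),
                    xout = log(mw_kda))$y)
}

#' Synthetic power-law calibration curve
#'
#' A stand-in for an instrument calibration (the real curve is instrument- and
#' buffer-specific and must be supplied as data). Follows the power law
#' `area = coef_pa_s * (MW/kDa)^exponent` sampled at `n_points` log-spaced
#' molecular weights; it is *synthetic* and carries no claim about any
#' particular pore.
#'
#' @param mw_range_kda molecular-weight range covered, kDa (min >= 50).
#' @param coef_pa_s area at 1 kDa under the power law, pA*s.
#' @param exponent power-law exponent (>1: larger chains carry
#'   more-than-proportional charge deficit).
#' @param n_points number of calibration points.
#' @return a `calibration_curve`.
#' @export
synthetic_power_law_calibration <- function(mw_range_kda = c(50, 10000),
                                            coef_pa_s = 1e-4,
                                            exponent = 1.2,
                                            n_points = 25L) {
  mw <- exp(seq(log(mw_range_kda[1L]), log(mw_range_kda[2L]),
                length.out = n_points))
  calibration_curve(coef_pa_s * mw^exponent, mw)
}
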