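# Synthetic-data generators.
#
# Every input the pipeline consumes can be generated here with a known ground
# truth sidecar, so each downstream stage is testable end-to-end without any
# experimental data. Generators are pure functions of (spec, seed).

# ---------------------------------------------------------------------------
# molecular-weight mixture

#' Specify a hyaluronan molecular-weight mixture
#'
#' A mixture of log-normal components truncated to `mw_bounds`. The default
#' emulates follicular-fluid HA polydispersity: predominantly low-molecular-
#' mass chains (median 150 kDa) with a high-mass tail (median 800 kDa).
#'
#' @param components data.frame with columns `weight` (fractions summing to 1),
#'   `median_kda`, `sigma_log` (log-scale sd, dimensionless).
#' @param mw_bounds length-2 positive vector `(min_kda, max_kda)`.
#' @return object of class `mw_distribution_spec`.
#' @export
mw_distribution_spec <- function(components = data.frame(
                                   weight = c(0.65, 0.35),
                                   median_kda = c(150, 800),
                                   sigma_log = c(0.55, 0.55)),
                                 mw_bounds = c(50, 5000)) {
  stopifnot(is.data.frame(components),
            all(c("weight", "median_kda", "sigma_log") %in% names(components)))
  if (abs(sum(components$weight) - 1) > 1e-9) {
    stop("mixture weights must sum to 1", call. = FALSE)
  }
  if (any(components$median_kda <= 0) || any(components$sigma_log <= 0) ||
      any(mw_bounds <= 0) || mw_bounds[1L] >= mw_bounds[2L]) {
    stop("medians, sigmas and bounds must be positive with min < max", call. = FALSE)
  }
  structure(list(components = components, mw_bounds = as.numeric(mw_bounds)),
            class = "mw_distribution_spec")
}

# draw n molecular weights from the truncated mixture (rejection sampling)
sample_mw <- function(spec, n) {
  out <- numeric(0)
  comp <- spec$components
  while (length(out) < n) {
    m <- max(2L * (n - length(out)), 32L)
    k <- sample.int(nrow(comp), m, replace = TRUE, prob = comp$weight)
    x <- stats::rlnorm(m, meanlog = log(comp$median_kda[k]),
                       sdlog = comp$sigma_log[k])
    out <- c(out, x[x >= spec$mw_bounds[1L] & x <= spec$mw_bounds[2L]])
  }
  out[seq_len(n)]
}

# ---------------------------------------------------------------------------
# nanopore traces

#' Specify a synthetic nanopore acquisition
#'
#' Defaults follow typical solid-state-nanopore HA acquisitions: 200 kHz
#' sampling through a 100 kHz 4-pole Bessel filter at 200-300 mV bias.
#'
#' @param baseline_pa open-pore current, pA.
#' @param noise_sd_pa baseline current noise sd (pre-filter, white), pA.
#' @param sampling_hz sampling rate (default 200000).
#' @param acq_filter_hz acquisition Bessel corner (default 100000).
#' @param duration_s trace length, s.
#' @param event_rate_hz mean translocation rate, events/s (Poisson arrivals).
#' @param mw_spec a [mw_distribution_spec()].
#' @param voltage_mv applied bias, mV (metadata only).
#' @param seed integer RNG seed.
#' @return object of class `trace_spec`.
#' @export
trace_spec <- function(baseline_pa = 4000, noise_sd_pa = 2,
                       sampling_hz = 200000, acq_filter_hz = 100000,
                       duration_s = 5, event_rate_hz = 60,
                       mw_spec = mw_distribution_spec(),
                       voltage_mv = 250, seed = 1L) {
  stopifnot_scalar_pos(baseline_pa, "baseline_pa")
  stopifnot_scalar_pos(noise_sd_pa, "noise_sd_pa")
  stopifnot_scalar_pos(sampling_hz, "sampling_hz")
  stopifnot_scalar_pos(duration_s, "duration_s")
  if (event_rate_hz < 0) stop("event_rate_hz must be >= 0", call. = FALSE)
  stopifnot(inherits(mw_spec, "mw_distribution_spec"))
  structure(list(baseline_pa = baseline_pa, noise_sd_pa = noise_sd_pa,
                 sampling_hz = sampling_hz, acq_filter_hz = acq_filter_hz,
                 duration_s = duration_s, event_rate_hz = event_rate_hz,
                 mw_spec = mw_spec, voltage_mv = voltage_mv,
                 seed = as.integer(seed)),
            class = "trace_spec")
}

#' Generate a synthetic ionic-current trace with ground truth
#'
#' Translocation events are rectangular conductance dips before acquisition
#' filtering (the Bessel filter supplies realistic rise/fall); each event's
#' depth x duration area equals the calibration inverse of its true molecular
#' weight exactly. Durations are drawn log-uniform in [50 us, 2 ms]; the
#' implied depth is capped at half the baseline, in which case the duration is
#' recomputed so the area is preserved. Gaussian noise (sd `noise_sd_pa`) is
#' added before the acquisition filter, as on the hardware noise path.
#' Arrivals are Poisson with a guard gap so events never overlap.
#'
#' @param spec a [trace_spec()].
#' @param calibration a [calibration_curve()] used to convert true molecular
#'   weights into event areas.
#' @return list with `trace` (a [current_trace()]) and `truth` (data.frame
#'   `onset_s`, `duration_s`, `depth_pa`, `true_mw_kda`, sorted by onset).
#' @export
gen_trace <- function(spec, calibration) {
  stopifnot(inherits(spec, "trace_spec"), inherits(calibration, "calibration_curve"))
  max_dur <- 2.5e-3
  if (spec$event_rate_hz * (max_dur + 1e-3) > 0.5) {
    stop("event_rate_hz too high for non-overlapping events", call. = FALSE)
  }
  with_seed(spec$seed, {
    fs <- spec$sampling_hz
    n <- round(spec$duration_s * fs)
    # Poisson arrivals with a guard gap after each event
    guard <- 1e-3
    onsets <- numeric(0); durs <- numeric(0); depths <- numeric(0); mws <- numeric(0)
    t <- 0
    if (spec$event_rate_hz > 0) {
      repeat {
        gap <- stats::rexp(1L, spec$event_rate_hz)
        mw <- sample_mw(spec$mw_spec, 1L)
        area <- cal_mw_to_area(calibration, mw)
        dur <- exp(stats::runif(1L, log(50e-6), log(2e-3)))
        depth <- area / dur
        if (depth > 0.5 * spec$baseline_pa) {  # cap depth, keep area exact
          depth <- 0.5 * spec$baseline_pa
          dur <- area / depth
        }
        onset <- t + gap
        if (onset + dur + guard > spec$duration_s) break
        onsets <- c(onsets, onset); durs <- c(durs, dur)
        depths <- c(depths, depth); mws <- c(mws, mw)
        t <- onset + dur + guard
      }
    }
    x <- rep(spec$baseline_pa, n)
    if (length(onsets)) {
      i0 <- pmax(1L, round(onsets * fs) + 1L)
      i1 <- pmin(n, round((onsets + durs) * fs))
      # snap durations to the sample grid and recompute depths so each
      # event's depth x duration still equals its calibration area exactly
      areas <- depths * durs
      durs <- (i1 - i0 + 1L) / fs
      depths <- areas / durs
      onsets <- (i0 - 1L) / fs
      for (k in seq_along(i0)) {
        x[i0[k]:i1[k]] <- x[i0[k]:i1[k]] - depths[k]
      }
    }
    x <- x + stats::rnorm(n, sd = spec$noise_sd_pa)
    x <- bessel4_lowpass(x, fs, spec$acq_filter_hz)
    trace <- current_trace(x, sampling_hz = fs,
                           voltage_mv = spec$voltage_mv,
                           acq_filter_hz = spec$acq_filter_hz,
                           source = "synthetic")
    truth <- data.frame(onset_s = onsets, duration_s = durs,
                        depth_pa = depths, true_mw_kda = mws)
    truth <- truth[order(truth$onset_s), , drop = FALSE]
    rownames(truth) <- NULL
    list(trace = trace, truth = truth)
  })
}

# ---------------------------------------------------------------------------
# COC images

#' Specify a synthetic COC image
#'
#' Emulates a confocal field of one cumulus-oocyte complex: a disk-shaped
#' complex (actin channel), DAPI-like nuclear speckles in the cumulus annulus
#' (DNA channel), and a particle/HABP channel whose infiltrated area fraction
#' inside the COC is controlled by `porosity_fraction`.
#'
#' @param shape_px image size `(rows, cols)`.
#' @param pixel_size_um pixel size, um/px.
#' @param coc_center_px COC center `(row, col)`; default image center.
#' @param coc_radius_px COC radius, px.
#' @param oocyte_radius_px oocyte radius, px (< coc_radius_px).
#' @param porosity_fraction target infiltrated-area fraction in [0, 1].
#' @param particle_intensity,cell_intensity,intercellular_intensity,background
#'   channel intensities, arbitrary units.
#' @param n_z number of z-planes.
#' @param noise_gain Poisson-like noise scale: sd = noise_gain * sqrt(intensity).
#' @param seed integer RNG seed.
#' @return object of class `coc_image_spec`.
#' @export
coc_image_spec <- function(shape_px = c(200L, 200L), pixel_size_um = 1.5,
                           coc_center_px = NULL, coc_radius_px = 80,
                           oocyte_radius_px = 25, porosity_fraction = 0.25,
                           particle_intensity = 120, cell_intensity = 80,
                           intercellular_intensity = 20, background = 5,
                           n_z = 3L, noise_gain = 0.5, seed = 1L) {
  if (is.null(coc_center_px)) coc_center_px <- shape_px / 2
  stopifnot_fraction(porosity_fraction, "porosity_fraction")
  stopifnot_scalar_pos(pixel_size_um, "pixel_size_um")
  if (!(oocyte_radius_px < coc_radius_px && coc_radius_px < min(shape_px) / 2)) {
    stop("need oocyte_radius_px < coc_radius_px < min(shape_px)/2", call. = FALSE)
  }
  structure(list(shape_px = as.integer(shape_px), pixel_size_um = pixel_size_um,
                 coc_center_px = as.numeric(coc_center_px),
                 coc_radius_px = coc_radius_px,
                 oocyte_radius_px = oocyte_radius_px,
                 porosity_fraction = porosity_fraction,
                 particle_intensity = particle_intensity,
                 cell_intensity = cell_intensity,
                 intercellular_intensity = intercellular_intensity,
                 background = background, n_z = as.integer(n_z),
                 noise_gain = noise_gain, seed = as.integer(seed)),
            class = "coc_image_spec")
}

# smooth Gaussian random field via FFT (blue-noise-free speckle base)
.smooth_field <- function(nr, nc, scale_px) {
  w <- matrix(stats::rnorm(nr * nc), nr, nc)
  fr <- c(seq(0, floor(nr / 2)), seq(ceiling(nr / 2) - 1, 1)) / nr
  fc <- c(seq(0, floor(nc / 2)), seq(ceiling(nc / 2) - 1, 1)) / nc
  g <- exp(-2 * pi^2 * scale_px^2 * outer(fr^2, fc^2, `+`))
  Re(stats::fft(stats::fft(w) * g, inverse = TRUE)) / (nr * nc)
}

.disk_mask <- function(shape, center, radius) {
  r <- outer((seq_len(shape[1L]) - center[1L])^2,
             (seq_len(shape[2L]) - center[2L])^2, `+`)
  r <= radius^2
}

#' Generate a synthetic COC image with ground truth
#'
#' The particle channel is nonzero only on the truth infiltrated mask inside
#' the COC disk plus the exterior of the COC. The infiltrated mask is carved
#' from a thresholded smooth speckle field so that its area fraction matches
#' `porosity_fraction` to within one pixel quantile step (well inside the
#' +-0.02 contract).
#'
#' @param spec a [coc_image_spec()].
#' @return list with `image` (a [coc_image()]) and `truth` (list:
#'   `coc_mask`, `infiltrated_mask` (per z), `infiltrated_fraction`,
#'   `nucleus_centers`).
#' @export
gen_coc_image <- function(spec) {
  stopifnot(inherits(spec, "coc_image_spec"))
  with_seed(spec$seed, {
    nr <- spec$shape_px[1L]; nc <- spec$shape_px[2L]
    coc <- .disk_mask(c(nr, nc), spec$coc_center_px, spec$coc_radius_px)
    oo <- .disk_mask(c(nr, nc), spec$coc_center_px, spec$oocyte_radius_px)
    n_in <- sum(coc)

    # nuclei in the cumulus annulus, shared across z (a cell spans planes)
    n_cells <- max(10L, round(n_in / 700))
    ann <- which(coc & !oo, arr.ind = TRUE)
    idx <- sample.int(nrow(ann), n_cells)
    centers <- ann[idx, , drop = FALSE]

    dna <- vector("list", spec$n_z); actin <- vector("list", spec$n_z)
    part <- vector("list", spec$n_z); infil <- vector("list", spec$n_z)
    rows <- matrix(rep(seq_len(nr), nc), nr, nc)
    cols <- matrix(rep(seq_len(nc), each = nr), nr, nc)
    for (z in seq_len(spec$n_z)) {
      # infiltrated mask: smooth speckle thresholded at the target quantile
      fld <- .smooth_field(nr, nc, scale_px = 4)
      v <- fld[coc]
      if (spec$porosity_fraction <= 0) {
        inf_mask <- matrix(FALSE, nr, nc)
      } else if (spec$porosity_fraction >= 1) {
        inf_mask <- coc
      } else {
        thr <- stats::quantile(v, 1 - spec$porosity_fraction, names = FALSE)
        inf_mask <- coc & (fld > thr)
      }
      infil[[z]] <- inf_mask

      pr <- matrix(spec$background, nr, nc)
      pr[!coc] <- pr[!coc] + spec$particle_intensity
      pr[inf_mask] <- spec$background + spec$particle_intensity

      ac <- matrix(spec$background, nr, nc)
      ac[coc] <- ac[coc] + spec$cell_intensity

      dn <- matrix(spec$background, nr, nc)
      for (k in seq_len(n_cells)) {
        d2 <- (rows - centers[k, 1L])^2 + (cols - centers[k, 2L])^2
        dn <- dn + spec$cell_intensity * exp(-d2 / (2 * 3^2))
      }
      dn[coc & !oo] <- dn[coc & !oo] + spec$intercellular_intensity

      ns <- function(m) {
        m + spec$noise_gain * sqrt(pmax(m, 0)) * stats::rnorm(length(m))
      }
      dna[[z]] <- ns(dn); actin[[z]] <- ns(ac); part[[z]] <- ns(pr)
    }
    img <- coc_image(channels = list(dna = simplify2array(dna),
                                     actin = simplify2array(actin),
                                     particles = simplify2array(part)),
                     pixel_size_um = spec$pixel_size_um)
    list(image = img,
         truth = list(coc_mask = coc,
                      infiltrated_mask = infil,
                      infiltrated_fraction = mean(vapply(infil, function(m)
                        sum(m & coc) / n_in, numeric(1L))),
                      nucleus_centers = centers))
  })
}

# ---------------------------------------------------------------------------
# expansion time-lapse

#' Specify a synthetic cumulus-expansion time course
#'
#' A logistic distance-vs-time curve sampled hourly over a 16 h observation,
#' mirroring time-lapse morphokinetics of cumulus expansion. An age-delayed
#' profile is obtained by shifting `t_mid_h` later.
#'
#' @param d_max_um asymptotic expansion distance, um.
#' @param t_mid_h inflection (peak-velocity) time, h.
#' @param rate_per_h logistic steepness, 1/h.
#' @param interval_h sampling interval, h (default 1).
#' @param horizon_h observation horizon, h (default 16).
#' @param noise_sd_um measurement noise sd, um.
#' @param seed integer RNG seed.
#' @return object of class `timelapse_spec`.
#' @export
timelapse_spec <- function(d_max_um = 75, t_mid_h = 6.5, rate_per_h = 0.6,
                           interval_h = 1, horizon_h = 16, noise_sd_um = 1,
                           seed = 1L) {
  stopifnot_scalar_pos(d_max_um, "d_max_um")
  stopifnot_scalar_pos(interval_h, "interval_h")
  if (horizon_h < interval_h) stop("horizon_h must be >= interval_h", call. = FALSE)
  if (noise_sd_um < 0) stop("noise_sd_um must be >= 0", call. = FALSE)
  structure(list(d_max_um = d_max_um, t_mid_h = t_mid_h,
                 rate_per_h = rate_per_h, interval_h = interval_h,
                 horizon_h = horizon_h, noise_sd_um = noise_sd_um,
                 seed = as.integer(seed)),
            class = "timelapse_spec")
}

#' Generate a synthetic expansion distance series
#'
#' @param spec a [timelapse_spec()].
#' @param coc_id,mouse_id identifiers attached to the series.
#' @return a [distance_series()]: times 0, interval, ..., horizon (h) and the
#'   logistic distances `d_max / (1 + exp(-rate * (t - t_mid)))` plus noise.
#' @export
gen_timelapse <- function(spec, coc_id = "coc1", mouse_id = "m1") {
  stopifnot(inherits(spec, "timelapse_spec"))
  with_seed(spec$seed, {
    t <- seq(0, spec$horizon_h, by = spec$interval_h)
    d <- spec$d_max_um / (1 + exp(-spec$rate_per_h * (t - spec$t_mid_h)))
    if (spec$noise_sd_um > 0) d <- d + stats::rnorm(length(t), sd = spec$noise_sd_um)
    distance_series(times_h = t, distances_um = d,
                    coc_id = coc_id, mouse_id = mouse_id)
  })
}

# ---------------------------------------------------------------------------
# Ct tables

#' Specify a synthetic gene x sample Ct table
#'
#' Emulates a customized RT2 array run on pooled young vs old samples: five
#' housekeeping genes with stable Ct, target genes whose old-group Ct is
#' shifted by a specified ddCt effect (a noiseless table then recovers
#' `FC = 2^-ddCt` exactly downstream).
#'
#' @param genes character vector of target genes (housekeeping genes are added
#'   automatically if absent).
#' @param n_young,n_old number of pooled samples (replicate experiments) per
#'   group; default 2 each (replicate r pairs young_r with old_r).
#' @param hkg_ct_mean,hkg_ct_sd housekeeping-gene Ct level and between-gene sd.
#' @param ddct_effects named numeric: gene -> ddCt (cycles; negative = higher
#'   expression in old). Housekeeping genes must have effect 0.
#' @param target_ct_mean baseline target-gene Ct level.
#' @param noise_sd technical Ct noise sd, cycles.
#' @param hkgs housekeeping gene names.
#' @param seed integer RNG seed.
#' @return object of class `ct_table_spec`.
#' @export
ct_table_spec <- function(genes = c("Has2", "Ptx3", "Tnfaip6", "Vcan", "Cd44"),
                          n_young = 2L, n_old = 2L,
                          hkg_ct_mean = 20, hkg_ct_sd = 0.5,
                          ddct_effects = c(Has2 = -1),
                          target_ct_mean = 25, noise_sd = 0.2,
                          hkgs = c("Gusb", "Actb", "Gapdh", "B2m", "Hsp90ab1"),
                          seed = 1L) {
  if (hkg_ct_mean <= 0 || hkg_ct_mean >= 45 || target_ct_mean <= 0 ||
      target_ct_mean >= 45) {
    stop("Ct means must lie in (0, 45)", call. = FALSE)
  }
  if (any(names(ddct_effects) %in% hkgs & ddct_effects != 0)) {
    stop("housekeeping genes must have ddCt effect 0", call. = FALSE)
  }
  if (noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  genes <- setdiff(unique(genes), hkgs)
  structure(list(genes = genes, n_young = as.integer(n_young),
                 n_old = as.integer(n_old), hkg_ct_mean = hkg_ct_mean,
                 hkg_ct_sd = hkg_ct_sd, ddct_effects = ddct_effects,
                 target_ct_mean = target_ct_mean, noise_sd = noise_sd,
                 hkgs = hkgs, seed = as.integer(seed)),
            class = "ct_table_spec")
}

#' Generate a synthetic Ct table
#'
#' @param spec a [ct_table_spec()].
#' @return a [ct_table()] with samples `young_1..n` and `old_1..n`, replicate
#'   ids pairing `young_r` with `old_r`.
#' @export
gen_ct_table <- function(spec) {
  stopifnot(inherits(spec, "ct_table_spec"))
  with_seed(spec$seed, {
    genes <- c(spec$hkgs, spec$genes)
    samples <- c(paste0("young_", seq_len(spec$n_young)),
                 paste0("old_", seq_len(spec$n_old)))
    group <- rep(c("young", "old"), c(spec$n_young, spec$n_old))
    replicate <- c(seq_len(spec$n_young), seq_len(spec$n_old))
    # per-gene baseline Ct, fixed across samples
    base <- c(stats::rnorm(length(spec$hkgs), spec$hkg_ct_mean, spec$hkg_ct_sd),
              stats::rnorm(length(spec$genes), spec$target_ct_mean, 1.5))
    names(base) <- genes
    ct <- matrix(base, nrow = length(genes), ncol = length(samples),
                 dimnames = list(genes, samples))
    eff <- spec$ddct_effects[match(genes, names(spec$ddct_effects))]
    eff[is.na(eff)] <- 0
    ct[, group == "old"] <- ct[, group == "old"] + eff
    if (spec$noise_sd > 0) {
      ct <- ct + matrix(stats::rnorm(length(ct), sd = spec$noise_sd),
                        nrow = nrow(ct))
    }
    ct_table(ct, sample_meta = data.frame(sample = samples, group = group,
                                          replicate = replicate),
             hkgs = spec$hkgs)
  })
}
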