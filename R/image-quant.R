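# Quantification of COC matrix permeability (particle exclusion assay) and
# HA staining (HABP) from multi-channel images.
#
# Images are plain numeric arrays: each channel is rows x cols (x z). Small
# binary-morphology primitives (Otsu threshold, 3x3 closing, hole fill,
# connected components) are implemented here on logical matrices; image sizes
# in this assay (single COC per field) keep them comfortably fast.

#' Construct a multi-channel COC image
#'
#' @param channels named list of numeric arrays (rows x cols or
#'   rows x cols x z), e.g. `dna`, `actin`, `particles` (or `habp`).
#' @param pixel_size_um pixel size, um/px.
#' @return object of class `coc_image`.
#' @export
coc_image <- function(channels, pixel_size_um) {
  stopifnot_scalar_pos(pixel_size_um, "pixel_size_um")
  if (!length(channels) || is.null(names(channels))) {
    stop("`channels` must be a named list", call. = FALSE)
  }
  dims <- lapply(channels, function(ch) dim(ch)[1:2])
  if (!all(vapply(dims, identical, logical(1L), dims[[1L]]))) {
    stop("all channels must share the same row/col shape", call. = FALSE)
  }
  nz <- vapply(channels, function(ch) if (length(dim(ch)) == 3L) dim(ch)[3L] else 1L,
               integer(1L))
  if (length(unique(nz)) != 1L) {
    stop("all channels must have the same number of z-planes", call. = FALSE)
  }
  structure(list(channels = channels, pixel_size_um = pixel_size_um,
                 z_count = nz[[1L]]),
            class = "coc_image")
}

#' @export
print.coc_image <- function(x, ...) {
  d <- dim(x$channels[[1L]])[1:2]
  cat(sprintf("coc_image: %d x %d px, %d z-plane(s), %.3g um/px, channels: %s\n",
              d[1L], d[2L], x$z_count, x$pixel_size_um,
              paste(names(x$channels), collapse = ", ")))
  invisible(x)
}

# z-plane extraction as a matrix
.plane <- function(ch, z) if (length(dim(ch)) == 3L) ch[, , z] else ch

# ---------------------------------------------------------------------------
# binary-morphology primitives

#' Otsu threshold of an intensity sample
#'
#' Exhaustive between-class-variance maximization over a 256-bin histogram.
#'
#' @param x numeric vector (or matrix) of intensities.
#' @return scalar threshold; pixels strictly above it are foreground.
#' @export
otsu_threshold <- function(x) {
  x <- as.numeric(x)
  x <- x[is.finite(x)]
  r <- range(x)
  if (r[1L] == r[2L]) return(r[1L])
  nb <- 256L
  br <- seq(r[1L], r[2L], length.out = nb + 1L)
  h <- tabulate(findInterval(x, br, rightmost.closed = TRUE), nbins = nb)
  p <- h / sum(h)
  mids <- (br[-1L] + br[-(nb + 1L)]) / 2
  w0 <- cumsum(p)
  mu <- cumsum(p * mids)
  mu_t <- mu[nb]
  w1 <- 1 - w0
  ok <- w0 > 0 & w1 > 0
  bcv <- rep(-Inf, nb)
  bcv[ok] <- (mu_t * w0[ok] - mu[ok])^2 / (w0[ok] * w1[ok])
  br[which.max(bcv) + 1L]
}

# 3x3 dilation / erosion by shift-and-combine
.dilate3 <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  out <- m
  sh <- function(dr, dc) {
    r <- pmin(pmax(seq_len(nr) + dr, 1L), nr)
    c <- pmin(pmax(seq_len(nc) + dc, 1L), nc)
    m[r, c, drop = FALSE]
  }
  for (dr in -1:1) for (dc in -1:1) out <- out | sh(dr, dc)
  out
}
.erode3 <- function(m) !.dilate3(!m)

# connected-component labeling (4-connectivity), two-pass with union-find
label_components <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  lab <- matrix(0L, nr, nc)
  parent <- integer(0)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  nxt <- 0L
  for (c in seq_len(nc)) for (r in seq_len(nr)) {
    if (!m[r, c]) next
    up <- if (r > 1L) lab[r - 1L, c] else 0L
    lf <- if (c > 1L) lab[r, c - 1L] else 0L
    if (up == 0L && lf == 0L) {
      nxt <- nxt + 1L; parent[nxt] <- nxt; lab[r, c] <- nxt
    } else if (up != 0L && lf != 0L) {
      ru <- find(up); rl <- find(lf)
      lab[r, c] <- ru
      if (ru != rl) parent[rl] <- ru
    } else {
      lab[r, c] <- max(up, lf)
    }
  }
  if (nxt > 0L) {
    roots <- vapply(seq_len(nxt), find, integer(1L))
    compact <- match(roots, unique(roots))
    pos <- lab > 0L
    lab[pos] <- compact[lab[pos]]
  }
  lab
}

# fill holes: background components not touching the border become foreground
fill_holes <- function(m) {
  lab <- label_components(!m)
  if (!any(lab > 0L)) return(m)
  border <- unique(c(lab[1L, ], lab[nrow(lab), ], lab[, 1L], lab[, ncol(lab)]))
  border <- border[border > 0L]
  m | !(lab %in% border | lab == 0L)
}

# ---------------------------------------------------------------------------
# COC segmentation and porosity

#' Construct a COC mask
#'
#' @param mask logical matrix, TRUE inside the COC.
#' @param pixel_size_um pixel size, um/px.
#' @return object of class `coc_mask` with `mask`, `area_px`, `area_mm2`.
#' @export
coc_mask <- function(mask, pixel_size_um) {
  stopifnot(is.logical(mask), is.matrix(mask))
  if (!any(mask)) stop("COC mask is empty", call. = FALSE)
  structure(list(mask = mask, area_px = sum(mask),
                 area_mm2 = sum(mask) * (pixel_size_um / 1000)^2),
            class = "coc_mask")
}

#' Segment the COC region from a structural channel
#'
#' Otsu threshold on the structural (actin) channel, 3x3 morphological
#' closing, hole filling, then the largest connected component. When several
#' z-planes are present their maximum projection is segmented.
#'
#' @param image a [coc_image()].
#' @param channel structural channel name (default `"actin"`).
#' @return a [coc_mask()].
#' @export
segment_coc <- function(image, channel = "actin") {
  stopifnot(inherits(image, "coc_image"))
  if (!channel %in% names(image$channels)) {
    stop(sprintf("channel '%s' not present", channel), call. = FALSE)
  }
  ch <- image$channels[[channel]]
  m <- if (length(dim(ch)) == 3L) apply(ch, 1:2, max) else ch
  thr <- otsu_threshold(m)
  fg <- m > thr
  if (!any(fg)) stop("empty foreground after thresholding", call. = FALSE)
  fg <- .erode3(.dilate3(fg))     # closing
  fg <- fill_holes(fg)
  lab <- label_components(fg)
  if (!any(lab > 0L)) stop("empty foreground after morphology", call. = FALSE)
  sizes <- tabulate(lab[lab > 0L])
  coc_mask(lab == which.max(sizes), image$pixel_size_um)
}

#' Particle-exclusion-assay porosity of a COC
#'
#' Two permeability readouts: (1) percent porosity = 100 x (area infiltrated
#' by nanoparticles within the COC) / (whole COC area); (2) nanoparticle mean
#' fluorescent intensity per pixel = total particle intensity over the COC /
#' number of COC pixels. With several z-planes both are computed per plane and
#' averaged.
#'
#' @param image a [coc_image()] with a particle channel.
#' @param mask a [coc_mask()].
#' @param particle_threshold `"otsu"` (per-plane Otsu within the mask,
#'   default) or a fixed numeric threshold; pixels strictly above it count as
#'   infiltrated.
#' @param channel particle channel name (default `"particles"`).
#' @return object of class `porosity_result`: `percent_porosity` in [0, 100],
#'   `mean_intensity_per_pixel`, and the per-plane values.
#' @export
porosity <- function(image, mask, particle_threshold = "otsu",
                     channel = "particles") {
  stopifnot(inherits(image, "coc_image"), inherits(mask, "coc_mask"))
  if (!channel %in% names(image$channels)) {
    stop(sprintf("channel '%s' not present", channel), call. = FALSE)
  }
  ch <- image$channels[[channel]]
  per_z <- vapply(seq_len(image$z_count), function(z) {
    v <- .plane(ch, z)[mask$mask]
    thr <- if (identical(particle_threshold, "otsu")) otsu_threshold(v)
           else as.numeric(particle_threshold)
    c(100 * mean(v > thr), mean(pmax(v, 0)))
  }, numeric(2L))
  structure(list(percent_porosity = mean(per_z[1L, ]),
                 mean_intensity_per_pixel = mean(per_z[2L, ]),
                 per_plane = data.frame(z = seq_len(image$z_count),
                                        percent_porosity = per_z[1L, ],
                                        mean_intensity_per_pixel = per_z[2L, ])),
            class = "porosity_result")
}

# ---------------------------------------------------------------------------
# HABP ROI intensities

#' Construct an ROI set
#'
#' @param rois data.frame with columns `row`, `col` (ROI center), `size_px`
#'   (square side), `category` (`"cellular"` or `"intercellular"`), `z`.
#' @return object of class `roi_set`.
#' @export
roi_set <- function(rois) {
  stopifnot(is.data.frame(rois),
            all(c("row", "col", "size_px", "category", "z") %in% names(rois)))
  if (!all(rois$category %in% c("cellular", "intercellular"))) {
    stop("ROI categories must be 'cellular' or 'intercellular'", call. = FALSE)
  }
  structure(list(rois = rois), class = "roi_set")
}

.roi_indices <- function(roi, nr, nc) {
  h <- floor(roi$size_px / 2)
  r <- (roi$row - h):(roi$row + h)
  c <- (roi$col - h):(roi$col + h)
  if (min(r) < 1L || max(r) > nr || min(c) < 1L || max(c) > nc) {
    stop("ROI extends outside the image", call. = FALSE)
  }
  list(rows = r, cols = c)
}

#' Mean HABP intensity per pixel in cellular and intercellular ROIs
#'
#' Per category, each ROI's mean intensity per pixel is computed on its
#' z-plane and the category value is the mean of ROI means (ROIs are the unit
#' of assessment, not pooled pixels).
#'
#' @param image a [coc_image()].
#' @param rois a [roi_set()].
#' @param channel intensity channel name (default `"habp"`, falling back to
#'   `"particles"` if absent).
#' @return object of class `habp_result`: `cellular_mean`,
#'   `intercellular_mean`, and per-ROI means.
#' @export
habp_intensity <- function(image, rois, channel = "habp") {
  stopifnot(inherits(image, "coc_image"), inherits(rois, "roi_set"))
  if (!channel %in% names(image$channels) && channel == "habp" &&
      "particles" %in% names(image$channels)) {
    channel <- "particles"
  }
  if (!channel %in% names(image$channels)) {
    stop(sprintf("channel '%s' not present", channel), call. = FALSE)
  }
  ch <- image$channels[[channel]]
  nr <- dim(ch)[1L]; nc <- dim(ch)[2L]
  d <- rois$rois
  if (!all(c("cellular", "intercellular") %in% d$category)) {
    stop("need at least one ROI per category", call. = FALSE)
  }
  d$mean_intensity <- vapply(seq_len(nrow(d)), function(k) {
    ix <- .roi_indices(d[k, ], nr, nc)
    mean(.plane(ch, d$z[k])[ix$rows, ix$cols])
  }, numeric(1L))
  structure(list(
    cellular_mean = mean(d$mean_intensity[d$category == "cellular"]),
    intercellular_mean = mean(d$mean_intensity[d$category == "intercellular"]),
    per_roi = d
  ), class = "habp_result")
}

#' Place cellular and intercellular ROIs deterministically
#'
#' Candidate square ROIs inside the COC mask (excluding the oocyte
#' neighbourhood) are scored by their DNA-channel mean; the `n_rois` highest-
#' scoring non-overlapping candidates per z-plane become cellular ROIs (a
#' proxy for "adjacent cumulus cells"), the `n_rois` lowest-scoring become
#' intercellular ROIs. All ROIs share one size. Deterministic given `seed`.
#'
#' @param image a [coc_image()] with a `dna` channel.
#' @param mask a [coc_mask()].
#' @param n_rois ROIs per category per z-plane (default 9).
#' @param n_z number of z-planes to use (default `min(3, z_count)`).
#' @param roi_size_px square ROI side, px (odd; default 11).
#' @param seed integer seed controlling candidate sampling.
#' @return a [roi_set()] with `n_rois * n_z` ROIs per category.
#' @export
place_rois <- function(image, mask, n_rois = 9L, n_z = NULL, roi_size_px = 11L,
                       seed = 1L) {
  stopifnot(inherits(image, "coc_image"), inherits(mask, "coc_mask"))
  if (!"dna" %in% names(image$channels)) {
    stop("ROI placement needs a 'dna' channel", call. = FALSE)
  }
  if (is.null(n_z)) n_z <- min(3L, image$z_count)
  if (n_z > image$z_count) stop("n_z exceeds available z-planes", call. = FALSE)
  h <- floor(roi_size_px / 2)
  nr <- nrow(mask$mask); nc <- ncol(mask$mask)
  # interior pixels whose whole ROI fits inside the mask: erode h times
  interior <- mask$mask
  for (i in seq_len(h + 1L)) interior <- .erode3(interior)
  cand <- which(interior, arr.ind = TRUE)
  if (nrow(cand) < 4L * n_rois) {
    stop("mask too small for the requested ROIs", call. = FALSE)
  }
  with_seed(seed, {
    out <- list()
    for (z in seq_len(n_z)) {
      dna <- .plane(image$channels$dna, z)
      take <- sample.int(nrow(cand), min(nrow(cand), 60L * n_rois))
      sc <- vapply(take, function(j) {
        mean(dna[(cand[j, 1L] - h):(cand[j, 1L] + h),
                 (cand[j, 2L] - h):(cand[j, 2L] + h)])
      }, numeric(1L))
      pick_nonoverlap <- function(order_idx) {
        sel <- integer(0)
        for (j in order_idx) {
          if (length(sel) == n_rois) break
          if (!length(sel) ||
              all(pmax(abs(cand[take[j], 1L] - cand[take[sel], 1L]),
                       abs(cand[take[j], 2L] - cand[take[sel], 2L])) > roi_size_px)) {
            sel <- c(sel, j)
          }
        }
        if (length(sel) < n_rois) {
          stop("could not place the requested number of ROIs", call. = FALSE)
        }
        sel
      }
      hi <- pick_nonoverlap(order(sc, decreasing = TRUE))
      lo <- pick_nonoverlap(order(sc))
      out[[z]] <- data.frame(
        row = cand[take[c(hi, lo)], 1L], col = cand[take[c(hi, lo)], 2L],
        size_px = roi_size_px,
        category = rep(c("cellular", "intercellular"), each = n_rois),
        z = z)
    }
    roi_set(do.call(rbind, out))
  })
}
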