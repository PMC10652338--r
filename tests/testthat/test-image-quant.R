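# COC image quantification: segmentation, porosity, HABP ROI intensities

test_that("segment_coc recovers a disk geometry", {
  g <- gen_coc_image(coc_image_spec(coc_radius_px = 70, seed = 5))
  m <- segment_coc(g$image)
  expect_lt(abs(m$area_px - pi * 70^2) / (pi * 70^2), 0.03)
  # area_mm2 consistent with the pixel size
  expect_equal(m$area_mm2, m$area_px * (g$image$pixel_size_um / 1000)^2)
  # blank image errors
  blank <- coc_image(list(actin = matrix(0, 50, 50)), pixel_size_um = 1)
  expect_error(segment_coc(blank))
  # two disks: the larger one is returned
  img <- matrix(0, 120, 120)
  for (r in 1:120) for (c in 1:120) {
    if ((r - 35)^2 + (c - 35)^2 <= 20^2) img[r, c] <- 100
    if ((r - 85)^2 + (c - 85)^2 <= 10^2) img[r, c] <- 100
  }
  m2 <- segment_coc(coc_image(list(actin = img), pixel_size_um = 1))
  expect_lt(abs(m2$area_px - pi * 400) / (pi * 400), 0.05)
  expect_true(m2$mask[35, 35])
  expect_false(m2$mask[85, 85])
})

test_that("porosity matches trivial and generator-truth cases", {
  g <- gen_coc_image(coc_image_spec(porosity_fraction = 0.5, seed = 8))
  mask <- coc_mask(g$truth$coc_mask, g$image$pixel_size_um)
  # particle channel zeroed inside the mask -> porosity 0, mean intensity 0
  img0 <- g$image
  for (z in seq_len(img0$z_count)) {
    pl <- img0$channels$particles[, , z]
    pl[mask$mask] <- 0
    img0$channels$particles[, , z] <- pl
  }
  p0 <- porosity(img0, mask, particle_threshold = 1)
  expect_equal(p0$percent_porosity, 0)
  expect_equal(p0$mean_intensity_per_pixel, 0)
  # saturating channel -> 100%
  img1 <- g$image
  img1$channels$particles[] <- 1000
  expect_equal(porosity(img1, mask, particle_threshold = 10)$percent_porosity, 100)
  # synthetic truth fraction 0.5 -> Otsu porosity within [48, 52]%
  p <- porosity(g$image, mask)
  expect_gt(p$percent_porosity, 48)
  expect_lt(p$percent_porosity, 52)
})

test_that("porosity invariances hold", {
  g <- gen_coc_image(coc_image_spec(porosity_fraction = 0.4, seed = 12))
  mask <- coc_mask(g$truth$coc_mask, g$image$pixel_size_um)
  p <- porosity(g$image, mask)
  # Otsu porosity invariant under uniform intensity rescaling
  img2 <- g$image
  img2$channels$particles <- img2$channels$particles * 3.7
  p2 <- porosity(img2, mask)
  expect_equal(p2$percent_porosity, p$percent_porosity, tolerance = 1e-10)
  # mean intensity per pixel linear in channel gain
  expect_equal(p2$mean_intensity_per_pixel, 3.7 * p$mean_intensity_per_pixel,
               tolerance = 1e-6)
})

test_that("porosity is monotone in the generated infiltrated fraction", {
  fr <- seq(0.05, 0.95, by = 0.1)
  meas <- vapply(fr, function(f) {
    g <- gen_coc_image(coc_image_spec(porosity_fraction = f, n_z = 1L, seed = 99))
    porosity(g$image, coc_mask(g$truth$coc_mask, 1.5))$percent_porosity
  }, numeric(1L))
  expect_equal(cor(fr, meas, method = "spearman"), 1)
})

test_that("habp_intensity averages ROI means, not pooled pixels", {
  # uniform channel: both category means equal the value
  img <- coc_image(list(dna = matrix(1, 100, 100), habp = matrix(7, 100, 100)),
                   pixel_size_um = 1)
  rs <- roi_set(data.frame(row = c(20, 50, 80), col = c(20, 50, 80),
                           size_px = 5,
                           category = c("cellular", "cellular", "intercellular"),
                           z = 1L))
  h <- habp_intensity(img, rs)
  expect_equal(h$cellular_mean, 7)
  expect_equal(h$intercellular_mean, 7)
  # constructed regions: cellular on 50, intercellular on 5
  ch <- matrix(5, 100, 100); ch[10:40, 10:40] <- 50
  img2 <- coc_image(list(habp = ch), pixel_size_um = 1)
  rs2 <- roi_set(data.frame(row = c(20, 80), col = c(20, 80), size_px = 5,
                            category = c("cellular", "intercellular"), z = 1L))
  h2 <- habp_intensity(img2, rs2)
  expect_equal(h2$cellular_mean, 50)
  expect_equal(h2$intercellular_mean, 5)
  # averaging order: ROI means {10, 20, 60} -> category mean 30
  ch3 <- matrix(0, 60, 200)
  ch3[, 1:40] <- 10; ch3[, 81:120] <- 20; ch3[, 161:200] <- 60
  img3 <- coc_image(list(habp = ch3), pixel_size_um = 1)
  rs3 <- roi_set(data.frame(row = 30, col = c(20, 100, 180, 20),
                            size_px = c(31, 11, 21, 5),
                            category = c(rep("cellular", 3), "intercellular"),
                            z = 1L))
  expect_equal(habp_intensity(img3, rs3)$cellular_mean, 30)
  # ROI outside the image errors
  rs_bad <- roi_set(data.frame(row = 1, col = 1, size_px = 9,
                               category = c("cellular", "intercellular"),
                               z = 1L))
  expect_error(habp_intensity(img, rs_bad), "outside")
})

test_that("place_rois is deterministic, counted, and contained in the mask", {
  g <- gen_coc_image(coc_image_spec(seed = 21))
  mask <- segment_coc(g$image)
  r1 <- place_rois(g$image, mask, n_rois = 9L, n_z = 3L, seed = 77)
  r2 <- place_rois(g$image, mask, n_rois = 9L, n_z = 3L, seed = 77)
  expect_identical(r1$rois, r2$rois)
  expect_identical(sum(r1$rois$category == "cellular"), 27L)
  expect_identical(sum(r1$rois$category == "intercellular"), 27L)
  h <- floor(11 / 2)
  for (k in seq_len(nrow(r1$rois))) {
    rr <- r1$rois$row[k]; cc <- r1$rois$col[k]
    expect_true(all(mask$mask[(rr - h):(rr + h), (cc - h):(cc + h)]))
  }
  # cellular ROIs land on higher DNA signal than intercellular ones
  hb <- habp_intensity(g$image, r1, channel = "dna")
  expect_gt(hb$cellular_mean, hb$intercellular_mean)
})

test_that("coc images round-trip through the text container", {
  g <- gen_coc_image(coc_image_spec(shape_px = c(60L, 60L), coc_radius_px = 25,
                                    oocyte_radius_px = 8, n_z = 2L, seed = 3))
  stem <- file.path(withr::local_tempdir(), "img")
  write_coc_image(g$image, stem)
  back <- read_coc_image(stem)
  expect_equal(back$channels$particles, g$image$channels$particles,
               tolerance = 1e-12)
  expect_identical(back$z_count, 2L)
  expect_equal(back$pixel_size_um, g$image$pixel_size_um)
})
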