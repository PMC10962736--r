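# single-shape rasterization helper: one ellipse centered in a padded image
raster_one <- function(a, b, rotation = 0, pixel_size_nm = 10) {
  mk <- generate_mask_fixture(data.frame(semi_major_px = a, semi_minor_px = b,
                                         rotation = rotation),
                              pixel_size_nm,
                              c(ceiling(4 * a) + 8, ceiling(4 * a) + 8),
                              seed = 1)
  region_features(mk$labels, pixel_size_nm)
}

test_that("equivalent-ellipse axes recover planted geometry", {
  circ <- raster_one(20, 20)
  expect_equal(circ$major_axis_nm, 400, tolerance = 0.02)
  expect_equal(circ$minor_axis_nm, 400, tolerance = 0.02)
  expect_equal(circ$aspect_ratio, 1, tolerance = 0.02)
  ell <- raster_one(30, 10, rotation = 0.5)
  expect_equal(ell$major_axis_nm, 600, tolerance = 0.02)
  expect_equal(ell$minor_axis_nm, 200, tolerance = 0.02)
  expect_equal(ell$aspect_ratio, 3, tolerance = 0.02)
})

test_that("features are invariant to a 90-degree rotation", {
  r0 <- raster_one(25, 12, rotation = 0)
  r90 <- raster_one(25, 12, rotation = pi / 2)
  expect_equal(r0$major_axis_nm, r90$major_axis_nm, tolerance = 0.01)
  expect_equal(r0$minor_axis_nm, r90$minor_axis_nm, tolerance = 0.01)
  expect_equal(r0$aspect_ratio, r90$aspect_ratio, tolerance = 0.01)
  expect_equal(r0$area_um2, r90$area_um2, tolerance = 0.01)
})

test_that("per-label areas conserve the total foreground exactly", {
  pp <- preset_s59l_population(seed = 2)
  mk <- generate_mask_fixture(pp$shapes[1:40, ], pp$pixel_size_nm,
                              c(1024, 1024), seed = 2)
  rf <- region_features(mk$labels, pp$pixel_size_nm, check_connectivity = FALSE)
  expect_identical(sum(rf$n_pixels), sum(mk$labels > 0))
  expect_equal(sum(rf$area_um2),
               sum(mk$labels > 0) * (pp$pixel_size_nm / 1000)^2)
})

test_that("features scale correctly with pixel size", {
  mk <- generate_mask_fixture(data.frame(semi_major_px = 18, semi_minor_px = 12,
                                         rotation = 1), 10, c(128, 128))
  f1 <- region_features(mk$labels, 10)
  f2 <- region_features(mk$labels, 20)
  expect_equal(f2$major_axis_nm, 2 * f1$major_axis_nm)
  expect_equal(f2$minor_axis_nm, 2 * f1$minor_axis_nm)
  expect_equal(f2$area_um2, 4 * f1$area_um2)
  expect_equal(f2$aspect_ratio, f1$aspect_ratio)
})

test_that("nano calls depend on physical size, not raster resolution", {
  # same physical shape (240 x 320 nm axes) sampled at 10 and 5 nm/px
  coarse <- raster_one(16, 12, pixel_size_nm = 10)
  fine <- raster_one(32, 24, pixel_size_nm = 5)
  expect_equal(classify_nano(coarse), classify_nano(fine))
  expect_equal(coarse$minor_axis_nm, fine$minor_axis_nm, tolerance = 0.02)
})

test_that("the nano rule is strict at both boundaries", {
  expect_true(classify_nano(249, 1.4))
  expect_false(classify_nano(250, 1.0))
  expect_false(classify_nano(200, 1.6))
  expect_false(classify_nano(200, 1.5))
  expect_false(classify_nano(250, 1.4))
})

test_that("tiny and disconnected labels are flagged, not dropped", {
  m <- matrix(0L, 16, 16)
  m[2, 2:3] <- 1L                 # 2-pixel label
  m[6:8, 6:8] <- 2L
  expect_warning(rf <- region_features(m, 10), NA)
  expect_true(rf$degenerate[rf$label == 1])
  expect_false(rf$degenerate[rf$label == 2])
  m[12:13, 12:13] <- 2L           # second component for label 2
  expect_warning(rf2 <- region_features(m, 10), "not 8-connected")
  expect_false(rf2$connected[rf2$label == 2])
})

test_that("population summaries report medians, IQRs and class frequencies", {
  pp <- preset_s59l_population(seed = 1)
  mk <- generate_mask_fixture(pp$shapes, pp$pixel_size_nm, pp$image_shape,
                              seed = 1)
  rf <- region_features(mk$labels, pp$pixel_size_nm, check_connectivity = FALSE)
  out <- summarize_population(rf)
  expect_equal(out$summary$n, 200)
  expect_equal(out$summary$pct_nano, 22, tolerance = 1e-9)
  expect_equal(out$summary$median_area_um2, median(rf$area_um2))
  ann <- data.frame(label = c(1, 2, 3, 3),
                    class = c("inclusion", "inclusion", "electrolucent",
                              "omm_rupture"))
  out2 <- summarize_population(rf, ann)
  cf <- out2$class_freq
  expect_equal(cf$n[cf$class == "inclusion"], 2)
  expect_equal(cf$pct[cf$class == "electrolucent"], 0.5)
  bad <- data.frame(label = 999, class = "inclusion")
  expect_error(summarize_population(rf, bad), class = "mtisr_contract_error")
})

test_that("median area recovery matches a planted population", {
  # plant circles whose median area is 0.57 um^2 (radius from pi r^2 = A)
  areas <- c(0.40, 0.50, 0.57, 0.70, 0.90)  # um^2, median 0.57
  r_px <- sqrt(areas / pi) * 1000 / 10       # at 10 nm/px
  mk <- generate_mask_fixture(data.frame(semi_major_px = r_px,
                                         semi_minor_px = r_px, rotation = 0),
                              10, c(512, 512), seed = 9)
  rf <- region_features(mk$labels, 10)
  expect_equal(median(rf$area_um2), 0.57, tolerance = 0.02)
})

test_that("fiber quantification measures CSA and mean intensity per label", {
  fb <- generate_fiber_fixture(seed = 3)
  fq <- fiber_quantify(fb$labels, fb$intensity, fb$pixel_size_nm,
                       fb$annotations)
  tr <- fb$truth[match(fq$label, fb$truth$label), ]
  expect_equal(fq$csa_um2, tr$csa_um2)
  expect_equal(fq$mean_intensity, tr$intensity)
  # uniform intensity image: every mean equals the constant
  uni <- fiber_quantify(fb$labels, matrix(7, nrow(fb$labels), ncol(fb$labels)),
                        fb$pixel_size_nm)
  expect_true(all(uni$mean_intensity == 7))
  expect_true(all(is.na(uni$ub_status)))
  expect_error(fiber_quantify(fb$labels, matrix(0, 2, 2), 1000),
               class = "mtisr_contract_error")
})

test_that("group percent difference follows its arithmetic definition", {
  rec <- data.frame(label = 1:4, csa_um2 = c(1, 1, 2, 2),
                    mean_intensity = c(10, 10, 10, 10),
                    ub_status = c("pos", "pos", "neg", "neg"))
  expect_equal(group_percent_difference(rec, "mean_intensity"), 0,
               ignore_attr = TRUE)
  rec$mean_intensity <- c(2.712, 2.712, 1, 1)
  expect_equal(group_percent_difference(rec, "mean_intensity"), 171.2,
               ignore_attr = TRUE)
  expect_equal(group_percent_difference(rec, "csa_um2"), -50,
               ignore_attr = TRUE)
  rec2 <- rec; rec2$ub_status[3] <- NA
  pd <- group_percent_difference(rec2, "mean_intensity")
  expect_equal(attr(pd, "n_unannotated"), 1L)
})
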