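test_that("expression fixtures are reproducible and seed-sensitive", {
  s <- preset_bat_coldstress(seed = 7)
  a <- generate_expression_fixture(s)
  b <- generate_expression_fixture(s)
  expect_identical(a$matrix, b$matrix)
  expect_identical(a$samples, b$samples)
  expect_identical(a$truth, b$truth)
  c <- generate_expression_fixture(preset_bat_coldstress(seed = 8))
  expect_false(identical(a$matrix, c$matrix))
})

test_that("planted arm means follow the dependence model", {
  fx <- make_fixture(beta = c(2, 2, 0), dep = c(100, 40, 50), noiseless = TRUE)
  m <- fx$matrix
  ctl <- rowMeans(m[, arm_samples(fx$samples, "m1", "control")])
  st <- rowMeans(m[, arm_samples(fx$samples, "m1", "stress_wt")])
  ko <- rowMeans(m[, arm_samples(fx$samples, "m1", "stress_ko")])
  expect_equal(unname(st - ctl), c(2, 2, 0))
  # full reversion: KO arm equals control exactly
  expect_equal(ko[["g001"]], ctl[["g001"]])
  expect_equal(unname(ko - ctl), c(0, 1.2, 0))
})

test_that("expected truth flags come from planted means, not noise", {
  fx <- make_fixture(beta = c(0, 2, 0.8, 2), dep = c(100, 100, 100, 40))
  tr <- fx$truth
  expect_false(tr$expected_deg[1])       # no planted effect
  expect_true(tr$expected_dependent[2])
  expect_false(tr$expected_deg[3])       # sub-gate effect
  expect_false(tr$expected_dependent[4]) # KO change under the gate
})

test_that("fixture specs validate their invariants", {
  plans <- data.frame(model = "m", gene_id = c("a", "a"), baseline = 8,
                      beta = 0, dependence_pct = 0, noise_sd = 0.1)
  expect_error(fixture_spec(plans), class = "mtisr_validation_error")
  plans$gene_id <- c("a", "b")
  expect_error(fixture_spec(plans, n_per_arm = 1), class = "mtisr_validation_error")
  plans$dependence_pct <- c(0, 200)
  expect_error(fixture_spec(plans), class = "mtisr_validation_error")
  plans$dependence_pct <- 0
  plans$noise_sd <- -1
  expect_error(fixture_spec(plans), class = "mtisr_validation_error")
  # a model missing plans for part of the gene universe
  two <- rbind(data.frame(model = "m1", gene_id = c("a", "b"), baseline = 8,
                          beta = 0, dependence_pct = 0, noise_sd = 0.1),
               data.frame(model = "m2", gene_id = "a", baseline = 8,
                          beta = 0, dependence_pct = 0, noise_sd = 0.1))
  expect_error(fixture_spec(two), class = "mtisr_validation_error")
})

test_that("noiseless three-model fixture recovers every planted truth flag", {
  hr <- run_heart(preset_heart_threemodel(seed = 1, noiseless = TRUE))
  for (m in names(hr$dep)) {
    truth <- hr$fx$truth[hr$fx$truth$model == m, ]
    stress <- hr$stress[[m]]
    expect_equal(stress$is_deg,
                 truth$expected_deg[match(stress$gene_id, truth$gene_id)])
    dep <- hr$dep[[m]]
    expect_equal(dep$is_dependent,
                 truth$expected_dependent[match(dep$gene_id, truth$gene_id)])
  }
})

test_that("mask fixtures are reproducible, in-bounds, and truth-consistent", {
  shapes <- data.frame(semi_major_px = c(20, 30, 13),
                       semi_minor_px = c(20, 10, 10),
                       rotation = c(0, 0.7, 2.1))
  a <- generate_mask_fixture(shapes, 10, c(256, 256), seed = 3)
  b <- generate_mask_fixture(shapes, 10, c(256, 256), seed = 3)
  expect_identical(a$labels, b$labels)
  expect_equal(sort(unique(as.vector(a$labels))), 0:3)
  # no shape touches the border
  expect_true(all(a$labels[1, ] == 0) && all(a$labels[, 1] == 0))
  expect_equal(a$truth$minor_axis_nm, 2 * shapes$semi_minor_px * 10)
  # circle of radius 20 px at 10 nm: minor axis 400 nm, not nano
  expect_equal(a$truth$minor_axis_nm[1], 400)
  expect_false(a$truth$is_nano[1])
  # 30 x 10 px semi-axes at 10 nm: minor 200 nm but AR 3 fails the nano rule
  expect_equal(a$truth$aspect_ratio[2], 3)
  expect_false(a$truth$is_nano[2])
  # 13 x 10 px: minor 200 nm, AR 1.3: nano by the rule
  expect_true(a$truth$is_nano[3])
})

test_that("impossible placements fail with a placement error", {
  shapes <- data.frame(semi_major_px = rep(30, 4), semi_minor_px = 30,
                       rotation = 0)
  expect_error(generate_mask_fixture(shapes, 10, c(70, 70), max_retries = 50),
               class = "mtisr_placement_error")
})

test_that("the ellipse-population preset plants a 22% nano fraction", {
  pp <- preset_s59l_population(seed = 1)
  expect_equal(nrow(pp$shapes), 200)
  mk <- generate_mask_fixture(pp$shapes, pp$pixel_size_nm, pp$image_shape,
                              seed = 1)
  expect_equal(100 * mean(mk$truth$is_nano), 22)
  # planted axes keep clear of both decision boundaries
  expect_true(all(abs(mk$truth$minor_axis_nm - 250) / 250 > 0.05))
  expect_true(all(abs(mk$truth$aspect_ratio - 1.5) / 1.5 > 0.05))
})

test_that("fiber fixtures hit planted group means exactly in noiseless mode", {
  fb <- generate_fiber_fixture(seed = 5)
  tr <- fb$truth
  expect_equal(mean(tr$csa_um2[tr$group == "ub_pos"]), 330.0)
  expect_equal(mean(tr$csa_um2[tr$group == "ub_neg"]), 446.9)
  expect_equal(unique(tr$intensity[tr$group == "ub_pos"]), 2712)
  b <- generate_fiber_fixture(seed = 5)
  expect_identical(fb$labels, b$labels)
  expect_identical(fb$intensity, b$intensity)
  expect_error(generate_fiber_fixture(csa_mean_by_group = c(ub_pos = -1,
                                                            ub_neg = 400)),
               class = "mtisr_validation_error")
})

test_that("single-group fiber populations flag the undefined comparison", {
  fb <- generate_fiber_fixture(n_fibers = c(ub_pos = 10, ub_neg = 10), seed = 2)
  fq <- fiber_quantify(fb$labels, fb$intensity, fb$pixel_size_nm,
                       fb$annotations[fb$annotations$ub_status == "pos", ])
  expect_warning(pd <- group_percent_difference(fq, "mean_intensity"),
                 "undefined")
  expect_true(is.na(pd))
})
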