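test_that("ground-truth barycentre tracks the programmed vertical offset", {
  for (off in c(0, 40, -40)) {
    vol <- generate_phantom_volume(small_config(vertical_offset = off))
    gt <- vol$ground_truth$per_slice
    # body raised above isocentre (positive offset) sits at smaller image y
    expect_true(all(abs(gt$bary_y_mm - (-off)) <= 2),
                label = sprintf("offset %d barycentre", off))
    expect_true(all(abs(gt$bary_x_mm) <= 2))
  }
})

test_that("lungs exist exactly in chest slices of the label volume", {
  vol <- generate_phantom_volume(small_config())
  gt <- vol$ground_truth$per_slice
  lung_px <- vapply(vol$labels, function(l) sum(l == "lung"), numeric(1))
  expect_true(all(lung_px[gt$zone == "chest"] > 0))
  expect_true(all(lung_px[gt$zone %in% c("pelvis", "abdomen")] == 0))
  bone_px <- vapply(vol$labels, function(l) sum(l == "bone"), numeric(1))
  expect_true(all(bone_px > 0))
})

test_that("invalid phantom configurations are rejected", {
  expect_error(phantom_config(mattress_thickness = -1), "mattress_thickness")
  expect_error(phantom_config(vertical_offset = 300), "field of view")
  expect_error(phantom_config(torso_axes = list(
    shoulder = c(300, 85), chest = c(150, 100),
    abdomen = c(135, 90), pelvis = c(155, 95))), "field of view")
  expect_error(phantom_config(hu_values = c(air = -1000, lung = -1000,
    soft = 40, bone = 700, foam = -850, table = 100)), "distinct")
})

test_that("topogram magnification follows the source geometry law", {
  vol <- generate_phantom_volume(small_config())
  t0 <- simulate_topogram(vol, vertical_offset = 0)
  expect_identical(t0$magnification, 1)
  tp <- simulate_topogram(vol, vertical_offset = 59.5)
  tm <- simulate_topogram(vol, vertical_offset = -59.5)
  expect_equal(tp$magnification, 1 / (1 - 0.1), tolerance = 1e-12)
  expect_equal(tm$magnification, 1 / (1 + 0.1), tolerance = 1e-12)
  # measured widths scale accordingly, to one lateral pixel
  dx <- diff(t0$lateral_mm[1:2])
  for (s in c(3, 7, 11)) {
    w0 <- topogram_width(t0, s)
    expect_equal(topogram_width(tp, s), w0 * tp$magnification,
                 tolerance = 2 * dx / w0)
    expect_equal(topogram_width(tm, s), w0 * tm$magnification,
                 tolerance = 2 * dx / w0)
  }
  expect_error(simulate_topogram(vol, vertical_offset = 600), "smaller")
})

test_that("magnification ratio across offsets matches 1/(1 - o/SID) closely", {
  for (o in c(-59.5, 20, 59.5)) {
    vol <- generate_phantom_volume(small_config())
    t <- simulate_topogram(vol, vertical_offset = o)
    expect_equal(t$magnification, 1 / (1 - o / 595), tolerance = 1e-9)
  }
})

test_that("tube-current modulation is flat at the calibration width and monotone in width", {
  # hand-built topogram on a half-integer grid: exactly 300 of the 1 mm
  # columns are body, so the measured width is exactly 300 mm
  lat <- seq(-249.5, 249.5, by = 1)
  flat <- structure(list(
    intensity = matrix(ifelse(abs(lat) <= 150, 1, 0), 5, length(lat),
                       byrow = TRUE),
    lateral_mm = lat, z_mm = 0:4 * 10, magnification = 1),
    class = "topogram")
  prof <- simulate_tcm_profile(flat, quality_ref_mas = 240,
                               reference_width_mm = 300)
  expect_equal(prof$mas, rep(240, 5), tolerance = 1e-12)

  # width ratio 330/300 = 1.1 at alpha = 1 scales the mAs by 1.1
  wide <- flat
  wide$intensity <- matrix(ifelse(abs(lat) <= 165, 1, 0),
                           5, length(lat), byrow = TRUE)
  pw <- simulate_tcm_profile(wide, quality_ref_mas = 240,
                             reference_width_mm = 300)
  expect_equal(pw$mas / prof$mas, rep(1.1, 5), tolerance = 1e-12)

  # a magnified (raised-body) topogram draws strictly more mAs on average
  vol <- generate_phantom_volume(small_config())
  m0 <- simulate_tcm_profile(simulate_topogram(vol, vertical_offset = 0))
  m1 <- simulate_tcm_profile(simulate_topogram(vol, vertical_offset = 50))
  expect_gt(mean(m1$mas), mean(m0$mas))
  expect_true(all(m1$mas >= m0$mas))
})

test_that("noisy rendering is reproducible and follows the mAs noise law", {
  cfg <- small_config(seed = 7)
  vol <- generate_phantom_volume(cfg)
  a <- render_noisy_series(vol)
  b <- render_noisy_series(vol)
  expect_identical(a$series$slices[[5]]$pixels, b$series$slices[[5]]$pixels)

  # doubled mAs divides the injected sigma by sqrt(2)
  n <- cfg$n_slices
  flat <- data.frame(slice_index = 1:n, z_mm = (1:n - 1) * 5,
                     mas = rep(cfg$quality_ref_mas, n))
  dbl <- flat; dbl$mas <- 2 * flat$mas
  r1 <- render_noisy_series(vol, flat, seed = 1)
  r2 <- render_noisy_series(vol, dbl, seed = 1)
  expect_equal(r1$ground_truth$sigma_realized[, "soft"] /
                 r2$ground_truth$sigma_realized[, "soft"],
               rep(sqrt(2), n), tolerance = 1e-12)

  # measured interior soft-tissue SD at reference mAs recovers base sigma
  lab <- do.call(cbind, lapply(vol$labels[7:12], function(l) l == "soft"))
  interior <- erode_k(lab, 2)
  px <- do.call(cbind, lapply(r1$series$slices[7:12],
                              function(s) s$pixels))
  expect_gt(sum(interior), 1e4)
  expect_equal(sd(px[interior]), 10, tolerance = 0.5 / 10)
})

test_that("study configurations reproduce the off-centering mechanism", {
  auto <- study_config("orange", "automatic")
  man <- study_config("orange", "manual")
  expect_gt(auto$vertical_offset, 0)
  expect_identical(man$vertical_offset, 0)
  expect_gt(man$table_height, auto$table_height)  # manual lowers further
  ref <- study_config("none")
  expect_identical(ref$mattress_thickness, 0)
  expect_identical(ref$vertical_offset, 0)
})
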