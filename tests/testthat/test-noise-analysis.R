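test_that("every local noise value equals the brute-force windowed SD", {
  set.seed(21)
  for (n in c(64, 96)) {
    px <- matrix(rnorm(n * n, 40, 10), n, n)
    px[, 1:(n %/% 3)] <- px[, 1:(n %/% 3)] - 790   # second material
    region <- matrix(runif(n * n) < 0.7, n, n)     # ragged support
    nm <- region_noise_map(px, region, half_width = 5, min_support = 10)
    idx <- which(region, arr.ind = TRUE)
    idx <- idx[seq(1, nrow(idx), length.out = 200), , drop = FALSE]
    for (r in seq_len(nrow(idx))) {
      i <- idx[r, 1]; j <- idx[r, 2]
      expect_equal(nm$values[i, j], bf_window_sd(px, region, i, j),
                   tolerance = 1e-9)
    }
    # undefined exactly where the window support is too small
    sup <- ctqc:::window_sums(region * 1, 5)
    expect_identical(is.na(nm$values[region]), (sup < 10)[region])
  }
})

test_that("a constant region yields zero noise at every defined pixel", {
  px <- matrix(40, 50, 50)
  px[1, 1] <- -1000                        # a second, out-of-region value
  region <- matrix(TRUE, 50, 50); region[1, 1] <- FALSE
  nm <- region_noise_map(px, region)
  expect_true(all(nm$values[region] == 0, na.rm = TRUE))
})

test_that("interior noise of an i.i.d. Gaussian region recovers sigma", {
  set.seed(22)
  n <- 128
  px <- matrix(rnorm(n * n, 0, 10), n, n)
  nm <- region_noise_map(px, matrix(TRUE, n, n))
  interior <- matrix(FALSE, n, n)
  interior[6:(n - 5), 6:(n - 5)] <- TRUE
  expect_gt(sum(interior), 1e4)
  expect_equal(mean(nm$values[interior]), 10, tolerance = 0.3 / 10)
})

test_that("noise values scale with the amplitude of the deviations", {
  set.seed(23)
  px <- matrix(rnorm(900, 40, 5), 30, 30)
  region <- matrix(TRUE, 30, 30)
  a <- region_noise_map(px, region)
  for (c in c(3, -2)) {
    b <- region_noise_map(40 + c * (px - 40), region)
    expect_equal(b$values, abs(c) * a$values, tolerance = 1e-9)
  }
})

test_that("the global map is the disjoint union of the region maps", {
  px <- step_image()
  reg <- step_regions()
  left <- region_noise_map(px, reg$left)
  right <- region_noise_map(px, reg$right)
  g <- global_noise_map(list(left, right))
  expect_identical(g$values[reg$left], left$values[reg$left])
  expect_identical(g$values[reg$right], right$values[reg$right])
  expect_identical(sum(!is.na(g$values)),
                   sum(!is.na(left$values)) + sum(!is.na(right$values)))
  expect_identical(global_noise_map(list(left))$values, left$values)
  overlap <- region_noise_map(px, reg$left | reg$right)
  expect_error(global_noise_map(list(left, overlap)), "overlap")
})

test_that("region restriction prevents boundary noise inflation on a step image", {
  px <- step_image(n = 96, lo = 0, hi = 200, sigma = 5)
  reg <- step_regions(96)
  g <- global_noise_map(list(region_noise_map(px, reg$left),
                             region_noise_map(px, reg$right)))
  naive <- naive_noise_map(px)
  expect_lte(global_noise_level(g), 1.1 * 5)
  expect_gt(global_noise_level(naive), 2 * 5)
  # windows straddling the 200 HU step read half the step as noise
  expect_gt(max(naive$values, na.rm = TRUE), 50)
})

test_that("the global noise level is the mean over defined pixels", {
  v <- matrix(NA_real_, 4, 4)
  v[1, 1] <- 2; v[2, 2] <- 4
  m <- structure(list(values = v, region = !is.na(v), half_width = 5,
                      min_support = 10), class = "noise_map")
  expect_identical(global_noise_level(m), 3)
  vc <- matrix(7, 3, 3)
  mc <- structure(list(values = vc, region = matrix(TRUE, 3, 3),
                       half_width = 5, min_support = 10),
                  class = "noise_map")
  expect_identical(global_noise_level(mc), 7)
  set.seed(24)
  px <- matrix(rnorm(625, 0, 3), 25, 25)
  nm <- region_noise_map(px, matrix(TRUE, 25, 25))
  expect_equal(global_noise_level(nm),
               sum(nm$values, na.rm = TRUE) / sum(!is.na(nm$values)),
               tolerance = 1e-12)
})

test_that("per-slice tissue noise tracks the generator ground truth", {
  vol <- generate_phantom_volume(small_config())
  out <- render_noisy_series(vol)        # flat profile at reference mAs
  chest <- out$series$slices[[4]]
  seg <- segment_tissues(chest, body_mask(chest))
  expect_equal(slice_tissue_noise(chest, seg, "lung"), 15,
               tolerance = 1 / 15)
  pelvis <- out$series$slices[[11]]
  seg_p <- segment_tissues(pelvis, body_mask(pelvis))
  expect_true(is.na(slice_tissue_noise(pelvis, seg_p, "lung")))
  expect_equal(slice_tissue_noise(pelvis, seg_p, "soft"), 10,
               tolerance = 1.5 / 10)

  # doubling the delivered mAs divides the measured noise by sqrt(2)
  n <- length(vol$slices)
  dbl <- data.frame(slice_index = 1:n, z_mm = (1:n - 1) * 5,
                    mas = rep(2 * 240, n))
  out2 <- render_noisy_series(vol, dbl)
  chest2 <- out2$series$slices[[4]]
  seg2 <- segment_tissues(chest2, body_mask(chest2))
  ratio <- slice_tissue_noise(chest, seg, "lung") /
    slice_tissue_noise(chest2, seg2, "lung")
  expect_equal(ratio, sqrt(2), tolerance = 0.05 / sqrt(2))
})

test_that("noise profiles cover exactly the zone's slices and stay flat for flat sigma", {
  vol <- generate_phantom_volume(small_config())
  out <- render_noisy_series(vol)
  an <- analyze_series(out$series)
  lung <- noise_profile(an, "lung")
  soft <- noise_profile(an, "soft")
  zones <- an$per_slice$zone
  expect_identical(nrow(lung), sum(zones == "chest", na.rm = TRUE))
  expect_identical(nrow(soft), sum(zones == "abdomen-pelvis", na.rm = TRUE))
  expect_lt(sd(soft$value, na.rm = TRUE) / mean(soft$value, na.rm = TRUE),
            0.05)
  expect_lt(sd(lung$value, na.rm = TRUE) / mean(lung$value, na.rm = TRUE),
            0.05)
})
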