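profile_of <- function(z, v) data.frame(z_mm = z, value = v)

test_that("profile alignment pairs nearest z within tolerance", {
  z <- seq(0, 45, by = 5)
  ref <- profile_of(z, 100 + z)
  test <- profile_of(z, 110 + z)
  p <- align_profiles(ref, test)
  expect_identical(nrow(p), 10L)
  expect_identical(p$ref, ref$value)
  expect_identical(p$test, test$value)

  p2 <- align_profiles(ref, test[-c(2, 5, 9), ])
  expect_identical(nrow(p2), 7L)
  expect_identical(attr(p2, "n_dropped_ref"), 3L)

  expect_error(align_profiles(ref, profile_of(z + 100, z)), "tolerance")
  # shifted-but-within-tolerance grids still pair one-to-one
  p3 <- align_profiles(ref, profile_of(z + 2, test$value))
  expect_identical(nrow(p3), 10L)
})

test_that("percent differences reproduce the reported dose increases", {
  expect_identical(percent_difference(10, 10), 0)
  # CTDIvol of the mattress acquisitions against the 8.68 mGy reference
  expect_equal(round(percent_difference(10.66, 8.68)), 23)
  expect_equal(round(percent_difference(11.33, 8.68)), 31)
  expect_equal(round(percent_difference(12.28, 8.68)), 41)
  expect_equal(round(percent_difference(9.04, 8.68)), 4)
  expect_equal(round(percent_difference(9.71, 8.68)), 12)
  expect_equal(percent_difference(10.66, 8.68), 22.81106, tolerance = 1e-6)
  expect_error(percent_difference(1, 0), "non-zero")
})

test_that("mean percent difference matches a brute-force loop", {
  pairs <- data.frame(ref = rep(100, 4), test = c(110, 110, 110, 110))
  r <- mean_percent_difference(pairs)
  expect_equal(r$mean_pct, 10)
  expect_identical(r$sd_pct, 0)

  pairs2 <- data.frame(ref = c(80, 100, 120), test = c(80, 100, 120) * 1.25)
  r2 <- mean_percent_difference(pairs2)
  expect_equal(r2$mean_pct, 25)
  expect_equal(r2$sd_pct, 0)

  set.seed(31)
  ref <- runif(10, 80, 120); test <- runif(10, 80, 160)
  d <- numeric(10)
  for (i in 1:10) d[i] <- 100 * (test[i] - ref[i]) / ref[i]
  r3 <- mean_percent_difference(data.frame(ref = ref, test = test))
  expect_equal(r3$mean_pct, mean(d), tolerance = 1e-12)
  expect_equal(r3$sd_pct, sd(d), tolerance = 1e-12)
})

test_that("the paired t-test matches its closed form and stats::t.test", {
  p <- paired_t_test(data.frame(ref = c(0, 0), test = c(1, -1)))
  expect_identical(p$t, 0)
  expect_identical(p$p, 1)

  deg <- paired_t_test(data.frame(ref = rep(0, 4), test = rep(1, 4)))
  expect_true(deg$degenerate)
  expect_identical(deg$p, 0)
  zer <- paired_t_test(data.frame(ref = rep(2, 3), test = rep(2, 3)))
  expect_true(deg$degenerate)
  expect_identical(zer$p, 1)

  # d = {2, 4, 6}: t = 4 / (2 / sqrt(3)), p from t on 2 df
  fix <- paired_t_test(data.frame(ref = c(0, 0, 0), test = c(2, 4, 6)))
  expect_equal(fix$t, 3.4641016, tolerance = 1e-7)
  expect_equal(fix$p, 2 * pt(-4 / (2 / sqrt(3)), df = 2), tolerance = 1e-12)

  set.seed(32)
  for (n in c(5, 12, 30)) {
    ref <- rnorm(n, 100, 10); test <- ref + rnorm(n, 2, 5)
    mine <- paired_t_test(data.frame(ref = ref, test = test))
    oracle <- t.test(test, ref, paired = TRUE)
    expect_equal(mine$t, unname(oracle$statistic), tolerance = 1e-9)
    expect_equal(mine$p, oracle$p.value, tolerance = 1e-9)
    # swapping ref and test negates the difference series
    swap <- paired_t_test(data.frame(ref = test, test = ref))
    expect_equal(swap$t, -mine$t, tolerance = 1e-12)
    expect_equal(swap$mean_diff, -mine$mean_diff, tolerance = 1e-12)
  }
})

test_that("zone classification follows the generator labels", {
  vol <- generate_phantom_volume(small_config())
  gt <- vol$ground_truth$per_slice
  for (s in c(4, 8, 11)) {
    seg <- segment_tissues(vol$slices[[s]],
                           label_is_body(vol$labels[[s]]))
    want <- if (gt$zone[s] == "chest") "chest" else "abdomen-pelvis"
    expect_identical(classify_zone(seg), want)
  }
  empty <- matrix("outside", 10, 10)
  class(empty) <- c("tissue_labels", class(empty))
  expect_true(is.na(classify_zone(empty)))
})

test_that("a series compared with itself reports null differences", {
  vol <- generate_phantom_volume(small_config())
  out <- render_noisy_series(vol, simulate_tcm_profile(simulate_topogram(vol)))
  an <- analyze_series(out$series)
  rep <- compare_acquisitions(an, an)
  expect_identical(rep$mas$mean_pct, 0)
  expect_identical(rep$mas$p, 1)
  expect_true(rep$mas$degenerate)
  expect_identical(rep$ctdi_vol$pct, 0)
  expect_identical(rep$table_height_delta_mm, 0)
  if (!is.null(rep$lung_noise)) expect_identical(rep$lung_noise$diff$mean_pct, 0)
  if (!is.null(rep$soft_noise)) expect_identical(rep$soft_noise$diff$mean_pct, 0)
})

test_that("reporting deltas against the reference row reproduce the printed table", {
  t1 <- read.csv(system.file("extdata", "mattress_study_table1.csv",
                             package = "ctqc"))
  d1 <- compare_to_reference(t1[t1$centering == "automatic", ])
  expect_identical(d1$table_height_delta_mm, c(16, 44, 84.5))
  expect_equal(d1$width_delta_mm, c(18, 23, 35), tolerance = 0)

  t2 <- read.csv(system.file("extdata", "mattress_study_table2.csv",
                             package = "ctqc"))
  d2 <- compare_to_reference(t2[t2$centering == "automatic", ])
  expect_identical(d2$ctdi_pct_printed, c(23, 31, 41))
  dman <- compare_to_reference(t2[t2$mattress == "none" |
                                    t2$centering == "manual", ])
  expect_identical(dman$ctdi_pct_printed, c(0, 4, 12))
})
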