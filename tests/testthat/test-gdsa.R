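test_that("ROI segmentation keeps high-dose low-gradient pixels", {
  flat <- uniform_image(1.0, px = 16)
  roi <- segment_roi(flat, roi_params(min_roi_pixels = 10))
  expect_identical(roi$pixel_count, 16L * 16L)
  expect_true(all(roi$mask))

  expect_error(segment_roi(uniform_image(0, px = 16), roi_params()),
               class = "epidwatch_degenerate_field_error")
})

test_that("segmentation equals brute-force evaluation of its two conditions", {
  # a square field with Gaussian penumbra on a 32x32 panel
  px <- 32
  field <- matrix(0, px, px)
  field[9:24, 9:24] <- 1
  field <- epidwatch:::gauss_blur(field, 1.5)
  img <- make_image(field)
  params <- roi_params(min_roi_pixels = 10)
  roi <- segment_roi(img, params)

  smoothed <- epidwatch:::gauss_blur(field, params$smoothing_sigma_px)
  pitch <- pixel_pitch(img$geometry)
  plateau <- max(smoothed)
  expected <- matrix(FALSE, px, px)
  for (i in 1:px) {
    for (j in 1:px) {
      high <- smoothed[i, j] > params$dose_threshold_fraction * plateau
      gy <- (smoothed[min(i + 1, px), j] - smoothed[max(i - 1, 1), j]) / (2 * pitch[1])
      gx <- (smoothed[i, min(j + 1, px)] - smoothed[i, max(j - 1, 1)]) / (2 * pitch[2])
      grad <- 100 * sqrt(gx^2 + gy^2) / max(smoothed[i, j], .Machine$double.eps)
      expected[i, j] <- high && grad <= params$gradient_limit_percent_per_mm
    }
  }
  expect_identical(roi$mask, expected)
  expect_identical(roi$pixel_count, sum(expected))
})

test_that("raising the dose threshold shrinks the ROI; raising the gradient limit grows it", {
  px <- 32
  field <- matrix(0.05, px, px)
  field[9:24, 9:24] <- 1
  img <- make_image(epidwatch:::gauss_blur(field, 2))
  count <- function(thr, grad) {
    segment_roi(img, roi_params(dose_threshold_fraction = thr,
                                gradient_limit_percent_per_mm = grad,
                                min_roi_pixels = 1))$pixel_count
  }
  counts_thr <- vapply(c(0.3, 0.5, 0.7, 0.9), count, numeric(1), grad = 3)
  expect_true(all(diff(counts_thr) <= 0))
  counts_grad <- vapply(c(0.5, 1, 3, 10), function(g) count(0.5, g), numeric(1))
  expect_true(all(diff(counts_grad) >= 0))
})

test_that("gdsa_mean is the ROI average of per-pixel relative differences", {
  b <- uniform_image(1.0, px = 16)
  roi <- full_roi(16)
  expect_identical(gdsa_mean(b, b, roi), 0)

  f <- uniform_image(1.05, px = 16)
  expect_equal(gdsa_mean(f, b, roi), 5, tolerance = 1e-9)

  base <- make_image(matrix(c(100, 200, 300, 400), 2, 2))
  frac <- make_image(matrix(c(110, 190, 300, 400), 2, 2))
  two_px <- structure(list(mask = matrix(c(TRUE, TRUE, FALSE, FALSE), 2, 2),
                           pixel_count = 2L), class = "roi_mask")
  expect_equal(gdsa_mean(frac, base, two_px), 2.5, tolerance = 1e-12)

  zero_base <- make_image(matrix(c(0, 1, 1, 1), 2, 2))
  expect_error(gdsa_mean(frac, zero_base, two_px),
               class = "epidwatch_division_domain_error")
})

test_that("gdsa_mean is homogeneous: scaling the fraction by c gives 100(c-1)", {
  withr::with_seed(17, {
    for (k in 1:10) {
      px <- 16
      m <- matrix(runif(px * px, 0.5, 2), px, px)
      b <- make_image(m)
      cc <- runif(1, 0.2, 3)
      f <- make_image(cc * m)
      expect_equal(gdsa_mean(f, b, full_roi(px)), 100 * (cc - 1),
                   tolerance = 1e-9)
    }
  })
})

test_that("course analysis freezes the baseline ROI and averages fields", {
  ph <- phantom_model()
  one <- generate_course(ph, test_config(n_fractions = 1, px = 16))
  rec1 <- course_gdsa(one$series)
  expect_identical(nrow(rec1), 1L)
  expect_identical(rec1$gdsa_percent, 0)

  # two fields, fraction 2 scaled x1.02 on both
  cfg <- course_config(n_fractions = 2, field_ids = c("F1", "F2"),
                       noise_sd_percent = 0, penumbra_sigma_mm = 0,
                       geometry = test_geometry(16))
  two <- generate_course(ph, cfg, error_injection("SPIKE", 2, 2))
  rec2 <- course_gdsa(two$series)
  expect_identical(rec2$n_fields, c(2L, 2L))
  expect_equal(rec2$gdsa_percent[2], 2, tolerance = 1e-9)
})

test_that("fractions with missing fields are omitted and excluded downstream", {
  ph <- phantom_model()
  cfg <- course_config(n_fractions = 3, field_ids = c("F1", "F2"),
                       noise_sd_percent = 0, penumbra_sigma_mm = 0,
                       geometry = test_geometry(16))
  gc1 <- generate_course(ph, cfg, error_injection("SPIKE", 3, 50))
  # simulate a beam interruption: drop one field of fraction 3
  gc1$series$fractions[[3]]$images <- gc1$series$fractions[[3]]$images[1]
  rec <- course_gdsa(gc1$series)
  expect_identical(rec$status, c("complete", "complete", "omitted"))
  expect_true(is.na(rec$gdsa_percent[3]))
  expect_identical(nrow(daily_summaries(rec)), 2L)
  expect_identical(nrow(scan_flags(rec)), 0L)
})

test_that("noise-free course analysis matches the analytic ground truth", {
  ph <- phantom_model()
  cfg <- test_config(n_fractions = 6, thickness_drift_cm_per_fraction = -0.15,
                     output_drift_percent_per_fraction = 0.2, px = 24)
  gc1 <- generate_course(ph, cfg, error_injection("SPIKE", 4, 8))
  rec <- course_gdsa(gc1$series)
  expect_lt(max(abs(rec$gdsa_percent - gc1$truth$expected_gdsa_percent)), 0.05)
})
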