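test_that("rendering follows the closed-form attenuation physics", {
  ph <- phantom_model()  # covers the whole panel
  cfg <- test_config(px = 32)
  base <- render_transit_image(ph, cfg, output_scale = 1, thickness_delta_cm = 0)
  again <- render_transit_image(ph, cfg, output_scale = 1, thickness_delta_cm = 0)
  expect_identical(base$pixels, again$pixels)

  scaled <- render_transit_image(ph, cfg, output_scale = 1.05)
  expect_equal(scaled$pixels, 1.05 * base$pixels, tolerance = 1e-12)

  thicker <- render_transit_image(ph, cfg, thickness_delta_cm = 1)
  expect_equal(thicker$pixels / base$pixels,
               matrix(exp(-0.05), 32, 32), tolerance = 1e-9)

  expect_error(render_transit_image(ph, cfg, thickness_delta_cm = -20),
               class = "epidwatch_domain_error")
})

test_that("a partial phantom leaves the open field unattenuated outside its shadow", {
  geom <- test_geometry(32)
  ph <- phantom_model(semi_axes_mm = c(60, 60), thickness_cm = 8)
  cfg <- course_config(n_fractions = 1, field_ids = "F1", noise_sd_percent = 0,
                       penumbra_sigma_mm = 0, geometry = geom)
  img <- render_transit_image(ph, cfg, output_scale = 1.2)
  tmap <- epidwatch:::thickness_map(ph, geom)
  expect_equal(unique(img$pixels[tmap == 0]), 1.2, tolerance = 1e-12)
  expect_equal(unique(img$pixels[tmap > 0]), 1.2 * exp(-0.05 * 8), tolerance = 1e-12)
})

test_that("course ground truth follows the closed-form expected GDSA", {
  ph <- phantom_model()
  quiet <- generate_course(ph, test_config(n_fractions = 5))
  expect_identical(quiet$truth$expected_gdsa_percent, rep(0, 5))

  spike <- generate_course(ph, test_config(n_fractions = 6),
                           error_injection("SPIKE", 5, 12))
  expect_equal(spike$truth$expected_gdsa_percent,
               c(0, 0, 0, 0, 12, 0), tolerance = 1e-12)

  shrink <- generate_course(ph, test_config(
    n_fractions = 10, thickness_drift_cm_per_fraction = -0.2))
  expect_equal(shrink$truth$expected_gdsa_percent[10],
               100 * (exp(0.05 * 1.8) - 1), tolerance = 1e-12)
  expect_identical(shrink$truth$expected_gdsa_percent[1], 0)
})

test_that("identical seeds give bit-identical noisy courses", {
  ph <- phantom_model()
  cfg <- test_config(n_fractions = 3, noise = 1, seed = 99L, px = 24)
  a <- generate_course(ph, cfg)
  b <- generate_course(ph, cfg)
  for (f in 1:3) {
    expect_identical(a$series$fractions[[f]]$images[[1]]$pixels,
                     b$series$fractions[[f]]$images[[1]]$pixels)
  }
  c3 <- generate_course(ph, test_config(n_fractions = 3, noise = 1, seed = 100L, px = 24))
  expect_false(identical(a$series$fractions[[1]]$images[[1]]$pixels,
                         c3$series$fractions[[1]]$images[[1]]$pixels))
})

test_that("overlapping OUTPUT_STEP injections are rejected", {
  ph <- phantom_model()
  cfg <- test_config(n_fractions = 6)
  expect_error(
    generate_course(ph, cfg, list(error_injection("OUTPUT_STEP", 2, 1, 4),
                                  error_injection("OUTPUT_STEP", 4, 1, 2))),
    class = "epidwatch_config_error")
  # non-overlapping steps are fine
  expect_no_error(
    generate_course(ph, cfg, list(error_injection("OUTPUT_STEP", 2, 1, 2),
                                  error_injection("OUTPUT_STEP", 5, 1, 2))))
})

test_that("clinic days share the day output scale across patients", {
  ph <- phantom_model()
  one <- generate_clinic_day(1, "2021-02-03", test_config(px = 24), 1.0, seed = 5)
  expect_equal(one[[1]]$truth$expected_gdsa_percent, c(0, 0))

  day <- generate_clinic_day(20, "2021-02-03", test_config(px = 24), 1.015, seed = 5)
  expect_length(day, 20)
  for (p in day) {
    expect_equal(p$truth$expected_gdsa_percent, c(0, 1.5), tolerance = 1e-12)
    expect_identical(format(p$truth$date[2]), "2021-02-03")
  }
})

test_that("patient-to-patient GDSA spread matches the pixel-noise model", {
  # GDSA = mean over N ROI pixels of (f - b)/b with independent 1% noise on
  # both images: SD ~ noise * sqrt(2/N) percent.
  ph <- phantom_model()
  px <- 24
  day <- generate_clinic_day(50, "2021-02-03", test_config(px = px, noise = 1),
                             1.0, seed = 31)
  gdsa <- vapply(day, function(p) {
    course_gdsa(p$series)$gdsa_percent[2]
  }, numeric(1))
  n_roi <- course_gdsa(day[[1]]$series)$roi_pixels[1]
  analytic_sd <- 1 * sqrt(2 / n_roi)
  se_of_sd <- analytic_sd / sqrt(2 * (50 - 1))
  expect_lt(abs(sd(gdsa) - analytic_sd), 3 * se_of_sd)
  expect_lt(abs(mean(gdsa)), 3 * analytic_sd / sqrt(50))
})

test_that("GDSA noise variance scales as 1/(ROI pixel count)", {
  ph <- phantom_model()
  px <- 16
  cfg <- test_config(n_fractions = 1, noise = 1, px = px)
  base <- render_transit_image(ph, cfg, seed = 1000)
  quarter <- matrix(FALSE, px, px)
  quarter[1:(px / 2), 1:(px / 2)] <- TRUE
  roi_full <- full_roi(px)
  roi_quarter <- structure(list(mask = quarter, pixel_count = sum(quarter)),
                           class = "roi_mask")
  g_full <- g_quarter <- numeric(80)
  for (k in 1:80) {
    fr <- render_transit_image(ph, cfg, seed = 2000 + k)
    g_full[k] <- gdsa_mean(fr, base, roi_full)
    g_quarter[k] <- gdsa_mean(fr, base, roi_quarter)
  }
  ratio <- stats::var(g_quarter) / stats::var(g_full)
  expect_gt(ratio, 2)
  expect_lt(ratio, 8)
})

test_that("generated courses can be written out and re-analyzed from disk", {
  ph <- phantom_model()
  gc1 <- generate_course(ph, test_config(n_fractions = 2, px = 16), patient_id = "RT01")
  dir <- withr::local_tempdir()
  paths <- write_course_series(gc1$series, dir)
  expect_length(list.files(dir, pattern = "\\.dcm$", recursive = TRUE), 2)
  rec <- analyze_directory(dir)
  expect_identical(nrow(rec), 2L)
  expect_identical(rec$patient_id, rep("RT01", 2))
  truth_path <- file.path(dir, "truth.csv")
  write_ground_truth(gc1$truth, truth_path)
  expect_true(file.exists(truth_path))
})
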