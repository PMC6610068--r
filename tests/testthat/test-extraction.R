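# Stripe-angle extraction, bidirectional splitting, size and diameter
# measurements, end-to-end recovery.

test_that("bidirectional kymographs split into mirrored halves", {
  sp <- scan_parameters(10, "anterograde", t_line = 11, x_pixel = 0.5,
                        n_pixels = 100)
  k <- simulate_kymograph(kymo_config(
    sp, rbc_train(32, 6, 1, 50, 40 * 11), n_lines = 40,
    bidirectional = TRUE, psf_fwhm = 1))
  expect_equal(ncol(k$pixels), 200)
  halves <- split_bidirectional(k)
  expect_equal(ncol(halves$anterograde$pixels), 100)
  expect_equal(ncol(halves$retrograde$pixels), 100)
  expect_equal(halves$anterograde$scan$direction, "anterograde")
  expect_equal(halves$retrograde$scan$direction, "retrograde")
  # retrograde half mirrored to increasing position
  expect_true(all(diff(halves$retrograde$x_positions) > 0))
  # discard fraction trims both ends of each sweep
  trimmed <- split_bidirectional(k, discard_fraction = 0.1)
  expect_equal(ncol(trimmed$anterograde$pixels), 80)
  expect_equal(ncol(trimmed$retrograde$pixels), 80)
  expect_error(split_bidirectional(halves$anterograde), "not flagged")
  expect_error(split_bidirectional(k, 0.5), "discard_fraction")
})

test_that("both halves of one bidirectional scan give consistent physics", {
  sp <- scan_parameters(10, "anterograde", t_line = 11, x_pixel = 0.5,
                        n_pixels = 100)
  v_real <- 1
  k <- simulate_kymograph(kymo_config(
    sp, rbc_train(36, 6, v_real, 50, 60 * 11), n_lines = 60,
    bidirectional = TRUE, psf_fwhm = 1))
  halves <- split_bidirectional(k, discard_fraction = 0.05)
  dur <- 60 * 11 / 1000
  v_aa <- estimate_apparent_velocity(halves$anterograde,
                                     window_s = dur)$v_app_mean
  v_ar <- estimate_apparent_velocity(halves$retrograde,
                                     window_s = dur)$v_app_mean
  # anterograde apparent speed always exceeds the retrograde one
  expect_gt(v_aa, v_ar)
  expect_equal(v_aa, apparent_velocity(v_real, sp), tolerance = 0.03)
  expect_equal(v_ar, apparent_velocity(v_real, flip_direction(sp)),
               tolerance = 0.03)
  # and both correct back to the same real velocity
  expect_equal(real_velocity(v_aa, sp), v_real, tolerance = 0.03)
  expect_equal(real_velocity(v_ar, flip_direction(sp)), v_real,
               tolerance = 0.03)
})

test_that("the angle estimator matches the forward model on clean images", {
  # shallow-stripe regime exercises the SVD angle search
  sp <- scan_parameters(40, "anterograde", n_pixels = 120L, x_pixel = 0.5,
                        t_line = 120 * 0.5 / 40 * 1.05)
  k <- sim_train_kymo(2, sp, n_lines = 120)
  dur <- 120 * sp$t_line / 1000
  res <- estimate_apparent_velocity(k, window_s = dur)
  expect_s3_class(res, "extraction_result")
  expect_equal(res$v_app_mean, 40 * 2 / 38, tolerance = 0.02)
  expect_false(any(res$windows$flagged))
  # radon criterion agrees with svd within 3%
  res_r <- estimate_apparent_velocity(k, method = "radon", window_s = dur)
  expect_equal(res_r$v_app_mean, res$v_app_mean, tolerance = 0.03)
  # windowing: two windows, mean of window speeds
  res_w <- estimate_apparent_velocity(k, window_s = dur / 2)
  expect_equal(nrow(res_w$windows), 2)
  expect_equal(res_w$v_app_mean, mean(res_w$windows$v_app))
})

test_that("stationary stripes give zero speed and pure noise is flagged", {
  sp <- scan_parameters(20, "anterograde", t_line = 3, x_pixel = 0.5,
                        n_pixels = 80)
  k0 <- simulate_kymograph(kymo_config(
    sp, data.frame(x0 = c(12, 30), d_real = 6, v_real = 0), n_lines = 60,
    psf_fwhm = 1))
  res <- estimate_apparent_velocity(k0, window_s = 0.18)
  expect_lt(res$v_app_mean, 0.02)
  # an image with no coherent orientation flags every window
  noise <- with(list(), {
    set.seed(4)
    matrix(rnorm(60 * 80, 100, 10), 60, 80)
  })
  kn <- kymograph(pmax(noise, 0), acquisition_time_map(sp, 60), sp)
  expect_error(estimate_apparent_velocity(kn, window_s = 0.18),
               "flagged|no coherent")
})

test_that("extraction is invariant to intensity rescaling", {
  sp <- scan_parameters(20, "anterograde", t_line = 3.2, x_pixel = 0.5,
                        n_pixels = 80)
  k <- sim_train_kymo(1, sp, n_lines = 60)
  dur <- 60 * sp$t_line / 1000
  v1 <- estimate_apparent_velocity(k, window_s = dur)$v_app_mean
  k2 <- k
  k2$pixels <- k$pixels * (255 / max(k$pixels))   # 8-bit style rescale
  v2 <- estimate_apparent_velocity(k2, window_s = dur)$v_app_mean
  expect_equal(v1, v2, tolerance = 1e-10)
})

test_that("apparent sizes measured on kymographs match the model", {
  sp <- scan_parameters(10, "anterograde", t_line = 8, x_pixel = 0.25,
                        n_pixels = 240)
  k <- simulate_kymograph(kymo_config(
    sp, data.frame(x0 = 5, d_real = 6, v_real = 5), n_lines = 6))
  expect_lt(abs(measure_apparent_size(k) - 12), 0.3)
  k_r <- simulate_kymograph(kymo_config(
    flip_direction(sp), data.frame(x0 = 30, d_real = 6, v_real = 5),
    n_lines = 6))
  expect_lt(abs(measure_apparent_size(k_r) - 4), 0.3)
  # featureless image: no shadow to measure
  flat <- kymograph(matrix(100, 10, 240), acquisition_time_map(sp, 10), sp)
  expect_error(measure_apparent_size(flat), "shadow")
})

test_that("vessel diameter uses the filtered half-maximum width", {
  expect_lt(abs(measure_vessel_diameter(simulate_vessel_image(6)) - 6), 0.5)
  vn <- simulate_vessel_image(10, psf_fwhm = 1, noise = "poisson", seed = 9L)
  expect_lt(abs(measure_vessel_diameter(vn) - 10), 0.5)
  # bare matrix needs the pixel size
  m <- simulate_vessel_image(6)$pixels
  expect_error(measure_vessel_diameter(m), "x_pixel")
  expect_lt(abs(measure_vessel_diameter(m, x_pixel = 0.5) - 6), 0.5)
  expect_error(measure_vessel_diameter(matrix(5, 32, 32), x_pixel = 0.5),
               "plateau|flat")
})

test_that("simulate-extract-correct recovers the true velocity", {
  run <- function(v_real, v_scan, direction, noise = "none",
                  background = 200) {
    scan <- make_scan(v_scan, direction)
    k <- sim_train_kymo(v_real, scan, n_lines = 120, noise = noise,
                        background = background, seed = 42L)
    res <- estimate_apparent_velocity(k, window_s = 120 * scan$t_line / 1000)
    real_velocity(res$v_app_mean, scan)
  }
  # noiseless: within 3% (anterograde up to the regime where a cell stays
  # visible across lines; retrograde across the full fast range)
  for (v in c(0.2, 1, 3.3)) expect_equal(run(v, 10, "anterograde"), v,
                                         tolerance = 0.03)
  expect_equal(run(13, 40, "anterograde"), 13, tolerance = 0.03)
  for (v in c(0.2, 2, 10, 20)) expect_equal(run(v, 10, "retrograde"), v,
                                            tolerance = 0.03)
  # shot noise at SNR ~ 5 (Poisson, 25-count background): within 10%
  expect_equal(run(1, 10, "anterograde", "poisson", 25), 1, tolerance = 0.1)
  expect_equal(run(5, 10, "retrograde", "poisson", 25), 5, tolerance = 0.1)
})
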