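# Closed-form size/velocity model: direct evaluations, inversions,
# direction handling, singularities.

sp_a <- scan_parameters(10, "anterograde", t_line = 10, x_pixel = 0.5,
                        n_pixels = 100)
sp_r <- flip_direction(sp_a)

test_that("traversal time and apparent size follow the relative-speed model", {
  # stationary cell: shadow equals the cell, traversal = d / v_scan
  expect_equal(time_to_scan_rbc(6, 0, sp_a), 0.6)
  expect_equal(time_to_scan_rbc(6, 0, sp_r), 0.6)
  expect_equal(apparent_size(6, 0, sp_a), 6)
  # moving cell: 6/(10-5) anterograde, 6/(10+5) retrograde
  expect_equal(time_to_scan_rbc(6, 5, sp_a), 1.2)
  expect_equal(time_to_scan_rbc(6, 5, sp_r), 0.4)
  expect_equal(apparent_size(6, 5, sp_a), 12)
  expect_equal(apparent_size(6, 5, sp_r), 4)
  # inversion recovers the real size
  expect_equal(real_size(12, 5, sp_a), 6)
  expect_equal(real_size(4, 5, sp_r), 6)
  expect_equal(real_size(7, 0, sp_a), 7)
})

test_that("apparent velocity from displacement and from angle agree", {
  sp <- scan_parameters(10, "anterograde", t_line = 1, x_pixel = 1,
                        n_pixels = 2)
  expect_equal(apparent_velocity_from_geometry(dx_mov = 2, scan = sp), 2)
  expect_equal(apparent_velocity_from_geometry(dx_mov = 0, scan = sp), 0)
  # 45-degree stripe on a 1 um x 1 ms grid is 1 mm/s
  expect_equal(apparent_velocity_from_geometry(alpha = pi / 4, scan = sp), 1)
  # the two parameterisations describe the same stripe
  for (v in c(0.3, 1, 4)) {
    alpha <- atan2(1, v * sp$t_line / sp$x_pixel)
    expect_equal(apparent_velocity_from_geometry(alpha = alpha, scan = sp), v,
                 tolerance = 1e-12)
  }
  expect_error(apparent_velocity_from_geometry(dx_mov = 1, alpha = 1,
                                               scan = sp),
               "exactly one")
})

test_that("velocity forward model and correction are exact inverses", {
  expect_equal(apparent_velocity(5, sp_a), 10)
  expect_equal(apparent_velocity(5, sp_r), 10 / 3)
  expect_equal(apparent_velocity(0, sp_a), 0)
  expect_equal(real_velocity(10, sp_a), 5)
  expect_equal(real_velocity(10 / 3, sp_r), 5)
  # slow flow: apparent ~ real
  expect_equal(real_velocity(0.01, sp_a), 0.01, tolerance = 2e-3)

  set.seed(11)
  for (vs in c(5, 10, 40)) {
    sa <- scan_parameters(vs, "anterograde", 20, 0.5, 100)
    sr <- flip_direction(sa)
    v_ant <- runif(60, 1e-4, 0.99 * vs)
    v_ret <- runif(60, 1e-4, 100 * vs)
    expect_equal(real_velocity(apparent_velocity(v_ant, sa), sa), v_ant,
                 tolerance = 1e-9)
    expect_equal(real_velocity(apparent_velocity(v_ret, sr), sr), v_ret,
                 tolerance = 1e-9)
    # size round-trip under the same sampling
    expect_equal(real_size(apparent_size(6, v_ant, sa), v_ant, sa),
                 rep(6, 60), tolerance = 1e-9)
    expect_equal(real_size(apparent_size(6, v_ret, sr), v_ret, sr),
                 rep(6, 60), tolerance = 1e-9)
  }
})

test_that("anterograde overestimates and retrograde underestimates", {
  v <- seq(0.1, 8, by = 0.1)
  v_aa <- apparent_velocity(v, sp_a)
  v_ar <- apparent_velocity(v, sp_r)
  expect_true(all(v_aa > v))
  expect_true(all(v_ar < v))
  # equality only at rest
  expect_equal(apparent_velocity(0, sp_a), 0)
  expect_equal(apparent_velocity(0, sp_r), 0)
  # strict monotonicity in v_real
  expect_true(all(diff(v_aa) > 0))
  expect_true(all(diff(v_ar) > 0))
  d_aa <- apparent_size(6, v, sp_a)
  d_ar <- apparent_size(6, v, sp_r)
  expect_true(all(d_aa > 6) && all(diff(d_aa) > 0))
  expect_true(all(d_ar < 6) && all(diff(d_ar) < 0))
  # errors: anterograde negative and larger in magnitude
  err_a <- relative_error(v, sp_a)
  err_r <- relative_error(v, sp_r)
  expect_true(all(err_a < 0) && all(err_r > 0))
  expect_true(all(abs(err_a) > abs(err_r)))
  expect_equal(relative_error(5, sp_a), -1)
  expect_equal(relative_error(5, sp_r), 1 / 3)
  expect_lt(abs(relative_error(1e-4, sp_a)), 1e-4)
})

test_that("bidirectional pairs satisfy the consistency identity", {
  expect_equal(bidirectional_residual(10, 10 / 3, 10), 0)
  expect_equal(bidirectional_residual(20 / 19, 20 / 21, 20), 0,
               tolerance = 1e-12)
  # equal apparents are never consistent
  expect_equal(bidirectional_residual(4, 4, 10), -0.2)
  set.seed(12)
  vs <- runif(200, 3, 60)
  v <- runif(200) * 0.95 * vs
  v_aa <- vs * v / (vs - v)
  v_ar <- vs * v / (vs + v)
  expect_lt(max(abs(bidirectional_residual(v_aa, v_ar, vs))), 1e-9)
})

test_that("the single-parameter pair model matches the composed corrections", {
  expect_equal(vaa_from_var(10 / 3, 10), 10)
  # slope 1 at the origin
  expect_equal(vaa_from_var(1e-6, 10), 1e-6, tolerance = 1e-6)
  # diverges at the pole v_scan / 2
  expect_gt(vaa_from_var(4.999, 10), 4000)
  set.seed(13)
  for (i in 1:50) {
    vs <- runif(1, 4, 50)
    v_ar <- runif(1) * 0.49 * vs
    sa <- scan_parameters(vs, "anterograde", 20, 0.5, 100)
    composed <- apparent_velocity(real_velocity(v_ar, flip_direction(sa)), sa)
    expect_equal(vaa_from_var(v_ar, vs), composed, tolerance = 1e-9)
  }
})

test_that("poles raise domain errors instead of returning infinities", {
  expect_error(time_to_scan_rbc(6, 10, sp_a), "singularity")
  expect_error(apparent_size(6, 12, sp_a), "singularity")
  expect_error(apparent_velocity(10, sp_a), "singularity")
  # within 1e-6 relative distance of the pole counts as the pole
  expect_error(apparent_velocity(10 * (1 - 1e-8), sp_a), "singularity")
  expect_silent(apparent_velocity(10 * (1 - 1e-5), sp_a))
  # retrograde correction: apparent >= v_scan is unobservable
  expect_error(real_velocity(10, sp_r), "inconsistent")
  expect_error(real_velocity(12, sp_r), "inconsistent")
  expect_error(vaa_from_var(5, 10), "singularity")
  # retrograde has no pole
  expect_silent(apparent_velocity(1e4, sp_r))
})

test_that("scan parameter validation enforces the acquisition geometry", {
  expect_error(scan_parameters(0, "anterograde", 1, 0.5, 10), "v_scan")
  expect_error(scan_parameters(10, "anterograde", 1, -1, 10), "x_pixel")
  expect_error(scan_parameters(10, "anterograde", 1, 0.5, 1), "n_pixels")
  # line period cannot be shorter than the active sweep
  expect_error(scan_parameters(10, "anterograde", 1, 0.5, 100), "sweep")
  sp <- scan_parameters(10, "retrograde", 5, 0.5, 100)
  expect_equal(sp$t_pixel, 0.05)
  expect_equal(flip_direction(sp)$direction, "anterograde")
})
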