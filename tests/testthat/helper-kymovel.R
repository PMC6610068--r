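# Shared fixtures and independent oracles for the test suite.
# All images are generated in code; no stored fixtures.

# Standard scan geometry: line period = sweep time * t_line_factor
# (fly-back kept short so fast flows remain sampled).
make_scan <- function(v_scan, direction, n_pixels = 120L, x_pixel = 0.5,
                      t_line_factor = 1.05) {
  scan_parameters(v_scan, direction,
                  t_line = n_pixels * x_pixel / v_scan * t_line_factor,
                  x_pixel = x_pixel, n_pixels = n_pixels)
}

# Cell spacing satisfying the sampling condition: the APPARENT spacing
# (real spacing scaled by v_scan/(v_scan -/+ v_real)) must exceed the
# per-line displacement by a margin, or the stripe slope is aliased.
safe_spacing <- function(v_real, scan) {
  v_app <- apparent_velocity(v_real, scan)
  size_factor <- scan$v_scan /
    (scan$v_scan + if (scan$direction == "anterograde") -v_real else v_real)
  max(15, (1.3 * v_app * scan$t_line + 15) / size_factor)
}

# Kymograph of a steady cell train at v_real under `scan`.
sim_train_kymo <- function(v_real, scan, n_lines = 120L, d_real = 6,
                           psf_fwhm = 1, noise = "none", background = 200,
                           seed = NULL) {
  segment <- scan$n_pixels * scan$x_pixel
  simulate_kymograph(kymo_config(
    scan, rbc_train(safe_spacing(v_real, scan), d_real, v_real, segment,
                    n_lines * scan$t_line),
    n_lines = n_lines, psf_fwhm = psf_fwhm, noise = noise,
    background = background, seed = seed))
}

# Independent stripe-speed oracle: simulate a SINGLE cell crossing the
# segment and regress the centre of its shadow (from simple thresholding)
# on the line index; slope * x_pixel / t_line is the apparent speed. Uses
# none of the estimator machinery.
edge_track_vapp <- function(v_real, scan, d_real = 6) {
  v_app <- apparent_velocity(v_real, scan)
  segment <- scan$n_pixels * scan$x_pixel
  n_lines <- if (v_app == 0) 6L else
    as.integer(ceiling(segment / (v_app * scan$t_line)) + 4L)
  x0 <- if (v_app == 0) segment / 2 else 1
  k <- simulate_kymograph(kymo_config(
    scan, data.frame(x0 = x0, d_real = d_real, v_real = v_real),
    n_lines = n_lines, psf_fwhm = 0.8))
  px <- k$pixels
  thr <- mean(range(px))
  centres <- rep(NA_real_, nrow(px))
  for (i in seq_len(nrow(px))) {
    rl <- rle(px[i, ] < thr)
    ends <- cumsum(rl$lengths)
    starts <- ends - rl$lengths + 1L
    dark <- which(rl$values)
    dark <- dark[starts[dark] > 1L & ends[dark] < ncol(px)]
    if (length(dark) == 1L)
      centres[i] <- (starts[dark] + ends[dark]) / 2
  }
  ok <- which(!is.na(centres))
  if (length(ok) < 2L) return(NA_real_)
  slope <- stats::coef(stats::lm(centres[ok] ~ ok))[2L]
  unname(slope) * scan$x_pixel / scan$t_line
}

# Brute-force chi-square grid search for the scan-speed fit: the oracle
# against the Levenberg-Marquardt minimiser.
grid_search_vscan <- function(pairs, lo, hi, n = 1e5) {
  grid <- seq(lo, hi, length.out = n)
  chisq <- vapply(grid, function(vs) {
    pred <- vs * pairs$v_ar / (vs - 2 * pairs$v_ar)
    sum((pairs$v_aa - pred)^2)
  }, numeric(1))
  grid[which.max(-chisq)]
}
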