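#' @title First-principles line-scan simulator
#'
#' @description
#' Renders synthetic kymographs from nothing but the per-pixel acquisition
#' timing of a scanning system and 1-D RBC occupancy: pixel (i, j) samples
#' position \code{x_j} at time \code{t(i, j)}, and is dark when an RBC
#' covers that position at that instant. The closed-form apparent-size and
#' apparent-velocity equations are \emph{not} used anywhere in the renderer,
#' so the emergent shadow widths and stripe slopes serve as an independent
#' oracle for them.
#'
#' @name kymo_sim
NULL

#' Per-pixel acquisition-time map
#'
#' Each pixel within a line is acquired sequentially at scan speed, so pixel
#' j of line i is acquired at \code{i * t_line + j * t_pixel} (0-based
#' indices, acquisition order). Columns are stored in position order (see
#' [kymograph()]), hence for retrograde scanning time decreases across the
#' stored columns of a line. For bidirectional acquisitions each line is a
#' forward sweep immediately followed by a backward sweep over the same
#' segment: the backward pixel k (acquisition order) is acquired at
#' \code{i * t_line + n * t_pixel + turnaround + k * t_pixel}.
#'
#' @param scan A [scan_parameters()] object.
#' @param n_lines Number of lines (rows), integer >= 2.
#' @param bidirectional Logical; if \code{TRUE} the map has
#'   \code{2 * n_pixels} columns.
#' @param turnaround Dead time between the forward and backward sweep, ms
#'   (default 0).
#' @return Matrix of acquisition times in ms, \code{n_lines} rows.
#' @examples
#' sp <- scan_parameters(10, "anterograde", t_line = 1, x_pixel = 1,
#'                       n_pixels = 3)
#' acquisition_time_map(sp, n_lines = 2)
#' @export
acquisition_time_map <- function(scan, n_lines, bidirectional = FALSE,
                                 turnaround = 0) {
  scan <- as_scan(scan)
  n_lines <- as.integer(n_lines)
  if (n_lines < 2L) stop("`n_lines` must be >= 2")
  if (turnaround < 0) stop("`turnaround` must be >= 0")
  n <- scan$n_pixels
  line_start <- (seq_len(n_lines) - 1) * scan$t_line
  if (bidirectional) {
    sweep_time <- 2 * n * scan$t_pixel + turnaround
    if (scan$t_line < sweep_time - 1e-9)
      stop(sprintf(paste("`t_line` (%g ms) too short for a bidirectional",
                         "line (two sweeps + turnaround = %g ms)"),
           scan$t_line, sweep_time))
    within <- c((seq_len(n) - 1) * scan$t_pixel,
                n * scan$t_pixel + turnaround + (seq_len(n) - 1) * scan$t_pixel)
  } else {
    within <- (seq_len(n) - 1) * scan$t_pixel
    if (scan$direction == "retrograde") within <- rev(within)
  }
  outer(line_start, within, `+`)
}

#' Simulation configuration for a synthetic kymograph
#'
#' @param scan A [scan_parameters()] object. For bidirectional simulations
#'   its \code{direction} describes the \emph{forward} sweep and must be
#'   \code{"anterograde"}.
#' @param rbcs Data frame with columns \code{x0} (initial position at t = 0,
#'   um), \code{d_real} (extent along the axis, um) and \code{v_real} (speed
#'   magnitude along the flow axis, mm/s). All cells move in the positive
#'   direction; see [rbc_train()] for a convenience generator.
#' @param n_lines Number of lines, integer >= 2.
#' @param background Mean background (plasma) intensity, arbitrary units.
#' @param shadow_contrast Fractional intensity drop inside an RBC shadow,
#'   in `[0, 1]`.
#' @param noise \code{"none"}, \code{"poisson"} (pixel ~ Poisson(mean)) or
#'   \code{"gaussian"} (additive, sd \code{noise_sigma}).
#' @param noise_sigma Standard deviation for Gaussian noise.
#' @param psf_fwhm Full width at half maximum of a 1-D Gaussian blur applied
#'   to the occupancy profile along the position axis, um; 0 disables it.
#' @param bidirectional Logical; simulate forward + backward sweeps per line.
#' @param turnaround Dead time between the sweeps of a bidirectional line, ms.
#' @param seed Integer seed making the noise reproducible, or \code{NULL}.
#' @return A list of class \code{"kymo_config"}.
#' @export
kymo_config <- function(scan, rbcs, n_lines, background = 200,
                        shadow_contrast = 0.8,
                        noise = c("none", "poisson", "gaussian"),
                        noise_sigma = 0, psf_fwhm = 0, bidirectional = FALSE,
                        turnaround = 0, seed = NULL) {
  scan <- as_scan(scan)
  noise <- match.arg(noise)
  rbcs <- as.data.frame(rbcs)
  need <- c("x0", "d_real", "v_real")
  if (!all(need %in% names(rbcs)))
    stop("`rbcs` needs columns x0, d_real, v_real")
  stopifnot(nrow(rbcs) >= 1L, all(rbcs$d_real >= 0), all(rbcs$v_real >= 0),
            n_lines >= 2, shadow_contrast >= 0, shadow_contrast <= 1,
            background > 0, psf_fwhm >= 0, noise_sigma >= 0, turnaround >= 0)
  if (bidirectional && scan$direction != "anterograde")
    stop("bidirectional simulations take `scan` describing the forward ",
         "(anterograde) sweep")
  structure(list(scan = scan, rbcs = rbcs, n_lines = as.integer(n_lines),
                 background = background, shadow_contrast = shadow_contrast,
                 noise = noise, noise_sigma = noise_sigma,
                 psf_fwhm = psf_fwhm, bidirectional = isTRUE(bidirectional),
                 turnaround = turnaround, seed = seed),
            class = "kymo_config")
}

#' Regularly spaced train of identical RBCs
#'
#' Places cells with fixed spacing so that the scanned segment stays
#' populated for the whole recording: cells start upstream by up to the
#' distance travelled during the acquisition.
#'
#' @param spacing Centre-to-centre spacing, um, > 0.
#' @param d_real,v_real Cell extent (um) and speed (mm/s), shared.
#' @param segment_length Scanned segment length, um.
#' @param duration Recording duration, ms.
#' @return Data frame suitable for the \code{rbcs} argument of
#'   [kymo_config()].
#' @export
rbc_train <- function(spacing, d_real, v_real, segment_length, duration) {
  stopifnot(spacing > 0, segment_length > 0, duration > 0)
  upstream <- v_real * duration + d_real + spacing
  x0 <- seq(-upstream, segment_length + d_real, by = spacing)
  data.frame(x0 = x0, d_real = d_real, v_real = v_real)
}

# run `expr` with a locally seeded RNG, restoring the caller's RNG state
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

# Gaussian blur of each row along columns, replicate-edge normalisation.
# K is (n_col x n_col), column-normalised, so edges renormalise correctly.
gauss_smooth_rows <- function(mat, sigma_px) {
  if (sigma_px <= 0) return(mat)
  n <- ncol(mat)
  idx <- seq_len(n)
  K <- outer(idx, idx, function(a, b) exp(-((a - b)^2) / (2 * sigma_px^2)))
  K <- sweep(K, 2, colSums(K), "/")
  mat %*% K
}

#' Simulate a line-scan kymograph
#'
#' Renders each pixel from the acquisition geometry alone: pixel (i, j)
#' samples position \code{x_j} at time \code{t(i, j)} from
#' [acquisition_time_map()]; its occupancy is 1 when any RBC interval
#' \code{[x0 + v t - d/2, x0 + v t + d/2]} covers \code{x_j} (maximum over
#' cells), optionally blurred along the position axis by a Gaussian of the
#' configured FWHM; intensity is
#' \code{background * (1 - shadow_contrast * occupancy)}; noise is applied
#' last. Deterministic for a fixed \code{seed}.
#'
#' @param config A [kymo_config()] object.
#' @return A [kymograph()] with \code{ground_truth = config}.
#' @examples
#' sp <- scan_parameters(10, "anterograde", t_line = 6, x_pixel = 0.5,
#'                       n_pixels = 100)
#' k <- simulate_kymograph(kymo_config(sp,
#'        data.frame(x0 = 25, d_real = 6, v_real = 0), n_lines = 20))
#' @export
simulate_kymograph <- function(config) {
  if (!inherits(config, "kymo_config")) stop("expected a `kymo_config`")
  scan <- config$scan
  tm <- acquisition_time_map(scan, config$n_lines, config$bidirectional,
                             config$turnaround)
  xs <- default_x_positions(ncol(tm), scan$x_pixel, config$bidirectional)
  xmat <- matrix(xs, nrow = nrow(tm), ncol = ncol(tm), byrow = TRUE)
  occ <- matrix(0, nrow(tm), ncol(tm))
  for (r in seq_len(nrow(config$rbcs))) {
    ctr <- config$rbcs$x0[r] + config$rbcs$v_real[r] * tm
    occ <- pmax(occ, (abs(xmat - ctr) < config$rbcs$d_real[r] / 2) * 1)
  }
  if (config$psf_fwhm > 0) {
    sigma_px <- config$psf_fwhm / (2 * sqrt(2 * log(2))) / scan$x_pixel
    if (config$bidirectional) {
      n <- scan$n_pixels
      occ[, seq_len(n)] <- gauss_smooth_rows(occ[, seq_len(n), drop = FALSE],
                                             sigma_px)
      occ[, n + seq_len(n)] <-
        gauss_smooth_rows(occ[, n + seq_len(n), drop = FALSE], sigma_px)
    } else {
      occ <- gauss_smooth_rows(occ, sigma_px)
    }
  }
  img <- config$background * (1 - config$shadow_contrast * occ)
  img <- with_seed(config$seed, {
    if (config$noise == "poisson") {
      matrix(stats::rpois(length(img), lambda = img), nrow(img), ncol(img))
    } else if (config$noise == "gaussian") {
      pmax(img + matrix(stats::rnorm(length(img), 0, config$noise_sigma),
                        nrow(img), ncol(img)), 0)
    } else img
  })
  kymograph(img, tm, scan, bidirectional = config$bidirectional,
            x_positions = xs, ground_truth = config)
}

#' Table of paired anterograde/retrograde apparent velocities
#'
#' For each (v_real, v_scan) combination (vectors recycled element-wise) the
#' two apparent speeds are computed from the forward model and perturbed by
#' independent multiplicative Gaussian noise \code{Normal(1, noise_cv)}.
#' Anterograde-pole combinations (v_real >= v_scan) are flagged with
#' \code{pole = TRUE} and \code{NA} apparent values rather than dropped.
#'
#' @param v_real,v_scan Real speeds and scan speeds, mm/s (recycled).
#' @param noise_cv Non-negative coefficient of variation of the noise.
#' @param seed Integer seed, or \code{NULL}.
#' @return Data frame with columns \code{v_real}, \code{v_scan},
#'   \code{v_aa}, \code{v_ar}, \code{pole}.
#' @examples
#' simulate_bidirectional_pair_table(5, 10, noise_cv = 0)
#' @export
simulate_bidirectional_pair_table <- function(v_real, v_scan, noise_cv = 0,
                                              seed = NULL) {
  stopifnot(noise_cv >= 0, all(v_real >= 0), all(v_scan > 0))
  n <- max(length(v_real), length(v_scan))
  v_real <- rep_len(v_real, n)
  v_scan <- rep_len(v_scan, n)
  pole <- v_real >= v_scan * (1 - .POLE_RTOL)
  v_aa <- ifelse(pole, NA_real_, v_scan * v_real / (v_scan - v_real))
  v_ar <- v_scan * v_real / (v_scan + v_real)
  with_seed(seed, {
    if (noise_cv > 0) {
      v_aa <- v_aa * stats::rnorm(n, 1, noise_cv)
      v_ar <- v_ar * stats::rnorm(n, 1, noise_cv)
    }
    data.frame(v_real = v_real, v_scan = v_scan, v_aa = v_aa, v_ar = v_ar,
               pole = pole)
  })
}

#' Simulate a single-frame vessel image
#'
#' A bright band of fluorescent plasma of the stated internal diameter on a
#' dark background, the fixture for diameter measurement. The vessel axis
#' runs along the image rows (the band spans all columns; its width is read
#' across rows).
#'
#' @param diameter Internal vessel diameter, um, > 0.
#' @param x_pixel Pixel size, um.
#' @param n_rows,n_cols Image size in pixels.
#' @param plasma,background Plasma and background mean intensities.
#' @param psf_fwhm Gaussian blur FWHM across the vessel, um (0 = off).
#' @param noise,noise_sigma,seed As in [kymo_config()].
#' @return A list of class \code{"vessel_image"} with \code{pixels} (matrix)
#'   and \code{x_pixel}.
#' @export
simulate_vessel_image <- function(diameter, x_pixel = 0.5, n_rows = 64,
                                  n_cols = 64, plasma = 200, background = 10,
                                  psf_fwhm = 0,
                                  noise = c("none", "poisson", "gaussian"),
                                  noise_sigma = 0, seed = NULL) {
  noise <- match.arg(noise)
  stopifnot(diameter > 0, x_pixel > 0, n_rows >= 4, n_cols >= 2)
  y <- (seq_len(n_rows) - 0.5) * x_pixel
  centre <- n_rows * x_pixel / 2
  inside <- abs(y - centre) < diameter / 2
  profile <- background + (plasma - background) * inside
  if (psf_fwhm > 0) {
    sigma_px <- psf_fwhm / (2 * sqrt(2 * log(2))) / x_pixel
    profile <- drop(gauss_smooth_rows(matrix(profile, nrow = 1), sigma_px))
  }
  img <- matrix(profile, n_rows, n_cols)
  img <- with_seed(seed, {
    if (noise == "poisson") {
      matrix(stats::rpois(length(img), img), n_rows, n_cols)
    } else if (noise == "gaussian") {
      pmax(img + matrix(stats::rnorm(length(img), 0, noise_sigma),
                        n_rows, n_cols), 0)
    } else img
  })
  structure(list(pixels = img, x_pixel = x_pixel), class = "vessel_image")
}
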