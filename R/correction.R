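#' @title Scanner-bias correction equations for line-scan RBC measurements
#'
#' @description
#' Closed-form model of how the finite scan speed of a laser line-scan
#' distorts the apparent size and apparent velocity of red blood cells in
#' space-time (kymograph) images, and its inversions. Because every pixel of
#' a line is acquired sequentially at speed \code{v_scan}, a cell moving with
#' the scanner (anterograde scanning) leaves a stretched shadow and an
#' overestimated stripe speed, while a cell moving against it (retrograde)
#' leaves a compressed shadow and an underestimated speed:
#' \deqn{D_{app} = D_{real} V_{scan} / (V_{scan} \mp V_{real})}
#' \deqn{V_{AA} = V_{scan} V_{real} / (V_{scan} - V_{real}), \quad
#'       V_{AR} = V_{scan} V_{real} / (V_{scan} + V_{real})}
#' with the upper sign for anterograde scanning. The anterograde forms have
#' a pole at \code{v_real = v_scan} (the scanner never overtakes the cell);
#' inputs within \code{1e-6} relative distance of a pole are treated as at
#' the pole and raise an error rather than returning infinities.
#'
#' All functions are vectorised over their velocity/size arguments.
#'
#' @name correction
NULL

# pole guard: relative closeness treated as "at the pole"
.POLE_RTOL <- 1e-6

.check_antero_pole <- function(v_real, v_scan) {
  bad <- v_real >= v_scan * (1 - .POLE_RTOL)
  if (any(bad))
    stop(sprintf(paste("anterograde singularity: v_real (%g mm/s) >= v_scan",
                       "(%g mm/s); the scanner cannot overtake the RBC and the",
                       "apparent size/velocity diverge"),
         max(v_real[bad]), v_scan), call. = FALSE)
  invisible(TRUE)
}

#' Time for the scanner to traverse one RBC
#'
#' The focal spot closes on a cell at the relative speed between scanner and
#' cell, so the traversal time is the real cell extent divided by
#' \code{v_scan - v_real} (anterograde) or \code{v_scan + v_real}
#' (retrograde).
#'
#' @param d_real Real RBC extent along the vessel axis, um, >= 0.
#' @param v_real Real RBC speed magnitude, mm/s, >= 0.
#' @param scan A [scan_parameters()] object (its \code{v_scan} and
#'   \code{direction} are used).
#' @return Traversal time in ms.
#' @examples
#' sp <- scan_parameters(10, "anterograde", t_line = 10, x_pixel = 0.5,
#'                       n_pixels = 100)
#' time_to_scan_rbc(6, 5, sp)   # 6/(10-5) = 1.2 ms
#' @export
time_to_scan_rbc <- function(d_real, v_real, scan) {
  scan <- as_scan(scan)
  stopifnot(all(d_real >= 0), all(v_real >= 0))
  if (scan$direction == "anterograde") {
    .check_antero_pole(v_real, scan$v_scan)
    d_real / (scan$v_scan - v_real)
  } else {
    d_real / (scan$v_scan + v_real)
  }
}

#' Apparent (shadow) size of a moving RBC
#'
#' The shadow length is the distance the focal spot covers while traversing
#' the cell, \code{v_scan * t_rbc}: stretched for anterograde scanning,
#' compressed for retrograde, equal to the real size for a stationary cell.
#'
#' @inheritParams time_to_scan_rbc
#' @return Apparent size in um.
#' @examples
#' sp <- scan_parameters(10, "anterograde", 10, 0.5, 100)
#' apparent_size(6, 5, sp)                   # 12 um
#' apparent_size(6, 5, flip_direction(sp))   # 4 um
#' @export
apparent_size <- function(d_real, v_real, scan) {
  scan <- as_scan(scan)
  scan$v_scan * time_to_scan_rbc(d_real, v_real, scan)
}

#' Real RBC size from the measured shadow size
#'
#' Inversion of [apparent_size()] given the (already corrected) real
#' velocity: \code{d_real = d_app * (v_scan -/+ v_real) / v_scan}.
#'
#' @param d_app Measured shadow extent, um, >= 0.
#' @inheritParams time_to_scan_rbc
#' @return Real RBC extent in um.
#' @export
real_size <- function(d_app, v_real, scan) {
  scan <- as_scan(scan)
  stopifnot(all(d_app >= 0), all(v_real >= 0))
  if (scan$direction == "anterograde") {
    .check_antero_pole(v_real, scan$v_scan)
    d_app * (scan$v_scan - v_real) / scan$v_scan
  } else {
    d_app * (scan$v_scan + v_real) / scan$v_scan
  }
}

#' Apparent velocity from per-line stripe displacement or stripe angle
#'
#' The camera-model apparent speed: per-line displacement of the shadow
#' divided by the line period, \code{v_app = dx_mov / t_line}. Equivalently,
#' with the image axes scaled to \code{x_pixel} per column and \code{t_line}
#' per row, it is the cotangent of the stripe angle \code{alpha} to the
#' horizontal: \code{v_app = (x_pixel / t_line) * cot(alpha_image)} where
#' \code{alpha_image} is measured on the pixel grid.
#'
#' @param dx_mov Apparent per-line displacement, um, >= 0. Exactly one of
#'   \code{dx_mov} and \code{alpha} must be given.
#' @param alpha Stripe angle to the horizontal on the pixel grid, radians,
#'   in (0, pi/2].
#' @param scan A [scan_parameters()] object (\code{t_line}, \code{x_pixel}).
#' @return Apparent speed in mm/s.
#' @examples
#' sp <- scan_parameters(10, "anterograde", 1, 1, 2)
#' apparent_velocity_from_geometry(dx_mov = 2, scan = sp)     # 2 mm/s
#' apparent_velocity_from_geometry(alpha = pi / 4, scan = sp) # 1 mm/s
#' @export
apparent_velocity_from_geometry <- function(dx_mov = NULL, alpha = NULL, scan) {
  scan <- as_scan(scan)
  if (is.null(dx_mov) == is.null(alpha))
    stop("supply exactly one of `dx_mov` or `alpha`")
  if (!is.null(dx_mov)) {
    stopifnot(all(dx_mov >= 0))
    dx_mov / scan$t_line
  } else {
    stopifnot(all(alpha > 0), all(alpha <= pi / 2))
    (scan$x_pixel / scan$t_line) / tan(alpha)
  }
}

#' Real RBC velocity from the apparent velocity
#'
#' The scan-speed-aware correction. The time for the cell to move by the
#' apparent per-line displacement is the line period plus the time the
#' scanner spends covering that displacement, which yields
#' \code{v_real = v_scan * v_app / (v_scan + v_app)} for anterograde and
#' \code{v_real = v_scan * v_app / (v_scan - v_app)} for retrograde
#' scanning. Strictly increasing in \code{v_app} on the valid domain. A
#' retrograde apparent speed at or above \code{v_scan} is inconsistent with
#' the model (no real velocity produces it) and raises an error.
#'
#' @param v_app Apparent speed magnitude, mm/s, >= 0.
#' @param scan A [scan_parameters()] object.
#' @return Real speed in mm/s.
#' @examples
#' sp <- scan_parameters(10, "anterograde", 10, 0.5, 100)
#' real_velocity(10, sp)                         # 5 mm/s
#' real_velocity(10 / 3, flip_direction(sp))     # 5 mm/s
#' @export
real_velocity <- function(v_app, scan) {
  scan <- as_scan(scan)
  stopifnot(all(v_app >= 0))
  if (scan$direction == "anterograde") {
    scan$v_scan * v_app / (scan$v_scan + v_app)
  } else {
    bad <- v_app >= scan$v_scan * (1 - .POLE_RTOL)
    if (any(bad))
      stop(sprintf(paste("inconsistent observation: retrograde apparent",
                         "velocity (%g mm/s) >= v_scan (%g mm/s); no real",
                         "velocity produces such a stripe"),
           max(v_app[bad]), scan$v_scan), call. = FALSE)
    scan$v_scan * v_app / (scan$v_scan - v_app)
  }
}

#' Apparent velocity predicted for a real RBC velocity
#'
#' Forward model: \code{v_aa = v_scan * v_real / (v_scan - v_real)}
#' (anterograde, pole at \code{v_real = v_scan}) and
#' \code{v_ar = v_scan * v_real / (v_scan + v_real)} (retrograde). Exact
#' round-trip with [real_velocity()].
#'
#' @inheritParams time_to_scan_rbc
#' @return Apparent speed in mm/s.
#' @export
apparent_velocity <- function(v_real, scan) {
  scan <- as_scan(scan)
  stopifnot(all(v_real >= 0))
  if (scan$direction == "anterograde") {
    .check_antero_pole(v_real, scan$v_scan)
    scan$v_scan * v_real / (scan$v_scan - v_real)
  } else {
    scan$v_scan * v_real / (scan$v_scan + v_real)
  }
}

#' Consistency residual of a bidirectional velocity pair
#'
#' Anterograde and retrograde apparent speeds of the same flow satisfy
#' \code{1/v_ar - 1/v_aa = 2/v_scan}; the residual
#' \code{1/v_ar - 1/v_aa - 2/v_scan} is zero (to tolerance) exactly when the
#' pair is consistent with a single underlying real velocity.
#'
#' @param v_aa Anterograde apparent speed, mm/s, > 0.
#' @param v_ar Retrograde apparent speed, mm/s, > 0.
#' @param v_scan Common scan speed magnitude, mm/s, > 0.
#' @return Residual in s/mm (i.e. (mm/s)^-1).
#' @examples
#' bidirectional_residual(v_aa = 10, v_ar = 10 / 3, v_scan = 10)  # 0
#' @export
bidirectional_residual <- function(v_aa, v_ar, v_scan) {
  stopifnot(all(v_aa > 0), all(v_ar > 0), all(v_scan > 0))
  1 / v_ar - 1 / v_aa - 2 / v_scan
}

#' Anterograde apparent speed predicted from the retrograde one
#'
#' The single-parameter validation model
#' \code{v_aa = v_scan * v_ar / (v_scan - 2 * v_ar)}, algebraically the
#' composition of the retrograde inversion with the anterograde forward
#' model. Pole at \code{v_ar = v_scan / 2} (corresponding to
#' \code{v_real = v_scan}).
#'
#' @param v_ar Retrograde apparent speed, mm/s, >= 0, < \code{v_scan / 2}.
#' @param v_scan Scan speed magnitude, mm/s, > 0.
#' @return Predicted anterograde apparent speed, mm/s.
#' @examples
#' vaa_from_var(10 / 3, 10)   # 10
#' @export
vaa_from_var <- function(v_ar, v_scan) {
  stopifnot(all(v_ar >= 0), all(v_scan > 0))
  bad <- v_ar >= (v_scan / 2) * (1 - .POLE_RTOL)
  if (any(bad))
    stop(sprintf(paste("singularity: v_ar (%g mm/s) >= v_scan/2 (%g mm/s);",
                       "corresponds to v_real >= v_scan"),
         max(v_ar[bad]), v_scan / 2), call. = FALSE)
  v_scan * v_ar / (v_scan - 2 * v_ar)
}

#' Relative error of reporting the apparent instead of the real velocity
#'
#' \code{(v_real - v_app) / v_real} with \code{v_app} from the forward model
#' [apparent_velocity()]: negative for anterograde scanning (overestimate),
#' positive for retrograde (underestimate), and larger in magnitude for
#' anterograde at equal speeds.
#'
#' @param v_real Real RBC speed, mm/s, > 0.
#' @param scan A [scan_parameters()] object.
#' @return Dimensionless relative error (multiply by 100 for percent).
#' @examples
#' sp <- scan_parameters(10, "anterograde", 10, 0.5, 100)
#' relative_error(5, sp)   # -1, i.e. -100%
#' @export
relative_error <- function(v_real, scan) {
  scan <- as_scan(scan)
  stopifnot(all(v_real > 0))
  (v_real - apparent_velocity(v_real, scan)) / v_real
}
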