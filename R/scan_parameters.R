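#' Scan parameters for a line-scan acquisition
#'
#' Bundles the acquisition geometry of a laser line-scan: the speed of the
#' focal spot along the vessel axis (\code{v_scan}), the scanning direction
#' relative to blood flow, the full line repetition period (\code{t_line},
#' sweep plus any dead time and fly-back), the spatial pixel size and the
#' number of pixels per sweep. The per-pixel dwell time
#' \code{t_pixel = x_pixel / v_scan} is derived.
#'
#' Units are fixed package-wide: micrometres for lengths, mm/s for speeds and
#' milliseconds for times. Since 1 mm/s = 1 um/ms, no conversion constants
#' appear in any formula.
#'
#' Velocities are stored as magnitudes; the sign convention of the underlying
#' model is carried entirely by \code{direction}: \code{"anterograde"} means
#' the scanner moves in the same direction as RBC flow, \code{"retrograde"}
#' the opposite.
#'
#' @param v_scan Scan speed magnitude along the vessel axis, mm/s, > 0.
#' @param direction \code{"anterograde"} or \code{"retrograde"}.
#' @param t_line Full line repetition period, ms. Must be at least
#'   \code{n_pixels * t_pixel} (the active sweep time).
#' @param x_pixel Spatial pixel size, um, > 0.
#' @param n_pixels Number of pixels per sweep, integer >= 2.
#'
#' @return An object of class \code{"scan_parameters"}: a list with fields
#'   \code{v_scan}, \code{direction}, \code{t_line}, \code{x_pixel},
#'   \code{n_pixels} and the derived \code{t_pixel} (ms).
#'
#' @examples
#' sp <- scan_parameters(v_scan = 10, direction = "anterograde",
#'                       t_line = 12, x_pixel = 0.5, n_pixels = 100)
#' sp$t_pixel   # 0.05 ms per pixel
#' @export
scan_parameters <- function(v_scan, direction = c("anterograde", "retrograde"),
                            t_line, x_pixel, n_pixels) {
  direction <- match.arg(direction)
  stopifnot(is.numeric(v_scan), length(v_scan) == 1L, is.finite(v_scan),
            is.numeric(t_line), length(t_line) == 1L, is.finite(t_line),
            is.numeric(x_pixel), length(x_pixel) == 1L, is.finite(x_pixel),
            length(n_pixels) == 1L, is.finite(n_pixels))
  n_pixels <- as.integer(n_pixels)
  if (v_scan <= 0) stop("`v_scan` must be > 0 (speeds are magnitudes)")
  if (x_pixel <= 0) stop("`x_pixel` must be > 0")
  if (n_pixels < 2L) stop("`n_pixels` must be an integer >= 2")
  t_pixel <- x_pixel / v_scan
  if (t_line < n_pixels * t_pixel - 1e-9)
    stop(sprintf(paste("`t_line` (%g ms) is shorter than the active sweep",
                       "n_pixels * t_pixel = %g ms"),
         t_line, n_pixels * t_pixel))
  structure(list(v_scan = v_scan, direction = direction, t_line = t_line,
                 x_pixel = x_pixel, n_pixels = n_pixels, t_pixel = t_pixel),
            class = "scan_parameters")
}

#' @export
print.scan_parameters <- function(x, ...) {
  cat("Line-scan parameters\n")
  cat(sprintf("  v_scan:    %g mm/s (%s)\n", x$v_scan, x$direction))
  cat(sprintf("  t_line:    %g ms   (t_pixel = %g ms)\n", x$t_line, x$t_pixel))
  cat(sprintf("  x_pixel:   %g um x %d pixels (segment %g um)\n",
              x$x_pixel, x$n_pixels, x$x_pixel * x$n_pixels))
  invisible(x)
}

is_scan_parameters <- function(x) inherits(x, "scan_parameters")

as_scan <- function(scan) {
  if (!is_scan_parameters(scan))
    stop("`scan` must be a scan_parameters object; see ?scan_parameters")
  scan
}

#' @rdname scan_parameters
#' @param other For \code{flip_direction}, a \code{scan_parameters} object
#'   whose direction is to be reversed (all other fields kept).
#' @export
flip_direction <- function(other) {
  s <- as_scan(other)
  s$direction <- if (s$direction == "anterograde") "retrograde" else "anterograde"
  s
}
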