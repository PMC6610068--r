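#' Kymograph (space-time image) container
#'
#' A kymograph holds the pixel matrix of a line-scan acquisition (rows =
#' successive line sweeps, i.e. time; columns = position along the vessel
#' axis), the per-pixel acquisition-time map, the [scan_parameters()] it was
#' acquired (or simulated) with, and, for simulated images, the ground-truth
#' configuration.
#'
#' Column convention: columns are stored in order of increasing position
#' along the flow axis. For retrograde scanning the acquisition therefore
#' runs right-to-left within each line, which the time map records. For
#' bidirectional images the first half of the columns is the forward
#' (anterograde) sweep in position order and the second half the immediately
#' following backward (retrograde) sweep in \emph{reverse} position order,
#' i.e. the raw detector layout.
#'
#' @param pixels Numeric matrix of non-negative intensities.
#' @param time_map Matrix of per-pixel acquisition times, ms, same shape.
#' @param scan A [scan_parameters()] object.
#' @param bidirectional Logical flag.
#' @param x_positions Numeric vector of column-centre positions, um.
#' @param ground_truth Optional simulation configuration (see
#'   [kymo_config()]).
#' @return An object of class \code{"kymograph"}.
#' @export
kymograph <- function(pixels, time_map, scan, bidirectional = FALSE,
                      x_positions = NULL, ground_truth = NULL) {
  scan <- as_scan(scan)
  pixels <- as.matrix(pixels)
  time_map <- as.matrix(time_map)
  if (!all(dim(pixels) == dim(time_map)))
    stop("`pixels` and `time_map` must have the same shape")
  if (any(pixels < 0)) stop("`pixels` must be non-negative")
  if (is.null(x_positions))
    x_positions <- default_x_positions(ncol(pixels), scan$x_pixel,
                                       bidirectional)
  if (length(x_positions) != ncol(pixels))
    stop("`x_positions` must have one entry per column")
  structure(list(pixels = pixels, time_map = time_map, scan = scan,
                 bidirectional = isTRUE(bidirectional),
                 x_positions = x_positions, ground_truth = ground_truth),
            class = "kymograph")
}

# column-centre positions (um): position order for unidirectional images,
# forward-then-mirrored-backward for bidirectional ones
default_x_positions <- function(n_col, x_pixel, bidirectional) {
  if (bidirectional) {
    if (n_col %% 2L != 0L)
      stop("bidirectional kymographs need an even number of columns")
    n <- n_col %/% 2L
    c((seq_len(n) - 0.5) * x_pixel, (n - seq_len(n) + 0.5) * x_pixel)
  } else {
    (seq_len(n_col) - 0.5) * x_pixel
  }
}

#' @export
print.kymograph <- function(x, ...) {
  cat(sprintf("Kymograph: %d lines x %d pixels (%s%s)\n",
              nrow(x$pixels), ncol(x$pixels), x$scan$direction,
              if (x$bidirectional) ", bidirectional" else ""))
  cat(sprintf("  duration %g ms, segment %g um, v_scan %g mm/s\n",
              nrow(x$pixels) * x$scan$t_line,
              diff(range(x$x_positions)) + x$scan$x_pixel, x$scan$v_scan))
  if (!is.null(x$ground_truth))
    cat(sprintf("  simulated (%d RBC track%s, seed %s)\n",
                nrow(x$ground_truth$rbcs),
                if (nrow(x$ground_truth$rbcs) == 1L) "" else "s",
                if (is.null(x$ground_truth$seed)) "none"
                else x$ground_truth$seed))
  invisible(x)
}

#' @export
#' @param y Ignored.
#' @param ... Passed to [graphics::image()].
#' @rdname kymograph
plot.kymograph <- function(x, y, ...) {
  graphics::image(x = seq_len(ncol(x$pixels)), y = seq_len(nrow(x$pixels)),
                  z = t(x$pixels), col = grDevices::gray.colors(256),
                  xlab = "column (position)", ylab = "line (time)",
                  useRaster = TRUE, ...)
  invisible(x)
}

is_kymograph <- function(x) inherits(x, "kymograph")

as_kymo <- function(x) {
  if (!is_kymograph(x)) stop("expected a `kymograph` object")
  x
}
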