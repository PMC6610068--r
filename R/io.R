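#' @title Reading and writing kymographs, metadata and tables
#'
#' @description
#' Kymographs travel as a TIFF image plus a JSON (or YAML) metadata sidecar
#' carrying the acquisition parameters the pixel data cannot: scan speed,
#' line period, pixel size, direction and the bidirectional flag. Simulated
#' images additionally embed their full ground-truth configuration and seed,
#' so any output can be regenerated.
#'
#' @name io_cli
NULL

REQUIRED_METADATA <- c("v_scan", "t_line", "x_pixel", "direction",
                       "bidirectional")

# 16-bit storage scale: integer-valued images round-trip exactly
intensity_scale_for <- function(pixels) {
  mx <- max(pixels)
  if (mx <= 65535 && all(abs(pixels - round(pixels)) < 1e-9)) 65535
  else mx
}

read_sidecar <- function(path) {
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) yaml::read_yaml(path)
  else jsonlite::read_json(path, simplifyVector = TRUE)
}

write_sidecar <- function(meta, path) {
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE))
    yaml::write_yaml(meta, path)
  else jsonlite::write_json(meta, path, auto_unbox = TRUE, digits = NA,
                            pretty = TRUE)
  invisible(path)
}

#' Write a kymograph as TIFF plus metadata sidecar
#'
#' The image is stored as 16-bit TIFF, intensities divided by an
#' \code{intensity_scale} recorded in the sidecar (65535 for integer-valued
#' images, which then round-trip exactly). The sidecar holds the scan
#' parameters and, for simulated images, the complete generating
#' configuration including the seed.
#'
#' @param kymo A [kymograph()].
#' @param path TIFF output path.
#' @param metadata_path Sidecar path; default is \code{path} with the
#'   extension replaced by \code{.json} (use \code{.yaml} for YAML).
#' @return \code{path}, invisibly.
#' @export
write_kymograph <- function(kymo, path,
                            metadata_path = sub("\\.tiff?$", ".json", path)) {
  kymo <- as_kymo(kymo)
  if (identical(metadata_path, path))
    metadata_path <- paste0(path, ".json")
  scale <- intensity_scale_for(kymo$pixels)
  # writeTIFF truncates on quantisation; bias integer-valued images by half
  # a step so every count round-trips exactly
  img <- if (scale == 65535) pmin((kymo$pixels + 0.5) / 65535, 1)
         else kymo$pixels / scale
  tiff::writeTIFF(img, path, bits.per.sample = 16L)
  meta <- list(v_scan = kymo$scan$v_scan, t_line = kymo$scan$t_line,
               x_pixel = kymo$scan$x_pixel, n_pixels = kymo$scan$n_pixels,
               direction = kymo$scan$direction,
               bidirectional = kymo$bidirectional,
               intensity_scale = scale)
  gt <- kymo$ground_truth
  if (!is.null(gt)) {
    meta$ground_truth <- list(
      rbcs = gt$rbcs, n_lines = gt$n_lines, background = gt$background,
      shadow_contrast = gt$shadow_contrast, noise = gt$noise,
      noise_sigma = gt$noise_sigma, psf_fwhm = gt$psf_fwhm,
      turnaround = gt$turnaround, seed = gt$seed)
  }
  write_sidecar(meta, metadata_path)
  invisible(path)
}

#' Read a kymograph from TIFF plus metadata sidecar
#'
#' Validates the sidecar (all missing required fields are listed in a
#' single error), reconstructs the [scan_parameters()] and the acquisition
#' time map, and checks that the image width matches the declared pixel
#' count. Rows are line sweeps (time), columns position.
#'
#' @param path TIFF path.
#' @param metadata_path JSON or YAML sidecar path; default as in
#'   [write_kymograph()].
#' @return A [kymograph()].
#' @export
read_kymograph <- function(path,
                           metadata_path = sub("\\.tiff?$", ".json", path)) {
  meta <- read_sidecar(metadata_path)
  missing_fields <- setdiff(REQUIRED_METADATA, names(meta))
  if (length(missing_fields))
    stop("metadata is missing required field(s): ",
         paste(missing_fields, collapse = ", "))
  img <- tiff::readTIFF(path)
  if (is.array(img) && length(dim(img)) == 3L) img <- img[, , 1L]
  scale <- if (is.null(meta$intensity_scale)) 1 else meta$intensity_scale
  pixels <- img * scale
  if (scale == 65535) pixels <- round(pixels)
  bidi <- isTRUE(meta$bidirectional)
  n_pixels <- if (!is.null(meta$n_pixels)) meta$n_pixels
              else if (bidi) ncol(pixels) %/% 2L else ncol(pixels)
  expected_cols <- if (bidi) 2L * n_pixels else n_pixels
  if (ncol(pixels) != expected_cols)
    stop(sprintf(paste("shape mismatch: image has %d columns but metadata",
                       "declares n_pixels = %d%s"),
         ncol(pixels), n_pixels, if (bidi) " (bidirectional)" else ""))
  scan <- scan_parameters(meta$v_scan, meta$direction, meta$t_line,
                          meta$x_pixel, n_pixels)
  turnaround <- if (is.null(meta$ground_truth$turnaround)) 0
                else meta$ground_truth$turnaround
  tm <- acquisition_time_map(scan, nrow(pixels), bidi, turnaround)
  kymograph(pixels, tm, scan, bidirectional = bidi,
            ground_truth = meta$ground_truth)
}

#' Read or write a table of bidirectional velocity pairs
#'
#' Plain CSV with at least the columns \code{v_ar} and \code{v_aa} (mm/s);
#' extra columns such as \code{v_real}, \code{v_scan} or \code{pole} are
#' preserved.
#'
#' @param pairs Data frame with \code{v_ar}/\code{v_aa} columns.
#' @param path CSV path.
#' @return The data frame (read) or \code{path} invisibly (write).
#' @export
write_pair_table <- function(pairs, path) {
  pairs <- as.data.frame(pairs)
  if (!all(c("v_ar", "v_aa") %in% names(pairs)))
    stop("`pairs` needs columns v_ar and v_aa")
  utils::write.csv(pairs, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_pair_table
#' @export
read_pair_table <- function(path) {
  tab <- utils::read.csv(path)
  if (!all(c("v_ar", "v_aa") %in% names(tab)))
    stop("pair table is missing required column(s): ",
         paste(setdiff(c("v_ar", "v_aa"), names(tab)), collapse = ", "))
  tab
}
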