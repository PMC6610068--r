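#' @title Apparent-velocity and size extraction from kymographs
#'
#' @description
#' Measures the stripe angle left by flowing RBCs in a space-time image and
#' converts it to an apparent speed, splits bidirectional acquisitions into
#' their anterograde and retrograde halves, and measures apparent shadow
#' sizes and vessel diameters. The extracted quantities are \emph{apparent}:
#' feed them to [real_velocity()] / [real_size()] for the scan-speed-aware
#' correction.
#'
#' @name velocity_extraction
NULL

#' Split a bidirectional kymograph into its two sweeps
#'
#' The left half of the columns (forward sweep) becomes an anterograde
#' kymograph; the right half (backward sweep, stored in reverse position
#' order) is spatially mirrored so position increases left to right and
#' becomes a retrograde kymograph. The first and last
#' \code{discard_fraction} of each sweep's columns are dropped to exclude
#' the scanner's acceleration and deceleration phases at the turnarounds.
#'
#' @param kymo A bidirectional [kymograph()].
#' @param discard_fraction Fraction of each sweep's columns removed at each
#'   end, in [0, 0.4).
#' @return List with elements \code{anterograde} and \code{retrograde}, both
#'   unidirectional [kymograph()] objects.
#' @export
split_bidirectional <- function(kymo, discard_fraction = 0) {
  kymo <- as_kymo(kymo)
  if (!kymo$bidirectional)
    stop("`kymo` is not flagged bidirectional")
  nc <- ncol(kymo$pixels)
  if (nc %% 2L != 0L)
    stop("malformed bidirectional kymograph: odd number of columns")
  if (discard_fraction < 0 || discard_fraction >= 0.4)
    stop("`discard_fraction` must be in [0, 0.4)")
  n <- nc %/% 2L
  drop_n <- floor(discard_fraction * n)
  keep <- (drop_n + 1L):(n - drop_n)
  fw <- keep
  bw <- n + keep                      # acquisition order within backward sweep
  take <- function(cols, mirror, direction) {
    if (mirror) cols <- rev(cols)     # to position order
    sc <- kymo$scan
    sc$direction <- direction
    sc$n_pixels <- length(cols)
    kymograph(kymo$pixels[, cols, drop = FALSE],
              kymo$time_map[, cols, drop = FALSE], sc,
              bidirectional = FALSE, x_positions = kymo$x_positions[cols],
              ground_truth = kymo$ground_truth)
  }
  list(anterograde = take(fw, mirror = FALSE, "anterograde"),
       retrograde  = take(bw, mirror = TRUE, "retrograde"))
}

# ---- stripe-angle estimation ------------------------------------------------

# Bilinear sampling of matrix M at (row, col) coordinate vectors (1-based,
# must lie inside the matrix). Returns a vector.
bilinear_sample <- function(M, row, col) {
  r0 <- pmin(floor(row), nrow(M) - 1L)
  c0 <- pmin(floor(col), ncol(M) - 1L)
  fr <- row - r0
  fc <- col - c0
  nr <- nrow(M)
  i00 <- (c0 - 1L) * nr + r0
  M[i00]          * (1 - fr) * (1 - fc) +
    M[i00 + 1L]   * fr       * (1 - fc) +
    M[i00 + nr]   * (1 - fr) * fc +
    M[i00 + nr + 1L] * fr    * fc
}

# Resample a rectangle of the window aligned with stripes of angle `alpha`
# (to the horizontal, pixel grid): the long axis (half-length H) runs along
# the stripe direction so the output's columns are constant when `alpha`
# matches, whatever the stripe steepness. centre = c(row, col); h =
# across-stripe half-width.
stripe_aligned_patch <- function(M, centre, h, H, alpha) {
  u <- seq(-H, H)
  w <- seq(-h, h)
  ca <- cos(alpha); sa <- sin(alpha)
  # output O[a, b]: a runs along the stripe direction, b across it
  col <- outer(u * ca, -w * sa, `+`) + centre[2L]
  row <- outer(u * sa,  w * ca, `+`) + centre[1L]
  matrix(bilinear_sample(M, as.vector(row), as.vector(col)),
         2L * H + 1L, 2L * h + 1L)
}

# Longest along-stripe half-length H that keeps the sampled rectangle
# inside an nr x nc window for a patch centred mid-column.
along_stripe_halflen <- function(nr, nc, h, alpha, margin = 1.5) {
  ca <- cos(alpha); sa <- sin(alpha)
  floor(min((nr / 2 - margin - h * ca) / max(sa, 1e-9),
            (nc / 2 - margin - h * sa) / max(ca, 1e-9)))
}

# Separability: energy fraction of the first singular value after removing
# the mean (the DC component otherwise dominates regardless of angle).
svd_separability <- function(O) {
  O <- O - mean(O)
  d <- svd(O, nu = 0L, nv = 0L)$d
  tot <- sum(d^2)
  if (tot <= .Machine$double.eps) return(0)
  d[1L]^2 / tot
}

# Radon-style score: variance of the across-stripe projection profile,
# normalised by the total pixel variance.
radon_concentration <- function(O) {
  tot <- stats::var(as.vector(O))
  if (!is.finite(tot) || tot <= .Machine$double.eps) return(0)
  stats::var(colMeans(O)) / tot
}

# Across-stripe half-width for a window; a window must accommodate at
# least a 5-pixel across-stripe profile at any angle.
across_halfwidth <- function(nr, nc) {
  h <- min(10L, floor(min(nr, nc) / 2 - 3L))
  if (h < 2L) stop("window too small for angle estimation (need >= 10x10)")
  h
}

# Mean score over up to `max_patches` stripe-aligned patches stacked along
# the rows at a given angle; H is cut to the per-patch row budget.
angle_score <- function(M, alpha, score_fun, max_patches, h) {
  nr <- nrow(M); nc <- ncol(M)
  H_full <- along_stripe_halflen(nr, nc, h, alpha)
  if (H_full < 4L) return(0)
  ca <- cos(alpha); sa <- sin(alpha)
  rad_full <- H_full * sa + h * ca + 1.5      # row half-extent of one patch
  n_p <- max(1L, min(max_patches, floor(nr / (2 * max(rad_full, 1)))))
  if (n_p > 1L) {
    # shrink H so n_p patches tile the rows without overlap
    H <- along_stripe_halflen(floor(nr / n_p), nc, h, alpha)
    if (H < 4L) { H <- H_full; n_p <- 1L }
  } else H <- H_full
  H <- min(H, 400L)
  rad <- H * sa + h * ca + 1.5
  cc <- (nc + 1) / 2
  centres <- if (n_p == 1L) (nr + 1) / 2
             else seq(1 + rad, nr - rad, length.out = n_p)
  mean(vapply(centres, function(cr)
    score_fun(stripe_aligned_patch(M, c(cr, cc), h, H, alpha)), numeric(1)))
}

# Golden-section maximisation of f on [lo, hi] to tolerance tol.
golden_max <- function(f, lo, hi, tol = 1e-4) {
  gr <- (sqrt(5) - 1) / 2
  a <- lo; b <- hi
  x1 <- b - gr * (b - a); x2 <- a + gr * (b - a)
  f1 <- f(x1); f2 <- f(x2)
  while (b - a > tol) {
    if (f1 < f2) {
      a <- x1; x1 <- x2; f1 <- f2
      x2 <- a + gr * (b - a); f2 <- f(x2)
    } else {
      b <- x2; x2 <- x1; f2 <- f1
      x1 <- b - gr * (b - a); f1 <- f(x1)
    }
  }
  xm <- (a + b) / 2
  list(x = xm, value = f(xm))
}

# Best stripe angle of one window: coarse angle grid over (0, pi/2], then
# golden-section refinement to 1e-4 rad around the bracketing candidates.
best_angle <- function(M, n_angles, max_patches, score_fun) {
  h <- across_halfwidth(nrow(M), ncol(M))
  f <- function(a) angle_score(M, a, score_fun, max_patches, h)
  grid <- seq(1e-3, pi / 2, length.out = n_angles)
  coarse <- vapply(grid, f, numeric(1))
  i <- which.max(coarse)
  step <- grid[2L] - grid[1L]
  golden_max(f, max(1e-4, grid[i] - step), min(pi / 2, grid[i] + step))
}

# Score of a surrogate with pixels permuted independently within each row
# (destroys stripes of every angle); used to flag windows with no coherent
# orientation. Deterministic.
surrogate_score <- function(M, max_patches, score_fun) {
  S <- with_seed(190919L, t(apply(M, 1L, sample)))
  h <- across_halfwidth(nrow(S), ncol(S))
  grid <- seq(1e-3, pi / 2, length.out = 64L)
  max(vapply(grid, function(a) angle_score(S, a, score_fun, max_patches, h),
             numeric(1)))
}

# ---- steep-stripe regime: consecutive-row displacement matching -----------
#
# Once the per-line displacement exceeds the shadow width, consecutive-row
# shadow segments are disjoint and resampling the window at a candidate
# angle interpolates between unrelated rows; the stripe slope must instead
# be measured by matching rows directly. The mean normalised
# cross-correlation between rows `sep` lines apart peaks at lag
# `sep * s` (s = pixels of displacement per line); an origin-constrained
# fit of peak lag against separation gives a sub-pixel s.

row_shift_cc <- function(M, sep, max_lag) {
  nr <- nrow(M); nc <- ncol(M)
  X <- M[seq_len(nr - sep), , drop = FALSE]
  Y <- M[seq_len(nr - sep) + sep, , drop = FALSE]
  vapply(0:max_lag, function(k) {
    a <- X[, seq_len(nc - k), drop = FALSE]
    b <- Y[, seq_len(nc - k) + k, drop = FALSE]
    den <- sqrt(sum(a * a) * sum(b * b))
    if (den <= .Machine$double.eps) 0 else sum(a * b) / den
  }, numeric(1))
}

# Interior local maxima of a correlation profile (indices).
local_maxima <- function(cc) {
  n <- length(cc)
  if (n < 3L) return(integer(0))
  i <- 2:(n - 1L)
  i[cc[i] > cc[i - 1L] & cc[i] >= cc[i + 1L]]
}

# Sub-pixel peak position by parabolic interpolation around index i.
parabolic_peak <- function(cc, i) {
  denom <- cc[i - 1L] - 2 * cc[i] + cc[i + 1L]
  delta <- if (abs(denom) > .Machine$double.eps)
    0.5 * (cc[i - 1L] - cc[i + 1L]) / denom else 0
  (i - 1L) + delta
}

# Estimate the per-line displacement s (pixels/line) from row pairs at
# separations 1..3. A periodic cell train correlates at lag s plus any
# multiple of the cell spacing, so the physical displacement is the FIRST
# substantial local maximum, not the global one; separations 2 and 3 then
# refine around 2s and 3s. Returns NA when no usable peak exists.
row_shift_estimate <- function(M, max_lag) {
  M <- M - rowMeans(M)        # kill the background plateau in the profile
  if (nrow(M) < 3L) return(list(s = NA_real_, peak = NA_real_))
  cc1 <- row_shift_cc(M, 1L, max_lag)
  cand <- local_maxima(cc1)
  cand <- cand[cc1[cand] >= max(0.3 * max(cc1[cand], -Inf), 0.05)]
  if (!length(cand)) return(list(s = NA_real_, peak = NA_real_))
  # lag 0 competes: a static pattern correlates best unshifted, and its
  # spatial self-similarity peaks at nonzero lags must not win
  cand <- unique(c(1L, cand))
  # a real displacement peak at lag c replicates at 2c and 3c in the
  # separation-2/3 profiles; spurious wiggles do not. Aliases from a
  # periodic cell train replicate too, so ties go to the smallest lag.
  cc2 <- if (nrow(M) > 3L) row_shift_cc(M, 2L, max_lag) else NULL
  cc3 <- if (nrow(M) > 4L) row_shift_cc(M, 3L, max_lag) else NULL
  evidence <- vapply(cand, function(i) {
    lag <- i - 1L
    vals <- cc1[i]
    for (p in list(list(cc2, 2L), list(cc3, 3L))) {
      cc <- p[[1L]]
      if (is.null(cc)) next
      at <- p[[2L]] * lag + 1L
      if (at + 1L <= length(cc))
        vals <- c(vals, max(cc[max(1L, at - 2L):(at + 2L)]))
    }
    mean(vals)
  }, numeric(1))
  ok <- which(evidence >= 0.9 * max(evidence))
  i1 <- cand[min(ok)]
  if (i1 == 1L) return(list(s = 0, peak = cc1[1L]))
  s1 <- parabolic_peak(cc1, i1)
  lags <- s1; seps <- 1; peaks <- cc1[i1]
  for (sep in 2:3) {
    if (nrow(M) <= sep + 1L) next
    target <- sep * s1
    if (target > max_lag - 2) next
    cc <- row_shift_cc(M, sep, max_lag)
    lm <- local_maxima(cc)
    lm <- lm[abs((lm - 1L) - target) <= pmax(2, s1 / 2)]
    if (!length(lm)) next
    i <- lm[which.max(cc[lm])]
    lags <- c(lags, parabolic_peak(cc, i))
    seps <- c(seps, sep)
    peaks <- c(peaks, cc[i])
  }
  if (peaks[1L] <= 0) return(list(s = NA_real_, peak = NA_real_))
  w <- pmax(peaks, 0)
  list(s = sum(w * lags * seps) / sum(w * seps^2), peak = peaks[1L])
}

# Correlation-peak height of the within-row-shuffled surrogate (separation
# 1 only); the quality reference for the steep regime.
surrogate_cc_peak <- function(M, max_lag) {
  S <- with_seed(190919L, t(apply(M, 1L, sample)))
  S <- S - rowMeans(S)
  max(row_shift_cc(S, 1L, max_lag))
}

# displacement (pixels/line) above which the angle-resampling criterion is
# unreliable and row matching takes over
.STEEP_SLOPE <- 4

#' Estimate the apparent RBC velocity from a kymograph
#'
#' Splits the recording into windows of \code{window_s} seconds (incomplete
#' trailing windows are dropped) and, per window, finds the stripe angle
#' that maximises either the SVD separability (energy fraction of the first
#' singular value of the window resampled so candidate stripes become
#' columns) or the Radon-style concentration (variance of the across-stripe
#' projection profile). The search runs a coarse grid of \code{n_angles}
#' candidates over (0, pi/2] followed by golden-section refinement to 1e-4
#' rad. The angle maps to a speed through the axis scaling:
#' \code{v_app = (x_pixel / t_line) * cot(alpha)}.
#'
#' Angle resampling assumes consecutive rows overlap along the stripe; once
#' the per-line displacement exceeds a few pixels the shadow segments of
#' successive lines are disjoint and no rotation criterion can connect
#' them. Each window therefore first measures the displacement by
#' consecutive-row cross-correlation (separations 1-3 lines, sub-pixel
#' parabolic peak); when it exceeds 4 pixels/line that measurement is used
#' directly (\code{v_app = s * x_pixel / t_line}) and the quality margin is
#' computed on the correlation peak instead of the separability score.
#'
#' Each window's quality is the margin of its best score over the best
#' score of a surrogate with pixels permuted independently within each row
#' (which destroys stripes of every orientation). Windows whose margin is
#' below \code{quality_margin} are flagged as no-flow/noise and excluded
#' from the mean; if every window is flagged an error is raised.
#'
#' @param kymo A unidirectional [kymograph()] (split bidirectional images
#'   first with [split_bidirectional()]).
#' @param method \code{"svd"} (default) or \code{"radon"}.
#' @param window_s Window length in seconds (default 1).
#' @param n_angles Coarse-grid size (default 1024).
#' @param quality_margin Flagging threshold on the score margin (default
#'   0.1).
#' @param max_patches Maximum number of square patches scored per window
#'   (default 4).
#' @return An object of class \code{"extraction_result"}: list with
#'   \code{windows} (data frame: \code{start_s}, \code{length_s},
#'   \code{v_app}, \code{alpha}, \code{quality}, \code{flagged}),
#'   \code{v_app_mean} (mean over unflagged windows, mm/s) and
#'   \code{method}.
#' @examples
#' sp <- scan_parameters(20, "anterograde", t_line = 4, x_pixel = 0.5,
#'                       n_pixels = 80)
#' k <- simulate_kymograph(kymo_config(sp,
#'        rbc_train(12, 6, 1, 40, 200), n_lines = 50))
#' estimate_apparent_velocity(k, window_s = 0.2)
#' @export
estimate_apparent_velocity <- function(kymo, method = c("svd", "radon"),
                                       window_s = 1, n_angles = 1024L,
                                       quality_margin = 0.1,
                                       max_patches = 4L) {
  kymo <- as_kymo(kymo)
  if (kymo$bidirectional)
    stop("split bidirectional kymographs first (split_bidirectional)")
  method <- match.arg(method)
  score_fun <- if (method == "svd") svd_separability else radon_concentration
  nr <- nrow(kymo$pixels)
  if (nr < 2L) stop("kymograph needs at least 2 lines")
  rows_per_win <- floor(window_s * 1000 / kymo$scan$t_line)
  if (rows_per_win < 2L) stop("`window_s` shorter than two line periods")
  n_win <- nr %/% rows_per_win
  if (n_win < 1L)
    stop(sprintf("recording (%d lines) shorter than one window (%d lines)",
                 nr, rows_per_win))
  res <- vector("list", n_win)
  for (w in seq_len(n_win)) {
    rows <- ((w - 1L) * rows_per_win + 1L):(w * rows_per_win)
    M <- kymo$pixels[rows, , drop = FALSE]
    M <- M - mean(M)
    max_lag <- ncol(M) - 8L
    shift <- if (max_lag >= 2L) row_shift_estimate(M, max_lag)
             else list(s = NA_real_, peak = NA_real_)
    if (!is.na(shift$s) && shift$s > .STEEP_SLOPE) {
      # steep stripes: consecutive-row matching (see row_shift_estimate)
      alpha <- atan2(1, shift$s)
      v_app <- shift$s * kymo$scan$x_pixel / kymo$scan$t_line
      qual <- shift$peak - surrogate_cc_peak(M, max_lag)
    } else {
      fit <- best_angle(M, n_angles, max_patches, score_fun)
      alpha <- fit$x
      v_app <- (kymo$scan$x_pixel / kymo$scan$t_line) / tan(fit$x)
      qual <- fit$value - surrogate_score(M, max_patches, score_fun)
    }
    res[[w]] <- data.frame(
      start_s = (rows[1L] - 1L) * kymo$scan$t_line / 1000,
      length_s = rows_per_win * kymo$scan$t_line / 1000,
      v_app = v_app, alpha = alpha, quality = qual,
      flagged = qual < quality_margin)
  }
  windows <- do.call(rbind, res)
  if (all(windows$flagged))
    stop("no coherent stripe orientation detected in any window ",
         "(all windows flagged low-quality)")
  structure(list(windows = windows,
                 v_app_mean = mean(windows$v_app[!windows$flagged]),
                 method = method),
            class = "extraction_result")
}

#' @export
print.extraction_result <- function(x, ...) {
  n_ok <- sum(!x$windows$flagged)
  cat(sprintf("Apparent velocity (%s method): %.4g mm/s\n", x$method,
              x$v_app_mean))
  cat(sprintf("  %d window(s), %d used, %d flagged low-quality\n",
              nrow(x$windows), n_ok, nrow(x$windows) - n_ok))
  invisible(x)
}

# ---- size / diameter measurements ------------------------------------------

# Midpoint threshold between the background and shadow intensity modes,
# via 1-D 2-means seeded at the extremes (deterministic).
two_mode_threshold <- function(v) {
  rng <- range(v)
  if (diff(rng) <= .Machine$double.eps)
    stop("no shadow crosses threshold: image has a single intensity mode")
  km <- stats::kmeans(v, centers = matrix(rng, 2L, 1L), iter.max = 50L)
  mean(km$centers)
}

#' Measure the apparent RBC size on a kymograph
#'
#' Thresholds the image at the midpoint between its background and shadow
#' intensity modes, measures the longest below-threshold run in each row
#' (runs touching the image border are discarded as truncated shadows) and
#' returns the median run length across rows times the pixel size.
#'
#' @param kymo A unidirectional [kymograph()].
#' @return Apparent size in um.
#' @export
measure_apparent_size <- function(kymo) {
  kymo <- as_kymo(kymo)
  if (kymo$bidirectional)
    stop("split bidirectional kymographs first (split_bidirectional)")
  thr <- two_mode_threshold(as.vector(kymo$pixels))
  nc <- ncol(kymo$pixels)
  widths <- apply(kymo$pixels, 1L, function(row) {
    rl <- rle(row < thr)
    ends <- cumsum(rl$lengths)
    starts <- ends - rl$lengths + 1L
    dark <- which(rl$values)
    dark <- dark[starts[dark] > 1L & ends[dark] < nc]  # interior runs only
    if (!length(dark)) return(NA_real_)
    max(rl$lengths[dark])
  })
  widths <- widths[!is.na(widths)]
  if (!length(widths))
    stop("no shadow crosses threshold in any row")
  stats::median(widths) * kymo$scan$x_pixel
}

#' Measure a vessel's internal diameter from a single-frame image
#'
#' Applies a 3x3 median filter, averages the image along the vessel axis
#' (the band of fluorescent plasma spans the image columns; the profile is
#' read across the rows) and returns the full width at half maximum of the
#' profile between the background level and the plasma plateau, in um.
#'
#' @param image A \code{vessel_image} from [simulate_vessel_image()], or a
#'   numeric matrix (then \code{x_pixel} is required).
#' @param x_pixel Pixel size in um (taken from the object if absent).
#' @return Diameter in um.
#' @export
measure_vessel_diameter <- function(image, x_pixel = NULL) {
  if (inherits(image, "vessel_image")) {
    if (is.null(x_pixel)) x_pixel <- image$x_pixel
    image <- image$pixels
  }
  if (is.null(x_pixel)) stop("`x_pixel` is required for a bare matrix")
  image <- as.matrix(image)
  top <- max(image)
  if (top <= 0) stop("no plasma plateau detected: image is empty")
  filtered <- EBImage::medianFilter(image / top, size = 1L) * top
  profile <- rowMeans(filtered)
  y <- (seq_along(profile) - 0.5) * x_pixel
  bg <- stats::quantile(profile, 0.1, names = FALSE)
  plateau <- max(profile)
  if (plateau - bg <= 0.05 * max(plateau, .Machine$double.eps))
    stop("no plasma plateau detected: profile is flat")
  half <- bg + (plateau - bg) / 2
  above <- profile >= half
  if (!any(above)) stop("no plasma plateau detected: nothing above half-max")
  i1 <- which(above)[1L]
  i2 <- rev(which(above))[1L]
  # linear interpolation of the two half-max crossings
  left <- if (i1 == 1L) y[1L] - x_pixel / 2 else {
    y[i1 - 1L] + (half - profile[i1 - 1L]) /
      (profile[i1] - profile[i1 - 1L]) * x_pixel
  }
  right <- if (i2 == length(profile)) y[i2] + x_pixel / 2 else {
    y[i2] + (half - profile[i2]) / (profile[i2 + 1L] - profile[i2]) * x_pixel
  }
  right - left
}
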