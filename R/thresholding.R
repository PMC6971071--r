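#' Center-line intensity profiles
#'
#' A line profile is the 1-D sequence of mean intensities sampled along a
#' bar laid across the center of the spheroid, averaging over `bar_width`
#' pixels perpendicular to the bar. In a brightfield micrograph the
#' background (gel or medium) is bright and the spheroid dark, so the
#' profile descends from the flanks into the core.
#'
#' @param intensities numeric vector of mean intensities in \[0, 255\].
#' @param positions 1-based pixel offsets along the bar; same length as
#'   `intensities`.
#' @param bar_width perpendicular averaging width in pixels.
#' @return A `line_profile` object.
#' @export
line_profile <- function(intensities, positions = seq_along(intensities),
                         bar_width = 1L) {
  if (!is.numeric(intensities) || length(intensities) < 3L)
    abort_validation("profile needs at least 3 intensity samples")
  if (length(positions) != length(intensities))
    abort_validation("`positions` and `intensities` must have equal length")
  if (anyNA(intensities))
    abort_validation("profile intensities contain NA")
  if (min(intensities) < 0 || max(intensities) > 255)
    abort_validation("profile intensities must lie in [0, 255]")
  structure(list(intensities = as.numeric(intensities),
                 positions = as.integer(positions),
                 bar_width = as.integer(bar_width)),
            class = "line_profile")
}

#' @export
print.line_profile <- function(x, ...) {
  cat(sprintf("<line_profile> %d samples, bar width %d, intensity [%.1f, %.1f]\n",
              length(x$intensities), x$bar_width,
              min(x$intensities), max(x$intensities)))
  invisible(x)
}

#' @export
length.line_profile <- function(x) length(x$intensities)

#' Extract a center-line intensity profile from a micrograph
#'
#' Lays a bar through `center` spanning the full image extent along the
#' chosen orientation and averages over `bar_width` pixels perpendicular
#' to it (the band is truncated at the image border if the center lies
#' close to it).
#'
#' @param m a [micrograph()].
#' @param center `c(row, col)` pixel coordinate the bar passes through;
#'   defaults to the image center.
#' @param orientation `"horizontal"` (bar along columns) or `"vertical"`.
#' @param bar_width perpendicular averaging width in pixels (>= 1).
#' @return A [line_profile()] with one sample per pixel along the bar.
#' @export
extract_profile <- function(m, center = NULL,
                            orientation = c("horizontal", "vertical"),
                            bar_width = 10L) {
  stopifnot(inherits(m, "micrograph"))
  orientation <- match.arg(orientation)
  h <- nrow(m$pixels); w <- ncol(m$pixels)
  if (is.null(center)) center <- c(ceiling(h / 2), ceiling(w / 2))
  if (length(center) != 2L || anyNA(center))
    abort_validation("`center` must be c(row, col)")
  if (center[1L] < 1 || center[1L] > h || center[2L] < 1 || center[2L] > w)
    abort_validation(sprintf("center (%d, %d) lies outside the %d x %d image",
                             center[1L], center[2L], h, w))
  if (!is.numeric(bar_width) || bar_width < 1)
    abort_validation("`bar_width` must be >= 1")
  bar_width <- as.integer(bar_width)
  half_lo <- (bar_width - 1L) %/% 2L
  half_hi <- bar_width - 1L - half_lo
  if (orientation == "horizontal") {
    rows <- max(1L, center[1L] - half_lo):min(h, center[1L] + half_hi)
    vals <- colMeans(m$pixels[rows, , drop = FALSE])
  } else {
    cols <- max(1L, center[2L] - half_lo):min(w, center[2L] + half_hi)
    vals <- rowMeans(m$pixels[, cols, drop = FALSE])
  }
  line_profile(vals, bar_width = bar_width)
}

# Centered moving average with windows truncated to available samples at
# the ends; output length equals input length. For even windows the
# window is [i - (w-1)%/%2, i + w%/%2].
moving_average <- function(x, window) {
  n <- length(x)
  lo <- pmax(1L, seq_len(n) - (window - 1L) %/% 2L)
  hi <- pmin(n, seq_len(n) + window %/% 2L)
  cs <- cumsum(c(0, x))
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

#' Smooth a line profile by a centered moving average
#'
#' Reduces pixel noise before differentiation. At the profile ends the
#' window is truncated to the available samples rather than padded, so no
#' out-of-image intensities are invented and constant regions stay
#' constant.
#'
#' @param p a [line_profile()].
#' @param window moving-average window in pixels (default 20, roughly the
#'   diameter of 6–7 cells at typical magnification).
#' @return A [line_profile()] of the same length.
#' @export
smooth_profile <- function(p, window = 20L) {
  stopifnot(inherits(p, "line_profile"))
  if (!is.numeric(window) || window < 1)
    abort_validation("`window` must be >= 1")
  if (window > length(p$intensities))
    abort_validation("`window` exceeds the profile length")
  line_profile(moving_average(p$intensities, as.integer(window)),
               positions = p$positions, bar_width = p$bar_width)
}

#' First derivative of a line profile
#'
#' Central differences at interior positions and one-sided differences at
#' the two ends, so the output has the same length as the input. The
#' derivative quantifies the local intensity change per pixel; sharp
#' intensity drops at zone boundaries appear as downward peaks.
#'
#' @param p a [line_profile()] (or bare numeric vector) of length >= 3.
#' @return Numeric vector of intensity change per pixel.
#' @export
first_derivative <- function(p) {
  x <- if (inherits(p, "line_profile")) p$intensities else p
  n <- length(x)
  if (!is.numeric(x) || n < 3L)
    abort_validation("profile must have at least 3 samples to differentiate")
  d <- numeric(n)
  d[1L] <- x[2L] - x[1L]
  d[n] <- x[n] - x[n - 1L]
  i <- 2L:(n - 1L)
  d[i] <- (x[i + 1L] - x[i - 1L]) / 2
  d
}

#' Objective threshold sets for three-zone segmentation
#'
#' An ordered triple of intensity cutoffs: `t_all` separates the whole
#' cell-covered area from the background gel, `t_intermediate` the loosely
#' aggregated grey zone, and `t_core` the darkest, tightly aggregated
#' core. Nested segmentation requires `0 <= t_core < t_intermediate <
#' t_all <= 255`.
#'
#' @param t_all,t_intermediate,t_core intensity cutoffs.
#' @param provenance optional record of how the cutoffs were derived
#'   (derivative-peak positions, smoothing window, scan side, prominence).
#' @return A `threshold_set` object.
#' @export
threshold_set <- function(t_all, t_intermediate, t_core, provenance = NULL) {
  for (a in c("t_all", "t_intermediate", "t_core"))
    check_scalar_number(get(a), a)
  if (!(0 <= t_core && t_core < t_intermediate &&
        t_intermediate < t_all && t_all <= 255))
    abort_validation(sprintf(
      "thresholds must satisfy 0 <= t_core < t_intermediate < t_all <= 255 (got %.2f, %.2f, %.2f)",
      t_core, t_intermediate, t_all))
  structure(list(t_all = t_all, t_intermediate = t_intermediate,
                 t_core = t_core, provenance = provenance),
            class = "threshold_set")
}

#' @export
print.threshold_set <- function(x, ...) {
  cat(sprintf("<threshold_set> all %.1f | intermediate %.1f | core %.1f\n",
              x$t_all, x$t_intermediate, x$t_core))
  if (!is.null(x$provenance))
    cat(sprintf("  from derivative peaks at positions %s (window %d, side %s)\n",
                paste(sprintf("%.1f", x$provenance$positions), collapse = ", "),
                x$provenance$window, x$provenance$side))
  invisible(x)
}

# Downward peaks of a derivative trace: local minima dipping below
# -min_prominence. Residual noise ripple can split one physical trough
# into several nearby local minima, so candidates closer together than
# merge_radius are treated as one peak and the deepest of them (earliest
# on a depth tie) is reported.
downward_peaks <- function(d, min_prominence, merge_radius = 1L) {
  n <- length(d)
  if (n < 3L) return(integer(0))
  i <- 2L:(n - 1L)
  is_min <- d[i] <= d[i - 1L] & d[i] <= d[i + 1L] & d[i] <= -min_prominence
  cand <- i[is_min]
  if (length(cand) == 0L) return(integer(0))
  clusters <- split(cand, cumsum(c(1L, diff(cand) > merge_radius)))
  peaks <- vapply(clusters, function(r) r[which.min(d[r])][1L], integer(1))
  unname(peaks)
}

# Sub-pixel peak localization: depth-weighted centroid of the trough's
# half-depth region around the integer local minimum. Argmin alone can
# jitter by a pixel or two on the flat bottom of a broad trough under
# noise; the centroid of a symmetric trough is its center. max_span must
# be generous enough to cover the whole half-depth region (the expansion
# normally stops where the derivative rises above half depth, well before
# the neighboring trough).
refine_peak <- function(d, peak, max_span) {
  half <- d[peak] / 2  # half the (negative) depth
  lo <- peak
  while (lo > 1L && peak - lo < max_span && d[lo - 1L] <= half) lo <- lo - 1L
  hi <- peak
  n <- length(d)
  while (hi < n && hi - peak < max_span && d[hi + 1L] <= half) hi <- hi + 1L
  i <- lo:hi
  w <- -d[i]
  sum(i * w) / sum(w)
}

# Linear interpolation of a profile at a fractional position.
interp_at <- function(x, pos) {
  pos <- min(max(pos, 1), length(x))
  i <- floor(pos)
  f <- pos - i
  if (i >= length(x)) x[length(x)] else (1 - f) * x[i] + f * x[i + 1L]
}

#' Detect segmentation thresholds from derivative downward peaks
#'
#' Implements the objective threshold-setting procedure: smooth the
#' profile, take its first derivative, and scan inward from the chosen
#' side for the first `n_levels` downward peaks — local minima of the
#' derivative at least `min_prominence` below zero — stopping at the
#' profile's global minimum (the spheroid core). The k-th cutoff is the
#' smoothed intensity at the k-th peak position, so the scan yields
#' `t_all` (gel/cell boundary) first, then `t_intermediate`, then
#' `t_core`.
#'
#' @param p a [line_profile()].
#' @param window smoothing window in pixels (default 20).
#' @param n_levels number of cutoffs to detect (1 to 3; default 3).
#' @param side `"left"` (default) or `"right"`: which flank to scan from.
#'   Cutoffs estimated from either side of a centered spheroid are
#'   similar; the left side is the package-wide convention.
#' @param min_prominence minimum derivative depth below zero, in intensity
#'   units per pixel, for a local minimum to count as a peak (default 0.5).
#' @return For `n_levels = 3`, a [threshold_set()]. For fewer levels, a
#'   numeric vector of cutoffs in scan order with a `provenance`
#'   attribute.
#' @export
detect_thresholds <- function(p, window = 20L, n_levels = 3L,
                              side = c("left", "right"),
                              min_prominence = 0.5) {
  stopifnot(inherits(p, "line_profile"))
  side <- match.arg(side)
  if (!n_levels %in% 1:3)
    abort_validation("`n_levels` must be 1, 2, or 3")
  sm <- smooth_profile(p, window)$intensities
  n <- length(sm)
  x <- if (side == "right") rev(sm) else sm
  d <- first_derivative(x)
  # scan only up to the global minimum region (the core); the first index
  # attaining the minimum, approached from the scan side
  stop_at <- which.min(x)
  peaks <- downward_peaks(d, min_prominence,
                          merge_radius = max(1L, as.integer(window) %/% 2L))
  peaks <- peaks[peaks <= stop_at]
  if (length(peaks) < n_levels)
    abort_detection(sprintf(
      "found %d of %d downward peaks with prominence >= %.3g on the %s side",
      length(peaks), n_levels, min_prominence, side))
  peaks <- peaks[seq_len(n_levels)]
  refined <- vapply(peaks, function(pk)
    refine_peak(d, pk, max_span = 3L * as.integer(window)), numeric(1))
  cutoffs <- vapply(refined, function(pos) interp_at(x, pos), numeric(1))
  positions <- if (side == "right") n + 1 - refined else refined
  prov <- list(positions = positions, window = as.integer(window),
               side = side, min_prominence = min_prominence)
  if (n_levels == 3L) {
    if (!(cutoffs[1L] > cutoffs[2L] && cutoffs[2L] > cutoffs[3L]))
      abort_detection(sprintf(
        "detected cutoffs %.2f, %.2f, %.2f are not strictly decreasing; the profile is unsuitable",
        cutoffs[1L], cutoffs[2L], cutoffs[3L]))
    threshold_set(cutoffs[1L], cutoffs[2L], cutoffs[3L], provenance = prov)
  } else {
    if (n_levels > 1L && any(diff(cutoffs) >= 0))
      abort_detection("detected cutoffs are not strictly decreasing")
    structure(cutoffs, provenance = prov)
  }
}

#' Single threshold for a spheroid in suspension
#'
#' For well-contrasted spheroids free in medium (no gel), a single
#' threshold slightly below the lowest background intensity captures the
#' whole cell-covered area. The background is taken from the outermost
#' 10\% of positions at each end of the bar, which lie in the surrounding
#' medium.
#'
#' @param p a [line_profile()].
#' @param margin intensity units subtracted from the background minimum
#'   (default 5).
#' @return A single intensity cutoff.
#' @export
suspension_threshold <- function(p, margin = 5) {
  stopifnot(inherits(p, "line_profile"))
  check_scalar_number(margin, "margin")
  n <- length(p$intensities)
  k <- max(1L, floor(0.1 * n))
  flanks <- c(p$intensities[seq_len(k)],
              p$intensities[(n - k + 1L):n])
  bg_min <- min(flanks)
  interior <- p$intensities[(k + 1L):(n - k)]
  if (length(interior) && bg_min <= min(interior))
    abort_validation(
      "background flanks are not brighter than the object; no background identified")
  if (margin >= bg_min)
    abort_validation(sprintf(
      "margin %.2f is not smaller than the background minimum %.2f",
      margin, bg_min))
  bg_min - margin
}

#' Write or read a threshold set as JSON
#'
#' @param t a [threshold_set()].
#' @param path JSON file path.
#' @export
write_thresholds <- function(t, path) {
  stopifnot(inherits(t, "threshold_set"))
  jsonlite::write_json(
    list(t_all = t$t_all, t_intermediate = t$t_intermediate,
         t_core = t$t_core, provenance = t$provenance),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_thresholds
#' @export
read_thresholds <- function(path) {
  if (!file.exists(path))
    abort_io(sprintf("cannot read threshold file '%s'", path))
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  threshold_set(x$t_all, x$t_intermediate, x$t_core,
                provenance = x$provenance)
}
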