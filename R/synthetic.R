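# Seeded spheroid phantoms: concentric intensity zones with smooth
# logistic transitions, thin radial protrusions, detached blobs, and
# additive Gaussian noise, plus the exact ground-truth geometry. Every
# pipeline stage can be validated against these without real micrographs.

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Specification of a synthetic spheroid phantom
#'
#' Describes a radially layered phantom emulating a brightfield spheroid
#' micrograph: a dark core, a grey loosely aggregated intermediate zone,
#' and a faint invasive edge on a bright background, with smooth
#' (logistic) transitions between zones, optional thin radial
#' protrusions, and optional detached blobs beyond the spheroid body.
#'
#' @param image_size pixels per side of the square image (default 384,
#'   roughly a cropped low-magnification field of view).
#' @param background_intensity background (gel/medium) grey level,
#'   default 230.
#' @param zone_intensities intensities of (core, intermediate, edge),
#'   strictly increasing and all below the background; default
#'   `c(50, 110, 170)`.
#' @param zone_radii radii of (core, intermediate, edge) boundaries in
#'   pixels, strictly increasing; default `c(40, 80, 125)`, giving zone
#'   boundaries 40–45 px apart — the proportions seen in real day-3
#'   invasion micrographs, and comfortably wider than the default 20-px
#'   smoothing window so the derivative troughs of adjacent boundaries
#'   stay distinct.
#' @param transition_width width in pixels over which each zone blends
#'   into the next (default 8; the logistic covers ~76% of the step over
#'   this width).
#' @param n_protrusions number of thin radial spikes at edge intensity.
#' @param protrusion_length,protrusion_width spike geometry in pixels.
#' @param n_detached number of detached blobs beyond the spheroid body.
#' @param detached_radius blob radius in pixels (default 5).
#' @param noise_sigma standard deviation of additive Gaussian pixel
#'   noise, in intensity units.
#' @param seed random seed controlling protrusion jitter, blob placement,
#'   and the noise realization.
#' @return A `phantom_spec` object.
#' @export
phantom_spec <- function(image_size = 384L,
                         background_intensity = 230,
                         zone_intensities = c(50, 110, 170),
                         zone_radii = c(40, 80, 125),
                         transition_width = 8,
                         n_protrusions = 0L,
                         protrusion_length = 25,
                         protrusion_width = 3,
                         n_detached = 0L,
                         detached_radius = 5,
                         noise_sigma = 0,
                         seed = 1L) {
  spec <- structure(
    list(image_size = as.integer(image_size),
         background_intensity = background_intensity,
         zone_intensities = as.numeric(zone_intensities),
         zone_radii = as.numeric(zone_radii),
         transition_width = transition_width,
         n_protrusions = as.integer(n_protrusions),
         protrusion_length = protrusion_length,
         protrusion_width = protrusion_width,
         n_detached = as.integer(n_detached),
         detached_radius = detached_radius,
         noise_sigma = noise_sigma,
         seed = as.integer(seed)),
    class = "phantom_spec")
  validate_phantom_spec(spec)
}

validate_phantom_spec <- function(spec) {
  z <- spec$zone_intensities; r <- spec$zone_radii
  if (length(z) != 3L || any(diff(z) <= 0) || any(z >= spec$background_intensity))
    abort_validation(
      "zone intensities must increase strictly from core to edge and stay below the background")
  if (any(z < 0) || spec$background_intensity > 255)
    abort_validation("phantom intensities must lie in [0, 255]")
  if (length(r) != 3L || any(diff(r) <= 0) || any(r <= 0))
    abort_validation("zone radii must be strictly increasing and positive")
  reach <- r[3L] + (if (spec$n_protrusions > 0L) spec$protrusion_length else 0)
  if (reach >= spec$image_size / 2)
    abort_validation(sprintf(
      "spheroid reach %.1f px does not fit inside half the image size (%d px)",
      reach, spec$image_size))
  if (spec$noise_sigma < 0)
    abort_validation("`noise_sigma` must be >= 0")
  if (spec$transition_width <= 0)
    abort_validation("`transition_width` must be positive")
  if (spec$n_detached > 0L &&
      reach + 2 * spec$detached_radius + 8 >= spec$image_size / 2)
    abort_validation("no room to place detached blobs inside the image")
  spec
}

logistic <- function(x) 1 / (1 + exp(-x))

#' Generate a spheroid phantom micrograph with ground truth
#'
#' Builds the radially layered intensity field, adds protrusions (thin
#' radial spikes at edge intensity, evenly spaced in angle with seeded
#' jitter, offset so none lies along the horizontal center line where the
#' profile bar is drawn), places detached blobs beyond the body, adds
#' seeded Gaussian noise clipped to \[0, 255\], and returns both the
#' image and the exact noiseless ground truth.
#'
#' The designed transition intensities — the midpoints of the three zone
#' steps — are what the derivative-peak threshold detector should
#' recover: `(background+edge)/2`, `(edge+intermediate)/2`, and
#' `(intermediate+core)/2` for `t_all`, `t_intermediate`, `t_core`.
#'
#' @param spec a [phantom_spec()].
#' @return List with elements `micrograph` (a [micrograph()]) and
#'   `truth`: nested noiseless masks (`mask_core`, `mask_intermediate`,
#'   `mask_all`), `truth_areas` (core, intermediate_region, edge, all, in
#'   pixels squared), `designed_transition_intensities` (t_all,
#'   t_intermediate, t_core), and `detached_centers`.
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  validate_phantom_spec(spec)
  n <- spec$image_size
  cx <- (n + 1) / 2
  row <- matrix(seq_len(n), n, n)
  col <- matrix(seq_len(n), n, n, byrow = TRUE)
  dy <- row - cx; dx <- col - cx
  rho <- sqrt(dx^2 + dy^2)

  z <- spec$zone_intensities; r <- spec$zone_radii
  bg <- spec$background_intensity
  s <- spec$transition_width / 4  # logistic scale: ~76% of the step in one width
  img <- z[1L] +
    (z[2L] - z[1L]) * logistic((rho - r[1L]) / s) +
    (z[3L] - z[2L]) * logistic((rho - r[2L]) / s) +
    (bg - z[3L]) * logistic((rho - r[3L]) / s)

  spike_mask <- matrix(FALSE, n, n)
  detached_mask <- matrix(FALSE, n, n)
  detached_centers <- matrix(numeric(0), 0L, 2L,
                             dimnames = list(NULL, c("row", "col")))
  with_seed(spec$seed, {
    if (spec$n_protrusions > 0L) {
      k <- spec$n_protrusions
      # half-step offset + small jitter keeps spikes off the horizontal bar
      jitter <- stats::runif(k, -0.2, 0.2) * 2 * pi / k
      theta <- 2 * pi * (seq_len(k) - 0.5) / k + jitter
      t0 <- r[3L] - spec$transition_width
      t1 <- r[3L] + spec$protrusion_length
      # keep every spike clear of the horizontal center line, where the
      # profile bar is drawn: nudge offending angles off the axis
      bar_clear <- 8 + spec$protrusion_width / 2
      target <- asin(min(1, bar_clear / t0))
      for (j in seq_len(k)) {
        if (t0 * abs(sin(theta[j])) < bar_clear) {
          sgn <- if (sin(theta[j]) >= 0) 1 else -1
          theta[j] <- if (cos(theta[j]) >= 0) sgn * target
                      else pi - sgn * target
        }
      }
      for (th in theta) {
        along <- dx * cos(th) + dy * sin(th)
        perp <- abs(-dx * sin(th) + dy * cos(th))
        spike_mask <- spike_mask |
          (along >= t0 & along <= t1 & perp <= spec$protrusion_width / 2)
      }
    }
    if (spec$n_detached > 0L) {
      reach <- r[3L] + (if (spec$n_protrusions > 0L) spec$protrusion_length else 0)
      rad_lo <- reach + spec$detached_radius + 4
      rad_hi <- n / 2 - spec$detached_radius - 2
      clearance <- spec$detached_radius + 8  # keep clear of the profile bar
      placed <- 0L
      tries <- 0L
      centers <- matrix(NA_real_, spec$n_detached, 2L)
      while (placed < spec$n_detached && tries < 1000L) {
        tries <- tries + 1L
        th <- stats::runif(1, 0, 2 * pi)
        rr <- stats::runif(1, rad_lo, rad_hi)
        cy_ <- cx + rr * sin(th); cx_ <- cx + rr * cos(th)
        if (abs(cy_ - cx) < clearance) next
        if (placed > 0L) {
          dmin <- min(sqrt((centers[seq_len(placed), 1L] - cy_)^2 +
                           (centers[seq_len(placed), 2L] - cx_)^2))
          if (dmin < 2 * spec$detached_radius + 3) next
        }
        placed <- placed + 1L
        centers[placed, ] <- c(cy_, cx_)
      }
      if (placed < spec$n_detached)
        abort_validation("could not place all detached blobs without overlap")
      detached_centers <- centers
      colnames(detached_centers) <- c("row", "col")
      for (i in seq_len(placed)) {
        detached_mask <- detached_mask |
          (sqrt((row - centers[i, 1L])^2 + (col - centers[i, 2L])^2) <=
             spec$detached_radius)
      }
    }
    img[spike_mask] <- pmin(img[spike_mask], z[3L])
    img[detached_mask] <- pmin(img[detached_mask], z[3L])
    if (spec$noise_sigma > 0)
      img <- img + stats::rnorm(length(img), 0, spec$noise_sigma)
  })
  img <- pmin(pmax(img, 0), 255)

  truth_core <- rho <= r[1L]
  truth_intermediate <- rho <= r[2L]
  truth_all <- (rho <= r[3L]) | spike_mask | detached_mask
  truth <- list(
    mask_core = truth_core,
    mask_intermediate = truth_intermediate,
    mask_all = truth_all,
    truth_areas = c(core = sum(truth_core),
                    intermediate_region = sum(truth_intermediate) - sum(truth_core),
                    edge = sum(truth_all) - sum(truth_intermediate),
                    all = sum(truth_all)),
    designed_transition_intensities = c(
      t_all = (bg + z[3L]) / 2,
      t_intermediate = (z[3L] + z[2L]) / 2,
      t_core = (z[2L] + z[1L]) / 2),
    detached_centers = detached_centers)
  list(micrograph = micrograph(round_half_up(img),
                               frame_label = sprintf("phantom_seed%d", spec$seed)),
       truth = truth)
}

#' Generate a phantom time course
#'
#' Produces a series of phantoms sharing one background and one set of
#' zone intensities, so a single threshold set detected on the first
#' frame applies to the whole series — the batch-processing situation of
#' a real time-course experiment. Growth is modeled as a per-frame
#' fractional increase applied to all three zone radii (isotropic
#' proliferation, which preserves the zone-area ratios); invasion as
#' per-frame additive increments to protrusion count/length and
#' detached-blob count.
#'
#' @param spec_initial [phantom_spec()] for frame 1.
#' @param n_frames number of frames (>= 1).
#' @param growth per-frame fractional radius increase (e.g. 0.1 grows all
#'   radii by 10\% per frame); default 0.
#' @param invasion named list of per-frame additive increments:
#'   `n_protrusions`, `protrusion_length`, `n_detached` (all default 0).
#' @return List of `n_frames` elements, each as returned by
#'   [generate_phantom()], with frame labels `frame_01`, `frame_02`, ...
#' @export
generate_time_course <- function(spec_initial, n_frames, growth = 0,
                                 invasion = list()) {
  stopifnot(inherits(spec_initial, "phantom_spec"))
  if (!is.numeric(n_frames) || n_frames < 1)
    abort_validation("`n_frames` must be >= 1")
  inv <- utils::modifyList(
    list(n_protrusions = 0L, protrusion_length = 0, n_detached = 0L),
    invasion)
  out <- vector("list", n_frames)
  for (k in seq_len(n_frames)) {
    g <- (1 + growth)^(k - 1L)
    spec_k <- spec_initial
    spec_k$zone_radii <- spec_initial$zone_radii * g
    spec_k$n_protrusions <- spec_initial$n_protrusions +
      (k - 1L) * inv$n_protrusions
    spec_k$protrusion_length <- spec_initial$protrusion_length +
      (k - 1L) * inv$protrusion_length
    spec_k$n_detached <- spec_initial$n_detached + (k - 1L) * inv$n_detached
    spec_k$seed <- spec_initial$seed + (k - 1L)
    ok <- tryCatch(validate_phantom_spec(spec_k), error = function(e) e)
    if (inherits(ok, "error"))
      abort_validation(sprintf("frame %d has an invalid phantom spec: %s",
                               k, conditionMessage(ok)))
    out[[k]] <- generate_phantom(spec_k)
    out[[k]]$micrograph$frame_label <- sprintf("frame_%02d", k)
  }
  out
}

#' Write a phantom series to a directory
#'
#' Writes each frame as a numbered 8-bit greyscale PNG plus a ground-truth
#' JSON (designed transition intensities, truth areas, detached centers),
#' ready for [run_timecourse()] or the command-line tool.
#'
#' @param frames list returned by [generate_time_course()].
#' @param dir output directory (created if needed).
#' @return Invisibly, the PNG paths.
#' @export
write_phantom_series <- function(frames, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(length(frames))
  for (k in seq_along(frames)) {
    f <- frames[[k]]
    paths[k] <- file.path(dir, sprintf("frame_%02d.png", k))
    png::writePNG(f$micrograph$pixels / 255, paths[k])
    jsonlite::write_json(
      list(truth_areas = as.list(f$truth$truth_areas),
           designed_transition_intensities =
             as.list(f$truth$designed_transition_intensities),
           detached_centers = f$truth$detached_centers),
      file.path(dir, sprintf("frame_%02d_truth.json", k)),
      auto_unbox = TRUE, digits = NA)
  }
  invisible(paths)
}
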