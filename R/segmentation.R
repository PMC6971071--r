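#' Binarize a micrograph at an intensity cutoff
#'
#' Foreground (cell-covered) is every pixel with intensity less than or
#' equal to the cutoff — the object is dark on a bright background, and
#' ties go to the darker region so a cutoff read at a zone transition is
#' included in it.
#'
#' @param m a [micrograph()].
#' @param cutoff intensity in \[0, 255\].
#' @return Logical matrix (`TRUE` = foreground).
#' @export
binarize <- function(m, cutoff) {
  stopifnot(inherits(m, "micrograph"))
  check_scalar_number(cutoff, "cutoff")
  if (cutoff < 0 || cutoff > 255)
    abort_validation("`cutoff` must lie in [0, 255]")
  m$pixels <= cutoff
}

#' Label 8-connected foreground components
#'
#' @param mask logical matrix.
#' @return Integer matrix: 0 = background, components numbered from 1 in
#'   order of first appearance.
#' @export
label_components <- function(mask) {
  check_mask(mask)
  label_components_cpp(mask)
}

#' Remove small particles from a binary mask
#'
#' Drops 8-connected foreground components whose pixel area is below
#' `min_area`, the headless counterpart of running a particle analyzer
#' with a minimum-size cut to discard debris and noise specks.
#'
#' @param mask logical matrix.
#' @param min_area minimum component area in pixels squared (>= 0).
#' @return Logical matrix with small components removed.
#' @export
filter_particles <- function(mask, min_area) {
  check_mask(mask)
  check_scalar_number(min_area, "min_area")
  if (min_area < 0)
    abort_validation("`min_area` must be >= 0")
  if (min_area <= 1 || !any(mask)) return(mask)
  lab <- label_components_cpp(mask)
  sizes <- tabulate(lab[lab > 0L])
  keep <- which(sizes >= min_area)
  out <- matrix(lab %in% keep & lab > 0L, nrow(mask), ncol(mask))
  out
}

#' Crack-length perimeter of a binary mask
#'
#' Counts the unit edges between a foreground pixel and a background (or
#' out-of-image) pixel: the total length of the boundary "cracks" between
#' pixels, an exactly defined integer. All downstream uses are ratios
#' (relative perimeter), which are insensitive to the perimeter
#' convention as long as one is used throughout.
#'
#' @param mask nonempty logical matrix.
#' @return Boundary length in pixel units (integer-valued).
#' @export
perimeter <- function(mask) {
  check_mask(mask)
  if (!any(mask))
    abort_validation("cannot compute the perimeter of an empty mask")
  nr <- nrow(mask); nc <- ncol(mask)
  # adjacent foreground pairs share an interior edge (counted once per pair)
  vert <- sum(mask[-nr, , drop = FALSE] & mask[-1L, , drop = FALSE])
  horiz <- sum(mask[, -nc, drop = FALSE] & mask[, -1L, drop = FALSE])
  4L * sum(mask) - 2L * (vert + horiz)
}

#' Segment a micrograph into core, intermediate, and edge zones
#'
#' Applies the three cutoffs of a [threshold_set()] to produce nested
#' binary masks: `mask_all` is the particle-filtered cell-covered area,
#' `mask_intermediate` and `mask_core` are the darker cutoffs intersected
#' with it, so nesting holds by construction. Subareas are set
#' differences: the edge is cell-covered but not intermediate, the
#' intermediate region is intermediate but not core.
#'
#' @param m a [micrograph()].
#' @param t a [threshold_set()].
#' @param min_area minimum particle area in pixels squared retained in
#'   `mask_all` (default 50).
#' @return A `segmentation_result`: masks (`mask_all`,
#'   `mask_intermediate`, `mask_core`), subareas in pixels squared
#'   (`area_all`, `area_intermediate_region`, `area_edge`, `area_core`),
#'   `perimeter_all`, the `centroid` of `mask_all` (row, col), and the
#'   input calibration/label.
#' @export
segment <- function(m, t, min_area = 50) {
  stopifnot(inherits(m, "micrograph"), inherits(t, "threshold_set"))
  mask_all <- filter_particles(binarize(m, t$t_all), min_area)
  if (!any(mask_all))
    abort_segmentation("no cell-covered area detected after particle filtering")
  mask_intermediate <- binarize(m, t$t_intermediate) & mask_all
  mask_core <- binarize(m, t$t_core) & mask_intermediate
  area_all <- sum(mask_all)
  area_intermediate <- sum(mask_intermediate)
  area_core <- sum(mask_core)
  idx <- which(mask_all, arr.ind = TRUE)
  structure(
    list(mask_all = mask_all,
         mask_intermediate = mask_intermediate,
         mask_core = mask_core,
         area_all = area_all,
         area_intermediate_region = area_intermediate - area_core,
         area_edge = area_all - area_intermediate,
         area_core = area_core,
         perimeter_all = perimeter(mask_all),
         centroid = c(row = mean(idx[, 1L]), col = mean(idx[, 2L])),
         thresholds = t,
         pixel_size = m$pixel_size,
         frame_label = m$frame_label),
    class = "segmentation_result"
  )
}

#' @export
print.segmentation_result <- function(x, ...) {
  cat(sprintf("<segmentation_result>%s\n",
              if (nzchar(x$frame_label)) paste0(" frame '", x$frame_label, "'") else ""))
  cat(sprintf("  areas (px^2): all %d = core %d + intermediate %d + edge %d\n",
              x$area_all, x$area_core, x$area_intermediate_region, x$area_edge))
  cat(sprintf("  perimeter %d px, centroid (%.1f, %.1f)\n",
              x$perimeter_all, x$centroid[1L], x$centroid[2L]))
  invisible(x)
}
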