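#' Compute the full metrics row for one segmented frame
#'
#' @param s [segment()] result for the frame.
#' @param s_ref [segment()] result for the reference frame.
#' @param min_size minimum detached-component area in pixels squared.
#' @return One-row `data.frame` of invasion metrics.
#' @export
frame_metrics <- function(s, s_ref, min_size = 20) {
  idx <- invasion_indices(s)
  sd_ <- shape_descriptors(s$mask_all)
  t <- s$thresholds
  data.frame(
    frame_label = s$frame_label,
    t_all = t$t_all, t_intermediate = t$t_intermediate, t_core = t$t_core,
    area_core = s$area_core,
    area_intermediate_region = s$area_intermediate_region,
    area_edge = s$area_edge,
    area_all = s$area_all,
    perimeter = s$perimeter_all,
    index_A = idx$index_A,
    index_B = idx$index_B,
    relative_area = relative_metric(s$area_all, s_ref$area_all),
    relative_perimeter = relative_metric(s$perimeter_all, s_ref$perimeter_all),
    max_invasion_length = max_invasion_length(s, s_ref) *
      (if (is.null(s$pixel_size)) 1 else s$pixel_size),
    n_endpoint_voxels = count_endpoint_voxels(s$mask_all),
    n_detached_cells = count_detached_cells(s$mask_all, min_size),
    volume = volume_from_area(s$area_all, s$pixel_size),
    roundness = sd_$roundness,
    equivalent_diameter = sd_$equivalent_diameter *
      (if (is.null(s$pixel_size)) 1 else s$pixel_size),
    stringsAsFactors = FALSE
  )
}

#' Analyze a time-course image series end to end
#'
#' Batch pipeline mirroring macro-driven analysis of an invasion-assay
#' time course: thresholds are detected once on the reference frame (or
#' taken from `thresholds`) and applied to every frame, so all frames of
#' one experiment share one threshold set; relative area and perimeter
#' are computed against the reference frame.
#'
#' @param input either a directory of single-frame TIFF/PNG images
#'   (lexicographic file order = time order) or a character vector of
#'   image paths, or a list of [micrograph()] objects.
#' @param reference index (or frame label) of the reference frame used
#'   for threshold detection and relative metrics; default the first
#'   frame.
#' @param window profile smoothing window in pixels (default 20).
#' @param min_prominence derivative-peak prominence (default 0.5).
#' @param min_area particle filter for the cell-covered mask (default 50
#'   px^2).
#' @param min_size minimum detached-component size (default 20 px^2).
#' @param orientation,bar_width profile bar orientation and perpendicular
#'   width (defaults horizontal, 10 px).
#' @param pixel_size optional micrometers per pixel, applied to all
#'   frames.
#' @param thresholds optional [threshold_set()] override; skips
#'   detection.
#' @param per_frame re-detect thresholds on every frame instead of
#'   sharing the reference set (exploratory; default `FALSE`).
#' @param output optional CSV path for the metrics table.
#' @param save_masks optional directory for the three zone masks of each
#'   frame as PNGs.
#' @param threshold_json optional path to write the applied threshold set
#'   as JSON.
#' @param log_file optional path for a plain-text run log recording every
#'   parameter and detected threshold.
#' @return `data.frame` with one metrics row per frame (see
#'   [frame_metrics()] for the columns), invisibly when `output` is
#'   given.
#' @export
run_timecourse <- function(input,
                           reference = 1L,
                           window = 20L,
                           min_prominence = 0.5,
                           min_area = 50,
                           min_size = 20,
                           orientation = "horizontal",
                           bar_width = 10L,
                           pixel_size = NULL,
                           thresholds = NULL,
                           per_frame = FALSE,
                           output = NULL,
                           save_masks = NULL,
                           threshold_json = NULL,
                           log_file = NULL) {
  frames <- load_series(input, pixel_size)
  n <- length(frames)
  if (n < 1L)
    abort_validation("input series contains no readable frames")
  labels <- vapply(frames, function(m) m$frame_label, character(1))
  ref_idx <- resolve_reference(reference, labels)

  if (is.null(thresholds)) {
    p_ref <- extract_profile(frames[[ref_idx]], orientation = orientation,
                             bar_width = bar_width)
    thresholds <- detect_thresholds(p_ref, window = window,
                                    min_prominence = min_prominence)
  } else {
    stopifnot(inherits(thresholds, "threshold_set"))
  }

  seg <- vector("list", n)
  for (k in seq_len(n)) {
    t_k <- if (per_frame && k != ref_idx) {
      p_k <- extract_profile(frames[[k]], orientation = orientation,
                             bar_width = bar_width)
      detect_thresholds(p_k, window = window, min_prominence = min_prominence)
    } else thresholds
    seg[[k]] <- tryCatch(
      segment(frames[[k]], t_k, min_area = min_area),
      error = function(e) abort_segmentation(sprintf(
        "frame '%s': %s", labels[k], conditionMessage(e))))
  }

  rows <- lapply(seq_len(n), function(k)
    frame_metrics(seg[[k]], seg[[ref_idx]], min_size = min_size))
  res <- do.call(rbind, rows)
  rownames(res) <- NULL

  if (!is.null(save_masks)) {
    dir.create(save_masks, showWarnings = FALSE, recursive = TRUE)
    for (k in seq_len(n)) {
      for (lvl in c("all", "intermediate", "core"))
        write_mask(seg[[k]][[paste0("mask_", lvl)]],
                   file.path(save_masks,
                             sprintf("%s_mask_%s.png", labels[k], lvl)))
    }
  }
  if (!is.null(threshold_json)) write_thresholds(thresholds, threshold_json)
  if (!is.null(log_file)) {
    writeLines(c(
      "spheroquant run_timecourse",
      sprintf("frames: %d (%s)", n, paste(labels, collapse = ", ")),
      sprintf("reference: %s (index %d)", labels[ref_idx], ref_idx),
      sprintf("window: %d  min_prominence: %g  min_area: %g  min_size: %g",
              window, min_prominence, min_area, min_size),
      sprintf("orientation: %s  bar_width: %d", orientation, bar_width),
      sprintf("pixel_size: %s",
              if (is.null(pixel_size)) "none" else format(pixel_size)),
      sprintf("thresholds: all %.4f  intermediate %.4f  core %.4f",
              thresholds$t_all, thresholds$t_intermediate, thresholds$t_core),
      sprintf("per_frame: %s", per_frame)
    ), log_file)
  }
  if (!is.null(output)) {
    write_metrics_csv(res, output)
    return(invisible(res))
  }
  res
}

# Accepts a directory, a vector of paths, or a list of micrographs.
load_series <- function(input, pixel_size = NULL) {
  if (is.list(input) && all(vapply(input, inherits, logical(1), "micrograph")))
    return(input)
  if (is.character(input) && length(input) == 1L && dir.exists(input)) {
    input <- sort(list.files(input, pattern = "\\.(png|tif|tiff)$",
                             ignore.case = TRUE, full.names = TRUE))
    if (length(input) == 0L)
      abort_validation("input directory contains no PNG or TIFF frames")
  }
  if (!is.character(input))
    abort_validation("`input` must be a directory, file paths, or micrographs")
  lapply(input, load_micrograph, pixel_size = pixel_size)
}

resolve_reference <- function(reference, labels) {
  if (is.character(reference)) {
    idx <- match(reference, labels)
    if (is.na(idx))
      abort_validation(sprintf("reference frame '%s' not found in the series",
                               reference))
    return(idx)
  }
  idx <- as.integer(reference)
  if (is.na(idx) || idx < 1L || idx > length(labels))
    abort_validation(sprintf("reference index %s is outside 1..%d",
                             as.character(reference), length(labels)))
  idx
}

# Fixed formatting so identical runs produce byte-identical CSVs.
write_metrics_csv <- function(res, path) {
  out <- res
  num <- vapply(out, is.double, logical(1))
  out[num] <- lapply(out[num], function(x) sprintf("%.6f", x))
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
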