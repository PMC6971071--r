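#' Micrograph objects
#'
#' A micrograph is an 8-bit greyscale image: an integer matrix of
#' intensities in \[0, 255\] (rows = image rows, columns = image columns,
#' both 1-based), plus optional physical calibration and a frame label.
#' Brightfield spheroid images are dark objects on a bright background.
#'
#' @param pixels numeric or integer matrix of intensities in \[0, 255\].
#'   Values are rounded to integers.
#' @param pixel_size optional physical length of one pixel side, in
#'   micrometers per pixel. Must be strictly positive when given.
#' @param frame_label free-text identifier for the frame (e.g. `"day 3"`).
#' @return A `micrograph` object: a list with elements `pixels`,
#'   `pixel_size`, and `frame_label`.
#' @export
micrograph <- function(pixels, pixel_size = NULL, frame_label = "") {
  if (!is.matrix(pixels) || !is.numeric(pixels))
    abort_validation("`pixels` must be a numeric matrix")
  if (nrow(pixels) < 1L || ncol(pixels) < 1L)
    abort_validation("micrograph must have at least one row and one column")
  if (anyNA(pixels))
    abort_validation("`pixels` contains NA")
  if (min(pixels) < 0 || max(pixels) > 255)
    abort_validation("pixel intensities must lie in [0, 255]")
  if (!is.null(pixel_size)) {
    check_scalar_number(pixel_size, "pixel_size")
    if (pixel_size <= 0)
      abort_validation("`pixel_size` must be strictly positive")
  }
  storage.mode(pixels) <- "integer"
  structure(
    list(pixels = round_half_up(pixels), pixel_size = pixel_size,
         frame_label = as.character(frame_label)),
    class = "micrograph"
  )
}

# round() in R rounds half to even; image quantization conventionally
# rounds half up, and the examples (full-scale 16-bit -> 255) need it.
round_half_up <- function(x) {
  y <- floor(x + 0.5)
  storage.mode(y) <- "integer"
  y
}

#' @export
print.micrograph <- function(x, ...) {
  cat(sprintf("<micrograph> %d x %d pixels", nrow(x$pixels), ncol(x$pixels)))
  if (!is.null(x$pixel_size))
    cat(sprintf(", %.4g um/pixel", x$pixel_size))
  if (nzchar(x$frame_label)) cat(sprintf(", frame '%s'", x$frame_label))
  cat(sprintf("\n  intensity range [%d, %d]\n",
              min(x$pixels), max(x$pixels)))
  invisible(x)
}

#' @export
dim.micrograph <- function(x) dim(x$pixels)

#' Read a micrograph from a TIFF or PNG file
#'
#' Reads a single-page TIFF (8- or 16-bit) or PNG (8-bit grey or RGB) and
#' normalizes it to 8-bit greyscale. Color images are converted by the
#' standard luminance weighting 0.299 R + 0.587 G + 0.114 B (what ImageJ's
#' weighted 8-bit conversion applies). Higher bit depths are rescaled
#' linearly from their full nominal range to \[0, 255\] — not per-image
#' min/max — so that one threshold set remains comparable across the
#' frames of a time course.
#'
#' @param path path to a `.tif`/`.tiff` or `.png` file.
#' @param pixel_size optional micrometers per pixel.
#' @param frame_label frame identifier; defaults to the file name without
#'   extension.
#' @return A [micrograph()].
#' @export
load_micrograph <- function(path, pixel_size = NULL, frame_label = NULL) {
  if (!is.character(path) || length(path) != 1L)
    abort_validation("`path` must be a single file path")
  if (!file.exists(path))
    abort_io(sprintf("cannot read image file '%s': no such file", path))
  ext <- tolower(tools::file_ext(path))
  arr <- tryCatch(
    switch(ext,
      png = png::readPNG(path),
      tif = ,
      tiff = tiff::readTIFF(path),
      abort_io(sprintf("unsupported image format '.%s' for '%s'", ext, path))
    ),
    error = function(e) {
      if (inherits(e, "spheroquant_error")) stop(e)
      abort_io(sprintf("cannot read image file '%s': %s", path,
                       conditionMessage(e)))
    }
  )
  # readPNG/readTIFF scale by the nominal bit-depth range to [0, 1].
  if (length(dim(arr)) == 3L) {
    nch <- dim(arr)[3L]
    grey <- if (nch >= 3L) {
      0.299 * arr[, , 1L] + 0.587 * arr[, , 2L] + 0.114 * arr[, , 3L]
    } else {
      arr[, , 1L]  # grey + alpha: alpha dropped
    }
  } else {
    grey <- arr
  }
  if (length(grey) == 0L || is.null(dim(grey)))
    abort_validation(sprintf("image '%s' has zero size", path))
  if (is.null(frame_label))
    frame_label <- tools::file_path_sans_ext(basename(path))
  micrograph(round_half_up(grey * 255), pixel_size = pixel_size,
             frame_label = frame_label)
}

#' Rectangular crop regions
#'
#' @param row_start,col_start 1-based inclusive offsets of the top-left
#'   pixel of the region.
#' @param row_extent,col_extent number of rows/columns; strictly positive.
#' @return A `crop_region` object.
#' @export
crop_region <- function(row_start, col_start, row_extent, col_extent) {
  for (a in c("row_start", "col_start", "row_extent", "col_extent"))
    check_scalar_number(get(a), a)
  if (row_start < 1 || col_start < 1)
    abort_validation("crop offsets must be >= 1")
  if (row_extent < 1 || col_extent < 1)
    abort_validation("crop extents must be strictly positive")
  structure(list(row_start = as.integer(row_start),
                 col_start = as.integer(col_start),
                 row_extent = as.integer(row_extent),
                 col_extent = as.integer(col_extent)),
            class = "crop_region")
}

#' Crop a micrograph
#'
#' @param m a [micrograph()].
#' @param region a [crop_region()] lying entirely inside `m`.
#' @return The cropped [micrograph()]; calibration and label are preserved.
#' @export
crop <- function(m, region) {
  stopifnot(inherits(m, "micrograph"), inherits(region, "crop_region"))
  r2 <- region$row_start + region$row_extent - 1L
  c2 <- region$col_start + region$col_extent - 1L
  if (r2 > nrow(m$pixels) || c2 > ncol(m$pixels))
    abort_validation(sprintf(
      "crop region [rows %d..%d, cols %d..%d] exceeds image size %d x %d",
      region$row_start, r2, region$col_start, c2,
      nrow(m$pixels), ncol(m$pixels)))
  micrograph(m$pixels[region$row_start:r2, region$col_start:c2, drop = FALSE],
             pixel_size = m$pixel_size, frame_label = m$frame_label)
}

#' Write a binary mask as an 8-bit PNG
#'
#' Foreground pixels are written as 255, background as 0, so the mask
#' round-trips through [load_micrograph()] followed by an intensity > 127
#' cut.
#'
#' @param mask logical matrix.
#' @param path output path ending in `.png`.
#' @export
write_mask <- function(mask, path) {
  check_mask(mask)
  ok <- tryCatch({
    png::writePNG(ifelse(mask, 1, 0), path)
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok))
    abort_io(sprintf("cannot write mask to '%s': %s", path,
                     conditionMessage(ok)))
  invisible(path)
}
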