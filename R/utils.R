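# Internal condition helpers: classed errors so callers can distinguish
# validation problems (bad arguments) from detection failures (unsuitable
# data) and I/O errors.

abort <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "spheroquant_error")))
}

abort_validation <- function(msg) abort(msg, "spheroquant_validation_error")
abort_io <- function(msg) abort(msg, "spheroquant_io_error")
abort_detection <- function(msg) abort(msg, "spheroquant_detection_error")
abort_segmentation <- function(msg) abort(msg, "spheroquant_segmentation_error")

check_mask <- function(mask, arg = "mask") {
  if (!is.matrix(mask) || !is.logical(mask))
    abort_validation(sprintf("`%s` must be a logical matrix", arg))
  if (anyNA(mask))
    abort_validation(sprintf("`%s` contains NA", arg))
  invisible(mask)
}

check_scalar_number <- function(x, arg) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    abort_validation(sprintf("`%s` must be a single finite number", arg))
  invisible(x)
}
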