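#' Read and write images on the 0-255 scale
#'
#' Thin wrappers around PNG I/O. Images are held in memory as H x W x 3
#' double arrays with channels on the 0-255 scale; writing clips, rescales
#' to `[0, 1]` and quantizes, reading undoes the rescale (alpha channels
#' are dropped, grayscale is replicated across channels).
#'
#' @param path File path (PNG).
#' @param image H x W x 3 array, channels 0-255.
#' @return `read_image` returns the image array; `write_image` returns
#'   `path` invisibly.
#' @export
read_image <- function(path) {
  x <- png::readPNG(path)
  if (length(dim(x)) == 2L) x <- array(rep(x, 3L), dim = c(dim(x), 3L))
  if (dim(x)[3L] > 3L) x <- x[, , 1:3, drop = FALSE]
  x * 255
}

#' @rdname read_image
#' @export
write_image <- function(image, path) {
  check_rgb_image(image)
  x <- image
  x[x < 0] <- 0
  x[x > 255] <- 255
  png::writePNG(round(x) / 255, path)
  invisible(path)
}

#' Read the long-format battery voltage table
#'
#' @param path CSV with columns `sample_id`, `class_label`, `r_l_ohm`,
#'   `v_l_mv` and optionally `replicate`.
#' @return Data frame.
#' @export
read_battery_csv <- function(path) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  needed <- c("sample_id", "class_label", "r_l_ohm", "v_l_mv")
  if (!all(needed %in% names(x))) {
    stop("battery CSV missing columns: ",
         paste(setdiff(needed, names(x)), collapse = ", "), call. = FALSE)
  }
  x
}

#' Read the per-fruit feature table
#'
#' @param path CSV with columns `sample_id`, `v_l_mv`, `r_over_g`, `label`.
#' @return Data frame.
#' @export
read_features_csv <- function(path) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  needed <- c("sample_id", "v_l_mv", "r_over_g", "label")
  if (!all(needed %in% names(x))) {
    stop("feature CSV missing columns: ",
         paste(setdiff(needed, names(x)), collapse = ", "), call. = FALSE)
  }
  x
}
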