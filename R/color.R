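#' @keywords internal
check_rgb_image <- function(image) {
  if (!is.array(image) || length(dim(image)) != 3L || dim(image)[3L] != 3L) {
    stop("`image` must be an H x W x 3 numeric array (channels 0-255)",
         call. = FALSE)
  }
  if (!is.numeric(image)) stop("`image` must be numeric", call. = FALSE)
  invisible(image)
}

#' Apply an affine RGB color transform to an image
#'
#' Each pixel `(r, g, b)` is mapped through the 3x4 matrix as
#' `a %*% c(r, g, b, 1)` and the result clipped to `[0, 255]`. Pixel
#' arithmetic stays in floating point; quantization to whole channel values
#' happens only when an image is written to disk.
#'
#' @param image H x W x 3 array, channels on the 0-255 scale.
#' @param transform A [fit_color_transform()] result or a bare 3x4 matrix.
#' @return Corrected image of the same dimensions.
#' @export
apply_color_transform <- function(image, transform) {
  check_rgb_image(image)
  a <- transform_matrix(transform)
  d <- dim(image)
  pix <- cbind(matrix(image, ncol = 3L), 1)
  out <- pix %*% t(a)
  out[out < 0] <- 0
  out[out > 255] <- 255
  array(out, dim = d)
}

#' @keywords internal
transform_matrix <- function(transform) {
  a <- if (inherits(transform, "color_transform")) transform$matrix else transform
  if (!is.matrix(a) || !all(dim(a) == c(3L, 4L)) || any(!is.finite(a))) {
    stop("color transform must be a finite 3 x 4 matrix", call. = FALSE)
  }
  a
}

#' Identity color transform
#' @return A `color_transform` that leaves every pixel unchanged.
#' @export
color_transform_identity <- function() {
  structure(list(matrix = cbind(diag(3), 0), residual_rms = 0),
            class = "color_transform")
}

#' Remove bright background from a fruit image
#'
#' A pixel is background when all three channels exceed the threshold
#' (default 90); such pixels are set to black and excluded from the
#' foreground mask. The rule is idempotent, and mask plus background
#' partition the image.
#'
#' @param image H x W x 3 array, channels on the 0-255 scale.
#' @param threshold Channel value above which (in all three channels) a
#'   pixel counts as background.
#' @return List with `image` (background blacked out) and `mask` (H x W
#'   logical, `TRUE` on foreground).
#' @export
remove_background <- function(image, threshold = 90) {
  check_rgb_image(image)
  bg <- image[, , 1L] > threshold & image[, , 2L] > threshold &
    image[, , 3L] > threshold
  out <- image
  for (ch in 1:3) {
    plane <- out[, , ch]
    plane[bg] <- 0
    out[, , ch] <- plane
  }
  list(image = out, mask = !bg)
}

#' Channel means over a pixel mask
#'
#' Average pixel value per channel: total pixel value divided by the number
#' of pixels, taken over the masked (foreground) region.
#'
#' @param image H x W x 3 array.
#' @param mask Optional H x W logical; defaults to all pixels.
#' @return Named numeric `c(r_ave, g_ave, b_ave)`.
#' @export
average_rgb <- function(image, mask = NULL) {
  check_rgb_image(image)
  d <- dim(image)
  if (is.null(mask)) mask <- matrix(TRUE, d[1L], d[2L])
  if (!is.logical(mask) || !all(dim(mask) == d[1:2])) {
    stop("`mask` must be an H x W logical matrix", call. = FALSE)
  }
  if (!any(mask)) stop("empty mask: no foreground pixels to average", call. = FALSE)
  c(r_ave = mean(image[, , 1L][mask]),
    g_ave = mean(image[, , 2L][mask]),
    b_ave = mean(image[, , 3L][mask]))
}

#' Red/green ripeness color feature
#'
#' The full vision feature pipeline: color-correct the image, black out the
#' bright background, and return the ratio of mean red to mean green over
#' the remaining fruit pixels. Ratioing against green acts as a reference
#' wavelength, in the spirit of remote-sensing vegetation indices, and makes
#' the feature robust to overall brightness.
#'
#' @param image H x W x 3 array.
#' @param transform Optional color transform applied first (`NULL` for
#'   none).
#' @param threshold Background threshold passed to [remove_background()].
#' @param denominator `"foreground"` (default) averages over foreground
#'   pixels only; `"all"` divides channel totals by the full pixel count,
#'   background zeros included.
#' @return Single number `r_ave / g_ave`.
#' @export
color_feature <- function(image, transform = NULL, threshold = 90,
                          denominator = c("foreground", "all")) {
  denominator <- match.arg(denominator)
  check_rgb_image(image)
  if (!is.null(transform)) image <- apply_color_transform(image, transform)
  seg <- remove_background(image, threshold = threshold)
  if (!any(seg$mask)) stop("no foreground pixels after background removal",
                           call. = FALSE)
  avg <- if (denominator == "foreground") {
    average_rgb(seg$image, seg$mask)
  } else {
    average_rgb(seg$image)
  }
  if (avg[["g_ave"]] == 0) stop("undefined color feature: mean green is zero",
                                call. = FALSE)
  unname(avg[["r_ave"]] / avg[["g_ave"]])
}
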