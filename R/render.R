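#' Render a synthetic fruit-and-chart photograph
#'
#' Paints the scene the vision pipeline expects: a bright uniform
#' background, a 16-chip calibration chart placed through a known
#' scale-plus-translation homography, and an elliptical fruit whose red and
#' green channels realize a prescribed R/G ratio. An affine illumination
#' transform (the "unknown lighting") is then applied to the whole frame,
#' followed by optional per-pixel Gaussian noise. Both the illumination
#' matrix and the fruit mask are returned as ground truth, so correction
#' and feature extraction can be validated as a round trip.
#'
#' Fruit pixels keep a dark blue channel so they survive background
#' thresholding; background and chip colors stay bright in every channel so
#' both are removed by it. If the drawn illumination nevertheless pushes any
#' fruit pixel past the background condition, the render is flagged
#' `contaminated` rather than rejected.
#'
#' @param r_over_g Target red/green ratio of the fruit's painted color.
#' @param layout A [chart_layout()].
#' @param illumination `"random"` (draw mild gains, cross-talk and offsets),
#'   `"identity"`, or an explicit 3x4 matrix.
#' @param size `c(height, width)` in pixels.
#' @param seed Integer seed for the illumination draw and noise; `NULL`
#'   leaves RNG state alone.
#' @param noise_sd Per-pixel Gaussian channel noise, 0-255 units.
#' @param bg_value Background channel value before illumination.
#' @param fruit_g,fruit_b Green and blue channel values of the painted
#'   fruit; red is `r_over_g * fruit_g`.
#' @return List with `image` (H x W x 3 double array) and `truth`
#'   (illumination matrix, fruit mask, true ratio, homography, layout,
#'   contamination flag).
#' @export
render_fruit_image <- function(r_over_g, layout = chart_layout(),
                               illumination = "random",
                               size = c(120, 160), seed = NULL,
                               noise_sd = 0, bg_value = 200,
                               fruit_g = 110, fruit_b = 45) {
  stopifnot(is.numeric(r_over_g), length(r_over_g) == 1L, r_over_g > 0)
  if (!is.null(seed)) set.seed(seed)
  h <- as.integer(size[1L]); w <- as.integer(size[2L])
  if (h < 20L || w < 30L) stop("image too small to hold fruit and chart",
                               call. = FALSE)
  img <- array(bg_value, dim = c(h, w, 3L))

  # chart occupies a square on the right half
  side <- min(h, floor(w / 2)) - 8L
  if (side < 16L) stop("frame too small for the chart", call. = FALSE)
  x0 <- w - side - 4L
  y0 <- floor((h - side) / 2)
  hom <- homography_scale_translate(side, side, x0, y0)
  for (i in seq_len(nrow(layout$chips))) {
    ch <- layout$chips[i, ]
    tl <- apply_homography(hom, cbind(ch$cx - ch$half, ch$cy - ch$half))
    br <- apply_homography(hom, cbind(ch$cx + ch$half, ch$cy + ch$half))
    cols <- max(1L, round(tl[1L])):min(w, round(br[1L]))
    rows <- max(1L, round(tl[2L])):min(h, round(br[2L]))
    img[rows, cols, 1L] <- ch$ref_r
    img[rows, cols, 2L] <- ch$ref_g
    img[rows, cols, 3L] <- ch$ref_b
  }

  # elliptical fruit on the left
  cx <- 0.25 * w; cy <- 0.5 * h
  ax <- 0.18 * w; ay <- 0.30 * h
  colg <- matrix(rep(seq_len(w), each = h), h, w)
  rowg <- matrix(rep(seq_len(h), times = w), h, w)
  fruit_mask <- ((colg - cx) / ax)^2 + ((rowg - cy) / ay)^2 <= 1
  if (!any(fruit_mask)) stop("degenerate fruit region: zero pixels",
                             call. = FALSE)
  fruit_rgb <- c(r_over_g * fruit_g, fruit_g, fruit_b)
  for (chn in 1:3) {
    plane <- img[, , chn]
    plane[fruit_mask] <- fruit_rgb[chn]
    img[, , chn] <- plane
  }

  a <- resolve_illumination(illumination)
  img <- apply_color_transform(img, a)
  if (noise_sd > 0) {
    img <- img + array(stats::rnorm(length(img), 0, noise_sd), dim = dim(img))
    img[img < 0] <- 0
    img[img > 255] <- 255
  }
  contaminated <- {
    rmat <- img[, , 1L][fruit_mask]
    gmat <- img[, , 2L][fruit_mask]
    bmat <- img[, , 3L][fruit_mask]
    any(rmat > 90 & gmat > 90 & bmat > 90)
  }
  list(image = img,
       truth = list(illumination = a, fruit_mask = fruit_mask,
                    r_over_g = r_over_g, homography = hom, layout = layout,
                    contaminated = contaminated))
}

#' @keywords internal
resolve_illumination <- function(illumination) {
  if (is.matrix(illumination)) {
    return(transform_matrix(illumination))
  }
  if (identical(illumination, "identity")) {
    return(cbind(diag(3), 0))
  }
  if (identical(illumination, "random")) {
    a <- matrix(stats::runif(9, -0.02, 0.02), 3L, 3L)
    diag(a) <- stats::runif(3, 0.9, 1.1)
    return(cbind(a, stats::runif(3, -6, 6)))
  }
  stop("`illumination` must be \"random\", \"identity\" or a 3x4 matrix",
       call. = FALSE)
}
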