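#' Sixteen-chip color chart layout
#'
#' Describes the calibration chart that accompanies each fruit photograph: a
#' 4 x 4 grid of 16 color chips in a unit chart frame, each with a known
#' reference color captured under ideal lighting. Positions are expressed in
#' chart coordinates; a homography maps them into any particular image, the
#' role an AR marker plays in a live camera setup.
#'
#' The default reference palette spans the RGB cube while keeping every
#' channel at 115 or above, so a chart photographed against a bright
#' background is removed together with the background by the intensity
#' threshold and never contaminates the fruit's foreground mask.
#'
#' @param half Half-width of a chip cell in chart units.
#' @return Object of class `chart_layout` with a `chips` data frame
#'   (`chip_id`, `cx`, `cy`, `half`, `ref_r`, `ref_g`, `ref_b`).
#' @export
chart_layout <- function(half = 0.09) {
  centers <- seq(0.125, 0.875, by = 0.25)
  pos <- expand.grid(cx = centers, cy = centers)
  pal <- default_chip_palette()
  structure(
    list(chips = data.frame(
      chip_id = seq_len(16L),
      cx = pos$cx, cy = pos$cy, half = half,
      ref_r = pal[, 1L], ref_g = pal[, 2L], ref_b = pal[, 3L]
    )),
    class = "chart_layout"
  )
}

#' @keywords internal
default_chip_palette <- function() {
  # 16 bright pastels: three levels per channel restricted to [115, 200]
  lv <- c(115, 157, 200)
  g <- as.matrix(expand.grid(r = lv, g = lv, b = lv))
  idx <- round(seq(1, nrow(g), length.out = 16))
  p <- g[idx, , drop = FALSE]
  dimnames(p) <- NULL
  p
}

#' Reference chip colors of a layout
#' @param layout A [chart_layout()].
#' @return Data frame `chip_id`, `r`, `g`, `b` in layout order.
#' @export
chips_reference <- function(layout) {
  stopifnot(inherits(layout, "chart_layout"))
  with(layout$chips,
       data.frame(chip_id = chip_id, r = ref_r, g = ref_g, b = ref_b))
}

#' Write / read a chart layout as JSON
#' @param layout A [chart_layout()].
#' @param path File path.
#' @return `read_chart_layout` returns a `chart_layout`;
#'   `write_chart_layout` returns `path` invisibly.
#' @export
write_chart_layout <- function(layout, path) {
  stopifnot(inherits(layout, "chart_layout"))
  jsonlite::write_json(layout$chips, path, dataframe = "columns", digits = NA)
  invisible(path)
}

#' @rdname write_chart_layout
#' @export
read_chart_layout <- function(path) {
  chips <- as.data.frame(jsonlite::read_json(path, simplifyVector = TRUE))
  needed <- c("chip_id", "cx", "cy", "half", "ref_r", "ref_g", "ref_b")
  if (!all(needed %in% names(chips))) {
    stop("layout JSON missing fields: ",
         paste(setdiff(needed, names(chips)), collapse = ", "), call. = FALSE)
  }
  if (nrow(chips) != 16L) stop("a chart layout must have exactly 16 chips",
                               call. = FALSE)
  structure(list(chips = chips[order(chips$chip_id), ]), class = "chart_layout")
}

#' Homography helpers
#'
#' `homography_scale_translate` builds the 3x3 projective matrix for an
#' axis-aligned placement of the unit chart frame at a pixel rectangle;
#' `apply_homography` maps chart-frame points (columns `x`, `y`) to pixel
#' coordinates.
#'
#' @param sx,sy Scale factors (chart unit -> pixels).
#' @param tx,ty Pixel offsets.
#' @return 3x3 matrix, or an n x 2 matrix of mapped points.
#' @export
homography_scale_translate <- function(sx, sy, tx, ty) {
  matrix(c(sx, 0, 0, 0, sy, 0, tx, ty, 1), nrow = 3L)
}

#' @rdname homography_scale_translate
#' @param h 3x3 homography matrix.
#' @param xy n x 2 matrix of chart-frame coordinates.
#' @export
apply_homography <- function(h, xy) {
  stopifnot(is.matrix(h), all(dim(h) == c(3L, 3L)))
  xy <- rbind(t(xy), 1)
  uvw <- h %*% xy
  t(uvw[1:2, , drop = FALSE] / rep(uvw[3L, ], each = 2L))
}

#' Sample mean chip colors from an image
#'
#' For every chip in the layout, maps the central portion of the chip cell
#' into the image through the homography and averages the RGB values of the
#' covered pixels. Sampling only the central 60% of each cell tolerates
#' edge bleed and slight localization error. Pixels under `exclude_mask`
#' (e.g. a fruit overlapping the chart) are dropped from the average.
#'
#' @param image H x W x 3 array, channels 0-255.
#' @param layout A [chart_layout()].
#' @param homography 3x3 matrix mapping chart coordinates (x right, y down)
#'   to pixel coordinates; defaults to identity, i.e. layout coordinates
#'   already in pixels.
#' @param exclude_mask Optional H x W logical; `TRUE` pixels are excluded.
#' @param frac Fraction of the chip cell sampled (centered).
#' @param grid_n Sampling grid density per chip side.
#' @return Data frame `chip_id`, `r`, `g`, `b` in layout order.
#' @export
extract_chips <- function(image, layout, homography = diag(3),
                          exclude_mask = NULL, frac = 0.6, grid_n = 21L) {
  check_rgb_image(image)
  stopifnot(inherits(layout, "chart_layout"))
  d <- dim(image)
  chips <- layout$chips
  res <- lapply(seq_len(nrow(chips)), function(i) {
    ch <- chips[i, ]
    s <- ch$half * frac
    gx <- seq(ch$cx - s, ch$cx + s, length.out = grid_n)
    gy <- seq(ch$cy - s, ch$cy + s, length.out = grid_n)
    pts <- as.matrix(expand.grid(x = gx, y = gy))
    px <- apply_homography(homography, pts)
    col <- round(px[, 1L]); row <- round(px[, 2L])
    if (any(col < 1 | col > d[2L] | row < 1 | row > d[1L])) {
      stop(sprintf("chip %s maps outside the image", ch$chip_id), call. = FALSE)
    }
    keep <- !duplicated(cbind(row, col))
    row <- row[keep]; col <- col[keep]
    if (!is.null(exclude_mask)) {
      excl <- exclude_mask[cbind(row, col)]
      row <- row[!excl]; col <- col[!excl]
      if (!length(row)) {
        stop(sprintf("chip %s fully occluded by the exclusion mask", ch$chip_id),
             call. = FALSE)
      }
    }
    idx <- cbind(row, col)
    data.frame(chip_id = ch$chip_id,
               r = mean(image[, , 1L][idx]),
               g = mean(image[, , 2L][idx]),
               b = mean(image[, , 3L][idx]))
  })
  do.call(rbind, res)
}

#' Fit the affine color-correction transform
#'
#' Least-squares fit of the 3x4 matrix `a` such that
#' `a %*% c(r_obs, g_obs, b_obs, 1)` best reproduces the reference chip
#' colors: one multiple linear regression per output channel over the 16
#' chip pairs. Applying the result to a target image standardizes its
#' colors against the reference lighting.
#'
#' @param reference Chip colors under reference lighting: data frame with
#'   `r`, `g`, `b` (and optionally `chip_id`), 16 rows in layout order.
#' @param observed Chip colors sampled from the target image, matching row
#'   order.
#' @return Object of class `color_transform`: 3x4 `matrix` (rows map to
#'   corrected R, G, B) and `residual_rms` over all chip channels.
#' @export
fit_color_transform <- function(reference, observed) {
  ref <- as.matrix(reference[, c("r", "g", "b")])
  obs <- as.matrix(observed[, c("r", "g", "b")])
  if (nrow(ref) != 16L || nrow(obs) != 16L) {
    stop("both chip sets must contain exactly 16 chips", call. = FALSE)
  }
  if ("chip_id" %in% names(reference) && "chip_id" %in% names(observed) &&
      !all(reference$chip_id == observed$chip_id)) {
    stop("chip sets are not in matching order", call. = FALSE)
  }
  x <- cbind(obs, 1)
  if (qr(x)$rank < 4L) {
    stop("degenerate chart: observed chips do not span a rank-4 design",
         call. = FALSE)
  }
  fit <- stats::lm.fit(x, ref)
  a <- t(fit$coefficients)
  dimnames(a) <- NULL
  rms <- sqrt(mean(fit$residuals^2))
  structure(list(matrix = a, residual_rms = rms), class = "color_transform")
}

#' @export
print.color_transform <- function(x, ...) {
  cat("<color_transform> 3x4 affine RGB map, residual RMS =",
      format(x$residual_rms, digits = 4), "\n")
  print(round(x$matrix, 4))
  invisible(x)
}
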