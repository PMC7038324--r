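# paints a chart into an existing image with the same axis-aligned geometry
# the extractor assumes; used to build chart fixtures independent of the
# full scene renderer
paint_chart <- function(img, layout, hom) {
  d <- dim(img)
  for (i in seq_len(nrow(layout$chips))) {
    ch <- layout$chips[i, ]
    tl <- apply_homography(hom, cbind(ch$cx - ch$half, ch$cy - ch$half))
    br <- apply_homography(hom, cbind(ch$cx + ch$half, ch$cy + ch$half))
    cols <- max(1, round(tl[1])):min(d[2], round(br[1]))
    rows <- max(1, round(tl[2])):min(d[1], round(br[2]))
    img[rows, cols, 1] <- ch$ref_r
    img[rows, cols, 2] <- ch$ref_g
    img[rows, cols, 3] <- ch$ref_b
  }
  img
}

test_that("apply_color_transform maps pixels affinely and clips", {
  img <- flat_image(c(100, 150, 250))
  expect_equal(apply_color_transform(img, color_transform_identity()), img)

  offset_red <- cbind(diag(3), c(10, 0, 0))
  out <- apply_color_transform(img, offset_red)
  expect_equal(out[1, 1, ], c(110, 150, 250))
  out2 <- apply_color_transform(flat_image(c(250, 0, 0)), offset_red)
  expect_equal(out2[1, 1, 1], 255) # clipped

  zero <- matrix(0, 3, 4)
  expect_true(all(apply_color_transform(img, zero) == 0))
  expect_error(apply_color_transform(img, matrix(0, 2, 4)), "3 x 4")
})

test_that("background removal zeroes bright pixels and partitions the image", {
  img <- flat_image(c(100, 100, 100), 2, 2)
  seg <- remove_background(img)
  expect_true(all(seg$image == 0))
  expect_false(any(seg$mask))

  img2 <- flat_image(c(100, 80, 100), 2, 2)
  seg2 <- remove_background(img2)
  expect_equal(seg2$image, img2)
  expect_true(all(seg2$mask))

  set.seed(601)
  for (i in 1:10) {
    img3 <- array(runif(3 * 20 * 30, 0, 255), dim = c(20, 30, 3))
    seg3 <- remove_background(img3)
    # idempotent on the image (once blacked out, nothing else changes)
    seg4 <- remove_background(seg3$image)
    expect_equal(seg4$image, seg3$image)
    # mask + background partition all pixels
    bg <- img3[, , 1] > 90 & img3[, , 2] > 90 & img3[, , 3] > 90
    expect_true(all(xor(seg3$mask, bg)))
  }
})

test_that("average_rgb equals the direct pixel sum", {
  expect_equal(average_rgb(flat_image(c(120, 60, 30))),
               c(r_ave = 120, g_ave = 60, b_ave = 30))

  two <- array(c(10, 30, 20, 20, 30, 10), dim = c(2, 1, 3))
  expect_equal(unname(average_rgb(two)), c(20, 20, 20))

  set.seed(602)
  img <- array(runif(3 * 8 * 9, 0, 255), dim = c(8, 9, 3))
  mask <- matrix(runif(72) > 0.5, 8, 9)
  got <- average_rgb(img, mask)
  want <- c(r_ave = sum(img[, , 1][mask]) / sum(mask),
            g_ave = sum(img[, , 2][mask]) / sum(mask),
            b_ave = sum(img[, , 3][mask]) / sum(mask))
  expect_equal(got, want)

  expect_error(average_rgb(img, matrix(FALSE, 8, 9)), "empty mask")
})

test_that("extract_chips recovers painted chip colors through a homography", {
  lay <- chart_layout()
  hom <- homography_scale_translate(80, 80, 10, 10)
  img <- paint_chart(array(220, dim = c(100, 100, 3)), lay, hom)
  chips <- extract_chips(img, lay, hom)
  expect_equal(chips$r, lay$chips$ref_r)
  expect_equal(chips$g, lay$chips$ref_g)
  expect_equal(chips$b, lay$chips$ref_b)

  # translated chart with the matching homography gives identical means
  hom2 <- homography_scale_translate(80, 80, 17, 12)
  img2 <- paint_chart(array(220, dim = c(100, 100, 3)), lay, hom2)
  chips2 <- extract_chips(img2, lay, hom2)
  expect_equal(chips2[, c("r", "g", "b")], chips[, c("r", "g", "b")])

  # chart partly outside the image names the offending chip
  hom3 <- homography_scale_translate(80, 80, 60, 10)
  expect_error(extract_chips(img, lay, hom3), "chip .* outside")
})

test_that("excluded pixels are dropped from chip means", {
  lay <- chart_layout()
  hom <- homography_scale_translate(80, 80, 10, 10)
  img <- paint_chart(array(220, dim = c(100, 100, 3)), lay, hom)
  # repaint the top rows of chip 1's cell and mark them excluded: the mean
  # over the remaining region must equal the original flat chip color
  c1 <- lay$chips[1, ]
  ctr <- apply_homography(hom, cbind(c1$cx, c1$cy))
  occl_rows <- 1:floor(ctr[2])
  mask <- matrix(FALSE, 100, 100)
  mask[occl_rows, ] <- TRUE
  img_occl <- img
  for (ch in 1:3) img_occl[occl_rows, , ch] <- 5
  with_mask <- extract_chips(img_occl, lay, hom, exclude_mask = mask)
  expect_equal(unlist(with_mask[1, c("r", "g", "b")], use.names = FALSE),
               c(c1$ref_r, c1$ref_g, c1$ref_b))
  # without the mask the repainted pixels drag the mean down
  without <- extract_chips(img_occl, lay, hom)
  expect_lt(without$r[1], c1$ref_r)
  # full occlusion is an error naming the chip
  mask_all <- matrix(TRUE, 100, 100)
  expect_error(extract_chips(img_occl, lay, hom, exclude_mask = mask_all),
               "occluded")
})

test_that("color transform fit recovers affine maps and matches the oracle", {
  ref <- chips_reference(chart_layout())
  # identity when observed equals reference
  t0 <- fit_color_transform(ref, ref)
  expect_equal(t0$matrix, cbind(diag(3), 0), tolerance = 1e-8)
  expect_lt(t0$residual_rms, 1e-8)

  # exact recovery of a known affine map from noiseless chips
  set.seed(603)
  truth <- cbind(diag(3) + matrix(runif(9, -0.05, 0.05), 3), runif(3, -8, 8))
  obs <- data.frame(chip_id = 1:16,
                    r = runif(16, 20, 240), g = runif(16, 20, 240),
                    b = runif(16, 20, 240))
  mapped <- cbind(as.matrix(obs[, c("r", "g", "b")]), 1) %*% t(truth)
  ref2 <- data.frame(chip_id = 1:16, r = mapped[, 1], g = mapped[, 2],
                     b = mapped[, 3])
  t1 <- fit_color_transform(ref2, obs)
  expect_equal(t1$matrix, truth, tolerance = 1e-6)
  expect_lt(t1$residual_rms, 1e-6)

  # noisy chips: coefficients equal the normal-equations oracle
  ref3 <- ref2
  ref3[, c("r", "g", "b")] <- ref3[, c("r", "g", "b")] +
    matrix(rnorm(48, 0, 3), 16)
  t2 <- fit_color_transform(ref3, obs)
  oracle <- affine_fit_oracle(obs[, c("r", "g", "b")], ref3[, c("r", "g", "b")])
  expect_equal(t2$matrix, unname(oracle), tolerance = 1e-9)

  # degenerate observed chips
  flat <- data.frame(chip_id = 1:16, r = 100, g = 100, b = 100)
  expect_error(fit_color_transform(ref, flat), "degenerate chart")
  expect_error(fit_color_transform(ref[1:10, ], obs), "16 chips")
})

test_that("color feature is the foreground red/green ratio", {
  expect_equal(color_feature(flat_image(c(120, 60, 30))), 2.0)
  expect_equal(color_feature(flat_image(c(80, 80, 200))), 1.0)
  # green-free foreground is undefined
  expect_error(color_feature(flat_image(c(50, 0, 0))), "mean green")
  # fully bright image has no foreground
  expect_error(color_feature(flat_image(c(200, 200, 200))), "foreground")
  # denominator mode: zeroed background dilutes both channels equally,
  # leaving the ratio, but changes the channel means
  img <- flat_image(c(120, 60, 30), 4, 4)
  img[1:2, , ] <- 200 # background half
  expect_equal(color_feature(img, denominator = "foreground"), 2.0)
  expect_equal(color_feature(img, denominator = "all"), 2.0)
})
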