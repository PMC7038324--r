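test_that("cohort generation is deterministic under a fixed seed", {
  a <- generate_cohort(cohort_spec(), seed = 9)
  b <- generate_cohort(cohort_spec(), seed = 9)
  expect_identical(a$samples, b$samples)
  expect_identical(a$voltages, b$voltages)
  expect_identical(a$truth, b$truth)
})

test_that("noiseless cohorts satisfy the voltage divider exactly", {
  spec <- cohort_spec(noise_sigma = 0, ri_sigma = 0, rg_sigma = 0)
  co <- generate_cohort(spec, seed = 4)
  # every stored reading equals the divider applied to the stored circuit
  for (i in seq_len(nrow(co$truth$fruits))) {
    fr <- co$truth$fruits[i, ]
    circ <- battery_circuit(fr$v_i, fr$r_i)
    v <- co$voltages[co$voltages$sample_id == fr$sample_id, ]
    expect_equal(v$v_l_mv, load_voltage(circ, v$r_l_ohm) * 1000)
  }
  # the full pipeline recovers the generator's calibration slope
  f <- fit_moisture_regression(co$samples$v_l_mv, co$samples$moisture_pct)
  expect_equal(f$slope, 1 / spec$vl_line[["slope"]], tolerance = 1e-6)
  expect_equal(f$intercept,
               -spec$vl_line[["intercept"]] / spec$vl_line[["slope"]],
               tolerance = 1e-6)
})

test_that("noiseless voltages stored in ground truth obey the divider even with noise on", {
  co <- generate_cohort(cohort_spec(), seed = 13)
  tv <- co$truth$voltages
  fr <- co$truth$fruits
  want <- mapply(function(id, rl) {
    i <- match(id, fr$sample_id)
    load_voltage(battery_circuit(fr$v_i[i], fr$r_i[i]), rl) * 1000
  }, tv$sample_id, tv$r_l_ohm)
  expect_equal(tv$vl_true_mv, unname(want))
})

test_that("unripe fruit reads higher voltage and the contrast shrinks with load", {
  co <- generate_cohort(cohort_spec(), seed = 21)
  s <- sweep_analysis(co$voltages)
  low <- s$r_l_ohm <= 1e4
  expect_true(all(s$mean_vl_unripe[low] > s$mean_vl_ripe[low]))
  expect_true(all(diff(s$dvl_pct) < 0))
})

test_that("generated moisture values round-trip through labeling", {
  co <- generate_cohort(cohort_spec(), seed = 31)
  expect_equal(as.character(label_ripeness(co$samples$moisture_pct)),
               co$samples$class_label)
  expect_equal(table(factor(co$samples$class_label, ripeness_levels()))[[1]], 21)
  expect_equal(nrow(co$samples), 52)
})

test_that("impossible cohort specifications are rejected", {
  expect_error(cohort_spec(0, 0, 0), "at least one class")
  expect_error(cohort_spec(n_ripe = -1), "non-negative")
  # calibration line exceeding the electromotive force
  expect_error(generate_cohort(cohort_spec(vl_line = c(20, 15)), seed = 1),
               "invalid spec")
  expect_error(generate_cohort(cohort_spec(vl_line = c(-900, 1)), seed = 1),
               "invalid spec")
})

test_that("rendered scenes expose exact chips under identity illumination", {
  rnd <- render_fruit_image(1.45, illumination = "identity", seed = 2)
  lay <- rnd$truth$layout
  chips <- extract_chips(rnd$image, lay, rnd$truth$homography)
  expect_equal(chips$r, lay$chips$ref_r)
  expect_equal(chips$g, lay$chips$ref_g)
  expect_equal(chips$b, lay$chips$ref_b)
  expect_false(rnd$truth$contaminated)
  # the raw feature equals the painted ratio when lighting is ideal
  expect_equal(color_feature(rnd$image), 1.45, tolerance = 1e-9)
})

test_that("fitting on chips inverts a known illumination", {
  truth_a <- cbind(matrix(c(1.06, 0.01, -0.015,
                            0.012, 0.95, 0.008,
                            -0.01, 0.015, 1.04), 3, byrow = TRUE),
                   c(4, -5, 2))
  rnd <- render_fruit_image(1.45, illumination = truth_a, seed = 6)
  lay <- rnd$truth$layout
  obs <- extract_chips(rnd$image, lay, rnd$truth$homography)
  tr <- fit_color_transform(chips_reference(lay), obs)
  corrected <- apply_color_transform(rnd$image, tr)
  chips <- extract_chips(corrected, lay, rnd$truth$homography)
  expect_lt(max(abs(as.matrix(chips[, c("r", "g", "b")]) -
                    as.matrix(chips_reference(lay)[, c("r", "g", "b")]))), 1.0)
  expect_lt(abs(color_feature(rnd$image, tr) - 1.45), 0.02)
})

test_that("degenerate frames and hostile illumination are surfaced", {
  expect_error(render_fruit_image(1.4, size = c(5, 10)), "too small")
  # gains that push the fruit past the background threshold get flagged
  bright <- cbind(diag(3) * 3, 0)
  rnd <- render_fruit_image(1.4, illumination = bright, seed = 1)
  expect_true(rnd$truth$contaminated)
})

test_that("fixture sets are complete and reproducible", {
  out1 <- file.path(tempdir(), "fix1")
  out2 <- file.path(tempdir(), "fix2")
  m1 <- write_fixtures(out1, seed = 5, n_images = 2)
  m2 <- write_fixtures(out2, seed = 5, n_images = 2)
  expect_equal(m1$n_samples, 52)
  expect_true(file.exists(file.path(out1, "samples.csv")))
  expect_true(file.exists(file.path(out1, "voltages.csv")))
  expect_true(file.exists(file.path(out1, "features.csv")))
  expect_true(file.exists(file.path(out1, "layout.json")))
  expect_equal(length(m1$images), 2)
  # same seed, byte-identical outputs
  expect_equal(lapply(m1$files, `[[`, "md5"), lapply(m2$files, `[[`, "md5"))
  # layout JSON round-trips
  lay <- read_chart_layout(file.path(out1, "layout.json"))
  expect_equal(lay$chips$ref_r, chart_layout()$chips$ref_r)
  unlink(c(out1, out2), recursive = TRUE)
})
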