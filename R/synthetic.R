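#' Specification of a synthetic fruit cohort
#'
#' Captures the statistical structure the analysis assumes: moisture drawn
#' uniformly within each ripeness class range; a fruit-battery whose load
#' voltage at a calibration load follows an approximately linear function of
#' moisture, inverted through the voltage divider to an internal resistance
#' that falls as moisture rises; triplicate voltage readings with relative
#' measurement noise; and a red/green color ratio that decreases with
#' moisture (riper fruit is redder), with its own independent noise.
#'
#' Defaults mirror the study conditions: 21 ripe / 15 under-ripe / 16 unripe
#' fruits, class moisture ranges anchored at the 24.3% ripe and 80.1% unripe
#' compositional extremes, a 0.9 V electromotive force, a 1 kOhm calibration
#' load with calibration line `V_L = 20 + 1.9 * moisture` (mV), loads swept
#' from 10 Ohm to 1 MOhm, three replicates per reading, and 10% relative
#' per-replicate measurement noise.
#'
#' @param n_ripe,n_under,n_unripe Class sizes.
#' @param moisture_ranges Named list of `c(lo, hi)` moisture ranges (%) for
#'   `ripe`, `under_ripe`, `unripe`.
#' @param v_i_mean Electromotive force in volts; `v_i_sd` adds optional
#'   fruit-to-fruit jitter (default none).
#' @param v_i_sd Standard deviation of `v_i` across fruits, volts.
#' @param r_cal Calibration load resistance, ohms.
#' @param vl_line `c(intercept, slope)` of the calibration line in mV and
#'   mV/%.
#' @param r_l_values Load resistances swept, ohms.
#' @param replicates Readings per (fruit, load).
#' @param noise_sigma Relative standard deviation of per-replicate
#'   measurement noise on the load voltage.
#' @param ri_sigma Lognormal sdlog of fruit-to-fruit deviation of the
#'   internal resistance from the calibration law (biological scatter).
#' @param rg_anchor_moisture,rg_anchor_ratio Two moisture/ratio anchor
#'   points defining the affine moisture-to-R/G map.
#' @param rg_sigma Standard deviation of noise added to the R/G feature.
#' @param seed Default seed used by [generate_cohort()].
#' @return Object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_ripe = 21, n_under = 15, n_unripe = 16,
                        moisture_ranges = list(ripe = c(24, 30),
                                               under_ripe = c(30, 53),
                                               unripe = c(53, 80.1)),
                        v_i_mean = 0.9, v_i_sd = 0,
                        r_cal = 1000,
                        vl_line = c(intercept = 20, slope = 1.9),
                        r_l_values = c(10, 100, 1e3, 1e4, 1e5, 1e6),
                        replicates = 3,
                        noise_sigma = 0.1,
                        ri_sigma = 0.03,
                        rg_anchor_moisture = c(24, 80.1),
                        rg_anchor_ratio = c(1.8, 0.9),
                        rg_sigma = 0.06,
                        seed = NULL) {
  counts <- c(n_ripe = n_ripe, n_under = n_under, n_unripe = n_unripe)
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("class counts must be non-negative integers", call. = FALSE)
  }
  if (sum(counts) < 1) stop("at least one class count must be positive",
                            call. = FALSE)
  stopifnot(all(c("ripe", "under_ripe", "unripe") %in% names(moisture_ranges)))
  rng <- do.call(rbind, moisture_ranges[c("ripe", "under_ripe", "unripe")])
  if (any(rng < 0) || any(rng > 100) || any(rng[, 1] > rng[, 2])) {
    stop("moisture ranges must be ordered and within [0, 100]", call. = FALSE)
  }
  stopifnot(v_i_mean > 0, v_i_sd >= 0, r_cal > 0, replicates >= 1,
            noise_sigma >= 0, ri_sigma >= 0, rg_sigma >= 0,
            all(r_l_values > 0), length(vl_line) == 2)
  structure(
    list(n_ripe = n_ripe, n_under = n_under, n_unripe = n_unripe,
         moisture_ranges = moisture_ranges, v_i_mean = v_i_mean,
         v_i_sd = v_i_sd, r_cal = r_cal,
         vl_line = c(intercept = unname(vl_line[1L]),
                     slope = unname(vl_line[2L])),
         r_l_values = r_l_values, replicates = replicates,
         noise_sigma = noise_sigma, ri_sigma = ri_sigma,
         rg_anchor_moisture = rg_anchor_moisture,
         rg_anchor_ratio = rg_anchor_ratio, rg_sigma = rg_sigma,
         seed = seed),
    class = "cohort_spec"
  )
}

#' @keywords internal
rg_of_moisture <- function(spec, moisture) {
  m <- spec$rg_anchor_moisture; r <- spec$rg_anchor_ratio
  slope <- (r[2L] - r[1L]) / (m[2L] - m[1L])
  r[1L] + slope * (moisture - m[1L])
}

#' Generate a synthetic fruit cohort with ground truth
#'
#' Draws a cohort according to a [cohort_spec()]. For each fruit: moisture is
#' uniform in its class range; the noiseless load voltage at the
#' calibration load comes from the calibration line; the internal
#' resistance is obtained by inverting the voltage divider,
#' `r_i = r_cal * (v_i / V_cal - 1)`, then perturbed by lognormal
#' fruit-to-fruit scatter (`ri_sigma`, median preserved); noiseless load
#' voltages at every swept load follow the voltage divider exactly from the
#' stored `(v_i, r_i)`; observed replicates add relative Gaussian
#' measurement noise; and the R/G color ratio is an affine, decreasing
#' function of moisture plus independent noise.
#'
#' @param spec A [cohort_spec()].
#' @param seed Integer seed; overrides `spec$seed`. `NULL` leaves the RNG
#'   state alone.
#' @return Object of class `fruit_cohort`: `samples` (per-fruit table with
#'   replicate-averaged calibration-load voltage `v_l_mv`, `r_over_g`,
#'   `moisture_pct`, `class_label`), `voltages` (long table of all replicate
#'   readings), `truth` (per-fruit `v_i`, `r_i`, noiseless voltages per
#'   load, true R/G) and the `spec`.
#' @export
generate_cohort <- function(spec = cohort_spec(), seed = spec$seed) {
  stopifnot(inherits(spec, "cohort_spec"))
  if (!is.null(seed)) set.seed(seed)
  counts <- c(ripe = spec$n_ripe, under_ripe = spec$n_under,
              unripe = spec$n_unripe)
  cls <- rep(names(counts), counts)
  n <- length(cls)
  moisture <- numeric(n)
  for (k in names(counts)) {
    rng <- spec$moisture_ranges[[k]]
    moisture[cls == k] <- stats::runif(sum(cls == k), rng[1L], rng[2L])
  }
  v_i <- rep(spec$v_i_mean, n) +
    if (spec$v_i_sd > 0) stats::rnorm(n, 0, spec$v_i_sd) else 0
  if (any(v_i <= 0)) stop("invalid spec: non-positive electromotive force drawn",
                          call. = FALSE)
  v_cal <- spec$vl_line[["intercept"]] + spec$vl_line[["slope"]] * moisture # mV
  if (any(v_cal <= 0) || any(v_cal >= v_i * 1000)) {
    stop("invalid spec: calibration line yields V_L outside (0, V_i)",
         call. = FALSE)
  }
  r_i <- spec$r_cal * (v_i * 1000 / v_cal - 1)
  if (spec$ri_sigma > 0) {
    r_i <- r_i * stats::rlnorm(n, meanlog = -spec$ri_sigma^2 / 2,
                               sdlog = spec$ri_sigma)
  }
  sample_id <- sprintf("F%03d", seq_len(n))

  # noiseless voltages per load, then observed replicates
  truth_vl <- do.call(rbind, lapply(seq_len(n), function(i) {
    circ <- battery_circuit(v_i[i], r_i[i])
    data.frame(sample_id = sample_id[i], r_l_ohm = spec$r_l_values,
               vl_true_mv = load_voltage(circ, spec$r_l_values) * 1000)
  }))
  reps <- spec$replicates
  voltages <- truth_vl[rep(seq_len(nrow(truth_vl)), each = reps), ]
  voltages$replicate <- rep(seq_len(reps), nrow(truth_vl))
  noise <- if (spec$noise_sigma > 0) {
    stats::rnorm(nrow(voltages), 0, spec$noise_sigma)
  } else 0
  voltages$v_l_mv <- voltages$vl_true_mv * (1 + noise)
  voltages$class_label <- cls[match(voltages$sample_id, sample_id)]
  voltages <- voltages[, c("sample_id", "class_label", "r_l_ohm",
                           "replicate", "v_l_mv")]
  rownames(voltages) <- NULL

  rg_true <- rg_of_moisture(spec, moisture)
  r_over_g <- rg_true + if (spec$rg_sigma > 0) stats::rnorm(n, 0, spec$rg_sigma) else 0

  # replicate-averaged calibration-load voltage as the per-fruit feature
  at_cal <- voltages[voltages$r_l_ohm == spec$r_cal, , drop = FALSE]
  v_feat <- if (nrow(at_cal)) {
    agg <- stats::aggregate(v_l_mv ~ sample_id, data = at_cal, FUN = mean)
    agg$v_l_mv[match(sample_id, agg$sample_id)]
  } else rep(NA_real_, n)

  samples <- data.frame(sample_id = sample_id, class_label = cls,
                        moisture_pct = moisture, v_l_mv = v_feat,
                        r_over_g = r_over_g)
  truth <- list(
    fruits = data.frame(sample_id = sample_id, moisture_pct = moisture,
                        v_i = v_i, r_i = r_i, r_over_g_true = rg_true),
    voltages = truth_vl
  )
  structure(list(samples = samples, voltages = voltages, truth = truth,
                 spec = spec),
            class = "fruit_cohort")
}

#' @export
print.fruit_cohort <- function(x, ...) {
  tab <- table(factor(x$samples$class_label, levels = ripeness_levels()))
  cat(sprintf("<fruit_cohort> %d fruits (%s), %d load resistances, %d replicates\n",
              nrow(x$samples),
              paste(sprintf("%s %d", names(tab), tab), collapse = ", "),
              length(x$spec$r_l_values), x$spec$replicates))
  invisible(x)
}

#' Write a complete synthetic fixture set
#'
#' Emits the default cohort as CSV tables, the chart layout as JSON, a
#' handful of rendered fruit-and-chart images spanning the ripeness stages,
#' and a JSON manifest recording the seed, per-image ground truth and an
#' MD5 checksum per file. Re-running with the same seed reproduces every
#' file byte for byte.
#'
#' @param outdir Output directory, created if needed.
#' @param spec A [cohort_spec()].
#' @param seed Integer seed for cohort and renders.
#' @param n_images Number of fruit images rendered (spread across classes).
#' @param image_size `c(height, width)` of rendered images.
#' @return The manifest, invisibly; also written as `manifest.json`.
#' @export
write_fixtures <- function(outdir, spec = cohort_spec(), seed = 1,
                           n_images = 6, image_size = c(120, 160)) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(outdir)) stop("cannot create output directory: ", outdir,
                                call. = FALSE)
  cohort <- generate_cohort(spec, seed = seed)
  layout <- chart_layout()
  paths <- character(0)
  wr <- function(obj, name, writer) {
    p <- file.path(outdir, name)
    writer(obj, p)
    paths <<- c(paths, p)
    p
  }
  wr(cohort$samples, "samples.csv",
     function(o, p) utils::write.csv(o, p, row.names = FALSE))
  wr(cohort$voltages, "voltages.csv",
     function(o, p) utils::write.csv(o, p, row.names = FALSE))
  feats <- data.frame(sample_id = cohort$samples$sample_id,
                      v_l_mv = cohort$samples$v_l_mv,
                      r_over_g = cohort$samples$r_over_g,
                      label = cohort$samples$class_label)
  wr(feats, "features.csv",
     function(o, p) utils::write.csv(o, p, row.names = FALSE))
  wr(layout, "layout.json", write_chart_layout)

  # spread images across the moisture range
  ord <- order(cohort$samples$moisture_pct)
  pick <- ord[unique(round(seq(1, length(ord), length.out = min(n_images, length(ord)))))]
  images <- list()
  for (j in seq_along(pick)) {
    i <- pick[j]
    rnd <- render_fruit_image(cohort$truth$fruits$r_over_g_true[i],
                              layout = layout, illumination = "random",
                              size = image_size, seed = seed + j)
    name <- sprintf("fruit_%s.png", cohort$samples$sample_id[i])
    p <- file.path(outdir, name)
    write_image(rnd$image, p)
    paths <- c(paths, p)
    images[[name]] <- list(sample_id = cohort$samples$sample_id[i],
                           r_over_g_true = cohort$truth$fruits$r_over_g_true[i],
                           illumination = rnd$truth$illumination,
                           contaminated = rnd$truth$contaminated)
  }
  manifest <- list(
    seed = seed,
    n_samples = nrow(cohort$samples),
    class_counts = as.list(table(cohort$samples$class_label)),
    r_l_values = spec$r_l_values,
    images = images,
    files = lapply(stats::setNames(paths, basename(paths)), function(p) {
      list(md5 = unname(tools::md5sum(p)))
    })
  )
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
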