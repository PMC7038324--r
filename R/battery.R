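#' Fruit-battery equivalent circuit
#'
#' A fruit pierced by a zinc and a copper electrode behaves as a galvanic
#' cell: an electromotive force `v_i` in series with an internal resistance
#' `r_i` set by the fruit's electrolyte (moisture) path. Ripe, drier fruit
#' has higher internal resistance than unripe fruit, which is what the
#' load-resistance voltage measurement exploits.
#'
#' @param v_i Electromotive force in volts; must be positive.
#' @param r_i Internal resistance in ohms; must be non-negative.
#' @return An object of class `battery_circuit`.
#' @examples
#' battery_circuit(v_i = 0.9, r_i = 5000)
#' @export
battery_circuit <- function(v_i, r_i) {
  if (!is.numeric(v_i) || length(v_i) != 1L || !is.finite(v_i) || v_i <= 0) {
    stop("`v_i` must be a single positive number (volts)", call. = FALSE)
  }
  if (!is.numeric(r_i) || length(r_i) != 1L || !is.finite(r_i) || r_i < 0) {
    stop("`r_i` must be a single non-negative number (ohms)", call. = FALSE)
  }
  structure(list(v_i = v_i, r_i = r_i), class = "battery_circuit")
}

#' @export
print.battery_circuit <- function(x, ...) {
  cat(sprintf("<battery_circuit> V_i = %g V, R_i = %g Ohm\n", x$v_i, x$r_i))
  invisible(x)
}

#' Load-resistance voltage of a fruit battery
#'
#' Voltage divider across the external load: `V_L = R_L / (R_i + R_L) * V_i`.
#' Strictly increasing in `r_l`, bounded by `v_i`, and exactly `v_i / 2`
#' when the load matches the internal resistance.
#'
#' @param circuit A [battery_circuit()].
#' @param r_l Load resistance(s) in ohms; all must be positive.
#' @return Load voltage(s) in volts, one per element of `r_l`.
#' @examples
#' load_voltage(battery_circuit(1, 1000), 1000) # 0.5 V
#' @export
load_voltage <- function(circuit, r_l) {
  stopifnot(inherits(circuit, "battery_circuit"))
  if (!is.numeric(r_l) || length(r_l) < 1L || any(!is.finite(r_l)) || any(r_l <= 0)) {
    stop("`r_l` must be positive (ohms)", call. = FALSE)
  }
  r_l / (circuit$r_i + r_l) * circuit$v_i
}

#' Percentage voltage difference between ripe and unripe fruit
#'
#' The sensitivity statistic used to shortlist load resistances:
#' `|d_VL| = |(V_L_ripe - V_L_unripe) / V_L_unripe| * 100`. The unripe
#' (wetter, lower internal resistance) voltage is the denominator.
#'
#' @param v_l_ripe,v_l_unripe Load voltages for the ripe and unripe class,
#'   in the same units (the statistic is scale invariant).
#' @return Absolute percentage difference, `>= 0`.
#' @examples
#' voltage_difference_pct(0.24, 1.0) # 76
#' @export
voltage_difference_pct <- function(v_l_ripe, v_l_unripe) {
  if (any(v_l_unripe == 0)) {
    stop("`v_l_unripe` must be non-zero (division by zero in |d_VL|)",
         call. = FALSE)
  }
  abs((v_l_ripe - v_l_unripe) / v_l_unripe) * 100
}

#' Load-resistance sweep analysis
#'
#' For each tested load resistance, averages the ripe and unripe class
#' voltages and computes the percentage difference statistic
#' [voltage_difference_pct()] on the class means. Replicate readings are
#' first averaged within each fruit, then fruit means are averaged within
#' each class. Only ripe and unripe fruit enter the sweep; under-ripe
#' samples are excluded.
#'
#' @param voltages Long-format data frame with columns `sample_id`,
#'   `class_label` (`"ripe"`, `"under_ripe"`, `"unripe"`), `r_l_ohm` and
#'   `v_l_mv`; an optional `replicate` column distinguishes repeated
#'   readings.
#' @param r_l_values Optional vector of load resistances selecting and
#'   ordering the summaries; defaults to the sorted distinct values present.
#' @return Data frame with one row per load resistance: `r_l_ohm`,
#'   `n_ripe`, `n_unripe`, `mean_vl_ripe`, `mean_vl_unripe` (same units as
#'   `v_l_mv`) and `dvl_pct`.
#' @export
sweep_analysis <- function(voltages, r_l_values = NULL) {
  required <- c("sample_id", "class_label", "r_l_ohm", "v_l_mv")
  missing_cols <- setdiff(required, names(voltages))
  if (length(missing_cols)) {
    stop("`voltages` is missing columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  v <- voltages[voltages$class_label %in% c("ripe", "unripe"), , drop = FALSE]
  for (cls in c("ripe", "unripe")) {
    if (!any(v$class_label == cls)) {
      stop(sprintf("no '%s' samples in `voltages`: cannot compute |d_VL|", cls),
           call. = FALSE)
    }
  }
  if (is.null(r_l_values)) {
    r_l_values <- sort(unique(v$r_l_ohm))
  }
  # replicate readings -> per-fruit mean, then per-class mean
  per_fruit <- stats::aggregate(
    v_l_mv ~ sample_id + class_label + r_l_ohm, data = v, FUN = mean
  )
  out <- lapply(r_l_values, function(rl) {
    sub <- per_fruit[per_fruit$r_l_ohm == rl, , drop = FALSE]
    ripe <- sub$v_l_mv[sub$class_label == "ripe"]
    unripe <- sub$v_l_mv[sub$class_label == "unripe"]
    if (!length(ripe) || !length(unripe)) {
      stop(sprintf("load resistance %g Ohm lacks %s samples", rl,
                   if (!length(ripe)) "ripe" else "unripe"), call. = FALSE)
    }
    data.frame(
      r_l_ohm = rl,
      n_ripe = length(ripe),
      n_unripe = length(unripe),
      mean_vl_ripe = mean(ripe),
      mean_vl_unripe = mean(unripe),
      dvl_pct = voltage_difference_pct(mean(ripe), mean(unripe))
    )
  })
  do.call(rbind, out)
}

#' Select the best load resistance
#'
#' Two-stage selection mirroring the measurement protocol: load resistances
#' whose ripe/unripe percentage voltage difference reaches `dvl_floor` are
#' shortlisted, and among those the one with the smallest absolute
#' moisture-regression slope (finest moisture resolution, in %/mV) wins.
#' Ties go to the smallest resistance.
#'
#' @param summaries Sweep summaries from [sweep_analysis()].
#' @param slopes Named numeric vector of regression slopes in %/mV, named by
#'   load resistance in ohms; must cover every shortlisted resistance.
#' @param dvl_floor Shortlist threshold on `dvl_pct`, percent. The default
#'   70 suits field cohorts whose low-resistance plateau sits near 76%;
#'   lower it for cohorts with milder ripe/unripe contrast.
#' @return Selected load resistance in ohms.
#' @examples
#' s <- data.frame(r_l_ohm = c(10, 100, 1000, 10000),
#'                 dvl_pct = c(76, 77, 74, 57))
#' select_load_resistance(s, c(`10` = 31.8, `100` = 3.83, `1000` = 0.517))
#' @export
select_load_resistance <- function(summaries, slopes, dvl_floor = 70) {
  stopifnot(is.data.frame(summaries),
            all(c("r_l_ohm", "dvl_pct") %in% names(summaries)))
  shortlist <- summaries$r_l_ohm[summaries$dvl_pct >= dvl_floor]
  if (!length(shortlist)) {
    stop(sprintf("no load resistance reaches dvl_floor = %g%%", dvl_floor),
         call. = FALSE)
  }
  key <- as.character(shortlist)
  if (!all(key %in% names(slopes))) {
    stop("`slopes` missing entries for shortlisted load resistance(s): ",
         paste(setdiff(key, names(slopes)), collapse = ", "), call. = FALSE)
  }
  s <- abs(slopes[key])
  best <- shortlist[order(s, shortlist)][1L]
  best
}
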