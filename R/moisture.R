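#' Ripeness label from moisture content
#'
#' Oil palm fruit ripeness classes are defined by mesocarp moisture: 30% or
#' less is ripe (oil content peaks around 30%), between 30% and 53% is
#' under-ripe, and above 53% (where maturation starts) is unripe. Both
#' boundaries belong to the lower class: 30 labels as ripe, 53 as
#' under-ripe.
#'
#' @param moisture Moisture content in percent, each value in `[0, 100]`.
#' @return Factor with levels `ripe`, `under_ripe`, `unripe`.
#' @examples
#' label_ripeness(c(25, 30, 40, 53, 60))
#' @export
label_ripeness <- function(moisture) {
  if (!is.numeric(moisture) || any(!is.finite(moisture))) {
    stop("`moisture` must be finite numeric percent values", call. = FALSE)
  }
  if (any(moisture < 0 | moisture > 100)) {
    stop("`moisture` must lie in [0, 100] percent", call. = FALSE)
  }
  lab <- ifelse(moisture <= 30, "ripe",
                ifelse(moisture <= 53, "under_ripe", "unripe"))
  factor(lab, levels = ripeness_levels())
}

#' Ripeness class levels, driest first
#' @return Character vector `c("ripe", "under_ripe", "unripe")`.
#' @export
ripeness_levels <- function() c("ripe", "under_ripe", "unripe")

#' Moisture-on-voltage calibration regression
#'
#' Ordinary least squares of moisture content (%) on load-resistance voltage
#' (mV), the direction whose slope carries the %/mV units used for
#' moisture-resolution analysis.
#'
#' @param v_l Load voltages in mV (predictor).
#' @param moisture Moisture contents in percent (response), same length.
#' @return Object of class `moisture_fit`: `slope` (%/mV), `intercept` (%),
#'   `r_squared`, `n`, plus the fitted [stats::lm] model in `$model`.
#' @examples
#' fit_moisture_regression(c(0, 10), c(10, 20))
#' @export
fit_moisture_regression <- function(v_l, moisture) {
  stopifnot(is.numeric(v_l), is.numeric(moisture))
  if (length(v_l) != length(moisture)) {
    stop("`v_l` and `moisture` must have equal length", call. = FALSE)
  }
  ok <- is.finite(v_l) & is.finite(moisture)
  v_l <- v_l[ok]; moisture <- moisture[ok]
  n <- length(v_l)
  if (n < 2L) stop("need at least 2 complete (v_l, moisture) pairs", call. = FALSE)
  if (length(unique(v_l)) < 2L) {
    stop("degenerate design: all `v_l` values identical", call. = FALSE)
  }
  fit <- stats::lm(moisture ~ v_l)
  rss <- sum(stats::residuals(fit)^2)
  tss <- sum((moisture - mean(moisture))^2)
  r2 <- if (tss <= 0) 1 else max(0, min(1, 1 - rss / tss))
  structure(
    list(slope = unname(stats::coef(fit)[2L]),
         intercept = unname(stats::coef(fit)[1L]),
         r_squared = r2, n = n, model = fit),
    class = "moisture_fit"
  )
}

#' @export
print.moisture_fit <- function(x, ...) {
  cat(sprintf(
    "<moisture_fit> moisture = %.4g + %.3g * V_L  (%%, mV; R^2 = %.3f, n = %d)\n",
    x$intercept, x$slope, x$r_squared, x$n))
  invisible(x)
}

#' ADC voltage resolution
#'
#' Smallest voltage step a successive-approximation converter can resolve:
#' `drive_voltage / 2^bits`, reported in millivolts. A 12-bit converter on a
#' 3.3 V rail resolves about 0.8 mV.
#'
#' @param drive_voltage Converter full-scale (drive) voltage in volts.
#' @param bits Converter resolution in bits, `>= 1`.
#' @return Voltage step in mV.
#' @examples
#' adc_voltage_resolution(3.3, 12) # ~0.8 mV
#' @export
adc_voltage_resolution <- function(drive_voltage = 3.3, bits = 12) {
  stopifnot(is.numeric(drive_voltage), length(drive_voltage) == 1L,
            drive_voltage > 0)
  if (!is.numeric(bits) || length(bits) != 1L || bits < 1 || bits != round(bits)) {
    stop("`bits` must be a whole number >= 1", call. = FALSE)
  }
  drive_voltage / 2^bits * 1000
}

#' Moisture-content resolution of a calibration
#'
#' Converts the calibration slope into the moisture resolution of the
#' digitized measurement: `percent_per_mv = |slope|` and
#' `percent_per_lsb = |slope| * adc_step`, the moisture change corresponding
#' to one converter count. A slope magnitude below 1 %/mV is flagged
#' acceptable: the sensor then resolves moisture to better than one percent
#' per millivolt.
#'
#' @param fit A [fit_moisture_regression()] result, or a bare slope in %/mV.
#' @param adc_step ADC voltage step in mV, e.g. from
#'   [adc_voltage_resolution()].
#' @return List with `percent_per_mv`, `percent_per_lsb` and logical
#'   `acceptable`.
#' @examples
#' moisture_resolution(0.517, adc_voltage_resolution(3.3, 12))
#' @export
moisture_resolution <- function(fit, adc_step) {
  stopifnot(is.numeric(adc_step), length(adc_step) == 1L, adc_step > 0)
  slope <- if (inherits(fit, "moisture_fit")) fit$slope else fit
  stopifnot(is.numeric(slope), length(slope) == 1L, is.finite(slope))
  per_mv <- abs(slope)
  list(percent_per_mv = per_mv,
       percent_per_lsb = per_mv * adc_step,
       acceptable = per_mv < 1)
}
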