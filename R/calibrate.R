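#' Convert reads-per-million to mass
#'
#' `ng = rpm / 1e6 * total_input_ng`: the fraction of reads attributed to a
#' family, applied to the total input mass. 37,000 RPM of a 25 ng sample is
#' 0.925 ng.
#'
#' @param rpm Reads per million (>= 0).
#' @param total_input_ng Total input mass in ng (> 0).
#' @return Mass in ng.
#' @examples
#' rpm_to_ng(37000, 25)
#' @export
rpm_to_ng <- function(rpm, total_input_ng) {
  if (any(rpm < 0)) dorq_error("rpm must be >= 0", "dorq_signal_error")
  if (total_input_ng <= 0) dorq_error("total input mass must be > 0", "dorq_signal_error")
  rpm / 1e6 * total_input_ng
}

#' Fit a spike-in standard-addition calibration
#'
#' Ordinary least squares of signal on spiked mass. The y-intercept is the
#' zero-spike signal; when the signal is reads-per-million and the total
#' input mass is known, the intercept converts directly to the endogenous
#' mass of the anchor family. The classical x-intercept estimate
#' (`-intercept/slope`) is computed alongside.
#'
#' @param series Data frame with columns `spike_ng` and `signal`, or a
#'   `dorq_calibration_series` from [simulate_spike_series()].
#' @param total_input_ng Total input mass in ng (taken from the series object
#'   when available); needed to convert the intercept to mass.
#' @param signal_is_rpm Whether `signal` is reads-per-million (default TRUE);
#'   with raw counts no mass conversion is performed.
#' @return A `dorq_calibration` model object with components `slope`,
#'   `intercept`, `r_squared`, `endogenous_ng`, `x_intercept_ng`, `flags`,
#'   and the underlying `lm` fit. Methods: `print`, `summary`, `coef`,
#'   `predict`, `residuals`, `plot`.
#' @export
fit_standard_addition <- function(series, total_input_ng = NULL,
                                  signal_is_rpm = TRUE) {
  anchor <- NA_character_
  if (inherits(series, "dorq_calibration_series")) {
    if (is.null(total_input_ng)) total_input_ng <- series$total_input_ng
    anchor <- series$anchor_family
    series <- series$series
  }
  if (!all(c("spike_ng", "signal") %in% names(series))) {
    dorq_error("series needs columns spike_ng and signal", "dorq_series_error")
  }
  if (nrow(series) < 2L || length(unique(series$spike_ng)) < 2L) {
    dorq_error("need >= 2 distinct spike levels", "dorq_degenerate_series_error")
  }
  fit <- lm(signal ~ spike_ng, data = series)
  cf <- coef(fit)
  flags <- character(0L)
  if (var(series$signal) == 0) {
    r2 <- 0
    flags <- c(flags, "zero_signal_variance")
  } else {
    r2 <- stats::cor(series$signal, series$spike_ng)^2
  }
  intercept <- unname(cf[1L])
  slope <- unname(cf[2L])
  endogenous_ng <- NA_real_
  if (signal_is_rpm && !is.null(total_input_ng)) {
    endogenous_ng <- rpm_to_ng(max(intercept, 0), total_input_ng)
  }
  if (intercept < 0) flags <- c(flags, "negative_intercept")
  x_int <- if (slope != 0) -intercept / slope else NA_real_
  structure(
    list(slope = slope, intercept = intercept, r_squared = r2,
         endogenous_ng = endogenous_ng,
         x_intercept_ng = x_int,
         total_input_ng = total_input_ng,
         anchor_family = anchor,
         flags = flags,
         series = series,
         model = fit),
    class = "dorq_calibration"
  )
}

#' @export
print.dorq_calibration <- function(x, ...) {
  cat("standard-addition calibration fit\n")
  if (!is.na(x$anchor_family)) cat(sprintf("anchor family: %s\n", x$anchor_family))
  cat(sprintf("slope     %.4g signal/ng\n", x$slope))
  cat(sprintf("intercept %.4g signal at zero spike\n", x$intercept))
  cat(sprintf("R^2       %.4f\n", x$r_squared))
  if (!is.na(x$endogenous_ng)) {
    cat(sprintf("endogenous mass %.4g ng (of %.4g ng total input)\n",
                x$endogenous_ng, x$total_input_ng))
  }
  if (length(x$flags)) cat("flags:", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}

#' @export
summary.dorq_calibration <- function(object, ...) {
  print(object)
  cat("\nunderlying linear model:\n")
  print(summary(object$model))
  invisible(object)
}

#' @export
coef.dorq_calibration <- function(object, ...) {
  c(intercept = object$intercept, slope = object$slope)
}

#' @export
predict.dorq_calibration <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(predict(object$model))
  if (is.numeric(newdata)) newdata <- data.frame(spike_ng = newdata)
  predict(object$model, newdata = newdata)
}

#' @export
residuals.dorq_calibration <- function(object, ...) {
  residuals(object$model)
}

#' @export
plot.dorq_calibration <- function(x, ...) {
  plot(x$series$spike_ng, x$series$signal,
       xlab = "spiked mass [ng]", ylab = "signal",
       main = "standard addition", pch = 19, ...)
  abline(x$intercept, x$slope, col = "grey40")
  points(0, x$intercept, col = "red", pch = 1, cex = 1.5)
  invisible(x)
}

#' Absolute masses for a whole pool from one calibrated anchor
#'
#' Once one family's absolute mass is known (from standard addition), every
#' other family's mass follows from the relative abundances:
#' `ng_f = anchor_ng * fraction_f / fraction_anchor`. Mass ratios equal
#' fraction ratios exactly and the anchor recovers `anchor_ng` exactly.
#'
#' @param ab A `dorq_abundance` table.
#' @param anchor_family Name of the calibrated family (count must be > 0).
#' @param anchor_ng Its absolute mass in ng.
#' @return Data frame `name, ng`.
#' @export
absolute_pool <- function(ab, anchor_family, anchor_ng) {
  tab <- ab$table
  i <- match(anchor_family, tab$name)
  if (is.na(i) || tab$count[i] == 0L) {
    dorq_error("anchor family absent or has zero counts", "dorq_anchor_missing_error")
  }
  data.frame(
    name = tab$name,
    ng = anchor_ng * tab$fraction / tab$fraction[i],
    stringsAsFactors = FALSE
  )
}
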