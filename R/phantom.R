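#' Zero-intercept linear regression of measured vs expected values
#'
#' Regression through the origin (slope = sum(xy) / sum(x^2)), as
#' appropriate when both variables are exactly zero before any absorber is
#' added. The F statistic and coefficient of determination use the
#' no-intercept conventions (df1 = 1, df2 = n - 1, R^2 = 1 - SSres /
#' sum(y^2)); residual normality is checked with a Shapiro-Wilk test.
#'
#' @param expected Expected values (regressor), per cm.
#' @param measured Measured values (response), per cm.
#' @return Object of class `origin_regression`: `slope`, `r_squared`,
#'   `f_stat`, `df1`, `df2`, `p_value`, `residuals`, `shapiro_p`, `n`.
#' @export
regress_through_origin <- function(expected, measured) {
  if (length(expected) != length(measured))
    stop("'expected' and 'measured' must have equal length")
  if (length(expected) < 3) stop("need at least 3 points")
  if (all(expected == 0)) stop("degenerate regressor: all expected values are 0")
  fit <- stats::lm(measured ~ 0 + expected)
  sm <- summary(fit)
  res <- stats::residuals(fit)
  structure(
    list(slope = unname(stats::coef(fit)[1]),
         r_squared = sm$r.squared,
         f_stat = unname(sm$fstatistic[1]),
         df1 = unname(sm$fstatistic[2]),
         df2 = unname(sm$fstatistic[3]),
         p_value = stats::pf(sm$fstatistic[1], sm$fstatistic[2],
                             sm$fstatistic[3], lower.tail = FALSE),
         residuals = unname(res),
         shapiro_p = stats::shapiro.test(res)$p.value,
         n = length(expected)),
    class = "origin_regression"
  )
}

#' Run the phantom titration validation analysis
#'
#' For every titration step the per-frame absorption change is computed
#' against the baseline measurement set (frame intensity over baseline mean
#' intensity, baseline-set pathlength), converted per frame and then
#' averaged over the step's frames; the step means are regressed through
#' the origin on the expected values from the ink dilution arithmetic.
#'
#' With `pathlength_mode = "chord"` each frame's absorption change uses the
#' trapezoid of the baseline and instantaneous pathlengths (the latter from
#' the frame's own mean time of flight), which removes the Beer-Lambert
#' linearization curvature at the large end of the titration.
#'
#' @param series A `phantom_series` from [generate_phantom_series()].
#' @param n_tissue Refractive index used for the pathlength.
#' @param pathlength_mode `"baseline"` (fixed baseline pathlength, the
#'   in-vivo protocol) or `"chord"`.
#' @return List of class `phantom_result`: `regression`
#'   ([regress_through_origin()] output), `steps` (data frame with expected
#'   and measured delta_mua and the per-frame SD), `pathlength` (cm).
#' @export
phantom_pipeline <- function(series, n_tissue = series$scene$n_tissue,
                             pathlength_mode = c("baseline", "chord")) {
  pathlength_mode <- match.arg(pathlength_mode)
  if (nrow(series$steps) < 3)
    stop("need at least 3 titration steps for the regression")
  base <- series$baseline_stack
  I_base <- rowSums(base$counts)
  I0 <- mean(I_base)
  base_hist <- list(counts = colSums(base$counts),
                    bin_centers = base$bin_centers,
                    bin_width = base$bin_width)
  p0 <- pathlength(base_hist, series$irf, n_tissue)$p
  if (p0 <= 0) stop("baseline pathlength is not positive")

  tm_irf <- mean_time_of_flight(series$irf)
  cn <- nirs_constants$c_vacuum / n_tissue
  meas <- t(vapply(series$step_stacks, function(st) {
    att <- log(I0 / rowSums(st$counts))
    dmua <- if (pathlength_mode == "baseline") att / p0 else {
      tm <- as.vector(st$counts %*% st$bin_centers) / rowSums(st$counts)
      att / ((p0 + cn * (tm - tm_irf)) / 2)
    }
    c(mean(dmua), stats::sd(dmua))
  }, numeric(2)))

  steps <- series$steps
  steps$measured_delta_mua <- meas[, 1]
  steps$measured_sd <- meas[, 2]
  reg <- regress_through_origin(steps$expected_delta_mua,
                                steps$measured_delta_mua)
  structure(list(regression = reg, steps = steps, pathlength = p0),
            class = "phantom_result")
}
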