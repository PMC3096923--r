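#' Linear peak-area response of a ligand
#'
#' Peak area = `slope * quantity + intercept`, valid up to `linear_upper`
#' pmol loaded. Intercepts may be negative (observed for one benzylamine
#' derivative); every quantification-validity threshold therefore uses the
#' *absolute* value of the intercept.
#'
#' @param slope Peak-area units per pmol, > 0.
#' @param intercept Peak-area units; may be negative.
#' @param linear_upper Upper limit of linearity in pmol, > 0 (30 pmol for all
#'   biotin derivatives of the model system).
#' @param r_squared Coefficient of determination of the calibration fit.
#' @return An object of class `linear_response`.
#' @export
linear_response <- function(slope, intercept, linear_upper = 30,
                            r_squared = NA_real_) {
  check_number(slope, "slope", lower = 0, allow_zero_lower = FALSE)
  check_number(intercept, "intercept")
  check_number(linear_upper, "linear_upper", lower = 0, allow_zero_lower = FALSE)
  structure(list(slope = slope, intercept = intercept,
                 linear_upper = linear_upper, r_squared = r_squared),
            class = "linear_response")
}

#' @export
print.linear_response <- function(x, ...) {
  cat(sprintf("Linear response: area = %.4g * pmol + %.4g (linear to %.3g pmol%s)\n",
              x$slope, x$intercept, x$linear_upper,
              if (is.na(x$r_squared)) "" else sprintf(", R^2 = %.4f", x$r_squared)))
  invisible(x)
}

#' Predict a peak area from a loaded quantity
#'
#' Mean response is `slope * q + intercept`; quantities beyond the linear
#' range are flagged (attribute `in_range`) and the area saturates at
#' `slope * linear_upper + intercept` rather than erroring, because the
#' composition optimizers intentionally probe beyond range. Noise is
#' multiplicative log-normal with coefficient of variation `noise_cv`
#' (mean-preserving).
#'
#' @param response A [linear_response()].
#' @param quantity Loaded quantity in pmol (vectorized, each >= 0).
#' @param noise_cv Coefficient of variation of the multiplicative noise;
#'   0 disables noise.
#' @param seed Optional integer seed applied locally.
#' @return Numeric areas with a logical attribute `in_range`.
#' @examples
#' r <- linear_response(862.1, 322.1)
#' predict_area(r, 4 * 322.1 / 862.1)  # exactly five times the intercept
#' @export
predict_area <- function(response, quantity, noise_cv = 0, seed = NULL) {
  stopifnot(inherits(response, "linear_response"))
  check_numeric_vec(quantity, "quantity", lower = 0)
  check_number(noise_cv, "noise_cv", lower = 0)
  in_range <- quantity <= response$linear_upper
  q_eff <- pmin(quantity, response$linear_upper)
  area <- response$slope * q_eff + response$intercept
  if (noise_cv > 0) {
    sdlog <- sqrt(log(1 + noise_cv^2))
    area <- with_seed(seed,
      area * exp(stats::rnorm(length(area), 0, sdlog) - sdlog^2 / 2))
  }
  structure(area, in_range = in_range)
}

#' Invert a peak area to a loaded quantity
#'
#' Full inversion is `(area - intercept)/slope`. When all four areas of a
#' candidate/reference pair exceed five times the absolute intercepts (a
#' prerequisite of the area-ratio estimator), the intercept can be neglected
#' and the inversion becomes `area/slope`.
#'
#' @param response A [linear_response()].
#' @param area Peak area(s).
#' @param neglect_intercept If `TRUE`, return `area/slope`.
#' @return Quantity in pmol.
#' @export
quantify <- function(response, area, neglect_intercept = FALSE) {
  stopifnot(inherits(response, "linear_response"))
  check_numeric_vec(area, "area")
  if (neglect_intercept) return(area / response$slope)
  if (any(area < response$intercept))
    stop_mixscreen("area below the intercept cannot be inverted",
                   "mixscreen_quantification_error")
  (area - response$intercept) / response$slope
}

#' Fit a linear peak-area response by ordinary least squares
#'
#' Calibration accepts either pure-compound quantities or amounts of the
#' screening mixture itself as the abscissa (for real mixtures no purified
#' counterpart exists, and the response to mixture amounts stands in). The
#' upper limit of linearity is the largest quantity whose residual stays
#' within `band` residual standard deviations of the straight line.
#'
#' @param quantity Loaded quantities (>= 3 values spanning a nonzero range).
#' @param area Observed peak areas, same length.
#' @param band Residual band (multiples of residual SD) defining the linear
#'   range; default 3.
#' @return A [linear_response()] with `r_squared` filled in.
#' @examples
#' fit_linear_response(1:5, 2 * (1:5) + 1)
#' @export
fit_linear_response <- function(quantity, area, band = 3) {
  check_numeric_vec(quantity, "quantity", lower = 0)
  check_numeric_vec(area, "area")
  if (length(quantity) < 3L || length(area) != length(quantity))
    stop_mixscreen("need at least 3 (quantity, area) pairs",
                   "mixscreen_fit_error")
  if (diff(range(quantity)) <= 0)
    stop_mixscreen("degenerate calibration design: quantities span no range",
                   "mixscreen_fit_error")
  fit <- stats::lm(area ~ quantity)
  res <- stats::residuals(fit)
  sd_res <- stats::sd(res)
  ok <- if (is.na(sd_res) || sd_res == 0) rep(TRUE, length(res))
        else abs(res) <= band * sd_res
  upper <- max(quantity[ok])
  ss_tot <- sum((area - mean(area))^2)
  r2 <- if (ss_tot > 0) 1 - sum(res^2) / ss_tot else NA_real_
  linear_response(slope = unname(stats::coef(fit)[2L]),
                  intercept = unname(stats::coef(fit)[1L]),
                  linear_upper = upper, r_squared = r2)
}
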