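#' Smallest injected quantity meeting the five-times-intercept rule
#'
#' The smallest loaded quantity `q` with `slope * q + intercept >=
#' area_multiple * |intercept|`: `4 * intercept / slope` for a positive
#' intercept, `6 * |intercept| / slope` for a negative one, and the
#' calibration floor when the threshold degenerates to zero.
#'
#' @param response A [linear_response()].
#' @param intercept_floor Minimum quantity reported when the intercept-based
#'   threshold vanishes (defaults to 0.5 pmol, a typical smallest calibrated
#'   quantity).
#' @param area_multiple Intercept multiple; default 5.
#' @return Quantity in pmol.
#' @export
min_injected_quantity <- function(response, intercept_floor = 0.5,
                                  area_multiple = 5) {
  stopifnot(inherits(response, "linear_response"))
  check_number(intercept_floor, "intercept_floor", lower = 0)
  q <- (area_multiple * abs(response$intercept) - response$intercept) /
    response$slope
  if (response$intercept <= 0) q <- max(q, intercept_floor)
  max(q, if (response$intercept == 0) intercept_floor else 0)
}

#' Minimum target quantity, parameter-dependent approach
#'
#' For each ligand of interest the chain runs: minimum quantity in the
#' injection ([min_injected_quantity()]); scaled to the whole extract by
#' `extract_volume / injection_volume`; divided by the recovery ratio to get
#' the minimum amount that must be bound in the system; divided by the
#' binding-site density to get the minimum target suspension volume. The sum
#' over all same-site ligands of one screening mixture is the optimized
#' quantity, and `safety_factor` times that is the practical quantity. Full
#' precision is carried throughout; rounding is a display concern (see
#' [print.target_sizing()]).
#'
#' @param calibration Calibration data.frame (slope, intercept, linear_upper,
#'   RR per ligand) restricted to the ligands of one screening mixture.
#' @param protocol A [processing_protocol()].
#' @param site_density Binding sites per uL of target suspension; default
#'   4.0 pmol/uL (the value consistent with the published sizing of the
#'   model system; the titrated capacity 4.2 pmol/uL may be passed instead).
#' @param intercept_floor See [min_injected_quantity()].
#' @param safety_factor Practical quantity = `safety_factor * summed`
#'   (default 2; the model system used about 4).
#' @param area_multiple Intercept multiple; default 5.
#' @return An object of class `target_sizing`: per-ligand data.frame plus
#'   `summed_min_target_volume` and `practical_target_volume` (uL).
#' @examples
#' fx <- table_fixtures()
#' min_target_parameter_approach(fx$calibration_single[1:2, ],
#'                               processing_protocol())
#' @export
min_target_parameter_approach <- function(calibration, protocol,
                                          site_density = 4.0,
                                          intercept_floor = 0.5,
                                          safety_factor = 2,
                                          area_multiple = 5) {
  calibration <- validate_calibration(calibration)
  stopifnot(inherits(protocol, "processing_protocol"))
  check_number(site_density, "site_density", lower = 0, allow_zero_lower = FALSE)
  check_number(safety_factor, "safety_factor", lower = 0, allow_zero_lower = FALSE)

  scale <- protocol$extract_volume / protocol$injection_volume
  rows <- do.call(rbind, lapply(seq_len(nrow(calibration)), function(i) {
    resp <- calibration_response(calibration, calibration$ligand_id[i])
    rr <- calibration$RR[i]
    q_inj <- min_injected_quantity(resp, intercept_floor, area_multiple)
    q_extract <- q_inj * scale
    q_bound <- q_extract / rr
    v_target <- q_bound / site_density
    data.frame(ligand_id = calibration$ligand_id[i],
               min_quantity_injected = q_inj,
               min_quantity_extract = q_extract,
               min_bound = q_bound,
               min_target_volume = v_target)
  }))
  rownames(rows) <- NULL
  summed <- sum(rows$min_target_volume)
  structure(list(per_ligand = rows,
                 summed_min_target_volume = summed,
                 practical_target_volume = safety_factor * summed,
                 site_density = site_density,
                 safety_factor = safety_factor,
                 protocol = protocol),
            class = "target_sizing")
}

#' @export
#' @rdname min_target_parameter_approach
#' @param x A `target_sizing` object.
#' @param digits Decimals used for the plain-text report; default 1, the
#'   precision of the published sizing table.
#' @param ... Unused.
print.target_sizing <- function(x, digits = 1, ...) {
  cat("Minimum target quantity (parameter-dependent approach)\n")
  df <- x$per_ligand
  df[-1] <- lapply(df[-1], round, digits = digits)
  print(df, row.names = FALSE)
  cat(sprintf("Summed minimum target volume: %.*f uL (site density %.3g pmol/uL)\n",
              digits, x$summed_min_target_volume, x$site_density))
  cat(sprintf("Practical target volume (x%.3g): %.*f uL\n",
              x$safety_factor, digits, x$practical_target_volume))
  invisible(x)
}

#' Minimum target quantity, experimental approach
#'
#' Fits, per ligand, the linear response of its extract peak area to the
#' target volume over a measured series, and solves for the volume at which
#' the area reaches `area_multiple * |intercept|` of that ligand's
#' calibration. The maximum of the per-ligand minima is the optimized
#' quantity for the mixture.
#'
#' @param series A data.frame with columns `target_volume` (mL or uL --
#'   units are the caller's, carried through), `ligand_id`, `area` (extract
#'   areas, replicates as extra rows).
#' @param calibration Calibration data.frame supplying each ligand's
#'   intercept.
#' @param area_multiple Intercept multiple; default 5.
#' @param extrapolate Allow the solved minimum to lie outside the tested
#'   volume range; default `FALSE` (an unbracketed threshold is an error).
#' @return An object of class `target_plan`: per-ligand minima with a
#'   `bracketed` flag, and `optimized` = the maximum minimum.
#' @export
min_target_experimental <- function(series, calibration, area_multiple = 5,
                                    extrapolate = FALSE) {
  if (!is.data.frame(series) ||
      !all(c("target_volume", "ligand_id", "area") %in% names(series)))
    stop_mixscreen("series needs columns target_volume, ligand_id, area",
                   "mixscreen_validation_error")
  calibration <- validate_calibration(calibration)
  ids <- unique(series$ligand_id)
  rows <- do.call(rbind, lapply(ids, function(id) {
    d <- series[series$ligand_id == id, ]
    if (length(unique(d$target_volume)) < 3L)
      stop_mixscreen(sprintf("need >= 3 target volumes for ligand '%s'", id),
                     "mixscreen_planning_error")
    resp <- calibration_response(calibration, id)
    thr <- area_multiple * abs(resp$intercept)
    fit <- stats::lm(area ~ target_volume, data = d)
    b <- stats::coef(fit)
    lo <- min(d$target_volume); hi <- max(d$target_volume)
    if (all(d$area >= thr)) {
      # threshold already met at the smallest tested volume
      return(data.frame(ligand_id = id, min_target_volume = lo,
                        bracketed = FALSE, already_above = TRUE))
    }
    if (b[2L] <= 0)
      stop_mixscreen(sprintf("extract area does not grow with target volume for '%s'", id),
                     "mixscreen_planning_error")
    v <- unname((thr - b[1L]) / b[2L])
    bracketed <- v >= lo && v <= hi
    if (!bracketed && !extrapolate)
      stop_mixscreen(sprintf("threshold volume for '%s' (%.3g) outside the tested range [%.3g, %.3g]",
                             id, v, lo, hi),
                     "mixscreen_planning_error")
    data.frame(ligand_id = id, min_target_volume = v,
               bracketed = bracketed, already_above = FALSE)
  }))
  rownames(rows) <- NULL
  structure(list(per_ligand = rows,
                 optimized = max(rows$min_target_volume),
                 area_multiple = area_multiple),
            class = "target_plan")
}

#' @export
print.target_plan <- function(x, ...) {
  cat("Minimum target quantity (experimental approach)\n")
  print(x$per_ligand, row.names = FALSE, digits = 3)
  cat(sprintf("Optimized target quantity: %.3g (max of per-ligand minima)\n",
              x$optimized))
  invisible(x)
}
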