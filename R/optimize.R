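#' Fine (stepwise) optimization of the mixture composition ratio
#'
#' Runs the assay over a strictly increasing schedule of composition values
#' (typically the candidate concentration scale with the reference fixed, or
#' the reference scale -- see [choose_escalation_axis()]), computing the
#' area-ratio affinity estimate at every step *without* validity gating, plus
#' the prerequisite report and binding ratios. The estimate of a reliable
#' candidate is independent of its concentration, so once the prerequisites
#' hold the trajectory plateaus: `stable_from` is the first step from which
#' every consecutive relative change stays below `plateau_rel_tol` through
#' the end of the schedule, the prerequisites hold throughout, and at least
#' `plateau_len` steps remain. `stable_value` is the mean estimate over the
#' plateau.
#'
#' @param feed A function taking one composition value and returning a
#'   [peak_table()] (usually a closure over a simulated or measured series;
#'   see [scenario_feed()]).
#' @param schedule Strictly increasing numeric vector, length >= 4.
#' @param calibration,reference,candidate,CR Passed to [affinity_screen()].
#' @param plateau_rel_tol Relative-change tolerance defining the plateau;
#'   default 0.10.
#' @param plateau_len Minimum plateau length in steps; default 2.
#' @param ... Further arguments to [affinity_screen()].
#' @return An object of class `optimization_trajectory`: a `steps`
#'   data.frame (composition, estimate, binding ratios, validity),
#'   `stable_from` (index or `NA`) and `stable_value`.
#' @export
fine_optimize <- function(feed, schedule, calibration, reference, candidate,
                          CR = NULL, plateau_rel_tol = 0.10, plateau_len = 2,
                          ...) {
  if (!is.function(feed))
    stop_mixscreen("feed must be a function of the composition value",
                   "mixscreen_validation_error")
  check_numeric_vec(schedule, "schedule")
  if (length(schedule) < 4L || any(diff(schedule) <= 0))
    stop_mixscreen("schedule must be strictly increasing with >= 4 points",
                   "mixscreen_validation_error")
  check_number(plateau_rel_tol, "plateau_rel_tol", lower = 0,
               allow_zero_lower = FALSE)

  steps <- do.call(rbind, lapply(schedule, function(x) {
    pt <- feed(x)
    fit <- affinity_screen(pt, calibration, reference,
                           candidates = candidate, CR = CR, ...)
    e <- fit$estimates[[candidate]]
    data.frame(composition = x, estimate = e$ratio,
               BR_candidate = e$prerequisites$BR[["candidate"]],
               BR_reference = e$prerequisites$BR[["reference"]],
               valid = e$prerequisites$valid)
  }))
  rownames(steps) <- NULL

  n <- nrow(steps)
  relch <- c(NA_real_,
             abs(diff(steps$estimate)) / abs(steps$estimate[-n]))
  stable_from <- NA_integer_
  for (i in seq_len(n - plateau_len + 1L)) {
    tail_ok <- all(steps$valid[i:n]) &&
      (i == n || all(relch[(i + 1L):n] < plateau_rel_tol))
    if (tail_ok) { stable_from <- i; break }
  }
  stable_value <- if (is.na(stable_from)) NA_real_
                  else mean(steps$estimate[stable_from:n])
  structure(list(steps = steps, stable_from = stable_from,
                 stable_value = stable_value,
                 plateau_rel_tol = plateau_rel_tol,
                 plateau_len = plateau_len,
                 candidate = candidate, reference = reference),
            class = "optimization_trajectory")
}

#' @export
print.optimization_trajectory <- function(x, ...) {
  cat(sprintf("Composition-ratio trajectory for %s vs %s (%d steps)\n",
              x$candidate, x$reference, nrow(x$steps)))
  print(x$steps, digits = 3, row.names = FALSE)
  if (is.na(x$stable_from))
    cat("No plateau reached within the schedule.\n")
  else
    cat(sprintf("Stable from step %d; stable relative affinity %.3g\n",
                x$stable_from, x$stable_value))
  invisible(x)
}

#' @export
plot.optimization_trajectory <- function(x, ...) {
  graphics::plot(x$steps$composition, x$steps$estimate, type = "b",
                 pch = ifelse(x$steps$valid, 19, 1), log = "x",
                 xlab = "composition value",
                 ylab = sprintf("relative affinity %s/%s",
                                x$candidate, x$reference), ...)
  if (!is.na(x$stable_from)) {
    graphics::abline(h = x$stable_value, lty = 2)
    graphics::abline(v = x$steps$composition[x$stable_from], lty = 3)
  }
  invisible(x)
}

#' Rough (exponential) optimization of the mixture composition ratio
#'
#' Escalates the composition exponentially (default four-fold per step, the
#' model system's worked step) and stops at the first composition where all
#' prerequisites of the area-ratio estimator hold, returning that
#' composition and its affinity estimate. All attempts are recorded.
#'
#' @param feed As in [fine_optimize()].
#' @param initial_composition Starting composition value, > 0.
#' @param calibration,reference,candidate,CR Passed to [affinity_screen()].
#' @param escalation_factor Multiplier between consecutive steps, > 1;
#'   default 4.
#' @param max_steps Maximum attempts; default 6.
#' @param ... Further arguments to [affinity_screen()].
#' @return An object of class `rough_optimization`: `success`,
#'   `composition`, `estimate` (the winning [affinity_screen()] estimate
#'   entry or the last diagnostics on failure), `step`, and the `attempts`
#'   data.frame.
#' @export
rough_optimize <- function(feed, initial_composition, calibration, reference,
                           candidate, CR = NULL, escalation_factor = 4,
                           max_steps = 6L, ...) {
  if (!is.function(feed))
    stop_mixscreen("feed must be a function of the composition value",
                   "mixscreen_validation_error")
  check_number(initial_composition, "initial_composition", lower = 0,
               allow_zero_lower = FALSE)
  if (!is.numeric(escalation_factor) || escalation_factor <= 1)
    stop_mixscreen("escalation_factor must be > 1", "mixscreen_validation_error")
  max_steps <- as.integer(max_steps)
  if (max_steps < 1L)
    stop_mixscreen("max_steps must be >= 1", "mixscreen_validation_error")

  attempts <- list()
  result <- NULL
  for (k in seq_len(max_steps)) {
    x <- initial_composition * escalation_factor^(k - 1L)
    pt <- feed(x)
    fit <- affinity_screen(pt, calibration, reference,
                           candidates = candidate, CR = CR, ...)
    e <- fit$estimates[[candidate]]
    attempts[[k]] <- data.frame(step = k, composition = x,
                                estimate = e$ratio,
                                BR_candidate = e$prerequisites$BR[["candidate"]],
                                BR_reference = e$prerequisites$BR[["reference"]],
                                valid = e$prerequisites$valid)
    if (e$prerequisites$valid) { result <- e; break }
    result <- e  # keep last diagnostics on failure
  }
  attempts <- do.call(rbind, attempts)
  structure(list(success = result$prerequisites$valid,
                 step = if (result$prerequisites$valid) nrow(attempts)
                        else NA_integer_,
                 composition = if (result$prerequisites$valid)
                   attempts$composition[nrow(attempts)] else NA_real_,
                 estimate = result, attempts = attempts,
                 escalation_factor = escalation_factor,
                 candidate = candidate, reference = reference),
            class = "rough_optimization")
}

#' @export
print.rough_optimization <- function(x, ...) {
  cat(sprintf("Rough composition optimization for %s vs %s (factor %.3g)\n",
              x$candidate, x$reference, x$escalation_factor))
  print(x$attempts, digits = 3, row.names = FALSE)
  if (isTRUE(x$success))
    cat(sprintf("Validated at step %d: relative affinity %.3g\n",
                x$step, x$estimate$ratio))
  else cat("Prerequisites never met within max_steps.\n")
  invisible(x)
}

#' Choose which composition axis to escalate
#'
#' A candidate far stronger than the reference keeps the reference's binding
#' ratio from falling below its limit however much mixture is added; for
#' such candidates the reference concentration is escalated instead of the
#' mixture content.
#'
#' @param pilot_ratio A pilot area-ratio affinity estimate (validity not
#'   required).
#' @param threshold Ratio above which the reference axis is chosen;
#'   default 3. At exactly the threshold the mixture axis is kept (tie goes
#'   to the cheaper axis -- mixture material is assumed more available than
#'   reference compound).
#' @return `"reference"` or `"mixture"`.
#' @export
choose_escalation_axis <- function(pilot_ratio, threshold = 3) {
  check_number(pilot_ratio, "pilot_ratio", lower = 0, allow_zero_lower = FALSE)
  check_number(threshold, "threshold", lower = 0, allow_zero_lower = FALSE)
  if (pilot_ratio > threshold) "reference" else "mixture"
}
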