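#' Forward-simulate the measurement chain into a peak table
#'
#' Given an equilibrium state, the measurement chain is: magnetic recovery of
#' the complexes and extraction (each bound amount survives with its recovery
#' ratio `RR`), concentration into the extract volume, and analysis of a
#' fixed injection volume. Injected quantities are
#' \describe{
#'   \item{extract record}{`bound * RR * injection_volume / extract_volume`}
#'   \item{pmfs record}{`total_conc * injection_volume` (in pmol), i.e. the
#'     mixture is analyzed at the binding-system concentration scale; the
#'     `dilution` column records `system_volume / pmfs_volume`.}
#' }
#'
#' Noise is multiplicative log-normal with total coefficient of variation
#' `noise_cv`, decomposed into a *run* component shared by every peak of one
#' injection (injection-volume and drift errors move all co-analyzed
#' components together, which is why area ratios within a run are far more
#' precise than single areas) and an independent per-peak component;
#' `run_share` is the fraction of log-variance in the shared component.
#'
#' @param state An [solve_equilibrium()] result.
#' @param system The [binding_system()] the state came from.
#' @param protocol A [processing_protocol()].
#' @param calibration Calibration data.frame (see [read_calibration()]) with
#'   a row for every ligand in the system.
#' @param noise_cv Total per-area coefficient of variation (default 0).
#' @param run_share Fraction of noise variance shared within an injection
#'   run; default 0.5.
#' @param replicates Number of injections per solution (the model protocol
#'   analyzes in duplicate); default 2.
#' @param seed Optional integer seed, applied locally.
#' @param contaminants Optional data.frame of spurious components
#'   (`ligand_id, kind, mz, rt_min, area`) appended as extra records, e.g.
#'   particle-derived peaks sharing an m/z channel but resolved by retention
#'   time.
#' @return A [peak_table()].
#' @export
simulate_peak_table <- function(state, system, protocol, calibration,
                                noise_cv = 0, run_share = 0.5,
                                replicates = 2L, seed = NULL,
                                contaminants = NULL) {
  stopifnot(inherits(state, "equilibrium_state"),
            inherits(system, "binding_system"),
            inherits(protocol, "processing_protocol"))
  calibration <- validate_calibration(calibration)
  check_number(noise_cv, "noise_cv", lower = 0)
  check_number(run_share, "run_share", lower = 0, upper = 1)
  replicates <- as.integer(replicates)
  if (replicates < 1L)
    stop_mixscreen("replicates must be >= 1", "mixscreen_validation_error")

  ids <- names(system$ligands)
  missing <- setdiff(ids, calibration$ligand_id)
  if (length(missing))
    stop_mixscreen(sprintf("missing calibration for ligand(s): %s",
                           paste(missing, collapse = ", ")),
                   "mixscreen_validation_error")

  with_seed(seed, {
    sdlog <- if (noise_cv > 0) sqrt(log(1 + noise_cv^2)) else 0
    sd_run <- sdlog * sqrt(run_share)
    sd_peak <- sdlog * sqrt(1 - run_share)

    rows <- list()
    for (kind in c("pmfs", "extract")) {
      for (rep_i in seq_len(replicates)) {
        run_factor <- if (sdlog > 0)
          exp(stats::rnorm(1, 0, sd_run) - sd_run^2 / 2) else 1
        for (id in ids) {
          lig <- system$ligands[[id]]
          resp <- calibration_response(calibration, id)
          rr <- calibration_rr(calibration, id)
          if (kind == "pmfs") {
            q <- injected_pmol(lig$total_conc, protocol$injection_volume)
            dil <- protocol$pmfs_dilution
          } else {
            q <- state$bound[[id]] * rr *
              protocol$injection_volume / protocol$extract_volume
            dil <- 1
          }
          mu <- as.numeric(predict_area(resp, q))
          peak_factor <- if (sdlog > 0)
            exp(stats::rnorm(1, 0, sd_peak) - sd_peak^2 / 2) else 1
          rows[[length(rows) + 1L]] <- data.frame(
            ligand_id = id, kind = kind,
            mz = as.integer(lig$mz %||% NA),
            rt_min = NA_real_, dilution = dil,
            area = mu * run_factor * peak_factor,
            replicate = rep_i)
        }
        if (!is.null(contaminants)) {
          keep <- contaminants$kind == kind
          if (any(keep)) {
            cc <- contaminants[keep, , drop = FALSE]
            rows[[length(rows) + 1L]] <- data.frame(
              ligand_id = cc$ligand_id, kind = kind,
              mz = as.integer(cc$mz), rt_min = cc$rt_min,
              dilution = if (kind == "pmfs") protocol$pmfs_dilution else 1,
              area = cc$area * run_factor, replicate = rep_i)
          }
        }
      }
    }
    peak_table(do.call(rbind, rows), protocol = protocol)
  })
}

#' Recovery ratio from extract and binding-mixture areas
#'
#' Determined with the target in large excess so every ligand molecule is
#' bound: the recovery ratio is the corrected area ratio of the ligand in
#' its concentrated extract to the same ligand in the binding mixture
#' (without particles), after dividing out the concentration effect `CR`.
#' Both areas must satisfy the quantification prerequisites (within linear
#' range, over five times the absolute intercept) when a response is given.
#'
#' @param extract_area Area of the ligand in the concentrated extract.
#' @param mixture_area Area in the binding mixture at the system
#'   concentration scale.
#' @param CR_correction The concentration factor between the two solutions
#'   (the protocol's `CR` when the mixture is measured at system scale).
#' @param response Optional [linear_response()]; when given, both areas are
#'   checked against the five-times-intercept and linear-range conditions.
#' @param area_multiple Threshold multiple of `|intercept|`; default 5.
#' @return The recovery ratio (fraction).
#' @examples
#' recovery_ratio(500, 10, 50)  # 1.0
#' @export
recovery_ratio <- function(extract_area, mixture_area, CR_correction,
                           response = NULL, area_multiple = 5) {
  check_number(extract_area, "extract_area", lower = 0)
  check_number(mixture_area, "mixture_area", lower = 0, allow_zero_lower = FALSE)
  check_number(CR_correction, "CR_correction", lower = 0, allow_zero_lower = FALSE)
  if (!is.null(response)) {
    thr <- area_multiple * abs(response$intercept)
    hi <- response$slope * response$linear_upper + response$intercept
    for (a in c(extract_area, mixture_area)) {
      if (a < thr)
        stop_mixscreen("area below the five-times-intercept threshold; recovery calibration requires valid areas",
                       "mixscreen_prerequisite_error")
      if (a > hi)
        stop_mixscreen("area beyond the linear range; recovery calibration requires valid areas",
                       "mixscreen_prerequisite_error")
    }
  }
  extract_area / (mixture_area * CR_correction)
}
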