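#' Processing protocol: volumes of the pull-down / extraction / analysis chain
#'
#' The concentration ratio `CR` is the system volume over the volume of the
#' concentrated extract of bound ligands (`CR = 1000 * system_volume_mL /
#' extract_volume_uL`). Mixture measurements ("pmfs" records) are interpreted
#' at the binding-system concentration scale: the proper dilution of the
#' screening mixture before direct analysis is `system_volume / pmfs_volume`,
#' which under the model protocol (40 uL mixture, 40 uL extract) is
#' numerically equal to `CR`. This is the only convention under which the
#' binding-ratio formula `A_B / (RR * CR * A_T)` is dimensionally exact; a
#' deviating protocol is corrected explicitly through the peak records'
#' `dilution` field and the estimator's `dilution_correction` argument.
#'
#' @param system_volume Binding-system volume, mL.
#' @param extract_volume Concentrated-extract volume, uL.
#' @param injection_volume Volume loaded per chromatographic analysis, uL.
#' @param pmfs_volume Volume of screening mixture added to the system, uL.
#' @return An object of class `processing_protocol` with the derived `CR`
#'   and `pmfs_dilution`.
#' @examples
#' processing_protocol(2.0, 40, 5, 40)  # CR = 50
#' @export
processing_protocol <- function(system_volume = 2.0, extract_volume = 40,
                                injection_volume = 5, pmfs_volume = 40) {
  check_number(system_volume, "system_volume", lower = 0, allow_zero_lower = FALSE)
  check_number(extract_volume, "extract_volume", lower = 0, allow_zero_lower = FALSE)
  check_number(injection_volume, "injection_volume", lower = 0, allow_zero_lower = FALSE)
  check_number(pmfs_volume, "pmfs_volume", lower = 0, allow_zero_lower = FALSE)
  structure(list(system_volume = system_volume,
                 extract_volume = extract_volume,
                 injection_volume = injection_volume,
                 pmfs_volume = pmfs_volume,
                 CR = 1000 * system_volume / extract_volume,
                 pmfs_dilution = 1000 * system_volume / pmfs_volume),
            class = "processing_protocol")
}

#' @export
print.processing_protocol <- function(x, ...) {
  cat(sprintf(paste0("Protocol: %.3g mL system, %.3g uL extract (CR = %.3g), ",
                     "%.3g uL injected, %.3g uL mixture added\n"),
              x$system_volume, x$extract_volume, x$CR,
              x$injection_volume, x$pmfs_volume))
  invisible(x)
}

#' Per-ligand overall recovery ratios
#'
#' `RR` is the fraction of a bound ligand surviving magnetic recovery,
#' extraction and concentration, determined by calibration with the target in
#' large excess. The estimators only ever use recovery ratios multiplied into
#' area ratios, so the *relative* recovery (candidate over reference) is what
#' carries information.
#'
#' @param RR Named numeric vector of recovery ratios, each in `(0, 1.05]`
#'   (a small calibration overshoot above 1 is tolerated).
#' @return An object of class `recovery_profile`.
#' @export
recovery_profile <- function(RR) {
  check_numeric_vec(RR, "RR", lower = 0, strict = TRUE)
  if (is.null(names(RR)) || any(!nzchar(names(RR))))
    stop_mixscreen("`RR` must be a named vector", "mixscreen_validation_error")
  if (any(RR > 1.05))
    stop_mixscreen("recovery ratios above 1.05 are not plausible",
                   "mixscreen_validation_error")
  structure(list(RR = RR), class = "recovery_profile")
}

#' Relative recovery ratio of each candidate to a reference ligand
#' @param recovery A [recovery_profile()].
#' @param reference Reference ligand id.
#' @return Named vector `RR_X / RR_A`.
#' @export
relative_recovery <- function(recovery, reference) {
  stopifnot(inherits(recovery, "recovery_profile"))
  if (!reference %in% names(recovery$RR))
    stop_mixscreen(sprintf("reference '%s' has no recovery ratio", reference),
                   "mixscreen_validation_error")
  recovery$RR / recovery$RR[[reference]]
}
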