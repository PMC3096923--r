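#' Binding ratio estimated from peak areas
#'
#' `BR = A_B * dilution_correction / (RR * CR * A_T)`: the bound amount read
#' from the extract area, divided by the total amount read from the mixture
#' area, with the recovery ratio and the concentration effect divided out.
#' Slopes cancel because both areas belong to the same ligand; intercepts are
#' neglected, which is what the five-times-intercept prerequisite licenses.
#'
#' @param A_B Extract (bound) peak area.
#' @param A_T Mixture (total) peak area, > 0.
#' @param RR Recovery ratio, > 0.
#' @param CR Concentration ratio, > 0.
#' @param dilution_correction Correction factor for protocols whose mixture
#'   measurement is not at the binding-system concentration scale; default 1.
#' @return The binding-ratio estimate. Values above 1 are physically
#'   implausible and carry attribute `implausible = TRUE` instead of
#'   raising, since noise can produce them near validity boundaries.
#' @examples
#' estimated_binding_ratio(500, 1000, RR = 0.5, CR = 50)  # 0.02
#' @export
estimated_binding_ratio <- function(A_B, A_T, RR, CR, dilution_correction = 1) {
  check_number(A_B, "A_B", lower = 0)
  check_number(RR, "RR", lower = 0, allow_zero_lower = FALSE)
  check_number(CR, "CR", lower = 0, allow_zero_lower = FALSE)
  check_number(dilution_correction, "dilution_correction", lower = 0,
               allow_zero_lower = FALSE)
  if (!is.numeric(A_T) || length(A_T) != 1L || !is.finite(A_T) || A_T <= 0)
    stop_mixscreen("A_T must be positive: binding ratio undefined",
                   "mixscreen_estimation_error")
  br <- A_B * dilution_correction / (RR * CR * A_T)
  if (br > 1) structure(br, implausible = TRUE) else br
}

#' Relative affinity with the ligand-depletion correction
#'
#' The exact mass-action form, valid at any binding ratio provided the pair
#' binds the same sites and both areas are quantifiable: with bound amounts
#' (in mixture-area units) `x = A_BX / (RR_X * CR)` and
#' `a = A_BA / (RR_A * CR)`,
#' \deqn{K_X/K_A = \frac{x}{A_{TX} - x} \cdot \frac{A_{TA} - a}{a}.}
#' The unoccupied-site quantity cancels between the two ligands.
#'
#' @param A_TA,A_TX Mixture-scale areas of reference and candidate.
#' @param A_BA,A_BX Extract areas of reference and candidate.
#' @param RR_A,RR_X Recovery ratios.
#' @param CR Concentration ratio.
#' @return The relative affinity `K_X/K_A`.
#' @export
relative_affinity_eq5 <- function(A_TA, A_TX, A_BA, A_BX, RR_A, RR_X, CR) {
  check_number(CR, "CR", lower = 0, allow_zero_lower = FALSE)
  x <- A_BX / (RR_X * CR)
  a <- A_BA / (RR_A * CR)
  if (!is.finite(x) || !is.finite(a) || a <= 0)
    stop_mixscreen("reference bound area must be positive",
                   "mixscreen_estimation_error")
  if (A_TX <= x || A_TA <= a)
    stop_mixscreen("free amount non-positive: depletion exceeds the measured total",
                   "mixscreen_depletion_error")
  (x / (A_TX - x)) * ((A_TA - a) / a)
}

#' Relative affinity in the low-binding-ratio regime
#'
#' When both binding ratios are below 10%, bound amounts are negligible
#' against totals and the depletion-corrected form reduces to a pure ratio of
#' areas and recovery ratios:
#' \deqn{K_X/K_A = \frac{A_{BX} \, RR_A \, A_{TA}}{A_{BA} \, RR_X \, A_{TX}}.}
#' The concentration ratio cancels -- deliberately, it is not an argument --
#' so the estimate is also invariant to each ligand's response slope and to
#' systematic sensitivity drift.
#'
#' @inheritParams relative_affinity_eq5
#' @return The relative affinity `K_X/K_A`.
#' @examples
#' relative_affinity_eq6(1000, 1000, 200, 400, 1, 1)  # 2
#' @export
relative_affinity_eq6 <- function(A_TA, A_TX, A_BA, A_BX, RR_A, RR_X) {
  vals <- c(A_TA = A_TA, A_TX = A_TX, A_BA = A_BA, A_BX = A_BX,
            RR_A = RR_A, RR_X = RR_X)
  if (any(!is.finite(vals)) || any(vals[c("A_TA", "A_TX", "A_BA", "RR_A", "RR_X")] <= 0))
    stop_mixscreen("areas and recovery ratios must be positive",
                   "mixscreen_estimation_error")
  (A_BX * RR_A * A_TA) / (A_BA * RR_X * A_TX)
}

#' Judge the prerequisites of the area-ratio estimator
#'
#' Four prerequisites license the low-binding-ratio estimator for a
#' candidate/reference pair: (a) both bind the same site(s) -- supplied as
#' external evidence, it cannot be derived from a single peak table; (b) all
#' four areas lie within the ligands' linear ranges; (c) all four areas
#' exceed `area_multiple` times the absolute intercepts; (d) both estimated
#' binding ratios are below `br_limit`. Area conditions are judged before
#' the binding-ratio condition, which itself is computed from the areas.
#'
#' @param pt A [peak_table()] holding pmfs and extract records for both
#'   ligands (replicate areas are averaged).
#' @param calibration Calibration data.frame with responses and recovery
#'   ratios for both ligands.
#' @param candidate,reference Ligand ids.
#' @param CR Concentration ratio; taken from the peak table's protocol
#'   attribute when `NULL`.
#' @param same_site One of `"untested"`, `"supported"`, `"refuted"` --
#'   evidence from competitive displacement and denatured-target controls
#'   (see [judge_binding_site()]). `"untested"` counts as satisfied so that
#'   purely chromatographic validity can be reported on its own.
#' @param area_multiple Intercept multiple for prerequisite (c); default 5.
#' @param br_limit Binding-ratio limit for prerequisite (d); default 0.10.
#' @param dilution_correction Passed to [estimated_binding_ratio()].
#' @return An object of class `prerequisite_report`: flags per area, per
#'   ligand binding ratios, and the overall conjunction `valid`.
#' @export
validate_prerequisites <- function(pt, calibration, candidate, reference,
                                   CR = NULL,
                                   same_site = c("untested", "supported", "refuted"),
                                   area_multiple = 5, br_limit = 0.10,
                                   dilution_correction = 1) {
  stopifnot(inherits(pt, "peak_table"))
  same_site <- match.arg(same_site)
  calibration <- validate_calibration(calibration)
  if (is.null(CR)) {
    proto <- attr(pt, "protocol")
    if (is.null(proto))
      stop_mixscreen("CR not given and the peak table carries no protocol",
                     "mixscreen_validation_error")
    CR <- proto$CR
  }

  need <- expand.grid(ligand = c(candidate, reference),
                      kind = c("pmfs", "extract"), stringsAsFactors = FALSE)
  areas <- mapply(function(l, k) mean_area(pt, l, k), need$ligand, need$kind)
  if (any(is.na(areas)))
    stop_mixscreen(sprintf("missing peak records: %s",
                           paste(sprintf("(%s, %s)", need$ligand[is.na(areas)],
                                         need$kind[is.na(areas)]),
                                 collapse = ", ")),
                   "mixscreen_validation_error")
  names(areas) <- paste(need$ligand, need$kind, sep = ".")

  flag <- function(ligand, kind) {
    r <- calibration_response(calibration, ligand)
    a <- areas[[paste(ligand, kind, sep = ".")]]
    c(above = a >= area_multiple * abs(r$intercept),
      in_range = a <= r$slope * r$linear_upper + r$intercept)
  }
  fl <- rbind(candidate.pmfs = flag(candidate, "pmfs"),
              candidate.extract = flag(candidate, "extract"),
              reference.pmfs = flag(reference, "pmfs"),
              reference.extract = flag(reference, "extract"))

  br <- c(
    candidate = as.numeric(estimated_binding_ratio(
      areas[[paste(candidate, "extract", sep = ".")]],
      areas[[paste(candidate, "pmfs", sep = ".")]],
      calibration_rr(calibration, candidate), CR, dilution_correction)),
    reference = as.numeric(estimated_binding_ratio(
      areas[[paste(reference, "extract", sep = ".")]],
      areas[[paste(reference, "pmfs", sep = ".")]],
      calibration_rr(calibration, reference), CR, dilution_correction)))
  br_ok <- br < br_limit

  valid <- all(fl) && all(br_ok) && same_site != "refuted"
  structure(list(candidate = candidate, reference = reference,
                 same_site = same_site,
                 in_linear_range = fl[, "in_range"],
                 above_intercept_multiple = fl[, "above"],
                 area_multiple = area_multiple,
                 BR = br, br_limit = br_limit, br_below_limit = br_ok,
                 areas = areas, CR = CR, valid = valid),
            class = "prerequisite_report")
}

#' @export
print.prerequisite_report <- function(x, ...) {
  cat(sprintf("Prerequisites for %s vs %s: %s\n", x$candidate, x$reference,
              if (x$valid) "VALID" else "NOT met"))
  cat(sprintf("  same site: %s\n", x$same_site))
  cat(sprintf("  areas >= %g x |intercept|: %s\n", x$area_multiple,
              paste(sprintf("%s=%s", names(x$above_intercept_multiple),
                            x$above_intercept_multiple), collapse = " ")))
  cat(sprintf("  within linear range: %s\n",
              paste(sprintf("%s=%s", names(x$in_linear_range),
                            x$in_linear_range), collapse = " ")))
  cat(sprintf("  binding ratios (< %g): candidate %.3g, reference %.3g\n",
              x$br_limit, x$BR[["candidate"]], x$BR[["reference"]]))
  invisible(x)
}

#' Classify ligands as specific, nonspecific or indeterminate binders
#'
#' Compares binding ratios across three matched measurements: a baseline
#' system, the same system with a large excess of a known same-site
#' competitor, and a denatured-target control. A specific ligand loses at
#' least `reduction_threshold` of its binding ratio under the competitor and
#' shows no detectable binding to the denatured target; a nonspecific ligand
#' changes by less than `negligible_threshold` under the competitor and binds
#' the denatured target unchanged.
#'
#' @param baseline,with_competitor,denatured [peak_table()]s sharing ligand
#'   ids and protocol.
#' @param calibration Calibration data.frame covering all ligands.
#' @param CR Concentration ratio; from the baseline protocol when `NULL`.
#' @param reduction_threshold Minimum relative BR reduction for a specific
#'   call; default 0.40.
#' @param negligible_threshold Maximum relative change counted as negligible;
#'   default 0.10.
#' @return A data.frame with per-ligand binding ratios, relative changes and
#'   the verdict (`specific` / `nonspecific` / `indeterminate`).
#' @export
judge_binding_site <- function(baseline, with_competitor, denatured,
                               calibration, CR = NULL,
                               reduction_threshold = 0.40,
                               negligible_threshold = 0.10) {
  for (pt in list(baseline, with_competitor, denatured))
    stopifnot(inherits(pt, "peak_table"))
  calibration <- validate_calibration(calibration)
  if (is.null(CR)) {
    proto <- attr(baseline, "protocol")
    if (is.null(proto))
      stop_mixscreen("CR not given and the baseline table carries no protocol",
                     "mixscreen_validation_error")
    CR <- proto$CR
  }
  ids <- sort(unique(baseline$ligand_id))
  for (pt in list(with_competitor, denatured))
    if (!setequal(ids, unique(pt$ligand_id)))
      stop_mixscreen("the three peak tables must share ligand ids",
                     "mixscreen_validation_error")

  br_of <- function(pt, id) as.numeric(estimated_binding_ratio(
    mean_area(pt, id, "extract"), mean_area(pt, id, "pmfs"),
    calibration_rr(calibration, id), CR))
  out <- do.call(rbind, lapply(ids, function(id) {
    b0 <- br_of(baseline, id)
    b1 <- br_of(with_competitor, id)
    b2 <- br_of(denatured, id)
    reduction <- if (b0 > 0) 1 - b1 / b0 else NA_real_
    denat_rel <- if (b0 > 0) b2 / b0 else NA_real_
    verdict <- if (is.na(reduction)) "indeterminate"
      else if (reduction >= reduction_threshold &&
               denat_rel <= negligible_threshold) "specific"
      else if (abs(reduction) < negligible_threshold &&
               abs(denat_rel - 1) <= reduction_threshold) "nonspecific"
      else "indeterminate"
    data.frame(ligand_id = id, BR_baseline = b0, BR_competitor = b1,
               BR_denatured = b2, reduction = reduction,
               denatured_relative = denat_rel, verdict = verdict)
  }))
  rownames(out) <- NULL
  out
}
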