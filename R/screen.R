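#' Estimate relative affinities of candidate ligands in a mixture
#'
#' The package's central fitting function. From one peak table (the screening
#' mixture analyzed directly and its concentrated extract of bound ligands)
#' and a calibration table, it computes for every candidate ligand the
#' relative affinity `K_X/K_A` to the reference ligand by the area-ratio
#' estimator ([relative_affinity_eq6()]), the depletion-corrected estimate
#' ([relative_affinity_eq5()]) where computable, the estimated binding
#' ratios, and a full prerequisite report. The area-ratio estimate is
#' reported even when the prerequisites fail -- the composition optimizers
#' need the invalid values -- with the `valid` flag carried alongside.
#'
#' @param pt A [peak_table()]; replicate injections are averaged per
#'   (ligand, kind) before estimation.
#' @param calibration Calibration data.frame (see [read_calibration()]).
#' @param reference Reference ligand id.
#' @param candidates Candidate ids; default all other calibrated ligands
#'   present in the table.
#' @param CR Concentration ratio; from the table's protocol when `NULL`.
#' @param same_site Same-site evidence passed to [validate_prerequisites()].
#' @param area_multiple,br_limit,dilution_correction Threshold settings, see
#'   [validate_prerequisites()].
#' @return An object of class `affinity_screen` with `print`, `summary`,
#'   `coef` and `as.data.frame` methods.
#' @examples
#' fx <- table_fixtures()
#' sc <- generate_scenario(candidates = c(BCHA = 3.23), candidate_conc = 2e-6,
#'                         noise_cv = 0, seed = 1)
#' fit <- affinity_screen(sc$peak_table, sc$calibration, reference = "BMPL")
#' coef(fit)
#' @export
affinity_screen <- function(pt, calibration, reference, candidates = NULL,
                            CR = NULL,
                            same_site = c("untested", "supported", "refuted"),
                            area_multiple = 5, br_limit = 0.10,
                            dilution_correction = 1) {
  stopifnot(inherits(pt, "peak_table"))
  same_site <- match.arg(same_site)
  calibration <- validate_calibration(calibration)
  ids <- unique(pt$ligand_id)
  if (!reference %in% ids)
    stop_mixscreen(sprintf("reference ligand '%s' absent from the peak table",
                           reference),
                   "mixscreen_config_error")
  if (is.null(candidates))
    candidates <- setdiff(intersect(ids, calibration$ligand_id), reference)
  if (length(candidates) == 0L)
    stop_mixscreen("no calibrated candidate ligands in the peak table",
                   "mixscreen_config_error")
  if (is.null(CR)) {
    proto <- attr(pt, "protocol")
    if (is.null(proto))
      stop_mixscreen("CR not given and the peak table carries no protocol",
                     "mixscreen_validation_error")
    CR <- proto$CR
  }

  rr_ref <- calibration_rr(calibration, reference)
  A_TA <- mean_area(pt, reference, "pmfs")
  A_BA <- mean_area(pt, reference, "extract")

  estimates <- lapply(candidates, function(id) {
    prereq <- validate_prerequisites(pt, calibration, id, reference, CR = CR,
                                     same_site = same_site,
                                     area_multiple = area_multiple,
                                     br_limit = br_limit,
                                     dilution_correction = dilution_correction)
    A_TX <- mean_area(pt, id, "pmfs")
    A_BX <- mean_area(pt, id, "extract")
    rr <- calibration_rr(calibration, id)
    eq6 <- relative_affinity_eq6(A_TA, A_TX, A_BA, A_BX, rr_ref, rr)
    eq5 <- tryCatch(
      relative_affinity_eq5(A_TA, A_TX, A_BA, A_BX, rr_ref, rr,
                            CR / dilution_correction),
      mixscreen_error = function(e) NA_real_)
    resp <- calibration_response(calibration, id)
    list(candidate = id, reference = reference,
         ratio = eq6, ratio_eq5 = eq5, method = "eq6",
         prerequisites = prereq,
         diagnostics = list(
           BR = prereq$BR, areas = prereq$areas,
           area_intercept_multiple = c(
             pmfs = A_TX / abs(resp$intercept),
             extract = A_BX / abs(resp$intercept))))
  })
  names(estimates) <- candidates

  structure(list(estimates = estimates, reference = reference, CR = CR,
                 thresholds = list(area_multiple = area_multiple,
                                   br_limit = br_limit,
                                   dilution_correction = dilution_correction),
                 calibration = calibration),
            class = "affinity_screen")
}

#' @export
print.affinity_screen <- function(x, digits = 3, ...) {
  cat(sprintf("Relative affinities vs reference '%s' (CR = %.3g)\n",
              x$reference, x$CR))
  print(as.data.frame(x), digits = digits, row.names = FALSE)
  invisible(x)
}

#' @export
coef.affinity_screen <- function(object, ...) {
  vapply(object$estimates, `[[`, 0, "ratio")
}

#' @export
as.data.frame.affinity_screen <- function(x, ...) {
  do.call(rbind, lapply(unname(x$estimates), function(e)
    data.frame(candidate = e$candidate, reference = e$reference,
               ratio = e$ratio, ratio_eq5 = e$ratio_eq5,
               BR_candidate = e$prerequisites$BR[["candidate"]],
               BR_reference = e$prerequisites$BR[["reference"]],
               valid = e$prerequisites$valid)))
}

#' @export
summary.affinity_screen <- function(object, ...) {
  df <- as.data.frame(object)
  structure(list(table = df, reference = object$reference,
                 thresholds = object$thresholds,
                 n_valid = sum(df$valid)),
            class = "summary.affinity_screen")
}

#' @export
print.summary.affinity_screen <- function(x, ...) {
  cat(sprintf("Affinity screen vs '%s': %d of %d estimates meet all prerequisites\n",
              x$reference, x$n_valid, nrow(x$table)))
  cat(sprintf("Thresholds: areas >= %g x |intercept|, binding ratios < %g\n",
              x$thresholds$area_multiple, x$thresholds$br_limit))
  print(x$table, digits = 3, row.names = FALSE)
  invisible(x)
}

#' Export screen estimates with provenance
#'
#' Writes the estimate table as CSV and a JSON report embedding the
#' thresholds used and md5 checksums of the input files.
#'
#' @param fit An [affinity_screen()] result.
#' @param path Output path without extension; `.csv` and `.json` are added.
#' @param inputs Character vector of input file paths to checksum.
#' @return Invisibly, the two paths written.
#' @export
write_estimates <- function(fit, path, inputs = character()) {
  stopifnot(inherits(fit, "affinity_screen"))
  df <- as.data.frame(fit)
  csv <- paste0(path, ".csv")
  json <- paste0(path, ".json")
  utils::write.csv(df, csv, row.names = FALSE)
  jsonlite::write_json(list(
    reference = fit$reference, CR = fit$CR,
    thresholds = fit$thresholds,
    input_checksums = as.list(file_checksums(inputs)),
    estimates = df
  ), json, auto_unbox = TRUE, digits = NA)
  invisible(c(csv = csv, json = json))
}
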