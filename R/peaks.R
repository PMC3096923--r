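#' Build a peak table
#'
#' The unit of data in this package: one row per detected component per
#' measurement. Two measurement kinds exist -- `"pmfs"` (the screening
#' mixture analyzed directly after proper dilution; areas `A_TA`, `A_TX`)
#' and `"extract"` (the concentrated extract of bound ligands; areas `A_BA`,
#' `A_BX`). The `dilution` column records the factor from the
#' binding-system concentration scale to the injected solution.
#'
#' @param records A data.frame with columns `ligand_id`, `kind`
#'   (`"pmfs"`/`"extract"`), `mz`, `rt_min`, `dilution`, `area`, `replicate`.
#'   Missing `mz`/`rt_min`/`replicate` columns are filled with defaults.
#' @param protocol A [processing_protocol()] attached as an attribute.
#' @return An object of classes `peak_table` and `data.frame`.
#' @export
peak_table <- function(records, protocol = NULL) {
  required <- c("ligand_id", "kind", "dilution", "area")
  if (!is.data.frame(records) || !all(required %in% names(records)))
    stop_mixscreen(sprintf("peak records need columns %s",
                           paste(required, collapse = ", ")),
                   "mixscreen_validation_error")
  if (nrow(records) == 0L)
    stop_mixscreen("empty peak table", "mixscreen_parse_error")
  if (!all(records$kind %in% c("pmfs", "extract")))
    stop_mixscreen("kind must be 'pmfs' or 'extract'", "mixscreen_validation_error")
  if (any(!is.finite(records$area)) || any(records$area < 0))
    stop_mixscreen("areas must be finite and >= 0", "mixscreen_validation_error")
  if (any(!is.finite(records$dilution)) || any(records$dilution <= 0))
    stop_mixscreen("dilutions must be positive", "mixscreen_validation_error")
  if (is.null(records$mz)) records$mz <- NA_integer_
  if (is.null(records$rt_min)) records$rt_min <- NA_real_
  if (is.null(records$replicate)) records$replicate <- 1L
  dup <- duplicated(records[c("ligand_id", "kind", "replicate")])
  if (any(dup))
    stop_mixscreen("at most one record per (ligand_id, kind, replicate)",
                   "mixscreen_validation_error")
  records <- records[c("ligand_id", "kind", "mz", "rt_min",
                       "dilution", "area", "replicate")]
  structure(records, class = c("peak_table", "data.frame"),
            protocol = protocol)
}

#' @export
print.peak_table <- function(x, ...) {
  cat(sprintf("Peak table: %d records, %d ligand(s)\n",
              nrow(x), length(unique(x$ligand_id))))
  print.data.frame(x, row.names = FALSE, ...)
  invisible(x)
}

# mean area over replicate injections for one (ligand, kind); NA if absent
mean_area <- function(pt, ligand_id, kind) {
  sel <- pt$ligand_id == ligand_id & pt$kind == kind
  if (!any(sel)) return(NA_real_)
  mean(pt$area[sel])
}

#' Read and write peak tables as CSV
#'
#' Column layout is fixed: `ligand_id, kind, mz, rt_min, dilution, area,
#' replicate` (comma separator, dot decimal, header required).
#'
#' @param pt A [peak_table()].
#' @param path CSV file path.
#' @param protocol Optional [processing_protocol()] to attach on read.
#' @return `write_peak_table` returns `path` invisibly; `read_peak_table`
#'   returns a [peak_table()].
#' @export
write_peak_table <- function(pt, path) {
  stopifnot(inherits(pt, "peak_table"))
  utils::write.csv(as.data.frame(unclass(pt))[
    c("ligand_id", "kind", "mz", "rt_min", "dilution", "area", "replicate")],
    path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_peak_table
#' @export
read_peak_table <- function(path, protocol = NULL) {
  if (!file.exists(path))
    stop_mixscreen(sprintf("peak table file not found: %s", path),
                   "mixscreen_parse_error")
  df <- tryCatch(utils::read.csv(path, stringsAsFactors = FALSE),
                 error = function(e)
                   stop_mixscreen(sprintf("malformed CSV '%s': %s",
                                          path, conditionMessage(e)),
                                  "mixscreen_parse_error"))
  if (nrow(df) == 0L)
    stop_mixscreen(sprintf("empty peak table: %s", path),
                   "mixscreen_parse_error")
  bad <- which(!is.finite(df$area))
  if (length(bad))
    stop_mixscreen(sprintf("non-numeric area at line %d of %s",
                           bad[1L] + 1L, path),
                   "mixscreen_parse_error")
  peak_table(df, protocol = protocol)
}

#' Read and write calibration tables as CSV
#'
#' One row per ligand with its linear-response parameters and recovery
#' ratio: `ligand_id, mz, slope, intercept, linear_upper, r2, RR`.
#'
#' @param calibration A data.frame in the layout above.
#' @param path CSV file path.
#' @return `write_calibration` returns `path` invisibly; `read_calibration`
#'   returns the validated data.frame.
#' @export
write_calibration <- function(calibration, path) {
  calibration <- validate_calibration(calibration)
  utils::write.csv(calibration, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_calibration
#' @export
read_calibration <- function(path) {
  if (!file.exists(path))
    stop_mixscreen(sprintf("calibration file not found: %s", path),
                   "mixscreen_parse_error")
  validate_calibration(utils::read.csv(path, stringsAsFactors = FALSE))
}

validate_calibration <- function(calibration) {
  required <- c("ligand_id", "slope", "intercept", "linear_upper", "RR")
  if (!is.data.frame(calibration) || !all(required %in% names(calibration)))
    stop_mixscreen(sprintf("calibration needs columns %s",
                           paste(required, collapse = ", ")),
                   "mixscreen_parse_error")
  if (anyDuplicated(calibration$ligand_id))
    stop_mixscreen("duplicated ligand_id in calibration",
                   "mixscreen_validation_error")
  if (any(calibration$slope <= 0) || any(calibration$linear_upper <= 0))
    stop_mixscreen("slopes and linear_upper must be positive",
                   "mixscreen_validation_error")
  if (any(calibration$RR <= 0 | calibration$RR > 1.05))
    stop_mixscreen("recovery ratios must be in (0, 1.05]",
                   "mixscreen_validation_error")
  if (is.null(calibration$mz)) calibration$mz <- NA_integer_
  if (is.null(calibration$r2)) calibration$r2 <- NA_real_
  calibration
}

# extract one ligand's linear_response / RR from a calibration data.frame
calibration_response <- function(calibration, ligand_id) {
  i <- match(ligand_id, calibration$ligand_id)
  if (is.na(i))
    stop_mixscreen(sprintf("no calibration for ligand '%s'", ligand_id),
                   "mixscreen_validation_error")
  linear_response(calibration$slope[i], calibration$intercept[i],
                  calibration$linear_upper[i], calibration$r2[i])
}

calibration_rr <- function(calibration, ligand_id) {
  i <- match(ligand_id, calibration$ligand_id)
  if (is.na(i))
    stop_mixscreen(sprintf("no recovery ratio for ligand '%s'", ligand_id),
                   "mixscreen_validation_error")
  calibration$RR[i]
}
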