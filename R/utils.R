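# internal helpers: argument checks, unit conversions, seeded RNG scopes

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_mixscreen <- function(msg, class) {
  stop(structure(class = c(class, "mixscreen_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

check_number <- function(x, name, lower = -Inf, upper = Inf,
                         allow_zero_lower = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop_mixscreen(sprintf("`%s` must be a single finite number", name),
                   "mixscreen_validation_error")
  ok_low <- if (allow_zero_lower) x >= lower else x > lower
  if (!ok_low || x > upper)
    stop_mixscreen(sprintf("`%s` = %g is outside [%g, %g]", name, x, lower, upper),
                   "mixscreen_validation_error")
  invisible(x)
}

check_numeric_vec <- function(x, name, lower = -Inf, strict = FALSE) {
  if (!is.numeric(x) || length(x) == 0L || any(!is.finite(x)))
    stop_mixscreen(sprintf("`%s` must be finite and non-empty", name),
                   "mixscreen_validation_error")
  bad <- if (strict) any(x <= lower) else any(x < lower)
  if (bad)
    stop_mixscreen(sprintf("`%s` has values %s %g", name,
                           if (strict) "at or below" else "below", lower),
                   "mixscreen_validation_error")
  invisible(x)
}

# amounts are pmol, volumes mL (system) / uL (handling), concentrations mol/L;
# conversions happen once, here
pmol_to_mol <- function(pmol) pmol * 1e-12
mol_to_pmol <- function(mol) mol * 1e12
uL_to_L <- function(uL) uL * 1e-6
mL_to_L <- function(mL) mL * 1e-3

# pmol of ligand injected when `vol_uL` of a solution at `conc_M` is loaded
injected_pmol <- function(conc_M, vol_uL) conc_M * uL_to_L(vol_uL) * 1e12

# evaluate `expr` under a fixed RNG seed without disturbing the caller's
# RNG stream; `seed = NULL` uses the current stream
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# md5 of an in-memory object via its serialized text representation
config_checksum <- function(x) {
  f <- tempfile(fileext = ".yaml")
  on.exit(unlink(f))
  yaml::write_yaml(x, f)
  unname(tools::md5sum(f))
}

file_checksums <- function(paths) {
  paths <- as.character(paths)
  paths <- paths[!is.na(paths) & nzchar(paths) & file.exists(paths)]
  if (length(paths) == 0L) return(character())
  sums <- tools::md5sum(paths)
  stats::setNames(unname(sums), basename(paths))
}
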