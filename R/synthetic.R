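#' Mixture composition specifications
#'
#' Three preparation modes are modeled. Pooling of individual compounds
#' gives exactly controlled molar fractions. A single-candidate parallel
#' combinatorial synthesis (`pcs_single`) gives one candidate of interest at
#' an approximate mass content (taken as 50% unless stated otherwise).
#' Solution-phase simultaneous addition of groups (`spsag`) gives candidate
#' fractions proportional to the input amine fractions times per-amine
#' relative yields, optionally jittered.
#'
#' @param components data.frame with columns `id`, `fraction` (molar,
#'   summing to 1 over all components), `role`.
#' @param preparation `"pooled"`, `"pcs_single"` or `"spsag"`.
#' @param nominal_total_content Mass fraction of the ligands of interest in
#'   the dry mixture.
#' @return An object of class `mixture_spec`.
#' @export
mixture_spec <- function(components,
                         preparation = c("pooled", "pcs_single", "spsag"),
                         nominal_total_content = 1) {
  preparation <- match.arg(preparation)
  if (!is.data.frame(components) ||
      !all(c("id", "fraction", "role") %in% names(components)))
    stop_mixscreen("components needs columns id, fraction, role",
                   "mixscreen_validation_error")
  if (nrow(components) == 0L)
    stop_mixscreen("empty mixture", "mixscreen_validation_error")
  if (abs(sum(components$fraction) - 1) > 1e-9)
    stop_mixscreen("molar fractions must sum to 1", "mixscreen_validation_error")
  if (preparation == "pcs_single" &&
      sum(components$role == "candidate") != 1L)
    stop_mixscreen("pcs_single mixtures have exactly one candidate of interest",
                   "mixscreen_validation_error")
  check_number(nominal_total_content, "nominal_total_content", lower = 0,
               upper = 1, allow_zero_lower = FALSE)
  structure(list(components = components, preparation = preparation,
                 nominal_total_content = nominal_total_content),
            class = "mixture_spec")
}

#' @rdname mixture_spec
#' @param fractions Named molar fractions of the candidates (normalized if
#'   needed).
#' @export
pooled_mixture <- function(fractions) {
  check_numeric_vec(fractions, "fractions", lower = 0, strict = TRUE)
  fractions <- fractions / sum(fractions)
  mixture_spec(data.frame(id = names(fractions), fraction = unname(fractions),
                          role = "candidate"),
               preparation = "pooled")
}

#' @rdname mixture_spec
#' @param id Candidate ligand id.
#' @param content Mass content of the candidate in its reaction mixture;
#'   default 0.5.
#' @export
pcs_single_mixture <- function(id, content = 0.5) {
  mixture_spec(data.frame(id = id, fraction = 1, role = "candidate"),
               preparation = "pcs_single", nominal_total_content = content)
}

#' Mixture from solution-phase simultaneous addition of groups
#'
#' The molar quantity of each candidate amide tracks the molar quantity of
#' its alkyl primary amine: fractions are `amine * relative_yield`,
#' renormalized, with optional log-normal yield jitter emulating the
#' imperfect proportionality seen in real syntheses (nominal 3:1 realized as
#' about 3.0:1 or 1:3.8).
#'
#' @param amine_fractions Named positive molar fractions of the input
#'   amines; names are the amine labels.
#' @param yield_model List with `relative_yield` (scalar or named per-amine,
#'   default 1), `cv` (log-normal jitter CV, default 0.15) and `seed`.
#' @param product_prefix Prefix turning an amine label into its biotinylated
#'   product id; default `"B"` (NEDA -> BNEDA).
#' @param byproducts Optional data.frame (`id`, `fraction`, `mz`) of
#'   nonspecific side products with positive-ion channels; their fractions
#'   are taken out of the total before normalizing candidates.
#' @return A [mixture_spec()] with preparation `"spsag"`.
#' @examples
#' make_spsag_mixture(c(NEDA = 1, BZA = 6),
#'                    yield_model = list(cv = 0))  # 1:6 exactly
#' @export
make_spsag_mixture <- function(amine_fractions,
                               yield_model = list(relative_yield = 1,
                                                  cv = 0.15, seed = NULL),
                               product_prefix = "B", byproducts = NULL) {
  check_numeric_vec(amine_fractions, "amine_fractions", lower = 0, strict = TRUE)
  if (is.null(names(amine_fractions)) || any(!nzchar(names(amine_fractions))))
    stop_mixscreen("amine_fractions must be named", "mixscreen_validation_error")
  ry <- yield_model$relative_yield %||% 1
  if (length(ry) > 1L) ry <- ry[names(amine_fractions)]
  cv <- yield_model$cv %||% 0.15
  jitter <- if (cv > 0) {
    sdlog <- sqrt(log(1 + cv^2))
    with_seed(yield_model$seed,
              exp(stats::rnorm(length(amine_fractions), 0, sdlog) - sdlog^2 / 2))
  } else rep(1, length(amine_fractions))
  w <- amine_fractions * ry * jitter
  cand <- data.frame(id = paste0(product_prefix, names(amine_fractions)),
                     fraction = unname(w / sum(w)), role = "candidate")
  comp <- cand
  if (!is.null(byproducts)) {
    bp_total <- sum(byproducts$fraction)
    if (bp_total >= 1)
      stop_mixscreen("byproduct fractions must total < 1",
                     "mixscreen_validation_error")
    cand$fraction <- cand$fraction * (1 - bp_total)
    comp <- rbind(cand, data.frame(id = byproducts$id,
                                   fraction = byproducts$fraction,
                                   role = "nonspecific"))
  }
  mixture_spec(comp, preparation = "spsag", nominal_total_content = 0.4)
}

#' Calibrations and affinity truths of the biotin/streptavidin model system
#'
#' Returns the published selected-ion-monitoring calibration parameters of
#' the single-candidate series (slopes, intercepts, recovery ratios; linear
#' to 30 pmol) and the reference relative affinities from the homogeneous
#' competitive assay, used as simulation truths. The multi-candidate series
#' was published without numeric calibrations, so `calibration_multi` is a
#' synthetic stand-in that preserves the documented qualitative structure
#' (slope ordering, one negative intercept, recovery ratios above 0.4).
#'
#' @return A list with `calibration_single`, `calibration_multi`
#'   (data.frames in the [read_calibration()] layout), `truths_bmpl`
#'   (relative affinities to BMPL) and `truths_bpdeda` (relative affinities
#'   to BPDEDA), plus `reference_Kd` (assumed absolute dissociation constant
#'   of a reference ligand, 1e-13 M).
#' @examples
#' table_fixtures()$calibration_single
#' @export
table_fixtures <- function() {
  calibration_single <- data.frame(
    ligand_id = c("BCHA", "BMPL", "BDETA", "BME"),
    mz = c(326L, 314L, 332L, 259L),
    slope = c(862.1, 279.8, 116.9, 49.2),
    intercept = c(322.1, 143.4, 59.9, 24.2),
    linear_upper = 30,
    r2 = c(0.998, 0.998, 0.994, 0.992),
    RR = c(0.47, 1.00, 0.57, 0.82))
  # synthetic: the multi-candidate calibrations were not printed
  calibration_multi <- data.frame(
    ligand_id = c("BPDEDA", "BDEDA", "BBZA", "BNEDA", "BCHA"),
    mz = c(667L, 520L, 334L, 413L, 326L),
    slope = c(200, 800, 400, 90, 862.1),
    intercept = c(80, 300, -50, 40, 322.1),
    linear_upper = 30,
    r2 = 0.995,
    RR = c(0.80, 0.60, 0.50, 0.45, 0.47))
  list(calibration_single = calibration_single,
       calibration_multi = calibration_multi,
       truths_bmpl = c(BCHA = 3.68, BME = 1.90, BDETA = 0.45),
       truths_bpdeda = c(BDEDA = 1.3, BBZA = 0.6, BCHA = 1.3, BNEDA = 2.0),
       reference_Kd = 1e-13)
}

#' Generate a fully specified synthetic screening scenario
#'
#' Composes the whole forward model: true association constants (reference
#' at `reference_Kd`, candidates scaled by their true ratios), a competitive
#' binding system, its mass-action equilibrium, and the simulated peak table
#' through magnetic recovery, extraction, concentration and analysis. The
#' truths are returned in a sealed element so test harnesses can score
#' estimator output without leaking them into estimator-facing data.
#'
#' @param candidates Named vector of true relative affinities `K_X/K_A`, or
#'   `NULL` when `mixture` is given.
#' @param candidate_conc Total molar concentration of all candidates in the
#'   binding system (split by mixture fractions, equally for plain
#'   `candidates`).
#' @param mixture Optional [mixture_spec()]; its candidate fractions split
#'   `candidate_conc`, and `truth_ratios` supplies their true ratios.
#' @param truth_ratios Named true ratios for mixture components; defaults to
#'   the model-system truths of [table_fixtures()].
#' @param reference Reference ligand id; default `"BMPL"`.
#' @param reference_conc Reference concentration in the system, mol/L;
#'   default 1.0 uM (binding ratio about 10% alone in the default geometry).
#' @param reference_Kd Absolute dissociation constant assigned to the
#'   reference, mol/L; default 1e-13 (all model-system ligands bind with
#'   sub-picomolar dissociation constants).
#' @param target_volume,site_density Target dosing (uL, pmol/uL); defaults
#'   50 uL at 4.2 pmol/uL.
#' @param protocol A [processing_protocol()]; default the single-candidate
#'   geometry (2.0 mL system, 40 uL extract, 5 uL injection).
#' @param calibration Calibration data.frame; defaults to the model-system
#'   fixtures covering the ligands present.
#' @param nonspecific Optional data.frame (`id`, `conc`, `ns_fraction`, `mz`)
#'   of nonspecific components carried through the simulation.
#' @param noise_cv,run_share,replicates Noise settings, see
#'   [simulate_peak_table()]; defaults 0.10, 0.5, 2.
#' @param seed Integer seed; the scenario is reproducible from it.
#' @return An object of class `scenario`: `system`, `state`, `peak_table`,
#'   `calibration`, `protocol`, and sealed `truth`.
#' @export
generate_scenario <- function(candidates = NULL, candidate_conc = 2e-6,
                              mixture = NULL, truth_ratios = NULL,
                              reference = "BMPL", reference_conc = 1e-6,
                              reference_Kd = 1e-13,
                              target_volume = 50, site_density = 4.2,
                              protocol = processing_protocol(),
                              calibration = NULL,
                              nonspecific = NULL,
                              noise_cv = 0.10, run_share = 0.5,
                              replicates = 2L, seed = NULL) {
  fx <- table_fixtures()
  if (is.null(candidates)) {
    if (is.null(mixture))
      stop_mixscreen("give either candidates or a mixture",
                     "mixscreen_config_error")
    stopifnot(inherits(mixture, "mixture_spec"))
    comp <- mixture$components[mixture$components$role == "candidate", ]
    if (is.null(truth_ratios))
      truth_ratios <- c(fx$truths_bmpl, fx$truths_bpdeda)
    missing <- setdiff(comp$id, names(truth_ratios))
    if (length(missing))
      stop_mixscreen(sprintf("no truth ratio for: %s",
                             paste(missing, collapse = ", ")),
                     "mixscreen_config_error")
    ratios <- stats::setNames(truth_ratios[comp$id], comp$id)
    fracs <- stats::setNames(comp$fraction / sum(comp$fraction), comp$id)
  } else {
    check_numeric_vec(candidates, "candidates", lower = 0, strict = TRUE)
    ratios <- candidates
    fracs <- stats::setNames(rep(1 / length(candidates), length(candidates)),
                             names(candidates))
  }
  check_number(candidate_conc, "candidate_conc", lower = 0)
  check_number(reference_conc, "reference_conc", lower = 0,
               allow_zero_lower = FALSE)

  if (is.null(calibration)) {
    pool <- rbind(fx$calibration_single,
                  fx$calibration_multi[!fx$calibration_multi$ligand_id %in%
                                         fx$calibration_single$ligand_id, ])
    want <- c(names(ratios), reference)
    calibration <- pool[match(want, pool$ligand_id), ]
    if (anyNA(calibration$ligand_id))
      stop_mixscreen(sprintf("no fixture calibration for: %s",
                             paste(want[is.na(calibration$ligand_id)],
                                   collapse = ", ")),
                     "mixscreen_config_error")
  }
  calibration <- validate_calibration(calibration)

  K_ref <- 1 / reference_Kd
  ligands <- c(
    lapply(names(ratios), function(id)
      ligand_species(id, "candidate", K = ratios[[id]] * K_ref,
                     total_conc = fracs[[id]] * candidate_conc,
                     mz = calibration$mz[match(id, calibration$ligand_id)])),
    list(ligand_species(reference, "reference", K = K_ref,
                        total_conc = reference_conc,
                        mz = calibration$mz[match(reference,
                                                  calibration$ligand_id)])))
  if (!is.null(nonspecific))
    ligands <- c(ligands, lapply(seq_len(nrow(nonspecific)), function(i)
      ligand_species(nonspecific$id[i], "nonspecific", K = 1e3,
                     total_conc = nonspecific$conc[i],
                     mz = nonspecific$mz[i] %||% NA_integer_,
                     ns_fraction = nonspecific$ns_fraction[i] %||% 0)))

  system <- binding_system(protocol$system_volume,
                           target_preparation(target_volume, site_density),
                           ligands)
  state <- solve_equilibrium(system)
  pt <- simulate_peak_table(state, system, protocol, calibration,
                            noise_cv = noise_cv, run_share = run_share,
                            replicates = replicates, seed = seed)
  truth <- list(ratios = ratios, K = vapply(ligands, `[[`, 0, "K"),
                conc = vapply(ligands, `[[`, 0, "total_conc"),
                BR = state$BR, reference = reference,
                noise_cv = noise_cv, seed = seed)
  structure(list(system = system, state = state, peak_table = pt,
                 calibration = calibration, protocol = protocol,
                 truth = truth),
            class = "scenario")
}

#' @export
print.scenario <- function(x, ...) {
  cat("Synthetic screening scenario\n")
  print(x$system)
  cat(sprintf("Peak table: %d records (noise CV %.3g, seed %s)\n",
              nrow(x$peak_table), x$truth$noise_cv,
              x$truth$seed %||% "none"))
  invisible(x)
}

#' Build a composition feed for the optimizers from a scenario template
#'
#' Returns a closure mapping a composition value to a freshly simulated
#' [peak_table()], regenerating the scenario with the candidate
#' concentration (axis `"mixture"`) or the reference concentration (axis
#' `"reference"`) set to the value. Each call draws a new measurement-noise
#' seed derived deterministically from `seed` and the call counter, so a
#' feed replayed over the same schedule reproduces identical tables.
#'
#' @param axis Which concentration the composition value controls.
#' @param seed Base seed for the derived per-call seeds.
#' @param ... Fixed arguments to [generate_scenario()] (candidates,
#'   reference, geometry, noise settings, ...).
#' @return `function(x)` returning a [peak_table()].
#' @export
scenario_feed <- function(axis = c("mixture", "reference"), seed = 1, ...) {
  axis <- match.arg(axis)
  fixed <- list(...)
  counter <- 0L
  function(x) {
    counter <<- counter + 1L
    args <- fixed
    if (axis == "mixture") args$candidate_conc <- x
    else args$reference_conc <- x
    args$seed <- (seed * 1000L + counter) %% .Machine$integer.max
    do.call(generate_scenario, args)$peak_table
  }
}

#' Write / read a scenario bundle on disk
#'
#' The bundle is a directory holding `config.yaml` (system and protocol),
#' `peak_table.csv`, `calibration.csv`, and -- sealed in a `truth/`
#' subdirectory so estimator-facing code need never touch it --
#' `truth/truth.json`.
#'
#' @param scenario A [generate_scenario()] result.
#' @param dir Bundle directory (created if needed).
#' @param with_truth For `read_scenario`: also load the sealed truth.
#' @return `write_scenario` returns `dir` invisibly; `read_scenario` a list
#'   with `peak_table`, `calibration`, `protocol`, `system` and optionally
#'   `truth`.
#' @export
write_scenario <- function(scenario, dir) {
  stopifnot(inherits(scenario, "scenario"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "truth"), showWarnings = FALSE)
  p <- scenario$protocol
  yaml::write_yaml(list(
    protocol = list(system_volume = p$system_volume,
                    extract_volume = p$extract_volume,
                    injection_volume = p$injection_volume,
                    pmfs_volume = p$pmfs_volume),
    target = list(suspension_volume = scenario$system$target$suspension_volume,
                  site_density = scenario$system$target$site_density),
    reference = scenario$truth$reference,
    seed = scenario$truth$seed,
    checksum = config_checksum(scenario$truth)
  ), file.path(dir, "config.yaml"))
  write_peak_table(scenario$peak_table, file.path(dir, "peak_table.csv"))
  write_calibration(scenario$calibration, file.path(dir, "calibration.csv"))
  truth_out <- scenario$truth
  for (f in c("ratios", "BR"))  # keep ligand names through unboxing
    truth_out[[f]] <- as.list(truth_out[[f]])
  jsonlite::write_json(truth_out, file.path(dir, "truth", "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname write_scenario
#' @export
read_scenario <- function(dir, with_truth = FALSE) {
  cfg <- yaml::read_yaml(file.path(dir, "config.yaml"))
  protocol <- processing_protocol(cfg$protocol$system_volume,
                                  cfg$protocol$extract_volume,
                                  cfg$protocol$injection_volume,
                                  cfg$protocol$pmfs_volume)
  out <- list(
    peak_table = read_peak_table(file.path(dir, "peak_table.csv"), protocol),
    calibration = read_calibration(file.path(dir, "calibration.csv")),
    protocol = protocol, reference = cfg$reference, config = cfg)
  if (with_truth)
    out$truth <- jsonlite::read_json(file.path(dir, "truth", "truth.json"),
                                     simplifyVector = TRUE)
  out
}
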