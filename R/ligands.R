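#' Define a ligand species in a competitive binding system
#'
#' A ligand is characterised by its role (a candidate from the mixture, the
#' exogenous reference ligand, or an expected nonspecific binder), its
#' association equilibrium constant `K` (per molar; only meaningful in
#' simulations -- the whole point of the method is that `K` ratios are
#' *estimated*, never known, for real mixtures), and its total molar
#' concentration in the binding system.
#'
#' @param id Short unique label, e.g. `"BCHA"`.
#' @param role One of `"candidate"`, `"reference"`, `"nonspecific"`.
#' @param K Association equilibrium constant in 1/M. Must be positive.
#'   Tight binders in the streptavidin/biotin model system have
#'   `K` around `1e13` (dissociation constants of ~100 fM).
#' @param total_conc Total molar concentration (mol/L) in the binding system.
#' @param mz Mass-to-charge channel used for selected-ion monitoring
#'   (metadata only).
#' @param ns_fraction Optional fraction of the ligand's total amount bound
#'   nonspecifically, independent of site occupancy (survives target
#'   denaturation). Default 0.
#' @return An object of class `ligand_species`.
#' @examples
#' ligand_species("BMPL", "reference", K = 1e13, total_conc = 1e-6, mz = 314)
#' @export
ligand_species <- function(id, role = c("candidate", "reference", "nonspecific"),
                           K, total_conc, mz = NA_integer_, ns_fraction = 0) {
  role <- match.arg(role)
  if (!is.character(id) || length(id) != 1L || !nzchar(id))
    stop_mixscreen("`id` must be a non-empty string", "mixscreen_validation_error")
  check_number(K, "K", lower = 0, allow_zero_lower = FALSE)
  check_number(total_conc, "total_conc", lower = 0)
  check_number(ns_fraction, "ns_fraction", lower = 0, upper = 1)
  structure(list(id = id, role = role, K = K, total_conc = total_conc,
                 mz = mz, ns_fraction = ns_fraction),
            class = "ligand_species")
}

#' Describe the immobilized-target preparation
#'
#' The target (streptavidin on paramagnetic particles, in the model system)
#' is dosed as a suspension volume times a binding-site density. A denatured
#' preparation binds nothing specifically and is used as the control when
#' judging binding sites.
#'
#' @param suspension_volume Volume of particle suspension used, in uL.
#' @param site_density Binding sites per uL of suspension, in pmol/uL. The
#'   model system was titrated at about 4.2 pmol/uL; 4.0 pmol/uL is the value
#'   consistent with the published sizing table. Both are accepted, neither
#'   is hard-coded.
#' @param denatured Logical; a denatured target retains no specific sites.
#' @return An object of class `target_preparation`.
#' @export
target_preparation <- function(suspension_volume, site_density = 4.2,
                               denatured = FALSE) {
  check_number(suspension_volume, "suspension_volume", lower = 0)
  check_number(site_density, "site_density", lower = 0)
  structure(list(suspension_volume = suspension_volume,
                 site_density = site_density,
                 denatured = isTRUE(denatured)),
            class = "target_preparation")
}

#' Assemble a competitive binding system
#'
#' @param volume System volume in mL.
#' @param target A [target_preparation()].
#' @param ligands A list of [ligand_species()] with unique ids.
#' @return An object of class `binding_system`. Total binding sites (pmol)
#'   are `suspension_volume * site_density`.
#' @examples
#' sys <- binding_system(2.0, target_preparation(50, 4.2),
#'                       list(ligand_species("BMPL", "reference", 1e13, 1e-6)))
#' total_sites(sys)
#' @export
binding_system <- function(volume, target, ligands = list()) {
  check_number(volume, "volume", lower = 0, allow_zero_lower = FALSE)
  if (!inherits(target, "target_preparation"))
    stop_mixscreen("`target` must be a target_preparation", "mixscreen_validation_error")
  if (!is.list(ligands) || !all(vapply(ligands, inherits, TRUE, "ligand_species")))
    stop_mixscreen("`ligands` must be a list of ligand_species", "mixscreen_validation_error")
  ids <- vapply(ligands, `[[`, "", "id")
  if (anyDuplicated(ids))
    stop_mixscreen("ligand ids must be unique within a system", "mixscreen_validation_error")
  names(ligands) <- ids
  structure(list(volume = volume, target = target, ligands = ligands),
            class = "binding_system")
}

#' Total binding sites of a system, in pmol
#' @param system A [binding_system()].
#' @return Sites in pmol (zero specific sites if the target is denatured is
#'   handled by the solver, not here).
#' @export
total_sites <- function(system) {
  stopifnot(inherits(system, "binding_system"))
  system$target$suspension_volume * system$target$site_density
}

#' Molar ratio of total ligand to binding sites
#'
#' A design diagnostic: the recommended first screening mixture loads the
#' system with ligand far in excess of sites (roughly thirty-fold in the
#' model system) so that binding ratios stay low.
#'
#' @param system A [binding_system()].
#' @return Total ligand amount (pmol) divided by total sites (pmol).
#' @export
ligand_site_ratio <- function(system) {
  stopifnot(inherits(system, "binding_system"))
  sites <- total_sites(system)
  if (sites <= 0)
    stop_mixscreen("system has no binding sites", "mixscreen_validation_error")
  conc <- vapply(system$ligands, `[[`, 0, "total_conc")
  sum(injected_pmol(conc, system$volume * 1000)) / sites
}

#' @export
print.binding_system <- function(x, ...) {
  cat(sprintf("Competitive binding system: %.3g mL, %s target, %.4g pmol sites\n",
              x$volume, if (x$target$denatured) "denatured" else "native",
              total_sites(x)))
  if (length(x$ligands)) {
    df <- as.data.frame(x)
    print(df, row.names = FALSE)
  } else cat("  (no ligands)\n")
  invisible(x)
}

#' @export
as.data.frame.binding_system <- function(x, ...) {
  data.frame(
    id = vapply(x$ligands, `[[`, "", "id"),
    role = vapply(x$ligands, `[[`, "", "role"),
    K = vapply(x$ligands, `[[`, 0, "K"),
    total_conc = vapply(x$ligands, `[[`, 0, "total_conc"),
    mz = vapply(x$ligands, function(l) as.integer(l$mz %||% NA), NA_integer_),
    row.names = NULL
  )
}

#' Write or read a binding system as a structured config file
#'
#' Systems serialize to a nested key-value (YAML) file so that simulation
#' scenarios are reproducible from disk.
#'
#' @param system A [binding_system()].
#' @param path File path.
#' @return `write_binding_system` returns `path` invisibly;
#'   `read_binding_system` returns a [binding_system()].
#' @export
write_binding_system <- function(system, path) {
  stopifnot(inherits(system, "binding_system"))
  lig <- lapply(unname(system$ligands), function(l)
    list(id = l$id, role = l$role, K = l$K, total_conc = l$total_conc,
         mz = if (is.na(l$mz)) NULL else as.integer(l$mz),
         ns_fraction = l$ns_fraction))
  yaml::write_yaml(list(
    volume = system$volume,
    target = list(suspension_volume = system$target$suspension_volume,
                  site_density = system$target$site_density,
                  denatured = system$target$denatured),
    ligands = lig
  ), path)
  invisible(path)
}

#' @rdname write_binding_system
#' @export
read_binding_system <- function(path) {
  cfg <- yaml::read_yaml(path)
  binding_system(
    volume = cfg$volume,
    target = target_preparation(cfg$target$suspension_volume,
                                cfg$target$site_density,
                                isTRUE(cfg$target$denatured)),
    ligands = lapply(cfg$ligands, function(l)
      ligand_species(l$id, l$role, l$K, l$total_conc,
                     mz = l$mz %||% NA_integer_,
                     ns_fraction = l$ns_fraction %||% 0))
  )
}
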