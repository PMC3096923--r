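#' Solve multi-ligand competitive binding at equilibrium
#'
#' Mass-action closure for a mixture of ligands competing for a single class
#' of sites on an immobilized target. With `S_tot` the total sites (moles),
#' `V` the system volume (L), `L_i` the total concentration of ligand *i*
#' (mol/L) and `K_i` its association constant (1/M), the free-site
#' concentration `s` is the unique root of
#'
#' \deqn{S_{tot} = sV + \sum_i \frac{K_i s}{1 + K_i s} L_i V}
#'
#' and the bound amount of ligand *i* is `K_i s / (1 + K_i s) * L_i * V`.
#' The left side is strictly increasing in `s`, so bisection on
#' `[0, S_tot/V]` always brackets the root; in the stiff femtomolar-K regime
#' (`K * S_tot/V > 1e6`) bisection runs on `log10(s)` instead, which keeps
#' full relative precision when the root is many orders of magnitude below
#' the total-site concentration.
#'
#' A ligand's binding ratio is `BR_i = K_i s / (1 + K_i s)` -- it depends on
#' the system only through `s`, so raising any total concentration lowers
#' every ligand's `BR`.
#'
#' Nonspecific binding (`ns_fraction > 0`) adds `ns_fraction * total` to the
#' bound amount independently of site occupancy; it is all that remains when
#' the target is denatured.
#'
#' @param system A [binding_system()].
#' @param rel_tol Relative tolerance on the mass balances, in `(0, 1e-3]`.
#'   Default `1e-10`.
#' @return An object of class `equilibrium_state`: a list with
#'   `free_site_conc` (mol/L), per-ligand `bound` and `free` (pmol), `BR`
#'   (fractions), and `N_FS` (unoccupied sites, pmol).
#' @examples
#' sys <- binding_system(2.0, target_preparation(50, 4.2),
#'                       list(ligand_species("BMPL", "reference", 1e13, 1e-6)))
#' st <- solve_equilibrium(sys)
#' st$BR  # about 0.105
#' @seealso [single_ligand_closed_form()] for the one-ligand quadratic.
#' @export
solve_equilibrium <- function(system, rel_tol = 1e-10) {
  stopifnot(inherits(system, "binding_system"))
  check_number(rel_tol, "rel_tol", lower = 0, upper = 1e-3,
               allow_zero_lower = FALSE)
  V <- mL_to_L(system$volume)
  sites_pmol <- total_sites(system)
  if (system$target$denatured) sites_pmol <- 0
  S_tot <- pmol_to_mol(sites_pmol)

  ids <- names(system$ligands)
  K <- vapply(system$ligands, `[[`, 0, "K")
  L <- vapply(system$ligands, `[[`, 0, "total_conc")
  nsf <- vapply(system$ligands, `[[`, 0, "ns_fraction")
  total_pmol <- mol_to_pmol(L * V)

  if (length(ids) == 0L || S_tot == 0 || all(L == 0)) {
    s <- S_tot / V
    bound_spec <- stats::setNames(numeric(length(ids)), ids)
  } else {
    s0 <- S_tot / V
    occupied <- function(s) sum(K * s / (1 + K * s) * L) * V
    g <- function(s) s * V + occupied(s) - S_tot
    stiff <- max(K) * s0 > 1e6
    if (!stiff) {
      lo <- 0; hi <- s0
      for (i in seq_len(200L)) {
        mid <- (lo + hi) / 2
        if (g(mid) < 0) lo <- mid else hi <- mid
        if (hi - lo <= rel_tol * max(hi, .Machine$double.xmin)) break
      }
      s <- (lo + hi) / 2
    } else {
      # log-spaced bracketing: root is strictly positive because g(0) < 0
      uhi <- log10(s0)
      ulo <- uhi - 40
      while (g(10^ulo) > 0 && ulo > uhi - 400) ulo <- ulo - 40
      if (g(10^ulo) > 0)
        stop_mixscreen("bracketing failure while solving the binding system",
                       "mixscreen_solver_error")
      for (i in seq_len(300L)) {
        um <- (ulo + uhi) / 2
        if (g(10^um) < 0) ulo <- um else uhi <- um
      }
      s <- 10^((ulo + uhi) / 2)
    }
    bound_spec <- stats::setNames(mol_to_pmol(K * s / (1 + K * s) * L * V), ids)
  }

  bound_ns <- stats::setNames(nsf * total_pmol, ids)
  bound <- bound_spec + bound_ns
  free <- stats::setNames(total_pmol, ids) - bound
  BR <- ifelse(total_pmol > 0, bound / total_pmol, 0)
  N_FS <- sites_pmol - sum(bound_spec)

  st <- structure(list(free_site_conc = s, bound = bound, free = free,
                       BR = stats::setNames(BR, ids), N_FS = N_FS,
                       total = stats::setNames(total_pmol, ids),
                       sites = sites_pmol),
                  class = "equilibrium_state")
  # invariant checks at the requested tolerance
  scale <- max(sites_pmol, 1e-12)
  if (abs(sum(bound_spec) + N_FS - sites_pmol) > rel_tol * scale * 10)
    stop_mixscreen("site mass balance violated beyond rel_tol",
                   "mixscreen_solver_error")
  st
}

#' @export
print.equilibrium_state <- function(x, ...) {
  cat(sprintf("Equilibrium: free sites %.4g pmol (%.3g mol/L free-site conc)\n",
              x$N_FS, x$free_site_conc))
  if (length(x$bound))
    print(data.frame(bound_pmol = x$bound, free_pmol = x$free,
                     BR = x$BR), digits = 4)
  invisible(x)
}

#' Single-ligand binding quadratic (closed form)
#'
#' For one ligand the mass-action equilibrium reduces to the quadratic
#' `c^2 - (L0 + S0 + 1/K) c + L0 S0 = 0` in the complex concentration `c`,
#' whose physical root is returned in the numerically stable form
#' `c = 2 L0 S0 / (A + sqrt(A^2 - 4 L0 S0))`, `A = L0 + S0 + 1/K`. Used as
#' an independent oracle for [solve_equilibrium()]; it remains accurate in
#' the tight-binding (stoichiometric) limit where `c -> min(L0, S0)`.
#'
#' @param K Association constant, 1/M.
#' @param total_conc Total ligand concentration, mol/L.
#' @param sites Total sites, pmol.
#' @param volume System volume, mL.
#' @return Bound amount in pmol.
#' @export
single_ligand_closed_form <- function(K, total_conc, sites, volume) {
  check_number(K, "K", lower = 0, allow_zero_lower = FALSE)
  check_number(total_conc, "total_conc", lower = 0)
  check_number(sites, "sites", lower = 0)
  check_number(volume, "volume", lower = 0, allow_zero_lower = FALSE)
  V <- mL_to_L(volume)
  L0 <- total_conc
  S0 <- pmol_to_mol(sites) / V
  if (L0 == 0 || S0 == 0) return(0)
  A <- L0 + S0 + 1 / K
  disc <- A^2 - 4 * L0 * S0
  c_conc <- 2 * L0 * S0 / (A + sqrt(disc))
  mol_to_pmol(c_conc * V)
}
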