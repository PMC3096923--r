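# shared fixtures and independent oracles

fx <- table_fixtures()

# the published single-candidate geometry: 2.0 mL system, 50 uL target at
# 4.2 pmol/uL, 40 uL extract, 5 uL injections
default_protocol <- processing_protocol(2.0, 40, 5, 40)

bmpl_system <- function(conc = 1e-6, Kd = 1e-13) {
  binding_system(2.0, target_preparation(50, 4.2),
                 list(ligand_species("BMPL", "reference", 1 / Kd, conc,
                                     mz = 314)))
}

# independent oracle for single-ligand binding: root of the mass-action
# polynomial in the complex concentration, found by stats::uniroot on a
# bracket that always contains the physical root
oracle_single_bound <- function(K, total_conc, sites, volume) {
  V <- volume * 1e-3
  L0 <- total_conc
  S0 <- sites * 1e-12 / V
  if (L0 == 0 || S0 == 0) return(0)
  f <- function(c) K * (L0 - c) * (S0 - c) - c
  hi <- min(L0, S0)
  root <- stats::uniroot(f, c(0, hi), tol = .Machine$double.eps)$root
  root * V * 1e12
}

# an ideal (slope-only) calibration so area ratios equal quantity ratios
ideal_calibration <- function(ids, RR = 1) {
  data.frame(ligand_id = ids, mz = NA_integer_, slope = 100, intercept = 0,
             linear_upper = 1e6, r2 = 1,
             RR = rep_len(RR, length(ids)))
}

# hand-built peak table: one pmfs and one extract record per ligand
manual_peak_table <- function(areas_pmfs, areas_extract,
                              protocol = default_protocol) {
  ids <- names(areas_pmfs)
  peak_table(data.frame(
    ligand_id = rep(ids, 2),
    kind = rep(c("pmfs", "extract"), each = length(ids)),
    dilution = rep(c(protocol$pmfs_dilution, 1), each = length(ids)),
    area = c(unname(areas_pmfs), unname(areas_extract))),
    protocol = protocol)
}

# replicate-averaged area for one (ligand, kind)
mean_area0 <- function(pt, id, kind) {
  mean(pt$area[pt$ligand_id == id & pt$kind == kind])
}

# randomized multi-ligand systems for the property tests
random_system <- function(n_ligands, seed) {
  set.seed(seed)
  ligs <- lapply(seq_len(n_ligands), function(i)
    ligand_species(paste0("L", i), "candidate",
                   K = 10^stats::runif(1, 6, 16),
                   total_conc = 10^stats::runif(1, -9, -5)))
  binding_system(stats::runif(1, 0.5, 5),
                 target_preparation(stats::runif(1, 10, 200),
                                    stats::runif(1, 1, 6)),
                 ligs)
}
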