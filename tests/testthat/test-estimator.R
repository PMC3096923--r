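test_that("estimated_binding_ratio is the corrected area ratio", {
  expect_equal(estimated_binding_ratio(0, 1000, 0.5, 50), 0)
  expect_equal(estimated_binding_ratio(500, 1000, 0.5, 50), 0.02)
  expect_error(estimated_binding_ratio(500, 0, 0.5, 50),
               class = "mixscreen_estimation_error")
  big <- estimated_binding_ratio(5000, 10, 0.5, 1)
  expect_true(isTRUE(attr(big, "implausible")))
})

test_that("round trip through the simulator reproduces the equilibrium BR", {
  sys <- bmpl_system()  # the 1.0 uM reference geometry
  st <- solve_equilibrium(sys)
  # intercept-free calibration: the estimator neglects intercepts by design
  pt <- simulate_peak_table(st, sys, default_protocol,
                            ideal_calibration("BMPL"), noise_cv = 0,
                            replicates = 1)
  br <- estimated_binding_ratio(mean_area0(pt, "BMPL", "extract"),
                                mean_area0(pt, "BMPL", "pmfs"), 1,
                                default_protocol$CR)
  expect_equal(as.numeric(br), unname(st$BR[["BMPL"]]), tolerance = 1e-6)
  # with the published intercept the neglect costs under a percentage point
  pt2 <- simulate_peak_table(st, sys, default_protocol, fx$calibration_single,
                             noise_cv = 0, replicates = 1)
  br2 <- estimated_binding_ratio(mean_area0(pt2, "BMPL", "extract"),
                                 mean_area0(pt2, "BMPL", "pmfs"), 1,
                                 default_protocol$CR)
  expect_equal(as.numeric(br2), unname(st$BR[["BMPL"]]), tolerance = 0.1)
})

test_that("the depletion-corrected estimator is exact at any binding ratio", {
  # symmetric observables give exactly 1
  expect_equal(relative_affinity_eq5(100, 100, 20, 20, 0.5, 0.5, 50), 1)
  # mass-action consistent areas at BR_X = 0.3, true ratio 3:
  # K_X s = 3/7 (BR_X = 0.3), K_A s = 1/7 (BR_A = 0.125)
  CR <- 50
  T_X <- 100; x <- 30; T_A <- 100; a <- 12.5
  eq5 <- relative_affinity_eq5(T_A, T_X, a * CR, x * CR, 1, 1, CR)
  expect_equal(eq5, 3, tolerance = 1e-12)
  eq6 <- relative_affinity_eq6(T_A, T_X, a * CR, x * CR, 1, 1)
  expect_gt(abs(eq6 - 3), 0.1)  # eq6 is biased when BR exceeds its limit
  # depletion beyond the measured total errors out
  expect_error(relative_affinity_eq5(100, 100, 20, 6000, 1, 1, 50),
               class = "mixscreen_depletion_error")
})

test_that("eq5 converges to eq6 as binding ratios vanish", {
  for (br in c(1e-3, 1e-4)) {
    T_X <- 1e6; T_A <- 1e6; CR <- 50
    x <- br * T_X; a <- 0.5 * br * T_A
    eq5 <- relative_affinity_eq5(T_A, T_X, a * CR, x * CR, 1, 1, CR)
    eq6 <- relative_affinity_eq6(T_A, T_X, a * CR, x * CR, 1, 1)
    gap <- abs(eq5 - eq6) / eq5
    expect_lt(gap, 10 * br)
    if (br == 1e-4) expect_lt(gap, 1e-3)
  }
})

test_that("the area-ratio estimator has its stated invariances", {
  expect_equal(relative_affinity_eq6(1000, 1000, 200, 200, 0.5, 0.5), 1)
  expect_equal(relative_affinity_eq6(1000, 1000, 200, 400, 0.5, 0.5), 2)
  set.seed(7)
  for (i in 1:20) {
    v <- stats::runif(6, 0.1, 10)
    r0 <- relative_affinity_eq6(v[1], v[2], v[3], v[4], v[5], v[6])
    # swapping candidate and reference gives the reciprocal
    expect_equal(relative_affinity_eq6(v[2], v[1], v[4], v[3], v[6], v[5]),
                 1 / r0, tolerance = 1e-12)
    # rescaling all areas of one ligand by a common factor changes nothing
    k <- stats::runif(1, 0.1, 10)
    expect_equal(relative_affinity_eq6(v[1], k * v[2], v[3], k * v[4],
                                       v[5], v[6]),
                 r0, tolerance = 1e-12)
  }
  expect_error(relative_affinity_eq6(0, 1, 1, 1, 1, 1),
               class = "mixscreen_estimation_error")
})

test_that("prerequisite validation follows the stated order and thresholds", {
  cal <- data.frame(ligand_id = c("X", "A"), mz = NA, slope = c(100, 100),
                    intercept = c(50, 50), linear_upper = 1e3, r2 = 1,
                    RR = c(0.5, 1))
  # all areas at 6x|intercept|, binding ratios ~ a few percent -> valid
  ok <- manual_peak_table(c(X = 3000, A = 3000), c(X = 300, A = 300))
  rep1 <- validate_prerequisites(ok, cal, "X", "A")
  expect_true(rep1$valid)
  expect_equal(unname(rep1$BR[["candidate"]]), 300 / (0.5 * 50 * 3000))

  # extract area at 3x|intercept| -> prerequisite (c) fails, eq6 still usable
  low <- manual_peak_table(c(X = 3000, A = 3000), c(X = 150, A = 300))
  rep2 <- validate_prerequisites(low, cal, "X", "A")
  expect_false(rep2$valid)
  expect_false(rep2$above_intercept_multiple[["candidate.extract"]])
  fit <- affinity_screen(low, cal, "A")
  expect_false(fit$estimates[["X"]]$prerequisites$valid)
  expect_true(is.finite(coef(fit)[["X"]]))

  # candidate binding ratio at 15% -> prerequisite (d) fails
  hot <- manual_peak_table(c(X = 3000, A = 3000),
                           c(X = 0.15 * 0.5 * 50 * 3000, A = 300))
  rep3 <- validate_prerequisites(hot, cal, "X", "A")
  expect_false(rep3$valid)
  expect_false(rep3$br_below_limit[["candidate"]])
  expect_true(all(rep3$above_intercept_multiple))

  # refuted same-site evidence invalidates regardless of areas
  rep4 <- validate_prerequisites(ok, cal, "X", "A", same_site = "refuted")
  expect_false(rep4$valid)

  # missing records are listed
  expect_error(validate_prerequisites(ok, cal, "Z", "A"),
               "Z", class = "mixscreen_validation_error")
})

test_that("binding sites are judged from competitor and denatured controls", {
  cal <- ideal_calibration(c("BIO", "DNAM"), RR = 1)
  base <- manual_peak_table(c(BIO = 1000, DNAM = 1000),
                            c(BIO = 2000, DNAM = 400))
  # biotin-derivative pattern: -45% under competitor, nothing on denatured
  comp <- manual_peak_table(c(BIO = 1000, DNAM = 1000),
                            c(BIO = 2000 * 0.55, DNAM = 400 * 0.98))
  dena <- manual_peak_table(c(BIO = 1000, DNAM = 1000),
                            c(BIO = 0, DNAM = 400))
  out <- judge_binding_site(base, comp, dena, cal)
  expect_equal(out$verdict[out$ligand_id == "BIO"], "specific")
  expect_equal(out$verdict[out$ligand_id == "DNAM"], "nonspecific")

  # a -20% reduction sits between the thresholds
  mid <- manual_peak_table(c(BIO = 1000, DNAM = 1000),
                           c(BIO = 2000 * 0.8, DNAM = 400))
  out2 <- judge_binding_site(base, mid, dena, cal)
  expect_equal(out2$verdict[out2$ligand_id == "BIO"], "indeterminate")

  bad <- manual_peak_table(c(BIO = 1000), c(BIO = 2000))
  expect_error(judge_binding_site(base, comp, bad, cal),
               class = "mixscreen_validation_error")
})

test_that("affinity_screen recovers sealed truths on a noiseless scenario", {
  sc <- generate_scenario(candidates = c(BCHA = 3.68), candidate_conc = 4e-6,
                          reference = "BMPL", reference_conc = 2e-6,
                          noise_cv = 0, seed = 5)
  fit <- affinity_screen(sc$peak_table, sc$calibration, "BMPL")
  expect_s3_class(fit, "affinity_screen")
  expect_equal(unname(coef(fit)[["BCHA"]]), 3.68, tolerance = 0.10)
  df <- as.data.frame(fit)
  expect_true(all(df$valid))
  expect_equal(df$BR_candidate, unname(sc$truth$BR[["BCHA"]]), tolerance = 0.1)
  # the depletion-corrected column is closer to truth than the area ratio
  expect_lt(abs(df$ratio_eq5 - 3.68), abs(df$ratio - 3.68) + 0.05)
})

test_that("estimator output is unbiased enough over a small recovery sweep", {
  set.seed(31)
  truths <- c(2.0, 0.6)
  errs <- unlist(lapply(truths, function(r) {
    sapply(1:10, function(i) {
      sc <- generate_scenario(candidates = c(BNEDA = r), candidate_conc = 4e-6,
                              reference = "BPDEDA", reference_conc = 2e-6,
                              noise_cv = 0.10,
                              seed = sample.int(1e6, 1))
      fit <- affinity_screen(sc$peak_table, sc$calibration, "BPDEDA")
      coef(fit)[["BNEDA"]] / r - 1
    })
  }))
  expect_lt(stats::median(abs(errs)), 0.15)
})
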