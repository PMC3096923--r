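test_that("minimum injected quantities match the published calibrations", {
  printed_q <- c(BCHA = 1.5, BMPL = 2.0, BDETA = 2.1, BME = 2.0)
  for (id in names(printed_q)) {
    r <- linear_response(
      fx$calibration_single$slope[fx$calibration_single$ligand_id == id],
      fx$calibration_single$intercept[fx$calibration_single$ligand_id == id])
    q <- min_injected_quantity(r)
    expect_lt(abs(q - printed_q[[id]]), 0.06)
    # by construction the area at q is exactly five times the intercept
    expect_equal(as.numeric(predict_area(r, q)), 5 * abs(r$intercept),
                 tolerance = 1e-12)
  }
  # floor rule for vanishing / negative intercepts
  expect_equal(min_injected_quantity(linear_response(100, 0),
                                     intercept_floor = 0.5), 0.5)
  expect_equal(min_injected_quantity(linear_response(100, -50)),
               6 * 50 / 100)
})

test_that("the sizing chain reproduces the published table step by step", {
  # published cells; each later cell derives from the *printed* predecessor,
  # so each step relation is checked against the printed input
  printed <- data.frame(
    ligand_id = c("BCHA", "BMPL", "BDETA", "BME"),
    q_inj = c(1.5, 2.0, 2.1, 2.0),
    q_extract = c(12, 16, 16.8, 16),
    bound = c(26, 16, 31.5, 20),       # 31.5 is internally inconsistent
    volume = c(6.5, 4.0, 7.8, 5.0),
    RR = c(0.47, 1.00, 0.57, 0.82))
  scale <- default_protocol$extract_volume / default_protocol$injection_volume
  expect_equal(scale, 8)
  # extract = 8 x printed injected minimum (exact for every ligand)
  expect_equal(printed$q_inj * scale, printed$q_extract, tolerance = 1e-12)
  # bound = printed extract / RR, within one unit of the last printed digit;
  # the BDETA cell is checked against the formula value 16.8/0.57 = 29.5
  bound_formula <- printed$q_extract / printed$RR
  expect_lt(abs(bound_formula[1] - 26), 1)
  expect_equal(bound_formula[2], 16)
  expect_equal(bound_formula[3], 29.47, tolerance = 1e-3)
  expect_lt(abs(bound_formula[4] - 20), 1)
  # volume = printed bound / 4.0 pmol/uL, within 0.1 uL
  expect_true(all(abs(printed$bound / 4.0 - printed$volume) <= 0.1 + 1e-9))

  sizing <- min_target_parameter_approach(fx$calibration_single,
                                          default_protocol,
                                          site_density = 4.0)
  per <- sizing$per_ligand
  expect_equal(per$ligand_id, printed$ligand_id)
  # full-precision chain values stay within the printed rounding slack
  expect_true(all(abs(per$min_quantity_injected - printed$q_inj) < 0.06))
  expect_true(all(abs(per$min_quantity_extract - printed$q_extract) < 0.45))
  expect_true(all(abs(per$min_target_volume -
                        per$min_bound / 4.0) < 1e-12))
  # summed minima per screening mixture (candidate + reference) ~ 9-12 uL
  v <- stats::setNames(per$min_target_volume, per$ligand_id)
  sums <- v[c("BCHA", "BDETA", "BME")] + v[["BMPL"]]
  expect_true(all(abs(sums - c(11, 12, 9)) <= 1.6))
  expect_equal(sizing$practical_target_volume,
               2 * sizing$summed_min_target_volume)
})

test_that("experimental sizing solves the threshold volume per ligand", {
  cal <- data.frame(ligand_id = c("BBZA", "BNEDA"), mz = NA,
                    slope = c(400, 90), intercept = c(-50, 40),
                    linear_upper = 30, r2 = 1, RR = c(0.5, 0.45))
  # linear area-vs-volume series engineered to cross 5|I| at 0.05 / 0.18 mL
  vols <- c(0.02, 0.05, 0.10, 0.15, 0.20)
  mk <- function(b0, b1) b0 + b1 * vols
  series <- rbind(
    data.frame(target_volume = vols, ligand_id = "BBZA",
               area = mk(100, (5 * 50 - 100) / 0.05)),
    data.frame(target_volume = vols, ligand_id = "BNEDA",
               area = mk(20, (5 * 40 - 20) / 0.18)))
  plan <- min_target_experimental(series, cal)
  per <- stats::setNames(plan$per_ligand$min_target_volume,
                         plan$per_ligand$ligand_id)
  expect_equal(unname(per[["BBZA"]]), 0.05, tolerance = 1e-9)
  expect_equal(unname(per[["BNEDA"]]), 0.18, tolerance = 1e-9)
  expect_gt(per[["BNEDA"]], 0.15)
  expect_equal(plan$optimized, unname(per[["BNEDA"]]))

  # all areas above threshold at the smallest volume -> flagged boundary
  high <- data.frame(target_volume = vols, ligand_id = "BBZA",
                     area = 1000 + 100 * vols)
  plan2 <- min_target_experimental(high, cal)
  expect_equal(plan2$per_ligand$min_target_volume, 0.02)
  expect_true(plan2$per_ligand$already_above)

  # unbracketed threshold errors unless extrapolation is allowed
  low <- data.frame(target_volume = vols, ligand_id = "BNEDA",
                    area = 20 + 100 * vols)
  expect_error(min_target_experimental(low, cal),
               class = "mixscreen_planning_error")
  plan3 <- min_target_experimental(low, cal, extrapolate = TRUE)
  expect_false(plan3$per_ligand$bracketed)
})

test_that("experimental sizing is honest in closed loop on simulations", {
  # low-affinity candidate whose extract peak needs enough target to clear
  # the five-intercept threshold
  vols <- c(10, 20, 30, 40, 50)
  series <- do.call(rbind, lapply(vols, function(v) {
    sc <- generate_scenario(candidates = c(BDETA = 0.45),
                            candidate_conc = 0.8e-6,
                            reference = "BMPL", reference_conc = 1e-6,
                            target_volume = v, noise_cv = 0, seed = 1)
    data.frame(target_volume = v, ligand_id = "BDETA",
               area = mean_area0(sc$peak_table, "BDETA", "extract"))
  }))
  plan <- min_target_experimental(series, fx$calibration_single)
  vmin <- plan$per_ligand$min_target_volume
  expect_true(plan$per_ligand$bracketed)
  # running the full estimator at (slightly above) the minimum validates
  sc <- generate_scenario(candidates = c(BDETA = 0.45),
                          candidate_conc = 0.8e-6,
                          reference = "BMPL", reference_conc = 1e-6,
                          target_volume = ceiling(vmin) + 1,
                          noise_cv = 0, seed = 2)
  fit <- affinity_screen(sc$peak_table, sc$calibration, "BMPL")
  expect_true(fit$estimates[["BDETA"]]$prerequisites$valid)
})

test_that("a constant noiseless feed plateaus from the first step", {
  sc <- generate_scenario(candidates = c(BME = 1.90), candidate_conc = 2e-6,
                          noise_cv = 0, seed = 3)
  feed <- function(x) sc$peak_table
  tr <- fine_optimize(feed, c(1, 2, 3, 4), sc$calibration, "BMPL", "BME")
  expect_equal(tr$stable_from, 1L)
  expect_equal(tr$stable_value, tr$steps$estimate[1])
  expect_error(fine_optimize(feed, c(1, 2, 3), sc$calibration, "BMPL", "BME"),
               class = "mixscreen_validation_error")
  expect_error(fine_optimize(feed, c(1, 2, 2, 3), sc$calibration, "BMPL", "BME"),
               class = "mixscreen_validation_error")
})

test_that("stepwise escalation of a tight binder reaches a stable estimate", {
  truth <- 3.23
  feed <- scenario_feed(axis = "mixture", seed = 7,
                        candidates = c(BCHA = truth),
                        reference = "BMPL", reference_conc = 1e-6,
                        noise_cv = 0)
  tr <- fine_optimize(feed, c(0.2, 0.4, 0.8, 1.2, 1.6) * 1e-6,
                      fx$calibration_single, "BMPL", "BCHA")
  expect_false(any(tr$steps$valid[1:2]))      # binding ratios above 10%
  expect_gt(tr$steps$BR_candidate[1], 0.10)
  expect_false(is.na(tr$stable_from))
  expect_equal(tr$stable_value / truth, 1, tolerance = 0.10)
  # the deviation from truth shrinks as the candidate concentration rises
  devs <- abs(tr$steps$estimate / truth - 1)
  expect_true(all(diff(devs) < 0))
})

test_that("a weak binder plateaus once its extract areas clear the threshold", {
  feed <- scenario_feed(axis = "mixture", seed = 9,
                        candidates = c(BDETA = 0.45),
                        reference = "BMPL", reference_conc = 1e-6,
                        noise_cv = 0)
  tr <- fine_optimize(feed, c(0.2, 0.4, 0.8, 1.6, 3.2) * 1e-6,
                      fx$calibration_single, "BMPL", "BDETA")
  expect_true(all(tr$steps$BR_candidate < 0.10))  # never the BR prerequisite
  expect_false(tr$steps$valid[1])                 # the area prerequisite
  expect_false(is.na(tr$stable_from))
  expect_gt(tr$stable_from, 1L)
})

test_that("exponential escalation validates at the expected step", {
  # equal-to-reference dosing: valid at the first screening mixture
  feed_bme <- scenario_feed(axis = "mixture", seed = 11,
                            candidates = c(BME = 1.90),
                            reference = "BMPL", reference_conc = 1e-6,
                            noise_cv = 0.10)
  ro1 <- rough_optimize(feed_bme, 1e-6, fx$calibration_single, "BMPL", "BME")
  expect_true(ro1$success)
  expect_equal(ro1$step, 1L)

  # overestimated mixture content: invalid at step 1, valid after the
  # four-fold escalation
  feed_bcha <- scenario_feed(axis = "mixture", seed = 13,
                             candidates = c(BCHA = 3.23),
                             reference = "BMPL", reference_conc = 1e-6,
                             noise_cv = 0.10)
  ro2 <- rough_optimize(feed_bcha, 0.3e-6, fx$calibration_single, "BMPL",
                        "BCHA")
  expect_true(ro2$success)
  expect_equal(ro2$step, 2L)
  expect_false(ro2$attempts$valid[1])
  expect_equal(ro2$attempts$composition[2] / ro2$attempts$composition[1], 4)
  # the rough estimate agrees with the fine plateau band
  feed_fine <- scenario_feed(axis = "mixture", seed = 7,
                             candidates = c(BCHA = 3.23),
                             reference = "BMPL", reference_conc = 1e-6,
                             noise_cv = 0)
  tr <- fine_optimize(feed_fine, c(0.2, 0.4, 0.8, 1.2, 1.6) * 1e-6,
                      fx$calibration_single, "BMPL", "BCHA")
  expect_equal(ro2$estimate$ratio / tr$stable_value, 1, tolerance = 0.25)

  expect_error(rough_optimize(feed_bme, 1e-6, fx$calibration_single, "BMPL",
                              "BME", escalation_factor = 1),
               class = "mixscreen_validation_error")
})

test_that("the escalation axis follows the pilot estimate", {
  expect_equal(choose_escalation_axis(0.5), "mixture")
  expect_equal(choose_escalation_axis(5), "reference")
  expect_equal(choose_escalation_axis(3), "mixture")  # tie-break documented
})
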