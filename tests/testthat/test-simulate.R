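test_that("the generator is deterministic and honours configured sizes", {
  cfg <- sim_config(seed = 101, n_intervention = 120L, n_control = 220L)
  r1 <- simulate_roster(cfg)
  r2 <- simulate_roster(cfg)
  expect_identical(r1, r2)
  expect_equal(sum(r1$group == "intervention"), 120L)
  expect_equal(sum(r1$group == "control"), 220L)
  f1 <- simulate_fills(r1, cfg, "baseline")
  f2 <- simulate_fills(r1, cfg, "baseline")
  expect_identical(f1, f2)
  # seeds separate the two periods
  expect_false(identical(f1, simulate_fills(r1, cfg, "follow_up")))
})

test_that("seed is mandatory and invalid configs fail before sampling", {
  expect_error(sim_config(), class = "pdcadhere_validation_error")
  expect_error(sim_config(seed = 1, membership_probs = c(0.5, 0.2, 0.2)),
               class = "pdcadhere_validation_error")
  expect_error(sim_config(seed = 1, rho = 1.4),
               class = "pdcadhere_validation_error")
  expect_error(sim_config(seed = 1, n_intervention = 0L),
               class = "pdcadhere_validation_error")
})

test_that("roster covariates follow the configured distributions", {
  cfg <- sim_config(seed = 5, n_intervention = 5000L, n_control = 5000L)
  r <- simulate_roster(cfg)
  # CLT check on truncated-normal age against its configured centre
  se <- cfg$age_sd / sqrt(nrow(r))
  expect_lt(abs(mean(r$age) - cfg$age_mean), 3 * se + 0.5)  # 0.5 for truncation bias
  expect_true(all(r$age >= 18L & r$age <= 89L))
  expect_lt(abs(mean(r$sex == "female") - cfg$p_female), 0.02)
  expect_true(all(r$enroll_start <= as.Date("2010-03-01")))
})

test_that("generated data round-trips through the CSV dialect and validates", {
  cfg <- sim_config(seed = 7, n_intervention = 40L, n_control = 60L)
  sim <- simulate_claims(cfg, out_dir = withr::local_tempdir())
  # readers apply full validation; identical content comes back
  dir <- withr::local_tempdir()
  write_fills(sim$fills, file.path(dir, "f.csv"))
  write_patients(sim$patients, file.path(dir, "p.csv"))
  expect_equal(read_fills(file.path(dir, "f.csv")), sim$fills)
  back <- read_patients(file.path(dir, "p.csv"))
  expect_equal(back, sim$patients[names(back)])
  expect_true(all(sim$fills$days_supply >= 1L))
})

test_that("propensity limits give perfect adherence and single-fill streams", {
  # perfect-adherence limit: every gap is zero, PDC exactly 1
  perfect <- sim_config(seed = 9, n_intervention = 10L, n_control = 10L,
                        bulk_weight = 1, bulk_range = c(0.999, 1),
                        initial_jitter_max = 0L)
  sim <- simulate_claims(perfect)
  pdc <- compute_pdc(sim$fills, study_windows(perfect$baseline_start))
  expect_true(all(pdc$pdc == 1))
  # never-refill limit: one 90-day fill, PDC 90/365
  never <- sim_config(seed = 9, n_intervention = 30L, n_control = 30L,
                      bulk_weight = 0, tail_range = c(0, 1e-4),
                      supply_levels = 90L, supply_probs = 1,
                      subclass_probs = c(1, 0, 0), initial_jitter_max = 0L)
  sim2 <- simulate_claims(never)
  bl <- sim2$fills[sim2$fills$fill_date < as.Date("2011-03-01"), ]
  fills_per_stream <- table(bl$patient_id, bl$drug_class)
  expect_gte(mean(fills_per_stream[fills_per_stream > 0] == 1), 0.9)
  pdc2 <- compute_pdc(sim2$fills, study_windows(never$baseline_start))
  expect_equal(median(pdc2$pdc), 90 / 365)
})

test_that("default refill streams hit the published PDC band", {
  cfg <- sim_config(seed = 13, n_intervention = 700L, n_control = 1300L)
  sim <- simulate_claims(cfg)
  pdc <- compute_pdc(sim$fills, study_windows(cfg$baseline_start))
  expect_gt(mean(pdc$pdc), 0.83)
  expect_lt(mean(pdc$pdc), 0.89)
  # adherence in the published 75-80% neighbourhood at baseline
  bl <- pdc[pdc$period == "baseline", ]
  expect_gt(mean(bl$adherent), 0.72)
  expect_lt(mean(bl$adherent), 0.82)
})

test_that("a larger intervention shift never lowers intervention adherence", {
  rates <- sapply(c(0, 0.25, 0.5), function(shift) {
    sapply(c(31L, 32L, 33L), function(seed) {
      cfg <- sim_config(seed = seed, n_intervention = 2500L, n_control = 10L,
                        effect_shift = c(antihypertensive = shift,
                                         antihyperlipidemic = 0))
      r <- simulate_roster(cfg)
      f <- simulate_fills(r, cfg, "follow_up")
      pdc <- compute_pdc(f, study_windows(cfg$baseline_start))
      fu <- pdc[pdc$drug_class == "antihypertensive" &
                  pdc$patient_id %in% r$patient_id[r$group == "intervention"], ]
      mean(fu$adherent)
    })
  })
  # monotone in the shift for every seed in the ensemble
  expect_true(all(apply(rates, 1, diff) >= 0))
})

test_that("calibration recovers a null effect and respects its tolerance", {
  cfg <- sim_config(seed = 17)
  out <- calibrate_effect(cfg, c(intervention = 0.76, control = 0.76),
                          drug_class = "antihyperlipidemic",
                          n = 8000L, tol = 0.01)
  expect_lt(abs(out$effect_shift[["antihyperlipidemic"]]), 0.08)
  achieved <- attr(out, "achieved_rates")
  expect_lt(abs(achieved[["control"]] - 0.76), 0.01)
  expect_lt(abs(achieved[["intervention"]] - 0.76), 0.01)
  expect_error(
    calibrate_effect(cfg, c(intervention = 0.999, control = 0.5), n = 2000L,
                     bounds = c(-0.5, 0.5)),
    class = "pdcadhere_calibration_error"
  )
})
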