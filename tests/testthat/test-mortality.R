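test_that("with no excess the schedule equals the corrected background", {
  p <- base_case_parameters()
  p$mortality$excess$state_scale <- 0
  p$mortality$excess$sevex_scale <- 0
  sch <- build_mortality_schedule(p)
  expected <- annual_to_cycle_probability(
    background_annual <- (1 - exp(-(p$mortality$background$makeham_a +
      p$mortality$background$gompertz_b *
        exp(p$mortality$background$gompertz_c * sch$age)))) *
      (1 - p$mortality$background$copd_death_fraction),
    p$settings$cycle_length_years)
  for (st in gold_states()) {
    expect_equal(unname(sch$state_death[, st]), unname(expected), tolerance = 1e-12)
  }
  expect_equal(sch$sevex_excess, rep(0, length(sch$age)))
})

test_that("schedules are monotone in age and GOLD severity", {
  params <- c(list(base_case_parameters()),
              lapply(c(3, 11, 27), generate_random_parameters))
  for (p in params) {
    sch <- build_mortality_schedule(p)
    expect_true(all(sch$state_death >= 0 & sch$state_death <= 1))
    expect_true(all(sch$sevex_excess >= 0 & sch$sevex_excess <= 1))
    # non-decreasing in age for each state
    expect_true(all(apply(sch$state_death, 2, function(q) all(diff(q) >= -1e-15))))
    # GOLD IV >= III >= II at every age
    expect_true(all(sch$state_death[, "GOLD_IV"] >= sch$state_death[, "GOLD_III"]))
    expect_true(all(sch$state_death[, "GOLD_III"] >= sch$state_death[, "GOLD_II"]))
  }
})

test_that("raising the state scale raises death probabilities where RR > 1", {
  p <- base_case_parameters()
  s1 <- build_mortality_schedule(p)
  p2 <- p
  p2$mortality$excess$state_scale <- 2 * p$mortality$excess$state_scale
  s2 <- build_mortality_schedule(p2)
  rr_above_1 <- p$mortality$excess$state_rr > 1  # GOLD III and IV in the base case
  for (st in gold_states()[rr_above_1]) {
    expect_true(all(s2$state_death[, st] > s1$state_death[, st]))
  }
  for (st in gold_states()[!rr_above_1]) {
    expect_true(all(s2$state_death[, st] >= s1$state_death[, st]))
  }
})

test_that("the decade gradient interpolates linearly between knots", {
  p <- base_case_parameters()
  ex <- p$mortality$excess
  sch <- build_mortality_schedule(p)
  q_annual <- cycle_to_annual_probability(sch$state_death[, "GOLD_IV"],
                                          p$settings$cycle_length_years)
  bg <- (1 - exp(-(p$mortality$background$makeham_a +
                     p$mortality$background$gompertz_b *
                     exp(p$mortality$background$gompertz_c * sch$age)))) *
    (1 - p$mortality$background$copd_death_fraction)
  implied_excess <- q_annual / bg - 1  # state_scale * (RR(age) - 1)
  base_excess <- ex$state_scale * (ex$state_rr[["GOLD_IV"]] - 1)
  # at the reference age: the point estimate; one decade later: gradient times it
  i65 <- which(sch$age == 65)
  i75 <- which(sch$age == 75)
  i70 <- which(sch$age == 70)
  expect_equal(implied_excess[i65], base_excess, tolerance = 1e-9)
  expect_equal(implied_excess[i75], base_excess * ex$state_age_gradient,
               tolerance = 1e-9)
  expect_equal(implied_excess[i70],
               base_excess * (1 + ex$state_age_gradient) / 2, tolerance = 1e-9)
})

test_that("calibration reproduces both anchors and is deterministic", {
  pc <- calibrated_base()
  expect_lt(abs(pc$calibration$residual[["uc"]]), 1e-3)
  expect_lt(abs(pc$calibration$residual[["gly"]]), 1e-3)
  sch <- build_mortality_schedule(pc)
  expect_equal(run_cohort("UC", pc, sch)$life_years,
               pc$anchors$uc_discounted_ly, tolerance = 1e-3)
  expect_equal(run_cohort("GLY", pc, sch)$life_years,
               pc$anchors$gly_discounted_ly, tolerance = 1e-3)
  # idempotence: recalibrating the calibrated model returns the same scales
  pc2 <- calibrate_mortality(pc)
  expect_equal(pc2$calibration$scales, pc$calibration$scales, tolerance = 1e-5)
  # determinism: a fresh calibration from the packaged defaults agrees
  pc3 <- calibrate_mortality(base_case_parameters())
  expect_equal(pc3$calibration$scales, pc$calibration$scales, tolerance = 1e-9)
})

test_that("the usual-care arm outlives its anchor without excess mortality", {
  p <- base_case_parameters()
  p$mortality$excess$state_scale <- 0
  p$mortality$excess$sevex_scale <- 0
  ly <- run_cohort("UC", p)$life_years
  expect_gt(ly, p$anchors$uc_discounted_ly)
})

test_that("life years decrease monotonically in each calibration scale", {
  p <- base_case_parameters()
  uc_ly <- sapply(c(0, 0.7, 1.4, 2.8), function(s) {
    p$mortality$excess$state_scale <- s
    run_cohort("UC", p)$life_years
  })
  expect_true(all(diff(uc_ly) < 0))
  p$mortality$excess$state_scale <- 1.4
  gly_ly <- sapply(c(0, 1, 2, 4), function(x) {
    p$mortality$excess$sevex_scale <- x
    run_cohort("GLY", p)$life_years
  })
  expect_true(all(diff(gly_ly) < 0))
})

test_that("undiscounted engine life years match direct survival summation", {
  pc <- calibrated_base()
  p0 <- pc
  p0$settings$discount_rate_annual <- 0
  sch <- build_mortality_schedule(p0)
  engine_ly <- run_cohort("UC", p0, sch)$life_years
  oracle_ly <- oracle_life_expectancy("UC", p0, sch,
                                      p0$settings$max_age - p0$settings$start_age)
  expect_equal(engine_ly, oracle_ly, tolerance = 0.02)
})

test_that("calibration succeeds across jittered synthetic backgrounds", {
  for (seed in c(2, 5, 8)) {
    p <- base_case_parameters()
    p$mortality$background <- generate_synthetic_mortality(seed, roughness = 0.1)
    pc <- calibrate_mortality(p)
    expect_lt(max(abs(pc$calibration$residual)), 1e-3)
  }
})

test_that("calibration sidecar records scales and provenance", {
  pc <- calibrated_base()
  path <- withr::local_tempfile(fileext = ".json")
  save_calibration(pc, path)
  side <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_equal(side$scales$state_scale, unname(pc$calibration$scales["state_scale"]))
  expect_equal(side$anchors$uc_discounted_ly, 10.18)
  expect_true(side$engine_runs > 0)
  expect_error(save_calibration(base_case_parameters(), path), "no calibration")
})
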