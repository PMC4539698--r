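test_that("treatment phases follow the duration boundaries", {
  expect_equal(treatment_phase(1, 4, 0.25), "FIRST_CYCLE")
  expect_equal(treatment_phase(16, 4, 0.25), "ON_TREATMENT")
  expect_equal(treatment_phase(17, 4, 0.25), "OFF_TREATMENT")
  expect_equal(treatment_phase(1, 0.25, 0.25), "FIRST_CYCLE")
  expect_equal(treatment_phase(2, 0.25, 0.25), "OFF_TREATMENT")
  expect_equal(treatment_phase(c(1, 2, 16, 17, 140), 4, 0.25),
               c("FIRST_CYCLE", "ON_TREATMENT", "ON_TREATMENT",
                 "OFF_TREATMENT", "OFF_TREATMENT"))
  expect_error(treatment_phase(0, 4, 0.25), ">= 1")
})

test_that("a degenerate cycle is a fixed point with closed-form accruals", {
  p <- fixed_point_parameters()
  eye <- diag(3); dimnames(eye) <- list(gold_states(), gold_states())
  occ <- setNames(c(1, 0, 0), gold_states())
  st <- step_cycle(occ, p$events$UC, eye, state_death = rep(0, 3),
                   sevex_excess = 0, costs = p$costs, utilities = p$utilities,
                   drug_cost_cycle = 0, discount = 0.9, cycle_length_years = 0.25)
  expect_equal(st$occupancy, occ)
  expect_equal(st$died, 0)
  expect_equal(st$accruals$direct_cost, p$costs["GOLD_II", "no_exacerbation"] * 0.9)
  expect_equal(st$accruals$qalys,
               p$utilities["GOLD_II", "no_exacerbation"] * 0.25 * 0.9)
  expect_equal(st$accruals$life_years, 0.25 * 0.9)
  expect_equal(unname(st$accruals$events), c(1, 0, 0))
})

test_that("an extinct cohort accrues nothing and stays extinct", {
  p <- base_case_parameters()
  occ <- setNames(c(0, 0, 0), gold_states())
  st <- step_cycle(occ, p$events$UC, p$transitions$UC$subsequent,
                   state_death = rep(0.01, 3), sevex_excess = 0.1,
                   costs = p$costs, utilities = p$utilities,
                   drug_cost_cycle = 100, discount = 1, cycle_length_years = 0.25)
  expect_equal(st$occupancy, occ)
  expect_equal(st$accruals$direct_cost + st$accruals$treatment_cost +
                 st$accruals$qalys + st$accruals$life_years, 0)
})

test_that("one usual-care first cycle reproduces the hand-multiplied product", {
  p <- base_case_parameters()
  occ <- p$settings$initial_distribution
  st <- step_cycle(occ, p$events$UC, p$transitions$UC$first_cycle,
                   state_death = rep(0, 3), sevex_excess = 0,
                   costs = p$costs, utilities = p$utilities,
                   drug_cost_cycle = 0, discount = 1, cycle_length_years = 0.25)
  # (0.48, 0.44, 0.08) %*% first-cycle matrix, multiplied out by hand:
  #   to II : .48*.86 + .44*.13 + .08*.02 = .4716
  #   to III: .48*.13 + .44*.81 + .08*.22 = .4364
  #   to IV : .48*.01 + .44*.06 + .08*.76 = .0920
  expect_equal(unname(st$occupancy), c(0.4716, 0.4364, 0.0920), tolerance = 1e-15)
})

test_that("the engine matches the enumeration oracle over eight cycles", {
  cases <- list(calibrated_base(),
                generate_random_parameters(41),
                generate_random_parameters(59))
  for (p in cases) {
    sch <- build_mortality_schedule(p)
    for (arm in model_arms()) {
      eng <- run_cohort(arm, p, sch, horizon_years = 2)
      ora <- oracle_run(arm, p, sch, horizon_years = 2)
      for (field in c("treatment_cost", "other_direct_cost", "total_cost",
                      "qalys", "life_years", "person_years")) {
        expect_equal(eng[[field]], ora[[field]], tolerance = 1e-9,
                     label = paste(arm, field))
      }
      expect_equal(unname(eng$events), unname(ora$events), tolerance = 1e-9)
    }
  }
})

test_that("cohort mass is conserved and the alive fraction never grows", {
  for (p in list(calibrated_base(), generate_random_parameters(101))) {
    res <- run_cohort("TIO", p, trace = TRUE)
    mass <- rowSums(res$trace)
    expect_true(all(abs(mass - 1) < 1e-10))
    alive <- rowSums(res$trace[, gold_states()])
    expect_true(all(diff(alive) <= 1e-12))
    expect_equal(sum(res$final_occupancy), 1, tolerance = 1e-10)
  }
})

test_that("heavier mortality never buys more life years, QALYs or costs", {
  pc <- calibrated_base()
  sch <- base_schedule()
  heavier <- sch
  heavier$state_death <- pmin(sch$state_death * 1.25, 1)
  for (arm in c("UC", "TIO")) {
    a <- run_cohort(arm, pc, sch)
    b <- run_cohort(arm, pc, heavier)
    expect_lt(b$life_years, a$life_years)
    expect_lt(b$qalys, a$qalys)
    expect_lt(b$total_cost, a$total_cost)
    expect_lt(b$person_years, a$person_years)
  }
})

test_that("discounting can only shrink non-negative accumulators", {
  pc <- calibrated_base()
  sch <- base_schedule()
  p0 <- pc
  p0$settings$discount_rate_annual <- 0
  for (arm in model_arms()) {
    r0 <- run_cohort(arm, p0, sch)
    r3 <- run_cohort(arm, pc, sch)
    for (field in c("treatment_cost", "other_direct_cost", "qalys", "life_years")) {
      expect_gte(r0[[field]], r3[[field]])
    }
    # undiscounted quantities are identical
    expect_equal(r0$events, r3$events)
    expect_equal(r0$person_years, r3$person_years)
  }
})

test_that("without mortality or discounting, life years equal the horizon", {
  p <- generate_random_parameters(7, corner = "zero_mortality")
  p$settings$discount_rate_annual <- 0
  for (h in c(1, 4, 10)) {
    res <- run_cohort("GLY", p, horizon_years = h)
    expect_equal(res$life_years, h, tolerance = 1e-9)
    expect_equal(res$person_years, h, tolerance = 1e-9)
  }
  expect_error(run_cohort("GLY", p, horizon_years = 1.1), "whole number")
})

test_that("annualised event rates recover the per-cycle probability", {
  p <- generate_random_parameters(13, corner = c("zero_mortality",
                                                 "identity_transitions",
                                                 "point_mass_initial"))
  sev <- 0.07
  for (arm in model_arms()) p$events[[arm]] <- build_event_table(c(0.2, 0, 0), c(sev, 0, 0))
  res <- run_cohort("UC", p, horizon_years = 0.25)
  expect_equal(annualized_event_rate(res, "severe"), sev / 0.25)
  expect_equal(annualized_event_rate(res, "nonsevere"), 0.2 / 0.25)
  res0 <- run_cohort("UC", p, horizon_years = 0.25)
  res0$person_years <- 0
  expect_error(annualized_event_rate(res0), "person-years")
})
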