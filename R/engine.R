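## ---------------------------------------------------------------------------
## Deterministic cohort engine.
##
## One cycle, in order, for each alive GOLD state:
##   1. split the state's occupancy across the three events (no / non-severe /
##      severe exacerbation) with the phase-appropriate event table;
##   2. accrue drug cost (while on treatment), direct cost, utility and life
##      years for the full cycle, discounted -- patients dying within the
##      cycle still accrue it, matching the event-then-death ordering of the
##      model (the hospitalisation cost of a fatal severe exacerbation is
##      real);
##   3. apply the state's per-cycle death probability, plus the per-event
##      severe-exacerbation excess for the severe fraction (capped at 1);
##   4. move survivors between GOLD states with the phase-appropriate
##      transition matrix (rows are conditional on survival, so no
##      renormalisation).
## Event counts and person-years accumulate undiscounted.
## ---------------------------------------------------------------------------

#' Treatment phase of a cycle
#'
#' The first cycle on treatment has its own transition matrix (capturing the
#' initial 30-day bronchodilation effect); cycles up to the end of the
#' treatment duration use the subsequent-cycle on-treatment inputs; later
#' cycles revert to usual-care behaviour (little persistence of LAMA effect
#' after stopping).
#'
#' @param cycle_index 1-based cycle index.
#' @param treatment_duration_years Treatment duration in years.
#' @param cycle_length_years Cycle length in years.
#' @return One of `"FIRST_CYCLE"`, `"ON_TREATMENT"`, `"OFF_TREATMENT"`.
#' @export
treatment_phase <- function(cycle_index, treatment_duration_years, cycle_length_years) {
  if (any(cycle_index < 1)) stop("cycle_index must be >= 1")
  n_on <- round(treatment_duration_years / cycle_length_years)
  ifelse(cycle_index == 1L, "FIRST_CYCLE",
         ifelse(cycle_index <= n_on, "ON_TREATMENT", "OFF_TREATMENT"))
}

#' Advance the cohort by one cycle
#'
#' Low-level single-cycle update; [run_cohort()] drives it over a horizon.
#' Exposed so the cycle arithmetic can be checked directly against hand
#' calculations and an enumeration oracle.
#'
#' @param occupancy Length-3 occupancy over the alive GOLD states (the DEAD
#'   mass is tracked by the caller).
#' @param events 3x3 state-by-event probability matrix for this cycle.
#' @param transitions 3x3 transition matrix (conditional on survival).
#' @param state_death Length-3 per-cycle death probabilities by state.
#' @param sevex_excess Additional per-cycle death probability for the severe
#'   exacerbation fraction.
#' @param costs,utilities 3x3 state-by-event cost (SEK per cycle) and annual
#'   utility tables.
#' @param drug_cost_cycle Drug cost accrued per alive patient this cycle
#'   (zero off treatment or in the usual-care arm).
#' @param discount Discount factor for this cycle.
#' @param cycle_length_years Cycle length in years.
#' @return List with the next `occupancy`, the `died` mass, and the cycle's
#'   accruals (`treatment_cost`, `direct_cost`, `qalys`, `life_years`
#'   discounted; `events`, `person_years` undiscounted).
#' @export
step_cycle <- function(occupancy, events, transitions, state_death, sevex_excess,
                       costs, utilities, drug_cost_cycle, discount,
                       cycle_length_years) {
  if (any(occupancy < -1e-12)) stop("negative occupancy mass")
  alive <- sum(occupancy)

  event_mass <- occupancy * events  # 3x3: state x event
  accruals <- list(
    treatment_cost = alive * drug_cost_cycle * discount,
    direct_cost = sum(event_mass * costs) * discount,
    qalys = sum(event_mass * utilities) * cycle_length_years * discount,
    life_years = alive * cycle_length_years * discount,
    events = colSums(event_mass),
    person_years = alive * cycle_length_years
  )

  ## deaths: state probability for everyone, plus the capped per-event excess
  ## for the severe fraction
  extra <- pmin(sevex_excess, 1 - state_death)
  died_by_state <- occupancy * state_death + event_mass[, "severe"] * extra
  survivors <- occupancy - died_by_state
  if (any(survivors < -1e-12)) stop("negative survivor mass")
  survivors <- pmax(survivors, 0)

  next_occ <- as.vector(crossprod(transitions, survivors))
  names(next_occ) <- names(occupancy)
  list(occupancy = next_occ, died = sum(died_by_state), accruals = accruals)
}

## Resolve the inputs an arm uses in a given phase.
phase_inputs <- function(arm, phase, params) {
  off <- phase == "OFF_TREATMENT"
  event_arm <- if (off && params$settings$off_treatment_event_risks == "usual_care")
    "UC" else arm
  list(
    events = params$events[[event_arm]],
    transitions = if (off) params$transitions$UC$subsequent
                  else if (phase == "FIRST_CYCLE") params$transitions[[arm]]$first_cycle
                  else params$transitions[[arm]]$subsequent,
    drug_cost_cycle = if (off) 0 else
      params$settings$drug_cost_per_day[[arm]] * 365.25 * params$settings$cycle_length_years
  )
}

#' Run one strategy arm over the model horizon
#'
#' Propagates the cohort from the initial GOLD distribution through
#' three-month cycles until the horizon (by default, until the cohort reaches
#' the maximum age), accumulating discounted costs, QALYs and life years and
#' undiscounted event counts. Deterministic.
#'
#' @param arm `"UC"`, `"TIO"`, or `"GLY"`.
#' @param params A `copd_parameters` object.
#' @param schedule A `copd_mortality_schedule`; built from `params` if `NULL`.
#' @param horizon_years Simulated horizon in years (whole number of cycles);
#'   defaults to `max_age - start_age`.
#' @param trace If `TRUE`, attach a cycle-by-cycle occupancy matrix.
#' @return A `copd_arm_result`: discounted `treatment_cost`,
#'   `other_direct_cost`, `total_cost`, `qalys`, `life_years`; undiscounted
#'   expected `events` per type and `person_years`; plus the run settings.
#' @export
run_cohort <- function(arm, params, schedule = NULL, horizon_years = NULL,
                       trace = FALSE) {
  arm <- match.arg(arm, ARMS)
  s <- params$settings
  cl <- s$cycle_length_years
  if (is.null(horizon_years)) horizon_years <- s$max_age - s$start_age
  n_cycles <- horizon_years / cl
  if (abs(n_cycles - round(n_cycles)) > 1e-9) {
    stop("horizon is not a whole number of cycles")
  }
  n_cycles <- round(n_cycles)
  if (is.null(schedule)) schedule <- build_mortality_schedule(params)
  if (length(schedule$age) < n_cycles) {
    stop("mortality schedule shorter than the requested horizon")
  }

  inputs <- list(
    FIRST_CYCLE = phase_inputs(arm, "FIRST_CYCLE", params),
    ON_TREATMENT = phase_inputs(arm, "ON_TREATMENT", params),
    OFF_TREATMENT = phase_inputs(arm, "OFF_TREATMENT", params)
  )
  dfs <- discount_factor(s$discount_rate_annual, seq_len(n_cycles), cl)
  phases <- treatment_phase(seq_len(n_cycles), s$treatment_duration_years, cl)

  occ <- s$initial_distribution
  dead <- 0
  acc <- list(treatment_cost = 0, direct_cost = 0, qalys = 0, life_years = 0,
              events = setNames(numeric(3), EVENT_TYPES), person_years = 0)
  occ_trace <- if (trace) matrix(NA_real_, n_cycles, 4,
                                 dimnames = list(NULL, c(GOLD_STATES, "DEAD")))

  for (k in seq_len(n_cycles)) {
    inp <- inputs[[phases[k]]]
    st <- step_cycle(occ, inp$events, inp$transitions,
                     schedule$state_death[k, ], schedule$sevex_excess[k],
                     params$costs, params$utilities, inp$drug_cost_cycle,
                     dfs[k], cl)
    occ <- st$occupancy
    dead <- dead + st$died
    a <- st$accruals
    acc$treatment_cost <- acc$treatment_cost + a$treatment_cost
    acc$direct_cost <- acc$direct_cost + a$direct_cost
    acc$qalys <- acc$qalys + a$qalys
    acc$life_years <- acc$life_years + a$life_years
    acc$events <- acc$events + a$events
    acc$person_years <- acc$person_years + a$person_years
    if (abs(sum(occ) + dead - 1) > 1e-12 * k) {
      stop("cohort mass not conserved at cycle ", k)
    }
    if (trace) occ_trace[k, ] <- c(occ, dead)
  }

  structure(list(
    arm = arm,
    treatment_cost = acc$treatment_cost,
    other_direct_cost = acc$direct_cost,
    total_cost = acc$treatment_cost + acc$direct_cost,
    qalys = acc$qalys,
    life_years = acc$life_years,
    events = acc$events,
    person_years = acc$person_years,
    final_occupancy = c(occ, DEAD = dead),
    settings = list(discount_rate_annual = s$discount_rate_annual,
                    cycle_length_years = cl, start_age = s$start_age,
                    horizon_years = horizon_years,
                    treatment_duration_years = s$treatment_duration_years),
    trace = if (trace) occ_trace
  ), class = "copd_arm_result")
}

#' @export
print.copd_arm_result <- function(x, ...) {
  cat(sprintf("%s arm over %g years (discounted at %g%%/y):\n", x$arm,
              x$settings$horizon_years, 100 * x$settings$discount_rate_annual))
  cat(sprintf("  costs (SEK): treatment %.0f + direct %.0f = %.0f\n",
              x$treatment_cost, x$other_direct_cost, x$total_cost))
  cat(sprintf("  effects: %.3f QALYs, %.3f life years\n", x$qalys, x$life_years))
  cat(sprintf("  events per patient: %.3f non-severe, %.3f severe (%.2f person-years)\n",
              x$events[["nonsevere"]], x$events[["severe"]], x$person_years))
  invisible(x)
}

#' Annualised event rate of a cohort run
#'
#' Expected events per patient-year: cumulative undiscounted expected event
#' count divided by cumulative undiscounted person-years alive.
#'
#' @param result A `copd_arm_result`.
#' @param event One of the event types (default `"severe"`).
#' @return Events per patient-year.
#' @export
annualized_event_rate <- function(result, event = "severe") {
  event <- match.arg(event, EVENT_TYPES)
  if (result$person_years <= 0) stop("no person-years at risk")
  unname(result$events[[event]] / result$person_years)
}
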