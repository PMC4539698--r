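# Independent explicit-enumeration re-implementation of the cohort model,
# used as an oracle for short runs. Written deliberately in a different
# style from the engine: scalar loops over states, events and destinations,
# no matrix algebra, discount factors recomputed in log space. Only shares
# the parameter object layout with the package.

oracle_run <- function(arm, params, schedule, horizon_years,
                       discount_rate = NULL) {
  s <- params$settings
  cl <- s$cycle_length_years
  if (is.null(discount_rate)) discount_rate <- s$discount_rate_annual
  n_cycles <- round(horizon_years / cl)
  n_on <- round(s$treatment_duration_years / cl)

  occ <- as.numeric(s$initial_distribution)
  dead <- 0
  treat_cost <- direct_cost <- qalys <- ly <- py <- 0
  events <- c(0, 0, 0)

  for (k in 1:n_cycles) {
    df <- exp(-log(1 + discount_rate) * (k - 1) * cl)
    on_treatment <- k <= n_on
    if (k == 1) {
      M <- params$transitions[[arm]]$first_cycle
    } else if (on_treatment) {
      M <- params$transitions[[arm]]$subsequent
    } else {
      M <- params$transitions$UC$subsequent
    }
    ev_arm <- if (on_treatment) arm else
      if (identical(s$off_treatment_event_risks, "arm")) arm else "UC"
    E <- params$events[[ev_arm]]
    drug <- if (on_treatment && arm != "UC") {
      s$drug_cost_per_day[[arm]] * 365.25 * cl
    } else 0

    nxt <- c(0, 0, 0)
    for (st in 1:3) {
      if (occ[st] == 0) next
      treat_cost <- treat_cost + occ[st] * drug * df
      ly <- ly + occ[st] * cl * df
      py <- py + occ[st] * cl
      for (ev in 1:3) {
        mass <- occ[st] * E[st, ev]
        direct_cost <- direct_cost + mass * params$costs[st, ev] * df
        qalys <- qalys + mass * params$utilities[st, ev] * cl * df
        events[ev] <- events[ev] + mass
        d <- schedule$state_death[k, st]
        if (ev == 3) d <- d + min(schedule$sevex_excess[k], 1 - d)
        dead <- dead + mass * d
        for (to in 1:3) {
          nxt[to] <- nxt[to] + mass * (1 - d) * M[st, to]
        }
      }
    }
    occ <- nxt
  }
  list(treatment_cost = treat_cost, other_direct_cost = direct_cost,
       total_cost = treat_cost + direct_cost, qalys = qalys, life_years = ly,
       person_years = py,
       events = stats::setNames(events, c("no_exacerbation", "nonsevere", "severe")),
       alive = sum(occ), dead = dead)
}

# Survival-curve life expectancy of the mixed cohort by direct summation:
# alive-mass trajectory from the same schedule and transition structure,
# undiscounted, summed cycle by cycle.
oracle_life_expectancy <- function(arm, params, schedule, horizon_years) {
  res <- oracle_run(arm, params, schedule, horizon_years, discount_rate = 0)
  res$life_years
}
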