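## ---------------------------------------------------------------------------
## One-way deterministic sensitivity analysis (scenario overrides / tornado)
## and Monte Carlo probabilistic sensitivity analysis with CEACs.
## ---------------------------------------------------------------------------

## Set a value at a dot-separated path inside a nested list/matrix structure.
set_in <- function(x, keys, value) {
  if (length(keys) == 1L) {
    x[[keys]] <- value
    return(x)
  }
  x[[keys[1L]]] <- set_in(x[[keys[1L]]], keys[-1L], value)
  x
}

#' Define a scenario override for one-way sensitivity analysis
#'
#' A scenario is a named patch applied to a copy of the base parameters
#' before a full deterministic model run. The patch is either a named list
#' mapping dot-separated parameter paths to replacement values (e.g.
#' `list("settings.discount_rate_annual" = 0)`) or a function
#' `params -> params` for structural changes (e.g. re-deriving an event table
#' from a relative risk). Patched parameters are re-validated.
#'
#' @param name Scenario label.
#' @param patch Named list of path/value pairs, or a function.
#' @param horizon_years Optional horizon override for the runs.
#' @param recalibrate If `TRUE`, the two mortality scales are re-calibrated
#'   to the anchors under the patched parameters before running.
#' @param group Optional parameter-group label used to pair low/high
#'   scenarios in a tornado layout.
#' @return A `copd_scenario` object.
#' @export
scenario_override <- function(name, patch = list(), horizon_years = NULL,
                              recalibrate = FALSE, group = NULL) {
  stopifnot(is.character(name), length(name) == 1L,
            is.list(patch) || is.function(patch))
  structure(list(name = name, patch = patch, horizon_years = horizon_years,
                 recalibrate = recalibrate, group = group),
            class = "copd_scenario")
}

#' Apply a scenario patch to a parameter set
#'
#' @param params A `copd_parameters` object.
#' @param patch Named list of dot-path/value pairs or a function; see
#'   [scenario_override()].
#' @return The patched, re-validated `copd_parameters`.
#' @export
apply_override <- function(params, patch) {
  if (is.function(patch)) {
    params <- patch(params)
  } else {
    for (path in names(patch)) {
      params <- set_in(params, strsplit(path, ".", fixed = TRUE)[[1L]], patch[[path]])
    }
  }
  out <- validate_parameters(params)
  out$calibration <- params$calibration
  out
}

## Patch helper: rebuild the GLY event table from the TIO table at a given
## severe relative risk (used by the RR scenarios and the PSA).
patch_gly_rr <- function(params, rr_severe) {
  params$events$GLY <- derive_comparator_events(params$events$TIO, rr_severe)
  params$rr_severe$point <- rr_severe
  params
}

#' Built-in one-way sensitivity scenarios
#'
#' The standard scenario battery for this model: discount rate 0%/5%, time
#' horizon 5/10/20 years, treatment duration 1/10 years and lifelong, sex as
#' a scalar background-mortality adjustment (re-calibrated), start age 40/80
#' (base-case calibration scales reused, since no life-year anchors exist for
#' those cohorts), initial GOLD distribution point masses, mortality
#' structure variants (general-population mortality for all states; +/-20%
#' severe-exacerbation excess), the GLY/TIO severe-exacerbation relative risk
#' at its 95% CI limits, severe-exacerbation costs +/-20%, and the
#' severe-exacerbation QoL decrement at 0%/20%.
#'
#' @param params Base `copd_parameters` (used for point values in the
#'   relative patches).
#' @param sex_background_factor Scalar applied to the background hazard for
#'   the male-only (x) and female-only (1/x) scenarios.
#' @return A list of `copd_scenario` objects.
#' @export
base_dsa_scenarios <- function(params, sex_background_factor = 1.25) {
  lifetime <- params$settings$max_age - params$settings$start_age
  scale_background <- function(f) function(p) {
    p$mortality$background$makeham_a <- p$mortality$background$makeham_a * f
    p$mortality$background$gompertz_b <- p$mortality$background$gompertz_b * f
    p
  }
  scale_sevex <- function(f) function(p) {
    p$mortality$excess$sevex_scale <- p$mortality$excess$sevex_scale * f
    p
  }
  scale_severe_cost <- function(f) function(p) {
    p$costs[, "severe"] <- p$costs[, "severe"] * f
    p
  }
  qol_loss_severe <- function(loss) function(p) {
    p$utilities[, "severe"] <- p$utilities[, "no_exacerbation"] * (1 - loss)
    p
  }
  point_mass <- function(state) {
    setNames(as.numeric(GOLD_STATES == state), GOLD_STATES)
  }
  list(
    scenario_override("Base case"),
    scenario_override("Discount rate 0%",
                      list("settings.discount_rate_annual" = 0), group = "Discount rate"),
    scenario_override("Discount rate 5%",
                      list("settings.discount_rate_annual" = 0.05), group = "Discount rate"),
    scenario_override("Time horizon 5 years", horizon_years = 5, group = "Time horizon"),
    scenario_override("Time horizon 10 years", horizon_years = 10, group = "Time horizon"),
    scenario_override("Time horizon 20 years", horizon_years = 20, group = "Time horizon"),
    scenario_override("Treatment duration 1 year",
                      list("settings.treatment_duration_years" = 1),
                      group = "Treatment duration"),
    scenario_override("Treatment duration 10 years",
                      list("settings.treatment_duration_years" = 10),
                      group = "Treatment duration"),
    scenario_override(sprintf("Treatment duration life (%g years)", lifetime),
                      list("settings.treatment_duration_years" = lifetime),
                      group = "Treatment duration"),
    scenario_override("Males only", scale_background(sex_background_factor),
                      recalibrate = TRUE, group = "Sex"),
    scenario_override("Females only", scale_background(1 / sex_background_factor),
                      recalibrate = TRUE, group = "Sex"),
    scenario_override("Start age 40", list("settings.start_age" = 40), group = "Start age"),
    scenario_override("Start age 80", list("settings.start_age" = 80), group = "Start age"),
    scenario_override("All start in GOLD II",
                      list("settings.initial_distribution" = point_mass("GOLD_II")),
                      group = "Initial GOLD distribution"),
    scenario_override("All start in GOLD III",
                      list("settings.initial_distribution" = point_mass("GOLD_III")),
                      group = "Initial GOLD distribution"),
    scenario_override("All start in GOLD IV",
                      list("settings.initial_distribution" = point_mass("GOLD_IV")),
                      group = "Initial GOLD distribution"),
    ## plain general-population mortality in every GOLD state (no state
    ## excess, no COPD-death removal); the severe-exacerbation event excess
    ## is a separate assumption and is varied by its own scenario pair
    scenario_override("Normal mortality (not adjusted for COPD) for all GOLD states",
                      function(p) {
                        p$mortality$excess$state_scale <- 0
                        p$mortality$background$copd_death_fraction <- 0
                        p
                      }, group = "Mortality structure"),
    scenario_override("20% higher excess mortality (severe exacerbation)",
                      scale_sevex(1.2), group = "Severe-exacerbation excess mortality"),
    scenario_override("20% lower excess mortality (severe exacerbation)",
                      scale_sevex(0.8), group = "Severe-exacerbation excess mortality"),
    scenario_override("RR severe exacerbation (GLY/TIO) low 95% CI",
                      function(p) patch_gly_rr(p, p$rr_severe$ci_low),
                      group = "RR severe exacerbation"),
    scenario_override("RR severe exacerbation (GLY/TIO) high 95% CI",
                      function(p) patch_gly_rr(p, p$rr_severe$ci_high),
                      group = "RR severe exacerbation"),
    scenario_override("Severe exacerbation costs +20%", scale_severe_cost(1.2),
                      group = "Severe-exacerbation cost"),
    scenario_override("Severe exacerbation costs -20%", scale_severe_cost(0.8),
                      group = "Severe-exacerbation cost"),
    scenario_override("Severe exacerbation QoL loss 0%", qol_loss_severe(0),
                      group = "Severe-exacerbation QoL loss"),
    scenario_override("Severe exacerbation QoL loss 20%", qol_loss_severe(0.2),
                      group = "Severe-exacerbation QoL loss")
  )
}

## Run the arms needed by a comparison label ("TIO_vs_UC" / "TIO_vs_GLY").
comparison_arms <- function(comparison) {
  switch(comparison,
         TIO_vs_UC = c(reference = "UC", intervention = "TIO"),
         TIO_vs_GLY = c(reference = "GLY", intervention = "TIO"),
         stop("unknown comparison: ", comparison))
}

#' One-way deterministic sensitivity analysis
#'
#' Applies each scenario to a copy of the base parameters, re-calibrates the
#' mortality scales where the scenario demands it, runs a full deterministic
#' model per comparison, and tabulates incremental results. A scenario whose
#' patch fails validation yields an error row; the remaining scenarios still
#' run.
#'
#' @param params Base (typically calibrated) `copd_parameters`.
#' @param scenarios List of `copd_scenario` objects; defaults to
#'   [base_dsa_scenarios()].
#' @param comparisons Character vector among `"TIO_vs_UC"`, `"TIO_vs_GLY"`.
#' @return A data frame with one row per scenario x comparison: `scenario`,
#'   `group`, `comparison`, `delta_cost`, `delta_qalys`, `icer`, `label`
#'   (`label` is `"ERROR"` with the message in `icer`'s place left `NA` when
#'   the patch was invalid).
#' @export
run_one_way_dsa <- function(params, scenarios = base_dsa_scenarios(params),
                            comparisons = c("TIO_vs_UC", "TIO_vs_GLY")) {
  rows <- list()
  for (sc in scenarios) {
    res <- tryCatch({
      p <- apply_override(params, sc$patch)
      if (isTRUE(sc$recalibrate)) p <- calibrate_mortality(p)
      schedule <- build_mortality_schedule(p)
      arms <- unique(unlist(lapply(comparisons, comparison_arms)))
      runs <- setNames(lapply(arms, run_cohort, params = p, schedule = schedule,
                              horizon_years = sc$horizon_years), arms)
      lapply(comparisons, function(cmp) {
        pair <- comparison_arms(cmp)
        inc <- incremental_analysis(runs[[pair[["reference"]]]],
                                    runs[[pair[["intervention"]]]])
        data.frame(scenario = sc$name,
                   group = if (is.null(sc$group)) NA_character_ else sc$group,
                   comparison = cmp, delta_cost = inc$delta_cost,
                   delta_qalys = inc$delta_qalys, icer = inc$icer,
                   label = inc$label, stringsAsFactors = FALSE)
      })
    }, error = function(e) {
      lapply(comparisons, function(cmp) {
        data.frame(scenario = sc$name,
                   group = if (is.null(sc$group)) NA_character_ else sc$group,
                   comparison = cmp, delta_cost = NA_real_, delta_qalys = NA_real_,
                   icer = NA_real_, label = paste("ERROR:", conditionMessage(e)),
                   stringsAsFactors = FALSE)
      })
    })
    rows <- c(rows, res)
  }
  do.call(rbind, rows)
}

#' Tornado layout of a one-way DSA table
#'
#' Pairs the low/high scenarios of each parameter group and reports their
#' ICERs side by side, ordered by the width of the ICER swing.
#'
#' @param dsa Data frame from [run_one_way_dsa()].
#' @param comparison Which comparison to lay out.
#' @return Data frame with `group`, `icer_low`, `icer_high`, `swing`.
#' @export
tornado_table <- function(dsa, comparison = "TIO_vs_UC") {
  d <- dsa[dsa$comparison == comparison & !is.na(dsa$group), ]
  out <- do.call(rbind, lapply(split(d, d$group), function(g) {
    rng <- range(g$icer, na.rm = TRUE)
    data.frame(group = g$group[1L], icer_low = rng[1L], icer_high = rng[2L],
               swing = diff(rng), stringsAsFactors = FALSE)
  }))
  out[order(-out$swing), , drop = FALSE]
}

#' Default PSA parameter distributions
#'
#' The probabilistic layer of the model: the GLY/TIO severe-exacerbation
#' relative risk is lognormal with median at the point estimate and sigma
#' derived from its 95% CI, `sigma = (log(ci_high) - log(ci_low)) / (2 *
#' 1.959964)`; every direct-cost and utility cell is drawn independently
#' from a uniform interval of +/- the given fraction around its point
#' estimate (utilities truncated at 1).
#'
#' @param params A `copd_parameters` object.
#' @param cost_fraction,utility_fraction Half-width of the uniform intervals
#'   as a fraction of the point estimates (default 0.2).
#' @return Distribution specification list for [run_psa()].
#' @export
psa_distributions <- function(params, cost_fraction = 0.2, utility_fraction = 0.2) {
  rr <- params$rr_severe
  list(
    rr_severe = list(family = "lognormal_ci", point = rr$point,
                     ci_low = rr$ci_low, ci_high = rr$ci_high,
                     sigma = (log(rr$ci_high) - log(rr$ci_low)) / (2 * qnorm(0.975))),
    costs = list(family = "uniform_fraction", fraction = cost_fraction),
    utilities = list(family = "uniform_fraction", fraction = utility_fraction)
  )
}

#' Draw one probabilistic parameter set
#'
#' Samples from the current RNG state: the severe relative risk lognormally,
#' each cost and utility cell uniformly within its fraction band (utilities
#' truncated at 1), and rebuilds the GLY event table from the drawn relative
#' risk. A draw producing an invalid probability table (e.g. a relative risk
#' pushing severe plus non-severe beyond 1) is redrawn, counted in the
#' `redraws` attribute. Because cost and utility cells are drawn
#' independently, the deterministic within-state orderings are not imposed
#' on the draws; only probability validity is.
#'
#' @param params Base `copd_parameters`.
#' @param distributions From [psa_distributions()].
#' @return A patched `copd_parameters` with attribute `rr_draw` (the sampled
#'   relative risk) and `redraws`.
#' @export
sample_psa_parameters <- function(params, distributions = psa_distributions(params)) {
  redraws <- 0L
  repeat {
    drawn <- tryCatch({
      p <- params
      rr <- exp(rnorm(1, log(distributions$rr_severe$point),
                      distributions$rr_severe$sigma))
      p <- patch_gly_rr(p, rr)
      fc <- distributions$costs$fraction
      p$costs <- params$costs * matrix(runif(9, 1 - fc, 1 + fc), 3, 3)
      fu <- distributions$utilities$fraction
      u <- params$utilities * matrix(runif(9, 1 - fu, 1 + fu), 3, 3)
      u[u > 1] <- 1  # utility weights are truncated at full health
      p$utilities <- u
      stopifnot(all(p$events$GLY >= 0 & p$events$GLY <= 1), all(p$costs >= 0))
      p
    }, error = function(e) NULL)
    if (!is.null(drawn)) break
    redraws <- redraws + 1L
    if (redraws > 1000L) stop("PSA redraw limit exceeded; distributions inconsistent")
  }
  attr(drawn, "rr_draw") <- drawn$rr_severe$point
  attr(drawn, "redraws") <- redraws
  drawn
}

#' Probabilistic sensitivity analysis with CEAC
#'
#' Monte Carlo propagation of parameter uncertainty through the full model:
#' per iteration a parameter set is drawn ([sample_psa_parameters()]), both
#' arms of the comparison are run deterministically, and the incremental
#' cost and QALYs are recorded. The calibrated mortality schedule is held
#' fixed across iterations. The cost-effectiveness acceptability curve gives,
#' for each willingness-to-pay value, the fraction of iterations with
#' positive net monetary benefit. Reproducible given `seed`.
#'
#' @param params Calibrated `copd_parameters`.
#' @param n_iterations Number of Monte Carlo iterations (the reference
#'   analysis uses 10,000).
#' @param seed Integer RNG seed.
#' @param comparison `"TIO_vs_GLY"` or `"TIO_vs_UC"`. For the usual-care
#'   comparison no published treatment-effect CI exists, so only costs and
#'   utilities vary unless a custom `distributions` object is supplied.
#' @param wtp_grid Willingness-to-pay grid (SEK/QALY) for the CEAC.
#' @param distributions Distribution specification; default
#'   [psa_distributions()].
#' @return A `copd_psa`: `ce_plane` (iteration, delta_cost, delta_qalys,
#'   rr_draw), `ceac` (wtp, probability), `comparison`, `n_iterations`,
#'   `seed`, `redraws`.
#' @export
run_psa <- function(params, n_iterations = 10000L, seed = 1L,
                    comparison = c("TIO_vs_GLY", "TIO_vs_UC"),
                    wtp_grid = seq(0, 1.2e6, by = 2e4),
                    distributions = psa_distributions(params)) {
  comparison <- match.arg(comparison)
  pair <- comparison_arms(comparison)
  schedule <- build_mortality_schedule(params)
  set.seed(seed)

  dc <- dq <- rr <- numeric(n_iterations)
  redraws <- 0L
  for (i in seq_len(n_iterations)) {
    p <- sample_psa_parameters(params, distributions)
    redraws <- redraws + attr(p, "redraws")
    ref <- run_cohort(pair[["reference"]], p, schedule)
    int <- run_cohort(pair[["intervention"]], p, schedule)
    dc[i] <- int$total_cost - ref$total_cost
    dq[i] <- int$qalys - ref$qalys
    rr[i] <- attr(p, "rr_draw")
  }

  ceac <- vapply(wtp_grid, function(w) mean(w * dq - dc > 0), numeric(1))
  structure(list(
    ce_plane = data.frame(iteration = seq_len(n_iterations), delta_cost = dc,
                          delta_qalys = dq, rr_draw = rr),
    ceac = data.frame(wtp = wtp_grid, probability = ceac),
    comparison = comparison, n_iterations = n_iterations, seed = seed,
    redraws = redraws
  ), class = "copd_psa")
}

#' Probability of cost-effectiveness at a threshold
#'
#' Reads the CEAC of a PSA at a willingness-to-pay value (recomputed from the
#' CE plane, so any threshold works, not just grid points).
#'
#' @param psa A `copd_psa`.
#' @param wtp Willingness to pay, SEK per QALY.
#' @return Fraction of iterations with positive net monetary benefit.
#' @export
probability_cost_effective <- function(psa, wtp) {
  stopifnot(inherits(psa, "copd_psa"))
  mean(wtp * psa$ce_plane$delta_qalys - psa$ce_plane$delta_cost > 0)
}

#' @export
print.copd_psa <- function(x, ...) {
  cat(sprintf("PSA %s: %d iterations (seed %d, %d redraws)\n", x$comparison,
              x$n_iterations, x$seed, x$redraws))
  cat(sprintf("  mean Δcost %.0f SEK, mean ΔQALY %.4f\n",
              mean(x$ce_plane$delta_cost), mean(x$ce_plane$delta_qalys)))
  for (w in c(2e5, 6e5, 1e6)) {
    cat(sprintf("  P(cost-effective at WTP %s): %.1f%%\n",
                format(w, big.mark = ","), 100 * probability_cost_effective(x, w)))
  }
  invisible(x)
}
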