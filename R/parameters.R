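## ---------------------------------------------------------------------------
## Model inputs: domain types, probability/discount conversions, validation,
## and configuration file I/O (YAML canonical, JSON equivalent).
##
## A `copd_parameters` object is an immutable snapshot of every input the
## cohort engine needs for one scenario:
##   settings    -- economic settings (discounting, ages, treatment duration,
##                  drug prices, initial GOLD distribution)
##   transitions -- per-arm 3x3 transition matrices between alive GOLD states,
##                  conditional on survival, per 3-month cycle, one matrix for
##                  the first cycle on treatment and one for subsequent cycles
##   events      -- per-arm 3x3 (state x event) exacerbation probabilities per
##                  cycle; the no-exacerbation column is always the complement
##                  of the non-severe and severe columns
##   costs       -- direct cost (SEK 2014) per cycle by state and event
##                  (maintenance plus exacerbation cost, merged)
##   utilities   -- annual utility weight by state and event
##   rr_severe   -- severe-exacerbation relative risk GLY vs TIO (point + CI)
##   mortality   -- background Gompertz-Makeham law and GOLD-state /
##                  severe-exacerbation excess configuration (see mortality.R)
##   anchors     -- discounted life-year anchors used to calibrate the two
##                  free mortality scales
## ---------------------------------------------------------------------------

#' Complete an exacerbation probability row
#'
#' Event probabilities are stored as non-severe and severe probabilities per
#' three-month cycle; the no-exacerbation probability is always recomputed as
#' their complement so each row sums to exactly 1. This also resolves rounding
#' slack in published two-decimal inputs (a printed row may sum to 0.99): the
#' severe and non-severe probabilities drive costs and excess mortality, so
#' the residual category absorbs the rounding.
#'
#' @param nonsevere Probability of a non-severe exacerbation in a cycle.
#' @param severe Probability of a severe (hospitalisation-requiring)
#'   exacerbation in a cycle. Vectors are recycled against `nonsevere`.
#' @return For scalar input, a named numeric triple
#'   `(no_exacerbation, nonsevere, severe)`; for vector input a matrix with
#'   one row per element and the three event columns.
#' @export
#' @examples
#' normalize_event_row(0.18, 0.08) # c(0.74, 0.18, 0.08)
normalize_event_row <- function(nonsevere, severe) {
  if (!is.numeric(nonsevere) || !is.numeric(severe)) {
    stop("event probabilities must be numeric")
  }
  n <- max(length(nonsevere), length(severe))
  nonsevere <- rep_len(nonsevere, n)
  severe <- rep_len(severe, n)
  if (any(nonsevere < 0) || any(severe < 0)) {
    stop("event probabilities must be non-negative")
  }
  if (any(nonsevere + severe > 1 + 1e-12)) {
    stop("nonsevere + severe exceeds 1; no room for the no-exacerbation complement")
  }
  out <- cbind(
    no_exacerbation = 1 - nonsevere - severe,
    nonsevere = nonsevere,
    severe = severe
  )
  if (n == 1L) out[1L, ] else out
}

## Build a full state x event probability matrix from per-state (nonsevere,
## severe) pairs, rows named by GOLD state.
build_event_table <- function(nonsevere, severe) {
  tab <- normalize_event_row(nonsevere, severe)
  if (is.null(dim(tab))) tab <- matrix(tab, nrow = 1L, dimnames = list(NULL, EVENT_TYPES))
  rownames(tab) <- GOLD_STATES
  tab
}

#' Derive a comparator exacerbation table by relative risk
#'
#' Applies a relative risk to the severe (and optionally non-severe)
#' exacerbation probabilities of a reference arm's event table, recomputing
#' the no-exacerbation column as the complement. Used to construct the
#' glycopyrronium table from the tiotropium table whenever the GLY/TIO severe
#' relative risk is varied (deterministic and probabilistic sensitivity
#' analysis); the packaged base case carries the published GLY probabilities
#' verbatim instead.
#'
#' @param events A 3x3 state-by-event probability matrix (rows sum to 1).
#' @param rr_severe Relative risk applied to the severe column.
#' @param rr_nonsevere Relative risk applied to the non-severe column
#'   (default 1: head-to-head evidence found no non-severe difference).
#' @return A 3x3 event table with the same dimnames.
#' @export
derive_comparator_events <- function(events, rr_severe, rr_nonsevere = 1) {
  stopifnot(is.matrix(events), ncol(events) == 3L)
  if (rr_severe < 0 || rr_nonsevere < 0) stop("relative risks must be non-negative")
  sev <- pmin(1, events[, "severe"] * rr_severe)
  nonsev <- events[, "nonsevere"] * rr_nonsevere
  if (any(nonsev + sev > 1 + 1e-12)) {
    stop("derived event probabilities exceed 1 in state(s): ",
         paste(rownames(events)[nonsev + sev > 1 + 1e-12], collapse = ", "))
  }
  out <- cbind(no_exacerbation = 1 - nonsev - sev, nonsevere = nonsev, severe = sev)
  rownames(out) <- rownames(events)
  out
}

#' Constant-hazard probability rescaling
#'
#' Converts an annual death/event probability to the probability over one
#' model cycle (or back) under a constant hazard within the year:
#' `p_cycle = 1 - (1 - p_annual)^cycle_length`.
#'
#' @param p_annual,p_cycle Probability in `[0, 1]`.
#' @param cycle_length Cycle length in years (0.25 for the 3-month cycle).
#' @return The rescaled probability.
#' @export
#' @examples
#' annual_to_cycle_probability(0.04, 0.25) # 0.010152
annual_to_cycle_probability <- function(p_annual, cycle_length) {
  if (any(p_annual < 0 | p_annual > 1)) stop("probability outside [0, 1]")
  if (cycle_length <= 0) stop("cycle_length must be positive")
  1 - (1 - p_annual)^cycle_length
}

#' @rdname annual_to_cycle_probability
#' @export
cycle_to_annual_probability <- function(p_cycle, cycle_length) {
  if (any(p_cycle < 0 | p_cycle > 1)) stop("probability outside [0, 1]")
  if (cycle_length <= 0) stop("cycle_length must be positive")
  1 - (1 - p_cycle)^(1 / cycle_length)
}

#' Per-cycle discount factor
#'
#' Annual-rate compound discounting evaluated at the start of each cycle,
#' with the first cycle undiscounted:
#' `(1 + rate)^(-(cycle_index - 1) * cycle_length)`.
#'
#' @param annual_rate Annual discount rate (fraction per year, >= 0).
#' @param cycle_index 1-based cycle index.
#' @param cycle_length Cycle length in years.
#' @return Discount factor in `(0, 1]`.
#' @export
#' @examples
#' discount_factor(0.03, 5, 0.25) # 1.03^-1
discount_factor <- function(annual_rate, cycle_index, cycle_length) {
  if (any(annual_rate < 0)) stop("discount rate must be non-negative")
  if (any(cycle_index < 1)) stop("cycle_index must be >= 1")
  (1 + annual_rate)^(-(cycle_index - 1) * cycle_length)
}

## --------------------------------------------------------------------------
## Configuration schema. Leaf entries name the expected type; used both to
## reject unknown keys (with their full path) and to report missing ones.
## --------------------------------------------------------------------------
state_block <- function(leaf) setNames(rep(list(leaf), 3L), GOLD_STATES)

config_schema <- function() {
  event_pair <- list(nonsevere = "number", severe = "number")
  trans_block <- list(first_cycle = state_block("row3"), subsequent = state_block("row3"))
  list(
    meta = "any",
    settings = list(
      discount_rate_annual = "number",
      cycle_length_years = "number",
      start_age = "number",
      max_age = "number",
      treatment_duration_years = "number",
      drug_cost_per_day = list(UC = "number", TIO = "number", GLY = "number"),
      initial_distribution = state_block("number"),
      off_treatment_event_risks = "string"
    ),
    transitions = list(UC = trans_block, TIO = trans_block, GLY = trans_block),
    exacerbations = list(
      UC = state_block(event_pair), TIO = state_block(event_pair),
      GLY = state_block(event_pair)
    ),
    relative_risk_severe = list(point = "number", ci_low = "number", ci_high = "number"),
    costs = state_block(list(no_exacerbation = "number", nonsevere = "number",
                             severe = "number")),
    utilities = state_block(list(no_exacerbation = "number", nonsevere = "number",
                                 severe = "number")),
    mortality = list(
      background = list(makeham_a = "number", gompertz_b = "number",
                        gompertz_c = "number", copd_death_fraction = "number"),
      excess = list(
        state_rr = state_block("number"),
        reference_age = "number",
        state_age_gradient = "number",
        sevex_base_excess = "number",
        sevex_age_gradient = "number",
        state_scale = "number",
        sevex_scale = "number"
      )
    ),
    anchors = list(uc_discounted_ly = "number", gly_discounted_ly = "number",
                   discount_rate = "number")
  )
}

## Walk a raw config against the schema, collecting unknown/missing/bad-type
## violations. "meta" is free-form; optional keys are listed explicitly.
OPTIONAL_KEYS <- c("meta", "settings.off_treatment_event_risks")

check_schema <- function(raw, schema, path = character()) {
  violations <- character()
  here <- function(k) paste(c(path, k), collapse = ".")
  if (!is.list(raw)) {
    return(sprintf("'%s' must be a mapping", paste(path, collapse = ".")))
  }
  unknown <- setdiff(names(raw), names(schema))
  if (length(unknown)) {
    violations <- c(violations, sprintf("unknown key '%s'", vapply(unknown, here, "")))
  }
  for (key in names(schema)) {
    full <- here(key)
    leaf <- schema[[key]]
    if (!key %in% names(raw)) {
      if (!full %in% OPTIONAL_KEYS) {
        violations <- c(violations, sprintf("missing key '%s'", full))
      }
      next
    }
    value <- raw[[key]]
    if (is.list(leaf)) {
      violations <- c(violations, check_schema(value, leaf, c(path, key)))
    } else if (identical(leaf, "number")) {
      if (!is.numeric(value) || length(value) != 1L || is.na(value)) {
        violations <- c(violations, sprintf("'%s' must be a single number", full))
      }
    } else if (identical(leaf, "row3")) {
      if (!is.numeric(value) || length(value) != 3L || anyNA(value)) {
        violations <- c(violations, sprintf("'%s' must be three numbers", full))
      }
    } else if (identical(leaf, "string")) {
      if (!is.character(value) || length(value) != 1L) {
        violations <- c(violations, sprintf("'%s' must be a single string", full))
      }
    }
  }
  violations
}

validation_stop <- function(violations) {
  stop(structure(
    class = c("copd_validation_error", "error", "condition"),
    list(message = paste0("invalid model parameters:\n  - ",
                          paste(violations, collapse = "\n  - ")),
         call = NULL, violations = violations)
  ))
}

## Assemble the internal object from a schema-checked raw config list.
as_parameters <- function(raw) {
  violations <- check_schema(raw, config_schema())
  if (length(violations)) validation_stop(violations)

  mk_matrix <- function(block) {
    m <- do.call(rbind, lapply(GOLD_STATES, function(s) as.numeric(block[[s]])))
    dimnames(m) <- list(GOLD_STATES, GOLD_STATES)
    m
  }
  mk_table <- function(block, cols) {
    m <- do.call(rbind, lapply(GOLD_STATES, function(s) as.numeric(unlist(block[[s]])[cols])))
    dimnames(m) <- list(GOLD_STATES, cols)
    m
  }

  settings <- raw$settings
  settings$initial_distribution <-
    setNames(as.numeric(unlist(settings$initial_distribution)[GOLD_STATES]), GOLD_STATES)
  settings$drug_cost_per_day <-
    setNames(as.numeric(unlist(settings$drug_cost_per_day)[ARMS]), ARMS)
  if (is.null(settings$off_treatment_event_risks)) {
    settings$off_treatment_event_risks <- "usual_care"
  }

  events <- lapply(raw$exacerbations, function(block) {
    pairs <- mk_table(block, c("nonsevere", "severe"))
    build_event_table(pairs[, "nonsevere"], pairs[, "severe"])
  })

  params <- structure(list(
    settings = settings,
    transitions = lapply(raw$transitions, function(arm) {
      list(first_cycle = mk_matrix(arm$first_cycle),
           subsequent = mk_matrix(arm$subsequent))
    }),
    events = events[ARMS],
    rr_severe = lapply(raw$relative_risk_severe, as.numeric),
    costs = mk_table(raw$costs, EVENT_TYPES),
    utilities = mk_table(raw$utilities, EVENT_TYPES),
    mortality = list(
      background = lapply(raw$mortality$background, as.numeric),
      excess = local({
        ex <- raw$mortality$excess
        ex$state_rr <- setNames(as.numeric(unlist(ex$state_rr)[GOLD_STATES]), GOLD_STATES)
        lapply(ex, function(x) if (is.numeric(x)) x else as.numeric(x))
      })
    ),
    anchors = lapply(raw$anchors, as.numeric),
    meta = raw$meta
  ), class = "copd_parameters")
  validate_parameters(params)
}

#' Validate a parameter set
#'
#' Checks every structural invariant of the model inputs: transition rows sum
#' to one (within 1e-9, then renormalised exactly), probabilities lie in
#' `[0, 1]`, costs are non-negative and ordered severe >= non-severe >=
#' no-exacerbation within each state, utility weights lie in `[0, 1]` with
#' the opposite ordering, the initial distribution sums to one, the relative
#' risk CI brackets its point estimate, the mortality configuration yields
#' valid age-increasing probabilities, and the calibration anchors are
#' ordered and attainable in principle. All violations are collected and
#' reported together in a condition of class `copd_validation_error`.
#'
#' @param params A `copd_parameters` object.
#' @return The (possibly renormalised) object, invisibly on success.
#' @export
validate_parameters <- function(params) {
  v <- character()
  s <- params$settings

  if (s$discount_rate_annual < 0) v <- c(v, "settings: discount rate must be >= 0")
  if (s$cycle_length_years <= 0) v <- c(v, "settings: cycle length must be > 0")
  if (s$start_age >= s$max_age) v <- c(v, "settings: start_age must be below max_age")
  horizon <- s$max_age - s$start_age
  for (what in c(treatment_duration = s$treatment_duration_years, horizon = horizon)) {
    if (abs(what / s$cycle_length_years - round(what / s$cycle_length_years)) > 1e-9) {
      v <- c(v, "settings: cycle length must divide treatment duration and horizon into whole cycles")
    }
  }
  init <- s$initial_distribution
  if (any(init < 0)) v <- c(v, "settings: initial distribution has negative mass")
  if (abs(sum(init) - 1) > 1e-9) {
    v <- c(v, sprintf("settings: initial distribution sums to %.12g, not 1", sum(init)))
  }
  if (any(s$drug_cost_per_day < 0)) v <- c(v, "settings: drug costs must be >= 0")
  if (!s$off_treatment_event_risks %in% c("usual_care", "arm")) {
    v <- c(v, "settings: off_treatment_event_risks must be 'usual_care' or 'arm'")
  }

  for (arm in ARMS) {
    for (phase in c("first_cycle", "subsequent")) {
      m <- params$transitions[[arm]][[phase]]
      if (any(m < 0 | m > 1)) {
        v <- c(v, sprintf("transitions.%s.%s: entries outside [0, 1]", arm, phase))
      }
      rs <- rowSums(m)
      bad <- abs(rs - 1) > 1e-9
      if (any(bad)) {
        v <- c(v, sprintf("transitions.%s.%s: row %s sums to %.12g, not 1",
                          arm, phase, rownames(m)[bad], rs[bad]))
      } else {
        params$transitions[[arm]][[phase]] <- m / rs
      }
    }
    e <- params$events[[arm]]
    if (any(e < -1e-12 | e > 1)) {
      v <- c(v, sprintf("exacerbations.%s: probabilities outside [0, 1]", arm))
    }
  }

  co <- params$costs
  if (any(co < 0)) v <- c(v, "costs: negative cost")
  bad <- co[, "severe"] < co[, "nonsevere"] | co[, "nonsevere"] < co[, "no_exacerbation"]
  if (any(bad)) {
    v <- c(v, sprintf("costs.%s: expected severe >= nonsevere >= no_exacerbation",
                      rownames(co)[bad]))
  }
  ## exacerbation decrements must be non-negative; the ordering between the
  ## non-severe and severe decrements is free so the QoL-loss scenario of the
  ## one-way DSA (severe decrement set to zero) remains a valid parameter set
  u <- params$utilities
  if (any(u < 0 | u > 1)) v <- c(v, "utilities: weights outside [0, 1]")
  bad <- u[, "no_exacerbation"] < u[, "nonsevere"] | u[, "no_exacerbation"] < u[, "severe"]
  if (any(bad)) {
    v <- c(v, sprintf("utilities.%s: exacerbation weights exceed the no-exacerbation weight",
                      rownames(u)[bad]))
  }

  rr <- params$rr_severe
  if (!(rr$ci_low > 0 && rr$ci_low <= rr$point && rr$point <= rr$ci_high)) {
    v <- c(v, "relative_risk_severe: need 0 < ci_low <= point <= ci_high")
  }

  bg <- params$mortality$background
  if (bg$makeham_a < 0 || bg$gompertz_b <= 0 || bg$gompertz_c <= 0) {
    v <- c(v, "mortality.background: need makeham_a >= 0, gompertz_b > 0, gompertz_c > 0")
  }
  if (bg$copd_death_fraction < 0 || bg$copd_death_fraction > 0.2) {
    v <- c(v, "mortality.background: copd_death_fraction outside [0, 0.2]")
  }
  ex <- params$mortality$excess
  if (any(ex$state_rr < 1)) v <- c(v, "mortality.excess: state relative risks must be >= 1")
  if (is.unsorted(ex$state_rr)) {
    v <- c(v, "mortality.excess: state relative risks must not decrease with GOLD severity")
  }
  if (ex$state_age_gradient <= 0 || ex$sevex_age_gradient <= 0) {
    v <- c(v, "mortality.excess: age gradients must be > 0")
  }
  if (ex$sevex_base_excess < 0 || ex$sevex_base_excess > 1) {
    v <- c(v, "mortality.excess: sevex_base_excess outside [0, 1]")
  }
  if (ex$state_scale < 0 || ex$sevex_scale < 0) {
    v <- c(v, "mortality.excess: calibration scales must be >= 0")
  }

  an <- params$anchors
  if (!(an$gly_discounted_ly <= an$uc_discounted_ly && an$gly_discounted_ly > 0)) {
    v <- c(v, "anchors: need 0 < gly_discounted_ly <= uc_discounted_ly")
  }
  if (an$uc_discounted_ly >= horizon) {
    v <- c(v, "anchors: uc_discounted_ly must lie below the undiscounted horizon")
  }

  if (length(v)) validation_stop(v)
  invisible(params)
}

#' Read model parameters from a configuration file
#'
#' Parses a YAML (or JSON, by extension) configuration holding one complete
#' parameter set, rejects unknown keys by full path, and validates every
#' invariant before returning.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` configuration file.
#' @return A validated `copd_parameters` object.
#' @seealso [base_case_parameters()] for the packaged base case,
#'   [write_parameters()] for the inverse operation.
#' @export
load_parameters <- function(path) {
  if (!file.exists(path)) stop("no such configuration file: ", path)
  ext <- tolower(tools::file_ext(path))
  raw <- switch(ext,
    yaml = , yml = yaml::read_yaml(path),
    json = jsonlite::read_json(path, simplifyVector = TRUE),
    stop("unsupported configuration format: .", ext)
  )
  as_parameters(raw)
}

## Inverse of as_parameters: flatten the internal object back to the raw
## config structure (used by write_parameters and the DSA patch machinery).
parameters_to_raw <- function(params) {
  row_list <- function(m) {
    out <- lapply(seq_len(nrow(m)), function(i) unname(m[i, ]))
    setNames(out, rownames(m))
  }
  pair_list <- function(e) {
    setNames(lapply(GOLD_STATES, function(st) {
      list(nonsevere = unname(e[st, "nonsevere"]), severe = unname(e[st, "severe"]))
    }), GOLD_STATES)
  }
  cell_list <- function(m) {
    setNames(lapply(rownames(m), function(st) as.list(m[st, ])), rownames(m))
  }
  raw <- list(
    settings = local({
      s <- params$settings
      s$initial_distribution <- as.list(s$initial_distribution)
      s$drug_cost_per_day <- as.list(s$drug_cost_per_day)
      s
    }),
    transitions = lapply(params$transitions, function(arm) {
      list(first_cycle = row_list(arm$first_cycle), subsequent = row_list(arm$subsequent))
    }),
    exacerbations = lapply(params$events, pair_list),
    relative_risk_severe = params$rr_severe,
    costs = cell_list(params$costs),
    utilities = cell_list(params$utilities),
    mortality = list(
      background = params$mortality$background,
      excess = local({
        ex <- params$mortality$excess
        ex$state_rr <- as.list(ex$state_rr)
        ex
      })
    ),
    anchors = params$anchors
  )
  if (!is.null(params$meta)) raw <- c(list(meta = params$meta), raw)
  raw
}

#' Write model parameters to a configuration file
#'
#' Serialises a parameter set to YAML or JSON (by extension). JSON output is
#' written at full floating-point precision, so a write/load round trip
#' reproduces the object exactly.
#'
#' @param params A `copd_parameters` object.
#' @param path Output path ending in `.yaml`, `.yml`, or `.json`.
#' @return `path`, invisibly.
#' @export
write_parameters <- function(params, path) {
  stopifnot(inherits(params, "copd_parameters"))
  raw <- parameters_to_raw(params)
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    yaml = , yml = yaml::write_yaml(raw, path, precision = 15L),
    json = jsonlite::write_json(raw, path, auto_unbox = TRUE, digits = I(17),
                                pretty = TRUE),
    stop("unsupported configuration format: .", ext)
  )
  invisible(path)
}

#' @export
print.copd_parameters <- function(x, ...) {
  s <- x$settings
  cat("COPD Markov cohort model parameters\n")
  cat(sprintf("  cohort: start age %g, horizon to age %g, cycle %g y\n",
              s$start_age, s$max_age, s$cycle_length_years))
  cat(sprintf("  treatment: %g y on treatment; TIO %.2f / GLY %.2f SEK per day\n",
              s$treatment_duration_years, s$drug_cost_per_day[["TIO"]],
              s$drug_cost_per_day[["GLY"]]))
  cat(sprintf("  discounting: %g%% per year; initial GOLD II/III/IV: %s\n",
              100 * s$discount_rate_annual,
              paste(format(s$initial_distribution), collapse = "/")))
  cat(sprintf("  severe-exacerbation RR (GLY/TIO): %.2f (%.2f-%.2f)\n",
              x$rr_severe$point, x$rr_severe$ci_low, x$rr_severe$ci_high))
  cat(sprintf("  mortality scales: state %.4g, severe-exacerbation %.4g\n",
              x$mortality$excess$state_scale, x$mortality$excess$sevex_scale))
  invisible(x)
}
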