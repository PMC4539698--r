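# Shared fixtures, computed once per test session.

.fixture_cache <- new.env(parent = emptyenv())

# Base-case parameters with calibrated mortality scales (expensive enough to
# share across test files; calibration itself is tested for determinism).
calibrated_base <- function() {
  if (is.null(.fixture_cache$calibrated)) {
    .fixture_cache$calibrated <- calibrate_mortality(base_case_parameters())
  }
  .fixture_cache$calibrated
}

base_schedule <- function() {
  if (is.null(.fixture_cache$schedule)) {
    .fixture_cache$schedule <- build_mortality_schedule(calibrated_base())
  }
  .fixture_cache$schedule
}

# A degenerate parameter set where one cycle is a fixed point: no mortality,
# identity transitions, whole cohort in GOLD II with certain no-exacerbation.
fixed_point_parameters <- function() {
  p <- generate_random_parameters(1, corner = c("zero_mortality",
                                                "identity_transitions",
                                                "point_mass_initial"))
  for (arm in model_arms()) {
    p$events[[arm]] <- build_event_table(c(0, 0, 0), c(0, 0, 0))
  }
  validate_parameters(p)
}

build_event_table <- function(nonsevere, severe) {
  tab <- normalize_event_row(nonsevere, severe)
  if (is.null(dim(tab))) tab <- matrix(tab, nrow = 1)
  rownames(tab) <- gold_states()[seq_len(nrow(tab))]
  colnames(tab) <- event_types()
  tab
}
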