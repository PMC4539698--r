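# Base-case inputs for the COPD Markov cohort cost-utility model
# (Swedish setting, SEK 2014, three-month cycles).
#
# Clinical inputs are published estimates derived from the UPLIFT trial
# (tiotropium added to usual non-LAMA care vs usual care, 4 years) and the
# SPARK trial (glycopyrronium vs tiotropium head-to-head); costs come from
# Swedish COPD costing studies and utility weights from a Swedish EQ-5D
# study with published exacerbation decrements. The mortality block is a
# synthetic stand-in for the Swedish 2012 life table (see below).

meta:
  description: Base case, moderate-to-very-severe COPD cohort, Swedish setting
  currency: SEK 2014

settings:
  discount_rate_annual: 0.03      # 3%/yr, costs and effects alike
  cycle_length_years: 0.25        # three-month Markov cycle
  start_age: 65                   # mean age at treatment initiation (UPLIFT)
  max_age: 100                    # cohort simulated until dead or age 100
  treatment_duration_years: 4     # observed UPLIFT treatment duration
  drug_cost_per_day:              # Swedish pharmacy prices, SEK/day
    UC: 0.0
    TIO: 12.77                    # tiotropium 18 ug dry-powder inhaler
    GLY: 10.48                    # glycopyrronium 44 ug inhaler
  initial_distribution:           # GOLD mix at entry (UPLIFT)
    GOLD_II: 0.48
    GOLD_III: 0.44
    GOLD_IV: 0.08
  off_treatment_event_risks: usual_care  # exacerbation risks revert with transitions

# Three-month GOLD-state transition probabilities, conditional on survival
# (death is carried separately by the mortality schedule). UPLIFT-derived:
# a distinct first-cycle matrix captures the initial 30-day bronchodilation
# effect; off-treatment cycles revert to the usual-care subsequent matrix.
# Rows: from-state; columns: [to GOLD_II, to GOLD_III, to GOLD_IV].
transitions:
  UC:
    first_cycle:
      GOLD_II:  [0.86, 0.13, 0.01]
      GOLD_III: [0.13, 0.81, 0.06]
      GOLD_IV:  [0.02, 0.22, 0.76]
    subsequent:
      GOLD_II:  [0.91, 0.09, 0.00]
      GOLD_III: [0.08, 0.88, 0.04]
      GOLD_IV:  [0.00, 0.13, 0.87]
  TIO:
    first_cycle:
      GOLD_II:  [0.92, 0.08, 0.00]
      GOLD_III: [0.17, 0.80, 0.03]
      GOLD_IV:  [0.03, 0.28, 0.69]
    subsequent:
      GOLD_II:  [0.92, 0.08, 0.00]
      GOLD_III: [0.08, 0.88, 0.04]
      GOLD_IV:  [0.00, 0.12, 0.88]
  GLY:                            # assumed equal to TIO on lung function
    first_cycle:
      GOLD_II:  [0.92, 0.08, 0.00]
      GOLD_III: [0.17, 0.80, 0.03]
      GOLD_IV:  [0.03, 0.28, 0.69]
    subsequent:
      GOLD_II:  [0.92, 0.08, 0.00]
      GOLD_III: [0.08, 0.88, 0.04]
      GOLD_IV:  [0.00, 0.12, 0.88]

# Three-month exacerbation probabilities by GOLD state. Only the non-severe
# and severe probabilities are stored; the no-exacerbation probability is
# always their complement (published two-decimal rows can carry rounding
# slack). UC and TIO from UPLIFT; GLY severe risks reflect the SPARK
# GLY/TIO severe-exacerbation relative risk applied to the TIO baseline.
exacerbations:
  UC:
    GOLD_II:  {nonsevere: 0.14, severe: 0.02}
    GOLD_III: {nonsevere: 0.17, severe: 0.05}
    GOLD_IV:  {nonsevere: 0.18, severe: 0.08}
  TIO:
    GOLD_II:  {nonsevere: 0.11, severe: 0.02}
    GOLD_III: {nonsevere: 0.14, severe: 0.05}
    GOLD_IV:  {nonsevere: 0.15, severe: 0.08}
  GLY:
    GOLD_II:  {nonsevere: 0.11, severe: 0.03}
    GOLD_III: {nonsevere: 0.14, severe: 0.07}
    GOLD_IV:  {nonsevere: 0.14, severe: 0.12}

# Severe-exacerbation relative risk, GLY vs TIO (SPARK, P = 0.025).
relative_risk_severe:
  point: 1.43
  ci_low: 1.05
  ci_high: 1.97

# Direct cost per three-month cycle (SEK 2014) by state and event:
# GOLD-state maintenance cost plus the exacerbation cost of the event
# (mild and moderate exacerbations merged into "nonsevere").
costs:
  GOLD_II:  {no_exacerbation: 1284, nonsevere: 4423, severe: 27817}
  GOLD_III: {no_exacerbation: 3032, nonsevere: 6170, severe: 29564}
  GOLD_IV:  {no_exacerbation: 4297, nonsevere: 7436, severe: 30830}

# Annual utility weights by state and event: Swedish EQ-5D baselines with
# published annual decrements for non-severe (1.66%) and severe (4.82%)
# exacerbations, as printed after rounding to two decimals.
utilities:
  GOLD_II:  {no_exacerbation: 0.73, nonsevere: 0.72, severe: 0.69}
  GOLD_III: {no_exacerbation: 0.74, nonsevere: 0.73, severe: 0.70}
  GOLD_IV:  {no_exacerbation: 0.52, nonsevere: 0.51, severe: 0.49}

# Synthetic mortality stand-in. The background law is a Gompertz-Makeham
# annual hazard a + b*e^(c*age) fitted to Swedish 2012-type all-cause
# one-year death probabilities (~0.007 at 65, ~0.019 at 75, ~0.075 at 85,
# ~0.27 at 95), with the share of deaths attributable to COPD removed so
# COPD mortality re-enters through the state and event excess. The excess
# layer is a GOLD-state relative-risk gradient anchored at age 65 whose
# relative excess (RR - 1) halves per decade of age, plus a per-severe-event
# additional death probability rising with age. The two scale parameters
# are free calibration multipliers: they are fitted so the usual-care and
# glycopyrronium arms reproduce the discounted life-year anchors below
# (values here are the pre-calibration defaults of 1).
mortality:
  background:
    makeham_a: 0.003              # age-independent hazard floor, 1/yr
    gompertz_b: 3.2e-07           # senescent hazard at age 0, 1/yr
    gompertz_c: 0.145             # log-hazard slope, 1/yr of age
    copd_death_fraction: 0.03     # share of all-cause deaths removed as COPD-related
  excess:
    state_rr:                     # mortality RR vs corrected background, at age 65
      GOLD_II: 1.1
      GOLD_III: 2.0
      GOLD_IV: 8.0
    reference_age: 65
    state_age_gradient: 0.5       # multiplicative change of (RR - 1) per decade
    sevex_base_excess: 0.05       # per-severe-event death probability at age 65
    sevex_age_gradient: 1.3       # per-decade increase of the per-event excess
    state_scale: 1.0              # calibrated multiplier on (RR - 1)
    sevex_scale: 1.0              # calibrated multiplier on the per-event excess

# Published discounted life-year results used to pin the two mortality
# scales (the tiotropium arm is never fitted; its life expectancy is an
# emergent model prediction).
anchors:
  uc_discounted_ly: 10.18
  gly_discounted_ly: 9.93
  discount_rate: 0.03
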