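## ---------------------------------------------------------------------------
## Packaged base case and synthetic input generators. Everything the tests
## and the reference analysis need is generated here or shipped as the
## plain-text base-case configuration -- no downloads.
## ---------------------------------------------------------------------------

#' The packaged base-case parameter set
#'
#' Loads and validates the base-case configuration shipped with the package:
#' UPLIFT-derived transition matrices and exacerbation probabilities, the
#' SPARK severe-exacerbation relative risk, Swedish direct costs (SEK 2014)
#' and utility weights, the economic settings (3% discounting, start age 65,
#' 4-year treatment duration), the synthetic mortality configuration, and
#' the discounted life-year calibration anchors. The mortality scales are
#' the pre-calibration defaults; run [calibrate_mortality()] before
#' producing base-case results.
#'
#' @return A validated `copd_parameters` object.
#' @export
base_case_parameters <- function() {
  load_parameters(system.file("extdata", "base_case.yaml", package = "copdcea",
                              mustWork = TRUE))
}

#' Generate a random valid parameter set
#'
#' Draws a validator-passing parameter set for property testing:
#' Dirichlet-like transition rows, event probabilities with room for the
#' no-exacerbation complement, ordered random costs and utilities, a random
#' relative risk with a consistent CI, and a jittered mortality
#' configuration. Deterministic per seed. Degenerate corners used by engine
#' tests are available on request.
#'
#' @param seed Integer seed.
#' @param corner `NULL` or a character vector among `"zero_mortality"`
#'   (background and excess forced to a negligible level),
#'   `"identity_transitions"`, and `"point_mass_initial"` (whole cohort
#'   starts in GOLD II).
#' @return A validated `copd_parameters` object.
#' @export
generate_random_parameters <- function(seed, corner = NULL) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  bad <- setdiff(corner, c("zero_mortality", "identity_transitions", "point_mass_initial"))
  if (length(bad)) stop("unknown corner request: ", paste(bad, collapse = ", "))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)

  random_transition <- function() {
    m <- matrix(rgamma(9, shape = c(8, 2, 1)), 3, 3, byrow = FALSE)
    ## concentrate mass on the diagonal so the chain is COPD-like (slowly
    ## progressing), then normalise rows
    diag(m) <- diag(m) + rgamma(3, 20)
    m <- m / rowSums(m)
    dimnames(m) <- list(GOLD_STATES, GOLD_STATES)
    m
  }
  random_events <- function() {
    nonsev <- runif(3, 0.05, 0.25)
    sev <- runif(3, 0.01, 0.15)
    build_event_table(nonsev, sev)
  }

  raw <- yaml::read_yaml(system.file("extdata", "base_case.yaml",
                                     package = "copdcea", mustWork = TRUE))
  params <- as_parameters(raw)

  for (arm in ARMS) {
    params$transitions[[arm]] <- list(first_cycle = random_transition(),
                                      subsequent = random_transition())
    params$events[[arm]] <- random_events()
  }
  base_cost <- sort(runif(3, 500, 5000))
  exac_cost <- sort(runif(2, 1000, 30000))
  params$costs <- cbind(no_exacerbation = base_cost,
                        nonsevere = base_cost + exac_cost[1],
                        severe = base_cost + exac_cost[2])
  rownames(params$costs) <- GOLD_STATES
  base_u <- sort(runif(3, 0.3, 0.95), decreasing = TRUE)[c(2, 1, 3)]
  params$utilities <- cbind(no_exacerbation = base_u,
                            nonsevere = base_u * (1 - runif(1, 0, 0.05)),
                            severe = base_u * (1 - runif(1, 0, 0.10)))
  rownames(params$utilities) <- GOLD_STATES
  point <- runif(1, 1.05, 2)
  params$rr_severe <- list(point = point, ci_low = point * runif(1, 0.7, 1),
                           ci_high = point * runif(1, 1, 1.5))
  init <- rgamma(3, c(5, 4, 1))
  params$settings$initial_distribution <- setNames(init / sum(init), GOLD_STATES)
  params$mortality$excess$state_rr <-
    setNames(1 + sort(runif(3, 0, 6)), GOLD_STATES)
  params$mortality$excess$sevex_base_excess <- runif(1, 0.01, 0.1)

  if ("zero_mortality" %in% corner) {
    params$mortality$background <- list(makeham_a = 0, gompertz_b = 1e-300,
                                        gompertz_c = 1e-6, copd_death_fraction = 0)
    params$mortality$excess$state_scale <- 0
    params$mortality$excess$sevex_scale <- 0
    params$mortality$excess$sevex_base_excess <- 0
  }
  if ("identity_transitions" %in% corner) {
    eye <- diag(3)
    dimnames(eye) <- list(GOLD_STATES, GOLD_STATES)
    for (arm in ARMS) {
      params$transitions[[arm]] <- list(first_cycle = eye, subsequent = eye)
    }
  }
  if ("point_mass_initial" %in% corner) {
    params$settings$initial_distribution <-
      setNames(c(1, 0, 0), GOLD_STATES)
  }
  validate_parameters(params)
}

#' Generate a synthetic background mortality model
#'
#' Jitters the default Gompertz-Makeham background multiplicatively
#' (log-normal noise of standard deviation `roughness` on each parameter),
#' always returning a model whose annual death probability increases
#' strictly with age on `[40, 100]`. `roughness = 0` returns the defaults
#' exactly. Used to show the calibration machinery is robust to the exact
#' shape of the background stand-in.
#'
#' @param seed Integer seed.
#' @param roughness Non-negative log-scale jitter (default 0.1).
#' @return A background mortality list (`makeham_a`, `gompertz_b`,
#'   `gompertz_c`, `copd_death_fraction`).
#' @export
generate_synthetic_mortality <- function(seed, roughness = 0.1) {
  stopifnot(roughness >= 0)
  defaults <- base_case_parameters()$mortality$background
  if (roughness == 0) return(defaults)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  out <- defaults
  out$makeham_a <- defaults$makeham_a * exp(rnorm(1, 0, roughness))
  out$gompertz_b <- defaults$gompertz_b * exp(rnorm(1, 0, roughness))
  out$gompertz_c <- defaults$gompertz_c * exp(rnorm(1, 0, roughness / 4))
  ages <- seq(40, 100, by = 0.25)
  q <- background_annual_probability(ages, out)
  stopifnot(all(diff(q) > 0), all(q > 0 & q < 1))
  out
}
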