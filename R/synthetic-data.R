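# Multivariate-normal synthetic-data generator. Each subject's response
# vector is drawn from N(X beta, Z g Z' + sigma2 I) over its timepoints,
# subjects independent, one shared covariance per scenario -- exactly the
# construction of the type I error / power study. A Blanton-like demo
# dataset (nested donors, change-from-baseline anchoring, 43 MCAR-missing
# records) is also provided.

#' Default simulation truth ("blanton_like_v1")
#'
#' The generating parameters used by default in the simulation scenarios:
#' percent-weight-change trajectories with clearly separated group slopes
#' and moderate between-mouse variation. Fixed effects
#' `beta = (0.3, -0.5, 0.55, -0.25)` (intercept %, group offset %, slope
#' %/day, interaction %/day); mouse intercept variance 4 (%^2), mouse slope
#' variance 0.02 ((%/day)^2), intercept-slope covariance 0, residual
#' variance 4 (%^2).
#'
#' @return named list with `fixed_effects`, `g_intercept`, `g_slope`,
#'   `g_cov`, `sigma2`.
#' @export
default_sim_params <- function() {
  list(fixed_effects = c(beta0 = 0.3, beta1 = -0.5, beta2 = 0.55,
                         beta3 = -0.25),
       g_intercept = 4, g_slope = 0.02, g_cov = 0, sigma2 = 4)
}

#' Simulation scenario: generating mean and covariance structure
#'
#' Three covariance scenarios mirror the fitted-model ladder: a random
#' intercept and slope for mouse (`"intercept_slope"`), a random intercept
#' for mouse (`"intercept_only"`), and no random effects (`"none"`). The
#' interaction coefficient is scaled by `effect_fraction` while the group
#' and time main effects are kept the same, so `effect_fraction = 0` gives a
#' type I error setting and fractions in (0, 1] trace a power curve.
#'
#' @param name one of `"intercept_slope"`, `"intercept_only"`, `"none"`.
#' @param fixed_effects numeric length-4 vector `(beta0, beta1, beta2,
#'   beta3)`; defaults to [default_sim_params()].
#' @param g subject-level covariance matrix: 2x2 PSD for
#'   `"intercept_slope"`, 1x1 for `"intercept_only"`, absent for `"none"`;
#'   defaults built from [default_sim_params()].
#' @param sigma2 residual variance.
#' @param effect_fraction multiplier in `[0, 1]` applied to `beta3` only.
#' @return an object of class `sim_scenario`.
#' @export
simulation_scenario <- function(name = c("intercept_slope", "intercept_only",
                                         "none"),
                                fixed_effects = NULL, g = NULL, sigma2 = NULL,
                                effect_fraction = 1) {
  name <- match.arg(name)
  dflt <- default_sim_params()
  if (is.null(fixed_effects)) fixed_effects <- dflt$fixed_effects
  stopifnot(length(fixed_effects) == 4)
  if (is.null(sigma2)) sigma2 <- dflt$sigma2
  if (effect_fraction < 0 || effect_fraction > 1) {
    stop("effect_fraction must be in [0, 1]")
  }
  if (is.null(g)) {
    g <- switch(name,
                intercept_slope = matrix(c(dflt$g_intercept, dflt$g_cov,
                                           dflt$g_cov, dflt$g_slope), 2, 2),
                intercept_only = matrix(dflt$g_intercept, 1, 1),
                none = NULL)
  }
  if (name == "none" && !is.null(g)) stop("scenario 'none' takes no g matrix")
  if (name == "intercept_only" && (is.null(g) || !all(dim(g) == c(1, 1)))) {
    stop("scenario 'intercept_only' needs a 1x1 g matrix")
  }
  if (name == "intercept_slope") {
    if (is.null(g) || !all(dim(g) == c(2, 2))) {
      stop("scenario 'intercept_slope' needs a 2x2 g matrix")
    }
    ev <- eigen(g, symmetric = TRUE, only.values = TRUE)$values
    if (any(ev < -1e-10)) stop("parameter error: g must be PSD")
  }
  structure(list(name = name,
                 fixed_effects = stats::setNames(as.numeric(fixed_effects),
                                                 c("beta0", "beta1", "beta2",
                                                   "beta3")),
                 g = g, sigma2 = sigma2,
                 effect_fraction = effect_fraction),
            class = "sim_scenario")
}

#' @export
print.sim_scenario <- function(x, ...) {
  cat(sprintf("<sim_scenario '%s'> beta = (%s), effect fraction %.2f, sigma2 = %g\n",
              x$name, paste(signif(x$fixed_effects, 4), collapse = ", "),
              x$effect_fraction, x$sigma2))
  invisible(x)
}

scenario_z <- function(scenario, timepoints) {
  switch(scenario$name,
         intercept_slope = cbind(1, timepoints),
         intercept_only = matrix(1, length(timepoints), 1),
         none = NULL)
}

#' Theoretical per-subject covariance of a scenario
#'
#' Returns `Z g Z' + sigma2 I` over the given timepoints (for
#' `"intercept_only"` this is `g * J + sigma2 * I`; for `"none"`,
#' `sigma2 * I`).
#'
#' @param scenario a [simulation_scenario()].
#' @param timepoints numeric vector of measurement days.
#' @return covariance matrix of dimension `length(timepoints)`.
#' @export
theoretical_covariance <- function(scenario, timepoints) {
  if (length(timepoints) == 0) stop("timepoints must be non-empty")
  nt <- length(timepoints)
  Z <- scenario_z(scenario, timepoints)
  V <- diag(scenario$sigma2, nt)
  if (!is.null(Z)) V <- V + Z %*% scenario$g %*% t(Z)
  V
}

scenario_mean <- function(scenario, X) {
  b <- scenario$fixed_effects
  b[4] <- b[4] * scenario$effect_fraction
  as.numeric(X %*% b)
}

#' Simulate a longitudinal dataset from a scenario
#'
#' For each subject in the design grid, the response vector over its
#' timepoints is drawn from a multivariate normal with mean `X beta` (the
#' interaction scaled by the scenario's effect fraction) and covariance
#' `Z g Z' + sigma2 I`. Subjects are independent and share one covariance
#' matrix. Byte-identical output for a fixed seed.
#'
#' @param scenario a [simulation_scenario()].
#' @param grid a [design_grid()].
#' @param seed integer seed.
#' @param skeleton optional pre-built [build_design()] result for `grid`
#'   (saves rebuilding it in tight replicate loops).
#' @return a [long_dataset()] with simulated responses.
#' @export
simulate_dataset <- function(scenario, grid = simulation_grid(), seed = 1L,
                             skeleton = NULL) {
  if (is.null(skeleton)) skeleton <- build_design(grid)
  tp <- grid$timepoints
  nt <- length(tp)
  n_subj <- nrow(skeleton) / nt
  stopifnot(n_subj == round(n_subj))
  g01 <- as.numeric(skeleton$group == levels(skeleton$group)[2])
  X <- cbind(1, g01, skeleton$time, g01 * skeleton$time)
  mu <- scenario_mean(scenario, X)
  Sigma <- theoretical_covariance(scenario, tp)
  eps <- with_seed(seed, MASS::mvrnorm(n_subj, rep(0, nt), Sigma))
  # build_design orders records subject-major, time ascending within subject
  skeleton$response <- mu + as.numeric(t(eps))
  long_dataset(as.data.frame(skeleton), grid = grid)
}

#' Independent design: one mouse per donor
#'
#' A grid with `n_subjects` donors (half per group) and a single mouse each,
#' used to study large-sample behaviour with fully independent subjects
#' (n = 40, 100, 1000).
#'
#' @param n_subjects even total number of subjects.
#' @param timepoints measurement days (defaults to the 12 standard days).
#' @return a [design_grid()].
#' @export
make_independent_design <- function(n_subjects,
                                    timepoints = blanton_timepoints()) {
  if (n_subjects %% 2 != 0) stop("argument error: n_subjects must be even")
  design_grid(donors_per_group = c(n_subjects / 2, n_subjects / 2),
              mice_per_donor = 1L, timepoints = timepoints)
}

#' Blanton-like demo dataset
#'
#' Emulates the re-analysed transplant study: 3 healthy + 5 undernourished
#' donors, 5 mice per donor, 12 days from 0 to 32 (480 design cells), with
#' 43 records removed completely at random to yield 437 observations.
#' Because growth is measured as percent change from baseline, every
#' trajectory is anchored at exactly 0 on day 0; the generator therefore
#' uses slope-only random effects at the donor and mouse levels (no random
#' or fixed intercepts) plus independent noise that is zero at baseline.
#'
#' @param seed integer seed.
#' @param params optional list overriding the generator defaults
#'   `beta2 = 0.55`, `beta3 = -0.25` (%/day), `donor_slope_sd = 0.12`,
#'   `mouse_slope_sd = 0.10` (%/day), `sigma = 1.5` (%), `n_missing = 43`.
#' @return a [long_dataset()] with 437 records and its grid attached.
#' @export
make_demo_dataset <- function(seed = 1L, params = list()) {
  dflt <- list(beta2 = 0.55, beta3 = -0.25, donor_slope_sd = 0.12,
               mouse_slope_sd = 0.10, sigma = 1.5, n_missing = 43L)
  params <- utils::modifyList(dflt, params)
  grid <- blanton_grid()
  ds <- build_design(grid)
  donors <- unique(ds$cluster)
  subjects <- unique(ds$subject)
  ds$response <- with_seed(seed, {
    d_slope <- stats::setNames(stats::rnorm(length(donors),
                                            sd = params$donor_slope_sd), donors)
    m_slope <- stats::setNames(stats::rnorm(length(subjects),
                                            sd = params$mouse_slope_sd), subjects)
    g01 <- as.numeric(ds$group == levels(ds$group)[2])
    slope <- params$beta2 + params$beta3 * g01 +
      d_slope[ds$cluster] + m_slope[ds$subject]
    noise <- ifelse(ds$time == 0, 0, stats::rnorm(nrow(ds), sd = params$sigma))
    as.numeric(slope * ds$time + noise)
  })
  ds <- long_dataset(as.data.frame(ds), grid = grid)
  apply_missingness(ds, params$n_missing, seed = derive_seed(seed, "demo-mcar"))
}
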