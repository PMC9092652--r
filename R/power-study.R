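# Monte-Carlo harness for type I error and power of the group-by-time Wald
# test. Each cell of a rejection-rate table simulates datasets from a
# scenario, fits a (possibly misspecified) model, and records the rejection
# proportion with an exact binomial confidence interval. Replicate datasets
# depend only on (root seed, scenario name, design), never on the fitted
# model or the effect fraction's noise stream, so model contrasts within a
# row are paired (common random numbers) and the fraction-0 column of a
# power curve reproduces the type I error cell.

#' Exact binomial (Clopper-Pearson) interval for a Monte-Carlo proportion
#'
#' @param p_hat observed proportion in `[0, 1]`.
#' @param n_reps number of replicates.
#' @param level confidence level (default 0.95).
#' @return numeric `c(lower, upper)`; contains `p_hat`, width shrinking to 0
#'   as `n_reps` grows.
#' @export
mc_ci <- function(p_hat, n_reps, level = 0.95) {
  stopifnot(p_hat >= 0, p_hat <= 1, n_reps >= 1)
  x <- round(p_hat * n_reps)
  a <- (1 - level) / 2
  lower <- if (x == 0) 0 else stats::qbeta(a, x, n_reps - x + 1)
  upper <- if (x == n_reps) 1 else stats::qbeta(1 - a, x + 1, n_reps - x)
  c(lower = lower, upper = upper)
}

cell_seed <- function(seed, scenario, grid) {
  derive_seed(seed, paste(scenario$name,
                          paste(grid$donors_per_group, collapse = "+"),
                          grid$mice_per_donor, length(grid$timepoints),
                          sep = "|"))
}

#' Monte-Carlo rejection rate of the interaction Wald test
#'
#' Per replicate: simulate a dataset from the scenario on the grid, fit the
#' requested model by REML, apply the Wald z-test to the group-by-time
#' interaction, and reject when `p < alpha`. The rejection proportion is
#' computed over converged fits only; non-converged replicates are counted
#' and excluded. Replicate responses are derived solely from `seed` and the
#' replicate index, so different fitted models see identical datasets.
#'
#' @param scenario a [simulation_scenario()] (its `effect_fraction` is
#'   honoured; override with `effect_fraction`).
#' @param model_id a named-model id (`"I"`..`"VIII"`), [make_model_spec()]
#'   result, or [model_spec()].
#' @param grid a [design_grid()].
#' @param effect_fraction optional override of the scenario's fraction.
#' @param n_reps number of Monte-Carlo replicates.
#' @param alpha test level (default 0.05).
#' @param seed integer root seed.
#' @return an object of class `rate_cell`: list with `rate`, `ci` (95%),
#'   `n_reps`, `n_converged`, `n_failed`, `flagged` (over 10%
#'   non-convergence), plus the cell coordinates.
#' @export
rejection_rate <- function(scenario, model_id, grid = simulation_grid(),
                           effect_fraction = NULL, n_reps = 1000L,
                           alpha = 0.05, seed = 1L) {
  stopifnot(n_reps >= 1, alpha > 0, alpha <= 1)
  if (!is.null(effect_fraction)) scenario$effect_fraction <- effect_fraction
  spec <- as_spec(model_id)
  id_label <- if (inherits(model_id, "named_model")) model_id$id
              else if (is.character(model_id)) model_id else "custom"

  skeleton <- build_design(grid)
  tp <- grid$timepoints
  nt <- length(tp)
  n_subj <- nrow(skeleton) / nt
  g01 <- as.numeric(skeleton$group == levels(skeleton$group)[2])
  X <- cbind(1, g01, skeleton$time, g01 * skeleton$time)
  mu <- scenario_mean(scenario, X)
  Sigma <- theoretical_covariance(scenario, tp)
  ch <- chol(Sigma)
  prep <- design_matrices(skeleton, spec)

  n_reject <- 0L
  n_converged <- 0L
  warm <- NULL
  for (r in seq_len(n_reps)) {
    z <- with_seed(derive_seed(seed, paste0("rep", r)),
                   matrix(stats::rnorm(n_subj * nt), n_subj, nt))
    y <- mu + as.numeric(t(z %*% ch))
    prep <- set_response(prep, y)
    f <- tryCatch(fit_prepared(prep, "REML",
                               starts = if (is.null(warm)) NULL
                                        else list(warm),
                               multi_start = FALSE),
                  error = function(e) NULL)
    if (!is.null(f) && f$converged) {
      n_converged <- n_converged + 1L
      warm <- f$theta
      w <- wald_test(f, "group:time")
      if (w$p_value < alpha) n_reject <- n_reject + 1L
    }
  }
  rate <- if (n_converged > 0) n_reject / n_converged else NA_real_
  structure(list(scenario = scenario$name,
                 model = id_label,
                 effect_fraction = scenario$effect_fraction,
                 design = sprintf("%s donors x %d mice x %d times",
                                  paste(grid$donors_per_group, collapse = "+"),
                                  grid$mice_per_donor, nt),
                 alpha = alpha,
                 rate = rate,
                 ci = if (n_converged > 0) mc_ci(rate, n_converged)
                      else c(lower = NA_real_, upper = NA_real_),
                 n_reps = n_reps,
                 n_converged = n_converged,
                 n_failed = n_reps - n_converged,
                 flagged = (n_reps - n_converged) > 0.1 * n_reps),
            class = "rate_cell")
}

#' @export
print.rate_cell <- function(x, ...) {
  cat(sprintf(paste0("<rate_cell> scenario %s | model %s | fraction %.2f | ",
                     "%s\n  rate = %.4f [%.4f, %.4f] over %d/%d converged%s\n"),
              x$scenario, x$model, x$effect_fraction, x$design, x$rate,
              x$ci[1], x$ci[2], x$n_converged, x$n_reps,
              if (x$flagged) " [FLAGGED: >10% non-convergence]" else ""))
  invisible(x)
}

cell_row <- function(cell) {
  data.frame(scenario = cell$scenario, model = cell$model,
             design = cell$design, effect_fraction = cell$effect_fraction,
             rate = cell$rate, lower = cell$ci[1], upper = cell$ci[2],
             n_reps = cell$n_reps, n_converged = cell$n_converged,
             n_failed = cell$n_failed, flagged = cell$flagged,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Type I error table across scenarios, models and designs
#'
#' All cells use effect fraction 0. Within a (scenario, design) row the
#' fitted models share replicate datasets (common random numbers), so model
#' contrasts are paired.
#'
#' @param scenarios list of [simulation_scenario()]s (or scenario names).
#' @param model_ids character vector of named-model ids.
#' @param designs named list of [design_grid()]s.
#' @param n_reps replicates per cell.
#' @param alpha test level.
#' @param seed root seed.
#' @return a `rejection_table` data frame with one row per cell.
#' @export
type1_table <- function(scenarios, model_ids, designs, n_reps = 1000L,
                        alpha = 0.05, seed = 1L) {
  if (!is.list(designs) || inherits(designs, "design_grid")) {
    designs <- list(design = designs)
  }
  rows <- list()
  for (sc in scenarios) {
    if (is.character(sc)) sc <- simulation_scenario(sc)
    sc$effect_fraction <- 0
    for (di in seq_along(designs)) {
      grid <- designs[[di]]
      s <- cell_seed(seed, sc, grid)
      for (m in model_ids) {
        cell <- rejection_rate(sc, m, grid, n_reps = n_reps, alpha = alpha,
                               seed = s)
        rows[[length(rows) + 1L]] <- cell_row(cell)
      }
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("rejection_table", "data.frame")
  out
}

#' Power curve over effect fractions
#'
#' One cell per (model, effect fraction); the fraction-0 column equals the
#' corresponding [type1_table()] cell for the same seed and design because
#' replicate noise depends only on (seed, scenario, design).
#'
#' @param scenario a [simulation_scenario()] or scenario name.
#' @param model_ids character vector of named-model ids.
#' @param grid a [design_grid()].
#' @param effect_fractions ascending fractions in `[0, 1]`.
#' @param n_reps replicates per cell.
#' @param alpha test level.
#' @param seed root seed.
#' @return a `rejection_table` data frame.
#' @export
power_curve <- function(scenario, model_ids, grid = simulation_grid(),
                        effect_fractions = c(0, 0.10, 0.25, 0.50, 1.0),
                        n_reps = 1000L, alpha = 0.05, seed = 1L) {
  if (is.character(scenario)) scenario <- simulation_scenario(scenario)
  if (is.unsorted(effect_fractions)) {
    stop("effect_fractions must be sorted ascending")
  }
  s <- cell_seed(seed, scenario, grid)
  rows <- list()
  for (f in effect_fractions) {
    for (m in model_ids) {
      cell <- rejection_rate(scenario, m, grid, effect_fraction = f,
                             n_reps = n_reps, alpha = alpha, seed = s)
      rows[[length(rows) + 1L]] <- cell_row(cell)
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("rejection_table", "data.frame")
  out
}
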