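# Hypothesis testing for the trajectory models: Wald z-tests on fixed
# effects, likelihood-ratio tests between nested covariance structures, and
# parametric bootstrap tests for variance components whose null value sits on
# the boundary of the parameter space (where the chi-square reference is
# anti-conservative).

new_test_result <- function(statistic, p_value, method, df = NA_real_,
                            n_boot = NA_integer_, n_boot_failed = NA_integer_,
                            term = NA_character_, boundary = FALSE,
                            unreliable = FALSE) {
  structure(list(statistic = statistic, df = df, p_value = p_value,
                 method = method, n_boot = n_boot,
                 n_boot_failed = n_boot_failed, term = term,
                 boundary = boundary, unreliable = unreliable),
            class = "test_result")
}

#' @export
print.test_result <- function(x, ...) {
  cat(sprintf("<test_result> %s%s: statistic = %.4f%s, p = %.4g%s%s\n",
              x$method, if (!is.na(x$term)) paste0(" [", x$term, "]") else "",
              x$statistic,
              if (!is.na(x$df)) paste0(", df = ", x$df) else "",
              x$p_value,
              if (isTRUE(x$boundary)) " (boundary null)" else "",
              if (isTRUE(x$unreliable)) " [unreliable]" else ""))
  invisible(x)
}

#' Wald z-test of a fixed effect
#'
#' Tests `beta = 0` with `z = beta_hat / se(beta_hat)` against a standard
#' normal reference. The group-by-time interaction is the default effect of
#' interest: it carries the difference in growth trajectories between the
#' two groups.
#'
#' @param fit a converged [fit_lmm()] result.
#' @param term fixed-effect name, one of `"(Intercept)"`, `"group"`,
#'   `"time"`, `"group:time"` (default).
#' @return a `test_result` with `statistic` (z), `p_value`.
#' @export
wald_test <- function(fit, term = "group:time") {
  if (!isTRUE(fit$converged)) {
    stop("fit did not converge (grad_norm = ", signif(fit$grad_norm, 3),
         "); refusing Wald test")
  }
  if (!term %in% names(fit$beta)) {
    stop("unknown term: ", term, "; available: ",
         paste(names(fit$beta), collapse = ", "))
  }
  z <- unname(fit$beta[term] / fit$beta_se[term])
  p <- 2 * stats::pnorm(-abs(z))
  new_test_result(z, p, "wald", term = term)
}

# Structural nesting: every random term of `null` must appear in `alt`, and
# the residual family of `null` must be the independent special case of (or
# equal to) `alt`'s.
is_nested_spec <- function(null, alt) {
  for (ln in null$levels) {
    match_lev <- Filter(function(la) la$level == ln$level, alt$levels)
    if (length(match_lev) == 0) return(FALSE)
    la <- match_lev[[1]]
    if ((ln$intercept && !la$intercept) || (ln$slope && !la$slope)) return(FALSE)
  }
  if (null$residual == "ar1" && alt$residual == "independent") return(FALSE)
  TRUE
}

# Is any parameter present in `alt` but absent in `null` a variance (or an
# AR coefficient tied to one)? Then the null lies on the parameter boundary.
boundary_difference <- function(null, alt) {
  for (la in alt$levels) {
    match_lev <- Filter(function(ln) ln$level == la$level, null$levels)
    if (length(match_lev) == 0) return(TRUE)
    ln <- match_lev[[1]]
    if ((la$intercept && !ln$intercept) || (la$slope && !ln$slope)) return(TRUE)
  }
  FALSE
}

#' Likelihood-ratio test of nested models
#'
#' `statistic = 2 (l_alt - l_null)` (clamped at zero) referenced to a
#' chi-square with degrees of freedom equal to the difference in free
#' parameter counts. Both fits must use ML. When the parameters being tested
#' are variance components the null sits on the boundary of the parameter
#' space and the chi-square reference is conservative; the result is flagged
#' (`boundary = TRUE`) and [parametric_bootstrap_test()] is the recommended
#' companion.
#'
#' @param fit_null,fit_alt ML [fit_lmm()] results with the null spec
#'   structurally nested in the alternative.
#' @return a `test_result` with `statistic`, `df`, `p_value`.
#' @export
lrt <- function(fit_null, fit_alt) {
  if (fit_null$method != "ML" || fit_alt$method != "ML") {
    stop("method error: likelihood-ratio tests require ML fits")
  }
  if (!is_nested_spec(fit_null$spec, fit_alt$spec)) {
    stop("nesting error: null spec is not nested in the alternative spec")
  }
  stat <- 2 * (fit_alt$loglik - fit_null$loglik)
  if (stat < -1e-6) {
    warning("negative LRT statistic (", signif(stat, 4),
            "); alternative fit may not have converged; clamping to 0")
  }
  stat <- max(stat, 0)
  df <- fit_alt$n_params - fit_null$n_params
  p <- if (df > 0) stats::pchisq(stat, df, lower.tail = FALSE) else
    as.numeric(stat <= 1e-6)
  boundary <- boundary_difference(fit_null$spec, fit_alt$spec)
  if (boundary) {
    message("tested parameters include variance components on the boundary ",
            "of the parameter space; chi-square p-value is conservative")
  }
  new_test_result(stat, p, "lrt", df = df, boundary = boundary)
}

#' Parametric bootstrap test of nested models
#'
#' Simulates `B` datasets from the fitted null model (its fixed effects,
#' variance components and residual family), refits both models on each
#' replicate, and compares the observed LRT statistic to the simulated
#' reference distribution: `p = (1 + #\{LRT* >= LRT_obs\}) / (B_ok + 1)`,
#' where replicates on which either refit fails are dropped from both counts
#' and reported in `n_boot_failed`. Valid for boundary nulls where the
#' chi-square LRT reference is not.
#'
#' @param spec_null,spec_alt nested [model_spec()]s with the same residual
#'   estimation family requirements as [lrt()].
#' @param ds a [long_dataset()].
#' @param B number of bootstrap replicates (default 1000).
#' @param seed integer root seed; each replicate draws from its own derived
#'   stream so results are reproducible.
#' @return a `test_result` with `statistic` (observed LRT), `p_value`,
#'   `n_boot`, `n_boot_failed`; flagged `unreliable` when more than 20% of
#'   replicates fail.
#' @export
parametric_bootstrap_test <- function(spec_null, spec_alt, ds, B = 1000L,
                                      seed = 1L) {
  if (!is_nested_spec(spec_null, spec_alt)) {
    stop("nesting error: null spec is not nested in the alternative spec")
  }
  fit0 <- fit_lmm(spec_null, ds, method = "ML")
  fit1 <- fit_lmm(spec_alt, ds, method = "ML",
                  starts = list(embed_theta(spec_null, spec_alt, fit0, 1e-5),
                                embed_theta(spec_null, spec_alt, fit0, 3e-2)))
  if (fit0$singular) {
    warning("null fit is singular (variance component at boundary); ",
            "proceeding with the boundary value")
  }
  lrt_obs <- max(2 * (fit1$loglik - fit0$loglik), 0)
  prep0 <- fit0$prep
  prep1 <- fit1$prep
  n_ge <- 0L
  n_ok <- 0L
  n_failed <- 0L
  for (b in seq_len(B)) {
    ystar <- with_seed(derive_seed(seed, paste0("pb", b)),
                       simulate_from_params(prep0, fit0$beta, fit0$vc))
    res <- tryCatch({
      p0 <- set_response(prep0, ystar)
      p1 <- set_response(prep1, ystar)
      f0 <- fit_prepared(p0, "ML", starts = list(fit0$theta),
                         multi_start = FALSE)
      f1 <- fit_prepared(p1, "ML",
                         starts = list(fit1$theta,
                                       embed_theta(spec_null, spec_alt, f0,
                                                   1e-5),
                                       embed_theta(spec_null, spec_alt, f0,
                                                   3e-2)),
                         multi_start = FALSE)
      if (!f0$converged || !f1$converged) NULL else
        max(2 * (f1$loglik - f0$loglik), 0)
    }, error = function(e) NULL)
    if (is.null(res)) n_failed <- n_failed + 1L else {
      n_ok <- n_ok + 1L
      if (res >= lrt_obs - 1e-6) n_ge <- n_ge + 1L
    }
  }
  p <- (1 + n_ge) / (n_ok + 1)
  new_test_result(lrt_obs, p, "parametric_bootstrap",
                  df = fit1$n_params - fit0$n_params,
                  n_boot = n_ok, n_boot_failed = n_failed,
                  boundary = boundary_difference(spec_null, spec_alt),
                  unreliable = n_failed > 0.2 * B)
}

# Warm start for a larger model from a smaller model's solution: shared
# components keep their values, extra variances start near (not at) zero.
# `eps` sets the starting SD of the extra terms relative to the residual SD;
# a very small eps reproduces the nested optimum almost exactly (guaranteeing
# nesting monotonicity of the fitted log-likelihoods), a moderate eps gives
# the optimizer room to grow the new component. Slope SDs are scaled by the
# time range so the perturbation is comparable in outcome units.
embed_theta <- function(spec_small, spec_large, fit_small, eps = 1e-2) {
  ps <- fit_small$vc
  ts <- max(abs(fit_small$prep$data$time), 1)
  eps_sd <- sqrt(ps$sigma2) * eps
  G <- list()
  for (li in seq_along(spec_large$levels)) {
    la <- spec_large$levels[[li]]
    q <- level_q(la)
    terms_a <- c("intercept", "slope")[c(la$intercept, la$slope)]
    sds <- ifelse(terms_a == "slope", eps_sd / ts, eps_sd)
    Gl <- diag(sds^2, q)
    rownames(Gl) <- colnames(Gl) <- terms_a
    match_idx <- which(vapply(spec_small$levels, function(l) l$level == la$level,
                              logical(1)))
    if (length(match_idx) == 1) {
      ln <- spec_small$levels[[match_idx]]
      terms_n <- c("intercept", "slope")[c(ln$intercept, ln$slope)]
      Gn <- ps$G[[match_idx]]
      rownames(Gn) <- colnames(Gn) <- terms_n
      Gl[terms_n, terms_n] <- Gn
    }
    dimnames(Gl) <- NULL
    G[[li]] <- Gl
  }
  params <- list(G = G, sigma2 = ps$sigma2,
                 phi = if (spec_large$residual == "ar1") {
                   if (is.null(ps$phi)) 0.05 else ps$phi
                 } else NULL)
  params_to_theta(spec_large, params)
}

#' Confidence intervals for the fixed effects
#'
#' Normal-theory intervals `beta_hat +/- z_(1+level)/2 * se`.
#'
#' @param fit a converged [fit_lmm()] result.
#' @param level confidence level in `[0, 1)`; `level = 0` gives the
#'   degenerate interval at the estimate.
#' @return data frame with `term`, `estimate`, `lower`, `upper`.
#' @export
fixed_effect_ci <- function(fit, level = 0.95) {
  if (!isTRUE(fit$converged)) stop("fit did not converge")
  if (level < 0 || level >= 1) stop("level must be in [0, 1)")
  z <- stats::qnorm((1 + level) / 2)
  data.frame(term = names(fit$beta),
             estimate = unname(fit$beta),
             lower = unname(fit$beta - z * fit$beta_se),
             upper = unname(fit$beta + z * fit$beta_se),
             row.names = NULL, stringsAsFactors = FALSE)
}
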