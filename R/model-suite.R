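# The eight named model parameterizations and the nested-comparison ladder.
# Coefficients are reported from REML fits; likelihood-ratio tests between
# nested structures use ML refits, warm-started along the ladder so the
# log-likelihoods respect nesting monotonicity.

model_catalog <- function() {
  list(
    I = list(label = "Donor intercept+slope, mouse intercept+slope",
             levels = list(re_level("cluster", TRUE, TRUE),
                           re_level("subject", TRUE, TRUE)),
             residual = "independent"),
    II = list(label = "Donor intercept, mouse intercept+slope",
              levels = list(re_level("cluster", TRUE, FALSE),
                            re_level("subject", TRUE, TRUE)),
              residual = "independent"),
    III = list(label = "Mouse intercept+slope",
               levels = list(re_level("subject", TRUE, TRUE)),
               residual = "independent"),
    IV = list(label = "Mouse intercept",
              levels = list(re_level("subject", TRUE, FALSE)),
              residual = "independent"),
    V = list(label = "No random effects (linear model)",
             levels = list(), residual = "independent"),
    VI = list(label = "Mouse slope + AR(1) errors",
              levels = list(re_level("subject", FALSE, TRUE)),
              residual = "ar1"),
    VII = list(label = "Mouse intercept + AR(1) errors",
               levels = list(re_level("subject", TRUE, FALSE)),
               residual = "ar1"),
    VIII = list(label = "AR(1) errors only",
                levels = list(), residual = "ar1")
  )
}

#' Construct one of the eight named model specifications
#'
#' The catalog follows the re-analysis ladder: Model I is the maximal model
#' (donor intercept and slope plus mouse intercept and slope, independent
#' errors); Models II-V drop terms down to the ordinary linear model; Models
#' VI-VIII replace independent errors by a stationary AR(1) process with, in
#' turn, a mouse slope, a mouse intercept, or no random effects.
#'
#' @param id one of `"I"` ... `"VIII"`.
#' @param nested set `FALSE` for non-nested data (one mouse per donor):
#'   donor-level models (I, II) are then refused.
#' @return an object of class `named_model` with fields `id`, `label`,
#'   `spec`.
#' @export
make_model_spec <- function(id, nested = TRUE) {
  cat_all <- model_catalog()
  id <- match.arg(as.character(id), names(cat_all))
  entry <- cat_all[[id]]
  if (!nested && id %in% c("I", "II")) {
    stop("spec error: donor-level model ", id,
         " requires nested data (nested = TRUE)")
  }
  structure(list(id = id, label = entry$label,
                 spec = model_spec(entry$levels, entry$residual)),
            class = "named_model")
}

#' @export
print.named_model <- function(x, ...) {
  cat(sprintf("<named_model %s> %s\n", x$id, x$label))
  print(x$spec)
  invisible(x)
}

# Fixed a-priori nesting edges of the comparison ladder: the chain
# I > II > III > IV > V for the independent-error models, and
# VI > VIII, VII > VIII, VIII > V for the AR(1) branch. `parent` is the
# more complex model a row is tested against.
ladder_parent <- function(id, available) {
  parents <- switch(id,
                    II = "I", III = "II", IV = "III", V = c("IV", "VIII"),
                    VIII = c("VI", "VII"), character(0))
  parents[parents %in% available][1]
}

as_spec <- function(model) {
  if (inherits(model, "named_model")) model$spec
  else if (inherits(model, "model_spec")) model
  else make_model_spec(model)$spec
}

#' Nested-model comparison table
#'
#' Fits the requested named models by REML (reported coefficients and
#' standard errors) and by ML (log-likelihoods and likelihood-ratio tests
#' along the fixed ladder edges). ML fits are warm-started from the solution
#' of the nested model below them, which guarantees the log-likelihood
#' ordering of nested structures up to optimizer tolerance. Non-nested pairs
#' are never compared.
#'
#' @param ds a [long_dataset()].
#' @param ids character vector of model ids (default the five independent
#'   error models `I`-`V` when the data carry a cluster column, `III`-`V`
#'   otherwise).
#' @param nested logical; passed to [make_model_spec()].
#' @return an object of class `comparison_table`: a data frame with one row
#'   per model (estimates, SEs, REML and ML log-likelihoods, parameter
#'   counts, the parent model used for the LRT, its statistic and p-value,
#'   convergence flags).
#' @export
comparison_table <- function(ds, ids = NULL, nested = NULL) {
  if (is.null(nested)) {
    nested <- "cluster" %in% names(ds) &&
      length(unique(ds$cluster)) < length(unique(ds$subject))
  }
  if (is.null(ids)) ids <- if (nested) c("I", "II", "III", "IV", "V")
                           else c("III", "IV", "V")
  models <- lapply(ids, make_model_spec, nested = nested)
  names(models) <- ids

  # fit in increasing complexity so warm starts flow up the ladder
  order_idx <- order(vapply(models, function(m) n_parameters(m$spec), numeric(1)))
  fits_reml <- fits_ml <- stats::setNames(vector("list", length(ids)), ids)
  for (k in order_idx) {
    id <- ids[k]
    spec <- models[[id]]$spec
    starts_ml <- starts_reml <- list()
    for (other in ids[order_idx]) {
      if (other == id || is.null(fits_ml[[other]])) next
      if (is_nested_spec(models[[other]]$spec, spec)) {
        # one near-exact embedding (preserves the nested optimum, hence
        # log-likelihood monotonicity) and one loose embedding the
        # optimizer can grow the extra components from
        starts_ml <- c(starts_ml,
                       list(embed_theta(models[[other]]$spec, spec,
                                        fits_ml[[other]], eps = 1e-5),
                            embed_theta(models[[other]]$spec, spec,
                                        fits_ml[[other]], eps = 3e-2)))
        starts_reml <- c(starts_reml,
                         list(embed_theta(models[[other]]$spec, spec,
                                          fits_reml[[other]], eps = 1e-5),
                              embed_theta(models[[other]]$spec, spec,
                                          fits_reml[[other]], eps = 3e-2)))
      }
    }
    fits_ml[[id]] <- tryCatch(fit_lmm(spec, ds, method = "ML",
                                      starts = starts_ml),
                              error = function(e) NULL)
    fits_reml[[id]] <- tryCatch(fit_lmm(spec, ds, method = "REML",
                                        starts = starts_reml),
                                error = function(e) NULL)
  }

  rows <- lapply(ids, function(id) {
    fr <- fits_reml[[id]]; fm <- fits_ml[[id]]
    parent <- ladder_parent(id, ids[!vapply(fits_ml, is.null, logical(1))])
    lrt_stat <- lrt_p <- NA_real_
    if (!is.na(parent) && length(parent) == 1 && !is.null(fm) &&
        !is.null(fits_ml[[parent]])) {
      tr <- tryCatch(suppressMessages(lrt(fm, fits_ml[[parent]])),
                     error = function(e) NULL)
      if (!is.null(tr)) { lrt_stat <- tr$statistic; lrt_p <- tr$p_value }
    }
    data.frame(
      model = id,
      label = model_catalog()[[id]]$label,
      beta0 = if (!is.null(fr)) fr$beta[1] else NA_real_,
      beta1 = if (!is.null(fr)) fr$beta[2] else NA_real_,
      beta2 = if (!is.null(fr)) fr$beta[3] else NA_real_,
      beta3 = if (!is.null(fr)) fr$beta[4] else NA_real_,
      se0 = if (!is.null(fr)) fr$beta_se[1] else NA_real_,
      se1 = if (!is.null(fr)) fr$beta_se[2] else NA_real_,
      se2 = if (!is.null(fr)) fr$beta_se[3] else NA_real_,
      se3 = if (!is.null(fr)) fr$beta_se[4] else NA_real_,
      loglik_reml = if (!is.null(fr)) fr$loglik else NA_real_,
      loglik_ml = if (!is.null(fm)) fm$loglik else NA_real_,
      n_params = n_parameters(models[[id]]$spec),
      parent = if (is.na(parent)) NA_character_ else parent,
      lrt_stat = lrt_stat,
      lrt_p = lrt_p,
      converged = !is.null(fr) && fr$converged && !is.null(fm) && fm$converged,
      singular = (!is.null(fr) && fr$singular) || (!is.null(fm) && fm$singular),
      row.names = NULL, stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  structure(out, class = c("comparison_table", "data.frame"),
            fits_reml = fits_reml, fits_ml = fits_ml)
}

#' @export
print.comparison_table <- function(x, digits = 4, ...) {
  df <- as.data.frame(x)
  show <- data.frame(
    model = df$model,
    interaction = sprintf("%.*g (%.*g)", digits, df$beta3, digits, df$se3),
    logLik_REML = round(df$loglik_reml, 2),
    logLik_ML = round(df$loglik_ml, 2),
    vs = ifelse(is.na(df$parent), "", df$parent),
    LRT_p = signif(df$lrt_p, 3),
    converged = df$converged,
    singular = df$singular
  )
  print(show, row.names = FALSE)
  invisible(x)
}

#' Per-subject conditional residual profiles
#'
#' Conditional residuals `y - X beta_hat - Z gamma_hat` grouped by subject
#' and ordered by time, with a per-time residual spread summary. Well
#' fitting models show a small constant band around zero; omitted random
#' structure shows up as fanning or drifting profiles.
#'
#' @param fit a converged [fit_lmm()] result.
#' @param ds ignored; the fit carries its data.
#' @return list with `profiles` (data frame `subject`, `group`, `time`,
#'   `residual`) and `spread` (data frame `time`, `sd`, `n`).
#' @export
residual_profiles <- function(fit, ds = NULL) {
  bl <- predict_blup(fit)
  pr <- bl$fitted[order(bl$fitted$subject, bl$fitted$time),
                  c("subject", "group", "time", "resid")]
  names(pr)[4] <- "residual"
  rownames(pr) <- NULL
  spread <- do.call(rbind, lapply(split(pr, pr$time), function(d) {
    data.frame(time = d$time[1], sd = stats::sd(d$residual), n = nrow(d))
  }))
  rownames(spread) <- NULL
  spread <- spread[order(spread$time), ]
  list(profiles = pr, spread = spread)
}

#' Fixed-effect confidence intervals across several fits
#'
#' @param fits named list of converged [fit_lmm()] results (names used as
#'   model labels).
#' @param level confidence level.
#' @return data frame keyed by (`model`, `term`) with `estimate`, `lower`,
#'   `upper`.
#' @export
coefficient_ci_table <- function(fits, level = 0.95) {
  if (is.null(names(fits))) names(fits) <- seq_along(fits)
  out <- do.call(rbind, lapply(names(fits), function(nm) {
    ci <- fixed_effect_ci(fits[[nm]], level)
    cbind(model = nm, ci)
  }))
  rownames(out) <- NULL
  out
}
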