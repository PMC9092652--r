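# Exact REML/ML engine for two-level nested linear mixed models with optional
# AR(1) residual correlation. The marginal covariance of each outermost block
# (donor, or mouse when no donor-level effects are present) is assembled
# explicitly as V = Zc Gc Zc' + blockdiag_s(Zs Gs Zs' + R_s) and the Gaussian
# (restricted) likelihood is evaluated through its Cholesky factor. Blocks
# sharing the same covariance pattern (identical times and subject layout)
# reuse a single factorization, so balanced designs cost one small Cholesky
# per objective evaluation regardless of the number of subjects.

#' Random-effects level descriptor
#'
#' @param level `"cluster"` (higher-level factor, e.g. donor) or `"subject"`
#'   (nested factor, e.g. mouse).
#' @param intercept include a random intercept at this level?
#' @param slope include a random time slope at this level?
#' @return a `re_level` list; at least one of `intercept`/`slope` must be set.
#' @export
re_level <- function(level = c("subject", "cluster"),
                     intercept = TRUE, slope = FALSE) {
  level <- match.arg(level)
  if (!intercept && !slope) stop("a random-effects level needs at least one term")
  structure(list(level = level, intercept = intercept, slope = slope),
            class = "re_level")
}

#' Model specification for a nested longitudinal mixed model
#'
#' The fixed part is always the full two-group trajectory mean
#' `response ~ group + time + group:time` (intercept, group offset, time
#' slope, group-by-time interaction). The random part is a list of
#' [re_level()] descriptors ordered outermost first; residuals are either
#' independent or follow a stationary AR(1) process over the within-subject
#' observation order.
#'
#' @param levels list of [re_level()] objects (possibly empty), ordered
#'   cluster before subject.
#' @param residual `"independent"` or `"ar1"`.
#' @param method default estimation method, `"REML"` or `"ML"`.
#' @return an object of class `model_spec`.
#' @export
model_spec <- function(levels = list(), residual = c("independent", "ar1"),
                       method = c("REML", "ML")) {
  residual <- match.arg(residual)
  method <- match.arg(method)
  if (inherits(levels, "re_level")) levels <- list(levels)
  stopifnot(all(vapply(levels, inherits, logical(1), "re_level")))
  levnames <- vapply(levels, `[[`, character(1), "level")
  if (anyDuplicated(levnames)) stop("each level may appear at most once")
  ord <- order(match(levnames, c("cluster", "subject")))
  structure(list(levels = levels[ord], residual = residual, method = method),
            class = "model_spec")
}

#' @export
print.model_spec <- function(x, ...) {
  lev <- if (length(x$levels) == 0) "none" else
    paste(vapply(x$levels, function(l) {
      paste0(l$level, "(", paste(c("intercept", "slope")[c(l$intercept, l$slope)],
                                 collapse = "+"), ")")
    }, character(1)), collapse = " / ")
  cat(sprintf("<model_spec> random: %s | residual: %s | default method: %s\n",
              lev, x$residual, x$method))
  invisible(x)
}

level_q <- function(lev) sum(c(lev$intercept, lev$slope))

has_cluster_level <- function(spec) {
  any(vapply(spec$levels, function(l) l$level == "cluster", logical(1)))
}

n_theta <- function(spec) {
  sum(vapply(spec$levels, function(l) { q <- level_q(l); q * (q + 1) / 2 },
             numeric(1))) + 1L + (spec$residual == "ar1")
}

#' Number of free parameters of a model (fixed effects + covariance)
#' @param spec a [model_spec()].
#' @return integer count (4 fixed effects plus variance/correlation
#'   parameters).
#' @export
n_parameters <- function(spec) 4L + n_theta(spec)

re_columns <- function(lev, times) {
  cols <- list()
  if (lev$intercept) cols <- c(cols, list(rep(1, length(times))))
  if (lev$slope) cols <- c(cols, list(times))
  do.call(cbind, cols)
}

#' Build per-cluster design blocks for a model
#'
#' Orders the data by (cluster, subject, time), builds the fixed-effects
#' design `X = [1, group, time, group x time]`, and partitions rows into
#' outermost blocks (clusters when the model has donor-level effects,
#' subjects otherwise) carrying the random-effects design columns for each
#' level. Blocks with identical covariance patterns are grouped so that the
#' likelihood can factor their shared covariance once.
#'
#' @param ds a [long_dataset()].
#' @param spec a [model_spec()].
#' @return an object of class `lmm_blocks` with fields `X`, `y`, `N`, `perm`
#'   (row order used, as indices into `ds`), `blocks` and `groups` (pattern
#'   groups; each holds the block size `nb`, the per-subject random-effects
#'   designs and AR lag matrices, and the stacked `[X | y]` matrix `M`).
#' @export
design_matrices <- function(ds, spec) {
  stopifnot(inherits(ds, "long_dataset"), inherits(spec, "model_spec"))
  if (has_cluster_level(spec) && !("cluster" %in% names(ds))) {
    stop("spec error: model has a cluster-level term but the dataset has no cluster column")
  }
  if (nlevels(ds$group) < 2) {
    stop("rank error: design matrix is rank-deficient (single group level)")
  }
  df <- as.data.frame(ds)
  block_of <- if (has_cluster_level(spec)) df$cluster else df$subject
  perm <- order(match(block_of, unique(block_of)),
                match(df$subject, unique(df$subject)), df$time)
  df <- df[perm, , drop = FALSE]
  block_of <- block_of[perm]
  g01 <- as.numeric(df$group == levels(df$group)[2])
  X <- cbind(`(Intercept)` = 1, group = g01, time = df$time,
             `group:time` = g01 * df$time)
  y <- df$response
  N <- nrow(df)

  cl_levels <- Filter(function(l) l$level == "cluster", spec$levels)
  su_levels <- Filter(function(l) l$level == "subject", spec$levels)

  idx_by_block <- split(seq_len(N), factor(block_of, levels = unique(block_of)))
  blocks <- vector("list", length(idx_by_block))
  keys <- character(length(idx_by_block))
  for (b in seq_along(idx_by_block)) {
    rows <- idx_by_block[[b]]
    tb <- df$time[rows]
    subj <- df$subject[rows]
    sub_split <- split(seq_along(rows), factor(subj, levels = unique(subj)))
    subjects <- lapply(sub_split, function(r_local) {
      ts <- tb[r_local]
      list(rows = r_local,
           subject = subj[r_local[1]],
           times = ts,
           Z = if (length(su_levels) == 1) re_columns(su_levels[[1]], ts) else NULL,
           lag = if (spec$residual == "ar1")
             abs(outer(seq_along(ts), seq_along(ts), "-")) else NULL)
    })
    Zc <- if (length(cl_levels) == 1) re_columns(cl_levels[[1]], tb) else NULL
    blocks[[b]] <- list(id = names(idx_by_block)[b], rows = rows,
                        times = tb, subjects = subjects, Zc = Zc)
    keys[b] <- paste(length(rows),
                     paste(vapply(subjects, function(s) length(s$rows),
                                  integer(1)), collapse = "."),
                     paste(signif(tb, 12), collapse = ","), sep = "|")
  }

  group_ids <- split(seq_along(blocks), factor(keys, levels = unique(keys)))
  groups <- lapply(group_ids, function(ids) {
    nb <- length(blocks[[ids[1]]]$rows)
    P <- length(ids)
    rows_all <- unlist(lapply(blocks[ids], `[[`, "rows"), use.names = FALSE)
    M <- matrix(0, nb, 5L * P)
    for (k in seq_len(P)) {
      r <- blocks[[ids[k]]]$rows
      M[, (5 * k - 4):(5 * k)] <- cbind(X[r, , drop = FALSE], y[r])
    }
    list(nb = nb, P = P, block_ids = ids, rows_all = rows_all, M = M,
         Zc = blocks[[ids[1]]]$Zc,
         subjects = lapply(blocks[[ids[1]]]$subjects,
                           function(s) s[c("rows", "times", "Z", "lag")]))
  })

  structure(list(spec = spec, X = X, y = y, N = N, p = 4L, perm = perm,
                 beta_names = colnames(X),
                 data = df, blocks = blocks, groups = groups),
            class = "lmm_blocks")
}

# Replace the response vector (given in the original dataset row order used
# to build `prep`) without rebuilding any design structure.
set_response <- function(prep, y_new) {
  stopifnot(length(y_new) == prep$N)
  yo <- y_new[prep$perm]
  prep$y <- yo
  prep$data$response <- yo
  for (gi in seq_along(prep$groups)) {
    g <- prep$groups[[gi]]
    prep$groups[[gi]]$M[, seq(5L, 5L * g$P, by = 5L)] <-
      matrix(yo[g$rows_all], g$nb, g$P)
  }
  prep
}

# ---- parameter transforms -------------------------------------------------

# Unconstrained vector theta <-> constrained covariance parameters.
# Per level: log-Cholesky of G (log of diagonal entries, free off-diagonal;
# order for q = 2: log L11, log L22, L21); then log residual SD; then
# atanh-scale AR(1) coefficient (phi = tanh(z)).
theta_to_params <- function(spec, theta) {
  i <- 0L
  G <- vector("list", length(spec$levels))
  for (li in seq_along(spec$levels)) {
    q <- level_q(spec$levels[[li]])
    if (q == 1) {
      i <- i + 1L
      G[[li]] <- matrix(exp(2 * min(theta[i], 30)), 1, 1)
    } else {
      l11 <- exp(min(theta[i + 1L], 30)); l22 <- exp(min(theta[i + 2L], 30))
      l21 <- theta[i + 3L]
      L <- matrix(c(l11, l21, 0, l22), 2, 2)
      G[[li]] <- L %*% t(L)
      i <- i + 3L
    }
  }
  sigma2 <- exp(2 * min(theta[i + 1L], 30))
  i <- i + 1L
  phi <- if (spec$residual == "ar1") tanh(theta[i + 1L]) else NULL
  list(G = G, sigma2 = sigma2, phi = phi)
}

params_to_theta <- function(spec, params, jitter = 1e-4) {
  th <- numeric(0)
  for (li in seq_along(spec$levels)) {
    q <- level_q(spec$levels[[li]])
    Gl <- params$G[[li]]
    if (q == 1) {
      th <- c(th, 0.5 * log(max(Gl[1, 1], jitter^2)))
    } else {
      ch <- tryCatch(t(chol(Gl + diag(jitter^2, 2))), error = function(e) NULL)
      if (is.null(ch)) ch <- diag(sqrt(pmax(diag(Gl), jitter^2)))
      th <- c(th, log(max(ch[1, 1], jitter)), log(max(ch[2, 2], jitter)),
              ch[2, 1])
    }
  }
  th <- c(th, 0.5 * log(max(params$sigma2, jitter^2)))
  if (spec$residual == "ar1") {
    phi <- if (is.null(params$phi)) 0 else max(min(params$phi, 0.999), -0.999)
    th <- c(th, atanh(phi))
  }
  th
}

#' Marginal covariance of one design block
#'
#' Assembles `V = Zc Gc Zc' + blockdiag_s(Zs Gs Zs' + R_s)` for a pattern
#' group produced by [design_matrices()], where `R_s = sigma2 * C` and
#' `C[j,k] = phi^|j-k|` over the within-subject observation order (identity
#' for independent residuals).
#'
#' @param spec a [model_spec()].
#' @param params list with `G` (list of per-level covariance matrices, outer
#'   level first), `sigma2`, and `phi` (AR(1) models only).
#' @param block one element of `design_matrices(ds, spec)$groups`.
#' @return the symmetric positive-definite block covariance matrix.
#' @export
marginal_covariance <- function(spec, params, block) {
  for (li in seq_along(spec$levels)) {
    Gl <- params$G[[li]]
    ev <- eigen(Gl, symmetric = TRUE, only.values = TRUE)$values
    if (any(ev < -1e-10 * max(abs(ev), 1))) stop("parameter error: G is not PSD")
  }
  if (params$sigma2 <= 0) stop("parameter error: sigma2 must be > 0")
  build_V(block, spec, params)
}

build_V <- function(g, spec, params) {
  V <- matrix(0, g$nb, g$nb)
  li <- 0L
  for (lev in spec$levels) {
    li <- li + 1L
    Gl <- params$G[[li]]
    if (lev$level == "cluster") {
      V <- V + g$Zc %*% Gl %*% t(g$Zc)
    } else {
      for (s in g$subjects) {
        r <- s$rows
        V[r, r] <- V[r, r] + s$Z %*% Gl %*% t(s$Z)
      }
    }
  }
  if (spec$residual == "independent") {
    diag(V) <- diag(V) + params$sigma2
  } else {
    for (s in g$subjects) {
      r <- s$rows
      V[r, r] <- V[r, r] + params$sigma2 * params$phi^s$lag
    }
  }
  V
}

BIG_PENALTY <- 1e10

# Core evaluator: profile beta out by GLS and return the exact (restricted)
# negative log-likelihood plus the ingredients needed for SEs.
nll_details <- function(prep, params, method) {
  CP <- matrix(0, 5, 5)
  logdet <- 0
  for (g in prep$groups) {
    V <- build_V(g, prep$spec, params)
    ch <- tryCatch(chol(V), error = function(e) NULL)
    if (is.null(ch)) return(list(nll = BIG_PENALTY, ok = FALSE))
    W <- backsolve(ch, g$M, transpose = TRUE)
    if (g$P == 1L) {
      CP <- CP + crossprod(W)
    } else {
      arr <- array(W, c(g$nb, 5L, g$P))
      CP <- CP + crossprod(matrix(aperm(arr, c(1, 3, 2)), g$nb * g$P, 5L))
    }
    logdet <- logdet + 2 * g$P * sum(log(diag(ch)))
  }
  XtViX <- CP[1:4, 1:4]
  XtViy <- CP[1:4, 5]
  ytViy <- CP[5, 5]
  beta <- tryCatch(solve(XtViX, XtViy), error = function(e) NULL)
  if (is.null(beta)) return(list(nll = BIG_PENALTY, ok = FALSE))
  quad <- max(ytViy - sum(beta * XtViy), 0)
  N <- prep$N; p <- prep$p
  nll <- if (method == "ML") {
    0.5 * (N * log(2 * pi) + logdet + quad)
  } else {
    ldx <- as.numeric(determinant(XtViX, logarithm = TRUE)$modulus)
    0.5 * ((N - p) * log(2 * pi) + logdet + ldx + quad)
  }
  if (!is.finite(nll)) return(list(nll = BIG_PENALTY, ok = FALSE))
  list(nll = nll, ok = TRUE, beta = as.numeric(beta), XtViX = XtViX,
       quad = quad, logdet = logdet)
}

#' Negative (restricted) log-likelihood of a model
#'
#' Exact evaluation of `-l(theta)` with the fixed effects profiled out by
#' generalized least squares: for ML,
#' `-l = 0.5 [N log 2 pi + log|V| + (y - X b)' V^-1 (y - X b)]` with
#' `b = (X'V^-1 X)^-1 X'V^-1 y`; REML adds `0.5 log|X'V^-1 X|` and replaces
#' `N` by `N - p` in the constant. Evaluation is per cluster block and
#' summed; numerically singular covariances yield a large finite penalty so
#' optimizers can recover.
#'
#' @param spec a [model_spec()].
#' @param theta unconstrained parameter vector (see [design_matrices()] /
#'   the package vignette for the log-Cholesky layout); ignored when
#'   `params` is given.
#' @param ds a [long_dataset()] (ignored when `prep` is given).
#' @param method `"REML"` or `"ML"`; defaults to the spec's method.
#' @param params optional explicit covariance parameters (list with `G`,
#'   `sigma2`, `phi`), allowing exact zero variance components.
#' @param prep optional prebuilt [design_matrices()] result.
#' @return scalar negative log-likelihood.
#' @export
neg_log_likelihood <- function(spec, theta = NULL, ds = NULL, method = NULL,
                               params = NULL, prep = NULL) {
  if (is.null(prep)) prep <- design_matrices(ds, spec)
  if (is.null(method)) method <- spec$method
  method <- match.arg(method, c("REML", "ML"))
  if (is.null(params)) params <- theta_to_params(spec, theta)
  nll_details(prep, params, method)$nll
}

mom_start <- function(prep, spec) {
  qr_fit <- stats::lm.fit(prep$X, prep$y)
  s2 <- sum(qr_fit$residuals^2) / max(prep$N - prep$p, 1)
  k <- length(spec$levels) + 1L
  share <- s2 / k
  ts <- stats::sd(prep$data$time)
  if (!is.finite(ts) || ts <= 0) ts <- 1
  th <- numeric(0)
  for (lev in spec$levels) {
    q <- level_q(lev)
    if (q == 1) {
      sd0 <- sqrt(share) / if (lev$slope && !lev$intercept) ts else 1
      th <- c(th, log(sd0))
    } else {
      th <- c(th, log(sqrt(share)), log(sqrt(share) / ts), 0)
    }
  }
  th <- c(th, 0.5 * log(share))
  if (spec$residual == "ar1") th <- c(th, atanh(0.2))
  th
}

numeric_grad <- function(fn, th, h = 1e-5) {
  vapply(seq_along(th), function(i) {
    e <- th; e[i] <- e[i] + h
    f1 <- fn(e)
    e[i] <- th[i] - h
    (f1 - fn(e)) / (2 * h)
  }, numeric(1))
}

run_optimizer <- function(fn, th0, optimizer, max_iter, tol) {
  optimizer <- tolower(optimizer)
  if (optimizer == "nlminb") {
    r <- stats::nlminb(th0, fn, control = list(iter.max = max_iter,
                                               eval.max = 4L * max_iter,
                                               rel.tol = tol))
    list(par = r$par, objective = r$objective, ok = r$convergence == 0)
  } else {
    meth <- switch(optimizer,
                   "nelder-mead" = "Nelder-Mead",
                   "bfgs" = "BFGS",
                   "l-bfgs-b" = "L-BFGS-B",
                   "cg" = "CG",
                   stop("unknown optimizer: ", optimizer))
    ctrl <- list(maxit = max(500L, max_iter))
    if (meth %in% c("Nelder-Mead", "BFGS", "CG")) ctrl$reltol <- tol
    if (meth == "L-BFGS-B") ctrl$factr <- tol / .Machine$double.eps
    r <- stats::optim(th0, fn, method = meth, control = ctrl)
    list(par = r$par, objective = r$value, ok = r$convergence == 0)
  }
}

ols_fit <- function(prep, method) {
  X <- prep$X; y <- prep$y; N <- prep$N; p <- prep$p
  XtX <- crossprod(X)
  beta <- as.numeric(solve(XtX, crossprod(X, y)))
  rss <- sum((y - X %*% beta)^2)
  ldx <- as.numeric(determinant(XtX, logarithm = TRUE)$modulus)
  if (method == "ML") {
    sigma2 <- rss / N
    loglik <- -0.5 * (N * (log(2 * pi) + log(sigma2) + 1))
  } else {
    sigma2 <- rss / (N - p)
    loglik <- -0.5 * ((N - p) * (log(2 * pi) + log(sigma2) + 1) + ldx)
  }
  vcov_beta <- solve(XtX) * sigma2
  list(beta = beta, vcov_beta = vcov_beta, sigma2 = sigma2, loglik = loglik)
}

fit_prepared <- function(prep, method, optimizer = "nlminb", max_iter = 500L,
                         tol = 1e-8, starts = NULL, check_grad = TRUE,
                         multi_start = TRUE) {
  spec <- prep$spec
  if (length(spec$levels) == 0 && spec$residual == "independent") {
    o <- ols_fit(prep, method)
    params <- list(G = list(), sigma2 = o$sigma2, phi = NULL)
    fit <- list(beta = stats::setNames(o$beta, prep$beta_names),
                beta_se = stats::setNames(sqrt(diag(o$vcov_beta)),
                                          prep$beta_names),
                vcov_beta = o$vcov_beta, vc = params,
                theta = params_to_theta(spec, params),
                loglik = o$loglik, method = method, optimizer = "closed-form",
                converged = TRUE, singular = FALSE,
                n_obs = prep$N, n_params = n_parameters(spec),
                grad_norm = 0, spec = spec, prep = prep)
    class(fit) <- "lmm_fit"
    return(fit)
  }
  fn <- function(th) nll_details(prep, theta_to_params(spec, th), method)$nll
  cand <- c(list(mom_start(prep, spec)), starts)
  vals <- vapply(cand, fn, numeric(1))
  from <- if (multi_start) order(vals) else which.min(vals)
  opt <- NULL
  for (k in from) {
    if (!is.finite(vals[k])) next
    o <- run_optimizer(fn, cand[[k]], optimizer, max_iter, tol)
    if (is.null(opt) || o$objective < opt$objective) opt <- o
  }
  if (is.null(opt)) opt <- list(par = cand[[1]], objective = vals[1], ok = FALSE)
  # never return a point worse than the best start
  if (min(vals) < opt$objective) {
    opt$par <- cand[[which.min(vals)]]
    opt$objective <- min(vals)
  }
  params <- theta_to_params(spec, opt$par)
  d <- nll_details(prep, params, method)
  gnorm <- if (check_grad && d$ok) max(abs(numeric_grad(fn, opt$par))) else NA_real_
  converged <- isTRUE(opt$ok) && d$ok && is.finite(opt$objective) &&
    (!check_grad || gnorm < 1e-3 * (1 + abs(opt$objective)))
  vcov_beta <- tryCatch(solve(d$XtViX), error = function(e) matrix(NA, 4, 4))
  singular <- is_singular_params(spec, params)
  fit <- list(beta = stats::setNames(d$beta, prep$beta_names),
              beta_se = stats::setNames(sqrt(pmax(diag(vcov_beta), 0)),
                                        prep$beta_names),
              vcov_beta = vcov_beta, vc = params, theta = opt$par,
              loglik = -opt$objective, method = method, optimizer = optimizer,
              converged = converged, singular = singular,
              n_obs = prep$N, n_params = n_parameters(spec),
              grad_norm = gnorm, spec = spec, prep = prep)
  class(fit) <- "lmm_fit"
  fit
}

is_singular_params <- function(spec, params) {
  s2 <- params$sigma2
  for (li in seq_along(spec$levels)) {
    Gl <- params$G[[li]]
    if (any(diag(Gl) < 1e-8 * s2)) return(TRUE)
    if (nrow(Gl) == 2) {
      den <- sqrt(Gl[1, 1] * Gl[2, 2])
      if (den > 0 && abs(Gl[1, 2] / den) > 1 - 1e-6) return(TRUE)
    }
  }
  if (!is.null(params$phi) && abs(params$phi) > 1 - 1e-6) return(TRUE)
  FALSE
}

#' Fit a nested longitudinal mixed model
#'
#' Minimizes the exact (restricted) negative log-likelihood over the
#' unconstrained log-Cholesky parameterization, starting from a
#' method-of-moments point (additional warm starts may be supplied). Models
#' with no random effects and independent residuals are solved in closed
#' form (ordinary least squares).
#'
#' @param spec a [model_spec()].
#' @param ds a [long_dataset()] with observed responses.
#' @param method `"REML"` (default, used for reported coefficients) or
#'   `"ML"` (required for likelihood-ratio tests).
#' @param optimizer one of `"nlminb"` (bound-free quasi-Newton, default),
#'   `"nelder-mead"`, `"bfgs"`, `"l-bfgs-b"`, `"cg"`.
#' @param max_iter iteration cap.
#' @param tol relative convergence tolerance on the objective.
#' @param starts optional list of additional unconstrained starting vectors.
#' @return an object of class `lmm_fit` with elements `beta`, `beta_se`,
#'   `vcov_beta`, `vc` (covariance parameters: `G` per level, `sigma2`,
#'   `phi`), `loglik`, `method`, `converged`, `singular`, `n_obs`,
#'   `n_params`.
#' @export
fit_lmm <- function(spec, ds, method = NULL, optimizer = "nlminb",
                    max_iter = 500L, tol = 1e-8, starts = NULL) {
  if (is.null(method)) method <- spec$method
  method <- match.arg(method, c("REML", "ML"))
  prep <- design_matrices(ds, spec)
  if (prep$N < n_parameters(spec)) {
    stop("dimension error: fewer observations than parameters")
  }
  fit_prepared(prep, method, optimizer, max_iter, tol, starts)
}

#' @export
print.lmm_fit <- function(x, ...) {
  cat(sprintf("<lmm_fit> %s | logLik = %.4f | converged: %s%s\n",
              x$method, x$loglik, x$converged,
              if (x$singular) " | singular" else ""))
  coefs <- cbind(Estimate = x$beta, `Std.Error` = x$beta_se)
  print(round(coefs, 5))
  for (li in seq_along(x$spec$levels)) {
    lev <- x$spec$levels[[li]]
    cat(sprintf("G[%s] variances: %s\n", lev$level,
                paste(signif(diag(x$vc$G[[li]]), 5), collapse = ", ")))
  }
  cat(sprintf("sigma2 = %s%s\n", signif(x$vc$sigma2, 5),
              if (!is.null(x$vc$phi)) paste0(", phi = ", signif(x$vc$phi, 4))
              else ""))
  invisible(x)
}

#' @export
logLik.lmm_fit <- function(object, ...) {
  structure(object$loglik, df = object$n_params, class = "logLik")
}

#' Refit a model with several optimizers and compare estimates
#'
#' Mirrors the practice of checking optimizer stability: the same model is
#' refit with each requested optimizer and the fixed-effect estimates of the
#' converged fits are compared. The fit is declared stable when the maximum
#' relative discrepancy is below `1e-4`.
#'
#' @param spec a [model_spec()].
#' @param ds a [long_dataset()].
#' @param optimizers character vector (length >= 2) of optimizer names.
#' @param method estimation method; defaults to the spec's.
#' @return an object of class `stability_report`: data frame `fits`
#'   (optimizer, loglik, converged, singular, beta columns), the
#'   `max_rel_discrepancy` among converged fits, and flags `stable` /
#'   `all_failed`.
#' @export
refit_all_optimizers <- function(spec, ds,
                                 optimizers = c("nlminb", "nelder-mead",
                                                "bfgs", "l-bfgs-b"),
                                 method = NULL) {
  if (length(optimizers) < 2) stop("need at least 2 optimizers")
  fits <- lapply(optimizers, function(o) {
    tryCatch(fit_lmm(spec, ds, method = method, optimizer = o),
             error = function(e) NULL)
  })
  ok <- !vapply(fits, is.null, logical(1))
  tab <- do.call(rbind, lapply(which(ok), function(i) {
    f <- fits[[i]]
    data.frame(optimizer = optimizers[i], loglik = f$loglik,
               converged = f$converged, singular = f$singular,
               t(as.matrix(f$beta)), check.names = FALSE)
  }))
  conv <- which(ok)[vapply(fits[ok], function(f) isTRUE(f$converged), logical(1))]
  disc <- 0
  if (length(conv) >= 2) {
    betas <- do.call(rbind, lapply(fits[conv], `[[`, "beta"))
    for (i in seq_len(nrow(betas) - 1)) {
      for (j in (i + 1):nrow(betas)) {
        disc <- max(disc, max(abs(betas[i, ] - betas[j, ]) /
                                pmax(1, abs(betas[i, ]), abs(betas[j, ]))))
      }
    }
  } else if (length(conv) < 2) {
    disc <- NA_real_
  }
  structure(list(fits = tab, max_rel_discrepancy = disc,
                 stable = isTRUE(disc < 1e-4),
                 n_converged = length(conv),
                 all_failed = length(conv) == 0),
            class = "stability_report")
}

#' @export
print.stability_report <- function(x, ...) {
  cat(sprintf("<stability_report> stable: %s | max rel discrepancy: %s | converged: %d\n",
              x$stable, signif(x$max_rel_discrepancy, 4), x$n_converged))
  print(x$fits)
  invisible(x)
}

#' Random-effect predictions (BLUPs) and fitted trajectories
#'
#' Computes the empirical best linear unbiased predictions
#' `gamma_hat = G Z' V^-1 (y - X beta_hat)` for each unit at each random
#' level, and per-record fitted values `X beta_hat + sum_levels Z gamma_hat`
#' together with conditional residuals.
#'
#' @param fit an [fit_lmm()] result (must have converged).
#' @param ds ignored; the fit carries its data.
#' @return list with `ranef` (named list of per-level data frames of unit
#'   effect estimates) and `fitted` (data frame with `subject`, `group`,
#'   `time`, `response`, `population` (X beta only), `fitted`, `resid`).
#' @export
predict_blup <- function(fit, ds = NULL) {
  if (!isTRUE(fit$converged)) stop("fit did not converge; refusing to predict")
  prep <- fit$prep
  spec <- fit$spec
  params <- fit$vc
  pop <- as.numeric(prep$X %*% fit$beta)
  fitted <- pop
  r <- prep$y - pop
  acc <- list(cluster = list(), subject = list())
  for (g in prep$groups) {
    V <- build_V(g, spec, params)
    for (k in seq_len(g$P)) {
      b <- prep$blocks[[g$block_ids[k]]]
      u <- solve(V, r[b$rows])
      li <- 0L
      for (lev in spec$levels) {
        li <- li + 1L
        Gl <- params$G[[li]]
        if (lev$level == "cluster") {
          gam <- as.numeric(Gl %*% crossprod(b$Zc, u))
          fitted[b$rows] <- fitted[b$rows] + as.numeric(b$Zc %*% gam)
          acc$cluster[[length(acc$cluster) + 1L]] <- c(unit = b$id, gam)
        } else {
          for (s in b$subjects) {
            gam <- as.numeric(Gl %*% crossprod(s$Z, u[s$rows]))
            rows_g <- b$rows[s$rows]
            fitted[rows_g] <- fitted[rows_g] + as.numeric(s$Z %*% gam)
            acc$subject[[length(acc$subject) + 1L]] <- c(unit = s$subject, gam)
          }
        }
      }
    }
  }
  ranef <- list()
  for (lev in spec$levels) {
    terms <- c("intercept", "slope")[c(lev$intercept, lev$slope)]
    rows <- acc[[lev$level]]
    m <- do.call(rbind, rows)
    df_r <- data.frame(unit = m[, 1], stringsAsFactors = FALSE)
    for (j in seq_along(terms)) df_r[[terms[j]]] <- as.numeric(m[, j + 1])
    ranef[[lev$level]] <- df_r
  }
  out <- data.frame(subject = prep$data$subject,
                    group = prep$data$group,
                    time = prep$data$time,
                    response = prep$y,
                    population = pop,
                    fitted = fitted,
                    resid = prep$y - fitted,
                    stringsAsFactors = FALSE)
  if ("cluster" %in% names(prep$data)) out$cluster <- prep$data$cluster
  list(ranef = ranef, fitted = out)
}

# Square root factor of a PSD matrix that tolerates boundary (rank-deficient)
# estimates.
psd_sqrt <- function(G) {
  ch <- tryCatch(chol(G), error = function(e) NULL)
  if (!is.null(ch)) return(t(ch))
  e <- eigen(G, symmetric = TRUE)
  e$vectors %*% diag(sqrt(pmax(e$values, 0)), nrow(G))
}

# Simulate a new response vector (in the original dataset row order of
# `prep`) from explicit parameters; used by the parametric bootstrap.
simulate_from_params <- function(prep, beta, params) {
  spec <- prep$spec
  y <- as.numeric(prep$X %*% beta)
  for (g in prep$groups) {
    for (k in seq_len(g$P)) {
      b <- prep$blocks[[g$block_ids[k]]]
      li <- 0L
      for (lev in spec$levels) {
        li <- li + 1L
        Lc <- psd_sqrt(params$G[[li]])
        if (lev$level == "cluster") {
          gam <- as.numeric(Lc %*% stats::rnorm(ncol(Lc)))
          y[b$rows] <- y[b$rows] + as.numeric(b$Zc %*% gam)
        } else {
          for (s in b$subjects) {
            gam <- as.numeric(Lc %*% stats::rnorm(ncol(Lc)))
            y[b$rows[s$rows]] <- y[b$rows[s$rows]] + as.numeric(s$Z %*% gam)
          }
        }
      }
      sdr <- sqrt(params$sigma2)
      if (spec$residual == "independent") {
        y[b$rows] <- y[b$rows] + stats::rnorm(length(b$rows), sd = sdr)
      } else {
        phi <- params$phi
        for (s in b$subjects) {
          ns <- length(s$rows)
          e <- numeric(ns)
          e[1] <- stats::rnorm(1, sd = sdr)
          if (ns > 1) {
            innov <- stats::rnorm(ns - 1, sd = sdr * sqrt(1 - phi^2))
            for (j in 2:ns) e[j] <- phi * e[j - 1] + innov[j - 1]
          }
          y[b$rows[s$rows]] <- y[b$rows[s$rows]] + e
        }
      }
    }
  }
  yout <- numeric(prep$N)
  yout[prep$perm] <- y
  yout
}
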