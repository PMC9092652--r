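test_that("fixed-effects design uses 0/1 indicator coding with time interaction", {
  ds <- tiny_dataset()
  prep <- design_matrices(ds, make_model_spec("IV")$spec)
  # subject s1 is in the reference group: rows [1,0,0,0] and [1,0,1,0]
  expect_equal(unname(prep$X[1:2, ]),
               rbind(c(1, 0, 0, 0), c(1, 0, 1, 0)))
  # subject s2 carries the indicator and the interaction column
  expect_equal(unname(prep$X[3:4, ]),
               rbind(c(1, 1, 0, 0), c(1, 1, 1, 1)))
  expect_equal(prep$N, 4)
})

test_that("slope-only level has a single Z column equal to time", {
  ds <- tiny_dataset()
  prep <- design_matrices(ds, make_model_spec("VI")$spec)
  s <- prep$groups[[1]]$subjects[[1]]
  expect_equal(ncol(s$Z), 1)
  expect_equal(as.numeric(s$Z), s$times)
})

test_that("full design produces a 480 x 4 fixed design", {
  skel <- build_design(blanton_grid())
  prep <- design_matrices(skel, make_model_spec("IV")$spec)
  expect_equal(dim(prep$X), c(480L, 4L))
})

test_that("design construction rejects missing factors and single-group data", {
  ds <- tiny_dataset()
  expect_error(design_matrices(ds, make_model_spec("I")$spec), "cluster")
  one_group <- long_dataset(data.frame(
    subject = rep(c("a", "b"), each = 2), group = "A",
    time = c(0, 1, 0, 1), response = 1:4))
  expect_error(design_matrices(one_group, make_model_spec("IV")$spec), "rank")
})

test_that("marginal covariance matches hand-computed forms", {
  ds <- tiny_dataset()
  spec <- make_model_spec("IV")$spec
  prep <- design_matrices(ds, spec)
  block <- prep$groups[[1]]
  V <- marginal_covariance(spec, list(G = list(matrix(2, 1, 1)), sigma2 = 1),
                           block)
  expect_equal(V, matrix(c(3, 2, 2, 3), 2, 2))
  # all variance components zero, independent errors -> identity
  V0 <- marginal_covariance(spec, list(G = list(matrix(0, 1, 1)), sigma2 = 1),
                            block)
  expect_equal(V0, diag(1, 2))
  # AR(1) with phi = 0 collapses to the independent form
  spec7 <- make_model_spec("VII")$spec
  prep7 <- design_matrices(ds, spec7)
  V_ar0 <- marginal_covariance(spec7, list(G = list(matrix(2, 1, 1)),
                                           sigma2 = 1, phi = 0),
                               prep7$groups[[1]])
  expect_equal(V_ar0, V)
  expect_error(marginal_covariance(spec, list(G = list(matrix(-1, 1, 1)),
                                              sigma2 = 1), block), "PSD")
})

test_that("engine likelihood matches the dense brute-force oracle on random instances", {
  for (s in 1:10) {
    inst <- random_small_instance(2000 + s)
    for (m in c("ML", "REML")) {
      eng <- neg_log_likelihood(inst$spec, ds = inst$ds, method = m,
                                params = inst$params)
      ora <- oracle_nll(inst$ds, inst$spec, inst$params, m)
      expect_equal(eng, ora, tolerance = 1e-9)
    }
  }
})

test_that("zero variance components reduce the likelihood to the OLS Gaussian density", {
  ds <- simulate_dataset(simulation_scenario("none"),
                         make_independent_design(6, c(0, 2, 4, 6)), seed = 61)
  spec_iv <- make_model_spec("IV")$spec
  sigma2 <- 1.3
  nll <- neg_log_likelihood(spec_iv, ds = ds, method = "ML",
                            params = list(G = list(matrix(0, 1, 1)),
                                          sigma2 = sigma2))
  X <- cbind(1, as.numeric(ds$group == levels(ds$group)[2]), ds$time,
             as.numeric(ds$group == levels(ds$group)[2]) * ds$time)
  b <- solve(crossprod(X), crossprod(X, ds$response))
  rss <- sum((ds$response - X %*% b)^2)
  n <- nrow(ds)
  nll_ols <- 0.5 * (n * log(2 * pi) + n * log(sigma2) + rss / sigma2)
  expect_equal(nll, nll_ols, tolerance = 1e-10)
})

test_that("AR(1) likelihood with phi = 0 equals the independent-error counterpart", {
  ds <- simulate_dataset(simulation_scenario("intercept_only"),
                         make_independent_design(8, c(0, 2, 4, 6, 8)),
                         seed = 62)
  g <- matrix(1.5, 1, 1)
  for (m in c("ML", "REML")) {
    nll_ar <- neg_log_likelihood(make_model_spec("VII")$spec, ds = ds,
                                 method = m,
                                 params = list(G = list(g), sigma2 = 2,
                                               phi = 0))
    nll_ind <- neg_log_likelihood(make_model_spec("IV")$spec, ds = ds,
                                  method = m,
                                  params = list(G = list(g), sigma2 = 2))
    expect_equal(nll_ar, nll_ind, tolerance = 1e-12)
  }
})

test_that("no-random-effect fits equal ordinary least squares exactly", {
  ds <- simulate_dataset(simulation_scenario("none"),
                         make_independent_design(10), seed = 63)
  f <- fit_lmm(make_model_spec("V")$spec, ds, method = "REML")
  lmfit <- stats::lm(response ~ group * time, data = as.data.frame(ds))
  expect_equal(unname(f$beta), unname(coef(lmfit)), tolerance = 1e-10)
  expect_equal(unname(f$beta_se),
               unname(sqrt(diag(vcov(lmfit)))), tolerance = 1e-10)
  expect_equal(f$vc$sigma2, summary(lmfit)$sigma^2, tolerance = 1e-10)
  fm <- fit_lmm(make_model_spec("V")$spec, ds, method = "ML")
  expect_equal(fm$loglik, as.numeric(stats::logLik(lmfit)), tolerance = 1e-8)
})

test_that("estimates agree with lme4 and nlme reference implementations", {
  ds <- simulate_dataset(simulation_scenario("intercept_slope"),
                         simulation_grid(), seed = 64)
  df <- as.data.frame(ds)
  f3 <- fit_lmm(make_model_spec("III")$spec, ds, method = "REML")
  m3 <- suppressWarnings(
    lme4::lmer(response ~ group * time + (time | subject), data = df,
               REML = TRUE))
  expect_equal(f3$loglik, as.numeric(stats::logLik(m3)), tolerance = 1e-6)
  expect_equal(unname(f3$beta), unname(lme4::fixef(m3)), tolerance = 1e-4)

  f8 <- fit_lmm(make_model_spec("VIII")$spec, ds, method = "ML")
  g8 <- nlme::gls(response ~ group * time, data = df,
                  correlation = nlme::corAR1(form = ~ 1 | subject),
                  method = "ML")
  expect_equal(f8$loglik, as.numeric(stats::logLik(g8)), tolerance = 1e-6)
  expect_equal(f8$vc$phi,
               as.numeric(coef(g8$modelStruct$corStruct,
                               unconstrained = FALSE)), tolerance = 1e-3)
})

test_that("refitting from a converged solution is a fixed point", {
  ds <- simulate_dataset(simulation_scenario("intercept_only"),
                         make_independent_design(20), seed = 65)
  spec <- make_model_spec("IV")$spec
  f1 <- fit_lmm(spec, ds)
  f2 <- fit_lmm(spec, ds, starts = list(f1$theta))
  expect_equal(f2$loglik, f1$loglik, tolerance = 1e-8)
})

test_that("variance parameters are recovered on simulated data", {
  sc <- simulation_scenario("intercept_only")
  grid <- make_independent_design(200)
  skel <- build_design(grid)
  spec <- make_model_spec("IV")$spec
  prep <- design_matrices(skel, spec)
  est <- t(vapply(1:30, function(r) {
    ds <- simulate_dataset(sc, grid, seed = 5200 + r, skeleton = skel)
    f <- nestlme:::fit_prepared(nestlme:::set_response(prep, ds$response),
                                "REML")
    c(g = f$vc$G[[1]][1, 1], s2 = f$vc$sigma2, b3 = unname(f$beta[4]))
  }, numeric(3)))
  mc_se <- apply(est, 2, stats::sd) / sqrt(nrow(est))
  truth <- c(4, 4, -0.25)
  expect_true(all(abs(colMeans(est) - truth) < 3 * mc_se + 1e-8))
})

test_that("estimation bias shrinks as the number of subjects grows", {
  sc <- simulation_scenario("intercept_only")
  spec <- make_model_spec("IV")$spec
  bias_at <- function(n, reps) {
    grid <- make_independent_design(n)
    skel <- build_design(grid)
    prep <- design_matrices(skel, spec)
    est <- vapply(seq_len(reps), function(r) {
      ds <- simulate_dataset(sc, grid, seed = 5600 + 97 * n + r,
                             skeleton = skel)
      f <- nestlme:::fit_prepared(nestlme:::set_response(prep, ds$response),
                                  "ML")
      f$vc$G[[1]][1, 1]
    }, numeric(1))
    c(bias = mean(est) - 4, se = stats::sd(est) / sqrt(reps))
  }
  small <- bias_at(20, 40)
  big <- bias_at(200, 40)
  # ML underestimates the variance at n = 20; the bias must shrink by n = 200
  expect_lt(abs(big["bias"]),
            abs(small["bias"]) + 3 * sqrt(small["se"]^2 + big["se"]^2))
})

test_that("optimizer stability report compares fixed effects across optimizers", {
  ds <- simulate_dataset(simulation_scenario("intercept_only"),
                         make_independent_design(20), seed = 66)
  spec <- make_model_spec("IV")$spec
  rep1 <- refit_all_optimizers(spec, ds, c("nlminb", "nelder-mead"))
  expect_true(rep1$stable)
  expect_lt(rep1$max_rel_discrepancy, 1e-4)
  # the same optimizer twice has zero discrepancy
  rep2 <- refit_all_optimizers(spec, ds, c("nlminb", "nlminb"))
  expect_equal(rep2$max_rel_discrepancy, 0)
  expect_error(refit_all_optimizers(spec, ds, "nlminb"), "at least 2")
})

test_that("overspecified donor-level model on donor-free data is flagged", {
  # data carry no donor effects, so the maximal model's donor variances sit
  # at the boundary: expect at least one singular or non-converged fit
  ds <- simulate_dataset(simulation_scenario("intercept_only"),
                         blanton_grid(), seed = 67)
  rep <- refit_all_optimizers(make_model_spec("I")$spec, ds,
                              c("nlminb", "nelder-mead"))
  expect_true(any(rep$fits$singular | !rep$fits$converged))
})

test_that("BLUPs vanish when variance components vanish and track true effects otherwise", {
  # fit the intercept model to independent-noise data: estimated g ~ 0
  ds <- simulate_dataset(simulation_scenario("none"),
                         make_independent_design(12, c(0, 2, 4, 6)), seed = 68)
  f <- fit_lmm(make_model_spec("IV")$spec, ds)
  bl <- predict_blup(f)
  expect_lt(max(abs(bl$ranef$subject$intercept)), 0.15)
  expect_equal(bl$fitted$fitted, bl$fitted$population, tolerance = 0.2)
  # conditional residual identity and per-subject record conservation
  expect_equal(bl$fitted$response - bl$fitted$fitted, bl$fitted$resid)
  expect_equal(as.numeric(table(bl$fitted$subject)),
               as.numeric(table(ds$subject)))

  # strong intercept variance, tiny noise: BLUPs recover the true draws
  gen <- intercept_dataset(30, c(0, 2, 4, 6, 8), g_sd = 5, sigma = 0.5,
                           seed = 69)
  f2 <- fit_lmm(make_model_spec("IV")$spec, gen$ds)
  bl2 <- predict_blup(f2)
  ord <- match(sprintf("s%02d", 1:30), bl2$ranef$subject$unit)
  expect_gt(stats::cor(bl2$ranef$subject$intercept[ord], gen$b), 0.9)
})
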