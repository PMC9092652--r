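# Small shared fixtures, built in code at test time.

# A tiny two-subject, two-group dataset with known responses.
tiny_dataset <- function() {
  long_dataset(data.frame(
    subject = rep(c("s1", "s2"), each = 2),
    group = rep(c("A", "B"), each = 2),
    time = c(0, 1, 0, 1),
    response = c(1, 2, 3, 5)))
}

# A stub fit object for closed-form tests of Wald statistics and intervals
# (beta and SE chosen by the test; no data behind it).
stub_fit <- function(beta, se, loglik = 0, n_params = 5L,
                     spec = model_spec(list(re_level("subject")))) {
  nm <- c("(Intercept)", "group", "time", "group:time")
  structure(list(beta = stats::setNames(rep_len(beta, 4), nm),
                 beta_se = stats::setNames(rep_len(se, 4), nm),
                 loglik = loglik, method = "ML", converged = TRUE,
                 singular = FALSE, n_obs = 100L, n_params = n_params,
                 grad_norm = 0, spec = spec),
            class = "lmm_fit")
}

# Independent-subject dataset with known per-subject random intercepts,
# for BLUP recovery checks.
intercept_dataset <- function(n_subj, times, g_sd, sigma, seed,
                              beta = c(1, 0.5, 0.3, -0.1)) {
  set.seed(seed)
  b <- rnorm(n_subj, sd = g_sd)
  rows <- lapply(seq_len(n_subj), function(i) {
    grp <- if (i <= n_subj / 2) "A" else "B"
    g01 <- as.numeric(grp == "B")
    mu <- beta[1] + beta[2] * g01 + (beta[3] + beta[4] * g01) * times
    data.frame(subject = sprintf("s%02d", i), group = grp, time = times,
               response = mu + b[i] + rnorm(length(times), sd = sigma))
  })
  list(ds = long_dataset(do.call(rbind, rows)), b = b)
}
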