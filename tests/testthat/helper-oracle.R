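# Independent brute-force likelihood oracle: assembles the full N x N
# marginal covariance entry by entry from the model definition and evaluates
# the (restricted) Gaussian log-density directly with solve()/determinant().
# Shares no code path with the engine's blocked Cholesky evaluator.

oracle_nll <- function(ds, spec, params, method = "ML") {
  df <- as.data.frame(ds)
  N <- nrow(df)
  g01 <- as.numeric(df$group == levels(df$group)[2])
  X <- cbind(1, g01, df$time, g01 * df$time)
  y <- df$response
  V <- matrix(0, N, N)
  for (li in seq_along(spec$levels)) {
    lev <- spec$levels[[li]]
    G <- params$G[[li]]
    unit <- if (lev$level == "cluster") df$cluster else df$subject
    for (i in 1:N) {
      for (j in 1:N) {
        if (unit[i] == unit[j]) {
          zi <- c(if (lev$intercept) 1, if (lev$slope) df$time[i])
          zj <- c(if (lev$intercept) 1, if (lev$slope) df$time[j])
          V[i, j] <- V[i, j] + as.numeric(t(zi) %*% G %*% zj)
        }
      }
    }
  }
  if (spec$residual == "independent") {
    V <- V + diag(params$sigma2, N)
  } else {
    ord <- stats::ave(df$time, df$subject, FUN = rank)
    for (i in 1:N) {
      for (j in 1:N) {
        if (df$subject[i] == df$subject[j]) {
          V[i, j] <- V[i, j] + params$sigma2 * params$phi^abs(ord[i] - ord[j])
        }
      }
    }
  }
  Vi <- solve(V)
  XtViX <- t(X) %*% Vi %*% X
  bhat <- solve(XtViX, t(X) %*% Vi %*% y)
  r <- y - X %*% bhat
  quad <- as.numeric(t(r) %*% Vi %*% r)
  ld <- as.numeric(determinant(V, logarithm = TRUE)$modulus)
  if (method == "ML") {
    0.5 * (N * log(2 * pi) + ld + quad)
  } else {
    0.5 * ((N - 4) * log(2 * pi) + ld +
             as.numeric(determinant(XtViX, logarithm = TRUE)$modulus) + quad)
  }
}

# Random small instance: <= 3 clusters, <= 3 subjects each, <= 4 times,
# a random model structure and random valid parameters.
random_small_instance <- function(seed) {
  set.seed(seed)
  n_cl <- sample(1:3, 1)
  base_times <- sort(sample(0:10, 4))
  rows <- list()
  for (cl in seq_len(n_cl)) {
    n_su <- sample(1:3, 1)
    for (su in seq_len(n_su)) {
      nt <- sample(2:4, 1)
      times <- sort(sample(base_times, nt))
      rows[[length(rows) + 1]] <- data.frame(
        subject = sprintf("c%d.s%d", cl, su),
        cluster = sprintf("c%d", cl),
        group = if (cl %% 2 == 0) "B" else "A",
        time = times, response = NA_real_)
    }
  }
  df <- do.call(rbind, rows)
  # both groups must appear for the fixed design to be full rank
  if (length(unique(df$group)) < 2) {
    subs <- unique(df$subject)
    if (length(subs) == 1) {
      extra <- df[df$subject == subs[1], ]
      extra$subject <- paste0(extra$subject, "x")
      extra$group <- "B"
      df <- rbind(df, extra)
    } else {
      flip <- subs[seq(1, length(subs), by = 2)]
      df$group[df$subject %in% flip] <- "B"
    }
  }
  df$response <- rnorm(nrow(df), mean = 1 + 0.5 * df$time, sd = 2)
  ds <- long_dataset(df)

  structure_id <- sample(1:6, 1)
  spec <- switch(structure_id,
    model_spec(list(re_level("cluster", TRUE, TRUE),
                    re_level("subject", TRUE, TRUE))),
    model_spec(list(re_level("cluster", TRUE, FALSE),
                    re_level("subject", TRUE, TRUE))),
    model_spec(list(re_level("subject", TRUE, TRUE))),
    model_spec(list(re_level("subject", TRUE, FALSE))),
    model_spec(list(re_level("subject", FALSE, TRUE)), residual = "ar1"),
    model_spec(list(re_level("subject", TRUE, FALSE)), residual = "ar1"))
  G <- lapply(spec$levels, function(lev) {
    q <- sum(c(lev$intercept, lev$slope))
    A <- matrix(rnorm(q * q, sd = 0.7), q, q)
    A %*% t(A) + diag(0.1, q)
  })
  params <- list(G = G, sigma2 = runif(1, 0.5, 2),
                 phi = if (spec$residual == "ar1") runif(1, -0.7, 0.7) else NULL)
  list(ds = ds, spec = spec, params = params)
}
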