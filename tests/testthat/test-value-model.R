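test_that("beta value recursion reproduces hand-computed sequences", {
  # gamma = 0.5, prior (1,1), outcomes [1, 0]
  v <- beta_value_series(c(1, 0), gamma = 0.5)
  expect_equal(v$V, c(0.5, 0.75))                 # pre-outcome values
  expect_equal(v$alpha, c(1, 1.5))
  expect_equal(v$beta, c(1, 0.5))
  expect_equal(v$V_post, c(0.75, 0.375))          # (0.75,1.25) after trial 2

  # gamma = 1, outcomes [1,1,1]: Laplace running mean, V after third = 4/5
  v2 <- beta_value_series(c(1, 1, 1), gamma = 1)
  expect_equal(v2$V_post[3], 0.8)
})

test_that("gamma = 1 recursion equals the closed-form Laplace mean exactly", {
  set.seed(1)
  for (rep in 1:5) {
    r <- rbinom(200, 1, runif(1, 0.2, 0.8))
    v <- beta_value_series(r, gamma = 1, prior = c(1, 1))
    t <- seq_along(r)
    closed <- (1 + cumsum(r)) / (2 + t)
    expect_equal(v$V_post, closed, tolerance = 1e-12)
    expect_equal(v$V, c(0.5, closed[-length(closed)]), tolerance = 1e-12)
  }
})

test_that("replacing a loss with a win weakly increases all later values", {
  set.seed(2)
  for (gamma in c(0.3, 0.7, 1)) {
    r <- rbinom(80, 1, 0.5)
    i <- sample(which(r == 0), 1)
    r2 <- r; r2[i] <- 1
    v1 <- beta_value_series(r, gamma)$V
    v2 <- beta_value_series(r2, gamma)$V
    expect_true(all(v2[(i + 1):80] >= v1[(i + 1):80]))
    expect_true(any(v2 > v1))
  }
})

test_that("at gamma = 1 the value converges to the stationary reward rate", {
  set.seed(3)
  r <- rbinom(10000, 1, 0.7)
  v <- beta_value_series(r, gamma = 1)
  expect_lt(abs(v$V[10000] - 0.7), 0.02)
})

test_that("terciles partition trials into thirds by value rank", {
  v <- beta_value_series(rbinom(90, 1, 0.5), gamma = 0.8)
  expect_equal(as.integer(table(v$tercile)[c("low", "med", "high")]),
               c(30L, 30L, 30L))
  expect_true(max(v$V[v$tercile == "low"]) <=
                min(v$V[v$tercile == "high"]))
})

test_that("fit_gamma recovers a perfect monotone coupling exactly", {
  beh <- gen_behavior(behavior_spec(n_blocks = 10, gamma_true = 0.8), 21)
  tr <- beh$trials
  V <- beta_value_series(tr, 0.8)$V
  tr$latency <- exp(-V)       # latency = exp(-V): log latency = -V
  fg <- fit_gamma(tr)
  expect_equal(fg$gamma_star, 0.8)
  expect_equal(min(fg$profile$r, na.rm = TRUE), -1, tolerance = 1e-9)
  tr$latency <- rep(0.5, nrow(tr))
  expect_error(fit_gamma(tr), "latency variance")
})

test_that("value regression recovers slopes and handles degenerate input", {
  beh <- gen_behavior(behavior_spec(n_blocks = 10), 22)
  v <- beta_value_series(beh$trials, 0.7)
  set.seed(4)
  y <- 10 - 5 * v$V + rnorm(nrow(v), 0, 1)
  r <- value_regression(y, v, "epoch")
  expect_lt(abs(r$coefficient - (-5)), 1)
  expect_lt(r$p_value, 0.01)
  expect_equal(r$sign, "negative")
  expect_true(r$rpe_consistent)

  # constant signal: coefficient 0, p = 1 convention
  rc <- value_regression(rep(3, nrow(v)), v, "epoch")
  expect_equal(rc$coefficient, 0)
  expect_equal(rc$p_value, 1)

  # zero variance in V is not identifiable
  expect_error(value_regression(y, rep(0.5, nrow(v)), "epoch"),
               "value not identified")
  expect_error(value_regression(y[1:5], v$V[1:5], "epoch"), "10 trials")
})

test_that("per-bin regression corrects across bins", {
  beh <- gen_behavior(behavior_spec(n_blocks = 10), 23)
  v <- beta_value_series(beh$trials, 0.7)
  n <- nrow(v)
  set.seed(5)
  mat <- matrix(rnorm(n * 20), n, 20)
  mat[, 7] <- 5 + 8 * v$V + rnorm(n, 0, 0.5)   # one truly coupled bin
  r <- value_regression(mat, v, "per_bin")
  expect_equal(nrow(r), 20L)
  expect_true(r$significant[7])
  expect_lt(sum(r$significant[-7]), 3)
  expect_true(all(r$p_adj >= r$p_value))
})

test_that("tonic value analysis bins minutes and groups by tercile", {
  tr <- mk_trials(30, spacing = 8)
  dur <- max(tr$side_in) + 5
  v <- beta_value_series(tr, 0.7)
  spk <- periodic_train(5, dur)
  res <- tonic_value_analysis(spk, tr, v, duration = dur)
  expect_equal(nrow(res$minute_rates), ceiling(dur / 60))
  expect_equal(res$n_dropped, 0)
  # periodic unit: identical ITI rates across terciles
  expect_lt(diff(range(res$iti_rates$rate)), 0.5)

  # a 60 s session yields exactly one minute bin
  tr1 <- mk_trials(3, spacing = 10)
  res1 <- tonic_value_analysis(periodic_train(5, 60), tr1,
                               beta_value_series(tr1, 0.7), duration = 60)
  expect_equal(nrow(res1$minute_rates), 1L)

  # value-coupled rate is detected in the tercile contrast
  beh <- gen_behavior(behavior_spec(n_blocks = 8), 31)
  dur2 <- beh$duration
  v2 <- beta_value_series(beh$trials, 0.7)
  # build an inhomogeneous train whose ITI rate tracks V_true
  st <- unlist(lapply(seq_len(nrow(beh$trials)), function(i) {
    lo <- beh$trials$light_on[i]
    rate <- 4 + 4 * beh$ground_truth$V_true[i]
    n <- rpois(1, rate * 3)
    sort(runif(n, lo - 3, lo))
  }))
  set.seed(6)
  spk2 <- spike_train("vt", sort(unique(st)))
  res2 <- tonic_value_analysis(spk2, beh$trials, v2, duration = dur2)
  expect_gt(res2$tercile_means[["high"]], res2$tercile_means[["low"]])
  expect_lt(res2$kruskal_p, 0.05)
})
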