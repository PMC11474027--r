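#' Bayesian beta-distribution trial value
#'
#' Maintains a beta distribution over reward probability whose
#' pseudo-counts decay with a single rate `gamma` per trial: after
#' observing outcome r (1 rewarded, 0 unrewarded),
#' `alpha <- gamma * alpha + r` and `beta <- gamma * beta + (1 - r)`.
#' The trial value V is the posterior mean `alpha / (alpha + beta)`
#' evaluated *before* the trial's outcome (the model's prediction), the
#' quantity used for reward-prediction-error analyses. At `gamma = 1`
#' the model reduces exactly to a Laplace running mean,
#' `V_t = (alpha0 + sum(r)) / (alpha0 + beta0 + t)`.
#'
#' Trials are ranked into value terciles (low/med/high) within the
#' session, ties broken by trial order.
#'
#' @param trials A [trial_table()] (only `outcome` is used), or a 0/1
#'   outcome vector.
#' @param gamma Decay rate in (0, 1].
#' @param prior `c(alpha0, beta0)` pseudo-count prior (default uniform,
#'   `c(1, 1)`).
#' @return A data.frame (class `value_series`) with per-trial `alpha`,
#'   `beta` (pre-outcome pseudo-counts), `V` (pre-outcome value),
#'   `V_post` (value after the trial's update) and `tercile`;
#'   attributes `gamma` and `prior`.
#' @export
#' @examples
#' v <- beta_value_series(c(1, 0, 1, 1), gamma = 0.9)
#' v$V
beta_value_series <- function(trials, gamma, prior = c(1, 1)) {
  if (gamma <= 0 || gamma > 1) stop("gamma must lie in (0, 1]", call. = FALSE)
  outcomes <- if (is.data.frame(trials)) trials$outcome else as.numeric(trials)
  stopifnot(all(outcomes %in% c(0, 1)))
  n <- length(outcomes)
  a <- numeric(n); b <- numeric(n)
  cur_a <- prior[1]; cur_b <- prior[2]
  for (t in seq_len(n)) {
    a[t] <- cur_a; b[t] <- cur_b
    cur_a <- gamma * cur_a + outcomes[t]
    cur_b <- gamma * cur_b + (1 - outcomes[t])
  }
  V <- a / (a + b)
  post_a <- gamma * a + outcomes
  post_b <- gamma * b + (1 - outcomes)
  out <- data.frame(trial = seq_len(n), alpha = a, beta = b, V = V,
                    V_post = post_a / (post_a + post_b))
  out$tercile <- value_terciles(V)
  attr(out, "gamma") <- gamma
  attr(out, "prior") <- prior
  class(out) <- c("value_series", "data.frame")
  out
}

value_terciles <- function(V) {
  n <- length(V)
  if (n == 0) return(character(0))
  r <- rank(V, ties.method = "first")
  cut(r, breaks = c(0, n / 3, 2 * n / 3, n) + 0.5,
      labels = c("low", "med", "high"), include.lowest = TRUE) |> as.character()
}

#' Fit the value-model decay rate from initiation latencies
#'
#' Selects `gamma` by maximizing the *negative* Pearson correlation
#' between the model's trial value and log initiation latency (Light On
#' to Center In): motivated rats start trials faster when expected
#' reward is high, so the best-fitting decay is the one whose value
#' series anticorrelates most strongly with log latency.
#'
#' @param trials A [trial_table()] with positive `latency`.
#' @param grid Candidate gamma values (default 0.50 to 1.00 by 0.01).
#' @param prior Beta prior passed to [beta_value_series()].
#' @return List with `gamma_star` (argmin of the correlation; ties take
#'   the smallest gamma), and `profile`, a data.frame of `gamma` and
#'   Pearson `r`.
#' @export
fit_gamma <- function(trials, grid = seq(0.50, 1.00, by = 0.01),
                      prior = c(1, 1)) {
  lat <- trials$latency
  if (any(!is.finite(lat)) || any(lat <= 0)) {
    stop("latencies must be positive and finite", call. = FALSE)
  }
  loglat <- log(lat)
  if (sd(loglat) == 0) stop("no latency variance", call. = FALSE)
  r <- vapply(grid, function(g) {
    V <- beta_value_series(trials, g, prior)$V
    if (sd(V) == 0) return(NA_real_)
    cor(V, loglat)
  }, numeric(1))
  if (all(is.na(r))) stop("value not identified on the whole grid", call. = FALSE)
  gamma_star <- grid[which.min(r)]  # which.min takes the first (smallest gamma) tie
  list(gamma_star = gamma_star,
       profile = data.frame(gamma = grid, r = r))
}

#' Regress a per-trial signal on trial value
#'
#' Ordinary least squares of a neural signal (per-trial firing rate or
#' dF/F) on the model value V. In `scope = "epoch"` mode the signal is
#' one number per trial (e.g. the mean rate 100--250 ms after Side In)
#' and a single regression is run, tested two-tailed by the F-test at
#' `alpha`. In `scope = "per_bin"` mode `signal` is a trials x bins
#' matrix and one regression is run per bin with Bonferroni correction
#' across bins. A negative coefficient on rewarded trials is labelled
#' RPE-consistent (stronger reward response when reward was less
#' expected).
#'
#' @param signal Numeric vector (epoch scope) or trials x bins matrix
#'   (per_bin scope).
#' @param values A `value_series` (or numeric V vector) aligned to trials.
#' @param scope "epoch" or "per_bin".
#' @param trial_filter Optional logical/integer selector applied to both
#'   signal rows and values.
#' @param alpha Significance level (default 0.05).
#' @return For epoch scope, one-row data.frame with `coefficient`,
#'   `p_value`, `significant`, `sign`, `rpe_consistent`; for per_bin
#'   scope, one row per bin plus a `p_adj` column.
#' @export
value_regression <- function(signal, values, scope = c("epoch", "per_bin"),
                             trial_filter = NULL, alpha = 0.05) {
  scope <- match.arg(scope)
  V <- if (is.data.frame(values)) values$V else as.numeric(values)
  if (scope == "epoch") signal <- as.numeric(signal) else signal <- as.matrix(signal)
  if (!is.null(trial_filter)) {
    V <- V[trial_filter]
    signal <- if (scope == "epoch") signal[trial_filter] else
      signal[trial_filter, , drop = FALSE]
  }
  n <- if (scope == "epoch") length(signal) else nrow(signal)
  if (n < 10) stop("need at least 10 trials after filtering", call. = FALSE)
  if (length(V) != n) stop("values and signal disagree in length", call. = FALSE)
  if (var(V) == 0) stop("value not identified (zero variance in V)", call. = FALSE)

  one <- function(y) {
    if (var(y) == 0) {
      return(c(coefficient = 0, p_value = 1))
    }
    fit <- lm(y ~ V)
    sm <- summary(fit)
    p <- pf(sm$fstatistic[1], sm$fstatistic[2], sm$fstatistic[3],
            lower.tail = FALSE)
    c(coefficient = unname(coef(fit)[2]), p_value = unname(p))
  }

  if (scope == "epoch") {
    res <- one(signal)
    out <- data.frame(scope = "epoch", coefficient = res["coefficient"],
                      p_value = res["p_value"],
                      significant = res["p_value"] < alpha,
                      row.names = NULL)
  } else {
    res <- t(apply(signal, 2L, one))
    out <- data.frame(scope = "per_bin", bin = seq_len(nrow(res)),
                      coefficient = res[, "coefficient"],
                      p_value = res[, "p_value"], row.names = NULL)
    out$p_adj <- p.adjust(out$p_value, method = "bonferroni")
    out$significant <- out$p_adj < alpha
  }
  out$sign <- ifelse(out$coefficient > 0, "positive",
                     ifelse(out$coefficient < 0, "negative", "zero"))
  out$rpe_consistent <- out$significant & out$coefficient < 0
  out
}

#' Tonic firing rate versus trial value
#'
#' Computes each trial's mean firing rate in the intertrial interval
#' (by default the 3 s preceding Light On), groups trials by value
#' tercile, and summarises the session's rate in 1-minute bins. Group
#' differences are reported with a Kruskal-Wallis rank test and a
#' one-way ANOVA (reported, not gated).
#'
#' @param spikes A [spike_train()].
#' @param trials A [trial_table()].
#' @param values A `value_series` for the same trials.
#' @param window ITI window relative to Light On, default `c(-3, 0)` s.
#' @param duration Session duration, seconds (for the minute binning;
#'   defaults to the last spike/event time rounded up).
#' @return List with `iti_rates` (per-trial data.frame: trial, rate,
#'   tercile), `tercile_means`, `kruskal_p`, `anova_p`,
#'   `minute_rates` (data.frame minute, rate) and `n_dropped` (trials
#'   with insufficient pre-Light-On history).
#' @export
tonic_value_analysis <- function(spikes, trials, values, window = c(-3, 0),
                                 duration = NULL) {
  st <- spikes$spike_times
  lo <- trials$light_on
  keep <- lo + window[1] >= 0
  n_dropped <- sum(!keep)
  a <- lo[keep] + window[1]
  b <- lo[keep] + window[2]
  counts <- findInterval(b, st) - findInterval(a, st)
  rate <- counts / (window[2] - window[1])
  iti <- data.frame(trial = which(keep), rate = rate,
                    tercile = values$tercile[keep])
  iti$tercile <- factor(iti$tercile, levels = c("low", "med", "high"))
  means <- tapply(iti$rate, iti$tercile, mean)
  kw <- if (nlevels(droplevels(iti$tercile)) > 1 && var(iti$rate) > 0) {
    kruskal.test(rate ~ tercile, data = iti)$p.value
  } else NA_real_
  an <- if (nlevels(droplevels(iti$tercile)) > 1 && var(iti$rate) > 0) {
    summary(aov(rate ~ tercile, data = iti))[[1]][["Pr(>F)"]][1]
  } else NA_real_
  if (is.null(duration)) {
    duration <- max(st[length(st)], trials$side_in[nrow(trials)], 60)
  }
  n_min <- max(1L, ceiling(duration / 60 - 1e-9))
  edges <- seq(0, by = 60, length.out = n_min + 1)
  mc <- findInterval(edges[-1], st) - findInterval(edges[-length(edges)], st)
  widths <- pmin(edges[-1], duration) - edges[-length(edges)]
  minute_rates <- data.frame(minute = seq_len(n_min), rate = mc / widths)
  list(iti_rates = iti, tercile_means = means, kruskal_p = kw, anova_p = an,
       minute_rates = minute_rates, n_dropped = n_dropped)
}
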