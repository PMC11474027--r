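#' Specification for synthetic bandit-task behavior
#'
#' Encodes the task the simulator emulates: blocks of 35--45 trials with
#' left/right reward probabilities drawn independently from
#' \{0.1, 0.5, 0.9\}, a uniform 500--1500 ms hold between Center In and
#' the Go cue, log-normal reaction times with median 161 ms, and trial
#' initiation latencies that shorten with the model's trial value:
#' `latency = exp(a - b * V + eps)`, `eps ~ N(0, sigma^2)`.
#'
#' @param n_blocks Number of blocks.
#' @param block_len_range Inclusive integer range of block lengths.
#' @param probs Reward-probability menu.
#' @param hold_range Hold period range (Center In to Go cue), s.
#' @param latency_model `c(a, b, sigma)`: log-latency intercept, value
#'   slope (>= 0) and log-s noise SD.
#' @param rt_median,rt_sdlog Log-normal reaction-time parameters.
#' @param move_range Center Out to Side In travel-time range, s.
#' @param food_delay_range Side In to Food In delay range (rewarded), s.
#' @param iti_range Side In (or Food In) to next Light On range, s.
#' @param gamma_true Decay rate of the generative value model.
#' @return A `behavior_spec` list.
#' @export
behavior_spec <- function(n_blocks = 8,
                          block_len_range = c(35L, 45L),
                          probs = c(0.1, 0.5, 0.9),
                          hold_range = c(0.5, 1.5),
                          latency_model = c(a = 0.2, b = 1.0, sigma = 0.4),
                          rt_median = 0.161, rt_sdlog = 0.25,
                          move_range = c(0.2, 0.5),
                          food_delay_range = c(0.3, 1.0),
                          iti_range = c(4, 8),
                          gamma_true = 0.7) {
  if (length(probs) == 0) stop("probs must be non-empty", call. = FALSE)
  if (latency_model[2] < 0) stop("latency value slope must be >= 0", call. = FALSE)
  structure(list(n_blocks = n_blocks, block_len_range = block_len_range,
                 probs = probs, hold_range = hold_range,
                 latency_model = latency_model,
                 rt_median = rt_median, rt_sdlog = rt_sdlog,
                 move_range = move_range,
                 food_delay_range = food_delay_range,
                 iti_range = iti_range, gamma_true = gamma_true),
            class = "behavior_spec")
}

#' Generate synthetic bandit-task behavior
#'
#' Draws block structure, choices, outcomes and event times for one
#' session. Choices follow probability matching on side-specific beta
#' values (choose left with probability `V_left / (V_left + V_right)`,
#' both sides decaying at `gamma_true`, the chosen side updated by the
#' outcome); outcomes are Bernoulli in the chosen side's programmed
#' probability. The generative trial value `V_true` is the
#' [beta_value_series()] of the realized outcome sequence at
#' `gamma_true`, and initiation latencies are coupled to it through the
#' log-normal latency model.
#'
#' @param spec A [behavior_spec()].
#' @param seed Integer seed; the result is a pure function of
#'   `(spec, seed)`.
#' @return List with `trials` (a [trial_table()]), `duration` (s), and
#'   `ground_truth` (`V_true`, `gamma_true`, per-block parameters).
#' @export
gen_behavior <- function(spec, seed) {
  stopifnot(inherits(spec, "behavior_spec"))
  with_seed(seed, {
    lens <- sample(seq(spec$block_len_range[1], spec$block_len_range[2]),
                   spec$n_blocks, replace = TRUE)
    p_left_b <- sample(spec$probs, spec$n_blocks, replace = TRUE)
    p_right_b <- sample(spec$probs, spec$n_blocks, replace = TRUE)
    n <- sum(lens)
    block <- rep(seq_len(spec$n_blocks), lens)
    p_left <- p_left_b[block]
    p_right <- p_right_b[block]

    g <- spec$gamma_true
    aL <- 1; bL <- 1; aR <- 1; bR <- 1      # side-value pseudo-counts
    va <- 1; vb <- 1                         # overall value model
    choice <- character(n); outcome <- integer(n); V_true <- numeric(n)
    for (t in seq_len(n)) {
      VL <- aL / (aL + bL); VR <- aR / (aR + bR)
      left <- runif(1) < VL / (VL + VR)
      choice[t] <- if (left) "left" else "right"
      p <- if (left) p_left[t] else p_right[t]
      r <- rbinom(1, 1, p)
      outcome[t] <- r
      V_true[t] <- va / (va + vb)
      # decay both sides, increment the chosen one
      aL <- g * aL; bL <- g * bL; aR <- g * aR; bR <- g * bR
      if (left) { aL <- aL + r; bL <- bL + (1 - r) }
      else      { aR <- aR + r; bR <- bR + (1 - r) }
      va <- g * va + r; vb <- g * vb + (1 - r)
    }

    lm_ <- spec$latency_model
    latency <- exp(lm_[1] - lm_[2] * V_true + rnorm(n, 0, lm_[3]))
    hold <- runif(n, spec$hold_range[1], spec$hold_range[2])
    rt <- exp(rnorm(n, log(spec$rt_median), spec$rt_sdlog))
    move <- runif(n, spec$move_range[1], spec$move_range[2])
    food_delay <- runif(n, spec$food_delay_range[1], spec$food_delay_range[2])
    iti <- runif(n, spec$iti_range[1], spec$iti_range[2])

    light_on <- numeric(n)
    t_cursor <- iti[1]
    side_in <- numeric(n); food_in <- rep(NA_real_, n)
    center_in <- numeric(n); go_cue <- numeric(n); center_out <- numeric(n)
    for (t in seq_len(n)) {
      light_on[t] <- t_cursor
      center_in[t] <- light_on[t] + latency[t]
      go_cue[t] <- center_in[t] + hold[t]
      center_out[t] <- go_cue[t] + rt[t]
      side_in[t] <- center_out[t] + move[t]
      t_end <- side_in[t]
      if (outcome[t] == 1) {
        food_in[t] <- side_in[t] + food_delay[t]
        t_end <- food_in[t]
      }
      t_cursor <- t_end + if (t < n) iti[t + 1] else iti[t]
    }
    duration <- ceiling(t_cursor + 5)

    trials <- trial_table(data.frame(
      light_on = light_on, center_in = center_in, go_cue = go_cue,
      center_out = center_out, side_in = side_in, food_in = food_in,
      choice = choice, outcome = outcome,
      p_left = p_left, p_right = p_right, block_index = block))
    list(trials = trials, duration = duration,
         ground_truth = list(V_true = V_true, gamma_true = g,
                             block_lengths = lens,
                             p_left = p_left_b, p_right = p_right_b))
  })
}
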