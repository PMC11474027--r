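# shared fixture builders (all generated in code; no stored data)

empty_trials <- function() {
  trial_table(data.frame(light_on = numeric(0), center_in = numeric(0),
                         go_cue = numeric(0), center_out = numeric(0),
                         side_in = numeric(0), food_in = numeric(0),
                         choice = character(0), outcome = integer(0),
                         p_left = numeric(0), p_right = numeric(0),
                         block_index = integer(0)))
}

# a deterministic n-trial table with fixed within-trial timing
mk_trials <- function(n, spacing = 8, hold = 1, rt = 0.161) {
  light_on <- seq(4, by = spacing, length.out = n)
  center_in <- light_on + 0.4 + 0.05 * (seq_len(n) %% 7)  # varied latencies
  go_cue <- center_in + hold
  center_out <- go_cue + rt
  side_in <- center_out + 0.3
  outcome <- rep_len(c(1L, 0L), n)
  trial_table(data.frame(
    light_on = light_on, center_in = center_in, go_cue = go_cue,
    center_out = center_out, side_in = side_in,
    food_in = ifelse(outcome == 1, side_in + 0.5, NA_real_),
    choice = rep_len(c("left", "right"), n), outcome = outcome,
    p_left = 0.5, p_right = 0.9, block_index = 1L))
}

periodic_train <- function(rate, duration, id = "per") {
  spike_train(id, seq(1 / rate, duration - 1e-9, by = 1 / rate))
}

# small complete session for I/O and pipeline tests
mk_small_session <- function(seed = 1) {
  tr <- mk_trials(12)
  dur <- 160
  g <- gen_spikes(tr, 5, 2, seed = seed, duration = dur)
  laser <- gen_laser_schedule(110, widths_ms = 5, freqs_hz = 2,
                              n_per_condition = 15)
  spk <- gen_laser(g$spikes, laser, p_follow = 0.9, latency = 0.004,
                   jitter = 0.0005, seed = seed + 1)
  ecog <- gen_ecog(data.frame(start = c(0, 60), end = c(60, 160),
                              state = c("wake", "sws")),
                   sample_rate = 200, seed = seed + 2)$ecog
  phot <- gen_photometry(tr, list(kernel_spec("side_in", 0, 0.01, 0.1)),
                         seed = seed + 3, duration = 12)$raw
  session("s1", dur, tr, list(spk), laser, ecog, phot,
          region_label = "DLS", hemisphere = "left")
}
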