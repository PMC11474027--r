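test_that("behavior generation is a pure function of (spec, seed)", {
  spec <- behavior_spec(n_blocks = 3)
  a <- gen_behavior(spec, 42)
  b <- gen_behavior(spec, 42)
  expect_identical(a$trials, b$trials)
  expect_identical(a$ground_truth$V_true, b$ground_truth$V_true)
  c <- gen_behavior(spec, 43)
  expect_false(identical(a$trials$light_on, c$trials$light_on))
})

test_that("generated behavior honours the task parameters", {
  for (seed in 1:5) {
    beh <- gen_behavior(behavior_spec(n_blocks = 4), seed)
    tr <- beh$trials
    lens <- table(tr$block_index)
    expect_true(all(lens >= 35 & lens <= 45))
    expect_true(all(tr$p_left %in% c(0.1, 0.5, 0.9)))
    expect_true(all(tr$p_right %in% c(0.1, 0.5, 0.9)))
    hold <- tr$go_cue - tr$center_in
    expect_true(all(hold >= 0.5 & hold <= 1.5))
    expect_true(all(tr$latency > 0))
    # unrewarded trials have no food-port entry recorded
    expect_true(all(is.na(tr$food_in[tr$outcome == 0])))
    expect_true(all(!is.na(tr$food_in[tr$outcome == 1])))
    # generated tables always satisfy the data-model invariants
    expect_silent(trial_table(as.data.frame(tr)))
  }
})

test_that("rewarded fraction matches the programmed probability", {
  # all-0.9 menu: whatever side is chosen pays at 0.9
  spec <- behavior_spec(n_blocks = 250, probs = 0.9)
  beh <- gen_behavior(spec, 7)
  expect_gt(nrow(beh$trials), 8000)
  expect_lt(abs(mean(beh$trials$outcome) - 0.9), 0.01)
})

test_that("latency couples to value through b, and decouples at b = 0", {
  beh <- gen_behavior(behavior_spec(n_blocks = 50,
                                    latency_model = c(0.2, 0, 0.4)), 11)
  r0 <- cor(beh$ground_truth$V_true, log(beh$trials$latency))
  expect_lt(abs(r0), 0.05)
  beh2 <- gen_behavior(behavior_spec(n_blocks = 50,
                                     latency_model = c(0.2, 1.5, 0.3)), 11)
  r1 <- cor(beh2$ground_truth$V_true, log(beh2$trials$latency))
  expect_lt(r1, -0.3)
})

test_that("gamma-renewal trains hit the requested rate and CV", {
  for (shape in c(1, 4, 16)) {
    g <- gen_spikes(empty_trials(), base_rate = 10, regularity = shape,
                    seed = shape, duration = 1200)
    st <- g$spikes$spike_times
    expect_lt(abs(length(st) / 1200 - 10) / 10, 0.05)
    isi <- diff(st)
    expect_lt(abs(sd(isi) / mean(isi) - 1 / sqrt(shape)), 0.05 / sqrt(shape) + 0.02)
  }
})

test_that("a pause kernel suppresses the PETH rate in its window", {
  tr <- mk_trials(300, spacing = 6)
  dur <- max(tr$side_in) + 10
  g <- gen_spikes(tr, 5, 2, list(kernel_spec("side_in", 0.100, 0.150, 0.2)),
                  seed = 5, duration = dur)
  p <- compute_peth(g$spikes, tr$side_in, c(-1, 1), duration = dur)
  inw <- p$bin_centers > 0.105 & p$bin_centers < 0.245
  base <- p$bin_centers < 0
  expect_lt(mean(p$mean_rate[inw]), 0.4 * mean(p$mean_rate[base]))
})

test_that("kernels referencing an absent event error", {
  expect_error(
    gen_spikes(mk_trials(5), 5, 1,
               list(kernel_spec("nose_out", 0, 0.1, 2)), 1, duration = 60),
    "absent event")
})

test_that("laser-evoked spikes follow pulses as specified", {
  tr <- empty_trials()
  g <- gen_spikes(tr, 5, 1, seed = 3, duration = 300)
  laser <- gen_laser_schedule(10, widths_ms = 5, freqs_hz = 1,
                              n_per_condition = 200, gap = 0)

  # p_follow = 1, jitter = 0: a spike at exactly +5 ms after every pulse
  all_follow <- gen_laser(g$spikes, laser, 1, latency = 0.005, jitter = 0,
                          seed = 9)
  hits <- vapply(laser$pulse_time_s, function(p)
    any(abs(all_follow$spike_times - (p + 0.005)) < 1e-9), logical(1))
  expect_true(all(hits))

  # p_follow = 0: identity
  none <- gen_laser(g$spikes, laser, 0, seed = 9)
  expect_identical(none$spike_times, g$spikes$spike_times)

  # p_follow = 0.5 over 200 pulses: binomial count within +-3 sigma
  half <- gen_laser(g$spikes, laser, 0.5, latency = 0.005, jitter = 0,
                    seed = 10)
  n_evoked <- length(half$spike_times) - length(g$spikes$spike_times)
  expect_gte(n_evoked, 79)
  expect_lte(n_evoked, 121)
})

test_that("ECoG generation is deterministic and schedules must not overlap", {
  sch <- data.frame(start = c(0, 100), end = c(100, 200),
                    state = c("wake", "sws"))
  a <- gen_ecog(sch, 200, 5)
  b <- gen_ecog(sch, 200, 5)
  expect_identical(a$ecog$samples, b$ecog$samples)
  bad <- data.frame(start = c(0, 50), end = c(100, 150),
                    state = c("wake", "sws"))
  expect_error(gen_ecog(bad, 200, 5), "overlap")
})

test_that("control-channel regression removes shared motion noise", {
  tr <- mk_trials(10)
  gp <- gen_photometry(tr, list(), artifact = list(bleach_tau = 500,
                                                   motion_sd = 0.02),
                       seed = 6, duration = 60)
  ch <- demultiplex(gp$raw)
  dff <- compute_dff(ch$sig470, ch$sig405)
  # uncorrected fractional signal about a smooth trend keeps the motion
  trend <- 0.25 + 0.75 * exp(-(seq_along(ch$sig470$samples) - 1) /
                               ch$sig470$sample_rate / 500)
  uncorrected <- ch$sig470$samples / (trend * mean(ch$sig470$samples / trend)) - 1
  expect_lt(var(dff$samples_raw), var(uncorrected))
})
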