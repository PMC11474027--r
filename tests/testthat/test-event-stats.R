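test_that("bin geometry: 3 s window at 10 ms / 5 ms gives 599 bins", {
  p <- compute_peth(c(1), event_times = 10, window = c(-1, 2))
  expect_equal(length(p$bin_centers), 599L)
  expect_equal(p$bin_centers[1], -0.995)
  expect_equal(p$bin_centers[599], 1.995)
})

test_that("a spike lands in exactly the bins a brute-force scan says", {
  # one trial, one spike exactly at event + 0.100 s; counting is done in
  # event-relative time, so place the event at 0 to keep the offset exact
  p <- compute_peth(c(0.100), 0, c(0, 0.3))
  # oracle: direct half-open membership test per bin, same arithmetic
  oracle <- vapply(p$bin_centers, function(c)
    (0.100 >= c - 0.005) && (0.100 < c + 0.005), logical(1))
  expect_equal(as.vector(p$trial_counts[1, ]), as.numeric(oracle))
  # exactly two of the overlapping bins contain the spike; the bin whose
  # upper edge *is* the spike time excludes it (half-open convention)
  expect_equal(sum(oracle), 2L)
  expect_equal(p$bin_centers[oracle], c(0.100, 0.105), tolerance = 1e-9)
  at_edge <- which(abs(p$bin_centers - 0.095) < 1e-12)
  expect_equal(unname(p$trial_counts[1, at_edge]), 0)

  # the oracle agrees with the PETH on arbitrary random spike patterns
  set.seed(99)
  st <- sort(runif(200, 0, 0.35))
  p2 <- compute_peth(st, 0, c(0, 0.3))
  oracle2 <- vapply(p2$bin_centers, function(c)
    sum(st >= c - 0.005 & st < c + 0.005), numeric(1))
  expect_equal(as.vector(p2$trial_counts[1, ]), oracle2)
})

test_that("homogeneous trains give flat PETHs at the base rate", {
  tr <- mk_trials(500, spacing = 5)
  dur <- max(tr$side_in) + 5
  g <- gen_spikes(empty_trials(), 5, 2, seed = 17, duration = dur)
  p <- compute_peth(g$spikes, tr$go_cue, c(-1, 2), duration = dur)
  # the grand mean recovers the rate tightly; per-bin estimates carry
  # binomial noise (sd ~ sqrt(p/n)/bw ~ 1 Hz at 500 trials), so individual
  # bins are only bounded at 5 sigma
  expect_lt(abs(mean(p$mean_rate) - 5) / 5, 0.02)
  bin_sd <- sqrt(0.05 / nrow(p$trial_counts)) / 0.010
  expect_true(all(abs(p$mean_rate - 5) < 5 * bin_sd))
})

test_that("non-overlapping bins conserve the exact spike count per trial", {
  tr <- mk_trials(40)
  dur <- max(tr$side_in) + 5
  g <- gen_spikes(empty_trials(), 8, 1, seed = 18, duration = dur)
  p <- compute_peth(g$spikes, tr$go_cue, c(-1, 1), bin_width = 0.010,
                    step = 0.010, duration = dur)
  st <- g$spikes$spike_times
  direct <- vapply(p$event_times, function(e)
    sum(st >= e - 1 & st < e + 1), numeric(1))
  expect_equal(rowSums(p$trial_counts), direct)
})

test_that("PETH, significance and onsets are shift invariant", {
  tr <- mk_trials(60)
  dur <- max(tr$side_in) + 5
  g <- gen_spikes(tr, 5, 2, list(kernel_spec("go_cue", 0.03, 0.1, 4)),
                  seed = 19, duration = dur)
  shift <- 37.5
  p1 <- compute_peth(g$spikes, tr$go_cue, c(-1, 2), duration = dur)
  p2 <- compute_peth(g$spikes$spike_times + shift, tr$go_cue + shift,
                     c(-1, 2), duration = dur + shift)
  expect_equal(p1$trial_counts, p2$trial_counts)
})

test_that("shuffle resolution contracts are enforced", {
  tr <- mk_trials(20)
  dur <- max(tr$side_in) + 5
  g <- gen_spikes(empty_trials(), 5, 1, seed = 20, duration = dur)
  p <- compute_peth(g$spikes, tr$go_cue, c(-1, 2), duration = dur)
  # 10,000 shuffles cannot resolve the Bonferroni tail 0.005/(2*599)
  # with raw empirical quantiles
  expect_error(
    shuffle_significance(g$spikes, p, dur, n_shuffles = 10000,
                         alpha = 0.005, correction = "bonferroni",
                         tail = "empirical", seed = 1),
    "insufficient shuffles")
  # pointwise mode at the same settings is fine
  expect_silent(
    shuffle_significance(g$spikes, p, dur, n_shuffles = 1000,
                         alpha = 0.005, correction = "pointwise", seed = 1))
  expect_error(
    shuffle_significance(g$spikes, p, dur, n_shuffles = 100,
                         alpha = 0.005, correction = "pointwise", seed = 1),
    "insufficient shuffles")
})

test_that("significance flags are reproducible and never up and down at once", {
  tr <- mk_trials(80)
  dur <- max(tr$side_in) + 5
  g <- gen_spikes(tr, 5, 2, list(kernel_spec("go_cue", 0.03, 0.1, 4)),
                  seed = 21, duration = dur)
  p <- compute_peth(g$spikes, tr$go_cue, c(-1, 2), duration = dur)
  s1 <- shuffle_significance(g$spikes, p, dur, 1000, seed = 7)
  s2 <- shuffle_significance(g$spikes, p, dur, 1000, seed = 7)
  expect_identical(s1$up, s2$up)
  expect_identical(s1$down, s2$down)
  expect_false(any(s1$up & s1$down))
})

test_that("an injected pause is flagged down inside its window", {
  tr <- mk_trials(300, spacing = 6)
  dur <- max(tr$side_in) + 5
  g <- gen_spikes(tr, 6, 2, list(kernel_spec("side_in", 0.1, 0.15, 0.2)),
                  seed = 22, duration = dur)
  p <- compute_peth(g$spikes, tr$side_in, c(-1, 2), duration = dur)
  sg <- shuffle_significance(g$spikes, p, dur, 2000, alpha = 0.005,
                             correction = "pointwise", seed = 8)
  inw <- sg$bin_centers >= 0.100 & sg$bin_centers <= 0.250
  expect_true(any(sg$down[inw]))
})

test_that("onset bookkeeping reads the flag runs correctly", {
  centers <- seq(-0.995, 1.995, by = 0.005)
  flags <- rep(FALSE, length(centers))
  sel <- centers >= 0.085 - 1e-9 & centers <= 0.120 + 1e-9
  flags[sel] <- TRUE
  sig <- structure(list(up = rep(FALSE, length(centers)), down = flags,
                        bin_centers = centers, bin_width = 0.010),
                   class = "significance_map")
  o <- onset_latency(sig, "down", c(0, 0.4))
  expect_equal(o$onset, 0.085)
  expect_equal(o$offset, 0.120)
  expect_equal(o$duration, 0.045)

  none <- structure(list(up = rep(FALSE, 10), down = rep(FALSE, 10),
                         bin_centers = seq(0, 0.045, by = 0.005),
                         bin_width = 0.010),
                    class = "significance_map")
  expect_true(is.na(onset_latency(none, "up")$onset))
})

test_that("selectivity index follows its defining arithmetic", {
  tr <- mk_trials(40)
  dur <- max(tr$side_in) + 5
  # contra trials at double the rate of ipsi trials
  groups <- rep(c("contra", "ipsi"), 20)
  st <- sort(unlist(lapply(seq_len(40), function(i) {
    n <- if (groups[i] == "contra") 40 else 20
    tr$go_cue[i] + seq(0.0, 0.5 - 1e-6, length.out = n)
  })))
  p <- compute_peth(st, tr$go_cue, c(-0.5, 1), groups = groups,
                    duration = dur)
  si <- selectivity_index(p, c(0, 0.5))
  expect_equal(si, 1 / 3, tolerance = 0.02)

  # swapping the labels negates the index
  p2 <- compute_peth(st, tr$go_cue, c(-0.5, 1),
                     groups = ifelse(groups == "contra", "ipsi", "contra"),
                     duration = dur)
  expect_equal(selectivity_index(p2, c(0, 0.5)), -si, tolerance = 1e-9)

  # equal groups give zero
  p3 <- compute_peth(st, tr$go_cue, c(-0.5, 1),
                     groups = rep(c("contra", "ipsi"), each = 20),
                     duration = dur)
  expect_lt(abs(selectivity_index(p3, c(0, 0.5))), 0.1)
})

test_that("cue-locked components label sensory; movement-locked label motor", {
  beh <- gen_behavior(behavior_spec(n_blocks = 8), 31)
  tr <- beh$trials
  dur <- beh$duration
  # burst locked to the Go cue (RT jitter decouples it from Center Out)
  g_cue <- gen_spikes(tr, 6, 2,
                      list(kernel_spec("go_cue", 0.030, 0.080, 4)),
                      seed = 23, duration = dur,
                      V_true = beh$ground_truth$V_true)
  lab_cue <- sensory_motor_label(g_cue$spikes, tr, "burst", dur, seed = 9)
  expect_true(lab_cue$included)
  expect_equal(lab_cue$label, "sensory")

  # burst locked to movement onset
  g_mov <- gen_spikes(tr, 6, 2,
                      list(kernel_spec("center_out", -0.040, 0.080, 4,
                                       lock = "movement")),
                      seed = 24, duration = dur,
                      V_true = beh$ground_truth$V_true)
  lab_mov <- sensory_motor_label(g_mov$spikes, tr, "burst", dur, seed = 10)
  expect_true(lab_mov$included)
  expect_equal(lab_mov$label, "motor")

  # a unit with no significant component is excluded, not labelled
  g_null <- gen_spikes(empty_trials(), 5, 2, seed = 25, duration = dur)
  lab_null <- sensory_motor_label(g_null$spikes, tr, "burst", dur, seed = 11)
  expect_false(lab_null$included)
  expect_true(is.na(lab_null$label))
})
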