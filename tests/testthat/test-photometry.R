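const_raw <- function(v470, v405, n_frames = 400, fs = 10000) {
  spf <- fs / 100; on_n <- fs * 4 / 1000
  sched <- rep(c("470", "405"), length.out = n_frames)
  frame_vals <- ifelse(sched == "470", v470, v405)
  det <- rep(frame_vals, each = spf) *
    rep(c(rep(1, on_n), rep(0, spf - on_n)), n_frames)
  photometry_raw(det, fs, 10, 4, schedule = sched)
}

test_that("demultiplexing splits constant channels exactly", {
  raw <- const_raw(3, 0)
  ch <- demultiplex(raw)
  expect_true(all(abs(ch$sig470$samples - 3) < 1e-12))
  expect_true(all(abs(ch$sig405$samples - 0) < 1e-12))
  expect_equal(ch$sig470$sample_rate, 100)
})

test_that("switching transients in the trimmed margin do not leak through", {
  raw <- const_raw(2, 1)
  det <- raw$detector
  spf <- 100
  # a large artifact confined to the first 0.5 ms of each on-period
  for (f in seq_along(raw$schedule)) {
    det[(f - 1) * spf + 1:5] <- det[(f - 1) * spf + 1:5] + 50
  }
  raw2 <- photometry_raw(det, 10000, 10, 4, schedule = raw$schedule)
  ch <- demultiplex(raw2)
  expect_true(all(abs(ch$sig470$samples - 2) < 1e-12))
  expect_true(all(abs(ch$sig405$samples - 1) < 1e-12))
})

test_that("schedules must cover every frame", {
  expect_error(photometry_raw(rep(1, 1000), 10000, 10, 4,
                              schedule = c("470", "405")),
               "one LED per frame")
})

test_that("dF/F is exactly zero when 470 is affine in 405", {
  set.seed(44)
  x <- 1 + 0.5 * exp(-(1:2000) / 800) + rnorm(2000, 0, 0.01)
  s405 <- continuous_signal(x, 100)
  s470 <- continuous_signal(2 * x, 100)
  dff <- compute_dff(s470, s405)
  expect_lt(max(abs(dff$samples_raw)), 1e-12)

  # common rescaling of both channels leaves dF/F unchanged
  dff_scaled <- compute_dff(continuous_signal(6 * x, 100),
                            continuous_signal(3 * x, 100))
  expect_equal(dff_scaled$samples_raw, dff$samples_raw, tolerance = 1e-9)

  expect_error(compute_dff(s470, continuous_signal(rep(1, 2000), 100)),
               "control channel constant")
})

test_that("a 10% transient on 470 only appears as a 0.1 dF/F excursion", {
  set.seed(45)
  x <- 2 + 0.3 * exp(-(1:4000) / 1500) + rnorm(4000, 0, 0.005)
  y <- 1.5 * x
  y[2000:2100] <- y[2000:2100] * 1.10
  dff <- compute_dff(continuous_signal(y, 100), continuous_signal(x, 100))
  pk <- max(dff$samples_raw)
  expect_lt(abs(pk - 0.10) / 0.10, 0.10)
})

test_that("the median filter preserves its root signals exactly", {
  # monotone sequences are fixed points ("roots") of the median filter:
  # filtering a second time changes nothing
  x <- cumsum(abs(rnorm(2000)))
  once <- as.numeric(runmed(x, 5, endrule = "median"))
  inner <- 3:1998          # the Tukey end rule may touch the 2 edge samples
  expect_equal(once[inner], x[inner], tolerance = 1e-12)
  # and for arbitrary signals repeated filtering converges to a root
  set.seed(46)
  f <- rnorm(2000)
  for (i in 1:60) f <- as.numeric(runmed(f, 5, endrule = "median"))
  expect_equal(as.numeric(runmed(f, 5, endrule = "median"))[inner], f[inner],
               tolerance = 1e-12)
})

test_that("bleaching alone leaves a near-zero dF/F at any tau", {
  for (tau in c(300, 3000)) {
    tr <- mk_trials(6)
    gp <- gen_photometry(tr, list(), artifact = list(bleach_tau = tau,
                                                     motion_sd = 0),
                         seed = tau, duration = 60)
    ch <- demultiplex(gp$raw)
    dff <- compute_dff(ch$sig470, ch$sig405)
    expect_lt(mean(abs(dff$samples_raw)), 0.01)
  }
})

test_that("event alignment extracts windows, groups and drops edges", {
  dff <- structure(list(samples = rep(1.5, 1000), samples_raw = rep(0.2, 1000),
                        sample_rate = 250, fit_params = c(1, 0), t0 = 0),
                   class = "dff_signal")
  al <- align_dff(dff, c(1, 2, 3), c(-0.2, 0.4),
                  groups = c("rewarded", "unrewarded", "rewarded"))
  expect_equal(dim(al$matrix), c(3L, length(al$time)))
  expect_true(all(al$matrix == 1.5))
  expect_equal(unname(al$group_sem$rewarded), rep(0, length(al$time)))
  expect_equal(al$n_dropped, 0)
  # event too close to the edge is dropped with a count
  al2 <- align_dff(dff, c(0.1, 2), c(-0.2, 0.4))
  expect_equal(al2$n_dropped, 1)
  # absent group is simply omitted
  expect_null(al$group_means$tercile_low)
})

test_that("rewarded reward-kernel trials exceed unrewarded in aligned dF/F", {
  beh <- gen_behavior(behavior_spec(n_blocks = 5, iti_range = c(3, 5)), 48)
  k <- kernel_spec("food_in", 0, 0.02, 0.08)
  gp <- gen_photometry(beh$trials, list(k), seed = 49,
                       duration = beh$duration)
  ch <- demultiplex(gp$raw)
  dff <- compute_dff(ch$sig470, ch$sig405)
  grp <- ifelse(beh$trials$outcome == 1, "rewarded", "unrewarded")
  al <- align_dff(dff, beh$trials$side_in, c(-0.5, 1.5), groups = grp,
                  zscored = FALSE)
  inw <- al$time > 0.2 & al$time < 1.2   # food_in happens ~0.3-1.0 s later
  expect_gt(max(al$group_means$rewarded[inw]),
            max(al$group_means$unrewarded[inw]) + 0.02)
})

test_that("dF/F significance flags are deterministic given the seed", {
  beh <- gen_behavior(behavior_spec(n_blocks = 3, iti_range = c(3, 5)), 50)
  gp <- gen_photometry(beh$trials, list(kernel_spec("side_in", 0, 0.01, 0.1)),
                       seed = 51, duration = beh$duration)
  ch <- demultiplex(gp$raw)
  dff <- compute_dff(ch$sig470, ch$sig405)
  s1 <- dff_significance(dff, beh$trials$side_in, c(-0.5, 1), 1000, seed = 12)
  s2 <- dff_significance(dff, beh$trials$side_in, c(-0.5, 1), 1000, seed = 12)
  expect_identical(s1$up, s2$up)
  expect_identical(s1$down, s2$down)
  expect_true(any(s1$up[s1$bin_centers > 0 & s1$bin_centers < 0.3]))
})
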