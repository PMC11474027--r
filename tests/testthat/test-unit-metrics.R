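test_that("basic metrics reproduce worked cases exactly", {
  # perfectly periodic 5 Hz train over 100 s
  m <- basic_metrics(periodic_train(5, 100), total_time = 100)
  expect_equal(m$mean_rate, length(periodic_train(5, 100)$spike_times) / 100)
  expect_equal(m$isi_cv, 0, tolerance = 1e-9)
  expect_equal(m$frac_time_long_isi, 0)

  # spikes at 0 and 10 s in a 10 s session: the whole session is one long ISI
  m2 <- basic_metrics(c(0, 10), total_time = 10)
  expect_equal(m2$frac_time_long_isi, 1.0)

  # 100 s with a single 4 s gap, all other ISIs < 2 s
  st <- c(seq(0, 48, by = 1), seq(52, 100, by = 1))
  m3 <- basic_metrics(st, total_time = 100)
  expect_equal(m3$frac_time_long_isi, 0.04)

  # < 2 spikes: explicit missing values
  m4 <- basic_metrics(c(1), total_time = 10)
  expect_true(is.na(m4$mean_rate) && is.na(m4$isi_cv))
})

test_that("frac_time_long_isi is non-increasing in the threshold", {
  g <- gen_spikes(empty_trials(), 2, 1, seed = 8, duration = 400)
  th <- c(0.5, 1, 2, 4, 8)
  fr <- vapply(th, function(x)
    basic_metrics(g$spikes, 400, isi_threshold = x)$frac_time_long_isi,
    numeric(1))
  expect_true(all(diff(fr) <= 1e-12))
})

test_that("metrics are invariant to a global time shift", {
  g <- gen_spikes(empty_trials(), 5, 4, seed = 9, duration = 300)
  st <- g$spikes$spike_times
  m1 <- basic_metrics(st, 300)
  m2 <- basic_metrics(st + 123.456, 300)
  expect_equal(m1$isi_cv, m2$isi_cv)
  expect_equal(m1$frac_time_long_isi, m2$frac_time_long_isi)
  expect_equal(postspike_suppression(st), postspike_suppression(st + 123.456))
})

test_that("state restriction limits ISIs and time to the intervals", {
  # 5 Hz inside [0,100), silent in [100,200), 5 Hz in [200,300)
  st <- c(seq(0.2, 99.8, by = 0.2), seq(200.2, 299.8, by = 0.2))
  iv <- rbind(c(0, 100), c(200, 300))
  m <- basic_metrics(st, total_time = 300, state_intervals = iv)
  expect_equal(m$mean_rate, length(st) / 200)
  expect_equal(m$isi_cv, 0, tolerance = 1e-9)  # the 100 s gap is excluded
  expect_equal(m$frac_time_long_isi, 0)
})

test_that("postspike suppression finds the refractory period", {
  # Poisson with no refractoriness: flat autocorrelogram, suppression <= 3 ms
  g <- gen_spikes(empty_trials(), 5, 1, seed = 10, duration = 2000)
  expect_lte(postspike_suppression(g$spikes), 3)

  # absolute refractory period of 50 ms then Poisson
  set.seed(11)
  isi <- 0.050 + rexp(20000, 10)
  ref <- spike_train("r", cumsum(isi))
  pss <- postspike_suppression(ref)
  expect_gte(pss, 48)
  expect_lte(pss, 54)

  # two spikes 1 s apart: empty autocorrelogram within 200 ms
  expect_true(is.na(postspike_suppression(c(0, 1))))
})

test_that("waveform metrics match analytic shapes", {
  sr <- 30000
  tt <- seq(0, 2e-3 - 1 / sr, by = 1 / sr)
  sigma <- 0.15e-3
  w <- unit_waveform(rbind(-80 * exp(-(tt - 0.6e-3)^2 / (2 * sigma^2))), sr)
  m <- waveform_metrics(w)
  expect_lt(abs(m$peak_width - 2.355 * sigma * 1000), 1000 / sr)

  # trough at 0.6 ms, positive max at 1.4 ms: peak-to-valley = 0.8 ms
  w2 <- unit_waveform(rbind(-80 * exp(-(tt - 0.6e-3)^2 / (2 * sigma^2)) +
                              30 * exp(-(tt - 1.4e-3)^2 / (2 * (0.1e-3)^2))),
                      sr)
  m2 <- waveform_metrics(w2)
  expect_lt(abs(m2$peak_to_valley - 0.8), 2 * 1000 / sr)

  expect_error(waveform_metrics(unit_waveform(rbind(abs(sin(tt * 1000))), sr)),
               "not a spike waveform")
})

test_that("the CIN enrichment filter applies the default box", {
  good <- list(mean_rate = 5, isi_cv = 0.9, postspike_suppression = 60,
               peak_width = 0.4)
  expect_true(cin_enrichment_filter(good)$pass)

  sporadic <- modifyList(good, list(mean_rate = 0.5))
  f1 <- cin_enrichment_filter(sporadic)
  expect_false(f1$pass)
  expect_match(f1$reason, "rate_low")

  fast <- list(mean_rate = 25, isi_cv = 1.1, postspike_suppression = 4,
               peak_width = 0.2)
  f2 <- cin_enrichment_filter(fast)
  expect_false(f2$pass)
  expect_match(f2$reason, "suppression")

  f3 <- cin_enrichment_filter(modifyList(good, list(isi_cv = NA)))
  expect_false(f3$pass)
  expect_match(f3$reason, "missing")
})

test_that("session_unit_metrics restricts CV to SWS when epochs exist", {
  tr <- mk_trials(10)
  dur <- 200
  g <- gen_spikes(tr, 5, 4, seed = 12, duration = dur)
  s <- session("m", dur, tr, list(g$spikes))
  out_all <- session_unit_metrics(s)
  expect_equal(out_all$state_restriction, "all")
  out_sws <- session_unit_metrics(s, sws_epochs = data.frame(start = 0,
                                                             end = 100))
  expect_equal(out_sws$state_restriction, "sws")
  expect_true(is.finite(out_sws$isi_cv))
})
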