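#' Evoked- versus null-latency statistics per stimulation condition
#'
#' For each pulse condition, the evoked latency is the time from each
#' pulse onset to the first subsequent spike. The null latency is the
#' same computation at `n_null` uniformly random times in the session.
#' A one-sided Wilcoxon rank-sum test (evoked shorter than null) gives
#' the condition's latency p-value, and reliability is the fraction of
#' pulses with a spike within the reliability window (15 ms).
#'
#' @param spikes A [spike_train()].
#' @param laser A [laser_table()].
#' @param duration Session duration, s (null-time placement range).
#' @param n_null Null draws per condition; default matches the
#'   condition's pulse count.
#' @param reliability_window Reliability window, s (default 0.015).
#' @param seed Integer seed.
#' @return data.frame, one row per condition: `condition`, `n_pulses`,
#'   `latency_p`, `reliability`, `median_evoked`, `median_null`,
#'   `tested` (FALSE when the condition has no pulses).
#' @export
evoked_latency_stats <- function(spikes, laser, duration, n_null = NULL,
                                 reliability_window = 0.015, seed = 1) {
  st <- spikes$spike_times
  first_latency <- function(times) {
    idx <- findInterval(times, st) + 1L
    lat <- rep(Inf, length(times))
    ok <- idx <= length(st)
    lat[ok] <- st[idx[ok]] - times[ok]
    lat
  }
  conds <- sort(unique(laser$condition))
  with_seed(seed, {
    rows <- lapply(conds, function(cid) {
      pt <- laser$pulse_time_s[laser$condition == cid]
      if (length(pt) == 0) {
        return(data.frame(condition = cid, n_pulses = 0L,
                          latency_p = NA_real_, reliability = NA_real_,
                          median_evoked = NA_real_, median_null = NA_real_,
                          tested = FALSE))
      }
      ev <- first_latency(pt)
      nn <- if (is.null(n_null)) length(pt) else n_null
      nul <- first_latency(runif(nn, 0, duration))
      ev_f <- ev[is.finite(ev)]; nul_f <- nul[is.finite(nul)]
      p <- if (length(ev_f) == 0) 1 else if (length(nul_f) == 0) 1 else
        suppressWarnings(
          wilcox.test(ev_f, nul_f, alternative = "less")$p.value)
      data.frame(condition = cid, n_pulses = length(pt), latency_p = p,
                 reliability = mean(ev <= reliability_window),
                 median_evoked = median(ev_f),
                 median_null = median(nul_f), tested = TRUE)
    })
    do.call(rbind, rows)
  })
}

#' Optogenetic-tagging classification of one unit
#'
#' A unit is tagged as light-responsive (ChAT+/opsin-expressing) when
#' (a) in at least one stimulation condition its evoked latency is
#' significantly shorter than the null latency (one-sided rank-sum,
#' p < 0.01) *and* it fires within 15 ms of laser onset on at least 25%
#' of pulses, and (b) the mean waveform of spikes occurring within
#' 10 ms of laser onset has Pearson correlation > 0.9 with the mean
#' spontaneous (pre-stimulus) waveform, guarding against evoked spikes
#' contributed by a different, mis-sorted neuron.
#'
#' @param spikes A [spike_train()] with per-spike waveform snippets
#'   (`spike_waveforms`).
#' @param laser A [laser_table()].
#' @param duration Session duration, s.
#' @param n_null Null draws per condition (default matched).
#' @param alpha Latency-test level (default 0.01).
#' @param reliability_min Minimum reliability (default 0.25).
#' @param reliability_window Reliability window, s (default 0.015).
#' @param waveform_window Evoked-waveform window, s (default 0.010).
#' @param waveform_r_min Waveform correlation criterion (default 0.9).
#' @param seed Integer seed.
#' @return A `tagging_result` list: `unit_id`, `conditions` (the
#'   [evoked_latency_stats()] table), `waveform_r`, `tagged`, `reason`.
#' @export
classify_tagged <- function(spikes, laser, duration, n_null = NULL,
                            alpha = 0.01, reliability_min = 0.25,
                            reliability_window = 0.015,
                            waveform_window = 0.010, waveform_r_min = 0.9,
                            seed = 1) {
  stats <- evoked_latency_stats(spikes, laser, duration, n_null,
                                reliability_window, seed)
  ok_cond <- stats$tested & !is.na(stats$latency_p) &
    stats$latency_p < alpha & stats$reliability >= reliability_min
  latency_ok <- any(ok_cond)

  wr <- NA_real_
  reason <- NULL
  if (is.null(spikes$spike_waveforms)) {
    reason <- "no per-spike waveforms available"
  } else {
    st <- spikes$spike_times
    prev_pulse <- findInterval(st, laser$pulse_time_s)
    dt_pulse <- rep(Inf, length(st))
    has_prev <- prev_pulse > 0
    dt_pulse[has_prev] <- st[has_prev] - laser$pulse_time_s[prev_pulse[has_prev]]
    evoked_sel <- dt_pulse < waveform_window
    spont_sel <- dt_pulse > 0.1 | !has_prev
    if (!any(evoked_sel)) {
      reason <- "no evoked waveform"
    } else if (!any(spont_sel)) {
      reason <- "no spontaneous waveform"
    } else {
      mean_ev <- colMeans(spikes$spike_waveforms[evoked_sel, , drop = FALSE])
      mean_sp <- colMeans(spikes$spike_waveforms[spont_sel, , drop = FALSE])
      wr <- cor(mean_ev, mean_sp)
    }
  }
  tagged <- latency_ok && !is.na(wr) && wr > waveform_r_min
  if (is.null(reason)) {
    reason <- if (tagged) "tagged" else if (!latency_ok)
      "no condition with significant short-latency, reliable response" else
        "waveform correlation below criterion"
  }
  structure(list(unit_id = spikes$unit_id, conditions = stats,
                 waveform_r = wr, tagged = tagged, reason = reason),
            class = "tagging_result")
}

#' @export
print.tagging_result <- function(x, ...) {
  cat("<tagging_result> ", x$unit_id, ": ",
      if (x$tagged) "TAGGED" else "not tagged", " (", x$reason,
      "); waveform r = ", format(x$waveform_r, digits = 3), "\n", sep = "")
  invisible(x)
}

#' Duplicate-unit screen for simultaneously recorded tagged units
#'
#' The same neuron recorded on two tetrodes produces near-coincident
#' spikes. For every pair of tagged units this computes the zero-lag
#' coincidence fraction -- spikes of the sparser train with a partner
#' spike within the coincidence window, divided by the sparser train's
#' count -- and flags pairs above threshold, recommending the unit with
#' the lower-amplitude mean waveform for removal.
#'
#' @param units List of [spike_train()] objects (the tagged units).
#' @param window Coincidence half-width, s (default 0.001).
#' @param threshold Flagging threshold on the coincidence fraction
#'   (default 0.5).
#' @return data.frame of flagged pairs: `unit_a`, `unit_b`,
#'   `coincidence`, `drop` (0 rows when fewer than 2 units or no pair
#'   crosses threshold).
#' @export
duplicate_check <- function(units, window = 0.001, threshold = 0.5) {
  empty <- data.frame(unit_a = character(0), unit_b = character(0),
                      coincidence = numeric(0), drop = character(0))
  if (length(units) < 2) return(empty)
  amp <- vapply(units, function(u)
    if (is.null(u$waveform)) NA_real_ else
      max(apply(u$waveform$samples, 1L, function(ch) diff(range(ch)))),
    numeric(1))
  rows <- list()
  for (i in seq_len(length(units) - 1)) for (j in (i + 1):length(units)) {
    a <- units[[i]]$spike_times; b <- units[[j]]$spike_times
    if (length(a) <= length(b)) { sp <- a; dn <- b } else { sp <- b; dn <- a }
    if (length(sp) == 0) next
    hit <- interval_counts(dn, sp - window, sp + window) > 0
    frac <- mean(hit)
    if (frac > threshold) {
      drop_idx <- if (!is.na(amp[i]) && !is.na(amp[j]) && amp[i] < amp[j])
        i else j
      rows[[length(rows) + 1]] <-
        data.frame(unit_a = units[[i]]$unit_id, unit_b = units[[j]]$unit_id,
                   coincidence = frac, drop = units[[drop_idx]]$unit_id)
    }
  }
  if (length(rows) == 0) empty else do.call(rbind, rows)
}
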