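#' Basic tonic-firing metrics
#'
#' Mean rate, interspike-interval coefficient of variation, and the
#' proportion of analysed time spent inside long ISIs (> 2 s by
#' default) -- the "proportion of time not spiking" signature that
#' separates tonically active CINs from sporadically firing projection
#' neurons. With `state_intervals` (e.g. detected SWS epochs) the
#' analysis is restricted to those intervals: only ISIs fully inside an
#' interval contribute, and time is the summed interval length.
#'
#' @param spikes A [spike_train()] or sorted spike-time vector.
#' @param total_time Analysed time, s, when no state restriction is
#'   given (typically the session duration).
#' @param state_intervals Optional two-column `[start, end)` matrix.
#' @param isi_threshold Long-ISI cut, s (default 2).
#' @return List `mean_rate` (Hz), `isi_cv`, `frac_time_long_isi`; all
#'   `NA` when fewer than 2 spikes are available.
#' @export
basic_metrics <- function(spikes, total_time, state_intervals = NULL,
                          isi_threshold = 2) {
  st <- if (inherits(spikes, "spike_train")) spikes$spike_times else
    as.numeric(spikes)
  if (!is.null(state_intervals)) {
    iv <- matrix(as.numeric(as.matrix(state_intervals)), ncol = 2)
    total_time <- sum(pmax(0, iv[, 2] - iv[, 1]))
    which_iv <- function(x) {
      out <- rep(NA_integer_, length(x))
      for (i in seq_len(nrow(iv))) {
        out[x >= iv[i, 1] & x < iv[i, 2]] <- i
      }
      out
    }
    memb <- which_iv(st)
    inside <- !is.na(memb)
    n_spk <- sum(inside)
    isis <- numeric(0)
    if (n_spk >= 2) {
      d <- diff(st)
      same <- !is.na(memb[-length(memb)]) & !is.na(memb[-1]) &
        memb[-length(memb)] == memb[-1]
      isis <- d[same]
    }
  } else {
    n_spk <- length(st)
    isis <- diff(st)
  }
  if (n_spk < 2 || total_time <= 0) {
    return(list(mean_rate = NA_real_, isi_cv = NA_real_,
                frac_time_long_isi = NA_real_))
  }
  list(mean_rate = n_spk / total_time,
       isi_cv = if (length(isis) >= 2) sd(isis) / mean(isis) else NA_real_,
       frac_time_long_isi = sum(isis[isis > isi_threshold]) / total_time)
}

#' Postspike suppression from the autocorrelogram
#'
#' Builds the spike-train autocorrelogram in 1 ms bins over lags up to
#' `max_lag` and returns the first lag whose count exceeds half the
#' mean count across all lags -- long for CINs, whose slow
#' afterhyperpolarisation suppresses firing for tens of milliseconds.
#'
#' @param spikes A [spike_train()] or sorted spike-time vector.
#' @param max_lag Maximum lag, s (default 0.200).
#' @param bin Lag bin width, s (default 0.001).
#' @return Suppression duration in ms (centre of the first
#'   half-mean-exceeding bin), or `NA` when the autocorrelogram is
#'   empty.
#' @export
postspike_suppression <- function(spikes, max_lag = 0.200, bin = 0.001) {
  st <- if (inherits(spikes, "spike_train")) spikes$spike_times else
    as.numeric(spikes)
  n <- length(st)
  if (n < 2) return(NA_real_)
  n_bins <- round(max_lag / bin)
  counts <- numeric(n_bins)
  j <- 1L
  for (i in seq_len(n - 1)) {
    k <- i + 1L
    while (k <= n && st[k] - st[i] < max_lag) {
      lag <- st[k] - st[i]
      b <- floor(lag / bin) + 1L
      if (b >= 1L && b <= n_bins) counts[b] <- counts[b] + 1
      k <- k + 1L
    }
  }
  if (sum(counts) == 0) return(NA_real_)
  half <- mean(counts) / 2
  idx <- which(counts > half)[1]
  if (is.na(idx)) return(NA_real_)
  (idx - 0.5) * bin * 1000
}

#' Spike-waveform shape metrics
#'
#' On the largest-amplitude channel: `peak_width` is the full width at
#' half maximum of the deepest negative deflection (linear interpolation
#' between samples), and `peak_to_valley` the time from that trough to
#' the most positive voltage after it within the 2 ms window.
#'
#' @param waveform A [unit_waveform()].
#' @return List `peak_width` (ms), `peak_to_valley` (ms).
#' @export
waveform_metrics <- function(waveform) {
  stopifnot(inherits(waveform, "unit_waveform"))
  ch <- which.max(apply(abs(waveform$samples), 1L, max))
  w <- waveform$samples[ch, ]
  if (min(w) >= 0) stop("not a spike waveform: no negative deflection",
                        call. = FALSE)
  sr <- waveform$sample_rate
  ti <- which.min(w)
  depth <- w[ti]
  half <- depth / 2
  # walk out from the trough to the half-depth crossings
  li <- ti
  while (li > 1 && w[li - 1] <= half) li <- li - 1
  t_left <- if (li == 1) li else
    li - 1 + (half - w[li - 1]) / (w[li] - w[li - 1])
  ri <- ti
  while (ri < length(w) && w[ri + 1] <= half) ri <- ri + 1
  t_right <- if (ri == length(w)) ri else
    ri + (half - w[ri]) / (w[ri + 1] - w[ri])
  peak_width <- (t_right - t_left) / sr * 1000
  after <- w[ti:length(w)]
  pv <- (which.max(after) - 1) / sr * 1000
  list(peak_width = peak_width, peak_to_valley = pv)
}

#' CIN-enrichment screen for untagged units
#'
#' A configurable box filter combining the metrics that jointly
#' characterise tagged CINs: firing rate within `rate_range`
#' (default 2--10 Hz), ISI CV at most `cv_max` (default 1.9), postspike
#' suppression at least `pss_min` ms (default 40) and peak width at
#' least `width_min` ms (default 0.3). An enrichment screen, not ground
#' truth.
#'
#' @param metrics List/row with `mean_rate`, `isi_cv`,
#'   `postspike_suppression` (ms), `peak_width` (ms).
#' @param rate_range,cv_max,pss_min,width_min Thresholds (all exposed
#'   via the `metrics` config section).
#' @return List `pass` (logical) and `reason` (character; "ok" when
#'   passing).
#' @export
cin_enrichment_filter <- function(metrics, rate_range = c(2, 10),
                                  cv_max = 1.9, pss_min = 40,
                                  width_min = 0.3) {
  need <- c("mean_rate", "isi_cv", "postspike_suppression", "peak_width")
  vals <- lapply(need, function(k) metrics[[k]])
  names(vals) <- need
  missing <- need[vapply(vals, function(v) is.null(v) || is.na(v), logical(1))]
  if (length(missing) > 0) {
    return(list(pass = FALSE,
                reason = paste("missing metric:",
                               paste(missing, collapse = ", "))))
  }
  checks <- c(
    rate_low = vals$mean_rate >= rate_range[1],
    rate_high = vals$mean_rate <= rate_range[2],
    cv = vals$isi_cv <= cv_max,
    suppression = vals$postspike_suppression >= pss_min,
    width = vals$peak_width >= width_min)
  if (all(checks)) list(pass = TRUE, reason = "ok") else
    list(pass = FALSE,
         reason = paste("failed:", paste(names(checks)[!checks],
                                         collapse = ", ")))
}

#' All unit metrics for one session
#'
#' Convenience wrapper computing [basic_metrics()] (CV restricted to
#' SWS epochs when provided, matching the convention of reporting CV
#' during slow-wave sleep), [postspike_suppression()],
#' [waveform_metrics()] and the [cin_enrichment_filter()] verdict for
#' every unit.
#'
#' @param s A `cin_session`.
#' @param sws_epochs Optional epochs data.frame from [detect_sws()].
#' @param cfg `metrics` config section (see [default_config()]).
#' @return data.frame, one row per unit.
#' @export
session_unit_metrics <- function(s, sws_epochs = NULL,
                                 cfg = default_config()$metrics) {
  rows <- lapply(s$units, function(u) {
    bm <- basic_metrics(u, s$duration, isi_threshold = cfg$isi_threshold)
    state <- "all"
    cv <- bm$isi_cv
    if (!is.null(sws_epochs) && nrow(sws_epochs) > 0) {
      bm_s <- basic_metrics(u, s$duration, state_intervals = sws_epochs,
                            isi_threshold = cfg$isi_threshold)
      if (!is.na(bm_s$isi_cv)) { cv <- bm_s$isi_cv; state <- "sws" }
    }
    pss <- postspike_suppression(u, max_lag = cfg$acg_max_lag)
    wm <- if (!is.null(u$waveform)) waveform_metrics(u$waveform) else
      list(peak_width = NA_real_, peak_to_valley = NA_real_)
    m <- list(mean_rate = bm$mean_rate, isi_cv = cv,
              frac_time_long_isi = bm$frac_time_long_isi,
              postspike_suppression = pss,
              peak_width = wm$peak_width, peak_to_valley = wm$peak_to_valley)
    filt <- cin_enrichment_filter(m, cfg$rate_range, cfg$cv_max,
                                  cfg$pss_min, cfg$width_min)
    data.frame(unit_id = u$unit_id, mean_rate = m$mean_rate,
               isi_cv = m$isi_cv, frac_time_long_isi = m$frac_time_long_isi,
               postspike_suppression = m$postspike_suppression,
               peak_width = m$peak_width, peak_to_valley = m$peak_to_valley,
               state_restriction = state, cin_like = filt$pass,
               filter_reason = filt$reason)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
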