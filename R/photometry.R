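#' Demultiplex a time-division-multiplexed photometry trace
#'
#' Splits the single detector trace into the 470 nm (dopamine) and
#' 405 nm (control) channels according to the per-frame LED schedule.
#' Each frame's channel value is the mean of the detector samples in the
#' *interior* of the LED on-period -- the first and last 0.5 ms of the
#' 4 ms on-window are discarded as switching transitions. Each channel
#' is then linearly interpolated onto a uniform grid at the frame rate.
#'
#' @param raw A [photometry_raw()].
#' @return List with `sig470` and `sig405`, both [continuous_signal()]
#'   at the frame rate (100 Hz for 10 ms frames).
#' @export
demultiplex <- function(raw) {
  stopifnot(inherits(raw, "photometry_raw"))
  fs <- raw$sample_rate
  spf <- as.integer(fs * raw$frame_ms / 1000)
  on_n <- as.integer(fs * raw$on_ms / 1000)
  trim <- as.integer(fs * 0.0005)              # 0.5 ms transition trim
  lo <- trim + 1L
  hi <- on_n - trim
  if (hi < lo) stop("on-period too short for transition trimming", call. = FALSE)
  n_frames <- length(raw$schedule)
  m <- matrix(raw$detector[seq_len(n_frames * spf)], nrow = spf)
  vals <- colMeans(m[lo:hi, , drop = FALSE])
  frame_rate <- 1000 / raw$frame_ms
  tt <- raw$t0 + (seq_len(n_frames) - 1) / frame_rate  # frame start times
  tc <- tt + (raw$on_ms / 1000) / 2                    # on-window centres
  grid <- raw$t0 + (seq_len(n_frames) - 1) / frame_rate
  chan <- function(label) {
    sel <- raw$schedule == label
    if (!any(sel)) stop("schedule contains no ", label, " frames", call. = FALSE)
    approx(tc[sel], vals[sel], xout = grid, rule = 2, ties = "ordered")$y
  }
  list(sig470 = continuous_signal(chan("470"), frame_rate, raw$t0),
       sig405 = continuous_signal(chan("405"), frame_rate, raw$t0))
}

#' Control-channel-corrected dF/F
#'
#' Rescales the 405 nm control channel onto the 470 nm channel by least
#' squares (`405_fit = a * 405 + b`, or slope-only when
#' `fit = "slope-only"`), forms
#' `dF/F = (470 - 405_fit) / 405_fit`, then resamples to 250 Hz,
#' applies a 5-point median filter, and z-scores over the session.
#' Because bleaching and motion are shared between the channels, the
#' fitted control removes them from the fractional signal.
#'
#' @param sig470,sig405 [continuous_signal()] channels on the same grid.
#' @param target_rate Output rate, Hz (default 250).
#' @param median_k Median-filter width, samples (odd; default 5).
#' @param fit "affine" (slope + intercept) or "slope-only".
#' @return A `dff_signal` list: `samples` (z-scored dF/F),
#'   `samples_raw` (pre-z-score dF/F after filtering), `sample_rate`,
#'   `fit_params` (slope, intercept), `t0`.
#' @export
compute_dff <- function(sig470, sig405, target_rate = 250, median_k = 5,
                        fit = c("affine", "slope-only")) {
  fit <- match.arg(fit)
  x <- sig405$samples; y <- sig470$samples
  if (length(x) != length(y)) stop("channels must share a grid", call. = FALSE)
  if (sd(x) == 0) stop("control channel constant: cannot fit 405 -> 470",
                       call. = FALSE)
  if (fit == "affine") {
    co <- coef(lm(y ~ x))
    b <- co[1]; a <- co[2]
  } else {
    a <- sum(x * y) / sum(x * x); b <- 0
  }
  fit405 <- a * x + b
  if (any(fit405 <= 0)) {
    stop("fitted control channel non-positive; check inputs", call. = FALSE)
  }
  dff <- (y - fit405) / fit405

  t_in <- sig470$t0 + (seq_along(dff) - 1) / sig470$sample_rate
  n_out <- floor((t_in[length(t_in)] - sig470$t0) * target_rate) + 1L
  t_out <- sig470$t0 + (seq_len(n_out) - 1) / target_rate
  res <- approx(t_in, dff, xout = t_out, rule = 2, ties = "ordered")$y
  if (median_k >= 3 && length(res) > median_k) {
    res <- runmed(res, median_k, endrule = "median")
  }
  z <- (res - mean(res)) / max(sd(res), 1e-300)
  structure(list(samples = z, samples_raw = res, sample_rate = target_rate,
                 fit_params = c(slope = unname(a), intercept = unname(b)),
                 t0 = sig470$t0),
            class = "dff_signal")
}

#' Event-aligned dF/F matrix
#'
#' Extracts per-trial windows of the dF/F signal around event times and
#' returns the trial x time matrix with group means and SEM. Trials
#' whose window is truncated by the recording edge are dropped and
#' counted.
#'
#' @param dff A `dff_signal` from [compute_dff()].
#' @param event_times Event times, s.
#' @param window `c(t_start, t_end)` relative to the event, s.
#' @param groups Optional per-trial group labels.
#' @param zscored Use the z-scored signal (default) or the pre-z-score
#'   dF/F (`FALSE`; used for amplitude recovery).
#' @return List with `time` (relative sample times), `matrix`
#'   (trials x time), `group_means`, `group_sem` (lists by group, absent
#'   groups omitted), `n_dropped`.
#' @export
align_dff <- function(dff, event_times, window, groups = NULL,
                      zscored = TRUE) {
  sig <- if (zscored) dff$samples else dff$samples_raw
  fs <- dff$sample_rate
  off <- seq(ceiling(window[1] * fs), floor(window[2] * fs))
  idx0 <- round((event_times - dff$t0) * fs) + 1L
  ok <- idx0 + off[1] >= 1L & idx0 + off[length(off)] <= length(sig)
  n_dropped <- sum(!ok)
  idx0 <- idx0[ok]
  if (!is.null(groups)) groups <- groups[ok]
  m <- t(vapply(idx0, function(i) sig[i + off], numeric(length(off))))
  out <- list(time = off / fs, matrix = m, n_dropped = n_dropped)
  if (!is.null(groups)) {
    gl <- unique(groups[!is.na(groups)])
    out$group_means <- lapply(stats::setNames(gl, gl), function(g)
      colMeans(m[groups == g & !is.na(groups), , drop = FALSE]))
    out$group_sem <- lapply(stats::setNames(gl, gl), function(g) {
      sub <- m[groups == g & !is.na(groups), , drop = FALSE]
      apply(sub, 2L, sd) / sqrt(nrow(sub))
    })
  }
  out
}

#' Shuffle-test significance for event-aligned dF/F
#'
#' The same pseudo-event logic as [shuffle_significance()], applied to
#' the mean aligned dF/F per time sample instead of binned spike counts:
#' `n_shuffles` pseudo-event sets (each the real trial count, placed
#' uniformly wherever the window fits) yield a null distribution of the
#' mean trace, against which each time sample is flagged up or down.
#'
#' @param dff A `dff_signal`.
#' @param event_times Real event times, s.
#' @param window `c(t_start, t_end)` relative to the event, s.
#' @param n_shuffles Number of pseudo-event sets (default 10000).
#' @param alpha Significance level (default 0.005).
#' @param correction "bonferroni", "pointwise" or "maxstat".
#' @param tail "gaussian" or "empirical" null tail (bonferroni mode).
#' @param seed Integer seed.
#' @param zscored Analyse the z-scored (default) or raw dF/F.
#' @return A `significance_map` (see [shuffle_significance()]), with
#'   `bin_centers` holding the relative sample times.
#' @export
dff_significance <- function(dff, event_times, window, n_shuffles = 10000,
                             alpha = 0.005, correction = "bonferroni",
                             tail = "gaussian", seed = 1, zscored = TRUE) {
  sig <- if (zscored) dff$samples else dff$samples_raw
  fs <- dff$sample_rate
  off <- seq(ceiling(window[1] * fs), floor(window[2] * fs))
  idx0 <- round((event_times - dff$t0) * fs) + 1L
  ok <- idx0 + off[1] >= 1L & idx0 + off[length(off)] <= length(sig)
  idx0 <- idx0[ok]
  if (length(idx0) == 0) stop("no events with a complete window", call. = FALSE)
  real <- colMeans(t(vapply(idx0, function(i) sig[i + off],
                            numeric(length(off)))))
  lo_i <- 1L - off[1]
  hi_i <- length(sig) - off[length(off)]
  if (hi_i <= lo_i) stop("signal too short to place shuffled windows",
                         call. = FALSE)
  null_mat <- with_seed(seed, {
    centers <- matrix(sample(seq(lo_i, hi_i), n_shuffles * length(idx0),
                             replace = TRUE), nrow = n_shuffles)
    shuffle_null_means(sig, centers, off)
  })
  flag_significance(real, null_mat, alpha, correction, tail,
                    bin_centers = off / fs, n_shuffles = n_shuffles,
                    seed = seed)
}
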