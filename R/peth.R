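#' Peri-event time histogram with overlapping bins
#'
#' Counts spikes per trial in 10 ms bins sliding in 5 ms steps (by
#' default) across a window around each event. Bins are indexed by
#' their centres `c_i = t_start + bin_width/2 + (i-1) * step` and count
#' spikes in the half-open interval `[event + c - bin_width/2,
#' event + c + bin_width/2)`; a 3 s window at 10 ms / 5 ms therefore
#' yields `floor((3 - 0.01)/0.005) + 1 = 599` bins. Events whose window
#' is truncated by the session edge are dropped and counted.
#'
#' @param spikes A [spike_train()] or a sorted numeric vector of spike
#'   times.
#' @param event_times Alignment event times, s.
#' @param window `c(t_start, t_end)` relative to the event, s.
#' @param bin_width Bin width, s (default 0.010).
#' @param step Bin step, s (default 0.005).
#' @param groups Optional per-trial labels (e.g. rewarded/unrewarded,
#'   contra/ipsi, value tercile), carried through to grouped analyses.
#' @param duration Session duration, s; events needing samples outside
#'   `[0, duration]` are dropped. Default: no edge dropping beyond 0.
#' @return A `peth_result`: `bin_centers`, `trial_counts`
#'   (trials x bins), `mean_rate` (Hz per bin), `group_labels`,
#'   `n_dropped`, plus the binning parameters.
#' @export
compute_peth <- function(spikes, event_times, window, bin_width = 0.010,
                         step = 0.005, groups = NULL, duration = Inf) {
  st <- if (inherits(spikes, "spike_train")) spikes$spike_times else
    as.numeric(spikes)
  if (length(event_times) < 1) stop("need at least one event", call. = FALSE)
  if (any(!is.finite(event_times))) {
    stop("event times must be finite", call. = FALSE)
  }
  span <- window[2] - window[1]
  if (span < bin_width) stop("window must cover at least one bin", call. = FALSE)
  n_bins <- floor((span - bin_width) / step + 1e-9) + 1L
  centers <- window[1] + bin_width / 2 + (seq_len(n_bins) - 1) * step

  ok <- event_times + window[1] >= 0 & event_times + window[2] <= duration
  n_dropped <- sum(!ok)
  ev <- event_times[ok]
  if (!is.null(groups)) groups <- groups[ok]
  if (length(ev) == 0) stop("no events with a complete window", call. = FALSE)

  # count in event-relative time so bin-edge semantics do not depend on
  # the absolute clock value of the event
  left <- centers - bin_width / 2
  counts <- t(vapply(ev, function(e) {
    rel <- st[st >= e + window[1] - bin_width & st < e + window[2] + bin_width] - e
    interval_counts(rel, left, left + bin_width)
  }, numeric(n_bins)))
  structure(list(bin_centers = centers,
                 trial_counts = counts,
                 mean_rate = colMeans(counts) / bin_width,
                 group_labels = groups,
                 window = window, bin_width = bin_width, step = step,
                 event_times = ev, n_dropped = n_dropped),
            class = "peth_result")
}

#' @export
print.peth_result <- function(x, ...) {
  cat("<peth_result> ", nrow(x$trial_counts), " trials x ",
      length(x$bin_centers), " bins; window [", x$window[1], ", ",
      x$window[2], ") s; bin ", x$bin_width * 1000, " ms / step ",
      x$step * 1000, " ms\n", sep = "")
  invisible(x)
}

#' Shuffle-test significance map for a PETH
#'
#' Compares each bin's mean rate against a null distribution built from
#' `n_shuffles` pseudo-event sets: each set has the same trial count as
#' the real alignment, with events placed uniformly anywhere in the
#' session where the full window fits (no exclusion of real-event
#' neighbourhoods unless `edge_margin` is set). Correction modes:
#' \describe{
#'   \item{bonferroni}{two-tailed, per-tail probability
#'     `alpha / (2 * n_bins)`. With `tail = "gaussian"` (default) the
#'     per-bin null is summarised by its shuffle mean and SD and the
#'     threshold taken from the normal quantile, so the corrected tail
#'     does not need to be resolved by the shuffle count; with
#'     `tail = "empirical"` raw shuffle quantiles are used and an error
#'     is raised when `n_shuffles` cannot resolve the corrected tail.}
#'   \item{pointwise}{raw shuffle quantiles at `alpha` per tail, no
#'     correction across bins.}
#'   \item{maxstat}{null distribution of the across-bin extremum of the
#'     standardised rate, `alpha/2` per tail.}
#' }
#'
#' @param spikes A [spike_train()] or sorted spike-time vector.
#' @param peth A `peth_result` from [compute_peth()].
#' @param duration Session duration, s (pseudo-event placement range).
#' @param n_shuffles Pseudo-event sets (default 10000).
#' @param alpha Significance level (default 0.005).
#' @param correction "bonferroni", "pointwise" or "maxstat".
#' @param tail "gaussian" or "empirical" (bonferroni mode only).
#' @param edge_margin Extra margin, s, excluded at both session edges.
#' @param seed Integer seed; flags are reproducible given the seed.
#' @return A `significance_map`: logical `up`/`down` per bin (never both
#'   for one bin), `null_mean`, `null_sd`, thresholds, and the echoed
#'   test parameters.
#' @export
shuffle_significance <- function(spikes, peth, duration, n_shuffles = 10000,
                                 alpha = 0.005,
                                 correction = c("bonferroni", "pointwise",
                                                "maxstat"),
                                 tail = c("gaussian", "empirical"),
                                 edge_margin = 0, seed = 1) {
  correction <- match.arg(correction)
  tail <- match.arg(tail)
  st <- if (inherits(spikes, "spike_train")) spikes$spike_times else
    as.numeric(spikes)
  step <- peth$step; bw <- peth$bin_width
  n_ev <- nrow(peth$trial_counts)
  # grid the session at the bin step; Q[p] = spikes in [p*step, p*step + bw)
  edges <- seq(0, duration - bw, by = step)
  Q <- sliding_counts(st, edges, bw)
  # pseudo-event grid positions: event at e = p*step must keep the whole
  # window inside [edge_margin, duration - edge_margin]
  left0 <- peth$bin_centers[1] - bw / 2
  offs <- as.integer(round((peth$bin_centers - bw / 2) / step))
  p_lo <- ceiling((edge_margin - left0) / step)
  p_hi <- floor((duration - edge_margin - (peth$window[2])) / step)
  # clamp so every offset indexes inside Q
  p_lo <- max(p_lo, -min(offs))
  p_hi <- min(p_hi, length(Q) - 1L - max(offs))
  if (p_hi <= p_lo) stop("session too short to place shuffled windows",
                         call. = FALSE)
  null_mat <- with_seed(seed, {
    centers <- matrix(sample(seq(p_lo, p_hi), n_shuffles * n_ev,
                             replace = TRUE) + 1L, nrow = n_shuffles)
    shuffle_null_means(Q, centers, offs) / bw   # counts -> Hz
  })
  flag_significance(peth$mean_rate, null_mat, alpha, correction, tail,
                    bin_centers = peth$bin_centers, n_shuffles = n_shuffles,
                    seed = seed, bin_width = bw)
}

# shared flagging logic for spike PETHs and dF/F traces
flag_significance <- function(real, null_mat, alpha, correction, tail,
                              bin_centers, n_shuffles, seed,
                              bin_width = NULL) {
  n_bins <- length(real)
  mu <- colMeans(null_mat)
  sdv <- apply(null_mat, 2L, sd)
  if (correction == "bonferroni") {
    a_tail <- alpha / (2 * n_bins)
    if (tail == "gaussian") {
      # The pseudo-event null is translation invariant, so all bins share
      # one null marginal: pool moments across the whole null matrix and
      # refine the Gaussian quantile with a Cornish-Fisher skewness term
      # (count-based nulls are right-skewed; a plain normal tail
      # under-covers the corrected level).
      pm <- mean(null_mat)
      ps <- sd(null_mat)
      g1 <- if (ps > 0) mean((null_mat - pm)^3) / ps^3 else 0
      zq <- qnorm(1 - a_tail)
      z_up <- zq + g1 / 6 * (zq^2 - 1)
      z_dn <- -zq + g1 / 6 * (zq^2 - 1)
      up_thr <- rep(pm + z_up * ps, n_bins)
      down_thr <- rep(pm + z_dn * ps, n_bins)
    } else {
      if (n_shuffles < 1 / a_tail) {
        stop("insufficient shuffles for requested alpha: need >= ",
             ceiling(1 / a_tail), " to resolve the Bonferroni tail ",
             "(use correction = 'pointwise' or tail = 'gaussian')",
             call. = FALSE)
      }
      up_thr <- apply(null_mat, 2L, quantile, probs = 1 - a_tail, names = FALSE)
      down_thr <- apply(null_mat, 2L, quantile, probs = a_tail, names = FALSE)
    }
  } else if (correction == "pointwise") {
    if (n_shuffles < 1 / alpha) {
      stop("insufficient shuffles for requested alpha", call. = FALSE)
    }
    up_thr <- apply(null_mat, 2L, quantile, probs = 1 - alpha, names = FALSE)
    down_thr <- apply(null_mat, 2L, quantile, probs = alpha, names = FALSE)
  } else { # maxstat
    sdv_safe <- pmax(sdv, 1e-300)
    zmat <- sweep(sweep(null_mat, 2L, mu), 2L, sdv_safe, "/")
    zmax <- apply(zmat, 1L, max)
    zmin <- apply(zmat, 1L, min)
    qhi <- quantile(zmax, 1 - alpha / 2, names = FALSE)
    qlo <- quantile(zmin, alpha / 2, names = FALSE)
    up_thr <- mu + qhi * sdv_safe
    down_thr <- mu + qlo * sdv_safe
  }
  structure(list(up = real > up_thr, down = real < down_thr,
                 real = real, null_mean = mu, null_sd = sdv,
                 up_threshold = up_thr, down_threshold = down_thr,
                 bin_centers = bin_centers,
                 bin_width = if (is.null(bin_width))
                   diff(bin_centers[1:2]) else bin_width,
                 alpha = alpha, n_shuffles = n_shuffles,
                 correction = correction, tail = tail, seed = seed),
            class = "significance_map")
}

#' @export
print.significance_map <- function(x, ...) {
  cat("<significance_map> ", length(x$up), " bins; ", sum(x$up), " up, ",
      sum(x$down), " down (alpha ", x$alpha, ", ", x$correction, ", ",
      x$n_shuffles, " shuffles)\n", sep = "")
  invisible(x)
}

#' Response onset from a significance map
#'
#' Finds the first bin flagged in the requested direction inside the
#' search window; the onset is that bin's centre, the offset the centre
#' of the last bin of the same contiguous flagged run, and the duration
#' `offset - onset + bin_width`. Units with no flagged bin are reported
#' as non-responsive (`onset = NA`).
#'
#' @param sig A `significance_map`.
#' @param direction "up" or "down".
#' @param search_window `c(lo, hi)` restriction on bin centres, s.
#' @return List `onset`, `offset`, `duration` (s; all `NA` when nothing
#'   is flagged), `direction`.
#' @export
onset_latency <- function(sig, direction = c("up", "down"),
                          search_window = range(sig$bin_centers)) {
  direction <- match.arg(direction)
  flags <- if (direction == "up") sig$up else sig$down
  inw <- sig$bin_centers >= search_window[1] &
    sig$bin_centers <= search_window[2]
  idx <- which(flags & inw)
  if (length(idx) == 0) {
    return(list(onset = NA_real_, offset = NA_real_, duration = NA_real_,
                direction = direction))
  }
  first <- idx[1]
  run_end <- first
  while (run_end + 1L <= length(flags) && flags[run_end + 1L] &&
         inw[run_end + 1L]) run_end <- run_end + 1L
  onset <- sig$bin_centers[first]
  offset <- sig$bin_centers[run_end]
  list(onset = onset, offset = offset,
       duration = offset - onset + sig$bin_width, direction = direction)
}

#' Contra/ipsi selectivity index
#'
#' `SI = (M_contra - M_ipsi) / (M_contra + M_ipsi)` where `M` is the
#' mean PETH rate over the response window for each choice-direction
#' group; SI lies in `[-1, 1]` for nonnegative rates.
#'
#' @param peth A grouped `peth_result` whose `group_labels` are
#'   "contra"/"ipsi".
#' @param response_window `c(lo, hi)` on bin centres, s.
#' @return Scalar SI (`NA` when both magnitudes are 0).
#' @export
selectivity_index <- function(peth, response_window) {
  g <- peth$group_labels
  if (is.null(g) || !all(c("contra", "ipsi") %in% g)) {
    stop("peth must be grouped by contra/ipsi", call. = FALSE)
  }
  bsel <- peth$bin_centers >= response_window[1] &
    peth$bin_centers <= response_window[2]
  m <- function(lbl) mean(peth$trial_counts[g == lbl, bsel, drop = FALSE]) /
    peth$bin_width
  mc <- m("contra"); mi <- m("ipsi")
  if (mc + mi == 0) return(NA_real_)
  (mc - mi) / (mc + mi)
}

# component-specific analysis windows (s) for the sensory-vs-motor ratio
sensorimotor_windows <- function(component) {
  switch(component,
         burst   = list(go = c(0, 0.120),     out = c(-0.400, 0.150)),
         pause   = list(go = c(0, 0.400),     out = c(-0.200, 0.200)),
         rebound = list(go = c(0.200, 0.500), out = c(0, 0.400)),
         stop("component must be burst, pause or rebound", call. = FALSE))
}

#' Sensory- versus movement-locked response classification
#'
#' Aligns a unit's firing on the Go cue and on Center Out, and compares
#' the response extremum in the component-specific windows: the ratio of
#' the movement-aligned to the cue-aligned extremum (maximum rate for
#' burst/rebound; baseline-minus-minimum for pause, baseline being the
#' mean rate 1--0.5 s before the event). A ratio greater than 1 labels
#' the response "motor", otherwise "sensory" (ties are sensory). Units
#' without a significant component of the requested type in the
#' cue-aligned window (shuffle test) are excluded.
#'
#' @param spikes A [spike_train()].
#' @param trials A [trial_table()].
#' @param component "burst", "pause" or "rebound".
#' @param duration Session duration, s.
#' @param n_shuffles,alpha,correction,tail,seed Passed to
#'   [shuffle_significance()] for the inclusion gate.
#' @param bin_width,step PETH binning, s.
#' @return List `ratio`, `label` ("sensory"/"motor"), `included`
#'   (FALSE with `ratio = NA` when the gate fails), `component`.
#' @export
sensory_motor_label <- function(spikes, trials, component, duration,
                                n_shuffles = 2000, alpha = 0.005,
                                correction = "pointwise", tail = "gaussian",
                                seed = 1, bin_width = 0.010, step = 0.005) {
  win <- sensorimotor_windows(component)
  full <- c(-1, 1)  # analysis window wide enough for baseline + components
  peth_go <- compute_peth(spikes, trials$go_cue, full, bin_width, step,
                          duration = duration)
  peth_out <- compute_peth(spikes, trials$center_out, full, bin_width, step,
                           duration = duration)
  sig <- shuffle_significance(spikes, peth_go, duration,
                              n_shuffles = n_shuffles, alpha = alpha,
                              correction = correction, tail = tail,
                              seed = seed)
  dirn <- if (component == "pause") "down" else "up"
  gate <- onset_latency(sig, dirn, search_window = win$go)
  if (is.na(gate$onset)) {
    return(list(ratio = NA_real_, label = NA_character_, included = FALSE,
                component = component))
  }
  extremum <- function(peth, w) {
    sel <- peth$bin_centers >= w[1] & peth$bin_centers <= w[2]
    base_sel <- peth$bin_centers >= -1 & peth$bin_centers <= -0.5
    if (component == "pause") {
      mean(peth$mean_rate[base_sel]) - min(peth$mean_rate[sel])
    } else {
      max(peth$mean_rate[sel])
    }
  }
  num <- extremum(peth_out, win$out)
  den <- extremum(peth_go, win$go)
  ratio <- if (den == 0) Inf else num / den
  list(ratio = ratio, label = if (ratio > 1) "motor" else "sensory",
       included = TRUE, component = component)
}
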