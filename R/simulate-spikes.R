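#' Phenomenological response-kernel specification
#'
#' One multiplicative rate component of a synthetic unit's (or, for the
#' photometry generator, one additive dF/F component of the dopamine
#' trace's) event response. `gain > 1` is a burst/rebound, `gain < 1` a
#' pause. Cue-locked kernels are positioned relative to `align_event`;
#' movement-locked kernels relative to Center Out regardless of
#' `align_event`. `rpe_scale` couples the gain deviation to the trial's
#' reward-prediction error `(outcome - V_true)`, and `direction_gain`
#' multiplies the deviation on contraversive-choice trials.
#'
#' @param align_event One of "light_on", "center_in", "go_cue",
#'   "center_out", "side_in", "food_in".
#' @param onset Kernel onset relative to the locking event, s.
#' @param duration Kernel duration, s.
#' @param gain Multiplicative rate factor (> 0); photometry kernels read
#'   this as the dF/F amplitude.
#' @param lock "cue" or "movement".
#' @param rpe_scale RPE coupling coefficient (0 = none).
#' @param direction_gain Optional contraversive multiplier on the gain
#'   deviation (`NULL` = no direction tuning).
#' @return A `kernel_spec` list.
#' @export
kernel_spec <- function(align_event, onset, duration, gain,
                        lock = c("cue", "movement"), rpe_scale = 0,
                        direction_gain = NULL) {
  lock <- match.arg(lock)
  if (gain <= 0) stop("kernel gain must be > 0", call. = FALSE)
  if (!is.finite(onset + duration)) stop("onset/duration must be finite",
                                         call. = FALSE)
  structure(list(align_event = align_event, onset = onset,
                 duration = duration, gain = gain, lock = lock,
                 rpe_scale = rpe_scale, direction_gain = direction_gain),
            class = "kernel_spec")
}

#' Canonical synthetic CIN waveform template
#'
#' A broad biphasic extracellular waveform over the 2 ms analysis
#' window: a deep negative trough followed by a slower positive
#' overshoot, on four tetrode channels with decaying amplitude.
#'
#' @param sample_rate Waveform sampling rate, Hz.
#' @param trough_t,trough_sd Trough centre and width (Gaussian SD), s.
#' @param amp Trough depth (positive number), arbitrary voltage units.
#' @return A [unit_waveform()] (4 channels x 2 ms).
#' @export
default_waveform <- function(sample_rate = 30000, trough_t = 0.6e-3,
                             trough_sd = 0.18e-3, amp = 100) {
  tt <- seq(0, 2e-3 - 1 / sample_rate, by = 1 / sample_rate)
  shape <- -amp * exp(-(tt - trough_t)^2 / (2 * trough_sd^2)) +
    0.35 * amp * exp(-(tt - 1.4e-3)^2 / (2 * (0.25e-3)^2))
  chans <- c(1, 0.55, 0.3, 0.15)
  unit_waveform(outer(chans, shape), sample_rate)
}

kernel_event_times <- function(kernel, trials) {
  ev <- if (kernel$lock == "movement") "center_out" else kernel$align_event
  if (!ev %in% names(trials)) {
    stop("kernel references absent event '", ev, "'", call. = FALSE)
  }
  trials[[ev]]
}

# per-trial multiplicative gain for one kernel
kernel_trial_gains <- function(kernel, trials, V_true, hemisphere) {
  dev <- kernel$gain - 1
  dev <- rep(dev, nrow(trials))
  if (kernel$rpe_scale != 0) {
    if (is.null(V_true)) stop("rpe_scale kernel needs V_true", call. = FALSE)
    dev <- dev * (1 + kernel$rpe_scale * (trials$outcome - V_true))
  }
  if (!is.null(kernel$direction_gain)) {
    contra <- is_contra(trials$choice, hemisphere)
    dev[contra] <- dev[contra] * kernel$direction_gain
  }
  pmax(1 + dev, 0)
}

#' Contraversive-choice indicator
#'
#' A choice is contraversive when it is directed away from the recorded
#' hemisphere (left hemisphere: right choices are contraversive).
#'
#' @param choice Character vector of "left"/"right" choices.
#' @param hemisphere "left" or "right".
#' @return Logical vector.
#' @export
is_contra <- function(choice, hemisphere) {
  if (is.na(hemisphere)) stop("hemisphere required for direction analyses",
                              call. = FALSE)
  if (hemisphere == "left") choice == "right" else choice == "left"
}

#' Generate a synthetic spike train
#'
#' Simulates a tonically active unit as a gamma-renewal process (shape =
#' `regularity`; shape 1 is Poisson, ISI CV = `1/sqrt(shape)`) by time
#' rescaling: the instantaneous rate is `base_rate` times the product of
#' all active kernel gains, its integral is accumulated on a fine grid,
#' and unit-mean gamma interspike intervals are drawn in rescaled time
#' and mapped back through the inverse of the cumulative intensity.
#'
#' @param trials A [trial_table()] (may have 0 rows for a homogeneous
#'   train).
#' @param base_rate Baseline firing rate, Hz (> 0).
#' @param regularity Gamma-renewal shape parameter.
#' @param kernels List of [kernel_spec()] objects.
#' @param seed Integer seed.
#' @param duration Session duration, s.
#' @param unit_id Unit label.
#' @param V_true Per-trial generative value (needed by `rpe_scale`
#'   kernels).
#' @param hemisphere Recording hemisphere (needed by `direction_gain`
#'   kernels).
#' @param waveform A [unit_waveform()] template; per-spike snippets are
#'   the template's peak channel plus white noise.
#' @param wf_noise_sd Per-sample waveform noise SD.
#' @param dt Rate-grid resolution, s.
#' @return List with `spikes` (a [spike_train()]) and `ground_truth`
#'   (kernel list, base rate, regularity).
#' @export
gen_spikes <- function(trials, base_rate, regularity = 1, kernels = list(),
                       seed = 1, duration, unit_id = "u0", V_true = NULL,
                       hemisphere = NA_character_,
                       waveform = default_waveform(), wf_noise_sd = 4,
                       dt = 0.001) {
  if (base_rate <= 0) stop("base_rate must be > 0", call. = FALSE)
  if (inherits(kernels, "kernel_spec")) kernels <- list(kernels)
  with_seed(seed, {
    if (length(kernels) == 0) {
      # homogeneous fast path: draw gamma ISIs directly
      n_exp <- base_rate * duration
      n_draw <- max(10, ceiling(n_exp + 6 * sqrt(n_exp)))
      isi <- rgamma(n_draw, shape = regularity, rate = regularity * base_rate)
      st <- cumsum(isi)
      while (length(st) > 0 && st[length(st)] < duration) {
        isi <- rgamma(n_draw, shape = regularity, rate = regularity * base_rate)
        st <- c(st, st[length(st)] + cumsum(isi))
      }
      st <- st[st < duration]
    } else {
      L <- ceiling(duration / dt)
      rate <- rep(base_rate, L)
      tgrid <- (seq_len(L) - 1) * dt
      for (k in kernels) {
        evs <- kernel_event_times(k, trials)
        gains <- kernel_trial_gains(k, trials, V_true, hemisphere)
        keep <- !is.na(evs)
        evs <- evs[keep]; gains <- gains[keep]
        i0 <- pmax(1L, floor((evs + k$onset) / dt) + 1L)
        i1 <- pmin(L, ceiling((evs + k$onset + k$duration) / dt))
        for (j in seq_along(evs)) {
          if (i1[j] >= i0[j]) {
            idx <- i0[j]:i1[j]
            rate[idx] <- rate[idx] * gains[j]
          }
        }
      }
      Lam <- c(0, cumsum(rate) * dt)
      total <- Lam[length(Lam)]
      n_draw <- max(10, ceiling(total + 6 * sqrt(total)))
      resc <- cumsum(rgamma(n_draw, shape = regularity, rate = regularity))
      while (resc[length(resc)] < total) {
        resc <- c(resc, resc[length(resc)] +
                    cumsum(rgamma(n_draw, shape = regularity, rate = regularity)))
      }
      resc <- resc[resc < total]
      st <- approx(x = Lam, y = c(tgrid, duration), xout = resc,
                   ties = "ordered")$y
    }
    st <- st[is.finite(st)]
    st <- st[c(TRUE, diff(st) > 1e-9)]
    swf <- NULL
    if (!is.null(waveform)) {
      pk <- which.max(apply(abs(waveform$samples), 1L, max))
      tmpl <- waveform$samples[pk, ]
      swf <- matrix(rep(tmpl, each = length(st)), nrow = length(st)) +
        matrix(rnorm(length(st) * length(tmpl), 0, wf_noise_sd),
               nrow = length(st))
    }
    spikes <- spike_train(unit_id, st, waveform = waveform,
                          spike_waveforms = swf)
    list(spikes = spikes,
         ground_truth = list(base_rate = base_rate, regularity = regularity,
                             kernels = kernels))
  })
}

#' Build a tagging pulse-train table
#'
#' Lays out laser pulse trains (one block per width x frequency
#' condition from the stated menus) starting at `start_time`.
#'
#' @param start_time Time of the first pulse, s.
#' @param widths_ms Pulse widths, subset of \{2, 5, 10\} ms.
#' @param freqs_hz Train frequencies, subset of \{1, 2, 5, 10\} Hz.
#' @param n_per_condition Pulses per condition.
#' @param gap Gap between condition blocks, s.
#' @return A [laser_table()].
#' @export
gen_laser_schedule <- function(start_time, widths_ms = c(2, 5, 10),
                               freqs_hz = c(1, 2, 5, 10),
                               n_per_condition = 30, gap = 2) {
  times <- numeric(0); widths <- numeric(0); freqs <- numeric(0)
  conds <- integer(0)
  t0 <- start_time; cid <- 0L
  for (w in widths_ms) for (f in freqs_hz) {
    cid <- cid + 1L
    pt <- t0 + seq(0, by = 1 / f, length.out = n_per_condition)
    times <- c(times, pt)
    widths <- c(widths, rep(w, n_per_condition))
    freqs <- c(freqs, rep(f, n_per_condition))
    conds <- c(conds, rep(cid, n_per_condition))
    t0 <- pt[n_per_condition] + gap
  }
  laser_table(times, widths, freqs, conds)
}

#' Superimpose laser-evoked spikes on a baseline train
#'
#' For each pulse, with probability `p_follow` one evoked spike is
#' inserted at `pulse_time + latency + N(0, jitter^2)`, then merged and
#' re-sorted with the baseline train. Evoked spikes carry the unit's
#' waveform template unless `evoked_waveform` supplies a different one
#' (emulating a spike-sorting contamination scenario).
#'
#' @param spikes Baseline [spike_train()].
#' @param laser A [laser_table()].
#' @param p_follow Per-pulse follow probability.
#' @param latency Mean evoked latency, s (>= 0).
#' @param jitter Evoked latency SD, s.
#' @param seed Integer seed.
#' @param evoked_waveform Optional [unit_waveform()] for evoked spikes.
#' @param wf_noise_sd Waveform noise SD for evoked snippets.
#' @return A [spike_train()] with the evoked spikes merged in.
#' @export
gen_laser <- function(spikes, laser, p_follow, latency = 0.005,
                      jitter = 0.001, seed = 1, evoked_waveform = NULL,
                      wf_noise_sd = 4) {
  if (latency < 0) stop("latency must be >= 0", call. = FALSE)
  with_seed(seed, {
    follow <- runif(nrow(laser)) < p_follow
    ev <- laser$pulse_time_s[follow] + latency +
      rnorm(sum(follow), 0, jitter)
    if (length(ev) == 0) return(spikes)
    st <- spikes$spike_times
    tmpl_src <- if (!is.null(evoked_waveform)) evoked_waveform else spikes$waveform
    swf <- spikes$spike_waveforms
    new_swf <- NULL
    if (!is.null(swf) && !is.null(tmpl_src)) {
      pk <- which.max(apply(abs(tmpl_src$samples), 1L, max))
      tmpl <- tmpl_src$samples[pk, ]
      new_swf <- matrix(rep(tmpl, each = length(ev)), nrow = length(ev)) +
        matrix(rnorm(length(ev) * length(tmpl), 0, wf_noise_sd),
               nrow = length(ev))
    }
    all_t <- c(st, ev)
    src_new <- c(rep(FALSE, length(st)), rep(TRUE, length(ev)))
    o <- order(all_t)
    all_t <- all_t[o]; src_new <- src_new[o]
    keep <- c(TRUE, diff(all_t) > 1e-9)
    all_t <- all_t[keep]; src_new <- src_new[keep]
    merged_swf <- NULL
    if (!is.null(swf) && !is.null(new_swf)) {
      stacked <- rbind(swf, new_swf)[o, , drop = FALSE][keep, , drop = FALSE]
      merged_swf <- stacked
    }
    spike_train(spikes$unit_id, all_t, waveform = spikes$waveform,
                tetrode_id = spikes$tetrode_id, spike_waveforms = merged_swf)
  })
}
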