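#' Generate a raw time-division-multiplexed photometry trace
#'
#' Builds an underlying dopamine trace as the sum of event kernels
#' (amplitude = `gain` of each [kernel_spec()], with the same RPE
#' coupling as the spike generator) convolved with a 200 ms exponential,
#' then forms the two fluorescence channels:
#' `F470 = (1 + DA) * bleach * (1 + motion)` and
#' `F405 = k405 * bleach * (1 + motion)`, sharing the bleaching trend
#' (exponential decay to an asymptote, time constant `bleach_tau`) and a
#' slow multiplicative motion artifact. The channels are then modulated
#' into a single detector trace at `sample_rate` according to the 10 ms
#' frame LED schedule (4 ms on, 6 ms off, channels on alternating
#' frames).
#'
#' @param trials A [trial_table()].
#' @param kernels List of [kernel_spec()]; `gain` is read as the dF/F
#'   amplitude of the component.
#' @param artifact List with `bleach_tau` (s) and `motion_sd`
#'   (fractional).
#' @param seed Integer seed.
#' @param duration Session duration, s.
#' @param sample_rate Detector rate, Hz (default 10000).
#' @param V_true Per-trial generative value for `rpe_scale` kernels.
#' @param hemisphere For `direction_gain` kernels.
#' @param da_tau Kernel convolution time constant, s (default 0.2).
#' @return List with `raw` (a [photometry_raw()]) and `ground_truth`
#'   (kernel amplitudes, DA trace at the frame rate).
#' @export
gen_photometry <- function(trials, kernels = list(),
                           artifact = list(bleach_tau = 1000, motion_sd = 0.005),
                           seed = 1, duration, sample_rate = 10000,
                           V_true = NULL, hemisphere = NA_character_,
                           da_tau = 0.2) {
  if (inherits(kernels, "kernel_spec")) kernels <- list(kernels)
  frame_ms <- 10; on_ms <- 4
  frame_rate <- 1000 / frame_ms
  n_frames <- floor(duration * frame_rate)
  with_seed(seed, {
    tf <- (seq_len(n_frames) - 1) / frame_rate
    da <- numeric(n_frames)
    for (k in kernels) {
      evs <- kernel_event_times(k, trials)
      amp <- rep(k$gain, nrow(trials))
      if (k$rpe_scale != 0) {
        if (is.null(V_true)) stop("rpe_scale kernel needs V_true", call. = FALSE)
        amp <- amp * (1 + k$rpe_scale * (trials$outcome - V_true))
      }
      if (!is.null(k$direction_gain)) {
        contra <- is_contra(trials$choice, hemisphere)
        amp[contra] <- amp[contra] * k$direction_gain
      }
      keep <- !is.na(evs)
      evs <- evs[keep] + k$onset; amp <- amp[keep]
      for (j in seq_along(evs)) {
        i0 <- floor(evs[j] * frame_rate) + 1L
        if (i0 > n_frames) next
        idx <- i0:min(n_frames, i0 + ceiling(8 * da_tau * frame_rate))
        da[idx] <- da[idx] + amp[j] * exp(-(tf[idx] - evs[j]) / da_tau)
      }
    }
    bleach <- 0.25 + 0.75 * exp(-tf / artifact$bleach_tau)
    motion <- rnorm(n_frames)
    if (artifact$motion_sd > 0) {
      kw <- min(51L, n_frames - (1 - n_frames %% 2))
      if (kw >= 3) motion <- runmed(motion, kw, endrule = "constant")
      motion <- motion / max(sd(motion), 1e-12) * artifact$motion_sd
    } else motion <- numeric(n_frames)
    f470 <- (1 + da) * bleach * (1 + motion)
    f405 <- 0.6 * bleach * (1 + motion)

    schedule <- rep(c("470", "405"), length.out = n_frames)
    spf <- as.integer(sample_rate * frame_ms / 1000)
    on_n <- as.integer(sample_rate * on_ms / 1000)
    frame_vals <- ifelse(schedule == "470", f470, f405)
    one_frame_mask <- c(rep(1, on_n), rep(0, spf - on_n))
    detector <- rep(frame_vals, each = spf) * rep(one_frame_mask, n_frames) +
      0.002 + rnorm(n_frames * spf, 0, 1e-4)
    raw <- photometry_raw(detector, sample_rate, frame_ms, on_ms,
                          schedule = schedule, t0 = 0)
    list(raw = raw,
         ground_truth = list(kernels = kernels, da = da, frame_rate = frame_rate,
                             bleach_tau = artifact$bleach_tau))
  })
}
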