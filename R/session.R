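#' Per-trial event table for the bandit task
#'
#' Builds and validates the trial table used throughout the pipeline.
#' Each trial carries the times (seconds on the session clock, starting
#' at 0) of the task events Light On, Center In, Go cue, Center Out and
#' Side In, plus Food In on trials where the animal entered the food
#' port. `latency` is Light On to Center In, `rt` is Go cue to Center
#' Out; both are recomputed here so stored values cannot drift from the
#' event times.
#'
#' @param df A data.frame with columns `light_on`, `center_in`, `go_cue`,
#'   `center_out`, `side_in`, `food_in` (NA when the food port was not
#'   entered), `choice` ("left"/"right"), `outcome` (0/1), `p_left`,
#'   `p_right` (each in {0.1, 0.5, 0.9}) and `block_index`.
#' @return The validated data.frame with class `trial_table` and derived
#'   `latency` and `rt` columns.
#' @export
trial_table <- function(df) {
  req <- c("light_on", "center_in", "go_cue", "center_out", "side_in",
           "food_in", "choice", "outcome", "p_left", "p_right", "block_index")
  missing <- setdiff(req, names(df))
  if (length(missing) > 0) {
    stop("trial table column ", paste(missing, collapse = ", "), " missing",
         call. = FALSE)
  }
  df <- as.data.frame(df)[, union(req, names(df)), drop = FALSE]
  n <- nrow(df)
  if (n > 0) {
    ev <- as.matrix(df[, c("light_on", "center_in", "go_cue", "center_out",
                           "side_in")])
    if (any(!is.finite(ev))) {
      stop("trial event times must be finite", call. = FALSE)
    }
    bad <- which(apply(ev, 1L, function(x) any(diff(x) < 0)))
    if (length(bad) > 0) {
      stop("event order violated in trial ", bad[1L],
           " (require light_on <= center_in <= go_cue <= center_out <= side_in)",
           call. = FALSE)
    }
    if (!all(df$outcome %in% c(0, 1))) {
      stop("outcome must be 0 or 1", call. = FALSE)
    }
    if (!all(df$choice %in% c("left", "right"))) {
      stop("choice must be 'left' or 'right'", call. = FALSE)
    }
    probs <- c(0.1, 0.5, 0.9)
    ok <- function(p) vapply(p, function(x) any(abs(x - probs) < 1e-9), logical(1))
    if (!all(ok(df$p_left)) || !all(ok(df$p_right))) {
      stop("reward probabilities must be 0.1, 0.5 or 0.9", call. = FALSE)
    }
    fed <- !is.na(df$food_in)
    if (any(df$food_in[fed] < df$side_in[fed])) {
      stop("food_in must not precede side_in", call. = FALSE)
    }
  }
  df$latency <- df$center_in - df$light_on
  df$rt <- df$center_out - df$go_cue
  class(df) <- c("trial_table", "data.frame")
  df
}

#' Mean spike waveform for one unit
#'
#' @param samples Numeric matrix, channels x samples, voltage over a 2 ms
#'   analysis window.
#' @param sample_rate Samples per second.
#' @return A `unit_waveform` object.
#' @export
unit_waveform <- function(samples, sample_rate) {
  samples <- rbind(samples)
  if (!is.numeric(samples) || any(!is.finite(samples))) {
    stop("waveform samples must be finite numeric", call. = FALSE)
  }
  dur <- ncol(samples) / sample_rate
  if (abs(dur - 0.002) > 1e-9) {
    stop("waveform window must span 2 ms (got ", format(dur * 1000), " ms)",
         call. = FALSE)
  }
  structure(list(samples = samples, sample_rate = sample_rate),
            class = "unit_waveform")
}

#' Sorted spike train for one unit
#'
#' @param unit_id Character id.
#' @param spike_times Strictly increasing spike times, seconds.
#' @param waveform A [unit_waveform()] (mean waveform), or `NULL`.
#' @param tetrode_id Integer tetrode label.
#' @param spike_waveforms Optional numeric matrix (n_spikes x samples) of
#'   per-spike snippets on the peak channel, used by the optotagging
#'   waveform-correlation criterion.
#' @return A `spike_train` object.
#' @export
spike_train <- function(unit_id, spike_times, waveform = NULL,
                        tetrode_id = 1L, spike_waveforms = NULL) {
  spike_times <- as.numeric(spike_times)
  if (any(!is.finite(spike_times))) {
    stop("spike times must be finite", call. = FALSE)
  }
  if (is.unsorted(spike_times, strictly = TRUE)) {
    stop("spike times must be strictly increasing (unit ", unit_id, ")",
         call. = FALSE)
  }
  if (!is.null(spike_waveforms)) {
    spike_waveforms <- rbind(spike_waveforms)
    if (nrow(spike_waveforms) != length(spike_times)) {
      stop("spike_waveforms must have one row per spike", call. = FALSE)
    }
  }
  structure(list(unit_id = as.character(unit_id),
                 spike_times = spike_times,
                 waveform = waveform,
                 tetrode_id = as.integer(tetrode_id),
                 spike_waveforms = spike_waveforms),
            class = "spike_train")
}

#' Laser stimulation pulse table
#'
#' Pulse trains delivered at the end of a session for optogenetic
#' tagging. Pulse widths come from the 2/5/10 ms menu and train
#' frequencies from 1/2/5/10 Hz.
#'
#' @param pulse_times Pulse onset times, seconds.
#' @param width_ms Pulse width per pulse, ms.
#' @param freq_hz Train frequency per pulse, Hz.
#' @param condition Integer condition id per pulse (one id per
#'   width x frequency combination).
#' @return A data.frame with class `laser_table`.
#' @export
laser_table <- function(pulse_times, width_ms, freq_hz, condition) {
  df <- data.frame(pulse_time_s = as.numeric(pulse_times),
                   width_ms = as.numeric(width_ms),
                   freq_hz = as.numeric(freq_hz),
                   condition = as.integer(condition))
  if (!all(df$width_ms %in% c(2, 5, 10))) {
    stop("pulse width must be 2, 5 or 10 ms", call. = FALSE)
  }
  if (!all(df$freq_hz %in% c(1, 2, 5, 10))) {
    stop("pulse frequency must be 1, 2, 5 or 10 Hz", call. = FALSE)
  }
  if (is.unsorted(df$pulse_time_s)) df <- df[order(df$pulse_time_s), ]
  class(df) <- c("laser_table", "data.frame")
  df
}

#' Uniformly sampled continuous signal
#'
#' @param samples Numeric vector.
#' @param sample_rate Samples per second (> 0).
#' @param t0 Time of the first sample, seconds.
#' @return A `continuous_signal` object.
#' @export
continuous_signal <- function(samples, sample_rate, t0 = 0) {
  if (sample_rate <= 0) stop("sample_rate must be > 0", call. = FALSE)
  samples <- as.numeric(samples)
  if (any(!is.finite(samples))) stop("samples must be finite", call. = FALSE)
  structure(list(samples = samples, sample_rate = sample_rate, t0 = t0),
            class = "continuous_signal")
}

#' Raw time-division-multiplexed photometry trace
#'
#' The bulk-fluorescence detector is sampled at 10 kHz while the 470 nm
#' (dopamine-sensitive) and 405 nm (control) LEDs are switched in 10 ms
#' frames, 4 ms on and 6 ms off, on alternating frames. `schedule` is
#' data, not an assumption: it records which LED was active in each
#' frame.
#'
#' @param detector Numeric detector samples.
#' @param sample_rate Detector sampling rate, Hz (default 10000).
#' @param frame_ms Frame duration, ms.
#' @param on_ms LED on-time within each frame, ms.
#' @param schedule Character vector, `"470"` or `"405"` per frame.
#' @param t0 Time of the first sample, seconds.
#' @return A `photometry_raw` object.
#' @export
photometry_raw <- function(detector, sample_rate = 10000, frame_ms = 10,
                           on_ms = 4, schedule, t0 = 0) {
  spf <- sample_rate * frame_ms / 1000
  if (abs(spf - round(spf)) > 1e-9) {
    stop("frame duration must be an integer number of detector samples",
         call. = FALSE)
  }
  n_frames <- floor(length(detector) / spf)
  schedule <- as.character(schedule)
  if (length(schedule) != n_frames) {
    stop("schedule must assign one LED per frame (", n_frames, " frames, ",
         length(schedule), " schedule entries)", call. = FALSE)
  }
  if (!all(schedule %in% c("470", "405"))) {
    stop("schedule entries must be '470' or '405'", call. = FALSE)
  }
  structure(list(detector = as.numeric(detector), sample_rate = sample_rate,
                 frame_ms = frame_ms, on_ms = on_ms, off_ms = frame_ms - on_ms,
                 schedule = schedule, t0 = t0),
            class = "photometry_raw")
}

#' Assemble and validate a recording session
#'
#' The session is the unit of analysis: one behavioral run with its
#' sorted units and optional laser, ECoG and photometry streams, all on
#' a single clock starting at 0 s.
#'
#' @param session_id Character id.
#' @param duration Session duration, seconds.
#' @param trials A [trial_table()].
#' @param units List of [spike_train()] objects.
#' @param laser Optional [laser_table()].
#' @param ecog Optional [continuous_signal()].
#' @param photometry Optional [photometry_raw()].
#' @param region_label One of "DLS", "DMS", "VS" (or NA).
#' @param hemisphere One of "left", "right" (or NA).
#' @return A validated `cin_session` object.
#' @export
session <- function(session_id, duration, trials, units = list(),
                    laser = NULL, ecog = NULL, photometry = NULL,
                    region_label = NA_character_, hemisphere = NA_character_) {
  s <- structure(list(session_id = as.character(session_id),
                      duration = as.numeric(duration),
                      trials = trials, units = units, laser = laser,
                      ecog = ecog, photometry = photometry,
                      region_label = region_label, hemisphere = hemisphere),
                 class = "cin_session")
  validate_session(s)
}

#' Validate a session against the data-model invariants
#'
#' Checks that all event and spike times lie in `[0, duration]`, trials
#' are a valid [trial_table()], spike trains are strictly increasing,
#' and categorical labels come from their menus.
#'
#' @param s A `cin_session`.
#' @return `s`, invisibly unchanged, or an error naming the violation.
#' @export
validate_session <- function(s) {
  stopifnot(inherits(s, "cin_session"))
  if (!is.finite(s$duration) || s$duration <= 0) {
    stop("session duration must be positive", call. = FALSE)
  }
  s$trials <- trial_table(s$trials)
  ev <- as.matrix(s$trials[, c("light_on", "center_in", "go_cue",
                               "center_out", "side_in")])
  tmax <- suppressWarnings(max(ev, s$trials$food_in, na.rm = TRUE))
  if (nrow(s$trials) > 0 && (min(ev) < 0 || tmax > s$duration)) {
    stop("trial event times must lie within [0, duration]", call. = FALSE)
  }
  for (u in s$units) {
    stopifnot(inherits(u, "spike_train"))
    if (length(u$spike_times) > 0 &&
        (u$spike_times[1] < 0 || u$spike_times[length(u$spike_times)] > s$duration)) {
      stop("spike times outside [0, duration] for unit ", u$unit_id,
           call. = FALSE)
    }
  }
  if (!is.null(s$laser)) {
    stopifnot(inherits(s$laser, "laser_table"))
    if (nrow(s$laser) > 0 &&
        (min(s$laser$pulse_time_s) < 0 || max(s$laser$pulse_time_s) > s$duration)) {
      stop("laser pulses outside [0, duration]", call. = FALSE)
    }
  }
  if (!is.na(s$region_label) && !s$region_label %in% c("DLS", "DMS", "VS")) {
    stop("region_label must be DLS, DMS or VS", call. = FALSE)
  }
  if (!is.na(s$hemisphere) && !s$hemisphere %in% c("left", "right")) {
    stop("hemisphere must be 'left' or 'right'", call. = FALSE)
  }
  s
}

#' @export
print.cin_session <- function(x, ...) {
  cat("<cin_session> ", x$session_id, "\n", sep = "")
  cat("  duration: ", format(x$duration), " s; trials: ", nrow(x$trials),
      "; units: ", length(x$units), "\n", sep = "")
  cat("  region: ", x$region_label, "; hemisphere: ", x$hemisphere, "\n",
      sep = "")
  cat("  laser: ", if (is.null(x$laser)) "none" else nrow(x$laser),
      "; ecog: ", if (is.null(x$ecog)) "none" else
        paste0(length(x$ecog$samples), " @ ", x$ecog$sample_rate, " Hz"),
      "; photometry: ", if (is.null(x$photometry)) "none" else
        paste0(length(x$photometry$detector), " samples"), "\n", sep = "")
  invisible(x)
}

#' @export
print.spike_train <- function(x, ...) {
  cat("<spike_train> ", x$unit_id, ": ", length(x$spike_times), " spikes",
      if (!is.null(x$waveform)) " (+waveform)", "\n", sep = "")
  invisible(x)
}
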