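#' Band-ratio slow-wave-sleep statistic k over time
#'
#' Computes, per analysis frame, the statistic
#' `k = P(0.5-8 Hz) / P(20-60 Hz) - P(0.5-4 Hz) / P(8-12 Hz)`,
#' where each `P` is the band-integrated power (integral of the PSD over
#' the band, Hann-tapered Welch periodogram averaged over sub-segments
#' inside the frame). The first ratio rises when low frequencies
#' dominate (slow-wave sleep); the subtracted second ratio suppresses
#' occasional low-frequency artifacts that lack 8--12 Hz power. For a
#' flat (white-noise) spectrum k is the band-width arithmetic
#' `7.5/40 - 3.5/4 = -0.6875`.
#'
#' @param ecog A [continuous_signal()]; sample rate must be at least
#'   120 Hz to resolve the 60 Hz band edge.
#' @param frame Frame length, s (>= 2 s to resolve 0.5 Hz).
#' @param overlap Fractional frame overlap in `[0, 1)`.
#' @param segment Welch sub-segment length inside each frame, s.
#' @return List with `frame_times` (frame start times, s), `k_series`,
#'   and `frame` (the frame length, echoed for epoch conversion).
#' @export
k_timeseries <- function(ecog, frame = 10, overlap = 0.5, segment = 4) {
  fs <- ecog$sample_rate
  if (fs < 120) stop("sample rate must be >= 120 Hz", call. = FALSE)
  if (frame < 2) stop("frame must be >= 2 s to resolve 0.5 Hz", call. = FALSE)
  nf <- round(frame * fs)
  step <- max(1L, round(nf * (1 - overlap)))
  starts <- seq(1L, length(ecog$samples) - nf + 1L, by = step)
  bands <- list(r1 = c(0.5, 8), r2 = c(20, 60), r3 = c(0.5, 4), r4 = c(8, 12))
  k <- vapply(starts, function(i) {
    seg <- ecog$samples[i:(i + nf - 1L)]
    p <- welch_band_power(seg, fs, bands, segment)
    p["r1"] / p["r2"] - p["r3"] / p["r4"]
  }, numeric(1))
  list(frame_times = ecog$t0 + (starts - 1L) / fs, k_series = unname(k),
       frame = frame)
}

# Hann-tapered Welch band-integrated power: mean periodogram over 50%
# overlapping sub-segments, summed over band bins ([lo, hi)) times df.
welch_band_power <- function(x, fs, bands, segment = 4) {
  n <- round(segment * fs)
  if (n > length(x)) n <- length(x)
  step <- max(1L, floor(n / 2))
  starts <- seq(1L, length(x) - n + 1L, by = step)
  w <- 0.5 - 0.5 * cos(2 * pi * seq_len(n) / (n + 1))  # Hann taper
  U <- mean(w^2)
  acc <- numeric(floor(n / 2) + 1L)
  for (i in starts) {
    seg <- x[i:(i + n - 1L)]
    seg <- (seg - mean(seg)) * w
    X <- fft(seg)
    pxx <- (Mod(X)^2 / (n^2 * U))[seq_along(acc)]
    pxx[-c(1L, length(acc))] <- 2 * pxx[-c(1L, length(acc))]  # one-sided
    acc <- acc + pxx
  }
  pxx <- acc / length(starts) / (fs / n)   # PSD, power per Hz
  f <- (seq_along(pxx) - 1L) * fs / n
  df <- fs / n
  vapply(bands, function(b) sum(pxx[f >= b[1] & f < b[2]]) * df, numeric(1))
}

#' Detect slow-wave-sleep epochs from the k series
#'
#' Labels maximal runs of frames with `k > threshold` as putative SWS,
#' bridges single-frame dropouts inside a run (so one noisy frame does
#' not split an epoch at the minimum-duration rule), converts runs to
#' time intervals `[first frame start, last frame start + frame)`, and
#' discards epochs shorter than `min_duration`.
#'
#' @param k_series Numeric k values per frame.
#' @param frame_times Frame start times, s.
#' @param threshold Detection threshold on k (default 3).
#' @param min_duration Minimum epoch duration, s (default 30).
#' @param frame Frame length, s (default 10).
#' @return data.frame with columns `start`, `end` (possibly 0 rows).
#' @export
detect_sws <- function(k_series, frame_times, threshold = 3,
                       min_duration = 30, frame = 10) {
  stopifnot(length(k_series) == length(frame_times))
  above <- is.finite(k_series) & k_series > threshold
  if (!any(above)) return(data.frame(start = numeric(0), end = numeric(0)))
  # bridge single-frame dropouts flanked by above-threshold frames
  n <- length(above)
  if (n >= 3) {
    bridge <- which(!above[2:(n - 1)] & above[1:(n - 2)] & above[3:n]) + 1L
    above[bridge] <- TRUE
  }
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts_i <- ends - r$lengths + 1L
  runs <- which(r$values)
  out <- data.frame(start = frame_times[starts_i[runs]],
                    end = frame_times[ends[runs]] + frame)
  out <- out[out$end - out$start >= min_duration, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Intersection-over-union of two interval sets
#'
#' @param a,b Two-column matrices/data.frames of `[start, end)` intervals.
#' @return Scalar IoU of the two unions.
#' @export
interval_iou <- function(a, b) {
  a <- matrix(as.numeric(as.matrix(a)), ncol = 2)
  b <- matrix(as.numeric(as.matrix(b)), ncol = 2)
  len <- function(m) sum(pmax(0, m[, 2] - m[, 1]))
  if (nrow(a) == 0 && nrow(b) == 0) return(1)
  inter <- 0
  for (i in seq_len(nrow(a))) for (j in seq_len(nrow(b))) {
    inter <- inter + max(0, min(a[i, 2], b[j, 2]) - max(a[i, 1], b[j, 1]))
  }
  uni <- len(a) + len(b) - inter
  if (uni <= 0) return(0)
  inter / uni
}

#' Restrict a spike train or analysis to state intervals
#'
#' Helper used for state-restricted unit metrics (e.g. CV during SWS).
#'
#' @param spike_times Sorted spike times, s.
#' @param intervals Two-column matrix/data.frame of `[start, end)`.
#' @return Logical vector marking spikes inside any interval.
#' @export
in_intervals <- function(spike_times, intervals) {
  intervals <- matrix(as.numeric(as.matrix(intervals)), ncol = 2)
  inside <- rep(FALSE, length(spike_times))
  for (i in seq_len(nrow(intervals))) {
    inside <- inside | (spike_times >= intervals[i, 1] &
                          spike_times < intervals[i, 2])
  }
  inside
}
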