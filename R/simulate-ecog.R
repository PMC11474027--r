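#' Generate a state-switching synthetic ECoG trace
#'
#' Produces 1/f-weighted broadband noise whose spectrum switches between
#' a wake profile (mild 8--12 Hz and 20--60 Hz emphasis) and a
#' slow-wave-sleep profile (strong 0.5--4 Hz power, at least an order of
#' magnitude above the wake delta amplitude, with elevated 4--12 Hz and
#' no high-frequency emphasis). Each scheduled segment is synthesised
#' independently in the frequency domain, so state transitions occur
#' exactly at the schedule boundaries.
#'
#' @param state_schedule data.frame with columns `start`, `end` (s) and
#'   `state` ("wake" or "sws"); intervals must not overlap.
#' @param sample_rate Sampling rate, Hz (default 200).
#' @param seed Integer seed.
#' @return List with `ecog` (a [continuous_signal()]) and
#'   `ground_truth` (the SWS intervals as a two-column matrix).
#' @export
gen_ecog <- function(state_schedule, sample_rate = 200, seed = 1) {
  sch <- as.data.frame(state_schedule)
  stopifnot(all(c("start", "end", "state") %in% names(sch)))
  sch <- sch[order(sch$start), ]
  if (nrow(sch) > 1 && any(sch$start[-1] < sch$end[-nrow(sch)] - 1e-9)) {
    stop("schedule intervals overlap", call. = FALSE)
  }
  if (!all(sch$state %in% c("wake", "sws"))) {
    stop("states must be 'wake' or 'sws'", call. = FALSE)
  }
  with_seed(seed, {
    segs <- lapply(seq_len(nrow(sch)), function(i) {
      n <- round((sch$end[i] - sch$start[i]) * sample_rate)
      shaped_noise(n, sample_rate, sch$state[i])
    })
    sws <- as.matrix(sch[sch$state == "sws", c("start", "end")])
    list(ecog = continuous_signal(unlist(segs), sample_rate, t0 = sch$start[1]),
         ground_truth = list(sws_intervals = sws))
  })
}

# frequency-domain shaped Gaussian noise for one state segment
shaped_noise <- function(n, fs, state) {
  if (n <= 1) return(numeric(n))
  x <- rnorm(n)
  X <- fft(x)
  f <- (seq_len(n) - 1) * fs / n
  f_eff <- pmin(f, fs - f)               # two-sided symmetric frequency
  A <- 1 / sqrt(pmax(f_eff, 0.5))        # 1/f power baseline
  if (state == "wake") {
    A[f_eff >= 8 & f_eff < 12] <- A[f_eff >= 8 & f_eff < 12] * 1.5
    A[f_eff >= 20 & f_eff < 60] <- A[f_eff >= 20 & f_eff < 60] * 2
  } else {
    A[f_eff >= 0.5 & f_eff < 4] <- A[f_eff >= 0.5 & f_eff < 4] * 10
    A[f_eff >= 4 & f_eff < 12] <- A[f_eff >= 4 & f_eff < 12] * 3
  }
  Re(fft(X * A, inverse = TRUE)) / n
}
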