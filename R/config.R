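#' Default analysis configuration
#'
#' Returns the fully resolved default parameter set used by every analysis
#' stage. Values follow the recording study's analysis conventions: 10 ms
#' peri-event bins sliding in 5 ms steps over a 3 s window, shuffle tests
#' with 10,000 pseudo-event draws at alpha = 0.005, slow-wave-sleep
#' detection with the band-ratio statistic thresholded at 3 and a 30 s
#' minimum epoch, and a beta-distribution value model with the decay rate
#' fitted on a 0.50--1.00 grid.
#'
#' @return A named nested list of parameters. Top-level sections:
#'   `peth`, `tagging`, `metrics`, `sws`, `photometry`, `value`.
#' @export
#' @examples
#' cfg <- default_config()
#' cfg$peth$bin_width
default_config <- function() {
  list(
    peth = list(
      window      = c(-1, 2),   # s relative to event
      bin_width   = 0.010,      # s
      step        = 0.005,      # s
      n_shuffles  = 10000L,
      alpha       = 0.005,
      correction  = "bonferroni",   # bonferroni | pointwise | maxstat
      tail        = "gaussian",     # gaussian | empirical null tail
      edge_margin = 0               # s excluded at session edges for pseudo-events
    ),
    tagging = list(
      alpha            = 0.01,
      reliability_min  = 0.25,
      reliability_window = 0.015,   # s
      waveform_window  = 0.010,     # s post-pulse for evoked waveform
      waveform_r_min   = 0.9,
      n_null           = NULL,      # default: matched to pulse count
      duplicate_window = 0.001,     # s coincidence window
      duplicate_threshold = 0.5
    ),
    metrics = list(
      isi_threshold = 2,        # s, long-ISI cut
      acg_max_lag   = 0.200,    # s, autocorrelogram span
      rate_range    = c(2, 10), # Hz, CIN enrichment box
      cv_max        = 1.9,
      pss_min       = 40,       # ms
      width_min     = 0.3       # ms
    ),
    sws = list(
      frame        = 10,        # s
      overlap      = 0.5,
      threshold    = 3,
      min_duration = 30,        # s
      segment      = 4          # s, Welch sub-segment inside each frame
    ),
    photometry = list(
      target_rate = 250,        # Hz after dF/F
      median_k    = 5,          # samples, median filter
      fit         = "affine"    # affine | slope-only 405 -> 470 fit
    ),
    value = list(
      gamma_grid = seq(0.50, 1.00, by = 0.01),
      prior      = c(1, 1),
      alpha      = 0.05,
      iti_window = c(-3, 0),    # s before Light On
      rpe_epoch  = c(0.100, 0.250)  # s after Side In
    )
  )
}

#' Load an analysis configuration file
#'
#' Reads a YAML configuration and merges it over [default_config()].
#' Every key must already exist in the defaults; unknown keys are an
#' error rather than being silently ignored, so typos cannot change an
#' analysis unnoticed. The resolved configuration is echoed into every
#' results file written by the pipeline.
#'
#' @param path Path to a YAML file, or `NULL` for pure defaults.
#' @return The resolved configuration list.
#' @export
load_config <- function(path = NULL) {
  cfg <- default_config()
  if (is.null(path)) return(validate_config(cfg))
  user <- yaml::read_yaml(path)
  if (is.null(user)) return(validate_config(cfg))
  cfg <- merge_config(cfg, user, prefix = NULL)
  validate_config(cfg)
}

merge_config <- function(base, user, prefix = NULL) {
  for (key in names(user)) {
    full <- paste(c(prefix, key), collapse = "$")
    if (!key %in% names(base)) {
      stop("unknown key in config: '", full, "'", call. = FALSE)
    }
    if (is.list(base[[key]]) && is.list(user[[key]])) {
      base[[key]] <- merge_config(base[[key]], user[[key]], c(prefix, key))
    } else {
      base[[key]] <- user[[key]]
    }
  }
  base
}

validate_config <- function(cfg) {
  stopifnot(is.list(cfg))
  for (a in c(cfg$peth$alpha, cfg$tagging$alpha, cfg$value$alpha)) {
    if (!is.numeric(a) || a <= 0 || a >= 1) {
      stop("alpha levels must lie strictly in (0, 1)", call. = FALSE)
    }
  }
  if (cfg$peth$bin_width <= 0 || cfg$peth$step <= 0) {
    stop("bin width and step must be positive", call. = FALSE)
  }
  if (cfg$peth$n_shuffles < 1) stop("n_shuffles must be >= 1", call. = FALSE)
  if (cfg$sws$min_duration < 0) stop("min_duration must be >= 0", call. = FALSE)
  cfg
}
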