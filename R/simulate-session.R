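#' Simulate a complete synthetic recording session
#'
#' Assembles behavior, units, optional laser tagging pulses, ECoG and
#' photometry into one validated session, with the generative ground
#' truth stored alongside for recovery testing. Defaults emulate the
#' recorded preparation: tonic ~5 Hz units with burst--pause--rebound
#' kernels around the Go cue and an RPE-scaled reward response after
#' Side In, a tagging pulse block appended after the behavioral run,
#' alternating wake/SWS ECoG, and a dopamine photometry fiber with a
#' reward-locked transient.
#'
#' @param seed Integer master seed; stage generators receive
#'   deterministic sub-seeds.
#' @param behavior A [behavior_spec()].
#' @param units List of unit descriptions, each a list with fields
#'   `base_rate`, `regularity`, `kernels` (list of [kernel_spec()]),
#'   and optional `p_follow`, `latency`, `jitter` for laser response
#'   (`p_follow = 0` or absent = not light-responsive).
#' @param with_laser Append a tagging pulse block and evoke spikes?
#' @param with_ecog Generate a state-switching ECoG trace?
#' @param with_photometry Generate a photometry trace with the given
#'   kernels (list of [kernel_spec()]; `NULL` = no photometry).
#' @param sws_schedule Optional explicit state schedule for the ECoG
#'   generator; default alternates wake and SWS through the session.
#' @param region_label,hemisphere Session labels.
#' @param session_id Session label.
#' @param artifact Photometry artifact parameters (see
#'   [gen_photometry()]).
#' @return List with `session` (a `cin_session`) and `ground_truth`.
#' @export
simulate_session <- function(seed = 1,
                             behavior = behavior_spec(),
                             units = list(list(base_rate = 5,
                                               regularity = 2,
                                               kernels = list())),
                             with_laser = FALSE,
                             with_ecog = FALSE,
                             with_photometry = NULL,
                             sws_schedule = NULL,
                             region_label = "DLS", hemisphere = "left",
                             session_id = sprintf("synth-%06d", seed),
                             artifact = list(bleach_tau = 1000,
                                             motion_sd = 0.005)) {
  beh <- gen_behavior(behavior, derive_seed(seed, "behavior"))
  trials <- beh$trials
  gt <- list(behavior = beh$ground_truth)
  duration <- beh$duration

  laser <- NULL
  if (with_laser) {
    laser <- gen_laser_schedule(duration + 10, widths_ms = c(2, 5, 10),
                                freqs_hz = c(1, 2), n_per_condition = 30)
    duration <- max(laser$pulse_time_s) + 10
  }

  unit_list <- list(); gt$units <- list()
  for (i in seq_along(units)) {
    u <- units[[i]]
    uid <- if (!is.null(u$unit_id)) u$unit_id else sprintf("u%02d", i - 1)
    g <- gen_spikes(trials, base_rate = u$base_rate,
                    regularity = if (is.null(u$regularity)) 1 else u$regularity,
                    kernels = if (is.null(u$kernels)) list() else u$kernels,
                    seed = derive_seed(seed, paste0("spikes-", uid)),
                    duration = duration, unit_id = uid,
                    V_true = beh$ground_truth$V_true,
                    hemisphere = hemisphere)
    spk <- g$spikes
    responsive <- !is.null(u$p_follow) && u$p_follow > 0
    if (with_laser && responsive) {
      spk <- gen_laser(spk, laser, p_follow = u$p_follow,
                       latency = if (is.null(u$latency)) 0.005 else u$latency,
                       jitter = if (is.null(u$jitter)) 0.001 else u$jitter,
                       seed = derive_seed(seed, paste0("laser-", uid)))
    }
    unit_list[[i]] <- spk
    gt$units[[uid]] <- c(g$ground_truth, list(light_responsive = responsive))
  }

  ecog <- NULL
  if (with_ecog) {
    if (is.null(sws_schedule)) {
      # alternate 120 s wake / 90 s SWS through the session
      starts <- seq(0, duration, by = 210)
      sws_schedule <- do.call(rbind, lapply(starts, function(s0) {
        data.frame(start = c(s0, s0 + 120),
                   end = c(s0 + 120, min(s0 + 210, duration)),
                   state = c("wake", "sws"))
      }))
      sws_schedule <- sws_schedule[sws_schedule$end > sws_schedule$start &
                                     sws_schedule$start < duration, ]
      sws_schedule$end <- pmin(sws_schedule$end, duration)
    }
    ge <- gen_ecog(sws_schedule, sample_rate = 200,
                   seed = derive_seed(seed, "ecog"))
    ecog <- ge$ecog
    gt$sws_intervals <- ge$ground_truth$sws_intervals
  }

  phot <- NULL
  if (!is.null(with_photometry)) {
    gp <- gen_photometry(trials, kernels = with_photometry,
                         artifact = artifact,
                         seed = derive_seed(seed, "photometry"),
                         duration = duration,
                         V_true = beh$ground_truth$V_true,
                         hemisphere = hemisphere)
    phot <- gp$raw
    gt$photometry <- gp$ground_truth
  }

  s <- session(session_id, duration, trials, unit_list, laser, ecog, phot,
               region_label = region_label, hemisphere = hemisphere)
  list(session = s, ground_truth = gt)
}

#' Standard CIN-like response kernels
#'
#' The canonical burst--pause--rebound kernel set used by the examples
#' and tests: a Go-cue burst, the subsequent pause, a rebound, and an
#' RPE-scaled reward response after Side In.
#'
#' @param burst_gain,pause_gain,rebound_gain,reward_gain Component
#'   gains.
#' @param rpe_scale RPE coupling of the reward component.
#' @return List of [kernel_spec()] objects.
#' @export
cin_kernels <- function(burst_gain = 4, pause_gain = 0.2, rebound_gain = 2,
                        reward_gain = 2, rpe_scale = 0) {
  list(
    kernel_spec("go_cue", onset = 0.030, duration = 0.070, gain = burst_gain),
    kernel_spec("go_cue", onset = 0.100, duration = 0.150, gain = pause_gain),
    kernel_spec("go_cue", onset = 0.300, duration = 0.200, gain = rebound_gain),
    kernel_spec("side_in", onset = 0.100, duration = 0.150,
                gain = reward_gain, rpe_scale = rpe_scale))
}
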