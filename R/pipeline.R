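#' Run the analysis pipeline on a session
#'
#' Orchestrates the stages in dependency order -- tagging, unit
#' metrics, slow-wave-sleep detection, peri-event statistics,
#' photometry, and the value model -- writing each stage's CSV outputs
#' plus a JSON run manifest (config echo, seeds, stage outputs,
#' timestamps) under `out_dir`. Stages whose inputs are absent (no
#' laser table, no ECoG, no photometry) are skipped with a logged note
#' rather than failing, and the same config + seed always regenerates
#' identical outputs.
#'
#' @param s A `cin_session`, or a path to a session directory.
#' @param out_dir Output directory (created if needed).
#' @param config A configuration list from [load_config()], or a path
#'   to a YAML config.
#' @param stages Character subset of
#'   `c("tag", "metrics", "sws", "peth", "photometry", "value")`.
#' @param seed Master seed; stages derive deterministic sub-seeds.
#' @return The run manifest, invisibly (also written to
#'   `manifest.json`).
#' @export
run_pipeline <- function(s, out_dir, config = default_config(),
                         stages = c("tag", "metrics", "sws", "peth",
                                    "photometry", "value"),
                         seed = 1) {
  if (is.character(s)) s <- load_session(s)
  if (is.character(config)) config <- load_config(config)
  config <- validate_config(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(session_id = s$session_id, seed = seed, stages = stages,
                   config = config, outputs = list(), notes = character(0),
                   started = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"))
  note <- function(msg) {
    manifest$notes <<- c(manifest$notes, msg)
    message(msg)
  }
  emit <- function(df, name) {
    path <- file.path(out_dir, name)
    write_num_csv(df, path)
    manifest$outputs[[name]] <<- path
  }

  tagged_ids <- character(0)
  if ("tag" %in% stages) {
    if (is.null(s$laser) || nrow(s$laser) == 0) {
      note("tag: no laser table; stage skipped")
    } else {
      tg <- config$tagging
      rows <- lapply(s$units, function(u) {
        res <- classify_tagged(u, s$laser, s$duration, n_null = tg$n_null,
                               alpha = tg$alpha,
                               reliability_min = tg$reliability_min,
                               reliability_window = tg$reliability_window,
                               waveform_window = tg$waveform_window,
                               waveform_r_min = tg$waveform_r_min,
                               seed = derive_seed(seed, paste0("tag-", u$unit_id)))
        cbind(data.frame(unit_id = u$unit_id, tagged = res$tagged,
                         waveform_r = res$waveform_r, reason = res$reason),
              best_p = suppressWarnings(min(res$conditions$latency_p,
                                            na.rm = TRUE)),
              best_reliability = suppressWarnings(
                max(res$conditions$reliability, na.rm = TRUE)))
      })
      tagging <- do.call(rbind, rows)
      tagged_ids <- tagging$unit_id[tagging$tagged]
      dup <- duplicate_check(s$units[vapply(s$units, `[[`, "", "unit_id")
                                     %in% tagged_ids],
                             window = config$tagging$duplicate_window,
                             threshold = config$tagging$duplicate_threshold)
      emit(tagging, "tagging.csv")
      emit(dup, "duplicates.csv")
    }
  }

  sws_epochs <- NULL
  if ("sws" %in% stages) {
    if (is.null(s$ecog)) {
      note("sws: no ECoG; stage skipped (metrics fall back to whole-session CV)")
    } else {
      kc <- k_timeseries(s$ecog, frame = config$sws$frame,
                         overlap = config$sws$overlap,
                         segment = config$sws$segment)
      sws_epochs <- detect_sws(kc$k_series, kc$frame_times,
                               threshold = config$sws$threshold,
                               min_duration = config$sws$min_duration,
                               frame = config$sws$frame)
      emit(data.frame(frame_time = kc$frame_times, k = kc$k_series), "k.csv")
      emit(sws_epochs, "sws.csv")
    }
  }

  if ("metrics" %in% stages) {
    metrics <- session_unit_metrics(s, sws_epochs, config$metrics)
    emit(metrics, "metrics.csv")
  }

  if ("peth" %in% stages) {
    if (length(s$units) == 0) {
      note("peth: no units; empty output")
      emit(data.frame(unit_id = character(0), event = character(0),
                      bin_center = numeric(0), rate = numeric(0)),
           "peth.csv")
    } else {
      pc <- config$peth
      events <- c("light_on", "go_cue", "center_out", "side_in")
      long <- list(); sig_long <- list()
      for (u in s$units) {
        for (ev in events) {
          peth <- compute_peth(u, s$trials[[ev]], pc$window, pc$bin_width,
                               pc$step, duration = s$duration)
          sg <- shuffle_significance(u, peth, s$duration,
                                     n_shuffles = pc$n_shuffles,
                                     alpha = pc$alpha,
                                     correction = pc$correction,
                                     tail = pc$tail,
                                     edge_margin = pc$edge_margin,
                                     seed = derive_seed(seed,
                                       paste0("peth-", u$unit_id, "-", ev)))
          long[[length(long) + 1]] <-
            data.frame(unit_id = u$unit_id, event = ev,
                       bin_center = peth$bin_centers, rate = peth$mean_rate)
          sig_long[[length(sig_long) + 1]] <-
            data.frame(unit_id = u$unit_id, event = ev,
                       bin_center = sg$bin_centers, up = sg$up,
                       down = sg$down, alpha = pc$alpha,
                       n_shuffles = pc$n_shuffles,
                       correction = pc$correction, seed = seed)
        }
      }
      emit(do.call(rbind, long), "peth.csv")
      emit(do.call(rbind, sig_long), "sigmap.csv")
    }
  }

  if ("photometry" %in% stages) {
    if (is.null(s$photometry)) {
      note("photometry: no photometry data; stage skipped")
    } else {
      ch <- demultiplex(s$photometry)
      dff <- compute_dff(ch$sig470, ch$sig405,
                         target_rate = config$photometry$target_rate,
                         median_k = config$photometry$median_k,
                         fit = config$photometry$fit)
      tt <- dff$t0 + (seq_along(dff$samples) - 1) / dff$sample_rate
      emit(data.frame(t = tt, dff_z = dff$samples, dff = dff$samples_raw),
           "dff.csv")
    }
  }

  if ("value" %in% stages) {
    fg <- if (nrow(s$trials) < 10) NULL else
      tryCatch(fit_gamma(s$trials, grid = config$value$gamma_grid,
                         prior = config$value$prior),
               error = function(e) NULL)
    if (is.null(fg)) {
      note("value: gamma not identifiable on this session; stage skipped")
    } else {
      vals <- beta_value_series(s$trials, fg$gamma_star, config$value$prior)
      emit(cbind(vals, gamma = fg$gamma_star), "values.csv")
      jsonlite::write_json(list(gamma_star = fg$gamma_star,
                                profile = fg$profile),
                           file.path(out_dir, "gamma_fit.json"),
                           auto_unbox = TRUE, digits = NA)
      manifest$outputs[["gamma_fit.json"]] <-
        file.path(out_dir, "gamma_fit.json")
    }
  }

  manifest$finished <- format(Sys.time(), "%Y-%m-%dT%H:%M:%S")
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       force = TRUE)
  invisible(manifest)
}
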