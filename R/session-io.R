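#' Write a session directory
#'
#' Serialises a session to a plain-text directory layout: `trials.csv`,
#' `session.json`, `units/<id>.csv` (+ `.waveform.csv` and optional
#' `.spikewaves.csv`), and optional `laser.csv`, `ecog.csv`,
#' `photometry.csv`. Numbers are written at full double precision so the
#' round trip is lossless at analysis precision.
#'
#' @param s A validated `cin_session`.
#' @param path Directory to create/overwrite.
#' @return `path`, invisibly.
#' @export
write_session <- function(s, path) {
  s <- validate_session(s)
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(path)) stop("cannot create directory ", path, call. = FALSE)
  # clear stale unit files from a previous write
  unlink(file.path(path, "units"), recursive = TRUE)
  unlink(file.path(path, c("laser.csv", "ecog.csv", "photometry.csv")))

  write_num_csv(as.data.frame(unclass_df(s$trials)), file.path(path, "trials.csv"))

  meta <- list(session_id = s$session_id, duration = s$duration,
               region_label = s$region_label, hemisphere = s$hemisphere,
               unit_ids = vapply(s$units, `[[`, "", "unit_id"))
  if (!is.null(s$ecog)) {
    meta$ecog <- list(sample_rate = s$ecog$sample_rate, t0 = s$ecog$t0)
  }
  if (!is.null(s$photometry)) {
    p <- s$photometry
    meta$photometry <- list(sample_rate = p$sample_rate, frame_ms = p$frame_ms,
                            on_ms = p$on_ms, t0 = p$t0)
  }
  jsonlite::write_json(meta, file.path(path, "session.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")

  udir <- file.path(path, "units")
  dir.create(udir, showWarnings = FALSE)
  for (u in s$units) {
    write_num_csv(data.frame(spike_time_s = u$spike_times),
                  file.path(udir, paste0(u$unit_id, ".csv")))
    if (!is.null(u$waveform)) {
      wf <- as.data.frame(u$waveform$samples)
      names(wf) <- paste0("s", seq_len(ncol(wf)))
      wf <- cbind(data.frame(sample_rate = u$waveform$sample_rate,
                             tetrode_id = u$tetrode_id), wf)
      write_num_csv(wf, file.path(udir, paste0(u$unit_id, ".waveform.csv")))
    }
    if (!is.null(u$spike_waveforms)) {
      sw <- as.data.frame(u$spike_waveforms)
      names(sw) <- paste0("s", seq_len(ncol(sw)))
      write_num_csv(sw, file.path(udir, paste0(u$unit_id, ".spikewaves.csv")))
    }
  }

  if (!is.null(s$laser)) {
    write_num_csv(as.data.frame(unclass_df(s$laser)), file.path(path, "laser.csv"))
  }
  if (!is.null(s$ecog)) {
    write_num_csv(data.frame(sample = s$ecog$samples),
                  file.path(path, "ecog.csv"))
  }
  if (!is.null(s$photometry)) {
    write_num_csv(data.frame(detector = s$photometry$detector),
                  file.path(path, "photometry.csv"))
    writeLines(s$photometry$schedule, file.path(path, "photometry.schedule.txt"))
  }
  invisible(path)
}

#' Load a session directory
#'
#' Reads the layout written by [write_session()] and returns a validated
#' session. Missing required files or columns raise an error naming the
#' field; invariant violations (non-monotonic spikes, event-order
#' breaks) raise validation errors naming the offender.
#'
#' @param path Session directory.
#' @return A validated `cin_session`.
#' @export
load_session <- function(path) {
  need <- function(f) {
    fp <- file.path(path, f)
    if (!file.exists(fp)) stop("required file ", f, " missing in ", path,
                               call. = FALSE)
    fp
  }
  meta <- jsonlite::read_json(need("session.json"), simplifyVector = TRUE)
  trials_df <- read.csv(need("trials.csv"), stringsAsFactors = FALSE)
  trials <- trial_table(trials_df)

  unit_ids <- meta$unit_ids
  if (is.null(unit_ids)) unit_ids <- character(0)
  units <- lapply(unit_ids, function(id) {
    sp <- read.csv(need(file.path("units", paste0(id, ".csv"))))
    if (!"spike_time_s" %in% names(sp)) {
      stop("column spike_time_s missing for unit ", id, call. = FALSE)
    }
    wf <- NULL; tet <- 1L
    wfp <- file.path(path, "units", paste0(id, ".waveform.csv"))
    if (file.exists(wfp)) {
      w <- read.csv(wfp)
      tet <- as.integer(w$tetrode_id[1])
      sr <- w$sample_rate[1]
      wf <- unit_waveform(as.matrix(w[, grep("^s[0-9]+$", names(w)), drop = FALSE]),
                          sr)
      dimnames(wf$samples) <- NULL
    }
    sw <- NULL
    swp <- file.path(path, "units", paste0(id, ".spikewaves.csv"))
    if (file.exists(swp)) {
      sw <- as.matrix(read.csv(swp))
      dimnames(sw) <- NULL
    }
    spike_train(id, sp$spike_time_s, waveform = wf, tetrode_id = tet,
                spike_waveforms = sw)
  })

  laser <- NULL
  if (file.exists(file.path(path, "laser.csv"))) {
    l <- read.csv(file.path(path, "laser.csv"))
    laser <- laser_table(l$pulse_time_s, l$width_ms, l$freq_hz, l$condition)
  }
  ecog <- NULL
  if (file.exists(file.path(path, "ecog.csv"))) {
    e <- read.csv(file.path(path, "ecog.csv"))
    ecog <- continuous_signal(e$sample, meta$ecog$sample_rate, meta$ecog$t0)
  }
  phot <- NULL
  if (file.exists(file.path(path, "photometry.csv"))) {
    d <- read.csv(file.path(path, "photometry.csv"))
    sched <- readLines(file.path(path, "photometry.schedule.txt"))
    phot <- photometry_raw(d$detector, meta$photometry$sample_rate,
                           meta$photometry$frame_ms, meta$photometry$on_ms,
                           schedule = sched, t0 = meta$photometry$t0)
  }

  session(meta$session_id, meta$duration, trials, units, laser, ecog, phot,
          region_label = if (is.null(meta$region_label)) NA_character_ else meta$region_label,
          hemisphere = if (is.null(meta$hemisphere)) NA_character_ else meta$hemisphere)
}

# full-precision CSV writer (numbers at 15 significant digits)
write_num_csv <- function(df, path) {
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(x) {
    out <- formatC(x, digits = 15, format = "g")
    out[is.na(x)] <- NA
    out
  })
  write.csv(df, path, row.names = FALSE, quote = FALSE, na = "")
}

unclass_df <- function(x) {
  class(x) <- "data.frame"
  x
}
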