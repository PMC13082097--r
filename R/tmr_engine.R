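#' Configuration for the simulated real-time TMR system
#'
#' @param so_threshold slow-oscillation detection threshold on the
#'   causally filtered Fz signal, in microvolts (default +35).
#' @param spindle_refractory seconds that must have passed since the last
#'   online spindle detection before a cue may play (default 2.5).
#' @param post_sound_lockout seconds after each sound during which SO
#'   detection is suspended (default 8).
#' @param so_band online SO band-pass in Hz (causal; default 0.25-2.5,
#'   chosen so the causal filter's group delay and pass-band noise keep
#'   cue delivery near the true up-state peak).
#' @param spindle_band online sigma band in Hz (default 11-16).
#' @param spindle_rms_threshold sigma-band RMS threshold in microvolts.
#' @param spindle_rms_window trailing RMS window in seconds.
#' @param cue_pattern repeating order in which cue kinds are consumed
#'   (default target, control, sham).
#' @param sham_lockout whether sham ("no sound") markers trigger the
#'   post-sound lockout (default FALSE: no sound was played).
#' @param peak_wait maximum seconds to wait for the SO peak after a
#'   threshold crossing before the detection is abandoned (default 2).
#' @return A `tmr_config` list.
#' @export
tmr_config <- function(so_threshold = 35, spindle_refractory = 2.5,
                       post_sound_lockout = 8, so_band = c(0.25, 2.5),
                       spindle_band = c(11, 16),
                       spindle_rms_threshold = 8,
                       spindle_rms_window = 0.25,
                       cue_pattern = c("target", "control", "sham"),
                       sham_lockout = FALSE, peak_wait = 2) {
  stopifnot(so_threshold > 0, spindle_refractory >= 0,
            post_sound_lockout > 0, length(cue_pattern) >= 1,
            all(cue_pattern %in% c("target", "control", "sham")))
  structure(list(so_threshold = so_threshold,
                 spindle_refractory = spindle_refractory,
                 post_sound_lockout = post_sound_lockout,
                 so_band = so_band, spindle_band = spindle_band,
                 spindle_rms_threshold = spindle_rms_threshold,
                 spindle_rms_window = spindle_rms_window,
                 cue_pattern = cue_pattern, sham_lockout = sham_lockout,
                 peak_wait = peak_wait),
            class = "tmr_config")
}

# causal band-pass (2nd-order Butterworth, forward filtering only)
causal_bandpass <- function(x, band, fs) {
  bf <- signal::butter(2, band / (fs / 2), type = "pass")
  as.numeric(signal::filter(bf, x))
}

#' Online spindle detection on a sample stream
#'
#' Causal sigma-band filtering followed by a trailing-window RMS; a
#' detection is emitted at each rising threshold crossing. The full
#' above-threshold sample mask (used for the cueing refractory, so that a
#' sustained spindle train keeps the refractory active) is attached as an
#' attribute.
#'
#' @param stream numeric Fz samples (microvolts).
#' @param fs sampling rate in Hz.
#' @param band sigma band in Hz.
#' @param rms_threshold RMS threshold in microvolts.
#' @param window trailing RMS window in seconds.
#' @return Numeric vector of detection (onset) times in seconds, with
#'   attribute `above` (logical per-sample mask).
#' @export
detect_spindles_online <- function(stream, fs, band = c(11, 16),
                                   rms_threshold = 8, window = 0.25) {
  stopifnot(rms_threshold > 0)
  sigma <- causal_bandpass(stream, band, fs)
  w <- max(1L, round(window * fs))
  ma <- stats::filter(sigma^2, rep(1 / w, w), sides = 1)
  ma[is.na(ma)] <- 0
  rms <- sqrt(as.numeric(ma))
  above <- rms > rms_threshold
  rising <- which(above & !c(FALSE, above[-length(above)]))
  structure((rising - 1) / fs, above = above)
}

#' Run the simulated closed-loop TMR engine over a record
#'
#' Streams the Fz channel causally, tracking slow oscillations and
#' spindles in parallel. An SO is detected when the causally band-passed
#' Fz signal crosses the positive threshold; the cue fires at the SO peak
#' (the first subsequent sample at which the filtered slope changes from
#' positive to negative). A cue is withheld if a spindle was detected
#' within the refractory window, and after every sound the detector is
#' suspended for the lockout period. Cue kinds are consumed cyclically
#' from `cue_pattern`; sham entries mark the timepoint without playing a
#' sound (and by default without triggering the lockout).
#'
#' @param record an `eeg_record` containing an Fz channel.
#' @param h the `hypnogram` covering the record (stages annotate events).
#' @param cfg a `tmr_config`.
#' @param stages_allowed stages in which cueing is permitted (default: any
#'   sleep stage; cueing is paused during wake, as an experimenter would).
#' @return A `cue_log`: data.frame with columns `kind`, `onset` (s),
#'   `stage`, `amplitude` (filtered microvolts at detection), plus
#'   attributes `counts` (kind x stage table) and `config`.
#' @export
run_tmr <- function(record, h, cfg = tmr_config(),
                    stages_allowed = c("N1", "N2", "N3", "REM")) {
  if (!"Fz" %in% record$channels) stop("record must contain an Fz channel")
  if (length(cfg$cue_pattern) < 1) stop("cue list must not be empty")
  fs <- record$srate
  x <- record$signals[, "Fz"]
  f <- causal_bandpass(x, cfg$so_band, fs)

  sp <- detect_spindles_online(x, fs, cfg$spindle_band,
                               cfg$spindle_rms_threshold,
                               cfg$spindle_rms_window)
  above <- attr(sp, "above")
  # most recent spindle-positive sample at or before each sample
  last_sp_idx <- cummax(ifelse(above, seq_along(above), 0L))

  # candidate SO detections: upward threshold crossings of the filtered
  # signal, each resolved to the next local maximum (causal slope test)
  crossings <- which(f[-1] >= cfg$so_threshold &
                       f[-length(f)] < cfg$so_threshold) + 1L
  d <- diff(f)
  falling <- c(d < 0, TRUE)
  epoch_len <- attr(h, "epoch_length")

  events <- list()
  last_sound <- -Inf
  cue_i <- 0L
  guard <- round(cfg$peak_wait * fs)
  for (ci in crossings) {
    t_cross <- (ci - 1) / fs
    if (t_cross < last_sound + cfg$post_sound_lockout) next
    # locate the peak: first falling-slope sample after the crossing
    j_end <- min(ci + guard, length(f) - 1L)
    rel <- which(falling[ci:j_end])
    if (!length(rel)) next  # no peak within the wait guard: abandon
    pk <- ci + rel[1] - 1L
    t_peak <- (pk - 1) / fs
    if (t_peak < last_sound + cfg$post_sound_lockout) next
    # spindle refractory at the moment of (intended) cue delivery
    lsp <- last_sp_idx[pk]
    if (lsp > 0 && (pk - lsp) / fs < cfg$spindle_refractory) next
    # sleep-stage gate (half-open epochs: boundary belongs to later epoch)
    ep <- floor(t_peak / epoch_len) + 1L
    if (ep > length(h)) next
    stage <- as.character(h[ep])
    if (!stage %in% stages_allowed) next
    kind <- cfg$cue_pattern[(cue_i %% length(cfg$cue_pattern)) + 1L]
    cue_i <- cue_i + 1L
    events[[length(events) + 1L]] <- data.frame(
      kind = kind, onset = t_peak, stage = stage, amplitude = f[pk])
    if (kind != "sham" || cfg$sham_lockout) last_sound <- t_peak
  }
  log <- if (length(events)) do.call(rbind, events) else
    data.frame(kind = character(0), onset = numeric(0),
               stage = character(0), amplitude = numeric(0))
  rownames(log) <- NULL
  structure(log, class = c("cue_log", "data.frame"),
            counts = table(factor(log$kind,
                                  levels = c("target", "control", "sham")),
                           factor(log$stage,
                                  levels = levels(h))),
            config = cfg)
}

#' Tally cues by kind and sleep stage
#'
#' Assigns each cue the stage of its containing 30-s scoring epoch
#' (half-open epochs: an event exactly on a boundary belongs to the later
#' epoch) and tabulates counts per kind and stage.
#'
#' @param log a `cue_log`.
#' @param h the `hypnogram`.
#' @return kind x stage contingency table; totals equal `nrow(log)`.
#' @export
tally_cues_by_stage <- function(log, h) {
  epoch_len <- attr(h, "epoch_length")
  ep <- floor(log$onset / epoch_len) + 1L
  if (any(ep > length(h) | log$onset < 0))
    stop("cue event outside hypnogram extent")
  stage <- h[ep]
  table(factor(log$kind, levels = c("target", "control", "sham")),
        factor(stage, levels = levels(h)))
}

#' Write a cue log to CSV with a JSON per-stage summary
#' @param log a `cue_log`.
#' @param path CSV path; the summary goes to `<path>.json` when
#'   `summary_json = TRUE`.
#' @param summary_json write the per-stage count summary too?
#' @export
write_cue_log <- function(log, path, summary_json = TRUE) {
  con <- file(path, "w"); on.exit(close(con))
  writeLines("# tmrstruct/cue_log/v1", con)
  write.csv(as.data.frame(log), con, row.names = FALSE)
  if (summary_json) {
    counts <- attr(log, "counts")
    jsonlite::write_json(
      list(schema = "tmrstruct/cue_log_summary/v1",
           counts = as.data.frame(counts)),
      paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' Read a cue log written by [write_cue_log()]
#' @param path CSV path.
#' @return A `cue_log` data.frame.
#' @export
read_cue_log <- function(path) {
  header <- readLines(path, n = 1)
  if (!grepl("^# tmrstruct/cue_log/v1", header))
    stop("schema mismatch: not a tmrstruct/cue_log/v1 file")
  df <- read.csv(path, comment.char = "#")
  structure(df, class = c("cue_log", "data.frame"))
}
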