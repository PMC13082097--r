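#' Generate a nap hypnogram (30-s epochs)
#'
#' Simulates a sleep-stage sequence as a first-order Markov chain over
#' Wake, N1, N2, N3 and REM in 30-second scoring epochs. The default
#' transition profile produces nap-like records: sleep onset through
#' N1 into consolidated N2 with N3 periods and occasional late REM.
#'
#' @param duration_min nap duration in minutes (default 120, a 2-h nap
#'   opportunity).
#' @param profile list with `initial` (named probabilities) and
#'   `transition` (5 x 5 row-stochastic matrix, rows/cols W,N1,N2,N3,REM).
#' @param seed RNG seed.
#' @return A `hypnogram`: factor vector of stages (one per 30-s epoch)
#'   with attributes `epoch_length` (30) and `duration_min`.
#' @export
generate_hypnogram <- function(duration_min = 120, profile = nap_profile(),
                               seed = 1) {
  stopifnot(duration_min > 0)
  set.seed(as.integer(seed))
  stages <- c("W", "N1", "N2", "N3", "REM")
  n_epochs <- ceiling(duration_min * 60 / 30)
  P <- profile$transition
  stopifnot(all(dim(P) == c(5, 5)), all(abs(rowSums(P) - 1) < 1e-8))
  out <- character(n_epochs)
  out[1] <- sample(stages, 1, prob = profile$initial)
  for (i in 2:n_epochs)
    out[i] <- sample(stages, 1, prob = P[out[i - 1], ])
  structure(factor(out, levels = stages), epoch_length = 30,
            duration_min = duration_min, class = c("hypnogram", "factor"))
}

#' Default nap stage-transition profile
#'
#' `wake_bias` models between-participant differences in sleep depth:
#' it shifts transition probability from every sleep stage toward Wake
#' (rows renormalized), so restless sleepers accumulate less N2/N3 time
#' and receive fewer cues — emulating the wide spread of sleep quality
#' seen in nap studies.
#'
#' @param wake_bias extra probability mass (0-0.5) moved toward Wake from
#'   each sleep stage.
#' @return list with `initial` and `transition` for [generate_hypnogram()].
#' @export
nap_profile <- function(wake_bias = 0) {
  stopifnot(wake_bias >= 0, wake_bias <= 0.5)
  stages <- c("W", "N1", "N2", "N3", "REM")
  P <- matrix(0, 5, 5, dimnames = list(stages, stages))
  P["W", ]   <- c(0.75, 0.25, 0.00, 0.00, 0.00)
  P["N1", ]  <- c(0.05, 0.50, 0.45, 0.00, 0.00)
  P["N2", ]  <- c(0.02, 0.02, 0.83, 0.11, 0.02)
  P["N3", ]  <- c(0.01, 0.00, 0.11, 0.88, 0.00)
  P["REM", ] <- c(0.03, 0.02, 0.10, 0.00, 0.85)
  if (wake_bias > 0) {
    for (s in c("N1", "N2", "N3", "REM")) {
      P[s, ] <- P[s, ] * (1 - wake_bias)
      P[s, "W"] <- P[s, "W"] + wake_bias
    }
  }
  list(initial = c(W = 0.9, N1 = 0.1, N2 = 0, N3 = 0, REM = 0),
       transition = P)
}

#' Total sleep time of a hypnogram, in minutes
#'
#' Sleep time counts N1 + N2 + N3 + REM epochs (30 s each).
#' @param h a `hypnogram`.
#' @return Minutes asleep.
#' @export
total_sleep_time <- function(h) {
  sum(h %in% c("N1", "N2", "N3", "REM")) * attr(h, "epoch_length") / 60
}

#' Stage minutes of a hypnogram
#' @param h a `hypnogram`.
#' @return Named numeric vector of minutes per stage.
#' @export
stage_minutes <- function(h) {
  tab <- table(h) * attr(h, "epoch_length") / 60
  setNames(as.numeric(tab), names(tab))
}

#' Synthesis parameters for the EEG generator
#'
#' @param so_rate slow oscillations per minute of N3 (default 5); N2
#'   carries SOs at `so_rate_n2` (default half the N3 rate).
#' @param so_amplitude positive-peak SO amplitude at Fz in microvolts
#'   (default 75).
#' @param so_frequency SO frequency in Hz (default 0.8; one full cycle =
#'   down-state half-wave then up-state half-wave).
#' @param spindle_rate spindles per minute of N2 (default 3); N3 carries
#'   spindles at `spindle_rate_n3` (default half).
#' @param spindle_band spindle frequency range in Hz (default 11-16).
#' @param spindle_amplitude spindle envelope amplitude in microvolts.
#' @param noise_slope exponent of the 1/f^slope background spectrum.
#' @param noise_scale background RMS in microvolts.
#' @param so_rate_n2,spindle_rate_n3 stage-specific rates.
#' @param seed RNG seed.
#' @return A `synth_params` list.
#' @export
synth_params <- function(so_rate = 5, so_amplitude = 75, so_frequency = 0.8,
                         spindle_rate = 3, spindle_band = c(11, 16),
                         spindle_amplitude = 25, noise_slope = 1,
                         noise_scale = 12, so_rate_n2 = so_rate / 2,
                         spindle_rate_n3 = spindle_rate / 2, seed = 1) {
  stopifnot(so_rate >= 0, spindle_rate >= 0, so_amplitude > 0,
            spindle_amplitude > 0, noise_scale > 0)
  structure(list(so_rate = so_rate, so_amplitude = so_amplitude,
                 so_frequency = so_frequency, spindle_rate = spindle_rate,
                 spindle_band = spindle_band,
                 spindle_amplitude = spindle_amplitude,
                 noise_slope = noise_slope, noise_scale = noise_scale,
                 so_rate_n2 = so_rate_n2, spindle_rate_n3 = spindle_rate_n3,
                 seed = seed),
            class = "synth_params")
}

# 1/f^slope background noise via spectral shaping, RMS-normalized
pink_noise <- function(n, slope, scale) {
  nf <- n %/% 2
  amp <- seq_len(nf)^(-slope / 2)
  ph <- runif(nf, 0, 2 * pi)
  spec <- complex(modulus = amp, argument = ph)
  full <- complex(real = numeric(n))
  full[2:(nf + 1)] <- spec
  if (n %% 2 == 0) {
    full[nf + 1] <- complex(real = amp[nf] * cos(ph[nf]))  # Nyquist bin real
    full[(nf + 2):n] <- Conj(rev(spec[1:(nf - 1)]))
  } else {
    full[(nf + 2):n] <- Conj(rev(spec))
  }
  x <- Re(fft(full, inverse = TRUE))
  x / sd(x) * scale
}

# single-cycle SO waveform: down-state half-wave then up-state half-wave;
# positive peak = amp at 3/4 of the cycle
so_waveform <- function(fs, freq, amp) {
  t <- seq(0, 1 / freq, by = 1 / fs)
  -amp * sin(2 * pi * freq * t)
}

# Hann-windowed sigma burst
spindle_waveform <- function(fs, freq, dur, amp) {
  t <- seq(0, dur, by = 1 / fs)
  env <- 0.5 * (1 - cos(2 * pi * seq_along(t) / length(t)))
  amp * env * sin(2 * pi * freq * t)
}

#' Synthesize a multichannel sleep-EEG record from a hypnogram
#'
#' Produces 1/f background activity plus stage-dependent injected slow
#' oscillations (N2/N3) and spindle bursts (N2/N3) on Fz, with Cz carrying
#' a scaled copy of the event content plus independent noise and the
#' mastoid pair (M1, M2) as low-amplitude reference stand-ins. Every
#' injected event is logged with its ground-truth onset, peak time and
#' amplitude, which downstream detection benchmarks use as the oracle.
#'
#' @param h a `hypnogram`.
#' @param p a `synth_params`.
#' @param srate sampling rate in Hz (512, as recorded).
#' @return An `eeg_record`: list with `signals` (samples x channels matrix,
#'   microvolts), `channels`, `srate`, `events` (data.frame: kind, channel,
#'   onset, peak, amplitude, freq), `duration_s`.
#' @export
synthesize_eeg <- function(h, p = synth_params(), srate = 512) {
  stopifnot(inherits(h, "hypnogram"), srate %in% c(256, 512))
  set.seed(as.integer(p$seed))
  epoch_len <- attr(h, "epoch_length")
  n_epochs <- length(h)
  dur <- n_epochs * epoch_len
  n <- dur * srate
  channels <- c("Fz", "Cz", "M1", "M2")

  fz_events <- numeric(n)
  events <- list()
  so_cycle <- 1 / p$so_frequency
  for (e in seq_len(n_epochs)) {
    st <- as.character(h[e])
    t0 <- (e - 1) * epoch_len
    so_rate <- switch(st, N3 = p$so_rate, N2 = p$so_rate_n2, 0)
    sp_rate <- switch(st, N2 = p$spindle_rate, N3 = p$spindle_rate_n3, 0)
    n_so <- rpois(1, so_rate * epoch_len / 60)
    n_so <- min(n_so, floor(epoch_len / (so_cycle + 0.5)))
    if (n_so > 0) {
      # non-overlapping onsets within the epoch
      slots <- sort(runif(n_so, 0, epoch_len - so_cycle))
      keep <- c(TRUE, diff(slots) > so_cycle)
      for (on in slots[keep]) {
        w <- so_waveform(srate, p$so_frequency, p$so_amplitude)
        i0 <- floor((t0 + on) * srate) + 1L
        idx <- i0:(i0 + length(w) - 1L)
        idx <- idx[idx <= n]
        fz_events[idx] <- fz_events[idx] + w[seq_along(idx)]
        events[[length(events) + 1L]] <- data.frame(
          kind = "SO", channel = "Fz", onset = t0 + on,
          peak = t0 + on + 0.75 * so_cycle, amplitude = p$so_amplitude,
          freq = p$so_frequency)
      }
    }
    n_sp <- rpois(1, sp_rate * epoch_len / 60)
    if (n_sp > 0) {
      for (k in seq_len(n_sp)) {
        dur_sp <- runif(1, 0.5, 1.5)
        f_sp <- runif(1, p$spindle_band[1], p$spindle_band[2])
        on <- runif(1, 0, epoch_len - dur_sp)
        w <- spindle_waveform(srate, f_sp, dur_sp, p$spindle_amplitude)
        i0 <- floor((t0 + on) * srate) + 1L
        idx <- i0:(i0 + length(w) - 1L)
        idx <- idx[idx <= n]
        fz_events[idx] <- fz_events[idx] + w[seq_along(idx)]
        events[[length(events) + 1L]] <- data.frame(
          kind = "spindle", channel = "Fz", onset = t0 + on,
          peak = t0 + on + dur_sp / 2, amplitude = p$spindle_amplitude,
          freq = f_sp)
      }
    }
  }
  ev <- if (length(events)) do.call(rbind, events) else
    data.frame(kind = character(0), channel = character(0),
               onset = numeric(0), peak = numeric(0),
               amplitude = numeric(0), freq = numeric(0))
  ev <- ev[order(ev$onset), ]
  rownames(ev) <- NULL

  signals <- matrix(0, n, length(channels),
                    dimnames = list(NULL, channels))
  signals[, "Fz"] <- fz_events + pink_noise(n, p$noise_slope, p$noise_scale)
  signals[, "Cz"] <- 0.8 * fz_events +
    pink_noise(n, p$noise_slope, p$noise_scale)
  signals[, "M1"] <- pink_noise(n, p$noise_slope, 0.05 * p$noise_scale)
  signals[, "M2"] <- pink_noise(n, p$noise_slope, 0.05 * p$noise_scale)

  structure(list(signals = signals, channels = channels, srate = srate,
                 events = ev, duration_s = dur),
            class = "eeg_record")
}

#' @export
print.eeg_record <- function(x, ...) {
  cat(sprintf("eeg_record: %d channels (%s), %.1f min at %d Hz, %d events\n",
              length(x$channels), paste(x$channels, collapse = ", "),
              x$duration_s / 60, x$srate, nrow(x$events)))
  invisible(x)
}

#' Write an EEG record as flat binary signal + JSON sidecar
#'
#' The signal matrix goes to `<path>.bin` (little-endian float64,
#' channel-interleaved by column) and channels, rate, and ground-truth
#' events to `<path>.json`.
#'
#' @param record an `eeg_record`.
#' @param path base path (no extension).
#' @export
write_eeg_record <- function(record, path) {
  con <- file(paste0(path, ".bin"), "wb")
  writeBin(as.numeric(record$signals), con, size = 8, endian = "little")
  close(con)
  side <- list(schema = "tmrstruct/eeg_record/v1",
               channels = record$channels, srate = record$srate,
               n_samples = nrow(record$signals),
               duration_s = record$duration_s,
               events = record$events)
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, dataframe = "columns")
  invisible(path)
}

#' Read an EEG record written by [write_eeg_record()]
#' @param path base path used at write time.
#' @return An `eeg_record`.
#' @export
read_eeg_record <- function(path) {
  side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  if (!identical(side$schema, "tmrstruct/eeg_record/v1"))
    stop("schema mismatch: not a tmrstruct/eeg_record/v1 sidecar")
  n <- side$n_samples * length(side$channels)
  con <- file(paste0(path, ".bin"), "rb")
  x <- readBin(con, "numeric", n = n, size = 8, endian = "little")
  close(con)
  signals <- matrix(x, nrow = side$n_samples,
                    dimnames = list(NULL, side$channels))
  ev <- as.data.frame(side$events)
  structure(list(signals = signals, channels = side$channels,
                 srate = side$srate, events = ev,
                 duration_s = side$duration_s),
            class = "eeg_record")
}

#' Write/read a hypnogram as CSV
#' @param h a `hypnogram`.
#' @param path CSV path.
#' @export
write_hypnogram_csv <- function(h, path) {
  df <- data.frame(epoch = seq_along(h), stage = as.character(h))
  con <- file(path, "w"); on.exit(close(con))
  writeLines(sprintf("# tmrstruct/hypnogram/v1 epoch_length=%d",
                     attr(h, "epoch_length")), con)
  write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_hypnogram_csv
#' @export
read_hypnogram_csv <- function(path) {
  header <- readLines(path, n = 1)
  if (!grepl("^# tmrstruct/hypnogram/v1", header))
    stop("schema mismatch: not a tmrstruct/hypnogram/v1 file")
  df <- read.csv(path, comment.char = "#")
  structure(factor(df$stage, levels = c("W", "N1", "N2", "N3", "REM")),
            epoch_length = 30, duration_min = length(df$stage) / 2,
            class = c("hypnogram", "factor"))
}
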