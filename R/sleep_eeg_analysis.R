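#' Preprocess a raw sleep-EEG record for cue-locked analysis
#'
#' Downsamples to 256 Hz, re-references every scalp channel to the average
#' of the linked mastoids (M1/M2), and zero-phase band-pass filters
#' 0.3-30 Hz. If mastoid channels are absent, re-referencing is skipped
#' with a warning.
#'
#' @param record an `eeg_record` (typically 512 Hz as recorded).
#' @param target_srate analysis sampling rate (default 256).
#' @param band offline band-pass in Hz (default 0.3-30).
#' @return The preprocessed `eeg_record` (mastoid channels dropped).
#' @export
preprocess <- function(record, target_srate = 256, band = c(0.3, 30)) {
  stopifnot(inherits(record, "eeg_record"))
  sig <- record$signals
  fs <- record$srate
  if (fs %% target_srate != 0 && fs != target_srate)
    stop("sampling rate must be an integer multiple of target_srate")
  q <- fs %/% target_srate
  if (q > 1) {
    sig <- apply(sig, 2, function(ch) signal::decimate(ch, q, ftype = "fir"))
    fs <- target_srate
  }
  mast <- intersect(c("M1", "M2"), colnames(sig))
  if (length(mast) == 2) {
    ref <- rowMeans(sig[, mast])
    keep <- setdiff(colnames(sig), mast)
    sig <- sig[, keep, drop = FALSE] - ref
  } else {
    warning("mastoid channels missing; re-referencing skipped")
  }
  bf <- signal::butter(2, band / (fs / 2), type = "pass")
  sig <- apply(sig, 2, function(ch) as.numeric(signal::filtfilt(bf, ch)))
  structure(list(signals = sig, channels = colnames(sig), srate = fs,
                 events = record$events, duration_s = record$duration_s),
            class = "eeg_record")
}

# per-trial artifact metrics
trial_kurtosis <- function(x) {
  x <- x - mean(x)
  n <- length(x)
  (sum(x^4) / n) / (sum(x^2) / n)^2 - 3
}

#' Epoch a preprocessed record around cue events
#'
#' Cuts \[-3, 3\] s windows around each cue onset, separately per cue kind,
#' and applies an automatic artifact screen standing in for manual
#' inspection: per-trial peak amplitude, variance, and kurtosis
#' (maximum across channels) are converted to robust z-scores
#' (median/MAD) across trials, and trials exceeding `reject_z` on any
#' metric are rejected. Cues too close to the record edges are dropped
#' and counted.
#'
#' @param record a preprocessed `eeg_record`.
#' @param log a `cue_log`.
#' @param window epoch window in seconds relative to cue onset.
#' @param reject_z rejection threshold in z units (default 5).
#' @param channels channels to epoch (default: all in the record).
#' @return Named list of `epoch_set` objects (one per cue kind present):
#'   each has `data` (trials x channels x time array), `times`, `srate`,
#'   `condition`, `kept` / `rejected` / `edge_dropped` counts, and the
#'   per-trial rejection mask.
#' @export
epoch_around_cues <- function(record, log, window = c(-3, 3), reject_z = 5,
                              channels = record$channels) {
  fs <- record$srate
  n <- nrow(record$signals)
  n_t <- round((window[2] - window[1]) * fs)
  times <- window[1] + (seq_len(n_t) - 1) / fs
  out <- list()
  for (kind in unique(log$kind)) {
    onsets <- log$onset[log$kind == kind]
    i0 <- round((onsets + window[1]) * fs) + 1L
    ok <- i0 >= 1 & (i0 + n_t - 1L) <= n
    edge_dropped <- sum(!ok)
    i0 <- i0[ok]
    if (!length(i0)) next
    arr <- array(0, dim = c(length(i0), length(channels), n_t),
                 dimnames = list(NULL, channels, NULL))
    for (tr in seq_along(i0)) {
      idx <- i0[tr]:(i0[tr] + n_t - 1L)
      arr[tr, , ] <- t(record$signals[idx, channels, drop = FALSE])
    }
    amp <- apply(arr, 1, function(m) max(abs(m)))
    va <- apply(arr, 1, function(m) max(apply(m, 1, var)))
    ku <- apply(arr, 1, function(m) max(apply(m, 1, trial_kurtosis)))
    # robust z (median/MAD): an ordinary z among few trials is bounded by
    # (n-1)/sqrt(n) and could never flag a gross artifact
    rz <- function(x) {
      s <- stats::mad(x)
      if (!is.finite(s) || s == 0) return(rep(0, length(x)))
      (x - median(x)) / s
    }
    rej <- rz(amp) > reject_z | rz(va) > reject_z | rz(ku) > reject_z
    out[[kind]] <- structure(
      list(data = arr[!rej, , , drop = FALSE], times = times, srate = fs,
           condition = kind, channels = channels,
           kept = sum(!rej), rejected = sum(rej),
           edge_dropped = edge_dropped, reject_mask = rej),
      class = "epoch_set")
  }
  out
}

#' @export
print.epoch_set <- function(x, ...) {
  cat(sprintf("epoch_set (%s): %d trials kept, %d rejected, %d edge-dropped; %d channels, [%.2g, %.2g] s at %d Hz\n",
              x$condition, x$kept, x$rejected, x$edge_dropped,
              length(x$channels), min(x$times), max(x$times), x$srate))
  invisible(x)
}

# complex Morlet wavelet transform of one signal at given frequencies;
# returns freq x time power matrix (FFT convolution)
morlet_power <- function(x, fs, freqs, n_cycles) {
  n <- length(x)
  nfft <- stats::nextn(2 * n, 2)
  X <- fft(c(x, numeric(nfft - n)))
  pow <- matrix(0, length(freqs), n)
  t_half <- (nfft %/% 2)
  for (fi in seq_along(freqs)) {
    f0 <- freqs[fi]
    sdt <- n_cycles / (2 * pi * f0)
    tw <- (seq_len(nfft) - 1 - t_half) / fs
    w <- exp(-tw^2 / (2 * sdt^2)) * exp(2i * pi * f0 * tw)
    w <- w / sum(abs(w))
    W <- fft(c(w[(t_half + 1):nfft], w[1:t_half]))  # center wavelet at lag 0
    conv <- fft(X * Conj(W), inverse = TRUE) / nfft
    pow[fi, ] <- Mod(conv[seq_len(n)])^2
  }
  pow
}

#' Morlet time-frequency decomposition of an epoch set
#'
#' Convolves each trial with complex Morlet wavelets (default 5 cycles) on
#' a 4-30 Hz grid in 0.5 Hz steps, resamples power onto a 5-ms time grid,
#' averages across trials (and optionally electrodes), and converts to
#' percent power change relative to the pre-cue baseline window
#' \[-1.25, -0.25\] s.
#'
#' @param ep an `epoch_set`.
#' @param freqs frequency grid in Hz.
#' @param time_step output time resolution in seconds (default 0.005).
#' @param baseline baseline window in seconds (default c(-1.25, -0.25)).
#' @param n_cycles Morlet width in cycles (default 5).
#' @param average_electrodes average power across channels before
#'   baselining (default TRUE, as used for the cluster statistics).
#' @return A `tfr_result`: list with `power` (freq x time matrix, percent
#'   change), `freqs`, `times`, `baseline`, `n_trials`, `condition`.
#' @export
morlet_tfr <- function(ep, freqs = seq(4, 30, by = 0.5), time_step = 0.005,
                       baseline = c(-1.25, -0.25), n_cycles = 5,
                       average_electrodes = TRUE) {
  stopifnot(inherits(ep, "epoch_set"))
  if (ep$kept < 1) stop("epoch set is empty after rejection")
  fs <- ep$srate
  out_times <- seq(min(ep$times), max(ep$times), by = time_step)
  out_idx <- round((out_times - min(ep$times)) * fs) + 1L
  out_idx <- pmin(out_idx, dim(ep$data)[3])
  n_ch <- dim(ep$data)[2]
  acc <- matrix(0, length(freqs), length(out_idx))
  per_channel <- vector("list", if (average_electrodes) 0 else n_ch)
  for (ch in seq_len(n_ch)) {
    acc_ch <- matrix(0, length(freqs), length(out_idx))
    for (tr in seq_len(dim(ep$data)[1])) {
      p <- morlet_power(ep$data[tr, ch, ], fs, freqs, n_cycles)
      acc_ch <- acc_ch + p[, out_idx]
    }
    acc_ch <- acc_ch / dim(ep$data)[1]
    if (average_electrodes) acc <- acc + acc_ch / n_ch
    else per_channel[[ch]] <- acc_ch
  }
  pct <- function(m) {
    bl <- out_times >= baseline[1] & out_times <= baseline[2]
    base <- rowMeans(m[, bl, drop = FALSE])
    100 * (m - base) / base
  }
  power <- if (average_electrodes) pct(acc) else lapply(per_channel, pct)
  structure(list(power = power, freqs = freqs, times = out_times,
                 baseline = baseline, n_trials = dim(ep$data)[1],
                 condition = ep$condition,
                 average_electrodes = average_electrodes),
            class = "tfr_result")
}

#' @export
print.tfr_result <- function(x, ...) {
  cat(sprintf("tfr_result (%s): %g-%g Hz x [%.2g, %.2g] s, %d trials, %% change vs [%g, %g] s\n",
              x$condition, min(x$freqs), max(x$freqs), min(x$times),
              max(x$times), x$n_trials, x$baseline[1], x$baseline[2]))
  invisible(x)
}

#' Cue-locked event-related potential
#'
#' High-pass filters the trial average at 0.5 Hz (zero-phase) and
#' baseline-corrects each channel to its mean over \[-200, 0\] ms.
#'
#' @param ep an `epoch_set`.
#' @param highpass high-pass cutoff in Hz (default 0.5).
#' @param baseline baseline window in seconds (default c(-0.2, 0)).
#' @return channel x time matrix of the ERP, with attribute `times`.
#' @export
erp <- function(ep, highpass = 0.5, baseline = c(-0.2, 0)) {
  stopifnot(inherits(ep, "epoch_set"))
  avg <- apply(ep$data, c(2, 3), mean)
  avg <- avg - rowMeans(avg)  # demean first: avoids filtfilt edge transients
  bf <- signal::butter(2, highpass / (ep$srate / 2), type = "high")
  avg <- t(apply(avg, 1, function(ch) as.numeric(signal::filtfilt(bf, ch))))
  bl <- ep$times >= baseline[1] & ep$times <= baseline[2]
  avg <- avg - rowMeans(avg[, bl, drop = FALSE])
  rownames(avg) <- ep$channels
  attr(avg, "times") <- ep$times
  avg
}

# label 4-connected clusters in a logical matrix; returns integer labels
label_clusters <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  cur <- 0L
  idx <- which(mask)
  for (start in idx) {
    if (lab[start] != 0L) next
    cur <- cur + 1L
    queue <- start
    lab[start] <- cur
    while (length(queue)) {
      p <- queue[[length(queue)]]
      queue <- queue[-length(queue)]
      r <- ((p - 1L) %% nr) + 1L
      cl <- ((p - 1L) %/% nr) + 1L
      nb <- c(if (r > 1L) p - 1L, if (r < nr) p + 1L,
              if (cl > 1L) p - nr, if (cl < nc) p + nr)
      nb <- nb[mask[nb] & lab[nb] == 0L]
      lab[nb] <- cur
      queue <- c(queue, nb)
    }
  }
  lab
}

# t statistics over participants for all grid points, for arbitrary sign
# flips: sum of squares is flip-invariant, only the mean changes
flip_t <- function(X, signs) {
  n <- nrow(X)
  m <- as.numeric(signs %*% X) / n
  ss <- colSums(X^2)
  v <- (ss - n * m^2) / (n - 1)
  m / sqrt(v / n)
}

#' Cluster-size permutation test on time-frequency difference maps
#'
#' Pointwise one-sample t-tests across participants (two-sided at
#' `alpha_form`) define candidate clusters of contiguous suprathreshold
#' points (4-connectivity, same sign). The null distribution of the
#' maximum cluster size is built by randomly flipping the sign of each
#' participant's map; each candidate's corrected p is the exceedance
#' frequency of its size in that null. With `exhaustive = TRUE` all `2^n`
#' sign patterns are enumerated (exact test; feasible for small n).
#'
#' @param maps list of per-participant freq x time matrices (e.g. TFR
#'   difference maps, target minus sham).
#' @param alpha_form cluster-forming pointwise alpha (default 0.01,
#'   two-sided).
#' @param n_perm number of sign-flip permutations (default 1000).
#' @param alpha_cluster cluster-level significance level (default 0.05).
#' @param seed RNG seed.
#' @param exhaustive enumerate all sign patterns instead of sampling.
#' @param freqs,times optional axes used to report cluster spans.
#' @return A `cluster_result`: list with `clusters` (data.frame: id, sign,
#'   size, p, and time/frequency spans when axes are given), `t_map`,
#'   `threshold`, `null_max` (null distribution of max cluster size),
#'   `alpha_form`, `alpha_cluster`, `n_perm`.
#' @export
cluster_permutation <- function(maps, alpha_form = 0.01, n_perm = 1000,
                                alpha_cluster = 0.05, seed = NULL,
                                exhaustive = FALSE, freqs = NULL,
                                times = NULL) {
  if (length(maps) < 2) stop("need at least 2 participants")
  if (!exhaustive && n_perm < 1) stop("n_perm must be >= 1")
  if (!is.null(seed)) set.seed(as.integer(seed))
  dm <- dim(maps[[1]])
  stopifnot(all(vapply(maps, function(m) all(dim(m) == dm), TRUE)))
  n <- length(maps)
  X <- t(vapply(maps, as.numeric, numeric(prod(dm))))
  tcrit <- qt(1 - alpha_form / 2, df = n - 1)
  tobs <- flip_t(X, matrix(1, 1, n))
  tmap <- matrix(tobs, dm[1], dm[2])

  cluster_sizes <- function(tv) {
    tv[!is.finite(tv)] <- 0  # zero-variance points carry no evidence
    tm <- matrix(tv, dm[1], dm[2])
    sizes <- c(); signs <- c(); labs <- list()
    for (sgn in c(1, -1)) {
      mask <- if (sgn > 0) tm > tcrit else tm < -tcrit
      if (!any(mask)) next
      lab <- label_clusters(mask)
      cs <- tabulate(lab[lab > 0])
      sizes <- c(sizes, cs)
      signs <- c(signs, rep(sgn, length(cs)))
      labs[[as.character(sgn)]] <- lab
    }
    list(sizes = sizes, signs = signs, labs = labs)
  }
  obs <- cluster_sizes(tobs)

  signs_mat <- if (exhaustive) {
    as.matrix(expand.grid(rep(list(c(1, -1)), n)))
  } else {
    matrix(sample(c(1, -1), n_perm * n, replace = TRUE), ncol = n)
  }
  T_all <- signs_mat %*% X / n
  ss <- colSums(X^2)
  null_max <- vapply(seq_len(nrow(signs_mat)), function(i) {
    m <- T_all[i, ]
    v <- (ss - n * m^2) / (n - 1)
    tv <- m / sqrt(v / n)
    cs <- cluster_sizes(tv)
    if (length(cs$sizes)) max(cs$sizes) else 0L
  }, 0)

  p_of <- function(sz) {
    if (exhaustive) mean(null_max >= sz)
    else (1 + sum(null_max >= sz)) / (length(null_max) + 1)
  }
  clusters <- if (length(obs$sizes)) {
    df <- data.frame(id = seq_along(obs$sizes), sign = obs$signs,
                     size = obs$sizes,
                     p = vapply(obs$sizes, p_of, 0))
    if (!is.null(freqs) || !is.null(times)) {
      spans <- lapply(seq_len(nrow(df)), function(k) {
        lab <- obs$labs[[as.character(df$sign[k])]]
        # this cluster's label id = its rank among clusters of the same sign
        ids_this_sign <- which(obs$signs == df$sign[k])
        rank_within <- which(ids_this_sign == df$id[k])
        cells <- which(lab == rank_within, arr.ind = TRUE)
        c(fmin = if (is.null(freqs)) NA else min(freqs[cells[, 1]]),
          fmax = if (is.null(freqs)) NA else max(freqs[cells[, 1]]),
          tmin = if (is.null(times)) NA else min(times[cells[, 2]]),
          tmax = if (is.null(times)) NA else max(times[cells[, 2]]))
      })
      df <- cbind(df, do.call(rbind, spans))
    }
    df
  } else data.frame(id = integer(0), sign = numeric(0), size = integer(0),
                    p = numeric(0))
  structure(list(clusters = clusters, t_map = tmap, threshold = tcrit,
                 null_max = null_max, alpha_form = alpha_form,
                 alpha_cluster = alpha_cluster,
                 n_perm = nrow(signs_mat),
                 significant = clusters[clusters$p <= alpha_cluster, ,
                                        drop = FALSE]),
            class = "cluster_result")
}

#' @export
print.cluster_result <- function(x, ...) {
  cat(sprintf("cluster permutation: %d candidate cluster(s), %d significant at p <= %.2f (n_perm = %d)\n",
              nrow(x$clusters), nrow(x$significant), x$alpha_cluster,
              x$n_perm))
  if (nrow(x$clusters)) print(x$clusters)
  invisible(x)
}
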