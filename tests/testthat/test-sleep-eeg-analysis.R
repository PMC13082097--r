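test_that("preprocessing yields 256 Hz mastoid-referenced band-passed data", {
  h <- fixed_hypnogram(rep("N2", 4))
  rec <- synthesize_eeg(h, synth_params(seed = 2))
  tt <- (seq_len(nrow(rec$signals)) - 1) / rec$srate
  rec$signals[, "Fz"] <- rec$signals[, "Fz"] + 40 * sin(2 * pi * 50 * tt) + 25
  pre <- preprocess(rec)
  expect_equal(pre$srate, 256)
  expect_false(any(c("M1", "M2") %in% pre$channels))
  # 50 Hz line component attenuated by >= 20 dB
  spec_amp <- function(x, fs, f0) {
    n <- length(x)
    i <- round(f0 * n / fs) + 1
    max(Mod(fft(x))[(i - 2):(i + 2)])
  }
  # compare against the same sinusoid amplitude measured pre-filter
  raw50 <- spec_amp(rec$signals[, "Fz"], rec$srate, 50) / nrow(rec$signals)
  out50 <- spec_amp(pre$signals[, "Fz"], pre$srate, 50) / nrow(pre$signals)
  expect_lt(out50 / raw50, 10^(-20 / 20))
  # DC offset removed by the 0.3 Hz high-pass edge
  expect_lt(abs(mean(pre$signals[, "Fz"])), 1)
  # missing mastoids: referencing skipped with a warning, still filtered
  rec2 <- rec
  rec2$signals <- rec2$signals[, c("Fz", "Cz")]
  rec2$channels <- c("Fz", "Cz")
  expect_warning(preprocess(rec2), "mastoid")
})

test_that("epoching honors the window, edges, and artifact screen", {
  h <- fixed_hypnogram(rep("N2", 10))
  rec <- synthesize_eeg(h, synth_params(so_rate = 0, spindle_rate = 0,
                                        so_rate_n2 = 0, spindle_rate_n3 = 0,
                                        seed = 3))
  pre <- preprocess(rec)
  onsets <- c(1, seq(10, 280, by = 10))  # first cue too close to the edge
  log <- structure(data.frame(kind = "target", onset = onsets,
                              stage = "N2", amplitude = 40),
                   class = c("cue_log", "data.frame"))
  eps <- epoch_around_cues(pre, log)
  ep <- eps$target
  expect_equal(dim(ep$data)[3], 6 * 256)
  expect_equal(ep$edge_dropped, 1)
  expect_equal(ep$kept + ep$rejected + ep$edge_dropped, length(onsets))
  # inject a 500 uV artifact into one trial's window and re-epoch
  art <- pre
  i0 <- round((100 - 1) * 256)
  art$signals[i0:(i0 + 256), "Fz"] <- 500
  eps2 <- epoch_around_cues(art, log)
  expect_gte(eps2$target$rejected, 1)
  expect_true(eps2$target$reject_mask[which(onsets == 100) - 1])
})

test_that("Morlet power peaks at an injected tone and matches an FFT oracle", {
  fs <- 256
  times <- seq(-3, 3 - 1 / fs, by = 1 / fs)
  post <- times > 0.5 & times < 1.5
  set.seed(8)
  mat <- t(replicate(5, {
    x <- rnorm(length(times), sd = 0.5)
    x[post] <- x[post] + 6 * sin(2 * pi * 10 * times[post])
    x
  }))
  ep <- toy_epoch_set(mat, fs)
  tf <- morlet_tfr(ep)
  expect_equal(length(tf$freqs), (30 - 4) / 0.5 + 1)
  expect_equal(range(tf$freqs), c(4, 30))
  win <- tf$times > 0.5 & tf$times < 1.5
  peak_freq <- tf$freqs[which.max(rowMeans(tf$power[, win]))]
  # brute-force oracle: periodogram of the post-cue window
  spec <- Mod(fft(mat[1, post]))^2
  fgrid <- (seq_along(spec) - 1) * fs / sum(post)
  oracle_freq <- fgrid[fgrid >= 4 & fgrid <= 30][
    which.max(spec[fgrid >= 4 & fgrid <= 30])]
  # both locate the tone within one wavelet bin (5-cycle wavelets have
  # ~f/5 bandwidth, so the argmax can sit one 0.5 Hz bin off)
  expect_lte(abs(peak_freq - 10), 0.5)
  expect_lte(abs(oracle_freq - 10), 0.5)
  # stationary signal: percent change about zero where its power lives
  mat0 <- t(replicate(4, 5 * sin(2 * pi * 7 * times)))
  tf0 <- morlet_tfr(toy_epoch_set(mat0, fs))
  mid <- tf0$times > -1 & tf0$times < 2
  near7 <- abs(tf0$freqs - 7) <= 2
  expect_lt(max(abs(tf0$power[near7, mid])), 1e-6)
})

test_that("electrode averaging happens on power before baselining", {
  fs <- 256
  times <- seq(-3, 3 - 1 / fs, by = 1 / fs)
  set.seed(9)
  arr <- array(rnorm(3 * 2 * length(times)), c(3, 2, length(times)))
  ep <- structure(list(data = arr, times = times, srate = fs,
                       condition = "toy", channels = c("Fz", "Cz"),
                       kept = 3, rejected = 0L, edge_dropped = 0L,
                       reject_mask = rep(FALSE, 3)),
                  class = "epoch_set")
  tf <- morlet_tfr(ep, freqs = c(6, 10, 14))
  # oracle: per-channel trial-averaged raw power, averaged across
  # channels, then percent change
  out_times <- tf$times
  out_idx <- round((out_times - min(times)) * fs) + 1
  acc <- 0
  for (ch in 1:2) {
    acc_ch <- 0
    for (tr in 1:3)
      acc_ch <- acc_ch + tmrstruct:::morlet_power(arr[tr, ch, ], fs,
                                                  c(6, 10, 14), 5)[, out_idx]
    acc <- acc + acc_ch / 3 / 2
  }
  bl <- out_times >= -1.25 & out_times <= -0.25
  expected <- 100 * (acc - rowMeans(acc[, bl])) / rowMeans(acc[, bl])
  expect_equal(tf$power, expected, tolerance = 1e-10)
})

test_that("ERPs are high-passed, baselined, and show cue-locked deflections", {
  fs <- 256
  times <- seq(-3, 3 - 1 / fs, by = 1 / fs)
  # constant signal: identically zero after high-pass and baseline
  epc <- toy_epoch_set(matrix(7, 4, length(times)), fs)
  e0 <- erp(epc)
  expect_lt(max(abs(e0)), 1e-6)
  # SO-locked deflection visible in target, absent in sham
  defl <- ifelse(times > 0 & times < 0.5, 10 * sin(pi * times / 0.5), 0)
  set.seed(10)
  target <- toy_epoch_set(t(replicate(6, defl + rnorm(length(times)))), fs)
  sham <- toy_epoch_set(t(replicate(6, rnorm(length(times)))), fs)
  et <- erp(target); es <- erp(sham)
  tt <- attr(et, "times")
  blm <- function(e) mean(e[, tt >= -0.2 & tt <= 0])
  expect_lt(abs(blm(et)), 0.2)
  win <- tt > 0.1 & tt < 0.4
  expect_gt(max(et[, win]), 5)
  expect_lt(max(abs(es[, win])), 3)
})

test_that("cluster permutation matches the exhaustive sign-flip oracle", {
  set.seed(11)
  maps <- lapply(1:6, function(i) {
    m <- matrix(rnorm(15 * 15), 15, 15)
    m[4:7, 4:7] <- m[4:7, 4:7] + 2.2
    m
  })
  ex <- cluster_permutation(maps, exhaustive = TRUE)
  expect_equal(ex$n_perm, 2^6)
  ra <- cluster_permutation(maps, n_perm = 1000, seed = 12)
  # corrected p of the big cluster agrees within Monte-Carlo error
  big_ex <- ex$clusters[which.max(ex$clusters$size), ]
  big_ra <- ra$clusters[which.max(ra$clusters$size), ]
  expect_equal(big_ex$size, big_ra$size)
  expect_lt(abs(big_ex$p - big_ra$p), 0.05)
  # independent oracle: enumerate sign patterns directly
  X <- t(vapply(maps, as.numeric, numeric(225)))
  n <- 6
  tcrit <- qt(1 - 0.01 / 2, n - 1)
  max_size <- function(signs) {
    Xs <- X * signs
    m <- colMeans(Xs); s <- apply(Xs, 2, sd)
    tv <- m / (s / sqrt(n))
    mx <- 0
    for (sgn in c(1, -1)) {
      mask <- matrix(if (sgn > 0) tv > tcrit else tv < -tcrit, 15, 15)
      if (any(mask)) {
        lab <- tmrstruct:::label_clusters(mask)
        mx <- max(mx, max(tabulate(lab[lab > 0])))
      }
    }
    mx
  }
  grid <- as.matrix(expand.grid(rep(list(c(1, -1)), n)))
  null_oracle <- apply(grid, 1, max_size)
  p_oracle <- mean(null_oracle >= big_ex$size)
  expect_equal(big_ex$p, p_oracle, tolerance = 1e-12)
})

test_that("injected group-level power bumps produce a covering cluster", {
  set.seed(13)
  freqs <- seq(4, 30, by = 2)
  times <- seq(0, 2, by = 0.05)
  maps <- lapply(1:10, function(i) {
    m <- matrix(rnorm(length(freqs) * length(times)),
                length(freqs), length(times))
    m[freqs >= 6 & freqs <= 12, times >= 0.5 & times <= 1.0] <-
      m[freqs >= 6 & freqs <= 12, times >= 0.5 & times <= 1.0] + 1.8
    m
  })
  cr <- cluster_permutation(maps, n_perm = 500, seed = 14,
                            freqs = freqs, times = times)
  sig <- cr$significant
  expect_gte(nrow(sig), 1)
  top <- sig[which.max(sig$size), ]
  expect_lte(top$fmin, 8)
  expect_gte(top$fmax, 10)
  expect_lte(top$tmin, 0.7)
  expect_gte(top$tmax, 0.8)
  # all-zero maps yield no candidate clusters
  cz <- cluster_permutation(lapply(1:5, function(i) matrix(0, 6, 6)),
                            n_perm = 20, seed = 1)
  expect_equal(nrow(cz$clusters), 0)
})
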