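# shared fixtures, all generated in code

fixed_hypnogram <- function(stages, n_each = 1) {
  structure(factor(rep(stages, each = n_each),
                   levels = c("W", "N1", "N2", "N3", "REM")),
            epoch_length = 30,
            duration_min = length(stages) * n_each / 2,
            class = c("hypnogram", "factor"))
}

# brute-force exemplar oracle: test all C(8,3) = 56 peripheral triplets
# against the graph's co-occurrence rule
oracle_exemplars <- function(g) {
  trips <- utils::combn(g$peripheral_ids, 3, simplify = FALSE)
  ok <- Filter(function(tr) {
    if (g$kind == "modular") {
      comm <- list(3:6, 7:10)
      any(vapply(comm, function(cm) all(tr %in% cm), TRUE))
    } else {
      ring <- 3:10
      pos <- sort(match(tr, ring)) - 1L
      circ_ok <- function(p) {
        d <- sort(p)
        spans <- c(diff(d), 8 - (d[3] - d[1]))
        # consecutive iff they occupy a window of 3 adjacent ring slots
        any(vapply(0:7, function(s) all(((s + 0:2) %% 8) %in% p), TRUE))
      }
      circ_ok(pos)
    }
  }, trips)
  lapply(ok, function(tr) sort(c(g$core_ids, tr)))
}

# quick epoch_set built from a trials x time matrix on one channel
toy_epoch_set <- function(mat, fs = 256, t0 = -3) {
  arr <- array(mat, dim = c(nrow(mat), 1, ncol(mat)))
  times <- t0 + (seq_len(ncol(mat)) - 1) / fs
  structure(list(data = arr, times = times, srate = fs,
                 condition = "toy", channels = "Fz", kept = nrow(mat),
                 rejected = 0L, edge_dropped = 0L,
                 reject_mask = rep(FALSE, nrow(mat))),
            class = "epoch_set")
}

# small z-scored RDM from a noise + signal mixture (for group tests)
noisy_rdm <- function(true, weight, seed, n = NULL) {
  set.seed(seed)
  tm <- tmrstruct:::rdm_mat(true)
  k <- nrow(tm)
  v <- tmrstruct:::zscore(tm[upper.tri(tm)]) * weight +
    rnorm(k * (k - 1) / 2)
  out <- matrix(0, k, k)
  out[upper.tri(out)] <- tmrstruct:::zscore(v)
  feature_rdm(out + t(out), zscored = TRUE)
}
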