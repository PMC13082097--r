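test_that("rdm_from_coords computes z-scored Euclidean dissimilarities", {
  # unit-spaced collinear points: distance(i, j) = |i - j| before z-scoring
  coords <- cbind(0:10, rep(0, 11))
  r <- rdm_from_coords(coords)
  expect_equal(dim(r$mat), c(11, 11))
  expect_true(r$zscored)
  d_expected <- abs(outer(0:10, 0:10, "-"))
  v <- tmrstruct:::zscore(d_expected[upper.tri(d_expected)])
  expect_equal(r$mat[upper.tri(r$mat)], v, tolerance = 1e-12)
  # z-scored upper triangle: mean 0, sd 1
  ut <- r$mat[upper.tri(r$mat)]
  expect_lt(abs(mean(ut)), 1e-10)
  expect_lt(abs(sd(ut) - 1), 1e-10)
  # coincident coordinates flag a degenerate matrix
  r0 <- rdm_from_coords(matrix(0.3, 11, 2))
  expect_true(attr(r0, "degenerate"))
})

test_that("group test recovers perfect alignment and matches the exhaustive
           permutation oracle on small instances", {
  g <- build_graph("modular")
  tr <- true_rdm(g)
  # all participants identical to the truth: r = 1
  res <- suppressMessages(group_structure_test(list(tr, tr, tr), tr,
                                               n_perm = 50, n_boot = 50,
                                               seed = 1))
  expect_equal(res$group_r, 1)
  expect_true(res$bootstrap_ci[1] <= median(res$boot) &&
                median(res$boot) <= res$bootstrap_ci[2])

  # 6-feature toy: exact mode equals an independent exhaustive oracle
  set.seed(42)
  mk6 <- function(seed) {
    set.seed(seed)
    m <- matrix(0, 6, 6)
    m[upper.tri(m)] <- rnorm(15)
    feature_rdm(m + t(m), zscored = TRUE)
  }
  t6m <- matrix(0, 6, 6)
  t6m[upper.tri(t6m)] <- c(0, 1, 1, 1, 0, 1, 1, 1, 0, 1, 1, 1, 0, 1, 0)
  t6 <- feature_rdm(t6m + t(t6m))
  rdms6 <- lapply(1:4, mk6)
  res6 <- group_structure_test(rdms6, t6, exact = TRUE, n_boot = 10, seed = 2)
  expect_equal(res6$n_iterations, factorial(6))
  # oracle: enumerate permutations independently and correlate directly
  mean6 <- Reduce(`+`, lapply(rdms6, function(r) r$mat)) / 4
  perms <- tmrstruct:::all_permutations(6)
  oracle_null <- apply(perms, 1, function(p) {
    pm <- t6$mat[p, p]
    cor(pm[upper.tri(pm)], mean6[upper.tri(mean6)])
  })
  expect_equal(sort(res6$null), sort(oracle_null), tolerance = 1e-12)
  expect_equal(res6$null_threshold, unname(quantile(oracle_null, 0.95)),
               tolerance = 1e-12)
})

test_that("sampled permutation thresholds approach the exhaustive ones", {
  # 8-feature toy: 8! label permutations vs a 1000-sample null
  set.seed(3)
  m8 <- matrix(0, 8, 8)
  m8[upper.tri(m8)] <- rnorm(28)
  t8m <- matrix(0, 8, 8)
  t8m[upper.tri(t8m)] <- rep(c(0, 1), 14)
  rdms8 <- lapply(1:5, function(i) {
    mm <- matrix(0, 8, 8)
    mm[upper.tri(mm)] <- rnorm(28) + 0.5 * t8m[upper.tri(t8m)]
    feature_rdm(mm + t(mm), zscored = TRUE)
  })
  t8 <- feature_rdm(t8m + t(t8m))
  ex <- group_structure_test(rdms8, t8, exact = TRUE, n_boot = 10, seed = 5)
  sam <- group_structure_test(rdms8, t8, n_perm = 1000, n_boot = 10, seed = 6)
  expect_lt(abs(ex$null_threshold - sam$null_threshold), 0.08)
})

test_that("permutation null is invariant to affine rescaling of the truth", {
  g <- build_graph("lattice")
  tr <- true_rdm(g)
  rdms <- lapply(1:5, function(s) noisy_rdm(tr, 0.4, s))
  a <- group_structure_test(rdms, tr, n_perm = 200, n_boot = 10, seed = 7)
  scaled <- feature_rdm(2 * tr$mat, labels = tr$labels)
  b <- group_structure_test(rdms, scaled, n_perm = 200, n_boot = 10, seed = 7)
  expect_equal(a$null, b$null, tolerance = 1e-12)
  expect_equal(a$group_r, b$group_r, tolerance = 1e-12)
})

test_that("participant regression matches the closed-form OLS oracle", {
  # 4-feature toy with hand-computable normal equations
  set.seed(9)
  mk4 <- function(v) {
    m <- matrix(0, 4, 4); m[upper.tri(m)] <- v; m + t(m)
  }
  y <- c(0.2, -1.0, 0.5, 1.3, -0.4, 0.1)
  x1 <- c(0, 1, 0, 1, 1, 0)
  x2 <- c(0.3, 0.1, 0.9, 0.2, 0.8, 0.4)
  res <- participant_structure_regression(
    feature_rdm(mk4(y), zscored = TRUE),
    feature_rdm(mk4(x1)), feature_rdm(mk4(x2)))
  X <- cbind(1, tmrstruct:::zscore(x1), tmrstruct:::zscore(x2))
  beta_hat <- solve(t(X) %*% X, t(X) %*% y)
  expect_equal(res$intercept, beta_hat[1], tolerance = 1e-10)
  expect_equal(res$beta_structure, beta_hat[2], tolerance = 1e-10)
  expect_equal(res$beta_visual, beta_hat[3], tolerance = 1e-10)

  # structure-only participant: positive structure beta, visual beta ~ 0
  g <- build_graph("modular")
  tr <- true_rdm(g)
  tvec <- tmrstruct:::upper_tri_vec(tr$mat)
  set.seed(10)
  ortho <- rnorm(55)
  ortho <- ortho - tvec * sum(ortho * tvec) / sum(tvec^2)
  vm <- matrix(0, 11, 11); vm[upper.tri(vm)] <- ortho
  visual <- feature_rdm(vm + t(vm))
  zt <- matrix(0, 11, 11)
  zt[upper.tri(zt)] <- tmrstruct:::zscore(tvec)
  rdm <- feature_rdm(zt + t(zt), zscored = TRUE)
  r2 <- suppressWarnings(participant_structure_regression(rdm, tr, visual))
  expect_gt(r2$beta_structure, 0.9)
  expect_lt(abs(r2$beta_visual), 0.05)
  # collinear predictors are flagged
  r3 <- participant_structure_regression(rdm, tr, feature_rdm(2 * tr$mat))
  expect_true(r3$collinear)
  expect_true(is.na(r3$beta_structure))
})

test_that("selection accuracy scores 0-3 core hits out of three", {
  expect_equal(selection_accuracy(c(0, 1, 2), 0:2), 1)
  expect_equal(selection_accuracy(c(5, 6, 7), 0:2), 0)
  expect_equal(selection_accuracy(c(0, 6, 7), 0:2), 1 / 3)
  expect_error(selection_accuracy(c(0, 0, 1), 0:2), "distinct")
  # exhaustive uniform choice has mean 3/11
  combos <- utils::combn(0:10, 3)
  accs <- apply(combos, 2, selection_accuracy, core_ids = 0:2)
  expect_equal(mean(accs), 3 / 11)
})

test_that("condition models match hand-computed contrasts", {
  set.seed(12)
  outcome <- c(rnorm(30, 0.5), rnorm(30, 0.8))
  cond <- rep(c("base", "other"), each = 30)
  m <- condition_model(outcome, cond, baseline = "base", "linear")
  expect_equal(unname(m$coefficients[".conditionother", "estimate"]),
               mean(outcome[31:60]) - mean(outcome[1:30]),
               tolerance = 1e-12)
  # two equal-mean groups: contrast near zero
  set.seed(13)
  y2 <- rnorm(400)
  c2 <- rep(c("a", "b"), 200)
  m2 <- condition_model(y2, c2, baseline = "a", "linear")
  expect_lt(abs(m2$coefficients[".conditionb", "estimate"]), 0.3)
  expect_gt(m2$model_test$p, 0.01)
  # absent baseline level rejected
  expect_error(condition_model(y2, c2, baseline = "z", "linear"), "absent")
  # logistic accepts fractions of 3 and counts equivalently
  k <- rbinom(40, 3, 0.6)
  cc <- rep(c("a", "b"), 20)
  mk <- condition_model(k, cc, "a", "logistic")
  mf <- condition_model(k / 3, cc, "a", "logistic")
  expect_equal(mk$coefficients, mf$coefficients, tolerance = 1e-10)
})

test_that("bootstrap confidence intervals are calibrated under the null", {
  # cohorts with known population alignment r = 0 (pure-noise RDMs); the
  # percentile interval of the resample-and-average statistic should cover
  # zero at close to its nominal 95% rate. (Percentile intervals for a
  # correlation at these group sizes are known to be mildly
  # anticonservative; for population r > 0 the resampled means are
  # noisier than the sample mean, so the statistic is attenuation-biased
  # and percentile coverage degrades further - a property of the
  # resample-and-average procedure itself, exercised here only at r = 0.)
  g <- build_graph("modular")
  tr <- true_rdm(g)
  gen0 <- function(n, seed) {
    set.seed(seed)
    lapply(seq_len(n), function(i) {
      v <- tmrstruct:::zscore(rnorm(55))
      m <- matrix(0, 11, 11); m[upper.tri(m)] <- v
      feature_rdm(m + t(m), zscored = TRUE)
    })
  }
  covered <- vapply(1:500, function(rep) {
    res <- group_structure_test(gen0(12, rep * 7), tr, n_perm = 1,
                                n_boot = 400, seed = 20000 + rep)
    res$bootstrap_ci[1] <= 0 && 0 <= res$bootstrap_ci[2]
  }, TRUE)
  expect_gt(mean(covered), 0.88)
  expect_lt(mean(covered), 0.98)
})
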