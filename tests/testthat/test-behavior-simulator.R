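test_that("missing-feature responses follow the knowledge mixture", {
  g <- build_graph("modular")
  fa <- feature_assignment("sp1", 3)
  tl <- generate_trials(g, fa, seed = 2)
  # full structure knowledge: every peripheral trial correct
  kp1 <- knowledge_params(p_core = 1, k_struct = 1, seed = 1)
  acc1 <- simulate_missing_feature(tl, kp1)
  expect_true(all(acc1[tl$trial_type != "catch"] == 1))
  # zero structure knowledge: peripheral accuracy at two-alternative chance
  kp0 <- knowledge_params(p_core = 0.5, k_struct = 0, seed = 1)
  peri_acc <- unlist(lapply(1:100, function(s) {
    acc <- simulate_missing_feature(tl, kp0, seed = s)
    acc[tl$trial_type == "peripheral"]
  }))
  se <- sqrt(0.25 / length(peri_acc))
  expect_lt(abs(mean(peri_acc) - 0.5), 3 * se)
  # intermediate knowledge: 0.5 + 0.5 * 0.5 = 75%
  kph <- knowledge_params(k_struct = 0.5)
  peri_acc2 <- unlist(lapply(1:200, function(s) {
    acc <- simulate_missing_feature(tl, kph, seed = 1000 + s)
    acc[tl$trial_type == "peripheral"]
  }))
  se2 <- sqrt(0.75 * 0.25 / length(peri_acc2))
  expect_lt(abs(mean(peri_acc2) - 0.75), 3 * se2)
})

test_that("feature selection respects the core-knowledge parameter", {
  kp1 <- knowledge_params(p_core = 1)
  expect_equal(selection_accuracy(
    simulate_selection(0:10, kp1, core_ids = 0:2, seed = 4), 0:2), 1)
  # p_core = 0 is uniform 3-of-11: hypergeometric mean 3 * 3/11,
  # oracle = exhaustive enumeration of all C(11,3) outcomes
  combos <- utils::combn(0:10, 3)
  oracle_mean <- mean(apply(combos, 2, function(ch) mean(ch %in% 0:2)))
  expect_equal(oracle_mean, 3 / 11)
  kp0 <- knowledge_params(p_core = 0)
  sims <- vapply(1:4000, function(s)
    selection_accuracy(simulate_selection(0:10, kp0, core_ids = 0:2,
                                          seed = s), 0:2), 0)
  se <- sd(sims) / sqrt(length(sims))
  expect_lt(abs(mean(sims) - oracle_mean), 3 * se)
  # always 3 distinct choices
  expect_true(all(vapply(1:50, function(s)
    !anyDuplicated(simulate_selection(0:10, knowledge_params(p_core = 0.6),
                                      core_ids = 0:2, seed = s)), TRUE)))
})

test_that("arrangement embedding blends structure, visual and noise", {
  g <- build_graph("modular")
  tr <- true_rdm(g)
  vis <- make_visual_rdm(11, seed = 8)
  # pure structure, low noise: distances recover the true RDM
  kp <- knowledge_params(p_core = 1, k_struct = 1,
                         arrangement_noise = 0.01, visual_weight = 0)
  co <- simulate_arrangement(tr, vis, kp, seed = 2)
  expect_true(all(sqrt(rowSums(co^2)) <= 1))
  r <- tmrstruct:::rdm_correlation(rdm_from_coords(co), tr)
  expect_gt(r, 0.9)
  # pure noise: correlation centered on zero across seeds
  kp0 <- knowledge_params(p_core = 0, k_struct = 0,
                          arrangement_noise = 0.6, visual_weight = 0)
  rs <- vapply(1:40, function(s) tmrstruct:::rdm_correlation(
    rdm_from_coords(simulate_arrangement(tr, vis, kp0, seed = s)), tr), 0)
  expect_lt(abs(mean(rs)), 3 * sd(rs) / sqrt(length(rs)) + 0.05)
  # visual-dominated: correlation with the visual RDM wins
  kpv <- knowledge_params(p_core = 0, k_struct = 0,
                          arrangement_noise = 0.05, visual_weight = 1)
  cov <- simulate_arrangement(tr, vis, kpv, seed = 2)
  rv <- rdm_from_coords(cov)
  expect_gt(tmrstruct:::rdm_correlation(rv, vis),
            tmrstruct:::rdm_correlation(rv, tr))
})

test_that("cohort generation follows the design and is reproducible", {
  d <- experiment_design("exp2")
  expect_equal(sum(d$conditions$n), 92)
  expect_equal(d$conditions$n, c(26L, 23L, 20L, 23L))
  # small cohort for speed: same condition layout, fewer participants
  d$conditions$n <- c(3L, 2L, 2L, 3L)
  co <- generate_cohort(d, master_seed = 11)
  expect_equal(nrow(co$participants), 10)
  expect_equal(sort(unique(co$participants$condition)),
               sort(d$conditions$condition))
  co2 <- generate_cohort(d, master_seed = 11)
  expect_identical(co$participants, co2$participants)
  expect_identical(co$arrangement, co2$arrangement)
  # zero participants: empty cohort
  d0 <- d; d0$conditions$n <- rep(0L, 4)
  co0 <- generate_cohort(d0, master_seed = 1)
  expect_equal(nrow(co0$participants), 0)
  # unknown condition rejected
  bad <- d
  bad$conditions$condition[1] <- "hypnopedia"
  expect_error(generate_cohort(bad, master_seed = 1), "unknown condition")
})

test_that("structure betas track the structure-knowledge parameter", {
  g <- build_graph("modular")
  tr <- true_rdm(g)
  vis <- make_visual_rdm(11, seed = 9)
  mean_beta <- function(k) {
    betas <- vapply(1:25, function(s) {
      kp <- knowledge_params(k_struct = k, arrangement_noise = 0.5,
                             visual_weight = 0.3)
      co <- simulate_arrangement(tr, vis, kp, seed = 100 * k + s)
      participant_structure_regression(rdm_from_coords(co), tr,
                                       vis)$beta_structure
    }, 0)
    mean(betas)
  }
  m <- vapply(c(0, 0.3, 0.6), mean_beta, 0)
  expect_true(all(diff(m) > 0))
})

test_that("cohorts export to CSV with a participants manifest", {
  d <- experiment_design("exp1")
  d$conditions$n <- c(3L, 3L)
  co <- generate_cohort(d, master_seed = 5)
  dir <- withr::local_tempdir()
  files <- write_cohort_csv(co, dir)
  expect_true(all(file.exists(files)))
  p <- read.csv(file.path(dir, "participants.csv"))
  expect_equal(nrow(p), 6)
  arr <- read.csv(file.path(dir, "arrangement.csv"))
  expect_equal(nrow(arr), 6 * 11)
})
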