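#' Knowledge parameters for the behavioral simulator
#'
#' The simulator models a participant as a mixture of knowledge and
#' guessing. `p_core` is the probability of knowing which features are
#' core; `k_struct` in \[0, 1\] is the weight of the true peripheral
#' structure in behavior (0 = chance, 1 = perfect); `arrangement_noise`
#' and `visual_weight` control the feature-arrangement task, where the
#' arranged geometry reflects a blend of the true structure, a nuisance
#' visual-similarity matrix, and noise.
#'
#' @param p_core probability of knowing core status, in \[0, 1\].
#' @param k_struct structure-knowledge weight, in \[0, 1\].
#' @param arrangement_noise sd of the noise added to the blended
#'   dissimilarities before embedding (> 0).
#' @param visual_weight weight of the visual nuisance RDM in arrangement.
#' @param p_catch probability of answering a catch trial correctly.
#' @param seed optional RNG seed.
#' @return A `knowledge_params` list.
#' @export
knowledge_params <- function(p_core = 0.5, k_struct = 0.2,
                             arrangement_noise = 0.6, visual_weight = 0.3,
                             p_catch = 0.95, seed = NULL) {
  stopifnot(p_core >= 0, p_core <= 1, k_struct >= 0, k_struct <= 1,
            arrangement_noise > 0, visual_weight >= 0,
            p_catch >= 0, p_catch <= 1)
  structure(list(p_core = p_core, k_struct = k_struct,
                 arrangement_noise = arrangement_noise,
                 visual_weight = visual_weight, p_catch = p_catch,
                 seed = seed),
            class = "knowledge_params")
}

#' Simulate missing-feature task responses
#'
#' Each trial is answered correctly with probability `0.5 + 0.5 * k`,
#' where `k` is `p_core` on core trials and `k_struct` on peripheral
#' trials (two-alternative chance is 50%). Catch trials are answered
#' correctly with probability `p_catch`.
#'
#' @param trials a `trial_list`.
#' @param kp a `knowledge_params`.
#' @param seed optional RNG seed (falls back to `kp$seed`).
#' @return Integer vector of per-trial accuracy (1 correct / 0 incorrect),
#'   scored on the initial response.
#' @export
simulate_missing_feature <- function(trials, kp, seed = kp$seed) {
  if (!is.null(seed)) set.seed(as.integer(seed))
  p <- ifelse(trials$trial_type == "core", 0.5 + 0.5 * kp$p_core,
         ifelse(trials$trial_type == "peripheral", 0.5 + 0.5 * kp$k_struct,
                kp$p_catch))
  rbinom(nrow(trials), 1, p)
}

#' Simulate the feature selection task (3 of 11)
#'
#' Three features are chosen sequentially without replacement. On each
#' pick, with probability `p_core` the participant picks an unchosen core
#' feature (if any remain); otherwise picks uniformly among all unchosen
#' features. With `p_core = 0` this is uniform 3-of-11 choice, whose
#' expected core hit rate is 3/11 (~27%).
#'
#' @param features the 11 candidate feature ids (first 3 treated as core
#'   when `core_ids` is missing).
#' @param kp a `knowledge_params`.
#' @param core_ids the core feature ids.
#' @param seed optional RNG seed.
#' @return Vector of 3 distinct chosen features.
#' @export
simulate_selection <- function(features, kp, core_ids = features[1:3],
                               seed = kp$seed) {
  stopifnot(length(features) >= 3)
  if (!is.null(seed)) set.seed(as.integer(seed))
  chosen <- c()
  for (i in 1:3) {
    rem <- setdiff(features, chosen)
    rem_core <- intersect(rem, core_ids)
    pick <- if (runif(1) < kp$p_core && length(rem_core) > 0)
      rem_core[sample.int(length(rem_core), 1)]
    else rem[sample.int(length(rem), 1)]
    chosen <- c(chosen, pick)
  }
  chosen
}

#' Synthesize a shared visual-dissimilarity nuisance matrix
#'
#' Random symmetric nonnegative matrix standing in for normative visual
#' arrangement data; shared across a simulated cohort.
#'
#' @param n_features number of features (default 11).
#' @param seed RNG seed.
#' @return A `feature_rdm` (not z-scored).
#' @export
make_visual_rdm <- function(n_features = 11, seed = 1) {
  set.seed(as.integer(seed))
  m <- matrix(0, n_features, n_features)
  m[upper.tri(m)] <- runif(n_features * (n_features - 1) / 2)
  m <- m + t(m)
  feature_rdm(m, labels = as.character(seq_len(n_features) - 1L))
}

#' Simulate the feature arrangement task
#'
#' Blends the true structure matrix, the visual nuisance matrix, and
#' Gaussian noise into a single dissimilarity matrix
#' (`k_struct * z(true) + visual_weight * z(visual) + noise`), embeds it in
#' the plane by classical (metric) multidimensional scaling, and rescales
#' the configuration into the unit circle "arena". If the blend is
#' degenerate (no variance), a jittered circular layout is returned and a
#' message logged.
#'
#' @param true ground-truth `feature_rdm`.
#' @param visual nuisance `feature_rdm` (or matrix).
#' @param kp a `knowledge_params`.
#' @param seed optional RNG seed.
#' @return 11 x 2 coordinate matrix (row names = feature labels), all rows
#'   inside the unit circle.
#' @export
simulate_arrangement <- function(true, visual, kp, seed = kp$seed) {
  if (!is.null(seed)) set.seed(as.integer(seed))
  tm <- rdm_mat(true); vm <- rdm_mat(visual)
  stopifnot(all(dim(tm) == dim(vm)))
  n <- nrow(tm)
  zt <- matrix(0, n, n); zv <- matrix(0, n, n)
  zt[upper.tri(zt)] <- zscore(upper_tri_vec(tm))
  zv[upper.tri(zv)] <- zscore(upper_tri_vec(vm))
  noise <- matrix(0, n, n)
  noise[upper.tri(noise)] <- rnorm(n * (n - 1) / 2, sd = kp$arrangement_noise)
  blend <- kp$k_struct * zt + kp$visual_weight * zv + noise
  blend <- blend + t(blend)
  # shift to a proper nonnegative dissimilarity
  off <- blend[upper.tri(blend) | lower.tri(blend)]
  if (sd(off) < 1e-12) {
    message("degenerate blended dissimilarity; using jittered circular layout")
    ang <- seq(0, 2 * pi, length.out = n + 1)[-1]
    coords <- 0.8 * cbind(cos(ang), sin(ang)) +
      matrix(rnorm(2 * n, sd = 0.05), n, 2)
  } else {
    blend <- blend - min(off)
    diag(blend) <- 0
    coords <- cmdscale(stats::as.dist(blend), k = 2)
    if (ncol(coords) < 2) coords <- cbind(coords, rnorm(n, sd = 1e-3))
  }
  r <- sqrt(rowSums(coords^2))
  coords <- coords / max(r) * 0.95
  rownames(coords) <- rownames(tm) %||% as.character(seq_len(n) - 1L)
  coords
}

#' Experiment design declarations
#'
#' Returns the condition layout of the two experiment designs: the
#' immediate-transfer design (`exp1`: incongruent N = 59, congruent
#' N = 48) and the 3-hour-break wake/nap design (`exp2`:
#' awake-incongruent N = 26, awake-congruent N = 23, sleep-incongruent
#' N = 20, sleep-congruent N = 23). The transfer category is always
#' modular; `phase1` lists each condition's earlier category structures.
#'
#' @param design `"exp1"` or `"exp2"`.
#' @param baseline optional baseline override (defaults to the design's
#'   incongruent condition).
#' @return An `experiment_design` list with `name`, `conditions`
#'   (data.frame: condition, n, sleep), `phase1` (list of structure
#'   vectors), `baseline`, `transfer_kind`.
#' @export
experiment_design <- function(design = c("exp2", "exp1"), baseline = NULL) {
  design <- match.arg(design)
  if (design == "exp1") {
    conditions <- data.frame(
      condition = c("incongruent", "congruent"),
      n = c(59L, 48L), sleep = c(FALSE, FALSE))
    phase1 <- list(incongruent = "lattice", congruent = "modular")
    baseline <- baseline %||% "incongruent"
  } else {
    conditions <- data.frame(
      condition = c("awake_incongruent", "awake_congruent",
                    "sleep_incongruent", "sleep_congruent"),
      n = c(26L, 23L, 20L, 23L),
      sleep = c(FALSE, FALSE, TRUE, TRUE))
    phase1 <- list(awake_incongruent = c("lattice", "lattice"),
                   awake_congruent = c("lattice", "modular"),
                   sleep_incongruent = c("lattice", "modular"),
                   sleep_congruent = c("lattice", "modular"))
    baseline <- baseline %||% "awake_incongruent"
  }
  structure(list(name = design, conditions = conditions, phase1 = phase1,
                 baseline = baseline, transfer_kind = "modular"),
            class = "experiment_design")
}

#' Default per-condition knowledge parameters
#'
#' Calibrated so that simulated group means on the transfer tasks emulate
#' the qualitative pattern of the study conditions: only the
#' sleep-congruent group carries substantial transfer-structure knowledge,
#' while all groups know core features well above chance.
#'
#' @param design an `experiment_design` (or its name).
#' @return Named list of `knowledge_params`, one per condition.
#' @export
default_condition_params <- function(design = "exp2") {
  if (inherits(design, "experiment_design")) design <- design$name
  if (design == "exp1") {
    list(incongruent = knowledge_params(p_core = 0.47, k_struct = 0.12),
         congruent = knowledge_params(p_core = 0.47, k_struct = 0.12))
  } else {
    list(awake_incongruent = knowledge_params(p_core = 0.47, k_struct = 0.02),
         awake_congruent = knowledge_params(p_core = 0.44, k_struct = 0.04),
         sleep_incongruent = knowledge_params(p_core = 0.47, k_struct = 0.03),
         sleep_congruent = knowledge_params(p_core = 0.72, k_struct = 0.25))
  }
}

#' Generate a simulated cohort for an experiment design
#'
#' Creates one `participant record` per subject: condition label, missing
#' feature accuracies for the earlier (phase-1) categories and the
#' transfer category, feature-selection choices and feature-arrangement
#' coordinates for the transfer category, plus the catch-trial exclusion
#' flag (participants with catch accuracy at or below 50% are excluded
#' from analysis, exercising the exclusion path).
#'
#' @param design an `experiment_design`.
#' @param params named list of per-condition `knowledge_params`
#'   (default [default_condition_params()]).
#' @param master_seed master RNG seed; every participant derives a child
#'   seed from it, so identical master seeds give identical cohorts.
#' @param cue_probability per-trial cue probability during phase-1
#'   learning.
#' @param visual_seed seed of the shared visual nuisance RDM.
#' @param params_by_participant optional list (length = cohort size) of
#'   `knowledge_params` overriding the condition defaults per participant
#'   (used by the pipeline to apply cue-dose-dependent knowledge).
#' @return A `cohort` list: `participants` (data.frame: id, condition,
#'   seed, catch_accuracy, excluded), `phase1_accuracy`,
#'   `transfer_accuracy` (vectors), `selection` (list of 3-vectors),
#'   `arrangement` (list of 11 x 2 matrices), `graphs`, `visual`,
#'   `true_transfer`, `design`, `params`.
#' @export
generate_cohort <- function(design = experiment_design("exp2"),
                            params = default_condition_params(design),
                            master_seed = 1, cue_probability = 1/3,
                            visual_seed = 99,
                            params_by_participant = NULL) {
  stopifnot(inherits(design, "experiment_design"))
  missing_p <- setdiff(design$conditions$condition, names(params))
  if (length(missing_p)) stop("unknown condition(s): ",
                              paste(missing_p, collapse = ", "))
  g_mod <- build_graph("modular"); g_lat <- build_graph("lattice")
  graphs <- list(modular = g_mod, lattice = g_lat)
  visual <- make_visual_rdm(11, seed = visual_seed)
  truth <- true_rdm(g_mod)

  n_total <- sum(design$conditions$n)
  ids <- sprintf("p%03d", seq_len(n_total))
  condition <- rep(design$conditions$condition, design$conditions$n)
  seeds <- vapply(seq_len(n_total), function(i) child_seed(master_seed, i), 0L)

  phase1_accuracy <- transfer_accuracy <- catch_accuracy <- numeric(n_total)
  selection <- vector("list", n_total)
  arrangement <- vector("list", n_total)

  for (i in seq_len(n_total)) {
    kp <- params_by_participant[[i]] %||% params[[condition[i]]]
    p1_kinds <- design$phase1[[condition[i]]]
    acc1 <- catch1 <- c()
    for (j in seq_along(p1_kinds)) {
      g <- graphs[[p1_kinds[j]]]
      fa <- feature_assignment(sprintf("sp%d", j), child_seed(seeds[i], j))
      tl <- generate_trials(g, fa, cue_probability,
                            seed = child_seed(seeds[i], 10 + j))
      acc <- simulate_missing_feature(tl, kp, seed = child_seed(seeds[i], 20 + j))
      acc1 <- c(acc1, mean(acc[tl$trial_type != "catch"]))
      catch1 <- c(catch1, mean(acc[tl$trial_type == "catch"]))
    }
    fa_t <- feature_assignment("transfer", child_seed(seeds[i], 3))
    tl_t <- generate_trials(graphs[[design$transfer_kind]], fa_t, 0,
                            seed = child_seed(seeds[i], 13))
    acc_t <- simulate_missing_feature(tl_t, kp, seed = child_seed(seeds[i], 23))
    phase1_accuracy[i] <- mean(acc1)
    transfer_accuracy[i] <- mean(acc_t[tl_t$trial_type != "catch"])
    catch_accuracy[i] <- mean(c(catch1, mean(acc_t[tl_t$trial_type == "catch"])))
    selection[[i]] <- simulate_selection(0:10, kp, core_ids = 0:2,
                                         seed = child_seed(seeds[i], 30))
    arrangement[[i]] <- simulate_arrangement(truth, visual, kp,
                                             seed = child_seed(seeds[i], 40))
  }
  participants <- data.frame(id = ids, condition = condition, seed = seeds,
                             catch_accuracy = catch_accuracy,
                             excluded = catch_accuracy <= 0.5)
  participants$exclusion_reason <-
    ifelse(participants$excluded, "catch accuracy <= 50%", "")
  structure(list(participants = participants,
                 phase1_accuracy = phase1_accuracy,
                 transfer_accuracy = transfer_accuracy,
                 selection = selection, arrangement = arrangement,
                 graphs = graphs, visual = visual, true_transfer = truth,
                 design = design, params = params,
                 master_seed = master_seed),
            class = "cohort")
}

#' @export
print.cohort <- function(x, ...) {
  cat(sprintf("cohort: %d participants (%d excluded), design %s\n",
              nrow(x$participants), sum(x$participants$excluded),
              x$design$name))
  print(table(x$participants$condition))
  invisible(x)
}

#' Write a cohort to CSV files plus a participants manifest
#'
#' @param cohort a `cohort`.
#' @param dir output directory (created if missing).
#' @return Invisibly, the vector of written file paths.
#' @export
write_cohort_csv <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- cohort$participants
  p$phase1_accuracy <- cohort$phase1_accuracy
  p$transfer_accuracy <- cohort$transfer_accuracy
  f1 <- file.path(dir, "participants.csv")
  write.csv(p, f1, row.names = FALSE)
  sel <- data.frame(id = rep(p$id, each = 3),
                    choice = unlist(cohort$selection))
  f2 <- file.path(dir, "selection.csv")
  write.csv(sel, f2, row.names = FALSE)
  arr <- do.call(rbind, lapply(seq_along(cohort$arrangement), function(i) {
    a <- cohort$arrangement[[i]]
    data.frame(id = p$id[i], feature = rownames(a), x = a[, 1], y = a[, 2])
  }))
  f3 <- file.path(dir, "arrangement.csv")
  write.csv(arr, f3, row.names = FALSE)
  invisible(c(f1, f2, f3))
}
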