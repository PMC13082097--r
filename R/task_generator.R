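#' Generate the missing-feature training trials for one category
#'
#' Builds the 102-trial training sequence for a category: 96 experimental
#' trials (48 core, 48 peripheral) plus 6 catch trials. On every trial an
#' exemplar is shown with one feature removed and two response options are
#' offered:
#'
#' * core trial: a core feature is missing; the incorrect option is a
#'   structure-consistent peripheral feature (one compatible with the shown
#'   exemplar's peripheral set), so only core-ness distinguishes the
#'   options.
#' * peripheral trial: a peripheral feature is missing; the correct option
#'   is a structure-consistent completion of the shown peripheral pair and
#'   the incorrect option is a structure-inconsistent peripheral feature.
#' * catch trial: the incorrect option is a never-seen catch feature.
#'
#' Each of the 8 exemplars contributes 6 core and 6 peripheral trials
#' (each missing feature used twice), trial order is randomized with catch
#' trials restricted to the second half (positions 52-102), and each trial
#' independently carries an auditory-cue flag with probability
#' `cue_probability`.
#'
#' @param g a `structure_graph`.
#' @param fa a `feature_assignment` for the same 11-node graph.
#' @param cue_probability per-trial probability that the category's
#'   auditory cue plays (default 1/3).
#' @param seed integer RNG seed.
#' @param category_id label recorded on the trial list.
#' @return A `trial_list`: data.frame with columns `index`, `trial_type`,
#'   `ex1`-`ex6` (exemplar node ids), `missing`, `opt_correct`,
#'   `opt_incorrect`, `cue` plus attributes `category_id`, `kind`,
#'   `counts`, `catch_ids`.
#' @export
generate_trials <- function(g, fa, cue_probability = 1/3, seed = 1,
                            category_id = fa$species_id) {
  validate_structure_graph(g)
  if (!inherits(fa, "feature_assignment") ||
      length(fa$node_to_feature) != length(g$node_ids))
    stop("feature assignment does not match the graph")
  stopifnot(cue_probability >= 0, cue_probability <= 1)
  set.seed(as.integer(seed))

  exemplars <- enumerate_exemplars(g)
  catch_ids <- seq_along(fa$catch_features) + 100L  # ids 101..106, never graph nodes

  # precompute option sets once per exemplar: the repetition loop below
  # only samples from them
  adjacent <- function(p, set) any(
    (g$peripheral_edges[, 1] == p & g$peripheral_edges[, 2] %in% set) |
      (g$peripheral_edges[, 2] == p & g$peripheral_edges[, 1] %in% set))
  opt_sets <- lapply(exemplars, function(ex) {
    peri <- setdiff(ex, g$core_ids)
    # core trials: incorrect option is a peripheral feature outside the
    # exemplar that co-occurs (shares an edge) with a shown peripheral
    core_elig <- Filter(function(p) adjacent(p, peri),
                        setdiff(g$peripheral_ids, peri))
    per_miss <- lapply(setNames(peri, peri), function(miss) {
      shown <- setdiff(peri, miss)
      completions <- Filter(function(p) is_consistent_triple(g, c(shown, p)),
                            setdiff(g$peripheral_ids, shown))
      list(completions = completions,
           inconsistent = setdiff(setdiff(g$peripheral_ids, peri),
                                  completions))
    })
    list(peri = peri, core_elig = unlist(core_elig), per_miss = per_miss)
  })

  core_rows <- list(); peri_rows <- list()
  for (e in seq_along(exemplars)) {
    ex <- exemplars[[e]]
    os <- opt_sets[[e]]
    for (rep_i in 1:2) {
      for (miss in g$core_ids) {
        core_rows[[length(core_rows) + 1L]] <-
          c(ex, miss, miss, resample(os$core_elig), 0L)
      }
      for (miss in os$peri) {
        pm <- os$per_miss[[as.character(miss)]]
        peri_rows[[length(peri_rows) + 1L]] <-
          c(ex, miss, resample(pm$completions), resample(pm$inconsistent), 1L)
      }
    }
  }
  catch_rows <- list()
  catch_ex <- sample(length(exemplars), 6, replace = TRUE)
  catch_feats <- sample(catch_ids)
  for (i in 1:6) {
    ex <- exemplars[[catch_ex[i]]]
    miss <- resample(ex)
    catch_rows[[i]] <- c(ex, miss, miss, catch_feats[i], 2L)
  }

  mk <- function(rows, type) {
    m <- do.call(rbind, rows)
    data.frame(trial_type = type, ex1 = m[, 1], ex2 = m[, 2], ex3 = m[, 3],
               ex4 = m[, 4], ex5 = m[, 5], ex6 = m[, 6], missing = m[, 7],
               opt_correct = m[, 8], opt_incorrect = m[, 9])
  }
  experimental <- rbind(mk(core_rows, "core"), mk(peri_rows, "peripheral"))
  catch <- mk(catch_rows, "catch")

  # order: catch trials only in the second half
  n_total <- nrow(experimental) + nrow(catch)
  catch_pos <- sort(sample(52:n_total, nrow(catch)))
  order_exp <- sample(nrow(experimental))
  trials <- data.frame(matrix(nrow = n_total, ncol = 0))
  slots <- setdiff(seq_len(n_total), catch_pos)
  out <- experimental[order_exp, ]
  full <- rbind(out, catch[sample(nrow(catch)), ])
  full_idx <- integer(n_total)
  full_idx[slots] <- seq_len(nrow(out))
  full_idx[catch_pos] <- nrow(out) + seq_len(nrow(catch))
  trials <- full[full_idx, ]
  trials$index <- seq_len(n_total)
  trials$cue <- rbinom(n_total, 1, cue_probability) == 1
  rownames(trials) <- NULL
  trials <- trials[, c("index", "trial_type", paste0("ex", 1:6),
                       "missing", "opt_correct", "opt_incorrect", "cue")]
  counts <- table(trials$trial_type)
  structure(trials, class = c("trial_list", "data.frame"),
            category_id = category_id, kind = g$kind,
            counts = counts, catch_ids = catch_ids,
            seed = as.integer(seed))
}

#' Validate a single trial against a structure graph
#'
#' Checks the internal-consistency rules a well-formed trial must satisfy
#' and reports every violated rule.
#'
#' @param t one-row data.frame (a row of a `trial_list`).
#' @param g the `structure_graph` the trial was generated from.
#' @param catch_ids ids reserved for catch features (default: attribute of
#'   the trial list, else 101-106).
#' @return list with `valid` (logical) and `violations` (character vector).
#' @export
validate_trial <- function(t, g, catch_ids = 101:106) {
  v <- character(0)
  ex <- sort(as.integer(t[paste0("ex", 1:6)]))
  peri <- setdiff(ex, g$core_ids)
  if (!all(g$core_ids %in% ex)) v <- c(v, "exemplar missing core features")
  if (!is_consistent_triple(g, peri)) v <- c(v, "exemplar peripheral triple inconsistent")
  if (!(t$missing %in% ex)) v <- c(v, "missing feature not in exemplar")
  type <- as.character(t$trial_type)
  if (type == "core") {
    if (!(t$missing %in% g$core_ids)) v <- c(v, "core trial must miss a core feature")
    if (t$opt_correct != t$missing) v <- c(v, "correct option must be the missing feature")
    inc <- t$opt_incorrect
    shown_peri <- peri
    ok <- inc %in% g$peripheral_ids && !(inc %in% ex) &&
      any(apply(g$peripheral_edges, 1, function(ed)
        (ed[1] == inc & ed[2] %in% shown_peri) |
          (ed[2] == inc & ed[1] %in% shown_peri)))
    if (!ok) v <- c(v, "incorrect option not a structure-consistent peripheral")
  } else if (type == "peripheral") {
    if (!(t$missing %in% g$peripheral_ids)) v <- c(v, "peripheral trial must miss a peripheral feature")
    shown <- setdiff(peri, t$missing)
    if (!is_consistent_triple(g, c(shown, t$opt_correct)))
      v <- c(v, "correct option not structure-consistent")
    if (is_consistent_triple(g, c(shown, t$opt_incorrect)))
      v <- c(v, "incorrect option structure-consistent")
    if (t$opt_incorrect %in% ex) v <- c(v, "incorrect option already shown")
  } else if (type == "catch") {
    if (t$opt_correct != t$missing) v <- c(v, "correct option must be the missing feature")
    if (!(t$opt_incorrect %in% catch_ids))
      v <- c(v, "catch incorrect option must be a never-seen catch feature")
  } else v <- c(v, "unknown trial type")
  list(valid = length(v) == 0, violations = v)
}

#' Write a trial list to CSV (schema-versioned)
#' @param trials a `trial_list`.
#' @param path output path.
#' @export
write_trials_csv <- function(trials, path) {
  con <- file(path, "w")
  on.exit(close(con))
  meta <- sprintf("# tmrstruct/trial_list/v1 category=%s kind=%s seed=%d",
                  attr(trials, "category_id"), attr(trials, "kind"),
                  attr(trials, "seed"))
  writeLines(meta, con)
  write.csv(as.data.frame(trials), con, row.names = FALSE)
  invisible(path)
}

#' Read a trial list written by [write_trials_csv()]
#' @param path CSV path.
#' @return A `trial_list` data.frame.
#' @export
read_trials_csv <- function(path) {
  header <- readLines(path, n = 1)
  if (!grepl("^# tmrstruct/trial_list/v1", header))
    stop("schema mismatch: not a tmrstruct/trial_list/v1 file")
  fields <- strsplit(sub("^# \\S+ ", "", header), " ")[[1]]
  kv <- strsplit(fields, "=")
  meta <- setNames(vapply(kv, `[`, "", 2), vapply(kv, `[`, "", 1))
  df <- read.csv(path, comment.char = "#")
  df$cue <- as.logical(df$cue)
  structure(df, class = c("trial_list", "data.frame"),
            category_id = meta[["category"]], kind = meta[["kind"]],
            counts = table(df$trial_type), catch_ids = 101:106,
            seed = as.integer(meta[["seed"]]))
}
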