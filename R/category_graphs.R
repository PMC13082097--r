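#' Build a feature-covariation category graph
#'
#' Constructs one of the two 11-node graphs that define how features covary
#' within a category. Both graphs have 3 high-frequency "core" features
#' (present in every category member) and 8 "peripheral" features whose
#' co-occurrence pattern carries the category's structure:
#'
#' * `modular`: the 8 peripheral features split into two fully
#'   intra-connected communities of 4 with no cross-community edges, so an
#'   exemplar draws its peripheral features from one community only.
#' * `lattice`: the 8 peripheral features form a single ring (every
#'   peripheral node has peripheral degree 2), which yields no community
#'   clusters.
#'
#' The two graphs are matched on node count, core/peripheral split, and the
#' number of exemplars they generate (8 each).
#'
#' @param kind `"modular"` or `"lattice"`.
#' @return A `structure_graph` object: a list with `kind`, `node_ids`
#'   (integers 0-10), `core_ids` (0-2), `peripheral_ids` (3-10), and
#'   `peripheral_edges` (two-column matrix of unordered node pairs).
#' @examples
#' g <- build_graph("modular")
#' nrow(g$peripheral_edges)  # 12 = 2 * choose(4, 2)
#' @export
build_graph <- function(kind = c("modular", "lattice")) {
  kind <- match.arg(kind)
  node_ids <- 0:10
  core_ids <- 0:2
  peripheral_ids <- 3:10
  if (kind == "modular") {
    comm <- list(3:6, 7:10)
    edges <- do.call(rbind, lapply(comm, function(cm) t(utils::combn(cm, 2))))
  } else {
    ring <- c(3:10, 3L)
    edges <- cbind(ring[1:8], ring[2:9])
  }
  edges <- t(apply(edges, 1, sort))
  edges <- edges[order(edges[, 1], edges[, 2]), , drop = FALSE]
  colnames(edges) <- c("a", "b")
  g <- list(kind = kind, node_ids = node_ids, core_ids = core_ids,
            peripheral_ids = peripheral_ids, peripheral_edges = edges)
  class(g) <- "structure_graph"
  validate_structure_graph(g)
  g
}

validate_structure_graph <- function(g) {
  stopifnot(inherits(g, "structure_graph"))
  if (length(g$node_ids) != 11L) stop("graph must have exactly 11 nodes")
  if (length(g$core_ids) != 3L) stop("graph must have exactly 3 core nodes")
  if (length(g$peripheral_ids) != 8L) stop("graph must have exactly 8 peripheral nodes")
  if (length(intersect(g$core_ids, g$peripheral_ids)) > 0L)
    stop("core and peripheral node sets must be disjoint")
  deg <- table(factor(c(g$peripheral_edges), levels = g$peripheral_ids))
  if (g$kind == "lattice" && any(deg != 2L))
    stop("lattice peripheral nodes must all have peripheral degree 2")
  if (g$kind == "modular" && nrow(g$peripheral_edges) != 12L)
    stop("modular graph must have 12 peripheral edges")
  invisible(g)
}

#' @export
print.structure_graph <- function(x, ...) {
  cat(sprintf("structure_graph (%s): 11 nodes, core {%s}, %d peripheral edges\n",
              x$kind, paste(x$core_ids, collapse = ","),
              nrow(x$peripheral_edges)))
  invisible(x)
}

# peripheral communities of the modular graph (connected components)
graph_communities <- function(g) {
  stopifnot(g$kind == "modular")
  list(3:6, 7:10)
}

# ring order of the lattice peripheral nodes
graph_ring <- function(g) {
  stopifnot(g$kind == "lattice")
  3:10
}

# the structure-consistent peripheral triples of a graph, one sorted
# integer vector per exemplar, in lexicographic order
peripheral_triples <- function(g) {
  if (g$kind == "modular") {
    trips <- do.call(c, lapply(graph_communities(g), function(cm) {
      apply(utils::combn(cm, 3), 2, sort, simplify = FALSE)
    }))
  } else {
    ring <- graph_ring(g)
    trips <- lapply(0:7, function(i) sort(ring[(c(i, i + 1, i + 2) %% 8) + 1]))
  }
  trips[order(vapply(trips, function(t) t[1] * 121 + t[2] * 11 + t[3], 0))]
}

#' Enumerate the exemplars of a category graph
#'
#' Every exemplar has 6 features: the full core set plus 3
#' structure-consistent peripheral features. For the modular graph those are
#' any 3 features within one community; for the lattice graph, 3 consecutive
#' ring nodes. Both graphs generate exactly 8 unique exemplars.
#'
#' @param g a `structure_graph`.
#' @return A list of 8 sorted integer vectors of length 6, in deterministic
#'   (lexicographic) order.
#' @export
enumerate_exemplars <- function(g) {
  validate_structure_graph(g)
  lapply(peripheral_triples(g), function(t) sort(c(g$core_ids, t)))
}

# does a sorted peripheral triple form a valid exemplar under g?
is_consistent_triple <- function(g, triple) {
  triple <- sort(triple)
  any(vapply(peripheral_triples(g), identical, TRUE, y = triple))
}

#' Ground-truth feature dissimilarity matrix of a graph
#'
#' Derives the 11 x 11 dissimilarity structure implied by feature
#' co-occurrence across the graph's exemplars. Peripheral pairs that ever
#' co-occur in an exemplar get dissimilarity 0; peripheral pairs that never
#' co-occur get 1. Pairs involving a core feature carry no structure signal
#' (core features co-occur with every peripheral feature) and are set to an
#' intermediate value, `core_value`. The scale is arbitrary: every analysis
#' built on this matrix uses Pearson correlation, which is invariant to
#' monotone affine rescaling.
#'
#' @param g a `structure_graph`.
#' @param core_value dissimilarity assigned to pairs involving a core
#'   feature (default 0.5).
#' @return A `feature_rdm` object (11 x 11 symmetric, zero diagonal,
#'   not z-scored).
#' @export
true_rdm <- function(g, core_value = 0.5) {
  validate_structure_graph(g)
  n <- 11L
  m <- matrix(core_value, n, n, dimnames = list(g$node_ids, g$node_ids))
  pidx <- g$peripheral_ids + 1L
  m[pidx, pidx] <- 1
  for (tr in peripheral_triples(g)) {
    ii <- tr + 1L
    m[ii, ii] <- 0
  }
  diag(m) <- 0
  feature_rdm(m, labels = g$node_ids, zscored = FALSE)
}

#' Random feature-to-node assignment for one species
#'
#' Assigns 11 species-specific feature labels to the 11 graph nodes
#' uniformly at random, and reserves 6 extra never-seen features for catch
#' trials.
#'
#' @param species_id label of the species (used to prefix feature labels).
#' @param seed integer RNG seed.
#' @return A `feature_assignment`: list with `species_id`, `node_to_feature`
#'   (named character vector, names = node ids 0-10), `catch_features`
#'   (6 labels), and `rng_seed`.
#' @export
feature_assignment <- function(species_id, seed) {
  stopifnot(is.character(species_id) || is.numeric(species_id))
  set.seed(as.integer(seed))
  feats <- sprintf("%s_f%02d", species_id, 1:11)
  node_to_feature <- setNames(sample(feats), as.character(0:10))
  catch <- sprintf("%s_catch%d", species_id, 1:6)
  fa <- list(species_id = as.character(species_id),
             node_to_feature = node_to_feature,
             catch_features = catch, rng_seed = as.integer(seed))
  class(fa) <- "feature_assignment"
  fa
}

#' Serialize a structure graph (plus optional assignment) to JSON
#'
#' @param g a `structure_graph`.
#' @param path output file path.
#' @param assignment optional `feature_assignment` stored alongside.
#' @export
write_graph_json <- function(g, path, assignment = NULL) {
  validate_structure_graph(g)
  obj <- list(schema = "tmrstruct/structure_graph/v1",
              kind = g$kind, node_ids = g$node_ids, core_ids = g$core_ids,
              peripheral_ids = g$peripheral_ids,
              peripheral_edges = unname(apply(g$peripheral_edges, 1, as.list)))
  if (!is.null(assignment)) {
    obj$assignment <- list(species_id = assignment$species_id,
                           node_to_feature = as.list(assignment$node_to_feature),
                           catch_features = assignment$catch_features,
                           rng_seed = assignment$rng_seed)
  }
  jsonlite::write_json(obj, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' Read a structure graph written by [write_graph_json()]
#' @param path JSON file path.
#' @return A list with elements `graph` and (possibly NULL) `assignment`.
#' @export
read_graph_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$schema, "tmrstruct/structure_graph/v1"))
    stop("schema mismatch: expected tmrstruct/structure_graph/v1, got ",
         obj$schema %||% "<missing>")
  g <- build_graph(obj$kind)
  assignment <- NULL
  if (!is.null(obj$assignment)) {
    assignment <- list(
      species_id = obj$assignment$species_id,
      node_to_feature = unlist(obj$assignment$node_to_feature),
      catch_features = obj$assignment$catch_features,
      rng_seed = as.integer(obj$assignment$rng_seed))
    class(assignment) <- "feature_assignment"
  }
  list(graph = g, assignment = assignment)
}

#' Export exemplars as a CSV table (one row per exemplar)
#' @param g a `structure_graph`.
#' @param path output CSV path.
#' @export
write_exemplars_csv <- function(g, path) {
  ex <- enumerate_exemplars(g)
  df <- as.data.frame(do.call(rbind, ex))
  names(df) <- paste0("feature", 1:6)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}
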