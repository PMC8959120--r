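#' Uniform random simple graph with a fixed edge count
#'
#' Draws a graph uniformly among all simple undirected graphs with \code{n}
#' nodes and exactly \code{m} edges (Erdos--Renyi G(n, m)), as a binary
#' symmetric adjacency matrix with zero diagonal.
#'
#' @param n node count.
#' @param m edge count, between 0 and \code{n(n-1)/2}.
#' @return an \code{n x n} integer adjacency matrix.
#' @export
random_graph <- function(n, m) {
  stopifnot(n >= 1, m >= 0, m <= n * (n - 1) / 2)
  g <- igraph::sample_gnm(n, m)
  a <- as.matrix(igraph::as_adjacency_matrix(g, type = "both", sparse = FALSE))
  storage.mode(a) <- "integer"
  a
}

#' Initial node activations
#'
#' Independent Uniform(0, 1) starting values for every node.
#'
#' @param n node count.
#' @return numeric vector of length \code{n}.
#' @export
init_activations <- function(n) {
  stopifnot(n >= 1)
  stats::runif(n)
}

# Named parameter families.  The majority always sits at the reference values
# alpha = 1.8, epsilon = 0.4; the minority (first `minority_size` nodes)
# deviates in one parameter per family:
#   BL baseline, LC less chaotic (alpha 1.7), MC more chaotic (alpha 1.9),
#   SC sub-coupled (epsilon 0.3), HC hyper-coupled (epsilon 0.5).
family_table <- function() {
  data.frame(
    name = c("BL", "LC", "MC", "SC", "HC"),
    minority_alpha   = c(1.8, 1.7, 1.9, 1.8, 1.8),
    minority_epsilon = c(0.4, 0.4, 0.4, 0.3, 0.5),
    majority_alpha   = 1.8,
    majority_epsilon = 0.4,
    stringsAsFactors = FALSE)
}

#' Parameter family specification
#'
#' Looks up one of the five named model families.  Each family fixes the
#' amplitude and coupling strength of the minority subset of nodes while the
#' majority keeps the baseline values (alpha = 1.8, epsilon = 0.4).
#'
#' @param name one of \code{"BL"}, \code{"LC"}, \code{"MC"}, \code{"SC"},
#'   \code{"HC"}.
#' @param minority_size nodes in the minority subset (default 50); the
#'   minority is the first \code{minority_size} node indices by convention.
#' @return a list of class \code{"family_spec"}.
#' @export
family_spec <- function(name, minority_size = 50) {
  tab <- family_table()
  if (!name %in% tab$name)
    stop("unknown family: ", name, " (expected BL, LC, MC, SC or HC)")
  row <- tab[tab$name == name, ]
  structure(list(name = name, minority_size = minority_size,
                 minority_alpha = row$minority_alpha,
                 minority_epsilon = row$minority_epsilon,
                 majority_alpha = row$majority_alpha,
                 majority_epsilon = row$majority_epsilon),
            class = "family_spec")
}

#' Per-node parameters of a family
#'
#' Expands a \code{\link{family_spec}} into per-node amplitude and coupling
#' vectors for a network of \code{n} nodes, the first
#' \code{spec$minority_size} of which form the minority.
#'
#' @param spec a \code{\link{family_spec}}.
#' @param n total node count.
#' @return a \code{\link{cml_params}} object.
#' @export
family_parameters <- function(spec, n) {
  stopifnot(inherits(spec, "family_spec"), spec$minority_size < n)
  k <- spec$minority_size
  cml_params(
    alpha = c(rep(spec$minority_alpha, k), rep(spec$majority_alpha, n - k)),
    epsilon = c(rep(spec$minority_epsilon, k), rep(spec$majority_epsilon, n - k)))
}

#' Random-graph baseline ensemble
#'
#' Independent G(n, m) draws used to normalize network statistics.
#'
#' @inheritParams random_graph
#' @param count ensemble size (default 100).
#' @return list of adjacency matrices.
#' @export
baseline_ensemble <- function(n, m, count = 100) {
  stopifnot(count >= 1)
  lapply(seq_len(count), function(i) random_graph(n, m))
}

#' Degree-preserving randomization
#'
#' Rewires a graph by repeated double-edge swaps that reject self-loops and
#' multi-edges, preserving every node's degree.  This is the null model
#' behind normalized rich-club coefficients.
#'
#' @param adj binary symmetric adjacency matrix with at least 2 edges.
#' @param n_swaps number of attempted swaps; default 10 times the edge count,
#'   a standard mixing heuristic.
#' @return a randomized adjacency matrix with the same degree sequence.
#' @export
degree_preserving_randomize <- function(adj, n_swaps = NULL) {
  m <- sum(adj) / 2
  stopifnot(m >= 2)
  if (is.null(n_swaps)) n_swaps <- 10 * m
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  g <- igraph::rewire(g, igraph::keeping_degseq(niter = n_swaps))
  a <- as.matrix(igraph::as_adjacency_matrix(g, type = "both", sparse = FALSE))
  storage.mode(a) <- "integer"
  a
}

# Deterministic substream seed: fold a label string into the master seed so
# that independent stages (initialization, dynamics, baselines) draw from
# reproducible, distinct streams.  Matched design: the "init" substream
# depends only on the instantiation index, never on the family, so all
# families share initial graphs and activations for a given instantiation.
substream_seed <- function(master, ...) {
  label <- paste(c(...), collapse = ":")
  h <- 0
  for (b in utf8ToInt(label)) h <- (h * 31 + b) %% 2147483647
  as.integer((as.numeric(master) * 7919 + h) %% 2147483647)
}
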