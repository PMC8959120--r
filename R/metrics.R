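as_igraph <- function(adj) {
  igraph::graph_from_adjacency_matrix(adj, mode = "undirected", diag = FALSE)
}

#' Edge density
#'
#' Proportion of realized edges: \code{sum(A) / (n (n - 1))} for an ordinary
#' (sub)graph.  For the interpartition scope, where only edges crossing the
#' minority/majority boundary exist, pass \code{cross_sizes = c(n_min,
#' n_maj)}: the denominator is then the number of cross pairs and each cross
#' edge is counted once.
#'
#' @param adj binary symmetric adjacency matrix (at least 2 nodes in scope).
#' @param cross_sizes optional integer pair: minority and majority sizes for
#'   a bipartite (interpartition) scope.
#' @return density in [0, 1].
#' @export
edge_density <- function(adj, cross_sizes = NULL) {
  if (is.null(cross_sizes)) {
    n <- nrow(adj)
    if (n < 2) stop("edge density needs at least 2 nodes")
    sum(adj) / (n * (n - 1))
  } else {
    stopifnot(length(cross_sizes) == 2, all(cross_sizes >= 1))
    (sum(adj) / 2) / (cross_sizes[1] * cross_sizes[2])
  }
}

#' Global clustering coefficient (transitivity)
#'
#' Ratio of closed to all connected triplets, 3 x triangles / triplets,
#' equivalently \code{Tr(A^3) / (sum(A^2) - Tr(A^2))}.  Returns 0 when the
#' graph has no connected triplet.
#'
#' @param adj binary symmetric adjacency matrix with at least 3 nodes.
#' @return clustering coefficient in [0, 1].
#' @export
global_clustering <- function(adj) {
  stopifnot(nrow(adj) >= 3)
  v <- igraph::transitivity(as_igraph(adj), type = "global")
  if (is.nan(v)) 0 else v
}

#' Average path length with the zero convention for disconnected pairs
#'
#' Mean shortest-path length over all ordered pairs of distinct nodes, with
#' \code{d_ij = 0} when no path connects i and j.  Note that this convention
#' (rather than dropping unreachable pairs) shortens the average on
#' disconnected graphs.
#'
#' @param adj binary symmetric adjacency matrix with at least 2 nodes.
#' @return mean path length (>= 0).
#' @export
avg_path_length <- function(adj) {
  n <- nrow(adj)
  stopifnot(n >= 2)
  d <- igraph::distances(as_igraph(adj))
  d[is.infinite(d)] <- 0
  sum(d) / (n * (n - 1))
}

#' Small-world index
#'
#' Clustering coefficient divided by average path length.  High clustering at
#' short path length -- the small-world regime -- pushes this ratio up.
#'
#' @param clustering global clustering coefficient.
#' @param path_length average path length.
#' @return \code{clustering / path_length}, or \code{NA} when
#'   \code{path_length} is 0.
#' @export
small_world <- function(clustering, path_length) {
  if (is.na(path_length) || path_length == 0) return(NA_real_)
  clustering / path_length
}

#' Modularity under fast-greedy community detection
#'
#' Detects communities by greedy agglomerative modularity maximization
#' (Clauset--Newman--Moore) and returns the modularity Q of the detected
#' partition, with the standard normalization by the edge count.
#'
#' @param adj binary symmetric adjacency matrix with at least 1 edge.
#' @return list with \code{Q} (scalar) and \code{membership} (integer labels).
#' @export
graph_modularity <- function(adj) {
  if (sum(adj) == 0) stop("modularity is undefined for an edgeless graph")
  cl <- igraph::cluster_fast_greedy(as_igraph(adj))
  list(Q = igraph::modularity(cl), membership = igraph::membership(cl))
}

#' Degree assortativity
#'
#' Newman's degree-mixing coefficient: the Pearson correlation of the
#' remaining degrees at the two ends of an edge.  Undefined (NA) on regular
#' graphs, where the remaining-degree variance vanishes.
#'
#' @param adj binary symmetric adjacency matrix with at least 2 edges.
#' @return correlation in [-1, 1], or \code{NA} when undefined.
#' @export
degree_assortativity <- function(adj) {
  v <- suppressWarnings(igraph::assortativity_degree(as_igraph(adj)))
  if (is.nan(v)) NA_real_ else v
}

#' Extract a partition scope from a network
#'
#' The minority and majority scopes are the subgraphs induced by the first
#' \code{minority_size} nodes and the remaining nodes; the interpartition
#' scope keeps all nodes but only the edges crossing the partition boundary.
#'
#' @param adj binary symmetric adjacency matrix.
#' @param minority_size size of the minority subset (first indices).
#' @param scope one of \code{"whole"}, \code{"minority"}, \code{"majority"},
#'   \code{"interpartition"}.
#' @return adjacency matrix of the requested scope.
#' @export
scope_subgraph <- function(adj, minority_size,
                           scope = c("whole", "minority", "majority", "interpartition")) {
  scope <- match.arg(scope)
  n <- nrow(adj)
  stopifnot(minority_size >= 0, minority_size <= n)
  mino <- seq_len(minority_size)
  switch(scope,
    whole = adj,
    minority = adj[mino, mino, drop = FALSE],
    majority = adj[-mino, -mino, drop = FALSE],
    interpartition = {
      a <- adj
      a[mino, mino] <- 0L
      a[-mino, -mino] <- 0L
      a
    })
}

metric_names <- c("edge_density", "clustering", "path_length",
                  "small_world", "modularity", "assortativity")

# Metrics of one plain graph; cross_sizes switches the density denominator
# for the interpartition scope.
graph_metrics_row <- function(adj, cross_sizes = NULL) {
  ed <- edge_density(adj, cross_sizes = cross_sizes)
  cc <- global_clustering(adj)
  pl <- avg_path_length(adj)
  q <- tryCatch(graph_modularity(adj)$Q, error = function(e) NA_real_)
  data.frame(edge_density = ed, clustering = cc, path_length = pl,
             small_world = small_world(cc, pl), modularity = q,
             assortativity = degree_assortativity(adj))
}

#' Network statistics for all partition scopes
#'
#' Computes edge density, global clustering, average path length, small-world
#' index, fast-greedy modularity and degree assortativity for the whole
#' network and the minority, majority and interpartition subgraphs.
#'
#' @param adj binary symmetric adjacency matrix.
#' @param minority_size minority subset size (first node indices).
#' @return data frame with one row per scope.
#' @export
network_metrics <- function(adj, minority_size) {
  n <- nrow(adj)
  scopes <- c("whole", "minority", "majority", "interpartition")
  out <- do.call(rbind, lapply(scopes, function(sc) {
    a <- scope_subgraph(adj, minority_size, sc)
    cs <- if (sc == "interpartition") c(minority_size, n - minority_size) else NULL
    cbind(data.frame(scope = sc, stringsAsFactors = FALSE),
          graph_metrics_row(a, cross_sizes = cs))
  }))
  rownames(out) <- NULL
  out
}

#' Rich-club profile with degree-preserving null normalization
#'
#' For every club size k up to the maximum degree, the raw rich-club
#' coefficient RC(k) is the edge density among nodes of degree >= k.  The raw
#' profile is normalized by the mean profile of \code{null_count}
#' degree-preserving randomizations of the same graph, and each k is flagged
#' significant where a one-sided one-sample Wilcoxon signed-rank test (normal
#' approximation with continuity correction) finds the observed RC(k) above
#' the null distribution at the given level.
#'
#' @param adj binary symmetric adjacency matrix with at least 2 edges.
#' @param null_count null-ensemble size (default 200).
#' @param significance significance level for the Wilcoxon flags
#'   (default 0.01).
#' @return data frame of class \code{"rich_club_profile"} with columns
#'   \code{k}, \code{n_club} (club size in nodes), \code{rc_raw},
#'   \code{rc_null_mean}, \code{rc_norm}, \code{p_value},
#'   \code{significant}.  Rows where fewer than 2 nodes survive the cutoff
#'   carry NAs.
#' @export
rich_club <- function(adj, null_count = 200, significance = 0.01) {
  stopifnot(sum(adj) / 2 >= 2)
  degs <- rowSums(adj)
  kmax <- max(degs)
  ks <- seq_len(kmax)
  rc_of <- function(a) {
    vapply(ks, function(k) {
      keep <- which(degs >= k)     # degrees are shared by all nulls
      if (length(keep) < 2) return(NA_real_)
      sum(a[keep, keep]) / (length(keep) * (length(keep) - 1))
    }, numeric(1))
  }
  rc_raw <- rc_of(adj)
  nulls <- vapply(seq_len(null_count),
                  function(i) rc_of(degree_preserving_randomize(adj)),
                  numeric(length(ks)))
  nulls <- matrix(nulls, nrow = length(ks))
  null_mean <- rowMeans(nulls)
  rc_norm <- ifelse(null_mean > 0, rc_raw / null_mean, NA_real_)
  pvals <- vapply(seq_along(ks), function(i) {
    if (is.na(rc_raw[i])) return(NA_real_)
    xs <- nulls[i, ]
    if (all(xs == rc_raw[i])) return(NA_real_)  # degenerate: no signed ranks
    suppressWarnings(stats::wilcox.test(xs, mu = rc_raw[i],
                                        alternative = "less",
                                        exact = FALSE, correct = TRUE)$p.value)
  }, numeric(1))
  n_club <- vapply(ks, function(k) sum(degs >= k), integer(1))
  structure(data.frame(k = ks, n_club = n_club, rc_raw = rc_raw,
                       rc_null_mean = null_mean, rc_norm = rc_norm,
                       p_value = pvals,
                       significant = !is.na(pvals) & pvals < significance),
            class = c("rich_club_profile", "data.frame"))
}

#' Baseline metric means of a random-graph ensemble
#'
#' Means over an ensemble of G(n, m) random graphs of each network statistic,
#' used to normalize the evolving series.  With \code{cross_sizes} the
#' ensemble instead consists of random bipartite graphs (edges sampled among
#' cross pairs), matching the interpartition scope.
#'
#' @inheritParams random_graph
#' @param count ensemble size (default 100).
#' @param cross_sizes optional pair c(n_min, n_maj) for a bipartite baseline.
#' @return named numeric vector of baseline means, one per metric.
#' @export
baseline_metric_means <- function(n, m, count = 100, cross_sizes = NULL) {
  rows <- lapply(seq_len(count), function(i) {
    a <- if (is.null(cross_sizes)) random_graph(n, m)
         else random_cross_graph(cross_sizes[1], cross_sizes[2], m)
    graph_metrics_row(a, cross_sizes = cross_sizes)
  })
  df <- do.call(rbind, rows)
  colMeans(as.matrix(df), na.rm = TRUE)
}

# Random bipartite (interpartition-style) graph: m edges sampled uniformly
# among the n1 x n2 cross pairs, returned on n1 + n2 nodes.
random_cross_graph <- function(n1, n2, m) {
  stopifnot(m <= n1 * n2)
  picks <- sample.int(n1 * n2, m)
  i <- ((picks - 1) %% n1) + 1
  j <- ((picks - 1) %/% n1) + 1 + n1
  a <- matrix(0L, n1 + n2, n1 + n2)
  a[cbind(i, j)] <- 1L
  a[cbind(j, i)] <- 1L
  a
}

#' Normalize a metric series by random-graph baselines
#'
#' Divides each statistic by the baseline-ensemble mean of the same statistic
#' on the matching scope.  Degree assortativity is passed through
#' unnormalized, since its natural zero for random graphs makes a ratio
#' meaningless.
#'
#' @param series data frame with a \code{scope} column and the metric
#'   columns produced by \code{\link{network_metrics}}.
#' @param baselines named list mapping scope names to the output of
#'   \code{\link{baseline_metric_means}}.
#' @return the series with normalized metric columns.
#' @export
normalize_metrics <- function(series, baselines) {
  out <- series
  for (sc in unique(series$scope)) {
    if (is.null(baselines[[sc]])) next
    base <- baselines[[sc]]
    rows <- series$scope == sc
    for (mname in setdiff(metric_names, "assortativity")) {
      b <- base[[mname]]
      out[rows, mname] <-
        if (is.null(b) || is.na(b) || b == 0) NA_real_ else series[rows, mname] / b
    }
  }
  out
}
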