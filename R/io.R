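#' Write a graph as an edge-list text file
#'
#' Plain-text format: comment header lines starting with \code{#} (recording
#' the node count, so isolated nodes survive a round trip), then one
#' undirected edge per line as two whitespace-separated 1-based node indices,
#' lower index first.
#'
#' @param adj binary symmetric adjacency matrix.
#' @param path output file path.
#' @return the path, invisibly.
#' @export
write_edgelist <- function(adj, path) {
  check_adjacency(adj)
  n <- nrow(adj)
  e <- which(upper.tri(adj) & adj == 1, arr.ind = TRUE)
  e <- e[order(e[, 1], e[, 2]), , drop = FALSE]
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# rewirenet edge list (1-based, lower index first)",
               paste("# nodes:", n)), con)
  if (nrow(e) > 0)
    writeLines(paste(e[, 1], e[, 2]), con)
  invisible(path)
}

#' Read an edge-list text file
#'
#' Counterpart of \code{\link{write_edgelist}}; malformed lines raise an
#' error that reports the line number.
#'
#' @param path input file path.
#' @return adjacency matrix.
#' @export
read_edgelist <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^# nodes:", lines, value = TRUE)
  if (length(hdr) != 1)
    stop("edge list is missing its '# nodes:' header: ", path)
  n <- as.integer(sub("^# nodes:\\s*", "", hdr))
  body <- which(!grepl("^#", lines) & nzchar(trimws(lines)))
  a <- matrix(0L, n, n)
  for (ln in body) {
    parts <- suppressWarnings(as.integer(strsplit(trimws(lines[ln]), "\\s+")[[1]]))
    if (length(parts) != 2 || anyNA(parts) || any(parts < 1) || any(parts > n))
      stop(sprintf("malformed edge at line %d of %s", ln, path))
    a[parts[1], parts[2]] <- 1L
    a[parts[2], parts[1]] <- 1L
  }
  a
}

#' Write / read a graph in GraphML format
#'
#' Thin wrappers over igraph's GraphML support that preserve node count and
#' labels.
#'
#' @param adj binary symmetric adjacency matrix.
#' @param path file path.
#' @return \code{write_graphml}: the path, invisibly; \code{read_graphml}:
#'   an adjacency matrix.
#' @export
write_graphml <- function(adj, path) {
  check_adjacency(adj)
  igraph::write_graph(as_igraph(adj), path, format = "graphml")
  invisible(path)
}

#' @rdname write_graphml
#' @export
read_graphml <- function(path) {
  g <- igraph::read_graph(path, format = "graphml")
  a <- as.matrix(igraph::as_adjacency_matrix(g, type = "both", sparse = FALSE))
  storage.mode(a) <- "integer"
  a
}

#' Seriation order of an adjacency matrix
#'
#' Orders nodes by their projection onto the first principal component of
#' the adjacency matrix, which places densely interconnected blocks
#' (modules) contiguously and makes them visible as squares along the
#' diagonal of the reordered matrix.  Sign convention: the loading of
#' largest magnitude is made positive, so the ordering is deterministic.
#'
#' @param adj binary symmetric adjacency matrix, nonempty.
#' @return integer permutation of \code{1..n}.
#' @export
seriation_order <- function(adj) {
  stopifnot(nrow(adj) >= 1)
  if (nrow(adj) == 1) return(1L)
  p <- stats::prcomp(adj, center = TRUE, scale. = FALSE)$x[, 1]
  if (p[which.max(abs(p))] < 0) p <- -p
  order(p, seq_along(p))
}

#' Write / read a metric series table
#'
#' Metric checkpoint series as tab-separated text, one row per
#' (attempt, scope) pair.
#'
#' @param metrics metric data frame from \code{\link{simulate_network}}.
#' @param path file path.
#' @return \code{write_metrics}: the path, invisibly; \code{read_metrics}:
#'   the data frame.
#' @export
write_metrics <- function(metrics, path) {
  utils::write.table(metrics, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_metrics
#' @export
read_metrics <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
}
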