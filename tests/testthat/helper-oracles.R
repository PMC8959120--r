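# Small graph builders and brute-force oracles used across tests.

adj_from_edges <- function(n, edges) {
  a <- matrix(0L, n, n)
  for (e in edges) {
    a[e[1], e[2]] <- 1L
    a[e[2], e[1]] <- 1L
  }
  a
}

path_graph <- function(n) adj_from_edges(n, lapply(seq_len(n - 1), function(i) c(i, i + 1)))
complete_graph <- function(n) { a <- matrix(1L, n, n); diag(a) <- 0L; a }
star_graph <- function(n) adj_from_edges(n, lapply(2:n, function(i) c(1, i)))

# literal per-node evaluation of the coupled update (independent of the
# vectorized implementation)
coupled_step_loop <- function(x, adj, alpha, eps, neighbor_amplitude = "self") {
  n <- length(x)
  out <- numeric(n)
  for (i in seq_len(n)) {
    nbrs <- which(adj[i, ] != 0)
    if (neighbor_amplitude == "self") {
      out[i] <- (1 - eps[i]) * (1 - alpha[i] * x[i]^2) +
        (eps[i] / length(nbrs)) * sum(1 - alpha[i] * x[nbrs]^2)
    } else {
      out[i] <- (1 - eps[i]) * (1 - alpha[i] * x[i]^2) +
        (eps[i] / length(nbrs)) * sum(1 - alpha[nbrs] * x[nbrs]^2)
    }
  }
  out
}

# triplet-enumeration clustering oracle
clustering_brute <- function(adj) {
  n <- nrow(adj)
  closed <- 0; connected <- 0
  for (i in seq_len(n - 2)) for (j in (i + 1):(n - 1)) for (k in (j + 1):n) {
    e <- adj[i, j] + adj[j, k] + adj[i, k]
    if (e == 3) { closed <- closed + 1; connected <- connected + 3 }
    else if (e == 2) connected <- connected + 1
  }
  if (connected == 0) return(0)
  3 * closed / connected
}

# BFS path-length oracle with the zero convention for unreachable pairs
path_length_brute <- function(adj) {
  n <- nrow(adj)
  total <- 0
  for (s in seq_len(n)) {
    dist <- rep(NA_integer_, n)
    dist[s] <- 0L
    queue <- s
    while (length(queue) > 0) {
      v <- queue[1]; queue <- queue[-1]
      for (w in which(adj[v, ] != 0)) if (is.na(dist[w])) {
        dist[w] <- dist[v] + 1L
        queue <- c(queue, w)
      }
    }
    dist[is.na(dist)] <- 0L
    total <- total + sum(dist)
  }
  total / (n * (n - 1))
}

modularity_of_partition <- function(adj, membership) {
  m <- sum(adj) / 2
  deg <- rowSums(adj)
  q <- 0
  n <- nrow(adj)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (membership[i] == membership[j])
      q <- q + adj[i, j] - deg[i] * deg[j] / (2 * m)
  }
  q / (2 * m)
}

# exhaustive modularity maximum over all set partitions (n <= 9 or so),
# enumerated via restricted growth strings
modularity_exhaustive <- function(adj) {
  n <- nrow(adj)
  best <- -Inf
  rec <- function(assign, kmax) {
    i <- length(assign) + 1
    if (i > n) {
      q <- modularity_of_partition(adj, assign)
      if (q > best) best <<- q
      return(invisible())
    }
    for (g in seq_len(kmax + 1)) rec(c(assign, g), max(kmax, g))
  }
  rec(integer(0), 0)
  best
}
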