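#' Distance and similarity score vectors for a rewiring pivot
#'
#' For a pivot node, computes the per-node activation distances
#' \code{d_j = |x_j - x_pivot|}, the similarities \code{s = 1 - d}, the
#' neighbor-masked distances \code{delta} (zero at non-neighbors and at the
#' pivot) and the non-neighbor-masked similarities \code{sigma} (zero at
#' neighbors and at the pivot).  \code{delta} and \code{sigma} are the score
#' vectors whose argmaxes select the edge to drop and the edge to add.
#'
#' @param pivot node index (1-based).
#' @param x activation vector.
#' @param adj binary symmetric adjacency matrix.
#' @return list with numeric vectors \code{d}, \code{s}, \code{delta},
#'   \code{sigma}.
#' @export
rewire_scores <- function(pivot, x, adj) {
  n <- length(x)
  stopifnot(pivot >= 1, pivot <= n, nrow(adj) == n)
  d <- abs(x - x[pivot])
  s <- 1 - d
  nbr <- adj[pivot, ] != 0
  non <- !nbr
  non[pivot] <- FALSE
  delta <- ifelse(nbr, d, 0)
  sigma <- ifelse(non, s, 0)
  list(d = d, s = s, delta = delta, sigma = sigma)
}

# argmax restricted to a logical mask; lowest index wins ties
masked_argmax <- function(v, mask) {
  idx <- which(mask)
  idx[which.max(v[idx])]
}

#' One adaptive rewiring attempt
#'
#' Draws a pivot node uniformly at random (one \code{runif} draw from R's RNG
#' stream), removes the edge to its most activity-dissimilar neighbor and adds
#' an edge to its most similar non-neighbor.  Ties at either argmax break at
#' the lowest node index.  The total edge count is conserved.
#'
#' If the pivot is connected to all other nodes there is no non-neighbor to
#' wire to; the attempt reports termination (\code{reason =
#' "no_non_neighbor"}) and leaves the adjacency unchanged.  An attempt may
#' isolate the dropped neighbor; that is allowed here and surfaces as a
#' degenerate-dynamics termination at the next update.
#'
#' @param x activation vector.
#' @param adj binary symmetric adjacency matrix.
#' @param pivot optional fixed pivot index; by default drawn uniformly.
#' @return list with the (possibly updated) \code{adjacency} and an
#'   \code{outcome} list: \code{pivot}, \code{removed}, \code{added},
#'   \code{terminated}, \code{reason} (one of \code{"none"},
#'   \code{"no_non_neighbor"}).
#' @export
rewire_step <- function(x, adj, pivot = NULL) {
  n <- length(x)
  if (is.null(pivot)) pivot <- floor(stats::runif(1) * n) + 1
  if (pivot > n) pivot <- n
  deg <- sum(adj[pivot, ])
  if (deg == n - 1) {
    return(list(adjacency = adj,
                outcome = list(pivot = pivot, removed = NA_integer_,
                               added = NA_integer_, terminated = TRUE,
                               reason = "no_non_neighbor")))
  }
  sc <- rewire_scores(pivot, x, adj)
  nbr <- adj[pivot, ] != 0
  non <- !nbr; non[pivot] <- FALSE
  xi <- masked_argmax(sc$d, nbr)
  zeta <- masked_argmax(sc$s, non)
  adj[pivot, xi] <- 0L; adj[xi, pivot] <- 0L
  adj[pivot, zeta] <- 1L; adj[zeta, pivot] <- 1L
  list(adjacency = adj,
       outcome = list(pivot = pivot, removed = xi, added = zeta,
                      terminated = FALSE, reason = "none"))
}

#' One rewiring epoch (reference implementation)
#'
#' Runs \code{updates_per_rewiring} coupled-map updates followed by one
#' rewiring attempt.  This pure-R path mirrors the compiled segment runner
#' used by \code{\link{simulate_network}} draw-for-draw and is used for
#' cross-validation and small experiments.
#'
#' @inheritParams coupled_step
#' @param updates_per_rewiring updates between rewiring attempts (default 20).
#' @return list with \code{x}, \code{adjacency} and the rewiring
#'   \code{outcome}; on a degenerate dynamics step the outcome carries
#'   \code{terminated = TRUE}, \code{reason = "isolated_node"} and the state
#'   is returned frozen as it was.
#' @export
rewire_epoch <- function(x, adj, params, updates_per_rewiring = 20,
                         neighbor_amplitude = c("self", "neighbor")) {
  neighbor_amplitude <- match.arg(neighbor_amplitude)
  stopifnot(updates_per_rewiring >= 1)
  xt <- tryCatch(
    iterate_dynamics(x, adj, params, updates_per_rewiring, neighbor_amplitude),
    rewirenet_degenerate = function(e) e)
  if (inherits(xt, "rewirenet_degenerate")) {
    return(list(x = x, adjacency = adj,
                outcome = list(pivot = NA_integer_, removed = NA_integer_,
                               added = NA_integer_, terminated = TRUE,
                               reason = "isolated_node", node = xt$node)))
  }
  st <- rewire_step(xt, adj)
  list(x = xt, adjacency = st$adjacency, outcome = st$outcome)
}
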