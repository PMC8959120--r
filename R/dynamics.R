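#' Logistic map
#'
#' One application of the chaotic logistic map \code{x' = 1 - alpha * x^2},
#' the elementary oscillator of the network model.  After one application any
#' trajectory is confined to \code{[1 - alpha, 1]}.
#'
#' @param x activation value(s), finite numeric scalar or vector.
#' @param alpha amplitude parameter(s); scalar or vector recycled against
#'   \code{x}.  Values around 1.7--1.9 put the map in a chaotic regime.
#' @return \code{1 - alpha * x^2}, elementwise.
#' @examples
#' logistic_map(0.5, 1.7)
#' @export
logistic_map <- function(x, alpha) {
  stopifnot(is.numeric(x), is.numeric(alpha), all(is.finite(x)), all(is.finite(alpha)))
  1 - alpha * x^2
}

#' Parameter set for a coupled-map network
#'
#' Bundles the per-node amplitude and coupling-strength vectors.
#'
#' @param alpha per-node amplitude vector, each value in (0, 2].
#' @param epsilon per-node coupling strength vector, each value in [0, 1).
#' @return An object of class \code{"cml_params"}: a list with elements
#'   \code{alpha} and \code{epsilon}.
#' @export
cml_params <- function(alpha, epsilon) {
  stopifnot(length(alpha) == length(epsilon),
            all(alpha > 0), all(alpha <= 2),
            all(epsilon >= 0), all(epsilon < 1))
  structure(list(alpha = as.numeric(alpha), epsilon = as.numeric(epsilon)),
            class = "cml_params")
}

#' @export
print.cml_params <- function(x, ...) {
  cat("Coupled-map parameter set,", length(x$alpha), "nodes\n")
  cat("  alpha:   ", paste(unique(round(x$alpha, 4)), collapse = ", "), "\n")
  cat("  epsilon: ", paste(unique(round(x$epsilon, 4)), collapse = ", "), "\n")
  invisible(x)
}

# Validate a binary symmetric zero-diagonal adjacency matrix.
check_adjacency <- function(adj) {
  stopifnot(is.matrix(adj), nrow(adj) == ncol(adj))
  if (!all(adj %in% c(0L, 1L)))
    stop("adjacency entries must be 0 or 1")
  if (!isTRUE(all.equal(adj, t(adj), check.attributes = FALSE)))
    stop("adjacency matrix must be symmetric")
  if (any(diag(adj) != 0))
    stop("adjacency matrix must have a zero diagonal")
  invisible(adj)
}

#' One coupled logistic-map update
#'
#' Advances all node activations by one discrete time step.  Each node mixes
#' its own logistic map with the mean map of its graph neighbors in proportion
#' to its coupling strength:
#' \deqn{x_i^+ = 1 - \alpha_i [ (1-\epsilon_i) x_i^2 +
#'       (\epsilon_i / |B_i|) \sum_{j \in B_i} x_j^2 ]}
#' where \eqn{B_i} is the neighbor set of node \eqn{i}.  With
#' \code{neighbor_amplitude = "neighbor"} the neighbor term uses each
#' neighbor's own amplitude \eqn{\alpha_j} instead of \eqn{\alpha_i}.
#'
#' A node of degree zero makes the neighbor average undefined; this raises a
#' condition of class \code{"rewirenet_degenerate"} carrying the offending
#' node index, mirroring the pathological breakdown of evolving models.
#'
#' @param x numeric vector of current activations.
#' @param adj binary symmetric adjacency matrix.
#' @param params a \code{\link{cml_params}} object.
#' @param neighbor_amplitude \code{"self"} (default) or \code{"neighbor"}:
#'   whose amplitude scales the neighbor activity term.
#' @return the next activation vector.
#' @export
coupled_step <- function(x, adj, params, neighbor_amplitude = c("self", "neighbor")) {
  neighbor_amplitude <- match.arg(neighbor_amplitude)
  n <- length(x)
  stopifnot(nrow(adj) == n, length(params$alpha) == n)
  deg <- rowSums(adj)
  if (any(deg == 0)) {
    i <- which(deg == 0)[1]
    stop(structure(class = c("rewirenet_degenerate", "error", "condition"),
                   list(message = sprintf("node %d has degree 0: coupling undefined", i),
                        call = sys.call(-1), node = i)))
  }
  a <- params$alpha; e <- params$epsilon
  if (neighbor_amplitude == "self") {
    w <- x * x
    1 - a * ((1 - e) * w + e * as.vector(adj %*% w) / deg)
  } else {
    w <- a * x * x
    1 - (1 - e) * w - e * as.vector(adj %*% w) / deg
  }
}

#' Iterate the coupled dynamics
#'
#' Applies \code{\link{coupled_step}} \code{n_steps} times on a fixed
#' adjacency matrix; \code{n_steps = 0} is the identity.
#'
#' @inheritParams coupled_step
#' @param n_steps number of updates, non-negative integer.
#' @return activation vector after \code{n_steps} updates.
#' @export
iterate_dynamics <- function(x, adj, params, n_steps,
                             neighbor_amplitude = c("self", "neighbor")) {
  neighbor_amplitude <- match.arg(neighbor_amplitude)
  stopifnot(n_steps >= 0)
  for (k in seq_len(n_steps))
    x <- coupled_step(x, adj, params, neighbor_amplitude)
  x
}
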