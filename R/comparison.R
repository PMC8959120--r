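#' Functional connectivity matrix
#'
#' Momentary functional connectivity: the matrix of pairwise absolute
#' differences of node activations, \code{f_ij = |x_i - x_j|}.  Symmetric
#' with a zero diagonal; invariant under adding a constant to all
#' activations.
#'
#' @param x activation vector.
#' @return numeric matrix.
#' @export
functional_connectivity <- function(x) {
  abs(outer(x, x, "-"))
}

#' Binarize a functional connectivity matrix
#'
#' Keeps the \code{target_edges} most similar node pairs (smallest absolute
#' activation difference) as edges, breaking ties toward the
#' lexicographically lowest index pair, so that the functional graph matches
#' the anatomical graph's edge budget.
#'
#' @param f functional connectivity matrix.
#' @param target_edges number of edges to keep.
#' @return binary adjacency matrix.
#' @export
functional_graph <- function(f, target_edges) {
  n <- nrow(f)
  pairs <- which(upper.tri(f), arr.ind = TRUE)
  stopifnot(target_edges >= 0, target_edges <= nrow(pairs))
  ord <- order(f[pairs], pairs[, 1], pairs[, 2])
  keep <- pairs[ord[seq_len(target_edges)], , drop = FALSE]
  a <- matrix(0L, n, n)
  a[keep] <- 1L
  a[keep[, c(2, 1), drop = FALSE]] <- 1L
  a
}

# Per-node NetSimile features: degree, local clustering, mean neighbor
# degree, mean neighbor clustering, egonet edge count, edges leaving the
# egonet, and distinct neighbors of the egonet.  Conventions: local
# clustering of degree < 2 nodes is 0; neighbor means of isolated nodes are 0.
netsimile_features <- function(adj) {
  g <- as_igraph(adj)
  n <- nrow(adj)
  deg <- rowSums(adj)
  cl <- igraph::transitivity(g, type = "local", isolates = "zero")
  cl[is.nan(cl)] <- 0
  mean_nb <- function(v) {
    out <- as.vector(adj %*% v)
    ifelse(deg > 0, out / deg, 0)
  }
  nb_deg <- mean_nb(deg)
  nb_cl <- mean_nb(cl)
  ego_edges <- numeric(n); ego_out <- numeric(n); ego_nbrs <- numeric(n)
  for (i in seq_len(n)) {
    ego <- c(i, which(adj[i, ] != 0))
    sub <- adj[ego, ego, drop = FALSE]
    ego_edges[i] <- sum(sub) / 2
    outside <- setdiff(seq_len(n), ego)
    cross <- adj[ego, outside, drop = FALSE]
    ego_out[i] <- sum(cross)
    ego_nbrs[i] <- sum(colSums(cross) > 0)
  }
  cbind(degree = deg, clustering = cl, nb_degree = nb_deg, nb_clustering = nb_cl,
        ego_edges = ego_edges, ego_out = ego_out, ego_nbrs = ego_nbrs)
}

# moment aggregators; skewness/kurtosis of a zero-variance feature are set
# to 0 so signatures stay finite on vertex-transitive graphs
aggregate_feature <- function(v) {
  s <- stats::sd(v)
  c(median = stats::median(v), mean = mean(v), sd = s,
    skewness = if (s > 0) e1071::skewness(v) else 0,
    kurtosis = if (s > 0) e1071::kurtosis(v) else 0)
}

#' NetSimile signature vector
#'
#' Summarizes a graph by 7 per-node structural features (degree, local
#' clustering, mean neighbor degree, mean neighbor clustering, egonet edges,
#' edges leaving the egonet, egonet neighbor count), each aggregated by
#' median, mean, standard deviation, skewness and kurtosis: a fixed-length
#' 35-entry signature that is invariant under node relabeling.
#'
#' @param adj binary symmetric adjacency matrix, nonempty.
#' @return named numeric vector of length 35.
#' @export
netsimile_signature <- function(adj) {
  stopifnot(nrow(adj) >= 1)
  feats <- netsimile_features(adj)
  out <- unlist(lapply(colnames(feats), function(fn) {
    agg <- aggregate_feature(feats[, fn])
    names(agg) <- paste(fn, names(agg), sep = "_")
    agg
  }))
  out
}

#' Canberra distance between NetSimile signatures
#'
#' \code{sum(|a_i - b_i| / (|a_i| + |b_i|))} over signature entries;
#' coordinates where both entries are zero contribute nothing.
#'
#' @param sig_a,sig_b equal-length signature vectors.
#' @return nonnegative scalar.
#' @export
netsimile_distance <- function(sig_a, sig_b) {
  stopifnot(length(sig_a) == length(sig_b))
  num <- abs(sig_a - sig_b)
  den <- abs(sig_a) + abs(sig_b)
  ok <- den > 0
  sum(num[ok] / den[ok])
}

# HHG association statistic between two distance matrices: for every ordered
# pair (i, j) the remaining points are cross-classified by whether they fall
# within radius d(i, j) of i in each space, and the 2x2 chi-square statistics
# are summed.
hhg_statistic <- function(dx, dy) {
  n <- nrow(dx)
  total <- 0
  for (i in seq_len(n)) {
    dxi <- dx[i, ]; dyi <- dy[i, ]
    m1 <- outer(dxi, dxi, "<=")       # [k, j]: is k within radius d(i, j) in x
    m2 <- outer(dyi, dyi, "<=")
    a11 <- colSums(m1 & m2) - 2       # k = i and k = j always land here
    a12 <- colSums(m1 & !m2)
    a21 <- colSums(!m1 & m2)
    a22 <- colSums(!m1 & !m2)
    a11[i] <- 0; a12[i] <- 0; a21[i] <- 0; a22[i] <- 0  # j = i is not a pair
    r1 <- a11 + a12; r2 <- a21 + a22; c1 <- a11 + a21; c2 <- a12 + a22
    den <- r1 * r2 * c1 * c2
    ok <- den > 0
    num <- (a12 * a21 - a11 * a22)^2
    total <- total + sum((n - 2) * num[ok] / den[ok])
  }
  total
}

#' HHG distance-based independence test
#'
#' Tests for association between two multivariate samples paired by shared
#' node identity, via the Heller--Heller--Gorfine statistic on the two
#' Euclidean distance matrices, with a permutation p-value obtained by
#' permuting the pairing.
#'
#' @param features_a,features_b numeric matrices with one row per node (same
#'   node count and order) or precomputed square distance matrices when
#'   \code{is_distance = TRUE}.
#' @param n_permutations permutation count (default 1000).
#' @param is_distance inputs are already distance matrices.
#' @return list with \code{statistic}, \code{p_value} (add-one permutation
#'   estimate) and \code{n_permutations}.
#' @export
hhg_test <- function(features_a, features_b, n_permutations = 1000,
                     is_distance = FALSE) {
  if (is_distance) {
    dx <- as.matrix(features_a); dy <- as.matrix(features_b)
  } else {
    stopifnot(nrow(features_a) == nrow(features_b))
    dx <- as.matrix(stats::dist(features_a))
    dy <- as.matrix(stats::dist(features_b))
  }
  n <- nrow(dx)
  if (n < 3) stop("HHG needs at least 3 paired observations")
  obs <- hhg_statistic(dx, dy)
  exceed <- 0
  for (b in seq_len(n_permutations)) {
    p <- sample.int(n)
    if (hhg_statistic(dx, dy[p, p]) >= obs) exceed <- exceed + 1
  }
  list(statistic = obs, p_value = (1 + exceed) / (1 + n_permutations),
       n_permutations = n_permutations)
}

#' Pairwise dissimilarity matrix over a model collection
#'
#' Builds the model-by-model dissimilarity matrix for a list of adjacency
#' matrices (anatomical connectivity) or functional graphs.  With
#' \code{method = "netsimile"} entries are Canberra distances between
#' NetSimile signatures, normalized to [0, 1] by the matrix maximum; with
#' \code{method = "hhg"} entries are permutation p-values of the HHG test on
#' per-node NetSimile features (higher p is read as lower resemblance).
#'
#' @param graphs named list of adjacency matrices (same node count for
#'   \code{"hhg"}).
#' @param method \code{"netsimile"} or \code{"hhg"}.
#' @param n_permutations permutations per HHG pair.
#' @param normalize divide NetSimile distances by the matrix maximum
#'   (default TRUE).
#' @return square matrix with model names as dimnames and a
#'   \code{"method"} attribute; zero diagonal.
#' @export
dissimilarity_matrix <- function(graphs, method = c("netsimile", "hhg"),
                                 n_permutations = 1000, normalize = TRUE) {
  method <- match.arg(method)
  k <- length(graphs)
  stopifnot(k >= 2)
  nm <- names(graphs)
  if (is.null(nm)) nm <- paste0("m", seq_len(k))
  d <- matrix(0, k, k, dimnames = list(nm, nm))
  if (method == "netsimile") {
    sigs <- lapply(graphs, netsimile_signature)
    for (i in seq_len(k - 1)) for (j in (i + 1):k) {
      v <- netsimile_distance(sigs[[i]], sigs[[j]])
      d[i, j] <- v; d[j, i] <- v
    }
    if (normalize && max(d) > 0) d <- d / max(d)
  } else {
    feats <- lapply(graphs, netsimile_features)
    for (i in seq_len(k - 1)) for (j in (i + 1):k) {
      v <- hhg_test(feats[[i]], feats[[j]], n_permutations)$p_value
      d[i, j] <- v; d[j, i] <- v
    }
  }
  attr(d, "method") <- method
  d
}

#' Within- and between-family contrast
#'
#' Averages the entries of a dissimilarity matrix over every family-by-family
#' block.  The denominator is the actual block size (so within-family blocks
#' include the zero self-pairs, and families shrunk by terminated-model
#' exclusion average over their remaining members).
#'
#' @param diss square dissimilarity matrix.
#' @param families character/factor vector assigning each model (row) to a
#'   family.
#' @return family-by-family matrix of mean dissimilarities.
#' @export
family_contrast <- function(diss, families) {
  stopifnot(nrow(diss) == length(families))
  fams <- unique(as.character(families))
  out <- matrix(NA_real_, length(fams), length(fams),
                dimnames = list(fams, fams))
  for (fi in fams) for (fj in fams) {
    ri <- which(families == fi); rj <- which(families == fj)
    out[fi, fj] <- mean(diss[ri, rj, drop = FALSE])
  }
  out
}

#' Family differentiation scores
#'
#' For each family, the within-family resemblance (1 minus the within
#' contrast) divided by the mean between-family resemblance.  Values above 1
#' mean the family's members resemble each other more than they resemble
#' other families.  Meaningful for dissimilarities normalized to [0, 1]
#' (NetSimile); not defined for HHG p-value matrices.
#'
#' @param contrasts family-by-family contrast matrix from
#'   \code{\link{family_contrast}} of a normalized NetSimile matrix.
#' @return named numeric vector, one score per family.
#' @export
differentiation_scores <- function(contrasts) {
  fams <- rownames(contrasts)
  stopifnot(length(fams) >= 2)
  vapply(fams, function(fi) {
    within <- 1 - contrasts[fi, fi]
    between <- mean(1 - contrasts[fi, setdiff(fams, fi)])
    if (between == 0) stop("zero between-family resemblance for ", fi)
    within / between
  }, numeric(1))
}

#' Composite dissimilarity matrix
#'
#' Packs two dissimilarity matrices over the same models into one: the lower
#' triangle holds the HHG p-values, the upper triangle the normalized
#' NetSimile distances, with a zero diagonal.
#'
#' @param netsimile,hhg square matrices with identical model ordering.
#' @return composite matrix.
#' @export
composite_dissimilarity <- function(netsimile, hhg) {
  stopifnot(all(dim(netsimile) == dim(hhg)))
  out <- matrix(0, nrow(netsimile), ncol(netsimile),
                dimnames = dimnames(netsimile))
  out[upper.tri(out)] <- netsimile[upper.tri(netsimile)]
  out[lower.tri(out)] <- hhg[lower.tri(hhg)]
  out
}
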