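#' Run manifest for one model instantiation
#'
#' Collects everything that determines a single simulated model: the
#' parameter family, the instantiation index (which selects the matched
#' initialization shared across families), the master seed, network size and
#' the rewiring/metric cadences.
#'
#' @param family family name (\code{"BL"}, \code{"LC"}, \code{"MC"},
#'   \code{"SC"}, \code{"HC"}) or a \code{\link{family_spec}}.
#' @param instantiation instantiation index (>= 1).
#' @param seed master seed; all randomness derives from it through named
#'   substreams.
#' @param n_nodes,n_edges network size (defaults 300 nodes, 5200 edges).
#' @param minority_size minority subset size (default 50).
#' @param attempts total rewiring attempts to run (the full-scale study
#'   default is 1e6; scaled runs use far fewer).
#' @param updates_per_rewiring coupled-map updates per rewiring attempt
#'   (default 20).
#' @param cadence metric checkpoint spacing in attempts (default 1000).
#' @param neighbor_amplitude amplitude convention in the coupling sum, see
#'   \code{\link{coupled_step}}.
#' @return list of class \code{"run_manifest"}.
#' @export
run_manifest <- function(family = "BL", instantiation = 1, seed = 1,
                         n_nodes = 300, n_edges = 5200, minority_size = 50,
                         attempts = 1e6, updates_per_rewiring = 20,
                         cadence = 1000,
                         neighbor_amplitude = c("self", "neighbor")) {
  if (!inherits(family, "family_spec"))
    family <- family_spec(family, minority_size = minority_size)
  neighbor_amplitude <- match.arg(neighbor_amplitude)
  stopifnot(attempts >= 0, updates_per_rewiring >= 1, cadence >= 1,
            minority_size < n_nodes)
  structure(list(family = family, instantiation = as.integer(instantiation),
                 seed = as.integer(seed), n_nodes = as.integer(n_nodes),
                 n_edges = as.integer(n_edges),
                 minority_size = as.integer(minority_size),
                 attempts = as.integer(attempts),
                 updates_per_rewiring = as.integer(updates_per_rewiring),
                 cadence = as.integer(cadence),
                 neighbor_amplitude = neighbor_amplitude),
            class = "run_manifest")
}

#' Simulate one adaptively rewiring network
#'
#' Runs the full trajectory of one model: a random initial graph and
#' Uniform(0,1) activations (drawn from the instantiation's matched
#' initialization substream, identical across families), then alternating
#' blocks of coupled-map updates and rewiring attempts, checkpointing the
#' network statistics of all four scopes every \code{cadence} attempts
#' (including attempt 0).  A pathological model -- a pivot connected to all
#' other nodes, or a node isolated by a rewiring -- terminates cleanly: the
#' state freezes, the metric series stops at the termination attempt, and
#' the termination record carries the reason.
#'
#' @param manifest a \code{\link{run_manifest}}.
#' @return object of class \code{"rewire_sim"}: list with \code{manifest},
#'   \code{adjacency}, \code{activations}, \code{metrics} (data frame with
#'   \code{attempt}, \code{scope} and the six statistics), \code{attempts_done}
#'   and \code{termination} (list \code{terminated}, \code{reason},
#'   \code{attempt}, \code{node}).
#' @export
simulate_network <- function(manifest) {
  stopifnot(inherits(manifest, "run_manifest"))
  m <- manifest
  set.seed(substream_seed(m$seed, "init", m$instantiation))
  adj <- random_graph(m$n_nodes, m$n_edges)
  x <- init_activations(m$n_nodes)
  params <- family_parameters(m$family, m$n_nodes)
  amp <- if (m$neighbor_amplitude == "self") 0L else 1L

  set.seed(substream_seed(m$seed, "dyn", m$family$name, m$instantiation))
  metrics <- list(cbind(attempt = 0, network_metrics(adj, m$minority_size)))
  attempts_done <- 0L
  term <- list(terminated = FALSE, reason = "none",
               attempt = NA_integer_, node = NA_integer_)
  while (attempts_done < m$attempts) {
    step <- min(m$cadence, m$attempts - attempts_done)
    seg <- run_segment_cpp(adj, x, params$alpha, params$epsilon,
                           step, m$updates_per_rewiring, amp)
    adj <- seg$adjacency
    x <- seg$activations
    attempts_done <- attempts_done + seg$attempts_done
    if (seg$terminated) {
      term <- list(terminated = TRUE, reason = seg$reason,
                   attempt = attempts_done, node = seg$term_node)
      metrics[[length(metrics) + 1]] <-
        cbind(attempt = attempts_done, network_metrics(adj, m$minority_size))
      break
    }
    metrics[[length(metrics) + 1]] <-
      cbind(attempt = attempts_done, network_metrics(adj, m$minority_size))
  }
  metrics <- do.call(rbind, metrics)
  rownames(metrics) <- NULL
  structure(list(manifest = m, adjacency = adj, activations = x,
                 metrics = metrics, attempts_done = attempts_done,
                 termination = term),
            class = "rewire_sim")
}

#' @export
print.rewire_sim <- function(x, ...) {
  m <- x$manifest
  cat(sprintf("Adaptive rewiring simulation: family %s, instantiation %d\n",
              m$family$name, m$instantiation))
  cat(sprintf("  %d nodes, %d edges, %d/%d rewiring attempts done\n",
              m$n_nodes, m$n_edges, x$attempts_done, m$attempts))
  if (x$termination$terminated)
    cat(sprintf("  TERMINATED at attempt %d (%s)\n",
                x$termination$attempt, x$termination$reason))
  cat(sprintf("  metric checkpoints: %d (cadence %d)\n",
              length(unique(x$metrics$attempt)), m$cadence))
  invisible(x)
}

#' @export
summary.rewire_sim <- function(object, window_start = 60000, ...) {
  ms <- object$metrics
  win <- ms[ms$attempt >= window_start, ]
  if (nrow(win) == 0) win <- ms[ms$attempt == max(ms$attempt), ]
  agg <- stats::aggregate(win[metric_names], by = list(scope = win$scope),
                          FUN = function(v) mean(v, na.rm = TRUE))
  structure(list(manifest = object$manifest, window_start = window_start,
                 window_means = agg, termination = object$termination),
            class = "summary.rewire_sim")
}

#' @export
print.summary.rewire_sim <- function(x, ...) {
  cat(sprintf("Windowed means (attempts >= %d), family %s #%d\n",
              x$window_start, x$manifest$family$name, x$manifest$instantiation))
  print(x$window_means, digits = 4)
  invisible(x)
}

#' @export
plot.rewire_sim <- function(x, scope = "whole",
                            metrics = c("clustering", "modularity",
                                        "small_world", "assortativity"), ...) {
  ms <- x$metrics[x$metrics$scope == scope, ]
  old <- graphics::par(mfrow = c(2, 2), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(old))
  for (mn in metrics)
    graphics::plot(ms$attempt, ms[[mn]], type = "l", xlab = "rewiring attempt",
                   ylab = mn, main = mn, ...)
  invisible(x)
}

#' Run a battery of model families with matched initializations
#'
#' Simulates \code{instantiations} models per family.  For a given
#' instantiation index the initial graph and activations are identical across
#' families (the initialization substream ignores the family), so families
#' differ only through their parameters and their own pivot-draw streams.
#'
#' @param families character vector of family names.
#' @param instantiations instantiations per family.
#' @param seed master seed.
#' @param attempts rewiring attempts per run.
#' @param ... further arguments to \code{\link{run_manifest}}.
#' @return object of class \code{"rewire_battery"}: list of
#'   \code{rewire_sim} runs plus the call settings.
#' @export
run_battery <- function(families = c("BL", "LC", "MC", "SC", "HC"),
                        instantiations = 3, seed = 1, attempts = 200000, ...) {
  runs <- list()
  for (fam in families) {
    for (k in seq_len(instantiations)) {
      man <- run_manifest(family = fam, instantiation = k, seed = seed,
                          attempts = attempts, ...)
      runs[[paste0(fam, k)]] <- simulate_network(man)
    }
  }
  structure(list(runs = runs, families = families,
                 instantiations = instantiations, seed = seed,
                 attempts = attempts),
            class = "rewire_battery")
}

#' @export
print.rewire_battery <- function(x, ...) {
  cat(sprintf("Battery: %d runs (%s x %d), %d attempts each, seed %d\n",
              length(x$runs), paste(x$families, collapse = "/"),
              x$instantiations, x$attempts, x$seed))
  term <- vapply(x$runs, function(r) r$termination$terminated, logical(1))
  if (any(term))
    cat("  terminated:", paste(names(x$runs)[term], collapse = ", "), "\n")
  invisible(x)
}

#' Windowed, normalized summary table of a battery
#'
#' Means and standard deviations per family, scope and statistic over the
#' checkpoints at or beyond \code{window_start} attempts, normalized by the
#' baseline-ensemble means (assortativity unnormalized).  Terminated runs
#' never contribute.
#'
#' @param battery a \code{\link{run_battery}} result.
#' @param baselines named list of scope baselines from
#'   \code{\link{baseline_metric_means}}; \code{NULL} for raw values.
#' @param window_start first attempt of the averaging window (default 60000).
#' @return data frame with columns family, scope, metric, mean, sd, n_runs.
#' @export
battery_summary <- function(battery, baselines = NULL, window_start = 60000) {
  keep <- Filter(function(r) !r$termination$terminated, battery$runs)
  if (length(keep) == 0) stop("no non-terminated runs to summarize")
  rows <- list()
  for (r in keep) {
    ms <- r$metrics
    ms <- ms[ms$attempt >= window_start, ]
    if (nrow(ms) == 0) next
    if (!is.null(baselines)) ms <- normalize_metrics(ms, baselines)
    ms$family <- r$manifest$family$name
    rows[[length(rows) + 1]] <- ms
  }
  all <- do.call(rbind, rows)
  out <- list()
  for (fam in unique(all$family)) for (sc in unique(all$scope)) {
    sub <- all[all$family == fam & all$scope == sc, ]
    for (mn in metric_names) {
      v <- sub[[mn]]
      out[[length(out) + 1]] <- data.frame(
        family = fam, scope = sc, metric = mn,
        mean = mean(v, na.rm = TRUE), sd = stats::sd(v, na.rm = TRUE),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Growth factors of network statistics
#'
#' Ratio of the windowed post-\code{window_start} mean of each statistic to
#' its value on the initial (attempt-0) random network, per scope.
#'
#' @param sim a \code{\link{simulate_network}} result (or its \code{metrics}
#'   data frame).
#' @param window_start start of the averaging window (default 60000
#'   attempts).
#' @return data frame with columns scope, metric, initial, windowed_mean,
#'   factor.
#' @export
growth_factors <- function(sim, window_start = 60000) {
  ms <- if (inherits(sim, "rewire_sim")) sim$metrics else sim
  stopifnot(any(ms$attempt == 0))
  if (max(ms$attempt) < window_start)
    stop("series ends before the averaging window starts")
  win <- ms[ms$attempt >= window_start, ]
  ini <- ms[ms$attempt == 0, ]
  rows <- list()
  for (sc in unique(ms$scope)) {
    w <- win[win$scope == sc, ]
    i0 <- ini[ini$scope == sc, ]
    for (mn in metric_names) {
      init_v <- i0[[mn]]
      mean_v <- mean(w[[mn]], na.rm = TRUE)
      rows[[length(rows) + 1]] <- data.frame(
        scope = sc, metric = mn, initial = init_v, windowed_mean = mean_v,
        factor = if (!is.na(init_v) && init_v != 0) mean_v / init_v else NA_real_,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
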