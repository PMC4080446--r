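#' Empirical p-value with the add-one rule
#'
#' \code{p = (1 + #\{v >= observed\}) / (B + 1)} for \code{tail = "ge"}
#' (mirrored for \code{"le"}); never 0, bounded below by \code{1/(B+1)}.
#'
#' @param observed observed statistic.
#' @param values numeric vector of null replicate values.
#' @param tail \code{"ge"} (observed large under the alternative) or
#'   \code{"le"}.
#' @return scalar p-value in \code{(0, 1]}.
#' @export
empirical_p <- function(observed, values, tail = c("ge", "le")) {
  tail <- match.arg(tail)
  if (length(values) < 1L) stop("need at least one null replicate")
  hits <- if (tail == "ge") sum(values >= observed) else sum(values <= observed)
  (1 + hits) / (length(values) + 1)
}

# Summarize one replicate into the statistics tracked by the null models.
replicate_stats <- function(net) {
  ts <- topology_summary(net)
  c(n_nodes = ts$n_nodes, n_edges = ts$n_edges,
    mean_degree = ts$mean_degree, mean_clustering = ts$mean_clustering,
    mean_betweenness = ts$mean_betweenness)
}

#' Global random-seed null model
#'
#' Each replicate samples \code{seed_size} nodes uniformly without
#' replacement from the network, extracts their seed subnetwork
#' (seeds + first neighbors, induced), and records its topology. The
#' observed subnetwork's statistics are compared to the replicate
#' distributions with add-one empirical p-values; for each statistic the
#' tail is chosen by the side of the null mean the observed value falls on,
#' and reported.
#'
#' @param net an igraph network (e.g. a weighted methylation network).
#' @param seeds observed seed gene ids (their count sets the replicate seed
#'   size, and the observed subnetwork is built from them).
#' @param B number of replicates (>= 1).
#' @param rng_seed integer seed.
#' @return list with \code{observed} (named statistics), \code{replicates}
#'   (B x statistic matrix) and \code{p} (data frame: statistic, observed,
#'   null_mean, tail, p).
#' @export
global_null <- function(net, seeds, B = 1000, rng_seed = 1) {
  if (B < 1) stop("B must be >= 1")
  seed_size <- length(intersect(seeds, igraph::V(net)$name))
  if (seed_size < 1) stop("no seeds present in the network")
  if (seed_size > igraph::vcount(net))
    stop("seed_size exceeds node count")
  obs <- replicate_stats(extract_seed_subnetwork(net, seeds))
  nodes <- igraph::V(net)$name
  reps <- local_seed(rng_seed, {
    t(vapply(seq_len(B), function(b) {
      rs <- sample(nodes, seed_size)
      replicate_stats(extract_seed_subnetwork(net, rs))
    }, obs))
  })
  list(observed = obs, replicates = reps, p = null_p_table(obs, reps))
}

null_p_table <- function(obs, reps) {
  do.call(rbind, lapply(names(obs), function(s) {
    tail <- if (obs[[s]] >= mean(reps[, s])) "ge" else "le"
    data.frame(statistic = s, observed = obs[[s]],
               null_mean = mean(reps[, s]), tail = tail,
               p = empirical_p(obs[[s]], reps[, s], tail),
               stringsAsFactors = FALSE)
  }))
}

#' Degree-preserving randomization by double-edge swaps
#'
#' Repeatedly picks two edges (a,b) and (c,d) with four distinct endpoints
#' and, when neither (a,d) nor (c,b) already exists, replaces the pair with
#' (a,d) and (c,b) — conserving every node's degree exactly and never
#' creating self-loops or duplicate edges. Swapping stops after
#' \code{ceil(swap_fraction * |E|)} accepted swaps; rejected proposals do
#' not count. If no valid swap is found within \code{max_tries} proposals
#' the graph achieved so far is returned with a warning (e.g. a triangle,
#' where no valid swap exists). Edge weights are dropped: the null is
#' purely topological.
#'
#' @param net an igraph network with >= 2 edges.
#' @param swap_fraction accepted swaps as a fraction of the edge count.
#' @param rng_seed integer seed.
#' @param max_tries proposal budget (default \code{100 * |E|}).
#' @return a rewired igraph with the same degree sequence; attribute
#'   \code{"swaps"} records the accepted swap count.
#' @export
degree_preserving_rewire <- function(net, swap_fraction = 0.5, rng_seed = 1,
                                     max_tries = NULL) {
  m <- igraph::ecount(net)
  if (m < 2) stop("need at least 2 edges to rewire")
  if (is.null(max_tries)) max_tries <- 100L * m
  target <- as.integer(ceiling(swap_fraction * m))
  el <- igraph::as_edgelist(net, names = FALSE)
  nodes <- igraph::V(net)$name
  exists <- new.env(hash = TRUE, parent = emptyenv(), size = 2L * m)
  key <- function(a, b) paste(min(a, b), max(a, b))
  for (i in seq_len(m)) assign(key(el[i, 1L], el[i, 2L]), TRUE, exists)

  done <- 0L
  local_seed(rng_seed, {
    tries <- 0L
    while (done < target && tries < max_tries) {
      tries <- tries + 1L
      ij <- sample.int(m, 2L)
      a <- el[ij[1L], 1L]; b <- el[ij[1L], 2L]
      c_ <- el[ij[2L], 1L]; d <- el[ij[2L], 2L]
      # randomize pairing direction so both matchings are reachable
      if (stats::runif(1) < 0.5) { tmp <- c_; c_ <- d; d <- tmp }
      if (length(unique(c(a, b, c_, d))) < 4L) next
      k1 <- key(a, d); k2 <- key(c_, b)
      if (exists(k1, envir = exists, inherits = FALSE) ||
          exists(k2, envir = exists, inherits = FALSE)) next
      rm(list = c(key(a, b), key(c_, d)), envir = exists)
      assign(k1, TRUE, exists); assign(k2, TRUE, exists)
      el[ij[1L], ] <- c(a, d)
      el[ij[2L], ] <- c(c_, b)
      done <- done + 1L
    }
  })
  if (done < target)
    warning(sprintf("rewiring stalled: %d of %d swaps accepted", done, target))
  g <- igraph::graph_from_edgelist(
    matrix(nodes[el], ncol = 2L), directed = FALSE)
  g <- igraph::add_vertices(g, length(setdiff(nodes, igraph::V(g)$name)),
                            name = setdiff(nodes, igraph::V(g)$name))
  attr(g, "swaps") <- done
  g
}

#' Local rewiring null model for a network component
#'
#' Generates \code{B} degree-preserving rewirings of the (giant) component
#' and summarizes the clustering coefficient and betweenness (plus degree)
#' of each replicate, yielding add-one empirical p-values for the observed
#' component against a null that keeps node and edge counts and the degree
#' sequence fixed but randomizes the wiring.
#'
#' @param component an igraph network (typically a giant component).
#' @param B number of replicates.
#' @param swap_fraction fraction of edges swapped per replicate.
#' @param rng_seed integer seed.
#' @return list as in \code{\link{global_null}}.
#' @export
local_null <- function(component, B = 1000, swap_fraction = 0.5,
                       rng_seed = 1) {
  if (B < 1) stop("B must be >= 1")
  obs <- replicate_stats(component)
  reps <- t(vapply(seq_len(B), function(b) {
    rw <- suppressWarnings(
      degree_preserving_rewire(component, swap_fraction,
                               rng_seed = rng_seed + b))
    replicate_stats(rw)
  }, obs))
  list(observed = obs, replicates = reps, p = null_p_table(obs, reps))
}
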