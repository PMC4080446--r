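#' Weight an interaction background by profile correlation
#'
#' For every background interaction whose two genes both carry a profile,
#' the Pearson correlation \code{r} of the two profile vectors and its
#' two-sided p-value (t approximation with \code{df = length - 2}) are
#' computed; the edge is retained iff \code{|r| > r_cut} and \code{p <
#' alpha} (strict, as both filters are defined). Genes without a profile are
#' dropped from the node set; edges touching a zero-variance profile are
#' skipped and logged (their correlation is undefined).
#'
#' @param interactions background edge data frame (gene_a, gene_b).
#' @param profiles numeric matrix of per-gene profile vectors (genes in
#'   rows: per-sample betas for the methylation layer, per-mark intensities
#'   for the chromatin layer), with >= 3 columns.
#' @param r_cut absolute-correlation threshold (edges need \code{|r| >
#'   r_cut}).
#' @param alpha p-value threshold (edges need \code{p < alpha}).
#' @return an undirected igraph whose nodes are the profiled genes and whose
#'   retained edges carry attributes \code{r} and \code{p}.
#' @export
weight_network <- function(interactions, profiles, r_cut = 0.8,
                           alpha = 0.05) {
  stopifnot(is.matrix(profiles), ncol(profiles) >= 3,
            !is.null(rownames(profiles)))
  genes <- rownames(profiles)
  have <- interactions$gene_a %in% genes & interactions$gene_b %in% genes
  if (any(!have))
    log_msg("weight_network", sum(!have),
            " background edges dropped (endpoint without profile)")
  e <- interactions[have, , drop = FALSE]

  n <- ncol(profiles)
  ctr <- profiles - rowMeans(profiles)
  ss <- rowSums(ctr^2)
  zero_var <- ss < .Machine$double.eps
  touches0 <- zero_var[e$gene_a] | zero_var[e$gene_b]
  if (any(touches0))
    log_msg("weight_network", sum(touches0),
            " edges skipped (zero-variance profile, r undefined)")
  e <- e[!touches0, , drop = FALSE]

  ia <- match(e$gene_a, genes)
  ib <- match(e$gene_b, genes)
  r <- rowSums(ctr[ia, , drop = FALSE] * ctr[ib, , drop = FALSE]) /
    sqrt(ss[ia] * ss[ib])
  r <- pmin(1, pmax(-1, r))
  df <- n - 2
  tstat <- abs(r) * sqrt(df / pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * stats::pt(tstat, df, lower.tail = FALSE)
  p[abs(r) >= 1] <- 0

  keep <- abs(r) > r_cut & p < alpha
  log_msg("weight_network", sum(keep), " of ", length(keep),
          " correlated edges retained at |r| > ", r_cut, ", p < ", alpha)
  g <- igraph::graph_from_data_frame(
    data.frame(e$gene_a[keep], e$gene_b[keep]),
    directed = FALSE, vertices = genes)
  igraph::E(g)$r <- r[keep]
  igraph::E(g)$p <- p[keep]
  # like the published weighted networks, the node set is the genes incident
  # to at least one retained edge
  igraph::delete_vertices(g, igraph::degree(g) == 0)
}

#' Extract the seed-gene subnetwork
#'
#' The node set is the seed genes present in the network together with all
#' their first neighbors; the edge set is every network edge with both ends
#' in that node set (induced subgraph). Seeds absent from the network are
#' ignored with a log entry; seed membership is annotated on the nodes.
#'
#' @param net an igraph network.
#' @param seeds character vector of seed gene ids.
#' @return the induced igraph subgraph with logical node attribute
#'   \code{seed}.
#' @export
extract_seed_subnetwork <- function(net, seeds) {
  present <- intersect(seeds, igraph::V(net)$name)
  if (length(present) < length(unique(seeds)))
    log_msg("seed_subnetwork", length(unique(seeds)) - length(present),
            " seeds absent from the network ignored")
  if (length(present) == 0L)
    return(igraph::induced_subgraph(net, integer(0)))
  nbrs <- igraph::V(net)$name[unique(unlist(
    igraph::adjacent_vertices(net, present), use.names = FALSE))]
  nodes <- union(present, nbrs)
  sub <- igraph::induced_subgraph(net, nodes)
  igraph::V(sub)$seed <- igraph::V(sub)$name %in% present
  sub
}

#' Largest connected component
#'
#' Ties on node count are broken by edge count, then by the lexicographically
#' smallest node id.
#'
#' @param net an igraph network.
#' @return the giant component as an igraph.
#' @export
giant_component <- function(net) {
  if (igraph::vcount(net) == 0L) stop("empty network")
  comp <- igraph::components(net)
  sizes <- comp$csize
  cand <- which(sizes == max(sizes))
  if (length(cand) > 1L) {
    ec <- vapply(cand, function(k)
      igraph::ecount(igraph::induced_subgraph(net, comp$membership == k)), 0)
    cand <- cand[ec == max(ec)]
    if (length(cand) > 1L) {
      firsts <- vapply(cand, function(k)
        min(igraph::V(net)$name[comp$membership == k]), "")
      cand <- cand[which.min(firsts)]
    }
  }
  igraph::induced_subgraph(net, comp$membership == cand[1L])
}

#' Topological summary of a network
#'
#' Reports node and edge counts, mean degree, mean local clustering
#' coefficient (\code{2 T_v / (k_v (k_v - 1))}, defined as 0 when
#' \code{k_v < 2}), mean non-normalized shortest-path betweenness, and the
#' power-law exponent of the degree distribution estimated as the negative
#' slope of a least-squares fit of \code{log10 count} on \code{log10 degree}
#' over degrees with nonzero counts.
#'
#' @param net an igraph network.
#' @return list with \code{n_nodes}, \code{n_edges}, \code{mean_degree},
#'   \code{mean_clustering}, \code{mean_betweenness}, \code{powerlaw_exp}
#'   (NA when fewer than 2 distinct positive degrees).
#' @export
topology_summary <- function(net) {
  if (igraph::vcount(net) == 0L) stop("empty network")
  deg <- igraph::degree(net)
  cc <- igraph::transitivity(net, type = "local", isolates = "zero")
  cc[deg < 2] <- 0
  btw <- igraph::betweenness(net, directed = FALSE, normalized = FALSE)
  list(n_nodes = igraph::vcount(net),
       n_edges = igraph::ecount(net),
       mean_degree = mean(deg),
       mean_clustering = mean(cc),
       mean_betweenness = mean(btw),
       powerlaw_exp = powerlaw_exponent(deg))
}

#' Degree-distribution power-law exponent by log-log regression
#'
#' @param degrees integer vector of node degrees.
#' @return negative slope of the least-squares fit of log10 count vs log10
#'   degree over nonzero-count positive degrees; NA if fewer than two
#'   distinct such degrees.
#' @export
powerlaw_exponent <- function(degrees) {
  tab <- table(degrees[degrees > 0])
  k <- as.numeric(names(tab))
  cnt <- as.numeric(tab)
  if (length(k) < 2L) return(NA_real_)
  fit <- stats::lm.fit(cbind(1, log10(k)), log10(cnt))
  -unname(fit$coefficients[2L])
}
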