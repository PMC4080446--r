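#' MCODE-style vertex weights
#'
#' A node's weight is the core number of the highest k-core of its closed
#' neighborhood, multiplied by that core's edge density
#' \code{2E / (n (n - 1))} (self-loops excluded). Dense local neighborhoods
#' thus weight high; an isolated node weights 0.
#'
#' @param net an igraph network.
#' @return named numeric vector of weights.
#' @export
mcode_weights <- function(net) {
  nodes <- igraph::V(net)
  w <- stats::setNames(numeric(length(nodes)), nodes$name)
  adj <- igraph::adjacent_vertices(net, nodes)
  for (i in seq_along(nodes)) {
    nb <- c(i, as.integer(adj[[i]]))
    sub <- igraph::induced_subgraph(net, unique(nb))
    if (igraph::vcount(sub) < 2 || igraph::ecount(sub) == 0) next
    core <- igraph::coreness(sub)
    kmax <- max(core)
    core_sub <- igraph::induced_subgraph(sub, core == kmax)
    n <- igraph::vcount(core_sub)
    dens <- if (n < 2) 0 else
      2 * igraph::ecount(core_sub) / (n * (n - 1))
    w[i] <- kmax * dens
  }
  w
}

#' MCODE-style dense module detection
#'
#' Greedy seed expansion: starting from the highest-weight unvisited node,
#' neighbors with weight at least \code{(1 - node_score_cutoff)} times the
#' seed weight are admitted recursively; visited nodes cannot join later
#' modules, so modules are vertex-disjoint. The optional haircut prunes a
#' module to its 2-core (removing singly-connected vertices); modules
#' smaller than \code{min_size} are dropped. Ties are broken by descending
#' weight then node id, making the output deterministic and invariant to
#' node relabeling up to that tie-break.
#'
#' @param net an igraph network.
#' @param node_score_cutoff admission slack relative to the seed weight.
#' @param haircut prune each module to its 2-core.
#' @param fluff unsupported expansion variant; must stay \code{FALSE}.
#' @param min_size minimum module size after pruning.
#' @return data frame with columns \code{module_id}, \code{score}
#'   (density x size of the module subgraph), \code{size} and list-column
#'   \code{genes}, ordered by decreasing score.
#' @export
mcode_modules <- function(net, node_score_cutoff = 0.2, haircut = TRUE,
                          fluff = FALSE, min_size = 3) {
  if (fluff) stop("fluff expansion is not implemented")
  if (igraph::vcount(net) == 0L)
    return(empty_module_set())
  w <- mcode_weights(net)
  name <- igraph::V(net)$name
  ord <- order(-w, name)
  visited <- stats::setNames(logical(length(w)), name)
  adj <- igraph::adjacent_vertices(net, igraph::V(net))
  names(adj) <- name

  raw <- list()
  for (i in ord) {
    seed <- name[i]
    if (visited[seed]) next
    thr <- (1 - node_score_cutoff) * w[seed]
    members <- seed
    visited[seed] <- TRUE
    frontier <- seed
    while (length(frontier)) {
      cand <- unique(unlist(lapply(frontier, function(v)
        name[as.integer(adj[[v]])]), use.names = FALSE))
      cand <- cand[!visited[cand] & w[cand] >= thr & w[cand] > 0]
      visited[cand] <- TRUE
      members <- c(members, cand)
      frontier <- cand
    }
    if (length(members) >= 2L) raw[[length(raw) + 1L]] <- members
  }

  mods <- list()
  for (members in raw) {
    sub <- igraph::induced_subgraph(net, members)
    if (haircut) {
      core <- igraph::coreness(sub)
      sub <- igraph::induced_subgraph(sub, core >= 2)
    }
    # dense regions joined only by a bridge edge are distinct modules:
    # split at bridges so every reported module is 2-edge-connected
    for (piece in split_at_bridges(sub)) {
      n <- igraph::vcount(piece)
      if (n < min_size) next
      dens <- if (n < 2) 0 else 2 * igraph::ecount(piece) / (n * (n - 1))
      mods[[length(mods) + 1L]] <-
        list(genes = sort(igraph::V(piece)$name), score = dens * n,
             size = as.integer(n))
    }
  }
  if (!length(mods)) return(empty_module_set())
  ordm <- order(-vapply(mods, `[[`, 0, "score"),
                vapply(mods, function(m) m$genes[1L], ""))
  mods <- mods[ordm]
  data.frame(module_id = seq_along(mods),
             score = vapply(mods, `[[`, 0, "score"),
             size = vapply(mods, `[[`, 0L, "size"),
             genes = I(lapply(mods, `[[`, "genes")),
             stringsAsFactors = FALSE)
}

# Delete bridge edges and return the resulting components as subgraphs
# (singletons included; callers filter by size).
split_at_bridges <- function(sub) {
  if (igraph::vcount(sub) == 0L) return(list())
  br <- igraph::bridges(sub)
  if (length(br)) sub <- igraph::delete_edges(sub, br)
  comp <- igraph::components(sub)
  lapply(seq_len(comp$no), function(k)
    igraph::induced_subgraph(sub, comp$membership == k))
}

empty_module_set <- function() {
  data.frame(module_id = integer(), score = numeric(), size = integer(),
             genes = I(list()))
}

#' Upper-tail cumulative hypergeometric probability
#'
#' \code{P(X >= x)} for the overlap \code{X} of a size-\code{H} draw with a
#' marked subset of size \code{M} in a background of \code{N} genes:
#' \code{1 - sum_{k=0}^{x-1} C(M,k) C(N-M,H-k) / C(N,H)}. Computed in log
#' space (log binomials accumulated with log-sum-exp) for numerical
#' stability at genome-scale \code{N}.
#'
#' @param N background gene count.
#' @param M size of the first module (marked genes).
#' @param H size of the second module (draw).
#' @param x observed overlap (lower limit of the tail).
#' @return the exact tail probability.
#' @export
hypergeom_upper <- function(N, M, H, x) {
  if (any(c(N, M, H, x) < 0) || M > N || H > N || x > min(M, H))
    stop("infeasible (N, M, H, x)")
  if (x <= max(0, M + H - N)) return(1)
  k <- seq.int(x, min(M, H))
  logp <- lchoose(M, k) + lchoose(N - M, H - k) - lchoose(N, H)
  mx <- max(logp)
  min(1, exp(mx + log(sum(exp(logp - mx)))))
}

#' Detect interplay modules between two module sets
#'
#' Every (methylation module, chromatin module) pair is scored by the size
#' of its gene overlap; pairs reaching \code{min_overlap} are the tested
#' candidates and get an upper-tail cumulative hypergeometric p-value
#' against the background gene universe, Bonferroni-corrected by the number
#' of tested candidates (optionally by the count of all pairs). Pairs with
#' corrected p below \code{alpha} are the significant interplay modules.
#'
#' @param meth,chrom module sets as returned by \code{\link{mcode_modules}}.
#' @param background character vector: the background gene universe (must
#'   contain every module gene); its length is \code{N}.
#' @param min_overlap smallest overlap admitted to testing.
#' @param alpha significance level on the corrected p-value.
#' @param correct_by Bonferroni denominator: candidates passing the overlap
#'   filter (default) or all cross pairs.
#' @return data frame with one row per pair: module ids and sizes, overlap
#'   size and genes (list-column), \code{p} and \code{p_bonferroni} (NA for
#'   untested pairs), and \code{significant}.
#' @export
interplay <- function(meth, chrom, background, min_overlap = 3,
                      alpha = 0.05, correct_by = c("tested", "all")) {
  correct_by <- match.arg(correct_by)
  if (nrow(meth) == 0L || nrow(chrom) == 0L)
    return(empty_interplay())
  all_genes <- unique(c(unlist(meth$genes), unlist(chrom$genes)))
  if (!all(all_genes %in% background))
    stop("background must contain every module gene")
  N <- length(unique(background))

  grid <- expand.grid(mi = seq_len(nrow(meth)), ci = seq_len(nrow(chrom)))
  res <- lapply(seq_len(nrow(grid)), function(i) {
    mg <- meth$genes[[grid$mi[i]]]
    cg <- chrom$genes[[grid$ci[i]]]
    ov <- intersect(mg, cg)
    list(meth_module = meth$module_id[grid$mi[i]], meth_size = length(mg),
         chrom_module = chrom$module_id[grid$ci[i]], chrom_size = length(cg),
         overlap = length(ov), overlap_genes = sort(ov))
  })
  overlap <- vapply(res, `[[`, 0L, "overlap")
  tested <- overlap >= min_overlap
  n_tests <- if (correct_by == "tested") sum(tested) else length(res)
  p <- rep(NA_real_, length(res))
  p[tested] <- vapply(which(tested), function(i)
    hypergeom_upper(N, res[[i]]$meth_size, res[[i]]$chrom_size,
                    res[[i]]$overlap), 0)
  p_bonf <- pmin(1, p * max(n_tests, 1L))
  out <- data.frame(
    meth_module = vapply(res, function(r) as.integer(r$meth_module), 0L),
    meth_size = vapply(res, `[[`, 0L, "meth_size"),
    chrom_module = vapply(res, function(r) as.integer(r$chrom_module), 0L),
    chrom_size = vapply(res, `[[`, 0L, "chrom_size"),
    overlap = overlap,
    overlap_genes = I(lapply(res, `[[`, "overlap_genes")),
    p = p, p_bonferroni = p_bonf,
    significant = !is.na(p_bonf) & p_bonf < alpha,
    stringsAsFactors = FALSE)
  out[order(out$p_bonferroni, -out$overlap), , drop = FALSE]
}

empty_interplay <- function() {
  data.frame(meth_module = integer(), meth_size = integer(),
             chrom_module = integer(), chrom_size = integer(),
             overlap = integer(), overlap_genes = I(list()),
             p = numeric(), p_bonferroni = numeric(),
             significant = logical())
}
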