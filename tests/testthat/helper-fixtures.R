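# Shared fixture builders and independent brute-force oracles.

# small profile matrix with labelled groups
make_gpm <- function(values, n_control, n_case, genes = NULL) {
  n <- n_control + n_case
  m <- matrix(values, ncol = n)
  rownames(m) <- genes %||% paste0("g", seq_len(nrow(m)))
  groups <- rep(c("control", "case"), c(n_control, n_case))
  colnames(m) <- paste0("s", seq_len(n))
  gene_profile_matrix(m, groups)
}
`%||%` <- function(x, y) if (is.null(x)) y else x

edge_df <- function(...) {
  e <- matrix(c(...), ncol = 2, byrow = TRUE)
  data.frame(gene_a = e[, 1], gene_b = e[, 2], stringsAsFactors = FALSE)
}

# ---- independent oracles -------------------------------------------------

# exhaustive hypergeometric upper tail: enumerate all size-H draws from N
oracle_hyper_upper <- function(N, M, H, x) {
  if (H == 0) return(as.numeric(x <= 0))
  draws <- utils::combn(N, H)
  hits <- colSums(draws <= M)  # first M elements are the marked set
  mean(hits >= x)
}

# brute-force betweenness: enumerate every shortest path via the BFS DAG
oracle_betweenness <- function(adj) {
  n <- length(adj)
  btw <- numeric(n)
  all_paths <- function(preds, v) {
    if (length(preds[[v]]) == 0) return(list(v))
    out <- list()
    for (u in preds[[v]])
      for (p in all_paths(preds, u)) out <- c(out, list(c(p, v)))
    out
  }
  for (s in seq_len(n)) {
    dist <- rep(Inf, n); dist[s] <- 0
    queue <- s
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      for (u in adj[[v]]) if (dist[u] == Inf) {
        dist[u] <- dist[v] + 1; queue <- c(queue, u)
      }
    }
    preds <- lapply(seq_len(n), function(v)
      adj[[v]][dist[adj[[v]]] == dist[v] - 1])
    for (t in seq_len(n)) {
      if (t <= s || !is.finite(dist[t])) next
      paths <- all_paths(preds, t)
      inner <- unlist(lapply(paths, function(p) p[-c(1, length(p))]))
      if (length(inner))
        for (v in unique(inner))
          btw[v] <- btw[v] + sum(inner == v) / length(paths)
    }
  }
  btw
}

# brute-force local clustering coefficient from an adjacency list
oracle_clustering <- function(adj) {
  n <- length(adj)
  vapply(seq_len(n), function(v) {
    nb <- adj[[v]]
    k <- length(nb)
    if (k < 2) return(0)
    tri <- 0
    for (i in seq_len(k - 1)) for (j in (i + 1):k)
      if (nb[j] %in% adj[[nb[i]]]) tri <- tri + 1
    2 * tri / (k * (k - 1))
  }, 0)
}

# brute-force k-core numbers by iterative minimum-degree peeling
oracle_coreness <- function(adj) {
  n <- length(adj)
  alive <- rep(TRUE, n)
  core <- integer(n)
  k <- 0L
  while (any(alive)) {
    repeat {
      deg <- vapply(seq_len(n), function(v)
        if (alive[v]) sum(alive[adj[[v]]]) else Inf, 0)
      low <- which(alive & deg <= k)
      if (!length(low)) break
      core[low] <- k
      alive[low] <- FALSE
    }
    k <- k + 1L
  }
  core
}

graph_adj_list <- function(g) {
  lapply(igraph::adjacent_vertices(g, igraph::V(g)), as.integer)
}

# flood-fill component labelling, independent of igraph::components
oracle_components <- function(adj) {
  n <- length(adj)
  lab <- integer(n)
  cur <- 0L
  for (s in seq_len(n)) {
    if (lab[s] > 0) next
    cur <- cur + 1L
    stack <- s
    while (length(stack)) {
      v <- stack[length(stack)]; stack <- stack[-length(stack)]
      if (lab[v] > 0) next
      lab[v] <- cur
      stack <- c(stack, adj[[v]][lab[adj[[v]]] == 0])
    }
  }
  lab
}
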