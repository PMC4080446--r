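test_that("edge retention honours both the |r| and p filters strictly", {
  prof <- rbind(A = c(1, 2, 3, 4, 5),
                B = c(2, 4, 6, 8, 10),    # r = 1 with A
                C = c(1, 2, 3, 4, 5) * 0 + c(0, 3, 1, 4, 2),
                D = rep(1, 5))            # zero variance
  edges <- edge_df("A", "B", "A", "C", "A", "D")
  net <- suppressMessages(weight_network(edges, prof))
  el <- igraph::as_edgelist(net)
  expect_equal(nrow(el), 1L)
  expect_setequal(as.vector(el), c("A", "B"))
  expect_equal(igraph::E(net)$r, 1)

  # |r| = 0.85 on 5-point profiles: passes the r filter but p(df=3) > 0.05
  x <- c(1, 2, 3, 4, 5)
  xn <- (x - mean(x)) / sqrt(sum((x - mean(x))^2))
  v <- c(1, -1, 0, 1, -1)
  vc <- v - mean(v); vc <- vc - sum(vc * xn) * xn
  y <- 0.85 * xn + sqrt(1 - 0.85^2) * vc / sqrt(sum(vc^2))
  expect_equal(cor(x, y), 0.85, tolerance = 1e-12)
  prof2 <- rbind(A = x, B = y)
  net2 <- suppressMessages(weight_network(edge_df("A", "B"), prof2))
  expect_equal(igraph::ecount(net2), 0L)
  # oracle: closed-form t and two-sided tail
  p_oracle <- 2 * pt(0.85 * sqrt(3 / (1 - 0.85^2)), 3, lower.tail = FALSE)
  expect_gt(p_oracle, 0.05)
  expect_equal(p_oracle, cor.test(x, y)$p.value, tolerance = 1e-6)

  # r = 0.5 removed regardless of p (many samples would make p tiny)
  set.seed(3)
  n <- 200
  a <- rnorm(n); b <- 0.5 * a + rnorm(n) * sqrt(1 - 0.25)
  prof3 <- rbind(A = a, B = b)
  expect_lt(cor.test(a, b)$p.value, 1e-6)
  net3 <- suppressMessages(weight_network(edge_df("A", "B"), prof3,
                                          r_cut = 0.8))
  expect_equal(igraph::ecount(net3), 0L)
})

test_that("weight_network is invariant to edge ordering and endpoint swaps", {
  set.seed(4)
  prof <- matrix(rnorm(10 * 16), 10,
                 dimnames = list(paste0("g", 1:10), NULL))
  edges <- edge_df("g1", "g2", "g2", "g3", "g4", "g5", "g1", "g6")
  swapped <- edges[c(3, 1, 4, 2), ]
  swapped[2, ] <- swapped[2, c(2, 1)]  # reverse one pair's endpoints
  names(swapped) <- names(edges)
  n1 <- suppressMessages(weight_network(edges, prof, r_cut = 0.1,
                                        alpha = 0.9))
  n2 <- suppressMessages(weight_network(swapped, prof, r_cut = 0.1,
                                        alpha = 0.9))
  key <- function(n) {
    el <- igraph::as_edgelist(n)
    o <- order(pmin(el[, 1], el[, 2]), pmax(el[, 1], el[, 2]))
    data.frame(a = pmin(el[, 1], el[, 2])[o], b = pmax(el[, 1], el[, 2])[o],
               r = round(igraph::E(n)$r[o], 12))
  }
  expect_equal(key(n1), key(n2))
})

test_that("seed subnetworks are induced first-neighbor subgraphs", {
  g <- igraph::graph_from_data_frame(
    edge_df("A", "B", "B", "C", "C", "D"), directed = FALSE)
  igraph::E(g)$r <- c(0.9, -0.85, 0.95); igraph::E(g)$p <- c(1, 2, 3) * 1e-3

  expect_equal(igraph::vcount(extract_seed_subnetwork(g, character(0))), 0L)

  sub <- extract_seed_subnetwork(g, "B")
  expect_setequal(igraph::V(sub)$name, c("A", "B", "C"))
  el <- igraph::as_edgelist(sub)
  expect_equal(nrow(el), 2L)  # C-D excluded: D is not in the node set
  expect_true(igraph::V(sub)$seed[igraph::V(sub)$name == "B"])

  # edges keep the parent's (r, p) annotations
  eid <- igraph::get_edge_ids(sub, c("B", "C"))
  expect_equal(igraph::E(sub)$r[eid], -0.85)

  # absent seeds are ignored with a log entry
  expect_message(extract_seed_subnetwork(g, c("B", "ZZ")), "absent")

  # reapplying with the same seeds is idempotent
  sub2 <- extract_seed_subnetwork(sub, "B")
  expect_setequal(igraph::V(sub2)$name, igraph::V(sub)$name)
  expect_equal(igraph::ecount(sub2), igraph::ecount(sub))
})

test_that("giant component selection matches flood-fill labelling", {
  tri2 <- igraph::graph_from_data_frame(
    edge_df("a", "b", "b", "c", "c", "a",
            "x", "y", "y", "z", "z", "x"), directed = FALSE)
  k4 <- igraph::make_full_graph(4)
  igraph::V(k4)$name <- paste0("k", 1:4)
  g <- igraph::disjoint_union(tri2, k4)
  expect_setequal(igraph::V(giant_component(g))$name, paste0("k", 1:4))

  conn <- igraph::make_ring(5); igraph::V(conn)$name <- letters[1:5]
  expect_equal(igraph::vcount(giant_component(conn)), 5L)

  set.seed(5)
  er <- igraph::sample_gnp(40, 0.05)
  igraph::V(er)$name <- sprintf("n%02d", 1:40)
  lab <- oracle_components(graph_adj_list(er))
  biggest <- which(lab == which.max(tabulate(lab)))
  expect_setequal(igraph::V(giant_component(er))$name,
                  igraph::V(er)$name[biggest])
})

test_that("topology summaries match brute-force oracles", {
  tri <- igraph::make_full_graph(3); igraph::V(tri)$name <- c("a", "b", "c")
  ts <- topology_summary(tri)
  expect_equal(ts$mean_degree, 2)
  expect_equal(ts$mean_clustering, 1)
  expect_equal(ts$mean_betweenness, 0)

  path3 <- igraph::make_ring(3, circular = FALSE)
  igraph::V(path3)$name <- c("a", "b", "c")
  tp <- topology_summary(path3)
  expect_equal(tp$mean_clustering, 0)
  bt <- igraph::betweenness(path3, directed = FALSE)
  expect_equal(unname(bt[2]), 1)  # center of the 3-path, non-normalized

  set.seed(6)
  er <- igraph::sample_gnp(30, 0.3)
  igraph::V(er)$name <- sprintf("n%02d", 1:30)
  adj <- graph_adj_list(er)
  expect_equal(unname(igraph::betweenness(er, directed = FALSE)),
               oracle_betweenness(adj), tolerance = 1e-9)
  cc <- igraph::transitivity(er, type = "local", isolates = "zero")
  cc[igraph::degree(er) < 2] <- 0
  expect_equal(unname(cc), oracle_clustering(adj), tolerance = 1e-12)

  expect_error(topology_summary(igraph::make_empty_graph(0)), "empty")
})
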