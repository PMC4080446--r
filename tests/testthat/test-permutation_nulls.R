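test_that("empirical p uses the add-one rule and matches direct tallies", {
  vals <- c(1, 2, 3, 4, 5, 6, 7, 8, 9) / 10
  expect_equal(empirical_p(0.95, vals, "ge"), 1 / 10)   # above all
  expect_equal(empirical_p(0.95, vals, "le"), 10 / 10)  # below none
  expect_equal(empirical_p(0.05, vals, "ge"), 1)
  expect_equal(empirical_p(0.45, vals, "ge"),
               (1 + sum(vals >= 0.45)) / 10)
  vals99 <- seq_len(99)
  expect_equal(empirical_p(1000, vals99, "ge"), 1 / 100)
  expect_gt(empirical_p(Inf, vals99, "ge"), 0)  # never zero
})

test_that("a triangle cannot be rewired and is returned with a warning", {
  k3 <- igraph::make_full_graph(3)
  igraph::V(k3)$name <- c("a", "b", "c")
  expect_warning(out <- degree_preserving_rewire(k3, rng_seed = 1),
                 "stalled")
  el <- igraph::as_edgelist(out)
  expect_setequal(paste(pmin(el[, 1], el[, 2]), pmax(el[, 1], el[, 2])),
                  c("a b", "a c", "b c"))
})

test_that("rewiring preserves the degree multiset, no loops, no duplicates", {
  e <- generate_interactome(150, 3, rng_seed = 10)
  g <- igraph::graph_from_data_frame(e, directed = FALSE)
  deg0 <- sort(unname(igraph::degree(g)))
  for (b in 1:20) {
    rw <- degree_preserving_rewire(g, rng_seed = b)
    expect_equal(sort(unname(igraph::degree(rw)[igraph::V(g)$name])), deg0)
    el <- igraph::as_edgelist(rw)
    expect_false(any(el[, 1] == el[, 2]))
    expect_false(any(duplicated(paste(pmin(el[, 1], el[, 2]),
                                      pmax(el[, 1], el[, 2])))))
  }
})

test_that("4-cycle rewiring only reaches brute-force-valid outcomes", {
  ring <- igraph::make_ring(4)
  igraph::V(ring)$name <- c("a", "b", "c", "d")
  canon <- function(g) {
    el <- igraph::as_edgelist(g)
    paste(sort(paste(pmin(el[, 1], el[, 2]), pmax(el[, 1], el[, 2]))),
          collapse = ";")
  }
  # brute force: all simple graphs on {a,b,c,d} with all degrees 2
  nodes <- c("a", "b", "c", "d")
  prs <- utils::combn(nodes, 2)
  valid <- character(0)
  for (pick in utils::combn(6, 4, simplify = FALSE)) {
    deg <- table(factor(prs[, pick], levels = nodes))
    if (all(deg == 2))
      valid <- c(valid, paste(sort(paste(prs[1, pick], prs[2, pick])),
                              collapse = ";"))
  }
  seen <- vapply(1:40, function(s)
    canon(suppressWarnings(
      degree_preserving_rewire(ring, swap_fraction = 0.25, rng_seed = s))),
    "")
  expect_true(all(seen %in% valid))
  expect_gt(length(unique(seen)), 1)  # both matching-complements reachable
})

test_that("global null replicates are valid seed subnetworks", {
  e <- generate_interactome(200, 3, rng_seed = 12)
  g <- igraph::graph_from_data_frame(e, directed = FALSE)
  seeds <- igraph::V(g)$name[1:10]

  # degenerate sampling: seed set = all nodes makes every replicate the
  # full network
  full <- global_null(g, igraph::V(g)$name, B = 3, rng_seed = 1)
  expect_true(all(full$replicates[, "n_nodes"] == igraph::vcount(g)))
  expect_true(all(full$replicates[, "n_edges"] == igraph::ecount(g)))

  r1 <- global_null(g, seeds, B = 5, rng_seed = 99)
  r2 <- global_null(g, seeds, B = 5, rng_seed = 99)
  expect_identical(r1$replicates, r2$replicates)  # seeded determinism
  expect_true(all(r1$p$p > 0 & r1$p$p <= 1))
  expect_error(global_null(g, seeds, B = 0), "B")
})

test_that("local null keeps node and edge counts fixed", {
  e <- generate_interactome(80, 3, rng_seed = 13)
  g <- igraph::graph_from_data_frame(e, directed = FALSE)
  ln <- local_null(g, B = 5, rng_seed = 3)
  expect_true(all(ln$replicates[, "n_nodes"] == igraph::vcount(g)))
  expect_true(all(ln$replicates[, "n_edges"] == igraph::ecount(g)))
  smoke <- local_null(g, B = 1, rng_seed = 4)
  expect_equal(nrow(smoke$replicates), 1L)
})
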