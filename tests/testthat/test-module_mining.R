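test_that("MCODE vertex weights equal core number times core density", {
  lone <- igraph::make_empty_graph(1, directed = FALSE)
  igraph::V(lone)$name <- "x"
  expect_equal(unname(mcode_weights(lone)), 0)

  k4 <- igraph::make_full_graph(4)
  igraph::V(k4)$name <- paste0("v", 1:4)
  expect_equal(unname(mcode_weights(k4)), rep(3, 4))  # 3-core, density 1

  star <- igraph::make_star(6, mode = "undirected")
  igraph::V(star)$name <- paste0("s", 1:6)
  w <- mcode_weights(star)
  expect_equal(unname(w["s1"]), 1 * 2 * 5 / (6 * 5))  # 1-core, density 1/3

  # brute-force core decomposition oracle on a random graph
  set.seed(8)
  g <- igraph::sample_gnp(25, 0.2)
  igraph::V(g)$name <- sprintf("n%02d", 1:25)
  adj <- graph_adj_list(g)
  expect_equal(unname(igraph::coreness(g)), oracle_coreness(adj))
})

test_that("planted cliques joined by a bridge come out as two modules", {
  g <- igraph::disjoint_union(igraph::make_full_graph(5),
                              igraph::make_full_graph(5))
  igraph::V(g)$name <- c(paste0("a", 1:5), paste0("b", 1:5))
  g <- igraph::add_edges(g, c(5, 6))  # single bridge
  mods <- mcode_modules(g)
  expect_equal(nrow(mods), 2L)
  expect_setequal(mods$genes[[1]],
                  if ("a1" %in% mods$genes[[1]]) paste0("a", 1:5)
                  else paste0("b", 1:5))
  expect_setequal(unlist(mods$genes), igraph::V(g)$name)

  empty <- igraph::make_empty_graph(0, directed = FALSE)
  expect_equal(nrow(mcode_modules(empty)), 0L)
})

test_that("module detection is invariant to node relabeling", {
  set.seed(10)
  g <- igraph::sample_gnp(30, 0.2)
  igraph::V(g)$name <- sprintf("n%02d", 1:30)
  m1 <- mcode_modules(g)
  perm <- sample(30)
  g2 <- igraph::permute(g, perm)
  m2 <- mcode_modules(g2)
  expect_equal(lapply(m1$genes, sort), lapply(m2$genes, sort))
})

test_that("hypergeometric upper tail is exact, stable and monotone", {
  expect_equal(hypergeom_upper(10, 4, 5, 0), 1)
  # brute-force enumeration: 66 of the 252 size-5 draws overlap >= 3
  expect_equal(oracle_hyper_upper(10, 4, 5, 3), 66 / 252)
  expect_equal(hypergeom_upper(10, 4, 5, 3), 66 / 252, tolerance = 1e-12)

  # monotone nonincreasing in x
  ps <- vapply(0:4, function(x) hypergeom_upper(12, 6, 4, x), 0)
  expect_true(all(diff(ps) <= 1e-15))

  # point probabilities sum to 1 (log-space implementation check)
  N <- 2060; M <- 6; H <- 5
  pts <- vapply(0:min(M, H), function(k)
    exp(lchoose(M, k) + lchoose(N - M, H - k) - lchoose(N, H)), 0)
  expect_equal(sum(pts), 1, tolerance = 1e-12)
  # tail identity against the summed points
  expect_equal(hypergeom_upper(N, M, H, 4), sum(pts[5:6]),
               tolerance = 1e-12)

  expect_error(hypergeom_upper(10, 11, 5, 1), "infeasible")
  expect_error(hypergeom_upper(10, 4, 5, 5), "infeasible")
})

test_that("interplay testing filters overlaps and corrects by tested pairs", {
  mods <- function(ids, sets) data.frame(
    module_id = ids, score = rep(1, length(ids)), size = lengths(sets),
    genes = I(sets), stringsAsFactors = FALSE)
  bg <- sprintf("g%02d", 1:40)

  disjoint <- interplay(mods(1, list(bg[1:5])), mods(1, list(bg[6:10])), bg)
  expect_equal(sum(!is.na(disjoint$p)), 0L)
  expect_equal(disjoint$overlap, 0L)

  # overlap of 2 is never tested, even though its p would be small
  two <- interplay(mods(1, list(bg[1:3])), mods(1, list(bg[2:4])), bg,
                   min_overlap = 3)
  expect_equal(two$overlap, 2L)
  expect_true(is.na(two$p))

  # a shared planted core is significant; background pairs are not
  meth <- mods(1:2, list(bg[1:6], bg[20:25]))
  chrom <- mods(1:2, list(bg[c(1:4, 30)], bg[35:39]))
  res <- interplay(meth, chrom, bg)
  sig <- res[res$significant, ]
  expect_equal(nrow(sig), 1L)
  expect_equal(sig$meth_module, 1L)
  expect_equal(sig$chrom_module, 1L)
  expect_equal(sig$overlap_genes[[1]], bg[1:4])
  # Bonferroni factor = number of tested candidates
  expect_equal(sig$p_bonferroni, pmin(1, sig$p * sum(!is.na(res$p))))

  expect_equal(nrow(interplay(mods(integer(0), list()), chrom, bg)), 0L)
})

test_that("a planted dense community is recovered from a sparse background", {
  # stochastic block model: 30 planted nodes at p_in = 0.9 inside a
  # 300-node background wired at p_out = 0.02
  pm <- matrix(0.02, 2, 2); pm[1, 1] <- 0.9
  g <- withr::with_seed(21, igraph::sample_sbm(300, pref.matrix = pm,
                                               block.sizes = c(30, 270)))
  igraph::V(g)$name <- sprintf("n%03d", 1:300)
  planted <- igraph::V(g)$name[1:30]
  mods <- mcode_modules(giant_component(g))
  jac <- vapply(mods$genes, function(m)
    length(intersect(m, planted)) / length(union(m, planted)), 0)
  expect_gte(max(jac), 0.8)
})
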