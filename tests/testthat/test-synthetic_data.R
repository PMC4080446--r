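test_that("interactome generator yields connected scale-free edge sets", {
  e <- generate_interactome(3, 1, rng_seed = 1)
  expect_equal(nrow(e), 2L)
  g <- igraph::graph_from_data_frame(e, directed = FALSE)
  expect_true(igraph::is_connected(g))

  e <- generate_interactome(500, 4, rng_seed = 7)
  g <- igraph::graph_from_data_frame(e, directed = FALSE)
  expect_equal(igraph::components(g)$no, 1L)
  expect_false(any(e$gene_a == e$gene_b))
  expect_false(any(duplicated(paste(e$gene_a, e$gene_b))))

  expect_identical(e, generate_interactome(500, 4, rng_seed = 7))
  expect_error(generate_interactome(2, 1), "n_genes")
})

test_that("degree-distribution slope of a generated interactome is heavy-tailed", {
  e <- generate_interactome(2000, 4, rng_seed = 7)
  g <- igraph::graph_from_data_frame(e, directed = FALSE)
  slope <- powerlaw_exponent(igraph::degree(g))
  # independent least-squares fit on the log-log degree histogram
  tab <- table(igraph::degree(g))
  lx <- log10(as.numeric(names(tab))); ly <- log10(as.numeric(tab))
  oracle <- -unname(coef(lm(ly ~ lx))[2])
  expect_equal(slope, oracle, tolerance = 1e-10)
  expect_gt(slope, 1.5)
  expect_lt(slope, 3.5)
})

test_that("methylation generator reproduces the control beta mixture", {
  # no planted genes here: planting forces control means high and would
  # confound the tally of the mixture's own shape
  cfg <- synthetic_config(n_genes = 2000, frac_hypo = 0.59,
                          frac_hyper = 0.06, n_differential = 0,
                          rng_seed = 11)
  e <- generate_interactome(2000, 4, rng_seed = 11)
  gm <- generate_methylation(cfg, e)
  m <- gm$matrix
  expect_true(all(m >= 0 & m <= 1))
  ctrl_mean <- rowMeans(m[, sample_groups(m) == "control"])
  frac_low <- mean(ctrl_mean < 0.2)
  expect_lt(abs(frac_low - 0.59), 0.05)
})

test_that("planted genes carry the requested case-group shift", {
  cfg <- synthetic_config(n_genes = 500, n_differential = 50,
                          effect_size = 0.3, rng_seed = 5)
  e <- generate_interactome(500, 4, rng_seed = 5)
  gm <- generate_methylation(cfg, e)
  g <- sample_groups(gm$matrix)
  d <- rowMeans(gm$matrix[gm$truth, g == "control"]) -
    rowMeans(gm$matrix[gm$truth, g == "case"])
  expect_true(all(abs(d - 0.3) <= 2 * cfg$sample_noise_sd))
  # planted genes sit in one neighborhood: they induce a connected-ish seed
  gr <- igraph::graph_from_data_frame(e, directed = FALSE)
  sub <- extract_seed_subnetwork(gr, gm$truth)
  expect_lte(igraph::components(sub)$no, 3)
  expect_error(synthetic_config(effect_size = 1.5), "effect_size")
})

test_that("identical seeds give bit-identical generator output", {
  cfg <- synthetic_config(n_genes = 200, rng_seed = 3)
  e <- generate_interactome(200, 3, rng_seed = 3)
  expect_identical(generate_methylation(cfg, e), generate_methylation(cfg, e))
  tss <- generate_tss(sprintf("g%03d", 1:50))
  expect_identical(generate_peaks(tss, tss$gene[1:10], 2, rng_seed = 4),
                   generate_peaks(tss, tss$gene[1:10], 2, rng_seed = 4))
})

test_that("peaks land in target promoters and map back to the target set", {
  genes <- sprintf("g%03d", 1:40)
  tss <- generate_tss(genes)

  pk <- generate_peaks(tss, character(0), 1, rng_seed = 2,
                       n_background = 30)
  mapped <- map_peaks(pk, tss)
  expect_true(all(mapped == 0))  # background midpoints miss every window

  targets <- genes[c(3, 17, 25)]
  pk <- generate_peaks(tss, targets, 7, rng_seed = 2, n_background = 20)
  mapped <- map_peaks(pk, tss)
  expect_setequal(names(mapped)[mapped > 0], targets)
  expect_true(all(mapped[targets] == 7))

  one <- generate_peaks(tss, targets[1], 5, rng_seed = 9, n_background = 0)
  expect_equal(unname(map_peaks(one, tss)[targets[1]]), 5)
})

test_that("expression coupling is recoverable and sign-correct", {
  cfg <- synthetic_config(n_genes = 300, expr_noise_sd = 0, rng_seed = 8)
  e <- generate_interactome(300, 3, rng_seed = 8)
  gm <- generate_methylation(cfg, e)
  ex <- generate_expression(gm$matrix, cfg)
  pairs <- gene_level_pairs(gm$matrix, ex, group = "case")
  fit <- suppressWarnings(fit_line(pairs))  # exact fit warns in summary.lm
  expect_equal(fit$slope, cfg$slope, tolerance = 1e-8)
  expect_equal(fit$intercept, cfg$intercept, tolerance = 1e-8)
  expect_lt(fit$spearman_rho, 0)  # negative slope, monotone signal
})
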