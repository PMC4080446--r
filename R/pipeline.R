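#' Pipeline configuration
#'
#' Collects every input and threshold of the end-to-end analysis. Inputs
#' come either from files (a SIF background, methylation and expression
#' matrices with group labels, a TSS table and one BED peak file per
#' chromatin mark) or from the synthetic generators via a
#' \code{\link{synthetic_config}}.
#'
#' @param out_dir output directory (created if needed).
#' @param synthetic optional \code{\link{synthetic_config}}; when given,
#'   all inputs are generated and the file paths are ignored.
#' @param sif,meth_matrix,meth_groups,expr_matrix,expr_groups,tss input
#'   file paths (required when \code{synthetic} is NULL).
#' @param peak_beds named character vector of BED paths, one per mark.
#' @param fdr q-value threshold for differential calls.
#' @param n_perm SAM label permutations.
#' @param r_cut,alpha edge-retention thresholds of the weighted networks.
#' @param flank promoter half-width in bp.
#' @param B null-model replicate count.
#' @param swap_fraction rewired fraction for the local null.
#' @param min_module_size minimum mined module size.
#' @param min_overlap minimum tested interplay overlap.
#' @param clique_size number of planted genes interconnected into a dense
#'   community (synthetic mode only; capped at n_differential).
#' @param rng_seed top-level seed; per-stage seeds are derived from it.
#' @return a validated list of class \code{"pipeline_config"}.
#' @export
pipeline_config <- function(out_dir, synthetic = NULL, sif = NULL,
                            meth_matrix = NULL, meth_groups = NULL,
                            expr_matrix = NULL, expr_groups = NULL,
                            tss = NULL, peak_beds = NULL,
                            fdr = 0.05, n_perm = 200, r_cut = 0.8,
                            alpha = 0.05, flank = 2000, B = 1000,
                            swap_fraction = 0.5, min_module_size = 3,
                            min_overlap = 3, clique_size = 30,
                            rng_seed = 1) {
  if (fdr < 0 || fdr > 1 || alpha <= 0 || alpha > 1)
    stop("fdr and alpha must lie in [0, 1]")
  if (r_cut < 0 || r_cut >= 1) stop("r_cut must lie in [0, 1)")
  if (B < 1 || n_perm < 20) stop("B >= 1 and n_perm >= 20 required")
  if (is.null(synthetic)) {
    paths <- c(sif = sif, meth_matrix = meth_matrix,
               meth_groups = meth_groups, expr_matrix = expr_matrix,
               expr_groups = expr_groups, tss = tss, peak_beds)
    if (length(paths) < 7L)
      stop("file mode needs sif, matrices, groups, tss and peak_beds")
    missing <- paths[!file.exists(paths)]
    if (length(missing))
      stop("missing input files: ", paste(missing, collapse = ", "))
  } else if (!inherits(synthetic, "synthetic_config"))
    stop("synthetic must be a synthetic_config")
  structure(list(out_dir = out_dir, synthetic = synthetic, sif = sif,
                 meth_matrix = meth_matrix, meth_groups = meth_groups,
                 expr_matrix = expr_matrix, expr_groups = expr_groups,
                 tss = tss, peak_beds = peak_beds, fdr = fdr,
                 n_perm = n_perm, r_cut = r_cut, alpha = alpha,
                 flank = flank, B = B, swap_fraction = swap_fraction,
                 min_module_size = min_module_size,
                 min_overlap = min_overlap, clique_size = clique_size,
                 rng_seed = rng_seed),
            class = "pipeline_config")
}

#' Demo configuration on generated data
#'
#' A complete synthetic study at desk scale: a 2000-gene scale-free
#' interactome with a planted 30-gene dense community among the planted
#' differentially methylated genes, 11 control vs 5 case methylation
#' samples, five chromatin marks whose intensities are rank-one (hence
#' strongly correlated) over the planted community, and expression coupled
#' to methylation with slope -2.793 and intercept 7.561. Null-model
#' replicate counts are reduced so the demo completes quickly.
#'
#' @param out_dir output directory.
#' @param rng_seed integer seed.
#' @return a \code{\link{pipeline_config}}.
#' @export
demo_config <- function(out_dir, rng_seed = 1) {
  pipeline_config(out_dir,
                  synthetic = synthetic_config(rng_seed = rng_seed),
                  n_perm = 100, B = 50, rng_seed = rng_seed)
}

# Generate all synthetic pipeline inputs and write them under out_dir/inputs.
synthesize_inputs <- function(config) {
  cfg <- config$synthetic
  seed <- cfg$rng_seed
  interactome <- generate_interactome(cfg$n_genes, 4, rng_seed = seed)
  gm <- generate_methylation(cfg, interactome)
  clique <- utils::head(gm$truth, min(config$clique_size, length(gm$truth)))
  interactome <- add_clique_edges(interactome, clique)
  genes <- sort(unique(c(interactome$gene_a, interactome$gene_b)))
  tss <- generate_tss(genes)

  # per-mark promoter intensities: rank-one (shared pattern x gene scale,
  # with mild lognormal jitter) over the planted community, independent
  # lognormal elsewhere
  marks <- sprintf("mark%02d", seq_len(cfg$n_marks))
  pattern <- 2^seq_len(cfg$n_marks)
  peak_sets <- local_seed(seed + 7L, {
    scale_g <- stats::setNames(exp(stats::rnorm(length(clique), 1, 0.3)),
                               clique)
    lapply(stats::setNames(seq_along(marks), marks), function(m) {
      inten <- stats::setNames(exp(stats::rnorm(length(genes), 0, 1)), genes)
      inten[clique] <- pattern[m] * scale_g *
        exp(stats::rnorm(length(clique), 0, 0.05))
      generate_peaks(tss, genes, inten, rng_seed = seed + 100L + m,
                     flank = config$flank)
    })
  })
  expr <- generate_expression(gm$matrix, cfg)

  dir.create(file.path(config$out_dir, "inputs"), recursive = TRUE,
             showWarnings = FALSE)
  inp <- function(f) file.path(config$out_dir, "inputs", f)
  write_sif(interactome, inp("background.sif"))
  write_matrix(gm$matrix, inp("methylation.tsv"), inp("groups.tsv"))
  write_matrix(expr, inp("expression.tsv"))
  write_tss(tss, inp("tss.tsv"))
  for (m in marks) write_bed(peak_sets[[m]], inp(paste0(m, ".bed")))
  writeLines(gm$truth, inp("truth_differential.txt"))
  writeLines(clique, inp("truth_module.txt"))

  list(interactome = interactome, meth = gm$matrix, truth = gm$truth,
       clique = clique, tss = tss, peak_sets = peak_sets, expr = expr)
}

load_inputs <- function(config) {
  peak_sets <- lapply(config$peak_beds, read_bed)
  if (is.null(names(peak_sets)))
    names(peak_sets) <- sprintf("mark%02d", seq_along(peak_sets))
  list(interactome = read_sif(config$sif),
       meth = read_matrix(config$meth_matrix, config$meth_groups,
                          beta = TRUE),
       truth = NULL, clique = NULL,
       tss = read_tss(config$tss),
       peak_sets = peak_sets,
       expr = read_matrix(config$expr_matrix,
                          config$expr_groups %||% config$meth_groups))
}

#' Run the full epigenetic-network analysis
#'
#' Stage order: differential methylation calling; weighted methylation
#' network; seed subnetwork; topology with global and local nulls; peak
#' mapping; weighted chromatin network; chromatin seed subnetwork with its
#' nulls; dense-module mining on both giant components; interplay testing;
#' methylation-expression regression. Every intermediate is written under
#' \code{out_dir} and a plain-text summary report is produced; the run is
#' deterministic for a fixed \code{rng_seed}.
#'
#' @param config a \code{\link{pipeline_config}}.
#' @return invisibly, a list with every stage result (see the report for
#'   the summary numbers).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  out <- function(f) file.path(config$out_dir, f)
  seed <- config$rng_seed

  inputs <- if (is.null(config$synthetic)) load_inputs(config)
            else synthesize_inputs(config)
  res <- list(config = config, inputs = inputs)
  report <- c("epimodnet pipeline report", "=========================")

  # -- differential methylation ------------------------------------------
  log_msg("diff", "calling differentially methylated genes")
  diff <- sam_fdr(inputs$meth, n_perm = config$n_perm,
                  fdr_cutoff = config$fdr, rng_seed = seed + 11L)
  utils::write.table(diff, out("differential.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  seeds <- diff$gene[diff$called]
  res$differential <- diff
  report <- c(report, "",
              sprintf("Differential methylation: %d of %d genes at q < %g",
                      length(seeds), nrow(diff), config$fdr))
  if (length(seeds) == 0L) {
    report <- c(report,
                "No seed genes called; network stages skipped.")
    writeLines(report, out("report.txt"))
    log_msg("pipeline", "no seeds; early exit")
    return(invisible(res))
  }

  # -- weighted methylation network + seed subnetwork --------------------
  log_msg("wmpn", "building weighted methylation network")
  wmpn <- weight_network(inputs$interactome, unclass(inputs$meth),
                         r_cut = config$r_cut, alpha = config$alpha)
  write_network(wmpn, out("wmpn.tsv"))
  tmsn <- extract_seed_subnetwork(wmpn, seeds)
  write_network(tmsn, out("tmsn.tsv"))
  res$wmpn <- wmpn; res$tmsn <- tmsn

  topo_rows <- list()
  topo_rows$WMPN <- topology_summary(wmpn)
  topo_rows$TMSN <- topology_summary(tmsn)
  log_msg("null", "global null for the methylation subnetwork")
  res$tmsn_global_null <- global_null(wmpn, seeds, B = config$B,
                                      rng_seed = seed + 23L)
  tmsn_giant <- giant_component(tmsn)
  log_msg("null", "local rewiring null for the methylation giant component")
  res$tmsn_local_null <- local_null(tmsn_giant, B = config$B,
                                    swap_fraction = config$swap_fraction,
                                    rng_seed = seed + 31L)

  # -- chromatin layer ----------------------------------------------------
  log_msg("chromatin", "mapping peaks into promoter windows")
  cmat <- chromatin_matrix(inputs$peak_sets, inputs$tss,
                           flank = config$flank)
  write_matrix_plain(cmat, out("chromatin_intensity.tsv"))
  wcpn <- weight_network(inputs$interactome, cmat, r_cut = config$r_cut,
                         alpha = config$alpha)
  write_network(wcpn, out("wcpn.tsv"))
  tmsn_genes <- igraph::V(tmsn)$name
  tcsn <- igraph::induced_subgraph(
    wcpn, intersect(tmsn_genes, igraph::V(wcpn)$name))
  igraph::V(tcsn)$seed <- igraph::V(tcsn)$name %in% seeds
  write_network(tcsn, out("tcsn.tsv"))
  res$wcpn <- wcpn; res$tcsn <- tcsn
  topo_rows$WCPN <- topology_summary(wcpn)
  if (igraph::vcount(tcsn) > 0) {
    topo_rows$TCSN <- topology_summary(tcsn)
    log_msg("null", "global null for the chromatin subnetwork")
    res$tcsn_global_null <- global_null(
      wcpn, intersect(tmsn_genes, igraph::V(wcpn)$name),
      B = config$B, rng_seed = seed + 43L)
    if (igraph::ecount(tcsn) >= 2) {
      tcsn_giant <- giant_component(tcsn)
      res$tcsn_local_null <- local_null(
        tcsn_giant, B = config$B,
        swap_fraction = config$swap_fraction, rng_seed = seed + 47L)
    }
  }

  topo <- do.call(rbind, lapply(names(topo_rows), function(n)
    data.frame(network = n, as.data.frame(topo_rows[[n]]))))
  utils::write.table(topo, out("topology.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  res$topology <- topo
  report <- c(report, "", "Network topology:",
              utils::capture.output(print(topo, row.names = FALSE)))
  for (nm in c("tmsn_global_null", "tmsn_local_null",
               "tcsn_global_null", "tcsn_local_null")) {
    if (is.null(res[[nm]])) next
    report <- c(report, "", paste0(nm, ":"),
                utils::capture.output(print(res[[nm]]$p, row.names = FALSE)))
  }

  # -- dense modules + interplay -----------------------------------------
  log_msg("modules", "mining dense modules")
  meth_mods <- mcode_modules(tmsn_giant, min_size = config$min_module_size)
  chrom_mods <- if (igraph::vcount(tcsn) > 0 && igraph::ecount(tcsn) > 0)
    mcode_modules(giant_component(tcsn),
                  min_size = config$min_module_size)
  else empty_module_set()
  write_modules(meth_mods, out("modules_methylation.tsv"))
  write_modules(chrom_mods, out("modules_chromatin.tsv"))
  res$meth_modules <- meth_mods; res$chrom_modules <- chrom_mods

  background <- union(tmsn_genes, igraph::V(tcsn)$name)
  ip <- interplay(meth_mods, chrom_mods, background,
                  min_overlap = config$min_overlap, alpha = config$alpha)
  res$interplay <- ip
  ip_flat <- ip
  ip_flat$overlap_genes <- vapply(ip$overlap_genes, paste, "",
                                  collapse = ",")
  utils::write.table(ip_flat, out("interplay.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  report <- c(report, "",
              sprintf("Modules: %d methylation, %d chromatin; %d interplay pairs tested, %d significant",
                      nrow(meth_mods), nrow(chrom_mods),
                      sum(!is.na(ip$p)), sum(ip$significant)))

  # -- methylation-expression regression ---------------------------------
  log_msg("methexpr", "fitting methylation-expression regression")
  pairs <- gene_level_pairs(inputs$meth, inputs$expr, group = "case")
  fit <- fit_line(pairs)
  fl <- flag_within_interval(fit, pairs)
  utils::write.table(fl$flags, out("methexpr.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  res$fit <- fit; res$flags <- fl
  report <- c(report, "",
              sprintf("Methylation-expression: y = %.4gx + %.4g; Spearman rho = %.4f; %d of %d genes within the %g%% prediction interval",
                      fit$slope, fit$intercept, fit$spearman_rho,
                      fl$n_within, nrow(pairs), 100 * fit$level))

  writeLines(report, out("report.txt"))
  log_msg("pipeline", "done; report at ", out("report.txt"))
  invisible(res)
}

# plain numeric matrix writer (no group labels)
write_matrix_plain <- function(x, path) {
  df <- data.frame(gene = rownames(x), x, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
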