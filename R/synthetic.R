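#' Configuration for the synthetic data generators
#'
#' Bundles every knob of the synthetic study design. The defaults reproduce
#' the data shapes the analysis was designed for: a bimodal beta-value
#' landscape dominated by hypomethylation (59\% of genes below 0.2, 6\% above
#' 0.8 in controls), 11 control vs 5 case methylation samples, planted
#' case-hypomethylation events of effect size 0.3, five chromatin marks, and
#' expression linearly coupled to methylation with slope -2.793 and
#' intercept 7.561.
#'
#' @param n_genes number of genes in the interactome and all matrices.
#' @param n_control,n_case per-group sample counts.
#' @param frac_hypo,frac_hyper mixture weights of the hypomethylated
#'   (mean < 0.2) and hypermethylated (mean >= 0.8) components; the
#'   remainder is mid-methylated.
#' @param n_differential number of planted differentially methylated genes.
#' @param effect_size beta-value drop applied to planted genes in the case
#'   group, in \code{[0, 1]}.
#' @param sample_noise_sd per-sample Gaussian noise on the beta scale.
#' @param n_marks number of chromatin marks.
#' @param slope,intercept,expr_noise_sd linear methylation-to-expression
#'   coupling and its Gaussian noise (expression units).
#' @param rng_seed integer seed; every generator threads it explicitly.
#' @return a validated list of class \code{"synthetic_config"}.
#' @export
synthetic_config <- function(n_genes = 2000, n_control = 11, n_case = 5,
                             frac_hypo = 0.59, frac_hyper = 0.06,
                             n_differential = 100, effect_size = 0.3,
                             sample_noise_sd = 0.05, n_marks = 5,
                             slope = -2.793, intercept = 7.561,
                             expr_noise_sd = 0.5, rng_seed = 1) {
  cfg <- list(n_genes = n_genes, n_control = n_control, n_case = n_case,
              frac_hypo = frac_hypo, frac_hyper = frac_hyper,
              n_differential = n_differential, effect_size = effect_size,
              sample_noise_sd = sample_noise_sd, n_marks = n_marks,
              slope = slope, intercept = intercept,
              expr_noise_sd = expr_noise_sd, rng_seed = rng_seed)
  counts <- c("n_genes", "n_control", "n_case", "n_marks")
  for (f in counts)
    if (cfg[[f]] < 1) stop(f, " must be a positive count")
  if (cfg$frac_hypo < 0 || cfg$frac_hyper < 0 ||
      cfg$frac_hypo + cfg$frac_hyper > 1)
    stop("frac_hypo + frac_hyper must lie in [0, 1]")
  if (cfg$n_differential > cfg$n_genes)
    stop("n_differential cannot exceed n_genes")
  if (cfg$effect_size < 0 || cfg$effect_size > 1)
    stop("effect_size must lie in [0, 1]; larger shifts cannot yield valid betas")
  if (cfg$sample_noise_sd < 0 || cfg$expr_noise_sd < 0)
    stop("noise sds must be nonnegative")
  class(cfg) <- "synthetic_config"
  cfg
}

#' Generate a scale-free background interactome
#'
#' Preferential-attachment (Barabasi-Albert) construction: connected,
#' undirected, self-loop-free, duplicate-free, with a heavy-tailed degree
#' distribution like the integrated protein-interaction background the
#' analysis runs on.
#'
#' @param n_genes number of genes (>= 3).
#' @param edges_per_node edges attached by each incoming node.
#' @param rng_seed integer seed.
#' @return data frame with columns \code{gene_a}, \code{gene_b}.
#' @export
generate_interactome <- function(n_genes, edges_per_node = 4, rng_seed = 1) {
  if (n_genes < 3) stop("n_genes must be >= 3")
  if (edges_per_node < 1 || n_genes <= edges_per_node)
    stop("need n_genes > edges_per_node >= 1")
  g <- local_seed(rng_seed,
                  igraph::sample_pa(n_genes, m = edges_per_node,
                                    directed = FALSE))
  ids <- gene_ids(n_genes)
  el <- igraph::as_edgelist(g, names = FALSE)
  a <- ids[pmin(el[, 1L], el[, 2L])]
  b <- ids[pmax(el[, 1L], el[, 2L])]
  keep <- !duplicated(paste(a, b, sep = "\r")) & a != b
  data.frame(gene_a = a[keep], gene_b = b[keep], stringsAsFactors = FALSE)
}

gene_ids <- function(n) sprintf("g%05d", seq_len(n))

interactome_graph <- function(edges, genes = NULL) {
  g <- igraph::graph_from_data_frame(edges, directed = FALSE,
                                     vertices = genes)
  igraph::simplify(g)
}

#' Add clique edges among a gene set
#'
#' Used to plant a dense community in a synthetic interactome so module
#' detection has a known ground truth; existing edges are not duplicated.
#'
#' @param edges interactome edge data frame.
#' @param genes genes to interconnect completely.
#' @return the augmented, deduplicated edge data frame.
#' @export
add_clique_edges <- function(edges, genes) {
  if (length(genes) < 2) return(edges)
  pairs <- utils::combn(sort(genes), 2L)
  add <- data.frame(gene_a = pairs[1L, ], gene_b = pairs[2L, ],
                    stringsAsFactors = FALSE)
  all <- rbind(edges, add)
  all[!duplicated(edge_key(all$gene_a, all$gene_b)), , drop = FALSE]
}

#' Generate a methylation beta-value matrix with planted differential genes
#'
#' Control-group per-gene means come from a three-component Beta mixture
#' (hypomethylated Beta(1,12), mid Beta(5,5), hypermethylated Beta(12,1));
#' the case group equals control minus \code{effect_size} for the planted
#' genes (clipped to \code{[0,1]}), emulating the case-hypomethylation events
#' that dominate islet methylation data. Planted genes are chosen inside one
#' interactome neighborhood (breadth-first from a mid-degree anchor) so that
#' a seed subnetwork exists by construction. Per-sample Gaussian noise is
#' added and values are clipped to \code{[0, 1]}.
#'
#' @param cfg a \code{\link{synthetic_config}}.
#' @param interactome interactome edge data frame (its genes define the
#'   matrix rows).
#' @return list with \code{matrix} (a \code{\link{gene_profile_matrix}} of
#'   betas) and \code{truth} (character vector of planted gene ids).
#' @export
generate_methylation <- function(cfg, interactome) {
  g <- interactome_graph(interactome)
  genes <- sort(igraph::V(g)$name)
  n <- length(genes)
  if (cfg$n_differential > n) stop("n_differential exceeds gene count")
  local_seed(cfg$rng_seed, {
    comp <- sample(c("hypo", "mid", "hyper"), n, replace = TRUE,
                   prob = c(cfg$frac_hypo,
                            1 - cfg$frac_hypo - cfg$frac_hyper,
                            cfg$frac_hyper))
    mu <- numeric(n)
    mu[comp == "hypo"] <- stats::rbeta(sum(comp == "hypo"), 1, 12)
    mu[comp == "mid"] <- stats::rbeta(sum(comp == "mid"), 5, 5)
    mu[comp == "hyper"] <- stats::rbeta(sum(comp == "hyper"), 12, 1)
    names(mu) <- genes

    planted <- character(0)
    if (cfg$n_differential > 0) {
      # anchor on the highest-degree node so one BFS ball covers the quota
      deg <- igraph::degree(g)
      anchor <- igraph::V(g)$name[which.max(deg)]
      ord <- igraph::bfs(g, root = anchor, order = TRUE)$order
      planted <- igraph::V(g)$name[ord][seq_len(cfg$n_differential)]
      # planted control means must sit high enough that the case-group drop
      # survives clipping; redraw them from the mid component above the shift
      lo <- min(cfg$effect_size + 0.1, 0.95)
      mu[planted] <- lo + (1 - lo) * stats::rbeta(length(planted), 2, 2)
    }

    mu_case <- mu
    mu_case[planted] <- pmax(0, mu_case[planted] - cfg$effect_size)

    n_s <- cfg$n_control + cfg$n_case
    groups <- rep(c("control", "case"), c(cfg$n_control, cfg$n_case))
    samples <- sprintf("s%02d_%s", seq_len(n_s), groups)
    m <- matrix(NA_real_, n, n_s, dimnames = list(genes, samples))
    for (j in seq_len(n_s)) {
      base <- if (groups[j] == "control") mu else mu_case
      m[, j] <- pmin(1, pmax(0, base + stats::rnorm(n, 0, cfg$sample_noise_sd)))
    }
    list(matrix = gene_profile_matrix(m, groups, beta = TRUE),
         truth = planted)
  })
}

#' Generate a synthetic TSS table
#'
#' Genes are laid out deterministically along chromosomes with a fixed
#' spacing larger than twice the promoter flank, so TSS-proximal windows are
#' pairwise disjoint (a documented simplification of real genomes).
#'
#' @param genes character vector of gene ids.
#' @param n_chrom number of chromosomes.
#' @param spacing base pairs between consecutive TSSs on a chromosome.
#' @return TSS data frame (gene, chrom, pos, strand).
#' @export
generate_tss <- function(genes, n_chrom = 5, spacing = 5000) {
  n <- length(genes)
  chrom <- paste0("chr", rep_len(seq_len(n_chrom), n))
  idx <- stats::ave(seq_len(n), chrom, FUN = seq_along)
  data.frame(gene = genes, chrom = chrom,
             pos = 3000L + (idx - 1L) * as.integer(spacing),
             strand = rep_len(c("+", "-"), n),
             stringsAsFactors = FALSE)
}

#' Generate chromatin-mark peaks around target promoters
#'
#' One peak is placed with its midpoint inside the TSS +/- \code{flank}
#' window of every target gene, carrying the requested intensity; background
#' peaks are placed with midpoints outside all promoter windows.
#'
#' @param tss TSS data frame.
#' @param target_genes genes that receive an in-window peak.
#' @param intensity peak score: a scalar, or a numeric vector named by
#'   target gene.
#' @param rng_seed integer seed.
#' @param flank promoter half-width in bp.
#' @param peak_halfwidth half-width of each generated peak in bp.
#' @param n_background number of out-of-window background peaks.
#' @return peak data frame (chrom, start, end, score).
#' @export
generate_peaks <- function(tss, target_genes, intensity, rng_seed = 1,
                           flank = 2000, peak_halfwidth = 200,
                           n_background = 50) {
  if (nrow(tss) == 0) stop("TSS table is empty")
  target_genes <- intersect(tss$gene, target_genes)
  local_seed(rng_seed, {
    out <- list()
    if (length(target_genes)) {
      sc <- if (is.null(names(intensity)))
        rep_len(intensity, length(target_genes))
      else {
        if (!all(target_genes %in% names(intensity)))
          stop("intensity vector must be named by target gene")
        unname(intensity[target_genes])
      }
      rows <- tss[match(target_genes, tss$gene), ]
      mid <- rows$pos + round(stats::runif(nrow(rows), -flank + 1, flank - 1))
      mid <- pmax(mid, peak_halfwidth)
      out$target <- data.frame(chrom = rows$chrom,
                               start = mid - peak_halfwidth,
                               end = mid + peak_halfwidth,
                               score = sc, stringsAsFactors = FALSE)
    }
    if (n_background > 0) {
      span <- max(tss$pos) + 10L * flank
      chroms <- unique(tss$chrom)
      acc <- data.frame(chrom = character(), start = integer(),
                        end = integer(), score = numeric())
      tries <- 0L
      while (nrow(acc) < n_background && tries < 200L) {
        tries <- tries + 1L
        cand_chrom <- sample(chroms, n_background, replace = TRUE)
        cand_mid <- round(stats::runif(n_background, peak_halfwidth, span))
        ok <- vapply(seq_len(n_background), function(i) {
          w <- tss[tss$chrom == cand_chrom[i], "pos"]
          all(abs(cand_mid[i] - w) > flank)
        }, TRUE)
        add <- data.frame(chrom = cand_chrom[ok],
                          start = cand_mid[ok] - peak_halfwidth,
                          end = cand_mid[ok] + peak_halfwidth,
                          score = round(stats::runif(sum(ok), 0.5, 2), 3),
                          stringsAsFactors = FALSE)
        acc <- rbind(acc, add)
        if (nrow(acc) >= n_background) { acc <- acc[seq_len(n_background), ]; break }
      }
      out$background <- acc
    }
    peaks <- do.call(rbind, out)
    rownames(peaks) <- NULL
    peaks
  })
}

#' Generate expression linearly coupled to methylation
#'
#' Per-gene expression equals \code{intercept + slope * methylation mean}
#' of the sample's group, plus Gaussian noise, so the regression module can
#' recover the coupling from the case group exactly in the noiseless limit.
#'
#' @param meth methylation \code{\link{gene_profile_matrix}}.
#' @param cfg a \code{\link{synthetic_config}} (slope, intercept,
#'   expr_noise_sd, rng_seed are used).
#' @return an expression \code{\link{gene_profile_matrix}} over the same
#'   genes and samples.
#' @export
generate_expression <- function(meth, cfg) {
  groups <- sample_groups(meth)
  mu_ctrl <- rowMeans(meth[, groups == "control", drop = FALSE])
  mu_case <- rowMeans(meth[, groups == "case", drop = FALSE])
  local_seed(cfg$rng_seed + 104729L, {
    m <- matrix(NA_real_, nrow(meth), ncol(meth), dimnames = dimnames(meth))
    for (j in seq_len(ncol(meth))) {
      mu <- if (groups[j] == "control") mu_ctrl else mu_case
      m[, j] <- cfg$intercept + cfg$slope * mu +
        stats::rnorm(nrow(meth), 0, cfg$expr_noise_sd)
    }
    gene_profile_matrix(m, groups)
  })
}
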