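#' Average probe-level profiles into gene-level profiles
#'
#' Genes measured by several array probes get the arithmetic mean of their
#' probes, per sample. Probes without a gene mapping are dropped and counted
#' in the log.
#'
#' @param probe_matrix a \code{\link{gene_profile_matrix}} keyed by probe id.
#' @param probe_to_gene named character vector: probe id -> gene id (each
#'   probe maps to at most one gene).
#' @return a \code{\link{gene_profile_matrix}} keyed by gene id.
#' @export
collapse_probes <- function(probe_matrix, probe_to_gene) {
  probes <- rownames(probe_matrix)
  mapped <- probes[probes %in% names(probe_to_gene)]
  dropped <- length(probes) - length(mapped)
  if (dropped > 0)
    log_msg("collapse_probes", dropped, " unmapped probes dropped")
  if (length(mapped) == 0L) stop("no probe maps to any gene")
  gene <- probe_to_gene[mapped]
  vals <- unclass(probe_matrix)[mapped, , drop = FALSE]
  agg <- rowsum(vals, group = gene, reorder = TRUE)
  agg <- agg / as.vector(table(gene)[rownames(agg)])
  gene_profile_matrix(agg, sample_groups(probe_matrix))
}

# Per-gene difference of means and pooled two-sample standard error.
group_stats <- function(matrix) {
  g <- sample_groups(matrix)
  x <- unclass(matrix)
  ctrl <- x[, g == "control", drop = FALSE]
  case <- x[, g == "case", drop = FALSE]
  n1 <- ncol(ctrl); n2 <- ncol(case)
  m1 <- rowMeans(ctrl); m2 <- rowMeans(case)
  ss <- rowSums((ctrl - m1)^2) + rowSums((case - m2)^2)
  s <- sqrt((1 / n1 + 1 / n2) * ss / (n1 + n2 - 2))
  list(diff = m2 - m1, s = s, mean_control = m1, mean_case = m2)
}

#' SAM moderated d statistic
#'
#' For each gene, \code{d = (mean_case - mean_control) / (s + s0)}, where
#' \code{s} is the pooled two-sample standard error and \code{s0} a small
#' positive "fudge" constant that damps the statistic for low-variance genes.
#' With \code{s0 = 0} this is the ordinary two-sample t statistic.
#'
#' @param matrix a \code{\link{gene_profile_matrix}}.
#' @param s0 nonnegative variance stabilizer; see \code{\link{estimate_s0}}.
#' @return named numeric vector of d values.
#' @export
sam_d <- function(matrix, s0) {
  if (s0 < 0) stop("s0 must be nonnegative")
  st <- group_stats(matrix)
  if (s0 == 0 && any(st$s == 0))
    stop("zero-variance gene with s0 = 0: d undefined")
  st$diff / (st$s + s0)
}

#' Estimate the SAM fudge factor s0
#'
#' The classic recipe: candidate values are percentiles of the per-gene
#' standard errors; for each candidate, genes are binned into 100 quantile
#' bins of \code{s} and the coefficient of variation of the per-bin median
#' absolute deviation of d is computed; the candidate minimizing that CV is
#' chosen. Falls back to the median of \code{s} when the search degenerates
#' (e.g. constant standard errors).
#'
#' @param matrix a \code{\link{gene_profile_matrix}}.
#' @param percentiles candidate percentiles of the s distribution.
#' @return scalar s0.
#' @export
estimate_s0 <- function(matrix, percentiles = seq(0, 1, by = 0.05)) {
  st <- group_stats(matrix)
  s <- st$s
  if (max(s) - min(s) < .Machine$double.eps^0.5)
    return(stats::median(s))
  cand <- stats::quantile(s, percentiles, names = FALSE)
  bins <- cut(rank(s, ties.method = "first"),
              breaks = 100, labels = FALSE)
  cv <- vapply(cand, function(s0) {
    d <- st$diff / (s + s0)
    mads <- tapply(d, bins, stats::mad)
    mads <- mads[is.finite(mads) & mads > 0]
    if (length(mads) < 2) return(Inf)
    stats::sd(mads) / mean(mads)
  }, 0)
  if (all(!is.finite(cv))) return(stats::median(s))
  cand[which.min(cv)]
}

#' Permutation FDR for SAM differential calls
#'
#' q-values come from group-label permutations: for each gene's symmetric
#' cutoff \code{|d|}, the expected number of false calls is the median over
#' permutations of the count of permuted \code{|d*|} at or above the cutoff,
#' and \code{q = expected false calls / observed calls}, capped at 1 and made
#' monotone nonincreasing in \code{|d|}. When the label space has fewer
#' distinct assignments than \code{n_perm}, all distinct assignments are
#' used (and logged).
#'
#' @param matrix a \code{\link{gene_profile_matrix}}.
#' @param n_perm number of label permutations (>= 20).
#' @param fdr_cutoff q-value threshold for calling a gene differential.
#' @param rng_seed integer seed for permutation sampling.
#' @param s0 fudge factor; estimated by \code{\link{estimate_s0}} if missing.
#' @return data frame (one row per gene): \code{gene}, \code{d}, \code{q},
#'   \code{mean_control}, \code{mean_case}, \code{class_control},
#'   \code{class_case}, \code{called}.
#' @export
sam_fdr <- function(matrix, n_perm = 200, fdr_cutoff = 0.05, rng_seed = 1,
                    s0 = NULL) {
  if (n_perm < 20) stop("n_perm must be >= 20")
  g <- sample_groups(matrix)
  x <- unclass(matrix)
  n <- ncol(x)
  n_case <- sum(g == "case")
  if (is.null(s0)) s0 <- estimate_s0(matrix)
  st <- group_stats(matrix)
  d_obs <- st$diff / (st$s + s0)

  n_distinct <- choose(n, n_case)
  case_sets <- local_seed(rng_seed, {
    if (n_distinct <= n_perm) {
      log_msg("sam_fdr", "only ", n_distinct,
              " distinct label assignments; using all of them")
      asplit(utils::combn(n, n_case), 2L)
    } else {
      lapply(seq_len(n_perm), function(i) sample.int(n, n_case))
    }
  })
  B <- length(case_sets)

  abs_obs <- abs(d_obs)
  # false-call counts per permutation at every gene's |d| cutoff
  false_counts <- matrix(NA_real_, length(abs_obs), B)
  ord <- order(abs_obs)
  sorted_cut <- abs_obs[ord]
  for (b in seq_len(B)) {
    idx <- case_sets[[b]]
    gp <- rep("control", n); gp[idx] <- "case"
    perm <- matrix; attr(perm, "groups") <- stats::setNames(gp, colnames(x))
    stp <- group_stats(perm)
    d_perm <- abs(stp$diff / (stp$s + s0))
    # #{|d*| >= cutoff} for each sorted cutoff via one sort
    cnt <- length(d_perm) -
      findInterval(sorted_cut, sort(d_perm), left.open = TRUE)
    false_counts[ord, b] <- cnt
  }
  med_false <- apply(false_counts, 1L, stats::median)
  obs_calls <- rank(-abs_obs, ties.method = "max")  # #{|d| >= |d_i|}
  q <- pmin(1, med_false / obs_calls)
  # enforce monotone nonincreasing q in |d|
  o <- order(abs_obs, decreasing = TRUE)
  q[o] <- cummax(q[o])

  data.frame(gene = rownames(x), d = d_obs, q = q,
             mean_control = st$mean_control, mean_case = st$mean_case,
             class_control = classify_level(st$mean_control),
             class_case = classify_level(st$mean_case),
             called = q < fdr_cutoff,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Classify a methylation level as hypo-, mid- or hypermethylated
#'
#' Thresholds follow the standard beta-value convention: hypomethylated when
#' the mean beta is at or below 0.2, hypermethylated at or above 0.8,
#' mid-methylated otherwise (boundaries inclusive).
#'
#' @param mean_beta numeric vector of mean beta values.
#' @return character vector in \code{\{"hypo", "mid", "hyper"\}}.
#' @export
classify_level <- function(mean_beta) {
  out <- rep("mid", length(mean_beta))
  out[mean_beta <= 0.2] <- "hypo"
  out[mean_beta >= 0.8] <- "hyper"
  out
}
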