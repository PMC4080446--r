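#' Gene profile matrices
#'
#' A gene profile matrix is the package's container for per-gene, per-sample
#' measurements: DNA methylation beta values in \code{[0, 1]} or continuous
#' expression values. It is a plain numeric matrix (genes in rows, samples in
#' columns) carrying a \code{"groups"} attribute that assigns each sample to
#' \code{"control"} or \code{"case"}.
#'
#' @param values numeric matrix, genes x samples, with row and column names.
#' @param groups character vector of \code{"control"}/\code{"case"} labels,
#'   one per sample, in column order (or named by sample id).
#' @param beta logical; if \code{TRUE}, values are checked to lie in
#'   \code{[0, 1]}.
#' @return the matrix with class \code{"gene_profile_matrix"}.
#' @export
gene_profile_matrix <- function(values, groups, beta = FALSE) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("values must be a numeric matrix")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("values must have gene row names and sample column names")
  if (anyDuplicated(rownames(values)))
    stop("duplicate gene ids: ",
         paste(unique(rownames(values)[duplicated(rownames(values))]),
               collapse = ", "))
  if (any(!is.finite(values)))
    stop("non-finite values in profile matrix")
  if (beta && (min(values) < 0 || max(values) > 1))
    stop("beta values must lie in [0, 1]")
  if (!is.null(names(groups))) {
    if (!setequal(names(groups), colnames(values)))
      stop("group names do not match sample ids")
    groups <- groups[colnames(values)]
  }
  if (length(groups) != ncol(values))
    stop("one group label per sample required")
  groups <- as.character(groups)
  if (!all(groups %in% c("control", "case")))
    stop("group labels must be 'control' or 'case'")
  if (!all(c("control", "case") %in% groups))
    stop("both groups must be non-empty")
  names(groups) <- colnames(values)
  structure(values, groups = groups, class = c("gene_profile_matrix", "matrix"))
}

#' @export
print.gene_profile_matrix <- function(x, ...) {
  g <- attr(x, "groups")
  cat(sprintf("gene_profile_matrix: %d genes x %d samples (%d control, %d case)\n",
              nrow(x), ncol(x), sum(g == "control"), sum(g == "case")))
  invisible(x)
}

#' Sample group labels of a profile matrix
#' @param x a \code{gene_profile_matrix}.
#' @return named character vector of \code{"control"}/\code{"case"} labels.
#' @export
sample_groups <- function(x) attr(x, "groups")

#' Read an interaction edge list in SIF format
#'
#' Accepts both the three-column dialect (\code{nodeA relation nodeB}) and the
#' bare two-column dialect (\code{nodeA nodeB}); the two may be mixed in one
#' file. Self-interactions are removed and redundant (duplicate, or reversed)
#' pairs collapsed, with the dropped counts logged.
#'
#' @param path path to a whitespace- or tab-delimited SIF file.
#' @return a data frame with character columns \code{gene_a}, \code{gene_b}:
#'   a deduplicated, self-loop-free undirected edge set (gene_a < gene_b).
#' @export
read_sif <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L)
    return(data.frame(gene_a = character(), gene_b = character(),
                      stringsAsFactors = FALSE))
  toks <- strsplit(trimws(lines), "[ \t]+")
  n_tok <- lengths(toks)
  bad <- which(!(n_tok %in% c(2L, 3L)))
  if (length(bad))
    stop("malformed SIF row at line ", bad[1L], ": '", lines[bad[1L]], "'")
  a <- vapply(toks, `[`, "", 1L)
  b <- vapply(toks, function(t) t[[length(t)]], "")
  self <- a == b
  lo <- pmin(a[!self], b[!self])
  hi <- pmax(a[!self], b[!self])
  dup <- duplicated(paste(lo, hi, sep = "\r"))
  log_msg("read_sif", sprintf("%d rows: %d self-loops and %d duplicates removed",
                              length(a), sum(self), sum(dup)))
  data.frame(gene_a = lo[!dup], gene_b = hi[!dup], stringsAsFactors = FALSE)
}

#' Write an interaction set as SIF
#' @param edges data frame with columns \code{gene_a}, \code{gene_b}.
#' @param path output path.
#' @param relation relation label for the middle column.
#' @export
write_sif <- function(edges, path, relation = "pp") {
  writeLines(paste(edges$gene_a, relation, edges$gene_b, sep = "\t"), path)
  invisible(path)
}

#' Read a gene x sample profile matrix from TSV
#'
#' The file must have a header of sample ids and gene ids in the first
#' column. Duplicate gene ids and non-numeric cells are rejected with their
#' locations.
#'
#' @param path path to a TSV file.
#' @param groups either a character vector of group labels (one per sample,
#'   optionally named by sample id) or the path to a two-column TSV of
#'   (sample id, group).
#' @param beta check values lie in \code{[0, 1]}.
#' @return a \code{\link{gene_profile_matrix}}.
#' @export
read_matrix <- function(path, groups, beta = FALSE) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                          colClasses = "character")
  if (ncol(df) < 2L) stop("matrix file needs a gene column plus >=1 sample")
  ids <- df[[1L]]
  if (anyDuplicated(ids)) {
    d <- ids[duplicated(ids)][1L]
    stop("duplicate gene id '", d, "' at data lines ",
         paste(which(ids == d), collapse = " and "))
  }
  vals <- as.matrix(df[, -1L, drop = FALSE])
  num <- suppressWarnings(array(as.numeric(vals), dim = dim(vals)))
  if (anyNA(num)) {
    idx <- which(is.na(num), arr.ind = TRUE)[1L, ]
    stop("non-numeric cell '", vals[idx[1L], idx[2L]], "' at data line ",
         idx[1L], ", sample '", colnames(vals)[idx[2L]], "'")
  }
  dimnames(num) <- list(ids, colnames(vals))
  if (is.character(groups) && length(groups) == 1L && file.exists(groups)) {
    g <- utils::read.delim(groups, header = FALSE, sep = "\t",
                           colClasses = "character")
    groups <- stats::setNames(g[[2L]], g[[1L]])
  }
  gene_profile_matrix(num, groups, beta = beta)
}

#' Write a profile matrix (and optionally its group labels) as TSV
#' @param x a \code{gene_profile_matrix} or plain named numeric matrix.
#' @param path output path for the matrix.
#' @param groups_path optional path for a (sample id, group) TSV.
#' @export
write_matrix <- function(x, path, groups_path = NULL) {
  df <- data.frame(gene = rownames(x), unclass(x)[, , drop = FALSE],
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(groups_path)) {
    g <- attr(x, "groups")
    utils::write.table(data.frame(names(g), g), groups_path, sep = "\t",
                       quote = FALSE, row.names = FALSE, col.names = FALSE)
  }
  invisible(path)
}

#' Read chromatin peaks from a BED-like file
#'
#' Columns are chrom, start, end, score with 0-based half-open intervals.
#' Empty intervals (start >= end) and negative scores are rejected with the
#' offending line number.
#'
#' @param path path to a tab- or space-delimited peak file (no header).
#' @return data frame with columns \code{chrom}, \code{start}, \code{end},
#'   \code{score}.
#' @export
read_bed <- function(path) {
  lines <- readLines(path)
  keep <- nzchar(trimws(lines)) & !startsWith(lines, "track") &
    !startsWith(lines, "#")
  lines <- lines[keep]
  line_no <- which(keep)
  if (length(lines) == 0L)
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), score = numeric()))
  toks <- strsplit(trimws(lines), "[ \t]+")
  bad <- which(lengths(toks) < 4L)
  if (length(bad))
    stop("BED row with fewer than 4 columns at line ", line_no[bad[1L]])
  chrom <- vapply(toks, `[`, "", 1L)
  start <- suppressWarnings(as.integer(vapply(toks, `[`, "", 2L)))
  end <- suppressWarnings(as.integer(vapply(toks, `[`, "", 3L)))
  score <- suppressWarnings(as.numeric(vapply(toks, `[`, "", 4L)))
  bad <- which(is.na(start) | is.na(end) | is.na(score))
  if (length(bad))
    stop("non-numeric BED coordinates/score at line ", line_no[bad[1L]])
  bad <- which(start >= end)
  if (length(bad))
    stop("empty or inverted interval (start >= end) at line ", line_no[bad[1L]])
  bad <- which(score < 0 | start < 0)
  if (length(bad))
    stop("negative start or score at line ", line_no[bad[1L]])
  data.frame(chrom = chrom, start = start, end = end, score = score,
             stringsAsFactors = FALSE)
}

#' Write a peak set as BED
#' @param peaks data frame with columns chrom, start, end, score.
#' @param path output path.
#' @export
write_bed <- function(peaks, path) {
  writeLines(paste(peaks$chrom, peaks$start, peaks$end, peaks$score,
                   sep = "\t"), path)
  invisible(path)
}

#' Read a transcription start site table
#'
#' Four tab-separated columns: gene id, chromosome, 0-based TSS position,
#' strand (\code{+}/\code{-}).
#'
#' @param path path to the TSS TSV (no header).
#' @return data frame with columns \code{gene}, \code{chrom}, \code{pos},
#'   \code{strand}.
#' @export
read_tss <- function(path) {
  df <- utils::read.delim(path, header = FALSE, sep = "\t",
                          colClasses = c("character", "character",
                                         "integer", "character"))
  names(df) <- c("gene", "chrom", "pos", "strand")
  if (any(df$pos < 0)) stop("negative TSS position at data line ",
                            which(df$pos < 0)[1L])
  if (!all(df$strand %in% c("+", "-")))
    stop("invalid strand at data line ",
         which(!(df$strand %in% c("+", "-")))[1L])
  df
}

#' @rdname read_tss
#' @param tss data frame with columns gene, chrom, pos, strand.
#' @export
write_tss <- function(tss, path) {
  utils::write.table(tss[, c("gene", "chrom", "pos", "strand")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' Write and read mined module tables
#'
#' The on-disk format is TSV with columns module_id, score, size and the
#' comma-joined gene list; \code{read_modules} is the exact inverse.
#'
#' @param modules a module set data frame as returned by
#'   \code{\link{mcode_modules}}.
#' @param path file path.
#' @export
write_modules <- function(modules, path) {
  df <- data.frame(module_id = modules$module_id,
                   score = modules$score,
                   size = modules$size,
                   genes = vapply(modules$genes, paste, "", collapse = ","),
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_modules
#' @export
read_modules <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          colClasses = c("integer", "numeric", "integer",
                                         "character"))
  df$genes <- strsplit(df$genes, ",", fixed = TRUE)
  df
}

#' Write a weighted network as an edge-list TSV
#' @param net an igraph network with edge attributes \code{r} and \code{p}.
#' @param path output path; columns gene_a, gene_b, r, p.
#' @export
write_network <- function(net, path) {
  el <- igraph::as_edgelist(net)
  df <- data.frame(gene_a = el[, 1L], gene_b = el[, 2L],
                   r = igraph::E(net)$r %||% rep(NA_real_, nrow(el)),
                   p = igraph::E(net)$p %||% rep(NA_real_, nrow(el)),
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
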