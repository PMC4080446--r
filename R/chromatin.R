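#' TSS-proximal promoter window
#'
#' The promoter region of a gene is the symmetric window of \code{flank}
#' base pairs up- and downstream of its transcription start site, inclusive
#' at both ends and clipped at position 0. Strand does not alter the window.
#'
#' @param tss_row one row of a TSS table (list or single-row data frame with
#'   \code{pos}).
#' @param flank half-width in bp (default 2000).
#' @return integer vector \code{c(start, end)} of the inclusive window.
#' @export
tss_region <- function(tss_row, flank = 2000) {
  pos <- tss_row$pos
  c(max(0L, as.integer(pos - flank)), as.integer(pos + flank))
}

#' Accumulate peak intensities into TSS-proximal regions
#'
#' Each peak is represented by its midpoint, \code{floor((start + end) / 2)}
#' for the 0-based half-open interval. A peak's score is added to every gene
#' whose promoter window (TSS +/- \code{flank}, both ends inclusive)
#' contains the midpoint; a midpoint inside two genes' windows contributes
#' to both. Genes with several TSS rows have their windows unioned, so a
#' midpoint counts once per gene. Every TSS-table gene gets a row (zeros
#' allowed); peaks on chromosomes absent from the TSS table are ignored
#' with a log entry.
#'
#' @param peaks peak data frame (chrom, start, end, score).
#' @param tss TSS data frame (gene, chrom, pos, strand).
#' @param flank promoter half-width in bp.
#' @return named numeric vector of accumulated intensity, one entry per
#'   TSS-table gene.
#' @export
map_peaks <- function(peaks, tss, flank = 2000) {
  genes <- unique(tss$gene)
  acc <- stats::setNames(numeric(length(genes)), genes)
  if (nrow(peaks) == 0L) return(acc)
  unknown <- !(peaks$chrom %in% tss$chrom)
  if (any(unknown))
    log_msg("map_peaks", sum(unknown),
            " peaks on chromosomes absent from the TSS table ignored")
  peaks <- peaks[!unknown, , drop = FALSE]
  mid <- floor((peaks$start + peaks$end) / 2)
  for (ch in unique(peaks$chrom)) {
    pk <- which(peaks$chrom == ch)
    win <- tss[tss$chrom == ch, , drop = FALSE]
    if (nrow(win) == 0L) next
    lo <- pmax(0L, win$pos - flank)
    hi <- win$pos + flank
    for (i in pk) {
      inside <- mid[i] >= lo & mid[i] <= hi
      if (any(inside)) {
        hit <- unique(win$gene[inside])  # union over a gene's multiple TSSs
        acc[hit] <- acc[hit] + peaks$score[i]
      }
    }
  }
  acc
}

#' Build the gene x mark chromatin intensity matrix
#'
#' Runs \code{\link{map_peaks}} once per mark and binds the columns; every
#' TSS-table gene has a row and intensities are nonnegative.
#'
#' @param peak_sets named list of peak data frames, one per chromatin mark.
#' @param tss TSS data frame.
#' @param flank promoter half-width in bp.
#' @return numeric matrix, genes x marks.
#' @export
chromatin_matrix <- function(peak_sets, tss, flank = 2000) {
  stopifnot(length(peak_sets) >= 1, !is.null(names(peak_sets)))
  cols <- lapply(peak_sets, map_peaks, tss = tss, flank = flank)
  do.call(cbind, cols)
}
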