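#' Classify peaks as TSS-proximal, distal or intermediate
#'
#' A peak is class "TSS" iff its interval overlaps any TSS +/- 1000 bp
#' window (inclusive bounds, realized half-open as
#' `[TSS-1000, TSS+1001)`); "distal" iff its midpoint
#' (`floor((start+end)/2)`) is more than 10,000 bp from every TSS;
#' otherwise "intermediate" (excluded from both downstream analyses).
#'
#' @param peaks data.frame with peak_id, chrom, start, end.
#' @param genes data.frame with gene_id, chrom, tss.
#' @param tss_flank TSS window half-width in bp (default 1000).
#' @param distal_min minimum midpoint-to-nearest-TSS distance for the
#'   distal class (default 10,000).
#' @return data.frame with peak_id, class, and `nearest_tss_dist`
#'   (NA on chromosomes without a TSS; such peaks are distal).
#' @export
classify_peaks <- function(peaks, genes, tss_flank = 1000L,
                           distal_min = 10000L) {
  pgr <- .as_granges0(peaks)
  tgr <- .as_granges0(data.frame(chrom = genes$chrom,
                                 start = genes$tss - tss_flank,
                                 end = genes$tss + tss_flank + 1L))
  at_tss <- GenomicRanges::countOverlaps(pgr, tgr) > 0
  mid <- .midpoint(peaks$start, peaks$end)
  nearest <- vapply(seq_len(nrow(peaks)), function(i) {
    tt <- genes$tss[genes$chrom == peaks$chrom[i]]
    if (!length(tt)) NA_real_ else min(abs(tt - mid[i]))
  }, 0)
  cls <- ifelse(at_tss, "TSS",
         ifelse(is.na(nearest) | nearest > distal_min, "distal",
                "intermediate"))
  data.frame(peak_id = peaks$peak_id, class = cls,
             nearest_tss_dist = nearest, stringsAsFactors = FALSE)
}

#' Correlate peak accessibility with gene expression and call links
#'
#' Replicate counts are put on the normalized `log2(x + 1)` scale and
#' then averaged per cell line; each candidate (peak, gene) pair's
#' Pearson r is computed across lines.  Candidates are genes whose TSS
#' lies within `window` bp of the peak midpoint.  TSS-class peaks pass
#' at `|r| > r_cutoff`; distal-class peaks pass at `r > r_cutoff`
#' (positive only) unless `distal_absolute = TRUE`.  Intermediate peaks
#' are skipped.
#'
#' @param peaks data.frame with peak_id, chrom, start, end.
#' @param classes output of [classify_peaks()] for the same peaks.
#' @param norm_counts peaks x replicates normalized count matrix.
#' @param design data.frame with replicate and line (replicate order
#'   matching `norm_counts` columns).
#' @param expression genes x lines expression matrix (FPKM-like values
#'   are transformed `log2(x + 0.5)` internally).
#' @param genes data.frame with gene_id, chrom, tss.
#' @param window TSS-to-midpoint candidate window in bp.
#' @param r_cutoff correlation cutoff (default 0.7).
#' @param distal_absolute allow negative distal correlations to pass on
#'   |r| (sensitivity analysis; default FALSE).
#' @return data.frame of links: peak_id, gene_id, class, r, n_lines,
#'   pass.
#' @export
link_and_correlate <- function(peaks, classes, norm_counts, design,
                               expression, genes, window = 500000L,
                               r_cutoff = 0.7, distal_absolute = FALSE) {
  lines <- unique(design$line)
  if (length(lines) < 4) stop("need >= 4 cell lines")
  stopifnot(identical(colnames(norm_counts), design$replicate))
  lg <- log2(norm_counts + 1)
  per_line <- vapply(lines, function(l)
    rowMeans(lg[, design$line == l, drop = FALSE]), numeric(nrow(lg)))
  expr <- log2(expression[, lines, drop = FALSE] + 0.5)

  cls <- classes$class[match(peaks$peak_id, classes$peak_id)]
  mid <- .midpoint(peaks$start, peaks$end)
  out <- vector("list", nrow(peaks))
  for (i in which(cls %in% c("TSS", "distal"))) {
    j <- which(genes$chrom == peaks$chrom[i] &
               abs(genes$tss - mid[i]) <= window &
               genes$gene_id %in% rownames(expr))
    if (!length(j)) next
    x <- per_line[peaks$peak_id[i], ]
    if (stats::sd(x) == 0) next
    r <- vapply(genes$gene_id[j], function(g) {
      y <- expr[g, ]
      if (stats::sd(y) == 0) NA_real_ else stats::cor(x, y)
    }, 0)
    pass <- if (cls[i] == "TSS" || distal_absolute) abs(r) > r_cutoff
            else r > r_cutoff
    out[[i]] <- data.frame(peak_id = peaks$peak_id[i],
                           gene_id = genes$gene_id[j],
                           class = cls[i], r = unname(r),
                           n_lines = length(lines),
                           pass = !is.na(r) & pass,
                           stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, out[!vapply(out, is.null, TRUE)])
  if (is.null(out))
    out <- data.frame(peak_id = character(), gene_id = character(),
                      class = character(), r = numeric(),
                      n_lines = integer(), pass = logical(),
                      stringsAsFactors = FALSE)
  out
}

#' Unique genes behind passing TSS links
#'
#' De-duplicated gene list from the passing TSS-class links, for
#' downstream clustering and signature use.
#'
#' @param links output of [link_and_correlate()].
#' @return character vector of unique gene ids (sorted).
#' @export
tss_gene_signature <- function(links) {
  sort(unique(links$gene_id[links$class == "TSS" & links$pass]))
}
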