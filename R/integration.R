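#' Fixed-width consensus windows around interval midpoints
#'
#' Replaces every interval by `[mid - size/2, mid + size/2)` with
#' `mid = floor((start+end)/2)`, clamped to chromosome bounds (the
#' clamped window may be shorter than `size`; it is never re-centered).
#' The interval count is preserved exactly.
#'
#' @param intervals data.frame with chrom, start, end (id columns are
#'   carried through).
#' @param size window width in bp; even and > 0.
#' @param chrom_lengths optional named vector of chromosome lengths for
#'   right-edge clamping.
#' @return data.frame like `intervals` with windowed start/end.
#' @export
consensus_windows <- function(intervals, size = 500L, chrom_lengths = NULL) {
  if (size <= 0) stop("size must be > 0")
  if (size %% 2 != 0) stop("size must be even")
  mid <- .midpoint(intervals$start, intervals$end)
  out <- intervals
  out$start <- pmax(0L, as.integer(mid - size / 2))
  out$end <- as.integer(mid + size / 2)
  if (!is.null(chrom_lengths)) {
    lim <- chrom_lengths[out$chrom]
    if (any(is.na(lim))) stop("chromosome missing from chrom_lengths")
    out$end <- pmin(out$end, as.integer(lim))
  }
  stopifnot(nrow(out) == nrow(intervals))
  out
}

#' Two-way interval overlap summary
#'
#' Counts, in both directions, how many intervals of A share at least
#' one base with any interval of B, and reports the fractions and
#' 1-decimal-place percentages.
#'
#' @param a,b data.frames with chrom, start, end (0-based half-open).
#' @return list: n_a, n_b, n_a_overlapped, n_b_overlapped, frac_a,
#'   frac_b, pct_a, pct_b (fractions NA when the corresponding set is
#'   empty).
#' @export
overlap_fraction <- function(a, b) {
  n_a <- nrow(a); n_b <- nrow(b)
  if (n_a == 0 || n_b == 0) {
    oa <- 0L; ob <- 0L
  } else {
    ga <- .as_granges0(a); gb <- .as_granges0(b)
    oa <- sum(GenomicRanges::countOverlaps(ga, gb) > 0)
    ob <- sum(GenomicRanges::countOverlaps(gb, ga) > 0)
  }
  frac_a <- if (n_a == 0) NA_real_ else oa / n_a
  frac_b <- if (n_b == 0) NA_real_ else ob / n_b
  list(n_a = n_a, n_b = n_b, n_a_overlapped = oa, n_b_overlapped = ob,
       frac_a = frac_a, frac_b = frac_b,
       pct_a = overlap_pct(oa, n_a), pct_b = overlap_pct(ob, n_b))
}

#' Overlap percentage at one decimal place
#'
#' The reporting convention used by [overlap_fraction()]:
#' `round(100 * k / n, 1)`.
#'
#' @param k overlapped count.
#' @param n total count.
#' @return percentage (NA for n = 0).
#' @export
overlap_pct <- function(k, n) {
  if (n == 0) return(NA_real_)
  round(100 * k / n, 1)
}

#' Module-level correlation profiles
#'
#' For each gene module and each data layer (cell-line peak-expression
#' links; tumor DMR-expression links), assigns every gene its
#' maximal-|r| link and tabulates the fraction of the module's genes per
#' correlation bin.  Genes without a link in a layer are tallied in a
#' separate `no_link` column.  Per module and layer the bin fractions
#' plus `no_link` sum to 1.
#'
#' @param assignment data.frame gene_id, module.
#' @param peak_links data.frame with gene_id and r (cell-line layer).
#' @param dmr_links data.frame with gene_id and r (tumor layer).
#' @param breaks increasing numeric vector of bin edges partitioning
#'   [-1, 1] (first = -1, last = 1); bins are right-closed.
#' @return data.frame: module, layer, one column per bin, no_link.
#' @export
module_profile <- function(assignment, peak_links, dmr_links,
                           breaks = seq(-1, 1, by = 0.25)) {
  if (is.unsorted(breaks, strictly = TRUE))
    stop("breaks must be strictly increasing (overlapping bins)")
  if (abs(breaks[1] + 1) > 1e-12 || abs(breaks[length(breaks)] - 1) > 1e-12)
    stop("breaks must partition [-1, 1]")
  bin_names <- paste0("(", utils::head(breaks, -1), ",",
                      utils::tail(breaks, -1), "]")
  best_r <- function(links) {
    links <- links[!is.na(links$r), , drop = FALSE]
    if (!nrow(links)) return(stats::setNames(numeric(0), character(0)))
    sp <- split(links$r, links$gene_id)
    vapply(sp, function(r) r[which.max(abs(r))], 0)
  }
  layers <- list(atac = best_r(peak_links), methylation = best_r(dmr_links))
  mods <- sort(unique(assignment$module))
  rows <- list()
  for (ly in names(layers)) {
    r_of <- layers[[ly]]
    for (m in mods) {
      g <- assignment$gene_id[assignment$module == m]
      r <- r_of[intersect(g, names(r_of))]
      counts <- if (length(r))
        table(cut(r, breaks, include.lowest = TRUE, labels = bin_names))
      else stats::setNames(rep(0L, length(bin_names)), bin_names)
      frac <- as.numeric(counts) / length(g)
      rows[[length(rows) + 1L]] <- data.frame(
        module = m, layer = ly,
        t(stats::setNames(frac, bin_names)),
        no_link = (length(g) - length(r)) / length(g),
        check.names = FALSE, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
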