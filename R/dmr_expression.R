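#' Link DMRs to candidate genes by TSS distance
#'
#' Produces all (DMR, gene) candidate pairs whose gene TSS lies within
#' `window` bp up- or downstream of the DMR midpoint
#' (`floor((start+end)/2)`, inclusive bound).  Genes can be restricted to
#' those with available expression by passing `expressed_genes`; DMRs
#' left with zero candidates are reported separately.
#'
#' @param dmrs data.frame with dmr_id, chrom, start, end.
#' @param genes data.frame with gene_id, chrom, tss.
#' @param window maximum |TSS - midpoint| in bp (> 0).
#' @param expressed_genes optional character vector restricting the
#'   candidate genes.
#' @return list with `pairs` (dmr_id, gene_id, distance), `unlinked`
#'   (dmr ids with no candidate) and `report` from [link_accounting()].
#' @export
link_dmr_genes <- function(dmrs, genes, window = 500000L,
                           expressed_genes = NULL) {
  if (window <= 0) stop("window must be positive")
  if (!is.null(expressed_genes))
    genes <- genes[genes$gene_id %in% expressed_genes, , drop = FALSE]
  mid <- .midpoint(dmrs$start, dmrs$end)
  pairs <- lapply(seq_len(nrow(dmrs)), function(i) {
    j <- which(genes$chrom == dmrs$chrom[i] &
               abs(genes$tss - mid[i]) <= window)
    if (!length(j)) return(NULL)
    data.frame(dmr_id = dmrs$dmr_id[i], gene_id = genes$gene_id[j],
               distance = abs(genes$tss[j] - mid[i]),
               stringsAsFactors = FALSE)
  })
  keep <- !vapply(pairs, is.null, TRUE)
  unlinked <- dmrs$dmr_id[!keep]
  pairs <- do.call(rbind, pairs[keep])
  if (is.null(pairs))
    pairs <- data.frame(dmr_id = character(), gene_id = character(),
                        distance = numeric(), stringsAsFactors = FALSE)
  list(pairs = pairs, unlinked = unlinked,
       report = link_accounting(nrow(pairs), nrow(dmrs), length(unlinked)))
}

#' Candidate-pair accounting
#'
#' The accounting used by [link_dmr_genes()]'s report: the mean number of
#' candidate genes per DMR (1 decimal place) and the number of linkable
#' DMRs (total minus those with no expressed candidate).
#'
#' @param n_pairs total candidate (DMR, gene) pairs.
#' @param n_dmrs total DMRs entering the linker.
#' @param n_unlinked DMRs with zero candidates.
#' @return list with `n_pairs`, `n_dmrs`, `n_unlinked`, `n_linkable` and
#'   `mean_genes_per_dmr`.
#' @export
link_accounting <- function(n_pairs, n_dmrs, n_unlinked) {
  stopifnot(n_unlinked <= n_dmrs)
  list(n_pairs = n_pairs, n_dmrs = n_dmrs, n_unlinked = n_unlinked,
       n_linkable = n_dmrs - n_unlinked,
       mean_genes_per_dmr = round(n_pairs / n_dmrs, 1))
}

#' Correlate DMR summary methylation with gene expression
#'
#' Pairwise-complete Pearson correlation between each candidate pair's
#' DMR summary beta and gene expression over the shared samples.  Pairs
#' with fewer than `min_n` complete observations or a zero-variance
#' vector get no r and are flagged.
#'
#' @param pairs data.frame with dmr_id, gene_id (from
#'   [link_dmr_genes()]).
#' @param dmr_beta DMRs x samples summary-beta matrix.
#' @param expression genes x samples expression matrix.
#' @param min_n minimum pairwise-complete sample count (>= 3).
#' @return data.frame of link records: dmr_id, gene_id, r, n, `ok`
#'   (FALSE when degenerate) and sign ("+"/"-").
#' @export
correlate_links <- function(pairs, dmr_beta, expression, min_n = 3L) {
  shared <- intersect(colnames(dmr_beta), colnames(expression))
  if (length(shared) == 0) stop("no shared samples between methylation and expression")
  if (min_n < 3) stop("min_n must be >= 3")
  db <- dmr_beta[, shared, drop = FALSE]
  ex <- expression[, shared, drop = FALSE]
  n_rec <- nrow(pairs)
  r <- n <- numeric(n_rec); ok <- logical(n_rec)
  for (i in seq_len(n_rec)) {
    x <- db[pairs$dmr_id[i], ]
    y <- ex[pairs$gene_id[i], ]
    use <- !is.na(x) & !is.na(y)
    n[i] <- sum(use)
    if (n[i] < min_n || stats::sd(x[use]) == 0 || stats::sd(y[use]) == 0) {
      r[i] <- NA_real_
    } else {
      r[i] <- stats::cor(x[use], y[use])
      ok[i] <- TRUE
    }
  }
  dropped <- sum(!ok)
  if (dropped) message(dropped, " link(s) without a computable correlation")
  data.frame(dmr_id = pairs$dmr_id, gene_id = pairs$gene_id,
             r = r, n = n, ok = ok,
             sign = ifelse(is.na(r) | r >= 0, "+", "-"),
             stringsAsFactors = FALSE)
}

#' Empirical percentile cutoff on absolute correlations
#'
#' The significance rule for methylation-expression links: the threshold
#' is the `percentile`-th percentile of the |r| distribution
#' (linear-interpolation quantile, type 7), and a link is significant iff
#' its |r| strictly exceeds the threshold.
#'
#' @param links link records from [correlate_links()] (rows without a
#'   computable r are ignored).
#' @param percentile percentile of |r| in (0, 100).
#' @param min_records minimum usable records required.
#' @return list with `percentile`, `threshold`, and `significant`
#'   (logical per input row).
#' @export
empirical_cutoff <- function(links, percentile = 98, min_records = 50L) {
  r <- links$r[links$ok & !is.na(links$r)]
  if (length(r) < min_records)
    stop("need at least ", min_records, " usable link records")
  thr <- unname(stats::quantile(abs(r), percentile / 100, type = 7))
  list(percentile = percentile, threshold = thr,
       significant = !is.na(links$r) & links$ok & abs(links$r) > thr)
}

#' Bonferroni-equivalent Pearson correlation threshold
#'
#' The smallest |r| whose two-sided Pearson test p-value (t transform,
#' `t = r*sqrt(n-2)/sqrt(1-r^2)`, df = n-2) satisfies
#' `p <= alpha / n_tests`, found by root-finding to |delta r| < 1e-6.
#' Reported alongside the empirical percentile cutoff for reference.
#'
#' @param n_samples samples per correlation (>= 4).
#' @param n_tests number of correlations tested (>= 1).
#' @param alpha family-wise error target in (0, 1].
#' @return the threshold |r| in [0, 1].
#' @export
bonferroni_r_threshold <- function(n_samples, n_tests, alpha = 0.05) {
  if (n_samples < 4) stop("n_samples must be >= 4")
  if (n_tests < 1) stop("n_tests must be >= 1")
  if (!is.numeric(alpha) || alpha <= 0 || alpha > 1) stop("alpha must be in (0, 1]")
  target <- alpha / n_tests
  pr <- function(r) {
    t <- r * sqrt(n_samples - 2) / sqrt(1 - r^2)
    2 * stats::pt(-abs(t), df = n_samples - 2)
  }
  if (pr(0) <= target) return(0)
  stats::uniroot(function(r) pr(r) - target, c(0, 1 - 1e-12),
                 tol = 1e-9)$root
}

#' Count significant links by sign
#'
#' Summarizes a link set at a given absolute-r threshold: positive and
#' negative significant links, their total, and the unique DMRs and
#' genes they involve (a DMR may hit several genes and vice versa).
#'
#' @param links link records from [correlate_links()].
#' @param threshold absolute-r threshold in [0, 1]; significance is
#'   `|r| > threshold`.
#' @return list with `n_positive`, `n_negative`, `n_total`,
#'   `n_unique_dmrs`, `n_unique_genes`.
#' @export
classify_links <- function(links, threshold) {
  stopifnot(threshold >= 0, threshold <= 1)
  sig <- links[!is.na(links$r) & abs(links$r) > threshold, , drop = FALSE]
  list(n_positive = sum(sig$r > 0),
       n_negative = sum(sig$r < 0),
       n_total = nrow(sig),
       n_unique_dmrs = length(unique(sig$dmr_id)),
       n_unique_genes = length(unique(sig$gene_id)))
}
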