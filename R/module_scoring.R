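#' Per-sample module expression scores
#'
#' Each gene row is z-scored across samples (mean 0, SD 1); a sample's
#' score for a module is the mean z over the module's genes present in
#' the expression matrix.  FPKM-like input is first offset by 0.5 and
#' log2-transformed when `fpkm = TRUE`.  Zero-variance gene rows cannot
#' be z-scored and are excluded; a module with no matched (scoreable)
#' gene gets NA scores with a warning.
#'
#' @param expression genes x samples matrix (>= 2 samples).
#' @param assignment data.frame with gene_id and module.
#' @param fpkm logical; apply `log2(x + 0.5)` first.
#' @return list with `scores` (samples x modules matrix), `matched`
#'   (scoreable genes per module) and `unmatched` (module genes absent
#'   from the matrix).
#' @export
module_scores <- function(expression, assignment, fpkm = FALSE) {
  if (ncol(expression) < 2) stop("need >= 2 samples")
  if (fpkm) expression <- log2(expression + 0.5)
  mu <- rowMeans(expression)
  sdv <- apply(expression, 1, stats::sd)
  usable <- sdv > 0
  z <- (expression[usable, , drop = FALSE] - mu[usable]) / sdv[usable]

  mods <- sort(unique(assignment$module))
  scores <- matrix(NA_real_, nrow = ncol(expression), ncol = length(mods),
                   dimnames = list(colnames(expression), paste0("module", mods)))
  matched <- stats::setNames(integer(length(mods)), paste0("module", mods))
  unmatched <- stats::setNames(integer(length(mods)), paste0("module", mods))
  if (sum(usable) == 0) {
    warning("no gene row with nonzero variance; all scores NA")
    return(list(scores = scores, matched = matched,
                unmatched = unmatched + as.integer(table(factor(assignment$module, mods)))))
  }
  for (i in seq_along(mods)) {
    g <- assignment$gene_id[assignment$module == mods[i]]
    hit <- intersect(g, rownames(z))
    matched[i] <- length(hit)
    unmatched[i] <- length(g) - length(hit)
    if (!length(hit)) {
      warning("module ", mods[i], " has no matched gene; scores NA")
      next
    }
    scores[, i] <- colMeans(z[hit, , drop = FALSE])
  }
  list(scores = scores, matched = matched, unmatched = unmatched)
}

#' ROC curve and AUC by the rank (Mann-Whitney) formulation
#'
#' AUC is the probability that a random positive scores above a random
#' negative, ties counted 1/2, computed from ranks.  The curve is a
#' threshold sweep over the observed scores (decreasing; predicted
#' positive when score >= threshold), which makes the trapezoidal area
#' under the swept curve equal the rank AUC.
#'
#' @param scores numeric score per sample (higher = more NE-like).
#' @param labels logical or 0/1 per sample; TRUE/1 = positive class.
#' @return list with `auc`, `thresholds`, `tpr`, `fpr`.
#' @export
roc_auc <- function(scores, labels) {
  labels <- as.logical(labels)
  ok <- !is.na(scores) & !is.na(labels)
  scores <- scores[ok]; labels <- labels[ok]
  n_pos <- sum(labels); n_neg <- sum(!labels)
  if (n_pos == 0 || n_neg == 0) stop("both classes must be present")
  r <- rank(scores)
  auc <- (sum(r[labels]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)

  thr <- c(Inf, sort(unique(scores), decreasing = TRUE))
  tpr <- vapply(thr, function(t) sum(scores >= t & labels) / n_pos, 0)
  fpr <- vapply(thr, function(t) sum(scores >= t & !labels) / n_neg, 0)
  list(auc = auc, thresholds = thr, tpr = tpr, fpr = fpr)
}
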