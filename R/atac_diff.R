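#' Median-of-ratios size factors
#'
#' Per-sample normalization factors for a peak-count matrix: each count
#' is divided by its peak's geometric mean across samples, the factor is
#' the per-sample median of those ratios over peaks with all-positive
#' counts, and the factors are rescaled to geometric mean 1.
#'
#' @param counts peaks x samples matrix of non-negative counts.
#' @param fallback "none" (error when no peak has all-positive counts)
#'   or "poscounts" (geometric means over positive entries only, ratios
#'   at positive counts).
#' @return numeric vector of size factors (> 0), one per sample.
#' @export
size_factors <- function(counts, fallback = c("none", "poscounts")) {
  fallback <- match.arg(fallback)
  if (any(counts < 0)) stop("counts must be non-negative")
  all_pos <- rowSums(counts > 0) == ncol(counts)
  if (!any(all_pos)) {
    if (fallback == "none")
      stop("no peak with all-positive counts; rerun with fallback = \"poscounts\"")
    logc <- log(counts)
    logc[!is.finite(logc)] <- NA
    geo <- exp(rowMeans(logc, na.rm = TRUE))
    ratios <- counts / geo
    ratios[counts == 0] <- NA
    sf <- apply(ratios, 2, stats::median, na.rm = TRUE)
  } else {
    sub <- counts[all_pos, , drop = FALSE]
    geo <- exp(rowMeans(log(sub)))
    sf <- apply(sub / geo, 2, stats::median)
  }
  sf <- sf / exp(mean(log(sf)))
  stats::setNames(sf, colnames(counts))
}

#' Negative-binomial Wald test for differential accessibility
#'
#' Per-peak NB log-link GLM of size-factor-normalized counts on a
#' two-level group (NE vs non-NE).  The two-group log-link model is
#' saturated in the group means, so the fitted means are the group
#' sample means; the coefficient is their log ratio and its Wald
#' standard error comes from the observed information,
#' `se = sqrt((1+a*muA)/(nA*muA) + (1+a*muB)/(nB*muB))` with dispersion
#' `a`.  Dispersion is estimated per peak by method of moments from the
#' pooled within-group variance, floored at 1e-8 and capped at 10.  No
#' empirical-Bayes shrinkage or independent filtering is applied.  Group
#' means are floored at 0.1 to keep the coefficient finite for all-zero
#' groups.
#'
#' @param norm_counts peaks x samples matrix of normalized counts.
#' @param group factor/character per sample with exactly two levels; the
#'   second level (or "NE" when present) is the test group.
#' @param fdr FDR threshold recorded in the result (calls are
#'   `q < fdr`).
#' @return data.frame per peak: baseMean, log2FC (test vs reference),
#'   dispersion, stat (Wald z), pvalue, padj (BH), significant.
#' @export
nb_wald_test <- function(norm_counts, group, fdr = 0.05) {
  group <- as.factor(as.character(group))
  if (nlevels(group) != 2) stop("group must have exactly two levels")
  if ("NE" %in% levels(group)) group <- stats::relevel(group, ref = setdiff(levels(group), "NE"))
  if (any(table(group) < 2)) stop("need >= 2 samples per group")
  ia <- which(group == levels(group)[1])   # reference
  ib <- which(group == levels(group)[2])   # test (NE)
  na <- length(ia); nb <- length(ib)

  ma <- rowMeans(norm_counts[, ia, drop = FALSE])
  mb <- rowMeans(norm_counts[, ib, drop = FALSE])
  m <- rowMeans(norm_counts)
  # pooled within-group variance (method of moments for the dispersion)
  ssa <- rowSums((norm_counts[, ia, drop = FALSE] - ma)^2)
  ssb <- rowSums((norm_counts[, ib, drop = FALSE] - mb)^2)
  v <- (ssa + ssb) / (na + nb - 2)
  disp <- pmin(10, pmax(1e-8, (v - m) / m^2))

  ma_f <- pmax(ma, 0.1); mb_f <- pmax(mb, 0.1)
  coef <- log(mb_f / ma_f)
  se <- sqrt((1 + disp * ma_f) / (na * ma_f) + (1 + disp * mb_f) / (nb * mb_f))
  z <- coef / se
  p <- pmin(1, pmax(2 * stats::pnorm(-abs(z)), .Machine$double.xmin))
  q <- bh_adjust(p)
  data.frame(peak_id = rownames(norm_counts),
             baseMean = m, log2FC = coef / log(2), dispersion = disp,
             stat = z, pvalue = p, padj = q, significant = q < fdr,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up FDR adjustment with monotonicity enforcement, with input
#' validation on (0, 1].
#'
#' @param p p-values in (0, 1].
#' @return q-values, same length and order as `p`.
#' @export
bh_adjust <- function(p) {
  if (any(is.na(p)) || any(p <= 0) || any(p > 1))
    stop("p-values must lie in (0, 1]")
  stats::p.adjust(p, method = "BH")
}
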