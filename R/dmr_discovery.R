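#' Filter methylation probes by missingness and zero variance
#'
#' Mirrors the two-step probe filter used before differential methylation
#' testing: first remove probes with more than `max_missing` missing
#' values within any of the three sample groups, then remove probes with
#' zero standard deviation within any group.
#'
#' @param beta probes x samples matrix of beta values in [0,1], NAs
#'   allowed.
#' @param groups factor/character per sample with levels NE, nonNE,
#'   normal.
#' @param max_missing maximum tolerated within-group missing fraction.
#' @return list with `beta` (the surviving rows), and `report`: counts
#'   removed per rule and the survivor accounting from
#'   [probe_filter_accounting()].
#' @export
filter_probes <- function(beta, groups, max_missing = 0.05) {
  if (!is.matrix(beta) || nrow(beta) == 0 || ncol(beta) == 0)
    stop("beta must be a non-empty probes x samples matrix")
  groups <- as.factor(groups)
  need <- c("NE", "nonNE", "normal")
  missing_grp <- setdiff(need, levels(droplevels(groups)))
  if (length(missing_grp))
    stop("group(s) absent from labels: ", paste(missing_grp, collapse = ", "))
  if (length(groups) != ncol(beta))
    stop("groups length must match the number of samples")
  if (any(table(groups)[need] < 2)) stop("need >= 2 samples per group")

  idx <- lapply(need, function(g) which(groups == g))
  miss_frac <- sapply(idx, function(j)
    rowMeans(is.na(beta[, j, drop = FALSE])))
  rm_miss <- apply(miss_frac, 1, max) > max_missing

  kept1 <- beta[!rm_miss, , drop = FALSE]
  zero_sd <- apply(sapply(idx, function(j) {
    apply(kept1[, j, drop = FALSE], 1, function(x) {
      x <- x[!is.na(x)]
      length(x) < 2 || stats::sd(x) == 0
    })
  }), 1, any)

  kept <- kept1[!zero_sd, , drop = FALSE]
  report <- list(n_input = nrow(beta),
                 n_removed_missing = sum(rm_miss),
                 n_removed_zero_sd = sum(zero_sd),
                 n_removed = sum(rm_miss) + sum(zero_sd))
  report$n_kept <- probe_filter_accounting(report$n_input, report$n_removed)
  stopifnot(report$n_kept == nrow(kept))
  list(beta = kept, report = report)
}

#' Probe-filter survivor accounting
#'
#' The accounting identity used by [filter_probes()]'s removal report:
#' survivors = input probes minus probes eliminated by the missingness
#' and zero-variance rules.
#'
#' @param n_input probes entering the filter.
#' @param n_removed probes eliminated by both rules combined.
#' @return number of surviving probes.
#' @export
probe_filter_accounting <- function(n_input, n_removed) {
  stopifnot(n_input >= n_removed, n_removed >= 0)
  n_input - n_removed
}

#' Mann-Whitney U test with exact small-sample enumeration
#'
#' Two-sided Mann-Whitney U test as used per probe.  Missing values are
#' dropped.  When the combined sample size is at most 12 the p-value is
#' exact, by enumeration of all C(nA+nB, nA) group assignments of the
#' observed values (ties handled naturally); the two-sided p is twice the
#' smaller tail (point included), capped at 1.  Larger samples use the
#' tie-corrected normal approximation with continuity correction.
#'
#' @param x,y numeric vectors for the two groups (NAs dropped).
#' @param exact_max combined size at or below which enumeration is used.
#' @return list with `U` (for the first group), `p` (two-sided, in
#'   (0,1]), `n_x`, `n_y` and `method` ("exact" or "normal").
#' @export
mann_whitney <- function(x, y, exact_max = 12L) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (!length(x) || !length(y)) stop("a group has no non-missing values")
  nx <- length(x); ny <- length(y)
  r <- rank(c(x, y))
  U <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  if (nx + ny <= exact_max) {
    p <- .mw_exact_p(c(x, y), nx, U)
    method <- "exact"
  } else {
    p <- .mw_normal_p(r, nx, ny, U)
    method <- "normal"
  }
  list(U = U, p = min(p, 1), n_x = nx, n_y = ny, method = method)
}

# exact two-sided p by full enumeration of group assignments
.mw_exact_p <- function(values, nx, U) {
  n <- length(values)
  r <- rank(values)
  sets <- utils::combn(n, nx)
  u_all <- colSums(matrix(r[sets], nrow = nx)) - nx * (nx + 1) / 2
  lo <- mean(u_all <= U)
  hi <- mean(u_all >= U)
  min(1, 2 * min(lo, hi))
}

# tie-corrected normal approximation with continuity correction
.mw_normal_p <- function(r, nx, ny, U) {
  n <- nx + ny
  ties <- rle(sort(r))$lengths
  mu <- nx * ny / 2
  sigma2 <- nx * ny / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
  if (sigma2 <= 0) return(1)
  z <- (U - mu - sign(U - mu) * 0.5) / sqrt(sigma2)
  min(1, 2 * stats::pnorm(-abs(z)))
}

#' Per-probe two-comparison Mann-Whitney testing
#'
#' Runs [mann_whitney()] for every probe for the two contrasts that
#' define NE-specific methylation: NE vs normal and NE vs non-NE.  Also
#' records the median difference (NE minus other) for each contrast,
#' computed on the same non-missing samples as the test.
#'
#' @param beta probes x samples beta matrix (NAs allowed).
#' @param groups factor per sample, levels NE/nonNE/normal.
#' @param exact_max passed to [mann_whitney()].
#' @return data.frame with one row per probe: U, p and median difference
#'   for each comparison.
#' @export
probe_tests <- function(beta, groups, exact_max = 12L) {
  groups <- as.factor(groups)
  ine <- which(groups == "NE")
  inn <- which(groups == "normal")
  int <- which(groups == "nonNE")
  one <- function(i) {
    xb <- beta[i, ]
    t1 <- mann_whitney(xb[ine], xb[inn], exact_max)
    t2 <- mann_whitney(xb[ine], xb[int], exact_max)
    c(U_ne_normal = t1$U, p_ne_normal = t1$p,
      dmed_ne_normal = stats::median(xb[ine], na.rm = TRUE) -
        stats::median(xb[inn], na.rm = TRUE),
      U_ne_nonne = t2$U, p_ne_nonne = t2$p,
      dmed_ne_nonne = stats::median(xb[ine], na.rm = TRUE) -
        stats::median(xb[int], na.rm = TRUE))
  }
  res <- t(vapply(seq_len(nrow(beta)), one, numeric(6)))
  out <- data.frame(probe_id = rownames(beta), res,
                    row.names = NULL, stringsAsFactors = FALSE)
  out
}

#' Select differentially methylated probes
#'
#' A probe is selected iff its Bonferroni-adjusted p-value (`min(1, p*m)`)
#' is below `alpha` AND its absolute median difference exceeds `delta`
#' in BOTH comparisons (NE vs normal and NE vs non-NE).
#'
#' @param tests output of [probe_tests()].
#' @param m number of probes tested (Bonferroni multiplier; the
#'   post-filter probe count).
#' @param alpha adjusted-p threshold.
#' @param delta minimum absolute median difference.
#' @return `tests` with columns `padj_ne_normal`, `padj_ne_nonne` and
#'   logical `pass` added.
#' @export
select_significant_probes <- function(tests, m, alpha = 0.01, delta = 0.1) {
  if (m <= 0) stop("m must be positive")
  tests$padj_ne_normal <- pmin(1, tests$p_ne_normal * m)
  tests$padj_ne_nonne <- pmin(1, tests$p_ne_nonne * m)
  tests$pass <- tests$padj_ne_normal < alpha & tests$padj_ne_nonne < alpha &
    abs(tests$dmed_ne_normal) > delta & abs(tests$dmed_ne_nonne) > delta
  tests
}

#' Merge significant probes into DMRs through 101 bp windows
#'
#' Every selected probe gets a 101 bp window `[pos-50, pos+51)`; windows
#' on the same chromosome sharing at least one base are merged
#' transitively (book-ended windows are not merged) into one DMR spanning
#' their union.  The per-sample DMR summary is the median beta over
#' member probes, ignoring missing values.
#'
#' @param probes data.frame with `probe_id`, `chrom`, `pos` for the
#'   selected probes.
#' @param beta optional probes x samples matrix providing member betas
#'   for the summary; rownames must cover the probe ids.
#' @param window_half half-widths of the probe window (left 50, right 51
#'   for the canonical 101 bp window).
#' @return list with `dmrs` (dmr_id, chrom, start, end, n_members),
#'   `members` (probe_id -> dmr_id map), `summary_beta` (DMRs x samples
#'   matrix, NULL when `beta` is NULL) and `report` with the merge
#'   accounting from [dmr_merge_accounting()].
#' @export
build_dmrs <- function(probes, beta = NULL, window_half = c(50L, 51L)) {
  stopifnot(all(c("probe_id", "chrom", "pos") %in% names(probes)))
  if (any(probes$pos < window_half[1]))
    stop("probe position closer to chromosome start than the window half-width")
  win <- data.frame(chrom = probes$chrom,
                    start = probes$pos - window_half[1],
                    end = probes$pos + window_half[2])
  gr <- .as_granges0(win)
  red <- GenomicRanges::reduce(gr, min.gapwidth = 0L)
  hit <- GenomicRanges::findOverlaps(gr, red)
  dmr_of <- integer(nrow(probes))
  dmr_of[S4Vectors::queryHits(hit)] <- S4Vectors::subjectHits(hit)
  stopifnot(all(dmr_of > 0))

  dmr_df <- .from_granges0(red)
  # stable ids in genomic order
  ord <- order(dmr_df$chrom, dmr_df$start)
  rank_of <- match(seq_along(ord), ord)
  dmr_df <- dmr_df[ord, , drop = FALSE]
  dmr_of <- rank_of[dmr_of]
  dmr_df$dmr_id <- sprintf("DMR%05d", seq_len(nrow(dmr_df)))
  members <- data.frame(probe_id = probes$probe_id,
                        dmr_id = dmr_df$dmr_id[dmr_of],
                        stringsAsFactors = FALSE)
  dmr_df$n_members <- as.integer(table(factor(dmr_of, seq_len(nrow(dmr_df)))))
  dmr_df <- dmr_df[, c("dmr_id", "chrom", "start", "end", "n_members")]

  summary_beta <- NULL
  if (!is.null(beta)) {
    if (!all(probes$probe_id %in% rownames(beta)))
      stop("beta rownames must cover all selected probes")
    summary_beta <- t(vapply(split(members$probe_id, members$dmr_id),
                             function(p) apply(beta[p, , drop = FALSE], 2,
                                               stats::median, na.rm = TRUE),
                             numeric(ncol(beta))))
    summary_beta <- summary_beta[dmr_df$dmr_id, , drop = FALSE]
    colnames(summary_beta) <- colnames(beta)
  }

  multi <- dmr_df$n_members > 1
  report <- list(n_probes = nrow(probes),
                 n_merged_probes = sum(dmr_df$n_members[multi]),
                 n_merged_regions = sum(multi))
  report$n_dmrs <- dmr_merge_accounting(report$n_probes,
                                        report$n_merged_probes,
                                        report$n_merged_regions)
  stopifnot(report$n_dmrs == nrow(dmr_df))
  list(dmrs = dmr_df, members = members, summary_beta = summary_beta,
       report = report)
}

#' DMR merge-count accounting
#'
#' The count identity behind [build_dmrs()]'s report: starting from the
#' selected probes, every probe that takes part in a multi-probe merge is
#' absorbed, and each merged region re-emerges as a single DMR, so
#' `n_dmrs = n_probes - n_merged_probes + n_merged_regions`.
#'
#' @param n_probes selected probes entering the merge.
#' @param n_merged_probes probes belonging to multi-probe regions.
#' @param n_merged_regions number of multi-probe regions.
#' @return total number of DMRs.
#' @export
dmr_merge_accounting <- function(n_probes, n_merged_probes, n_merged_regions) {
  stopifnot(n_merged_probes <= n_probes, n_merged_regions <= n_merged_probes)
  n_probes - n_merged_probes + n_merged_regions
}

#' Annotate DMRs with gene-model overlaps and nearby TSSs
#'
#' Computes, per DMR on half-open intervals: overlapping gene bodies,
#' promoter overlaps (promoter = `[TSS-2000, TSS+500)` on the coding
#' strand), CpG island/shore class (shore = 2 kb island flank), and all
#' TSSs within `tss_window` of the DMR midpoint
#' (`floor((start+end)/2)`, inclusive bound).
#'
#' @param dmrs data.frame with dmr_id, chrom, start, end.
#' @param genome a `synthetic_genome` or any list with `genes`
#'   (gene_id, chrom, strand, tss, start, end) and `cpg_islands`
#'   (chrom, start, end).
#' @param tss_window maximum |TSS - midpoint| in bp.
#' @return list with `annotation` (per-DMR island class and overlapping
#'   gene/promoter id strings) and `tss_links` (dmr_id, gene_id,
#'   distance).
#' @export
annotate_dmrs <- function(dmrs, genome, tss_window = 500000L) {
  genes <- genome$genes
  known <- unique(c(genes$chrom, genome$cpg_islands$chrom))
  unknown <- !(dmrs$chrom %in% known)
  if (any(unknown)) {
    warning("skipping ", sum(unknown), " DMR(s) on unknown chromosomes")
    dmrs <- dmrs[!unknown, , drop = FALSE]
  }
  dgr <- .as_granges0(dmrs)

  ggr <- .as_granges0(genes)
  prom_start <- ifelse(genes$strand == "+", genes$tss - 2000L, genes$tss - 499L)
  pgr <- .as_granges0(data.frame(chrom = genes$chrom,
                                 start = pmax(0L, prom_start),
                                 end = prom_start + 2500L))
  igr <- .as_granges0(genome$cpg_islands)
  sgr <- .as_granges0(data.frame(chrom = genome$cpg_islands$chrom,
                                 start = pmax(0L, genome$cpg_islands$start - 2000L),
                                 end = genome$cpg_islands$end + 2000L))

  paste_hits <- function(hits) {
    v <- character(length(dgr))
    sp <- split(genes$gene_id[S4Vectors::subjectHits(hits)],
                S4Vectors::queryHits(hits))
    v[as.integer(names(sp))] <- vapply(sp, paste, "", collapse = ",")
    v
  }
  ann <- data.frame(
    dmr_id = dmrs$dmr_id,
    genes = paste_hits(GenomicRanges::findOverlaps(dgr, ggr)),
    promoters = paste_hits(GenomicRanges::findOverlaps(dgr, pgr)),
    island_class = ifelse(GenomicRanges::countOverlaps(dgr, igr) > 0, "island",
                   ifelse(GenomicRanges::countOverlaps(dgr, sgr) > 0, "shore",
                          "open_sea")),
    stringsAsFactors = FALSE)

  mid <- .midpoint(dmrs$start, dmrs$end)
  links <- lapply(seq_len(nrow(dmrs)), function(i) {
    j <- which(genes$chrom == dmrs$chrom[i] &
               abs(genes$tss - mid[i]) <= tss_window)
    if (!length(j)) return(NULL)
    data.frame(dmr_id = dmrs$dmr_id[i], gene_id = genes$gene_id[j],
               distance = abs(genes$tss[j] - mid[i]),
               stringsAsFactors = FALSE)
  })
  links <- do.call(rbind, links[!vapply(links, is.null, TRUE)])
  list(annotation = ann, tss_links = links)
}
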