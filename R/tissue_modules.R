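#' Preprocess a tissue-panel expression matrix
#'
#' RPKM-like values are transformed `log10(x + 1)`; duplicate gene rows
#' are resolved by keeping the entry with the highest standard deviation
#' (computed on the log scale); zero-variance rows are dropped with a
#' logged count; finally each row is mean-centered.
#'
#' @param mat genes x tissues matrix of non-negative RPKM-like values;
#'   rownames are gene ids (duplicates allowed).
#' @return list with `mat` (the centered log matrix) and `report`
#'   (duplicates resolved, zero-variance rows dropped).
#' @export
preprocess_tissue <- function(mat) {
  if (any(mat < 0, na.rm = TRUE)) stop("tissue expression must be non-negative")
  lx <- log10(mat + 1)
  sds <- apply(lx, 1, stats::sd)
  n_dup <- 0L
  if (anyDuplicated(rownames(lx))) {
    ord <- order(rownames(lx), -sds)
    lx <- lx[ord, , drop = FALSE]
    dup <- duplicated(rownames(lx))
    n_dup <- sum(dup)
    lx <- lx[!dup, , drop = FALSE]
    sds <- apply(lx, 1, stats::sd)
  }
  zero <- sds == 0
  if (any(zero)) message(sum(zero), " zero-variance gene row(s) dropped")
  lx <- lx[!zero, , drop = FALSE]
  centered <- lx - rowMeans(lx)
  list(mat = centered,
       report = list(n_duplicates_resolved = n_dup,
                     n_zero_variance_dropped = sum(zero),
                     n_genes = nrow(centered)))
}

#' Classical multidimensional scaling of gene rows
#'
#' Classical (Torgerson) MDS of the Euclidean distances between gene
#' rows, via `stats::cmdscale`.  Coordinates are ordered by decreasing
#' eigenvalue; each dimension's sign is fixed so its first nonzero
#' loading is positive.
#'
#' @param mat standardized genes x tissues matrix.
#' @param dims embedding dimensionality (default 3).
#' @return list with `coords` (genes x dims), `eig` (all eigenvalues).
#' @export
mds_embed <- function(mat, dims = 3L) {
  if (nrow(mat) < dims + 1) stop("need at least dims + 1 gene rows")
  fit <- stats::cmdscale(stats::dist(mat), k = dims, eig = TRUE)
  coords <- fit$points
  for (j in seq_len(ncol(coords))) {
    nz <- which(abs(coords[, j]) > 1e-12)
    if (length(nz) && coords[nz[1], j] < 0) coords[, j] <- -coords[, j]
  }
  rownames(coords) <- rownames(mat)
  colnames(coords) <- paste0("MDS", seq_len(ncol(coords)))
  list(coords = coords, eig = fit$eig)
}

#' Derive gene modules by k-means on MDS coordinates
#'
#' Lloyd's algorithm with `restarts` random initializations (best
#' within-cluster sum of squares kept).  Module labels are made
#' deterministic by renumbering clusters by descending size, ties broken
#' by the lexicographically smallest member gene id.
#'
#' @param coords genes x dims MDS coordinates with gene-id rownames.
#' @param k number of modules (default 6).
#' @param restarts random restarts (default 50).
#' @param seed integer seed.
#' @return list with `assignment` (data.frame gene_id, module),
#'   `sizes` (per-module counts) and `tot_withinss`.
#' @export
kmeans_modules <- function(coords, k = 6L, restarts = 50L, seed = 1L) {
  if (k > nrow(coords)) stop("k cannot exceed the number of genes")
  set.seed(seed)
  # Lloyd restarts can transiently empty a cluster; the kept best-of-
  # restarts solution is still valid, so muffle that specific warning
  fit <- withCallingHandlers(
    stats::kmeans(coords, centers = k, nstart = restarts,
                  iter.max = 100L, algorithm = "Lloyd"),
    warning = function(w) {
      if (grepl("empty cluster", conditionMessage(w)))
        invokeRestart("muffleWarning")
    })
  raw <- fit$cluster
  first_gene <- vapply(seq_len(k), function(c)
    min(rownames(coords)[raw == c]), "")
  ord <- order(-tabulate(raw, k), first_gene)
  relabel <- match(seq_len(k), ord)
  module <- relabel[raw]
  assignment <- data.frame(gene_id = rownames(coords), module = module,
                           stringsAsFactors = FALSE)
  list(assignment = assignment, sizes = module_sizes(assignment),
       tot_withinss = fit$tot.withinss)
}

#' Per-module gene counts
#'
#' Sizes of each module in an assignment; the partition invariant
#' (every gene in exactly one module) makes the sizes sum to the number
#' of assigned genes.
#'
#' @param assignment data.frame with gene_id and module.
#' @return named integer vector of module sizes.
#' @export
module_sizes <- function(assignment) {
  if (anyDuplicated(assignment$gene_id))
    stop("assignment is not a partition: duplicated gene ids")
  tab <- table(assignment$module)
  stats::setNames(as.integer(tab), names(tab))
}

#' Hierarchical-clustering consistency check of k-means modules
#'
#' Ward.D2 agglomerative clustering (Euclidean distance) of the
#' standardized matrix, cut at `k` groups, cross-tabulated against the
#' k-means modules with an adjusted Rand index.  With `k = 1` the ARI is
#' undefined and reported as NA.
#'
#' @param mat standardized genes x tissues matrix.
#' @param assignment k-means assignment (data.frame gene_id, module).
#' @param k number of groups to cut the tree at (default: number of
#'   modules in `assignment`).
#' @return list with `ari`, `crosstab`, and `hclust_groups`.
#' @importFrom mclust adjustedRandIndex
#' @export
hclust_check <- function(mat, assignment, k = NULL) {
  if (!all(rownames(mat) %in% assignment$gene_id))
    stop("assignment must cover all matrix rows")
  mod <- assignment$module[match(rownames(mat), assignment$gene_id)]
  if (is.null(k)) k <- length(unique(mod))
  tree <- stats::hclust(stats::dist(mat), method = "ward.D2")
  grp <- stats::cutree(tree, k = k)
  ari <- if (k < 2) NA_real_ else mclust::adjustedRandIndex(mod, grp)
  list(ari = ari, crosstab = table(module = mod, hclust = grp),
       hclust_groups = grp)
}
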