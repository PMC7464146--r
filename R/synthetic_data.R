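#' Configuration for the synthetic genome and ground-truth manifest
#'
#' Collects every size, count and effect parameter of the synthetic-data
#' generator in one validated list.  The defaults describe the simulation
#' conditions used throughout the package's recovery tests: three tumor
#' groups of 30 samples, ~5,000 CpG probes of which 40 planted DMRs carry
#' three clustered probes each with a |delta beta| of 0.4, six tissue
#' coexpression modules of 30 genes (module 6 brain-high), and 2,000 ATAC
#' peaks of which 100 carry a planted log2 fold-change of 4 across
#' 3 neuroendocrine and 5 non-neuroendocrine cell lines with two
#' replicates each (mirroring an 8-line, 2-replicate design).
#'
#' @param n_chromosomes number of synthetic chromosomes.
#' @param chrom_length length of each chromosome in bp (>= 1 Mb advised).
#' @param n_genes number of genes; each gene has exactly one TSS.
#' @param n_dmrs number of planted DMR intervals.
#' @param probes_per_dmr clustered probes per planted DMR (>= 2 gives
#'   multi-probe DMRs after 101 bp window merging).
#' @param probe_spacing spacing in bp between clustered probes; below 101
#'   so that adjacent probe windows overlap and merge.
#' @param n_background_probes probes placed uniformly outside planted DMRs.
#' @param n_cpg_islands number of CpG island intervals.
#' @param delta_beta magnitude of the planted NE methylation shift.
#' @param n_links number of planted DMR-gene expression couplings
#'   (at most `n_dmrs`); each link's gene TSS lies within `link_window`
#'   of its DMR midpoint.
#' @param link_window maximum |TSS - DMR midpoint| for planted links, bp.
#' @param link_strength |slope| of expression on DMR summary beta.
#' @param n_modules number of tissue coexpression modules.
#' @param genes_per_module genes per module in the tissue panel.
#' @param n_tissues number of tissue types in the panel (one is "brain").
#' @param n_peaks total ATAC peaks.
#' @param n_diff_peaks planted differentially accessible peaks.
#' @param peak_log2fc planted log2 fold-change (NE vs non-NE) at
#'   differential peaks.
#' @param peak_dmr_frac fraction of differential peaks whose midpoint is
#'   placed inside a planted-DMR 500 bp consensus window.
#' @param peak_tss_frac fraction of differential peaks placed on a gene
#'   TSS (the rest are planted distal, > 10 kb from every TSS).
#' @param n_peak_links planted peak-gene accessibility/expression
#'   couplings among the differential peaks.
#' @return a validated list of class `nedmr_config`.
#' @export
synthetic_config <- function(n_chromosomes = 2L,
                             chrom_length = 10e6,
                             n_genes = 300L,
                             n_dmrs = 40L,
                             probes_per_dmr = 3L,
                             probe_spacing = 40L,
                             n_background_probes = 4880L,
                             n_cpg_islands = 80L,
                             delta_beta = 0.4,
                             n_links = 30L,
                             link_window = 500000L,
                             link_strength = 2,
                             n_modules = 6L,
                             genes_per_module = 30L,
                             n_tissues = 31L,
                             n_peaks = 2000L,
                             n_diff_peaks = 100L,
                             peak_log2fc = 4,
                             peak_dmr_frac = 0.3,
                             peak_tss_frac = 0.4,
                             n_peak_links = 40L) {
  cfg <- list(n_chromosomes = as.integer(n_chromosomes),
              chrom_length = as.numeric(chrom_length),
              n_genes = as.integer(n_genes),
              n_dmrs = as.integer(n_dmrs),
              probes_per_dmr = as.integer(probes_per_dmr),
              probe_spacing = as.integer(probe_spacing),
              n_background_probes = as.integer(n_background_probes),
              n_cpg_islands = as.integer(n_cpg_islands),
              delta_beta = delta_beta,
              n_links = as.integer(n_links),
              link_window = as.integer(link_window),
              link_strength = link_strength,
              n_modules = as.integer(n_modules),
              genes_per_module = as.integer(genes_per_module),
              n_tissues = as.integer(n_tissues),
              n_peaks = as.integer(n_peaks),
              n_diff_peaks = as.integer(n_diff_peaks),
              peak_log2fc = peak_log2fc,
              peak_dmr_frac = peak_dmr_frac,
              peak_tss_frac = peak_tss_frac,
              n_peak_links = as.integer(n_peak_links))
  counts <- c("n_chromosomes", "chrom_length", "n_genes", "n_dmrs",
              "probes_per_dmr", "n_cpg_islands", "n_tissues", "n_peaks")
  for (nm in counts)
    if (cfg[[nm]] <= 0) stop("config field '", nm, "' must be positive")
  if (cfg$n_background_probes < 0 || cfg$n_diff_peaks < 0)
    stop("counts must be non-negative")
  if (cfg$delta_beta <= 0) stop("delta_beta must be > 0")
  if (cfg$n_links > cfg$n_dmrs) stop("n_links cannot exceed n_dmrs")
  if (cfg$n_diff_peaks > cfg$n_peaks) stop("n_diff_peaks cannot exceed n_peaks")
  if (cfg$peak_dmr_frac < 0 || cfg$peak_dmr_frac > 1 ||
      cfg$peak_tss_frac < 0 || cfg$peak_tss_frac > 1)
    stop("peak fractions must be in [0, 1]")
  class(cfg) <- "nedmr_config"
  cfg
}

#' Generate a synthetic genome annotation with a planted truth manifest
#'
#' Builds chromosomes, genes (one TSS each), CpG probes, CpG islands and
#' ATAC peak intervals, planting the ground truth that every downstream
#' recovery test reads back: DMR intervals with signed methylation shifts,
#' DMR-gene expression couplings, tissue-module memberships and
#' differentially accessible peaks with their fold-changes.  Probes are
#' placed both clustered inside planted DMR intervals (spacing below the
#' 101 bp merge window) and uniformly as background.  The shift sign of
#' each planted DMR points away from the nearer beta boundary (baselines
#' above 0.5 shift down) so the planted effect survives clipping to
#' [0, 1].
#'
#' All coordinates are 0-based half-open.  Identical seeds give
#' byte-identical output.
#'
#' @param config a [synthetic_config()] list.
#' @param seed integer seed controlling all placement randomness.
#' @return an object of class `synthetic_genome`: a list with
#'   `chromosomes` (named lengths), `genes`, `probes`, `cpg_islands`
#'   data frames, and `truth`, the manifest with elements `dmrs`
#'   (chrom/start/end/delta_beta/baseline), `links`
#'   (dmr_id/gene_id/sign/strength), `modules` (gene_id/module/is_brain),
#'   `peaks` (intervals with planted log2fc, TSS/distal/DMR placement
#'   flags), `peak_links`, the `config` echo and the `seed`.
#' @export
generate_annotation <- function(config = synthetic_config(), seed = 1L) {
  if (!inherits(config, "nedmr_config")) config <- do.call(synthetic_config, config)
  set.seed(seed)
  chroms <- stats::setNames(rep(config$chrom_length, config$n_chromosomes),
                            paste0("chr", seq_len(config$n_chromosomes)))

  # genes: uniform TSS, strand random, gene body 2-50 kb downstream
  gid <- sprintf("G%04d", seq_len(config$n_genes))
  gchrom <- sample(names(chroms), config$n_genes, replace = TRUE)
  tss <- floor(stats::runif(config$n_genes, 1e5, config$chrom_length - 1e5))
  strand <- sample(c("+", "-"), config$n_genes, replace = TRUE)
  glen <- floor(stats::runif(config$n_genes, 2e3, 5e4))
  gstart <- ifelse(strand == "+", tss, tss - glen)
  gend <- ifelse(strand == "+", tss + glen, tss + 1)
  genes <- data.frame(gene_id = gid, symbol = gid, chrom = gchrom,
                      strand = strand, tss = as.integer(tss),
                      start = as.integer(pmax(0, gstart)),
                      end = as.integer(pmin(config$chrom_length, gend)),
                      stringsAsFactors = FALSE)

  # planted DMRs: cluster of probes_per_dmr probes, spacing < 101 bp
  span <- (config$probes_per_dmr - 1L) * config$probe_spacing
  dchrom <- sample(names(chroms), config$n_dmrs, replace = TRUE)
  dpos <- floor(stats::runif(config$n_dmrs, 2e5, config$chrom_length - 2e5))
  dmr_probe_pos <- lapply(seq_len(config$n_dmrs), function(i)
    as.integer(dpos[i] + seq(0L, span, by = config$probe_spacing)))
  baseline <- stats::runif(config$n_dmrs, 0.15, 0.85)
  delta <- ifelse(baseline > 0.5, -config$delta_beta, config$delta_beta)
  truth_dmrs <- data.frame(
    dmr_id = sprintf("TD%03d", seq_len(config$n_dmrs)),
    chrom = dchrom,
    start = as.integer(dpos - 50L),
    end   = as.integer(dpos + span + 51L),
    delta_beta = delta,
    baseline = baseline,
    stringsAsFactors = FALSE)

  # probes: clustered (inside planted intervals) + uniform background
  bg_pos <- floor(stats::runif(config$n_background_probes, 1e3,
                               config$chrom_length - 1e3))
  bg_chrom <- sample(names(chroms), config$n_background_probes, replace = TRUE)
  probes <- data.frame(
    chrom = c(rep(dchrom, each = config$probes_per_dmr), bg_chrom),
    pos = as.integer(c(unlist(dmr_probe_pos), bg_pos)),
    in_dmr = c(rep(truth_dmrs$dmr_id, each = config$probes_per_dmr),
               rep(NA_character_, config$n_background_probes)),
    stringsAsFactors = FALSE)
  probes$probe_id <- sprintf("cg%06d", seq_len(nrow(probes)))
  probes <- probes[, c("probe_id", "chrom", "pos", "in_dmr")]

  # CpG islands
  iw <- floor(stats::runif(config$n_cpg_islands, 300, 2000))
  ipos <- floor(stats::runif(config$n_cpg_islands, 1e4,
                             config$chrom_length - 1e4))
  cpg_islands <- data.frame(
    chrom = sample(names(chroms), config$n_cpg_islands, replace = TRUE),
    start = as.integer(ipos), end = as.integer(ipos + iw),
    stringsAsFactors = FALSE)

  # tissue-module membership: disjoint gene sets, module n_modules is the
  # brain-high ("neural") module
  n_mod_genes <- config$n_modules * config$genes_per_module
  if (n_mod_genes > config$n_genes)
    stop("not enough genes for the requested module structure")
  mod_genes <- sample(genes$gene_id, n_mod_genes)
  truth_modules <- data.frame(
    gene_id = mod_genes,
    module = rep(seq_len(config$n_modules), each = config$genes_per_module),
    stringsAsFactors = FALSE)
  truth_modules$is_brain <- truth_modules$module == config$n_modules

  # planted DMR-gene links: for each linked DMR pick the nearest TSS on
  # the same chromosome within the window (guaranteed present at the
  # default gene density); sign random.  Brain-module genes are excluded
  # so their NE expression shift cannot distort a planted correlation.
  brain_ids <- truth_modules$gene_id[truth_modules$is_brain]
  mid <- .midpoint(truth_dmrs$start, truth_dmrs$end)
  link_rows <- vector("list", config$n_links)
  used <- character(0)   # one coupling per gene
  for (i in seq_len(config$n_links)) {
    cand <- which(genes$chrom == truth_dmrs$chrom[i] &
                  abs(genes$tss - mid[i]) <= config$link_window &
                  !(genes$gene_id %in% c(brain_ids, used)))
    if (!length(cand)) next
    g <- cand[which.min(abs(genes$tss[cand] - mid[i]))]
    used <- c(used, genes$gene_id[g])
    link_rows[[i]] <- data.frame(dmr_id = truth_dmrs$dmr_id[i],
                                 gene_id = genes$gene_id[g],
                                 sign = sample(c(1, -1), 1),
                                 strength = config$link_strength,
                                 stringsAsFactors = FALSE)
  }
  truth_links <- do.call(rbind, link_rows[!vapply(link_rows, is.null, TRUE)])

  truth_peaks <- .plant_peaks(config, chroms, genes, truth_dmrs)

  # planted peak-gene couplings among differential peaks with a gene in
  # reach (TSS peaks couple to their own gene; distal to nearest gene)
  diff_idx <- which(truth_peaks$is_differential)
  take <- diff_idx[seq_len(min(config$n_peak_links, length(diff_idx)))]
  pl <- lapply(take, function(i) {
    pm <- .midpoint(truth_peaks$start[i], truth_peaks$end[i])
    cand <- which(genes$chrom == truth_peaks$chrom[i] &
                  abs(genes$tss - pm) <= 1e6)
    if (!length(cand)) return(NULL)
    g <- cand[which.min(abs(genes$tss[cand] - pm))]
    data.frame(peak_id = truth_peaks$peak_id[i], gene_id = genes$gene_id[g],
               stringsAsFactors = FALSE)
  })
  truth_peak_links <- do.call(rbind, pl[!vapply(pl, is.null, TRUE)])

  out <- list(chromosomes = chroms, genes = genes, probes = probes,
              cpg_islands = cpg_islands,
              truth = list(dmrs = truth_dmrs, links = truth_links,
                           modules = truth_modules, peaks = truth_peaks,
                           peak_links = truth_peak_links,
                           config = unclass(config), seed = seed))
  class(out) <- "synthetic_genome"
  .validate_genome(out)
  out
}

# peak interval planting: differential peaks split between DMR-window /
# TSS-proximal / distal placements; null peaks uniform
.plant_peaks <- function(config, chroms, genes, truth_dmrs) {
  width <- 400L
  n_diff <- config$n_diff_peaks
  n_dmrp <- round(config$peak_dmr_frac * n_diff)
  n_tssp <- round(config$peak_tss_frac * n_diff)
  n_dist <- n_diff - n_dmrp - n_tssp
  if (n_dist < 0) stop("peak_dmr_frac + peak_tss_frac must be <= 1")

  place_uniform <- function(n) {
    data.frame(chrom = sample(names(chroms), n, replace = TRUE),
               mid = floor(stats::runif(n, 1e4, config$chrom_length - 1e4)),
               stringsAsFactors = FALSE)
  }
  # inside a planted-DMR 500 bp consensus window: peak midpoint = DMR mid
  dsel <- sample(nrow(truth_dmrs), n_dmrp, replace = n_dmrp > nrow(truth_dmrs))
  dmr_pl <- data.frame(chrom = truth_dmrs$chrom[dsel],
                       mid = .midpoint(truth_dmrs$start, truth_dmrs$end)[dsel],
                       stringsAsFactors = FALSE)
  # on a TSS
  gsel <- sample(nrow(genes), n_tssp)
  tss_pl <- data.frame(chrom = genes$chrom[gsel], mid = genes$tss[gsel],
                       stringsAsFactors = FALSE)
  # distal: > 10 kb from every TSS (rejection sampling)
  distal_pl <- place_uniform(0)
  while (nrow(distal_pl) < n_dist) {
    cand <- place_uniform(2L * (n_dist - nrow(distal_pl)) + 4L)
    keep <- vapply(seq_len(nrow(cand)), function(j) {
      tt <- genes$tss[genes$chrom == cand$chrom[j]]
      !length(tt) || min(abs(tt - cand$mid[j])) > 10000 + width
    }, TRUE)
    distal_pl <- rbind(distal_pl, cand[keep, , drop = FALSE])
  }
  distal_pl <- distal_pl[seq_len(n_dist), , drop = FALSE]

  null_pl <- place_uniform(config$n_peaks - n_diff)
  all_pl <- rbind(dmr_pl, tss_pl, distal_pl, null_pl)
  peaks <- data.frame(
    peak_id = sprintf("PK%05d", seq_len(config$n_peaks)),
    chrom = all_pl$chrom,
    start = as.integer(all_pl$mid - width / 2),
    end   = as.integer(all_pl$mid + width / 2),
    is_differential = rep(c(TRUE, FALSE), c(n_diff, config$n_peaks - n_diff)),
    placement = c(rep(c("dmr_window", "tss", "distal"),
                      c(n_dmrp, n_tssp, n_dist)),
                  rep("background", config$n_peaks - n_diff)),
    stringsAsFactors = FALSE)
  fc_sign <- sample(c(1, -1), n_diff, replace = TRUE, prob = c(0.6, 0.4))
  peaks$log2fc <- c(config$peak_log2fc * fc_sign,
                    rep(0, config$n_peaks - n_diff))
  peaks
}

.validate_genome <- function(g) {
  for (df in list(g$genes, g$cpg_islands, g$truth$dmrs, g$truth$peaks)) {
    lim <- g$chromosomes[df$chrom]
    if (any(df$start < 0) || any(df$end > lim))
      stop("synthetic interval outside chromosome bounds")
  }
  if (anyDuplicated(g$probes$probe_id)) stop("duplicate probe ids")
  if (any(g$probes$pos < 0) || any(g$probes$pos >= g$chromosomes[g$probes$chrom]))
    stop("probe position outside chromosome bounds")
  if (!is.null(g$truth$links) && nrow(g$truth$links)) {
    m <- .midpoint(g$truth$dmrs$start, g$truth$dmrs$end)
    names(m) <- g$truth$dmrs$dmr_id
    tss <- stats::setNames(g$genes$tss, g$genes$gene_id)
    if (any(abs(tss[g$truth$links$gene_id] - m[g$truth$links$dmr_id]) >
            g$truth$config$link_window))
      stop("planted link outside its window")
  }
  if (any(abs(g$truth$dmrs$delta_beta) <= 0)) stop("planted delta beta must be > 0")
  invisible(g)
}

#' Simulate a beta-value methylation matrix with planted group shifts
#'
#' Baseline methylation per probe is drawn from a bimodal
#' Beta(2,10)/Beta(10,2) mixture (450K-like marginals); per-sample values
#' are Beta-distributed around the probe baseline with precision 50.
#' Neuroendocrine (NE) samples are then shifted by the planted signed
#' delta beta at probes inside planted DMR intervals and clipped to
#' [0, 1].  Missing entries are injected completely at random.
#'
#' @param genome a `synthetic_genome` from [generate_annotation()].
#' @param n_ne,n_nonne,n_normal samples per group (>= 3 each).
#' @param missing_rate fraction of entries set missing, in [0, 1).
#' @param seed integer seed.
#' @return list with `beta` (probes x samples matrix in [0,1] with NAs),
#'   `groups` (factor NE/nonNE/normal named by sample) and `probes`
#'   (the genome's probe table).
#' @export
simulate_methylation <- function(genome, n_ne = 30L, n_nonne = 30L,
                                 n_normal = 30L, missing_rate = 0.01,
                                 seed = 1L) {
  stopifnot(inherits(genome, "synthetic_genome"))
  if (min(n_ne, n_nonne, n_normal) < 3) stop("group sizes must be >= 3")
  if (missing_rate < 0 || missing_rate >= 1) stop("missing_rate must be in [0, 1)")
  set.seed(seed)
  probes <- genome$probes
  m <- nrow(probes)
  n <- n_ne + n_nonne + n_normal
  groups <- factor(rep(c("NE", "nonNE", "normal"), c(n_ne, n_nonne, n_normal)),
                   levels = c("NE", "nonNE", "normal"))
  samples <- paste0(rep(c("NE", "T", "N"), c(n_ne, n_nonne, n_normal)),
                    c(seq_len(n_ne), seq_len(n_nonne), seq_len(n_normal)))
  names(groups) <- samples

  hi <- stats::runif(m) < 0.5
  base <- ifelse(hi, stats::rbeta(m, 10, 2), stats::rbeta(m, 2, 10))
  # planted probes inherit the manifest baseline so the shifted value has
  # room before clipping
  planted <- !is.na(probes$in_dmr)
  base[planted] <- genome$truth$dmrs$baseline[
    match(probes$in_dmr[planted], genome$truth$dmrs$dmr_id)]
  base <- pmin(pmax(base, 0.02), 0.98)
  prec <- 50
  beta <- matrix(stats::rbeta(m * n, rep(base, n) * prec,
                              rep(1 - base, n) * prec),
                 nrow = m, ncol = n,
                 dimnames = list(probes$probe_id, samples))

  if (any(planted)) {
    shift <- genome$truth$dmrs$delta_beta[
      match(probes$in_dmr[planted], genome$truth$dmrs$dmr_id)]
    ne_cols <- which(groups == "NE")
    beta[planted, ne_cols] <- pmin(pmax(beta[planted, ne_cols] + shift, 0), 1)
  }
  if (missing_rate > 0) {
    beta[stats::runif(m * n) < missing_rate] <- NA_real_
  }
  list(beta = beta, groups = groups, probes = probes)
}

#' Simulate tumor expression coupled to planted DMR methylation
#'
#' For every planted (DMR, gene) link the gene's expression across tumor
#' samples is `a + sign * strength * median-beta(DMR) + N(0, noise_sd)`,
#' where the median is taken over the planted DMR's member probes.  All
#' other genes are independent Gaussian noise around a gene-specific
#' baseline.  Genes of the brain-high tissue module are additionally
#' raised by `ne_module_effect` standard deviations in NE samples, so
#' module scoring has a planted positive class.
#'
#' @param genome a `synthetic_genome`.
#' @param methylation output of [simulate_methylation()].
#' @param noise_sd Gaussian noise standard deviation on expression.
#' @param ne_module_effect NE up-shift (in noise SD units relative to the
#'   baseline SD of 1) applied to brain-module genes.
#' @param seed integer seed.
#' @return genes x samples expression matrix (log-intensity scale).
#' @export
simulate_expression <- function(genome, methylation, noise_sd = 0.2,
                                ne_module_effect = 1, seed = 1L) {
  stopifnot(inherits(genome, "synthetic_genome"))
  set.seed(seed)
  genes <- genome$genes
  samples <- colnames(methylation$beta)
  ng <- nrow(genes)
  n <- length(samples)
  expr <- matrix(stats::rnorm(ng * n, mean = rep(stats::runif(ng, 5, 8), n), sd = 1),
                 nrow = ng, ncol = n, dimnames = list(genes$gene_id, samples))

  links <- genome$truth$links
  if (!is.null(links) && nrow(links)) {
    bad <- !(links$gene_id %in% genes$gene_id) |
      !(links$dmr_id %in% genome$truth$dmrs$dmr_id)
    if (any(bad)) stop("planted link references unknown gene or DMR id")
    for (i in seq_len(nrow(links))) {
      members <- genome$probes$probe_id[
        !is.na(genome$probes$in_dmr) & genome$probes$in_dmr == links$dmr_id[i]]
      summ <- apply(methylation$beta[members, , drop = FALSE], 2,
                    stats::median, na.rm = TRUE)
      expr[links$gene_id[i], ] <- 6 + links$sign[i] * links$strength[i] * summ +
        stats::rnorm(n, sd = noise_sd)
    }
  }
  mods <- genome$truth$modules
  brain <- mods$gene_id[mods$is_brain]
  ne <- names(methylation$groups)[methylation$groups == "NE"]
  if (length(brain) && length(ne) && ne_module_effect != 0)
    expr[brain, ne] <- expr[brain, ne] + ne_module_effect
  expr
}

#' Simulate an RPKM-like tissue-panel expression matrix
#'
#' Each planted module receives a distinct block of signature tissues in
#' which its genes are elevated; the last module's signature is centred
#' on a designated "brain" tissue where its mean is strictly highest (the
#' neural-module analogue).  Values are generated on the log10 scale and
#' returned as non-negative RPKM-like values (`10^x - 1`).  By default
#' the panel holds exactly the module genes (the matched-gene situation
#' the module discovery runs on); unstructured non-module genes can be
#' added with `include_background`.
#'
#' @param genome a `synthetic_genome`.
#' @param separation module-vs-background mean difference on the log10
#'   scale (brain gets 1.5x for the neural module).
#' @param noise_sd i.i.d. log10-scale noise SD.
#' @param include_background also emit the annotation's non-module genes
#'   as pure-noise rows.
#' @param seed integer seed.
#' @return genes x tissues matrix of RPKM-like values; the brain column
#'   is named `"brain"`.
#' @export
simulate_tissue_panel <- function(genome, separation = 2, noise_sd = 0.3,
                                  include_background = FALSE, seed = 1L) {
  stopifnot(inherits(genome, "synthetic_genome"))
  set.seed(seed)
  cfg <- genome$truth$config
  mods <- genome$truth$modules
  nt <- cfg$n_tissues
  k <- cfg$n_modules
  tissues <- c(paste0("tissue", seq_len(nt - 1L)), "brain")
  gene_ids <- if (include_background) genome$genes$gene_id else mods$gene_id
  ng <- length(gene_ids)

  # block of signature tissues per module; brain (last column) belongs to
  # the last module's block
  block_size <- max(1L, (nt - 1L) %/% k)
  profile <- matrix(0, nrow = k, ncol = nt, dimnames = list(NULL, tissues))
  for (j in seq_len(k)) {
    cols <- ((j - 1L) * block_size + 1L):min(j * block_size, nt - 1L)
    profile[j, cols] <- separation
  }
  profile[k, nt] <- 1.5 * separation  # brain, strictly highest for module k

  logx <- matrix(stats::rnorm(ng * nt, mean = 1, sd = noise_sd),
                 nrow = ng, ncol = nt, dimnames = list(gene_ids, tissues))
  mrow <- match(gene_ids, mods$gene_id)
  in_mod <- !is.na(mrow)
  logx[in_mod, ] <- logx[in_mod, ] + profile[mods$module[mrow[in_mod]], ]
  pmax(10^logx - 1, 0)
}

#' Simulate ATAC peak counts and coupled cell-line expression
#'
#' Counts follow a negative binomial: per-peak base means are log-normal,
#' replicate library sizes vary log-normally, and planted differential
#' peaks have their mean multiplied by `2^log2fc` in NE lines.  Cell-line
#' expression is FPKM-like; genes in the planted peak-gene couplings
#' track their peak's per-line mean accessibility on the log2 scale.
#'
#' @param genome a `synthetic_genome`.
#' @param n_ne_lines,n_nonne_lines cell lines per group.
#' @param reps replicates per line (>= 1; >= 2 for inference).
#' @param dispersion NB dispersion (> 0); variance = mu + dispersion*mu^2.
#' @param expr_noise_sd log2-scale noise on coupled gene expression.
#' @param seed integer seed.
#' @return list with `counts` (peaks x replicates integer matrix),
#'   `peaks` (interval table), `design` (replicate, line, group),
#'   `expression` (genes x lines FPKM-like matrix).
#' @export
simulate_atac <- function(genome, n_ne_lines = 3L, n_nonne_lines = 5L,
                          reps = 2L, dispersion = 0.05,
                          expr_noise_sd = 0.25, seed = 1L) {
  stopifnot(inherits(genome, "synthetic_genome"))
  if (reps < 1) stop("reps must be >= 1")
  if (dispersion <= 0) stop("dispersion must be > 0")
  set.seed(seed)
  peaks <- genome$truth$peaks
  np <- nrow(peaks)
  lines <- c(paste0("NE_L", seq_len(n_ne_lines)),
             paste0("T_L", seq_len(n_nonne_lines)))
  grp <- rep(c("NE", "nonNE"), c(n_ne_lines, n_nonne_lines))
  design <- data.frame(
    replicate = paste0(rep(lines, each = reps), "_r", seq_len(reps)),
    line = rep(lines, each = reps),
    group = factor(rep(grp, each = reps), levels = c("nonNE", "NE")),
    stringsAsFactors = FALSE)
  nrep <- nrow(design)

  base <- exp(stats::rnorm(np, log(200), 0.8))
  libsize <- exp(stats::rnorm(nrep, 0, 0.2))
  mu <- outer(base, libsize)
  ne_rep <- design$group == "NE"
  mu[, ne_rep] <- mu[, ne_rep] * 2^peaks$log2fc
  counts <- matrix(stats::rnbinom(np * nrep, mu = mu, size = 1 / dispersion),
                   nrow = np, ncol = nrep,
                   dimnames = list(peaks$peak_id, design$replicate))

  # per-line mean accessibility on log2(count+1), for coupling
  line_mean <- sapply(lines, function(l)
    rowMeans(log2(counts[, design$line == l, drop = FALSE] + 1)))
  gene_ids <- genome$genes$gene_id
  expr_log <- matrix(stats::rnorm(length(gene_ids) * length(lines),
                                  mean = 3, sd = 1),
                     nrow = length(gene_ids), ncol = length(lines),
                     dimnames = list(gene_ids, lines))
  plinks <- genome$truth$peak_links
  if (!is.null(plinks) && nrow(plinks)) {
    for (i in seq_len(nrow(plinks))) {
      z <- line_mean[plinks$peak_id[i], ]
      expr_log[plinks$gene_id[i], ] <- scale(z)[, 1] * 2 + 4 +
        stats::rnorm(length(lines), sd = expr_noise_sd)
    }
  }
  list(counts = counts,
       peaks = peaks[, c("peak_id", "chrom", "start", "end")],
       design = design,
       expression = pmax(2^expr_log - 0.5, 0))
}
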