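#' Pipeline configuration
#'
#' All thresholds, window sizes and seeds of the end-to-end synthetic
#' run in one validated list.  The config is echoed verbatim into the
#' output manifest.
#'
#' @param seed master seed for the synthetic inputs.
#' @param alpha Bonferroni-adjusted p threshold for probe selection.
#' @param delta minimum |median difference| for probe selection.
#' @param percentile empirical |r| cutoff percentile.
#' @param fdr FDR threshold for differential peaks.
#' @param r_cutoff peak-gene correlation cutoff.
#' @param link_window DMR-to-TSS linking window, bp.
#' @param peak_windows distal peak-gene windows, bp.
#' @param consensus_size DMR consensus window width, bp.
#' @param synthetic a [synthetic_config()] for the generator.
#' @return list of class `nedmr_pipeline_config`.
#' @export
pipeline_config <- function(seed = 1L, alpha = 0.01, delta = 0.1,
                            percentile = 98, fdr = 0.05, r_cutoff = 0.7,
                            link_window = 500000L,
                            peak_windows = c(200000L, 500000L, 1000000L),
                            consensus_size = 500L,
                            synthetic = synthetic_config()) {
  stopifnot(alpha > 0, alpha <= 1, delta >= 0, delta < 1,
            percentile > 0, percentile < 100, fdr > 0, fdr <= 1,
            r_cutoff >= 0, r_cutoff <= 1, link_window > 0,
            all(peak_windows > 0), consensus_size > 0)
  cfg <- list(seed = as.integer(seed), alpha = alpha, delta = delta,
              percentile = percentile, fdr = fdr, r_cutoff = r_cutoff,
              link_window = as.integer(link_window),
              peak_windows = as.integer(peak_windows),
              consensus_size = as.integer(consensus_size),
              synthetic = synthetic)
  class(cfg) <- "nedmr_pipeline_config"
  cfg
}

#' Load a pipeline configuration from YAML
#'
#' Reads a YAML file whose top-level keys are [pipeline_config()]
#' arguments; a `synthetic` mapping holds [synthetic_config()]
#' arguments.  Unknown keys are rejected.
#'
#' @param path YAML file path.
#' @return a validated `nedmr_pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  syn_args <- raw$synthetic
  raw$synthetic <- NULL
  bad <- setdiff(names(raw), names(formals(pipeline_config)))
  if (length(bad)) stop("unknown config key(s): ", paste(bad, collapse = ", "))
  if (!is.null(syn_args)) {
    bad_s <- setdiff(names(syn_args), names(formals(synthetic_config)))
    if (length(bad_s))
      stop("unknown synthetic key(s): ", paste(bad_s, collapse = ", "))
    raw$synthetic <- do.call(synthetic_config, syn_args)
  }
  do.call(pipeline_config, raw)
}

#' Run the full synthetic pipeline
#'
#' Chains every stage in dependency order on generated data: simulate
#' (genome + methylation + expression + tissue panel + ATAC), DMR
#' discovery, DMR-expression linking, tissue modules, module scoring
#' with ROC, differential peaks, peak-gene links, and DMR/peak
#' integration.  When `out_dir` is given, stage artifacts (BED/TSV) and
#' a JSON provenance manifest with per-stage record counts are written.
#'
#' @param config a [pipeline_config()].
#' @param out_dir optional output directory (created if missing).
#' @return list with all stage results and `manifest`.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = NULL) {
  stopifnot(inherits(config, "nedmr_pipeline_config"))
  log_stage <- function(...) message("[nedmr] ", ...)

  log_stage("simulate")
  genome <- generate_annotation(config$synthetic, seed = config$seed)
  meth <- simulate_methylation(genome, seed = config$seed + 1L)
  expr <- simulate_expression(genome, meth, seed = config$seed + 2L)
  tissue <- simulate_tissue_panel(genome, seed = config$seed + 3L)
  atac <- simulate_atac(genome, seed = config$seed + 4L)

  log_stage("dmr")
  filt <- filter_probes(meth$beta, meth$groups)
  probes_kept <- meth$probes[match(rownames(filt$beta), meth$probes$probe_id), ]
  tests <- probe_tests(filt$beta, meth$groups)
  tests <- select_significant_probes(tests, m = nrow(filt$beta),
                                     alpha = config$alpha, delta = config$delta)
  sel <- probes_kept[tests$pass, , drop = FALSE]
  dmr <- build_dmrs(sel, beta = filt$beta[tests$pass, , drop = FALSE])
  annot <- annotate_dmrs(dmr$dmrs, genome, tss_window = config$link_window)

  log_stage("link")
  lk <- link_dmr_genes(dmr$dmrs, genome$genes, window = config$link_window,
                       expressed_genes = rownames(expr))
  links <- correlate_links(lk$pairs, dmr$summary_beta, expr)
  cut <- if (sum(links$ok) >= 50) empirical_cutoff(links, config$percentile)
         else list(percentile = config$percentile,
                   threshold = NA_real_, significant = rep(FALSE, nrow(links)))
  link_counts <- if (!is.na(cut$threshold))
    classify_links(links, cut$threshold) else NULL

  log_stage("modules")
  prep <- preprocess_tissue(tissue)
  emb <- mds_embed(prep$mat, dims = 3L)
  km <- kmeans_modules(emb$coords, k = config$synthetic$n_modules,
                       seed = config$seed)
  hc <- hclust_check(prep$mat, km$assignment)

  log_stage("score")
  sc <- module_scores(expr, km$assignment)
  is_ne <- meth$groups[rownames(sc$scores)] == "NE"
  rocs <- lapply(colnames(sc$scores), function(m)
    roc_auc(sc$scores[, m], is_ne))
  names(rocs) <- colnames(sc$scores)

  log_stage("atac-diff")
  sf <- size_factors(atac$counts)
  norm <- sweep(atac$counts, 2, sf, "/")
  diff <- nb_wald_test(norm, atac$design$group, fdr = config$fdr)

  log_stage("peak-link")
  cls <- classify_peaks(atac$peaks, genome$genes)
  sig_peaks <- atac$peaks[diff$significant, , drop = FALSE]
  peak_links <- lapply(config$peak_windows, function(w)
    link_and_correlate(sig_peaks, cls, norm, atac$design, atac$expression,
                       genome$genes, window = w, r_cutoff = config$r_cutoff))
  names(peak_links) <- paste0("w", config$peak_windows)
  tss_sig <- tss_gene_signature(peak_links[[length(peak_links)]])

  log_stage("integrate")
  cw <- consensus_windows(dmr$dmrs, size = config$consensus_size,
                          chrom_lengths = genome$chromosomes)
  ov <- overlap_fraction(cw, sig_peaks)
  sig_dmrs <- unique(links$dmr_id[cut$significant])
  ov_sig <- overlap_fraction(cw[cw$dmr_id %in% sig_dmrs, , drop = FALSE],
                             sig_peaks)
  prof <- module_profile(km$assignment,
                         peak_links[[length(peak_links)]],
                         links[cut$significant, , drop = FALSE])

  manifest <- list(
    package_version = as.character(utils::packageVersion("nedmr")),
    config = .config_echo(config),
    counts = list(probes_simulated = nrow(meth$beta),
                  probes_after_filter = filt$report$n_kept,
                  probes_selected = sum(tests$pass),
                  dmrs = dmr$report$n_dmrs,
                  candidate_pairs = lk$report$n_pairs,
                  linkable_dmrs = lk$report$n_linkable,
                  significant_links = sum(cut$significant),
                  module_genes = nrow(km$assignment),
                  differential_peaks = sum(diff$significant),
                  dmr_peak_overlap_pct = ov$pct_a))

  res <- list(genome = genome, methylation = meth, expression = expr,
              tissue = tissue, atac = atac, filter = filt, tests = tests,
              dmr = dmr, dmr_annotation = annot, candidate_links = lk,
              links = links, cutoff = cut, link_counts = link_counts,
              modules = km, hclust = hc, scores = sc, roc = rocs,
              size_factors = sf, diff_peaks = diff, peak_classes = cls,
              peak_links = peak_links, tss_signature = tss_sig,
              consensus = cw, overlap = ov, overlap_significant = ov_sig,
              profile = prof, manifest = manifest)
  if (!is.null(out_dir)) .write_pipeline(res, out_dir)
  res
}

.config_echo <- function(config) {
  cfg <- unclass(config)
  cfg$synthetic <- unclass(cfg$synthetic)
  cfg
}

.write_pipeline <- function(res, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(out_dir, f)
  dmrs <- res$dmr$dmrs
  write_bed(data.frame(chrom = dmrs$chrom, start = dmrs$start, end = dmrs$end,
                       name = dmrs$dmr_id, score = dmrs$n_members), p("dmrs.bed"))
  write_matrix_tsv(res$dmr$summary_beta, p("dmr_summary_beta.tsv"), "dmr_id")
  utils::write.table(res$links, p("links.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(res$modules$assignment, p("modules.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  write_matrix_tsv(res$scores$scores, p("module_scores.tsv"), "sample")
  utils::write.table(res$diff_peaks, p("diff_peaks.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  cw <- res$consensus
  write_bed(data.frame(chrom = cw$chrom, start = cw$start, end = cw$end,
                       name = cw$dmr_id), p("dmr_consensus.bed"))
  jsonlite::write_json(res$manifest, p("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(out_dir)
}
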