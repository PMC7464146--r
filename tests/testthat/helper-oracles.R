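# Independent brute-force oracles used across the suite.

# exact two-sided Mann-Whitney p by enumeration over index subsets,
# with U computed from pairwise wins (independent of rank arithmetic)
oracle_mw_exact <- function(x, y) {
  vals <- c(x, y)
  nx <- length(x)
  u_of <- function(sel) {
    xs <- vals[sel]; ys <- vals[-sel]
    sum(outer(xs, ys, ">")) + 0.5 * sum(outer(xs, ys, "=="))
  }
  u_all <- apply(utils::combn(length(vals), nx), 2, u_of)
  U <- u_of(seq_len(nx))
  list(U = U,
       p = min(1, 2 * min(mean(u_all <= U), mean(u_all >= U))))
}

# two-pass Pearson correlation
oracle_pearson <- function(x, y) {
  dx <- x - mean(x); dy <- y - mean(y)
  sum(dx * dy) / sqrt(sum(dx^2) * sum(dy^2))
}

# O(n^2) any-overlap scan on 0-based half-open intervals
oracle_overlap_any <- function(a, b) {
  vapply(seq_len(nrow(a)), function(i)
    any(b$chrom == a$chrom[i] & b$start < a$end[i] & a$start[i] < b$end),
    logical(1))
}

# NB log-likelihood (gamma form, valid for non-integer y) and the
# two-group likelihood-ratio test at fixed dispersion
oracle_nb_ll <- function(y, mu, disp) {
  s <- 1 / disp
  sum(lgamma(y + s) - lgamma(s) - lgamma(y + 1) +
        s * log(s / (s + mu)) + y * log(mu / (s + mu)))
}
oracle_nb_lrt_p <- function(y, is_b, disp) {
  muA <- max(mean(y[!is_b]), 1e-8)
  muB <- max(mean(y[is_b]), 1e-8)
  mu0 <- max(mean(y), 1e-8)
  lr <- 2 * (oracle_nb_ll(y[!is_b], muA, disp) +
               oracle_nb_ll(y[is_b], muB, disp) -
               oracle_nb_ll(y, mu0, disp))
  stats::pchisq(max(lr, 0), df = 1, lower.tail = FALSE)
}

# small synthetic genome shared by fast tests
tiny_config <- function(...) {
  args <- utils::modifyList(
    list(n_genes = 120L, n_dmrs = 10L, probes_per_dmr = 3L,
         n_background_probes = 470L, n_cpg_islands = 20L,
         n_links = 8L, genes_per_module = 10L,
         n_peaks = 300L, n_diff_peaks = 30L, n_peak_links = 10L),
    list(...))
  do.call(synthetic_config, args)
}
tiny_genome <- function(seed = 1L, ...) generate_annotation(tiny_config(...), seed)
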