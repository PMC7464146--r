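toy_linker_inputs <- function() {
  dmrs <- data.frame(dmr_id = c("d1", "d2"), chrom = c("chr1", "chr2"),
                     start = c(999950L, 100L), end = c(1000051L, 201L))
  genes <- data.frame(gene_id = c("gA", "gB", "gC"),
                      chrom = c("chr1", "chr1", "chr1"),
                      tss = c(1000000L, 1400000L, 1500001L))
  list(dmrs = dmrs, genes = genes)
}

test_that("candidate linking honors the inclusive window and reports gaps", {
  ti <- toy_linker_inputs()
  # d1 midpoint 1000000: gA at distance 0 (linked), gB at 400 kb (linked),
  # gC at 500,001 (not); d2 sits on chr2 with no gene -> unlinked
  lk <- link_dmr_genes(ti$dmrs, ti$genes, window = 500000L)
  expect_setequal(lk$pairs$gene_id[lk$pairs$dmr_id == "d1"], c("gA", "gB"))
  expect_equal(lk$unlinked, "d2")
  expect_equal(lk$report$n_linkable, 1)
  expect_equal(lk$report$n_pairs, 2)
  # TSS exactly at the midpoint is linked at distance zero
  expect_equal(min(lk$pairs$distance), 0)
  expect_error(link_dmr_genes(ti$dmrs, ti$genes, window = 0), "positive")

  # expressed-gene restriction drops candidates
  lk2 <- link_dmr_genes(ti$dmrs, ti$genes, expressed_genes = "gB")
  expect_equal(lk2$pairs$gene_id, "gB")
})

test_that("link correlations match exact and hand-computed values", {
  dmr_beta <- matrix(c(0.1, 0.2, 0.3, 0.4), nrow = 1,
                     dimnames = list("d1", paste0("s", 1:4)))
  expr <- rbind(gA = 2 * dmr_beta[1, ] + 1,
                gB = -dmr_beta[1, ],
                gC = c(1.0, 0.9, 1.2, 1.5),
                gD = rep(2, 4))
  colnames(expr) <- paste0("s", 1:4)
  pairs <- data.frame(dmr_id = "d1", gene_id = c("gA", "gB", "gC", "gD"))
  links <- suppressMessages(correlate_links(pairs, dmr_beta, expr))
  expect_equal(links$r[1], 1)
  expect_equal(links$r[2], -1)
  expect_equal(links$r[3], oracle_pearson(dmr_beta[1, ], expr["gC", ]))
  expect_equal(links$r[3], 0.8783101, tolerance = 1e-6)
  expect_equal(links$sign[1:3], c("+", "-", "+"))
  # zero-variance expression is flagged, not correlated
  expect_false(links$ok[4])
  expect_true(is.na(links$r[4]))

  expect_error(correlate_links(pairs, dmr_beta,
                               matrix(1, 1, 1, dimnames = list("gA", "x1"))),
               "shared")
})

test_that("correlation engine agrees with the two-pass oracle to 1e-12", {
  set.seed(5)
  dmr_beta <- matrix(runif(3 * 30), nrow = 3,
                     dimnames = list(paste0("d", 1:3), paste0("s", 1:30)))
  expr <- matrix(rnorm(4 * 30), nrow = 4,
                 dimnames = list(paste0("g", 1:4), paste0("s", 1:30)))
  pairs <- expand.grid(dmr_id = rownames(dmr_beta), gene_id = rownames(expr),
                       stringsAsFactors = FALSE)
  links <- correlate_links(pairs, dmr_beta, expr)
  for (i in seq_len(nrow(links)))
    expect_equal(links$r[i],
                 oracle_pearson(dmr_beta[links$dmr_id[i], ],
                                expr[links$gene_id[i], ]),
                 tolerance = 1e-12)
})

test_that("pairwise-complete correlation drops sparse pairs at min_n", {
  dmr_beta <- matrix(c(0.1, 0.2, 0.3, NA, NA), nrow = 1,
                     dimnames = list("d1", paste0("s", 1:5)))
  expr <- matrix(c(1, 2, NA, 4, 5), nrow = 1,
                 dimnames = list("gA", paste0("s", 1:5)))
  links <- suppressMessages(correlate_links(
    data.frame(dmr_id = "d1", gene_id = "gA"), dmr_beta, expr))
  expect_equal(links$n, 2)     # only s1, s2 complete
  expect_false(links$ok)
})

test_that("empirical cutoff is the type-7 98th percentile of |r|", {
  links <- data.frame(dmr_id = "d", gene_id = paste0("g", 1:100),
                      r = seq(0.01, 1, by = 0.01), n = 60,
                      ok = TRUE, sign = "+")
  cut <- empirical_cutoff(links, percentile = 98)
  # sort/interpolate oracle: h = 99*0.98 + 1 = 98.02
  expect_equal(cut$threshold, 0.98 + 0.02 * 0.01)
  expect_equal(sum(cut$significant), 2)

  # all |r| equal: threshold c, nothing strictly exceeds it
  links$r <- 0.5
  cut2 <- empirical_cutoff(links)
  expect_equal(cut2$threshold, 0.5)
  expect_equal(sum(cut2$significant), 0)

  expect_error(empirical_cutoff(links[1:10, ]), "at least")
})

test_that("raising the percentile never increases the significant count", {
  set.seed(8)
  links <- data.frame(dmr_id = "d", gene_id = paste0("g", 1:500),
                      r = runif(500, -1, 1), n = 60, ok = TRUE, sign = "+")
  counts <- vapply(c(90, 95, 98, 99),
                   function(p) sum(empirical_cutoff(links, p)$significant), 0)
  expect_true(all(diff(counts) <= 0))
})

test_that("Bonferroni r threshold solves the t-transform inversion", {
  # published setting: 151 samples, 135,250 tests
  r <- bonferroni_r_threshold(151, 135250, alpha = 0.05)
  expect_equal(round(r, 1), 0.4)
  # the threshold is the boundary of significance
  p_of <- function(r, n) 2 * pt(-abs(r * sqrt(n - 2) / sqrt(1 - r^2)), n - 2)
  expect_lte(p_of(r + 1e-9, 151), 0.05 / 135250)
  expect_gt(p_of(r - 1e-6, 151), 0.05 / 135250)

  # everything significant when a single test at alpha = 1
  expect_equal(bonferroni_r_threshold(10, 1, alpha = 1), 0)

  # brute-force grid oracle at n = 10, 100 tests
  grid <- seq(0, 0.9999, by = 1e-4)
  ora <- grid[which(p_of(grid, 10) <= 0.05 / 100)[1]]
  expect_equal(bonferroni_r_threshold(10, 100), ora, tolerance = 1e-4)

  expect_error(bonferroni_r_threshold(151, 100, alpha = 0), "alpha")
  expect_error(bonferroni_r_threshold(3, 100), "n_samples")
})

test_that("link classification counts signs and unique ids", {
  links <- data.frame(dmr_id = c("d1", "d1", "d2"),
                      gene_id = c("gA", "gB", "gA"),
                      r = c(0.9, -0.8, 0.85), n = 60, ok = TRUE,
                      sign = c("+", "-", "+"))
  cl <- classify_links(links, threshold = 0.7)
  expect_equal(cl$n_positive, 2)
  expect_equal(cl$n_negative, 1)
  expect_equal(cl$n_total, 3)
  expect_equal(cl$n_unique_dmrs, 2)
  expect_equal(cl$n_unique_genes, 2)

  empty <- classify_links(links, threshold = 1)
  expect_equal(empty$n_total, 0)
  expect_equal(empty$n_unique_dmrs, 0)
})

test_that("planted link signs are recovered at low noise", {
  for (s in 1:3) {
    g <- tiny_genome(seed = s)
    m <- simulate_methylation(g, missing_rate = 0, seed = s + 10)
    e <- simulate_expression(g, m, noise_sd = 0.05, seed = s + 20)
    lk <- g$truth$links
    signs <- vapply(seq_len(nrow(lk)), function(i) {
      members <- g$probes$probe_id[!is.na(g$probes$in_dmr) &
                                     g$probes$in_dmr == lk$dmr_id[i]]
      summ <- apply(m$beta[members, , drop = FALSE], 2, median)
      sign(cor(summ, e[lk$gene_id[i], ]))
    }, 0)
    expect_equal(signs, lk$sign)
  }
})
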