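make_groups <- function(n_ne = 20, n_nonne = 20, n_normal = 20) {
  factor(rep(c("NE", "nonNE", "normal"), c(n_ne, n_nonne, n_normal)),
         levels = c("NE", "nonNE", "normal"))
}

test_that("probe filter removes missing-heavy and constant probes", {
  set.seed(1)
  groups <- make_groups()
  beta <- matrix(runif(10 * 60), nrow = 10,
                 dimnames = list(paste0("p", 1:10), paste0("s", 1:60)))
  beta[1, 1:2] <- NA              # 10% missing in NE (> 5%)
  beta[2, groups == "NE"] <- 0.5  # constant within NE
  res <- filter_probes(beta, groups)
  expect_equal(nrow(res$beta), 8)
  expect_false(any(c("p1", "p2") %in% rownames(res$beta)))
  expect_equal(res$report$n_removed_missing, 1)
  expect_equal(res$report$n_removed_zero_sd, 1)
  expect_equal(res$report$n_kept, 8)

  # constant within the normal group only is also removed
  beta2 <- matrix(runif(5 * 60), nrow = 5,
                  dimnames = list(paste0("q", 1:5), paste0("s", 1:60)))
  beta2[3, groups == "normal"] <- 0.2
  expect_false("q3" %in% rownames(filter_probes(beta2, groups)$beta))

  expect_error(filter_probes(beta[0, , drop = FALSE], groups), "non-empty")
  expect_error(filter_probes(beta, rep("NE", 60)), "absent")
})

test_that("Mann-Whitney matches its exact enumeration oracle for n <= 12", {
  # spec toy: complete separation of 3 vs 3
  t1 <- mann_whitney(c(0.1, 0.2, 0.3), c(0.7, 0.8, 0.9))
  expect_equal(t1$U, 0)
  expect_equal(t1$p, 0.1)
  expect_equal(t1$method, "exact")

  # identical value sets give p = 1
  expect_equal(mann_whitney(c(1, 2, 3), c(1, 2, 3))$p, 1)

  # random cases, with and without ties, against the subset-enumeration
  # oracle
  set.seed(42)
  for (i in 1:20) {
    nx <- sample(3:6, 1); ny <- sample(3:6, 1)
    vals <- if (i %% 2) round(runif(nx + ny), 1) else runif(nx + ny)
    x <- vals[seq_len(nx)]; y <- vals[-seq_len(nx)]
    got <- mann_whitney(x, y)
    ora <- oracle_mw_exact(x, y)
    expect_equal(got$U, ora$U)
    expect_equal(got$p, ora$p)
  }
  expect_error(mann_whitney(c(NA_real_, NA_real_), c(1, 2)), "non-missing")
})

test_that("tie-free exact path agrees with wilcox.test", {
  set.seed(7)
  for (i in 1:10) {
    x <- rnorm(5); y <- rnorm(6)
    got <- mann_whitney(x, y)
    ref <- wilcox.test(x, y, exact = TRUE, correct = FALSE)
    expect_equal(got$U, unname(ref$statistic))
    expect_equal(got$p, ref$p.value)
  }
})

test_that("normal approximation stays within 0.02 of the exact p at 6 vs 6", {
  set.seed(11)
  for (i in 1:25) {
    x <- rnorm(6); y <- rnorm(6, mean = runif(1, 0, 1.5))
    p_asym <- mann_whitney(x, y, exact_max = 0L)$p
    p_exact <- oracle_mw_exact(x, y)$p
    expect_lt(abs(p_asym - p_exact), 0.02)
  }
})

test_that("probe selection needs both comparisons significant and shifted", {
  base <- data.frame(probe_id = "p", U_ne_normal = 1, U_ne_nonne = 1)
  mk <- function(p1, p2, d1, d2)
    cbind(base, p_ne_normal = p1, p_ne_nonne = p2,
          dmed_ne_normal = d1, dmed_ne_nonne = d2)
  # adjusted p significant in both but delta fails the second comparison
  r <- select_significant_probes(mk(0.005, 0.005, 0.2, 0.05), m = 1)
  expect_false(r$pass)
  # second adjusted p not significant
  r <- select_significant_probes(mk(0.005, 0.5, 0.2, 0.2), m = 1)
  expect_false(r$pass)
  r <- select_significant_probes(mk(0.001, 0.001, 0.2, 0.2), m = 1)
  expect_true(r$pass)
  # Bonferroni multiplier is applied and capped
  r <- select_significant_probes(mk(0.001, 0.001, 0.2, 0.2), m = 100)
  expect_equal(r$padj_ne_normal, 0.1)
  expect_false(r$pass)
  expect_error(select_significant_probes(mk(0.1, 0.1, 0, 0), m = 0), "m must")
})

test_that("window merging follows the 101 bp interval arithmetic", {
  probes <- data.frame(probe_id = c("a", "b"), chrom = "chr1",
                       pos = c(100L, 150L))
  d <- build_dmrs(probes)
  expect_equal(nrow(d$dmrs), 1)
  expect_equal(d$dmrs$start, 50)
  expect_equal(d$dmrs$end, 201)
  expect_equal(d$dmrs$n_members, 2)

  far <- build_dmrs(data.frame(probe_id = c("a", "b"), chrom = "chr1",
                               pos = c(100L, 300L)))
  expect_equal(nrow(far$dmrs), 2)

  # book-ended windows (share no base) stay separate: probes 101 bp
  # apart give windows [50,151) and [151,252)
  touch <- build_dmrs(data.frame(probe_id = c("a", "b"), chrom = "chr1",
                                 pos = c(100L, 201L)))
  expect_equal(nrow(touch$dmrs), 2)
  # one bp closer and the windows share base 150, so they merge
  merge1 <- build_dmrs(data.frame(probe_id = c("a", "b"), chrom = "chr1",
                                  pos = c(100L, 200L)))
  expect_equal(nrow(merge1$dmrs), 1)
  expect_equal(merge1$dmrs$end - merge1$dmrs$start, 201)

  # single probe: identity DMR and summary equal to the probe betas
  beta <- matrix(c(0.1, 0.9, NA), nrow = 1,
                 dimnames = list("a", c("s1", "s2", "s3")))
  single <- build_dmrs(data.frame(probe_id = "a", chrom = "chr1", pos = 500L),
                       beta = beta)
  expect_equal(single$dmrs$start, 450)
  expect_equal(single$dmrs$end, 551)
  expect_equal(unname(single$summary_beta[1, 1:2]), c(0.1, 0.9))
})

test_that("merge report, membership and summaries satisfy the invariants", {
  set.seed(3)
  n <- 200
  probes <- data.frame(probe_id = sprintf("p%03d", 1:n),
                       chrom = sample(c("chr1", "chr2"), n, TRUE),
                       pos = sample(1000:40000, n))
  beta <- matrix(runif(n * 10), nrow = n,
                 dimnames = list(probes$probe_id, paste0("s", 1:10)))
  beta[sample(length(beta), 50)] <- NA
  d <- build_dmrs(probes, beta = beta)

  # every probe in exactly one DMR; member counts add up
  expect_setequal(d$members$probe_id, probes$probe_id)
  expect_equal(sum(d$dmrs$n_members), n)
  expect_lte(nrow(d$dmrs), n)
  # count identity agrees with the realized DMR number
  expect_equal(d$report$n_dmrs, nrow(d$dmrs))
  expect_equal(dmr_merge_accounting(d$report$n_probes,
                                    d$report$n_merged_probes,
                                    d$report$n_merged_regions),
               nrow(d$dmrs))
  # every member window overlaps its DMR interval
  win <- data.frame(chrom = probes$chrom, start = probes$pos - 50,
                    end = probes$pos + 51)
  dm <- d$dmrs[match(d$members$dmr_id, d$dmrs$dmr_id), ]
  expect_true(all(win$start < dm$end & dm$start < win$end &
                    win$chrom == dm$chrom))
  expect_true(all(d$dmrs$end - d$dmrs$start >= 101))

  # rebuilding from the same probes is identical (merging idempotence)
  expect_identical(d$dmrs, build_dmrs(probes, beta = beta)$dmrs)

  # summary beta equals the brute-force median over members
  for (id in sample(d$dmrs$dmr_id, 5)) {
    mem <- d$members$probe_id[d$members$dmr_id == id]
    for (s in c(1, 5, 10)) {
      expect_equal(d$summary_beta[id, s],
                   median(beta[mem, s], na.rm = TRUE))
    }
  }
})

test_that("DMR annotation links TSSs at the inclusive 500 kb boundary", {
  genome <- list(
    genes = data.frame(gene_id = c("g1", "g2", "g3"), symbol = c("g1", "g2", "g3"),
                       chrom = "chr1", strand = "+",
                       tss = c(600000L, 999000L, 1100000L),
                       start = c(600000L, 999000L, 1100000L),
                       end = c(605000L, 1004000L, 1105000L),
                       stringsAsFactors = FALSE),
    cpg_islands = data.frame(chrom = "chr1", start = 499000L, end = 501000L))
  dmrs <- data.frame(dmr_id = "d1", chrom = "chr1",
                     start = 499950L, end = 500051L)   # midpoint 500000
  ann <- annotate_dmrs(dmrs, genome)
  # distances: 100 kb, 499 kb, 600 kb -> 2 links
  expect_equal(nrow(ann$tss_links), 2)
  expect_setequal(ann$tss_links$gene_id, c("g1", "g2"))
  expect_equal(ann$annotation$island_class, "island")

  # exact boundary: |TSS - midpoint| = 500,000 linked, 500,001 not
  genome$genes$tss <- c(1000000L, 1000001L, 2000000L)
  ann2 <- annotate_dmrs(dmrs, genome)
  expect_equal(ann2$tss_links$gene_id, "g1")

  # shore classification within the 2 kb island flank
  dmr_shore <- data.frame(dmr_id = "d2", chrom = "chr1",
                          start = 502500L, end = 502601L)
  expect_equal(annotate_dmrs(dmr_shore, genome)$annotation$island_class,
               "shore")
  dmr_sea <- data.frame(dmr_id = "d3", chrom = "chr1",
                        start = 900000L, end = 900101L)
  expect_equal(annotate_dmrs(dmr_sea, genome)$annotation$island_class,
               "open_sea")

  expect_warning(
    annotate_dmrs(data.frame(dmr_id = "dX", chrom = "chrZ",
                             start = 0L, end = 101L), genome),
    "unknown")
})
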