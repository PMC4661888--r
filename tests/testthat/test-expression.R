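test_that("FPKM follows the defining formula and its invariances", {
  # one real gene plus a filler gene so the library size is exactly 1e6
  counts <- matrix(c(1000, 999000), 2, 1,
                   dimnames = list(c("g1", "filler"), "s1"))
  lens <- c(g1 = 2000, filler = 1000)
  fpkm <- compute_fpkm(counts, lens)
  expect_equal(fpkm["g1", "s1"], 500)
  expect_equal(compute_fpkm(matrix(c(0, 10), 2, 1), c(100, 100))[1], 0)
  # doubling every count in a sample leaves FPKM unchanged
  m <- matrix(c(10, 20, 30, 40), 2, 2)
  f1 <- compute_fpkm(m, c(500, 1500))
  f2 <- compute_fpkm(cbind(m[, 1] * 2, m[, 2]), c(500, 1500))
  expect_equal(f1, unname(f2), ignore_attr = TRUE)
  expect_error(compute_fpkm(matrix(0, 2, 1), c(10, 10)), "library size")
})

test_that("size factors are median-of-ratios against the geometric mean", {
  m <- cbind(a = c(10, 20, 30), b = c(20, 40, 60))
  expect_equal(size_factors(m), c(a = 1 / sqrt(2), b = sqrt(2)),
               tolerance = 1e-12)
  same <- cbind(a = c(5, 7), b = c(5, 7), c = c(5, 7))
  expect_equal(unname(size_factors(same)), rep(1, 3))
  expect_equal(unname(size_factors(matrix(c(3, 9), 2, 1))), 1)
  expect_error(size_factors(rbind(c(0, 1), c(1, 0))), "nonzero")
})

test_that("the DE test is sane on null and planted genes", {
  set.seed(61)
  sim <- simulate_counts(500, NULL, 3, 0.1)
  # plant a clean 8-fold change at high mean on top of a null background
  counts <- sim$em$counts
  counts[1, ] <- c(rpois(3, 1000), rpois(3, 8000))
  counts[2, ] <- 50   # identical in all samples
  em <- expression_matrix(counts, sim$em$gene_lengths, sim$em$groups)
  de <- nb_de_test(em)
  expect_equal(de$direction[1], "up")
  expect_gt(de$fc[1], 6); expect_lt(de$fc[1], 10)
  expect_lt(de$padj[1], 0.01)
  expect_gt(de$p[2], 0.5)
  expect_lt(abs(de$fc[2] - 1), 0.2)
  expect_error(nb_de_test(expression_matrix(
    counts[, c(1, 4)], sim$em$gene_lengths,
    sim$em$groups[c(1, 4)])), ">= 2 samples")
})

test_that("null p-values are approximately uniform", {
  set.seed(67)
  sim <- simulate_counts(2000, NULL, 3, 0.1)
  de <- nb_de_test(sim$em)
  keep <- de$mean_ref + de$mean_alt > 0
  frac <- mean(de$p[keep] < 0.05)
  expect_gt(frac, 0.03); expect_lt(frac, 0.07)
})

test_that("DE classification applies both criteria strictly", {
  tab <- data.frame(
    gene_id = c("a", "b", "c", "d"),
    fc = c(2.5, 2.5, 2.0, 3.0),
    direction = c("up", "up", "up", "down"),
    padj = c(0.01, 0.2, 0.001, 0.04),
    stringsAsFactors = FALSE)
  cls <- classify_de(tab)
  expect_equal(cls$table$status, c("up", "unchanged", "unchanged", "down"))
  s <- cls$summary
  expect_equal(s$n_total, 2)
  expect_equal(s$pct_up, 50)
  expect_error(classify_de(tab[, 1:3]), "padj")
  # summary percentages are exact arithmetic
  expect_equal(de_summary(558, 57)$n_total, 615)
  expect_equal(de_summary(558, 57)$pct_up, 100 * 558 / 615)
})

test_that("clustering reproduces the hand-worked correlation example", {
  # s1 and s2 perfectly correlated (d = 0); s3 anti-correlated (d = 2)
  m <- cbind(s1 = c(1, 2, 3), s2 = c(1, 2, 3), s3 = c(3, 2, 1))
  hc <- hcluster(m, log_transform = FALSE)
  expect_equal(sort(hc$height), c(0, 2), tolerance = 1e-12)
  mt <- cluster_merge_table(hc)
  expect_equal(nrow(mt), 2)
  first <- sort(-unlist(mt[1, c("member_a", "member_b")]))
  expect_equal(unname(first), c(1, 2))
  expect_error(hcluster(m[, 1, drop = FALSE]), ">= 2 samples")
  nwk <- cluster_newick(hc)
  expect_match(nwk, "^\\(.*\\);$")
  expect_true(all(c("s1", "s2", "s3") %in%
                    ape::read.tree(text = nwk)$tip.label))
})

test_that("average linkage agrees with brute-force UPGMA", {
  set.seed(71)
  for (rep in 1:12) {
    n <- sample(3:8, 1)
    d <- matrix(0, n, n)
    d[upper.tri(d)] <- stats::runif(n * (n - 1) / 2, 0.1, 2)
    d <- d + t(d)
    hc <- stats::hclust(stats::as.dist(d), method = "average")
    coph_got <- as.matrix(stats::cophenetic(hc))
    coph_want <- oracle_upgma_cophenetic(d)
    expect_equal(unname(coph_got), coph_want, tolerance = 1e-9)
  }
})

test_that("simulated two-group data clusters into the two groups", {
  set.seed(73)
  lfc <- stats::setNames(runif(200, 1, 5) * sample(c(-1, 1), 200, TRUE),
                         sprintf("gene%05d", 1:200))
  sim <- simulate_counts(2000, lfc, 3, 0.1)
  fpkm <- compute_fpkm(sim$em)
  hc <- hcluster(fpkm)
  grp <- stats::cutree(hc, 2)
  expect_equal(length(unique(grp[sim$em$groups == "NP"])), 1)
  expect_equal(length(unique(grp[sim$em$groups == "LP"])), 1)
  expect_false(grp[1] == grp[6])
})

test_that("2^-ddCt fold changes follow the textbook arithmetic", {
  ct <- rbind(target = c(25, 25, 24, 24),
              Rpl7 = c(20, 20, 20, 20))
  colnames(ct) <- c("n1", "n2", "l1", "l2")
  groups <- c(n1 = "NP", n2 = "NP", l1 = "LP", l2 = "LP")
  # target drops one cycle in LP, reference unchanged -> fold change 2
  expect_equal(unname(ddct_foldchange(ct, groups, "Rpl7")), 2)
  # ddCt = 0 -> 1
  ct0 <- rbind(target = c(25, 25, 25, 25), Rpl7 = c(20, 20, 20, 20))
  colnames(ct0) <- names(groups)
  expect_equal(unname(ddct_foldchange(ct0, groups, "Rpl7")), 1)
  # ddCt = +2 -> 0.25
  ct2 <- rbind(target = c(24, 24, 26, 26), Rpl7 = c(20, 20, 20, 20))
  colnames(ct2) <- names(groups)
  expect_equal(unname(ddct_foldchange(ct2, groups, "Rpl7")), 0.25)
  expect_error(ddct_foldchange(ct, groups, "Actb"), "Actb")
})

test_that("platform correlation is Pearson on log2 fold changes", {
  fc <- c(a = 2, b = 4, c = 0.5, d = 8)
  expect_equal(correlate_platforms(fc, fc)$r, 1, tolerance = 1e-12)
  expect_equal(correlate_platforms(fc, 1 / fc)$r, -1, tolerance = 1e-12)
  expect_error(correlate_platforms(fc[1:2], fc[1:2]), ">= 3")
  set.seed(79)
  # null calibration: independent fold changes give uniform p
  ps <- replicate(400, {
    a <- stats::setNames(2^stats::rnorm(10), letters[1:10])
    b <- stats::setNames(2^stats::rnorm(10), letters[1:10])
    correlate_platforms(a, b)$p
  })
  expect_gt(suppressWarnings(stats::ks.test(ps, "punif"))$p.value, 0.01)
})

test_that("presence calls use the >= cutoff convention per group", {
  fpkm <- rbind(hi = c(1.2, 1.2, 0.4, 0.4),
                lo = c(0.5, 0.5, 0.5, 0.5),
                edge = c(1.0, 1.0, 1.0, 1.0))
  colnames(fpkm) <- c("n1", "n2", "l1", "l2")
  groups <- c(n1 = "NP", n2 = "NP", l1 = "LP", l2 = "LP")
  pc <- presence_call(fpkm, groups, c("hi", "lo", "edge", "ghost"))
  expect_equal(pc$present[pc$gene_id == "hi" & pc$group == "NP"], TRUE)
  expect_equal(pc$present[pc$gene_id == "hi" & pc$group == "LP"], FALSE)
  expect_true(all(!pc$present[pc$gene_id == "lo"]))
  expect_true(all(pc$present[pc$gene_id == "edge"]))   # boundary: >= 1
  expect_equal(attr(pc, "missing"), "ghost")
})

test_that("the pathway panel verdict flags any DE member", {
  tab <- data.frame(
    gene_id = c("Tshr", "Tg", "Tpo", "other"),
    fc = c(1.5, 1.2, 4, 10),
    direction = c("up", "down", "up", "up"),
    padj = c(0.5, 0.9, 1e-6, 1e-8),
    stringsAsFactors = FALSE)
  ok <- panel_flag(tab, c("Tshr", "Tg"))
  expect_equal(ok$verdict, "not altered")
  hit <- panel_flag(tab, c("Tshr", "Tg", "Tpo"))
  expect_equal(hit$verdict, "altered")
  expect_equal(hit$table$status[hit$table$gene_id == "Tpo"], "up")
  miss <- panel_flag(tab, c("Tshr", "Duox2"))
  expect_equal(miss$table$status[miss$table$gene_id == "Duox2"], "missing")
  expect_warning(empty <- panel_flag(tab, character(0)), "empty")
  expect_equal(empty$verdict, "not altered")
})

test_that("external DE tables are converted to the magnitude convention", {
  tmp <- tempfile(fileext = ".tsv")
  utils::write.table(
    data.frame(gene_id = c("a", "b", "c"), log2fc = c(2, -1, 0),
               padj = c(0.01, 0.2, 1)),
    tmp, sep = "\t", quote = FALSE, row.names = FALSE)
  d <- read_de_table(tmp)
  expect_equal(d$fc, c(4, 2, 1))
  expect_equal(d$direction, c("up", "down", "none"))
})
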