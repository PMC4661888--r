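test_that("reference generation is deterministic and lays out clean promoters", {
  r1 <- gen_reference(10, promoter_len = 50, gene_len = 20, seed = 5)
  r2 <- gen_reference(10, promoter_len = 50, gene_len = 20, seed = 5)
  expect_identical(r1$genome, r2$genome)
  expect_identical(r1$annotation, r2$annotation)
  ps <- extract_promoters(r1$genome, select_tss(r1$annotation), 50)
  expect_equal(nrow(ps), 10)
  expect_true(all(nchar(ps$sequence) == 50))
  expect_false(any(ps$clipped))
  # promoter intervals recorded by the generator match the extractor's
  expect_equal(ps$start, r1$promoters$start)
  expect_equal(ps$end, r1$promoters$end)
})

test_that("background GC content matches the requested rate", {
  r <- gen_reference(50, promoter_len = 100, gene_len = 50, gc = 0.5,
                     seed = 9)
  chars <- strsplit(r$genome[["chr1"]], "")[[1]]
  gc <- mean(chars %in% c("G", "C"))
  n <- length(chars)
  expect_lt(abs(gc - 0.5), 3 * sqrt(0.25 / n))
  r6 <- gen_reference(50, promoter_len = 100, gene_len = 50, gc = 0.6,
                      seed = 9)
  gc6 <- mean(strsplit(r6$genome[["chr1"]], "")[[1]] %in% c("G", "C"))
  expect_lt(abs(gc6 - 0.6), 3 * sqrt(0.24 / n))
  expect_error(gen_reference(0), ">= 1")
})

test_that("consensus planting at p_up = 1, p_bg = 0 is found in every up gene", {
  set.seed(15)
  ref <- gen_reference(30, promoter_len = 120, gene_len = 30)
  causal <- tfbsflow:::.sharp_pwm(8, "CAUS")
  up <- ref$annotation$gene_id[1:10]
  res <- plant_motifs(ref, list(CAUS = causal), "CAUS", up,
                      p_up = 1, p_bg = 0, consensus = TRUE)
  ps <- extract_promoters(res$reference$genome,
                          select_tss(res$reference$annotation), 120)
  found <- genes_with_site(causal, ps, 0.9)
  expect_true(all(up %in% found))
  expect_setequal(res$truth$planted_sites$gene_id, up)
})

test_that("planted site records point at the planted letters", {
  set.seed(17)
  ref <- gen_reference(20, promoter_len = 100, gene_len = 30)
  p <- tfbsflow:::.sharp_pwm(7, "M")
  res <- plant_motifs(ref, list(M = p), "M", ref$annotation$gene_id[1:8],
                      p_up = 1, p_bg = 0.2, consensus = TRUE)
  ps <- extract_promoters(res$reference$genome,
                          select_tss(res$reference$annotation), 100)
  cons <- pwm_consensus(p)
  sites <- res$truth$planted_sites
  # later insertions can overwrite earlier ones; with a single matrix each
  # promoter carries at most one site, so every record must be intact
  for (i in seq_len(nrow(sites))) {
    seq <- ps$sequence[ps$gene_id == sites$gene_id[i]]
    win <- substr(seq, sites$offset[i] + 1, sites$offset[i] + 7)
    expect_equal(win, if (sites$strand[i] == "+") cons
                 else oracle_revcomp(cons))
  }
})

test_that("sampled (non-consensus) sites usually clear the 0.9 threshold", {
  set.seed(19)
  p <- tfbsflow:::.sharp_pwm(10, "S")
  probs <- pwm_probs(p)
  rels <- replicate(400, {
    site <- paste(tfbsflow:::.sample_site(probs), collapse = "")
    relative_score(p, site)
  })
  expect_gt(mean(rels > 0.9), 0.9)
})

test_that("count simulation hits the requested fold changes and is seeded", {
  s1 <- simulate_counts(100, c(gene00001 = 3), seed = 21)
  s2 <- simulate_counts(100, c(gene00001 = 3), seed = 21)
  expect_identical(s1$em$counts, s2$em$counts)
  expect_equal(s1$truth$true_lfc[["gene00001"]], 3)
  # high-mean gene with lfc 3: observed ratio near 8
  set.seed(23)
  big <- simulate_counts(2000, stats::setNames(rep(3, 200),
                                               sprintf("gene%05d", 1:200)),
                         n_per_group = 3, dispersion = 0.05,
                         mean_log = log(500), mean_sdlog = 0.2)
  q <- sweep(big$em$counts, 2, size_factors(big$em$counts), "/")
  r <- rowMeans(q[1:200, 4:6]) / rowMeans(q[1:200, 1:3])
  expect_gt(median(r), 6.5); expect_lt(median(r), 9.5)
  expect_true(all(big$em$gene_lengths >= 500 &
                  big$em$gene_lengths <= 10000))
})

test_that("truth bundles are reproducible and internally consistent", {
  cfg <- list(n_genes = 60, n_up = 10, n_down = 4, n_decoy = 3,
              promoter_len = 80, gene_len = 30)
  b1 <- gen_truth_bundle(cfg, seed = 25)
  b2 <- gen_truth_bundle(cfg, seed = 25)
  expect_identical(b1$reference$genome, b2$reference$genome)
  expect_identical(b1$em$counts, b2$em$counts)
  expect_identical(b1$truth$planted_sites, b2$truth$planted_sites)
  # up-gene list implied by the counts matches the planted-motif up set
  lfc <- b1$truth$true_de
  expect_setequal(names(lfc)[lfc > 0], b1$truth$up_genes)
  expect_setequal(names(lfc)[lfc < 0], b1$truth$down_genes)
  expect_equal(sum(lfc > 0), 10)
  expect_equal(sum(lfc < 0), 4)
  expect_length(b1$pwms, 5)
  expect_length(b1$truth$causal_tf_ids, 2)
  # invalid configs fail before generating anything
  expect_error(gen_truth_bundle(list(n_genes = 5, n_up = 4, n_down = 3)),
               "exceeds")
  expect_error(gen_truth_bundle(list(bogus_key = 1)), "bogus_key")
  expect_error(gen_truth_bundle(list(p_up = 1.4)), "\\[0, 1\\]")
})

test_that("bundle files are written in formats the pipeline reads back", {
  b <- gen_truth_bundle(list(n_genes = 40, n_up = 8, n_down = 2,
                             n_decoy = 3, promoter_len = 60,
                             gene_len = 30), seed = 27)
  dir <- tempfile("bundle")
  paths <- write_truth_bundle(b, dir)
  expect_true(all(file.exists(paths)))
  genome <- Biostrings::readDNAStringSet(paths["genome"])
  expect_equal(as.character(genome[[1]]), b$reference$genome[["chr1"]])
  pwms <- parse_transfac(paths["transfac"])
  expect_length(pwms, 5)
  expect_equal(pwms[[1]]$counts, b$pwms[[1]]$counts)
  em <- read_expression_inputs(paths["counts"], paths["samples"],
                               paths["gene_lengths"])
  expect_equal(em$counts, b$em$counts)
  expect_equal(em$groups, b$em$groups)
  ann <- read_annotation(paths["annotation"])
  expect_equal(ann$start, b$reference$annotation$start)
  truth <- jsonlite::read_json(paths["truth"])
  expect_equal(unlist(truth$causal_tf_ids), b$truth$causal_tf_ids)
})
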