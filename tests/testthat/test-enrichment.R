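test_that("hypergeometric tail matches enumeration on the worked example", {
  expect_equal(hypergeom_sf(3, 10, 5, 4), 55 / 210, tolerance = 1e-12)
  expect_identical(hypergeom_sf(0, 10, 5, 4), 1)
  expect_identical(hypergeom_sf(5, 10, 5, 4), 0)   # k > n
  expect_identical(hypergeom_sf(3, 10, 2, 4), 0)   # k > K
  expect_error(hypergeom_sf(1, 10, 11, 4), "requires")
  expect_error(hypergeom_sf(-1, 10, 5, 4), "requires")
})

test_that("hypergeometric tail equals enumeration across small universes", {
  for (N in c(1, 4, 8)) for (K in 0:N) for (n in 0:N) for (k in 0:(n + 1))
    expect_equal(hypergeom_sf(k, N, K, n), oracle_hyper_sf(k, N, K, n),
                 tolerance = 1e-12)
})

test_that("BH adjustment follows the step-up rule", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(c(0.005, 0.5)), c(0.01, 0.5))
  expect_equal(bh_adjust(0.3), 0.3)
  expect_error(bh_adjust(c(0.1, 1.2)), "\\[0, 1\\]")
  set.seed(5)
  for (rep in 1:10) {
    p <- stats::runif(sample(1:40, 1))
    adj <- bh_adjust(p)
    expect_equal(adj, oracle_bh(p), tolerance = 1e-12)
    # monotone in the raw order, idempotent on the adjusted ladder
    expect_true(all(diff(adj[order(p)]) >= -1e-12))
    expect_true(all(adj >= p - 1e-12))
    expect_equal(bh_adjust(adj)[which.max(adj)], max(adj))
  }
})

test_that("TF enrichment assembles the contingency counts correctly", {
  bg <- sprintf("g%d", 1:10)
  up <- c("g1", "g2", "g3", "g10")
  site_map <- list(TF_A = sprintf("g%d", 1:5),
                   TF_B = character(0),
                   TF_C = bg)
  res <- enrich_tfs(up, bg, site_map)
  a <- res[res$matrix_id == "TF_A", ]
  expect_equal(c(a$k, a$K, a$n, a$N), c(3, 5, 4, 10))
  expect_equal(a$p, 55 / 210, tolerance = 1e-12)
  expect_equal(a$pct_up, 75)
  expect_equal(a$pct_bg, 50)
  expect_equal(res$p[res$matrix_id == "TF_B"], 1)
  expect_equal(res$k[res$matrix_id == "TF_B"], 0)
  cc <- res[res$matrix_id == "TF_C", ]
  expect_equal(cc$k, cc$n)
  expect_equal(cc$p, 1)   # K = N forces X = n
  expect_true(all(res$padj >= res$p - 1e-12))
  # sorted by padj then p
  expect_true(!is.unsorted(res$padj))
})

test_that("query genes outside the background are an error", {
  expect_error(enrich_tfs(c("g1", "zz"), c("g1", "g2"), list(A = "g1")),
               "zz")
  expect_equal(nrow(enrich_tfs("g1", c("g1", "g2"), list())), 0)
})

test_that("generic ORA computes exactly the same numbers", {
  bg <- sprintf("g%d", 1:10)
  up <- c("g1", "g2", "g3", "g10")
  sets <- list(TF_A = sprintf("g%d", 1:5))
  a <- enrich_tfs(up, bg, sets)
  b <- ora_gene_sets(up, bg, sets)
  expect_equal(as.data.frame(a), as.data.frame(b))
  # query == background: k = K and the draw is the whole universe
  r <- ora_gene_sets(bg, bg, sets)
  expect_equal(r$k, r$K)
  expect_equal(r$p, 1)
  # disjoint query and set
  r2 <- ora_gene_sets(c("g9", "g10"), bg, list(S = c("g1", "g2")))
  expect_equal(r2$k, 0)
  expect_equal(r2$p, 1)
})

test_that("raw-alpha mode thresholds the unadjusted p-value", {
  bg <- sprintf("g%d", 1:40)
  up <- sprintf("g%d", 1:10)
  sets <- list(A = sprintf("g%d", 1:12),      # strongly enriched in up
               B = sprintf("g%d", c(1, 20:25)),
               C = sprintf("g%d", 30:40))
  raw <- enrich_tfs(up, bg, sets, adjust = FALSE)
  adj <- enrich_tfs(up, bg, sets, adjust = TRUE)
  expect_equal(raw$significant, raw$p < 0.05)
  expect_equal(adj$significant, adj$padj < 0.05)
})

test_that("GMT files round-trip into named gene-set lists", {
  gmt <- tempfile(fileext = ".gmt")
  writeLines(c("setA\tdesc\tg1\tg2\tg3", "setB\tdesc\tg9"), gmt)
  sets <- read_gmt(gmt)
  expect_equal(names(sets), c("setA", "setB"))
  expect_equal(sets$setA, c("g1", "g2", "g3"))
  writeLines("bad\tonly_desc", gmt)
  expect_error(read_gmt(gmt), "malformed")
})

test_that("null site maps keep the raw rejection rate near its exact level", {
  # equal-rate planting null at moderate scale: exchangeable query/background
  set.seed(31)
  N <- 2000; n_up <- 200; rate <- 0.25; n_tf <- 10; reps <- 30
  bg <- sprintf("g%d", seq_len(N))
  up <- bg[seq_len(n_up)]
  frac <- mean(replicate(reps, {
    sm <- lapply(seq_len(n_tf), function(i) bg[stats::runif(N) < rate])
    names(sm) <- sprintf("TF%02d", seq_len(n_tf))
    res <- enrich_tfs(up, bg, sm)
    mean(res$p < 0.05)
  }))
  # generous Monte-Carlo band around the nominal 5% for a smoke check;
  # the tight 99%-bound version runs in the acceptance suite
  expect_lt(frac, 0.08)
  expect_gt(frac, 0.02)
})

test_that("causal sets planted at 0.6 vs 0.2 outrank decoys", {
  set.seed(37)
  N <- 1000; n_up <- 100
  bg <- sprintf("g%d", seq_len(N))
  up <- bg[seq_len(n_up)]
  wins <- replicate(10, {
    sm <- c(lapply(1:2, function(i)
              unique(c(up[stats::runif(n_up) < 0.6],
                       bg[stats::runif(N) < 0.2]))),
            lapply(1:20, function(i) bg[stats::runif(N) < 0.2]))
    names(sm) <- c("CAUSAL1", "CAUSAL2", sprintf("DECOY%02d", 1:20))
    res <- enrich_tfs(up, bg, sm)
    causal_rows <- which(res$matrix_id %in% c("CAUSAL1", "CAUSAL2"))
    all(causal_rows == c(1, 2)) && all(res$padj[causal_rows] < 0.05)
  })
  expect_gte(mean(wins), 0.95)
})
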