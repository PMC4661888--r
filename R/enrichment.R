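#' Upper-tail hypergeometric probability
#'
#' `P(X >= k)` for `X ~ Hypergeometric(N, K, n)`: the probability of drawing
#' at least `k` marked genes when `n` genes are drawn without replacement
#' from a universe of `N` genes of which `K` are marked. Evaluated on the
#' log scale internally, so it is stable for genome-sized universes
#' (`N ~ 2e4`).
#'
#' @param k observed number of marked genes in the draw.
#' @param N universe size.
#' @param K number of marked genes in the universe.
#' @param n draw size.
#' @return probability in `[0, 1]`; exactly 1 when `k <= 0`, exactly 0 when
#'   `k > min(K, n)`.
#' @export
hypergeom_sf <- function(k, N, K, n) {
  for (v in list(k = k, N = N, K = K, n = n))
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v != round(v))
      .err("hypergeom_sf arguments must be single finite integers")
  if (N < 0 || K < 0 || K > N || n < 0 || n > N || k < 0)
    .err("hypergeom_sf requires 0 <= K <= N, 0 <= n <= N, 0 <= k")
  if (k <= 0) return(1)
  if (k > min(K, n)) return(0)
  exp(stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE, log.p = TRUE))
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Classic FDR step-up: sort ascending, `adj_(i) = min_(j >= i) p_(j) * m / j`
#' capped at 1, mapped back to input order.
#'
#' @param pvalues numeric vector of p-values in `[0, 1]`.
#' @return adjusted p-values in the input order.
#' @export
bh_adjust <- function(pvalues) {
  if (length(pvalues) == 0L) return(numeric(0))
  if (!is.numeric(pvalues) || anyNA(pvalues) ||
      any(pvalues < 0 | pvalues > 1))
    .err("p-values must all lie in [0, 1]")
  stats::p.adjust(pvalues, method = "BH")
}

.enrich_core <- function(query, background, sets, alpha, adjust, set_names) {
  query <- unique(as.character(query))
  background <- unique(as.character(background))
  bad <- setdiff(query, background)
  if (length(bad))
    .err("query genes absent from the background: %s",
         paste(utils::head(bad, 10L), collapse = ", "))
  N <- length(background)
  n <- length(query)
  if (!length(sets)) {
    out <- data.frame(matrix_id = character(0), tf_name = character(0),
                      k = integer(0), n = integer(0), K = integer(0),
                      N = integer(0), pct_up = numeric(0),
                      pct_bg = numeric(0), p = numeric(0), padj = numeric(0),
                      significant = logical(0), stringsAsFactors = FALSE)
    class(out) <- c("enrichment_result", "data.frame")
    return(out)
  }
  ids <- names(sets)
  if (is.null(ids)) .err("gene sets must be named")
  K <- k <- integer(length(sets))
  for (i in seq_along(sets)) {
    g <- intersect(unique(as.character(sets[[i]])), background)
    K[i] <- length(g)
    k[i] <- length(intersect(g, query))
  }
  p <- vapply(seq_along(sets), function(i) hypergeom_sf(k[i], N, K[i], n),
              numeric(1))
  padj <- bh_adjust(p)
  out <- data.frame(
    matrix_id = ids,
    tf_name = if (is.null(set_names)) ids else
      ifelse(is.na(set_names[ids]), ids, set_names[ids]),
    k = k, n = n, K = K, N = N,
    pct_up = if (n > 0) 100 * k / n else NA_real_,
    pct_bg = if (N > 0) 100 * K / N else NA_real_,
    p = p, padj = padj,
    significant = (if (adjust) padj else p) < alpha,
    stringsAsFactors = FALSE)
  out <- out[order(out$padj, out$p), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("enrichment_result", "data.frame")
  out
}

#' Transcription-factor binding-site enrichment
#'
#' For each matrix, tests whether genes carrying at least one binding site
#' are over-represented among the up-regulated genes relative to the
#' background universe, using the upper-tail hypergeometric test with
#' Benjamini-Hochberg correction across matrices. The contingency counts
#' per matrix are: `k` = up-regulated genes with a site, `n` = up-regulated
#' genes tested, `K` = background genes with a site, `N` = background size.
#'
#' @param up_genes character vector of up-regulated gene ids (must be a
#'   subset of `background_genes`).
#' @param background_genes the gene universe (typically all genes with an
#'   extractable promoter).
#' @param site_map named list, `matrix_id` -> gene ids with >= 1 site (see
#'   [build_site_map]); gene sets are intersected with the background
#'   before counting.
#' @param alpha significance level (default 0.05).
#' @param adjust apply `alpha` to the BH-adjusted p (default `TRUE`); set
#'   `FALSE` to threshold the raw p instead.
#' @param tf_names optional named character vector, `matrix_id` -> factor
#'   name, for the `tf_name` column.
#' @return an `enrichment_result` data.frame sorted by `padj` then `p`,
#'   with columns `matrix_id`, `tf_name`, `k`, `n`, `K`, `N`, `pct_up`,
#'   `pct_bg`, `p`, `padj`, `significant`.
#' @export
enrich_tfs <- function(up_genes, background_genes, site_map, alpha = 0.05,
                       adjust = TRUE, tf_names = NULL) {
  .enrich_core(up_genes, background_genes, site_map, alpha, adjust, tf_names)
}

#' Generic gene-set over-representation analysis
#'
#' The same hypergeometric/BH machinery as [enrich_tfs] applied to arbitrary
#' named gene sets (e.g. pathway or GO collections read with [read_gmt]).
#'
#' @param query_genes gene ids of interest (subset of the background).
#' @param background_genes the gene universe.
#' @param gene_sets named list of gene-id vectors.
#' @param alpha significance level (default 0.05).
#' @param adjust threshold the adjusted p (default) or the raw p.
#' @return an `enrichment_result` data.frame (see [enrich_tfs]).
#' @export
ora_gene_sets <- function(query_genes, background_genes, gene_sets,
                          alpha = 0.05, adjust = TRUE) {
  .enrich_core(query_genes, background_genes, gene_sets, alpha, adjust, NULL)
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat(sprintf("TFBS/gene-set enrichment: %d sets tested, %d significant\n",
              nrow(x), sum(x$significant)))
  df <- as.data.frame(x)
  df$pct_up <- round(df$pct_up, 1)
  df$pct_bg <- round(df$pct_bg, 1)
  df$p <- signif(df$p, 3)
  df$padj <- signif(df$padj, 3)
  print(utils::head(df, 20L), row.names = FALSE)
  if (nrow(df) > 20L) cat("...", nrow(df) - 20L, "more rows\n")
  invisible(x)
}

#' Read gene sets in GMT format
#'
#' One set per line: name, description, then member gene ids, tab-separated.
#' @param file path to a `.gmt` file.
#' @return named list of character vectors.
#' @export
read_gmt <- function(file) {
  lines <- readLines(file, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  sets <- lapply(lines, function(l) {
    f <- strsplit(l, "\t", fixed = TRUE)[[1]]
    if (length(f) < 3L) .err("malformed GMT line: '%s'", substr(l, 1, 60))
    f[-(1:2)]
  })
  names(sets) <- vapply(lines, function(l)
    strsplit(l, "\t", fixed = TRUE)[[1]][1], character(1), USE.NAMES = FALSE)
  sets
}
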