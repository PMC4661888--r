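#' Bundle counts, gene lengths and sample groups
#'
#' Container for a gene x sample fragment-count matrix together with the
#' per-gene transcript lengths (bp) and the two-group sample labels that the
#' quantification and testing stages need.
#'
#' @param counts non-negative integer matrix, genes in rows (rownames are
#'   gene ids), samples in columns.
#' @param gene_lengths positive lengths in bp, named by gene or in row
#'   order.
#' @param sample_groups group label per sample (e.g. `NP`/`LP`), named by
#'   sample or in column order.
#' @return an object of class `expression_matrix`.
#' @export
expression_matrix <- function(counts, gene_lengths, sample_groups) {
  counts <- as.matrix(counts)
  if (any(counts < 0) || any(!is.finite(counts)))
    .err("counts must be finite and non-negative")
  if (is.null(rownames(counts)))
    rownames(counts) <- sprintf("gene%05d", seq_len(nrow(counts)))
  if (is.null(colnames(counts)))
    colnames(counts) <- sprintf("sample%d", seq_len(ncol(counts)))
  if (!is.null(names(gene_lengths)))
    gene_lengths <- gene_lengths[rownames(counts)]
  if (length(gene_lengths) != nrow(counts) || any(is.na(gene_lengths)) ||
      any(gene_lengths <= 0))
    .err("gene_lengths must be positive, one per gene")
  if (!is.null(names(sample_groups)))
    sample_groups <- sample_groups[colnames(counts)]
  if (length(sample_groups) != ncol(counts) || anyNA(sample_groups))
    .err("sample_groups must provide one label per sample")
  structure(list(counts = counts,
                 gene_lengths = stats::setNames(as.numeric(gene_lengths),
                                                rownames(counts)),
                 groups = stats::setNames(as.character(sample_groups),
                                          colnames(counts))),
            class = "expression_matrix")
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("expression_matrix: %d genes x %d samples (groups: %s)\n",
              nrow(x$counts), ncol(x$counts),
              paste(sprintf("%s=%d", names(table(x$groups)), table(x$groups)),
                    collapse = ", ")))
  invisible(x)
}

#' FPKM quantification
#'
#' Fragments per kilobase of transcript per million mapped fragments:
#' `fpkm[g, s] = count[g, s] / (length_g / 1000) / (libsize_s / 1e6)` with
#' the library size taken as the column sum.
#'
#' @param x an [expression_matrix], or a counts matrix.
#' @param gene_lengths required when `x` is a bare matrix.
#' @return numeric matrix of FPKM values, same dimensions as the counts.
#' @export
compute_fpkm <- function(x, gene_lengths = NULL) {
  if (inherits(x, "expression_matrix")) {
    counts <- x$counts; gene_lengths <- x$gene_lengths
  } else {
    counts <- as.matrix(x)
    if (is.null(gene_lengths)) .err("gene_lengths required")
  }
  libsize <- colSums(counts)
  if (any(libsize == 0)) .err("zero library size in sample(s): %s",
                              paste(colnames(counts)[libsize == 0],
                                    collapse = ", "))
  sweep(counts / (gene_lengths / 1000), 2L, libsize / 1e6, "/")
}

#' Median-of-ratios size factors
#'
#' For every gene with a nonzero count in all samples, the ratio of each
#' sample's count to the gene's geometric mean is formed; a sample's size
#' factor is the median of those ratios.
#'
#' @param counts counts matrix or [expression_matrix].
#' @return named numeric vector of per-sample size factors.
#' @export
size_factors <- function(counts) {
  if (inherits(counts, "expression_matrix")) counts <- counts$counts
  counts <- as.matrix(counts)
  if (ncol(counts) == 1L)
    return(stats::setNames(1, colnames(counts)))
  ok <- rowSums(counts > 0) == ncol(counts)
  if (!any(ok))
    .err(paste("no gene has nonzero counts in every sample;",
               "add a pseudo-count or filter samples"))
  lg <- log(counts[ok, , drop = FALSE])
  geo <- rowMeans(lg)
  apply(exp(lg - geo), 2L, stats::median)
}

#' Simplified differential-expression test for NB counts
#'
#' A self-contained two-group test for synthetic, end-to-end testing of the
#' pipeline (it is deliberately *not* a reimplementation of DESeq's
#' dispersion machinery; externally computed DE tables can be supplied to
#' [classify_de] instead). Counts are normalised by median-of-ratios size
#' factors; per-gene group means get a +0.5 offset before the ratio so zero
#' counts stay finite. The p-value is a two-sided moderated t test on
#' `log2(normalised count + 0.5)` (limma with a mean-variance trend): under
#' negative-binomial noise at the study's group sizes this empirical
#' log-scale test is well calibrated, where a Wald statistic with a
#' moment-matched NB variance is visibly anti-conservative at n = 3.
#'
#' @param x an [expression_matrix].
#' @param ref_level group treated as the reference (default: first level in
#'   the group vector); fold changes are alt vs ref.
#' @return data.frame with columns `gene_id`, `mean_ref`, `mean_alt`
#'   (normalised group means), `fc` (magnitude, >= 1), `direction`
#'   (`up`/`down`/`none`), `p`, `padj` (BH across genes).
#' @export
nb_de_test <- function(x, ref_level = NULL) {
  stopifnot(inherits(x, "expression_matrix"))
  lev <- unique(x$groups)
  if (length(lev) != 2L) .err("exactly two sample groups are required")
  if (is.null(ref_level)) ref_level <- lev[1]
  if (!ref_level %in% lev) .err("unknown ref_level '%s'", ref_level)
  alt_level <- setdiff(lev, ref_level)
  i1 <- which(x$groups == ref_level)
  i2 <- which(x$groups == alt_level)
  n1 <- length(i1); n2 <- length(i2)
  if (n1 < 2L || n2 < 2L) .err("each group needs >= 2 samples")
  sf <- size_factors(x$counts)
  q <- sweep(x$counts, 2L, sf, "/")
  m1 <- rowMeans(q[, i1, drop = FALSE])
  m2 <- rowMeans(q[, i2, drop = FALSE])
  lq <- log2(q + 0.5)
  design <- stats::model.matrix(~ factor(x$groups,
                                         levels = c(ref_level, alt_level)))
  fit <- limma::eBayes(limma::lmFit(lq, design), trend = TRUE)
  p <- fit$p.value[, 2L]
  r <- (m2 + 0.5) / (m1 + 0.5)
  data.frame(gene_id = rownames(x$counts),
             mean_ref = m1, mean_alt = m2,
             fc = pmax(r, 1 / r),
             direction = ifelse(r > 1, "up", ifelse(r < 1, "down", "none")),
             p = p, padj = bh_adjust(p),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Classify genes as up / down / unchanged
#'
#' A gene is called differentially expressed when its fold-change magnitude
#' strictly exceeds `fc_threshold` *and* its adjusted p-value is strictly
#' below `alpha`; the status then follows the direction of change.
#'
#' @param de_table data.frame with columns `gene_id`, `fc` (magnitude >= 1),
#'   `direction`, `padj` — from [nb_de_test] or an external results file
#'   ([read_de_table]).
#' @param fc_threshold fold-change cutoff, exceeded strictly (default 2).
#' @param alpha adjusted-p cutoff, strict (default 0.05).
#' @return list with `table` (the input plus a `status` column) and
#'   `summary` (`n_up`, `n_down`, `n_total`, `pct_up`), class `de_result`.
#' @export
classify_de <- function(de_table, fc_threshold = 2, alpha = 0.05) {
  need <- c("gene_id", "fc", "direction", "padj")
  miss <- setdiff(need, names(de_table))
  if (length(miss))
    .err("DE table lacks columns: %s", paste(miss, collapse = ", "))
  sig <- de_table$fc > fc_threshold & de_table$padj < alpha
  status <- ifelse(sig & de_table$direction == "up", "up",
                   ifelse(sig & de_table$direction == "down", "down",
                          "unchanged"))
  de_table$status <- status
  structure(list(table = de_table,
                 summary = de_summary(sum(status == "up"),
                                      sum(status == "down"))),
            class = "de_result")
}

#' Differential-expression summary arithmetic
#'
#' @param n_up,n_down numbers of up- and down-regulated genes.
#' @return list with `n_up`, `n_down`, `n_total` (= n_up + n_down) and
#'   `pct_up` (= 100 * n_up / n_total).
#' @export
de_summary <- function(n_up, n_down) {
  n_total <- n_up + n_down
  list(n_up = n_up, n_down = n_down, n_total = n_total,
       pct_up = if (n_total > 0) 100 * n_up / n_total else NA_real_)
}

#' @export
print.de_result <- function(x, ...) {
  s <- x$summary
  cat(sprintf("DE classification: %d genes DE (%d up, %d down; %.1f%% up) of %d tested\n",
              s$n_total, s$n_up, s$n_down, s$pct_up, nrow(x$table)))
  invisible(x)
}

#' Read an externally computed DE results table
#'
#' Expects tab-separated columns `gene_id`, `log2fc` (signed), `padj` (or
#' ready-made `fc` + `direction` + `padj`); signed log2 fold changes are
#' converted to the magnitude + direction convention.
#'
#' @param file path to the TSV.
#' @return data.frame with `gene_id`, `fc`, `direction`, `padj`.
#' @export
read_de_table <- function(file) {
  d <- .read_tsv(file)
  if (all(c("fc", "direction", "padj", "gene_id") %in% names(d)))
    return(d)
  need <- c("gene_id", "log2fc", "padj")
  miss <- setdiff(need, names(d))
  if (length(miss))
    .err("external DE table lacks columns: %s", paste(miss, collapse = ", "))
  data.frame(gene_id = d$gene_id,
             fc = 2^abs(d$log2fc),
             direction = ifelse(d$log2fc > 0, "up",
                                ifelse(d$log2fc < 0, "down", "none")),
             padj = d$padj, stringsAsFactors = FALSE)
}

#' Average-linkage clustering on Pearson correlation distance
#'
#' Samples are clustered with distance `1 - r` (Pearson correlation of
#' `log2(FPKM + 1)` profiles by default) and average-linkage (UPGMA)
#' agglomeration. Genes with zero variance across samples are dropped
#' before the correlation.
#'
#' @param fpkm genes x samples FPKM matrix.
#' @param log_transform apply `log2(x + 1)` first (default `TRUE`).
#' @return an `hclust` object; see [cluster_merge_table] and
#'   [cluster_newick] for tabular and Newick exports.
#' @export
hcluster <- function(fpkm, log_transform = TRUE) {
  fpkm <- as.matrix(fpkm)
  if (ncol(fpkm) < 2L) .err("clustering needs >= 2 samples")
  x <- if (log_transform) log2(fpkm + 1) else fpkm
  keep <- apply(x, 1L, function(r) stats::var(r) > 0)
  x <- x[keep, , drop = FALSE]
  if (nrow(x) < 2L) .err("fewer than 2 genes with nonzero variance")
  d <- stats::as.dist(1 - stats::cor(x, method = "pearson"))
  stats::hclust(d, method = "average")
}

#' Merge table of a cluster tree
#'
#' @param hc an `hclust` object.
#' @return data.frame with one row per merge: `member_a`, `member_b`
#'   (negative = leaf index, positive = earlier merge id), `height`,
#'   `cluster_id`.
#' @export
cluster_merge_table <- function(hc) {
  data.frame(member_a = hc$merge[, 1], member_b = hc$merge[, 2],
             height = hc$height, cluster_id = seq_along(hc$height))
}

#' Newick export of a cluster tree
#' @param hc an `hclust` object.
#' @return a single Newick string.
#' @export
cluster_newick <- function(hc) {
  ape::write.tree(ape::as.phylo(hc))
}

#' Relative qPCR quantification by 2^-ddCt
#'
#' Per sample, `dCt = Ct_target - Ct_reference`; per gene,
#' `ddCt = mean dCt(alt group) - mean dCt(ref group)` and the fold change is
#' `2^-ddCt`, so a 1-cycle drop of the target in the alt group doubles it.
#'
#' @param ct numeric matrix of Ct values, genes x samples, including a row
#'   for the reference gene.
#' @param groups group label per sample (named by sample or in column
#'   order).
#' @param reference_gene row name of the reference (housekeeping) gene.
#' @param ref_level reference group (default: first label).
#' @return named numeric vector of fold changes (alt vs ref) for every gene
#'   except the reference gene.
#' @export
ddct_foldchange <- function(ct, groups, reference_gene,
                            ref_level = NULL) {
  ct <- as.matrix(ct)
  if (!reference_gene %in% rownames(ct))
    .err("reference gene '%s' missing from the Ct table", reference_gene)
  if (!is.null(names(groups))) groups <- groups[colnames(ct)]
  if (length(groups) != ncol(ct) || anyNA(groups))
    .err("groups must label every sample")
  if (anyNA(ct) || any(!is.finite(ct)))
    .err("Ct values must be finite (reference gene present in every sample)")
  lev <- unique(groups)
  if (length(lev) != 2L) .err("exactly two groups are required")
  if (is.null(ref_level)) ref_level <- lev[1]
  alt_level <- setdiff(lev, ref_level)
  dct <- sweep(ct, 2L, ct[reference_gene, ], "-")
  dct <- dct[setdiff(rownames(ct), reference_gene), , drop = FALSE]
  ddct <- rowMeans(dct[, groups == alt_level, drop = FALSE]) -
          rowMeans(dct[, groups == ref_level, drop = FALSE])
  2^(-ddct)
}

#' Cross-platform fold-change correlation
#'
#' Pearson correlation of log2 fold changes over the genes shared by two
#' platforms (e.g. RNA-seq vs qRT-PCR), with the usual t-distribution
#' p-value on n - 2 degrees of freedom.
#'
#' @param fc_a,fc_b named numeric vectors of fold-change ratios (> 0).
#' @return list with `r`, `p` and `n` (shared genes).
#' @export
correlate_platforms <- function(fc_a, fc_b) {
  shared <- intersect(names(fc_a), names(fc_b))
  if (length(shared) < 3L) .err("need >= 3 shared genes (got %d)",
                                length(shared))
  ct <- stats::cor.test(log2(fc_a[shared]), log2(fc_b[shared]),
                        method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n = length(shared))
}

#' Presence calls at an FPKM cutoff
#'
#' A gene is called present in a condition when its group-mean FPKM is at
#' least `cutoff` (boundary inclusive).
#'
#' @param fpkm genes x samples FPKM matrix.
#' @param groups group label per sample.
#' @param genes genes to call; unknown genes are reported in the `missing`
#'   attribute rather than failing.
#' @param cutoff FPKM cutoff (default 1).
#' @return data.frame with `gene_id`, `group`, `mean_fpkm`, `present`;
#'   attribute `missing` lists unknown genes.
#' @export
presence_call <- function(fpkm, groups, genes, cutoff = 1) {
  fpkm <- as.matrix(fpkm)
  if (!is.null(names(groups))) groups <- groups[colnames(fpkm)]
  missing <- setdiff(genes, rownames(fpkm))
  genes <- intersect(genes, rownames(fpkm))
  lev <- unique(groups)
  rows <- lapply(lev, function(g) {
    mf <- rowMeans(fpkm[genes, groups == g, drop = FALSE])
    data.frame(gene_id = genes, group = g, mean_fpkm = unname(mf),
               present = unname(mf >= cutoff), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "missing") <- missing
  out
}

#' Flag a gene panel for differential expression
#'
#' Applies the fold-change / adjusted-p classification to a fixed panel
#' (e.g. the thyroid-hormone-synthesis genes Tshr, Slc5a5, Slc26a4, Tg,
#' Tpo, Duoxa2, Duox2) and reports whether any panel member is
#' differentially expressed.
#'
#' @param de_table DE table as for [classify_de].
#' @param panel_genes character vector of panel gene ids.
#' @param fc_threshold,alpha classification cutoffs.
#' @return list with `table` (per-panel-gene status; genes missing from the
#'   DE table get status `"missing"`) and `verdict` (`"not altered"` iff no
#'   panel gene is DE).
#' @export
panel_flag <- function(de_table, panel_genes, fc_threshold = 2,
                       alpha = 0.05) {
  if (!length(panel_genes)) {
    .warnf("empty gene panel; verdict trivially 'not altered'")
    return(list(table = data.frame(gene_id = character(0),
                                   status = character(0)),
                verdict = "not altered"))
  }
  present <- intersect(panel_genes, de_table$gene_id)
  cls <- if (length(present))
    classify_de(de_table[match(present, de_table$gene_id), , drop = FALSE],
                fc_threshold, alpha)$table else NULL
  tab <- data.frame(gene_id = panel_genes,
                    status = "missing", stringsAsFactors = FALSE)
  if (!is.null(cls))
    tab$status[match(cls$gene_id, tab$gene_id)] <- cls$status
  list(table = tab,
       verdict = if (any(tab$status %in% c("up", "down")))
         "altered" else "not altered")
}
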