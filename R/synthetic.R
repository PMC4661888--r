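# Ground-truth-bearing synthetic inputs: a genome with laid-out genes and
# clear promoter space, PWMs planted at controlled rates, and
# negative-binomial count matrices with known fold changes. Everything is a
# pure function of (parameters, seed): one RNG stream per bundle, consumed
# in a fixed, documented order.

#' Random informative PWM
#'
#' Columns are drawn from a symmetric Dirichlet (lower `concentration` =
#' sharper columns) and scaled to integer counts, mimicking the width and
#' information diversity of TRANSFAC matrices. Used for decoy matrices.
#'
#' @param width motif width.
#' @param matrix_id,tf_name identifiers.
#' @param concentration Dirichlet concentration parameter (default 0.5).
#' @param depth total count per column (default 100).
#' @return a [pwm].
#' @export
random_pwm <- function(width, matrix_id = "RAND", tf_name = matrix_id,
                       concentration = 0.5, depth = 100) {
  counts <- t(vapply(seq_len(width), function(i) {
    g <- stats::rgamma(4, concentration)
    x <- round(depth * g / sum(g))
    x
  }, numeric(4)))
  pwm(counts, matrix_id = matrix_id, tf_name = tf_name)
}

# Very sharp PWM whose sampled site instances usually stay above a 0.9
# relative score: one dominant letter per column at ~97% probability.
.sharp_pwm <- function(width, matrix_id, tf_name = matrix_id, depth = 1000) {
  counts <- matrix(0, width, 4)
  dom <- sample.int(4L, width, replace = TRUE)
  for (i in seq_len(width)) {
    counts[i, ] <- round(depth * 0.005)
    counts[i, dom[i]] <- depth - 3 * round(depth * 0.005)
  }
  pwm(counts, matrix_id = matrix_id, tf_name = tf_name)
}

#' Generate a synthetic genome with laid-out genes
#'
#' One contig carries `n_genes` non-overlapping single-transcript genes on
#' alternating strands. Each gene slot reserves `promoter_len` bp of
#' clearance on both sides of the gene body, so every promoter is fully on
#' the contig and never clipped. Background sequence is i.i.d. at the given
#' GC content.
#'
#' @param n_genes number of genes (>= 1).
#' @param promoter_len upstream clearance / promoter length in bp.
#' @param gc GC content of the background sequence.
#' @param gene_len gene-body length in bp.
#' @param seed optional integer seed (omit to consume the current RNG
#'   stream).
#' @return a `synthetic_reference`: list with `genome` (named character,
#'   one string per contig), `annotation` (0-based transcript table),
#'   `promoters` (per-gene promoter intervals used for planting) and
#'   `params`.
#' @export
gen_reference <- function(n_genes, promoter_len = 1000L, gc = 0.5,
                          gene_len = 300L, seed = NULL) {
  if (n_genes < 1L) .err("n_genes must be >= 1")
  if (gc <= 0 || gc >= 1) .err("gc must be in (0, 1)")
  if (!is.null(seed)) set.seed(seed)
  slot <- 2L * promoter_len + gene_len
  L <- n_genes * slot
  base_prob <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  seq_chars <- sample(.DNA_LETTERS, L, replace = TRUE, prob = base_prob)
  i <- seq_len(n_genes)
  slot_start <- (i - 1L) * slot
  start <- slot_start + promoter_len
  end <- start + gene_len
  strand <- ifelse(i %% 2L == 1L, "+", "-")
  ann <- data.frame(gene_id = sprintf("gene%05d", i), chrom = "chr1",
                    start = start, end = end, strand = strand,
                    stringsAsFactors = FALSE)
  prom <- data.frame(gene_id = ann$gene_id, chrom = "chr1",
                     start = ifelse(strand == "+", start - promoter_len, end),
                     end = ifelse(strand == "+", start, end + promoter_len),
                     strand = strand, stringsAsFactors = FALSE)
  structure(list(genome = c(chr1 = paste(seq_chars, collapse = "")),
                 annotation = ann, promoters = prom,
                 params = list(n_genes = n_genes,
                               promoter_len = promoter_len, gc = gc,
                               gene_len = gene_len)),
            class = "synthetic_reference")
}

# sample one site instance from the PWM's probability columns
.sample_site <- function(probs) {
  w <- nrow(probs)
  idx <- vapply(seq_len(w), function(i)
    sample.int(4L, 1L, prob = probs[i, ]), integer(1))
  .DNA_LETTERS[idx]
}

#' Plant motif instances into synthetic promoters
#'
#' Each causal PWM is inserted into each up-gene promoter with probability
#' `p_up` and into every other promoter with probability `p_bg`; decoy PWMs
#' are inserted everywhere at `p_bg`. Site instances are sampled
#' letter-by-letter from the PWM's probability columns (or the consensus
#' with `consensus = TRUE`), placed at a uniform offset and uniform strand
#' within the promoter. Planted positions are recorded in the returned
#' truth.
#'
#' @param reference a `synthetic_reference` from [gen_reference].
#' @param pwms named list of [pwm] objects (causal and decoy).
#' @param causal_ids matrix ids of the causal subset of `pwms`.
#' @param up_genes gene ids receiving causal motifs at the elevated rate.
#' @param p_up,p_bg planting probabilities in `[0, 1]`.
#' @param consensus plant the consensus sequence instead of sampled sites.
#' @param seed optional integer seed.
#' @return list with `reference` (modified genome) and `truth`
#'   (`causal_tf_ids`, `planted_sites` data.frame with promoter-space
#'   offsets, `params`).
#' @export
plant_motifs <- function(reference, pwms, causal_ids, up_genes,
                         p_up, p_bg, consensus = FALSE, seed = NULL) {
  stopifnot(inherits(reference, "synthetic_reference"))
  if (any(c(p_up, p_bg) < 0) || any(c(p_up, p_bg) > 1))
    .err("p_up and p_bg must lie in [0, 1]")
  bad <- setdiff(up_genes, reference$annotation$gene_id)
  if (length(bad)) .err("up_genes not in the annotation: %s",
                        paste(utils::head(bad, 5L), collapse = ", "))
  plen <- reference$params$promoter_len
  widths <- vapply(pwms, pwm_width, integer(1))
  if (any(widths > plen))
    .err("motif wider than the promoter: %s",
         paste(names(pwms)[widths > plen], collapse = ", "))
  if (!is.null(seed)) set.seed(seed)
  prom <- reference$promoters
  n <- nrow(prom)
  is_up <- prom$gene_id %in% up_genes
  chars <- strsplit(reference$genome[["chr1"]], "", fixed = TRUE)[[1]]
  sites <- vector("list", length(pwms))
  for (m in seq_along(pwms)) {
    p <- pwms[[m]]
    w <- pwm_width(p)
    probs <- pwm_probs(p)
    causal <- p$matrix_id %in% causal_ids
    rate <- if (causal) ifelse(is_up, p_up, p_bg) else rep(p_bg, n)
    plant <- which(stats::runif(n) < rate)
    if (!length(plant)) next
    recs <- vector("list", length(plant))
    for (j in seq_along(plant)) {
      g <- plant[j]
      o <- sample.int(plen - w + 1L, 1L) - 1L
      st <- sample(c("+", "-"), 1L)
      letters <- if (consensus)
        strsplit(pwm_consensus(p), "", fixed = TRUE)[[1]]
      else .sample_site(probs)
      comp <- c(A = "T", C = "G", G = "C", T = "A")
      x <- if (st == "+") letters else rev(unname(comp[letters]))
      if (prom$strand[g] == "+") {
        a <- prom$start[g] + o
        chars[(a + 1L):(a + w)] <- x
      } else {
        a <- prom$end[g] - o - w
        chars[(a + 1L):(a + w)] <- rev(unname(comp[x]))
      }
      recs[[j]] <- data.frame(gene_id = prom$gene_id[g],
                              matrix_id = p$matrix_id, offset = o,
                              strand = st, stringsAsFactors = FALSE)
    }
    sites[[m]] <- do.call(rbind, recs)
  }
  planted <- do.call(rbind, sites)
  if (is.null(planted))
    planted <- data.frame(gene_id = character(0), matrix_id = character(0),
                          offset = integer(0), strand = character(0))
  reference$genome[["chr1"]] <- paste(chars, collapse = "")
  list(reference = reference,
       truth = list(causal_tf_ids = causal_ids, planted_sites = planted,
                    params = list(p_up = p_up, p_bg = p_bg,
                                  consensus = consensus)))
}

#' Simulate a two-group negative-binomial count matrix
#'
#' Baseline means are log-normal; the second group's means are scaled by
#' `2^lfc` for each gene's true log2 fold change; counts are
#' negative-binomial around `mean * sizefactor_s` at the given dispersion.
#' Gene lengths are uniform on 500-10000 bp.
#'
#' @param n_genes number of genes (gene ids `gene00001`...).
#' @param true_lfc signed true log2 fold changes (group 2 vs group 1);
#'   recycled `0` for genes beyond its length, or a named vector over a
#'   subset of gene ids.
#' @param n_per_group samples per group (default 3).
#' @param dispersion NB dispersion (`Var = mu + dispersion * mu^2`;
#'   default 0.1; 0 gives Poisson).
#' @param libsize_factor_range library-size factors are drawn uniformly in
#'   this range and normalised to geometric mean 1.
#' @param mean_log,mean_sdlog log-normal parameters of the baseline means.
#' @param groups labels for the two groups (reference first).
#' @param seed optional integer seed.
#' @return list with `em` (an [expression_matrix]) and `truth` (named
#'   `true_lfc` over all genes, `params`).
#' @export
simulate_counts <- function(n_genes, true_lfc = NULL, n_per_group = 3L,
                            dispersion = 0.1,
                            libsize_factor_range = c(0.7, 1.3),
                            mean_log = log(64), mean_sdlog = 1.6,
                            groups = c("NP", "LP"), seed = NULL) {
  stopifnot(n_genes >= 1L, n_per_group >= 1L, dispersion >= 0)
  if (!is.null(seed)) set.seed(seed)
  ids <- sprintf("gene%05d", seq_len(n_genes))
  lfc <- stats::setNames(rep(0, n_genes), ids)
  if (!is.null(true_lfc)) {
    if (!is.null(names(true_lfc))) {
      bad <- setdiff(names(true_lfc), ids)
      if (length(bad)) .err("true_lfc names outside the gene set")
      lfc[names(true_lfc)] <- true_lfc
    } else {
      lfc[seq_along(true_lfc)] <- true_lfc
    }
  }
  base <- stats::rlnorm(n_genes, meanlog = mean_log, sdlog = mean_sdlog)
  gene_lengths <- round(stats::runif(n_genes, 500, 10000))
  ns <- 2L * n_per_group
  sf <- stats::runif(ns, libsize_factor_range[1], libsize_factor_range[2])
  sf <- sf / exp(mean(log(sf)))
  grp <- rep(groups, each = n_per_group)
  mu <- cbind(matrix(base, n_genes, n_per_group),
              matrix(base * 2^lfc, n_genes, n_per_group))
  mu <- sweep(mu, 2L, sf, "*")
  counts <- if (dispersion > 0)
    matrix(stats::rnbinom(length(mu), mu = mu, size = 1 / dispersion),
           n_genes, ns)
  else matrix(stats::rpois(length(mu), mu), n_genes, ns)
  dimnames(counts) <- list(ids, sprintf("%s_%d", grp,
                                        rep(seq_len(n_per_group), 2L)))
  em <- expression_matrix(counts, gene_lengths,
                          stats::setNames(grp, colnames(counts)))
  list(em = em,
       truth = list(true_lfc = lfc,
                    params = list(n_genes = n_genes,
                                  n_per_group = n_per_group,
                                  dispersion = dispersion,
                                  size_factors = sf,
                                  mean_log = mean_log,
                                  mean_sdlog = mean_sdlog)))
}

.bundle_defaults <- function() {
  list(n_genes = 15000L, n_up = 558L, n_down = 57L,
       lfc_up = c(1, 9), lfc_down = c(1, log2(10)),
       n_causal = 2L, n_decoy = 20L, p_up = 0.6, p_bg = 0.2,
       causal_width = 10L, n_per_group = 3L, dispersion = 0.1,
       promoter_len = 1000L, gene_len = 300L, gc = 0.5,
       consensus = FALSE)
}

#' Generate a complete ground-truth pipeline input bundle
#'
#' Produces a mutually consistent input set emulating the study's
#' statistical shape: by default ~15000 genes with 558 up- and 57
#' down-regulated (fold changes spanning 2-512), 3 vs 3 samples at NB
#' dispersion 0.1, and 2 causal transcription factors planted in up-gene
#' promoters at rate 0.6 versus 0.2 genome-background, among 20 decoy
#' matrices. The up-gene list used for motif planting is exactly the gene
#' set with positive true log2 fold change in the counts.
#'
#' @param config named list overriding any of the defaults (unknown keys
#'   are rejected): `n_genes`, `n_up`, `n_down`, `lfc_up`, `lfc_down`,
#'   `n_causal`, `n_decoy`, `p_up`, `p_bg`, `causal_width`, `n_per_group`,
#'   `dispersion`, `promoter_len`, `gene_len`, `gc`, `consensus`.
#' @param seed integer seed; the whole bundle is a pure function of
#'   (config, seed).
#' @return a `truth_bundle`: list with `reference`, `pwms` (named list,
#'   causal first), `em` ([expression_matrix]) and `truth`
#'   (`causal_tf_ids`, `planted_sites`, `true_de` = named signed log2 fold
#'   changes, `up_genes`, `down_genes`, `params`, `seed`).
#' @export
gen_truth_bundle <- function(config = list(), seed = 1L) {
  cfg <- .bundle_defaults()
  unknown <- setdiff(names(config), names(cfg))
  if (length(unknown))
    .err("unknown config keys: %s", paste(unknown, collapse = ", "))
  cfg[names(config)] <- config
  if (cfg$n_up + cfg$n_down > cfg$n_genes)
    .err("n_up + n_down exceeds n_genes")
  if (cfg$p_up < 0 || cfg$p_up > 1 || cfg$p_bg < 0 || cfg$p_bg > 1)
    .err("planting probabilities must lie in [0, 1]")
  if (cfg$causal_width > cfg$promoter_len)
    .err("causal motif wider than the promoter")
  set.seed(seed)
  ref <- gen_reference(cfg$n_genes, cfg$promoter_len, cfg$gc, cfg$gene_len)
  causal <- lapply(seq_len(cfg$n_causal), function(i)
    .sharp_pwm(cfg$causal_width, sprintf("CAUSAL%02d", i)))
  decoys <- lapply(seq_len(cfg$n_decoy), function(i)
    random_pwm(sample(6:14, 1L), sprintf("DECOY%02d", i)))
  pwms <- c(causal, decoys)
  names(pwms) <- vapply(pwms, function(p) p$matrix_id, character(1))
  ids <- ref$annotation$gene_id
  up_genes <- sort(sample(ids, cfg$n_up))
  down_genes <- sort(sample(setdiff(ids, up_genes), cfg$n_down))
  lfc <- c(stats::setNames(stats::runif(cfg$n_up, cfg$lfc_up[1],
                                        cfg$lfc_up[2]), up_genes),
           stats::setNames(-stats::runif(cfg$n_down, cfg$lfc_down[1],
                                         cfg$lfc_down[2]), down_genes))
  planted <- plant_motifs(ref, pwms,
                          causal_ids = names(pwms)[seq_len(cfg$n_causal)],
                          up_genes = up_genes, p_up = cfg$p_up,
                          p_bg = cfg$p_bg, consensus = cfg$consensus)
  sim <- simulate_counts(cfg$n_genes, true_lfc = lfc,
                         n_per_group = cfg$n_per_group,
                         dispersion = cfg$dispersion)
  structure(list(reference = planted$reference, pwms = pwms, em = sim$em,
                 truth = list(causal_tf_ids = planted$truth$causal_tf_ids,
                              planted_sites = planted$truth$planted_sites,
                              true_de = sim$truth$true_lfc,
                              up_genes = up_genes, down_genes = down_genes,
                              params = cfg, seed = seed)),
            class = "truth_bundle")
}

#' @export
print.truth_bundle <- function(x, ...) {
  cfg <- x$truth$params
  cat(sprintf(paste0("truth_bundle: %d genes (%d up, %d down), %d causal + ",
                     "%d decoy PWMs, p_up=%.2f vs p_bg=%.2f, seed %d\n"),
              cfg$n_genes, cfg$n_up, cfg$n_down, cfg$n_causal, cfg$n_decoy,
              cfg$p_up, cfg$p_bg, x$truth$seed))
  invisible(x)
}

#' Write a truth bundle as pipeline input files
#'
#' Writes `genome.fa`, `genes.bed` (BED6), `matrices.transfac`,
#' `counts.tsv`, `gene_lengths.tsv`, `samples.tsv` and `truth.json` into
#' `dir`, all in the formats the pipeline stages read.
#'
#' @param bundle a `truth_bundle`.
#' @param dir output directory (created if absent).
#' @return invisibly, the named vector of file paths.
#' @export
write_truth_bundle <- function(bundle, dir) {
  stopifnot(inherits(bundle, "truth_bundle"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(genome = file.path(dir, "genome.fa"),
             annotation = file.path(dir, "genes.bed"),
             transfac = file.path(dir, "matrices.transfac"),
             counts = file.path(dir, "counts.tsv"),
             gene_lengths = file.path(dir, "gene_lengths.tsv"),
             samples = file.path(dir, "samples.tsv"),
             truth = file.path(dir, "truth.json"))
  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(bundle$reference$genome), paths["genome"])
  ann <- bundle$reference$annotation
  utils::write.table(
    data.frame(ann$chrom, ann$start, ann$end, ann$gene_id, 0L, ann$strand),
    paths["annotation"], sep = "\t", quote = FALSE,
    row.names = FALSE, col.names = FALSE)
  write_transfac(bundle$pwms, paths["transfac"])
  counts <- data.frame(gene_id = rownames(bundle$em$counts),
                       bundle$em$counts, check.names = FALSE)
  .write_tsv(counts, paths["counts"])
  .write_tsv(data.frame(gene_id = names(bundle$em$gene_lengths),
                        length = unname(bundle$em$gene_lengths)),
             paths["gene_lengths"])
  .write_tsv(data.frame(sample = names(bundle$em$groups),
                        group = unname(bundle$em$groups)),
             paths["samples"])
  truth <- bundle$truth
  truth$true_de <- as.list(truth$true_de[truth$true_de != 0])
  jsonlite::write_json(truth, paths["truth"], auto_unbox = TRUE,
                       digits = NA, dataframe = "columns")
  invisible(paths)
}
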