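# Orchestration: a flat key-value config drives the stage sequence
# quantify -> DE classify -> cluster -> promoters -> scan -> enrich ->
# report, each stage writing its outputs before the next starts.

.config_defaults <- function() {
  list(
    # input paths
    counts = NULL, sample_sheet = NULL, gene_lengths = NULL,
    genome_fasta = NULL, annotation = NULL, transfac = NULL,
    de_table = NULL, qpcr = NULL, outdir = "tfbsflow_out",
    panel_genes = NULL, presence_genes = NULL,
    # thresholds
    fc_threshold = 2, alpha = 0.05, relative_score = 0.9,
    upstream_bp = 1000L, fpkm_cutoff = 1,
    # mode flags
    enrich_on = "padj",       # "padj" or "raw"
    both_strands = TRUE,
    include_down = FALSE,     # enrich the down-set too
    ref_group = NULL,
    seed = 1L)
}

#' Assemble and validate a pipeline configuration
#'
#' A flat key-value configuration; unknown keys are rejected and thresholds
#' must lie in their documented ranges (`fc_threshold >= 1`, `alpha` and
#' `relative_score` in `[0, 1]`, `upstream_bp >= 1`).
#'
#' @param ... configuration entries (see [run_pipeline] for the paths and
#'   thresholds each stage uses).
#' @return a validated `pipeline_config` list.
#' @export
pipeline_config <- function(...) {
  cfg <- .config_defaults()
  user <- list(...)
  if (length(user) == 1L && is.null(names(user)) && is.list(user[[1]]))
    user <- user[[1]]
  unknown <- setdiff(names(user), names(cfg))
  if (length(unknown))
    .err("unknown config keys: %s", paste(unknown, collapse = ", "))
  cfg[names(user)] <- user
  if (cfg$fc_threshold < 1) .err("fc_threshold must be >= 1")
  if (cfg$alpha <= 0 || cfg$alpha >= 1) .err("alpha must be in (0, 1)")
  if (cfg$relative_score < 0 || cfg$relative_score > 1)
    .err("relative_score must be in [0, 1]")
  if (cfg$upstream_bp < 1) .err("upstream_bp must be >= 1")
  if (!cfg$enrich_on %in% c("padj", "raw"))
    .err("enrich_on must be 'padj' or 'raw'")
  class(cfg) <- "pipeline_config"
  cfg
}

#' Read a pipeline configuration from a YAML file
#'
#' The file is a flat key-value document; entries in `overrides` (e.g.
#' parsed command-line flags) take precedence over file values.
#'
#' @param file path to a YAML config.
#' @param overrides named list of overriding entries.
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(file, overrides = list()) {
  cfg <- yaml::read_yaml(file)
  if (!is.list(cfg)) .err("config file must be a key-value mapping")
  cfg[names(overrides)] <- overrides
  do.call(pipeline_config, cfg)
}

#' Read a counts TSV, sample sheet and gene lengths into an expression matrix
#'
#' @param counts TSV with a `gene_id` column plus one column per sample.
#' @param sample_sheet TSV with columns `sample`, `group`.
#' @param gene_lengths TSV with columns `gene_id`, `length`.
#' @return an [expression_matrix].
#' @export
read_expression_inputs <- function(counts, sample_sheet, gene_lengths) {
  cts <- .read_tsv(counts)
  if (!"gene_id" %in% names(cts)) .err("counts TSV needs a gene_id column")
  m <- as.matrix(cts[, setdiff(names(cts), "gene_id"), drop = FALSE])
  rownames(m) <- cts$gene_id
  ss <- .read_tsv(sample_sheet)
  if (!all(c("sample", "group") %in% names(ss)))
    .err("sample sheet needs columns sample, group")
  gl <- .read_tsv(gene_lengths)
  if (!all(c("gene_id", "length") %in% names(gl)))
    .err("gene length table needs columns gene_id, length")
  expression_matrix(m, stats::setNames(gl$length, gl$gene_id),
                    stats::setNames(ss$group, ss$sample))
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    .err("pipeline stage '%s' failed: %s", name, conditionMessage(e)))
}

#' Run the full TFBS enrichment pipeline
#'
#' Executes, in order: FPKM quantification; differential-expression testing
#' (internal NB test, or an external DE table if `de_table` is configured)
#' and fold-change/adjusted-p classification; sample clustering; promoter
#' extraction; PWM scanning of all promoters; hypergeometric TFBS
#' enrichment of the up-regulated genes against all promoter-bearing genes;
#' and the final report. Every stage writes its outputs into
#' `config$outdir` before the next stage starts; with fixed inputs and
#' config the run is deterministic.
#'
#' @param config a `pipeline_config` (see [pipeline_config]).
#' @param dry_run print the stage DAG and return without computing.
#' @return invisibly, a list with the per-stage results (`em`, `fpkm`,
#'   `de`, `cluster`, `promoters`, `site_map`, `enrichment`, `report`,
#'   `outputs` = named file paths).
#' @export
run_pipeline <- function(config, dry_run = FALSE) {
  if (!inherits(config, "pipeline_config"))
    config <- do.call(pipeline_config, config)
  dag <- c(quantify = "counts + sample_sheet + gene_lengths -> fpkm.tsv",
           de = "counts (or de_table) -> de_results.tsv",
           cluster = "fpkm.tsv -> cluster.newick + cluster_merges.tsv",
           promoters = "genome_fasta + annotation -> promoters.fa/.bed",
           scan = "promoters.fa + transfac -> site_map.tsv + hits.tsv",
           enrich = "de_results + site_map -> enrichment.tsv",
           report = "all stage outputs -> report.txt")
  if (dry_run) {
    cat(paste(sprintf("%-10s %s", names(dag), dag), collapse = "\n"), "\n")
    return(invisible(dag))
  }
  for (p in c("counts", "sample_sheet", "gene_lengths", "genome_fasta",
              "annotation", "transfac")) {
    if (is.null(config[[p]])) .err("config is missing required path '%s'", p)
    if (!file.exists(config[[p]]))
      .err("input '%s' does not exist: %s", p, config[[p]])
  }
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  out <- function(f) file.path(config$outdir, f)
  outputs <- c()
  yaml::write_yaml(unclass(config)[!vapply(config, is.null, logical(1))],
                   out("config_used.yaml"))

  # quantify
  em <- .stage("quantify", read_expression_inputs(
    config$counts, config$sample_sheet, config$gene_lengths))
  fpkm <- .stage("quantify", compute_fpkm(em))
  .write_tsv(data.frame(gene_id = rownames(fpkm), fpkm,
                        check.names = FALSE), out("fpkm.tsv"))
  outputs["fpkm"] <- out("fpkm.tsv")

  # differential expression
  de_tab <- .stage("de", {
    if (!is.null(config$de_table)) read_de_table(config$de_table)
    else nb_de_test(em, ref_level = config$ref_group)
  })
  de <- .stage("de", classify_de(de_tab, config$fc_threshold, config$alpha))
  .write_tsv(de$table, out("de_results.tsv"))
  outputs["de"] <- out("de_results.tsv")

  # clustering
  cl <- .stage("cluster", hcluster(fpkm))
  writeLines(cluster_newick(cl), out("cluster.newick"))
  .write_tsv(cluster_merge_table(cl), out("cluster_merges.tsv"))
  outputs["cluster"] <- out("cluster.newick")

  # promoters
  promoters <- .stage("promoters", {
    ann <- read_annotation(config$annotation)
    extract_promoters(config$genome_fasta, select_tss(ann),
                      config$upstream_bp)
  })
  write_promoters_fasta(promoters, out("promoters.fa"))
  write_promoters_bed(promoters, out("promoters.bed"))
  outputs["promoters"] <- out("promoters.fa")

  # scan
  pwms <- .stage("scan", parse_transfac(config$transfac))
  site_map <- .stage("scan", build_site_map(
    pwms, promoters, config$relative_score, config$both_strands))
  sm <- data.frame(
    matrix_id = rep(names(site_map), lengths(site_map)),
    gene_id = unlist(site_map, use.names = FALSE))
  .write_tsv(sm, out("site_map.tsv"))
  outputs["site_map"] <- out("site_map.tsv")

  # enrich
  tf_names <- stats::setNames(vapply(pwms, function(p) p$tf_name,
                                     character(1)),
                              vapply(pwms, function(p) p$matrix_id,
                                     character(1)))
  background <- promoters$gene_id
  up <- intersect(de$table$gene_id[de$table$status == "up"], background)
  enr <- NULL
  if (de$summary$n_total > 0 && length(up) > 0) {
    enr <- .stage("enrich", enrich_tfs(
      up, background, site_map, alpha = config$alpha,
      adjust = config$enrich_on == "padj", tf_names = tf_names))
    .write_tsv(as.data.frame(enr), out("enrichment.tsv"))
    outputs["enrichment"] <- out("enrichment.tsv")
  }
  enr_down <- NULL
  if (config$include_down) {
    dn <- intersect(de$table$gene_id[de$table$status == "down"], background)
    if (length(dn)) {
      enr_down <- .stage("enrich", enrich_tfs(
        dn, background, site_map, alpha = config$alpha,
        adjust = config$enrich_on == "padj", tf_names = tf_names))
      .write_tsv(as.data.frame(enr_down), out("enrichment_down.tsv"))
    }
  }

  # presence calls / panel verdict
  presence <- NULL
  if (!is.null(config$presence_genes))
    presence <- presence_call(fpkm, em$groups, config$presence_genes,
                              config$fpkm_cutoff)
  panel <- NULL
  if (!is.null(config$panel_genes)) {
    panel <- panel_flag(de$table, config$panel_genes,
                        config$fc_threshold, config$alpha)
    .write_tsv(panel$table, out("panel_report.tsv"))
  }

  report <- .stage("report", write_report(
    de = de, cluster = cl, enrichment = enr, panel = panel,
    presence = presence, file = out("report.txt")))
  outputs["report"] <- out("report.txt")

  invisible(list(config = config, em = em, fpkm = fpkm, de = de,
                 cluster = cl, promoters = promoters, site_map = site_map,
                 enrichment = enr, enrichment_down = enr_down,
                 panel = panel, presence = presence, report = report,
                 outputs = outputs))
}

#' Write the human-readable pipeline report
#'
#' Summarises the differential-expression counts (total, up, down, percent
#' up), fold-change ranges per direction, the sample cluster tree, the top
#' enriched transcription factors with their contingency counts, the
#' pathway-panel verdict and the presence calls.
#'
#' @param de a `de_result` from [classify_de].
#' @param cluster optional `hclust` from [hcluster].
#' @param enrichment optional `enrichment_result` from [enrich_tfs].
#' @param panel optional result of [panel_flag].
#' @param presence optional result of [presence_call].
#' @param file optional output path.
#' @return character vector of report lines (invisibly if `file` given).
#' @export
write_report <- function(de, cluster = NULL, enrichment = NULL,
                         panel = NULL, presence = NULL, file = NULL) {
  s <- de$summary
  lines <- c("== Differential expression ==",
             sprintf("total DE genes: %d", s$n_total),
             sprintf("up-regulated: %d (%.1f%%)", s$n_up, s$pct_up),
             sprintf("down-regulated: %d", s$n_down))
  tab <- de$table
  for (dir in c("up", "down")) {
    fc <- tab$fc[tab$status == dir]
    if (length(fc))
      lines <- c(lines, sprintf("fold-change range (%s): %.1f-%.1f",
                                dir, min(fc), max(fc)))
  }
  if (!is.null(cluster))
    lines <- c(lines, "", "== Sample clustering (Newick) ==",
               cluster_newick(cluster))
  lines <- c(lines, "", "== TFBS enrichment ==")
  if (is.null(enrichment)) {
    lines <- c(lines, paste("no enrichment performed: no up-regulated",
                            "genes passed the DE criteria"))
  } else {
    top <- utils::head(as.data.frame(enrichment), 10L)
    lines <- c(lines,
               sprintf("%d matrices tested, %d significant",
                       nrow(enrichment), sum(enrichment$significant)),
               sprintf(
                 "%-12s %-12s k=%d/n=%d K=%d/N=%d pct_up=%.1f pct_bg=%.1f p=%.3g padj=%.3g%s",
                 top$matrix_id, top$tf_name, top$k, top$n, top$K, top$N,
                 top$pct_up, top$pct_bg, top$p, top$padj,
                 ifelse(top$significant, " *", "")))
  }
  if (!is.null(panel))
    lines <- c(lines, "", "== Pathway panel ==",
               sprintf("verdict: %s", panel$verdict),
               sprintf("%s: %s", panel$table$gene_id, panel$table$status))
  if (!is.null(presence))
    lines <- c(lines, "", "== Presence calls ==",
               sprintf("%s [%s]: mean FPKM %.2f -> %s",
                       presence$gene_id, presence$group, presence$mean_fpkm,
                       ifelse(presence$present, "present", "absent")))
  if (!is.null(file)) {
    writeLines(lines, file)
    return(invisible(lines))
  }
  lines
}
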