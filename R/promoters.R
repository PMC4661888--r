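#' Read a gene annotation as a transcript table
#'
#' Accepts GTF (1-based, converted on read) or BED6 (0-based) and returns a
#' transcript-level table in the package's internal convention: 0-based
#' half-open coordinates.
#'
#' @param file path to a `.gtf`/`.gff` or `.bed` file.
#' @param format `"auto"` (by extension), `"gtf"` or `"bed"`.
#' @return data.frame with columns `gene_id`, `chrom`, `start`, `end`
#'   (0-based half-open), `strand`.
#' @export
read_annotation <- function(file, format = c("auto", "gtf", "bed")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.bed$", file, ignore.case = TRUE)) "bed" else "gtf"
  if (format == "bed") {
    gr <- rtracklayer::import(file, format = "BED")
    data.frame(gene_id = gr$name,
               chrom = as.character(GenomeInfoDb::seqnames(gr)),
               start = BiocGenerics::start(gr) - 1L,
               end = BiocGenerics::end(gr),
               strand = as.character(BiocGenerics::strand(gr)),
               stringsAsFactors = FALSE)
  } else {
    gr <- rtracklayer::import(file, format = "GTF")
    keep <- if ("type" %in% names(S4Vectors::mcols(gr)))
      gr$type %in% c("transcript", "mRNA") else rep(TRUE, length(gr))
    if (!any(keep)) keep <- rep(TRUE, length(gr))  # bare exon-only files
    gr <- gr[keep]
    data.frame(gene_id = gr$gene_id,
               chrom = as.character(GenomeInfoDb::seqnames(gr)),
               start = BiocGenerics::start(gr) - 1L,
               end = BiocGenerics::end(gr),
               strand = as.character(BiocGenerics::strand(gr)),
               stringsAsFactors = FALSE)
  }
}

#' Collapse transcripts to one TSS per gene
#'
#' The gene-level TSS is the 5'-most transcript start: the minimum start for
#' `+` genes and the maximum end for `-` genes (reported as the 0-based
#' position of the last base). Genes whose transcripts sit on conflicting
#' strands are skipped with a warning.
#'
#' @param annotation a transcript table as returned by [read_annotation]
#'   (columns `gene_id`, `chrom`, `start`, `end`, `strand`; 0-based
#'   half-open).
#' @return data.frame with columns `gene_id`, `chrom`, `tss` (0-based
#'   position of the first transcribed base), `strand`.
#' @export
select_tss <- function(annotation) {
  need <- c("gene_id", "chrom", "start", "end", "strand")
  miss <- setdiff(need, names(annotation))
  if (length(miss))
    .err("annotation lacks columns: %s", paste(miss, collapse = ", "))
  if (!all(annotation$strand %in% c("+", "-")))
    .err("annotation strand must be '+' or '-'")
  parts <- split(annotation, annotation$gene_id)
  rows <- lapply(parts, function(d) {
    if (length(unique(d$strand)) > 1L) {
      .warnf("gene '%s' has transcripts on conflicting strands; skipped",
             d$gene_id[1])
      return(NULL)
    }
    if (length(unique(d$chrom)) > 1L) {
      .warnf("gene '%s' spans multiple contigs; skipped", d$gene_id[1])
      return(NULL)
    }
    s <- d$strand[1]
    data.frame(gene_id = d$gene_id[1], chrom = d$chrom[1],
               tss = if (s == "+") min(d$start) else max(d$end) - 1L,
               strand = s, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(gene_id = character(0), chrom = character(0),
                      tss = integer(0), strand = character(0))
  # restore annotation order of first appearance
  out <- out[order(match(out$gene_id, annotation$gene_id)), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Extract strand-aware upstream promoter sequences
#'
#' For each gene the `upstream_bp` bases immediately 5' of the TSS are
#' extracted, excluding the TSS base itself: a `+` gene with TSS `t` yields
#' the genomic interval `[t - upstream_bp, t)` as-is, a `-` gene the
#' interval `[t + 1, t + 1 + upstream_bp)` reverse-complemented, so the
#' returned sequence always reads 5' to 3' towards the gene. Intervals are
#' clipped at contig edges (flagged); genes whose promoter clips to zero
#' length are dropped with a warning.
#'
#' @param genome a named `DNAStringSet`, a named character vector of contig
#'   sequences, or the path to a FASTA file.
#' @param tss_map data.frame from [select_tss].
#' @param upstream_bp promoter length in bp (default 1000).
#' @return a `promoter_set`: data.frame with columns `gene_id`, `chrom`,
#'   `start`, `end` (0-based half-open genomic interval), `strand`,
#'   `clipped`, `sequence` (uppercase).
#' @export
extract_promoters <- function(genome, tss_map, upstream_bp = 1000L) {
  stopifnot(upstream_bp >= 1L)
  if (is.character(genome) && length(genome) == 1L && file.exists(genome))
    genome <- Biostrings::readDNAStringSet(genome)
  if (is.character(genome))
    genome <- Biostrings::DNAStringSet(toupper(genome))
  # FASTA headers may carry descriptions; keep the first word
  names(genome) <- sub("\\s.*$", "", names(genome))
  missing_chr <- setdiff(unique(tss_map$chrom), names(genome))
  if (length(missing_chr))
    .err("contig(s) absent from the genome FASTA: %s",
         paste(missing_chr, collapse = ", "))
  clen <- stats::setNames(Biostrings::width(genome), names(genome))[tss_map$chrom]
  plus <- tss_map$strand == "+"
  start <- ifelse(plus, tss_map$tss - upstream_bp, tss_map$tss + 1L)
  end <- ifelse(plus, tss_map$tss, tss_map$tss + 1L + upstream_bp)
  start_c <- pmax(start, 0L)
  end_c <- pmin(end, clen)
  clipped <- (start_c != start) | (end_c != end)
  keep <- end_c > start_c
  if (any(!keep))
    .warnf("%d gene(s) dropped: promoter clipped to zero length",
           sum(!keep))
  idx <- which(keep)
  seqs <- character(length(idx))
  for (chr in unique(tss_map$chrom[idx])) {
    ii <- idx[tss_map$chrom[idx] == chr]
    v <- Biostrings::Views(genome[[chr]], start = start_c[ii] + 1L,
                           end = end_c[ii])
    seqs[match(ii, idx)] <- toupper(as.character(v))
  }
  minus <- tss_map$strand[idx] == "-"
  if (any(minus))
    seqs[minus] <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAStringSet(seqs[minus])))
  out <- data.frame(gene_id = tss_map$gene_id[idx],
                    chrom = tss_map$chrom[idx],
                    start = as.integer(start_c[idx]),
                    end = as.integer(end_c[idx]),
                    strand = tss_map$strand[idx],
                    clipped = clipped[idx],
                    sequence = seqs,
                    stringsAsFactors = FALSE)
  if (anyDuplicated(out$gene_id))
    .err("duplicate gene ids in TSS map: %s",
         paste(unique(out$gene_id[duplicated(out$gene_id)]), collapse = ", "))
  rownames(out) <- NULL
  class(out) <- c("promoter_set", "data.frame")
  out
}

#' Write a promoter set as FASTA
#'
#' Headers follow `gene_id|chrom:start-end|strand` (0-based half-open).
#' @param promoters a `promoter_set`.
#' @param file output FASTA path.
#' @export
write_promoters_fasta <- function(promoters, file) {
  hdr <- sprintf("%s|%s:%d-%d|%s", promoters$gene_id, promoters$chrom,
                 promoters$start, promoters$end, promoters$strand)
  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(stats::setNames(promoters$sequence, hdr)), file)
  invisible(file)
}

#' Write promoter intervals as BED6
#' @param promoters a `promoter_set`.
#' @param file output BED path.
#' @export
write_promoters_bed <- function(promoters, file) {
  bed <- data.frame(promoters$chrom, promoters$start, promoters$end,
                    promoters$gene_id, 0L, promoters$strand)
  utils::write.table(bed, file, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(file)
}
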