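#' Position weight matrices in the TRANSFAC dialect
#'
#' A `pwm` object holds a transcription factor's position count matrix over
#' the DNA alphabet together with the pseudocount and background model used
#' to turn counts into log2-odds scores. Window matches are reported on the
#' min-max *relative score* scale, `(raw - min) / (max - min)`, so a
#' threshold such as 0.9 is comparable across matrices of different widths
#' and information content.
#'
#' @param counts numeric matrix, width x 4, column order A, C, G, T;
#'   all cells must be non-negative and every row must have a positive
#'   total once the pseudocount is added.
#' @param matrix_id identifier of the matrix (TRANSFAC `ID`/`AC`).
#' @param tf_name transcription factor name (TRANSFAC `NA` line).
#' @param pseudocount non-negative number added to every cell before
#'   converting to probabilities (Laplace smoothing; default 1).
#' @param background length-4 vector of background base probabilities
#'   (A, C, G, T), strictly positive and summing to 1; default uniform.
#' @return an object of class `pwm`.
#' @examples
#' m <- pwm(rbind(c(8, 0, 0, 0), c(0, 8, 0, 0)), matrix_id = "M1")
#' relative_score(m, "AC")
#' @export
pwm <- function(counts, matrix_id = "PWM", tf_name = matrix_id,
                pseudocount = 1, background = rep(0.25, 4)) {
  counts <- as.matrix(counts)
  if (!is.numeric(counts) || ncol(counts) != 4L || nrow(counts) < 1L)
    .err("PWM counts must be a numeric matrix with >= 1 row and 4 columns (A,C,G,T)")
  if (any(!is.finite(counts)) || any(counts < 0))
    .err("PWM counts must be finite and non-negative")
  if (!is.numeric(pseudocount) || length(pseudocount) != 1L || pseudocount < 0)
    .err("pseudocount must be a single non-negative number")
  if (length(background) != 4L || any(background <= 0) ||
      abs(sum(background) - 1) > 1e-9)
    .err("background must be 4 positive probabilities summing to 1")
  if (any(rowSums(counts) + 4 * pseudocount <= 0))
    .err("every PWM row must have a positive total after pseudocount")
  dimnames(counts) <- list(NULL, .DNA_LETTERS)
  structure(
    list(matrix_id = as.character(matrix_id), tf_name = as.character(tf_name),
         counts = counts, pseudocount = pseudocount,
         background = as.numeric(background)),
    class = "pwm")
}

#' @export
print.pwm <- function(x, ...) {
  lo <- build_log_odds(x)
  cat(sprintf("PWM %s (%s): width %d, score range [%.3f, %.3f]\n",
              x$matrix_id, x$tf_name, pwm_width(x), lo$min_score, lo$max_score))
  print(round(x$counts, 3))
  invisible(x)
}

#' @rdname pwm
#' @param x a `pwm` object.
#' @export
pwm_width <- function(x) nrow(x$counts)

#' Consensus sequence of a PWM (highest-count letter per position)
#' @param x a `pwm` object.
#' @return character string of length `pwm_width(x)`.
#' @export
pwm_consensus <- function(x) {
  paste(.DNA_LETTERS[apply(x$counts, 1L, which.max)], collapse = "")
}

#' Per-position probability matrix of a PWM
#'
#' Counts plus pseudocount, normalised per row. Used both for scoring and
#' for sampling site instances in the synthetic-data generator.
#' @param x a `pwm` object.
#' @return width x 4 matrix of probabilities, rows summing to 1.
#' @export
pwm_probs <- function(x) {
  p <- x$counts + x$pseudocount
  p / rowSums(p)
}

#' Log2-odds table and score range of a PWM
#'
#' `lo[i, b] = log2(p[i, b] / background[b])` with
#' `p[i, b] = (counts[i, b] + pseudocount) / (rowtotal_i + 4 * pseudocount)`.
#' `max_score` (`min_score`) is the sum over positions of the per-position
#' maximum (minimum) log-odds; any window's raw score lies between them.
#'
#' @param x a `pwm` object.
#' @return list with `lo` (width x 4 matrix), `min_score`, `max_score`.
#' @export
build_log_odds <- function(x) {
  stopifnot(inherits(x, "pwm"))
  lo <- log2(pwm_probs(x)) - rep(log2(x$background), each = nrow(x$counts))
  list(lo = lo,
       min_score = sum(apply(lo, 1L, min)),
       max_score = sum(apply(lo, 1L, max)))
}

# Raw scores of every window of an encoded sequence (integer codes).
# Returns numeric vector of length L - w + 1 (length 0 if L < w); windows
# touching an NA code (non-ACGT base) score NA. Scoring runs in compiled
# code (see src/scan.cpp).
.window_scores <- function(lo, codes) {
  as.numeric(cpp_window_scores_batch(lo, matrix(as.integer(codes),
                                                ncol = 1L)))
}

# Batch variant: codes is an L x nseq integer matrix (pad ragged sets with
# NA); returns an (L - w + 1) x nseq matrix of raw scores.
.window_scores_batch <- function(lo, codes) {
  cpp_window_scores_batch(lo, codes)
}

# log-odds table for scoring the minus strand on the forward sequence:
# reverse position order and swap complementary columns.
.lo_revcomp <- function(lo) {
  lo[rev(seq_len(nrow(lo))), c(4L, 3L, 2L, 1L), drop = FALSE]
}

#' Min-max relative score of a single window
#'
#' `(raw - min_score) / (max_score - min_score)`, in `[0, 1]`; the consensus
#' window scores 1 and the anti-consensus 0. A degenerate matrix with
#' `max_score == min_score` scores every window 1. Windows containing a
#' non-ACGT letter are unscorable and return `NA`.
#'
#' @param x a `pwm` object.
#' @param window character string whose length equals the PWM width.
#' @return a number in `[0, 1]`, or `NA` for an unscorable window.
#' @export
relative_score <- function(x, window) {
  stopifnot(inherits(x, "pwm"))
  codes <- .encode_seq(window)
  w <- pwm_width(x)
  if (length(codes) != w)
    .err("window length (%d) does not match PWM width (%d)", length(codes), w)
  sc <- build_log_odds(x)
  if (sc$max_score == sc$min_score) return(1)
  raw <- sum(sc$lo[cbind(seq_len(w), codes)])
  (raw - sc$min_score) / (sc$max_score - sc$min_score)
}

.rel_from_raw <- function(raw, min_score, max_score) {
  if (max_score == min_score) return(rep(1, length(raw)))
  (raw - min_score) / (max_score - min_score)
}

#' Scan a sequence for PWM matches above a relative-score threshold
#'
#' Every window with relative score strictly above `threshold` is reported.
#' With `both_strands = TRUE` the reverse complement of each window is also
#' scored; minus-strand hits are reported at the window's offset on the
#' forward strand. Windows containing non-ACGT letters are skipped.
#'
#' @param x a `pwm` object.
#' @param seq a single DNA string.
#' @param threshold relative-score cutoff in `[0, 1]`; hits must exceed it
#'   strictly (default 0.9).
#' @param both_strands scan the minus strand too (default `TRUE`).
#' @param seq_id identifier copied into the hit table.
#' @return data.frame with columns `seq_id`, `offset` (0-based, forward
#'   strand), `strand`, `raw_score`, `relative_score`, sorted by offset then
#'   strand (`+` before `-`). Zero rows if the sequence is shorter than the
#'   matrix.
#' @export
scan_sequence <- function(x, seq, threshold = 0.9, both_strands = TRUE,
                          seq_id = "seq") {
  stopifnot(inherits(x, "pwm"))
  if (!is.numeric(threshold) || length(threshold) != 1L ||
      threshold < 0 || threshold > 1)
    .err("threshold must be a single number in [0, 1]")
  sc <- build_log_odds(x)
  codes <- .encode_seq(seq)
  empty <- data.frame(seq_id = character(0), offset = integer(0),
                      strand = character(0), raw_score = numeric(0),
                      relative_score = numeric(0), stringsAsFactors = FALSE)
  raw_p <- .window_scores(sc$lo, codes)
  if (length(raw_p) == 0L) return(empty)
  hits <- list()
  rel_p <- .rel_from_raw(raw_p, sc$min_score, sc$max_score)
  keep <- which(!is.na(rel_p) & rel_p > threshold)
  if (length(keep))
    hits[["+"]] <- data.frame(seq_id = seq_id, offset = keep - 1L,
                              strand = "+", raw_score = raw_p[keep],
                              relative_score = rel_p[keep],
                              stringsAsFactors = FALSE)
  if (both_strands) {
    raw_m <- .window_scores(.lo_revcomp(sc$lo), codes)
    rel_m <- .rel_from_raw(raw_m, sc$min_score, sc$max_score)
    keep <- which(!is.na(rel_m) & rel_m > threshold)
    if (length(keep))
      hits[["-"]] <- data.frame(seq_id = seq_id, offset = keep - 1L,
                                strand = "-", raw_score = raw_m[keep],
                                relative_score = rel_m[keep],
                                stringsAsFactors = FALSE)
  }
  if (!length(hits)) return(empty)
  out <- do.call(rbind, hits)
  out <- out[order(out$offset, match(out$strand, c("+", "-"))), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Genes whose promoter contains at least one PWM match
#'
#' @param x a `pwm` object.
#' @param promoters a [promoter_set] (or any data.frame with `gene_id` and
#'   `sequence` columns).
#' @param threshold relative-score cutoff, exceeded strictly.
#' @param both_strands scan both strands (default `TRUE`).
#' @return character vector of gene ids with >= 1 hit (annotation order).
#' @export
genes_with_site <- function(x, promoters, threshold = 0.9,
                            both_strands = TRUE) {
  if (nrow(promoters) == 0L) return(character(0))
  hit <- .site_indicator(list(x), promoters, threshold, both_strands)[1L, ]
  promoters$gene_id[hit]
}

# Indicator matrix (pwms x promoters) of "has >= 1 hit above threshold".
# Encodes the promoter set once and pads ragged sequences with NA codes,
# which the window scorer skips naturally.
.site_indicator <- function(pwms, promoters, threshold = 0.9,
                            both_strands = TRUE) {
  seqs <- promoters$sequence
  n <- length(seqs)
  lens <- nchar(seqs)
  L <- max(lens)
  codes <- matrix(NA_integer_, L, n)
  for (j in seq_len(n)) if (lens[j] > 0L)
    codes[seq_len(lens[j]), j] <- .encode_seq(seqs[j])
  out <- matrix(FALSE, length(pwms), n)
  for (i in seq_along(pwms)) {
    sc <- build_log_odds(pwms[[i]])
    if (sc$max_score == sc$min_score) {
      # every scorable window has relative score 1
      if (threshold < 1 && L >= nrow(sc$lo)) {
        raw <- .window_scores_batch(sc$lo, codes)
        out[i, ] <- apply(!is.na(raw), 2L, any)
      }
      next
    }
    thr_raw <- sc$min_score + threshold * (sc$max_score - sc$min_score)
    out[i, ] <- cpp_any_hit(sc$lo, .lo_revcomp(sc$lo), codes, thr_raw,
                            both_strands)
  }
  out
}

#' Map each PWM to the genes whose promoters it matches
#'
#' Batch version of [genes_with_site] over a list of matrices; this is the
#' scanning step of the TFBS enrichment workflow.
#'
#' @param pwms list of `pwm` objects.
#' @param promoters a [promoter_set].
#' @param threshold relative-score cutoff, exceeded strictly (default 0.9).
#' @param both_strands scan both strands (default `TRUE`).
#' @return named list, `matrix_id` -> character vector of gene ids.
#' @export
build_site_map <- function(pwms, promoters, threshold = 0.9,
                           both_strands = TRUE) {
  if (!length(pwms)) return(structure(list(), names = character(0)))
  ind <- .site_indicator(pwms, promoters, threshold, both_strands)
  out <- lapply(seq_along(pwms), function(i) promoters$gene_id[ind[i, ]])
  names(out) <- vapply(pwms, function(p) p$matrix_id, character(1))
  out
}

#' Scan a promoter set and return the full hit table
#'
#' @inheritParams build_site_map
#' @return data.frame with columns `seq_id`, `offset`, `strand`,
#'   `raw_score`, `relative_score`, `matrix_id`.
#' @export
scan_promoters <- function(pwms, promoters, threshold = 0.9,
                           both_strands = TRUE) {
  res <- lapply(pwms, function(p) {
    per_seq <- lapply(seq_len(nrow(promoters)), function(j)
      scan_sequence(p, promoters$sequence[j], threshold, both_strands,
                    seq_id = promoters$gene_id[j]))
    tab <- do.call(rbind, per_seq)
    if (!is.null(tab) && nrow(tab)) tab$matrix_id <- p$matrix_id
    tab
  })
  out <- do.call(rbind, res)
  if (is.null(out))
    out <- data.frame(seq_id = character(0), offset = integer(0),
                      strand = character(0), raw_score = numeric(0),
                      relative_score = numeric(0), matrix_id = character(0),
                      stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}
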