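# Internal helpers shared across modules.

# DNA letter -> integer code (A=1, C=2, G=3, T=4); anything else NA.
.DNA_CODE <- local({
  x <- rep(NA_integer_, 127L)
  x[utf8ToInt("A")] <- 1L; x[utf8ToInt("a")] <- 1L
  x[utf8ToInt("C")] <- 2L; x[utf8ToInt("c")] <- 2L
  x[utf8ToInt("G")] <- 3L; x[utf8ToInt("g")] <- 3L
  x[utf8ToInt("T")] <- 4L; x[utf8ToInt("t")] <- 4L
  x
})

.DNA_LETTERS <- c("A", "C", "G", "T")

#' Encode a DNA string as integer codes
#'
#' A/C/G/T (case-insensitive) map to 1:4; any other letter becomes `NA`,
#' which downstream scanning treats as unscorable.
#' @param seq a single character string.
#' @return integer vector, one code per base.
#' @keywords internal
.encode_seq <- function(seq) {
  stopifnot(is.character(seq), length(seq) == 1L)
  if (nchar(seq) == 0L) return(integer(0))
  .DNA_CODE[utf8ToInt(seq)]
}

.decode_seq <- function(codes) {
  paste(.DNA_LETTERS[codes], collapse = "")
}

#' Reverse-complement a DNA string
#' @param seq character vector of sequences.
#' @return character vector of reverse complements (case preserved per base).
#' @keywords internal
.revcomp <- function(seq) {
  vapply(seq, function(s) {
    if (nchar(s) == 0L) return("")
    intToUtf8(rev(utf8ToInt(chartr("ACGTacgtNn", "TGCAtgcaNn", s))))
  }, character(1), USE.NAMES = FALSE)
}

# stop() without the call, with sprintf-style formatting
.err <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

.warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

# Write a data.frame as TSV (no quoting, no row names).
.write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

.read_tsv <- function(path, ...) {
  utils::read.table(path, header = TRUE, sep = "\t", quote = "",
                    stringsAsFactors = FALSE, check.names = FALSE, ...)
}
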