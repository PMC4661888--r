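#' Parse TRANSFAC-format matrix records
#'
#' Reads the TRANSFAC flat-file matrix dialect: records separated by `//`,
#' with `ID`/`AC`/`NA` metadata lines, a `P0  A  C  G  T` column header and
#' numbered count rows (an optional trailing consensus letter per row is
#' ignored), terminated by `//`. Unknown tags are skipped.
#'
#' @param file path to a TRANSFAC matrix file, or a character vector of
#'   lines (anything of length > 1, or containing a newline, is treated as
#'   text rather than a path).
#' @param pseudocount,background passed to [pwm] for every record.
#' @return list of [pwm] objects, one per record.
#' @export
parse_transfac <- function(file, pseudocount = 1, background = rep(0.25, 4)) {
  lines <- if (length(file) == 0L) {
    character(0)
  } else if (length(file) > 1L || any(grepl("\n", file))) {
    unlist(strsplit(file, "\n", fixed = TRUE))
  } else if (file.exists(file)) {
    readLines(file, warn = FALSE)
  } else {
    unlist(strsplit(file, "\n", fixed = TRUE))
  }
  pwms <- list()
  id <- ac <- name <- NULL
  rows <- list()
  in_record <- FALSE
  flush <- function() {
    if (!length(rows))
      .err("TRANSFAC record '%s' has zero matrix positions",
           if (is.null(id)) if (is.null(ac)) "?" else ac else id)
    counts <- do.call(rbind, rows)
    mid <- if (!is.null(ac)) ac else if (!is.null(id)) id else
      sprintf("M%05d", length(pwms) + 1L)
    pwm(counts, matrix_id = mid,
        tf_name = if (is.null(name)) mid else name,
        pseudocount = pseudocount, background = background)
  }
  for (i in seq_along(lines)) {
    line <- lines[i]
    if (!nzchar(trimws(line))) next
    tag <- substr(line, 1L, 2L)
    rest <- trimws(substr(line, 3L, nchar(line)))
    if (tag == "//") {
      if (in_record) {
        pwms[[length(pwms) + 1L]] <- flush()
        id <- ac <- name <- NULL; rows <- list(); in_record <- FALSE
      }
      next
    }
    if (tag == "ID") { id <- rest; in_record <- TRUE; next }
    if (tag == "AC") { ac <- rest; in_record <- TRUE; next }
    if (tag == "NA") { name <- rest; in_record <- TRUE; next }
    if (tag %in% c("P0", "PO")) { in_record <- TRUE; next }
    if (grepl("^[0-9]", tag)) {
      fields <- strsplit(trimws(line), "[[:space:]]+")[[1]]
      vals <- suppressWarnings(as.numeric(fields[-1]))
      # drop one trailing non-numeric consensus symbol if present
      if (length(vals) == 5L && is.na(vals[5L]) && !is.na(fields[2L]))
        vals <- vals[1:4]
      if (length(vals) != 4L || anyNA(vals))
        .err("malformed TRANSFAC position row at line %d: '%s'", i, line)
      rows[[length(rows) + 1L]] <- vals
      in_record <- TRUE
      next
    }
    # any other tag (XX, BF, DE, ...) is metadata we ignore
  }
  if (in_record)
    .err("TRANSFAC stream ends inside a record: missing '//' terminator")
  pwms
}

#' Write PWMs as a TRANSFAC-format matrix file
#'
#' Inverse of [parse_transfac]: counts are written at full precision, so a
#' parse/write round trip preserves them exactly.
#'
#' @param pwms list of [pwm] objects.
#' @param file output path (or `""` to return the text invisibly only).
#' @return invisibly, the character vector of lines written.
#' @export
write_transfac <- function(pwms, file = "") {
  fmt_num <- function(x) {
    ifelse(x == round(x), format(x, scientific = FALSE, trim = TRUE),
           format(x, digits = 15, scientific = FALSE, trim = TRUE))
  }
  lines <- unlist(lapply(pwms, function(p) {
    body <- vapply(seq_len(pwm_width(p)), function(i)
      paste0(sprintf("%02d", i), "  ",
             paste(fmt_num(p$counts[i, ]), collapse = "  ")),
      character(1))
    c(paste0("ID  ", p$matrix_id),
      paste0("AC  ", p$matrix_id),
      paste0("NA  ", p$tf_name),
      "P0      A      C      G      T",
      body, "XX", "//")
  }))
  if (nzchar(file)) writeLines(lines, file)
  invisible(lines)
}
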