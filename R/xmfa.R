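# XMFA (extended multi-FASTA): one aligned block per locus, blocks
# terminated by "=" lines. Headers follow "> isolate:start-end strand locus"
# with 1-based inclusive coordinates over the ungapped sequence; the strand
# field is always "+" because alleles are stored on the coding strand.

#' Write alignments as XMFA
#'
#' @param alignments Named list of `locus_alignment`s.
#' @param path Output file.
#' @param width Line-wrap width for sequence lines.
#' @export
write_xmfa <- function(alignments, path, width = 80L) {
  con <- file(path, "w")
  on.exit(close(con))
  for (a in alignments) {
    for (nm in names(a$rows)) {
      row <- a$rows[[nm]]
      ungapped <- nchar(degap(row))
      cat(sprintf("> %s:1-%d + %s\n", nm, ungapped, a$locus), file = con)
      starts <- seq(1L, nchar(row), by = width)
      writeLines(substring(row, starts, pmin(starts + width - 1L, nchar(row))),
                 con)
    }
    cat("=\n", file = con)
  }
  invisible(path)
}

#' Read an XMFA file
#'
#' Inverse of [write_xmfa()]; malformed headers or unterminated blocks are
#' errors reporting the offending line number.
#'
#' @param path XMFA file.
#' @return Named list of `locus_alignment`s (names taken from the locus
#'   field of each block's headers).
#' @export
read_xmfa <- function(path) {
  lines <- readLines(path)
  blocks <- list()
  cur_names <- character(0)
  cur_seqs <- character(0)
  cur_locus <- NULL
  seq_buf <- character(0)
  pending <- NULL

  flush_record <- function() {
    if (is.null(pending)) return(invisible(NULL))
    cur_names <<- c(cur_names, pending$isolate)
    cur_seqs <<- c(cur_seqs, paste(seq_buf, collapse = ""))
    seq_buf <<- character(0)
    pending <<- NULL
  }

  for (i in seq_along(lines)) {
    line <- trimws(lines[i])
    if (!nzchar(line)) next
    if (line == "=") {
      flush_record()
      if (length(cur_names) == 0L)
        stop("empty XMFA block ending at line ", i)
      w <- unique(nchar(cur_seqs))
      if (length(w) != 1L)
        stop("unequal row lengths in block ending at line ", i)
      blocks[[cur_locus]] <- .locus_alignment(
        cur_locus, stats::setNames(cur_seqs, cur_names))
      cur_names <- character(0); cur_seqs <- character(0); cur_locus <- NULL
    } else if (startsWith(line, ">")) {
      flush_record()
      m <- regmatches(line,
        regexec("^>\\s*(\\S+):(\\d+)-(\\d+)\\s+([+-])\\s+(\\S+)\\s*$", line))[[1]]
      if (length(m) == 0L)
        stop("malformed XMFA header at line ", i, ": ", line)
      pending <- list(isolate = m[2], locus = m[6])
      if (is.null(cur_locus)) cur_locus <- m[6]
      else if (cur_locus != m[6])
        stop("mixed loci within one block at line ", i)
    } else {
      if (is.null(pending))
        stop("sequence data outside any record at line ", i)
      if (grepl("[^A-Za-z*-]", line))
        stop("invalid sequence characters at line ", i)
      seq_buf <- c(seq_buf, toupper(line))
    }
  }
  if (!is.null(pending) || length(cur_names) > 0L)
    stop("unterminated XMFA block at end of file (missing '=' separator)")
  blocks
}
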