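# FASTA plumbing. Sequences travel through the package as named character
# vectors; Biostrings does the parsing so the usual edge cases (wrapped
# lines, CRLF, trailing whitespace) are someone else's solved problem.

#' Read a (multi-)FASTA file into a named character vector
#' @param path FASTA file.
#' @return Named character vector of uppercase sequences; names are the
#'   first whitespace-delimited token of each header.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  set <- tryCatch(Biostrings::readBStringSet(path),
                  error = function(e) stop("FASTA parse error in ", path, ": ",
                                           conditionMessage(e)))
  seqs <- toupper(as.character(set))
  names(seqs) <- vapply(strsplit(names(set), "[ \t]"), `[`, character(1), 1L)
  seqs
}

#' Write a named character vector as FASTA
#' @param seqs Named character vector of sequences.
#' @param path Output file.
#' @param width Line-wrap width.
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(seqs)) {
    cat(">", names(seqs)[i], "\n", sep = "", file = con)
    s <- seqs[[i]]
    n <- nchar(s)
    if (n == 0L) next
    starts <- seq(1L, n, by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, n)), con)
  }
  invisible(path)
}
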