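# Locus catalogue: which loci make up a typing scheme and what coding-sequence
# lengths are plausible at each. The default catalogue lists the 53
# ribosomal-protein (rps) loci conventionally used for rMLST: the small-subunit
# genes rpsB..rpsU, the large-subunit genes rplA..rplY and rpmA..rpmJ.

#' Read a scheme catalogue
#'
#' A scheme is a tab-separated file with columns `locus`, `min_len`, `max_len`
#' (expected coding-sequence length range in bp, inclusive).
#'
#' @param path Path to the TSV file.
#' @return A `data.frame` with columns `locus` (character), `min_len`,
#'   `max_len` (integer), one row per locus.
#' @export
read_scheme <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  req <- c("locus", "min_len", "max_len")
  if (!all(req %in% names(df)))
    stop("scheme file must have columns: ", paste(req, collapse = ", "))
  df <- df[, req]
  df$min_len <- as.integer(df$min_len)
  df$max_len <- as.integer(df$max_len)
  validate_scheme(df)
  df
}

#' Write a scheme catalogue
#' @param scheme Scheme `data.frame` as returned by [read_scheme()].
#' @param path Output path.
#' @export
write_scheme <- function(scheme, path) {
  utils::write.table(scheme, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

validate_scheme <- function(scheme) {
  if (anyDuplicated(scheme$locus))
    stop("duplicate locus names in scheme: ",
         paste(unique(scheme$locus[duplicated(scheme$locus)]), collapse = ", "))
  bad <- scheme$min_len <= 0L | scheme$max_len <= 0L |
    scheme$min_len > scheme$max_len
  if (any(bad))
    stop("invalid length range for loci: ",
         paste(scheme$locus[bad], collapse = ", "))
  invisible(scheme)
}

#' The default 53-locus rMLST scheme
#'
#' Catalogue of the 53 bacterial ribosomal-protein genes with plausible
#' coding-sequence length ranges. The ranges are deliberately wide (roughly
#' half to twice a typical bacterial length) and serve as a curation sanity
#' check, not a hard biological bound.
#'
#' @return Scheme `data.frame` (53 rows).
#' @export
default_scheme <- function() {
  path <- system.file("extdata", "rmlst_scheme.tsv", package = "ribomlst",
                      mustWork = TRUE)
  read_scheme(path)
}

#' Names of the default rMLST loci
#' @return Character vector of 53 gene symbols.
#' @export
rmlst_loci <- function() default_scheme()$locus
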