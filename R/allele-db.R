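# Allele reference database: for every locus of a scheme, the catalogue of
# distinct coding sequences seen so far, each indexed by a small integer.
# Curation mirrors standard MLST practice: an allele must be an in-frame CDS
# with no internal stop codon and no ambiguity characters; identical sequences
# at a locus always map to one id, and ids are never reassigned.

#' Create an empty allele database
#'
#' @param scheme Scheme `data.frame` (see [read_scheme()]); defaults to the
#'   shipped 53-locus rMLST catalogue.
#' @return An object of class `allele_db`.
#' @export
allele_db <- function(scheme = default_scheme()) {
  validate_scheme(scheme)
  alleles <- stats::setNames(
    replicate(nrow(scheme),
              data.frame(allele_id = integer(0), sequence = character(0),
                         stringsAsFactors = FALSE),
              simplify = FALSE),
    scheme$locus)
  structure(list(scheme = scheme, alleles = alleles), class = "allele_db")
}

#' @export
print.allele_db <- function(x, ...) {
  n <- vapply(x$alleles, nrow, integer(1))
  cat("<allele_db> ", nrow(x$scheme), " loci, ", sum(n), " alleles (",
      sum(n > 0L), " loci populated)\n", sep = "")
  invisible(x)
}

#' Number of alleles in a database
#' @param db An `allele_db`.
#' @param locus Optional locus name; if omitted, total over all loci.
#' @return Integer count.
#' @export
n_alleles <- function(db, locus = NULL) {
  if (is.null(locus)) return(sum(vapply(db$alleles, nrow, integer(1))))
  nrow(.locus_tbl(db, locus))
}

.locus_tbl <- function(db, locus) {
  tbl <- db$alleles[[locus]]
  if (is.null(tbl)) stop("unknown locus: ", locus)
  tbl
}

#' Validate a candidate allele sequence
#'
#' An allele must be uppercase-normalisable DNA over {A,C,G,T}, a length
#' multiple of 3, free of stop codons before the final codon, and (when a
#' locus is given) within the scheme's expected length range. A terminal stop
#' codon is allowed and retained. A non-standard start codon (not ATG/GTG/TTG)
#' is reported as a warning flag, not a rejection.
#'
#' @param sequence DNA string.
#' @param locus Optional locus name for the length-range check.
#' @param scheme Scheme `data.frame` used when `locus` is given.
#' @return A list with `ok` (logical), `reason` (character, `NA` if ok) and
#'   `warnings` (character vector, possibly empty).
#' @export
validate_allele <- function(sequence, locus = NULL, scheme = NULL) {
  seq <- toupper(sequence)
  fail <- function(reason) list(ok = FALSE, reason = reason,
                                warnings = character(0))
  if (!nzchar(seq)) return(fail("empty sequence"))
  if (grepl("[^ACGT]", seq)) return(fail("ambiguity character"))
  if (nchar(seq) %% 3L != 0L) return(fail("frameshift/length not multiple of 3"))
  if (has_internal_stop(seq)) return(fail("internal stop codon"))
  if (!is.null(locus) && !is.null(scheme)) {
    row <- scheme[scheme$locus == locus, ]
    if (nrow(row) == 1L &&
        (nchar(seq) < row$min_len || nchar(seq) > row$max_len))
      return(fail(sprintf("length %d outside expected range [%d, %d]",
                          nchar(seq), row$min_len, row$max_len)))
  }
  w <- character(0)
  if (!substring(seq, 1L, 3L) %in% .START_CODONS)
    w <- "non-standard start codon"
  list(ok = TRUE, reason = NA_character_, warnings = w)
}

#' Look up an allele id by exact sequence
#'
#' Case-insensitive exact match on the coding strand.
#'
#' @param db An `allele_db`.
#' @param locus Locus name (must exist in the scheme).
#' @param sequence DNA string.
#' @return Integer allele id, or `NA_integer_` if the sequence is unknown.
#' @export
lookup_exact <- function(db, locus, sequence) {
  tbl <- .locus_tbl(db, locus)
  i <- match(toupper(sequence), tbl$sequence)
  if (is.na(i)) NA_integer_ else tbl$allele_id[i]
}

#' Retrieve an allele sequence by id
#' @param db An `allele_db`.
#' @param locus Locus name.
#' @param allele_id Integer id.
#' @return DNA string; error if the id is undefined.
#' @export
allele_sequence <- function(db, locus, allele_id) {
  tbl <- .locus_tbl(db, locus)
  i <- match(allele_id, tbl$allele_id)
  if (is.na(i)) stop("no allele ", allele_id, " at locus ", locus)
  tbl$sequence[i]
}

#' Define (or look up) an allele
#'
#' Idempotent: a sequence already present at the locus returns its existing
#' id and leaves the database unchanged; a new sequence passing
#' [validate_allele()] is assigned the next sequential integer id.
#'
#' @param db An `allele_db`.
#' @param locus Locus name.
#' @param sequence Candidate DNA string.
#' @return A list with `db` (possibly augmented), `allele_id` (integer) and
#'   `new` (logical). Validation failure is an error whose message carries
#'   the failed rule.
#' @export
define_allele <- function(db, locus, sequence) {
  seq <- toupper(sequence)
  tbl <- .locus_tbl(db, locus)
  i <- match(seq, tbl$sequence)
  if (!is.na(i))
    return(list(db = db, allele_id = tbl$allele_id[i], new = FALSE))
  v <- validate_allele(seq, locus, db$scheme)
  if (!v$ok)
    stop("allele rejected at ", locus, ": ", v$reason)
  id <- if (nrow(tbl) == 0L) 1L else max(tbl$allele_id) + 1L
  db$alleles[[locus]] <- rbind(
    tbl, data.frame(allele_id = id, sequence = seq, stringsAsFactors = FALSE))
  list(db = db, allele_id = id, new = TRUE)
}

#' Load an allele database from a directory of per-locus FASTA files
#'
#' Each file `<locus>.fas` (or `.fasta`/`.fa`) holds the alleles of one locus
#' with headers `"<locus>_<allele_id>"`. Records failing curation are rejected
#' individually and reported in the `rejected` attribute of the result; a
#' duplicate (locus, id) pair with different sequences, or one sequence filed
#' under two ids, is a hard error.
#'
#' @param dir Directory of FASTA files.
#' @param scheme Scheme `data.frame`; loci found on disk but absent from the
#'   scheme are an error.
#' @return An `allele_db`; attribute `rejected` is a `data.frame`
#'   (locus, allele_id, reason) of per-record rejections.
#' @export
load_allele_db <- function(dir, scheme = default_scheme()) {
  db <- allele_db(scheme)
  files <- sort(list.files(dir, pattern = "\\.(fas|fasta|fa)$",
                           full.names = TRUE))
  rejected <- list()
  for (f in files) {
    locus <- sub("\\.(fas|fasta|fa)$", "", basename(f))
    if (!locus %in% scheme$locus)
      stop("file ", basename(f), " does not match any scheme locus")
    recs <- read_fasta(f)
    ids <- suppressWarnings(as.integer(sub(paste0("^", locus, "_"), "",
                                           names(recs))))
    if (anyNA(ids))
      stop("malformed header(s) in ", basename(f), ": ",
           paste(names(recs)[is.na(ids)], collapse = ", "))
    seqs <- toupper(recs)
    # hard invariant checks before any insertion
    dup_id <- ids[duplicated(ids)]
    for (d in dup_id) {
      if (length(unique(seqs[ids == d])) > 1L)
        stop("duplicate allele id ", locus, "_", d, " with differing sequences")
    }
    dup_seq <- seqs[duplicated(seqs)]
    for (s in unique(dup_seq)) {
      under <- unique(ids[seqs == s])
      if (length(under) > 1L)
        stop("one sequence filed under multiple ids at ", locus, ": ",
             paste(sort(under), collapse = " and "))
    }
    keep <- !duplicated(ids)
    ids <- ids[keep]; seqs <- seqs[keep]
    ord <- order(ids)
    for (k in ord) {
      v <- validate_allele(seqs[k], locus, scheme)
      if (!v$ok) {
        rejected[[length(rejected) + 1L]] <-
          data.frame(locus = locus, allele_id = ids[k], reason = v$reason,
                     stringsAsFactors = FALSE)
        next
      }
      tbl <- db$alleles[[locus]]
      db$alleles[[locus]] <- rbind(
        tbl, data.frame(allele_id = ids[k], sequence = seqs[k],
                        stringsAsFactors = FALSE))
    }
  }
  attr(db, "rejected") <- if (length(rejected)) do.call(rbind, rejected) else
    data.frame(locus = character(0), allele_id = integer(0),
               reason = character(0), stringsAsFactors = FALSE)
  db
}

#' Save an allele database as per-locus FASTA files
#'
#' Inverse of [load_allele_db()]: writes `<locus>.fas` with headers
#' `"<locus>_<allele_id>"` for every populated locus.
#'
#' @param db An `allele_db`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
save_allele_db <- function(db, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (locus in names(db$alleles)) {
    tbl <- db$alleles[[locus]]
    if (nrow(tbl) == 0L) next
    write_fasta(stats::setNames(tbl$sequence,
                                paste0(locus, "_", tbl$allele_id)),
                file.path(dir, paste0(locus, ".fas")))
  }
  invisible(dir)
}
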