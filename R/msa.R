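# Codon-aware multiple alignment of the alleles called at one locus.
# Sequences are translated, the peptides are aligned progressively (UPGMA
# guide tree on a shared amino-acid 4-mer distance; profiles merged through
# global alignment of their consensus peptides), and the result is
# back-translated so every gap is codon-sized and starts on a codon
# boundary. This is deliberately simple: rMLST alleles are close homologues
# where indels are rare and codon-sized, so a consensus-based progressive
# scheme recovers the alignment a heavier aligner would.

#' Align the sequences of one locus by codon
#'
#' @param sequences Named character vector of in-frame CDS (names are
#'   isolate or allele identifiers; must be unique). All must pass
#'   [validate_allele()]'s frame rules (length a multiple of 3).
#' @param locus Locus name stored on the result.
#' @return A `locus_alignment`: list with `locus`, `rows` (named character
#'   vector of equal-length gapped DNA strings) and `width`.
#' @export
align_locus <- function(sequences, locus = "?") {
  if (length(sequences) == 0L) stop("no sequences to align")
  if (is.null(names(sequences)) || anyDuplicated(names(sequences)))
    stop("sequences must carry unique names")
  sequences <- toupper(sequences)
  bad <- nchar(sequences) %% 3L != 0L
  if (any(bad))
    stop("length not a multiple of 3: ", paste(names(sequences)[bad],
                                               collapse = ", "))
  if (length(sequences) == 1L)
    return(.locus_alignment(locus, sequences))
  peps <- vapply(sequences, translate_cds, character(1))
  aln_aa <- .progressive_align(peps)
  rows <- vapply(names(sequences), function(nm)
    .backtranslate(aln_aa[[nm]], sequences[[nm]]), character(1))
  .locus_alignment(locus, rows)
}

.locus_alignment <- function(locus, rows) {
  w <- unique(nchar(rows))
  stopifnot(length(w) == 1L)
  structure(list(locus = locus, rows = rows, width = w),
            class = "locus_alignment")
}

#' @export
print.locus_alignment <- function(x, ...) {
  cat("<locus_alignment> ", x$locus, ": ", length(x$rows), " rows x ",
      x$width, " columns\n", sep = "")
  invisible(x)
}

# shared-4-mer distance between peptides (k shrinks for very short ones)
.kmer_dist <- function(peps) {
  k <- max(1L, min(4L, min(nchar(peps))))
  sets <- lapply(peps, function(p) {
    n <- nchar(p)
    unique(substring(p, seq_len(n - k + 1L), k:n))
  })
  n <- length(peps)
  d <- matrix(0, n, n, dimnames = list(names(peps), names(peps)))
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    sh <- length(intersect(sets[[i]], sets[[j]]))
    d[i, j] <- d[j, i] <- 1 - sh / max(1L, min(lengths(sets)[c(i, j)]))
  }
  d
}

# progressive alignment; returns named list of gapped peptide strings
.progressive_align <- function(peps) {
  n <- length(peps)
  if (n == 2L) return(.merge_profiles(peps[1], peps[2]))
  d <- .kmer_dist(peps)
  hc <- stats::hclust(stats::as.dist(d), method = "average")
  profs <- lapply(seq_len(n), function(i) peps[i])  # singleton profiles
  merged <- vector("list", nrow(hc$merge))
  for (m in seq_len(nrow(hc$merge))) {
    a <- hc$merge[m, 1]; b <- hc$merge[m, 2]
    pa <- if (a < 0) profs[[-a]] else merged[[a]]
    pb <- if (b < 0) profs[[-b]] else merged[[b]]
    merged[[m]] <- .merge_profiles(pa, pb)
  }
  merged[[nrow(hc$merge)]]
}

# majority non-gap residue per column of a gapped-profile list
.consensus <- function(prof) {
  if (length(prof) == 1L) return(prof[[1]])
  mat <- do.call(rbind, strsplit(unlist(prof, use.names = FALSE), ""))
  paste(apply(mat, 2, function(col) {
    col <- col[col != "-"]
    if (length(col) == 0L) return("X")
    names(sort(table(col), decreasing = TRUE))[1]
  }), collapse = "")
}

# align two profiles through their consensus peptides; project gaps back
.merge_profiles <- function(pa, pb) {
  ca <- .consensus(pa); cb <- .consensus(pb)
  aln <- Biostrings::pairwiseAlignment(
    pattern = Biostrings::AAString(gsub("-", "X", ca)),
    subject = Biostrings::AAString(gsub("-", "X", cb)),
    type = "global", substitutionMatrix = .aa_submat(),
    gapOpening = 10, gapExtension = 1)
  ga <- as.character(Biostrings::pattern(aln))
  gb <- as.character(Biostrings::subject(aln))
  ins_a <- which(strsplit(ga, "")[[1]] == "-")  # new columns for profile a
  ins_b <- which(strsplit(gb, "")[[1]] == "-")
  c(lapply(pa, .insert_gaps, at = ins_a),
    lapply(pb, .insert_gaps, at = ins_b))
}

# insert gap characters so they land at (1-based) positions `at` of result
.insert_gaps <- function(s, at) {
  if (length(at) == 0L) return(s)
  out_len <- nchar(s) + length(at)
  chars <- character(out_len)
  chars[at] <- "-"
  chars[setdiff(seq_len(out_len), at)] <- strsplit(s, "")[[1]]
  paste(chars, collapse = "")
}

# expand a gapped peptide row back to codons of the original CDS
.backtranslate <- function(gapped_pep, cds) {
  cod <- codons_of(cds)
  out <- character(nchar(gapped_pep))
  j <- 0L
  for (i in seq_len(nchar(gapped_pep))) {
    ch <- substring(gapped_pep, i, i)
    if (ch == "-") out[i] <- "---"
    else { j <- j + 1L; out[i] <- cod[j] }
  }
  if (j != length(cod)) stop("back-translation length mismatch")
  paste(out, collapse = "")
}

#' Remove gaps from an alignment row
#' @param row Gapped sequence string.
#' @return Ungapped string.
#' @export
degap <- function(row) gsub("-", "", row)

#' Translate a codon alignment into a protein alignment
#' @param alignment A `locus_alignment` of codon-aligned DNA.
#' @return A `locus_alignment` whose rows are gapped peptides (gap codons
#'   become single `-` columns).
#' @export
translate_alignment <- function(alignment) {
  rows <- vapply(alignment$rows, function(r) {
    cod <- substring(r, seq(1L, nchar(r), 3L), seq(3L, nchar(r), 3L))
    paste(ifelse(cod == "---", "-",
                 ifelse(grepl("[^ACGT]", cod), "X",
                        unname(.GENCODE11[cod]))), collapse = "")
  }, character(1))
  .locus_alignment(alignment$locus, rows)
}

#' Concatenate per-locus alignments into one matrix
#'
#' Loci are concatenated in the order given (use catalogue order); isolates
#' absent from a block are padded with gaps across that block.
#'
#' @param alignments Named list of `locus_alignment`s (names are loci).
#' @param isolates Isolate set and row order; defaults to the union of row
#'   names in first-seen order.
#' @return List of class `concat_alignment` with `rows` (named character
#'   vector), `width`, and `provenance` (`data.frame`: locus, start, end
#'   columns, 1-based inclusive).
#' @export
concatenate_alignments <- function(alignments, isolates = NULL) {
  if (length(alignments) == 0L) stop("no alignment blocks")
  if (is.null(isolates))
    isolates <- unique(unlist(lapply(alignments, function(a) names(a$rows))))
  pieces <- matrix("", length(isolates), length(alignments),
                   dimnames = list(isolates, names(alignments)))
  prov <- data.frame(locus = names(alignments),
                     start = integer(length(alignments)),
                     end = integer(length(alignments)))
  pos <- 0L
  for (j in seq_along(alignments)) {
    a <- alignments[[j]]
    pad <- strrep("-", a$width)
    pieces[, j] <- ifelse(isolates %in% names(a$rows),
                          unname(a$rows[isolates]), pad)
    prov$start[j] <- pos + 1L
    prov$end[j] <- pos + a$width
    pos <- pos + a$width
  }
  rows <- stats::setNames(apply(pieces, 1, paste, collapse = ""), isolates)
  structure(list(rows = rows, width = pos, provenance = prov),
            class = "concat_alignment")
}
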