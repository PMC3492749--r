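# Low-level sequence helpers shared across the package. All sequences are
# plain uppercase character strings over {A,C,G,T} (IUPAC ambiguity codes and
# '-' may appear in alignments and raw contigs, never in curated alleles).

#' Bacterial genetic code (translation table 11)
#'
#' Named character vector mapping each of the 64 codons to its one-letter
#' amino acid, stop codons to `"*"`. Table 11 shares its codon assignments
#' with the standard code; it differs only in permitted start codons, which
#' is handled separately (see [validate_allele()]).
#'
#' @return Named character vector of length 64.
#' @export
genetic_code_11 <- function() .GENCODE11

.BASES <- c("A", "C", "G", "T")

.make_gencode <- function() {
  aa <- strsplit(paste0(
    "KNKNTTTTRSRSIIMIQHQHPPPPRRRRLLLL",
    "EDEDAAAAGGGGVVVV*Y*YSSSS*CWCLFLF"), "")[[1]]
  codons <- character(64)
  i <- 1L
  for (b1 in c("A", "C", "G", "T"))
    for (b2 in c("A", "C", "G", "T"))
      for (b3 in c("A", "C", "G", "T")) {
        codons[i] <- paste0(b1, b2, b3)
        i <- i + 1L
      }
  names(aa) <- codons
  aa
}
.GENCODE11 <- .make_gencode()

.STOP_CODONS <- c("TAA", "TAG", "TGA")
# common bacterial start codons under table 11
.START_CODONS <- c("ATG", "GTG", "TTG")

#' Reverse complement of DNA strings
#'
#' @param x Character vector of DNA strings (IUPAC codes allowed).
#' @return Character vector of reverse complements, same length as `x`.
#' @export
revcomp <- function(x) {
  vapply(x, function(s) {
    s <- chartr("ACGTUMRWSYKVHDBNacgtumrwsykvhdbn",
                "TGCAAKYWSRMBDHVNtgcaakywsrmbdhvn", s)
    intToUtf8(rev(utf8ToInt(s)))
  }, character(1), USE.NAMES = FALSE)
}

#' Split a DNA string into codons
#' @param seq DNA string; trailing bases short of a codon are dropped.
#' @return Character vector of 3-base codons.
#' @export
codons_of <- function(seq) {
  n <- nchar(seq) %/% 3L
  if (n == 0L) return(character(0))
  substring(seq, 3L * seq_len(n) - 2L, 3L * seq_len(n))
}

#' Translate an in-frame DNA string (frame 0, table 11)
#'
#' Stop codons are rendered as `"*"`; codons containing non-ACGT characters
#' as `"X"`. Trailing bases short of a codon are dropped.
#'
#' @param seq DNA string.
#' @return Single amino-acid string.
#' @export
translate_cds <- function(seq) {
  cod <- codons_of(toupper(seq))
  aa <- unname(.GENCODE11[cod])
  aa[is.na(aa)] <- "X"
  paste(aa, collapse = "")
}

#' Six-frame translation
#'
#' Translates the sequence in frames 0, 1 and 2 on the forward strand and on
#' the reverse complement, using bacterial code 11; stops appear as `"*"`.
#'
#' @param seq DNA string of length >= 3.
#' @return Named character vector of 6 peptides
#'   (`"F0","F1","F2","R0","R1","R2"`); frames shorter than one codon are
#'   empty strings.
#' @export
six_frame_translate <- function(seq) {
  seq <- toupper(seq)
  if (nchar(seq) < 3L) stop("sequence shorter than one codon")
  rc <- revcomp(seq)
  out <- c(
    F0 = translate_cds(seq),
    F1 = translate_cds(substring(seq, 2L)),
    F2 = translate_cds(substring(seq, 3L)),
    R0 = translate_cds(rc),
    R1 = translate_cds(substring(rc, 2L)),
    R2 = translate_cds(substring(rc, 3L))
  )
  out
}

# random DNA of length n at given GC content (uses current RNG stream)
random_dna <- function(n, gc = 0.5) {
  if (n <= 0L) return("")
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  paste(sample(names(p), n, replace = TRUE, prob = p), collapse = "")
}

# does `seq` (in frame 0) contain a stop codon before the final codon?
has_internal_stop <- function(seq) {
  cod <- codons_of(seq)
  if (length(cod) < 2L) return(FALSE)
  any(cod[-length(cod)] %in% .STOP_CODONS)
}
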