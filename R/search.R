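# Seeded local-alignment search of assembly contigs against the allele
# catalogue of one locus. Candidate regions are anchored on exact shared
# words (k-mers of the contig vs k-mers of each allele, both strands),
# clustered by diagonal, and each candidate window is then aligned against
# the allele with an affine-gap local alignment (match +2 / mismatch -3 /
# gap open 5 / gap extend 2 in nucleotide mode). The translated mode runs
# the same machinery on six-frame conceptual translations with amino-acid
# words, and maps coordinates back to nucleotide space.
#
# All coordinates in Hit tables are 0-based half-open on the forward strand
# of the contig; strand "-" means the reverse complement of that interval
# aligns to the allele's coding strand.

#' Search parameter set
#'
#' @param min_identity Minimum alignment identity (fraction of alignment
#'   columns that match), in `[0, 1]`.
#' @param min_coverage Minimum subject coverage: aligned allele span divided
#'   by allele length, in `[0, 1]`.
#' @param word_size Exact-word seed length in nucleotides (>= 4).
#' @param word_size_aa Seed length in amino acids for translated mode (>= 3).
#' @param window_pad Extra flank (bp or aa) added around a seed cluster
#'   before alignment.
#' @return A list of class `search_params`.
#' @export
search_params <- function(min_identity = 0.70, min_coverage = 0.50,
                          word_size = 15L, word_size_aa = 3L,
                          window_pad = 60L) {
  stopifnot(min_identity >= 0, min_identity <= 1,
            min_coverage >= 0, min_coverage <= 1,
            word_size >= 4L, word_size_aa >= 3L)
  structure(list(min_identity = min_identity, min_coverage = min_coverage,
                 word_size = as.integer(word_size),
                 word_size_aa = as.integer(word_size_aa),
                 window_pad = as.integer(window_pad)),
            class = "search_params")
}

.nt_submat <- function() {
  m <- get0(".nt_submat_cache", envir = .pkg_cache)
  if (is.null(m)) {
    # blastn default reward/penalty: local alignments stay extendable down
    # to 60% identity, which the relaxation ladder requires; a +1/-2 scheme
    # would turn negative below 2/3 identity and fragment valid hits
    m <- Biostrings::nucleotideSubstitutionMatrix(match = 2, mismatch = -3,
                                                  baseOnly = FALSE)
    assign(".nt_submat_cache", m, envir = .pkg_cache)
  }
  m
}

.aa_submat <- function() {
  m <- get0(".aa_submat_cache", envir = .pkg_cache)
  if (is.null(m)) {
    aas <- c(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], "X", "*")
    m <- matrix(-1, length(aas), length(aas), dimnames = list(aas, aas))
    diag(m) <- 2
    m["X", ] <- 0; m[, "X"] <- 0
    m["*", ] <- -4; m[, "*"] <- -4   # alignments should not cross stops
    m["*", "*"] <- 1                 # except terminal stop vs terminal stop
    assign(".aa_submat_cache", m, envir = .pkg_cache)
  }
  m
}

.pkg_cache <- new.env(parent = emptyenv())

# memoise `expr` under `key` in environment `cache`
.cached <- function(cache, key, expr) {
  v <- get0(key, envir = cache, inherits = FALSE)
  if (is.null(v)) {
    v <- expr
    assign(key, v, envir = cache)
  }
  v
}

# Guard gap inserted between blocks in the global seed index; must exceed
# any allele length plus window padding so that no seed cluster or window
# can bridge two blocks.
.IDX_GUARD <- 10000L

# One hashed k-mer index over a set of sequence blocks (contigs, or
# translation frames) laid out on a global coordinate axis with guard gaps.
.block_index <- function(blocks, k) {
  starts <- integer(length(blocks))
  off <- 0L
  pos_acc <- vector("list", length(blocks))
  km_acc <- vector("list", length(blocks))
  for (b in seq_along(blocks)) {
    s <- blocks[[b]]
    n <- nchar(s)
    starts[b] <- off
    if (n >= k) {
      pos_acc[[b]] <- off + 0:(n - k)
      km_acc[[b]] <- substring(s, seq_len(n - k + 1L), k:n)
    }
    off <- off + n + .IDX_GUARD
  }
  env <- new.env(hash = TRUE, parent = emptyenv())
  sp <- split(unlist(pos_acc, use.names = FALSE),
              unlist(km_acc, use.names = FALSE))
  list2env(sp, envir = env)
  list(env = env, n = length(sp), starts = starts,
       lens = nchar(unlist(blocks, use.names = FALSE)))
}

# Seed-derived candidate windows against a block index: diagonal clustering
# with a minimum-seeds-per-cluster filter (the classic multi-hit heuristic;
# with short amino-acid words single spurious seeds are everywhere and would
# trigger hopeless alignments). Returns a list of (block, w1, w2) with the
# window in 0-based half-open local block coordinates.
.seed_windows <- function(bidx, qk, query_len, pad, cluster_gap = 30L,
                          min_seeds = 1L) {
  if (length(qk) == 0L || bidx$n == 0L) return(NULL)
  vals <- mget(qk, envir = bidx$env, ifnotfound = list(NULL))
  hit <- which(lengths(vals) > 0L)
  if (length(hit) == 0L) return(NULL)
  pos <- unlist(vals[hit], use.names = FALSE)
  apos <- rep(hit - 1L, lengths(vals[hit]))
  est <- pos - apos
  ord <- order(est)
  est <- est[ord]; pos <- pos[ord]
  grp <- cumsum(c(TRUE, diff(est) > cluster_gap))
  keep <- if (min_seeds > 1L) {
    sizes <- tabulate(grp)
    grp %in% which(sizes >= min_seeds)
  } else rep(TRUE, length(grp))
  if (!any(keep)) return(NULL)
  out <- list()
  for (g in unique(grp[keep])) {
    ii <- which(grp == g)
    b <- findInterval(pos[ii[1]], bidx$starts)
    bs <- bidx$starts[b]; bl <- bidx$lens[b]
    w1 <- max(bs, min(est[ii]) - pad) - bs
    w2 <- min(bs + bl, max(est[ii]) + query_len + pad) - bs
    out[[length(out) + 1L]] <- list(block = b, w1 = w1, w2 = w2)
  }
  out
}

# query k-mers of an allele (or peptide), cached per allele and k
.query_kmers <- function(cache, key, seq, k) {
  .cached(cache, key, {
    n <- nchar(seq)
    if (n < k) character(0) else substring(seq, seq_len(n - k + 1L), k:n)
  })
}

# align many candidate windows against one subject in a single vectorised
# call; returns one row per window (alen 0 rows are kept, filter on alen)
.align_windows_batch <- function(window_seqs, subject_seq, submat, gap_open,
                                 gap_ext, protein = FALSE) {
  p <- if (protein) Biostrings::AAStringSet(window_seqs) else window_seqs
  s <- if (protein) Biostrings::AAString(subject_seq) else subject_seq
  aln <- Biostrings::pairwiseAlignment(
    pattern = p, subject = s, type = "local",
    substitutionMatrix = submat, gapOpening = gap_open, gapExtension = gap_ext)
  alen <- nchar(as.character(Biostrings::pattern(aln)))  # gapped columns
  data.frame(
    score = Biostrings::score(aln),
    nmatch = Biostrings::nmatch(aln),
    alen = alen,
    p_start = Biostrings::start(Biostrings::pattern(aln)) - 1L,  # 0-based
    p_end = Biostrings::end(Biostrings::pattern(aln)),
    s_start = Biostrings::start(Biostrings::subject(aln)) - 1L,
    s_end = Biostrings::end(Biostrings::subject(aln))
  )
}

.empty_hits <- function() {
  data.frame(locus = character(0), allele_id = integer(0),
             contig = character(0), c_start = integer(0), c_end = integer(0),
             a_start = integer(0), a_end = integer(0), strand = character(0),
             identity = numeric(0), coverage = numeric(0),
             alignment_length = integer(0), score = numeric(0),
             mode = character(0), stringsAsFactors = FALSE)
}

#' Nucleotide search of contigs against one locus's alleles
#'
#' Every exact full-length occurrence of an allele (either strand) is
#' guaranteed to be reported with identity and coverage 1.0 whenever
#' `word_size` does not exceed the allele length. Candidate hits are first
#' reduced so that overlapping hits on the same contig region keep only the
#' best-scoring allele (ties broken towards the lowest allele id, then the
#' leftmost coordinate); identity/coverage thresholds are applied last, so
#' relaxing `min_identity` only ever adds hits.
#'
#' @param contigs Named character vector of contig sequences.
#' @param alleles `data.frame` with columns `allele_id`, `sequence` (the
#'   per-locus table of an [allele_db()]), or a named character vector whose
#'   names parse as integer ids.
#' @param params A [search_params()] object.
#' @param locus Locus name recorded in the hits.
#' @param cache Optional environment reused across calls on the same contig
#'   set (e.g. one genome scanned locus by locus) to avoid re-indexing.
#' @return Hit `data.frame` with columns locus, allele_id, contig, c_start,
#'   c_end, a_start, a_end, strand, identity, coverage, alignment_length,
#'   score, mode.
#' @export
nucleotide_search <- function(contigs, alleles, params = search_params(),
                              locus = "?", cache = NULL) {
  alleles <- .as_allele_tbl(alleles)
  if (length(contigs) == 0L || nrow(alleles) == 0L) return(.empty_hits())
  if (is.null(cache)) cache <- new.env(parent = emptyenv())
  k <- params$word_size
  cnames <- names(contigs)
  fwd <- lapply(seq_along(contigs), function(ci)
    .cached(cache, paste0("seq:", cnames[ci], "+"), toupper(contigs[[ci]])))
  rows <- list()
  for (ai in seq_len(nrow(alleles))) {
    aseq <- alleles$sequence[ai]
    la <- nchar(aseq)
    # genes much shorter than ~12-15 words are unseedable at any real
    # divergence; cap the word near 1/15 of the allele, quantised to three
    # tiers so a genome needs at most three k-mer indexes
    bound <- la %/% 15L
    ka <- if (bound >= k) k else if (bound >= 11L) 11L else 8L
    bidx <- .cached(cache, paste0("ntidx:", ka), .block_index(fwd, ka))
    # the minus strand is searched as the reverse-complemented allele
    # against the forward contigs
    for (strand in c("+", "-")) {
      qseq <- if (strand == "+") aseq else
        .cached(cache, paste0("rc:", locus, ":", alleles$allele_id[ai]),
                revcomp(aseq))
      qk <- .query_kmers(cache,
                         paste0("qk:", strand, locus, ":",
                                alleles$allele_id[ai], ":", ka),
                         qseq, ka)
      wins <- .seed_windows(bidx, qk, la, params$window_pad)
      if (is.null(wins)) next
      ws <- list()
      for (w in wins) {
        cseq <- fwd[[w$block]]
        wseq <- substring(cseq, w$w1 + 1L, w$w2)
        # fast path: exact full-length occurrence needs no DP
        em <- regexpr(qseq, wseq, fixed = TRUE)
        if (em > 0L) {
          cs <- w$w1 + em - 1L
          rows[[length(rows) + 1L]] <- data.frame(
            locus = locus, allele_id = alleles$allele_id[ai],
            contig = cnames[w$block], c_start = cs, c_end = cs + la,
            a_start = 0L, a_end = la, strand = strand,
            identity = 1, coverage = 1, alignment_length = la,
            score = 2 * as.numeric(la), mode = "nucleotide",
            stringsAsFactors = FALSE)
        } else {
          ws[[length(ws) + 1L]] <- list(block = w$block, w1 = w$w1,
                                        wseq = wseq)
        }
      }
      if (length(ws) == 0L) next
      al <- .align_windows_batch(vapply(ws, `[[`, character(1), "wseq"),
                                 qseq, .nt_submat(), 5, 2)
      for (j in seq_len(nrow(al))) {
        if (al$alen[j] == 0L) next
        w <- ws[[j]]
        cs <- w$w1 + al$p_start[j]; ce <- w$w1 + al$p_end[j]
        # subject interval is on the oriented allele; map back for "-"
        as0 <- al$s_start[j]; ae0 <- al$s_end[j]
        if (strand == "-") { tmp <- as0; as0 <- la - ae0; ae0 <- la - tmp }
        rows[[length(rows) + 1L]] <- data.frame(
          locus = locus, allele_id = alleles$allele_id[ai],
          contig = cnames[w$block], c_start = cs, c_end = ce,
          a_start = as0, a_end = ae0, strand = strand,
          identity = al$nmatch[j] / al$alen[j],
          coverage = (ae0 - as0) / la,
          alignment_length = al$alen[j], score = al$score[j],
          mode = "nucleotide", stringsAsFactors = FALSE)
      }
    }
  }
  .finalize_hits(rows, params)
}

#' Translated (six-frame) search of contigs against one locus's alleles
#'
#' Both sides are conceptually translated (bacterial code 11): the allele in
#' frame 0 (terminal stop stripped), the contig in all six frames. Seeding
#' and alignment happen in amino-acid space; identity is the fraction of
#' matching amino-acid columns and coverage the aligned fraction of the
#' allele's peptide. Reported coordinates are mapped back to nucleotide
#' space on the contig's forward strand.
#'
#' @inheritParams nucleotide_search
#' @return Hit `data.frame` as in [nucleotide_search()], `mode` "translated".
#' @export
translated_search <- function(contigs, alleles, params = search_params(),
                              locus = "?", cache = NULL) {
  alleles <- .as_allele_tbl(alleles)
  if (length(contigs) == 0L || nrow(alleles) == 0L) return(.empty_hits())
  if (is.null(cache)) cache <- new.env(parent = emptyenv())
  k <- params$word_size_aa
  peps <- sub("\\*$", "", vapply(alleles$sequence, translate_cds, character(1)))
  # blocks: the six translation frames of every contig, with metadata to map
  # amino-acid coordinates back to the forward nucleotide strand
  fb <- .cached(cache, "frameblocks", {
    seqs <- list(); meta <- list()
    for (ci in seq_along(contigs)) {
      cname <- names(contigs)[ci]
      fwd <- .cached(cache, paste0("seq:", cname, "+"),
                     toupper(contigs[[ci]]))
      lc <- nchar(fwd)
      if (lc < 3L) next
      frames <- six_frame_translate(fwd)
      for (fr in names(frames)) {
        seqs[[length(seqs) + 1L]] <- frames[[fr]]
        meta[[length(meta) + 1L]] <- list(
          cname = cname, lc = lc,
          f_off = as.integer(substring(fr, 2L)),
          rev = substring(fr, 1L, 1L) == "R")
      }
    }
    list(seqs = seqs, meta = meta)
  })
  if (length(fb$seqs) == 0L) return(.empty_hits())
  bidx <- .cached(cache, paste0("aaidx:", k), .block_index(fb$seqs, k))
  rows <- list()
  for (ai in seq_len(nrow(alleles))) {
    apep <- peps[ai]
    laa <- nchar(apep)
    if (laa < k) next
    qk <- .query_kmers(cache,
                       paste0("qkaa:", locus, ":", alleles$allele_id[ai],
                              ":", k),
                       apep, k)
    wins <- .seed_windows(bidx, qk, laa, 20L, cluster_gap = 12L,
                          min_seeds = if (laa < 40L) 1L else 3L)
    if (is.null(wins)) next
    wseqs <- vapply(wins, function(w)
      substring(fb$seqs[[w$block]], w$w1 + 1L, w$w2), character(1))
    al <- .align_windows_batch(wseqs, apep, .aa_submat(), 10, 1,
                               protein = TRUE)
    for (j in seq_len(nrow(al))) {
      if (al$alen[j] == 0L) next
      w <- wins[[j]]
      m <- fb$meta[[w$block]]
      # aa interval on this frame's peptide -> nt on the oriented strand
      aa_s <- w$w1 + al$p_start[j]; aa_e <- w$w1 + al$p_end[j]
      nt_s <- m$f_off + 3L * aa_s; nt_e <- m$f_off + 3L * aa_e
      if (!m$rev) { cs <- nt_s; ce <- nt_e; strand <- "+" }
      else { cs <- m$lc - nt_e; ce <- m$lc - nt_s; strand <- "-" }
      rows[[length(rows) + 1L]] <- data.frame(
        locus = locus, allele_id = alleles$allele_id[ai], contig = m$cname,
        c_start = cs, c_end = ce,
        a_start = 3L * al$s_start[j], a_end = 3L * al$s_end[j],
        strand = strand, identity = al$nmatch[j] / al$alen[j],
        coverage = (al$s_end[j] - al$s_start[j]) / laa,
        alignment_length = al$alen[j], score = al$score[j],
        mode = "translated", stringsAsFactors = FALSE)
    }
  }
  .finalize_hits(rows, params)
}

.as_allele_tbl <- function(alleles) {
  if (is.data.frame(alleles)) return(alleles)
  data.frame(allele_id = as.integer(names(alleles)),
             sequence = toupper(unname(alleles)), stringsAsFactors = FALSE)
}

# overlap resolution (best score wins per contig region) then thresholding
.finalize_hits <- function(rows, params) {
  if (length(rows) == 0L) return(.empty_hits())
  h <- do.call(rbind, rows)
  # drop exact duplicates arising from overlapping seed windows
  h <- h[!duplicated(h[, c("allele_id", "contig", "c_start", "c_end",
                           "strand")]), , drop = FALSE]
  h <- h[order(-h$score, -h$identity, h$allele_id, h$c_start), , drop = FALSE]
  keep <- logical(nrow(h))
  for (cn in unique(h$contig)) {
    ii <- which(h$contig == cn)
    kept_s <- integer(0); kept_e <- integer(0)
    for (i in ii) {
      if (all(h$c_start[i] >= kept_e | h$c_end[i] <= kept_s)) {
        keep[i] <- TRUE
        kept_s <- c(kept_s, h$c_start[i]); kept_e <- c(kept_e, h$c_end[i])
      }
    }
  }
  h <- h[keep & h$identity >= params$min_identity &
           h$coverage >= params$min_coverage, , drop = FALSE]
  h <- h[order(h$contig, h$c_start, h$allele_id), , drop = FALSE]
  rownames(h) <- NULL
  h
}

#' Write a hit table as a BLAST outfmt-6-like TSV
#'
#' Column order: locus, allele_id, contig, c_start, c_end, a_start, a_end,
#' strand, identity, coverage, alignment_length, score, mode.
#' @param hits Hit `data.frame`.
#' @param path Output file.
#' @export
write_hits <- function(hits, path) {
  utils::write.table(hits, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
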