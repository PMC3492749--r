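# Deterministic synthetic test substrate: an ancestral allele per locus,
# seeded sequence evolution (any / synonymous-only / nonsynonymous modes),
# and fragmented genome assemblies with embedded alleles plus a ground-truth
# manifest recording what was placed where and with which intended status.
# Spacer (intergenic) composition is uniform at a configurable GC content;
# sequencing error is modelled only as homopolymer slippage inside
# designated genes (yielding intended pseudogenes) and optional substitution
# noise in the spacers, so intended locus statuses stay exact.

#' Generate an ancestral allele set for a scheme
#'
#' Every ancestral allele is a valid CDS: a standard start codon, sense
#' codons throughout, and a terminal stop codon. With `n_loci = 53` the
#' default rMLST catalogue (locus names and length ranges) is used; smaller
#' schemes get generic locus names with lengths drawn from `codon_range`.
#'
#' @param n_loci Number of loci.
#' @param codon_range Codon-count range for generic schemes.
#' @param seed Integer seed; output is a pure function of the arguments.
#' @return List of class `synth_scheme`: `scheme` (catalogue `data.frame`),
#'   `ancestors` (named DNA vector) and `db` (an [allele_db()] seeded with
#'   each ancestor as allele 1).
#' @export
generate_scheme <- function(n_loci = 53L, codon_range = c(60L, 200L),
                            seed = 1L) {
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(seed)
  if (n_loci == 53L) {
    scheme <- default_scheme()
  } else {
    nc <- sample(codon_range[1]:codon_range[2], n_loci, replace = TRUE)
    scheme <- data.frame(locus = sprintf("locus%03d", seq_len(n_loci)),
                         min_len = pmax(30L, 3L * nc - 90L),
                         max_len = 3L * nc + 90L)
  }
  sense <- setdiff(names(.GENCODE11), .STOP_CODONS)
  ancestors <- character(nrow(scheme))
  for (i in seq_len(nrow(scheme))) {
    lo <- ceiling(scheme$min_len[i] / 3); hi <- floor(scheme$max_len[i] / 3)
    ncod <- sample(lo:hi, 1L)
    body <- sample(sense, max(0L, ncod - 2L), replace = TRUE)
    ancestors[i] <- paste(c("ATG", body, sample(.STOP_CODONS, 1L)),
                          collapse = "")
  }
  names(ancestors) <- scheme$locus
  db <- allele_db(scheme)
  for (lc in scheme$locus)
    db <- define_allele(db, lc, ancestors[[lc]])$db
  structure(list(scheme = scheme, ancestors = ancestors, db = db),
            class = "synth_scheme")
}

#' Evolve an allele by point substitution
#'
#' Applies exactly `n` substitutions at distinct positions. The result is
#' always a valid allele: substitutions creating an internal stop (or
#' destroying the terminal stop) are resampled. In `"synonymous"` mode the
#' encoded protein is preserved exactly; in `"nonsynonymous"` mode every
#' substitution changes the amino acid.
#'
#' @param sequence Valid allele CDS.
#' @param n Number of substitutions.
#' @param mode `"any"`, `"synonymous"` or `"nonsynonymous"`.
#' @param seed Optional integer seed (otherwise the current RNG stream is
#'   used, so corpus generation stays reproducible end to end).
#' @return Mutated DNA string.
#' @export
evolve_allele <- function(sequence, n, mode = c("any", "synonymous",
                                                "nonsynonymous"),
                          seed = NULL) {
  mode <- match.arg(mode)
  if (!is.null(seed)) {
    old <- .save_rng(); on.exit(.restore_rng(old))
    set.seed(seed)
  }
  seq <- toupper(sequence)
  len <- nchar(seq)
  if (n == 0L) return(seq)
  used <- logical(len)
  applied <- 0L
  attempts <- 0L
  while (applied < n) {
    attempts <- attempts + 1L
    if (attempts > 200L * n)
      stop("could not place ", n, " ", mode, " substitutions")
    pos <- sample.int(len, 1L)
    if (used[pos]) next
    ci <- (pos - 1L) %/% 3L + 1L
    cod <- substring(seq, 3L * ci - 2L, 3L * ci)
    off <- pos - (3L * ci - 3L)
    cur <- substring(cod, off, off)
    alt <- sample(setdiff(.BASES, cur), 1L)
    newcod <- cod
    substring(newcod, off, off) <- alt
    aa_old <- .GENCODE11[[cod]]; aa_new <- .GENCODE11[[newcod]]
    terminal <- ci == len %/% 3L
    ok <- if (terminal) (aa_old == "*") == (aa_new == "*") else aa_new != "*"
    ok <- ok && switch(mode,
      any = TRUE,
      synonymous = aa_new == aa_old,
      nonsynonymous = aa_new != aa_old && aa_new != "*")
    if (!ok) next
    substring(seq, pos, pos) <- alt
    used[pos] <- TRUE
    applied <- applied + 1L
  }
  seq
}

#' Saturate every synonymously substitutable position
#'
#' Deterministically substitutes each position where some single-base change
#' preserves the amino acid (choosing the alphabetically first such base),
#' codon by codon against the current state. The protein is unchanged while
#' nucleotide identity to the input typically drops to roughly 2/3, and no
#' long exact nucleotide stretch survives - the construction used to show
#' that translated search succeeds where nucleotide search cannot seed.
#'
#' @param sequence Valid allele CDS.
#' @return Saturated DNA string (same protein).
#' @export
saturate_synonymous <- function(sequence) {
  seq <- toupper(sequence)
  len <- nchar(seq)
  for (pos in seq_len(len)) {
    ci <- (pos - 1L) %/% 3L + 1L
    cod <- substring(seq, 3L * ci - 2L, 3L * ci)
    off <- pos - (3L * ci - 3L)
    cur <- substring(cod, off, off)
    aa <- .GENCODE11[[cod]]
    for (b in setdiff(.BASES, cur)) {
      trial <- cod
      substring(trial, off, off) <- b
      if (.GENCODE11[[trial]] == aa) {
        substring(seq, pos, pos) <- b
        break
      }
    }
  }
  seq
}

# delete one base from the longest homopolymer run (>= min_run) inside the
# CDS, emulating a sequencing slip; returns NULL if no run qualifies
.homopolymer_slip <- function(seq, min_run = 3L) {
  r <- rle(strsplit(seq, "")[[1]])
  cand <- which(r$lengths >= min_run)
  if (length(cand) == 0L) return(NULL)
  best <- cand[which.max(r$lengths[cand])]
  at <- sum(r$lengths[seq_len(best - 1L)]) + 1L
  paste0(substring(seq, 1L, at - 1L), substring(seq, at + 1L))
}

#' Build a synthetic assembly corpus with a truth manifest
#'
#' Each isolate's genome is a set of contigs: alleles (ancestors evolved by
#' the divergence plan) embedded among random intergenic spacers, in scheme
#' order, distributed round-robin over `n_contigs`. Plans may delete a locus
#' (intended missing), truncate it at a contig end (intended partial), or
#' apply a homopolymer slip (frameshift, intended pseudogene). Everything is
#' a pure function of `seed`.
#'
#' @param ss A `synth_scheme` from [generate_scheme()].
#' @param n_isolates Number of genomes.
#' @param divergence Per-isolate substitution fraction(s) applied to every
#'   locus (recycled); 0 embeds the ancestors verbatim.
#' @param mode Substitution mode passed to [evolve_allele()].
#' @param n_contigs Contigs per genome.
#' @param spacer_range Intergenic spacer length range (bp).
#' @param gc Spacer GC content.
#' @param minus_prob Probability a gene is embedded on the minus strand.
#' @param missing `data.frame(isolate, locus)` of loci to omit.
#' @param truncate `data.frame(isolate, locus, keep)` of loci to cut at a
#'   contig end, keeping fraction `keep` (gene start side retained).
#' @param slip `data.frame(isolate, locus)` of loci receiving a homopolymer
#'   slip.
#' @param spacer_error Substitution rate applied to spacers only.
#' @param seed Integer seed.
#' @return List of class `synth_corpus`: `genomes` (named list of named
#'   contig vectors), `manifest` (`data.frame`: isolate, locus, allele_id,
#'   contig, start, end, strand, status, sequence; coordinates 0-based
#'   half-open on the forward strand), `db_full` (database holding every
#'   complete embedded variant under the ids the manifest uses) and
#'   `db_seed` (ancestors only).
#' @export
build_corpus <- function(ss, n_isolates = 5L, divergence = 0,
                         mode = "any", n_contigs = 4L,
                         spacer_range = c(120L, 280L), gc = 0.5,
                         minus_prob = 0.35, missing = NULL, truncate = NULL,
                         slip = NULL, spacer_error = 0, seed = 1L) {
  stopifnot(inherits(ss, "synth_scheme"))
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(seed)
  divergence <- rep_len(divergence, n_isolates)
  isolates <- sprintf("iso%02d", seq_len(n_isolates))
  loci <- ss$scheme$locus
  db_full <- ss$db
  planned <- function(plan, iso, lc) {
    !is.null(plan) && any(plan$isolate == iso & plan$locus == lc)
  }
  genomes <- list()
  man <- list()
  for (ii in seq_along(isolates)) {
    iso <- isolates[ii]
    # per-locus embedded segment and intent
    segs <- list()
    for (lc in loci) {
      if (planned(missing, iso, lc)) {
        man[[length(man) + 1L]] <- data.frame(
          isolate = iso, locus = lc, allele_id = NA_integer_,
          contig = NA_character_, start = NA_integer_, end = NA_integer_,
          strand = NA_character_, status = "missing",
          sequence = NA_character_, stringsAsFactors = FALSE)
        next
      }
      anc <- ss$ancestors[[lc]]
      nsub <- round(divergence[ii] * nchar(anc))
      var <- if (nsub == 0L) anc else evolve_allele(anc, nsub, mode)
      status <- "complete"
      aid <- NA_integer_
      emb <- var
      if (planned(slip, iso, lc)) {
        slipped <- .homopolymer_slip(var)
        if (is.null(slipped)) stop("no homopolymer run to slip in ", lc)
        emb <- slipped
        status <- "pseudogene"
      } else if (planned(truncate, iso, lc)) {
        keep <- truncate$keep[truncate$isolate == iso &
                                truncate$locus == lc][1]
        emb <- substring(var, 1L, max(1L, round(keep * nchar(var))))
        status <- "partial"
      } else {
        aid <- lookup_exact(db_full, lc, var)
        if (is.na(aid)) {
          res <- define_allele(db_full, lc, var)
          db_full <- res$db
          aid <- res$allele_id
        }
      }
      segs[[lc]] <- list(locus = lc, seq = emb, status = status,
                         allele_id = aid)
    }
    # lay segments onto contigs round-robin in scheme order; a truncated
    # segment is forced to the end of its contig (cut side outward)
    contigs <- stats::setNames(vector("list", n_contigs),
                               sprintf("%s_c%02d", iso, seq_len(n_contigs)))
    for (k in seq_along(segs))
      contigs[[(k - 1L) %% n_contigs + 1L]] <-
        c(contigs[[(k - 1L) %% n_contigs + 1L]], segs[k])
    built <- stats::setNames(character(n_contigs), names(contigs))
    for (cn in names(contigs)) {
      items <- contigs[[cn]]
      # truncated segments go last so the cut lands on the contig end
      trunc_i <- vapply(items, function(s) s$status == "partial", logical(1))
      if (sum(trunc_i) > 1L)
        stop("more than one truncated locus on one contig; use more contigs")
      if (length(items) > 1L)
        items <- c(items[!trunc_i], items[trunc_i])
      parts <- character(0)
      cursor <- 0L
      add <- function(s) {
        parts[[length(parts) + 1L]] <<- s
        cursor <<- cursor + nchar(s)
      }
      spacer <- function() {
        s <- random_dna(sample(spacer_range[1]:spacer_range[2], 1L), gc)
        if (spacer_error > 0 && nchar(s) > 0L) {
          nmut <- stats::rbinom(1L, nchar(s), spacer_error)
          if (nmut > 0L) {
            pos <- sample.int(nchar(s), nmut)
            for (p in pos)
              substring(s, p, p) <- sample(.BASES, 1L)
          }
        }
        s
      }
      add(spacer())
      for (j in seq_along(items)) {
        s <- items[[j]]
        # a truncated gene keeps its start and is cut at its 3' end, which
        # must coincide with the contig end: force the plus strand
        strand <- if (s$status == "partial") "+"
        else if (stats::runif(1) < minus_prob) "-" else "+"
        emb <- if (strand == "-") revcomp(s$seq) else s$seq
        start <- cursor
        add(emb)
        man[[length(man) + 1L]] <- data.frame(
          isolate = iso, locus = s$locus, allele_id = s$allele_id,
          contig = cn, start = start, end = cursor, strand = strand,
          status = s$status, sequence = s$seq, stringsAsFactors = FALSE)
        last_partial <- s$status == "partial" && j == length(items)
        if (!last_partial) add(spacer())
      }
      built[[cn]] <- paste(parts, collapse = "")
    }
    genomes[[iso]] <- built
  }
  manifest <- do.call(rbind, man)
  # manifest order: isolate then scheme locus order
  manifest <- manifest[order(match(manifest$isolate, isolates),
                             match(manifest$locus, loci)), ]
  rownames(manifest) <- NULL
  structure(list(genomes = genomes, manifest = manifest,
                 db_full = db_full, db_seed = ss$db),
            class = "synth_corpus")
}

#' Write a synthetic corpus to disk
#'
#' Emits `genomes/<isolate>.fasta`, `manifest.tsv`, the full and seed
#' databases (per-locus FASTA under `db_full/` and `db_seed/`) and
#' `scheme.tsv`.
#'
#' @param corpus A `synth_corpus`.
#' @param dir Output directory.
#' @param scheme The generating scheme `data.frame` (written alongside).
#' @export
write_corpus <- function(corpus, dir, scheme) {
  gd <- file.path(dir, "genomes")
  dir.create(gd, recursive = TRUE, showWarnings = FALSE)
  for (iso in names(corpus$genomes))
    write_fasta(corpus$genomes[[iso]], file.path(gd, paste0(iso, ".fasta")))
  utils::write.table(corpus$manifest, file.path(dir, "manifest.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  save_allele_db(corpus$db_full, file.path(dir, "db_full"))
  save_allele_db(corpus$db_seed, file.path(dir, "db_seed"))
  write_scheme(scheme, file.path(dir, "scheme.tsv"))
  invisible(dir)
}
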