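# Tagging: turning search hits into per-(isolate, locus) calls and growing
# the allele database to a fixpoint by iterative stringency relaxation.
# A tag's status is one of:
#   complete   - full-length CDS recovered, passes allele curation
#   partial    - coding sequence truncated at a contig end
#   pseudogene - full-length region recovered but frameshifted or carrying
#                an internal stop codon
#   missing    - no qualifying hit in any phase of the schedule
# New alleles are defined only from status-complete extractions.

TAG_STATUSES <- c("complete", "partial", "missing", "pseudogene")

#' Stringency relaxation schedule
#'
#' The discovery loop starts at `start_identity`, rescans to a fixpoint,
#' relaxes identity by `step`, and repeats down to `floor_identity`; it then
#' switches from nucleotide to translated search and walks the same ladder.
#' Coverage is held fixed throughout.
#'
#' @param start_identity Initial identity cut-off (default 0.70).
#' @param step Identity decrement per relaxation (default 0.05).
#' @param floor_identity Lowest identity tried (default 0.50).
#' @param coverage Subject-coverage cut-off held constant (default 0.50).
#' @param max_rounds Non-convergence guard: maximum rescans per level.
#' @return A list of class `stringency_schedule`.
#' @export
stringency_schedule <- function(start_identity = 0.70, step = 0.05,
                                floor_identity = 0.50, coverage = 0.50,
                                max_rounds = 100L) {
  stopifnot(start_identity >= floor_identity, step > 0, coverage >= 0,
            coverage <= 1, max_rounds >= 1L)
  structure(list(start_identity = start_identity, step = step,
                 floor_identity = floor_identity, coverage = coverage,
                 max_rounds = as.integer(max_rounds)),
            class = "stringency_schedule")
}

.schedule_levels <- function(sch) {
  lv <- seq(sch$start_identity, sch$floor_identity, by = -sch$step)
  if (utils::tail(lv, 1L) > sch$floor_identity + 1e-9)
    lv <- c(lv, sch$floor_identity)
  round(lv, 10)
}

#' Extract the full coding sequence under a hit
#'
#' Extends the aligned allele span outwards to the allele's full bounds on
#' the contig, reverse-complementing minus-strand hits, and reports how many
#' bases fall off either contig end.
#'
#' @param hit One row of a hit `data.frame`.
#' @param contig The contig sequence the hit lies on.
#' @param allele_length Full length (bp) of the matched allele.
#' @return List with `sequence` (coding-strand DNA), `start`, `end`
#'   (0-based half-open, forward strand, clipped to the contig),
#'   `truncated` (logical) and `missing_bp` (bases lost off contig ends).
#' @export
extract_cds <- function(hit, contig, allele_length) {
  lc <- nchar(contig)
  if (hit$strand == "+") {
    s <- hit$c_start - hit$a_start
    e <- hit$c_end + (allele_length - hit$a_end)
  } else {
    s <- hit$c_start - (allele_length - hit$a_end)
    e <- hit$c_end + hit$a_start
  }
  cs <- max(0L, s); ce <- min(lc, e)
  missing_bp <- (cs - s) + (e - ce)
  seq <- substring(contig, cs + 1L, ce)
  if (hit$strand == "-") seq <- revcomp(seq)
  list(sequence = seq, start = cs, end = ce,
       truncated = missing_bp > 0L, missing_bp = as.integer(missing_bp))
}

#' Classify an extraction into a tag status
#'
#' @param extraction Result of [extract_cds()], or `NULL` for no hit.
#' @return One of `"complete"`, `"partial"`, `"missing"`, `"pseudogene"`.
#'   A full-length extraction failing the in-frame/no-internal-stop rule
#'   (or containing ambiguity characters, which equally disqualify it from
#'   allele definition) is a pseudogene call.
#' @export
classify_extraction <- function(extraction) {
  if (is.null(extraction)) return("missing")
  if (extraction$truncated) return("partial")
  v <- validate_allele(extraction$sequence)
  if (v$ok) "complete" else "pseudogene"
}

.empty_tags <- function() {
  data.frame(isolate = character(0), locus = character(0),
             status = character(0), allele_id = integer(0),
             contig = character(0), start = integer(0), end = integer(0),
             strand = character(0), identity = numeric(0),
             coverage = numeric(0), paralogue = logical(0),
             nonstd_start = logical(0), level = numeric(0),
             phase = character(0), sequence = character(0),
             stringsAsFactors = FALSE)
}

.tag_row <- function(isolate, locus, status, allele_id = NA_integer_,
                     contig = NA_character_, start = NA_integer_,
                     end = NA_integer_, strand = NA_character_,
                     identity = NA_real_, coverage = NA_real_,
                     paralogue = FALSE, nonstd_start = FALSE,
                     level = NA_real_, phase = NA_character_,
                     sequence = NA_character_) {
  data.frame(isolate = isolate, locus = locus, status = status,
             allele_id = allele_id, contig = contig, start = start, end = end,
             strand = strand, identity = identity, coverage = coverage,
             paralogue = paralogue, nonstd_start = nonstd_start,
             level = level, phase = phase, sequence = sequence,
             stringsAsFactors = FALSE)
}

# tag all qualifying hits at one locus; first row is the primary tag
.tag_locus_hits <- function(hits, contigs, db, locus, isolate, level, phase) {
  la <- vapply(hits$allele_id, function(id)
    nchar(allele_sequence(db, locus, id)), integer(1))
  # primary = best (identity x coverage), ties -> lowest allele id, leftmost
  ord <- order(-(hits$identity * hits$coverage), hits$allele_id, hits$c_start)
  hits <- hits[ord, , drop = FALSE]
  la <- la[ord]
  out <- vector("list", nrow(hits))
  for (i in seq_len(nrow(hits))) {
    h <- hits[i, ]
    ex <- extract_cds(h, contigs[[h$contig]], la[i])
    status <- classify_extraction(ex)
    aid <- NA_integer_
    seq <- NA_character_
    nonstd <- FALSE
    if (status == "complete") {
      seq <- ex$sequence
      aid <- lookup_exact(db, locus, seq)
      nonstd <- length(validate_allele(seq)$warnings) > 0L
    }
    out[[i]] <- .tag_row(isolate, locus, status, aid, h$contig,
                         ex$start, ex$end, h$strand, h$identity, h$coverage,
                         paralogue = i > 1L, nonstd_start = nonstd,
                         level = level, phase = phase, sequence = seq)
  }
  do.call(rbind, out)
}

#' Scan one isolate's assembly against an allele database
#'
#' One pass at a single stringency: every populated locus of the database is
#' searched, the best hit per locus becomes the primary tag (ranking by
#' identity x coverage, ties towards the lowest allele id then the leftmost
#' coordinate), and further non-overlapping qualifying hits are emitted as
#' paralogue-flagged secondary tags. Loci with no qualifying hit are tagged
#' missing. Complete extractions whose sequence is not yet in the database
#' get `allele_id` `NA`; use [iterative_discovery()] to define them.
#'
#' @param contigs Named character vector: the isolate's assembly.
#' @param db An [allele_db()].
#' @param params [search_params()] for this pass.
#' @param isolate Isolate identifier recorded in the tags.
#' @param mode `"nucleotide"` or `"translated"`.
#' @param loci Subset of loci to scan (default: all populated loci).
#' @param cache Optional per-genome search cache environment.
#' @return Tag `data.frame`; the `sequence` column carries the extracted CDS
#'   for complete tags.
#' @export
scan_isolate <- function(contigs, db, params = search_params(),
                         isolate = "isolate", mode = "nucleotide",
                         loci = NULL, cache = NULL) {
  populated <- names(db$alleles)[vapply(db$alleles, nrow, integer(1)) > 0L]
  if (length(populated) == 0L) stop("allele database is empty")
  if (is.null(loci)) loci <- populated
  loci <- intersect(loci, populated)
  if (is.null(cache)) cache <- new.env(parent = emptyenv())
  search_fun <- if (mode == "translated") translated_search else
    nucleotide_search
  out <- list()
  for (locus in loci) {
    hits <- search_fun(contigs, db$alleles[[locus]], params, locus = locus,
                       cache = cache)
    out[[locus]] <- if (nrow(hits) == 0L)
      .tag_row(isolate, locus, "missing", level = params$min_identity,
               phase = mode)
    else
      .tag_locus_hits(hits, contigs, db, locus, isolate,
                      level = params$min_identity, phase = mode)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

# does `new` supersede `old` as the stored primary tag for a pair?
.supersedes <- function(new, old) {
  rank <- c(complete = 3, pseudogene = 2, partial = 2, missing = 1)
  if (is.null(old)) return(TRUE)
  if (rank[[new$status]] != rank[[old$status]])
    return(rank[[new$status]] > rank[[old$status]])
  isTRUE(new$identity > old$identity + 1e-12)
}

#' Iterative allele discovery and tagging
#'
#' Implements the stringency-relaxing loop: at each identity level, all
#' genomes with loci not yet tagged complete are rescanned; every complete,
#' curation-passing extraction that is new to the database is defined as the
#' next allele of its locus; the pass repeats until it defines nothing new
#' and completes nothing new, then the identity is relaxed by `step`. After
#' the nucleotide ladder reaches the floor, the translated ladder runs the
#' same way. Genomes are processed in input order and loci in catalogue
#' order, so allele numbering is reproducible for a fixed corpus ordering.
#'
#' A newly defined allele whose best within-database match is at a different
#' locus triggers a warning (offline analogue of an external cross-check).
#'
#' @param genomes Named list of assemblies (each a named character vector of
#'   contigs), in a deterministic order.
#' @param db Seed [allele_db()]; must hold at least one allele at every
#'   locus that should be discoverable.
#' @param schedule A [stringency_schedule()].
#' @param params Base [search_params()]; identity and coverage are
#'   overridden by the schedule level.
#' @param quiet Suppress per-round progress messages.
#' @return List with `db` (augmented database), `tags` (final tag table: one
#'   primary tag per isolate x locus plus paralogue tags, each carrying the
#'   level and phase at which it was found) and `log` (round-by-round
#'   `data.frame`: round, phase, level, pairs_scanned, new_alleles,
#'   new_complete, untagged_after).
#' @export
iterative_discovery <- function(genomes, db, schedule = stringency_schedule(),
                                params = search_params(), quiet = TRUE) {
  stopifnot(is.list(genomes), !is.null(names(genomes)))
  loci <- db$scheme$locus
  store <- new.env(parent = emptyenv())   # primary tags, key "iso\rlocus"
  paralogues <- list()
  log_rows <- list()
  round_no <- 0L
  levels <- .schedule_levels(schedule)
  caches <- stats::setNames(
    replicate(length(genomes), new.env(parent = emptyenv()), simplify = FALSE),
    names(genomes))

  pending_loci <- function(iso) {
    done <- vapply(loci, function(lc) {
      t <- get0(paste0(iso, "\r", lc), envir = store, inherits = FALSE)
      !is.null(t) && t$status == "complete"
    }, logical(1))
    loci[!done]
  }

  for (phase in c("nucleotide", "translated")) {
    for (lev in levels) {
      pass <- 0L
      repeat {
        pass <- pass + 1L
        if (pass > schedule$max_rounds)
          stop("no convergence after ", schedule$max_rounds,
               " passes at level ", lev, " (", phase, " phase)")
        round_no <- round_no + 1L
        p <- search_params(min_identity = lev,
                           min_coverage = schedule$coverage,
                           word_size = params$word_size,
                           word_size_aa = params$word_size_aa,
                           window_pad = params$window_pad)
        new_alleles <- 0L; new_complete <- 0L; scanned <- 0L
        for (iso in names(genomes)) {
          todo <- pending_loci(iso)
          todo <- todo[vapply(db$alleles[todo], nrow, integer(1)) > 0L]
          if (length(todo) == 0L) next
          scanned <- scanned + length(todo)
          tags <- scan_isolate(genomes[[iso]], db, p, isolate = iso,
                               mode = phase, loci = todo,
                               cache = caches[[iso]])
          for (i in seq_len(nrow(tags))) {
            tg <- tags[i, ]
            if (tg$status == "missing") next   # decided after all phases
            if (tg$status == "complete" && is.na(tg$allele_id)) {
              res <- tryCatch(define_allele(db, tg$locus, tg$sequence),
                              error = function(e) NULL)
              if (!is.null(res)) {
                db <- res$db
                tg$allele_id <- res$allele_id
                if (res$new) {
                  new_alleles <- new_alleles + 1L
                  .cross_locus_check(db, tg$locus, tg$sequence, p)
                }
              }
            }
            if (tg$paralogue) {
              paralogues[[length(paralogues) + 1L]] <- tg
              next
            }
            key <- paste0(iso, "\r", tg$locus)
            old <- get0(key, envir = store, inherits = FALSE)
            if (.supersedes(tg, old)) {
              if (tg$status == "complete" &&
                  (is.null(old) || old$status != "complete"))
                new_complete <- new_complete + 1L
              assign(key, tg, envir = store)
            }
          }
        }
        untagged <- sum(vapply(names(genomes), function(iso)
          length(pending_loci(iso)), integer(1)))
        log_rows[[length(log_rows) + 1L]] <- data.frame(
          round = round_no, phase = phase, level = lev,
          pairs_scanned = scanned, new_alleles = new_alleles,
          new_complete = new_complete, untagged_after = untagged,
          stringsAsFactors = FALSE)
        if (!quiet)
          message(sprintf("round %d [%s @ %.2f]: %d new alleles, %d untagged",
                          round_no, phase, lev, new_alleles, untagged))
        if (new_alleles == 0L && new_complete == 0L) break
      }
    }
  }

  # finalize: pairs never hit in any phase become explicit missing tags
  final <- list()
  for (iso in names(genomes)) {
    for (lc in loci) {
      t <- get0(paste0(iso, "\r", lc), envir = store, inherits = FALSE)
      final[[length(final) + 1L]] <- if (is.null(t))
        .tag_row(iso, lc, "missing") else t
    }
  }
  tags <- do.call(rbind, c(final, paralogues))
  rownames(tags) <- NULL
  list(db = db, tags = tags, log = do.call(rbind, log_rows))
}

# warn when a fresh allele matches another locus better than its own
.cross_locus_check <- function(db, locus, sequence, params) {
  for (other in names(db$alleles)) {
    if (other == locus || nrow(db$alleles[[other]]) == 0L) next
    if (!is.na(lookup_exact(db, other, sequence)))
      warning("new allele at ", locus,
              " is identical to an allele of locus ", other)
  }
  invisible(NULL)
}

#' Export a tag table as TSV
#'
#' Drops the internal `sequence` column; columns are isolate, locus, status,
#' allele_id, contig, start, end, strand, identity, coverage, paralogue,
#' nonstd_start, level, phase.
#' @param tags Tag `data.frame`.
#' @param path Output file.
#' @export
write_tags <- function(tags, path) {
  cols <- setdiff(names(tags), "sequence")
  utils::write.table(tags[, cols], path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a tag table written by [write_tags()]
#' @param path TSV file.
#' @return Tag `data.frame`.
#' @export
read_tags <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}
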