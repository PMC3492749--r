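# Allelic profiles and ribosomal sequence types (rSTs). A profile maps every
# scheme locus to an integer allele id or to a typed absence marker; isolates
# with identical complete profiles share an rST. Paralogue-flagged secondary
# tags never contribute to a profile (the primary tag at that locus does).

ABSENCE_MARKERS <- c("missing", "partial", "pseudogene")

#' Build an allelic profile from one isolate's tags
#'
#' @param tags Tag `data.frame` for a single isolate (primary and paralogue
#'   rows; paralogues are ignored).
#' @param scheme Scheme `data.frame` defining the loci (and their order).
#' @return Named character vector over the scheme's loci: the allele id as a
#'   string for complete calls, otherwise one of `"missing"`, `"partial"`,
#'   `"pseudogene"`. Attribute `isolate` records the isolate id. Class
#'   `rmlst_profile`.
#' @export
build_profile <- function(tags, scheme = default_scheme()) {
  if (nrow(tags) > 0L && length(unique(tags$isolate)) > 1L)
    stop("tags for more than one isolate; split first")
  prim <- tags[!tags$paralogue, , drop = FALSE]
  calls <- stats::setNames(rep("missing", nrow(scheme)), scheme$locus)
  for (i in seq_len(nrow(prim))) {
    lc <- prim$locus[i]
    if (!lc %in% scheme$locus) next
    calls[lc] <- if (prim$status[i] == "complete" && !is.na(prim$allele_id[i]))
      as.character(prim$allele_id[i]) else prim$status[i]
  }
  structure(calls, class = "rmlst_profile",
            isolate = if (nrow(tags) > 0L) tags$isolate[1] else NA_character_)
}

#' Is a profile complete (an allele id at every locus)?
#' @param profile An `rmlst_profile`.
#' @return Logical.
#' @export
profile_complete <- function(profile) {
  !any(unclass(profile) %in% ABSENCE_MARKERS)
}

#' Count mismatches between two profiles
#'
#' Only loci where both profiles carry allele ids are compared; loci absent
#' (missing/partial/pseudogene) in either are excluded from the comparison
#' but reported separately.
#'
#' @param p1,p2 `rmlst_profile` objects over the same scheme.
#' @return List with `mismatches`, `compared` and `excluded` counts.
#' @export
profile_mismatches <- function(p1, p2) {
  if (!identical(names(p1), names(p2)))
    stop("profiles are over different schemes")
  a <- unclass(p1); b <- unclass(p2)
  ok <- !(a %in% ABSENCE_MARKERS) & !(b %in% ABSENCE_MARKERS)
  list(mismatches = sum(a[ok] != b[ok]),
       compared = sum(ok),
       excluded = sum(!ok))
}

#' Assign ribosomal sequence types
#'
#' Identical complete profiles share one rST; numbering is sequential in
#' first-seen order; incomplete profiles get `NA`.
#'
#' @param profiles List of `rmlst_profile` objects.
#' @return Integer vector of rSTs, named by isolate where available.
#' @export
assign_rst <- function(profiles) {
  keys <- vapply(profiles, function(p) {
    if (!profile_complete(p)) NA_character_
    else paste(unclass(p), collapse = "|")
  }, character(1))
  seen <- character(0)
  rst <- integer(length(keys))
  for (i in seq_along(keys)) {
    if (is.na(keys[i])) { rst[i] <- NA_integer_; next }
    j <- match(keys[i], seen)
    if (is.na(j)) { seen <- c(seen, keys[i]); j <- length(seen) }
    rst[i] <- j
  }
  names(rst) <- vapply(profiles, function(p)
    as.character(attr(p, "isolate") %||% NA_character_), character(1))
  rst
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.mode_int <- function(x) {
  tb <- table(x)
  as.integer(names(tb)[which.max(tb)])
}

#' Corpus-level tagging summary
#'
#' Per-strain counts of complete, partial, missing and internal-stop
#' (pseudogene) loci, reported as mean (3 decimals) and mode, plus the
#' number of strains with every locus tagged (no locus missing), mirroring
#' the usual tagging-status table layout.
#'
#' @param tags Tag `data.frame` covering one or more isolates (primary tags;
#'   paralogue rows are ignored).
#' @param scheme Scheme `data.frame`.
#' @return List of class `tagging_summary` with `n_strains`, `per_strain`
#'   (`data.frame` of counts) and `table` (`data.frame` with rows for each
#'   statistic, columns `mean` and `mode`), plus `all_tagged` count.
#' @export
tagging_summary <- function(tags, scheme = default_scheme()) {
  prim <- tags[!tags$paralogue, , drop = FALSE]
  if (nrow(prim) == 0L) stop("empty tag table")
  isolates <- unique(prim$isolate)
  counts <- lapply(isolates, function(iso) {
    st <- prim$status[prim$isolate == iso]
    n_known <- sum(prim$isolate == iso)
    data.frame(isolate = iso,
               complete = sum(st == "complete"),
               partial = sum(st == "partial"),
               missing = sum(st == "missing") + (nrow(scheme) - n_known),
               pseudogene = sum(st == "pseudogene"),
               stringsAsFactors = FALSE)
  })
  per <- do.call(rbind, counts)
  all_tagged <- sum(per$missing == 0L)
  tab <- data.frame(
    statistic = c("complete", "partial", "missing", "internal_stop"),
    mean = round(c(mean(per$complete), mean(per$partial),
                   mean(per$missing), mean(per$pseudogene)), 3),
    mode = c(.mode_int(per$complete), .mode_int(per$partial),
             .mode_int(per$missing), .mode_int(per$pseudogene)))
  structure(list(n_strains = length(isolates), all_tagged = all_tagged,
                 per_strain = per, table = tab),
            class = "tagging_summary")
}

#' @export
print.tagging_summary <- function(x, ...) {
  cat("Tagging summary over", x$n_strains, "strains;",
      x$all_tagged, "with all loci tagged\n")
  tb <- x$table
  for (i in seq_len(nrow(tb)))
    cat(sprintf("  %-14s %7.3f (%d)\n", tb$statistic[i], tb$mean[i],
                tb$mode[i]))
  invisible(x)
}

#' Write profiles as a tab-separated matrix
#'
#' Rows are isolates, columns the scheme loci; absence markers are spelled
#' out. An `rST` column is appended when `rst` is supplied.
#'
#' @param profiles List of `rmlst_profile`s.
#' @param path Output file.
#' @param rst Optional integer vector from [assign_rst()].
#' @export
write_profiles <- function(profiles, path, rst = NULL) {
  m <- do.call(rbind, lapply(profiles, unclass))
  rownames(m) <- vapply(profiles, function(p)
    as.character(attr(p, "isolate") %||% ""), character(1))
  df <- data.frame(isolate = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  if (!is.null(rst)) df$rST <- rst
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a tagging summary as TSV
#' @param summary A `tagging_summary`.
#' @param path Output file.
#' @export
write_tagging_summary <- function(summary, path) {
  hdr <- data.frame(statistic = c("n_strains", "all_tagged"),
                    mean = c(summary$n_strains, summary$all_tagged),
                    mode = NA_integer_)
  utils::write.table(rbind(hdr, summary$table), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
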