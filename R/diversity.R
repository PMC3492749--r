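# Locus diversity statistics: the Hunter-Gaston discriminatory index,
# per-locus overall mean p-distance, and a codon-based test of positive
# selection using Nei-Gojobori counting of synonymous and nonsynonymous
# sites and differences (pathway averaging, Jukes-Cantor correction),
# with a codon-position bootstrap for the variance of dN - dS.

#' Hunter-Gaston discriminatory index
#'
#' `D = 1 - sum(n_j (n_j - 1)) / (N (N - 1))`: the probability that two
#' isolates drawn at random without replacement belong to different types.
#'
#' @param counts Integer vector of type counts (one entry per distinct type).
#' @return `D` in `[0, 1]`; `NA` when fewer than two isolates.
#' @export
hunter_gaston <- function(counts) {
  counts <- counts[counts > 0]
  n <- sum(counts)
  if (n < 2) return(NA_real_)
  1 - sum(counts * (counts - 1)) / (n * (n - 1))
}

#' Per-position synonymous site fractions of a codon
#'
#' For each of the three positions, the fraction of the three possible
#' single-base substitutions that are synonymous under bacterial code 11;
#' substitutions creating a stop codon count as nonsynonymous. The
#' synonymous and nonsynonymous fractions sum to 3 over the codon.
#'
#' @param codon 3-base string over ACGT; must be a sense codon.
#' @return List with `syn` and `nonsyn` (totals over the three positions)
#'   and `by_position` (length-3 vector of synonymous fractions).
#' @export
codon_sites <- function(codon) {
  codon <- toupper(codon)
  key <- paste0("cs:", codon)
  v <- get0(key, envir = .pkg_cache, inherits = FALSE)
  if (!is.null(v)) return(v)
  if (nchar(codon) != 3L || grepl("[^ACGT]", codon))
    stop("not an unambiguous codon: ", codon)
  aa <- .GENCODE11[[codon]]
  if (aa == "*") stop("stop codon has no site decomposition: ", codon)
  byp <- numeric(3)
  for (pos in 1:3) {
    cur <- substring(codon, pos, pos)
    for (b in setdiff(.BASES, cur)) {
      mut <- codon
      substring(mut, pos, pos) <- b
      maa <- .GENCODE11[[mut]]
      if (maa == aa) byp[pos] <- byp[pos] + 1 / 3   # stop -> nonsynonymous
    }
  }
  v <- list(syn = sum(byp), nonsyn = 3 - sum(byp), by_position = byp)
  assign(key, v, envir = .pkg_cache)
  v
}

#' Pathway-averaged synonymous/nonsynonymous differences between codons
#'
#' Counts the synonymous and nonsynonymous changes between two codons,
#' averaged over all orderings of the differing positions; pathways passing
#' through a stop codon are excluded and the average renormalised over the
#' remaining pathways (if every pathway is blocked, all are used).
#'
#' @param c1,c2 Sense codons over ACGT.
#' @return List with `sd` (synonymous differences) and `nd` (nonsynonymous
#'   differences); `sd + nd` equals the number of differing positions.
#' @export
codon_path_differences <- function(c1, c2) {
  c1 <- toupper(c1); c2 <- toupper(c2)
  key <- paste0("cp:", c1, c2)
  v <- get0(key, envir = .pkg_cache, inherits = FALSE)
  if (!is.null(v)) return(v)
  diffpos <- which(strsplit(c1, "")[[1]] != strsplit(c2, "")[[1]])
  if (length(diffpos) == 0L) return(list(sd = 0, nd = 0))
  perms <- .permutations(diffpos)
  tally <- function(order_) {
    cur <- c1; sd <- 0; nd <- 0
    for (pos in order_) {
      nxt <- cur
      substring(nxt, pos, pos) <- substring(c2, pos, pos)
      a1 <- .GENCODE11[[cur]]; a2 <- .GENCODE11[[nxt]]
      if (a2 == "*" || a1 == "*") { nd <- nd + 1 }       # stop step
      else if (a1 == a2) sd <- sd + 1 else nd <- nd + 1
      cur <- nxt
    }
    c(sd, nd)
  }
  blocked <- vapply(perms, function(ord) {
    cur <- c1
    for (pos in ord[-length(ord)]) {
      substring(cur, pos, pos) <- substring(c2, pos, pos)
      if (.GENCODE11[[cur]] == "*") return(TRUE)
    }
    FALSE
  }, logical(1))
  use <- if (all(blocked)) perms else perms[!blocked]
  res <- rowMeans(vapply(use, tally, numeric(2)))
  v <- list(sd = res[1], nd = res[2])
  assign(key, v, envir = .pkg_cache)
  v
}

.permutations <- function(x) {
  if (length(x) <= 1L) return(list(x))
  out <- list()
  for (i in seq_along(x))
    for (rest in .permutations(x[-i]))
      out[[length(out) + 1L]] <- c(x[i], rest)
  out
}

# per-codon-column contributions for one aligned pair; NA rows mark columns
# dropped by pairwise deletion (gap, ambiguity, or stop in either codon)
.ng_columns <- function(s1, s2) {
  cod1 <- codons_of(toupper(s1))
  cod2 <- codons_of(toupper(s2))
  L <- min(length(cod1), length(cod2))
  out <- matrix(NA_real_, L, 4,
                dimnames = list(NULL, c("s", "n", "sd", "nd")))
  for (k in seq_len(L)) {
    a <- cod1[k]; b <- cod2[k]
    if (grepl("[^ACGT]", a) || grepl("[^ACGT]", b)) next
    if (.GENCODE11[[a]] == "*" || .GENCODE11[[b]] == "*") next
    sa <- codon_sites(a); sb <- codon_sites(b)
    pd <- codon_path_differences(a, b)
    out[k, ] <- c((sa$syn + sb$syn) / 2, (sa$nonsyn + sb$nonsyn) / 2,
                  pd$sd, pd$nd)
  }
  out
}

.jc_correct <- function(p) {
  if (is.na(p)) return(NA_real_)
  if (p >= 0.75) return(NA_real_)       # saturated
  -3 / 4 * log(1 - 4 * p / 3)
}

.codon_stats_from_columns <- function(cols, n_boot, seed) {
  ok <- which(!is.na(cols[, 1]))
  tot <- colSums(cols[ok, , drop = FALSE])
  S <- tot[["s"]]; N <- tot[["n"]]; Sd <- tot[["sd"]]; Nd <- tot[["nd"]]
  pS <- if (S > 0) Sd / S else NA_real_
  pN <- if (N > 0) Nd / N else NA_real_
  dS <- .jc_correct(pS); dN <- .jc_correct(pN)
  Z <- NA_real_; p <- NA_real_; se <- NA_real_
  if (!is.na(dS) && !is.na(dN) && length(ok) > 1L) {
    if (!is.null(seed)) {
      old <- .save_rng(); on.exit(.restore_rng(old))
      set.seed(seed)
    }
    reps <- vapply(seq_len(n_boot), function(r) {
      idx <- sample(ok, length(ok), replace = TRUE)
      t2 <- colSums(cols[idx, , drop = FALSE])
      ds <- .jc_correct(if (t2[["s"]] > 0) t2[["sd"]] / t2[["s"]] else NA_real_)
      dn <- .jc_correct(if (t2[["n"]] > 0) t2[["nd"]] / t2[["n"]] else NA_real_)
      dn - ds
    }, numeric(1))
    se <- stats::sd(reps, na.rm = TRUE)
    diff <- dN - dS
    Z <- if (is.na(se) || se == 0) { if (diff == 0) 0 else sign(diff) * Inf }
    else diff / se
    p <- stats::pnorm(Z, lower.tail = FALSE)
  }
  structure(list(codons_compared = length(ok), S = S, N = N, Sd = Sd, Nd = Nd,
                 pS = pS, pN = pN, dS = dS, dN = dN,
                 saturated = (!is.na(pS) && pS >= 0.75) ||
                   (!is.na(pN) && pN >= 0.75),
                 se = se, Z = Z, p_one_sided = p, n_boot = n_boot),
            class = "codon_stats")
}

.save_rng <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.restore_rng <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}

#' @export
print.codon_stats <- function(x, ...) {
  cat(sprintf(
    "<codon_stats> %d codons: S=%.2f N=%.2f Sd=%.2f Nd=%.2f dS=%s dN=%s Z=%s p=%s\n",
    x$codons_compared, x$S, x$N, x$Sd, x$Nd,
    format(x$dS, digits = 4), format(x$dN, digits = 4),
    format(x$Z, digits = 4), format(x$p_one_sided, digits = 4)))
  invisible(x)
}

#' Nei-Gojobori statistics for one pair of aligned coding sequences
#'
#' Sites are averaged over the two sequences; codons containing gaps,
#' ambiguity characters or stop codons in either sequence are dropped
#' pairwise. `Z = (dN - dS) / se`, with `se` estimated by a seeded
#' codon-position bootstrap, and the one-sided p-value from the upper
#' normal tail tests neutrality against positive selection (dN > dS).
#'
#' @param cds1,cds2 Equal-length, in-frame aligned CDS strings.
#' @param n_boot Bootstrap replicates (default 1000).
#' @param seed Optional integer seed for the bootstrap.
#' @return A `codon_stats` list: codons_compared, S, N, Sd, Nd, pS, pN, dS,
#'   dN (`NA` when saturated, `pX >= 3/4`), saturated, se, Z, p_one_sided.
#' @export
nei_gojobori_pair <- function(cds1, cds2, n_boot = 1000L, seed = NULL) {
  if (nchar(cds1) != nchar(cds2)) stop("aligned sequences differ in length")
  if (nchar(cds1) %% 3L != 0L) stop("alignment length not a multiple of 3")
  .codon_stats_from_columns(.ng_columns(cds1, cds2), n_boot, seed)
}

#' Codon-based positive-selection test over an aligned CDS set
#'
#' Aggregates Nei-Gojobori site and difference counts over all unordered
#' sequence pairs, then bootstraps codon columns (jointly across pairs) to
#' obtain the variance of dN - dS.
#'
#' @param sequences Named character vector of equal-length aligned CDS (e.g.
#'   rows of a codon alignment; gap columns are handled by pairwise
#'   deletion).
#' @inheritParams nei_gojobori_pair
#' @return A `codon_stats` list (aggregated over pairs).
#' @export
positive_selection_test <- function(sequences, n_boot = 1000L, seed = NULL) {
  if (length(sequences) < 2L) stop("need at least two sequences")
  w <- unique(nchar(sequences))
  if (length(w) != 1L) stop("sequences must be aligned to equal length")
  n <- length(sequences)
  L <- w %/% 3L
  acc <- matrix(0, L, 4, dimnames = list(NULL, c("s", "n", "sd", "nd")))
  cnt <- integer(L)
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    cols <- .ng_columns(sequences[[i]], sequences[[j]])
    ok <- !is.na(cols[, 1])
    acc[ok, ] <- acc[ok, , drop = FALSE] + cols[ok, , drop = FALSE]
    cnt <- cnt + ok
  }
  agg <- acc
  agg[cnt == 0L, ] <- NA_real_
  .codon_stats_from_columns(agg, n_boot, seed)
}

#' Overall mean p-distance of a locus alignment
#'
#' Average of the pairwise p-distance (pairwise deletion) over all unordered
#' row pairs; pairs with no comparable sites are dropped from the average.
#'
#' @param alignment A `locus_alignment`, `concat_alignment`, or named
#'   character vector of aligned rows.
#' @param type See [p_distance()].
#' @return Mean distance (`NA` for fewer than two rows).
#' @export
mean_p_distance <- function(alignment, type = c("dna", "protein")) {
  rows <- if (is.list(alignment)) alignment$rows else alignment
  if (length(rows) < 2L) return(NA_real_)
  pm <- p_distance_matrix(rows, type)
  mean(pm$d[upper.tri(pm$d)], na.rm = TRUE)
}

#' Per-locus diversity table
#'
#' Convenience wrapper computing, for each locus alignment: the number of
#' rows, Hunter-Gaston index of the allele assignment, overall mean
#' p-distance, and the positive-selection test.
#'
#' @param alignments Named list of `locus_alignment`s.
#' @param profiles Optional list of `rmlst_profile`s; when given, the
#'   Hunter-Gaston index is computed from the profile column of each locus
#'   (complete calls only), otherwise from distinct sequences per alignment.
#' @param n_boot,seed Passed to [positive_selection_test()].
#' @return `data.frame`: locus, n, D, mean_p_distance, dN, dS, Z, p.
#' @export
diversity_table <- function(alignments, profiles = NULL, n_boot = 200L,
                            seed = 1L) {
  rows <- lapply(names(alignments), function(lc) {
    a <- alignments[[lc]]
    typ <- if (!is.null(profiles)) {
      calls <- vapply(profiles, function(p) unclass(p)[[lc]], character(1))
      calls[!calls %in% ABSENCE_MARKERS]
    } else degap(a$rows)
    D <- hunter_gaston(as.integer(table(typ)))
    ng <- if (length(a$rows) >= 2L)
      positive_selection_test(a$rows, n_boot = n_boot, seed = seed)
    else NULL
    data.frame(locus = lc, n = length(a$rows), D = D,
               mean_p_distance = mean_p_distance(a),
               dN = ng$dN %||% NA_real_, dS = ng$dS %||% NA_real_,
               Z = ng$Z %||% NA_real_, p = ng$p_one_sided %||% NA_real_,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
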