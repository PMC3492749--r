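# Distance phylogenetics: p-distance with pairwise deletion (ambiguous or
# gapped columns are dropped per sequence pair, not alignment-wide) and a
# deterministic Saitou-Nei neighbour-joining implementation.

.DNA_OK <- c("A", "C", "G", "T")
.AA_OK <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

#' p-distance between two aligned rows
#'
#' Columns where either row carries a gap or a symbol outside the unambiguous
#' alphabet are excluded for this pair only (pairwise deletion); the distance
#' is mismatches over the remaining compared sites.
#'
#' @param a,b Aligned sequence strings of equal length.
#' @param type `"dna"` (compare over ACGT) or `"protein"` (the 20 standard
#'   amino acids).
#' @return List with `distance` (`NA` if no site is comparable) and `sites`
#'   (number of compared sites).
#' @export
p_distance <- function(a, b, type = c("dna", "protein")) {
  type <- match.arg(type)
  if (nchar(a) != nchar(b)) stop("rows differ in length")
  ok_set <- if (type == "dna") .DNA_OK else .AA_OK
  x <- strsplit(toupper(a), "")[[1]]
  y <- strsplit(toupper(b), "")[[1]]
  ok <- x %in% ok_set & y %in% ok_set
  n <- sum(ok)
  list(distance = if (n == 0L) NA_real_ else sum(x[ok] != y[ok]) / n,
       sites = n)
}

#' Pairwise p-distance matrix of an alignment
#'
#' @param rows Named character vector of equal-length aligned rows (e.g.
#'   `$rows` of a `locus_alignment` or `concat_alignment`).
#' @param type See [p_distance()].
#' @return List of class `pdist_matrix`: `d` (symmetric distance matrix,
#'   `NA` where no sites compare), `sites` (compared-site counts) and
#'   `labels`.
#' @export
p_distance_matrix <- function(rows, type = c("dna", "protein")) {
  type <- match.arg(type)
  labels <- names(rows)
  if (is.null(labels) || anyDuplicated(labels))
    stop("rows must carry unique names")
  ok_set <- if (type == "dna") .DNA_OK else .AA_OK
  n <- length(rows)
  chars <- do.call(rbind, strsplit(toupper(unname(rows)), ""))
  valid <- matrix(chars %in% ok_set, nrow = n)
  d <- matrix(0, n, n, dimnames = list(labels, labels))
  s <- matrix(0L, n, n, dimnames = list(labels, labels))
  diag(s) <- as.integer(rowSums(valid))
  if (n > 1L) for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    ok <- valid[i, ] & valid[j, ]
    ns <- sum(ok)
    s[i, j] <- s[j, i] <- ns
    d[i, j] <- d[j, i] <- if (ns == 0L) NA_real_ else
      sum(chars[i, ok] != chars[j, ok]) / ns
  }
  structure(list(d = d, sites = s, labels = labels), class = "pdist_matrix")
}

#' Neighbour-joining tree from a distance matrix
#'
#' Saitou-Nei agglomeration on the Q criterion with a deterministic
#' tie-break (among equal-Q pairs, the pair whose cluster representatives -
#' the lexicographically smallest leaf inside each cluster - sort first).
#' Negative inferred branch lengths are clamped to zero with the deficit
#' moved to the sibling branch. For an additive matrix the generating
#' topology and path lengths are recovered exactly.
#'
#' @param d Symmetric numeric matrix with dimnames, or a `pdist_matrix`.
#' @return An unrooted tree of class `phylo` (ape).
#' @export
neighbor_joining <- function(d) {
  if (inherits(d, "pdist_matrix")) d <- d$d
  labels <- rownames(d)
  if (is.null(labels)) stop("distance matrix must have dimnames")
  if (anyNA(d)) {
    bad <- which(is.na(d) & upper.tri(d), arr.ind = TRUE)[1, ]
    stop("undefined distance between ", labels[bad[1]], " and ",
         labels[bad[2]])
  }
  n <- length(labels)
  if (n < 3L) stop("neighbour joining needs at least 3 taxa")
  frag <- .quote_label(labels)
  reps <- labels
  D <- d
  while (n > 3L) {
    R <- rowSums(D)
    Q <- (n - 2) * D - outer(R, R, "+")
    diag(Q) <- Inf
    qmin <- min(Q)
    cand <- which(Q <= qmin + 1e-12 & upper.tri(Q), arr.ind = TRUE)
    if (nrow(cand) > 1L) {
      keys <- apply(cand, 1L, function(ij) {
        pr <- sort(c(reps[ij[1]], reps[ij[2]]))
        paste(pr, collapse = "\r")
      })
      cand <- cand[order(keys)[1], , drop = FALSE]
    }
    i <- cand[1, 1]; j <- cand[1, 2]
    vi <- D[i, j] / 2 + (R[i] - R[j]) / (2 * (n - 2))
    vj <- D[i, j] - vi
    if (vi < 0) { vj <- vj + vi; vi <- 0 }
    if (vj < 0) { vi <- vi + vj; vj <- 0; vi <- max(vi, 0) }
    newd <- (D[i, ] + D[j, ] - D[i, j]) / 2
    newfrag <- sprintf("(%s:%.15g,%s:%.15g)", frag[i], vi, frag[j], vj)
    newrep <- min(reps[i], reps[j])
    keep <- setdiff(seq_len(n), c(i, j))
    D <- rbind(cbind(D[keep, keep, drop = FALSE], newd[keep]),
               c(newd[keep], 0))
    frag <- c(frag[keep], newfrag)
    reps <- c(reps[keep], newrep)
    n <- n - 1L
  }
  v1 <- (D[1, 2] + D[1, 3] - D[2, 3]) / 2
  v2 <- (D[1, 2] + D[2, 3] - D[1, 3]) / 2
  v3 <- (D[1, 3] + D[2, 3] - D[1, 2]) / 2
  v <- pmax(c(v1, v2, v3), 0)
  nwk <- sprintf("(%s:%.15g,%s:%.15g,%s:%.15g);",
                 frag[1], v[1], frag[2], v[2], frag[3], v[3])
  ape::read.tree(text = nwk)
}

.quote_label <- function(x) {
  # ']' first so the bracket expression stays POSIX-valid
  needs <- grepl("[][ \t(),:;']", x)
  x[needs] <- paste0("'", gsub("'", "''", x[needs]), "'")
  x
}

#' Serialize a tree as Newick text
#'
#' Branch lengths are written in full precision; labels containing spaces or
#' Newick metacharacters are single-quoted.
#'
#' @param tree A `phylo` object.
#' @return Single Newick string (terminated by `;`).
#' @export
write_newick <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  nt <- length(tree$tip.label)
  root <- nt + 1L
  kids <- split(seq_len(nrow(tree$edge)), tree$edge[, 1])
  rec <- function(node, edge_idx) {
    lab <- if (node <= nt) .quote_label(tree$tip.label[node]) else {
      ch <- kids[[as.character(node)]]
      paste0("(", paste(vapply(ch, function(e)
        rec(tree$edge[e, 2], e), character(1)), collapse = ","), ")")
    }
    if (is.na(edge_idx) || is.null(tree$edge.length)) lab
    else sprintf("%s:%.15g", lab, tree$edge.length[edge_idx])
  }
  paste0(rec(root, NA), ";")
}

#' Write a distance matrix as a PHYLIP-style square matrix
#' @param d `pdist_matrix` or plain matrix with dimnames.
#' @param path Output file.
#' @export
write_phylip_dist <- function(d, path) {
  if (inherits(d, "pdist_matrix")) d <- d$d
  con <- file(path, "w")
  on.exit(close(con))
  cat(nrow(d), "\n", file = con)
  for (i in seq_len(nrow(d)))
    cat(rownames(d)[i], sprintf("%.8f", d[i, ]), "\n", file = con)
  invisible(path)
}
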