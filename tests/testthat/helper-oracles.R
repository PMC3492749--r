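# Independent oracles, deliberately implemented with none of the package's
# search/statistics code paths: plain quadratic dynamic programming, pair
# enumeration and permutation walks.

# Full Smith-Waterman local alignment with affine gaps, same scoring as the
# package engine (match +2, mismatch -3, open 5, extend 2). Returns the best
# score and the identity over alignment columns via traceback.
sw_oracle <- function(a, b, match = 2, mismatch = -3, open = 5, ext = 2) {
  x <- strsplit(toupper(a), "")[[1]]
  y <- strsplit(toupper(b), "")[[1]]
  n <- length(x); m <- length(y)
  NEG <- -1e9
  M <- matrix(0, n + 1, m + 1)
  IX <- matrix(NEG, n + 1, m + 1)  # gap in b (consumes x)
  IY <- matrix(NEG, n + 1, m + 1)
  ptr <- array(0L, c(n + 1, m + 1, 3))  # 1=M,2=IX,3=IY; 0 = local start
  best <- 0; bi <- 0; bj <- 0; bs <- 1L
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      s <- if (x[i] == y[j]) match else mismatch
      cand <- c(0, M[i, j], IX[i, j], IY[i, j])  # start preferred on ties
      k <- which.max(cand)
      M[i + 1, j + 1] <- cand[k] + s
      ptr[i + 1, j + 1, 1] <- k - 1L
      cx <- c(M[i, j + 1] - open - ext, IX[i, j + 1] - ext)
      kx <- which.max(cx)
      IX[i + 1, j + 1] <- cx[kx]
      ptr[i + 1, j + 1, 2] <- kx  # 1 from M, 2 continue IX
      cy <- c(M[i + 1, j] - open - ext, IY[i + 1, j] - ext)
      ky <- which.max(cy)
      IY[i + 1, j + 1] <- cy[ky]
      ptr[i + 1, j + 1, 3] <- ky
      if (M[i + 1, j + 1] > best) {
        best <- M[i + 1, j + 1]; bi <- i + 1; bj <- j + 1; bs <- 1L
      }
    }
  }
  if (best <= 0) return(list(score = 0, identity = NA_real_, alen = 0L))
  i <- bi; j <- bj; state <- bs
  nmatch <- 0L; alen <- 0L
  repeat {
    if (state == 1L) {
      alen <- alen + 1L
      if (x[i - 1] == y[j - 1]) nmatch <- nmatch + 1L
      prev <- ptr[i, j, 1]
      i <- i - 1; j <- j - 1
      if (prev == 0L) break
      state <- prev
    } else if (state == 2L) {
      alen <- alen + 1L
      prev <- ptr[i, j, 2]
      i <- i - 1
      state <- if (prev == 1L) 1L else 2L
    } else {
      alen <- alen + 1L
      prev <- ptr[i, j, 3]
      j <- j - 1
      state <- if (prev == 1L) 1L else 3L
    }
  }
  list(score = best, identity = nmatch / alen, alen = alen)
}

# Hunter-Gaston by explicit enumeration of unordered isolate pairs
hgdi_oracle <- function(counts) {
  types <- rep(seq_along(counts), counts)
  n <- length(types)
  if (n < 2) return(NA_real_)
  same <- 0L; total <- 0L
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    total <- total + 1L
    if (types[i] == types[j]) same <- same + 1L
  }
  1 - same / total
}

# Nei-Gojobori pathway counting by brute-force permutation walk, with its
# own tiny codon table derived from Biostrings
.oracle_code <- as.list(Biostrings::GENETIC_CODE)
oracle_aa <- function(codon) {
  v <- .oracle_code[[codon]]
  if (is.null(v)) NA_character_ else v
}

ng_path_oracle <- function(c1, c2) {
  pos <- which(strsplit(c1, "")[[1]] != strsplit(c2, "")[[1]])
  if (length(pos) == 0) return(c(sd = 0, nd = 0))
  perm_list <- function(v) {
    if (length(v) <= 1) return(list(v))
    out <- list()
    for (i in seq_along(v))
      for (r in perm_list(v[-i])) out[[length(out) + 1]] <- c(v[i], r)
    out
  }
  results <- list()
  for (ord in perm_list(pos)) {
    cur <- c1; sd <- 0; nd <- 0; blocked <- FALSE
    for (step in seq_along(ord)) {
      p <- ord[step]
      nxt <- cur
      substring(nxt, p, p) <- substring(c2, p, p)
      a1 <- oracle_aa(cur); a2 <- oracle_aa(nxt)
      if (a1 == "*" || a2 == "*") nd <- nd + 1
      else if (a1 == a2) sd <- sd + 1 else nd <- nd + 1
      if (step < length(ord) && a2 == "*") blocked <- TRUE
      cur <- nxt
    }
    results[[length(results) + 1]] <- list(sd = sd, nd = nd,
                                           blocked = blocked)
  }
  usable <- Filter(function(r) !r$blocked, results)
  if (length(usable) == 0) usable <- results
  c(sd = mean(vapply(usable, `[[`, 0, "sd")),
    nd = mean(vapply(usable, `[[`, 0, "nd")))
}

# per-column brute force p-distance with pairwise deletion
pdist_oracle <- function(a, b, alphabet = c("A", "C", "G", "T")) {
  x <- strsplit(a, "")[[1]]; y <- strsplit(b, "")[[1]]
  mism <- 0L; comp <- 0L
  for (k in seq_along(x)) {
    if (x[k] %in% alphabet && y[k] %in% alphabet) {
      comp <- comp + 1L
      if (x[k] != y[k]) mism <- mism + 1L
    }
  }
  list(distance = if (comp == 0) NA_real_ else mism / comp, sites = comp)
}

# random additive distance matrix from a random unrooted binary tree;
# returns the matrix and the ape tree it came from
random_additive <- function(ntaxa, seed) {
  set.seed(seed)
  tr <- ape::rtree(ntaxa, rooted = FALSE)
  tr$edge.length <- stats::runif(nrow(tr$edge), 0.05, 0.6)
  D <- stats::cophenetic(tr)
  ord <- sort(rownames(D))
  list(tree = tr, d = D[ord, ord])
}

# small fixture: a scheme + zero-divergence corpus reused by several files
fixture_corpus <- function(n_loci = 6, n_isolates = 3, divergence = 0,
                           seed = 11, ...) {
  ss <- generate_scheme(n_loci = n_loci, seed = seed)
  corpus <- build_corpus(ss, n_isolates = n_isolates,
                         divergence = divergence, n_contigs = 3,
                         seed = seed + 1, ...)
  list(ss = ss, corpus = corpus)
}
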