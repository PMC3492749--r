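make_allele_tbl <- function(...) {
  seqs <- c(...)
  data.frame(allele_id = seq_along(seqs), sequence = seqs,
             stringsAsFactors = FALSE)
}

test_that("six-frame translation covers both strands, code 11, stops as *", {
  expect_equal(six_frame_translate("ATGAAA")[["F0"]], "MK")
  fr <- six_frame_translate("TTA")
  expect_equal(fr[["F0"]], "L")      # TTA = Leu forward
  expect_equal(fr[["R0"]], "*")      # revcomp TAA = stop
  # tails shorter than a codon are dropped
  expect_equal(nchar(six_frame_translate("ATGAAAC")[["F0"]]), 2)
  expect_error(six_frame_translate("AT"), "shorter")
})

test_that("exact embedded alleles are found with identity/coverage 1 on both strands", {
  set.seed(5)
  allele <- paste0("ATG", paste(sample(c("AAA", "CCT", "GGA", "TCT", "GAT"),
                                       80, replace = TRUE), collapse = ""),
                   "TAA")
  contig <- paste0(random_dna(300), allele, random_dna(250))
  h <- nucleotide_search(c(ctg = contig), make_allele_tbl(allele),
                         locus = "rpsB")
  expect_equal(nrow(h), 1)
  expect_equal(h$identity, 1.0)
  expect_equal(h$coverage, 1.0)
  expect_equal(h$strand, "+")
  expect_equal(h$c_start, 300)
  expect_equal(h$c_end, 300 + nchar(allele))
  expect_equal(substring(contig, h$c_start + 1, h$c_end), allele)

  h2 <- nucleotide_search(c(ctg = revcomp(contig)), make_allele_tbl(allele),
                          locus = "rpsB")
  expect_equal(nrow(h2), 1)
  expect_equal(h2$identity, 1.0)
  expect_equal(h2$strand, "-")
  expect_equal(revcomp(substring(revcomp(contig), h2$c_start + 1, h2$c_end)),
               allele)
})

test_that("engine identity matches a full Smith-Waterman oracle on mutated embeds", {
  for (seed in 1:6) {
    set.seed(seed)
    ss <- generate_scheme(n_loci = 1, codon_range = c(95, 105), seed = seed)
    allele <- unname(ss$ancestors[1])
    variant <- evolve_allele(allele, 30, "any")
    contig <- paste0(random_dna(120), variant, random_dna(120))
    h <- nucleotide_search(c(ctg = contig), make_allele_tbl(allele),
                           search_params(min_identity = 0.5), locus = "L")
    expect_equal(nrow(h), 1)
    # oracle: full DP over the embedded region +/- 50 bp
    win <- substring(contig, max(1, 120 - 50), 120 + nchar(variant) + 50)
    o <- sw_oracle(win, allele)
    expect_lt(abs(h$identity - o$identity), 0.01)
    expect_equal(h$score, o$score)
  }
})

test_that("random contigs yield no hits at default parameters", {
  set.seed(99)
  ss <- generate_scheme(n_loci = 2, seed = 42)
  contig <- random_dna(4000)
  h <- nucleotide_search(c(ctg = contig),
                         ss$db$alleles[[1]], locus = "x")
  expect_equal(nrow(h), 0)
  ht <- translated_search(c(ctg = contig), ss$db$alleles[[1]], locus = "x")
  expect_equal(nrow(ht), 0)
})

test_that("translated search finds synonymously saturated variants that nucleotide search cannot", {
  ss <- generate_scheme(n_loci = 1, codon_range = c(100, 120), seed = 31)
  allele <- unname(ss$ancestors[1])
  sat <- saturate_synonymous(allele)
  ident <- mean(strsplit(allele, "")[[1]] == strsplit(sat, "")[[1]])
  expect_lt(ident, 0.75)   # roughly 2/3 nucleotide identity
  expect_equal(translate_cds(sat), translate_cds(allele))
  set.seed(8)
  contig <- paste0(random_dna(200), sat, random_dna(200))
  tbl <- make_allele_tbl(allele)
  # nucleotide search misses even at the 0.50 floor: no 15-mer seed survives
  expect_equal(nrow(nucleotide_search(c(ctg = contig), tbl,
                                      search_params(min_identity = 0.5),
                                      locus = "L")), 0)
  ht <- translated_search(c(ctg = contig), tbl, locus = "L")
  expect_equal(nrow(ht), 1)
  expect_equal(ht$identity, 1.0)
  expect_equal(ht$coverage, 1.0)
  expect_equal(ht$strand, "+")
  # nucleotide coordinates map back onto the embedded CDS
  expect_equal(ht$c_start, 200)
  expect_equal(ht$c_end, 200 + nchar(sat) - 3)  # stop codon not aligned
})

test_that("translated hits on the minus strand map coordinates correctly", {
  ss <- generate_scheme(n_loci = 1, codon_range = c(90, 100), seed = 13)
  allele <- unname(ss$ancestors[1])
  sat <- saturate_synonymous(allele)
  set.seed(2)
  contig <- revcomp(paste0(random_dna(157), sat, random_dna(90)))
  ht <- translated_search(c(ctg = contig), make_allele_tbl(allele),
                          locus = "L")
  expect_equal(nrow(ht), 1)
  expect_equal(ht$strand, "-")
  expect_equal(revcomp(substring(contig, ht$c_start + 1, ht$c_end)),
               substring(sat, 1, nchar(sat) - 3))
})

test_that("lowering min_identity only ever adds hits", {
  set.seed(17)
  ss <- generate_scheme(n_loci = 1, codon_range = c(100, 110), seed = 17)
  allele <- unname(ss$ancestors[1])
  contig <- paste0(random_dna(100), evolve_allele(allele, 25, "any"),
                   random_dna(100), evolve_allele(allele, 60, "any"),
                   random_dna(100))
  tbl <- make_allele_tbl(allele)
  prev <- NULL
  for (ident in c(0.95, 0.9, 0.8, 0.7, 0.6, 0.5)) {
    h <- nucleotide_search(c(ctg = contig), tbl,
                           search_params(min_identity = ident), locus = "L")
    if (!is.null(prev)) {
      keys_prev <- paste(prev$c_start, prev$c_end, prev$allele_id)
      keys_now <- paste(h$c_start, h$c_end, h$allele_id)
      expect_true(all(keys_prev %in% keys_now),
                  info = paste("identity", ident))
    }
    prev <- h
  }
})

test_that("overlapping hits keep the best allele; distinct copies are both reported", {
  ss <- generate_scheme(n_loci = 1, codon_range = c(80, 90), seed = 23)
  a1 <- unname(ss$ancestors[1])
  a2 <- evolve_allele(a1, 10, "any", seed = 5)   # worse match for the embed
  set.seed(6)
  contig <- paste0(random_dna(150), a1, random_dna(200), a1, random_dna(150))
  h <- nucleotide_search(c(ctg = contig), make_allele_tbl(a1, a2),
                         locus = "L")
  # two embedded copies, each assigned to the exact allele 1
  expect_equal(nrow(h), 2)
  expect_equal(h$allele_id, c(1L, 1L))
  expect_equal(h$identity, c(1, 1))
})

test_that("search is deterministic", {
  fx <- fixture_corpus(n_loci = 3, n_isolates = 1, divergence = 0.1)
  g <- fx$corpus$genomes[[1]]
  tbl <- fx$ss$db$alleles[[1]]
  h1 <- nucleotide_search(g, tbl, locus = "a")
  h2 <- nucleotide_search(g, tbl, locus = "a")
  expect_identical(h1, h2)
})
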