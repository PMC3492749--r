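test_that("extract_cds recovers full embedded alleles on either strand", {
  fx <- fixture_corpus(n_loci = 4, n_isolates = 2)
  co <- fx$corpus
  tags <- scan_isolate(co$genomes[[1]], co$db_full, isolate = "iso01")
  m <- co$manifest[co$manifest$isolate == "iso01", ]
  expect_equal(sort(tags$locus), sort(m$locus))
  for (i in seq_len(nrow(tags))) {
    row <- m[m$locus == tags$locus[i], ]
    expect_equal(tags$sequence[i], row$sequence)
    expect_equal(tags$strand[i], row$strand)
  }
})

test_that("truncation at a contig end yields a truncation report", {
  ss <- generate_scheme(n_loci = 1, codon_range = c(80, 90), seed = 3)
  allele <- unname(ss$ancestors[1])
  # keep 60% of the gene, cut at the contig's right end
  keep <- round(0.6 * nchar(allele))
  contig <- paste0(random_dna(100), substring(allele, 1, keep))
  h <- nucleotide_search(c(c1 = contig), ss$db$alleles[[1]], locus = "L")
  expect_equal(nrow(h), 1)
  ex <- extract_cds(h[1, ], contig, nchar(allele))
  expect_true(ex$truncated)
  expect_equal(ex$missing_bp, nchar(allele) - keep)
  expect_equal(classify_extraction(ex), "partial")
})

test_that("frameshift from a homopolymer slip classifies as pseudogene", {
  ss <- generate_scheme(n_loci = 1, codon_range = c(90, 100), seed = 9)
  allele <- unname(ss$ancestors[1])
  slipped <- ribomlst:::.homopolymer_slip(allele)
  expect_equal(nchar(slipped), nchar(allele) - 1)
  # independent oracle: the frameshifted tail must contain an in-frame stop
  # or break the frame length rule
  expect_false(validate_allele(slipped)$ok)
  set.seed(4)
  contig <- paste0(random_dna(150), slipped, random_dna(150))
  tags <- scan_isolate(c(c1 = contig), ss$db, isolate = "x")
  expect_equal(tags$status, "pseudogene")
  expect_true(is.na(tags$allele_id))
})

test_that("scan_isolate tags all loci, flags paralogues, reports missing", {
  ss <- generate_scheme(n_loci = 5, seed = 21)
  co <- build_corpus(ss, n_isolates = 1, divergence = 0, n_contigs = 2,
                     seed = 22)
  g <- co$genomes[[1]]
  # append a second, diverged copy of locus 1 on its own contig
  lc1 <- ss$scheme$locus[1]
  copy2 <- evolve_allele(ss$ancestors[[lc1]], 12, "any", seed = 7)
  set.seed(30)
  g <- c(g, extra = paste0(random_dna(80), copy2, random_dna(80)))
  tags <- scan_isolate(g, co$db_full, isolate = "iso01")
  prim <- tags[!tags$paralogue, ]
  expect_equal(nrow(prim), 5)
  expect_equal(unname(table(prim$status)[["complete"]]), 5)
  para <- tags[tags$paralogue, ]
  expect_equal(nrow(para), 1)
  expect_equal(para$locus, lc1)
  # deleting one locus changes only that locus's tag
  co2 <- build_corpus(ss, n_isolates = 1, divergence = 0, n_contigs = 2,
                      seed = 22,
                      missing = data.frame(isolate = "iso01", locus = lc1))
  tags2 <- scan_isolate(co2$genomes[[1]], co2$db_full, isolate = "iso01")
  expect_equal(tags2$status[tags2$locus == lc1], "missing")
  others <- tags2[tags2$locus != lc1, c("locus", "status", "allele_id")]
  others_ref <- prim[prim$locus != lc1, c("locus", "status", "allele_id")]
  expect_equal(others[order(others$locus), ],
               others_ref[order(others_ref$locus), ],
               ignore_attr = TRUE)
})

test_that("iterative discovery reaches a fixpoint and defines every variant once", {
  ss <- generate_scheme(n_loci = 6, seed = 41)
  co <- build_corpus(ss, n_isolates = 4,
                     divergence = c(0, 0.08, 0.15, 0.22),
                     n_contigs = 3, seed = 42)
  res <- iterative_discovery(co$genomes, co$db_seed)
  prim <- res$tags[!res$tags$paralogue, ]
  expect_true(all(prim$status == "complete"))
  expect_equal(n_alleles(res$db), n_alleles(co$db_full))
  # allele assignments agree with an exact-sequence lookup in the truth db
  for (i in seq_len(nrow(prim))) {
    truth <- co$manifest[co$manifest$isolate == prim$isolate[i] &
                           co$manifest$locus == prim$locus[i], ]
    expect_equal(allele_sequence(res$db, prim$locus[i], prim$allele_id[i]),
                 truth$sequence)
  }
  # round log: levels never increase within a phase; fixpoint reached
  lg <- res$log
  for (ph in unique(lg$phase))
    expect_true(all(diff(lg$level[lg$phase == ph]) <= 0))
  expect_equal(lg$new_alleles[nrow(lg)], 0)
  # fixpoint: rescanning against the augmented db defines nothing new
  res2 <- iterative_discovery(co$genomes, res$db)
  expect_equal(n_alleles(res2$db), n_alleles(res$db))
  expect_equal(sum(res2$log$new_alleles), 0)
})

test_that("genomes identical to the seeded alleles converge in one scanning round", {
  fx <- fixture_corpus(n_loci = 4, n_isolates = 2)
  res <- iterative_discovery(fx$corpus$genomes, fx$corpus$db_full)
  expect_equal(sum(res$log$new_alleles), 0)
  expect_equal(res$log$untagged_after[1], 0)
})

test_that("synonymously saturated variants are discovered only in the translated phase", {
  ss <- generate_scheme(n_loci = 3, codon_range = c(100, 130), seed = 51)
  co <- build_corpus(ss, n_isolates = 1, divergence = 0, n_contigs = 2,
                     seed = 52)
  g <- co$genomes[[1]]
  lc <- ss$scheme$locus[2]
  # replace the embedded locus-2 gene by its synonymous saturation
  m <- co$manifest[co$manifest$locus == lc, ]
  sat <- saturate_synonymous(m$sequence)
  emb <- if (m$strand == "-") revcomp(sat) else sat
  ctg <- g[[m$contig]]
  substring(ctg, m$start + 1, m$end) <- emb
  g[[m$contig]] <- ctg
  res <- iterative_discovery(list(iso01 = g), co$db_seed)
  prim <- res$tags[!res$tags$paralogue, ]
  expect_true(all(prim$status == "complete"))
  expect_equal(prim$phase[prim$locus == lc], "translated")
  expect_true(all(prim$phase[prim$locus != lc] == "nucleotide"))
  lg <- res$log
  expect_gt(sum(lg$new_alleles[lg$phase == "translated"]), 0)
})

test_that("stringency schedule validates and enumerates levels", {
  sch <- stringency_schedule()
  expect_equal(ribomlst:::.schedule_levels(sch),
               c(0.70, 0.65, 0.60, 0.55, 0.50))
  expect_error(stringency_schedule(start_identity = 0.4,
                                   floor_identity = 0.5))
})
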