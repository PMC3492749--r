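test_that("Hunter-Gaston formula matches pair enumeration on random vectors", {
  expect_equal(hunter_gaston(5), 0)
  expect_equal(hunter_gaston(rep(1, 4)), 1)
  expect_equal(hunter_gaston(c(3, 2)), 0.6)
  expect_true(is.na(hunter_gaston(1)))
  set.seed(71)
  for (i in 1:50) {
    counts <- sample(1:6, sample(2:8, 1), replace = TRUE)
    expect_equal(hunter_gaston(counts), hgdi_oracle(counts))
  }
})

test_that("codon site fractions match mutant enumeration and sum to 3", {
  cs <- codon_sites("TTT")
  expect_equal(cs$syn, 1 / 3)
  expect_equal(cs$nonsyn, 8 / 3)
  cs2 <- codon_sites("ATG")
  expect_equal(cs2$syn, 0)
  expect_equal(cs2$nonsyn, 3)
  sense <- setdiff(names(genetic_code_11()),
                   c("TAA", "TAG", "TGA"))
  expect_length(sense, 61)
  for (cod in sense) {
    cs <- codon_sites(cod)
    expect_equal(cs$syn + cs$nonsyn, 3)
    # oracle: enumerate the nine single-base mutants
    syn <- 0
    for (p in 1:3) for (b in setdiff(c("A", "C", "G", "T"),
                                     substring(cod, p, p))) {
      mut <- cod
      substring(mut, p, p) <- b
      if (oracle_aa(mut) != "*" && oracle_aa(mut) == oracle_aa(cod))
        syn <- syn + 1 / 3
    }
    expect_equal(cs$syn, syn, tolerance = 1e-12)
  }
  expect_error(codon_sites("TAA"), "stop")
})

test_that("pathway averaging equals brute-force permutation enumeration", {
  expect_equal(codon_path_differences("TTT", "TTC"), list(sd = 1, nd = 0))
  pd <- codon_path_differences("TTT", "GTA")
  expect_equal(pd$sd, 0.5)
  expect_equal(pd$nd, 1.5)
  expect_equal(codon_path_differences("AAA", "AAA"), list(sd = 0, nd = 0))
  sense <- setdiff(names(genetic_code_11()), c("TAA", "TAG", "TGA"))
  set.seed(81)
  pairs <- cbind(sample(sense, 150, replace = TRUE),
                 sample(sense, 150, replace = TRUE))
  for (k in seq_len(nrow(pairs))) {
    got <- codon_path_differences(pairs[k, 1], pairs[k, 2])
    want <- ng_path_oracle(pairs[k, 1], pairs[k, 2])
    expect_equal(got$sd, unname(want["sd"]), tolerance = 1e-12)
    expect_equal(got$nd, unname(want["nd"]), tolerance = 1e-12)
    ndiff <- sum(strsplit(pairs[k, 1], "")[[1]] !=
                   strsplit(pairs[k, 2], "")[[1]])
    expect_equal(got$sd + got$nd, ndiff, tolerance = 1e-12)
  }
})

test_that("nei_gojobori_pair: identity, synonymous-only and saturation cases", {
  ss <- generate_scheme(n_loci = 1, codon_range = c(100, 110), seed = 85)
  anc <- unname(ss$ancestors[1])
  same <- nei_gojobori_pair(anc, anc, seed = 1)
  expect_equal(same$dN, 0)
  expect_equal(same$dS, 0)
  expect_equal(same$Z, 0)
  # one synonymous change over ~100 codons
  syn1 <- evolve_allele(anc, 1, "synonymous", seed = 2)
  r <- nei_gojobori_pair(anc, syn1, seed = 3)
  expect_equal(r$Nd, 0)
  expect_equal(r$Sd, 1)
  expect_gt(r$dS, 0)
  expect_equal(r$dN, 0)
  expect_lt(r$Z, 0)
  expect_gt(r$p_one_sided, 0.5)
  # sites S + N account for 3 x codons compared
  expect_equal(r$S + r$N, 3 * r$codons_compared, tolerance = 1e-9)
  # codons with gaps/ambiguity are dropped pairwise
  gapped <- paste0("---", substring(anc, 4))
  r2 <- nei_gojobori_pair(anc, gapped, seed = 4)
  expect_equal(r2$codons_compared, r$codons_compared - 1)
})

test_that("selection regimes give the expected Z sign in seeded replicates", {
  ss <- generate_scheme(n_loci = 1, codon_range = c(120, 130), seed = 91)
  anc <- unname(ss$ancestors[1])
  sign_ok_syn <- 0; sign_ok_nonsyn <- 0
  n_rep <- 20
  for (i in seq_len(n_rep)) {
    syn <- evolve_allele(anc, 12, "synonymous", seed = 100 + i)
    rs <- nei_gojobori_pair(anc, syn, n_boot = 300, seed = i)
    if (rs$Z < 0) sign_ok_syn <- sign_ok_syn + 1
    nsy <- evolve_allele(anc, 12, "nonsynonymous", seed = 200 + i)
    rn <- nei_gojobori_pair(anc, nsy, n_boot = 300, seed = i)
    if (rn$Z > 0) sign_ok_nonsyn <- sign_ok_nonsyn + 1
  }
  expect_gte(sign_ok_syn / n_rep, 0.95)
  expect_gte(sign_ok_nonsyn / n_rep, 0.95)
})

test_that("positive_selection_test aggregates pairs and stays deterministic under seed", {
  ss <- generate_scheme(n_loci = 1, codon_range = c(80, 90), seed = 95)
  anc <- unname(ss$ancestors[1])
  seqs <- c(a = anc,
            b = evolve_allele(anc, 6, "synonymous", seed = 1),
            c = evolve_allele(anc, 9, "synonymous", seed = 2))
  r1 <- positive_selection_test(seqs, n_boot = 200, seed = 9)
  r2 <- positive_selection_test(seqs, n_boot = 200, seed = 9)
  expect_identical(r1, r2)
  expect_equal(r1$dN, 0)
  expect_gt(r1$dS, 0)
  expect_lt(r1$Z, 0)
})

test_that("mean_p_distance equals the brute-force pair average", {
  set.seed(97)
  rows <- vapply(1:5, function(i)
    paste(sample(c("A", "C", "G", "T", "N"), 90, replace = TRUE,
                 prob = c(rep(0.23, 4), 0.08)), collapse = ""),
    character(1))
  names(rows) <- paste0("s", 1:5)
  vals <- c()
  for (i in 1:4) for (j in (i + 1):5)
    vals <- c(vals, pdist_oracle(rows[[i]], rows[[j]])$distance)
  expect_equal(mean_p_distance(rows), mean(vals, na.rm = TRUE))
  expect_equal(mean_p_distance(rows[1]), NA_real_)
  expect_equal(mean_p_distance(c(a = "AAAA", b = "AAAA", c = "AAAA")), 0)
})
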