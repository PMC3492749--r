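mk_tags <- function(iso, statuses, ids = NULL, scheme) {
  n <- length(statuses)
  data.frame(isolate = rep(iso, n), locus = scheme$locus[seq_len(n)],
             status = statuses,
             allele_id = if (is.null(ids)) ifelse(statuses == "complete",
                                                  1L, NA_integer_) else ids,
             paralogue = rep(FALSE, n), stringsAsFactors = FALSE)
}

test_that("build_profile records ids for complete calls and markers otherwise", {
  sc <- generate_scheme(n_loci = 5, seed = 1)$scheme
  tg <- mk_tags("A", c("complete", "complete", "pseudogene", "partial",
                       "missing"), scheme = sc)
  p <- build_profile(tg, sc)
  expect_equal(as.vector(unclass(p)),
               c("1", "1", "pseudogene", "partial", "missing"),
               ignore_attr = TRUE)
  expect_false(profile_complete(p))
  # all complete -> complete profile
  p2 <- build_profile(mk_tags("B", rep("complete", 5), scheme = sc), sc)
  expect_true(profile_complete(p2))
  # empty tag set -> all-missing profile
  p3 <- build_profile(mk_tags("C", character(0), scheme = sc), sc)
  expect_true(all(unclass(p3) == "missing"))
})

test_that("paralogue-flagged secondary tags never enter profiles", {
  sc <- generate_scheme(n_loci = 3, seed = 1)$scheme
  tg <- mk_tags("A", rep("complete", 3), ids = c(1L, 2L, 3L), scheme = sc)
  extra <- tg[1, ]
  extra$allele_id <- 9L
  extra$paralogue <- TRUE
  p <- build_profile(rbind(tg, extra), sc)
  expect_equal(unclass(p)[[sc$locus[1]]], "1")
})

test_that("profile_mismatches compares only doubly-called loci", {
  sc <- generate_scheme(n_loci = 53, seed = 1)$scheme
  mk <- function(calls) structure(stats::setNames(calls, sc$locus),
                                  class = "rmlst_profile", isolate = "x")
  a <- mk(as.character(rep(1, 53)))
  expect_equal(profile_mismatches(a, a),
               list(mismatches = 0L, compared = 53L, excluded = 0L))
  b <- mk(c("2", as.character(rep(1, 52))))
  expect_equal(profile_mismatches(a, b)$mismatches, 1L)
  cc <- mk(c(rep("missing", 3), as.character(rep(1, 50))))
  r <- profile_mismatches(a, cc)
  expect_equal(r$compared, 50L)
  expect_equal(r$excluded, 3L)
})

test_that("assign_rst is a congruence with first-seen numbering", {
  sc <- generate_scheme(n_loci = 4, seed = 2)$scheme
  mk <- function(iso, ids) structure(stats::setNames(ids, sc$locus),
                                     class = "rmlst_profile", isolate = iso)
  ps <- list(mk("a", c("1", "1", "1", "1")),
             mk("b", c("1", "2", "1", "1")),
             mk("c", c("1", "1", "1", "1")),
             mk("d", c("1", "2", "missing", "1")),
             mk("e", c("3", "1", "1", "1")))
  rst <- assign_rst(ps)
  expect_equal(unname(rst), c(1L, 2L, 1L, NA, 3L))
  # property: equal profiles <=> equal rST (complete profiles only)
  set.seed(77)
  rand <- lapply(1:40, function(i)
    mk(paste0("r", i), as.character(sample(1:2, 4, replace = TRUE))))
  rr <- assign_rst(rand)
  keys <- vapply(rand, function(p) paste(unclass(p), collapse = "|"), "")
  expect_equal(length(unique(rr)), length(unique(keys)))
  expect_true(all(tapply(rr, keys, function(v) length(unique(v)) == 1)))
})

test_that("tagging_summary equals brute-force aggregation of a corpus with known statuses", {
  ss <- generate_scheme(n_loci = 8, seed = 5)
  co <- build_corpus(
    ss, n_isolates = 4, divergence = 0, n_contigs = 4, seed = 6,
    missing = data.frame(isolate = "iso02", locus = ss$scheme$locus[1]),
    truncate = data.frame(isolate = "iso03", locus = ss$scheme$locus[2],
                          keep = 0.6),
    slip = data.frame(isolate = "iso04", locus = ss$scheme$locus[3]))
  tags <- do.call(rbind, lapply(names(co$genomes), function(iso)
    scan_isolate(co$genomes[[iso]], co$db_full, isolate = iso)))
  s <- tagging_summary(tags, ss$scheme)
  # oracle: aggregate the truth manifest directly
  m <- co$manifest
  per <- t(vapply(unique(m$isolate), function(iso)
    c(complete = sum(m$isolate == iso & m$status == "complete"),
      partial = sum(m$isolate == iso & m$status == "partial"),
      missing = sum(m$isolate == iso & m$status == "missing"),
      pseudogene = sum(m$isolate == iso & m$status == "pseudogene")),
    integer(4)))
  expect_equal(s$n_strains, 4)
  expect_equal(s$all_tagged, sum(per[, "missing"] == 0))
  expect_equal(s$table$mean,
               unname(round(colMeans(per), 3)))
  expect_equal(s$per_strain$complete, unname(per[, "complete"]))
  expect_error(tagging_summary(tags[0, ], ss$scheme), "empty")
})

test_that("profiles round-trip through the TSV writer", {
  sc <- generate_scheme(n_loci = 3, seed = 2)$scheme
  mk <- function(iso, ids) structure(stats::setNames(ids, sc$locus),
                                     class = "rmlst_profile", isolate = iso)
  ps <- list(mk("a", c("1", "2", "1")), mk("b", c("1", "missing", "1")))
  tf <- withr::local_tempfile()
  write_profiles(ps, tf, rst = assign_rst(ps))
  df <- read.delim(tf, check.names = FALSE)
  expect_equal(df$isolate, c("a", "b"))
  expect_equal(as.character(df[[sc$locus[2]]]), c("2", "missing"))
  expect_equal(df$rST, c(1L, NA))
})
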