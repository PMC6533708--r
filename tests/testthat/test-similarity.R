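test_that("self-alignment gives full identity and coverage", {
  r <- align_pair("MKVLA", "MKVLA")
  expect_equal(r$pct_identity, 100)
  expect_equal(r$query_cov, 1.0)
  expect_equal(r$subject_cov, 1.0)
  expect_equal(r$matches, 5L)
  expect_error(align_pair("", "MKV"), "empty")
})

test_that("coverage is forced by construction for nested sequences", {
  r <- align_pair("AAAA", "AAAAAAAA")
  expect_equal(r$query_cov, 1.0)
  expect_equal(r$subject_cov, 0.5)
})

test_that("local alignment scores equal exhaustive enumeration on short strings", {
  alpha <- c("A", "C", "D", "E")
  set.seed(31)
  for (case in 1:25) {
    S <- scoring_matrix(alpha, match = sample(2:5, 1),
                        mismatch = -sample(1:3, 1))
    # random off-diagonal perturbation keeps the oracle honest
    S["A", "C"] <- S["C", "A"] <- 1
    open <- sample(0:3, 1); ext <- sample(1:2, 1)
    a <- random_aa(sample(3:8, 1), alpha)
    b <- random_aa(sample(3:8, 1), alpha)
    got <- align_pair(a, b, scoring = S, gap_open = open, gap_extend = ext)
    want <- bf_local_score(a, b, S, open, ext)
    expect_equal(got$score, want,
                 info = paste(a, b, open, ext))
  }
})

test_that("aligned strings are consistent with reported statistics", {
  r <- align_pair("MKVANNDE", "MKVNNDE", keep_strings = TRUE)
  expect_equal(nchar(r$query_aln), nchar(r$subject_aln))
  expect_equal(nchar(r$query_aln), r$aln_length)
  qa <- strsplit(r$query_aln, "")[[1]]
  sa <- strsplit(r$subject_aln, "")[[1]]
  expect_equal(sum(qa == sa & qa != "-"), r$matches)
  expect_identical(gsub("-", "", r$query_aln),
                   substr("MKVANNDE", r$qstart, r$qend))
})

test_that("all-vs-all emits directed hits for identical triplets and none for disjoint k-mer sets", {
  recs <- toy_records(c(s1 = "MKVLAHGWERTYIPAS", s2 = "MKVLAHGWERTYIPAS",
                        s3 = "MKVLAHGWERTYIPAS"))
  cfg <- run_config(similarity = list(min_raw_score = 5))
  hits <- all_vs_all(recs, cfg)
  expect_equal(nrow(hits), 6L)
  expect_true(all(hits$pct_identity == 100))

  polys <- toy_records(c(pa = strrep("A", 40), pw = strrep("W", 40)))
  expect_equal(nrow(all_vs_all(polys, cfg)), 0L)
})

test_that("simulated families pass the filter and outsiders do not", {
  set.seed(21)
  anc <- random_aa(200, LETTERS[c(1, 3:9, 11:14, 16:20, 22:23, 25)])
  fam <- setNames(vapply(1:5, function(i) mutate_sequence(anc, 0.05),
                         character(1)), paste0("fam", 1:5))
  outs <- setNames(vapply(1:5, function(i)
    random_aa(200, LETTERS[c(1, 3:9, 11:14, 16:20, 22:23, 25)]),
    character(1)), paste0("out", 1:5))
  recs <- toy_records(c(fam, outs))
  hits <- all_vs_all(recs)
  pairs <- filter_bidirectional(hits)
  in_family <- grepl("^fam", pairs$a) & grepl("^fam", pairs$b)
  expect_equal(sum(in_family), choose(5, 2))
  cross <- xor(grepl("^fam", pairs$a), grepl("^fam", pairs$b))
  expect_equal(sum(cross), 0L)
})

test_that("prefilter never drops pairs that pass the final filter at moderate divergence", {
  spec <- sim_spec(n_genomes = 4, n_spoilers = 2, n_core_families = 20,
                   n_shell_families = 0, n_unique_per_genome = 2,
                   n_niche_families = 0, niche_min_pos = 2, paralog_prob = 0,
                   substitution_rate = 0.2, mean_protein_len = 120,
                   sd_protein_len = 30, seed = 13)
  sim <- simulate_pangenome(spec)
  with_pf <- filter_bidirectional(all_vs_all(sim$records, prefilter = TRUE))
  without <- filter_bidirectional(all_vs_all(sim$records, prefilter = FALSE))
  expect_identical(with_pf, without)
})

test_that("bidirectional filter requires both directions to pass", {
  one_way <- data.frame(
    query_id = "a", subject_id = "b", pct_identity = 90, aln_length = 100,
    query_cov = 1, subject_cov = 1, score = 100, evalue = NA_real_)
  expect_equal(nrow(filter_bidirectional(one_way)), 0L)

  hits <- data.frame(
    query_id   = c("a", "b", "a", "c", "b", "c"),
    subject_id = c("b", "a", "c", "a", "c", "b"),
    pct_identity = c(90, 90, 29.9, 45, 60, 60),
    aln_length = 100, query_cov = 0.95, subject_cov = 0.95,
    score = 100, evalue = NA_real_)
  pairs <- filter_bidirectional(hits)
  # a~c fails on one direction's identity (29.9 < 30)
  expect_identical(paste(pairs$a, pairs$b), c("a b", "b c"))
})

test_that("bidirectional filter equals an independent set-comprehension oracle", {
  set.seed(55)
  ids <- paste0("g", 1:6)
  for (rep in 1:100) {
    n <- sample(4:14, 1)
    hits <- data.frame(
      query_id = sample(ids, n, TRUE), subject_id = sample(ids, n, TRUE),
      pct_identity = runif(n, 20, 100), aln_length = 100L,
      query_cov = runif(n, 0.5, 1), subject_cov = runif(n, 0.5, 1),
      score = runif(n, 10, 200),
      evalue = ifelse(runif(n) < 0.3, NA, 10^runif(n, -20, -2)))
    hits <- hits[hits$query_id != hits$subject_id, , drop = FALSE]
    if (!nrow(hits)) next
    got <- filter_bidirectional(hits)
    expect_identical(sort(paste(got$a, got$b, sep = "|")),
                     oracle_bidirectional(hits))
  }
})

test_that("qualified pairs are symmetric and monotone in thresholds", {
  set.seed(17)
  anc <- random_aa(150, LETTERS[c(1, 3:9, 11:14, 16:20, 22:23, 25)])
  seqs <- setNames(vapply(1:6, function(i) mutate_sequence(anc, 0.25),
                          character(1)), paste0("s", 1:6))
  hits <- all_vs_all(toy_records(seqs))
  base <- filter_bidirectional(hits)

  flipped <- hits
  flipped[, c("query_id", "subject_id")] <- hits[, c("subject_id", "query_id")]
  flipped[, c("query_cov", "subject_cov")] <- hits[, c("subject_cov", "query_cov")]
  expect_identical(filter_bidirectional(flipped)[, c("a", "b")],
                   base[, c("a", "b")])

  stricter <- filter_bidirectional(
    hits, run_config(similarity = list(min_identity_pct = 60)))
  expect_true(all(paste(stricter$a, stricter$b) %in% paste(base$a, base$b)))
  stricter2 <- filter_bidirectional(
    hits, run_config(similarity = list(min_coverage_frac = 0.95)))
  expect_true(all(paste(stricter2$a, stricter2$b) %in% paste(base$a, base$b)))
})
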