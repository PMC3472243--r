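test_that("binomial overlap probability matches closed forms", {
  expect_equal(binomial_overlap_probability(1, 1), 0.25)
  expect_equal(binomial_overlap_probability(0, 2), 0.5625)
  expect_equal(binomial_overlap_probability(20, 20), 0.25^20)
  expect_lt(binomial_overlap_probability(20, 20), 1e-10)
  expect_gt(binomial_overlap_probability(16, 16), 1e-10)
  expect_error(binomial_overlap_probability(3, 2), "0 <= k <= n")
  expect_error(binomial_overlap_probability(1, 0), "n must be")
})

test_that("overlap enumeration covers every offset with correct geometry", {
  # identical 100-nt fragment sequenced exactly: candidate at f = 100 is a
  # perfect full-length overlap
  set.seed(5)
  frag <- rand_seq(100)
  pr <- make_pair(frag)
  cand <- enumerate_overlaps(pr$read1$seq, pr$read2$seq)
  full <- cand[cand$fragment == 100, ]
  expect_equal(full$n, 100L)
  expect_equal(full$k, 100L)
  expect_equal(full$p, 0.25^100)

  # a 74-nt error-free overlap (126-nt fragment, 100-nt reads)
  frag <- rand_seq(126)
  pr <- make_pair(frag)
  cand <- enumerate_overlaps(pr$read1$seq, pr$read2$seq)
  best <- cand[which.min(cand$p), ]
  expect_equal(best$fragment, 126L)
  expect_equal(best$n, 74L)
  expect_equal(best$k, 74L)
})

test_that("unrelated reads almost never reach the significance threshold", {
  set.seed(13)
  n_sig <- 0L
  for (i in 1:1000) {
    cand <- enumerate_overlaps(rand_seq(100), rand_seq(100))
    if (min(cand$p) < 1e-10) n_sig <- n_sig + 1L
  }
  expect_lte(n_sig, 1L)
})

test_that("merge decision applies the p and ratio thresholds", {
  mk <- function(ps) {
    # synthetic candidates realizing the requested probabilities
    data.frame(fragment = seq_along(ps), n = 200, k = vapply(ps, function(p) {
      which.min(abs(binomial_overlap_probability(0:200, 200) - p)) - 1L
    }, integer(1)))
  }
  d <- decide_merge(mk(c(1e-12, 1e-8, 0.3)))
  expect_true(d$accepted)
  expect_equal(d$reason, "ok")

  d <- decide_merge(mk(c(1e-9, 0.5)))
  expect_false(d$accepted)
  expect_equal(d$reason, "p_too_large")

  d <- decide_merge(mk(c(1e-12, 1e-10)))
  expect_false(d$accepted)
  expect_equal(d$reason, "ratio_too_small")

  # exact tie for the minimum is a ratio of 1
  cand <- data.frame(fragment = 1:2, n = c(100L, 100L), k = c(90L, 90L))
  d <- decide_merge(cand)
  expect_false(d$accepted)
  expect_equal(d$reason, "ratio_too_small")

  d <- decide_merge(cand[0, ])
  expect_equal(d$reason, "no_candidate")

  # invariant to candidate ordering
  set.seed(31)
  cand <- data.frame(fragment = 1:50, n = sample(20:100, 50, TRUE))
  cand$k <- vapply(cand$n, function(n) sample.int(n, 1), integer(1))
  d1 <- decide_merge(cand)
  d2 <- decide_merge(cand[sample.int(50), ])
  expect_equal(d1$accepted, d2$accepted)
  expect_equal(d1$best$fragment, d2$best$fragment)
  expect_equal(d1$second_best_p, d2$second_best_p)
})

test_that("base recombination follows the quality-sum rule", {
  expect_equal(combine_base("A", 30, "A", 30), list(base = "A", quality = 60L))
  expect_equal(combine_base("A", 40, "A", 40), list(base = "A", quality = 60L))
  expect_equal(combine_base("A", 35, "C", 20), list(base = "A", quality = 15L))
  expect_equal(combine_base("C", 20, "A", 35), list(base = "A", quality = 15L))
  expect_equal(combine_base("A", 20, "C", 20), list(base = "A", quality = 0L))
  expect_equal(combine_base("N", 2, "C", 20), list(base = "C", quality = 20L))
  expect_equal(combine_base("G", 17, "N", 2), list(base = "G", quality = 17L))
})

test_that("merge_pair reconstructs fragments and trims adaptor read-through", {
  set.seed(17)
  # 170-nt fragment, 100-nt reads: 30-nt overlap, 170-nt composite
  frag <- rand_seq(170)
  pr <- make_pair(frag)
  m <- merge_pair(pr$read1, pr$read2)
  expect_true(m$accepted)
  expect_equal(m$overlap_n, 30L)
  expect_identical(m$merged$seq, frag)
  expect_equal(unname(m$trimmed_adaptor_nt), c(0L, 0L))

  # 80-nt fragment: full-fragment overlap, 20 adaptor nt trimmed per mate
  frag <- rand_seq(80)
  pr <- make_pair(frag)
  m <- merge_pair(pr$read1, pr$read2)
  expect_true(m$accepted)
  expect_identical(m$merged$seq, frag)
  expect_equal(unname(m$trimmed_adaptor_nt), c(20L, 20L))

  # overlap qualities sum (capped), non-overlap qualities unchanged
  frag <- rand_seq(170)
  pr <- make_pair(frag, qual_char = "?")  # Q30
  m <- merge_pair(pr$read1, pr$read2)
  q <- qual_to_int(m$merged$qual)[[1]]
  expect_equal(q[1:70], rep(30L, 70))       # mate-1 only
  expect_equal(q[71:100], rep(60L, 30))     # overlap, 30 + 30
  expect_equal(q[101:170], rep(30L, 70))    # mate-2 only
})

test_that("batch merging agrees with the single-pair path", {
  set.seed(19)
  frags <- vapply(sample(60:199, 50, TRUE), rand_seq, character(1))
  prs <- lapply(frags, make_pair)
  r1 <- do.call(rbind, lapply(prs, function(p) as.data.frame(p$read1)))
  r2 <- do.call(rbind, lapply(prs, function(p) as.data.frame(p$read2)))
  batch <- merge_pairs(r1, r2)
  singles <- lapply(prs, function(p) merge_pair(p$read1, p$read2))
  acc <- vapply(singles, `[[`, logical(1), "accepted")
  expect_equal(sum(acc), nrow(batch$merged))
  expect_identical(batch$merged$seq,
                   vapply(singles[acc], function(s) s$merged$seq, character(1)))
  expect_equal(nrow(batch$unmerged1) + nrow(batch$merged), 50L)
})

test_that("merge_stream writes outputs and reports stats", {
  set.seed(29)
  dir <- withr::local_tempdir()
  # one mergeable pair (170-nt fragment) and one unrelated pair
  pr <- make_pair(rand_seq(170))
  r1 <- data.frame(id = c("a/1", "b/1"), seq = c(pr$read1$seq, rand_seq(100)),
                   qual = strrep("I", 100), stringsAsFactors = FALSE)
  r2 <- data.frame(id = c("a/2", "b/2"), seq = c(pr$read2$seq, rand_seq(100)),
                   qual = strrep("I", 100), stringsAsFactors = FALSE)
  f1 <- file.path(dir, "r1.fastq"); f2 <- file.path(dir, "r2.fastq")
  write_fastq(r1, f1); write_fastq(r2, f2)
  stats <- merge_stream(f1, f2, file.path(dir, "out"))
  expect_equal(stats$merged_fraction, 0.5)
  expect_equal(nrow(read_fastq(file.path(dir, "out_merged.fastq"))), 1L)
  expect_equal(nrow(read_fastq(file.path(dir, "out_unmerged_1.fastq"))), 1L)

  # empty inputs: zero counts, valid (empty) outputs
  write_fastq(r1[0, ], f1); write_fastq(r2[0, ], f2)
  stats <- merge_stream(f1, f2, file.path(dir, "empty"))
  expect_equal(stats$pairs, 0L)

  # unequal lengths name the shorter file
  write_fastq(r1, f1); write_fastq(r2[1, ], f2)
  expect_error(merge_stream(f1, f2, file.path(dir, "x")), "r2.fastq")
})

test_that("merged length tracks the true fragment length distribution", {
  txo <- simulate_transcriptome(n_clusters = 0L, rng_seed = 41)
  sim <- simulate_reads(txo, read_sim_config(n_pairs = 4000L, rng_seed = 42))
  res <- merge_pairs(sim$r1, sim$r2)
  truth <- sim$truth[match(sub("/1$", "", res$merged$id), sim$truth$id), ]
  expect_identical(res$merged$fragment, truth$fragment)
  expect_lt(abs(mean(nchar(res$merged$seq)) - mean(truth$fragment)), 2)
})
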