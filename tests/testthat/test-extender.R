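test_that("quality filtering keeps exactly the reads with all bases >= Q", {
  reads <- data.frame(id = c("a", "b", "c"),
                      seq = c("ACGT", "ACGT", "ACGT"),
                      qual = c(int_to_qual(rep(30L, 4)),
                               int_to_qual(c(30L, 29L, 30L, 30L)),
                               int_to_qual(c(60L, 60L, 60L, 60L))),
                      stringsAsFactors = FALSE)
  expect_equal(filter_reads_quality(reads, 30L)$id, c("a", "c"))
  expect_equal(filter_reads_quality(reads, 0L)$id, reads$id)
})

test_that("replicate seeds trim one base from each end", {
  expect_equal(nchar(make_replicates(rand_seq(10), 3L, k = 4L)), c(10L, 8L, 6L))
  s <- rand_seq(40)
  expect_equal(make_replicates(s, 1L, k = 10L), s)
  expect_warning(reps <- make_replicates(rand_seq(102), 20L, k = 100L),
                 "reduced")
  expect_equal(length(reps), 2L)
  expect_error(make_replicates(rand_seq(50), 2L, k = 100L), "shorter than k")
})

test_that("seed tables enforce end-k-mer uniqueness", {
  set.seed(61)
  s1 <- rand_seq(30); s2 <- rand_seq(30)
  st <- build_seed_tables(c(s1, s2), k = 10L)
  expect_equal(length(ls(st$five)), 2L)
  expect_equal(length(ls(st$three)), 2L)

  expect_warning(st <- build_seed_tables(c(s1, s1), k = 10L), "dropped")
  expect_true(st$dropped[2])
  expect_equal(length(ls(st$five)), 1L)

  # a seed whose 5' and 3' k-mers coincide is allowed
  s <- paste0("ACGTACGTAC", rand_seq(15), "ACGTACGTAC")
  st <- build_seed_tables(s, k = 10L)
  expect_false(st$dropped[1])
  expect_equal(get("ACGTACGTAC", st$five), get("ACGTACGTAC", st$three))
})

test_that("try_extend concatenates non-overlapping bases and rotates keys", {
  st <- build_seed_tables("AAAACGTT", k = 4L)
  ev <- try_extend(st, "CGTTGG")
  expect_equal(ev$end, "3p")
  expect_equal(ev$added, "GG")
  expect_equal(st$seeds[1], "AAAACGTTGG")
  expect_false(exists("CGTT", st$three, inherits = FALSE))
  expect_true(exists("TTGG", st$three, inherits = FALSE))

  # same extension through the reverse complement
  st <- build_seed_tables("AAAACGTT", k = 4L)
  ev <- try_extend(st, reverse_complement("CGTTGG"))
  expect_equal(ev$orientation, "revcomp")
  expect_equal(st$seeds[1], "AAAACGTTGG")

  # no shared end k-mer: no event
  st <- build_seed_tables("AAAACGTT", k = 4L)
  expect_null(try_extend(st, "GGGGGG"))
  # read equal to a seed end: zero non-overlapping bases, no event
  expect_null(try_extend(st, "CGTT"))
  expect_equal(st$seeds[1], "AAAACGTT")
})

test_that("C++ and R extension engines agree", {
  set.seed(67)
  tx <- rand_seq(400)
  reads <- tile_reads(tx, read_lengths = c(21L, 25L, 30L), step = 3L)
  seeds <- substr(tx, 181L, 240L)
  cfg <- extender_config(k = 20L, replicates = 5L, cycles = 3L)
  a <- run_extender(seeds, reads, cfg, engine = "cpp")
  b <- run_extender(seeds, reads, cfg, engine = "r")
  expect_identical(a$consensus, b$consensus)
  expect_identical(a$replicate_sequences[[1]], b$replicate_sequences[[1]])
})

test_that("consensus anchors replicates on the seed with plurality voting", {
  seed <- "ACGTACGTGGCCAAT"
  # three identical replicates reproduce themselves
  expect_equal(consensus_sequences(rep(seed, 3), seed, trims = c(0, 0, 0)),
               seed)
  # disagreement at one column goes to the lowest-index replicate
  r1 <- paste0(seed, "A")
  r2 <- paste0(substr(seed, 2, 15), "C")
  expect_equal(consensus_sequences(c(r1, r2), seed, trims = c(0, 1)), r1)
  # a replicate that lost its seed is excluded with a warning
  expect_warning(
    cons <- consensus_sequences(c(seed, "TTTTTTTTTTTTT"), seed,
                                trims = c(0, 1)),
    "excluded")
  expect_equal(cons, seed)
})

test_that("zero cycles returns the seed unchanged", {
  set.seed(71)
  tx <- rand_seq(500)
  reads <- tile_reads(tx)
  seed <- substr(tx, 150L, 320L)
  res <- run_extender(seed, reads, extender_config(cycles = 0L))
  expect_identical(res$consensus, seed)
})

test_that("error-free tiling reads extend a seed to the exact transcript", {
  set.seed(73)
  tx <- rand_seq(1500)
  reads <- tile_reads(tx)  # 1-nt steps, read-length ladder including k + 1
  seed <- substr(tx, 676L, 825L)
  res <- run_extender(seed, reads, extender_config())
  expect_identical(res$consensus, tx)
  expect_equal(res$extended_5p, 675L)
  expect_equal(res$extended_3p, 675L)
  # with error-free reads the replicates never disagree where they overlap,
  # and the seed stays a substring of every replicate
  for (r in res$replicate_sequences[[1]]) {
    expect_true(grepl(r, tx, fixed = TRUE))
  }
})

test_that("a seed unique to one variant never absorbs the other variant", {
  set.seed(79)
  flank5 <- rand_seq(400); flank3 <- rand_seq(400)
  core_a <- rand_seq(300); core_b <- rand_seq(300)
  tx_a <- paste0(flank5, core_a, flank3)
  tx_b <- paste0(flank5, core_b, flank3)
  reads <- rbind(tile_reads(tx_a), tile_reads(tx_b))
  seed <- substr(tx_a, 451L, 600L)  # inside the A-specific core
  res <- run_extender(seed, reads, extender_config())
  expect_identical(res$consensus, tx_a)
})

test_that("de novo mode is deterministic and deduplicates consensi", {
  set.seed(83)
  tx <- rand_seq(600)
  txo <- list(transcripts = data.frame(id = "T1", seq = tx, abundance = 1,
                                       stringsAsFactors = FALSE))
  mr <- simulate_merged_reads(structure(txo, class = "sim_transcriptome"),
                              n_reads = 30000L, rng_seed = 84)
  cfg <- extender_config(n_denovo_seeds = 20L)
  a <- denovo_extender(mr$reads, cfg, rng_seed = 85)
  b <- denovo_extender(mr$reads, cfg, rng_seed = 85)
  expect_identical(a, b)
  expect_equal(anyDuplicated(a$consensus[!a$duplicate]), 0L)
  # every consensus is a genuine substring of the source transcript
  for (cc in a$consensus) expect_true(grepl(cc, tx, fixed = TRUE))
})

test_that("extension only grows seeds and bounds total added bases", {
  set.seed(89)
  tx <- rand_seq(800)
  reads <- tile_reads(tx, read_lengths = c(101L, 120L), step = 2L)
  seeds <- c(substr(tx, 300L, 450L), substr(tx, 500L, 650L))
  res <- run_extender(seeds, reads, extender_config(replicates = 5L))
  expect_true(all(res$length >= nchar(seeds)))
  expect_true(all(res$extended_5p >= 0L & res$extended_3p >= 0L))
  total_added <- sum(nchar(unlist(res$replicate_sequences))) -
    sum(nchar(unlist(lapply(seeds, make_replicates, r = 5L, k = 100L))))
  expect_lte(total_added, sum(nchar(reads$seq)) * 10)
})
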