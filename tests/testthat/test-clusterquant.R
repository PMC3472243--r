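test_that("global alignment handles matches, substitutions and gaps", {
  al <- global_align("ACGT", "ACGT")
  expect_equal(al$matches, 4L)
  expect_equal(al$mismatches, 0L)
  expect_equal(nrow(al$gap_runs), 0L)
  expect_equal(al$score, 0L)

  al <- global_align("ACGT", "AGT")
  expect_equal(nrow(al$gap_runs), 1L)
  expect_equal(al$gap_runs$sequence, "b")
  expect_equal(al$gap_runs$length, 1L)
  expect_equal(al$matches, 3L)

  # ungapping the aligned strings recovers the inputs
  a <- rand_seq(80); b <- rand_seq(70)
  al <- global_align(a, b)
  expect_equal(gsub("-", "", al$aligned_a), a)
  expect_equal(gsub("-", "", al$aligned_b), b)
})

test_that("alignment scores match a brute-force DP oracle on short pairs", {
  set.seed(97)
  for (rep in 1:120) {
    na <- sample(1:30, 1); nb <- sample(1:30, 1)
    a <- rand_seq(na); b <- rand_seq(nb)
    # bias some pairs toward relatedness so gaps actually occur
    if (rep %% 3 == 0 && na > 10) {
      b <- paste0(substr(a, 1, na %/% 2), rand_seq(sample(0:5, 1)),
                  substr(a, na %/% 2 + 2, na))
    }
    expect_equal(global_align(a, b)$score, oracle_align_cost(a, b),
                 info = paste(a, b))
  }
})

test_that("divergence counts mismatches over gap-free columns only", {
  expect_equal(pairwise_divergence("ACGTACGT", "ACGTACGT"), 0)
  set.seed(101)
  a <- rand_seq(200)
  b <- a
  substr(b, 50, 50) <- if (substr(a, 50, 50) == "A") "C" else "A"
  expect_equal(pairwise_divergence(a, b), 1 / 200)

  # a 48-nt insertion does not inflate divergence
  ins <- paste0(substr(a, 1, 100), rand_seq(48), substr(a, 101, 200))
  expect_equal(pairwise_divergence(a, ins), 0)

  # symmetry
  for (i in 1:10) {
    x <- rand_seq(60); y <- rand_seq(60)
    expect_equal(pairwise_divergence(x, y), pairwise_divergence(y, x))
  }
})

test_that("single-linkage chaining joins transitive neighbours", {
  set.seed(103)
  a <- rand_seq(400)
  mutate <- function(s, n) {
    for (p in sample.int(nchar(s), n)) {
      substr(s, p, p) <- sample(setdiff(c("A", "C", "G", "T"),
                                        substr(s, p, p)), 1)
    }
    s
  }
  b <- mutate(a, 2)   # ~0.5% from a
  c_ <- mutate(b, 2)  # ~0.5% from b, ~1-2% from a
  tx <- data.frame(id = c("A", "B", "C"), seq = c(a, b, c_),
                   stringsAsFactors = FALSE)
  cl <- single_linkage_cluster(tx, threshold = 0.01)
  expect_equal(length(unique(cl$cluster)), 1L)

  # all pairwise divergences above the threshold: all singletons
  tx2 <- data.frame(id = c("X", "Y", "Z"),
                    seq = replicate(3, rand_seq(300)),
                    stringsAsFactors = FALSE)
  cl2 <- single_linkage_cluster(tx2, threshold = 0.01)
  expect_equal(length(unique(cl2$cluster)), 3L)
  expect_true(all(is.na(cl2$letter)))

  # clustering is invariant to input order and monotone in the threshold
  perm <- c(3, 1, 2)
  cl3 <- single_linkage_cluster(tx[perm, ], threshold = 0.01)
  expect_equal(length(unique(cl3$cluster)), 1L)
  n_tight <- length(unique(single_linkage_cluster(tx, 0.001)$cluster))
  n_loose <- length(unique(single_linkage_cluster(tx, 0.05)$cluster))
  expect_gte(n_tight, 1L)
  expect_lte(n_loose, n_tight)
})

test_that("cluster naming combines class, number and member letters", {
  set.seed(107)
  mk <- function() rand_seq(200)
  a <- mk(); a2 <- a
  substr(a2, 10, 10) <- if (substr(a, 10, 10) == "A") "G" else "A"
  tx <- data.frame(id = c("s1", "s2", "s3", "s4"),
                   seq = c(a, a2, mk(), mk()),
                   class_label = c("CTL", "CTL", "CTL", "SVSP"),
                   stringsAsFactors = FALSE)
  cl <- name_clusters(single_linkage_cluster(tx))
  expect_setequal(unique(cl$cluster_name[cl$class_label == "CTL"]),
                  c("CTL-1", "CTL-2"))
  expect_equal(cl$cluster_name[cl$class_label == "SVSP"], "SVSP-1")
  two <- cl[cl$id %in% c("s1", "s2"), ]
  expect_setequal(two$letter, c("a", "b"))
  expect_true(all(is.na(cl$letter[cl$id %in% c("s3", "s4")])))

  tx$class_label[2] <- "SVSP"  # mixed-class cluster
  expect_error(name_clusters(single_linkage_cluster(tx)), "mixes class")
})

test_that("indel profiles report single merged gap runs", {
  set.seed(109)
  # deletion variants patterned on the 132-nt and 27-nt splice differences
  for (del in c(132L, 27L)) {
    a <- rand_seq(600)
    b <- paste0(substr(a, 1, 300), substr(a, 301 + del, 600))
    runs <- indel_profile(a, b)
    expect_equal(nrow(runs), 1L)
    expect_equal(runs$sequence, "b")
    expect_equal(runs$length, del)
  }
  expect_equal(nrow(indel_profile("ACGTACGTAA", "ACGTACGTAA")), 0L)
})

test_that("read assignment respects identity threshold and ambiguity rules", {
  set.seed(113)
  refs <- data.frame(id = c("T1", "T2"),
                     seq = c(rand_seq(500), rand_seq(500)),
                     stringsAsFactors = FALSE)
  # exact substring read is assigned to its source
  rd <- substr(refs$seq[1], 101, 250)
  asn <- assign_reads(rd, refs)
  expect_equal(asn$assignments$status, "assigned")
  expect_equal(asn$assignments$ref, "T1")
  expect_equal(asn$assignments$identity, 1)

  # a read with ~10% errors stays unassigned at 95% identity
  noisy <- rd
  for (p in seq(5, 150, by = 10)) {
    substr(noisy, p, p) <- sample(setdiff(c("A", "C", "G", "T"),
                                          substr(noisy, p, p)), 1)
  }
  asn <- assign_reads(noisy, refs)
  expect_equal(asn$assignments$status, "unassigned")

  # identical references: cross-cluster tie discarded, within-cluster kept
  refs2 <- data.frame(id = c("A1", "A2"), seq = refs$seq[1],
                      stringsAsFactors = FALSE)
  asn <- assign_reads(rd, refs2)
  expect_equal(asn$assignments$status, "ambiguous")
  asn <- assign_reads(rd, refs2, clusters = c("c1", "c1"))
  expect_equal(asn$assignments$status, "assigned")
  expect_equal(asn$assignments$cluster, "c1")

  # assigned + ambiguous + unassigned partitions the input
  reads <- c(rd, noisy, substr(refs$seq[2], 1, 140))
  asn <- assign_reads(reads, refs2)
  s <- asn$summary
  expect_equal(s$assigned + s$ambiguous + s$unassigned, s$n_reads)
})

test_that("error-free reads with unique sources recover exact provenance", {
  txo <- simulate_transcriptome(n_clusters = 0L, rng_seed = 127)
  mr <- simulate_merged_reads(txo, n_reads = 3000L, rng_seed = 128)
  refs <- txo$transcripts[, c("id", "seq")]
  asn <- assign_reads(mr$reads, refs, quant_config(min_identity = 1))
  ok <- asn$assignments$status == "assigned"
  expect_gt(mean(ok), 0.99)  # rare multi-source fragments are ambiguous
  expect_equal(asn$assignments$ref[ok],
               mr$truth$source[ok])
})

test_that("abundance tables normalize totals and toxin percentages", {
  counts <- data.frame(target = c("A", "B"), count = c(50L, 50L),
                       stringsAsFactors = FALSE)
  ab <- abundance_table(counts, 200L)
  expect_equal(ab$pct_total_reads, c(25, 25))
  expect_equal(ab$pct_toxin_reads, c(50, 50))

  ab <- abundance_table(data.frame(target = "A", count = 10L), 10L)
  expect_equal(ab$pct_toxin_reads, 100)

  expect_error(abundance_table(counts, 0L), "positive")

  set.seed(131)
  counts <- data.frame(target = paste0("t", 1:12),
                       count = sample(0:500, 12),
                       stringsAsFactors = FALSE)
  flags <- setNames(rep(c(TRUE, FALSE), 6), counts$target)
  ab <- abundance_table(counts, sum(counts$count), flags)
  expect_equal(sum(ab$pct_toxin_reads, na.rm = TRUE), 100, tolerance = 1e-9)
  expect_true(all(diff(ab$pct_total_reads[ab$toxin]) <= 0))
  expect_equal(ab$rank[ab$toxin], seq_len(sum(ab$toxin)))
})
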