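# Independent oracles used to validate the package implementations.

rand_seq <- function(n, alphabet = c("A", "C", "G", "T")) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

# Reference affine-gap global alignment cost (Gotoh, full 3-matrix DP in
# plain R). Same model as global_align: match 0, mismatch 1, gap of
# length g costs gap_open + g * gap_extend, all state transitions allowed.
oracle_align_cost <- function(a, b, mismatch = 1, gap_open = 5,
                              gap_extend = 1) {
  av <- strsplit(a, "")[[1]]
  bv <- strsplit(b, "")[[1]]
  n <- length(av); m <- length(bv)
  INF <- 1e9
  M <- matrix(INF, n + 1, m + 1); X <- M; Y <- M
  M[1, 1] <- 0
  for (i in seq_len(n)) X[i + 1, 1] <- gap_open + i * gap_extend
  for (j in seq_len(m)) Y[1, j + 1] <- gap_open + j * gap_extend
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      sub <- if (av[i] == bv[j] && av[i] != "N") 0 else mismatch
      M[i + 1, j + 1] <- sub + min(M[i, j], X[i, j], Y[i, j])
      X[i + 1, j + 1] <- gap_extend + min(M[i, j + 1] + gap_open,
                                          X[i, j + 1],
                                          Y[i, j + 1] + gap_open)
      Y[i + 1, j + 1] <- gap_extend + min(M[i + 1, j] + gap_open,
                                          X[i + 1, j] + gap_open,
                                          Y[i + 1, j])
    }
  }
  min(M[n + 1, m + 1], X[n + 1, m + 1], Y[n + 1, m + 1])
}

# Exhaustive ATG scan: longest ORF by walking every ATG in every frame.
oracle_longest_orf <- function(seq, min_length_aa = 1L) {
  stops <- c("TAA", "TAG", "TGA")
  best <- NULL
  n <- nchar(seq)
  for (start in seq_len(max(0L, n - 2L))) {
    if (substr(seq, start, start + 2L) != "ATG") next
    pos <- start
    aa <- 0L
    has_stop <- FALSE
    while (pos + 2L <= n) {
      codon <- substr(seq, pos, pos + 2L)
      if (codon %in% stops) { has_stop <- TRUE; break }
      aa <- aa + 1L
      pos <- pos + 3L
    }
    end <- if (has_stop) pos + 3L - 1L else pos - 1L
    if (aa >= min_length_aa &&
        (is.null(best) || aa > best$aa ||
         (aa == best$aa && start < best$start))) {
      best <- list(start = start - 1L, end = end, aa = aa,
                   has_stop = has_stop)
    }
  }
  best
}

# Construct an error-free read pair from a fragment (mate 2 reverse
# complemented), padding with a marker adaptor when the fragment is
# shorter than the read length.
make_pair <- function(fragment, read_length = 100L, qual_char = "I",
                      adaptor = strrep("CTGACGGTACTTAGCACCTGATCGTAGGCTTACG", 4L)) {
  f <- nchar(fragment)
  r1 <- substr(fragment, 1L, read_length)
  r2 <- substr(venomxtend::reverse_complement(fragment), 1L, read_length)
  if (f < read_length) {
    r1 <- paste0(r1, substr(adaptor, 1L, read_length - f))
    r2 <- paste0(r2, substr(adaptor, 1L, read_length - f))
  }
  list(read1 = list(id = "p/1", seq = r1, qual = strrep(qual_char, nchar(r1))),
       read2 = list(id = "p/2", seq = r2, qual = strrep(qual_char, nchar(r2))))
}
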