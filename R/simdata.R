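.sim_classes <- c("MYO", "CTL", "SVMP", "SVSP", "PLA2", "LAAO", "CRISP",
                  "VEGF", "BPP", "NUC", "KUN", "HYAL")

# Fixed synthetic adaptor (not a vendor sequence); long enough to fill any
# read-through when the fragment is shorter than the read.
.sim_adaptor <- paste0("CTGACGGTACTTAGCACCTGATCGTAGGCTTACGATCCAGTGCTAACGT",
                      "GATCCTAGGACTTGCA")

.random_seq <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

.sense_codons <- local({
  b <- c("A", "C", "G", "T")
  all <- as.vector(outer(as.vector(outer(b, b, paste0)), b, paste0))
  setdiff(all, c("TAA", "TAG", "TGA"))
})

# A coding sequence of n_codons sense codons framed by ATG and a stop.
.random_cds <- function(n_codons) {
  paste0("ATG", paste(sample(.sense_codons, n_codons, replace = TRUE),
                      collapse = ""), sample(c("TAA", "TAG", "TGA"), 1L))
}

# Random UTR sequence free of ATG (so the planted initiator is the first).
.random_utr <- function(n) {
  s <- .random_seq(n)
  while (grepl("ATG", s, fixed = TRUE)) s <- gsub("ATG", "ACG", s, fixed = TRUE)
  s
}

# Transcript = 5' UTR + CDS + 3' UTR; returns sequence and 0-based
# half-open CDS interval (stop codon included). The planted CDS is
# guaranteed to be the transcript's longest ORF (rejection sampling
# guards against chance off-frame ORFs outrunning it).
.random_transcript <- function(len, utr_range = c(40L, 80L)) {
  utr5 <- sample(utr_range[1L]:utr_range[2L], 1L)
  utr3 <- sample(utr_range[1L]:utr_range[2L], 1L)
  n_codons <- (len - utr5 - utr3) %/% 3L - 2L
  stopifnot(n_codons >= 20L)
  for (try in 1:50) {
    cds <- .random_cds(n_codons)
    utr3n <- len - utr5 - nchar(cds)
    seq <- paste0(.random_utr(utr5), cds, .random_utr(utr3n))
    o <- longest_orf(seq, min_length_aa = 5L)
    if (nrow(o) == 1L && o$start == utr5 && o$end == utr5 + nchar(cds)) {
      return(list(seq = seq, cds_start = utr5, cds_end = utr5 + nchar(cds)))
    }
  }
  stop("could not plant a dominant CDS; transcript too short")
}

# Zipf weights over ranks with the exponent solved so the top rank gets
# `top_share` of the total.
.zipf_for_top <- function(n, top_share) {
  if (n == 1L) return(1)
  if (top_share <= 1 / n) stop("top_share must exceed 1/n")
  f <- function(a) 1 / sum(seq_len(n)^(-a)) - top_share
  a <- stats::uniroot(f, c(1e-9, 20))$root
  w <- seq_len(n)^(-a)
  w / sum(w)
}

#' Simulate a skewed-abundance transcriptome with planted clusters
#'
#' Generates random transcripts with Zipf-like abundances whose top
#' transcript receives `top_share` of the reads (default 6\%, matching the
#' myotoxin's share of total reads in the study system). The first
#' `n_clusters` transcripts each receive a second cluster member derived
#' from the parent by point substitutions below 1\% divergence; the first
#' cluster's variant additionally carries a 48-nt insertion (the
#' splice-variant pattern). Cluster abundance is split between members
#' (`1 - minor_share` / `minor_share`). Intra-cluster divergence < 1\% and
#' inter-cluster divergence > 2\% are verified at generation time.
#'
#' @param n_transcripts number of base transcripts (= clusters).
#' @param length_range integer range of transcript lengths (nt).
#' @param n_clusters how many transcripts get a near-duplicate member.
#' @param top_share read share of the most abundant transcript.
#' @param minor_share share of a cluster's reads on its minor member.
#' @param insertion_length length of the planted insertion variant block.
#' @param sub_rate substitution rate used to derive cluster members
#'   (must stay below 0.01).
#' @param n_nontoxin how many of the least abundant clusters are labelled
#'   nontoxin (class `NON`).
#' @param rng_seed integer seed; output is byte-identical for a fixed seed.
#' @return An object of class `sim_transcriptome`: a list with
#'   `transcripts` (data frame: `id`, `seq`, `class_label`, `cluster`,
#'   `toxin`, `abundance`, `cds_start`, `cds_end` — 0-based half-open CDS
#'   including the stop codon; each transcript is 5' UTR + CDS + 3' UTR
#'   and the planted CDS is guaranteed to be its longest ORF),
#'   `clusters` (per-cluster summary with planted abundances),
#'   `planted_variants`, `alpha` (fitted Zipf exponent) and `params`.
#' @export
simulate_transcriptome <- function(n_transcripts = 20L,
                                   length_range = c(300L, 600L),
                                   n_clusters = 5L, top_share = 0.06,
                                   minor_share = 0.15,
                                   insertion_length = 48L,
                                   sub_rate = 0.006, n_nontoxin = 5L,
                                   rng_seed = 1L) {
  stopifnot(n_transcripts >= 1L, n_clusters <= n_transcripts,
            length_range[1L] <= length_range[2L], length_range[1L] >= 60L,
            sub_rate < 0.01, minor_share > 0, minor_share < 0.5)
  set.seed(rng_seed)
  lens <- sample(length_range[1L]:length_range[2L], n_transcripts,
                 replace = TRUE)
  ptx <- lapply(lens, .random_transcript)
  parents <- vapply(ptx, `[[`, character(1), "seq")
  cds_start <- vapply(ptx, `[[`, integer(1), "cds_start")
  cds_end <- vapply(ptx, `[[`, integer(1), "cds_end")
  weights <- .zipf_for_top(n_transcripts, top_share)
  alpha <- if (n_transcripts > 1L)
    -log(weights[2L] / weights[1L]) / log(2) else 0
  classes <- rep(.sim_classes, length.out = n_transcripts)
  n_nontoxin <- min(n_nontoxin, max(0L, n_transcripts - n_clusters))
  if (n_nontoxin > 0L) {
    classes[(n_transcripts - n_nontoxin + 1L):n_transcripts] <- "NON"
  }

  ids <- sprintf("TX%03d", seq_len(n_transcripts))
  rows <- list()
  planted <- list()
  for (i in seq_len(n_transcripts)) {
    in_cluster <- i <= n_clusters
    ab <- weights[i]
    if (!in_cluster) {
      rows[[length(rows) + 1L]] <- data.frame(
        id = ids[i], seq = parents[i], class_label = classes[i],
        cluster = i, toxin = classes[i] != "NON", abundance = ab,
        cds_start = cds_start[i], cds_end = cds_end[i],
        stringsAsFactors = FALSE)
      next
    }
    variant <- parents[i]
    n_sub <- max(1L, round(sub_rate * lens[i]))
    pos <- sample.int(lens[i], n_sub)
    for (p in pos) {
      cur <- substr(variant, p, p)
      substr(variant, p, p) <- sample(setdiff(c("A", "C", "G", "T"), cur), 1L)
    }
    ins_at <- NA_integer_
    v_cds_end <- cds_end[i]
    if (i == 1L && insertion_length > 0L) {
      # in-frame sense-codon block inside the CDS (the splice-variant pattern)
      n_cod <- insertion_length %/% 3L
      codon_slots <- seq(cds_start[i] + 3L, cds_end[i] - 6L, by = 3L)
      ins_at <- sample(codon_slots, 1L)
      block <- paste(sample(.sense_codons, n_cod, replace = TRUE),
                     collapse = "")
      if (insertion_length %% 3L)
        block <- paste0(block, .random_seq(insertion_length %% 3L))
      variant <- paste0(substr(variant, 1L, ins_at), block,
                        substr(variant, ins_at + 1L, nchar(variant)))
      v_cds_end <- v_cds_end + insertion_length
    }
    rows[[length(rows) + 1L]] <- data.frame(
      id = c(ids[i], paste0(ids[i], "v")),
      seq = c(parents[i], variant),
      class_label = classes[i], cluster = i, toxin = classes[i] != "NON",
      abundance = c(ab * (1 - minor_share), ab * minor_share),
      cds_start = cds_start[i], cds_end = c(cds_end[i], v_cds_end),
      stringsAsFactors = FALSE)
    planted[[length(planted) + 1L]] <- data.frame(
      cluster = i, parent = ids[i], member = paste0(ids[i], "v"),
      n_substitutions = n_sub, insertion_at = ins_at,
      insertion_length = if (!is.na(ins_at)) insertion_length else 0L,
      stringsAsFactors = FALSE)
  }
  tx <- do.call(rbind, rows)

  # generation-time invariants
  stopifnot(abs(sum(tx$abundance) - 1) < 1e-9)
  for (pv in planted) {
    a <- tx$seq[tx$id == pv$parent]
    b <- tx$seq[tx$id == pv$member]
    stopifnot(pairwise_divergence(a, b) < 0.01)
  }
  dpar <- divergence_matrix(parents, prescreen = TRUE)
  off <- dpar[upper.tri(dpar)]
  stopifnot(all(is.na(off) | off > 0.02))

  structure(list(
    transcripts = tx,
    clusters = data.frame(cluster = seq_len(n_transcripts), parent = ids,
                          class_label = classes,
                          toxin = classes != "NON",
                          abundance = weights, size = ifelse(
                            seq_len(n_transcripts) <= n_clusters, 2L, 1L),
                          stringsAsFactors = FALSE),
    planted_variants = if (length(planted)) do.call(rbind, planted) else NULL,
    alpha = alpha,
    params = list(n_transcripts = n_transcripts, length_range = length_range,
                  n_clusters = n_clusters, top_share = top_share,
                  minor_share = minor_share, sub_rate = sub_rate,
                  insertion_length = insertion_length, rng_seed = rng_seed)),
    class = "sim_transcriptome")
}

#' Read-simulation configuration
#'
#' Defaults reproduce the study library geometry: 100-nt paired reads from
#' fragments of mean ~170 nt (sd 30), with a per-position error rate that
#' rises linearly from the 5' to the 3' end of each read (the 3'-declining
#' quality profile). Insert sizes are truncated to
#' `[read_length/2, 2*read_length + 100]`.
#'
#' @param read_length read length (nt).
#' @param insert_mean,insert_sd insert (fragment) size distribution.
#' @param error_rate_5p,error_rate_3p substitution error rate at the first
#'   and last read position (linearly interpolated between them).
#' @param n_pairs number of read pairs.
#' @param rng_seed integer seed.
#' @return An object of class `read_sim_config`.
#' @export
read_sim_config <- function(read_length = 100L, insert_mean = 170,
                            insert_sd = 30, error_rate_5p = 0,
                            error_rate_3p = 0, n_pairs = 10000L,
                            rng_seed = 1L) {
  stopifnot(read_length >= 20L, insert_mean > 0, insert_sd >= 0,
            error_rate_5p >= 0, error_rate_5p <= 0.2,
            error_rate_3p >= 0, error_rate_3p <= 0.2, n_pairs >= 0L)
  structure(list(read_length = as.integer(read_length),
                 insert_mean = insert_mean, insert_sd = insert_sd,
                 error_rate_5p = error_rate_5p, error_rate_3p = error_rate_3p,
                 n_pairs = as.integer(n_pairs),
                 rng_seed = as.integer(rng_seed)),
            class = "read_sim_config")
}

# Draw fragment coordinates: source transcript, start, length.
.draw_fragments <- function(txome, n, read_length, insert_mean, insert_sd) {
  tx <- txome$transcripts
  lens <- nchar(tx$seq)
  min_insert <- read_length %/% 2L
  ok <- lens >= min_insert
  if (!all(ok)) {
    warning(sum(!ok), " transcript(s) shorter than the minimum insert ",
            "excluded from sampling")
  }
  w <- tx$abundance * ok
  w <- w / sum(w)
  src <- sample.int(nrow(tx), n, replace = TRUE, prob = w)
  f <- as.integer(round(rnorm(n, insert_mean, insert_sd)))
  f <- pmax(min_insert, pmin(f, 2L * read_length + 100L))
  f <- pmin(f, lens[src])
  s <- as.integer(floor(runif(n) * (lens[src] - f + 1)))
  list(src = src, start = s, len = f)
}

# Apply positional substitution errors to reads (vector of sequences).
# Rates are per read position, interpolated 5'->3'. Returns the mutated
# sequences and a list of 1-based error positions per read.
.apply_errors <- function(seqs, rate5, rate3) {
  if (rate5 == 0 && rate3 == 0) {
    return(list(seqs = seqs, errors = NULL, n_errors = integer(length(seqs))))
  }
  bases <- c("A", "C", "G", "T")
  n_err <- integer(length(seqs))
  errors <- vector("list", length(seqs))
  for (i in seq_along(seqs)) {
    L <- nchar(seqs[i])
    if (L == 0L) next
    rate <- rate5 + (rate3 - rate5) * (seq_len(L) - 1) / max(1L, L - 1L)
    hit <- which(runif(L) < rate)
    if (!length(hit)) next
    ch <- strsplit(seqs[i], "", fixed = TRUE)[[1L]]
    for (p in hit) ch[p] <- sample(setdiff(bases, ch[p]), 1L)
    seqs[i] <- paste(ch, collapse = "")
    errors[[i]] <- hit
    n_err[i] <- length(hit)
  }
  list(seqs = seqs, errors = errors, n_errors = n_err)
}

# Quality string for a read of length L under the interpolated error model.
.profile_qual <- function(L, rate5, rate3) {
  rate <- rate5 + (rate3 - rate5) * (seq_len(L) - 1) / max(1L, L - 1L)
  q <- as.integer(round(-10 * log10(pmax(rate, 1e-6))))
  intToUtf8(pmin(q, 60L) + 33L)
}

#' Simulate paired-end reads with full provenance
#'
#' Fragments are drawn from transcripts in proportion to abundance (read
#' share), insert length from a truncated normal; mate 1 is the fragment
#' prefix, mate 2 the reverse-complemented suffix, each clipped to the
#' read length and padded with a fixed synthetic adaptor when the fragment
#' is shorter than the read (read-through). Substitution errors follow the
#' positional rate; phred qualities are derived deterministically from
#' that rate.
#'
#' @param txome a [simulate_transcriptome()] result.
#' @param config a [read_sim_config()].
#' @param detail_errors record per-base error positions in the truth table
#'   (list columns; off by default to keep large simulations light).
#' @return A list with `r1`, `r2` (data frames: `id`, `seq`, `qual`) and
#'   `truth` (data frame: `id`, `source`, `start`, `end` 0-based half-open
#'   on the transcript, `fragment`, `adaptor1`, `adaptor2`, `n_err1`,
#'   `n_err2`, plus `err_pos1`/`err_pos2` when `detail_errors`).
#' @export
simulate_reads <- function(txome, config = read_sim_config(),
                           detail_errors = FALSE) {
  set.seed(config$rng_seed)
  n <- config$n_pairs
  rl <- config$read_length
  tx <- txome$transcripts
  if (n == 0L) {
    empty <- data.frame(id = character(), seq = character(),
                        qual = character(), stringsAsFactors = FALSE)
    return(list(r1 = empty, r2 = empty, truth = data.frame()))
  }
  fr <- .draw_fragments(txome, n, rl, config$insert_mean, config$insert_sd)
  frag <- substring(tx$seq[fr$src], fr$start + 1L, fr$start + fr$len)
  r1 <- substr(frag, 1L, rl)
  r2 <- substr(.revcomp_cpp(frag), 1L, rl)
  pad <- pmax(0L, rl - fr$len)
  need <- pad > 0L
  if (any(need)) {
    ad <- substring(.sim_adaptor, 1L, pad[need])
    r1[need] <- paste0(r1[need], ad)
    r2[need] <- paste0(r2[need], ad)
  }
  e1 <- .apply_errors(r1, config$error_rate_5p, config$error_rate_3p)
  e2 <- .apply_errors(r2, config$error_rate_5p, config$error_rate_3p)
  qual <- .profile_qual(rl, config$error_rate_5p, config$error_rate_3p)
  ids <- sprintf("sim%07d", seq_len(n))
  truth <- data.frame(id = ids, source = tx$id[fr$src], start = fr$start,
                      end = fr$start + fr$len, fragment = fr$len,
                      adaptor1 = pad, adaptor2 = pad,
                      n_err1 = e1$n_errors, n_err2 = e2$n_errors,
                      stringsAsFactors = FALSE)
  if (detail_errors) {
    truth$err_pos1 <- I(if (is.null(e1$errors))
      rep(list(integer()), n) else lapply(e1$errors, function(x)
        if (is.null(x)) integer() else x))
    truth$err_pos2 <- I(if (is.null(e2$errors))
      rep(list(integer()), n) else lapply(e2$errors, function(x)
        if (is.null(x)) integer() else x))
  }
  list(r1 = data.frame(id = paste0(ids, "/1"), seq = e1$seqs, qual = qual,
                       stringsAsFactors = FALSE),
       r2 = data.frame(id = paste0(ids, "/2"), seq = e2$seqs, qual = qual,
                       stringsAsFactors = FALSE),
       truth = truth)
}

#' Simulate already-merged (composite) reads
#'
#' Draws fragments exactly as [simulate_reads()] but emits each fragment
#' as a single read, the shape the Extender consumes after pair merging.
#' Useful for exercising assembly and quantification without the merging
#' stage.
#'
#' @param txome a [simulate_transcriptome()] result.
#' @param n_reads number of fragments.
#' @param read_length,insert_mean,insert_sd as in [read_sim_config()].
#' @param error_rate uniform per-base substitution rate.
#' @param rng_seed integer seed.
#' @return A list with `reads` (data frame `id`, `seq`, `qual`) and
#'   `truth` (as in [simulate_reads()], without mate columns).
#' @export
simulate_merged_reads <- function(txome, n_reads, read_length = 100L,
                                  insert_mean = 170, insert_sd = 30,
                                  error_rate = 0, rng_seed = 1L) {
  set.seed(rng_seed)
  tx <- txome$transcripts
  fr <- .draw_fragments(txome, n_reads, read_length, insert_mean, insert_sd)
  frag <- substring(tx$seq[fr$src], fr$start + 1L, fr$start + fr$len)
  e <- .apply_errors(frag, error_rate, error_rate)
  q60 <- intToUtf8(60L + 33L)
  ids <- sprintf("mrg%07d", seq_len(n_reads))
  qual <- strrep(q60, nchar(e$seqs))
  list(reads = data.frame(id = ids, seq = e$seqs, qual = qual,
                          stringsAsFactors = FALSE),
       truth = data.frame(id = ids, source = tx$id[fr$src], start = fr$start,
                          end = fr$start + fr$len, fragment = fr$len,
                          n_err = e$n_errors, stringsAsFactors = FALSE))
}

#' Tile a transcript with error-free reads
#'
#' Emits every substring of each requested read length at the given start
#' step. A ladder of read lengths that includes `k + 1` guarantees the
#' Extender can refine its seed ends all the way to the transcript
#' termini (a single read length only allows extension steps of exactly
#' `length - k` nt, which strands seed ends in one residue class).
#'
#' @param seq transcript sequence.
#' @param read_lengths vector of read lengths.
#' @param step start-position step (nt).
#' @return A data frame with columns `id`, `seq`, `qual` (uniform Q40).
#' @export
tile_reads <- function(seq, read_lengths = c(101L, 125L, 150L), step = 1L) {
  n <- nchar(seq)
  out <- list()
  for (rl in read_lengths) {
    if (rl > n) next
    starts <- seq(1L, n - rl + 1L, by = step)
    out[[length(out) + 1L]] <- data.frame(
      id = sprintf("tile_%d_%d", rl, starts),
      seq = substring(seq, starts, starts + rl - 1L),
      qual = strrep(intToUtf8(40L + 33L), rl), stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}
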