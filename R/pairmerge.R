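#' Configuration for significance-based pair merging
#'
#' Defaults are the study values: merge only when the smallest overlap
#' probability is below `1e-10` and the second smallest is at least
#' `1000`-fold larger.
#'
#' @param p_threshold probability below which the best overlap is significant.
#' @param ratio_threshold minimum ratio of second-best to best probability.
#' @param min_overlap smallest overlap length scored (nt).
#' @param quality_cap maximum phred quality after recombination.
#' @return An object of class `merge_config`.
#' @export
merge_config <- function(p_threshold = 1e-10, ratio_threshold = 1000,
                         min_overlap = 1L, quality_cap = 60L) {
  stopifnot(p_threshold > 0, p_threshold < 1, ratio_threshold >= 1,
            min_overlap >= 1L, quality_cap >= 0L)
  structure(list(p_threshold = p_threshold, ratio_threshold = ratio_threshold,
                 min_overlap = as.integer(min_overlap),
                 quality_cap = as.integer(quality_cap)),
            class = "merge_config")
}

#' Binomial probability of k matches in an overlap of length n
#'
#' The null model assumes each of the four nucleotides is equally likely at
#' any position, so a position matches by chance with probability 1/4:
#' \eqn{P(k|n) = C(n,k) (1/4)^k (3/4)^{n-k}}. Computed in log space.
#'
#' @param k observed matches (vectorized).
#' @param n overlap length (vectorized).
#' @param log return the log probability.
#' @return Numeric vector of probabilities.
#' @export
binomial_overlap_probability <- function(k, n, log = FALSE) {
  if (any(n < 1L)) stop("overlap length n must be >= 1")
  if (any(k < 0L) || any(k > n)) stop("k must satisfy 0 <= k <= n")
  lp <- lchoose(n, k) + k * base::log(0.25) + (n - k) * base::log(0.75)
  if (log) lp else exp(lp)
}

#' Enumerate all candidate overlaps of a read pair
#'
#' Mate 2 is reverse complemented and slid along mate 1 through every
#' relative offset. Candidates are indexed by the implied fragment length
#' `f` in `[1, len1 + len2 - 1]`; the overlap length is
#' `n(f) = min(len1, len2, f, len1 + len2 - f)`, which covers overlaps where
#' the fragment is shorter than the read (adaptor read-through). N bases
#' never count as matches.
#'
#' @param seq1,seq2 mate sequences (mate 2 in its raw orientation).
#' @param config a [merge_config()].
#' @return Data frame with columns `fragment`, `n`, `k`, `p`, restricted to
#'   candidates with `n >= min_overlap`.
#' @export
enumerate_overlaps <- function(seq1, seq2, config = merge_config()) {
  cand <- .overlap_counts_cpp(seq1, seq2)
  cand <- cand[cand$n >= config$min_overlap, , drop = FALSE]
  cand$p <- binomial_overlap_probability(cand$k, cand$n)
  row.names(cand) <- NULL
  cand
}

#' Decide whether a pair merges given its overlap candidates
#'
#' The best candidate is the one with the smallest probability; the pair is
#' accepted when that probability is below `p_threshold` and the second
#' smallest probability is at least `ratio_threshold` times larger. A tie
#' for the minimum is rejected (`ratio_too_small`). The decision is
#' invariant to candidate ordering.
#'
#' @param candidates data frame as returned by [enumerate_overlaps()].
#' @param config a [merge_config()].
#' @return A list with elements `accepted`, `best` (one-row data frame or
#'   `NULL`), `second_best_p`, `reason` (one of `ok`, `p_too_large`,
#'   `ratio_too_small`, `no_candidate`).
#' @export
decide_merge <- function(candidates, config = merge_config()) {
  if (is.null(candidates) || nrow(candidates) == 0L) {
    return(list(accepted = FALSE, best = NULL, second_best_p = NA_real_,
                reason = "no_candidate"))
  }
  lp <- binomial_overlap_probability(candidates$k, candidates$n, log = TRUE)
  o <- order(lp)
  best <- candidates[o[1L], , drop = FALSE]
  second_lp <- if (nrow(candidates) >= 2L) lp[o[2L]] else Inf
  second_p <- if (is.finite(second_lp)) exp(second_lp) else NA_real_
  if (!(lp[o[1L]] < log(config$p_threshold))) {
    reason <- "p_too_large"; accepted <- FALSE
  } else if (!(second_lp >= lp[o[1L]] + log(config$ratio_threshold))) {
    reason <- "ratio_too_small"; accepted <- FALSE
  } else {
    reason <- "ok"; accepted <- TRUE
  }
  list(accepted = accepted, best = best, second_best_p = second_p,
       reason = reason)
}

#' Recombine one overlapping base pair
#'
#' Agreement sums the qualities (capped); disagreement keeps the
#' higher-quality base with quality `|q1 - q2|`; an exact tie keeps the
#' mate-1 base with quality 0. An N base is replaced by its partner with
#' the partner's quality.
#'
#' @param base1,base2 single bases.
#' @param q1,q2 integer phred qualities.
#' @param quality_cap maximum phred quality.
#' @return A list with elements `base` and `quality`.
#' @export
combine_base <- function(base1, q1, base2, q2, quality_cap = 60L) {
  stopifnot(q1 >= 0, q2 >= 0)
  if (base1 == "N" && base2 == "N") return(list(base = "N", quality = 0L))
  if (base1 == "N") return(list(base = base2, quality = as.integer(q2)))
  if (base2 == "N") return(list(base = base1, quality = as.integer(q1)))
  if (base1 == base2)
    return(list(base = base1, quality = as.integer(min(q1 + q2, quality_cap))))
  if (q1 > q2) return(list(base = base1, quality = as.integer(q1 - q2)))
  if (q2 > q1) return(list(base = base2, quality = as.integer(q2 - q1)))
  list(base = base1, quality = 0L)
}

.merge_reasons <- c("ok", "p_too_large", "ratio_too_small", "no_candidate")

#' Merge a single read pair
#'
#' On acceptance the composite read is the mate-1 prefix, the recombined
#' overlap and the reverse-complemented mate-2 suffix; when the implied
#' fragment is shorter than a read, bases beyond the fragment are treated
#' as adaptor read-through and deleted. Qualities outside the overlap are
#' left unchanged.
#'
#' @param read1,read2 lists (or one-row data frames) with `id`, `seq`, `qual`.
#' @param config a [merge_config()].
#' @return A list with `accepted`, `reason`, and on acceptance `merged`
#'   (list with `id`, `seq`, `qual`), `overlap_n`, `fragment`,
#'   `trimmed_adaptor_nt` (named vector, left = mate 1, right = mate 2).
#' @export
merge_pair <- function(read1, read2, config = merge_config()) {
  res <- .merge_pairs_cpp(read1$seq, read1$qual, read2$seq, read2$qual,
                          config$p_threshold, config$ratio_threshold,
                          config$min_overlap, config$quality_cap)
  reason <- .merge_reasons[res$reason[1L] + 1L]
  if (!res$accepted[1L]) {
    return(list(accepted = FALSE, reason = reason,
                best_p = res$best_p[1L], second_best_p = res$second_p[1L]))
  }
  list(accepted = TRUE, reason = reason,
       merged = list(id = read1$id, seq = res$seq[1L], qual = res$qual[1L]),
       overlap_n = res$overlap_n[1L], fragment = res$fragment[1L],
       trimmed_adaptor_nt = c(left = res$trimmed1[1L], right = res$trimmed2[1L]),
       best_p = res$best_p[1L], second_best_p = res$second_p[1L])
}

#' Merge a batch of read pairs
#'
#' @param reads1,reads2 data frames with columns `id`, `seq`, `qual`, mates
#'   in matched order.
#' @param config a [merge_config()].
#' @return A list with `merged` (data frame: `id`, `seq`, `qual`,
#'   `overlap_n`, `fragment`, `trimmed1`, `trimmed2`), `unmerged1`,
#'   `unmerged2` (the rejected pairs), and `stats` (pair count, merged count
#'   and fraction, mean merged length and quality, rejection reasons).
#' @export
merge_pairs <- function(reads1, reads2, config = merge_config()) {
  if (nrow(reads1) != nrow(reads2)) {
    shorter <- if (nrow(reads1) < nrow(reads2)) "reads1" else "reads2"
    stop("mate sets differ in length; ", shorter, " is shorter")
  }
  if (nrow(reads1) == 0L) {
    empty <- reads1[0L, ]
    return(list(
      merged = data.frame(id = character(), seq = character(),
                          qual = character(), overlap_n = integer(),
                          fragment = integer(), trimmed1 = integer(),
                          trimmed2 = integer(), stringsAsFactors = FALSE),
      unmerged1 = empty, unmerged2 = empty,
      stats = list(pairs = 0L, merged = 0L, merged_fraction = NA_real_,
                   mean_merged_length = NA_real_, mean_merged_quality = NA_real_,
                   reasons = table(factor(character(), .merge_reasons)))))
  }
  res <- .merge_pairs_cpp(reads1$seq, reads1$qual, reads2$seq, reads2$qual,
                          config$p_threshold, config$ratio_threshold,
                          config$min_overlap, config$quality_cap)
  acc <- res$accepted
  merged <- data.frame(id = reads1$id[acc], seq = res$seq[acc],
                       qual = res$qual[acc], overlap_n = res$overlap_n[acc],
                       fragment = res$fragment[acc],
                       trimmed1 = res$trimmed1[acc], trimmed2 = res$trimmed2[acc],
                       stringsAsFactors = FALSE)
  stats <- list(
    pairs = nrow(reads1), merged = sum(acc),
    merged_fraction = mean(acc),
    mean_merged_length = if (any(acc)) mean(nchar(merged$seq)) else NA_real_,
    mean_merged_quality = res$mean_quality,
    reasons = table(factor(.merge_reasons[res$reason + 1L],
                           levels = .merge_reasons)))
  list(merged = merged, unmerged1 = reads1[!acc, , drop = FALSE],
       unmerged2 = reads2[!acc, , drop = FALSE], stats = stats)
}

#' Merge two FASTQ files and write the results
#'
#' Writes `<prefix>_merged.fastq`, `<prefix>_unmerged_1.fastq`,
#' `<prefix>_unmerged_2.fastq` and `<prefix>_stats.json`.
#'
#' @param fastq1,fastq2 input FASTQ paths (mates in matched order).
#' @param out_prefix output path prefix.
#' @param config a [merge_config()].
#' @return The summary statistics, invisibly.
#' @export
merge_stream <- function(fastq1, fastq2, out_prefix, config = merge_config()) {
  r1 <- read_fastq(fastq1)
  r2 <- read_fastq(fastq2)
  if (nrow(r1) != nrow(r2)) {
    shorter <- if (nrow(r1) < nrow(r2)) fastq1 else fastq2
    stop("unequal FASTQ lengths; ", shorter, " is shorter")
  }
  res <- merge_pairs(r1, r2, config)
  write_fastq(res$merged[, c("id", "seq", "qual")],
              paste0(out_prefix, "_merged.fastq"))
  write_fastq(res$unmerged1, paste0(out_prefix, "_unmerged_1.fastq"))
  write_fastq(res$unmerged2, paste0(out_prefix, "_unmerged_2.fastq"))
  stats <- res$stats
  stats$reasons <- as.list(stats$reasons)
  jsonlite::write_json(stats, paste0(out_prefix, "_stats.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(res$stats)
}
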