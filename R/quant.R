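#' Configuration for read-count quantification
#'
#' @param min_identity minimum identity (matches / read length) for a read
#'   to be assigned; default 0.95 as in high-stringency reference mapping.
#' @param sample_size number of reads subsampled for quantification
#'   (`NULL` = all).
#' @param kmer k-mer length of the shared-k-mer candidate prefilter.
#' @param band half-width of the banded alignment used to rescue gapped
#'   candidates.
#' @return An object of class `quant_config`.
#' @export
quant_config <- function(min_identity = 0.95, sample_size = NULL,
                         kmer = 31L, band = 12L) {
  stopifnot(min_identity > 0, min_identity <= 1)
  structure(list(min_identity = min_identity, sample_size = sample_size,
                 kmer = as.integer(kmer), band = as.integer(band)),
            class = "quant_config")
}

#' Assign reads to reference transcripts at a minimum identity
#'
#' Candidate references share at least one k-mer with the read; each
#' candidate is scored ungapped on the best shared diagonal (with a banded
#' semi-global rescue for near-threshold candidates), and identity is
#' matches divided by read length. A read goes to the best reference at or
#' above `min_identity`. Ties spanning different clusters are discarded as
#' ambiguous; ties within one cluster are assigned to the cluster, which
#' is how reads that cannot be assigned uniquely below the clustering
#' threshold are counted.
#'
#' @param reads character vector of read sequences, or a data frame with a
#'   `seq` column.
#' @param refs data frame with columns `id`, `seq`.
#' @param config a [quant_config()].
#' @param clusters optional vector (parallel to `refs`) of cluster labels;
#'   defaults to one cluster per reference.
#' @param rng_seed seed used when `sample_size` subsampling is requested.
#' @return A list with `assignments` (data frame: `read`, `ref`, `cluster`,
#'   `identity`, `status` in assigned/ambiguous/unassigned), `counts`
#'   (data frame: `target`, `count`, cluster-level), and `summary`
#'   (`n_reads`, `assigned`, `ambiguous`, `unassigned`).
#' @export
assign_reads <- function(reads, refs, config = quant_config(),
                         clusters = NULL, rng_seed = NULL) {
  read_seq <- if (is.data.frame(reads)) reads$seq else as.character(reads)
  stopifnot(nrow(refs) >= 1L)
  if (is.null(clusters)) clusters <- refs$id
  clusters <- as.character(clusters)
  stopifnot(length(clusters) == nrow(refs))
  if (!is.null(config$sample_size) && length(read_seq) > config$sample_size) {
    if (!is.null(rng_seed)) set.seed(rng_seed)
    read_seq <- read_seq[sample.int(length(read_seq), config$sample_size)]
  }
  cl_levels <- unique(clusters)
  cl_idx <- match(clusters, cl_levels)
  res <- .assign_reads_cpp(read_seq, refs$seq, cl_idx, config$kmer,
                           config$min_identity, config$band)
  status <- ifelse(is.na(res$cluster), "unassigned",
                   ifelse(res$cluster == -1L, "ambiguous", "assigned"))
  assignments <- data.frame(
    read = seq_along(read_seq),
    ref = ifelse(is.na(res$best_ref), NA_character_, refs$id[res$best_ref]),
    cluster = ifelse(status == "assigned", cl_levels[pmax(res$cluster, 1L)],
                     NA_character_),
    identity = res$identity, status = status, stringsAsFactors = FALSE)
  counts <- table(factor(assignments$cluster, levels = cl_levels))
  list(assignments = assignments,
       counts = data.frame(target = cl_levels, count = as.integer(counts),
                           stringsAsFactors = FALSE),
       summary = list(n_reads = length(read_seq),
                      assigned = sum(status == "assigned"),
                      ambiguous = sum(status == "ambiguous"),
                      unassigned = sum(status == "unassigned")))
}

#' Abundance table from assigned read counts
#'
#' Abundance is the percentage of reads assigned to each target; for
#' toxin-flagged targets the percentage of toxin-assigned reads is also
#' reported. Records are sorted by descending total-read percentage within
#' the toxin and nontoxin partitions, with a rank within each partition.
#'
#' @param counts data frame with columns `target`, `count` (e.g. from
#'   [assign_reads()]).
#' @param total_reads denominator for `pct_total_reads` (the number of
#'   reads used for quantification).
#' @param toxin_flags named logical vector (names = targets) or logical
#'   vector parallel to `counts`; defaults to all toxin.
#' @return A data frame: `rank`, `target`, `toxin`, `count`,
#'   `pct_total_reads`, `pct_toxin_reads`.
#' @export
abundance_table <- function(counts, total_reads, toxin_flags = NULL) {
  if (total_reads <= 0L) stop("total_reads must be positive")
  if (is.null(toxin_flags)) {
    toxin <- rep(TRUE, nrow(counts))
  } else if (!is.null(names(toxin_flags))) {
    toxin <- as.logical(toxin_flags[counts$target])
    toxin[is.na(toxin)] <- FALSE
  } else {
    stopifnot(length(toxin_flags) == nrow(counts))
    toxin <- as.logical(toxin_flags)
  }
  toxin_total <- sum(counts$count[toxin])
  out <- data.frame(target = counts$target, toxin = toxin,
                    count = counts$count,
                    pct_total_reads = 100 * counts$count / total_reads,
                    pct_toxin_reads = ifelse(toxin & toxin_total > 0,
                                             100 * counts$count / toxin_total,
                                             NA_real_),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$toxin, -out$pct_total_reads, out$target), , drop = FALSE]
  out$rank <- stats::ave(seq_len(nrow(out)), out$toxin,
                         FUN = seq_along)
  row.names(out) <- NULL
  out[, c("rank", "target", "toxin", "count", "pct_total_reads",
          "pct_toxin_reads")]
}
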