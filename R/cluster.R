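#' Optimal global alignment with affine gap costs
#'
#' Cost-minimizing Needleman-Wunsch/Gotoh alignment: match 0, mismatch 1,
#' a gap of length g costs `gap_open + g * gap_extend` (defaults 5 and 1).
#' The traceback is deterministic: on ties the diagonal is preferred, then
#' a gap in `b`, then a gap in `a`. N never matches.
#'
#' @param a,b nucleotide sequences (single strings).
#' @param match,mismatch,gap_open,gap_extend cost parameters.
#' @return A list of class `pairwise_alignment` with `aligned_a`,
#'   `aligned_b` (equal-length gapped strings), `score`, `matches`,
#'   `mismatches`, and `gap_runs` (data frame: `sequence` = which input is
#'   gapped, `start` = 0-based alignment column, `length`).
#' @export
global_align <- function(a, b, match = 0L, mismatch = 1L, gap_open = 5L,
                         gap_extend = 1L) {
  stopifnot(length(a) == 1L, length(b) == 1L, nzchar(a), nzchar(b))
  res <- .global_align_cpp(a, b, match, mismatch, gap_open, gap_extend)
  class(res) <- "pairwise_alignment"
  res
}

#' Nucleotide divergence over gap-free alignment columns
#'
#' Divergence is mismatches / (matches + mismatches) over the gap-free
#' columns of the optimal global alignment; gapped columns are excluded
#' entirely, so an insertion (e.g. a 48-nt splice-variant block) does not
#' inflate the divergence between otherwise identical sequences.
#'
#' @param a,b nucleotide sequences.
#' @param alignment optionally, a precomputed [global_align()] result.
#' @return Divergence as a fraction in [0, 1].
#' @export
pairwise_divergence <- function(a, b, alignment = NULL) {
  if (identical(a, b)) return(0)
  if (is.null(alignment)) alignment <- global_align(a, b)
  tot <- alignment$matches + alignment$mismatches
  if (tot == 0L) stop("no gap-free columns; divergence undefined")
  alignment$mismatches / tot
}

#' Pairwise divergence matrix
#'
#' Computes [pairwise_divergence()] for every pair. With `prescreen = TRUE`
#' pairs sharing no k-mer of length `prescreen_k` are not aligned and get
#' `NA` (they are far beyond any clustering threshold of interest; safe for
#' thresholds up to ~5\%).
#'
#' @param seqs character vector of sequences.
#' @param prescreen skip alignment for pairs sharing no k-mer.
#' @param prescreen_k k-mer length for the prescreen.
#' @return A symmetric numeric matrix (`NA` for prescreened-out pairs).
#' @export
divergence_matrix <- function(seqs, prescreen = TRUE, prescreen_k = 31L) {
  n <- length(seqs)
  d <- matrix(NA_real_, n, n)
  diag(d) <- 0
  if (n < 2L) return(d)
  kmers <- NULL
  if (prescreen) {
    kmers <- lapply(seqs, function(s) {
      if (nchar(s) < prescreen_k) return(s)
      unique(substring(s, 1:(nchar(s) - prescreen_k + 1L),
                       prescreen_k:nchar(s)))
    })
  }
  for (i in 1:(n - 1L)) {
    for (j in (i + 1L):n) {
      if (prescreen && !any(kmers[[i]] %in% kmers[[j]])) next
      d[i, j] <- d[j, i] <- pairwise_divergence(seqs[i], seqs[j])
    }
  }
  d
}

#' Single-linkage clustering at a divergence threshold
#'
#' Transcripts are joined whenever their pairwise divergence is below the
#' threshold; clusters are the connected components (single linkage).
#' Members within a cluster are ordered by descending length, then id; the
#' representative is the longest member. Clusters are ordered by
#' descending total abundance when an `abundance` column is present,
#' otherwise by representative id.
#'
#' @param transcripts data frame with columns `id`, `seq`, optionally
#'   `class_label`, `abundance`, and optionally `cds_start`/`cds_end`
#'   (0-based half-open; when present, divergence is computed on the CDS).
#' @param threshold divergence threshold (default 0.01, i.e. <1\%).
#' @param prescreen passed to [divergence_matrix()].
#' @return A data frame with one row per transcript: `id`, `cluster`
#'   (integer), `member` (order within cluster), `letter` (`a`, `b`, ...;
#'   `NA` for singletons), `representative` (logical), plus any
#'   `class_label` column carried through.
#' @export
single_linkage_cluster <- function(transcripts, threshold = 0.01,
                                   prescreen = TRUE) {
  stopifnot(nrow(transcripts) >= 1L, threshold > 0, threshold < 1)
  seqs <- transcripts$seq
  if (!is.null(transcripts$cds_start) && !is.null(transcripts$cds_end)) {
    has <- !is.na(transcripts$cds_start) & !is.na(transcripts$cds_end)
    seqs[has] <- substr(transcripts$seq[has], transcripts$cds_start[has] + 1L,
                        transcripts$cds_end[has])
  }
  n <- length(seqs)
  d <- divergence_matrix(seqs, prescreen = prescreen)
  # union-find over edges with divergence < threshold
  parent <- seq_len(n)
  find <- function(x) {
    while (parent[x] != x) {
      parent[x] <<- parent[parent[x]]
      x <- parent[x]
    }
    x
  }
  if (n >= 2L) {
    for (i in 1:(n - 1L)) {
      for (j in (i + 1L):n) {
        if (!is.na(d[i, j]) && d[i, j] < threshold) {
          ri <- find(i); rj <- find(j)
          if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
        }
      }
    }
  }
  comp <- vapply(seq_len(n), find, integer(1))
  groups <- split(seq_len(n), comp)
  # cluster order: descending total abundance, else representative id
  ab <- transcripts$abundance
  key <- vapply(groups, function(g) {
    if (!is.null(ab)) -sum(ab[g]) else 0
  }, numeric(1))
  rep_id <- vapply(groups, function(g) {
    lens <- nchar(transcripts$seq[g])
    transcripts$id[g[order(-lens, transcripts$id[g])[1L]]]
  }, character(1))
  ord <- if (!is.null(ab)) order(key, rep_id) else order(rep_id)
  groups <- groups[ord]

  out <- data.frame(id = transcripts$id, cluster = NA_integer_,
                    member = NA_integer_, letter = NA_character_,
                    representative = FALSE, stringsAsFactors = FALSE)
  if (!is.null(transcripts$class_label)) out$class_label <- transcripts$class_label
  for (ci in seq_along(groups)) {
    g <- groups[[ci]]
    g <- g[order(-nchar(transcripts$seq[g]), transcripts$id[g])]
    out$cluster[g] <- ci
    out$member[g] <- seq_along(g)
    if (length(g) > 1L) out$letter[g] <- letters[seq_along(g)]
    out$representative[g[1L]] <- TRUE
  }
  out
}

#' Name clusters by toxin class
#'
#' Cluster names combine the class abbreviation and a per-class cluster
#' number (`CTL-1`, `CTL-2`, ...); members of multi-member clusters carry
#' lower-case letters (`CTL-3b`), singletons none. A cluster mixing class
#' labels is an error.
#'
#' @param clusters result of [single_linkage_cluster()] (must carry
#'   `class_label`).
#' @return `clusters` with added columns `cluster_name` and `member_name`.
#' @export
name_clusters <- function(clusters) {
  if (is.null(clusters$class_label))
    stop("class labels required to name clusters")
  out <- clusters
  out$cluster_name <- NA_character_
  counter <- new.env(parent = emptyenv())
  for (ci in sort(unique(out$cluster))) {
    g <- which(out$cluster == ci)
    cls <- unique(out$class_label[g])
    if (length(cls) != 1L) {
      stop("cluster ", ci, " mixes class labels (",
           paste(cls, collapse = ", "), "); members: ",
           paste(out$id[g], collapse = ", "))
    }
    i <- (get0(cls, envir = counter, ifnotfound = 0L)) + 1L
    assign(cls, i, envir = counter)
    out$cluster_name[g] <- paste0(cls, "-", i)
  }
  out$member_name <- ifelse(is.na(out$letter), out$cluster_name,
                            paste0(out$cluster_name, out$letter))
  out
}

#' Indel profile of a pair of sequences
#'
#' Reports the gap runs of the optimal global alignment: which sequence is
#' gapped, the 0-based alignment column where the run starts, and its
#' length. Adjacent runs in the same sequence are merged.
#'
#' @param a,b nucleotide sequences.
#' @return A data frame with columns `sequence` (`"a"` or `"b"`), `start`,
#'   `length`.
#' @export
indel_profile <- function(a, b) {
  if (identical(a, b)) {
    return(data.frame(sequence = character(), start = integer(),
                      length = integer(), stringsAsFactors = FALSE))
  }
  al <- global_align(a, b)
  runs <- al$gap_runs
  if (nrow(runs) < 2L) return(runs)
  # merge same-sequence runs separated by zero columns
  keep <- rep(TRUE, nrow(runs))
  for (i in 2:nrow(runs)) {
    prev <- max(which(keep[1:(i - 1L)]))
    if (runs$sequence[i] == runs$sequence[prev] &&
        runs$start[prev] + runs$length[prev] == runs$start[i]) {
      runs$length[prev] <- runs$length[prev] + runs$length[i]
      keep[i] <- FALSE
    }
  }
  runs[keep, , drop = FALSE]
}
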