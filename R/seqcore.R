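#' Reverse complement of nucleotide sequences
#'
#' Alphabet {A,C,G,T,N}; N complements to N. Vectorized; an involution.
#'
#' @param x character vector of sequences.
#' @return Character vector of reverse complements.
#' @export
reverse_complement <- function(x) {
  .revcomp_cpp(as.character(x))
}

#' Translate coding sequences with the standard genetic code
#'
#' Codons containing N translate to `X`. A trailing stop codon yields no
#' residue; an internal stop truncates the protein and is flagged in the
#' `internal_stop` attribute (with a warning).
#'
#' @param cds character vector of coding sequences, lengths divisible by 3.
#' @return Character vector of proteins, with a logical attribute
#'   `internal_stop`.
#' @export
translate_cds <- function(cds) {
  cds <- toupper(as.character(cds))
  if (any(nchar(cds) %% 3L != 0L))
    stop("coding sequence length must be divisible by 3")
  code <- Biostrings::GENETIC_CODE
  out <- character(length(cds))
  internal <- logical(length(cds))
  for (i in seq_along(cds)) {
    n <- nchar(cds[i])
    if (n == 0L) next
    codons <- substring(cds[i], seq(1L, n, 3L), seq(3L, n, 3L))
    aa <- unname(code[codons])
    aa[is.na(aa)] <- "X"
    stops <- which(aa == "*")
    if (length(stops)) {
      if (stops[1L] < length(aa)) {
        internal[i] <- TRUE
        warning("internal stop codon in sequence ", i, "; translation truncated")
      }
      aa <- aa[seq_len(stops[1L] - 1L)]
    }
    out[i] <- paste(aa, collapse = "")
  }
  attr(out, "internal_stop") <- internal
  out
}

.stop_codons <- c("TAA", "TAG", "TGA")

# ORFs (ATG..stop) in the three forward frames of one strand.
# Returns 0-based half-open coordinates including the stop codon when present.
.orfs_one_strand <- function(seq, strand) {
  n <- nchar(seq)
  res <- list()
  for (frame in 0:2) {
    if (frame + 1L > n - 2L) next
    starts <- seq(frame + 1L, n - 2L, by = 3L)
    codons <- substring(seq, starts, starts + 2L)
    atg <- which(codons == "ATG")
    if (!length(atg)) next
    stp <- which(codons %in% .stop_codons)
    # first stop at or after each ATG
    nxt <- stp[findInterval(atg - 1L, stp) + 1L]
    has_stop <- !is.na(nxt)
    end_codon <- ifelse(has_stop, nxt, length(codons))
    # residues incl. Met; stop codon excluded, a no-stop run keeps all codons
    aa_len <- end_codon - atg + ifelse(has_stop, 0L, 1L)
    keep <- aa_len >= 1L
    if (!any(keep)) next
    res[[length(res) + 1L]] <- data.frame(
      start = frame + (atg[keep] - 1L) * 3L,
      end = frame + end_codon[keep] * 3L,
      frame = frame, strand = strand,
      aa_len = aa_len[keep], has_stop = has_stop[keep],
      stringsAsFactors = FALSE)
  }
  if (!length(res)) return(NULL)
  do.call(rbind, res)
}

#' Longest open reading frame of a transcript
#'
#' Scans the three forward frames (six with `search_reverse`) for the
#' longest ATG-to-stop ORF. Ties are broken by smallest start coordinate,
#' then lowest frame index (forward strand preferred). An ORF running off
#' the transcript end is reported with `has_stop = FALSE` and does not
#' qualify as a full-length coding sequence. Coordinates are 0-based,
#' half-open, on the reported strand, and include the stop codon.
#'
#' @param sequence a single nucleotide sequence.
#' @param search_reverse also scan the reverse complement.
#' @param min_length_aa minimum protein length (residues, including the
#'   initiator Met) for an ORF to be reported.
#' @return A one-row data frame with columns `start`, `end`, `frame`,
#'   `strand`, `protein`, `aa_len`, `has_stop`; zero rows when no ORF of
#'   the minimum length exists.
#' @export
longest_orf <- function(sequence, search_reverse = FALSE, min_length_aa = 30L) {
  stopifnot(length(sequence) == 1L, nzchar(sequence))
  sequence <- toupper(sequence)
  orfs <- .orfs_one_strand(sequence, "+")
  if (search_reverse) {
    orfs <- rbind(orfs, .orfs_one_strand(reverse_complement(sequence), "-"))
  }
  empty <- data.frame(start = integer(), end = integer(), frame = integer(),
                      strand = character(), protein = character(),
                      aa_len = integer(), has_stop = logical(),
                      stringsAsFactors = FALSE)
  if (is.null(orfs)) return(empty)
  orfs <- orfs[orfs$aa_len >= min_length_aa, , drop = FALSE]
  if (!nrow(orfs)) return(empty)
  ord <- order(-orfs$aa_len, orfs$strand != "+", orfs$start, orfs$frame)
  best <- orfs[ord[1L], , drop = FALSE]
  src <- if (best$strand == "+") sequence else reverse_complement(sequence)
  cds <- substr(src, best$start + 1L, best$end)
  if (best$has_stop) {
    prot <- translate_cds(cds)
  } else {
    prot <- translate_cds(substr(cds, 1L, (nchar(cds) %/% 3L) * 3L))
  }
  data.frame(start = best$start, end = best$end, frame = best$frame,
             strand = best$strand, protein = as.character(prot),
             aa_len = best$aa_len, has_stop = best$has_stop,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' ORF table for a set of transcripts
#'
#' Applies [longest_orf()] to each transcript and returns one row per
#' transcript (rows with `NA` where no qualifying ORF exists).
#'
#' @param transcripts data frame with columns `id`, `seq`.
#' @inheritParams longest_orf
#' @return Data frame with columns `id`, `start`, `end`, `frame`, `strand`,
#'   `precursor_aa`, `has_stop`.
#' @export
orf_table <- function(transcripts, search_reverse = FALSE, min_length_aa = 30L) {
  rows <- lapply(seq_len(nrow(transcripts)), function(i) {
    o <- longest_orf(transcripts$seq[i], search_reverse, min_length_aa)
    if (!nrow(o)) {
      data.frame(id = transcripts$id[i], start = NA_integer_, end = NA_integer_,
                 frame = NA_integer_, strand = NA_character_,
                 precursor_aa = NA_integer_, has_stop = NA,
                 stringsAsFactors = FALSE)
    } else {
      data.frame(id = transcripts$id[i], start = o$start, end = o$end,
                 frame = o$frame, strand = o$strand, precursor_aa = o$aa_len,
                 has_stop = o$has_stop, stringsAsFactors = FALSE)
    }
  })
  do.call(rbind, rows)
}
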