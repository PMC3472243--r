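#' Read a FASTQ file (phred+33)
#'
#' Streams 4-line FASTQ records into a data frame. Qualities are kept as
#' phred+33 strings; use [qual_to_int()] to decode.
#'
#' @param path path to an uncompressed FASTQ file.
#' @return A data frame with columns `id`, `seq`, `qual` (one row per read).
#' @export
read_fastq <- function(path) {
  if (!file.exists(path)) stop("FASTQ file not found: ", path)
  lines <- readLines(path)
  n <- length(lines)
  if (n == 0L) {
    return(data.frame(id = character(), seq = character(),
                      qual = character(), stringsAsFactors = FALSE))
  }
  if (n %% 4L != 0L) {
    stop("malformed FASTQ (", path, "): ", n,
         " lines is not a multiple of 4; truncated record begins at line ",
         (n %/% 4L) * 4L + 1L)
  }
  hdr <- lines[seq(1L, n, by = 4L)]
  seq <- lines[seq(2L, n, by = 4L)]
  sep <- lines[seq(3L, n, by = 4L)]
  qual <- lines[seq(4L, n, by = 4L)]
  bad <- which(!startsWith(hdr, "@"))
  if (length(bad)) {
    stop("malformed FASTQ (", path, "): header at line ", (bad[1L] - 1L) * 4L + 1L,
         " does not start with '@'")
  }
  bad <- which(!startsWith(sep, "+"))
  if (length(bad)) {
    stop("malformed FASTQ (", path, "): separator at line ", (bad[1L] - 1L) * 4L + 3L,
         " does not start with '+'")
  }
  bad <- which(nchar(seq) != nchar(qual))
  if (length(bad)) {
    stop("malformed FASTQ (", path, "): sequence/quality length mismatch for ",
         "record at line ", (bad[1L] - 1L) * 4L + 1L)
  }
  data.frame(id = sub("^@", "", hdr), seq = seq, qual = qual,
             stringsAsFactors = FALSE)
}

#' Write reads to a FASTQ file (phred+33)
#'
#' @param reads data frame with columns `id`, `seq`, `qual`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path) {
  stopifnot(all(c("id", "seq", "qual") %in% names(reads)))
  if (any(nchar(reads$seq) != nchar(reads$qual)))
    stop("sequence/quality length mismatch")
  out <- character(4L * nrow(reads))
  if (nrow(reads)) {
    out[seq(1L, length(out), by = 4L)] <- paste0("@", reads$id)
    out[seq(2L, length(out), by = 4L)] <- reads$seq
    out[seq(3L, length(out), by = 4L)] <- "+"
    out[seq(4L, length(out), by = 4L)] <- reads$qual
  }
  writeLines(out, path)
  invisible(path)
}

#' Read a FASTA file of transcripts
#'
#' Wrapped and unwrapped FASTA are both accepted (Biostrings does the
#' parsing). Duplicate ids are kept but disambiguated with a numeric
#' suffix, with a warning.
#'
#' @param path path to a FASTA file.
#' @return A data frame with columns `id`, `seq`, `desc` (the remainder of
#'   the header line, possibly empty).
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  ss <- Biostrings::readDNAStringSet(path)
  hdr <- names(ss)
  id <- sub("\\s.*$", "", hdr)
  desc <- ifelse(grepl("\\s", hdr), sub("^\\S+\\s+", "", hdr), "")
  if (anyDuplicated(id)) {
    warning("duplicate FASTA ids in ", path, "; disambiguating")
    id <- make.unique(id, sep = ".")
  }
  data.frame(id = id, seq = as.character(ss), desc = desc,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Write transcripts to a FASTA file
#'
#' @param transcripts data frame with columns `id`, `seq` and optionally
#'   `desc` (appended to the header line).
#' @param path output path.
#' @param width line wrap width.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(transcripts, path, width = 70L) {
  stopifnot(all(c("id", "seq") %in% names(transcripts)))
  ss <- Biostrings::DNAStringSet(transcripts$seq)
  hdr <- transcripts$id
  if (!is.null(transcripts$desc)) {
    has <- !is.na(transcripts$desc) & nzchar(transcripts$desc)
    hdr[has] <- paste(hdr[has], transcripts$desc[has])
  }
  names(ss) <- hdr
  Biostrings::writeXStringSet(ss, path, width = width)
  invisible(path)
}

#' Decode phred+33 quality strings to integer vectors
#'
#' @param qual character vector of phred+33 strings.
#' @return A list of integer vectors.
#' @export
qual_to_int <- function(qual) {
  lapply(qual, function(q) {
    if (is.na(q) || !nzchar(q)) return(integer())
    utf8ToInt(q) - 33L
  })
}

#' Encode integer phred scores as phred+33 strings
#'
#' @param q list of integer vectors (or a single integer vector).
#' @return A character vector.
#' @export
int_to_qual <- function(q) {
  if (is.numeric(q)) q <- list(q)
  vapply(q, function(x) {
    if (!length(x)) return("")
    if (any(x < 0)) stop("phred scores must be >= 0")
    intToUtf8(pmin(x, 93L) + 33L)
  }, character(1))
}
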