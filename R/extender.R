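#' Configuration for the Extender
#'
#' Defaults are the study values: k-mer length 100, 20 replicate seeds,
#' 10 cycles through the read list, reads discarded if any base is below
#' Q30, and 1000 random seeds in de novo mode.
#'
#' @param k end k-mer length (nt).
#' @param replicates number of replicate seeds per seed (trimmed one base
#'   at a time from both ends).
#' @param cycles full passes through the read list.
#' @param min_base_quality minimum per-base phred quality; a read with any
#'   base below this is excluded.
#' @param n_denovo_seeds number of random reads used as seeds in de novo mode.
#' @param min_coverage minimum number of replicates that must cover a
#'   column outside the original seed for it to enter the consensus.
#' @return An object of class `extender_config`.
#' @export
extender_config <- function(k = 100L, replicates = 20L, cycles = 10L,
                            min_base_quality = 30L, n_denovo_seeds = 1000L,
                            min_coverage = 1L) {
  stopifnot(k >= 1L, replicates >= 1L, cycles >= 0L, min_base_quality >= 0L,
            n_denovo_seeds >= 1L, min_coverage >= 1L)
  structure(list(k = as.integer(k), replicates = as.integer(replicates),
                 cycles = as.integer(cycles),
                 min_base_quality = as.integer(min_base_quality),
                 n_denovo_seeds = as.integer(n_denovo_seeds),
                 min_coverage = as.integer(min_coverage)),
            class = "extender_config")
}

#' Filter reads on minimum per-base quality
#'
#' Retains exactly the reads whose every base quality is at or above the
#' threshold.
#'
#' @param reads data frame with columns `id`, `seq`, `qual`.
#' @param min_base_quality phred threshold.
#' @return The retained rows of `reads`.
#' @export
filter_reads_quality <- function(reads, min_base_quality = 30L) {
  if (nrow(reads) == 0L) return(reads)
  keep <- .min_qual_cpp(reads$qual) >= min_base_quality
  reads[keep, , drop = FALSE]
}

#' Replicate seeds by sequential end trimming
#'
#' Replicate `i` (0-based) is the seed with `i` bases removed from each
#' end; replicate 0 is the seed itself. If the seed is too short to
#' support `r` replicates of length at least `k`, `r` is reduced to the
#' feasible maximum with a warning.
#'
#' @param seed a single sequence.
#' @param r requested number of replicates.
#' @param k minimum (k-mer) length every replicate must retain.
#' @return Character vector of replicate sequences.
#' @export
make_replicates <- function(seed, r, k = 100L) {
  len <- nchar(seed)
  if (len < k) stop("seed shorter than k (", len, " < ", k, ")")
  r_max <- (len - k) %/% 2L + 1L
  if (r > r_max) {
    warning("seed of length ", len, " supports only ", r_max,
            " replicates at k = ", k, "; r reduced")
    r <- r_max
  }
  i <- seq_len(r) - 1L
  substring(seed, 1L + i, len - i)
}

#' Build the end-k-mer hash tables for a set of seeds
#'
#' The k-mer at the 5' end of each seed keys the 5' table and the 3'-end
#' k-mer keys the 3' table; the value is the seed index. Initial keys must
#' be unique per table: a later seed whose end k-mer duplicates an earlier
#' key is dropped from extension with a warning. A seed whose own 5' and
#' 3' k-mers coincide is allowed (the tables are separate).
#'
#' @param seeds character vector of seed sequences (each of length >= k).
#' @param k end k-mer length.
#' @return An object of class `seed_table`: an environment with hash
#'   environments `five` and `three`, the seed sequences, and per-seed
#'   `dropped`/`frozen5`/`frozen3` state.
#' @export
build_seed_tables <- function(seeds, k = 100L) {
  if (any(nchar(seeds) < k)) stop("all seeds must have length >= k")
  st <- new.env(parent = emptyenv())
  st$k <- as.integer(k)
  st$seeds <- as.character(seeds)
  ns <- length(seeds)
  st$dropped <- logical(ns)
  st$frozen5 <- logical(ns)
  st$frozen3 <- logical(ns)
  st$ext5 <- integer(ns)
  st$ext3 <- integer(ns)
  st$five <- new.env(parent = emptyenv(), hash = TRUE)
  st$three <- new.env(parent = emptyenv(), hash = TRUE)
  for (s in seq_len(ns)) {
    len <- nchar(st$seeds[s])
    k5 <- substr(st$seeds[s], 1L, k)
    k3 <- substr(st$seeds[s], len - k + 1L, len)
    if (exists(k5, envir = st$five, inherits = FALSE) ||
        exists(k3, envir = st$three, inherits = FALSE)) {
      st$dropped[s] <- TRUE
      warning("seed ", s, " shares an end k-mer with an earlier seed; dropped")
      next
    }
    assign(k5, s, envir = st$five)
    assign(k3, s, envir = st$three)
  }
  class(st) <- "seed_table"
  st
}

#' Attempt one extension with a single read
#'
#' Lookup order: the read's 3'-end k-mer against the 5' table (leftward
#' extension by the read's leading bases), the read's 5'-end k-mer against
#' the 3' table (rightward extension by the trailing bases), then the same
#' two lookups with the reverse complement; the first hit wins. On a hit
#' the consumed key is removed and the new end k-mer inserted; if the new
#' key already exists in its table the extended end freezes (key not
#' inserted). A read no longer than k triggers no event.
#'
#' @param table a `seed_table` from [build_seed_tables()] (modified in place).
#' @param read a single read sequence.
#' @return A list describing the event (`seed`, `end` = `"5p"`/`"3p"`,
#'   `added` bases, `orientation`), or `NULL` when no extension occurred.
#' @export
try_extend <- function(table, read) {
  k <- table$k
  len <- nchar(read)
  if (len <= k) return(NULL)
  for (orient in c("forward", "revcomp")) {
    rd <- if (orient == "forward") read else reverse_complement(read)
    k3 <- substr(rd, len - k + 1L, len)
    s <- get0(k3, envir = table$five, inherits = FALSE)
    if (!is.null(s)) {
      added <- substr(rd, 1L, len - k)
      table$seeds[s] <- paste0(added, table$seeds[s])
      table$ext5[s] <- table$ext5[s] + nchar(added)
      rm(list = k3, envir = table$five)
      nk <- substr(table$seeds[s], 1L, k)
      if (exists(nk, envir = table$five, inherits = FALSE)) {
        table$frozen5[s] <- TRUE
      } else {
        assign(nk, s, envir = table$five)
      }
      return(list(seed = s, end = "5p", added = added, orientation = orient))
    }
    k5 <- substr(rd, 1L, k)
    s <- get0(k5, envir = table$three, inherits = FALSE)
    if (!is.null(s)) {
      added <- substr(rd, k + 1L, len)
      table$seeds[s] <- paste0(table$seeds[s], added)
      table$ext3[s] <- table$ext3[s] + nchar(added)
      rm(list = k5, envir = table$three)
      slen <- nchar(table$seeds[s])
      nk <- substr(table$seeds[s], slen - k + 1L, slen)
      if (exists(nk, envir = table$three, inherits = FALSE)) {
        table$frozen3[s] <- TRUE
      } else {
        assign(nk, s, envir = table$three)
      }
      return(list(seed = s, end = "3p", added = added, orientation = orient))
    }
  }
  NULL
}

#' Consensus across replicate extensions
#'
#' Replicates are anchored by the known position of their trimmed seed and
#' assumed collinear. Each column is called by plurality over the
#' replicates covering it (ties go to the lowest-index replicate); columns
#' outside the original seed require coverage of at least `min_coverage`
#' replicates. Columns of the original seed are always emitted.
#'
#' @param replicate_sequences character vector of extended replicates.
#' @param seed the original (untrimmed) seed.
#' @param trims integer vector: bases trimmed from each end of the seed for
#'   each replicate (0 for replicate 0).
#' @param min_coverage minimum replicate coverage outside the seed.
#' @return The consensus sequence (single string).
#' @export
consensus_sequences <- function(replicate_sequences, seed,
                                trims = seq_along(replicate_sequences) - 1L,
                                min_coverage = 1L) {
  stopifnot(length(replicate_sequences) >= 1L,
            length(trims) == length(replicate_sequences))
  len <- nchar(seed)
  offs <- integer(length(replicate_sequences))
  keep <- logical(length(replicate_sequences))
  for (i in seq_along(replicate_sequences)) {
    tseed <- substr(seed, 1L + trims[i], len - trims[i])
    pos <- regexpr(tseed, replicate_sequences[i], fixed = TRUE)
    if (pos < 0L) {
      warning("replicate ", i, " no longer contains its trimmed seed; excluded")
      next
    }
    keep[i] <- TRUE
    # global coordinate of replicate position 1 (seed coordinate origin = 1)
    offs[i] <- (1L + trims[i]) - pos
  }
  if (!any(keep)) return(seed)
  reps <- replicate_sequences[keep]
  offs <- offs[keep]
  # matrix spans the union of replicate extents and the original seed
  first <- min(1L, offs + 1L)
  last <- max(len, offs + nchar(reps))
  width <- last - first + 1L
  bases <- c("A", "C", "G", "T", "N")
  counts <- matrix(0L, nrow = 5L, ncol = width, dimnames = list(bases, NULL))
  cover <- matrix(FALSE, nrow = length(reps), ncol = width)
  chars <- vector("list", length(reps))
  for (i in seq_along(reps)) {
    ch <- strsplit(reps[i], "", fixed = TRUE)[[1L]]
    cols <- (offs[i] + seq_along(ch)) - first + 1L
    chars[[i]] <- list(ch = ch, cols = cols)
    cover[i, cols] <- TRUE
    for (b in bases) {
      sel <- cols[ch == b]
      if (length(sel)) counts[b, sel] <- counts[b, sel] + 1L
    }
  }
  coverage <- colSums(cover)
  seed_cols <- (1L:len) - first + 1L  # global coords 1..len
  emit <- coverage >= min_coverage
  emit[seed_cols] <- TRUE
  # restrict to the contiguous block containing the seed
  blocks <- rle(emit)
  idx <- cumsum(blocks$lengths)
  start_block <- c(1L, head(idx, -1L) + 1L)
  sb <- which(blocks$values & start_block <= seed_cols[1L] &
                idx >= seed_cols[1L])
  lo <- start_block[sb]
  hi <- idx[sb]
  cols <- lo:hi
  out <- character(width)
  maxc <- apply(counts[, cols, drop = FALSE], 2L, max)
  for (j in seq_along(cols)) {
    col <- cols[j]
    tied <- bases[counts[, col] == maxc[j] & counts[, col] > 0L]
    if (length(tied) == 0L) {
      # uncovered seed column (all covering replicates were excluded)
      out[j] <- substr(seed, col + first - 1L, col + first - 1L)
    } else if (length(tied) == 1L) {
      out[j] <- tied
    } else {
      # tie: base of the lowest-index covering replicate among the tied
      for (i in seq_along(reps)) {
        m <- match(col, chars[[i]]$cols)
        if (!is.na(m) && chars[[i]]$ch[m] %in% tied) {
          out[j] <- chars[[i]]$ch[m]
          break
        }
      }
    }
  }
  paste(out[seq_along(cols)], collapse = "")
}

#' Run the Extender on seeds and reads
#'
#' Each seed is expanded into trimmed replicate seeds, all replicates are
#' extended together against the read list for `cycles` passes (the scan
#' pointer does not reset after an extension), and a consensus is taken
#' across the replicates of each seed. Deterministic given seed and read
#' order.
#'
#' @param seeds character vector of seed sequences, or a data frame with
#'   columns `id`, `seq`.
#' @param reads data frame with columns `id`, `seq`, `qual` (assumed
#'   already quality-filtered), or a character vector of sequences.
#' @param config an [extender_config()].
#' @param engine `"cpp"` (default) or `"r"`; the R engine is a reference
#'   implementation built on [try_extend()] for small inputs.
#' @return A data frame with one row per input seed: `seed_id`,
#'   `consensus`, `replicates_used`, `extended_5p`, `extended_3p`,
#'   `length`; replicate sequences are attached as the list column
#'   `replicate_sequences`.
#' @export
run_extender <- function(seeds, reads, config = extender_config(),
                         engine = c("cpp", "r")) {
  engine <- match.arg(engine)
  if (is.data.frame(seeds)) {
    seed_id <- seeds$id
    seed_seq <- seeds$seq
  } else {
    seed_seq <- as.character(seeds)
    seed_id <- if (!is.null(names(seeds))) names(seeds) else
      paste0("seed", seq_along(seed_seq))
  }
  read_seq <- if (is.data.frame(reads)) reads$seq else as.character(reads)
  k <- config$k
  short <- nchar(seed_seq) < k
  if (any(short)) {
    warning(sum(short), " seed(s) shorter than k dropped")
    seed_seq <- seed_seq[!short]
    seed_id <- seed_id[!short]
  }
  if (!length(seed_seq)) stop("no usable seeds (all shorter than k)")

  rep_seqs <- character(0)
  rep_group <- integer(0)
  rep_trim <- integer(0)
  for (s in seq_along(seed_seq)) {
    reps <- suppressWarnings(make_replicates(seed_seq[s], config$replicates, k))
    rep_seqs <- c(rep_seqs, reps)
    rep_group <- c(rep_group, rep(s, length(reps)))
    rep_trim <- c(rep_trim, seq_along(reps) - 1L)
  }

  if (engine == "cpp") {
    res <- .extender_run_cpp(rep_seqs, k, read_seq, config$cycles)
  } else {
    st <- build_seed_tables(rep_seqs, k)
    if (config$cycles > 0L) {
      for (cycle in seq_len(config$cycles)) {
        for (rd in read_seq) try_extend(st, rd)
      }
    }
    res <- list(sequence = st$seeds, extended_5p = st$ext5,
                extended_3p = st$ext3, dropped = st$dropped)
  }

  out <- vector("list", length(seed_seq))
  for (s in seq_along(seed_seq)) {
    sel <- which(rep_group == s & !res$dropped)
    if (!length(sel)) {
      cons <- seed_seq[s]
      reps_used <- 0L
      e5 <- 0L; e3 <- 0L
      rep_list <- character(0)
    } else {
      rep_list <- res$sequence[sel]
      cons <- consensus_sequences(rep_list, seed_seq[s], rep_trim[sel],
                                  config$min_coverage)
      reps_used <- length(sel)
      anchor <- as.integer(regexpr(seed_seq[s], cons, fixed = TRUE))
      if (anchor > 0L) {
        e5 <- anchor - 1L
        e3 <- nchar(cons) - (anchor - 1L) - nchar(seed_seq[s])
      } else {
        e5 <- NA_integer_; e3 <- NA_integer_
      }
    }
    out[[s]] <- data.frame(seed_id = seed_id[s], consensus = cons,
                           replicates_used = reps_used, extended_5p = e5,
                           extended_3p = e3, length = nchar(cons),
                           stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, out)
  out$replicate_sequences <- I(lapply(seq_along(seed_seq), function(s)
    res$sequence[rep_group == s & !res$dropped]))
  out
}

#' Run the Extender as a de novo assembler
#'
#' Seeds are drawn uniformly without replacement from the (quality-filtered)
#' reads, each is expanded into replicates and extended, and the resulting
#' consensus sequences are deduplicated by exact sequence identity.
#'
#' @param reads data frame with columns `id`, `seq`, `qual`, or a character
#'   vector of sequences.
#' @param config an [extender_config()]; `n_denovo_seeds` controls the
#'   number of seeds.
#' @param rng_seed integer seed for the draw (required for reproducibility).
#' @return As [run_extender()], with an additional logical column
#'   `duplicate` marking rows whose consensus duplicates an earlier one.
#' @export
denovo_extender <- function(reads, config = extender_config(), rng_seed = 1L) {
  read_seq <- if (is.data.frame(reads)) reads$seq else as.character(reads)
  usable <- which(nchar(read_seq) >= config$k)
  if (!length(usable)) stop("no reads of length >= k to seed from")
  n <- config$n_denovo_seeds
  if (length(usable) < n) {
    warning("only ", length(usable), " reads of length >= k; using all as seeds")
    n <- length(usable)
  }
  set.seed(rng_seed)
  pick <- usable[sample.int(length(usable), n)]
  seeds <- data.frame(id = paste0("denovo", seq_len(n)),
                      seq = read_seq[pick], stringsAsFactors = FALSE)
  res <- run_extender(seeds, reads, config)
  res$duplicate <- duplicated(res$consensus)
  res
}
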