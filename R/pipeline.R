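#' Run the full simulate-merge-extend-cluster-quantify pipeline
#'
#' Orchestrates the whole workflow on simulated data and writes every
#' artifact plus a JSON manifest with md5 checksums; a rerun with the same
#' configuration reproduces identical checksums.
#'
#' @param out_dir output directory (created if missing).
#' @param n_transcripts,length_range,n_clusters passed to
#'   [simulate_transcriptome()].
#' @param n_pairs number of simulated read pairs.
#' @param error_rate_5p,error_rate_3p read error rates.
#' @param n_seeds de novo seeds for the Extender.
#' @param sample_size reads used for quantification.
#' @param rng_seed master seed; stage seeds are derived from it.
#' @param extender an [extender_config()] (the seed count is overridden by
#'   `n_seeds`).
#' @param merge a [merge_config()].
#' @param quant a [quant_config()] (the sample size is overridden by
#'   `sample_size`).
#' @return The manifest (list), invisibly; also written as
#'   `manifest.json` in `out_dir`.
#' @export
run_pipeline <- function(out_dir, n_transcripts = 20L,
                         length_range = c(300L, 600L), n_clusters = 5L,
                         n_pairs = 200000L, error_rate_5p = 0,
                         error_rate_3p = 0, n_seeds = 50L,
                         sample_size = 100000L, rng_seed = 1L,
                         extender = extender_config(),
                         merge = merge_config(), quant = quant_config()) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  t0 <- Sys.time()
  log_lines <- character()
  stage <- function(name, expr) {
    st <- Sys.time()
    out <- tryCatch(force(expr), error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
    log_lines <<- c(log_lines, sprintf("%s\t%.2fs", name,
                                       as.numeric(Sys.time() - st, "secs")))
    out
  }

  txome <- stage("simulate_transcriptome", simulate_transcriptome(
    n_transcripts = n_transcripts, length_range = length_range,
    n_clusters = n_clusters, rng_seed = rng_seed))
  tx <- txome$transcripts
  tx$desc <- sprintf("class=%s toxin=%d cluster=%d", tx$class_label,
                     as.integer(tx$toxin), tx$cluster)
  truth_fa <- file.path(out_dir, "truth_transcripts.fasta")
  write_fasta(tx, truth_fa)

  sim <- stage("simulate_reads", simulate_reads(txome, read_sim_config(
    error_rate_5p = error_rate_5p, error_rate_3p = error_rate_3p,
    n_pairs = n_pairs, rng_seed = rng_seed + 1L)))
  r1_fq <- file.path(out_dir, "reads_1.fastq")
  r2_fq <- file.path(out_dir, "reads_2.fastq")
  write_fastq(sim$r1, r1_fq)
  write_fastq(sim$r2, r2_fq)
  truth_tsv <- file.path(out_dir, "read_truth.tsv")
  write.table(sim$truth, truth_tsv, sep = "\t", quote = FALSE,
              row.names = FALSE)

  merged <- stage("merge_pairs", merge_pairs(sim$r1, sim$r2, merge))
  merged_fq <- file.path(out_dir, "merged.fastq")
  write_fastq(merged$merged[, c("id", "seq", "qual")], merged_fq)

  hq <- stage("filter_reads_quality",
              filter_reads_quality(merged$merged, extender$min_base_quality))
  extender$n_denovo_seeds <- as.integer(n_seeds)
  ext <- stage("denovo_extender",
               denovo_extender(hq, extender, rng_seed = rng_seed + 2L))
  uniq <- ext[!ext$duplicate, , drop = FALSE]
  contigs_fa <- file.path(out_dir, "extender_contigs.fasta")
  write_fasta(data.frame(id = uniq$seed_id, seq = uniq$consensus,
                         stringsAsFactors = FALSE), contigs_fa)

  clus <- stage("single_linkage_cluster", {
    full <- uniq[!duplicated(uniq$consensus), , drop = FALSE]
    single_linkage_cluster(data.frame(id = full$seed_id, seq = full$consensus,
                                      stringsAsFactors = FALSE))
  })
  clusters_tsv <- file.path(out_dir, "clusters.tsv")
  write.table(clus, clusters_tsv, sep = "\t", quote = FALSE,
              row.names = FALSE)

  quant$sample_size <- sample_size
  asn <- stage("assign_reads", assign_reads(
    merged$merged, data.frame(id = tx$id, seq = tx$seq,
                              stringsAsFactors = FALSE),
    quant, clusters = tx$cluster, rng_seed = rng_seed + 3L))
  ab <- abundance_table(asn$counts, asn$summary$n_reads,
                        setNames(txome$clusters$toxin,
                                 as.character(txome$clusters$cluster)))
  abundance_tsv <- file.path(out_dir, "abundance.tsv")
  write.table(ab, abundance_tsv, sep = "\t", quote = FALSE, row.names = FALSE)

  files <- c(truth_fa, r1_fq, r2_fq, truth_tsv, merged_fq, contigs_fa,
             clusters_tsv, abundance_tsv)
  manifest <- list(
    created = format(t0, "%Y-%m-%d %H:%M:%S"),
    parameters = list(n_transcripts = n_transcripts,
                      length_range = length_range, n_clusters = n_clusters,
                      n_pairs = n_pairs, error_rate_5p = error_rate_5p,
                      error_rate_3p = error_rate_3p, n_seeds = n_seeds,
                      sample_size = sample_size, rng_seed = rng_seed),
    stats = list(merged_fraction = merged$stats$merged_fraction,
                 mean_merged_length = merged$stats$mean_merged_length,
                 n_contigs = nrow(uniq),
                 n_clusters_recovered = max(clus$cluster)),
    files = lapply(files, function(f)
      list(path = basename(f), md5 = unname(tools::md5sum(f)))),
    stage_timings = log_lines)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
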