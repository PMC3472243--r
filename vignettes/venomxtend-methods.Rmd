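---
title: "Methods: merging, seed extension, clustering and quantification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: merging, seed extension, clustering and quantification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

venomxtend reconstructs and quantifies highly expressed transcripts from
short-insert paired-end RNA-seq, the library geometry typical of
venom-gland transcriptome studies: cDNA fragments of roughly 170 nt
sequenced with 100-nt paired reads, so that most pairs overlap at their
3' ends where base quality is worst. This vignette describes each model,
its assumptions, the tunable parameters, and the design choices made
where the underlying methodology left the details open.

## Significance-based pair merging

For a read pair, mate 2 is reverse complemented and slid along mate 1
through every relative offset. A candidate at implied fragment length
$f$ has overlap $n(f) = \min(\ell_1, \ell_2, f, \ell_1+\ell_2-f)$ and
$k$ observed matches, scored with the binomial null probability

$$P(k \mid n) = \binom{n}{k} \left(\tfrac14\right)^k
  \left(\tfrac34\right)^{n-k},$$

the chance of $k$ matches if every position were independently one of
four equally likely bases. The pair is merged at the best candidate when
$\min_f P < 10^{-10}$ and the second-smallest probability is at least
1000-fold larger; the ratio condition protects repetitive sequence,
where several offsets explain the data almost equally well. A perfect
overlap needs $n \ge 17$ to clear the threshold, which is why no
separate minimum-overlap heuristic is applied. Probabilities are
computed in log space (cached log-factorials), so overlaps up to full
read length do not underflow.

Enumerating candidates by fragment length rather than by overlap length
is deliberate: each overlap length $n < \min(\ell_1,\ell_2)$ is realized
at two offsets (fragment shorter vs. longer than a read), and both are
physically distinct hypotheses. Offsets where the fragment is shorter
than a read model adaptor read-through: on acceptance the bases beyond
the fragment are deleted and reported in `trimmed_adaptor_nt`.

Quality recombination on overlap columns: agreeing bases sum their
phred scores, capped at 60; disagreeing bases keep the higher-quality
base with quality $|q_1-q_2|$; an exact tie keeps the mate-1 base at
quality 0. An N is replaced by its partner with the partner's quality.
Non-overlap qualities are untouched. The additive update is one
reasonable reading of posterior-style quality recombination; the exact
historical update is not recoverable from the source description, so the
rule is documented here and fixed.

## The Extender

The Extender is a greedy assembler specialized for completing highly
covered transcripts. Two hash tables map the k-mer at the 5' and 3' end
of every seed to that seed. For each read (in list order, `cycles` = 10
full passes, never resetting the scan pointer after an extension), the
read's two end k-mers are looked up — read 3'-end k-mer against the 5'
table (leftward extension by the read's leading bases), read 5'-end
k-mer against the 3' table (rightward extension) — then the same with
the reverse complement; the first hit wins, and a read triggers at most
one extension per encounter. After an extension the consumed key is
removed and the new end k-mer inserted; if the new key already exists
the end freezes (bases kept, key not inserted). Initial end k-mers must
be unique per table; a later seed violating this is dropped.

Defaults are the method's stated operating point: `k = 100`,
`replicates = 20` (the seed trimmed by one base from each end per
replicate, so replicates start from different keys and evolve
independently), `cycles = 10`, and reads discarded if any base is below
Q30. De novo mode seeds with 1000 random reads and deduplicates the
resulting consensi.

**Coverage requirements.** An extension requires a read *ending at an
exact position* (end-k-mer identity). The method is therefore
data-hungry by design: progress at a seed end stalls unless some read
ends exactly k bases beyond the current end, so reliable extension
needs several read ends per position, and capturing the final bases of
a transcript needs reads terminating exactly at the transcript
boundary. This is why the method suits only very deeply covered
transcripts, and why this package scores de novo recovery on complete
coding sequences (see below) rather than on exact transcript
boundaries, which are recovered only opportunistically.

**Consensus.** Replicates are anchored on the known position of their
trimmed seed and assumed collinear. Each column is called by plurality
over the replicates covering it, ties resolved toward the lowest-index
replicate; columns outside the original seed require at least
`min_coverage` covering replicates (default 1), and the seed's own
columns are always emitted. A majority-of-all-replicates quorum was
considered and rejected: replicate walks stall at random points, so a
strict quorum truncates the consensus to the *median* replicate extent
and discards the completions the replicates were created to find; the
method's own alternative of simply taking the longest replicate
corresponds to coverage 1 at the extremes. With high-quality reads the
replicates never disagree where they overlap, so the default changes
length, not content; `min_coverage` can be raised for noisy data.

**Tiling geometry.** With reads of a single length $L_r$, every
extension step advances exactly $L_r - k$ nt, so seed ends are trapped
in one residue class modulo $L_r - k$ and transcript termini are
generally unreachable. `tile_reads()` therefore tiles at 1-nt steps
with a ladder of read lengths including $k + 1$, which guarantees a
single-base refinement step always exists; under that tiling the
consensus provably reaches both termini, and the tiling acceptance
check asserts exact whole-transcript recovery.

## Clustering and naming

Nucleotide divergence between two transcripts is computed over the
gap-free columns of an optimal global alignment (affine costs: match 0,
mismatch 1, gap open 5, gap extend 1; deterministic traceback
preferring diagonal, then a gap in the second sequence). Excluding
gapped columns entirely is the only definition under which
splice-variant insertions (e.g. an in-frame 48-nt block) leave their
cluster membership intact, mirroring how such variants co-cluster with
their parents in practice. Clusters are single-linkage connected
components at divergence < 1% — the "cluster = connected set" reading,
consistent with variable cluster sizes — and are named
`CLASS-number`, with members of multi-member clusters lettered
`a`, `b`, `c` by descending length. Pairs sharing no 31-mer are not
aligned (their divergence is far beyond any threshold of interest;
the shortcut is safe for thresholds up to roughly 5%).

## Read-count quantification

Abundance is the percentage of reads assigned to each transcript
cluster. A read's candidate references share at least one 31-mer; each
candidate is scored ungapped on the best shared diagonal, with a banded
semi-global alignment rescuing near-threshold candidates, and identity
is matches divided by read length (the "minimum match percentage"
convention of reference mappers), with 0.95 as the default threshold.
Ties across different clusters are discarded as ambiguous —
conservative and deterministic; a fractional mode was considered
unnecessary because cluster-level counting already absorbs the
within-cluster ambiguity that motivates clustering in the first place.
Subsampling to a fixed read count is seeded and reported.

## The synthetic-data generator

`simulate_transcriptome()` emulates the features of a venom-gland
library that the algorithms above are sensitive to, at a size a desk
machine can process:

* **Abundances**: Zipf-like weights whose exponent is solved so the top
  transcript receives 6% of reads, the share observed for the most
  abundant toxin transcript in this system. With the default 20
  transcripts this forces a nearly flat profile (20 shares summing to 1
  with maximum 0.06 cannot be steep); the 6% anchor was kept because it
  is the quantity that calibrates depth per transcript.
* **Coding structure**: each transcript is 5' UTR + CDS + 3' UTR, the
  CDS built from sense codons between ATG and a stop; UTRs are ATG-free
  and construction rejects the rare draw where a chance off-frame ORF
  outruns the planted CDS, so the planted CDS is always the longest
  ORF. Lengths default to 300–600 nt, the range of the short, highly
  expressed toxin classes (myotoxins, C-type lectins, PLA2s); longer
  classes would need proportionally more reads.
* **Clusters**: the first `n_clusters` transcripts get a second member
  at < 1% substitution divergence; the first cluster's member carries an
  in-frame 48-nt sense-codon insertion (the splice-variant pattern).
  Intra-cluster divergence < 1% and inter-cluster divergence > 2% are
  verified at generation time.
* **Reads**: fragments drawn proportional to abundance (abundance is
  defined as read share, the proxy the downstream quantification
  estimates), insert length truncated-normal (170 ± 30 nt, clipped to
  [50, 300]), 100-nt mates, a fixed synthetic adaptor filling
  read-through, substitution errors at a per-position rate interpolated
  from the 5' to the 3' end of the read, and qualities derived
  deterministically from that rate (giving the 3'-declining profile
  without modelling instrument noise). No indel errors are simulated:
  neither the merger nor the Extender models indels, a documented
  limitation.

What passing tests on these simulations do *not* show: robustness to
indel sequencing errors, chimeric fragments, unspliced introns, rRNA
contamination, or abundance distributions spanning many more orders of
magnitude than 20 transcripts allow.

## Problem sizes and numerical choices

The recovery checks run at these sizes, chosen so every transcript
sees the deep per-position end coverage the Extender's exact-position
extension rule requires (hundreds of read ends per position for the
least abundant transcript):

* merging: 10,000 pairs (error-free and 1% uniform error), compared
  against a truth-coordinate oracle;
* de novo assembly: 2,000,000 error-free pairs over 20 transcripts,
  merged, Q30-filtered, 1000 seeds; recovery = the complete planted CDS
  contained in a deduplicated consensus, reported alongside the
  stricter exact-boundary rate;
* clustering: the 25-sequence planted-cluster transcriptome;
* quantification: 100,000 error-free composite reads, estimates within
  3 binomial standard errors of the planted cluster shares.

Determinism: every stochastic step takes an explicit seed; identical
seeds give byte-identical transcripts, reads, and Extender output.
Ties are resolved deterministically throughout (argmin ties reject a
merge; consensus ties go to the lowest-index replicate; alignment
traceback prefers diagonal, then gap-in-b, then gap-in-a; equal-length
ORFs resolve to the smallest start, then lowest frame). Degenerate
inputs are defined rather than undefined: empty FASTQ files are empty
streams, a pair with no candidate overlap is `no_candidate`, a
no-stop ORF is reported but flagged not full-length, zero gap-free
columns make divergence an error rather than 0/0.

## Known limitations

The Extender cannot resolve near-duplicate haplotypes mixed in one
read pool (reads from a < 1% divergent sibling can extend a seed
through shared regions); that ambiguity is exactly what downstream
clustering absorbs, and the de novo recovery conditions therefore use
distinct transcripts. Exact transcript termini are recovered only when
reads end precisely at the boundary. The merger assumes FR orientation
and substitution-only errors, and scores overlaps without gaps.
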