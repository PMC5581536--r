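---
title: "Adapter trimming by semi-global alignment and insert matching"
author: "readtrim"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Adapter trimming by semi-global alignment and insert matching}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(readtrim)
```

# The problem

Short-read sequencing libraries ligate synthetic adapter oligonucleotides
to both ends of each DNA fragment (the *insert*). Whenever the insert is
shorter than the read length, the sequencer reads through the insert into
the adapter, so the 3' end of the read carries partial-to-full adapter
sequence. Untrimmed adapter bases and low-quality tails inflate
misalignment and spurious-variant rates downstream, so trimming is the
first step of essentially every short-read pipeline. The difficulty is the
trade-off between *under-trimming* (leaving adapter bases behind) and
*over-trimming* (eating genuine template): an adapter suffix of one to
three bases is statistically indistinguishable from template, while an
aggressive matcher happily finds short "adapters" in reads that contain
none.

`readtrim` implements two complementary detectors.

# Adapter matching by semi-global alignment

For a single read, the only evidence is the adapter sequence itself. Let
$a$ (length $m$) be the adapter and $r$ (length $n$) the read. We compute
edit distances $D(i,j)$ between the $i$-prefix of $a$ and the $j$-prefix of
$r$ with the standard recurrence

$$D(i,j) = \min\{D(i-1,j-1) + [a_i \neq r_j],\; D(i-1,j),\; D(i,j-1)\},$$

with base cases chosen by adapter type: a 3' adapter may skip any read
prefix at no cost ($D(0,j)=0$, $D(i,0)=i$), a 5' adapter is the mirror
image (implemented by reversing both strings). Alongside $D$ the
implementation tracks the number of matching columns $M(i,j)$ and the
alignment origin $O(i,j)$, fills all three column by column keeping a
single column in memory, and inspects the bottom row (full adapter ending
at position $j$; everything from the match start to the read end is
removed) plus the final column (partial adapter occurrence running off the
3' read end).

Rather than maximising an alignment score, candidates are accepted by an
*error rate*: edits divided by the number of aligned adapter characters.
A candidate is discarded when this exceeds `max_error_rate` (default 0.1)
or when fewer than `min_overlap` (default 3) adapter characters are
aligned; among survivors the candidate with the most matching columns
wins. Ties prefer fewer edits, then a longer aligned adapter span, then
the leftmost start — the first rule is the substantive one; the rest make
the result deterministic. `min_overlap` is applied to the aligned
*adapter* length (the two lengths differ only when indels occur).

Columns are abandoned early once the running cost provably cannot return
below $\lfloor \texttt{max\_error\_rate} \cdot m \rfloor$; the cutoff is
an optimisation only and the test suite asserts it never changes the
result. When an adapter is anchored and indels are disabled the
implementation switches to a position-wise (Hamming) comparison against
the read prefix or suffix.

Degenerate adapter positions use IUPAC codes, represented internally as
4-bit nucleotide masks compared with a bitwise AND. An `N` in the *read*
matches nothing except an adapter `N`: base callers emit `N` runs in
low-quality regions, and letting them match concrete adapter characters
would fake adapter hits. Quality values never influence alignment.

# Insert matching for read pairs

A read pair sequences the same insert from opposite ends, so read 1 and
the reverse complement of read 2 overlap over the entire insert whenever
the insert is shorter than the read length — and then the adapters begin
at exactly the insert length in both reads. Locating the overlap therefore
pinpoints the adapters with far more evidence (up to a full read of
matching positions) than the adapter sequence alone provides.

All relative shifts of read 1 against rc(read 2) with at least
`min_insert_overlap` overlapping bases are scored without indels. A shift
survives when it passes three thresholds:

1. overlap length $\geq$ `min_insert_overlap` (default 10);
2. mismatches $\leq \lfloor$ `max_mismatch_frac` $\cdot$ overlap$\rfloor$
   (default fraction 0.2);
3. the probability that an unrelated shift would match this well,
   $$P = \sum_{i=k}^{n} \binom{n}{i} p^i (1-p)^{n-i}$$
   with $k$ matches out of $n$ compared bases and base match probability
   $p = 0.25$, is at most `max_random_match_prob` (default $10^{-6}$;
   computed with the binomial survival function).

The defaults are chosen so that a random 125 bp pair passes with
probability well below $10^{-4}$: threshold 3 does most of the work, and
10 exactly matching bases ($0.25^{10} \approx 9.5\times10^{-7}$) is the
shortest overlap that can pass it. Candidates are tested in order of
decreasing overlap. Two geometries arise: an implied insert *shorter* than
the read means both reads contain adapter in their overhangs, while an
insert *longer* than the read means the reads overlap only at their 3'
ends and there is nothing to trim — such a candidate is accepted as-is.

For a candidate with overhangs, the configured adapters must be confirmed:
each adapter is compared position-wise against its read's overhang
starting at the end of the insert overlap, and confirms when its mismatch
fraction over the compared bases is at most `overhang_error_rate`
(default 0.2, deliberately permissive because overhangs may be a single
base and 3' quality is poor; the binomial bound cannot be demanded of a
one-base overhang, which is why confirmation does not reuse threshold 3).
If either adapter confirms, *both* reads are trimmed at the insert length
— adapter location is symmetric across a proper pair — which is what makes
the method robust to a corrupted overhang in one mate.

If no candidate's adapters confirm, or no candidate exists, the pipeline
falls back to unconstrained semi-global adapter matching in each read
independently. A fallback hit must additionally satisfy the same binomial
random-match bound (on matches over aligned adapter length): without it, a
three-base suffix match — accepted by the error-rate rule with probability
$4^{-3} \approx 1.6\%$ per adapter-free read — would dominate the error
budget of the whole pipeline. This reuse of threshold 3 on the fallback
path is a design choice of this package.

## Error correction, overwrite and merging

Because the overlap covers the same template twice, disagreements can be
repaired: at each mismatching overlap column the base with the higher
Phred quality becomes the consensus in both reads (read 2 stores its
complement) and the position's quality becomes the maximum of the two.
Quality ties are left alone, converted to `N`, or resolved toward the read
with the higher mean quality (`correction_policy` modes `keep`/`N`/`best`;
`best` is the constructor default, and correction as a whole is off by
default in the pipeline). Optionally a mate whose mean error probability
exceeds three times its partner's is overwritten from the partner over the
overlap, and matched pairs can be merged into a single read covering the
full insert — useful to avoid double-counting in depth-based analyses.

# The pipeline

Modifiers run in a fixed order on both mates: fixed-base trimming, then
adapter/insert trimming, then quality trimming, then the minimum-length
filter (default 25 bp; shorter pairs are discarded, as short inserts map
spuriously). Fixed cuts come first because they remove technical bases
that would otherwise distort alignment; quality trimming runs after
adapter removal so that low-quality adapter bases still count as overhang
evidence. Quality trimming uses the partial-sum method: scanning from the
3' end, the running sum of $(\textrm{cutoff} - q)$ is accumulated and the
read is cut where the sum is maximal; ties keep the longer read. NextSeq
two-channel chemistry encodes G as the absence of signal, so in NextSeq
mode G bases are treated as quality 0 during the scan, removing spurious
high-quality poly-G tails. Linked (5' + 3') adapters trim the 5' side
first and search the 3' adapter only downstream of it.

Execution follows a reader/worker/writer contract: one cursor batches the
input preserving file order (default 5000 reads per batch, which bounds
buffered memory), workers apply the whole modifier stack per batch (via
forked processes when `threads > 1`), and output is written in one of
three modes — workers compress and a serializer concatenates the gzip
members; a single serializer compresses one stream; or each worker writes
its own file pair (gzip members are concatenable by construction). All
modes yield the same record multiset, pairs remain in sync within any one
stream, and record content is independent of thread count; `auto` picks
worker compression at eight or more threads, where serializer compression
becomes the bottleneck.

# Adapter detection, error estimation, QC

**Detection.** From a sample of reads (the first 10,000 by default),
poly-A tails of eight or more A's and everything 3' of them are removed
(a read-through signature), and low-complexity reads are dropped, where
complexity is Shannon entropy over base frequencies,
$X(S) = -\sum_i f_i \log_2 f_i$ with $f_i = C(i,S)/|S|$, and $X < 1.0$
bit counts as low-complexity. (With raw counts inside the logarithm this
expression would be negative for any count above one; the frequency form
is the meaningful reading and is what this package computes.) $k$-mers
are profiled starting at $k = 12$; a $k$-mer qualifies as high-abundance
when its count strictly exceeds

$$\frac{N \cdot (l - k + 1) \cdot O}{4^k},$$

with sample size $N$, read length $l$ (the mean sampled length) and
over-representation factor $O = 100$ — at the defaults
($N = 10^4$, $l = 125$, $k = 12$) the threshold is about 6.8, so counts of
7 and above qualify. Because the formula is vacuous (below 1) for
$k \geq 24$, a hard floor of two supporting occurrences is added.
Profiling repeats with doubled $k$ (capped at $l/2$) on the reads linked
to the previous round's qualifying $k$-mers. Qualifying $k$-mers are then
ranked by support times length; the strongest candidates are assembled —
$k$-mers overlapping by at least $k_0 - 1$ bases are joined, so a
contaminant longer than the largest profiled $k$ is reported in full —
contained sequences are dropped, and up to 20 hits are reported,
optionally labelled against a list of known contaminants at $\geq 90\%$
identity (a bundled TruSeq/Nextera list ships with the package). The
low-complexity rule is applied to candidate $k$-mers as well as reads.

**Error estimation** converts each Phred quality to its error probability
$10^{-q/10}$ and averages over a read sample — fast, and biased upward
relative to the true error rate, which is acceptable for its purpose of
choosing mismatch tolerances. The alternative shadow-regression estimator
is exposed as a named method that fails fast, since its definition lives
in external literature.

**QC metrics** (per-position quality distribution, per-read mean quality,
base composition, GC and length histograms) are collected in the same pass
as trimming, before and/or after, and serialize to versioned JSON.
Collection is a pure observer, and merging two summaries equals collecting
over the concatenated input, so per-worker summaries can be combined.

# The simulator and the accuracy taxonomy

The bundled generator produces the benchmark conditions used throughout
the tests: 125 bp pairs whose inserts are drawn from a truncated normal
(mean 200, sd 60, clamped to $[1, 400]$ and rounded — a typical
fragment-size profile for a short-insert library, chosen here since no
single canonical distribution exists; it is configurable and recorded in
the truth-table header). Read 1 is the insert prefix; read 2 the
reverse-complement insert prefix; when the insert is shorter than the
read, the TruSeq adapter and then random filler pad the read to full
length. Base-call errors are substitutions only (the dominant Illumina
mode): each base is substituted with probability $10^{-q/10}$, where the
quality $q$ is drawn from a supplied per-position profile or is the flat
integer $\mathrm{round}(-10\log_{10} e)$ for a target rate $e$ — so a
0.2% target realises $10^{-2.7} \approx 0.1995\%$, within quantisation of
the target. Everything is reproducible from the mandatory seed.

A quality profile (per position, counts $r_i$ over Phred bins with error
probabilities $e_i$) has overall error rate
$E = \sum_i e_i r_i / \sum_i r_i$. To reach a target $E'$, an equal count
$C$ is added to every bin so that the recomputed rate equals $E'$; since
the rate is a ratio of two linear functions of $C$, the root is solved in
closed form and verified to $|E(C) - E'| < 10^{-9}$. Reachable targets lie
between the current rate and the unweighted bin mean (the $C \to \infty$
limit); anything else is rejected with the reachable interval.

What the simulator does *not* model: indel sequencing errors, PCR
duplicates, position-dependent empirical error profiles (unless supplied),
quality miscalibration, or genomic repeats — so passing accuracy tests
demonstrates correct geometry recovery under substitution noise, not
robustness to every real-data pathology.

Trimmed output is scored per mate against the truth: a read with no
adapter that lost bases is *wrongly trimmed*; a read with an adapter is
*over-* or *under-trimmed* by the signed difference between its trimmed
length and the true adapter start, with exact equality required for
*correct*. Base-level counts accumulate those differences. Pairs removed
by the length filter are counted separately, not as trimming errors, and
every mate lands in exactly one bucket. Fractions are reported over reads
(two per pair); the JSON report also carries per-pair denominators since
both conventions appear in the literature.

# Numerical and design notes

* Coordinates are 0-based half-open everywhere; FASTQ is Phred+33.
* Error-rate comparisons add an epsilon ($10^{-9}$) so that boundary cases
  like 1 edit over 10 aligned bases at rate 0.1 are accepted regardless of
  floating-point representation.
* Allowed insert-overlap mismatches are $\lfloor$fraction $\times$
  overlap$\rfloor$; the threshold could equally be read as an absolute
  count, which users can emulate by scaling the fraction.
* The degenerate inputs — empty reads, adapters longer than reads,
  zero-length trims, all-N reads — are exercised in the test suite; a
  trimmed-to-zero read is a legal record that the length filter then
  discards.
* `readtrim` holds one decompressed batch per worker in memory; inputs
  are otherwise streamed through connections.
* Problem sizes in the shipped checks: the headline accuracy runs use
  100,000 simulated pairs at 0.2% error (and repeats at 0.6%/1.2%), the
  oracle-equivalence suites use 500 random instances each, detection
  round-trips use ten seeded 10,000-read samples, and the
  pipeline-equivalence check uses 10,000 pairs across thread counts
  {1, 4} and all three output modes. These sizes were chosen to give
  stable rates for fractions of order $10^{-4}$ while keeping a full run
  in minutes on one core.

# Known limitations

* Insert matching assumes inward-facing (FR) libraries; mate-pair
  (outward-facing) geometries and 5' adapter overhangs are out of scope.
* The fallback adapter matcher shares the pair's specificity thresholds;
  datasets needing per-read tuning should use the `adapter` aligner with
  explicit `adapter_spec` settings.
* Error correction applies only on the insert path — on the fallback path
  there is no overlap evidence to correct from.
* Detection reports can include flank-extended variants of a true adapter
  when it occurs at near-fixed positions; the known-contaminant labelling
  is the intended disambiguation.
* Biostrings' FASTQ parser (used for input) rejects zero-length records;
  with the default minimum-length filter the package never writes any,
  but `min_length = 0` output containing empty reads is not re-readable.
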