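# readtrim

Adapter and quality trimming for short sequencing reads, with an
insert-match algorithm for paired-end data.

## The problem

Short-read libraries ligate synthetic adapters to both ends of each DNA
fragment. Whenever a fragment (*insert*) is shorter than the read length,
the sequencer reads through it into the adapter, leaving adapter bases at
the 3' end of the read. Removing them — without eating genuine template —
is the first step of essentially every short-read pipeline. `readtrim` is
for anyone processing Illumina-style FASTQ data who wants a trimmer whose
two core algorithms are small, tested, and inspectable, plus the
companion tooling (adapter detection, error-rate estimation, QC metrics,
a ground-truth simulator and an accuracy evaluator) needed to validate a
trimming protocol end to end.

## The methods in brief

**Adapter match** (single reads): semi-global alignment of the adapter
*a* (length *m*) against the read by the edit-distance recurrence
`D(i,j) = min{ D(i-1,j-1) + [a_i != r_j], D(i-1,j), D(i,j-1) }` with free
end gaps by adapter type, accepting a candidate end position when
*edits / aligned adapter length* ≤ `max_error_rate` (default 0.1) and
picking the accepted candidate with the most matches. IUPAC codes are
4-bit masks compared by bitwise AND; a column cost cutoff and a
single-column memory layout keep it fast.

**Insert match** (read pairs): find the overlap between read 1 and the
reverse complement of read 2. A candidate overlap of *n* bases with *k*
matches passes when it is long enough (≥ 10), clean enough (mismatches ≤
0.2 *n*), and unlikely by chance — the binomial tail
`P = sum_{i=k..n} C(n,i) p^i (1-p)^(n-i)` with `p = 0.25` must be
≤ 1e-6. The implied insert length is then the trim point for *both*
mates once an adapter is confirmed in an overhang. Failing that, the
pipeline falls back to per-read adapter matching. The overlap also
enables mutual error correction (higher quality wins), overwrite of a
very poor mate, and merging the pair into one insert-length read.

## Worked example

Simulate 2,000 read pairs with ground truth, trim them, and score the
result:

```r
library(readtrim)

cfg <- sim_config(n_pairs = 2000, error_rate = 0.002, seed = 7)
sim <- simulate_pairs(cfg, out_prefix = "demo")

tc <- trim_config(adapter1 = "AGATCGGAAGAGCACACGTCTGAACTCCAGTCAC",
                  adapter2 = "AGATCGGAAGAGCGTCGTGTAGGGAAAGAGTGTA")
stats <- run_pipeline(tc, in1 = "demo_1.fq.gz", in2 = "demo_2.fq.gz",
                      out1 = "trimmed_1.fq.gz", out2 = "trimmed_2.fq.gz")
print(stats)
#> <trim_stats>
#>   pairs read:      2000
#>   pairs written:   2000
#>   pairs discarded: 0
#>   reads with adapter: 390
#>   bases removed (fixed/adapter/quality): 0/10998/0
#>   outcomes: insert=195 insert_untrimmed=1293 untrimmed=512

report <- evaluate_accuracy("trimmed_1.fq.gz", "trimmed_2.fq.gz",
                            truth = "demo_truth.tsv")
print(report)
#> <accuracy_report>
#>                         count   fraction
#>   wrongly trimmed           0    0.0000%
#>   over trimmed              0    0.0000%
#>   under trimmed             0    0.0000%
#>   correct                4000
#>   read-level total error: 0.0000%
#>   bases over/under-trimmed: 0 / 0 (total error 0.00000%)
#>   discarded pairs: 0 (0.00%)
```

Reading the output: 2,000 pairs went in; 195 pairs had their adapters
located via the insert overlap and were trimmed to the insert length;
1,293 pairs overlapped only at their 3' ends (insert longer than the
read, nothing to trim); 512 had no detectable overlap; no pair fell
below the 25 bp length filter in this draw. Scored against the
simulator's truth table, every read was cut at exactly the right base.

A single read works too:

```r
loc <- semiglobal_align(adapter_spec("AGATCGGAA"), "CCCCCAGATCGGAA")
str(loc[c("read_start", "read_stop", "matches", "errors")])
#> List of 4
#>  $ read_start: int 5
#>  $ read_stop : int 14
#>  $ matches   : int 9
#>  $ errors    : int 0
```

Adapter detection, error estimation and QC are available as
`detect_adapters()`, `estimate_error()` and `collect_qc()`; a thin CLI
over all subcommands ships in `inst/cli/readtrim`.

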