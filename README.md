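# crosstalkqc

Quantify and mitigate **sample cross-talk** in dual-indexed Illumina
sequencing runs.

When many samples are multiplexed on one lane, each cluster is identified by
a *triplet* of reads — the i5 index read, the i7 index read, and the sequence
read. De-multiplexing occasionally assigns a read to the wrong sample: a
cluster can carry one incorrect index (an *index misassignment*) or a
correct, expected index pair with another sample's sequence (a *sequence
misassignment*). The aggregate leakage, on the order of 0.1–0.3% of reads,
is invisible to ordinary QC but fatal for rare-variant detection, ancient
DNA work, and large multiplex panels. The package is for sequencing cores
and analysts who want to measure that leakage on their own runs and remove
it with an optimized index-read quality filter.

## What it computes

For a run with sample set *s₁…sₙ*, observed index reads are matched to the
expected indices within *k* mismatches (hamming distance, default *k* = 1,
an `N` counting as a mismatch), and the sequence read is assigned to the
nearest expected amplicon within an edit distance of 4 (banded Levenshtein;
substitutions, insertions and deletions). Each triplet then gets exactly one
label:

| label | pattern |
|---|---|
| `CORRECT` | (i5ₛ, i7ₛ, refₛ) |
| `SEQ_MIS` | expected pair (i5ₛ, i7ₛ), reference of a different sample |
| `INDEX_MIS_I5` / `INDEX_MIS_I7` | exactly one index disagrees with the sample anchored by the other two steps |
| `MULTI_MIS` | two or more steps disagree |
| `UNASSIGNED` | any step matched nothing, or ambiguously |

Pooled rates follow the run-level definitions: the sequence misassignment
rate is `SEQ_MIS / (CORRECT + SEQ_MIS)`, the index misassignment rate is
`(INDEX_MIS_I5 + INDEX_MIS_I7)` over all reads mapped to a known reference.

Two further tools interpret those numbers:

* **Negative-control index pairs.** Under unique dual indexing the (i5ᵢ,
  i7ⱼ), i≠j, combinations belong to no sample; reads landing there estimate
  the number of misassigned reads (ε) without needing control samples or
  known amplicons — *n* samples give *n² − n* controls.
* **Theoretical substitution model.** The closed-form probability that
  independent per-base misreads (error *p*, uniform over the 3 alternative
  bases, acceptance within *k* mismatches) convert one index into another at
  hamming distance *d*. Its geometric decay in *d* is what observed
  misassignment rates do *not* follow, ruling misreads out as the mechanism.

Because misassigned read steps carry low quality scores across their whole
length, filtering on the **mean per-base error probability of the index
reads** (pass ⇔ mean `10^(-Q/10)` ≤ `10^(-Q_thresh/10)`, boundary inclusive)
removes most misassignments while keeping most reads. `sweep_thresholds()`
tabulates ε and retention across a threshold grid; `choose_threshold()`
returns the smallest threshold whose surviving ε is below a target fraction.

A seeded simulator (`sim_config()`, `generate_design()`, `simulate_run()`)
generates complete runs — FASTQ triplets, sample sheet, references, ground
truth — with the same statistical structure, so every stage is testable
without sequencing data.

## Worked example

```r
library(crosstalkqc)

cfg <- sim_config(n_samples = 6, reads_per_sample = 5000,
                  p_index_mis_i5 = 0.002, p_index_mis_i7 = 0.002,
                  p_seq_mis = 0.002, seed = 42)
run <- simulate_run(cfg)

classified <- classify_triplets(
  demultiplex(run$triplets, run$sheet, run$refs), run$sheet)
report <- crosstalk_report(classified, run$sheet)
print(report)
#> Cross-talk report over 30000 triplets
#>   counts:
#>     CORRECT           29820
#>     INDEX_MIS_I5         53
#>     INDEX_MIS_I7         46
#>     SEQ_MIS              56
#>     MULTI_MIS             0
#>     UNASSIGNED           25
#>   sequence misassignment rate: 0.1874%
#>   index misassignment rate:    0.3303%
#>   overall incorrect rate:      0.5171%
#>   control pairs: 30  summed epsilon: 99

curve <- sweep_thresholds(classified, run$sheet, strategy = "INDEX_ONLY")
q <- choose_threshold(curve, max_epsilon_fraction = 0.1)
cat("Q_thresh:", q, " retained:", round(100 * attr(q, "frac_retained"), 1), "%\n")
#> Q_thresh: 19  retained: 99.4 %
```

Reading: of 30,000 simulated triplets, 0.52% were misassigned (the injected
0.6% minus events lost to `UNASSIGNED`), split roughly equally between wrong
i5, wrong i7, and wrong sequence. The 30 unused index pairs caught ε = 99
misassigned reads; filtering both index reads at an average quality of
Q ≥ 19 removes over 90% of that ε while keeping 99.4% of reads.

The same pipeline runs on real data via `read_triplets(r1, i7, i5)` (the
bcl2fastq `--create-fastq-for-index-reads` layout), `read_sample_sheet()`
and `read_references()`.

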