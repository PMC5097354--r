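---
title: "Measuring and removing sample cross-talk in dual-indexed runs"
author: "crosstalkqc"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring and removing sample cross-talk in dual-indexed runs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(crosstalkqc)
```

## The problem

Multiplexed Illumina libraries tag every fragment with two short barcodes,
the i5 and i7 indices, read in separate sequencing steps from the insert.
Each cluster therefore yields a *triplet* — i5 read, i7 read, sequence read
— and de-multiplexing trusts the index pair to name the sample. A small
fraction of triplets, typically one or two per thousand, disagree
internally: the sequence belongs to one sample while an index (or, more
rarely, the sequence itself under a correct index pair) belongs to another.
This *cross-talk* leaks reads between samples. It does not matter for bulk
abundance estimates, but it destroys any analysis that must distinguish "a
few reads of variant X in sample A" from zero: rare-variant surveys,
contamination screens, ancient DNA, large multiplex panels.

`crosstalkqc` implements the full measurement-and-mitigation loop on
triplet-level FASTQ data: demultiplexing, a misassignment taxonomy,
negative-control estimation of the misassigned read count, and an optimized
index-quality filter. A seeded simulator reproduces the statistical
structure of a multiplexed lane so the whole loop is testable end to end.

## Demultiplexing model

**Index matching.** An observed index read matches an expected index when
their hamming distance is at most `max_mismatch` (default 1, matching
standard demultiplexer behaviour). An `N` counts as a mismatch at its
position — against every base, including another `N` — because an uncalled
base should never *support* an identification. If two expected indices are
both within reach the read is *ambiguous*; ambiguity and failure are kept
distinct from a unique match and both are excluded from every rate
denominator. A sheet is usable at tolerance *k* only when its indices are
pairwise more than 2*k* apart; `validate_samplesheet()` computes the full
hamming matrices and warns otherwise.

**Sequence assignment.** The sequence read is assigned to the unique
nearest expected amplicon within `max_edit = 4` by full-string banded
Levenshtein distance (unit costs; band half-width equal to `max_edit`, so
any distance above the band is reported as `max_edit + 1` without wasted
work). Full-string rather than semi-global alignment is deliberate: reads
and references have the same cycle count, so genuine length differences are
indels and should be charged as such. The kernel is written in C++ for
speed; the test suite checks it against R's unbanded dynamic-programming
implementation (`utils::adist`) on thousands of randomized pairs.

**Taxonomy.** The three matches are made independently, then combined:

* every step unique and mutually consistent → `CORRECT`;
* index pair on the sheet, sequence of a different sample → `SEQ_MIS`;
* exactly one index disagreeing with the sample anchored by the other two
  steps → `INDEX_MIS_I5` / `INDEX_MIS_I7`;
* two or more disagreements → `MULTI_MIS`;
* any non-unique step → `UNASSIGNED`.

The sequence read is the truth anchor for index misassignments because each
sample's amplicon is unique and far from all others in edit distance. When
a read carries another sample's *complete* index pair together with a third
party's sequence, the pair rule fires first and the read counts as
`SEQ_MIS`: seen from the pair's sample, that is exactly what it is. Labels
are exhaustive and mutually exclusive; counts always sum to the number of
input triplets (a tested invariant).

**Rates.** The sequence misassignment rate is `SEQ_MIS / (CORRECT +
SEQ_MIS)` (reads whose index pair is on the sheet); the index misassignment
rate divides `INDEX_MIS_I5 + INDEX_MIS_I7` by all reads mapped to a known
reference, which by construction is every non-`UNASSIGNED` read. Zero
denominators yield `NA` plus an explicit flag — an undefined rate is never
silently reported as 0.

## Why misreads cannot explain cross-talk

If misassignment were caused by independent per-base misreads, crossing
from one index to another at hamming distance *d* would require at least
*d* specific positions to fail — to leading order probability `p^d`, i.e.
`1e-6` at a 1% error rate (Q20) for the minimum separation of 3 used here,
and `1e-12` for both indices of a unique dual pair
(`misread_crossover_approx()`). `theoretical_misassignment_rate()` makes
this exact: under independent substitution with probability `p`, uniform
over the 3 alternative bases, it sums over the differing positions repaired
toward the wrong index (`p/3` each), those switched to a third base
(`2p/3`), and the agreeing positions misread (`p`), subject to the ≤ *k*
acceptance rule. By default the event also requires *rejection by the true
index* (hamming > *k*), since only then does the read switch identity; the
simpler accepted-by-B-only variant is available via
`condition_on_true_reject = FALSE`. Which of the two a given figure uses is
rarely stated, so both are exposed; they differ only in the rare overlap
where a corrupted read stays within *k* of both indices. At *d* = 0 the two
definitions coincide in the self-match probability `1 - P(> k errors)` and
the function returns that. The closed form is verified against exhaustive
enumeration of all `4^L` corrupted reads to `1e-12`.

The model predicts geometric decay with *d*. Observed misassignment rates,
grouped by index distance with `rate_vs_distance_table()`, stay roughly
flat — the signature that misassignment is a per-read event (cluster-level,
not base-level), which is also how the simulator injects it.

A related side note: crossing the ≥ 21-substitution gap between amplicon
sequences by misreads alone has binomial tail probability
`substitution_tail_prob(51, 17, 0.01)` ≈ 1.3e-21 — an exact `pbinom` upper
tail, reported as computed.

## Negative-control pairs and ε

Under unique dual indexing, a single wrong index lands a read on an (i5,
i7) combination assigned to no sample. `enumerate_control_pairs()` lists
all such pairs (n² − n of them for n samples, 182 for 14);
`estimate_epsilon()` counts reads whose uniquely matched pair is a control
pair. ε needs no knowledge of the amplicons and can be computed *post hoc*
on any run that kept its index-read FASTQs, which is what makes it the
right objective for threshold tuning. ε counts reads by their matched index
pair regardless of where the sequence mapped, because the control pair
itself is the evidence of misassignment.

## Quality filtering

Misassigned read steps carry low quality scores across their entire length,
and the i5 and i7 qualities are largely independent of each other; sequence
misassignments are low-quality in all three steps. Filtering therefore
works on the **mean per-base error probability** of whole segments:
threshold Q passes a segment iff mean `10^(-q/10)` ≤ `10^(-Q/10)`, boundary
inclusive ("average quality ≥ Q" passes). Averaging is done in the
probability domain, not over Q values: the mean error rate is the quantity
the filter is supposed to bound, and averaging Q values understates it for
mixed-quality reads. Whether run summaries elsewhere average Q instead is
often unclear, so `mean_error_prob(..., domain = "q")` exposes the other
convention for sensitivity analysis; the filter itself always uses
probabilities.

Three strategies are compared: `SEQUENCE_ONLY`, `INDEX_ONLY` (both indices
must pass), `ALL_READS`. Sequence-only filtering removes sequence
misassignments but cannot touch index misassignments (their sequence reads
are high quality); index-only filtering removes both kinds — the package's
central, property-tested ordering. `sweep_thresholds()` classifies once and
evaluates the whole grid (default Q = 0…40, step 1 — the resolution of the
integer Phred scale) in a single pass; `choose_threshold()` returns the
smallest threshold whose surviving ε is at most `max_epsilon_fraction`
(default 10%) of the unfiltered ε, falling back to the ε-minimizing
threshold (ties toward more retained reads) with a warning when the target
is unattainable, and to the smallest threshold when ε is already zero. The
right threshold varies run to run, which is exactly why it is chosen from
the run's own control pairs rather than fixed.

## The simulator

`sim_config()` defaults *are* the study conditions this package targets:
14 samples, 8-bp unique dual indices with pairwise hamming distance ≥ 3 per
side, 51-cycle reads with pairwise edit distance ≥ 14 (both enforced by
bounded rejection sampling in `generate_design()`), 7,143 reads per sample
(~100,000 triplets — a lane scaled to desk size; the real lane's ~10⁸ reads
only narrow the binomial error bars), and per-read misassignment
probabilities at the observed magnitudes: 8e-4 per index side and 9e-4 for
sequence misassignment, ~0.25% combined.

Each read draws a label from those probabilities, independently of index
distance (matching the observation that misassignment is
distance-independent). Misassigned steps take their bases from a uniformly
chosen other sample. Quality is modelled as a segment-level mean —
`Normal(35, 3)` for correct steps, `Normal(15, 3)` for misassigned ones,
chosen to reproduce the clear high/low separation seen in real runs — plus
unit-SD per-base jitter, rounded and clamped to [2, 41] (the extremes of
Illumina RTA quality binning). A flat low-quality profile (not a localized
dip) reflects how misassigned reads actually look. Substitution errors are
then coupled to the emitted scores: every base is misread with exactly
probability `10^(-Q/10)`, uniformly into the 3 alternatives, so the quality
strings are honest. `substitute = FALSE` turns substitutions off, which
makes classification and ε exactly traceable to the injected ground truth —
the basis of the exact-zero acceptance test.

All draws flow from one seeded generator; the same seed yields
byte-identical FASTQ. What the simulator does **not** model: position-
dependent quality decay along the read, motif-specific errors, indels,
optical/cluster geometry, carryover between runs, and PhiX. Passing tests
therefore demonstrate correctness of the measurement machinery under the
stated statistical structure, not performance on every pathology of real
data.

## Numerical and design choices

* Quality encoding is fixed to Phred+33; other offsets are rejected rather
  than auto-detected (silent misdetection being worse than an error).
  Cluster identity is the read-id token before the first whitespace with
  `/1`–`/3` suffixes stripped; the three FASTQ streams must agree record by
  record, and any desynchronization is a hard error naming the record.
* Upstream chastity ("pass filter") screening is assumed already applied by
  the base-calling pipeline; the package starts from the emitted FASTQs.
* Ties in sequence assignment (two references at the same minimal distance)
  are `ambiguous`, never broken arbitrarily; `ambiguous` is tracked apart
  from `none` though both end up `UNASSIGNED`.
* Filtering is applied after classification, so one classification pass
  serves every threshold and strategy; the outcome is identical to
  filtering first, and the sweep is O(grid) rather than O(grid × demux).
* Problem sizes in the test suite: the end-to-end acceptance checks run on
  one ~100,000-triplet simulated lane (rate recovery is checked within 3
  binomial standard errors, filtering orderings as inequalities); oracle
  equivalences use 1,000 random string pairs and full `4^L` enumerations
  for L ≤ 6. These sizes make every binomial check well-powered while
  keeping the suite fast.

## Known limitations

* The taxonomy needs each sample's amplicon to be unique and well
  separated; it does not apply to shotgun libraries where samples share
  sequence content (ε from control pairs still does).
* Rates among *mapped* reads slightly understate injected event rates,
  because heavily corrupted (very low quality) misassigned reads fall into
  `UNASSIGNED`; the same is true of any real demultiplexer.
* `MULTI_MIS` events are reported but rare by construction; almost all
  unexpected triplets differ from an expected one by a single step.
* No per-position trimming: the filter accepts or rejects whole segments
  on their mean error probability.
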