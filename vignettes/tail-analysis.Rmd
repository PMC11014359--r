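---
title: "Methods: 3′ RACE-seq tail classification and censored length estimation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: 3′ RACE-seq tail classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tailrace)
```

## The measurement model

A targeted 3′ RACE-seq library interrogates the non-templated 3′ end
(NTA) of one transcript at a time. A preadenylated adapter carrying a
15-nt random unique molecular identifier (UMI) and a fixed delimiter
is ligated to every RNA 3′ end; reverse transcription from the adapter
adds a 6-nt sample index; nested PCR with a transcript-specific
forward primer produces the sequenced amplicon. Paired reads then
carry complementary information:

* **R2** starts inside the adapter: `[UMI(15)][delimiter][payload]`.
  The payload is the reverse complement of the molecule's 3′ end, so
  its first base is the complement of the 3′-terminal nucleotide —
  uridylation status is determined by R2 even when the tail's length
  is not measurable.
* **R1** reads the sense strand from the forward-primer site through
  the templated region, the tail, and (for short enough inserts) into
  the adapter.

The NTA is defined as every base 3′ of the last reference-matching
base. This definition is implemented with a *greedy templated* rule:
when the junction is ambiguous because the reference itself ends in
adenosines, the ambiguous As belong to the template, not the tail.
The alternative (greedy tail) systematically inflates A-tail lengths;
the choice matters only for references whose annotated 3′ end is
A/U-rich, and is symmetric for all samples in a comparison.

### Tail classes

NTAs are classified by strict pattern match (U ≡ T):
empty → `NONE`; `A+` → `A`; `A+U+` → `AU`; `U+` → `U`; anything else →
`OTHER`. The four-class fractions reported downstream exclude `OTHER`
from the denominator (it is tabulated separately), because the
four-class composition is the biological quantity of interest and
`OTHER` is dominated by sequencing artefacts under this chemistry.
How interleaved tails (e.g. AUA…A) or G/C-containing tails should be
counted is genuinely open; a strict pattern with a separate `OTHER`
bin makes the choice visible in the output instead of hiding it. An
error-tolerant mode (`tolerance = 1`) corrects up to one isolated
non-conforming base inside tails of ≥10 nt before matching, for use on
real (error-containing) libraries.

### Length estimation and right-censoring

Short-read lengths bound the observable tail: after the index, UMI and
delimiter are excluded, a 100-nt R2 leaves an 81-nt payload, hence the
default window of `window = 80` nt. Estimation is hierarchical:

1. if the R2 payload reaches templated sequence (boundary found with
   an anchored span of at least `min_anchor` nt), the tail length is
   exact from R2;
2. else if R1 reaches the adapter, the length is exact from R1;
3. else the tail overruns both views: the call is right-censored,
   reported at `total_len = window` with `censored = TRUE`, and lands
   in the terminal "≥ window + 1" histogram category.

Censored calls are still classified. The terminal U run always sits
inside the R2 payload, so the U count of a censored AU/U tail is
exact; the R1 prefix contributes only the fact that the tail *starts*
with adenosines. Internally this is encoded by prepending a single `A`
to the R2 evidence when the R1 prefix is adenosine-leading — a naive
concatenation of both views would double-count their overlap and
produce spurious `OTHER` calls. For the same reason a read that ends
1–3 bases into the adapter has that partial adapter prefix stripped
from its R1 tail view before classification.

Exact lengths larger than the window are also reported censored at the
window: the window is a reporting convention, not a read-length fact,
and this keeps the "≥ window + 1" category faithful regardless of read
length.

## The boundary scan

Because the chemistry produces substitution-dominated errors, the
templated/NTA boundary is found by a substitution-only scan (C++,
`src/boundary.cpp`): for increasing candidate NTA lengths *t*, the
payload suffix starting at *t* is compared against the
reverse-complemented reference; the first *t* whose aligned span (≥
`min_anchor`, default 10 nt) has mismatch rate ≤ `max_mismatch_rate`
(default 0.05) is accepted. Scanning *t* upward implements the greedy
templated rule (minimal tail). `N` never matches. Indels are not
modelled; an indel in the templated span typically fails the mismatch
budget and the read is rejected as `unanchored` rather than miscalled.

Reads are routed to a reference amplicon by positional comparison of
the R1 segment (which always starts at the forward-primer site)
against every loaded amplicon, taking the best mismatch rate. This is
what allows a panel of close LINE-1 subfamily consensus windows to be
used: diagnostic mismatches count against the anchor budget, so
`max_mismatch_rate` must exceed (number of diagnostic positions) /
(anchored span) in that use — with 4 diagnostics in a 60-nt window,
0.15 is a workable setting.

By default molecules are assumed to extend to the annotated 3′
terminus (`max_end_trim = 0`); a nonzero `max_end_trim` lets the
templated end stop up to that many bases earlier, for assays where
truncated 3′ ends are expected.

## UMI deduplication

The dedup key is `(sample, reference, UMI)` — deliberately not the
anchor position, since PCR artefacts can shift apparent anchors and a
UMI identifies a molecule regardless. Two grouping modes exist:

* `exact` (default): identical UMIs. With a 15-nt UMI (4¹⁵ ≈ 1.1 ×
  10⁹ sequences) true collisions are negligible at library scale.
* `directional-1mm`: additionally absorbs a UMI into a ≥2×-more-
  abundant UMI at Hamming distance 1 (the standard directional rule,
  implemented with position-masked bucketing). This reabsorbs
  sequencing-error derivatives of abundant UMIs; with the default
  0.1% error rate and exact mode, roughly `15 × error_rate` of reads
  found new spurious UMI groups, visible as a few-percent inflation of
  molecule counts.

The consensus call of a group is the plurality class; ties break
toward the class of the member with the longest uncensored evidence,
then lexicographically (A < AU < NONE < OTHER < U) for determinism.
Lengths are member medians within the winning class; the consensus is
censored only if every winning-class member is.

## Summaries and tests

* Class fractions over {A, AU, U, NONE}; uridylated fraction = AU + U.
* Length classes 1–32 / 33–64 / ≥65 nt (censored calls in the top
  class), per-length histograms 1…window plus "≥ window + 1", 10-nt
  bins of total length with no-tail molecules excluded from bin
  denominators, and the U-stretch length joint with total length.
* Medians include censored calls at the window value — consistent with
  reporting inside the observable window, and biased low when
  censoring is heavy, which is why `prop_censored` is reported next to
  every median.
* Between-sample class composition: Pearson chi-square without
  continuity correction on the 2×k count table (k ≤ 4), df = k − 1.
  Between-sample lengths: two-sided Mann–Whitney U, exact by full
  enumeration when the smaller sample has ≤ 8 observations and no ties
  (where the exact two-sided p equals the symmetric tail probability),
  otherwise the normal approximation with tie correction and no
  continuity correction, so identical inputs give p = 1 exactly. No
  multiple-testing correction is applied by default (comparisons are
  reported per stratum); `adjust_comparisons()` provides
  Benjamini–Hochberg when many strata are tested together.

## The simulator

`library_params()` defaults describe a wild-type-like library:
class probabilities (A 0.77, AU 0.15, U 0.02, NONE 0.06) giving a 17%
uridylated fraction and ~6% tailless; A-lengths from a zero-truncated
negative binomial (mean 45, dispersion 5; median 42); U-stretches
1 + Geometric with mean 2; PCR copies 1 + Poisson(2); per-base
substitution error 0.1%; 100 + 100-nt reads so the R2 payload exactly
covers the 0–80 window. The delimiter defaults to a declared 4-nt
placeholder (`CTAG`, self-reverse-complementary and containing G/C so
it cannot arise inside an A/U tail); the real adapter layout is
configuration, never hard-coded. UMIs are drawn uniformly and redrawn
to be pairwise distinct: at these scales the birthday effect would
otherwise produce a handful of collisions per 10⁴–10⁵ molecules, and a
simulated UMI's purpose is to identify one molecule.

The simulator writes reads whose sample index travels in the FASTQ
header comment (Illumina `1:N:0:INDEX` convention); an in-line R1
index layout is supported in parsing via
`read_layout(index_source = "r1_prefix")`. Index sequencing errors are
not simulated (the index is in the header, not the sequence).

What the simulator deliberately does **not** model: indels and
homopolymer slippage, polymerase-dependent truncation of long poly(A)
tracts, RT stutter, internal A-to-G editing, amplification bias
between tailed and tailless species, and quality-score variation
(constant Q40 is written). Passing tests therefore demonstrate the
*logic* of parsing, anchoring, classification, censoring, dedup and
statistics — not robustness to every artefact of real libraries.

## Degenerate inputs and edge rules

* Empty FASTA → empty amplicon table with a warning; an empty FASTQ
  run completes with n = 0 summaries.
* Sequences outside A/C/G/T/N are rejected naming the record (the
  FASTA is read as raw strings first, because the DNA parser would
  silently drop invalid codes).
* Sample sheets must keep indices at Hamming distance > 2 ×
  `max_index_mismatch`; ties in demultiplexing give `undetermined`.
* Every read pair receives exactly one fate (`ok`, rejection reason,
  or `undetermined_index`); fates are asserted to sum to the input
  count in `run_pipeline()`'s conservation ledger.
* Zero-count categories abort the chi-square with advice to pool;
  empty samples abort the Mann–Whitney.

## Problem sizes

The shipped checks use 20 000 molecules per condition for exact
recovery and dedup invariance, 50 000 for sampling-consistency of
fractions (3 binomial SDs) and medians (±1 around the
generating-distribution medians, computed from the pmfs, not the
sampler), 5 000 for censoring behaviour, and 1 000 random tables for
the chi-square closed-form property — sizes at which the checked
quantities are statistically sharp while a full run stays in the
minutes range on one core.
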