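---
title: "Classifying miRNA isoforms and 3' nontemplated additions: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying miRNA isoforms and 3' nontemplated additions: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mirtail)
```

## The classification model

Every analysis in this package reduces to one decision made per read and
per annotated mature product: is the read a templated slice of its
precursor hairpin, a templated slice carrying extra 3′ nucleotides absent
from the genome, or something else?

Given a hairpin sequence, a mature annotation (0-based half-open
coordinates on the hairpin) and a read, `align_anchored()` considers every
placement of the read whose 5′ start lies within `anchor_window` (default
±3 nt) of the annotated mature start. Each placement is scored by a
position-by-position substitution-only comparison; read positions
extending past the hairpin 3′ end have no template and therefore count as
mismatches, and `N` never matches anything. The placement minimising
(mismatch count, |5′ offset|, start coordinate) — in that lexicographic
order — wins, and is classified:

* **TEMPLATED** — zero mismatches. The read is a literal hairpin
  substring; its length (18–24 nt tabulated) defines its isoform class.
* **NTA** — all mismatches form one contiguous run ending at the read's
  last position, of length ≤ `tail_max` (default 2), with total
  mismatches ≤ `max_mismatches` (default 2). The run is the nontemplated
  tail, reported in the RNA alphabet.
* **INTERNAL_MM** — at least one mismatch strictly before the last
  position, total within the mismatch budget. These reads are the error
  background and never enter isoform or tailing statistics.
* **UNASSIGNED** — anything else (too many mismatches, or no candidate
  placement).

Two consequences of this rule set deserve emphasis. First,
*templated-extension precedence*: a 3′ base that matches the next hairpin
base is not a mismatch, so such a read is a longer templated isoform and
never a tail. An NTA is defined by its mismatch to the genome; tails that
coincide with genomic sequence are systematically invisible, and any
observed tail incidence is an underestimate by exactly the coincidence
probability. Second, the mismatch budget couples tails and errors: a
mono-tailed read that also carries one internal sequencing error shows two
mismatches that do not form a terminal run, and correctly falls into
`INTERNAL_MM`.

Indels are not modelled: the comparison is substitution-only, which is the
appropriate model for short Illumina reads on a known reference.

`classify_library()` applies the same rule to every (hairpin, mature)
pair, after first diverting reads that exactly equal a spike-in sequence
to `SPIKEIN`. A read assigned to k > 1 matures receives k calls flagged
`multimap_n = k`; downstream statistics count each call once, with a
`unique_only` switch to drop multimapped calls entirely. Internally the
library path is vectorised over reads of equal length; the test suite
certifies it against the scalar aligner and against
`brute_force_oracle()`, an exhaustive re-enumeration of every placement on
an independent code path.

## From calls to statistics

**Guide selection.** Per hairpin, the arm with the larger templated count
is the guide (ties resolve to the 5′ arm, i.e. the smaller start). Guides
enter the modification statistics only when their templated count is
strictly greater than `min_guide_count = 50` — a count of exactly 50 is
excluded. The cutoff is applied per library, so each sample stands alone.

**Isoform spectrum.** Templated calls only, tabulated by read length over
18–24 nt; fractions are counts over their total. `heatmap_matrix()`
assembles spectra across samples into the matrix behind the usual heat-map
display (rows ordered by descending total count); rendering is a thin
convenience over this matrix.

**Tail composition.** Mono additions only (|tail| = 1), tabulated by the
1-based read position of the added base (21–24) and the added nucleotide,
with per-position percentage shares. The pooled profile sums counts across
retained guides before computing shares, so abundant miRNAs weigh more —
a percentage sum of variant reads, not an average of percentages.

**Normalisation.** Counts are scaled to per-million units anchored on the
spike-in matched total (fallback: total classified non-spike reads when no
spike-ins are present). Normalisation is one global factor, so every
fraction and percentage is invariant under it; the published quantities
are scale-free.

**Terminal-vs-internal fold.** The count of mono additions whose added
base sits at the focal read position (default 23) divided by the mean,
over internal positions 1 to focal−1, of per-position counts of
single-mismatch internal calls. Uniform sequencing error would give a fold
near 1; genuine enzymatic tailing gives tens of fold. The internal
position range is configurable (`exclude_internal`) but defaults to all
positions, and the fold is `NA` when the internal background is empty.

## The synthetic library generator

`sim_config()` fixes the simulated conditions; `make_reference()` draws
random hairpins (uniform base composition, 60–90 nt) each carrying one
5′-arm and one 3′-arm 22 nt mature, placed so that the longest configured
templated window always fits on the hairpin; `generate_library()` then
emits reads built as: templated window (sampled length class and 5′
offset) + optional 3′ tail + per-base substitution errors + the 3′
adapter, with spike-in reads interleaved and a constant FASTQ quality
string (the pipeline never reads qualities).

The default parameters are the conditions under which the package
validates itself: length weights (0.05, 0.10, 0.70, 0.10, 0.05) over
20–24 nt, 5′ offset mass 0.8 at 0 (±1: 0.08, ±2: 0.02), tail rate 0.07,
mono:di tail lengths 0.9:0.1, tail mix U:A:C:G = 0.55:0.30:0.10:0.05,
error rate 0.001 per base, spike fraction 0.02, guide:star ratio 9:1.
Offset mass and the mono:di split are field-realistic choices (most
isomiRs keep the canonical 5′ end; mono additions dominate observed
tailing); the remaining values define the recovery experiments reported by
`scripts/acceptance.R`.

Two deliberate simplifications: sequencing errors are applied to the
insert only, not to the appended adapter, so the truth table's `sequence`
column is exactly the post-trim sequence the pipeline should recover
(adapter-trimming robustness under mismatches is exercised separately by
the trimmer's own tests); and hairpins are uniform random sequences with
no secondary-structure realism, because classification depends only on
sequence identity.

**The tail-coincidence ambiguity.** When a generated tail's final base
equals the hairpin base aligned to the read's last position, the read is,
by the genome-mismatch definition, a templated extension — no classifier
could call it a tail. The generator truth-flags these reads
(`tail_indistinguishable`) rather than forbidding the coincidence, keeping
the realistic ambiguity while keeping recall well defined. A subtle
corollary: a di-tail whose final base coincides but whose first does not
presents as a single *internal* mismatch and is classified `INTERNAL_MM`;
such reads are also flagged.

`score_recovery()` joins calls back to truth and reports a confusion
matrix, NTA precision/recall excluding flagged reads, and recovered
parameters. Two corrections keep the estimates unbiased. The tail rate
divides the raw NTA incidence by the truth-observed distinguishability
rate (≈ 3/4 for uniform references). The tail mix divides each
nucleotide's observed share by its own distinguishability rate before
renormalising: with a finite reference (20 hairpins), reads concentrate on
a few dozen hairpin positions, whose base composition fluctuates several
percent from uniform between seeds, pruning each tail nucleotide at its
own rate; the per-nucleotide correction removes that seed-to-seed bias.

## What passing tests do and do not show

The simulator shares the classifier's sequence model, so recovery tests
certify internal consistency, placement logic, tie-breaking, the
tail/extension boundary and the statistical machinery — not robustness to
features the generator omits: ligation bias, PCR duplication, quality-
dependent error profiles, indels, genomic SNPs between sample and
reference, or cross-mapping between paralogous hairpins (random references
make multimapping vanishingly rare; real miRNA families do not). Results
on real libraries inherit those caveats.

## Numerical and design choices

* Coordinates are 0-based half-open everywhere; 1-based values appear only
  in report columns suffixed `_1based`. The internal alphabet is DNA
  (U→T on input); tails are rendered as RNA in reports.
* Tie-breaks are fully specified (mismatches, then |offset|, then start),
  so classification is deterministic; output tables render floats at six
  significant digits and are byte-identical across runs on identical
  input.
* Adapter trimming uses leftmost-match semantics with mismatch tolerance
  `floor(rate × overlap)`, overlap ≥ 5 — the standard behaviour of 3′
  adapter trimmers. No quality trimming is performed.
* The length-18 boundary is kept ("shorter than 18" discarded), and the
  guide cutoff is strict ("above 50").
* The anchor window (±3 nt) is wider than the generator's offset range
  (±2 nt): annotation coordinates in public references are themselves
  uncertain by a base or two, and the window is configurable.
* `tail_max` and `max_mismatches` are independent knobs: whether a
  2-mismatch budget is spent on a di-tail or on one tail plus one internal
  error is a data property, not a configuration.
* Degenerate inputs are defined: empty libraries produce empty tables; a
  mature with no reads yields no guide; a zero internal background yields
  an `NA` fold; normalisation with no anchor is an error.

## Problem sizes

The test suite validates the aligner against the exhaustive oracle on
10,000 randomised instances, and runs parameter recovery on one simulated
50,000-read library (20 hairpins, 40 matures) — large enough that every
recovered proportion is tested against a 4× binomial standard-error band
around its generator value, and the terminal/internal fold against a
closed-form expectation within ±25%. End-to-end determinism is checked by
running the full pipeline twice on a 10,000-read library and comparing
output bytes.

## Limitations

5′ nontemplated additions are not called; tails longer than `tail_max`
are not recognised as tails; genome-wide mapping and novel-miRNA
discovery are out of scope (annotations must be provided); and the
terminal/internal fold assumes the internal background is error-driven —
abundant RNA editing or SNPs would inflate specific internal positions
and deflate the fold.
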