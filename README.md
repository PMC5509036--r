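# mirtail

Classification and quantification of miRNA length isoforms (isomiRs) and
3′ nontemplated nucleotide additions (tailing) from small RNA sequencing
data.

## The problem

Mature miRNAs are not a single sequence: deep sequencing shows each miRNA
as a family of length variants, plus reads carrying one or two extra 3′
nucleotides that do not match the genome — nontemplated additions (NTAs),
predominantly mono-uridylation and mono-adenylation catalysed by terminal
uridylyl transferases. Distinguishing genuine tailing from templated
extension and from sequencing error is a classification problem on the
precursor hairpin:

* a read that is a literal substring of its hairpin, starting near the
  annotated mature 5′ end, is a **templated isoform** of its length;
* a read whose mismatches to the hairpin form a contiguous terminal run
  (≤ 2 nt here) is a read carrying a **3′ nontemplated addition**, with the
  run as the tail;
* a read with a mismatch before its final position is an
  **internal mismatch** (sequencing error, SNP, editing) and is excluded
  from tailing statistics;
* the alignment permits at most two mismatches in total.

From the per-read calls the package computes the standard summaries:
per-miRNA isoform length spectra over 18–24 nt (fractions of templated
reads per length), per-position tail nucleotide composition (percent U/A/C/G
among mono additions at read positions 21–24), spike-in per-million
normalisation, and the **terminal-vs-internal fold** — the summed count of
mono additions at the focal 3′ position (default 23) divided by the mean
per-position count of single internal mismatches. A large fold is the
signature that terminal additions are enzymatic rather than a uniform
error artefact.

A key design rule is templated-extension precedence: a 3′ nucleotide that
matches the next hairpin base is counted as a templated isoform, never as a
tail, because an NTA is defined by its mismatch to the genome. This
under-counts tails that coincide with genomic sequence; the simulator
truth-labels exactly those reads so the effect is measurable.

Only guide miRNAs pass into the modification statistics: per hairpin, the
arm with the larger templated count is the guide, and guides are kept only
when that count is strictly above 50.

## What is in the package

* `read_fasta()`, `read_fastq()`, `read_annotation_tsv()`, `read_spikes()`,
  `collapse_reads()`, `write_count_table()` — strict, validated I/O with a
  single internal sequence convention (uppercase DNA; U→T on input; tails
  reported back in the RNA alphabet).
* `trim_config()` / `trim_adapter()` / `length_filter()` /
  `preprocess_reads()` — leftmost-match 3′ adapter trimming with a
  mismatch-rate tolerance, and the "shorter than 18 nt discarded" filter.
* `map_config()` / `align_anchored()` / `classify_library()` — the anchored
  hairpin aligner and library-scale classifier (`brute_force_oracle()` is
  the exhaustive reference used by the tests).
* `select_guides()`, `isoform_spectrum()`, `nta_profile()`,
  `normalize_counts()`, `terminal_internal_fold()`, `heatmap_matrix()` —
  the summary statistics.
* `sim_config()` / `make_reference()` / `generate_library()` /
  `score_recovery()` — a fully ground-truthed synthetic library generator
  and its recovery scorer.
* `mirtail_fit()` — the one-call interface returning a classed fit object
  with `print`, `summary`, `coef`, `plot` and `simulate` methods; and
  `run_pipeline()` / `validate_inputs()` for config-driven (YAML) runs
  writing the result tables and a provenance manifest.

## Worked example

Simulate a 20,000-read library (default conditions: 22 nt matures, length
mix centred on 22 nt, 7% tailing with mix U:A:C:G = 0.55:0.30:0.10:0.05,
0.1% per-base error, TruSeq small RNA adapter, 2% spike-ins) and fit it:

```r
library(mirtail)
cfg <- sim_config(seed = 7, n_reads = 20000)
ref <- make_reference(cfg)
lib <- generate_library(cfg, ref)
fit <- mirtail_fit(lib$reads, ref$hairpins,
                   ref$annotations[c("mature_id", "hairpin_id",
                                     "start", "end")],
                   spikes = ref$spikes)
print(fit)
#> mirtail fit
#>   input reads: 20000 (0 discarded as < 18 nt)
#>   calls by category: INTERNAL_MM=438, NTA=959, SPIKEIN=409, TEMPLATED=18184, UNASSIGNED=10
#>   spike-in matched reads: 409
#>   guides retained (templated count > 50): 20 of 40 matures

round(coef(fit), 4)
#>             frac_len18             frac_len19             frac_len20
#>                 0.0000                 0.0000                 0.0489
#>             frac_len21             frac_len22             frac_len23
#>                 0.0983                 0.6926                 0.1089
#>             frac_len24           tail_share_U           tail_share_A
#>                 0.0513                 0.5331                 0.3082
#>           tail_share_C           tail_share_G         tail_incidence
#>                 0.0952                 0.0635                 0.0493
#> fold_terminal_internal
#>                33.7458
```

Reading the output: 18,184 of 20,000 reads are mismatch-free templated
isoforms; the recovered length fractions peak at 22 nt (0.69, generator
truth 0.70); mono-addition shares are U-dominated (53% U, 31% A) as
configured; observed tail incidence is 4.9% — below the simulated 7%
because tails whose final base happens to match the hairpin are, by
definition, templated extensions; and terminal additions at position 23
stand ~34-fold above the per-position internal mismatch background, the
artefact-exclusion contrast. `score_recovery(lib$truth, fit$calls,
fit$reads)` quantifies all of this against the generator's truth,
including NTA precision/recall on distinguishable tails.

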