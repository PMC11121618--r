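---
title: "G4 sequence context around somatic mutation sites: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{G4 sequence context around somatic mutation sites: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(g4context)
```

## The question

G-quadruplexes (G4) are four-stranded DNA structures formed by stacked
tetrads of Hoogsteen-paired guanines. They stall replication forks, resist
repair, and are therefore candidate drivers of localized mutagenesis in
tumors. `g4context` asks, for each tumor in a cohort: *are this tumor's
somatic mutations found in G4-forming sequence context more often than
expected for its exome capture panel?* Samples are classified by that
criterion, and the classification is then used to stratify mutation spectra,
predicted G4 gains/losses, and germline variant sharing.

## Motif model

Two motif classes are scanned, each on both strands of the duplex:

* **weak**: four runs of exactly two guanines, `G{2}\D{1,10}` repeated —
  plus the mirror pattern over `C{2}` that detects quadruplex potential on
  the complementary strand;
* **strong**: four runs of three to four guanines, `G{3,4}\D{1,10}` repeated,
  and its `C{3,4}` mirror.

Loops between runs are 1–10 characters long, and the loop element matches
*any* character — on a DNA string the non-digit class `\D` admits every
base, including G, C and N. This has real consequences: a run of sixteen
guanines satisfies the strong pattern (three-G runs joined by single-G
"loops"), and loops may themselves be G-rich. We reproduce this semantics
exactly rather than quietly substituting a restricted loop class, because
every enrichment count downstream depends on it; `strict_loops = TRUE` is
available on the scanning functions for sensitivity analysis (loops that
cannot extend a run), and is not used in any headline number. N bases can
never sit inside a G/C run but are accepted in loops. Scanning is done on
uppercased sequence, so soft-masked repeats are *not* excluded.

A window's category is `STRONG` if any strong motif matches, else `WEAK` if
a weak motif matches, else `NONE`; strong dominance makes the three
categories disjoint, which is what lets the combined weak-plus-strong count
be formed by addition.

The scanner is a thin layer over PCRE (`gregexpr`/`grepl`). Its
presence/absence calls are certified in the test suite against an
independent brute-force enumerator (`oracle_has_g4`) that searches all
run/loop decompositions by a reachability sweep — 10,000 random 141-mers
per strength, plus hand-picked corner cases such as the all-G stretch.

## Windows and haplotypes

For an SNV at 1-based position *p* the analysis window is
`[p - 70, p + 70]`, 141 nt. The mutated base itself is included: its own
guanine can participate in a G-run, and excluding it would be an arbitrary
hole in the middle of the scanned sequence. For indels the anchor spans the
full reference allele, giving `140 + nchar(ref)` nt. Windows that run off a
contig end are clipped and flagged, never dropped — dropping them would
silently change per-sample denominators. Internally all coordinates are
1-based closed, the Bioconductor convention; BED input/output is converted
at the boundary.

Each patient's germline variants (depth-filtered: DP strictly greater
than 10 *and* alt-allele depth strictly greater than 5; variants lacking
either field are dropped and tallied) are spliced into the reference window
before classification, so the scanned sequence is the patient's own
haplotype around the somatic site. Edits are applied right-to-left so indel
length changes never invalidate the coordinates of edits still to be
applied. Any non-reference genotype is applied, heterozygous or homozygous:
zygosity-aware scanning of both haplotypes would double the window count
for het sites and the depth-filtered call sets here do not reliably phase
them. For the before/after comparison under a somatic mutation, both states
are rebuilt from the reference window by genomic coordinates (germline
only, then germline plus somatic), so a germline indel upstream cannot
shift the somatic splice point.

## Enrichment test

For each sample, the fraction of somatic windows with `STRONG` context (and
separately with `WEAK` or `STRONG`) is compared against 2000 windows of the
same length anchored at positions drawn uniformly over the bases of that
sample's capture panel — interval chosen proportionally to its length, then
a uniform base, with replacement (at 2000 draws from a megabase-scale panel,
collisions are negligible). Controls are classified on the reference
sequence without germline edits: the control set describes the panel, not a
patient. Each sample is compared against the control set of *its* panel,
since cohorts sequenced with different capture kits have different
background G4 rates.

Three statistics are reported per context:

* the Wilson score interval for each proportion (better small-sample
  behavior than the Wald interval; bounds pinned to exactly 0 and 1 at
  `k = 0` and `k = n`);
* the Pearson chi-square test of independence on the 2×2 table, 1 df,
  continuity correction off by default (a flag turns Yates on);
* the pooled two-proportion z-test, two-sided, with `z > 0` when the tumor
  proportion exceeds the control. On small tables `z² = χ²` exactly, which
  the tests verify exhaustively.

A sample is labelled `G4_STRONG` when the strong context passes **both**
tests at `alpha = 0.05` *and* the tumor proportion exceeds the control;
otherwise `G4_WEAK_PLUS_STRONG` by the same rule on the combined context;
otherwise `NONE`. Enrichment is one-directional by definition — a
significant deficit is not enrichment. No multiple-testing correction is
applied across samples, matching the source analysis; a Benjamini–Hochberg
option exists behind a flag. This two-sided-plus-direction rule is
deliberately conservative: its null rejection rate is asymptotically
`alpha/2`, about 0.035 in our calibration (discreteness pushes it above the
asymptotic value), which the calibration analysis treats as type-I control
at `alpha` rather than as a quantity that should equal `alpha`.

For the cohort summary, `NONE` and `G4_WEAK_PLUS_STRONG` samples are pooled
as "without G4 strong enrichment" when computing group mean mutation
counts — the combined-context sample shows no *strong*-context enrichment,
which is the grouping criterion.

## Downstream stratifications

Substitution spectra use the 12 strand-specific types (`C>A` distinct from
`G>T`): the analysis explicitly contrasts complementary pairs, so the
usual pyrimidine folding would destroy the signal of interest. Each
(group, stratum) cell reports counts, proportions, and the binomial
standard deviation `sqrt(p(1-p)/n)` of each proportion. Indels and MNVs are
excluded from spectra and tallied. Consequence labels (VEP-style strings)
are consumed as input and cross-tabulated with G4 category verbatim;
variants without a label are bucketed as `unannotated`.

Group-exclusive germline SNP discovery keys variants by
`(chrom, pos, ref, alt)` — not rsid, so unannotated variants participate —
and returns keys present in every sample of the query group and in no
other sample. The population-frequency filter keeps `af_pop < 0.1`
(strict), reading the frequency from a configurable INFO field; variants
lacking it are reported separately rather than silently kept or dropped.

## The synthetic study

No patient data are distributed with the study this design mirrors, so the
package carries a generator that emulates its structure end to end. The
defaults *are* the study conditions: 11 samples with the published
per-tumor somatic totals (115, 63, 87, 234, 182, 191, 119, 662, 267, 82,
227); planted strong-motif enrichment 0.6 for the three samples the study
called G4-strong and a weak-motif enrichment of 0.45 for the fourth,
combined-context sample; 15 group-exclusive germline SNPs of which 8 have
population frequency below 0.1. The genome is 2 contigs × 100 kb at GC
0.45 (exome-like), with 25 strong and 25 weak motifs per contig and a
capture panel tiling half of it in 2 kb chunks — large enough that 2000
control windows sample the panel sparsely, small enough that the full
11-sample analysis runs in seconds. The 0.6/0.45 planted fractions are a
choice, not a published value: they are the smallest round fractions that
put the enriched samples far from the decision boundary (detection is
already near-certain at f = 0.3 for n = 100), so label recovery tests the
pipeline rather than luck.

Planted strong motifs are drawn as four runs of 3–4 G (or C, coin-flip per
motif) with random 1–10 nt loops; weak motifs as four runs of exactly two.
Every planted locus is re-verified with `classify_window` before acceptance
— a weak plant that accidentally forms a strong match is re-drawn. Enriched
somatic sites are placed uniformly within ±70 nt of a uniformly chosen
planted motif (intersected with the panel); background sites are placed at
least `motif_exclusion` nt (default 200) from any planted motif so truth
labels stay unambiguous. Background G4 matches arising by chance in random
sequence are allowed and measured, not suppressed — at GC 0.45 about 6% of
panel positions classify `STRONG`, which is what makes the control
comparison non-trivial.

One master seed drives independent per-purpose substreams (reference,
per-sample somatic, germline), so regenerating one sample never shifts
another, and identical configs are byte-identical on disk.

What the generator does *not* emulate: mutational-signature structure in
the spectra (substitutions are uniform over the three non-reference bases),
linkage between germline SNPs, sequencing noise, and the real genome's
non-uniform G4 density. Passing recovery tests therefore demonstrates that
the pipeline measures what it claims on data with known truth — not that
the biological effect exists in any particular cohort.

## Calibration and power

`simulate_enrichment_labels` replays the whole decision rule over replicate
synthetic samples against a precomputed per-position category index (pure
memoisation of window classification — identical results, orders of
magnitude faster). Two designs are used:

* **null calibration** — planted f = 0 with `motif_exclusion = 0`, making
  the somatic generator distributionally identical to the control draw.
  Over 500 replicates (n_somatic = 100, n_controls = 2000) the `G4_STRONG`
  label rate is ~0.03–0.05, within the conservative bound described above.
  The default 200 nt exclusion must *not* be used here: it forces a
  strong-context deficit and would measure conservatism, not type-I error.
* **power** — planted f ∈ {0, 0.15, 0.3, 0.45, 0.6} with the exclusion on;
  detection of the `G4_STRONG` label rises monotonically and exceeds 90%
  well before f = 0.6 at n_somatic = 100.

Problem sizes in the shipped tests and acceptance script (500 null
replicates, 50 power replicates per f, 10,000 oracle sequences per
strength, the full 11-sample default study) were chosen so the complete
suite runs in a couple of minutes on one core while leaving the binomial
bands tight enough to be meaningful.

## Numerical and degenerate-input choices

* `two_proportion_z` with pooled proportion 0 or 1 returns `z = 0, p = 1`
  with a `degenerate` flag rather than NaN; a degenerate chi-square table
  (zero marginal) is an error that `evaluate_sample` catches and treats as
  non-significant.
* Empty spectrum cells keep all-zero counts with `NA` proportions and are
  flagged, so downstream joins never silently lose strata.
* Multiallelic VCF records are split into one variant per alt; non-PASS
  records are excluded by default (`keep_nonpass` reverses this). No
  further left-normalization is attempted.
* `read_panel` merges overlapping and book-ended intervals and sorts
  contigs naturally, so panel length is well-defined; malformed rows fail
  with their line number.
* The brute-force oracle refuses sequences over 1000 nt — it exists to
  certify the scanner on window-sized inputs, not to scan genomes.

## Known limitations

The motif model is the source analysis's regex definition, not a
thermodynamic G4 predictor (no G4Hunter-style scoring, no loop-length
penalty, no RNA G4s). Enrichment inherits the limits of parametric
2×2 tests at very small mutation counts. Germline application ignores
phase. The group-exclusive SNP search is presence/absence only — zygosity
and local haplotype structure are out of scope, as are annotation lookups
(GWAS catalog, ClinVar) and signature fitting.
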