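# g4context

Analysis of G-quadruplex (G4) forming sequence context around somatic
mutation sites in tumor exomes.

G-quadruplexes — four-stranded structures formed by stacked tetrads of
Hoogsteen-paired guanines — stall replication and impede repair, and are
suspected drivers of localized mutagenesis in cancer. Given per-patient
somatic and germline variant calls (VCF), a reference genome (FASTA) and the
exome capture panel (BED), `g4context` answers, per tumor: **are somatic
mutations located in G4-forming context more often than expected for this
capture panel?** It then uses that classification to stratify mutation
spectra, predict G4 gains/losses under somatic mutations, and search for
germline SNPs exclusive to the enriched group. A fully synthetic study
generator with planted truth makes every stage testable without patient
data. The package is aimed at cancer-genomics analysts working from
tumor–normal exome call sets.

## Method

Around every somatic site the ±70 nt window (141 nt for SNVs, patient
germline variants spliced in) is scanned with two strand-symmetric motif
classes:

```
weak:    G{2}\D{1,10}G{2}\D{1,10}G{2}\D{1,10}G{2}        (and the C-strand mirror)
strong:  G{3,4}\D{1,10}G{3,4}\D{1,10}G{3,4}\D{1,10}G{3,4} (and the C-strand mirror)
```

The loop element matches *any* character (the `\D` class on a DNA string),
which is reproduced deliberately — see the vignette. Windows are labelled
STRONG > WEAK > NONE.

Per sample, the proportion of STRONG-context windows (and of combined
WEAK+STRONG) is tested against 2000 random windows drawn uniformly from the
sample's own capture panel:

- Wilson score intervals for each proportion p̂ = k/n;
- Pearson χ² test of independence on the 2×2 table (1 df);
- pooled two-proportion z-test,
  z = (p̂₁ − p̂₂) / √( p̄(1−p̄)(1/n₁ + 1/n₂) ).

A sample is `G4_STRONG` when both tests give p < 0.05 **and** the tumor
proportion exceeds the control (one-directional enrichment); else
`G4_WEAK_PLUS_STRONG` by the same rule on the combined context; else `NONE`.

## Worked example

The `analysis/` scripts run the whole study on synthetic data and are the
quickest tour. `analysis/01_simulate_study.R` writes an 11-sample study
(two 100 kb contigs, 50 planted strong and 50 weak motifs, capture panel,
per-sample somatic/germline VCFs) under `results/study/`;
`analysis/02_enrichment.R` then runs the full pipeline:

```
Group means (strong-enriched vs the rest):
                        group n_samples mean_mutations
           G4_strong_enriched         3         88.000
 without_G4_strong_enrichment         8        245.625
```

Three samples (S12, P23, P37 — the ones generated with planted enrichment
0.6) are labelled `G4_STRONG`; the sample generated with weak-motif
enrichment is labelled `G4_WEAK_PLUS_STRONG` and pools with the unenriched
group. Because the generator uses the published per-tumor mutation totals,
the group means reproduce the published 88 vs 245.6 contrast exactly.

The same objects are available programmatically:

```r
library(g4context)

ref    <- load_reference("results/study/reference.fa")
panel  <- read_panel("results/study/panel.bed")
som    <- read_variants("results/study/S12.somatic.vcf", "S12", "SOMATIC")
germ   <- filter_germline(read_variants("results/study/S12.germline.vcf",
                                        "S12", "GERMLINE"))
win    <- apply_germline(extract_windows(ref, som), germ)
win$category <- classify_window(win$seq)

ctrl   <- sample_random_windows(ref, panel, n = 2000, seed = 1)
ctrl$category <- classify_window(ctrl$seq)

evaluate_sample(win$category, ctrl$category, sample = "S12")$label
#> [1] "G4_STRONG"
```

`analysis/03`–`05` continue with stratified substitution spectra, G4
gain/loss predictions, group-exclusive germline SNP discovery (15 planted
SNPs recovered, 8 below population frequency 0.1), and the classifier's
operating characteristics — null `G4_STRONG` label rate 0.032 over 500
replicates, detection 1.00 at planted enrichment 0.3 and above
(n_somatic = 100).

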