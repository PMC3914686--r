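# svpopgen

Population genomics of large (≥ 1 kb) indel structural variants among
resequenced inbred lines, from discordant paired-end read alignments.

## The problem

When a set of fully homozygous (inbred) lines from one natural population
is resequenced with paired-end short reads against a reference genome,
large deletions betray themselves twice over: read pairs that straddle a
deleted interval map with an outer insert span inflated by the deleted
length, and the deleted interval itself is left essentially uncovered in
carrier lines.  `svpopgen` turns those signals into a reusable,
fully tested pipeline:

1. **Discordant-pair SV calling** — pairs with both mates mapped at
   quality ≥ 29 are classified by orientation and insert span
   (inward-facing pairs with insert ≥ 1,000 bp signal deletions; same
   strand pairs, inversions; outward-facing or interchromosomal pairs,
   transpositions).  Discordant pairs from all accessions are pooled and
   clustered by two-dimensional single linkage (both anchor starts
   within 225 bp); clusters need at least three supporting pairs.
2. **A filter cascade** — candidates supported by the resequenced
   reference accession are discarded (self-alignment marks unreliable
   regions); SVs < 1 kb are dropped; each deletion carrier's mean depth
   over the interval must fall in the lowest decile of that accession's
   genome-wide (1 kb-tile) depth distribution; candidate endpoints in
   5 kb windows whose background discordant-read count exceeds the
   genome-wide 90th percentile are dropped; inversions/transpositions
   must keep mid-band (10th–90th percentile) coverage.  One failing
   accession rejects the candidate for all accessions.
3. **SNP calling** for homozygous lines — a base is called at 3–25×
   coverage when > 75 % of reads agree; population SNPs require calls in
   every focal line.
4. **Neutral null machinery** — a Kingman coalescent simulator with a
   fixed number of segregating sites (n = 10, S = 100, 10,000
   replicates) yields 95 % envelopes for Tajima's *D* and normalized Fay
   & Wu's *H*, and a Monte-Carlo calculator gives the expected
   |observed − true| allele-frequency error for ten sampled lines
   (≈ 0.097 under censored binomial sampling).
5. **Allele age and selection strength** — intra-allelic diversity π_A
   on a 500 bp haplotype around each variant, divided by the grand-mean
   synonymous π_A, estimates mean allele age *T* in units of 2*N*ₑ
   generations; inverting the diffusion expectation of mean allele age
   under additive selection (Kimura–Ohta/Maruyama sojourn times, age
   symmetric in ±γ) converts *T* into |*N*ₑ*s*|.
6. **Annotation overlap and enrichment** — genic/TE context against an
   alignable-fraction null, 100-bin metagene indel-density profiles with
   binomial bounds, TE-family and gene-family enrichment (Fisher,
   Bonferroni), indel-size-by-MAF Welch ANOVA, and window-density
   correlation of indels and SNPs.
7. **Selection scan** — joint Tajima's-*D*/normalized-*H* outliers in
   10 kb windows around polarized indels, flagged when both statistics
   fall below the neutral envelope's lower bounds.

Because the original resequencing data are not desk-reproducible, the
package ships a first-class synthetic-data generator
(`sim_config()`, `generate_truth()`, `simulate_read_pairs()`) that
plants deletions (1–200 kb, log-normal sizes with median 2,563 bp),
SNPs, gene/TE annotation, paired-end records with outer insert
Normal(275.8, 28.8) bp, chimeric-pair noise concentrated in repeat
hotspots, and low-mapping-quality noise — so every stage is exercised
against known truth.

## Worked example

```r
library(svpopgen)
cfg <- pipeline_config(
  sim = sim_config(seed = 11, genome_length = 1e6, n_genes = 60,
                   n_tes = 120, deletion_count = 12,
                   deletion_size_range = c(1000, 50000),
                   repeat_hotspot_count = 2),
  envelope_reps = 2000)
report <- run_pipeline(cfg)
print(report)
```

```
Synthetic SV population-genomics pipeline report
  planted deletions: 12; candidates: 12; retained: 12
  precision 1.000, recall 1.000
  SNPs called in all lines: 8061 (mean MAF 0.228)
  envelope D (-1.71, 1.58), H (-1.93, 1.57)
  scan outliers: 0 (candidates at freq >= 0.8: 0)
```

All 12 planted deletions survive the cascade with no false positives;
the SNP mean MAF (0.228) sits at the neutral folded-spectrum
expectation for ten lines, and no scan outlier is flagged on purely
neutral synthetic data.  The diffusion inversion reproduces the
published selection-strength anchors:

```r
nes_from_age(0.63, 0.2)   # 1.95  — synonymous class
nes_from_age(0.36, 0.2)   # 5.39  — genic deletions
```

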