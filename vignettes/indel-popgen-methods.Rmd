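---
title: "Methods: large-indel population genomics from discordant read pairs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: large-indel population genomics from discordant read pairs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the models, thresholds and numerical choices
behind `svpopgen`.  It states no empirical result that the test suite or
`scripts/acceptance.R` does not itself compute.

## Study design the package models

The pipeline targets a resequencing design of ten fully inbred
(homozygous) focal lines from one population — one of which is the
accession the reference genome was assembled from — plus two distant
outgroup lines used only to polarize variants.  Because every line is
homozygous, one haplotype represents each line, minor-allele frequencies
take values 0.1–0.5 in steps of 0.1, and a deletion carrier should have
essentially no coverage over the deleted interval.

## Discordant-pair calling

A read pair is *usable* when both mates map with quality ≥ 29, and
*discordant* when it is not in the inward-facing (+,−) orientation, its
outer insert span is ≥ 1,000 bp, or its mates map to different
chromosomes.  The insert span is the outer distance (|TLEN|); the
library mean of 275.8 bp (SD 28.8 bp) makes a 1,000 bp threshold ≈ 25
standard deviations from the mean, so concordant pairs essentially never
cross it.  Signatures follow the standard paired-end configuration
table: inward-facing long inserts → deletion; (+,+)/(−,−) → inversion;
outward-facing (−,+) → eversion and interchromosomal → transposition
candidates.

Pooled discordant pairs are clustered by single linkage in two
dimensions: two pairs link when both their left and their right anchor
starts lie within 225 bp.  Single-linkage chaining is accepted; the
result is order-independent (the implementation sorts before union-find,
and a property test permutes the input).  Clusters need ≥ 3 supporting
pairs.  The deletion interval is taken as the inner edges of the two
anchor groups — `[max(left ends), min(right starts))` — with no
insert-size subtraction; the planted-truth tests hold breakpoints to
within one insert span plus two standard deviations.  A pair-id
blacklist argument provides the hook where a second-opinion re-alignment
step would remove pairs confirmed elsewhere.

## The filter cascade

Filters run in a fixed order (reference accession → minimum size →
type-specific depth → discordant density); the order affects only which
filter a dropped candidate is attributed to, not the retained set, and
the cascade is idempotent and monotone (both tested).

Two choices the depth filters depend on were genuinely open:

* **Depth granularity.** "Genome-wide depth distribution" is implemented
  as the distribution of per-1 kb-tile mean depths per accession, and
  the interval statistic is the length-weighted mean of tile depths.
  Tiles make percentiles well defined and cheap; intervals of interest
  are ≥ 1 kb, so tile resolution does not blur them.
* **Density background.** The 90th-percentile discordant background is
  computed over non-overlapping 5 kb tiles of pooled anchor positions,
  before any filtering; endpoint counts discount the focal candidate's
  own pairs.  Non-overlapping tiling was chosen over sliding windows for
  determinism.

## SNP calling

Per accession and site, a base is called when coverage is between 3×
and 25× (a designated high-coverage line may raise the ceiling, e.g. to
40×) and strictly more than 75 % of reads agree — ties at exactly 75 %
remain uncalled.  Population SNPs must be callable in *all* focal lines
and polymorphic among them; multi-allelic sites are retained with all
non-major alleles pooled as the minor allele, which preserves the MAF
definition.  Coding effects are recomputed per SNP on the longest
transcript's frame, strand-aware, and verified in tests against
whole-CDS translation of mutant versus wild-type sequence.

## Neutral null machinery

### Fixed-S coalescent envelope

`neutral_envelope()` simulates Kingman genealogies (time in units of
2*N*ₑ generations; while *k* lineages remain the next coalescence is
Exp(*k*(*k*−1)/2)) and drops exactly S = 100 mutations per replicate,
multinomially with probability proportional to branch length.  Tajima's
*D* is computed on all ten chromosomes.  For normalized Fay & Wu's *H*,
1–5 of the ten chromosomes are designated outgroup per replicate;
ingroup sites are polarized by strict outgroup consensus (mixed-outgroup
sites are dropped for *H* only, a conservative choice) and *H* is
computed on the remaining ingroup.  All statistics depend only on
relative branch lengths, so the time-unit convention cannot affect the
envelope (tested by rescaling branches).

Two findings from building this module are worth recording:

* **Fixed-S conditioning changes the site-frequency law.**  With a fixed
  number of segregating sites, the derived-count law per site is the
  expected *relative* branch length E[ℓᵢ/ℓ_tot], not the unconditional
  E[ℓᵢ]/E[ℓ_tot] ∝ 1/i.  For n = 10 the singleton share rises from
  0.354 to ≈ 0.414 and the mean folded MAF drops from 0.2282 to
  ≈ 0.222.  The tests use a branch-length-ratio oracle computed
  independently of the mutation-placement code.
* **The normalized-H upper envelope.**  The standardized *H* of Zeng and
  colleagues — (π − θ_L)/√Var with θ estimated by S/a₁ and θ² by
  S(S−1)/(a₁²+a₂) — is bounded above by ≈ +1.7 at these sample sizes
  for *any* spectrum (the numerator is maximized by an all-singleton
  SFS and the variance grows with it).  Simulated 97.5th percentiles
  are ≈ +1.6, and the simulated 2.5th percentile is ≈ −2.05.  Published
  envelopes with a much larger upper bound cannot be produced by this
  statistic; the package reports what the standard statistic gives.

### Allele-frequency sampling error

`maf_sampling_error()` draws a true frequency uniformly, a size-10
binomial sample, and censors monomorphic observations.  Censoring is
implemented as *clamping* the observed frequency into [0.1, 0.9]
(exact expectation 0.0963 for ten lines); the alternative
discard-and-redraw scheme has exact expectation 0.1035 and is available
via `censor = "redraw"`.  The clamp is the default because it is the
literal reading of censoring observed values into a range and because
its expectation matches the published 0.097.

## Allele age and |NeS|

Mean π_A is computed among carrier haplotypes on a 500 bp window centred
on the variant (small enough to make recombination within the haplotype
unlikely); singleton alleles have no defined π_A and are excluded.
Pairwise differences are counted at sites callable in all carriers, and
the per-site value divides by the window length.  Dividing a class's
mean π_A by the grand-mean synonymous π_A converts it to a mean allele
age *T* in 2*N*ₑ-generation units.

`mean_allele_age(x, gamma)` evaluates the diffusion expectation of the
age of a derived allele at frequency *x* under additive (no-dominance)
selection, using the age/extinction-time duality: the age distribution
equals that of the time to loss for an allele at *x* destined for loss,
so the mean age is the conditional mean absorption time, an integral of
conditional sojourn-time densities.  With drift γ·x(1−x) and variance
x(1−x) (γ = *N*ₑ·s, time in 2*N*ₑ generations), the integrand is
written in an overflow-safe form valid for |γ| up to several hundred;
the neutral limit is the closed form −2x·ln(x)/(1−x), which the
integrator matches to 10⁻⁴ in tests.  The scaling convention (γ = *N*ₑs
with drift γx(1−x), not 2γx(1−x)) is pinned by parameter-recovery tests
and reproduces the published anchor values; the alternative scaling
yields half-sized coefficients and is rejected.  `nes_from_age()`
inverts the strictly decreasing age-vs-γ relation by bisection to a
relative tolerance of 10⁻⁶; ages above the neutral expectation clamp to
γ = 0 with a warning since selection of either sign only makes alleles
younger (the age is symmetric in ±γ, also tested).

## Overlap and enrichment analyses

Context flags (genic, TE) are independent — a base inside both a gene
and a TE counts toward both, since annotations may overlap — and the
null composition is the gene/TE share of the alignable mask.  The
composition test is a χ² on base-pair counts; note that bases within one
indel are correlated, so on planted-null data the test is anti-
conservative and the package's tests assert composition closeness, not
the null p-value.  Metagene profiles divide each region (5′ UTR, gene
body, 3′ UTR) into 100 bins, map each indel-covered base by its
midpoint, and are strand-aware so bin 1 is always 5′; per-bin 95 %
bounds come from Binomial(n = region indel bp, p = 0.01).  TE-family
attribution requires ≥ 90 % of the indel length covered by one family;
enrichment is per-family Fisher's exact against the annotation
composition with Bonferroni correction over the families tested.

## Selection scan

For each polarized indel, a 10 kb window centred on the interval
midpoint supplies the SNPs for Tajima's *D* (all ten lines) and
normalized *H* (unfolded spectrum from outgroup polarization; sites of
unknown polarity enter *D* but not *H*).  An indel is an outlier when
*both* statistics fall below the envelope's lower bounds; windows with
no usable SNPs score NA and are never outliers.  The reported candidate
list further requires a derived-allele frequency ≥ 0.8, but all scores
are retained.  On data drawn from the envelope's own null the joint
flag rate is at most the marginal 2.5 % (tested).

## The synthetic-data generator

`sim_config()` defaults encode the emulated design: 10 focal + 2
outgroup lines; 75 bp reads; outer inserts Normal(275.8, 28.8);
deletions 1–200 kb with truncated log-normal sizes (median 2,563 bp,
log-SD 1.3 — reproducing a heavy right tail with a small median);
minor-allele counts 1–5 drawn from the neutral folded spectrum; 72 % of
deletion alleles and 62 % of SNP minor alleles derived; a genome of
5 Mb at 8× coverage with 250 genes, 500 TEs and 40 deletions; a
2×10⁻⁴ chimera rate multiplied 25-fold inside five 5 kb repeat
hotspots; and 15 % of pairs given one mate below mapping quality 29.
Genome size, feature counts and noise rates are desk-scale choices made
once; library parameters, size range, size median, depth and derived
fractions follow the emulated design.  Tests run reduced genomes
(0.2–1 Mb) for speed; the acceptance recovery check runs the full
default configuration.

Alignment records are simulated directly — no base-level reads — since
the pipeline consumes alignments; this preserves every tested signal
(insert-span inflation, orientation, depth deficits, chimera and
mapping-quality noise) at desk-scale runtime.  Reads crossing a deletion
junction are dropped, standing in for the clipped/unmapped alignments a
real aligner would produce.  What the generator does *not* emulate —
sequencing error in base calls (optional, off by default), alignment
ambiguity in repeats beyond the hotspot chimera model, linkage
disequilibrium between planted SNPs (carrier sets are independent
draws), and real TE/gene sequence content — bounds what passing tests
show: they validate the pipeline's logic and calibration, not its
performance on any real genome's repeat structure.

Because planted SNP carrier sets are independent across sites, the
synthetic population carries no linkage signal: π_A-based ages come out
neutral (T ≈ 1, γ ≈ 0) and the scan flags nothing, which is exactly the
correct null behaviour for these analyses.

## Degenerate inputs and edge rules

Tajima's *D* and *H* return NA at S = 0; monomorphic sites are excluded
from spectra with a warning; deletion candidates whose inner anchor
edges cross are rejected; jackknife subsets yielding NA are skipped
with a warning; a π_A window truncates at contig edges through its
per-site normalization; and the clamp at γ = 0 covers ages older than
neutral.

## Known limitations

Single-chromosome synthetic genomes; no recombination or demography in
the coalescent null; no re-genotyping of carriers after filtering (a
candidate's accession set is its cluster's support); inversion and
transposition candidates are called and filtered but not analyzed
further; and the diffusion inversion assumes additive selection at
constant population size.
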