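---
title: "Methods: targeted mQTL, allelic imbalance and open-chromatin analysis in developing and aged skeletal tissue"
author: "devmqtl authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: targeted mQTL, allelic imbalance and open-chromatin analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(devmqtl)
```

## Scope and scientific setting

`devmqtl` implements a targeted molecular-epigenetics workflow for
osteoarthritis (OA) risk loci in human skeletal tissue. The study design
it models quantifies DNA methylation by pyrosequencing at a fixed panel
of 39 CpGs spanning seven OA GWAS loci in three tissues — fetal limb
(FL), fetal cartilage (FC) and aged articular cartilage (AC) — genotypes
each donor at the locus association SNV, measures allelic expression of
nine effector genes in heterozygotes, and maps open chromatin by
ATAC-seq in fetal and aged hip and knee cartilage (FH/FK/AH/AK). The
package provides the full statistical layer of that design: replicate
quality control, beta/M-value transformation, differential methylation,
methylation QTL (mQTL) regression with genotypic-effect summaries,
co-methylation clustering, allelic expression imbalance (AEI) inference,
methylation–expression (meQTL) regression, and interval algebra for
consensus peak sets, chromatin-state enrichment and LD-proxy variant
prioritization — together with a synthetic-cohort generator so every
stage can be exercised and validated closed-loop without access to the
human samples.

## Data model

The panel is held in a `LocusPanel` (S4): one or two association SNVs
per locus with effect-allele frequencies (EAF), the effector gene
symbols, and the ordered CpG positions. Coordinates are stored exactly
as printed in the source table (1-based, hg19); the interval layer alone
converts between conventions, and all interval work is done on
`GRanges`. Where a locus carries two association SNVs (locus 6:
rs143384, rs143383) the first listed is the genotyping SNV for dosage
unless overridden — downstream stages need a single dosage column.

## Measurement model and QC

Pyrosequencing reports per-CpG methylation as a percentage. Each sample
is measured in duplicate; a record is excluded when the replicates
differ by more than 5 percentage points (the `qcThreshold` default,
configurable). The QC rule operates on the raw percentage scale and is
invariant to shifting both replicates by a constant. A single replicate
passes vacuously.

Analysis runs on M-values, \(M = \log_2\big(\beta/(1-\beta)\big)\),
with \(\beta\) clamped to \([10^{-6}, 1-10^{-6}]\) so boundary values
stay finite. M-values are closer to homoscedastic across the \(\beta\)
range, which matters because group variances at hypo- and
hypermethylated CpGs differ strongly on the \(\beta\) scale. Effects
are nevertheless *reported* in percentage points, the field's
convention.

## Differential methylation

For each CpG, two tissues are compared with a Welch two-sample t-test
on M-values; the effect size and its 95% confidence interval are
computed on the percentage scale with Welch–Satterthwaite degrees of
freedom. The source study does not name its test; Welch on M-values was
chosen as standard practice for unequal group sizes, and no exact match
to the study's reported p-values is claimed. Benjamini–Hochberg (BH)
adjustment is applied across the 39-CpG panel per comparison: the
study's reported significance boundary (adjusted p < 0.014) behaves
like a rank-dependent cutoff, which is consistent with BH and not with
a fixed Bonferroni level.

## mQTL model and the genotypic effect

Methylation is regressed on effect-allele dosage (0/1/2, additive
coding) by ordinary least squares on M-values; the slope's two-sided t
test gives the p-value, and BH is applied per tissue across the panel.
An additive linear model was chosen because the study summarizes mQTLs
with graded genotypic effects; a rank-based alternative
(Kruskal–Wallis) would discard that structure.

The genotypic effect (GE) is reported in percentage points. No formula
for it is given in the emulated study, so the package adopts an
interpretation and documents it: when both homozygote classes hold at
least two samples, GE is the absolute difference of their mean
methylation percentages; otherwise it falls back to twice the absolute
OLS slope on the percentage scale (the extrapolated two-allele effect).
The two rules coincide exactly for balanced, perfectly linear data. GE
is invariant to swapping which allele is called "effect"; the
accompanying sign flips.

## Co-methylation

Pairwise Pearson correlations of mean beta values are computed with
pairwise-complete observations; any pair backed by fewer than three
complete observations is reported as missing rather than estimated.
Clustering uses the signed distance \(d = 1 - r\) with average linkage.
The signed distance is deliberate: at one locus the study's CpGs form
two blocks with strong *negative* cross-correlations, and a magnitude
distance (\(1-|r|\)) would merge them. Labels are pre-sorted
lexicographically so equal-height merges resolve deterministically.
Flat clusters come from cutting the tree at a distance in \([0, 2]\).

## Allelic expression imbalance

For each heterozygous donor, allele percentages are measured in
triplicate in cDNA and genomic DNA. Each replicate percentage \(A\)
becomes a ratio \(A/(100-A)\); the record's normalized ratio is the
geometric mean cDNA ratio divided by the geometric mean gDNA ratio, so
assay bias measured in the (expected 50/50) genomic DNA cancels. The
geometric mean is used because it makes allele relabelling an exact
symmetry — swapping A and B maps the ratio to its reciprocal and the
log2 ratio to its negation — which an arithmetic mean of ratios only
approximates (the two agree to second order in the replicate
coefficient of variation, i.e. to well below measurement noise at the
1–2% replicate sd seen in practice). Triplicates whose range exceeds 5
percentage points fail QC, mirroring the methylation rule on the same
scale.

Inference on the log2 ratios uses a two-sided **exact** Wilcoxon
signed-rank test against symmetry about zero. The exact test was
inferred rather than copied: the study's reported extreme p-values
(0.008 at n = 8, 0.016 at n = 7, both with unanimous direction) equal
exactly \(2/2^n\), the smallest two-sided p attainable by this test at
those sample sizes. The null distribution is computed by the standard
counting recursion over all \(2^n\) sign assignments (run on doubled
ranks so midranks for tied magnitudes stay integral); zeros are dropped
before ranking. Above n = 25 a normal approximation with tie and
continuity corrections takes over. Being discrete, the exact test is
conservative: at n = 12 its attainable level at nominal
\(\alpha = 0.05\) is 0.0425, and the calibration tests check the
empirical rejection rate against that attainable level, not against
nominal.

For loci where the transcript SNV is in linkage equilibrium with the
association SNV (the RUNX2 situation), per-donor ratios cannot be
phase-oriented; `aeiUnphasedTest()` instead compares cDNA ratios
between association-SNV heterozygotes and homozygotes with a rank-sum
test.

## meQTL regression

Methylation M-values are regressed on log2 AEI ratios across QC-passing
heterozygotes, per CpG × same-locus gene, within tissue; \(r^2\) is the
squared Pearson correlation, and Bonferroni adjustment is applied per
gene across its CpGs (the study names Bonferroni for this analysis).
At least four complete pairs are required — below that the regression
is meaningless, and sample dropout at this stage is the study's own
stated caveat.

## Interval algebra

All intervals live in `GRanges` (1-based, closed); BED I/O converts at
the boundary, and 1-based point positions (CpGs, SNVs) map directly.
The consensus peak set for a group is defined at base level: a position
belongs to the consensus iff at least *k* of *n* samples cover it
(k = 4 of 6 for fetal groups, 3 of 5 for aged, the study's occupancy
rule). This definition is deterministic, order-independent, idempotent
under pre-split peaks, and trivially checkable against a per-base
oracle; it approximates, not clones, the occupancy-based consensus of
the original tooling. Four-way sharing is classified on the merged
union of the four consensus sets with a ≥ 1 bp overlap rule
(configurable via `minOverlapFrac`); total bases are conserved across
categories. Chromatin-state enrichment assigns each peak to the state
of maximal base overlap (ties to state-map order), compares
peak-count fractions against the state's share of the map length, and
tests with a two-sided exact binomial. LD proxies are kept at
r² > 0.8 (strict, matching the study's threshold) and classified by
which tissue consensus sets contain them.

## The synthetic cohort: what it emulates and what it does not

`cohortSpec()` defaults define the emulated study: 19 FL, 75 FC and
100 AC donors (the study's FL and FC counts; AC within its 71–139
per-CpG methylation range), 6/6/5/5 peak samples, fetal ages 32–119
days and aged ages 25–91 years. Genotypes are drawn from Hardy–Weinberg
proportions at each locus's tabulated EAF. Methylation is additive on the
beta scale — baseline per tissue plus GE/2 per effect allele plus a
small fixed per-CpG offset (sd 0.03) plus a per-donor, per-locus
biological effect (sd 0.05) — clamped to (0.01, 0.99), then measured
twice with Gaussian technical noise and truncated to [0, 100]. The
per-locus baseline and GE defaults mirror the qualitative structure the
study reports (broad developmental effect at locus 1, strong
cartilage-specific effect at locus 4, limb-specific effect at locus 7),
with the study's reported GE values used where available and moderate
mid-range values elsewhere; AEI means use the reported mean allelic
ratios where reported. The study gives no technical noise magnitudes;
replicate and triplicate sds default to 1.5 percentage points and
dropout to 0.05 as plausible pyrosequencing values, exposed in the
spec, and are claims about the simulator, not the data.

Allelic imbalance is coupled to methylation through
\(\log_2 r = \mu_{\text{tissue}} + b\,(M_i - \bar M)\), with \(M_i\)
the donor's mean M over the locus's QC-passing CpGs. The regression the
package fits (M on log2 ratio) therefore recovers slope \(1/b\) and
\(r^2 \to 1\) as technical noise vanishes — the closed loop the meQTL
tests exercise. The per-donor biological effect is what gives
heterozygous donors methylation variance for this coupling; without it
the closed loop would be degenerate.

The peak simulator plants shared, fetal-only and aged-only regions of
width 400 bp on a 10 Mb toy contig (120/77/97 regions by default —
the study's genome-wide class proportions scaled to desk size), then
includes each region per sample with probability 0.9 and jitters
boundaries by up to 25 bp.

What passing closed-loop tests show is that the estimators recover the
generator's truth under its assumptions. Real pyrosequencing data add
features the generator deliberately omits: bisulfite-conversion error,
cell-type heterogeneity (strongest in pooled limb tissue),
batch structure, non-Gaussian assay noise near the 0/100 boundaries,
LD-imperfect genotyping and sequencing-depth effects in peak calls.
Recovery on synthetic cohorts is therefore necessary, not sufficient,
evidence about real data.

## Numerical choices and degenerate inputs

* Beta clamping: \(10^{-6}\) in `betaToM()` (measurement side);
  simulation clamps latent betas at 0.01 to keep logits finite.
* Exact signed-rank: full enumeration to n = 25 (distribution vector of
  at most \(n(n+1)+1\) doubled-rank states, trivially cheap), normal
  approximation with continuity and tie corrections above; zeros
  dropped, midranks for ties; an all-zero vector is an undefined test,
  reported as a flagged non-significant summary, not an error.
* Hierarchical clustering refuses matrices with unresolved missing
  correlations rather than imputing.
* Allele percentages at exactly 0 or 100 raise a degenerate-ratio
  error: the ratio scale is undefined there.
* Monomorphic genotypes raise a not-estimable error; groups below
  minimum size raise insufficient-data errors carrying the sizes.
  Panel-level scans catch these per CpG, report `NA` statistics, and
  exclude the rows from multiple-testing adjustment.
* `consensusPeaks(k = 1)` equals the merged union and
  `consensusPeaks(k = n)` the intersection — both are tested against
  independent implementations.

## Problem sizes used in the validation suite

The shipped tests run the closed loops at desk scale, chosen as the
smallest sizes at which the properties under test are comfortably
identified: GE recovery uses 200 seeded cohorts of 60 donors at a
two-CpG locus (mean absolute GE error < 5 points against a planted 30);
type-I calibration uses 2000 null mQTL regressions at n = 60 and 2000
exact signed-rank tests at n = 12; interval oracles run 500 random
instances against per-base brute force on a 2 kb toy chromosome; the
meQTL loop uses 30 cartilage donors.

## Known limitations

* The GE formula and the differential-methylation test are documented
  interpretations, so the study's cohort-dependent numbers (specific
  GE percentages, counts of significant CpGs) are structural, not
  numerical, targets.
* The pipeline is a targeted-panel engine; nothing scales to
  epigenome-wide scans.
* Chromatin-state enrichment treats peaks as count units (peak-level
  binomial), not base-level fractions; differential-accessibility
  statistics are consumed as labels only.
* The AEI model is pyrosequencing-percentage based; read-count allelic
  expression (RNA-seq ASE) needs different error models.
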