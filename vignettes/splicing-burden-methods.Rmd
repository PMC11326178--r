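---
title: "Quantifying aberrant splicing burden in tumor cohorts"
author: "SpliceBurden package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying aberrant splicing burden in tumor cohorts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(SpliceBurden)
```

## The problem

Bulk RNA-seq of tumor cohorts — here motivated by pediatric central nervous
system tumors — rarely comes with matched normal tissue, so "aberrant"
splicing cannot be defined against a control sample. This package instead
defines aberration against the cohort itself: for each splice event, a
sample's percent-spliced-in (PSI) value is standardized against the cohort
distribution of that event, and events far in either tail are called
differential for that sample. The per-sample **Splicing Burden Index (SBI)**
is then the proportion of the sample's measured events that are
differential. Because every sample is scored against the same cohort
distribution, SBI supports cross-histology comparisons without normals.

## PSI from junction reads

rMATS-style tables report inclusion junction reads $I$, skipping junction
reads $S$, and effective form lengths $l_I$, $l_S$. PSI is the
length-normalized inclusion fraction

$$\psi = \frac{I / l_I}{I / l_I + S / l_S},$$

undefined when $I + S = 0$. Events with fewer than 10 total junction reads
are removed by default (`applyJunctionFilter()`); the threshold is the
`min_reads` parameter (reads, default 10). Coordinates are held internally
in the 0-based half-open convention of `exonStart_0base`; the single
conversion to 1-based GTF coordinates happens inside the functional-impact
stage, which prevents off-by-one drift between modules.

Events are harmonized across samples by their coordinate tuple
(splice type, chromosome, strand, exon interval, upstream exon end,
downstream exon start). Gene annotation is deliberately not part of the
key: annotation-version drift must not split one physical event into two.
Events measured in fewer than 80% of samples (`min_sample_fraction`) are
dropped before any variance ranking; the original analysis does not state
how incomplete events were treated, so this completeness floor is this
package's own choice, recorded in the output metadata, and it exists to
stop missingness from masquerading as variance.

## Burden calling

For event $e$ and sample $i$,
$z_{ei} = (\psi_{ei} - \bar\psi_e) / s_e$ over the non-missing cohort
values, with the focal sample included in the moments (a single-sample
design has nothing else to condition on; a leave-one-out variant is
available via `leaveOneOut = TRUE`). Calls use the strict rule $|z| > 2$
(`z_threshold`, dimensionless), signed into inclusion gains and skipping.
Two guards make the statistic usable on real matrices: events with fewer
than three measured values have no defined $z$, and events with cohort SD
below `sd_floor` (PSI units, default 0.01) are suppressed entirely because
$z$ explodes as $s_e \to 0$ on quasi-constant events.

The SBI denominator is the sample's measured events, not the cohort event
universe (configurable), so samples with different missingness are
comparable. Strata follow the quartile convention: high at or above Q3,
low at or below Q1, boundary ties inside the stratum.

One finite-sample subtlety: with the focal sample included, the
standardized deviation has slightly lighter tails than a standard normal,
so at realistic cohort sizes the null call rate sits just below the
asymptotic two-sided tail mass $2\Phi(-2) \approx 0.0455$. The calibration
tests account for Monte-Carlo error around that reference.

## Recurrence and set decomposition

Within any grouping — histology for cohort description, cluster for
within-cluster analyses — an event is recurrent when at least `min_n = 2` samples carry a
differential call; the direction is the common sign, or `mixed` when both
signs occur (mixed events stay their own category downstream). Group sets
are decomposed UpSet-style into exact membership patterns; group-specific
counts are normalized per patient for fair comparison between
histologies of very different sizes.

## Clustering and enrichment

Samples are clustered on the `top_events = 5000` most variable events
(variance over non-missing values, ties broken by event key so the
selection is deterministic). Distances are Euclidean over
event-mean-imputed PSI and linkage is Ward (D2); both are configurable and
recorded, since the original analysis does not state its choices. When no
`k` is given, `k` in 2–15 maximizing the mean silhouette width is chosen
and the whole profile is returned rather than hidden. Cluster–label
enrichment uses the two-sided Fisher exact test per (cluster, label) pair;
the reported effect is the sample odds ratio $(ad)/(bc)$ with a flagged
Haldane–Anscombe 0.5 correction when a cell is zero, and
Benjamini–Hochberg adjustment across all pairs (raw p-values are kept).

## Functional impact of cassette exons

Skipped-exon events are projected onto protein space through transcript
models: the CDS-overlapping part of the exon is mapped to 1-based residues
by $r = \lfloor o/3 \rfloor + 1$ at each boundary, where $o$ is the coding
offset in transcript orientation (strand-aware). A feature overlaps the
exon span when they share at least one residue (closed intervals). All
transcripts of the gene whose CDS overlaps the exon are evaluated and the
event-level annotation is the union of hits — no isoform-selection rule is
invented. Impact is the event direction crossed with the presence of hits:
gain (inclusion), loss (skipping), mixed, or none. Out-of-frame exons
(length not divisible by 3) are not propagated into downstream-of-event
consequences — no NMD or truncation modelling — but carry
`frame_preserving = FALSE` for the consumer. UniProt-style feature keys
are normalized onto four reported categories (domain, disulfide bond,
modified residue, localization signal) plus "other". Both per-event and
per-event-times-transcript counts are emitted, since the original totals
could be either.

## Pathway activity

Single-sample scores use a rank-based running sum: walking genes in
decreasing expression, in-set genes add their expression rank to the power
$\alpha = 0.25$ (normalized to 1 over the set), out-of-set genes subtract
$1/(N - |S|)$, and the score integrates the running sum. At $\alpha = 0$
this is a Kolmogorov–Smirnov-type statistic. Scores depend only on ranks
(average ranks on ties, for determinism on TPM matrices full of zeros), so
any monotone transform of a sample's expression leaves them unchanged.
This is a documented, deterministic statistic of the ssGSEA family — it is
not a reimplementation of the GSVA kernel-ECDF method, and score values are
not comparable to GSVA's; all conclusions drawn from it in this package are
directional or rank-based. Group comparisons are one-vs-rest Welch tests
with Bonferroni adjustment; the primary effect is the mean difference, with
a secondary log2 ratio on positively shifted scores for readers who expect
fold changes (the shift is reported, since ratios of signed scores are not
meaningful otherwise).

## Survival modelling

Kaplan–Meier, log-rank, and Cox proportional-hazards fits are delegated to
the survival package with Efron tie handling; this package owns the
interface: explicit reference levels for factor covariates (emitted as
reference rows for forest plots), interaction terms, quartile
stratification with boundary ties to the lower stratum and Q1 reference,
and error surfaces for non-convergence and separation. PSI dichotomization
thresholds are never invented: continuous-covariate fits are primary and a
median-split mode exists as sensitivity analysis. Correlation panels
(e.g., splicing-factor expression against SBI) are pairwise-complete
Pearson or Spearman with BH FDR across the panel; zero-variance genes are
excluded from the FDR rather than silently given r = 0.

## Paired perturbation comparison

For small replicate designs (the splice-blocking morpholino setting: a
targeted arm versus a non-targeting control arm), $\Delta PSI$ is the
difference of arm means and its p-value comes from label permutation of
the absolute mean difference — exhaustive when the number of relabelings
is at most 10,000, seeded Monte-Carlo otherwise. This is a transparent
desk-scale substitute producing the same output schema (ΔPSI, p, FDR) as
the rMATS paired likelihood model, which is deliberately not reimplemented.
A consequence worth knowing: the statistic is symmetric under swapping
arms, so each relabeling has an equal-valued complement and the smallest
attainable p in a 3-vs-3 design is 2/20 = 0.1. After BH adjustment across
events, no 3-vs-3 event can reach FDR < 0.05; designs with at least four
or five replicates per arm are required for FDR-controlled calls, and the
package's power checks use five. Gene-level differential expression is
delegated to edgeR quasi-likelihood fits behind a stable interface; the
package owns the thresholds and the DS/DE/dependency set logic
(exact Venn decomposition, hypergeometric over-representation with
Bonferroni, strict dependency-score filters z < −1.5 at FDR < 0.05).

## The synthetic cohort generator

`simulateCohort()` emulates the statistical structure the pipeline
assumes: per-event baseline PSI drawn from a Beta-shaped mid-range
distribution, cluster structure as ±`clusterSeparation`·SD offsets on an
informative subset of events, per-sample aberrant fractions implemented as
±`aberrantShift`·SD shifts (default 3) on randomly chosen events, junction
counts back-computed from PSI at `depth = 100` reads so the PSI formula
round-trips to within 1/depth, cluster-conditional histology labels,
linearly burden-coupled "splicing factor" expression, and exponential
proportional-hazards survival with configurable log-hazards on cluster and
burden plus a target censoring fraction. The baseline support is kept at
least four noise-SDs away from the PSI boundaries so that boundary
clipping stays negligible and planted shifts remain exactly controlled in
SD units — that control is the generator's purpose.

What the generator does **not** emulate, and hence what green tests do not
demonstrate about real tumors: bimodal near-boundary PSI distributions,
read-depth variation and overdispersion, correlated events within genes,
batch structure, and annotation errors. The generator is a calibration
instrument, not a tumor simulator.

Default problem sizes in the test-suite property checks were chosen to
make Monte-Carlo error small relative to the tested effects: 500 samples ×
2,000 events for null calibration, 200 × 2,000 for burden recovery across
planted fractions {0, 0.05, 0.1, 0.2}, 200 × 6,000 with four planted
clusters for recovery after top-5,000 selection, 600 samples with 30%
censoring (100 replicates) for hazard-ratio recovery, and 1,000 permuted
replicates for each type-I-error check.

## Numerical choices and degenerate inputs

* Ties: average ranks in scores; boundary ties to the lower quartile
  stratum; variance ties in event selection broken lexicographically.
* `sd_floor = 0.01` marks quasi-constant events non-informative rather
  than producing huge z-scores.
* Cox fits: partial-likelihood tolerance 1e-9, at most 100 iterations,
  non-convergence is an error carrying the iteration count, suspected
  separation is flagged.
* Empty inputs return empty, typed results (header-only rMATS files,
  all-below-threshold filters); all-censored survival input returns curves
  with an explicitly undefined p.
* All randomness flows from a single root seed through a deterministic
  derivation, and pipeline reruns with the same configuration produce
  hash-identical manifests.

## Known limitations

The z-score caller assumes the cohort is the reference — a cohort
dominated by one aberrant subtype will absorb that subtype into the
"normal" center. The single-sample score is rank-based and should not be
compared numerically to GSVA output. The permutation test's granularity
bounds its resolution at small replicate numbers, as discussed above.
Protein-impact annotation is coordinate-based only: it does not model NMD,
domain folding, or downstream frame consequences.
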