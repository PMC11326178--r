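# SpliceBurden

Cohort-scale analysis of aberrant alternative splicing from rMATS-style
junction-count tables, for transcriptomics analysts studying tumor cohorts
without matched normal tissue (the motivating setting is pediatric CNS
tumors).

## What it computes

For each splice event, a sample's percent-spliced-in value

PSI = (I/l_I) / (I/l_I + S/l_S)

(I, S inclusion/skipping junction reads; l_I, l_S form lengths) is
standardized against the cohort distribution of that event,

z_ei = (PSI_ei − mean_e) / sd_e,

and events with |z| > 2 are called differential for that sample. The
**Splicing Burden Index** is the per-sample proportion of measured events
called differential:

SBI_i = n_differential,i / n_measured,i,

with samples stratified by the cohort SBI quartiles (high ≥ Q3, low ≤ Q1).
Around this core the package provides: recurrent-event (N ≥ 2) set
decomposition across histologies; hierarchical clustering of samples on
the top-5,000 most variable events with Fisher-exact cluster–label
enrichment (sample odds ratios, BH adjustment); projection of cassette
exons onto protein residues to flag gain/loss of functional sites
(domains, disulfide bonds, modified residues, localization signals) with
a kinase filter; rank-based single-sample pathway scores; Kaplan–Meier /
log-rank / Cox proportional-hazards models including interactions and
quartile stratification; a paired-replicate perturbation comparison with
exhaustive permutation ΔPSI tests and DS/DE/dependency set logic; and a
seeded synthetic-data generator with known ground truth for all of the
above.

## Worked example

```r
library(SpliceBurden)

spec <- cohortSpec(nSamples = 60, nEvents = c(SE = 1000), nClusters = 3,
                   aberrantFraction = rep(c(0, 0.05, 0.15), each = 20),
                   seed = 101)
sim <- simulateCohort(spec)
pe  <- buildPsiMatrix(sim$tables$SE, clinical = sim$clinical)
pe
#> PsiExperiment: 1000 events x 60 samples
#>   missing cells: 0 (0.0%)
#>   splice type: SE

sbi <- splicingBurdenIndex(callDifferential(eventZScores(pe), 2))
head(sbi, 4)
#>   sample_id splice_type n_differential n_measured   sbi stratum
#> 1     S0001          SE              9       1000 0.009     low
#> 2     S0002          SE             13       1000 0.013     low
#> 3     S0003          SE             17       1000 0.017     mid
#> 4     S0004          SE             11       1000 0.011     low
```

Samples S0001–S0020 were simulated with no planted aberration, so their
SBI sits near the null call rate (~0.9–1.7% here); samples with planted
aberrant fractions 0.05 and 0.15 rise accordingly (cohort median SBI
0.0375, Spearman correlation between planted fraction and SBI 0.944).

```r
fit <- hierarchicalCluster(selectVariableEvents(pe, 500), k = 3)
adjustedRand(fit$cluster, sim$truth$cluster[names(fit$cluster)])
#> [1] 1

enr <- clusterEnrichment(fit, setNames(sim$clinical$histology,
                                       sim$clinical$sample_id))
head(enr[order(enr$p), c("cluster_id","label","odds_ratio","p","p_adj")], 3)
#>   cluster_id label odds_ratio            p        p_adj
#> 7          3 HIST1   49.33333 2.384848e-08 2.146363e-07
#> 6          2 HIST3   17.00000 7.865820e-06 3.539619e-05
#> 2          1 HIST2   13.22222 7.091821e-05 1.741333e-04
```

The three planted clusters are recovered exactly (adjusted Rand index 1),
and each cluster is enriched for its dominant simulated histology — the
odds ratios are the 2×2 cross-product ratios of cluster membership against
the label, with two-sided Fisher p-values BH-adjusted across all
cluster×label tests.

A Cox model on event-free survival with the usual covariates (resection,
age, cluster, SBI) returns a hazard table with explicit reference rows for
factor covariates, 95% confidence intervals, and Wald p-values:

```r
df <- within(sim$clinical, { time <- efs_days; status <- efs_status })
df$cluster <- paste0("C", fit$cluster[df$sample_id])
df$sbi <- sbi$sbi[match(df$sample_id, sbi$sample_id)]
coxFit(df, c("resection", "age_at_diagnosis", "cluster", "sbi"))
```

The whole chain — simulate, harmonize, burden, sets, cluster, score,
survive — also runs from one configuration via `runPipeline()`, which
writes stage TSVs and a JSON manifest whose checksums are identical across
reruns with the same seed.

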