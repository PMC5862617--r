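# islandmeth

Integrated differential-methylation analysis of Illumina BeadChip beta
values, built around a cross-platform CpG-island validation algorithm.
The package is aimed at analysts who have probe-level methylation
fractions from a sparse array (one or two probes per CpG island, as on
the HumanMethylation27 design) and want to confirm island-level findings
against an independent dense-array dataset (3-20 probes per island, as
on the HumanMethylation450 design) — the situation that arises when a
small in-house tumor cohort is validated against a public reference
series.

## What it computes

**Per-probe differential methylation.** For each probe, the group-mean
beta values, their difference Δβ = β̄₂ − β̄₁, a two-sided
unequal-variance (Welch) test p-value, and the signed score

    DiffScore = sign(Δβ) · (−10 · log₁₀ p)

so |DiffScore| = 13 at p = 0.05. Probes are tiered at the conventional
score thresholds 13 / 22 / 33, and the false discovery rate of each
threshold is estimated by whole-sample label permutation (1000
permutations by default; findings are conventionally retained up to
FDR 0.20).

**Cross-platform island validation.** Candidate probes
(|DiffScore| ≥ 22, autosomal, on a CpG island) are enriched with every
dense-platform probe on the same island, and the island is validated
when all four criteria hold: (1) the dense island-mean Δβ agrees in
sign with the sparse finding; (2) at least 30% of island probes are
concordant with the island mean; (3) mean |Δβ| over island probes
≥ 0.05; (4) at least 3 probes.

**Around the core:** detection-p filtering, sample stratification by
brain compartment and age of onset, unsupervised hierarchical
clustering of samples on significant loci (with adjusted-Rand agreement
against a priori groups), ΔΔCT relative expression with fold change
2^(−ΔΔCT) and a Welch test, and median-expression-split Kaplan–Meier /
log-rank survival comparison. A synthetic-data generator produces
paired sparse/dense datasets with planted island effects, CT tables and
survival tables, so every stage is testable without external downloads.

## Worked example

```r
library(islandmeth)

sim <- simulate_paired_dataset(sim_config(seed = 104))   # 200 islands, 20% DM
res <- run_island_pipeline(sim$beta_27k, sim$groups_27k, sim$manifest_27k,
                           sim$manifest_450k, sim$beta_450k, sim$groups_450k)
tier_counts(res$records)
#>   direction threshold count
#> 1     hyper        13    34
#> 2     hyper        22    30
#> 3     hyper        33    30
#> 4      hypo        13    26
#> 5      hypo        22    24
#> 6      hypo        33    22

head(res$validations[, c("island_id", "n_probes", "mean_delta", "validated")], 3)
#>   island_id n_probes mean_delta validated
#> 1   isl0002        5  0.1511771      TRUE
#> 2   isl0013       20  0.1439276      TRUE
#> 3   isl0023        6  0.1503620      TRUE

length(res$validated_islands)                       # 38
sum(res$validated_islands %in% sim$truth$island_id) # 38: all planted, none spurious
```

The tier counts say how many sparse-platform probes reach each score
threshold in each direction; the validation table gives, per candidate
island, the dense-platform probe count, island-mean Δβ and the verdict
of the four criteria. Here the pipeline validates all 38 planted
islands and no null island.

Sample stratification on the packaged clinical roster:

```r
sheet <- read_sample_sheet(system.file("extdata", "table1_samples.csv",
                                       package = "islandmeth"))
lengths(stratify_by_location(sheet))   # supratentorial 10, infratentorial 10
lengths(stratify_by_age(sheet, 3))     # young (≤3 yrs) 9, old 11
```

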