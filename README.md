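# tumorevo

Reconstructing chromosome-arm copy-number evolution in tumors — from
single-cell expression and from bulk mutation multiplicities — with a
fully synthetic, ground-truth-known test bed.

Recurrent chromosome-arm losses (chr4p among them) arise early in basal
breast cancer. Establishing *that* requires two machines this package
implements end to end:

1. **CNA inference from scRNA-seq.** Copy-number changes leave a dosage
   footprint on expression. The pipeline TMM-normalizes each cell against
   a reference, merges consecutive genes into genome-ordered bins,
   computes per-bin Z-scores, smooths them with a rolling median (window
   5) and winsorizes into [-3, 3]; PCA fitted on non-cycling cells feeds
   a KNN graph (weights 1/(1+D)) and Louvain community detection with a
   Rand-index-stability choice of the resolution γ. Per community,
   meta-cells (random half-community count sums) are re-scored against a
   normal-cell baseline and a 3-state Gaussian HMM (loss/neutral/gain,
   emission means {-δ, 0, +δ}, δ = 0.5) segments the genome; runs under 5
   bins are dropped and segments tested by Wilcoxon rank-sum against
   same-chromosome neutral bins, with hypergeometric community-by-cluster
   enrichment.
2. **Mutation-time reconstruction.** For a clonal gain at mutation time
   π ∈ [0, 1], clonal SNVs at multiplicity 2 arise with probability
   π/(3-π) (2+1 gain) or π/(2-π) (2+0 gain, 2+2 WGD). The posterior over
   π under a uniform prior is sampled with 30 chains × 2000 steps (1000
   burn-in); WGD is called by ploidy > 2.9 - 2·LOH and timed jointly over
   all major-CN-2 gained segments; major-CN 3/4 segments are classified
   pre- vs post-WGD by comparing their implied WGD-time distribution with
   the sample-wide one (Bhattacharyya similarity). A league model
   aggregates pairwise event orders across tumors into rank
   distributions, and presence-pattern heuristics assign SNVs to clones
   (PT/PDX/single-cell quartet) and reconstruct the MRCA's
   allele-specific copy numbers by four ordered rules.

A synthetic-data module generates clone-structured count matrices with
planted arm events, mutation-accrual histories with known gain times,
multi-sample SNV presence tables and cohort timelines — the ground truth
every test and acceptance criterion is scored against.

## Worked example

Timing a gain from multiplicity counts — 100 of 400 clonal SNVs at
multiplicity 2 on a 2+1 segment:

```r
library(tumorevo)
post <- sample_gain_timing(list(n1 = 300, n2 = 100), "gain_2+1", seed = 1)
post
#> <timing_posterior> mean 0.600, 90% CI [0.532, 0.668] (30000 samples)
grid_gain_timing(list(n1 = 300, n2 = 100), "gain_2+1")$mean
#> [1] 0.6001672
```

A multiplicity-2 fraction of 0.25 inverts to π = 3f/(1+f) = 0.6: the gain
happened 60% of the way through the segment's mutational history, and the
deterministic quadrature twin agrees with the MCMC to under 0.01.

Ordering events across a simulated cohort:

```r
tls <- simulate_cohort_timelines(c("TP53_mut", "loss_17p", "loss_4p", "WGD"),
                                 n_tumors = 12, timing_noise_sd = 0.05,
                                 dropout = 0.2, seed = 2)
league_rank(tls, n_iter = 100, seed = 3)
#> <league_ranking>
#>      event mean_rank mean_score prevalence
#> 1 TP53_mut         1          3       0.83
#> 2 loss_17p         2          1       0.83
#> 3  loss_4p         3         -1       0.75
#> 4      WGD         4         -3       0.75
```

Despite 20% event dropout, the planted order is recovered in all 100
repetitions (mean ranks exactly 1–4); prevalence is the fraction of
tumors carrying each event.

The full expression pipeline on the default planted scenario (3 clones ×
200 cells + 150 normal cells, two arm events per clone):

```r
res <- run_pipeline()   # simulate -> cna -> segment -> enrich
# artifacts in tumorevo_run/: counts/, communities.tsv, segments.tsv,
# enrichment.tsv, cell_cycle.tsv, manifest.json
```

On this scenario the community partition matches the true clones with
Rand index ≥ 0.95 and segment calls reach bin-level precision/recall
≥ 0.9 with arm-state accuracy 1.0 (see
`tests/testthat/test-acceptance.R`, which asserts exactly these bounds).

## Command line

```sh
inst/cli/tumorevo simulate expression --out sim --seed 1
inst/cli/tumorevo cna run --config config.json --out run --seed 1
inst/cli/tumorevo evo time-gains --counts multiplicity.tsv --out timing.tsv
inst/cli/tumorevo clones assign --snvs presence.tsv --out clones.tsv
inst/cli/tumorevo clones mrca --profile1 p1.tsv --profile2 p2.tsv --out mrca.tsv
```

See the methods vignette (`vignettes/tumor-cna-evolution.Rmd`) for the
model assumptions, parameter defaults and the design decisions behind
the numerical choices.
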