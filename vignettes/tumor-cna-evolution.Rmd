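---
title: "Methods: copy-number inference from single-cell expression and mutation-time reconstruction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: copy-number inference from single-cell expression and mutation-time reconstruction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tumorevo)
```

# Scope

`tumorevo` reconstructs chromosome-arm copy-number evolution in tumors from
two complementary data modalities:

1. **Single-cell RNA-seq**: copy-number aberrations (CNAs) are inferred
   from dosage effects on expression. Cells are normalized, genes merged
   into genome-ordered bins, per-bin Z-scores smoothed and winsorized,
   cells grouped into communities on a KNN graph, and each community's
   genome segmented into loss/neutral/gain states by a three-state
   Gaussian HMM on meta-cells.
2. **Bulk WGS mutation multiplicities**: clonal copy-number gains and
   whole-genome doubling (WGD) are placed in *mutation time*
   $\pi \in [0,1]$ — the fraction of a segment's mutational history that
   elapsed before the event — from counts of clonal SNVs at multiplicity
   1 versus 2. Event orders are aggregated across a cohort by a league
   model, and presence-pattern heuristics assign SNVs to clones and
   reconstruct the MRCA's allele-specific copy numbers.

Everything is exercised against a synthetic-data generator with known
ground truth; no external cohort is needed.

# The expression model and the CNA pipeline

## Normalization

Each cell is rescaled by a single trimmed-mean-of-M (TMM) factor against a
reference pseudo-cell (per-gene mean counts by default). M-values
$\log_2(y_g/r_g)$ are computed over genes expressed in both cell and
reference, 30% of M-values and 5% of A-values are trimmed from each tail,
and the remainder averaged with inverse asymptotic-variance weights; the
factor is $2^{-\mathrm{TMM}}$. Cells sharing fewer than 50 expressed genes
with the reference are dropped with a warning.

**Numerical choice — zero-truncation correction.** Conditioning on
"expressed in both" inflates the conditional mean of a Poisson count,
$E[y \mid y>0] = \lambda/(1-e^{-\lambda})$, and does so more strongly in
shallow cells. Left uncorrected this biases the factor by up to ~20% and
leaves a library-depth axis in the normalized data that community
detection picks up as a spurious cell cluster. Counts therefore enter the
M/A computation multiplied by $1-e^{-\hat\lambda}$, with $\hat\lambda$
from a first-pass total-count depth estimate. The correction is the exact
identity for counts above ~40, so high-count algebraic identities (e.g.
a cell equal to twice the reference maps to factor 0.5) are untouched.

## Binning, Z-scores, smoothing

Consecutive same-chromosome genes are pooled greedily until the bin's
summed per-gene mean reaches `min_mean_expression` (default 1.0; the
threshold is not stated by the source method and is exposed in the
config). A trailing under-threshold remnant merges into the previous bin
of its chromosome. Per bin, expression is centered and scaled across
cells (sample sd, $n-1$; zero-variance bins give Z = 0), smoothed by a
rolling median of window 5 restricted to the chromosome (the window
shrinks at chromosome ends; no padding), and winsorized into $[-3, 3]$.

## Cell cycle

Per-cell scores are the mean cross-cell-standardized expression of a G1/S
and a G2/M marker set, and each set score is then itself standardized
across cells. A cell is cycling iff the larger standardized score exceeds
1.0. Standardizing the set score matters: when 10–20% of cells cycle they
inflate the per-gene standardization, diluting raw scores to well below 1
for genuinely cycling cells; on the score-sd scale cycling cells sit at
about +2. Marker sets are supplied by the user (the generator plants its
own); phase is G1 when non-cycling, otherwise S or G2M by the larger
score, with ties going to S.

## Embedding, graph, communities

PCA is fitted on non-cycling cells only (cell-cycle signal stays out of
the axes) and all cells are projected; the top 20 components feed a KNN
graph (K defaults to `min(100, n/3)`; edges by union symmetrization;
weight $1/(1+D)$ with Euclidean $D$). Louvain community detection is run
10 times per resolution $\gamma$ in $\{0.4, 0.6, \dots, 1.6\}$; the mean
and variance of the pairwise Rand index across runs measure partition
stability, and the $\gamma$ with the highest mean is selected, breaking
ties by lower variance and then by **larger** $\gamma$.

**Design note — tie-break direction.** Coarse partitions are trivially
stable: on planted data, a 2-community collapse and the correct
4-community partition can both reach mean Rand 1.0 with variance 0.
Preferring the smaller $\gamma$ in that tie selects the collapse and
halves recovery; the finest equally-stable resolution is the informative
choice, so ties resolve toward larger $\gamma$.

# Meta-cells and segmentation

Per community (minimum 10 cells), 5 meta-cells are built by summing the
raw counts of a random half of the community's cells; baseline meta-cells
are built the same way from baseline (e.g. normal) cells. Pseudo-cells
are renormalized **against the baseline-cell mean reference** and each
bin's Z is computed with the per-bin mean and standard deviation across
the baseline *cells*, then smoothed and winsorized as before.

**Design note — the Z scale.** The baseline statistics are taken across
single cells, not across baseline meta-cells. A meta-cell's measurement
noise (CV ~4%) is far below one baseline-cell sd, so on this scale a
half-dose copy-number change moves the smoothed Z by about 0.5 — which is
exactly the separation the HMM's emission means assume — while residual
~2% normalization biases stay near Z ≈ 0.02. Dividing by the meta-cell sd
instead amplifies those same biases into arm-wide |Z| offsets of 0.3–0.6
and produces whole-arm false calls.

The HMM has states loss/neutral/gain with emission means
$\{-\delta, 0, +\delta\}$ ($\delta = 0.5$ on the winsorized Z scale), a
shared emission sd $\sigma$, and transitions that stay with probability
$1-2\tau$ and switch with $\tau = 10^{-3}$ to each other state. One state
path per community is decoded by Viterbi per chromosome (uniform initial
state), with emissions multiplied over the community's meta-cells.

**Design note — emission scale.** Meta-cells of one community share
sampled cells and are strongly correlated, so the product over meta-cells
behaves like $n_{\text{meta}}\,\bar z^2$, not a sum of independent terms.
$\sigma$ is therefore estimated as $\sqrt{n_{\text{meta}}}$ times the MAD
of the per-bin mean meta-Z, which calibrates the joint likelihood in both
the correlated and the independent regime (for independent meta-cells it
reduces to the per-meta-cell sd). $\delta$, $\sigma$, $\tau$ remain
configurable.

Non-neutral runs shorter than 5 bins are set to neutral in a single
left-to-right pass (runs merged *by* the filtering are not re-filtered).
Each surviving segment is tested by a two-sided Wilcoxon rank-sum of its
(bin, meta-cell) Z values against the neutral bins of the same chromosome
— exact null enumeration up to 20 observations, normal approximation with
tie and continuity correction beyond — and Benjamini–Hochberg adjusted
p-values are reported alongside raw ones. Community-by-cluster enrichment
uses the hypergeometric upper/lower tails and fold over the background
fraction.

# Mutation-time models

Mutations accrue at a constant rate per chromosomal copy. A mutation that
lands on the gained allele before the gain is carried by both product
copies (multiplicity 2). With multiplicity collapsed to 1 vs ≥2 — the
only distinction the input data makes — the multiplicity-2 probability of
a clonal SNV is

* gain 2+1: $p(\pi) = \pi/(3-\pi)$ (saturates at 1/2: the un-gained
  minor allele keeps contributing multiplicity-1 SNVs),
* gain 2+0 and WGD 2+2: $p(\pi) = \pi/(2-\pi)$.

The likelihood is $\mathrm{Binomial}(n_2 \mid n_1+n_2, p(\pi))$ with a
uniform prior on $\pi$. Sampling uses a reflecting random-walk Metropolis
(proposal sd 0.1) with 30 independent chains of 2000 steps and 1000
burn-in — the printed protocol — pooled after burn-in; a between/within
chain variance ratio is stored (flagged above 1.1). A deterministic grid
quadrature of the same posterior ($\Delta\pi = 0.001$) ships alongside as
the validation oracle, and an ensemble sampler is deliberately not used:
the target is one-dimensional and the two routes agree to well under
0.01.

WGD is called when ploidy $> 2.9 - 2 \times \mathrm{LOH}$ (strict), and
timed jointly: the posterior over one shared $\pi_{\mathrm{WGD}}$
multiplies the route likelihoods of all eligible major-CN-2 segments
(2+2 as WGD, 2+0 as gain). Eligibility for timing: ≥ 10 SNVs, minor CN ≤
2, major CN ≤ 4 in WGD tumors and ≤ 2 otherwise.

## Pre/post-WGD routes for major CN 3 and 4

The source method does not print the route algebra; it is derived here
from the same accrual model, in a LOH (minor CN 0) context, with the
pre-WGD major-3 route assuming one copy is lost immediately after the
WGD:

| major | route | constraint | $p(\cdot)$ |
|---|---|---|---|
| 3 | gain then WGD | $t_g \le t_w$ | $t_w/(3-t_g-t_w)$ |
| 3 | WGD then gain | $t_g \ge t_w$ | $t_g/(3-t_g-t_w)$ |
| 4 | gain then WGD | $t_g \le t_w$ | $(2t_w-t_g)/(4-t_g-2t_w)$ |
| 4 | WGD then two gains (avg $s$) | $s \ge t_w$ | $(2s-t_w)/(4-t_w-2s)$ |

For major 4 post-WGD the two gain times are not separately identifiable,
so their average $s$ is the timed quantity. Route classification starts
from equal prior probability 0.5; each route's joint grid posterior over
(WGD time, gain time) yields a segment-implied WGD-time marginal whose
similarity to the sample-wide WGD posterior — Bhattacharyya coefficient
over 100 equal bins (overlap coefficient available) — weights the route.
The forward simulator, which draws per-SNV lineages from branch lengths
of the same copy histories, validates the closed forms independently.

# League model

Per repetition every event starts at score zero. For each unordered event
pair, one tumor containing both is drawn uniformly from the sharing
subset (cohort-wide averaging is a config option; the source text is
ambiguous between the two), one timing draw per event is taken from that
tumor's posterior, and the earlier event gains a point while the later
loses one. Untimed events fall back to the tumor's recorded relative
order; indistinguishable pairs (no order information, or exactly equal
draws) and pairs shared by no tumor leave scores unchanged. Events are
ranked by descending score (ties average), and 100 repetitions give the
rank distribution. On complete cohorts with point-mass timings the
mean-rank order coincides with the brute-force Condorcet order.

# Clone and MRCA heuristics

SNVs enter clone assignment only if they are not indels, have TLOD ≥ 40,
and were genotyped in ≥ 10 cells (inclusive bounds, as printed). The
presence pattern over (PT_bulk, PDX_bulk, SCS12, SCS34) maps to: all
four → clonal; (1,0,1,0) → subclone 1; (1,1,0,1) → subclone 2;
(0,1,0,1) → subclone 3; anything else → unassigned (no attempt to define
smaller subclones). Events clonal in the primary tumor but absent from
the matched PDX are reclassified subclonal.

The MRCA's allele-specific copy number is resolved per allele, rules in
order: (1) equal in both subclones → keep; (2) LOH in exactly one
subclone → keep the allele-retaining (non-zero) state, since an allele
present in one descendant existed in the ancestor; (3) a nearest
same-chromosome neighbor segment with allele CN shared between subclones
and equal to one of the two discordant values → adopt it (left neighbor
before right, no distance cap by default); (4) elementwise minimum. The
rule used is reported per segment and allele.

# The synthetic world

The generator's defaults are the stated evaluation scenario:

* **Expression**: 3 tumor clones × 200 cells, 150 diploid baseline
  cells, two chromosome-arm events per clone (loss → CN 1, gain → CN 3),
  linear dosage (`dosage_effect = 1`), 10% cycling cells with G2/M
  marker means tripled, per-gene log-normal means
  ($\mu=-0.3, \sigma=0.8$: a median ~0.7 counts/gene, 10x-like depth)
  and per-cell log-normal library factors ($\sigma=0.2$). Counts are
  Poisson; a gamma-Poisson overdispersion knob exists for robustness
  experiments but defaults to 0, the simplest model satisfying the
  pipeline's assumptions.
* **Mutations**: per segment, SNV lineages are drawn with probability
  proportional to branch length of the route's copy history and
  multiplicity read off the lineage — an independent formulation of the
  accrual process, not the binomial closed form it validates.
* **Presence patterns** are noise-free by default (`fn_rate` exposed),
  TLOD log-normal around 60, genotyped-cell counts 20+Poisson(30), so
  default tables pass the quality filters.
* **Cohort timelines** center each present event's timing draws at its
  true rank position $(r-0.5)/n$ with truncated Gaussian noise.

What a green test does *not* establish: the generator has no UMI
chemistry, doublets, ambient RNA, batch effects, spatial structure, or
read-level noise; expression dosage is exactly multiplicative; presence
calls have no false positives. Recovery numbers on this world are upper
bounds on real-data behavior, and the pipeline's robustness to, e.g.,
strong overdispersion is exercised only through the exposed knobs.

# Degenerate inputs and tie rules

Zero-variance bins give Z = 0; single-cell matrices are rejected for
Z-scores; communities under 10 cells are skipped with a warning; segments
with no neutral bin on their chromosome get `NA` p-values and are
flagged; equal cell-cycle scores above threshold resolve to phase S;
Louvain ties resolve as described above; league draws that are exactly
equal leave scores unchanged; `n2 = 0` likelihoods peak at $\pi = 0$ and
are handled by the reflecting sampler without special casing.

# Known limitations

* Allele-specific inference from expression, subclonal deconvolution
  within a community, and CN calling from raw sequencing are out of
  scope; multiplicity counts are inputs.
* The major-3 pre-WGD route fixes the post-WGD loss at the WGD itself; a
  delayed loss would bleed multiplicity-1 mass and bias $t_w$ upward.
* Route classification for near-boundary geometries (gain time close to
  the WGD time) is weakly identified; the reported route probabilities
  then stay near 0.5 by construction.
* The league model inherits the identifiability limits of pairwise
  orderings: only events co-occurring in some tumor are comparable.
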