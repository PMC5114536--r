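---
title: "Transkingdom causal inference: models, parameters and design choices"
author: "transkingdom package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Transkingdom causal inference: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(transkingdom)
```

# The inference chain

The package links four statistical screens into one causal-inference chain
for host–microbiome systems. A factor (typically a cytokine) is perturbed in
two independent experimental designs; the chain then asks which microbes the
factor regulates, which of those microbes plausibly mediate an effect on a
host phenotype, how the factor-dependent host genes organize into a
co-expression network, and which of those genes is the best candidate
regulator of the mediator microbe.

## Stage 1 — concordant differential abundance

Counts are converted to relative abundances by total-sum scaling
(`toRelativeAbundance()`). Each experiment is screened with a two-group test
per taxon (`differentialFeatures()`), Welch's unequal-variance t by default,
on `log2(relative abundance + pseudocount)`; the pseudocount defaults to half
the smallest nonzero relative abundance in the table. The pooled-variance
variant and a raw-scale switch exist because the upstream literature rarely
states which was used; log + Welch is the robust default. P values are
adjusted with the Benjamini–Hochberg step-up procedure across all taxa of a
table, and a taxon is *concordant* (`concordantFeatures()`) when it passes
FDR < τ in both experiments with the same direction of change. τ defaults
to 0.1, the conventional exploratory-phase threshold for this kind of
screen.

The two-group test is a deliberate stand-in for count-model alternatives
(negative-binomial GLMs, compositional methods): the downstream stages
consume only directions, fold changes and p values, and the synthetic-data
calibration below shows the stand-in recovers planted five-fold effects at
the default sample sizes essentially always.

## Stage 2 — sign-matched mediator screening

A concordant taxon is a candidate mediator of a phenotype only if the sign
of its within-perturbed-group correlation with the phenotype matches its
direction of regulation (`nominateMediators()`). Correlations are computed
with `phenotypeCorrelations()` on the perturbed-group samples *only*, so the
factor itself cannot drive both sides of the correlation; supplying the
metadata together with the control label makes the function verify this and
refuse contaminated input. In the designs this package targets the
"perturbed" group is the factor-*free* one (a knockout), so a taxon that is
UP in the perturbed group is depleted by the factor; `factorRemoved = FALSE`
flips the mapping for gain-of-function designs.

Both phenotype metrics must pass the sign rule at α = 0.05 (two-sided) by
default. Requiring all metrics, rather than any one, follows from the logic
of the screen — a genuine mediator of glucose metabolism should move fasting
glucose and glucose-tolerance AUC coherently — and is relaxable via
`requireAll = FALSE`. Candidates are ordered by their minimum p across
phenotypes with the feature id as a deterministic tiebreak; two-sided p
values are used throughout because the screen's direction information is
carried by the sign rule, not the test's tail.

`signConsistencySummary()` implements the cohort-style variant of the same
idea: given per-group correlations of many genes with a target microbe, it
counts genes whose correlation sign is identical in every group and tests
the negative/positive split of those genes against 0.5 with the exact
binomial one-proportion test (`oneProportionTest()`, minimum-likelihood
two-sided rule). `selectSamplesByFeature()` provides the companion ≥ 1%
relative-abundance subject filter used before such cohort correlations, on
the rationale that a microbe present only in traces cannot contribute
measurably to a systemic phenotype.

## Stage 3 — per-group correlation network

`perGroupCorrelations()` computes, for every gene pair, the Pearson
correlation and two-sided p value separately within each of k sample groups
(different mouse genetic backgrounds, different patient groups), then merges
the k p values with Fisher's combined probability test:
$\chi^2 = -2\sum_{i=1}^{k}\ln P_i$, referred to the upper tail of
$\chi^2(2k)$. Splitting by group and combining — rather than pooling the
samples — means an edge must be supported *within* every genetic background,
which removes correlations driven by between-group mean differences.

A pair becomes an edge (`edgeAdmissible()`) iff

1. every within-group P < 0.3,
2. the combined P < 0.01,
3. the correlation signs agree (all positive or all negative) across groups,
4. the shared sign equals `sign(lfcA * lfcB)`: co-regulated genes must
   correlate positively, oppositely regulated genes negatively.

Criterion 4 is the package's reading of "consistent with the fold-change
relationship": it is the only interpretation that uses both fold changes
and the correlation sign, and it removes edges whose correlation
contradicts the genes' joint response to the perturbation. A pairwise FDR is
reported alongside but is deliberately *not* an inclusion criterion — the
edge rules are p-value thresholds. Genes with no admissible edge are not
network members; `buildNetwork()` reports the membership fraction rather
than asserting any particular value, since membership depends strongly on
group sizes and signal strength. Zero fold changes cannot satisfy
criterion 4, so such genes end up without edges.

`avgShortestPathLength()` is the mean unweighted hop distance from a gene to
every other gene of its connected component (igraph's BFS distances; an
independent Floyd–Warshall implementation serves as the test oracle).
Distances are unweighted because the edge rules are binary; no edge weights
are defined.

## Stage 4 — four-source regulator ranking

`prioritizeRegulators()` scores every network member gene from four sources:
s₁, the absolute mean per-group Pearson correlation between the gene's
expression and the target microbe's abundance; s₂, the gene's average
shortest path length; s₃, the absolute log₁₀ fold change (log₂ inputs are
converted); s₄, s₁ carrying a positive sign when the per-group correlations
share one sign and a negative sign otherwise. Each source is ranked
ascending with average ties (`rankAscending()`; tie-average keeps every rank
column summing to n(n+1)/2), the four ranks are summed, and the gene with
the largest total is the top candidate. The orientation follows from the
construction: a longer path (more peripheral), a larger |correlation|, a
larger |FC| and a consistent sign all push a gene's ranks up, so candidate
regulators sit at the interface between the host network and the microbe
rather than at the network's core. Exactly zero correlations count as
sign-inconsistent for s₄ (a zero carries no directional evidence), and ties
in the total are broken lexicographically by gene id so the output is
deterministic. Genes outside the network are excluded with a warning — the
path-length source is undefined for them.

# The synthetic-data generator

The generator exists so that every stage has a recoverable planted answer.
It emulates the structure of the motivating study design, not its raw data.

## Microbiome arm

Two experiments share one truth. Baseline composition weights are drawn as
`0.8 + 0.8·Exp(1)` — right-skewed but without an ultra-rare tail, since taxa
observed at a handful of reads carry no usable differential signal at n = 10
per group. Per-sample compositions are Dirichlet-multinomial with precision
800 (≈ 50% compositional CV for a taxon at 0.5% abundance, a realistic 16S
overdispersion) and 50 000 reads per sample.

Half the taxa (100 of 200) are regulated. A small bloom set (5% of the
regulated taxa, always including the mediator) is multiplied by
`regulationFold` (default 5) in the perturbed group; the remaining regulated
taxa are depleted by the fold that conserves total composition weight
exactly (recorded in the truth; ≈ 1/4 at defaults). Load conservation is a
deliberate design choice: because the two experiments share the planted
truth, any net inflation of total weight would renormalize *every*
unregulated taxon by the same factor in both experiments, and the screen
would then reproducibly call those compositional artifacts concordant.
Conserving load keeps unregulated taxa null, which is what a
concordance-based screen implicitly assumes about its negatives.

The mediator is an abundant mucin-specialist-like taxon (6% baseline
weight, blooming to ≈ 30% when the factor is removed) with extra
between-sample biological variability (log-normal factor, s.d. 0.7, on its
Dirichlet weight) — the wide abundance dispersion typical of such blooms is
exactly what gives the phenotype correlation its power. Phenotypes are
generated for perturbed-group samples only (matching the within-knockout
correlation design): fasting glucose `150 + β₁·(mediator relative
abundance) + N(0, 5)` with β₁ = −50 mg/dl per unit relative abundance, and
AUC-GTT as an independently noised scaled version. The two metrics carry
independent noise; their coherence comes from the shared abundance signal,
as in real glucose-tolerance data.

## Expression arm

Four sample groups of 8, 7, 9 and 10 samples mirror a typical multi-strain
panel. Module genes load on a per-group latent factor with loadings drawn
from (0.8, 0.97) — the dense correlation regime of real co-expression
modules — and carry negative log₂ fold changes (most factor-dependent genes
drop when the factor is removed), so within-module edges satisfy the
fold-change sign rule by construction. The microbe abundance vector is an
independent Gaussian variable per group.

The planted regulator carries the target microbe coupling (Pearson ≈ −0.85
in every group), a large assigned fold change (log₂ FC −2.5) and sits at the
network's edge. Because the edge criteria make correlations below ≈ 0.8
unreliable as edges at these group sizes, the regulator is tied into
module 1 through four bridge genes: two anchors that are module members
sharing part of the regulator's latent signature and two partners strongly
correlated with both the regulator and the anchors. The result is a
reliable chain regulator → partner → anchor → module, which keeps the
regulator a network member (degree ≈ 2–5) while leaving it two to three
hops from the module core — the "peripheral but connected" placement the
ranking is designed to reward. The default coupling strength reflects the
scenario being planted: a *strong, consistently* negative regulator–microbe
relation; weaker couplings flip sign in one small group often enough to
contradict the intended plant.

All randomness derives from the mandatory master seed through one stream
per logical component (taxa, phenotype, expression), so adding a component
never perturbs another's draws, and identical configurations produce
byte-identical outputs.

## What the generator does not emulate

No phylogenetic correlation between taxa, no sequencing-error or chimera
model, no batch effects, no library-size variation, no zero-inflation beyond
what the Dirichlet-multinomial produces, and no real taxonomy or gene
annotation. Passing the recovery tests therefore demonstrates that the
*inference chain* is implemented correctly and is well calibrated under its
own assumptions — not that those assumptions hold for any particular real
data set.

# Calibration and verification

The test suite and `scripts/acceptance.R` verify, among others:

* the global null (no planted effects, 100 replicates): the mean number of
  concordant taxa at τ = 0.1 stays below the independence bound
  200·0.1² + 3 s.e. (observed: ≈ 0), and pure-noise gene pairs form
  admissible edges at ≤ 0.1%;
* planted-effect recovery: ≥ 95% of planted taxa are concordant on average;
  the planted mediator is classified `candidate_improver` with the smallest
  minimum p among candidates in ≥ 90 of 100 seeds; the planted regulator is
  ranked first in ≥ 80 and within the top 3 in ≥ 95 of 100 seeds;
* kernel-level oracles: Fisher combination against its closed form (k = 1
  identity to 1e−10, χ² to 1e−10, monotonicity), BFS distances against
  Floyd–Warshall on 100 random graphs, rank-sum output against brute-force
  recomputation on 100 random instances;
* end-to-end determinism: reruns under a fixed seed give identical file
  digests.

Simulation sizes in the tests are the study-scale defaults (200 taxa,
2 × 2 × 10 microbiome samples, 200 genes, 4 expression groups); 100-seed
batteries complete in well under a minute each.

# Numerical choices and degenerate inputs

* Fisher combination clamps exact-zero p values to 1e−300 (warning) to keep
  the log finite; p values above 1 or below 0 are errors, not clamped.
* Correlation p values come from the t transform of r; |r| = 1 maps to
  p = 0. Spearman uses tie-averaged ranks and the same transform (the
  large-sample approximation — adequate at the n ≥ 10 scales of the
  screens).
* Constant features/genes are flagged (degenerate differential records,
  untestable correlation pairs) rather than raised as errors inside batch
  operations; scalar operations on fully constant input raise errors naming
  the offending feature.
* Pairwise-complete observations are used for phenotype correlations, with
  the effective n recorded per record; fewer than 3 complete pairs marks the
  record untestable.
* All record tables are written with 10 significant digits, fixed column
  order and input row order, so write→read round trips are stable and run
  digests are reproducible.

# Known limitations

The two-group test ignores the compositional, overdispersed-count nature of
the data by design (see Stage 1). The mediator screen is a sign-matching
filter, not a formal mediation model — it cannot distinguish mediation from
pleiotropy given these designs. The rank-sum score has no attached
significance measure; it is a prioritization index. Network membership and
the 0.3/0.01 edge thresholds interact strongly with group sizes: with
groups of 7–10 samples, true correlations below ≈ 0.6 rarely survive, so
sparse true structure will be under-recovered — a property inherited from
the method, faithfully reproduced here.
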