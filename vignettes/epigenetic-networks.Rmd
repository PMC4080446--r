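---
title: "Methods: weighted epigenetic networks and interplay modules"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: weighted epigenetic networks and interplay modules}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the statistical model behind `epimodnet`, the
parameters that matter, the synthetic data the tests run on, and the design
choices made where more than one reasonable convention existed.

## The model

The package treats epigenetic dysregulation as a network phenomenon. The
analysis assumes:

1. a background interactome of undirected gene–gene interactions (physical
   and pathway edges, deduplicated, self-loop-free), in which disease
   processes occupy connected neighborhoods rather than isolated genes;
2. gene-level DNA methylation summarized as beta values in [0, 1], with
   case/control groups comparable gene by gene;
3. chromatin state summarized per gene as the accumulated intensity of
   ChIP-seq peaks whose midpoints fall in the promoter window (TSS ± 2 kb);
4. genes acting together epigenetically have *correlated* profiles, so an
   interaction is epigenetically active when its endpoints' profiles
   correlate strongly.

The pipeline stages are: differential-methylation calling → weighted
methylation network (WMPN) → differential-seed subnetwork (TMSN) →
topology + null models → peak mapping → weighted chromatin network (WCPN)
→ chromatin subnetwork on the TMSN gene set (TCSN) → dense-module mining
on both giant components → interplay testing → methylation–expression
regression.

## Differential methylation

The moderated statistic is `d = (mean_case − mean_control) / (s + s0)`
with `s` the pooled two-sample standard error. `s0` damps the inflation of
`d` for low-variance genes; it is chosen among percentiles of the `s`
distribution to minimize the coefficient of variation of the median
absolute deviation of `d` across 100 quantile bins of `s`, falling back to
`median(s)` when the spread of `s` degenerates. With `s0 = 0` the statistic
is the ordinary equal-variance t; a zero-variance gene with `s0 = 0` is an
error rather than an Inf.

The FDR is permutation-based: for each gene's symmetric cutoff `|d|`, the
expected false-call count is the *median* over label permutations of the
number of permuted `|d*|` at or above the cutoff, and
`q = expected false calls / observed calls`, capped at 1 and forced
monotone nonincreasing in `|d|`. When the label space is small (e.g. 4 + 2
samples give only 15 distinct assignments) all distinct assignments are
enumerated, which also makes the q-values exactly invariant to sample
order; with the study-scale 11 + 5 design the space (4368) is sampled.
Calls are two-sided; the predominance of hypomethylation in islet data is
a property of the data, not of the test.

Methylation levels are classed hypo (mean beta ≤ 0.2), hyper (≥ 0.8), mid
otherwise, with *inclusive* boundaries.

## Weighted networks and subnetworks

An edge of the background is kept when both endpoints have profiles,
`|r| > r_cut` (default 0.8) and the two-sided correlation p-value
(`t = |r|·sqrt(df/(1−r²))`, `df = n − 2`) is `< alpha` (default 0.05),
both strict. For 5-long chromatin profiles (five marks) the p filter is
the stricter of the two — it demands roughly `|r| > 0.878` — and both are
applied as stated. Zero-variance profiles make `r` undefined; such edges
are skipped and counted. The network's node set is the genes incident to
at least one retained edge. Profile correlations use all samples (both
groups) by default: the correlation measures co-variation of the
epigenetic profile across the cohort, not a group contrast.

The seed subnetwork is the induced subgraph on the seed genes present in
the network plus their first neighbors; edges keep the parent's `(r, p)`.
The giant component breaks node-count ties by edge count, then smallest
node id, so it is deterministic.

Topology: degree; local clustering coefficient `2T/(k(k−1))`, defined as 0
for `k < 2`; non-normalized shortest-path betweenness; and a
degree-distribution exponent estimated as the negative slope of the
least-squares fit of `log10 count` on `log10 degree` over nonzero-count
degrees. The regression estimator (rather than a maximum-likelihood
power-law fit) is used deliberately: it is the estimator under which
reported sub-1 exponents for dense subnetworks are meaningful.

## Null models

*Global null*: replicate seed sets of the observed size are drawn
uniformly without replacement and their seed subnetworks summarized.
*Local null*: the giant component is rewired by double-edge swaps — pick
edges (a,b), (c,d) with four distinct endpoints, replace with (a,d), (c,b)
when neither exists — until accepted swaps reach `ceil(0.5 × |E|)`;
rejected proposals do not count, so the amount of randomization is
deterministic. The degree multiset is conserved exactly and no self-loops
or duplicates can arise. A graph with no valid swap (e.g. a triangle) is
returned unchanged with a warning. Weights are dropped in the rewired
replicates: the null is purely topological.

Empirical p-values use the add-one rule `p = (1 + #{v ≥ obs})/(B + 1)`
(mirrored for the lower tail), so `p ∈ (0, 1]` and the resolution is
`1/(B+1)`. The tail for each statistic is chosen by the side of the null
mean the observation falls on and is reported alongside `p`; this is a
one-sided p with declared direction, which we prefer to an undirected
two-sided rule because the scientific questions (is the subnetwork
smaller? more clustered?) are directional.

## Dense modules and interplay

Vertex weight = core number of the highest k-core of the closed
neighborhood × that core's edge density. Modules grow greedily from the
highest-weight unvisited vertex, admitting neighbors with weight ≥
`(1 − node_score_cutoff)` × seed weight (default cutoff 0.2); visited
vertices cannot re-join, so modules are vertex-disjoint. The haircut prunes
each module to its 2-core, and modules are additionally split at bridge
edges so that every reported module is 2-edge-connected — two dense
communities joined by a single edge are two modules, not one. Modules
below `min_size = 3` are dropped (pairs are not modules). Tie-breaks
(descending weight, then node id) make the output deterministic and
invariant to relabeling. The fluff expansion variant is intentionally not
implemented (off in the reference tool's defaults).

The interplay test scores each (methylation module, chromatin module) pair
by its gene overlap; pairs with overlap ≥ 3 are tested with the exact
upper-tail cumulative hypergeometric probability, computed from log
binomial coefficients with log-sum-exp so genome-scale `N` is stable, and
Bonferroni-corrected by the number of *tested* candidates (a flag switches
to all pairs). The background `N` defaults to the *union* of the two
subnetworks' gene sets: the chromatin subnetwork's genes derive from the
methylation subnetwork's gene set, so summing the two sizes would count
shared genes twice; a configuration option supports the sum reading. For
the canonical worked overlap (N = 2060, M = 6, H = 5, x = 4) both readings
are significant far below 0.001.

## Methylation–expression regression

Gene-level means (case-group samples by default, since the question is
the diseased state) are paired across the shared gene universe. The
package reports the Spearman rank correlation (average ranks for ties,
t-approximation p) and the OLS line with the exact prediction interval
`ŷ(x0) ± t_{1−α/2, n−2}·s·sqrt(1 + 1/n + (x0 − x̄)²/Sxx)`. Genes *inside*
the band are flagged as having expression consistent with methylation
control; a small floating-point epsilon keeps a noiseless (zero-residual)
fit from excluding its own points. Pooling per-gene means (rather than
per-sample values) is the default because the pairing of methylation and
expression cohorts is at the gene level.

## The synthetic data

The generators produce every input the pipeline needs, with the structure
the analysis assumes, so the full pipeline is testable offline:

* **Interactome**: preferential attachment (4 edges per incoming node),
  connected, heavy-tailed degrees. Real interactomes additionally have
  database-driven ascertainment bias and motif structure not emulated
  here.
* **Methylation**: control-group gene means from a three-component Beta
  mixture — hypo `Beta(1,12)` with weight 0.59, hyper `Beta(12,1)` with
  weight 0.06, mid `Beta(5,5)` — reproducing the bimodal beta-value
  landscape of islet controls. Because `Beta(1,12)` carries ~7% of its
  mass above 0.2, the observed fraction of genes with mean < 0.2 sits
  slightly below the nominal 0.59 weight; tests account for this. Planted
  differential genes (default 100, effect size 0.3) are
  case-hypomethylation events, chosen inside one interactome neighborhood
  (breadth-first ball from the highest-degree anchor) so a seed
  subnetwork exists by construction, with control means redrawn above the
  shift so the effect survives clipping to [0, 1]. Per-sample Gaussian
  noise sd 0.05 (beta scale) matches array-replicate variability.
* **Chromatin**: a deterministic TSS layout with disjoint promoter
  windows; one peak per target promoter plus background peaks outside all
  windows. In the demo, planted-community genes get rank-one mark
  intensities (shared pattern × gene scale, 5% lognormal jitter) so their
  5-mark profiles correlate near 1, while other genes get independent
  intensities; real ChIP-seq has correlated marks genome-wide, peak-width
  variation and mappability artifacts that are not emulated.
* **Expression**: `intercept + slope × methylation group mean + noise`,
  defaults slope −2.793, intercept 7.561, noise sd 0.5 — a linear
  inverse coupling at realistic noise.

Group sizes default to 11 control vs 5 case, the scale of the islet
methylation cohort the method was designed around. One explicit seed is
threaded through every generator (no global RNG state), and same-seed
runs are bit-identical. Passing tests on these data show the machinery
recovers planted structure under the model's own assumptions; they cannot
show robustness to batch effects, probe chemistry, or mis-specified
backgrounds, which the generators deliberately do not simulate.

## Problem sizes and budgets

The demo and the deeper tests run at 2000 genes (≈8300 background edges),
100 planted differential genes, a 30-gene planted community, 100–200
label permutations and 50–200 null replicates; unit tests use 80–500-gene
designs. These sizes were chosen so every property of interest (mixture
shape, FDR calibration, planted-structure recovery, null-model
separation) is measurable with comfortable margins while a full test run
stays fast on a laptop. Brute-force oracles (exhaustive hypergeometric
enumeration, shortest-path enumeration for betweenness, peeling for
k-cores) are kept at ≤ 30-node instances where enumeration is exact.

## Known limitations

* The SAM implementation follows the classic recipe but does not
  reproduce any particular legacy implementation's tie-breaking or delta
  tables.
* Peak-to-promoter mapping assigns a midpoint inside two genes' windows
  to both genes; with the synthetic disjoint layout this never occurs,
  but on real genomes overlapping promoters share peaks.
* The rewiring null requires enough swappable edge pairs; very dense or
  very tiny components (triangles, near-cliques) rewire partially and
  warn rather than fail.
* Module mining is deterministic but greedy; it recovers clearly planted
  communities, not arbitrary overlapping community structure.
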