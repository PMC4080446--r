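# epimodnet

Epigenetic dysregulation in complex metabolic disease — type 2 diabetes in
particular — rarely acts through a single gene: aberrantly methylated genes
and genes with altered chromatin marks cluster into interacting groups on
the protein-interaction network. `epimodnet` is an R package for finding
those groups. It takes a protein-interaction background, a gene × sample
DNA-methylation beta-value matrix (case vs control), ChIP-seq peak sets for
a panel of chromatin marks, and an expression matrix, and produces:

* **differentially methylated genes**, called with a SAM-style moderated
  statistic and permutation FDR;
* a **weighted methylation network** (interactions kept only when the two
  genes' methylation profiles are strongly correlated) and the **seed
  subnetwork** induced by the differential genes and their first neighbors;
* a parallel **weighted chromatin network** built from promoter-accumulated
  mark intensities, and its subnetwork on the methylation subnetwork's
  genes;
* **topology summaries** (degree, clustering coefficient, betweenness,
  power-law exponent) assessed against a **global random-seed null** and a
  **degree-preserving rewiring null**, with add-one empirical p-values;
* **dense modules** in each layer (MCODE-style k-core vertex weighting and
  greedy expansion), and **interplay modules** — module pairs from the two
  layers whose gene overlap is significant under the cumulative
  hypergeometric test with Bonferroni correction;
* a **methylation–expression regression** with Spearman correlation and a
  95% prediction interval.

## The statistics at the core

Differential methylation uses the moderated statistic
`d_i = (mean_case − mean_control) / (s_i + s0)`, where `s_i` is the pooled
two-sample standard error and `s0` a fudge factor chosen to minimize the
coefficient of variation of `d` across the spread of `s_i`; q-values come
from group-label permutations (median false-call count over symmetric |d|
cutoffs).

Edges of the background interactome are retained in a weighted network when
the endpoint profiles satisfy `|r| > 0.8` with correlation p-value `< 0.05`
(two-sided t approximation, `df = n − 2`).

An interplay candidate — a methylation module of `M` genes and a chromatin
module of `H` genes sharing `x ≥ 3` genes in a background of `N` subnetwork
genes — is scored with the upper-tail cumulative hypergeometric probability

    P(X ≥ x) = 1 − Σ_{k=0}^{x−1} C(M,k) C(N−M,H−k) / C(N,H)

computed in log space, and Bonferroni-corrected by the number of tested
candidates.

Null models: the global null re-samples random seed sets of the observed
size and rebuilds the seed subnetwork; the local null rewires the giant
component by double-edge swaps (degree sequence conserved exactly, accepted
swaps = 50% of the edge count). Empirical p-values use the add-one rule
`p = (1 + #{v ≥ obs}) / (B + 1)`, so they are never zero.

## Worked example

The bundled demo generates a complete synthetic study — a 2000-gene
scale-free interactome, 11 control vs 5 case methylation samples with 100
planted differential genes (30 of them interconnected into a planted dense
community), five chromatin marks, and expression coupled to methylation —
then runs the full pipeline:

```r
library(epimodnet)
res <- run_pipeline(demo_config("demo_out", rng_seed = 1))
```

The run writes every intermediate (networks, module tables, null
summaries) under `demo_out/` and prints a report that ends with:

```
Differential methylation: 104 of 2000 genes at q < 0.05
...
Modules: 1 methylation, 1 chromatin; 1 interplay pairs tested, 1 significant
Methylation-expression: y = -2.828x + 7.565; Spearman rho = -0.9091;
1899 of 2000 genes within the 95% prediction interval
```

Reading the numbers: 104 called genes at FDR 0.05 recover all 100 planted
differential genes; the one significant interplay pair is exactly the
planted 30-gene community, shared between the methylation and chromatin
module sets (hypergeometric p ≈ 5e-26); and the regression recovers the
planted coupling `y = −2.793x + 7.561` to within sampling error, with the
95% prediction band covering ~95% of genes.

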