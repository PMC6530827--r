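---
title: "Methods: reconstructing and benchmarking gene co-expression networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: reconstructing and benchmarking gene co-expression networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`gcnbench` implements a complete screening workflow for gene co-expression
networks (GCNs): build candidate networks from a normalized expression
compendium by several association measures, partition them into modules,
measure their structure, score the biological coherence of the modules by
gene-set overrepresentation, and screen and rank the candidates against
regulatory gold standards. This vignette is the package's own account of
the models and the design choices behind them.

## The data model

All reconstruction methods consume a genes × samples matrix of normalized
log-scale signal. Two preprocessing steps mirror standard compendium
practice:

* **Replicate aggregation** (`aggregate_replicates`): one column per
  condition, each value the *median* across that condition's replicates.
  Medians rather than means throughout, for robustness to single outlying
  arrays; the operation is idempotent on already-aggregated data.
* **Gene filtering** (`filter_genes`): "noisy expression" is
  operationalized as the median replicate coefficient of variation (CV =
  replicate sd / replicate mean per condition, median over conditions);
  genes above `cv_max` (default 0.5) are removed, as are genes whose median
  signal falls below the `low_quantile` (default 0.05) global signal
  quantile. Both rules are configurable, the CV rule alternatively as a
  data-driven quantile (`cv_quantile`), and every removal is returned with
  its reason. The defaults are deliberately permissive: published
  compendium studies state that noisy and low-signal genes were excluded
  but rarely give a rule, so the rule here is explicit and logged rather
  than canonical.

## Reconstruction methods

Five methods produce a simple, undirected, weighted network; in all of
them, genes left without any qualifying edge are excluded from the network
(the adjacency-inclusion rule), thresholds act monotonically (raising a
threshold never adds an edge), and zero-variance genes are skipped with a
warning rather than generating undefined correlations.

**Correlation thresholding** (`correlation_network`). Edge iff
$|r_{ij}| \ge r$ (Pearson, or Spearman on ranks). Association is unsigned
by default — common co-expression practice, and single-threshold parameter
conventions are ambiguous about sign — with a signed mode available. A
matched edge-count mode (`n_edges`) keeps exactly the strongest k pairs,
for comparisons of methods at equal network size.

**Shrinkage partial correlations with empirical-Bayes edge calling**
(`genenet_network`). The correlation matrix is shrunk toward the identity,
$R^* = \lambda^* I + (1-\lambda^*) R$, with the analytic intensity
$\lambda^* = \sum_{i \ne j} \widehat{\mathrm{Var}}(r_{ij}) / \sum_{i \ne j}
r_{ij}^2$ clipped to $[0,1]$ — guaranteeing an invertible estimate even for
more genes than samples. Partial correlations come from the inverse; the
observed values are then modelled as a mixture of the null correlation
density $f_0(\rho;\kappa) \propto (1-\rho^2)^{(\kappa-3)/2}$ (fraction
$\eta_0$) and a uniform alternative. An edge is called when the posterior
probability of the alternative reaches $\omega$ (default 0.9). Two
numerical safeguards stabilize the likelihood fit: $\kappa$ is bounded
below by the theoretical null degrees of freedom $n - p + 1$ (shrinkage can
only narrow the null) and above by $2n$ (preventing the degenerate
$\kappa \to \infty$ optimum on very short vectors), and $\eta_0$ carries a
weak Beta(2, 1) prior — one extra $\log \eta_0$ term — encoding the
empirical-null framework's core assumption that most pairs are null. Both
are negligible at realistic problem sizes and matter only for tiny ones.

**Sparse partial correlation estimation** (`space_network`). The symmetric
partial-correlation matrix minimizes the joint lasso loss
$$\tfrac12 \sum_i \Big\| X_i - \sum_{j\neq i} \rho_{ij}
\sqrt{\sigma_{jj}/\sigma_{ii}}\, X_j \Big\|^2
+ \lambda \sum_{i<j} |\rho_{ij}|,$$
by cyclic coordinate descent with soft-thresholding; each update of
$\rho_{ij}$ pools the two regression rows in which it appears, so symmetry
is maintained by construction. Outer iterations (3 by default) alternate
full coordinate-descent convergence with residual-variance updates of the
precision diagonals $\sigma_{ii} = n/\mathrm{RSS}_i$; after each variance
update the regression coefficients are rebuilt from $\rho$ under the new
variance ratios. Regression weights are uniform (the simplest published
variant). $\lambda = \texttt{lambda\_scale} \cdot \sqrt{n \log p}$, with
$\rho$-thresholding as the operative pruning parameter. The objective is
asserted non-increasing across sweeps (this assertion caught a real
bookkeeping bug during development); convergence is declared when the
largest coordinate change falls below `tol` ($10^{-4}$), and
non-convergence within `max_sweeps` raises an error reporting the last
change.

**Soft-threshold adjacency with topological overlap** (`wgcna_network`).
Unsigned adjacency $a_{ij} = |r_{ij}|^\beta$, default $\beta = 5$;
$\mathrm{TOM}_{ij} = (\sum_u a_{iu}a_{uj} + a_{ij}) / (\min(k_i,k_j) + 1 -
a_{ij})$. Edges are thresholded on the *adjacency* ($a_{ij} \ge \tau$) —
thresholding on TOM is equally defensible, so the full TOM matrix is
returned for any downstream use. `select_soft_power` implements the
standard scale-free-fit criterion: for each candidate power, bin the
weighted degrees, regress log frequency on log mean degree, and return the
lowest power whose $R^2$ reaches the target (0.8), falling back to the
argmax with a warning — with the fit table attached for inspection.

## Module detection and modularity

Walktrap (walk length $t = 4$, the algorithm's canonical default),
fast-greedy and label propagation come from igraph, the same implementations
used across the field; modularity
$Q = \sum_c [e_c/m - (d_c/2m)^2]$ is computed by this package directly (and
cross-checked against igraph in the tests). Modularity is computed
*unweighted* by default, since detection operates on thresholded networks;
a weighted variant is a flag. Label propagation is randomized; it is made
reproducible by seeding, and ties are broken uniformly at random within the
igraph implementation. `detect_modules` relabels modules by decreasing size
with a deterministic tie-break (smallest member gene id), so "module 0" is
always the largest module, and flags modules under `min_module_size`
(default 5 genes) as ineligible for enrichment rather than deleting them —
module counts therefore include small modules, with the flags exposed.
Externally computed partitions (e.g. from partitioners not shipped here,
such as Infomap) enter through `partition =` or `read_partition`.

## Enrichment and the ψ statistics

Gene-set overrepresentation per module uses the one-sided hypergeometric
tail, accumulated in log space and verified against exhaustive enumeration
to $10^{-12}$ in the tests. The test universe is the intersection of the
partitioned genes and the annotated genes — the conservative choice for
network-restricted testing. Multiple testing is corrected within each
module (BH by default; `"none"` reproduces raw-p workflows) at
$\alpha = 0.05$. Annotations are flat term–gene sets; no ontology-graph
propagation is performed (annotations are consumed the way flat
genome-annotation exports provide them).

Two summary statistics describe how biologically coherent a partitioned
network is: $\psi_1$, the average number of significant terms per
*enriched* module (modules with at least one significant term), and
$\psi_2$, the ratio of the total significant-test count to the number of
modules with at least one *annotated* term. The published verbal definition
of $\psi_2$ admits a second, literal reading with the enriched-module count
in the denominator; that reading collapses onto $\psi_1$, which is one
reason to prefer the first. Both are computed and reported
(`psi2`, `psi2_literal`), so no information is lost to the ambiguity.

## Topology and power-law fits

Structural summaries report density, the edges-to-genes ratio $n_e/n_g$
(the primary density criterion for candidate screening), average shortest
path length and diameter on the largest connected component (path metrics
on disconnected graphs are otherwise undefined; the component count is
reported alongside so nothing is hidden), and hub genes (degree ≥ 5 by
default). Degree distributions are discrete PMFs over observed degrees.

Power-law fitting offers two estimators, reported side by side because
plotted "power-law fits" in the literature rarely state their procedure:
the exact discrete maximum-likelihood estimate — numerical maximization of
the zeta-normalized likelihood, seeded by the closed-form
continuity-correction formula, which by itself is visibly biased
(≈ −0.13 at $k_{min} = 2$) — with the Kolmogorov–Smirnov distance between
empirical and fitted CDFs; and a log-log regression of the PMF by unique
degree (no logarithmic binning, matching the usual plotted style) with its
$R^2$. Degenerate inputs are handled explicitly: a single observed degree
is an error, fewer than 10 observations a low-support warning.

## Benchmarking against gold standards

Directed TF→target gold standards are undirected for structural comparison
(reciprocal pairs collapse). Robustness to missing regulation is probed by
*random edge addition*: exactly $\lceil \varphi n_e \rceil$ new edges among
non-adjacent pairs, sampled with probability proportional to the product of
endpoint degrees. The degree-proportional rule is an interpretive choice —
it preserves the heavy tail while shifting the degree distribution
rightward, which is the behaviour the comparison needs — and is flagged as
such. Candidate screening discards networks that are too dense
($n_e/n_g >$ `ratio_max`), too sparse ($n_g <$ `g_min`) or weakly modular
($Q <$ `q_min`), and orders survivors by distance to the nearest
gold-standard $n_e/n_g$; every discard carries its triggering rule.
Method ranking aggregates per-criterion ranks (significant terms, $\psi_1$,
$\psi_2$, $Q$, power-law fit quality) by rank-sum with $\psi_2$ breaking
ties — a deliberately simple, order-invariant scheme. Recovery metrics
(edge precision/recall/F1, adjusted Rand index with the standard
expected-index correction) and regulon projection (coverage and
single-module cohesion per gene set) close the loop against known truth.

## The synthetic compendium: what it emulates, and what it does not

`simulate_expression` draws, per module, a latent regulator profile over
conditions; module genes are that profile scaled by per-gene loadings
(uniform in `loading_range`) plus independent Gaussian noise; replicates
share the condition value and differ by replicate noise; background genes
are pure noise. The noise scale is calibrated so the *expected*
within-module Pearson correlation equals `within_module_cor` exactly under
the loading distribution; noise is absolute while signal scales with the
loading, so individual pairs vary around that target — wider loading ranges
give more heterogeneous modules. Regulator profiles share a global
condition factor with per-module shared-variance fractions drawn around
`between_module_cor`: cross-regulon correlations are heterogeneous, the
way compendium-wide condition effects (growth phase, medium) hit regulons
unevenly. Noisy genes get replicate variance inflated ×10; low-signal genes
are shifted below the 5th percentile of the global signal (the detection
floor is a modelling choice; published exclusions state no rule). All
generators are bit-reproducible under a seed.

The default benchmark configuration (`benchmark_config`) is 8 modules of 6
genes plus 20 background genes, 100 conditions in duplicate,
`within_module_cor = 0.7`, `between_module_cor = 0.6`,
`loading_range = c(0.4, 1)`, with 5% noisy and 5% low-signal genes — small
enough to run the five-method comparison in seconds, large enough for the
partial-correlation methods to see signal. The method thresholds scale with
a structural fact of latent-factor data: a module of $m$ exchangeable genes
with marginal correlation $r$ implies pairwise *partial* correlations near
$r/(1+(m-2)r)$ — about 0.2 for $m = 6$, $r = 0.7$ — which is why the
benchmark's SPACE threshold (0.12) sits far below thresholds appropriate
for real compendia, where modules are larger but sample sizes and
correlation structure differ.

What the generator does **not** emulate, and what that implies for
interpreting green tests: probe-level microarray artifacts and
normalization residue; overlapping regulons (planted modules are disjoint);
and — most consequentially — the *continuum* correlation structure of real
compendia. Real expression data show a dense spectrum of intermediate
correlations from chained and overlapping regulation; thresholded
correlation networks built from such data degrade into weakly modular
hairballs, while sparse partial-correlation networks stay modular. With
clean planted blocks, a matched-size correlation network instead remains a
union of near-cliques, so its best-partition modularity stays high and the
modularity gap between correlation-based and partial-correlation networks
largely closes — the benchmark reproduces the density contrast (at equal
edge counts the correlation network concentrates on fewer genes) and the
enrichment ordering between methods, but not the low absolute modularity of
real-data correlation networks. Passing tests therefore demonstrate correct
mechanics and the recoverable parts of the qualitative method comparison,
not a full emulation of real-compendium behaviour.

## Problem sizes and numerical conventions

The shipped tests and the acceptance script use compendia of 60–120 genes
over 50–200 samples, networks up to a few thousand edges, exhaustive
modularity oracles on up to 8 nodes, and 10–20 replicate seeds per
stochastic claim; the implementation targets up to a few thousand genes on
one CPU. Edge lists are canonicalized (lexicographic pair order) so equal
networks are byte-identical on disk; module labels, ranking and screening
use deterministic tie-breaks; every writer emits header comments with the
package version, a configuration fingerprint and the seed, and one global
seed fans out to per-stage seeds by stable hashing of stage names, so
stages stay independently reproducible.
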