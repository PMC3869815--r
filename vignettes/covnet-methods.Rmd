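---
title: "Structural covariance network analysis: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Structural covariance network analysis: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

covnet builds group-level *structural covariance networks* from
subject-by-region cortical thickness tables and compares them between two
groups. This vignette is the package's own account of the method: what is
estimated, under which assumptions, which parameters matter, and where the
design was genuinely open.

## The analysis chain

A structural covariance network treats each cortical region as a node and
the across-subject correlation of a morphometric measure — here, regional
mean thickness in millimetres — as the weight of the edge between two
nodes. The chain is:

1. **Residualization.** For every region, thickness is regressed (ordinary
   least squares) on an intercept, subject age, and the subject's mean
   cortical thickness (the mean over all atlas regions of that subject).
   The residuals replace the raw values, so correlations are not driven by
   age trends or by global thickness differences between subjects.
   Residualization is done within each group separately, which prevents
   group-mean differences from leaking into either group's covariance
   estimate. If age is constant in a sample the age regressor is dropped
   with a warning rather than producing a rank-deficient fit.
2. **Correlation.** Pearson correlations between the residuals of every
   region pair form a symmetric region-by-region matrix per group.
3. **Binarization at fixed sparsity.** Applying one correlation cutoff to
   both groups would give networks with different edge counts, so group
   differences in graph metrics would partly reflect wiring cost. Instead
   the matrix is thresholded at fixed *sparsity* (edge count over
   `n(n-1)/2`): the `round(s * n(n-1)/2)` strongest correlations become
   edges. Both groups' networks then carry identical cost at every
   threshold. A sweep over sparsities (default 0.36 to 0.50 in steps of
   0.01) replaces any single arbitrary choice.
4. **Graph metrics.** Binary undirected graphs are characterized by
   efficiency-based small-world measures, betweenness-centrality hubs,
   regional efficiency and nodal vulnerability (definitions below).
5. **Inference.** Edge-level differences use Fisher r-to-z tests with
   Benjamini–Hochberg FDR control; network-level differences use
   label-permutation tests that re-estimate everything per permutation.

## Graph measures

For a binary graph with `n` nodes and shortest-path lengths `L_ij`:

* **Global efficiency** `E_glob = mean over ordered pairs of 1/L_ij`, the
  inverse harmonic mean of path lengths, with `1/Inf = 0` for
  disconnected pairs. This is exactly why efficiency is used instead of
  characteristic path length: it remains well defined on fragmented
  graphs, which sparsity-thresholded networks can be.
* **Local efficiency** `E_loc`: the mean over nodes of the global
  efficiency of each node's neighbour subgraph (the node itself
  excluded). Nodes with fewer than two neighbours contribute 0 — their
  neighbour subgraph has no pairs.
* **Regional efficiency** `e_i`: the inverse harmonic mean of the path
  lengths from node `i` to all others; its node-average equals `E_glob`.
* **Betweenness** `b_i`: the fraction of shortest paths between other
  node pairs passing through `i`, on the unordered-pair convention
  (each pair counted once; any doubling would cancel in the normalized
  version anyway). Normalized betweenness `nb_i = b_i / mean(b)` has mean
  1 by construction. **Hubs** are nodes with `nb_i >= 1 + sd(nb)`, using
  the population (n-denominator) standard deviation; when `sd(nb) = 0`
  every node is exactly average and the hub set is defined as empty
  rather than all-inclusive.
* **Vulnerability** `V_i = (E_glob(G) - E_glob(G - i)) / E_glob(G)`: the
  relative efficiency drop after deleting node `i`, the reduced graph
  evaluated over its own `n - 1` nodes. Negative values are legitimate —
  removing a peripheral node can raise the mean over the remaining
  pairs. Global vulnerability is the maximum over nodes.

The distance, betweenness and rewiring kernels are compiled (Rcpp); they
are validated in the test suite against independent brute-force oracles
(Floyd–Warshall distances, explicit shortest-path enumeration) on
hundreds of random graphs, and against igraph as a second opinion.

## Small-world assessment

A network is small-world when its local efficiency clearly exceeds that
of matched random networks while its global efficiency remains comparable
to them. The reference ensemble (default 100 copies) preserves node
count, edge count and the exact degree sequence via repeated double-edge
swaps (default `10 x edge count` successful swaps per copy, a standard
mixing heuristic; attempts are capped at `100 x` that so rigid graphs
such as stars terminate with a warning and an unchanged copy).

The criterion implemented is `E_loc_real / E_loc_rand > 1` **and**
`E_glob_real / E_glob_rand > 0.5`. The first inequality does the
discriminating work: random-like graphs fail it because their ratio is
~1, and the complete graph fails it exactly. The second is a
same-order-of-magnitude reading of "comparable global efficiency": on
the canonical positive control — a 100-node ring lattice with 3
neighbours per side and 5% rewiring — the ratio ranges roughly 0.64–0.75
across seeds, while dense thresholded covariance networks sit near 1 and
strongly lattice-like graphs fall below as they grow. A hard near-unity
cutoff (say 0.9) would misclassify the canonical small-world regime at
this scale, so the band is deliberately loose and exposed as a
configuration parameter (`eglob_ratio_min`) rather than fixed.

## Statistical inference

**Edge level.** For each region pair the group correlations are compared
with `z = (atanh(r1) - atanh(r2)) / sqrt(1/(n1-3) + 1/(n2-3))` and a
two-tailed normal p-value; both directions of change are of interest and
the direction is reported separately. All `n(n-1)/2` edges form one
Benjamini–Hochberg family at level `q` (default 0.05). Correlations of
exactly ±1 (possible on degenerate toy input) are clipped to
`1 - 1e-12` with a warning so small examples do not crash the transform.

Two calibration subtleties matter here. First, correlations of
residuals are *partial* correlations: each group loses one degree of
freedom per partialled covariate (age, mean thickness), so the `n`
entering the z statistic is the effective size `n_subjects - k`
(recorded on the correlation object as `n_eff`). Ignoring this makes
the far tail of the test anti-conservative — in null simulations at
30+30 subjects and 780 edges, the BH any-discovery rate is ~0.135 with
raw counts versus ~0.08 with the partial-correlation convention.
Second, even with correct degrees of freedom the normal approximation
to the Fisher z difference slightly understates far-tail probabilities
at a few dozen subjects, and a step-up correction over hundreds of
edges probes exactly that depth of the tail; the residual excess over
`q` (~0.06–0.08 observed versus 0.05 nominal at n = 30 per group) is a
property of the z-test at small samples, shrinking as group sizes grow
toward the 40+ typical of real cohorts. The package reports this
calibration honestly rather than substituting a different test
statistic for the conventional one.

**Network level.** Observed group differences of global and nodal metrics
are referenced against a permutation null: subjects are pooled and
randomly reassigned to two groups of the original sizes, and the *entire*
chain — residualization, correlation, binarization at the same sparsity,
metric computation — is re-run per permutation (relabeling precomputed
residuals would understate the null variability). One relabeling stream
drives all metrics and nodes, preserving their dependence. P-values use
the add-one convention `p = (1 + #{null >= obs}) / (B + 1)`, which is
exact under exchangeability and never zero; at `B = 200` the implied
finite-sample levels are 10/201 ≈ 0.0497 for the 0.05 criterion and
2/201 ≈ 0.00995 for the 0.01 criterion. The 95th and 99th empirical
percentile points of each null distribution are reported as critical
values (95th: overall graph characteristics, type I error 0.05; 99th:
regional nodal characteristics, type I error 0.01). The direction of the
one-tailed test is pre-declared (`tail = "upper"` by default) rather
than chosen after seeing the data; both tail p-values are stored. Nodal
p-values are reported uncorrected across nodes, and the sweep summarizes
each node by its mean p across the sparsity grid. A permutation on which
a metric is undefined (e.g. zero mean betweenness on an extremely sparse
graph) is counted as extreme for both tails — conservative — with a
warning.

## The synthetic cohort generator

No clinical data ship with the package; the generator provides cohorts
with *known* structure so every stage is testable. Each subject's
regional thickness vector is

```
baseline + age_effect * age + global_offset + correlated_component + noise
```

with defaults chosen once as conventional values for an adolescent
cortical-thickness cohort:

| parameter | default | units | rationale |
|---|---|---|---|
| `baseline` | 2.5 | mm | typical mean cortical thickness |
| regional SD (diag of `base_covariance`) | 0.2 | mm | typical between-subject spread |
| `age_range` | 12–18 | years | adolescent cohort; ages uniform (only a range is meaningfully specifiable) |
| `age_effect` | −0.02 | mm/year | mild adolescent cortical thinning |
| `global_effect_sd` | 0.1 | mm | subject-level global thickness offset |
| `noise_sd` | 0.02 | mm | regional means average many vertices, so measurement noise is small relative to between-subject SD |
| `n_subjects` | 42, 41 | — | two groups of roughly forty adolescents |
| `n_regions` | 154 | — | gyral/sulcal parcellation scale |

The correlated component is multivariate Gaussian with a
block-structured correlation matrix (communities of 8 regions,
within-block r = 0.55, adjacent-block r = 0.25, blocks on a ring):
thresholding such a matrix yields clustered graphs with short
inter-community bridges, i.e. small-world-like topology. Group
differences are *planted* by forcing selected region pairs' population
correlations to group-specific targets; if planting breaks positive
definiteness the matrix is projected back by eigenvalue flooring
(`1e-6 x` mean variance), and generation aborts with the offending edge
named if the projection cannot honour a target to within 0.05. Note that
strong targets are only geometrically feasible where the surrounding
correlation structure supports them: forcing r = 0.8 between members of
two different communities (whose other correlations remain near zero or
anchored at 0.55 to their own blocks) has no positive-definite
completion, and the generator rejects it rather than silently sampling
from a different population. Planted group differences in the validation
suite therefore live within blocks. The
synthetic atlas splits regions evenly into hemispheres with lobes
assigned round-robin, enough to exercise the hemisphere/lobe hub
summaries.

What the generator does **not** emulate: realistic anatomical covariance
patterns, hemispheric asymmetries, spatially smooth noise, non-Gaussian
thickness distributions, or any disease biology. Passing tests therefore
demonstrate that the chain is *correct and calibrated* — type-I error at
nominal level, planted effects recovered — not that it would detect any
particular clinical effect.

## Numerical choices

* Sparsity-to-edge-count conversion rounds halves away from zero
  (`round_half_away`), making edge counts bit-exact across platforms;
  base R's round-half-to-even would differ at exact halves.
* Binarization ranks signed correlations by default (the strongest
  positive covariances survive); magnitude ranking is available via
  `ranking = "absolute"`. Ties at the cutoff break by ascending `(i, j)`
  order, so toy matrices with equal values binarize deterministically.
* Every random stage (cohort generation, rewiring, permutation) takes a
  seed; pipeline stages derive theirs from one master seed through a
  mixing function (`derive_seed`), so a full `run_pipeline()` bundle is
  byte-identical across runs with the same configuration. RNG state of
  the caller is restored after each seeded operation.
* Disconnected pairs contribute 0 to every efficiency sum (`1/Inf = 0`);
  networks below the connectivity threshold are permitted, and the
  pipeline records largest-component size per sparsity so users can see
  where fragmentation begins.

## Validation scale

The statistical calibration checks in the test suite and the acceptance
script use deliberately modest problem sizes chosen to estimate rates
with useful Monte-Carlo precision: 300 replicate null cohorts of 40
regions and 20+20 subjects with 200 permutations each for the type-I
error of the permutation tests (binomial SE ≈ 0.013 at the 0.05 level),
200 replicate cohorts for the FDR bound, and 150 replicates of 60+60
subjects for planted-edge power. Metric correctness is checked exactly
(to 1e-10) against brute-force oracles on graphs of up to 12 nodes,
where exhaustive path enumeration is feasible.

## Known limitations

* Only two covariates (age, mean thickness) are residualized; partial
  correlations or richer covariate models are out of scope.
* Binary undirected networks only: no weighted, directed or
  minimum-spanning-tree variants.
* Hub analysis relies on betweenness; eigenvector or closeness
  centrality are not implemented.
* Nodal permutation p-values are reported uncorrected across nodes by
  design fidelity; users comparing many nodes should interpret single
  uncorrected nodal findings cautiously.
* The sparsity range default (0.36–0.50) is conventional, not derived
  from a formal criterion; the largest-component and stability curves
  are reported so users can judge the regime, but no sparsity is
  auto-selected.
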