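---
title: "Topology-aware subnetwork markers by affinity propagation: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Topology-aware subnetwork markers by affinity propagation: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Single-gene expression markers for two-phenotype classification (the
motivating case is metastatic versus non-metastatic breast cancer) are
notoriously irreproducible across cohorts and platforms: independent studies
select largely disjoint gene lists with similar accuracy. A robust
alternative is the *subnetwork marker*: a set of genes whose protein
products sit close together on a protein--protein interaction (PPI) network,
aggregated into a single classification feature. Grouping genes by both
their discriminative power and their network context yields features that
are more stable across datasets and more interpretable as putative
functional modules.

`subnetap` discovers such markers by clustering genes on the induced PPI
network with affinity propagation, using a pairwise gene similarity that
fuses two signals: how well a pair of genes separates the phenotypes, and
how strongly their network neighborhoods overlap.

## The model

### Gene-level evidence: Gaussian log-likelihood ratios

For gene $i$ with expression $x_i$, each phenotype $j \in \{1, 2\}$ gets a
class-conditional Gaussian $f^j$, fitted by the per-class sample mean and
standard deviation ($n-1$ denominator). The gene's evidence in a sample is
the log-likelihood ratio

$$\lambda(x_i) = \log\left[f^1(x_i) / f^2(x_i)\right],$$

positive when the observation favours phenotype 1. Discriminative power is
the two-sample $t$ statistic of a feature between the phenotype groups;
$t_i$ denotes the $t$ score of gene $i$'s LLR profile, and $t_{ik}$ the
$t$ score of the per-sample *sum* of two genes' LLR profiles.

### Discriminative-power similarity

The directed similarity of gene $i$ to candidate exemplar $k$ is

$$s_{DP}(i,k) = t_k + \min\{t_{ik} - t_i,\; t_{ik} - t_k\} - \alpha\,|t_i - t_k|,$$

with $\alpha \in [0,1]$ (default 0.5, the package's standard evaluation
setting). The three terms encode the design assumptions: the
exemplar itself should be discriminative; joining the two genes should not
hurt joint discrimination; and partners should have comparable power, with
$\alpha$ scaling that penalty. Larger $\alpha$ therefore yields smaller,
more homogeneous subnetworks.

Two points are deliberate implementation choices:

* **Magnitudes, not signed scores.** By default $t_i, t_k, t_{ik}$ enter as
  absolute values (`use_abs_t = TRUE`). Discriminative power is a magnitude;
  mixing signed scores would make the $\min$ and the penalty incoherent for
  anti-correlated gene pairs. The signed variant remains available for
  sensitivity analysis and the choice is recorded in marker provenance.
* **Welch $t$ by default.** The equal-variance (pooled) form is a config
  switch (`t_variant`); Welch is the robust default for microarray group
  comparisons with unequal group sizes and variances.

### Topological similarity

Let $N_i$ be the neighbor set of protein $i$ on the induced network. Three
association indices are supported:

| index | definition | range |
|---|---|---|
| Jaccard | $|N_i \cap N_k| / |N_i \cup N_k|$ | $[0,1]$ |
| Kulczyński | $\tfrac12\!\left(\frac{|N_i \cap N_k|}{|N_i|} + \frac{|N_i \cap N_k|}{|N_k|}\right)$ | $[0,1]$ |
| Tversky | $\frac{|N_i \cap N_k|}{|N_i \cap N_k| + a|N_i \setminus N_k| + b|N_k \setminus N_i|}$ | $[0,1]$ |

Tversky with $(a,b) = (1,1)$ is exactly Jaccard and with $(0.5, 0.5)$
exactly Dice; the default $(1, 0)$ reduces to $|N_i \cap N_k| / |N_i|$, an
*asymmetric* index that is maximal whenever the candidate member's
neighborhood is contained in the exemplar's. This pushes densely connected
proteins toward the exemplar role. Dice and Ochiai are implemented for
rank-comparison purposes only (Dice orders pairs identically to Jaccard —
an exact algebraic fact, $J = D/(2-D)$ — so it would change nothing
downstream; Ochiai's concordance with Kulczyński is empirical, not an
identity, and the test suite measures it rather than asserting it).

Two conventions matter in practice:

* **Self-inclusion** (`include_self = TRUE`, default): each protein counts
  itself in its own neighborhood. Without this, two directly interacting
  proteins with no shared third partner would score 0 on every index —
  contradicting the premise that interacting proteins are candidates for
  the same module. The flag is recorded in output metadata.
* **Empty neighborhoods** score 0 whenever a denominator would vanish.

Neighborhoods are computed on the *induced* network (after overlaying the
expression data), not the full published network, since that is the graph
the clustering actually sees.

### Fusing the two similarities

Two fusion modes produce the final directed similarity $s(i,k)$ on
candidate pairs:

* **Product:** $s(i,k) = s_T(i,k) \cdot s_{DP}(i,k)$. Topology acts as a
  damping factor; the sign of $s_{DP}$ is preserved. (A sensitivity flag
  can clamp negative $s_{DP}$ at 0 first; by default a negative similarity
  damped toward 0 simply becomes less unfavourable.)
* **Linear combination:** $s_{DP}$ is first min--max rescaled to $[0,1]$
  over all candidate pairs,
  $\hat s_{DP} = (s_{DP} - \min)/(\max - \min)$, then
  $s(i,k) = \beta\, s_T(i,k) + (1-\beta)\, \hat s_{DP}(i,k)$ with
  $\beta \in [0,1]$ (default 0.5; the standard sensitivity grid is
  $\beta \in \{0.25, 0.5, 0.75\}$). A constant $s_{DP}$ collection rescales
  to 0.5 by convention. The min and max are taken over the candidate-pair
  set — the same set the clustering sees.

The six standard method variants are available as presets: `jac_p`,
`kul_p`, `tve_p` (product) and `jac_lc`, `kul_lc`, `tve_lc` (linear
combination).

### Candidate pairs and the preference

Similarity is only defined for *candidate pairs*: genes whose proteins
interact directly (`pair_policy = "adjacent"`, default) or lie within
shortest-path distance 2 (`"within2"`). All other pairs are absent and
behave as $-\infty$ in the clustering — they are not zeros. The default is
distance 1 because the association indices already reward shared
neighbors, and distance-1 keeps the similarity graph sparse; `within2`
produces larger clusters and, on the synthetic benchmark below, cleaner
convergence (one exemplar can cover a whole planted module).

Every gene's self-similarity is set to a single shared preference $c$,
chosen so that only 1 % of all directed candidate-pair similarities fall
at or below $c$ (linear-interpolation percentile). A uniformly low
preference gives every gene the same modest prior chance of becoming an
exemplar, so cluster count emerges from the data. Whether "all gene pairs"
means candidate pairs or all $n^2$ pairs is ambiguous; we use candidate
pairs — the only pairs with defined similarity — and record the choice in
metadata.

### Affinity propagation

Clustering runs the standard responsibility/availability message-passing
updates, restricted to the sparse candidate-pair support (memory is
O(candidate pairs)):

$$r(i,k) \leftarrow s(i,k) - \max_{k' \ne k}\left[a(i,k') + s(i,k')\right]$$
$$a(i,k) \leftarrow \min\Big\{0,\; r(k,k) + \sum_{i' \notin \{i,k\}} \max(0, r(i',k))\Big\},
\qquad a(k,k) \leftarrow \sum_{i' \ne k} \max(0, r(i',k))$$

both damped by $\lambda_d$ (default 0.7; valid range $[0.5, 1)$).
Convergence is declared when the exemplar set is unchanged for
`conv_window` sweeps (default 200) within `max_iter` (default 2000); a
non-converged run returns a flagged best-effort result with a warning
rather than failing. These are message-passing defaults tuned for sparse
graphs and all configurable; they are recorded in output metadata.

Numerical choices:

* a tiny deterministic jitter (scale $10^{-12}$, seeded) breaks exact
  similarity ties, as in reference implementations;
* final assignment maximizes $a + r$ per gene; genes whose chosen exemplar
  did not declare itself one are reassigned to their best self-declared
  exemplar, or become singletons if none is reachable;
* the result is always a partition — member sets are disjoint and cover
  every clusterable gene. Isolated nodes can form no candidate pair; they
  are retained in the dataset, excluded from clustering, and counted.

On small instances the exhaustive maximizer of the net-similarity
objective $\sum_i s(i, e(i))$ is tractable, and the test suite uses it as
an independent oracle: affinity propagation never exceeds the optimum and
attains it in the large majority of seeded random block instances. The
residual misses are near-tie exemplar choices — expected behaviour for an
approximate maximizer, not a defect.

### Activity, ranking, selection

A subnetwork's activity in a sample is the sum of its member genes' LLRs,
$A(\mathcal G) = \sum_i \lambda(x_i)$ — aggregated probabilistic evidence,
additive over any partition of the members. Clusters are ranked by the
absolute $t$ score of their activity between phenotypes (markers may be
risk- or protective-directional), ties broken by the smaller exemplar
identifier, and the top $K$ (default 50) become the marker set. Marker
sets serialize to GMT (gene-set standard) and to JSON with scores and full
provenance: configuration, seed, input content hashes, package version.

## Evaluation protocols

* **Size statistics** — mean member count and number of unique genes of
  the top markers.
* **Discriminative-power curve** — mean of the top-$K$ absolute activity
  $t$ scores for $K \in \{10, 20, 30, 40, 50\}$; non-increasing in $K$ by
  construction.
* **Cross-dataset rescoring** — markers discovered on dataset A keep their
  ranking but have activities and $t$ scores recomputed on dataset B, with
  LLR parameters re-fit there; member genes unmeasured in B are dropped per
  marker (counted), markers losing all genes are removed (counted).
* **Marker overlap** — Jaccard between the unions of member genes of two
  marker sets (a containment variant is available; the definition used is
  recorded). Gene-level overlap is the default because subnetwork-level
  matching would conflate clustering granularity with reproducibility.
* **Classification** — repeated stratified five-fold cross-validation
  (default 100 random partitions), linear discriminant analysis on marker
  activities, AUC per repeat from the pooled out-of-fold decision scores,
  mean and dispersion over repeats. AUC uses the exact rank (Mann–Whitney)
  formula with a fixed score direction, so null calibration is unbiased.
  When the pooled covariance is singular, a diagonal discriminant with
  variances shrunk toward their mean (intensity $p/(p+n)$) stands in.
  When markers transfer to an evaluation dataset, LLR parameters are re-fit
  on each training fold, so no test-sample information enters the features.

## The synthetic benchmark

`synthetic_spec()` describes a planted-partition network with
class-conditional Gaussian expression: modules of genes connected with
probability $p_\text{in}$, background pairs with $p_\text{out}$, and a
subset of *disease modules* whose genes gain a mean shift of $\Delta$
(units of the within-class SD) in phenotype 1. All randomness flows from
one master seed through named substreams (network, expression, folds), so
instances are exactly reproducible. The generator writes standard files
(expression TSV, label TSV, edge list, truth JSON) so the whole pipeline
can be exercised through its public file interfaces.

The benchmark conditions used by the test suite and the acceptance script
are the generator defaults: 300 genes in 30 modules of 10, $p_\text{in} =
0.6$, $p_\text{out} = 0.01$, 3 disease modules, $\Delta = 1.5$, 50 samples
per class, 10 seeds. Recovery is the Jaccard overlap between the union of
top-marker genes and the union of planted disease genes, with $K$ set to
the number of planted disease modules — ground truth defines how many
markers a perfect method would need, whereas the operational default
$K = 50$ would select every cluster and make recovery a constant. Held-out
classification uses 10 random five-fold partitions per seed; the null
calibrations use 1000 genes and $n = 200$ samples with 100 partitions.
These problem sizes are the package's benchmark definition and are stated
here so results are interpretable.

What the generator emulates: dense modules against a sparse background,
two-class Gaussian expression matching the LLR model's assumption, planted
effect sizes. What it does not: probe-level effects, batch structure,
heavy-tailed noise, degree-correlated expression, or the many-to-many
probe/protein multiplicities of real platforms (a power-law degree
multiplier is available, but realism of microarray noise is out of
scope). Passing recovery tests therefore demonstrates correctness of the
machinery under the model's own assumptions, not performance on real
cohorts.

### A measured caveat: recovery is not monotone in the planted effect

One property one might expect — recovery improving as $\Delta$ grows —
does **not** hold under these conditions, and the acceptance suite
measures the fact rather than hiding it. Ranking saturates early: even at
$\Delta = 0.5$ a 10-gene module's summed-LLR activity separates the
classes decisively, so the top markers are already the disease modules.
Meanwhile cluster *purity degrades* with $\Delta$: for a mixed pair
(background gene $i$, disease gene $k$) the fused similarity grows with
$t_k$ whenever $\alpha < 1/\sqrt 2$ (the summed profile dilutes to roughly
$t_k/\sqrt 2$, leaving $s_{DP} \approx t_{ik} - \alpha t_k + \alpha t_i$),
so strong disease genes attract their background neighbors into the
cluster. At the default $\alpha = 0.5$, stronger planted signal therefore
means larger, less pure top markers and a lower recovery Jaccard. This is
a real property of the similarity — the same mechanism that lets markers
grow around strongly discriminative genes — not an implementation
artifact.

## Known limitations

* Affinity propagation is an approximate maximizer; on near-tie instances
  it can converge to a slightly suboptimal exemplar choice, and on some
  dense adjacent-policy graphs it oscillates and returns a flagged
  best-effort clustering.
* With the `within2` policy clusters may be disconnected on the raw
  interaction graph; they are kept intact (connectivity is reported, not
  enforced).
* Duplicate probes are collapsed by mean; a protein mapped by several genes
  keeps the most variable one. Both are deterministic, label-independent
  conventions for gaps the data formats leave open, and both are flagged
  in output metadata.
* The preference quantile, candidate-pair radius, and $\alpha$ interact:
  very dense networks with a low preference can collapse into few large
  clusters. The similarity-distribution plot (`autoplot()` on the
  similarity graph) is the quickest diagnostic.
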