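---
title: "Transcriptogram analysis: model, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Transcriptogram analysis: model, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(transcriptogram)
```

## The method in one paragraph

A transcriptogram analysis replaces gene-level differential expression with
a *systems-level* view. Genes of a protein–protein interaction (PPI) network
are first seriated onto a line so that genes whose products are likely to
collaborate in a biological function sit at nearby positions. Expression is
then projected through a sliding window along this ordering: the value at
position $i$ for sample $s$ is the mean log-CPM of the genes at positions
$i-r \dots i+r$. Because the window aggregates functionally related genes,
coordinated shifts of whole biochemical systems that are too subtle at the
single-gene level become detectable, and noise that is independent across
genes averages out. Each position is tested case-versus-control; maximal
runs of significant, same-direction positions are *differentially expressed
clusters* — contiguous stretches of the ordering, hence candidate
biochemical systems. Clusters are then characterized by their induced PPI
subnetworks (inner/outer connectivity), by hypergeometric GO
over-representation, and by dendrograms over the enriched terms built from
pairwise Jaccard similarity of their gene sets.

## Gene seriation

The ordering is obtained by minimizing the **weighted linear arrangement
cost** with unit weights,

$$C(\pi) \;=\; \sum_{(u,v) \in E} \bigl|\pi(u) - \pi(v)\bigr|,$$

where $\pi$ maps genes to positions $1..N$. Published transcriptogram work
inherits its ordering from earlier simulation studies and does not write
down a closed-form objective; we adopt the linear arrangement because it has
the same qualitative goal (interacting genes adjacent), is well defined, and
is brute-force checkable on small graphs. `ordering_cost()` is the single
cost interface, so a windowed-neighbourhood cost could be substituted
without touching the optimizer.

Minimizing $C$ is NP-hard, so `order_genes()` runs **simulated annealing**
over pairwise position swaps:

* start from the spectral ordering (genes sorted by their Fiedler-vector
  coordinate of the graph Laplacian, per connected component) — a good
  seriation heuristic that already concentrates communities;
* `n_steps = 200 N log N` proposals per component;
* the initial temperature is calibrated on a 100-proposal probe so that a
  median uphill move is accepted with probability about one half;
* geometric cooling by a factor 0.995 every $N$ proposals;
* the best permutation ever visited is returned, so the final cost never
  exceeds the initial one (anytime property).

Disconnected networks are annealed component by component, largest first,
each component keeping a contiguous block of positions; ties everywhere
break on the lexicographic gene identifier, so a seed fully determines the
result. On every connected graph with up to 7 nodes the annealer reaches the
enumerated exact optimum in practice (the test suite checks a rate of at
least 90% over five seeds per graph; the observed rate is 100%).

## Window projection and position tests

`window_average()` truncates windows at the ends of the list — the ordering
is a line, not a circle — which keeps the radius-0 identity exact: at
$r = 0$ the profile *is* the reordered expression matrix. The conventional
radius for a human-scale interactome (about 9000 ordered genes) is $r = 80$,
a window of 161 genes or roughly 2% of the positions, and that is the
package default. For the 300-gene synthetic demo we use $r = 5$ (window of
11, 3.7% of positions), keeping the window well below the planted module
size of 50 so that module boundaries stay sharp.

Each position is tested with the empirical-Bayes **moderated t** of limma:
per-position residual variances $s_i^2$ on $d$ degrees of freedom are shrunk
toward a prior $(d_0, s_0^2)$ fitted by moment matching on the scaled-F
distribution of the $s_i^2$, giving the posterior variance

$$\tilde s_i^2 = \frac{d_0 s_0^2 + d\, s_i^2}{d_0 + d},$$

and $t_i = \Delta_i / (\tilde s_i \sqrt{1/n_1 + 1/n_2})$ on $d_0 + d$
degrees of freedom. `moderated_t()` exposes $d_0$ for its two analytic
limits ($d_0 = 0$: ordinary pooled t; $d_0 = \infty$: shared variance),
which the tests compare against direct-formula oracles. Some descriptions of
the approach mention a Fisher test in the same breath as limma; the two
cannot both be literal, and this package implements the moderated-t route —
it is what the limma machinery actually computes — with no Fisher
combination anywhere.

P-values are Benjamini–Hochberg adjusted across positions and clusters are
called at adjusted $p \le 0.001$. The threshold is read as applying to the
*adjusted* value since BH is specified for the same step. `call_clusters()`
merges same-direction runs separated by at most `gap` non-significant
positions (default 0); an opposing significant run always blocks a merge. A
cluster's gene set is exactly the genes positioned inside its interval — the
window half-width is *not* added back, a deliberate choice that keeps
membership unambiguous at the cost of possibly clipping a few boundary
genes whose windows leak signal outward.

Windowed values at nearby positions are strongly dependent. BH control is
robust under this kind of positive dependence, and the null-simulation
battery (50 runs, 600 positions, 6 vs 6 samples, no planted effect)
empirically yields zero called clusters in at least 95% of runs.

## Cluster network statistics

"Connections" are counted as **edges, once each**: `inner` edges have both
endpoints in the cluster, `outer` exactly one, and the average connectivity
is $\langle k\rangle = (\mathrm{inner} + \mathrm{outer})/n$. An isolated
triangle therefore has $\langle k\rangle = 1$, not 2 — the toy examples in
the test suite pin this semantics. Interactome coverage is the fraction of
network genes inside at least one cluster (union semantics).

When two analyses share one ordering (verified by an MD5 checksum over the
(gene, position) pairs), `match_clusters()` relabels the second analysis by
positional overlap: each cluster inherits the label of the
largest-overlap counterpart (ties toward the leftmost), and clusters with no
overlap — or whose best label was already claimed — receive fresh capital
letters left to right. Matching is driven by positions, not gene sets,
mirroring how cluster bars are compared across time intervals; a
mixed-direction successor simply appears as two separate clusters whose
split the match table documents.

## Enrichment and term dendrograms

Per cluster, `ora()` computes the upper-tail hypergeometric probability of
the observed term overlap against the universe of **annotated genes of the
ordering** (not the whole genome — using the genome would overstate
enrichment for every term). Annotations are taken as given, with no GO-DAG
propagation: the input is expected pre-propagated, which keeps the universe
well defined. BH adjustment is applied across the tested terms; the default
significance cutoff is adjusted $p \le 0.05$ (the choice is configurable —
published analyses do not print the value they used). Each enriched term
carries its occupation rate (overlap / term size) normalized by the
cluster's maximum rate, the quantity term-dendrogram figures encode as node
colour.

`term_dendrogram()` agglomerates terms by average linkage on the distance
$1 - J$, $J$ the Jaccard index of universe-restricted term gene sets, and
reads groups at the conventional 0.25-Jaccard cutoff (height 0.75). Average
linkage is chosen for robustness to single shared genes (no linkage is
named in published descriptions); ties break by term identifier. Trees are
exported as Newick plus a plain attribute table rather than rendered.

## Sample grouping and markers

`pca_samples()` runs PCA with samples as observations and centred,
unscaled genes as variables, retaining the smallest component count whose
cumulative variance reaches the target (default 0.95).
`cluster_samples()` applies Ward-linkage hierarchical clustering to the
retained scores and picks $k \in [2, k_{max}]$ maximizing the relative loss
of within-group inertia between consecutive cuts,
$\Delta W(k) / \Delta W(k{+}1)$ — the criterion behind automatic cluster
detection in principal-component clustering. We deliberately skip the
optional k-means consolidation step so that the assignment is
deterministic.

`marker_tests()` runs all pairwise group comparisons per marker with a
common pooled standard deviation (the behaviour of `pairwise.t.test`),
BH-FDR *within each marker across its pairs* (the smallest defensible
family; the alternative — one family across all markers — is stricter but
not what a per-marker trajectory plot tests), and flags significance at
adjusted $p \le 0.01$. Default marker sets ship with the package:
MSI1/NES/NOTCH1/SOX1 for neural progenitors and
TH/NEUROD6/DCX/RBFOX3/GAD1/GAD2 for neurons. A sample is never assigned to
two groups; analyses that reuse a single boundary sample in two intervals
must construct those groups explicitly.

## The synthetic study

The generators provide ground truth the real data cannot. `gen_network()`
draws a planted-partition graph; `gen_expression()` draws control values
from $\mathcal N(\mu_g, \sigma)$ with per-gene baselines
$\mu_g \sim \mathcal N(6, 2)$ (a typical log-CPM spread) drawn once, and
adds each DE module's signed effect to its genes in the case samples;
`gen_annotation()` emits one term per module plus random extra terms, with
a `noise_frac` dial that reassigns annotations at random (at 1.0 the
annotation–module link is destroyed, a negative control for enrichment
recovery); `gen_timecourse()` shifts whole sample blocks by a common drift
per block. Every generator is a pure function of its parameters and seed.

The reference scenario (`gen_demo()`): 6 modules × 50 genes,
$p_{in} = 0.25$, $p_{out} = 0.01$, modules 2 and 5 perturbed by +1 and −1
log-CPM, noise sd 0.5, six case and six control samples, analysis radius 5.
Effect size 1.0 at sd 0.5 is a strong but realistic treatment effect on the
log2 scale (a twofold change against 40% sample-to-sample noise); the
window averages ~11 genes, so module interiors reach very large moderated t
while unperturbed regions stay flat. Under these conditions the pipeline
recovers ≥ 80% of planted DE genes inside correctly-signed clusters with
≤ 5% false inclusion (observed: ≈ 98–99% and ≈ 3%).

What the synthetic data does **not** emulate: count-level sampling noise
and library-size effects (values are Gaussian on the log-CPM scale by
design, since the statistics operate there), correlated gene-gene noise
within modules, hub-dominated degree distributions, annotation
incompleteness and DAG structure. Passing the recovery batteries therefore
demonstrates the pipeline's logic and statistics, not its behaviour on raw
RNA-seq; real analyses must supply properly normalized log-CPM input.

## Numerical and degenerate-input choices

* Windows truncate, never wrap; a radius spanning the whole list warns and
  returns the global per-sample mean everywhere.
* Zero residual variance at every position is an error (degenerate input),
  not a silent division by zero.
* Duplicate PPI records and both edge orientations collapse keeping the
  maximum score; self-loops are dropped and counted; the score threshold is
  inclusive (≥).
* Genes present in only one of network/expression are dropped with logged
  counts before any analysis (there is no principled imputation for them).
* All tabular output is written with fixed 15-significant-digit formatting,
  so identical configurations reproduce outputs byte for byte.

## Problem sizes

The bundled batteries run at deliberately modest sizes — 300-gene demo
networks, 600-position null simulations, 24-sample time courses, exhaustive
graph enumeration up to 7 nodes — chosen so that the complete suite
executes in a few minutes on a single core while still exercising every
code path at the study's statistical operating point. Full-scale analyses
(9000+ genes, radius 80) use exactly the same functions; only the annealing
step count grows, as $200 N \log N$.

## Known limitations

* The seriation optimum is only certified on small graphs; on large
  networks annealing gives a good, reproducible, but not provably optimal
  arrangement, and different seeds give different (equally usable)
  orderings.
* Cluster boundaries inherit the window's smearing: a cluster interval can
  extend a few positions beyond the underlying module, and very close
  modules with the same direction can merge.
* The moderated-t route treats window means as the analysis unit;
  position-to-position dependence is handled only through BH's robustness,
  not modelled.
* Enrichment assumes pre-propagated annotations and a shared identifier
  namespace between network, expression and annotation inputs.
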