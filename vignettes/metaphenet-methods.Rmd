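---
title: "Methods: condition-specific genes and their network centrality"
author: "metaphenet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: condition-specific genes and their network centrality}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(metaphenet)
```

# The analysis in one page

`metaphenet` asks two questions of a multi-condition community omics data
set keyed by EC-number gene functions:

* **Which gene functions are signatures of each condition?** Detected
  metabolites and over-expressed genes are jointly embedded in a master
  metabolite–reaction network; the smallest subnetwork connecting them
  implicates a set of genes per condition, and genes implicated under
  exactly one condition are that condition's unique (signature) genes.
* **How central are those signatures to the community's overall
  transcriptional organisation?** A co-expression network is inferred across
  all conditions from mutual-information Z-scores (CLR), and the signature
  genes' betweenness and degree are compared with network-wide baselines.

The sections below describe each model, its assumptions, the tunable
parameters, and the numerical conventions, in the order the pipeline runs
them.

# Synthetic study generator

No public multi-condition soil data set couples expression, metabolite
lists and a reaction network with known ground truth, so the generator is a
first-class module: it defines the study conditions under which every
downstream claim in this package is tested.

**Design.** Four conditions (`dry`, `wet`, `glycine`, `control`), three
sites, three replicates per condition and site by default — the layout of a
perturbed-microcosm experiment. All outputs are pure functions of the
configuration: each artifact (network wiring, expression, detections) draws
from its own RNG stream derived from `seed`, so adding one generator never
perturbs another's output.

**Master network.** A hub metabolite (the community's common currency) is
joined to `nCoreMetabolites` core metabolites by dedicated linker
reactions; each non-control condition gets a planted chain of
`nResponsivePerCondition` reactions walking away from the hub, whose unique
EC labels are the planted responsive genes and whose intermediate
metabolites are the planted condition-specific terminals. Remaining
reactions and metabolites are random background wired as pendant structure:
a background reaction anchors on one already-connected metabolite and
otherwise touches only background metabolites. This guarantees (i) a
connected map covering every metabolite and (ii) unique shortest paths
between planted terminals, which is what makes noiseless recovery exact
rather than merely likely. Background reaction degree is
`1 + Poisson(meanReactionDegree/2 - 1)` per side, so the expected edge
count is about `nReactions * meanReactionDegree`.

**Expression.** Baseline log2 abundance is drawn Normal(6, 1) per gene —
log-normal on the linear scale, matching the right-skewed abundance
distributions typical of community transcriptomes. Genes of a planted
module (disjoint modules, placed on filler genes so module and responsive
signals never overlap) share a per-sample latent factor with weight
`latentStrength` (default 2). Responsive genes gain
`log2(responsiveFoldChange)` (default fold 4, i.e. +2 log2 units) in their
condition only. Replicate noise is Normal(0, `noiseSd`) with default 0.5.
Values are truncated at zero; with the default baseline this affects
essentially no entries.

**Detections.** One shared draw keeps each core metabolite with probability
`metaboliteDetectionRate` (default 0.9); every condition receives that same
core plus its planted terminals. This mirrors assays in which the detected
compound panel is nearly identical across conditions, so condition
specificity enters through expression, not metabolite presence.

**What the generator does not emulate:** taxonomic structure, compositional
effects, count noise, batch effects, or correlated metabolite/transcript
noise. Passing tests therefore demonstrate correctness of the algorithms
under a clean, favourable signal model, not performance on raw field data.

# Over-expression calling

Log2 fold change is the difference of group means; the test is Welch's
two-sample t on log2 values (robust to unequal variances, sensible for
already-normalised expression), with Benjamini–Hochberg adjustment. A gene
is over-expressed when `log2FC >= log2(fcThreshold)` **and**
`q <= qThreshold`, both inclusive. Defaults are fold 2 and q 0.05 — the
standard omics thresholds — and both are explicit configuration echoed into
the run manifest.

Degenerate inputs follow documented conventions rather than erroring:
fewer than two replicates in a group gives p = 1 with an
`insufficientReplication` flag; within-group variances are floored at
1e-12, so exactly identical groups give p = 1 while constant but separated
groups are called with vanishing p.

# Minimal subnetworks and condition-unique genes

"Minimal subnetwork" is formalised as the **minimum-edge Steiner tree** on
the undirected bipartite metabolite–reaction graph. Terminals are the
detected metabolites found in the network (missing ones are reported, not
dropped) plus every reaction carrying an over-expressed EC. Reaction
directionality is deliberately ignored: the integration asks what is
*connected*, not what is thermodynamically feasible, and an undirected
reading keeps the problem well-posed without stoichiometry.

The production algorithm is the classical metric-closure 2-approximation:
all-pairs shortest distances among terminals, a deterministic Kruskal MST
of that closure (ties broken by lexicographic node pair), expansion of each
closure edge into a shortest path, and iterative pruning of non-terminal
leaves. Terminals split across master components yield a Steiner forest
plus a warning — environmental data routinely contain unreachable
metabolites, and failing outright would be wrong. An exact oracle
(`exactSteinerOracle`) enumerates non-terminal subsets by increasing size
and certifies the heuristic in tests: never better than optimal, and within
the proved 2x bound (observed worst case across random instances ~1.3x).

Per-condition gene sets are the union of implicated genes over sites
(union, not intersection: a pathway active at any site belongs to the
condition), and control-condition subnetworks — built from the shared
metabolite core alone — participate in uniqueness calling so that genes
reachable from the core are never mistaken for condition signatures. A gene
is condition-unique iff it occurs in exactly one condition's set.

# CLR co-expression inference

Mutual information is estimated with the plug-in entropy of binned
profiles. The default binning is **B-spline fuzzy membership** (order 3
over 10 bins — the canonical CLR configuration): each sample spreads unit
mass over up to 3 adjacent bins, which smooths the hard-bin estimator's
discretisation noise at these sample sizes (36 samples by default).
Hard equal-width binning is retained as a cheap, exactly-analysable
alternative and is the estimator used in closed-form tests, where plug-in
MI equals the hand-computed discrete value. Profiles are rank-transformed
per gene first (switchable) to stabilise against outliers; constant genes
are excluded with a warning. All pairwise joints are computed in a single
cross-product of stacked weight matrices, so the cost is one
`(genes x bins)^2` matrix product rather than a per-pair loop.

Two standardisations of the MI matrix are provided because the field's
descriptions genuinely diverge:

* `per_gene` (default, canonical CLR): `z_i(j) = max(0, (MI_ij - mean_i) /
  sd_i)` against gene i's own off-diagonal background, combined as
  `Z_ij = sqrt(z_i(j)^2 + z_j(i)^2)`.
* `global`: every score standardised against the mean and sd of all
  off-diagonal MI values — the literal reading of a cutoff "standard
  deviations above the mean of all mutual information scores".

Which of the two a given published network used is often unknowable; both
are first-class modes and the default follows the canonical CLR definition.

Edges are selected either by threshold (`Z >= 4.20` inclusive — an
upper-tail standard-normal probability of 1.3e-5, comfortably below 5e-5)
or as the top-k pairs with lexicographic tie-breaking for bit-identical
networks. Both paths exist because "rank then select k edges" and
"threshold then count" are different operations that coincide only without
ties. Centrality analysis runs on the largest connected component (size
ties broken toward the component containing the smallest gene id), and a
least-squares line on the log-log degree distribution summarises scale-free
structure (slope = negative exponent, R²).

# Centrality conventions

Betweenness is Brandes' algorithm on the undirected unweighted graph,
normalised by `(n-1)(n-2)/2` with endpoint pairs excluded — the convention
under which published community co-expression networks of ~1,000 nodes show
group means in the 0.006–0.06 range, as the bundled reference table does.
With fewer than 3 nodes betweenness is defined as 0. Group summaries use
arithmetic means, fold = group mean / network mean, and **strict**
inequality for below-mean counts; these conventions reproduce the bundled
table's published aggregates (wet mean betweenness 0.007, mean degree 6,
2/3 below-mean; glycine mean betweenness 0.008, mean degree 3, 4/8 and 5/8
below-mean) exactly. Display rounding is to 3 decimals; raw precision is
kept internally.

The centrality-ratio scatter uses `log2(betweenness / median betweenness)`
against `degree / median degree`; zero-betweenness genes are flagged and
floored at one tenth of the smallest positive value so they remain
plottable, and a zero median triggers the same documented floor.

Neighbourhood subnetworks take a seed set (typically one condition's unique
genes), add every gene adjacent to at least one seed, and induce the edge
set. With `dropIsolatedSeeds`, a seed whose closed neighbourhood shares no
node with any other seed's closed neighbourhood is excluded together with
its exclusive neighbours — the rule used in practice to drop a signature
gene lying far from the rest of its cluster.

# Pipeline, determinism and problem sizes

`runPipeline()` sequences simulate/load → differential → integration → CLR
→ centrality, writes each stage's outputs (TSV, SIF, GraphML, JSON), and
ends with a manifest echoing every configuration default, hashing every
output, and recording timings and captured warnings. Identical
configuration reproduces identical hashes; no stage consumes global RNG
state. A stage failure retains partial outputs and records the failure
point.

The test suite and acceptance script exercise the pipeline at deliberately
modest sizes — around 80 genes, 30 metabolites, 25 reactions, 36 samples,
with 20-seed replications for stochastic properties and 100 random
instances for oracle comparisons — chosen so the full suite completes in
well under a minute while every code path, including forests, ties and
degenerate inputs, is still reached.

# Known limitations

* The Steiner formulation minimises edges on an undirected graph; it cannot
  distinguish thermodynamically infeasible connections, and co-optimal
  trees are resolved by lexicographic convention, not biology.
* MI estimation at 36 samples carries positive bias (visible under
  independence); CLR's background standardisation removes most of it, but
  absolute MI values should not be compared across data sets with different
  sample counts.
* The uniqueness call is sensitive to the condition universe: adding a
  condition can only shrink unique sets.
* The generator's clean additive log-normal model is favourable to every
  stage; real soil data with compositional noise, shallow coverage and
  partial EC annotation will degrade recovery in ways the tests do not
  measure.
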