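---
title: "Methods: semantic network propagation and ego decomposition"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: semantic network propagation and ego decomposition}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`egosig` turns a phosphoproteomics fold-change table and a protein
interaction network into a small set of functional modules — an "active
signaling signature". This vignette documents the model, the parameters
that matter, the numerical choices, and what the synthetic test data do and
do not demonstrate.

## The base network

The interaction network is an undirected simple graph restricted to
proteins carrying at least one Gene Ontology term. Edge weights are simGIC
semantic similarities over ancestor-closed annotation sets: with
information content $IC(t) = -\log_2(n_t / n)$ (bits; $n_t$ counts proteins
annotated to $t$ or a descendant),

$$\mathrm{simGIC}(a,b) =
\frac{\sum_{t \in A \cap B} IC(t)}{\sum_{t \in A \cup B} IC(t)} \in [0,1].$$

All three GO namespaces hang under one virtual root with $IC = 0$, so
similarity is computed jointly across namespaces rather than averaged per
namespace. The logarithm base is 2; any fixed base cancels in the simGIC
ratio and only changes reported IC values. Terms that annotate no protein
in the corpus keep infinite IC — they can never occur inside a closed
annotation set, so no downstream quantity depends on them.

Hub bias is corrected by Laplacian (square-root degree) normalization,
$w_{ij} \leftarrow w_{ij} / \sqrt{d_i d_j}$ with weighted degrees $d$ taken
on the raw weights. The raw degrees are stored on the network object so the
transformation is exactly invertible (a property the test suite checks to
1e-12). Nodes with zero weighted degree cannot be normalized and are
dropped with a warning.

The null model is an ensemble of degree-preserving rewirings (double-edge
swaps, at least $10\,|E|$ attempted swaps per replicate, simple-graph
constraint enforced). Because rewiring creates new pairs, every rewired
edge is re-weighted by the simGIC of its new endpoints and the replicate is
re-normalized. Pairwise similarities are computed once into a cached matrix
and shared by the real network, the ensemble, the semantic profiles and the
ego stages — the results are identical to recomputation, only cheaper.

## Seed selection and layered propagation

Sites are aggregated to protein level per direction: the maximum |LFC| and
maximum functional score among a protein's direction-consistent sites. A
protein with sites of both signs legitimately appears in both directions.
Proteins are partitioned into tyrosine kinases, other kinases and
substrates (tyrosine kinases take precedence when a protein is on both
lists). Kinase layers keep proteins with a functional score whose |LFC|
and score both exceed their layer's 20th percentile; substrates must exceed
the 80th percentile of both. Percentiles are linear-interpolation quantiles
computed within each layer and direction — the wording of the underlying
rule leaves both the "score and LFC" conjunction and the per-layer scope
ambiguous, so both cuts are applied per layer, and both thresholds are
user-configurable (a top-N mode replaces them entirely). Strict `>`
comparisons mean a degenerate layer of identical values would be emptied;
that case falls back to keeping the layer, with a warning.

Restart probabilities are |LFC| values min–max scaled within the layer.
The layer minimum maps to a floor of 0.01 rather than 0: a zero restart
weight would silently delete a seed the user explicitly provided. The
scaled weights are normalized to a probability vector over all network
nodes.

The walk iterates $p \leftarrow d\,T p + (1-d)\,r$ to its fixed point,
where $T$ column-normalizes the Laplacian-normalized weights (the
normalized weights are symmetric but not stochastic; column normalization
is the conventional way to make a walk operator of them) and $d = 0.85$ is
the continuation probability, the same damping used at every later stage.
Convergence is declared when the L1 change drops below 1e-10 (at most
10^4 iterations); on graphs of a few hundred nodes this agrees with the
direct linear-system solution to well below 1e-8.

Each layer's walk is repeated with the identical restart vector on every
ensemble replicate. A node survives if its real score strictly exceeds its
null score in more than a fraction $1-\alpha$ of replicates
($\alpha = 0.05$: more than 950 of 1000); ties count against retention.
The surviving nodes of any layer, plus all seeds of the direction
(regardless of score), induce the coarse direction network. A protein
present in both direction networks is kept only where its mean score
across the configured layers (zeros included for layers that did not score
it) is larger; seeds are never evicted from their own direction, a protein
seeded on one side only always resolves to that side, and exact ties
resolve to the up network. The resolution step can be disabled.

## Ego decomposition

Every seed of a direction becomes an ego. Candidates are all nodes within
two steps inside the direction network. The semantic z-score
$(\mathrm{simGIC}(ego,j) - \mu_{ego}) / \sigma_{ego} > 1.64$ (the
one-tailed 95% normal quantile) filters candidates, using the ego's
precomputed network-wide similarity mean and population standard
deviation; the filter is applied uniformly to first- and second-order
candidates. A zero spread degenerates to a plain mean comparison, with a
warning.

Edges of the filtered subgraph are re-weighted — ego-incident edges take
$\mathrm{simGIC}(ego, j)$; all others take the mean of their endpoints'
similarities to the ego — and the subgraph is re-normalized. When more
than 5 neighbors survive, a one-hot restart walk runs from every member
and each member $j$ is placed at

$$x_j = 1000\,\log_2\!\big(2 - \mathrm{jsd}(p_{ego}, p_j)\big), \qquad
  y_j = 1000\,\log_2\!\big(1 + \mathrm{simGIC}(ego, j)\big),$$

with the base-2 Jensen–Shannon distance (base 2 keeps
$\mathrm{jsd} \in [0,1]$ and hence both coordinates in $[0,1000]$). A 2-D
Gaussian KDE with per-dimension Silverman bandwidth
$h_d = \sigma_d\,n^{-1/6}$ is fitted to the rescaled cloud and every
member is scored by the KDE's joint lower-tail CDF at its own coordinates
— for a Gaussian mixture this is exactly the mean over kernels of the
product of univariate normal CDFs, so no numerical integration is
involved. Members with CDF at or above the user threshold (default 0.85)
join the ego's supernode. This "joint upper-quantile region" reading makes
the user parameter act as a probability cutoff, which is the only
interpretation under which the conventional settings 0.85/0.9 are
meaningful; the selection rectangle published for this construction is a
single rectangle mass rather than a per-node score, so a per-node reading
had to be fixed here as a design decision. Degenerate clouds (all points
identical) select everyone, with a warning. Egos with 5 or fewer neighbors
skip decomposition and keep their whole functional ego network; an empty
selection collapses the supernode to the ego alone.

## The supernode graph and modules

For each pair of supernodes, the subgraph induced by the union of their
members is re-normalized; if the two egos are connected within it, one-hot
walks from each ego give an edge weight
$\mathrm{jsd}(p_{ego_A}, p_{ego_B})$ — small values mean strongly related
supernodes. Community detection needs similarity weights, so Leiden runs
on $1 - \mathrm{jsd}$ (rank-preserving, stays in $[0,1]$), with the
modularity objective, resolution 1, and a fixed seed recorded in the run
manifest. Isolated supernodes are dropped. Components with at least 4
supernodes are partitioned by Leiden; smaller components are kept whole as
modules — the published rules cover "≥ 4" and "< 3" and leave size-3
components unassigned, so they are kept whole here (the choice is
documented, and a resolution argument is exposed).

## Evaluation utilities

Over-representation uses the one-sided Fisher exact test (the
over-representation tail is the only sidedness under which enrichment
semantics make sense) with Bonferroni correction over the sets tested, and
fold enrichment as observed/expected. Module-versus-reference similarity
uses the Szymkiewicz–Simpson overlap coefficient
$|X \cap Y| / \min(|X|, |Y|)$ and its complement as a distance; the form
printed in the source describing this coefficient uses $|X \cup Y|$ in the
numerator, which contradicts the coefficient's name and can exceed 1, and
is treated as an erratum. `best_module_match()` discards modules below 10
proteins, since tiny modules inflate the coefficient.

## The synthetic study

The generator emulates every input format at toy scale with planted
structure: a random term DAG (three levels, leaf terms partitioned into
per-community pools), annotations drawn from a protein's own community
pool with probability `coherence` (0.9 by default), a stochastic block
model network (3 communities of 30; within-community edge probability 0.3,
between 0.01; a random spanning tree per community guarantees internal
connectivity), and a phospho table with 40 strong, functionally scored,
mixed-sign sites on one active community plus 10% weak noise sites spread
over all proteins. Pathway kinases are appointed inside the active
community and receive one strong site of each sign, mirroring the fact
that the kinases of a perturbed pathway are themselves modulated. All
generators are pure functions of their seed.

What passing tests on these fixtures show: that propagation, the empirical
filter, the semantic filter and the KDE selection jointly recover a
planted, semantically coherent community from sparse noisy seeds, and that
every stage honors its contracts. What they do not show: performance on
real interactomes (heavy-tailed degrees, annotation bias toward
well-studied proteins, correlated LFC/functional-score noise,
mass-spectrometry missingness), none of which the generator models.
Planted-community recovery is measured as the union of the largest module
of each direction, because the generator plants one signal with sites of
both signs — the up and down signatures are two halves of the same planted
pathway, and the dual-membership resolution deliberately splits shared
proteins between them.

## Problem sizes and determinism

Unit tests run on hand-built graphs of 2–16 nodes and a 36-protein study;
the end-to-end recovery property and the acceptance script use the default
90-protein study with 100-replicate ensembles over ten generator seeds —
sizes at which every quantity is exactly checkable against closed forms or
brute-force oracles. Every stochastic step (rewiring, Leiden refinement,
generators) is governed by an explicit integer seed, and identical inputs
with identical seeds reproduce module tables bitwise.

## Known limitations

Propagation is symmetric and undirected; no edge signs or directions are
modeled. Decomposition operates at protein, not phosphosite, resolution.
The up/down split is resolved by a hard rule rather than a joint model.
Identifier namespaces are taken at face value: gene-set collections whose
identifiers differ from the network's accessions need a user-supplied
mapping.
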