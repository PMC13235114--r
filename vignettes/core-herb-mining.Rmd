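---
title: "Mining core herb combinations from prescription corpora"
author: "HerbMiner authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mining core herb combinations from prescription corpora}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(HerbMiner)
```

## The problem

Traditional-medicine prescriptions for a given indication are sets of herbs
chosen under an implicit compatibility logic. Given two labeled corpora —
prescriptions aimed specifically at preventing disease recurrence and
prescriptions for general treatment of the same disease — the question is
which small combination of herbs forms the reproducible *core* of the
anti-recurrence formulations. HerbMiner answers it by running four
independent lines of evidence over the corpora and intersecting them:

1. **Association-rule mining** (Apriori) finds herb combinations that
   co-occur far more often than chance.
2. **Graph embedding and clustering** builds the weighted herb
   co-occurrence network, learns node embeddings with a graph-convolutional
   encoder, clusters them, and prioritizes clusters by a composite
   network/coverage score.
3. **Frequency banding** contrasts per-herb frequencies between the two
   groups.
4. A **random-forest classifier** measures how much each herb contributes
   to telling the two groups apart.

The treatment unit everywhere is the *prescription as a set*: dosages,
preparation and administration are deliberately out of scope, because every
statistic downstream is presence-based. Duplicate compositions within one
group are collapsed to a single record; the same composition appearing in
both groups is kept in each, since the two-group comparison needs it.

## Association rules

For an antecedent set $X$ and consequent set $Y$ ($X \cap Y = \emptyset$),
with $N$ prescriptions,

$$\mathrm{supp}(X \Rightarrow Y) = \frac{|\{p : X \cup Y \subseteq p\}|}{N},
\qquad
\mathrm{conf}(X \Rightarrow Y) = \frac{\mathrm{supp}(X \cup Y)}{\mathrm{supp}(X)},
\qquad
\mathrm{lift} = \frac{\mathrm{conf}}{\mathrm{supp}(Y)}.$$

`frequentItemsets()` is a from-scratch level-wise Apriori: candidates of
size $k$ come from joining frequent $(k-1)$-itemsets sharing a $(k-2)$
prefix and are pruned by downward closure before any counting. Support is
thresholded on integer counts with a $10^{-9}$ additive guard so rational
boundaries (a herb in exactly 1 of 5 prescriptions at `minSupport = 0.2`)
are inclusive, as intended, rather than at the mercy of floating-point
rounding. Default thresholds are support 0.08 and confidence 0.80 — low
enough to retain clinically meaningful but infrequent combinations, high
enough to demand near-implication — and rules are ranked by lift, ties
broken by confidence, then support, then the antecedent alphabetically.
Consequents default to a single herb (`rhsSize = 1`), the conventional
reading of a rule "combination ⇒ herb"; multi-herb consequents sit behind
the parameter. An undefined confidence (antecedent never observed) is
reported as an explicit no-support result, never as a number.

## The co-occurrence graph and its embedding

Herbs are nodes; an undirected edge joins two herbs iff some prescription
contains both, weighted by the count of such prescriptions. Isolated herbs
stay in the graph, so node order equals the vocabulary.

`gcnEmbed()` is a two-layer graph-convolutional encoder written directly in
dense linear algebra (the graphs here have a few hundred nodes, so dense
propagation is simpler and faster than sparse machinery):

$$Z = \hat{S}\,\mathrm{ReLU}(\hat{S} X W_1)\, W_2,
\qquad \hat{S} = \tilde{D}^{-1/2} (A + I) \tilde{D}^{-1/2},$$

with $A$ the weighted adjacency and $X$ the standardized weighted degree
(one scalar per node; `weightedDegree = FALSE` switches to the raw edge
count — weighted is the default because edge weights are the only
quantitative signal in the graph). Hidden and output widths default to 32
and 16. Training is self-supervised link prediction on the whole graph:
every observed edge is a positive pair, one uniformly resampled non-edge
per edge per epoch is a negative pair, pair scores are inner products
$z_i^\top z_j$, and the logistic cross-entropy is minimized by Adam
(learning rate 0.01, 200 epochs). No train/validation edge split is made —
the embeddings, not held-out link AUC, are the product. Gradients are
derived by hand; the loss trace is returned so divergence is visible, and a
non-finite loss aborts naming the epoch. On a graph with *no* non-edges
(tiny dense corpora) training proceeds on positives alone with a warning,
so the output contract holds for any valid input.

Two numerical notes. First, because the input feature is a scalar degree,
two nodes with identical degrees *and* degree-identical neighborhoods get
identical embeddings; real corpora never achieve that symmetry, but
perfectly symmetric toy graphs do. Second, all randomness (initialization,
negative sampling) flows from one seed argument, making embeddings
bit-reproducible.

## Clustering and cluster prioritization

`clusterEmbeddings()` runs K-means (10 restarts per K, deterministic seed
stream, Euclidean metric) either at a fixed K or over a range (default
2–10), selecting the K that maximizes the mean silhouette width. K = 1 is
rejected outright — the silhouette is undefined there. Silhouette ties
resolve toward the smaller K.

`scoreClusters()` rates each cluster on three components:

* **average degree** — mean weighted degree of members in the full graph;
* **intra-cluster density** — total intra-cluster edge weight divided by
  the member pair count $\binom{|c|}{2}$ (0 for singletons). Weighted mass
  can exceed 1; the normalization absorbs the scale;
* **coverage** — fraction of prescriptions containing at least one member
  (`minMembers` raises the requirement for a stricter reading).

Each component is min–max normalized across clusters (a constant component
maps to 0.5 everywhere, staying neutral instead of dominating), and the
composite is their unweighted mean — the aggregation formula is this
package's own choice, which is why the raw components are reported
alongside for audit. A one-cluster assignment therefore scores exactly 0.5.

## Two-group validation

`frequencyDifferential()` interprets "frequency variance" as the signed
difference of group frequencies in percentage points — band labels only
make sense on a bounded difference scale. The three bands partition the
positive axis with half-open intervals: high $(20, \infty)$, moderate
$(10, 20]$, slight $(0, 10]$, following the strict ">" of the high cut;
a difference of exactly 0 is a balanced slight record.

`rfDifferential()` trains a random forest (default 1000 trees, seed 123)
on the stacked binary matrix with the union vocabulary as predictors —
bootstrap resampling, $\sqrt{p}$ feature subsampling, Gini splits,
unlimited depth — and reports the out-of-bag error plus both importance
measures (permutation-based mean decrease in accuracy, and mean decrease in
Gini). Inputs are canonicalized (sorted vocabulary, stored row order) so
the report depends only on the corpora and the seed. A `minCount` floor
can drop very rare herbs from the predictors; the default keeps the full
union vocabulary.

## Consensus

`consensusCore()` intersects the rule-arm herb set (union of the top
`topN` rules by lift) with the cluster-arm set (members of the top
`nClusters` clusters by composite) and tags every herb in the union with
its evidence: `apriori`, `gcn`, `frequency_high` (high band *and* enriched
in the anti-recurrence group), and `rf_top` (inside the top-14 mean
decrease accuracy ranks — the widest rank window the underlying analysis
tradition cites). The final narrowing from a core spectrum to a handful of
herbs for wet-lab follow-up is a judgment call, not an algorithm, so the
package reports the full spectrum with provenance and
`rankConsensusHerbs()` orders it by evidence count (ties by frequency
difference) rather than silently truncating.

One default deserves its rationale: `selectRuleHerbs()` defaults to the
single top rule, but the *pipeline* pools the top 10 rules
(`top_n_rules = 10`). A single rule names at most its antecedent plus
consequent — typically 3–5 herbs — so an intersection against an 8-herb
cluster can never recover a full 8-herb module from one rule alone;
pooling a short head of the lift ranking lets the rule arm express the
same module the clustering sees, while still excluding the long tail.

## The synthetic generator

`generateTwoGroupCorpus()` builds each prescription from three independent
mechanisms whose union is the herb set:

1. **modules** — a planted co-prescription block activates with probability
   `activation_prob` (scaled by `group_bias` in the general group) and then
   includes each member independently with `inclusion_prob`;
2. **differential herbs** — included with group-specific marginal
   frequencies;
3. **background herbs** — each included with `background_prob`.

Sizes outside `size_range` are rejected and the prescription resampled
(rejection, not truncation, so within-prescription dependence survives);
more than 1000 rejections for one prescription aborts as an infeasible
configuration. One master seed streams all randomness, with sub-stage
seeds derived deterministically from it.

The reference conditions — the generator defaults — are: 210 herbs; one
planted 8-herb module (activation 0.6 anti / 0.3 general, inclusion 0.9);
three module herbs additionally differential at 60% vs 20% (a
40-point shift); background 3%; 150 + 120 prescriptions clamped to 5–20
herbs. Under these conditions expected prescription size is ≈ 12 herbs,
inside the observed 5–20 range of real recurrence-prevention corpora, and
the module's pairwise co-occurrence (≈ 0.6 · 0.9² ≈ 0.49) towers over the
background (≈ 0.03² ≈ 0.001), which is exactly the planted/background
contrast the mining stages are supposed to exploit.

What the generator does **not** emulate: herb-name synonymy and
misspelling (the lexicon path is exercised separately), dosage, prescription
size correlation with group, nested sub-formulas (a classical base formula
plus additions), and correlated background herbs. Passing the recovery
tests therefore shows the pipeline recovers *block-structured
co-prescription with marginal shifts*, not that it is robust to every
structure in historical corpora.

`generateNetpharmTables()` emulates screening-database exports: OB uniform
on 0–60%, DL on 0–0.5, SVM/RF scores on 0–1, with each record drawn on the
pass or fail side of the screening thresholds (OB ≥ 30, DL ≥ 0.18;
SVM ≥ 0.8, RF ≥ 0.7) according to `pass_fraction` — conditional draws give
the same distribution a rejection loop would, at deterministic cost.

## Problem sizes and test design

The test suite fixes its own scales: oracle-equivalence checks run 100
random corpora of up to 12 herbs and 20 prescriptions against an
exhaustive enumerator that shares no code with the level-wise miner;
recovery checks run the full pipeline under the reference conditions on
5 seeds and require the planted module in ≥ 4 of them (one seed is allowed
to fall to sampling noise); forest sanity uses 200–300 trees on 30–100
prescriptions per group. These sizes make the whole suite run in about a
minute while keeping every binomial tolerance at 3 standard deviations of
the relevant closed form.

## Known limitations

* The composite cluster score's equal weighting of its three components is
  a convention; with the raw components exposed, alternative weightings are
  a one-liner for the user, but the ranking shipped is the equal-weight one.
* Scalar degree input limits the encoder's expressiveness on
  degree-regular graphs (see above); richer initial features (e.g. rows of
  the adjacency) were deliberately not used so that the embedding remains a
  function of the network alone.
* Silhouette-selected K on embeddings of module-plus-background corpora
  usually lands at small K (the module cluster versus everything else)
  rather than a fine partition; the composite score, not K itself, is what
  identifies the core cluster.
* The random-forest OOB error depends on the bootstrap RNG; identical
  numbers across platforms require the same R RNG kind and seed, which the
  canonicalized inputs and the seed argument provide.
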