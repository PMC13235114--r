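# HerbMiner

HerbMiner identifies the **core herb combination** hidden in a corpus of
traditional-medicine prescriptions. Given prescriptions labeled as
*anti-recurrence* (formulated specifically to prevent disease recurrence,
e.g. of colorectal cancer) versus *general treatment*, it runs four
independent lines of evidence and intersects them:

1. **Apriori association-rule mining** on the prescription–herb incidence
   matrix. For antecedent X and consequent Y:
   `supp = P(X ∪ Y)`, `conf = P(X ∪ Y)/P(X)`, `lift = conf / P(Y)`;
   rules are mined level-wise with downward-closure pruning and ranked by
   lift (defaults: support ≥ 0.08, confidence ≥ 0.80, single-herb
   consequents).
2. **Graph-convolutional embedding** of the weighted herb co-occurrence
   network (edge weight = number of prescriptions containing both herbs):
   a two-layer encoder `Z = Ŝ · ReLU(Ŝ X W₁) · W₂` with
   `Ŝ = D̃⁻¹ᐟ² (A+I) D̃⁻¹ᐟ²`, standardized node degree as the input
   feature, trained 200 epochs with Adam (lr 0.01) under a self-supervised
   link-prediction objective. Embeddings are clustered by K-means with
   silhouette-selected K, and clusters are prioritized by a composite of
   average degree, intra-cluster density and formula coverage.
3. **Frequency banding** of the per-herb difference between groups
   (high > 20 points, moderate 10–20, slight 0–10).
4. A **random forest** (1000 trees, OOB error, mean decrease in
   accuracy/Gini) discriminating the two groups from herb presence.

The consensus module intersects the rule-derived and cluster-derived herb
sets into the core spectrum and tags every herb with its supporting
evidence. A compound/target screening module (OB ≥ 30%, DL ≥ 0.18;
SVM ≥ 0.8, RF ≥ 0.7; bipartite degree ranking) covers the
network-pharmacology follow-up, and a synthetic two-group generator with
planted co-prescription modules provides ground truth for every stage.

## Worked example

```r
library(HerbMiner)

## two-group corpus with one planted 8-herb module (Herb001..Herb008)
sim <- generateTwoGroupCorpus(syntheticConfig(seed = 1))
sim$corpus
#> PrescriptionCorpus with 270 prescriptions, 210 herbs
#>   anti_recurrence: 150  general: 120
#>   median prescription size: 11

res <- runPipeline(pipelineConfig(synthetic = syntheticConfig(seed = 1),
                                  seed = 1))

head(res$rules[, c("lhs", "rhs", "confidence", "lift")], 3)
#>                                       lhs     rhs confidence     lift
#> 1 Herb001|Herb002|Herb003|Herb004|Herb006 Herb007  0.9218750 1.707176
#> 2         Herb001|Herb002|Herb003|Herb006 Herb007  0.9178082 1.699645
#> 3 Herb...|Herb006|Herb008                 Herb007  0.9166667 1.697531

res$clusterScores[1:2, c("cluster_id", "n_members", "avg_degree",
                         "density", "coverage", "composite")]
#>   cluster_id n_members avg_degree    density  coverage composite
#> 1          2         8  1171.6250 81.8214286 0.9733333 0.6666667
#> 2          1       199    53.0603  0.1463885 1.0000000 0.3333333

res$consensus
#> ConsensusResult
#>   rule arm: 8 herbs; cluster arm: 8 herbs
#>   venn: only_rules 0 | both 8 | only_cluster 0
#>   core spectrum: Herb001, ..., Herb008

round(res$forest$oob_error, 4)
#> [1] 0.3074
```

Reading the output: the highest-lift rules all implicate planted module
herbs (a 92% conditional probability of Herb007 given five of its module
partners, 1.71× over its baseline); the top-composite cluster is exactly
the 8-herb module, with an average co-occurrence degree 22× the background
cluster's; and the consensus intersection recovers the full planted
combination. The OOB error of 0.31 reflects that the two groups share the
module (at halved activation) and differ mainly in three differential
herbs — the forest's importance ranking, not raw accuracy, carries the
signal.

Real corpora are read with `readCorpus()` (long or wide CSV/TSV), herb
names standardized against a user-supplied lexicon with
`standardizeHerbs()`, and the same `runPipeline()` applies with
`corpus_anti =` / `corpus_general =` paths.

## Documentation

`vignettes/core-herb-mining.Rmd` describes the models, parameters,
numerical conventions, the synthetic generator's assumptions, and known
limitations.
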