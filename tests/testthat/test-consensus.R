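fakeRules <- function(lhs, rhs, lift) {
  data.frame(lhs = lhs, rhs = rhs, support = 0.1, confidence = 0.9,
             lift = lift, count = 5L, stringsAsFactors = FALSE)
}

test_that("rule-herb selection pools the top rules by lift", {
  rules <- fakeRules(c("A|B", "C"), c("C", "D"), c(3, 2))
  expect_equal(selectRuleHerbs(rules, 1), c("A", "B", "C"))
  expect_equal(selectRuleHerbs(rules, 2), c("A", "B", "C", "D"))
  # saturation: asking for more rules than exist is the full union
  expect_equal(selectRuleHerbs(rules, 10), c("A", "B", "C", "D"))
  expect_warning(empty <- selectRuleHerbs(rules[0, ], 1), "empty")
  expect_length(empty, 0)
  # two rules over the same herbs give the same set at topN = 1 and 2
  dup <- fakeRules(c("A", "B"), c("B", "A"), c(2, 1))
  expect_equal(selectRuleHerbs(dup, 1), selectRuleHerbs(dup, 2))
})

test_that("cluster-herb selection is monotone in the number of clusters", {
  scores <- data.frame(cluster_id = 1:3, members = c("A|B", "C", "D|E"),
                       composite = c(0.9, 0.5, 0.1),
                       stringsAsFactors = FALSE)
  s1 <- selectClusterHerbs(scores, 1)
  s2 <- selectClusterHerbs(scores, 2)
  s3 <- selectClusterHerbs(scores, 3)
  expect_equal(s1, c("A", "B"))
  expect_true(all(s1 %in% s2) && all(s2 %in% s3))
  expect_equal(s3, c("A", "B", "C", "D", "E"))
  rules <- fakeRules(c("A|B", "C"), c("C", "D"), c(3, 2))
  expect_true(all(selectRuleHerbs(rules, 1) %in% selectRuleHerbs(rules, 2)))
})

test_that("consensus set arithmetic and venn counts are exact", {
  res <- consensusCore(c("A", "B", "C"), c("B", "C", "D"))
  expect_equal(res@intersection, c("B", "C"))
  expect_equal(res@vennCounts,
               c(only_rules = 1L, only_cluster = 1L, both = 2L))
  # identical sets
  same <- consensusCore(c("A", "B"), c("B", "A"))
  expect_equal(same@intersection, c("A", "B"))
  expect_equal(same@vennCounts,
               c(only_rules = 0L, only_cluster = 0L, both = 2L))
  # disjoint sets
  disj <- consensusCore(c("A"), c("B", "C"))
  expect_length(disj@intersection, 0)
  expect_equal(disj@vennCounts,
               c(only_rules = 1L, only_cluster = 2L, both = 0L))
})

test_that("consensus is symmetric up to swapping the venn fields", {
  a <- c("A", "B", "C"); b <- c("B", "D")
  r1 <- consensusCore(a, b)
  r2 <- consensusCore(b, a)
  expect_equal(r1@intersection, r2@intersection)
  expect_equal(r1@union, r2@union)
  expect_equal(unname(r1@vennCounts[c("only_cluster", "only_rules")]),
               unname(r2@vennCounts[c("only_rules", "only_cluster")]))
})

test_that("evidence tags reflect the differential and forest reports", {
  diffTab <- data.frame(
    herb = c("A", "B", "E"), freq_anti = c(0.8, 0.5, 0.9),
    freq_general = c(0.2, 0.45, 0.3),
    diff_points = c(60, 5, 60), band = c("high", "slight", "high"),
    direction = c("anti_enriched", "anti_enriched", "anti_enriched"),
    stringsAsFactors = FALSE)
  forest <- list(ranking = c("B", "A", "Z"))
  res <- consensusCore(c("A", "B"), c("B", "C"), diffTab, forest,
                       rfTopN = 2)
  prov <- res@provenance
  expect_true(prov$frequency_high[prov$herb == "A"])
  expect_false(prov$frequency_high[prov$herb == "B"])   # slight band
  expect_true(all(prov$rf_top[prov$herb %in% c("A", "B")]))
  expect_false(any(prov$rf_top[prov$herb == "C"]))
  # A and B both carry three tags; A wins the tie on its +60-point shift
  ranked <- rankConsensusHerbs(res, diffTab)
  expect_equal(ranked$herb[1], "A")
  expect_equal(ranked$herb[2], "B")
})

test_that("the pipeline recovers the planted module end to end", {
  hits <- vapply(1:5, function(s) {
    res <- runPipeline(pipelineConfig(synthetic = syntheticConfig(seed = s),
                                      seed = s))
    length(intersect(res$consensus@intersection,
                     sprintf("Herb%03d", 1:8)))
  }, 0L)
  expect_gte(sum(hits >= 6L), 4L)
})

test_that("pipeline failures name the failing stage", {
  cfg <- pipelineConfig(corpus_anti = "/nonexistent/a.csv",
                        corpus_general = "/nonexistent/g.csv")
  expect_error(runPipeline(cfg), "stage 'corpus'")
})

test_that("configs round-trip through YAML", {
  f <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("min_support: 0.1",
               "min_confidence: 0.9",
               "seed: 5",
               "synthetic:",
               "  n_anti: 20",
               "  n_general: 15",
               "  seed: 5"), f)
  cfg <- readPipelineConfig(f)
  expect_equal(cfg$min_support, 0.1)
  expect_equal(cfg$synthetic$n_anti, 20L)
  f2 <- withr::local_tempfile(fileext = ".yaml")
  writeLines("bogus_key: 1", f2)
  expect_error(readPipelineConfig(f2), "bogus_key")
})
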