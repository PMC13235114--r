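mkGroup <- function(sets, prefix, group) {
  names(sets) <- paste0(prefix, seq_along(sets))
  PrescriptionCorpus(sets, group, deduplicate = FALSE)
}

test_that("frequency differences land in the documented bands", {
  # herb X: 8/10 anti vs 2/10 general -> +60 points, high
  anti <- mkGroup(c(replicate(8, c("X", "F"), simplify = FALSE),
                    replicate(2, list("F"))), "A", "anti_recurrence")
  gen <- mkGroup(c(replicate(2, c("X", "F"), simplify = FALSE),
                   replicate(8, list("F"))), "G", "general")
  d <- frequencyDifferential(anti, gen)
  x <- d[d$herb == "X", ]
  expect_equal(x$diff_points, 60)
  expect_equal(x$band, "high")
  expect_equal(x$direction, "anti_enriched")
  # 35% vs 20% -> +15 points, moderate
  anti2 <- mkGroup(c(replicate(7, c("Y", "F"), simplify = FALSE),
                     replicate(13, list("F"))), "A", "anti_recurrence")
  gen2 <- mkGroup(c(replicate(4, c("Y", "F"), simplify = FALSE),
                    replicate(16, list("F"))), "G", "general")
  y <- frequencyDifferential(anti2, gen2)
  expect_equal(y[y$herb == "Y", "diff_points"], 15)
  expect_equal(y[y$herb == "Y", "band"], "moderate")
})

test_that("identical corpora give all-zero balanced slight records", {
  corp <- mkGroup(list(c("A", "B"), c("B", "C")), "P", "anti_recurrence")
  corpG <- mkGroup(list(c("A", "B"), c("B", "C")), "Q", "general")
  d <- frequencyDifferential(corp, corpG)
  expect_true(all(d$diff_points == 0))
  expect_true(all(d$band == "slight"))
  expect_true(all(d$direction == "balanced"))
})

test_that("band assignment is an exact function of the difference", {
  bandFor <- function(fa, fg) {
    n <- 20L
    anti <- mkGroup(c(replicate(round(fa * n), c("H", "F"),
                                simplify = FALSE),
                      replicate(n - round(fa * n), list("F"))),
                    "A", "anti_recurrence")
    gen <- mkGroup(c(replicate(round(fg * n), c("H", "F"),
                               simplify = FALSE),
                     replicate(n - round(fg * n), list("F"))),
                   "G", "general")
    d <- frequencyDifferential(anti, gen)
    d[d$herb == "H", c("diff_points", "band")]
  }
  # strict-">" boundary convention: 20 points is moderate, 10 is slight
  expect_equal(bandFor(0.40, 0.20)$band, "moderate")
  expect_equal(bandFor(0.45, 0.20)$band, "high")
  expect_equal(bandFor(0.30, 0.20)$band, "slight")
  expect_equal(bandFor(0.35, 0.20)$band, "moderate")
  set.seed(71)
  for (i in 1:20) {
    fa <- sample(0:20, 1) / 20
    fg <- sample(0:20, 1) / 20
    if (fa == 0 && fg == 0) next
    got <- bandFor(max(fa, 1 / 20), max(fg, 1 / 20))
    ref <- abs(got$diff_points)
    expect_equal(got$band,
                 if (ref > 20) "high" else if (ref > 10) "moderate"
                 else "slight")
  }
})

test_that("a perfectly separating herb drives OOB to ~0 and ranks first", {
  corpora <- plantedSeparatorCorpora(nPerGroup = 30, seed = 5)
  rep <- rfDifferential(corpora$anti, corpora$general, nTrees = 200,
                        seed = 123)
  expect_lte(rep$oob_error, 0.05)
  expect_equal(rep$ranking[1], "Marker")
  expect_true(all(rep$importance$mean_decrease_gini >= 0))
  expect_setequal(rep$ranking,
                  union(vocabulary(corpora$anti),
                        vocabulary(corpora$general)))
})

test_that("the forest report is reproducible for a fixed seed", {
  corpora <- plantedSeparatorCorpora(nPerGroup = 15, seed = 9)
  r1 <- rfDifferential(corpora$anti, corpora$general, nTrees = 100,
                       seed = 42)
  r2 <- rfDifferential(corpora$anti, corpora$general, nTrees = 100,
                       seed = 42)
  expect_identical(r1$oob_error, r2$oob_error)
  expect_identical(r1$importance, r2$importance)
})

test_that("planted differential herbs reach the importance top decile", {
  hits <- vapply(1:5, function(s) {
    cfg <- syntheticConfig(
      n_anti = 100, n_general = 100, vocab_size = 120,
      modules = list(list(members = sprintf("Herb%03d", 1:8),
                          activation_prob = 0.5, inclusion_prob = 0.9,
                          group_bias = 1.0)),
      differential_herbs = data.frame(
        herb = sprintf("Herb%03d", 110:112),
        freq_anti = 0.6, freq_general = 0.2),
      size_range = c(1L, 40L), seed = s)
    sim <- generateTwoGroupCorpus(cfg)
    rep <- rfDifferential(subsetByGroup(sim$corpus, "anti_recurrence"),
                          subsetByGroup(sim$corpus, "general"),
                          nTrees = 300, seed = 123)
    decile <- head(rep$ranking, ceiling(length(rep$ranking) / 10))
    all(sprintf("Herb%03d", 110:112) %in% decile)
  }, TRUE)
  expect_gte(sum(hits), 4L)
})

test_that("undersized groups are refused", {
  corpora <- plantedSeparatorCorpora(nPerGroup = 5, seed = 1)
  tiny <- PrescriptionCorpus(list(P1 = "A"), "general")
  expect_error(rfDifferential(corpora$anti, tiny), "at least 2")
})
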