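threeCorpusMatrix <- function() binaryMatrix(exampleCorpus())

test_that("frequent itemsets on the three-prescription corpus are exact", {
  fi <- frequentItemsets(threeCorpusMatrix(), 0.6)
  expect_setequal(fi$items, c("A", "B", "C", "A|B", "B|C"))
  supp <- structure(fi$support, names = fi$items)
  expect_equal(unname(supp["B"]), 1)
  expect_equal(unname(supp[c("A", "C", "A|B", "B|C")]), rep(2 / 3, 4))
})

test_that("all-common and threshold-boundary cases behave", {
  corp <- PrescriptionCorpus(list(P1 = c("A", "B"), P2 = c("A", "B")),
                             "anti_recurrence", deduplicate = FALSE)
  fi <- frequentItemsets(binaryMatrix(corp), 1.0)
  expect_setequal(fi$items, c("A", "B", "A|B"))
  # a herb unique to one of five prescriptions dies just above support 1/5
  corp5 <- PrescriptionCorpus(
    list(P1 = c("A", "Z"), P2 = "A", P3 = "A", P4 = "A", P5 = "A"),
    "anti_recurrence", deduplicate = FALSE)
  fi5 <- frequentItemsets(binaryMatrix(corp5), 0.2001)
  expect_false("Z" %in% fi5$items)
  # exactly at the rational boundary 1/5 it survives (inclusive threshold)
  fi5b <- frequentItemsets(binaryMatrix(corp5), 0.2)
  expect_true("Z" %in% fi5b$items)
})

test_that("rules on the three-prescription corpus are exactly the two implications", {
  m <- threeCorpusMatrix()
  rules <- deriveRules(frequentItemsets(m, 0.6), m, 0.8)
  expect_equal(nrow(rules), 2L)
  expect_setequal(rules$lhs, c("A", "C"))
  expect_true(all(rules$rhs == "B"))
  expect_true(all(rules$confidence == 1))
  expect_true(all(rules$lift == 1))
})

test_that("an unattainable confidence threshold yields no rules", {
  set.seed(1)
  corp <- randomCorpus(6, 12, density = 0.5)
  m <- binaryMatrix(corp)
  rules <- deriveRules(frequentItemsets(m, 0.1), m, 1.0)
  if (nrow(rules)) expect_true(all(rules$confidence == 1))
  # on a corpus with no deterministic implication the list is empty
  corp2 <- PrescriptionCorpus(
    list(P1 = c("A", "B"), P2 = "A", P3 = "B", P4 = c("A", "B"), P5 = "A"),
    "anti_recurrence", deduplicate = FALSE)
  m2 <- binaryMatrix(corp2)
  expect_equal(nrow(deriveRules(frequentItemsets(m2, 0.2), m2, 1.0)), 0L)
})

test_that("downward closure and anti-monotonicity hold on random corpora", {
  for (i in 1:10) {
    set.seed(300 + i)
    m <- binaryMatrix(randomCorpus(sample(5:9, 1), sample(8:16, 1)))
    fi <- frequentItemsets(m, 0.25)
    keys <- fi$items
    for (it in strsplit(keys, "|", fixed = TRUE)) {
      if (length(it) < 2) next
      for (d in seq_along(it))
        expect_true(paste(it[-d], collapse = "|") %in% keys)
    }
    hi <- frequentItemsets(m, 0.45)
    expect_true(all(hi$items %in% keys))
    rLo <- deriveRules(fi, m, 0.6)
    rHi <- deriveRules(fi, m, 0.85)
    expect_true(all(paste(rHi$lhs, rHi$rhs) %in% paste(rLo$lhs, rLo$rhs)))
  }
})

test_that("rule ranking is lift-first with documented tie-breaks", {
  set.seed(7)
  m <- binaryMatrix(randomCorpus(7, 15, density = 0.5))
  rules <- deriveRules(frequentItemsets(m, 0.2), m, 0.5)
  expect_true(!is.unsorted(rev(rules$lift)))
  ties <- which(diff(rules$lift) == 0)
  expect_true(all(rules$confidence[ties] >= rules$confidence[ties + 1L]))
})

test_that("single-rule metrics match hand enumeration", {
  m <- threeCorpusMatrix()
  rm1 <- ruleMetrics(m, "A", "C")
  expect_equal(rm1$support, 1 / 3)
  expect_equal(rm1$confidence, 0.5)
  expect_equal(rm1$lift, 0.75)
  # rhs present everywhere forces confidence = lift = 1
  rm2 <- ruleMetrics(m, "A", "B")
  expect_equal(rm2$confidence, 1)
  expect_equal(rm2$lift, 1)
  expect_error(ruleMetrics(m, "A", "A"), "disjoint")
  expect_error(ruleMetrics(m, "A", "Q"), "vocabulary")
})

test_that("a never-seen antecedent is an explicit no-support result", {
  corp <- PrescriptionCorpus(
    list(P1 = c("A", "B"), P2 = c("B", "C")), "anti_recurrence")
  m <- binaryMatrix(corp)
  # A and C never co-occur, so lhs = {A, C} has zero support
  res <- ruleMetrics(m, c("A", "C"), "B")
  expect_true(res$no_support)
  expect_true(is.na(res$confidence))
  expect_true(is.na(res$lift))
})

test_that("multi-consequent rules are available behind rhsSize", {
  m <- threeCorpusMatrix()
  fi <- frequentItemsets(m, 0.3)
  r2 <- deriveRules(fi, m, 0.5, rhsSize = 2L)
  expect_true(all(lengths(strsplit(r2$rhs, "|", fixed = TRUE)) == 2L))
  expect_identical(canonRules(r2), canonRules(bruteRules(m, 0.3, 0.5, 2L)))
})
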