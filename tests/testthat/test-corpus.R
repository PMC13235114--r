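test_that("long-format parsing builds deduplicated herb sets", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("prescription_id,group,herb",
               "P1,anti_recurrence,A",
               "P1,anti_recurrence,B",
               "P2,anti_recurrence,A"), f)
  corp <- readCorpus(f, "long")
  expect_equal(nPrescriptions(corp), 2L)
  expect_equal(vocabulary(corp), c("A", "B"))
  expect_equal(herbSets(corp)$P1, c("A", "B"))
})

test_that("identical compositions within a group collapse, keeping the earliest id", {
  corp <- PrescriptionCorpus(
    list(P1 = c("A", "B"), P2 = c("B", "A"), P3 = "A"),
    "anti_recurrence")
  expect_equal(prescriptionIds(corp), c("P1", "P3"))
  # but identical compositions in *different* groups are both retained
  corp2 <- PrescriptionCorpus(
    list(P1 = c("A", "B"), P2 = c("A", "B")),
    c("anti_recurrence", "general"))
  expect_equal(nPrescriptions(corp2), 2L)
})

test_that("wide format drops within-row duplicate herbs", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("prescription_id,group,herbs", "P3,general,A;B;B"), f)
  corp <- readCorpus(f, "wide")
  expect_equal(herbSets(corp)$P3, c("A", "B"))
})

test_that("format and record errors are reported by name", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("id,group,herb", "P1,anti_recurrence,A"), f)
  expect_error(readCorpus(f, "long"), "prescription_id")
  f2 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("prescription_id,group,herbs", "P9,general, ; "), f2)
  expect_error(readCorpus(f2, "wide"), "P9")
})

test_that("corpus round-trips through the long CSV dialect", {
  set.seed(23)
  raw <- randomCorpus(8, 15)
  # canonicalize first: reading applies the duplicate-collapse contract
  corp <- PrescriptionCorpus(herbSets(raw), groupLabels(raw))
  f <- withr::local_tempfile(fileext = ".csv")
  writeCorpus(corp, f)
  back <- readCorpus(f, "long")
  expect_equal(herbSets(back), herbSets(corp))
  expect_equal(groupLabels(back), groupLabels(corp))
})

test_that("standardization maps, merges, re-deduplicates, and warns on gaps", {
  lex <- HerbLexicon(data.frame(
    raw_name = c("huangqi", "qi"),
    standard_name = c("Astragalus Membranacei Radix",
                      "Astragalus Membranacei Radix"),
    nature = "warm", flavor = "sweet", stringsAsFactors = FALSE))
  corp <- PrescriptionCorpus(
    list(P1 = c("huangqi", "Poria Cocos"), P2 = c("huangqi", "qi")),
    "anti_recurrence")
  expect_warning(std <- standardizeHerbs(corp, lex), "Poria Cocos")
  expect_equal(herbSets(std)$P1,
               sort(c("Astragalus Membranacei Radix", "Poria Cocos")))
  # two raw names mapping to one standard name collapse within P2
  expect_equal(herbSets(std)$P2, "Astragalus Membranacei Radix")
  # idempotence: a second application changes nothing further
  expect_warning(std2 <- standardizeHerbs(std, lex), "Poria Cocos")
  expect_equal(herbSets(std2), herbSets(std))
  # empty lexicon is the identity
  expect_identical(herbSets(standardizeHerbs(corp, HerbLexicon())),
                   herbSets(corp))
})

test_that("binary matrix dimensions, row sums and column sums are consistent", {
  corp <- PrescriptionCorpus(list(P1 = c("A", "B"), P2 = "B"),
                             "anti_recurrence")
  m <- binaryMatrix(corp)
  expect_equal(dim(m), c(2L, 2L))
  expect_equal(unname(colSums(m)), c(1, 2))
  for (i in 1:5) {
    set.seed(i)
    corp <- randomCorpus(sample(4:10, 1), sample(5:20, 1))
    m <- binaryMatrix(corp)
    expect_equal(unname(rowSums(m)), unname(lengths(herbSets(corp))))
    ft <- herbFrequency(corp)
    expect_equal(structure(ft$count, names = ft$herb)[colnames(m)],
                 colSums(m)[colnames(m)], ignore_attr = TRUE)
  }
})

test_that("herb frequencies count containing prescriptions", {
  corp <- PrescriptionCorpus(
    list(P1 = c("A", "B"), P2 = "B", P3 = "B"), "anti_recurrence",
    deduplicate = FALSE)
  ft <- herbFrequency(corp)
  expect_equal(ft$frequency[ft$herb == "B"], 1)
  expect_equal(ft$frequency[ft$herb == "A"], 1 / 3)
  # double-counting identity on random corpora
  for (i in 1:5) {
    set.seed(100 + i)
    corp <- randomCorpus(sample(4:10, 1), sample(5:20, 1))
    expect_equal(sum(herbFrequency(corp)$count),
                 sum(lengths(herbSets(corp))))
  }
})

test_that("property distributions tally nature once and every flavor", {
  lex <- HerbLexicon(data.frame(
    raw_name = c("a", "b"), standard_name = c("A", "B"),
    nature = c("cold", "cold"), flavor = c("bitter", "bitter|sweet"),
    stringsAsFactors = FALSE))
  ps <- propertyDistribution(c("A", "B"), lex)
  expect_equal(ps$nature_counts[["cold"]], 2L)
  expect_equal(ps$flavor_counts[["bitter"]], 2L)
  expect_equal(ps$flavor_counts[["sweet"]], 1L)
  expect_equal(ps$herbs_unknown, 0L)
  empty <- propertyDistribution(character(), lex)
  expect_true(all(empty$nature_counts == 0L))
  unk <- propertyDistribution("C", lex)
  expect_equal(unk$herbs_unknown, 1L)
  expect_equal(unk$nature_counts[["unknown"]], 1L)
})
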