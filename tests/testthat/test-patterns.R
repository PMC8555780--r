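test_that("pattern parsing validates the IUPAC language", {
  p <- parsePattern("NSTCTANN")
  expect_s4_class(p, "CategoryPattern")
  expect_identical(p@text, "NSTCTANN")
  # S = {C, G} at position 2
  expect_identical(which(p@sets[, 2L]), c(C = 2L, G = 3L))
  expect_false(p@joker)
  expect_true(parsePattern("nnnnnnnn")@joker)

  expect_error(parsePattern("NNNATGNN"), "position 4")
  expect_error(parsePattern("NNNCYANN"), "disjoint")
  expect_error(parsePattern("NNNCNANN"), "single base or a pair")
  expect_error(parsePattern("NBNCTANN"), "three-base")
  expect_error(parsePattern("NXNCTANN"), "invalid")
  expect_error(parsePattern("NNCTANN"), "8 characters")
})

test_that("size, span and reach match the published worked example", {
  expect_identical(patternSize("NSTCTANN"), 128L)
  expect_identical(patternSize("NNNCTARC"), 128L)
  expect_identical(patternSize("AAACTAAA"), 1L)
  expect_identical(patternSize("NNNNNNNN"), 24576L)

  expect_identical(patternSpan("NSTCTANN"), 5L)
  expect_identical(patternSpan("NNNCTARC"), 5L)
  expect_identical(patternSpan("NNNCTNNN"), 2L)
  expect_identical(patternSpan("NNNNNNNN"), 0L)

  expect_identical(patternReach("NSTCTANN"), 2L)
  expect_identical(patternReach("NNNCTARC"), 3L)
  expect_identical(patternReach("NNNCTNNN"), 0L)
})

test_that("pattern size agrees with brute-force enumeration over the universe", {
  set.seed(11)
  pats <- c(
    "NSTCTANN", "NNNCTARC", "NNNNNNNN", "AAACTAAA", "NNTCTANN",
    replicate(6, sampleCategory(10))
  )
  for (p in pats) {
    expect_identical(
      patternSize(p),
      sum(patternMatches(seq_len(24576L), p)),
      info = p
    )
  }
})

test_that("matching and tie-breaking reproduce the assignment example", {
  expect_true(patternMatches("TGTCTAAC", "NSTCTANN"))
  expect_true(patternMatches("TGTCTAAC", "NNNCTARC"))
  expect_true(patternMatches("TGTCTAAC", "NNNNNNNN"))
  expect_false(patternMatches("TGTCTAAC", "NNACTANN"))

  a <- assignSequence("TGTCTAAC", c("NSTCTANN", "NNNCTARC", "NNNNNNNN"))
  expect_identical(a$label, "NSTCTANN")
  expect_false(a$ambiguous)

  # a sequence matching only the joker
  b <- assignSequence("AAATGAAA", c("NSTCTANN", "NNNCTARC", "NNNNNNNN"))
  expect_identical(b$label, "NNNNNNNN")
  expect_false(b$ambiguous)

  # identical duplicated patterns force an ambiguous tie
  set.seed(3)
  d <- assignSequence("TGTCTAAC", c("NSTCTANN", "NSTCTANN", "NNNNNNNN"))
  expect_true(d$ambiguous)
})

test_that("the standard categorization is an exact 96-way partition", {
  std <- standardCategorization()
  expect_identical(nCategories(std), 96L)
  expect_identical(conflictRate(std), 0)
  occ <- tabulate(assignmentTable(std), 96L)
  expect_identical(sum(occ), 24576L)
  expect_true(all(occ == 256L))
  expect_identical(assignSequence("TGTCTAAC", std)$label, "T[C>T]A")
  # assigned pattern really matches, for a random sample of sequences
  set.seed(5)
  idx <- sample.int(24576L, 250L)
  pats <- categoryPatterns(std)[assignmentTable(std)[idx]]
  expect_true(all(mapply(patternMatches, idx, pats)))
})

test_that("the generic table builder reproduces the direct standard partition", {
  set.seed(1)
  tab <- ddcat:::.buildTable(categoryPatterns(standardCategorization()))
  expect_identical(tab$assignment, assignmentTable(standardCategorization()))
  expect_identical(tab$conflictRate, 0)
})

test_that("the two-flank categorization has 1536 disjoint categories of size 16", {
  tf <- twoFlankCategorization()
  expect_identical(nCategories(tf), 1536L)
  occ <- tabulate(assignmentTable(tf), 1536L)
  expect_true(all(occ == 16L))
  expect_identical(patternSize(categoryPatterns(tf)[1L]), 16L)
  set.seed(6)
  idx <- sample.int(24576L, 150L)
  pats <- categoryPatterns(tf)[assignmentTable(tf)[idx]]
  expect_true(all(mapply(patternMatches, idx, pats)))
})

test_that("random categorizations are uniform, seeded and patternless", {
  r1 <- randomCategorization(seed = 9)
  r2 <- randomCategorization(seed = 9)
  expect_identical(assignmentTable(r1), assignmentTable(r2))
  expect_length(categoryPatterns(r1), 0L)
  occ <- tabulate(assignmentTable(r1), 96L)
  expect_identical(sum(occ), 24576L)
  expect_equal(mean(occ), 256)
  # occupancy fluctuates around 256 within binomial range
  expect_lt(max(abs(occ - 256)), 5 * sqrt(256))
  expect_false(identical(
    assignmentTable(randomCategorization(seed = 10)),
    assignmentTable(r1)
  ))
})

test_that("transformation matrices are row-stochastic maps to the standard categories", {
  std <- standardCategorization()
  Tm <- transformationMatrix(std)
  expect_equal(unname(Tm), diag(96), tolerance = 1e-12, ignore_attr = TRUE)

  toy <- newCategorization(c("NNTCTANN", "NNNNNNNN"), seed = 2)
  Tt <- transformationMatrix(toy)
  expect_equal(unname(rowSums(Tt)), c(1, 1), tolerance = 1e-12)
  # NNTCTANN covers exactly the standard category T[C>T]A
  expect_equal(unname(Tt["NNTCTANN", "T[C>T]A"]), 1)

  sc <- sampleCategorization(gaConfig(), seed = 21)
  Ts <- transformationMatrix(sc)
  nonEmpty <- setdiff(seq_len(96L), attr(Ts, "emptyCategories"))
  expect_equal(unname(rowSums(Ts)[nonEmpty]), rep(1, length(nonEmpty)),
    tolerance = 1e-12
  )
})

test_that("categorizations survive a JSON round trip and TSV export", {
  toy <- newCategorization(c("NSTCTANN", "NNNCTARC", "NNNNNNNN"), seed = 4)
  f <- tempfile(fileext = ".json")
  writeCategorization(toy, f)
  back <- readCategorization(f)
  expect_identical(assignmentTable(back), assignmentTable(toy))
  expect_identical(categoryPatterns(back), categoryPatterns(toy))
  expect_equal(conflictRate(back), conflictRate(toy))

  tsv <- tempfile(fileext = ".tsv")
  exportAssignmentTable(toy, tsv)
  df <- read.delim(tsv)
  expect_identical(nrow(df), 24576L)
  expect_identical(df$category_index, assignmentTable(toy))
})
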