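test_that("simulated genomes hit the requested composition and exome layout", {
  g <- simulateGenome(length = 1e5, gcContent = 0.4, exomeFraction = 0.2, seed = 31)
  chars <- strsplit(as.character(g$genome[[1L]]), "")[[1L]]
  gc <- mean(chars %in% c("C", "G"))
  expect_lt(abs(gc - 0.4), 0.01)
  st <- GenomicRanges::start(g$exome)
  en <- GenomicRanges::end(g$exome)
  expect_true(all(diff(st) > 0)) # sorted
  expect_true(all(st[-1L] > en[-length(en)])) # disjoint
  expect_lt(abs(sum(en - st + 1) / 1e5 - 0.2), 0.05)
  # same seed, same bytes
  g2 <- simulateGenome(length = 1e5, gcContent = 0.4, exomeFraction = 0.2, seed = 31)
  expect_identical(as.character(g$genome), as.character(g2$genome))
  expect_error(simulateGenome(exomeFraction = 1.5), "exomeFraction")
})

test_that("planted signatures concentrate mass on their generating patterns", {
  tr <- simulateTruth(kTrue = 3, patternsPerSignature = 3, seed = 32)
  expect_equal(unname(rowSums(tr$Hseq)), rep(1, 3), tolerance = 1e-12)
  for (k in 1:3) {
    support <- Reduce(`|`, lapply(tr$patterns[[k]], function(p) {
      patternMatches(seq_len(24576L), p)
    }))
    expect_equal(sum(tr$Hseq[k, support]), 0.9, tolerance = 1e-9)
  }
  # planted signatures are mutually distinguishable
  for (i in 1:2) {
    for (j in (i + 1):3) {
      expect_lt(cosineSimilarity(tr$Hseq[i, ], tr$Hseq[j, ]), 0.3)
    }
  }
  tr2 <- simulateTruth(kTrue = 3, patternsPerSignature = 3, seed = 32)
  expect_identical(tr$Hseq, tr2$Hseq)
})

test_that("emitted mutation records round-trip through sequence extraction", {
  fx <- ddcatFixture()
  for (cohort in c("wgs", "wes")) {
    rec <- fx$cohort[[cohort]]
    sub <- rec[seq(1L, nrow(rec), length.out = 300L), ]
    x <- extractMutationSequences(fx$genome$genome, sub)
    expect_true(all(x$reject == ""))
    expect_identical(x$seqIndex, sub$seqIndex)
  }
  # WES mutations lie inside the exome
  inExome <- rep(FALSE, 200000L)
  ex <- fx$genome$exome
  for (i in seq_along(ex)) {
    inExome[GenomicRanges::start(ex)[i]:GenomicRanges::end(ex)[i]] <- TRUE
  }
  expect_true(all(inExome[fx$cohort$wes$position]))
})

test_that("empirical category frequencies converge to the planted mixture", {
  fx <- ddcatFixture()
  std <- standardCategorization()
  # pool all WGS mutations; expectation is the burden-weighted exposure mix
  A <- assignmentTable(std)
  emp <- tabulate(A[fx$cohort$wgs$seqIndex], 96L)
  emp <- emp / sum(emp)
  Wt <- fx$cohort$truth$W_wgs
  perSample <- table(factor(fx$cohort$wgs$sample_id, rownames(Wt)))
  mix <- as.numeric(perSample %*% Wt) / sum(perSample)
  Hcat <- aggregateTruthSignatures(std, fx$truth)
  expected <- as.numeric(mix %*% Hcat)
  tv <- sum(abs(emp - expected)) / 2
  expect_lt(tv, 0.05)
})

test_that("decoupled expression carries no exposure signal", {
  g <- ddcatFixture()$genome
  tr <- ddcatFixture()$truth
  c0 <- simulateCohort(g, tr,
    nWgs = 2, nWes = 40, burdenMean = 100,
    couplingStrength = 0, seed = 33
  )
  E0 <- c0$expression[, c0$geneSets$ddr_like]
  r0 <- ccaTestCorrelation(c0$truth$W_wes, E0, nFolds = 5, seed = 34)$meanCorrelation
  c1 <- simulateCohort(g, tr,
    nWgs = 2, nWes = 40, burdenMean = 100,
    couplingStrength = 1, seed = 33
  )
  E1 <- c1$expression[, c1$geneSets$ddr_like]
  r1 <- ccaTestCorrelation(c1$truth$W_wes, E1, nFolds = 5, seed = 34)$meanCorrelation
  expect_gt(r1, 0.8) # coupled: strong held-out correlation
  expect_lt(abs(r0), 0.5) # decoupled: consistent with the null
  expect_gt(r1 - r0, 0.3)
})

test_that("the small fixture is deterministic and self-consistent", {
  fx <- ddcatFixture()
  ds <- fx$dataset
  expect_s4_class(ds, "MutationDataset")
  expect_identical(length(unique(ds@wgs$sample_id)), 30L)
  expect_identical(length(unique(ds@wes$sample_id)), 30L)
  expect_identical(dim(ds@expression), c(30L, 60L))
  # regenerating with the same seed reproduces the dataset exactly
  fx2 <- fixtureSmall(seed = 101)
  expect_identical(fx2$dataset@wgs, ds@wgs)
  expect_identical(fx2$dataset@expression, ds@expression)
  expect_identical(fx2$dataset@genomeKmers, ds@genomeKmers)
  # all emitted files exist and re-read cleanly
  expect_true(all(file.exists(unlist(fx$cohort$files[c("wgs", "wes", "expression")]))))
  tbl <- readMutationTable(fx$cohort$files$wgs)
  expect_identical(nrow(tbl), nrow(fx$cohort$wgs))
})
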