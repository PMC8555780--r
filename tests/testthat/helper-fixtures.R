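# Shared fixtures, generated once per test run and cached.

.fixtureCache <- new.env(parent = emptyenv())

ddcatFixture <- function() {
  if (is.null(.fixtureCache$fx)) {
    .fixtureCache$fx <- fixtureSmall(seed = 101)
  }
  .fixtureCache$fx
}

# the fixture dataset with the planted signature order as K*
ddcatDataset <- function(kStar = 3) {
  ds <- ddcatFixture()$dataset
  ds@kStar <- kStar
  ds
}

ddcatPlanted <- function() {
  if (is.null(.fixtureCache$planted)) {
    .fixtureCache$planted <- plantedCategorization(ddcatFixture()$truth, seed = 7)
  }
  .fixtureCache$planted
}

# true signatures aggregated to the categories of a categorization
aggregateTruthSignatures <- function(categorization, truth = ddcatFixture()$truth) {
  A <- assignmentTable(categorization)
  M <- nCategories(categorization)
  H <- t(apply(truth$Hseq, 1L, function(r) {
    tapply(r, factor(A, levels = seq_len(M)), sum, default = 0)
  }))
  H[is.na(H)] <- 0
  H
}

# best-match cosine of each row of A against the rows of B
rowwiseBestCosine <- function(A, B) {
  vapply(seq_len(nrow(A)), function(i) {
    max(vapply(
      seq_len(nrow(B)),
      function(j) cosineSimilarity(A[i, ], B[j, ]), numeric(1)
    ))
  }, numeric(1))
}
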