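test_that("mutation sequences are extracted with pyrimidine collapsing", {
  g <- Biostrings::DNAStringSet(c(chr1 = "TGTCAACG", chr2 = "CGTTGACA"))
  rec <- data.frame(
    sample_id = c("s1", "s2", "s3", "s4", "s5"),
    chromosome = c("chr1", "chr2", "chr1", "chr1", "chrX"),
    position = c(4L, 5L, 4L, 2L, 4L),
    reference_allele = c("C", "G", "T", "G", "C"),
    mutated_allele = c("T", "A", "A", "T", "T")
  )
  x <- extractMutationSequences(g, rec)
  # context TGT[C]AAC, alt T
  expect_identical(indexToSequence(x$seqIndex[1L]), "TGTCTAAC")
  # chr2 GTT[G]ACA alt A reverse-complements to the same mutation sequence
  expect_identical(x$seqIndex[2L], x$seqIndex[1L])
  expect_identical(x$reject[3L], "reference_mismatch")
  expect_identical(x$reject[4L], "window_out_of_bounds")
  expect_identical(x$reject[5L], "unknown_chromosome")
  expect_true(is.na(x$seqIndex[3L]))

  gN <- Biostrings::DNAStringSet(c(chr1 = "TGNCAACG"))
  xN <- extractMutationSequences(gN, rec[1L, ])
  expect_identical(xN$reject, "ambiguous_base_in_window")
})

test_that("strand collapsing is involution-consistent on the fixture cohort", {
  fx <- ddcatFixture()
  rec <- fx$cohort$wgs
  sub <- rec[seq(1L, nrow(rec), length.out = 400L), ]
  x <- extractMutationSequences(fx$genome$genome, sub)
  expect_true(all(x$reject == ""))
  expect_identical(x$seqIndex, sub$seqIndex)
  # records on the purine strand collapse to the same universe sequence as
  # their pyrimidine representation
  pur <- sub$reference_allele %in% c("A", "G")
  expect_gt(sum(pur), 0L)
})

test_that("catalog construction conserves counts", {
  std <- standardCategorization()
  rec <- data.frame(
    sample_id = c("a", "a", "b"),
    seqIndex = sequenceIndex(c("TGTCTAAC", "TGTCTAAC", "TGTCTAAC"))
  )
  cat1 <- buildCatalog(rec, std)
  expect_identical(sum(catalogCounts(cat1)), 3L)
  expect_identical(unname(catalogCounts(cat1)["a", "T[C>T]A"]), 2L)
  # identical records in two samples give proportional rows
  expect_equal(
    unname(catalogCounts(cat1)["a", ] / 2L),
    unname(as.numeric(catalogCounts(cat1)["b", ]))
  )

  fx <- ddcatFixture()
  ds <- fx$dataset
  cc <- buildCatalog(ds@wgs, std)
  expect_identical(sum(catalogCounts(cc)), nrow(ds@wgs))
  expect_identical(dim(cc), c(30L, 96L))
})

test_that("row normalization yields stochastic rows and rejects empty samples", {
  m <- matrix(c(2, 2, 0, 0, 5, 0), 2, byrow = TRUE,
    dimnames = list(c("s1", "s2"), NULL)
  )
  V <- normalizeCatalog(m)
  expect_equal(unname(V[1L, ]), c(0.5, 0.5, 0))
  expect_equal(unname(V[2L, ]), c(0, 1, 0)) # single-category sample: unit row
  expect_equal(unname(rowSums(V)), c(1, 1), tolerance = 1e-12)
  m0 <- rbind(m, s3 = c(0, 0, 0))
  expect_error(normalizeCatalog(m0), "s3")
})

test_that("opportunity counting enumerates (position, alt) pairs", {
  std <- standardCategorization()
  g <- Biostrings::DNAStringSet(c(chr1 = "AAACAAA"))
  U <- countOpportunities(g, std)
  expect_equal(sum(U), 3)
  expect_equal(unname(U[c("A[C>A]A", "A[C>G]A", "A[C>T]A")]), c(1, 1, 1))

  gAllN <- Biostrings::DNAStringSet(c(chr1 = "NNNNNNNN"))
  expect_error(countOpportunities(gAllN, std), "no eligible positions")

  fx <- ddcatFixture()
  Ug <- ddcat:::.opportunityFromKmers(fx$dataset@genomeKmers, std)
  L <- 200000L
  expect_equal(sum(Ug), 3 * (L - 6L))
  # uniform-random genome: opportunities near proportional to category size
  expect_lt(max(abs(Ug / sum(Ug) - 1 / 96)) * 96, 0.10)
  # exome restriction by central-base membership
  Ue <- ddcat:::.opportunityFromKmers(fx$dataset@exomeKmers, std)
  expect_lt(abs(sum(Ue) / sum(Ug) - 0.25), 0.01)
})

test_that("exome opportunities match a direct per-position enumeration", {
  # tiny genome + one region; oracle: loop over centres inside the region
  g <- Biostrings::DNAStringSet(c(chr1 = "ACGTACGTACGTACGTACGT"))
  region <- GenomicRanges::GRanges("chr1", IRanges::IRanges(6, 12))
  std <- standardCategorization()
  U <- countOpportunities(g, std, region)
  chars <- strsplit(as.character(g[[1L]]), "")[[1L]]
  oracle <- numeric(96)
  for (pos in 6:12) {
    if (pos < 4 || pos > length(chars) - 3) next
    ctx <- chars[(pos - 3):(pos + 3)]
    ref <- ctx[4L]
    for (alt in setdiff(c("A", "C", "G", "T"), ref)) {
      s8 <- paste(c(ctx[1:3], ref, alt, ctx[5:7]), collapse = "")
      idx <- tryCatch(sequenceIndex(s8), error = function(e) NULL)
      if (is.null(idx)) {
        # purine centre: collapse by hand
        comp <- c(A = "T", C = "G", G = "C", T = "A")
        rc <- rev(comp[ctx])
        s8 <- paste(c(rc[1:3], comp[ref], comp[alt], rc[5:7]), collapse = "")
        idx <- sequenceIndex(s8)
      }
      k <- assignmentTable(std)[idx]
      oracle[k] <- oracle[k] + 1
    }
  }
  expect_equal(unname(U), oracle)
})

test_that("signature renormalization rescales and restores stochastic rows", {
  H <- matrix(c(0.5, 0.5), 1)
  expect_equal(unname(renormalizeSignatures(H, c(1, 1), c(1, 1))), H)
  expect_equal(
    unname(renormalizeSignatures(H, c(1, 1), c(2, 1))),
    matrix(c(2 / 3, 1 / 3), 1)
  )
  set.seed(8)
  H3 <- matrix(rgamma(3 * 96, 1), 3)
  H3 <- H3 / rowSums(H3)
  u1 <- rgamma(96, 5)
  u2 <- rgamma(96, 5)
  out <- renormalizeSignatures(H3, u1, u2)
  expect_equal(unname(rowSums(out)), rep(1, 3), tolerance = 1e-12)
  expect_warning(
    renormalizeSignatures(H, c(0, 1), c(1, 1)),
    "unobservable"
  )
})

test_that("mutation tables read with column mapping and SNV filtering", {
  f <- tempfile(fileext = ".tsv")
  df <- data.frame(
    donor = c("d1", "d2", "d3"), chr = "chr1", pos = c(10L, 11L, 12L),
    ref = c("A", "AT", "C"), alt = c("G", "A", "C")
  )
  write.table(df, f, sep = "\t", quote = FALSE, row.names = FALSE)
  out <- readMutationTable(f, columnMap = c(
    sample_id = "donor", chromosome = "chr", position = "pos",
    reference_allele = "ref", mutated_allele = "alt"
  ))
  # the indel and the ref==alt row are dropped
  expect_identical(nrow(out), 1L)
  expect_identical(attr(out, "nonSnv"), 2L)
  expect_error(readMutationTable(f), "missing column")
})
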