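# Fully self-contained synthetic data: a random genome with an "exome"
# subset, cohorts of WGS-like and WES-like single base substitutions drawn
# from planted context-specific signatures placed at real genome positions
# (so FASTA round-trips, strand collapsing and opportunity counting are all
# exercised), and expression matrices linearly coupled to the planted
# exposures through a non-negative (softplus) link plus Gaussian noise.

#' Simulate a random genome with an exome subset
#'
#' Bases are i.i.d. with the requested GC content. The exome is a set of
#' disjoint, sorted fixed-length intervals covering approximately
#' `exomeFraction` of the genome (one interval placed uniformly inside each
#' of `nExons` equal blocks).
#'
#' @param length genome length in bases (>= 1000).
#' @param gcContent target GC fraction.
#' @param exomeFraction fraction of the genome covered by exons (< 1).
#' @param exonLength exon length in bases.
#' @param seed integer seed.
#' @param dir optional directory; when given, `genome.fa` and `exome.bed`
#'   are written there.
#' @return list with `genome` ([Biostrings::DNAStringSet]), `exome`
#'   (`GRanges`) and `files` (paths or `NULL`).
#' @export
simulateGenome <- function(length = 2e5, gcContent = 0.5, exomeFraction = 0.25,
                           exonLength = 500L, seed = 1L, dir = NULL) {
  stopifnot(length >= 1000, exomeFraction < 1, exomeFraction > 0)
  withSeed(seed, {
    p <- c((1 - gcContent) / 2, gcContent / 2, gcContent / 2, (1 - gcContent) / 2)
    codes <- sample.int(4L, length, replace = TRUE, prob = p)
    genome <- DNAStringSet(setNames(
      paste(.BASES[codes], collapse = ""), "chr1"
    ))
    nExons <- max(1L, floor(length * exomeFraction / exonLength))
    block <- length %/% nExons
    if (block <= exonLength) stop("exome fraction too large for the exon length")
    starts <- (seq_len(nExons) - 1L) * block +
      sample.int(block - exonLength, nExons, replace = TRUE)
    exome <- GRanges("chr1", IRanges(start = starts, width = exonLength))
    files <- NULL
    if (!is.null(dir)) {
      dir.create(dir, recursive = TRUE, showWarnings = FALSE)
      fasta <- file.path(dir, "genome.fa")
      bed <- file.path(dir, "exome.bed")
      writeXStringSet(genome, fasta)
      rtracklayer::export(exome, bed)
      files <- list(fasta = fasta, bed = bed)
    }
    list(genome = genome, exome = exome, files = files)
  })
}

#' Plant context-specific true signatures
#'
#' Each true signature concentrates `withinPatternMass` of its probability
#' uniformly over the universe sequences matching a few generating category
#' patterns (degenerate patterns with specificity up to three bases from
#' the mutation, drawn by [sampleCategory()]), and spreads the rest
#' uniformly over the remaining sequences. Signatures whose supports
#' overlap too strongly (cosine > 0.3 with an earlier signature) are
#' redrawn so the planted factors are identifiable.
#'
#' @param kTrue number of true signatures.
#' @param patternsPerSignature generating patterns per signature.
#' @param withinPatternMass probability mass on the generating patterns.
#' @param concentration interval-length concentration for
#'   [sampleCategory()].
#' @param seed integer seed.
#' @return list with `patterns` (list of character vectors) and `Hseq`
#'   (`kTrue` x 24,576 row-stochastic matrix over the sequence universe).
#' @export
simulateTruth <- function(kTrue = 3L, patternsPerSignature = 3L,
                          withinPatternMass = 0.9, concentration = 10,
                          seed = 1L) {
  stopifnot(kTrue >= 1L, withinPatternMass > 0, withinPatternMass <= 1)
  withSeed(seed, {
    Hseq <- matrix(0, kTrue, .N_UNIVERSE)
    patterns <- vector("list", kTrue)
    for (k in seq_len(kTrue)) {
      for (try in seq_len(50L)) {
        ps <- replicate(patternsPerSignature, sampleCategory(concentration))
        support <- Reduce(`|`, lapply(ps, function(p) .matchVector(parsePattern(p))))
        if (!any(support)) next
        row <- rep((1 - withinPatternMass) / max(1L, sum(!support)), .N_UNIVERSE)
        row[support] <- withinPatternMass / sum(support)
        if (all(support)) row <- rep(1 / .N_UNIVERSE, .N_UNIVERSE)
        row <- row / sum(row)
        ok <- k == 1L || all(vapply(
          seq_len(k - 1L),
          function(j) cosineSimilarity(Hseq[j, ], row) < 0.3, logical(1L)
        ))
        if (ok) {
          Hseq[k, ] <- row
          patterns[[k]] <- ps
          break
        }
      }
      if (all(Hseq[k, ] == 0)) {
        stop("could not plant a distinct signature ", k)
      }
    }
    list(
      patterns = patterns, Hseq = Hseq,
      withinPatternMass = withinPatternMass
    )
  })
}

#' Categorization containing the planted generating patterns
#'
#' Combines the truth's generating patterns with freshly sampled categories
#' (to a total of 95 plus the joker) and resolves conflicts. Useful as the
#' "oracle" categorization in recovery experiments.
#'
#' @param truth result of [simulateTruth()].
#' @param config a [gaConfig()] list.
#' @param seed optional seed.
#' @return a [MutationCategorization-class].
#' @export
plantedCategorization <- function(truth, config = gaConfig(), seed = NULL) {
  withSeed(seed, {
    pool <- unique(unlist(truth$patterns))
    while (length(pool) < 95L) {
      pool <- unique(c(pool, sampleCategory(config$concentration)))
    }
    resolveConflicts(c(pool, .JOKER), config, name = "planted")
  })
}

# rolling 7-mer index over a chromosome's base codes; returns the vector of
# eligible central positions and their collapsed context k-mer index
.positionContexts <- function(codes) {
  L <- length(codes)
  if (L < 7L) {
    return(list(pos = integer(0), ctx = integer(0)))
  }
  P <- 4:(L - 3L)
  k <- codes[P - 3L] - 1L
  for (off in -2:3) k <- k * 4L + (codes[P + off] - 1L)
  ok <- !is.na(k)
  km <- .kmerMaps()
  list(pos = P[ok], ctx = km$collapsed[k[ok] + 1L])
}

#' Simulate WGS and WES cohorts with coupled expression
#'
#' Per-sample exposures are drawn from a symmetric Dirichlet
#' (gamma-normalized) prior; mutation counts are Poisson with mean
#' `burdenMean` for WGS samples and `burdenMean` scaled by the
#' exome/genome eligible-position ratio for WES samples. Each mutation
#' draws a mutation sequence from the exposure-mixed true signatures, then
#' a genome position carrying that (collapsed) 7-mer context — uniformly
#' over the whole genome for WGS, over exome centres for WES. A drawn
#' context absent from the genome is redrawn (up to 50 rounds, then an
#' error). Records are emitted on the genomic strand, so purine-reference
#' rows round-trip through pyrimidine collapsing.
#'
#' Expression for the WES samples is `softplus(coupling * W_true %*% B)`
#' plus Gaussian noise (clamped at zero) for the coupled ("DDR-like")
#' genes, and exposure-independent noise of the same marginal form for the
#' control genes.
#'
#' @param genomeSim result of [simulateGenome()] (or a list with `genome`
#'   and `exome`).
#' @param truth result of [simulateTruth()].
#' @param nWgs,nWes cohort sizes.
#' @param burdenMean mean WGS mutations per sample.
#' @param exposureShape gamma shape of the exposure prior.
#' @param couplingStrength scale of the exposure-to-expression map (0
#'   decouples expression entirely).
#' @param nCoupledGenes,nControlGenes gene counts for the coupled and
#'   control sets.
#' @param noiseSd Gaussian noise on expression.
#' @param seed integer seed.
#' @param dir optional output directory for `wgs_mutations.tsv`,
#'   `wes_mutations.tsv`, `expression.tsv`, gene-set lists and
#'   `truth.json`.
#' @return list with `wgs`, `wes` (record data.frames incl. the intended
#'   `seqIndex`), `expression`, `geneSets`, `truth` (per-cohort true
#'   exposures and the coupling matrix `B`) and `files`.
#' @export
simulateCohort <- function(genomeSim, truth, nWgs = 30L, nWes = 30L,
                           burdenMean = 500, exposureShape = 2,
                           couplingStrength = 1, nCoupledGenes = 40L,
                           nControlGenes = 20L, noiseSd = 0.1, seed = 1L,
                           dir = NULL) {
  genome <- genomeSim$genome
  exome <- genomeSim$exome
  codes <- match(strsplit(as.character(genome[[1L]]), "", fixed = TRUE)[[1L]], .BASES)
  chrom <- sub("\\s.*$", "", names(genome)[1L])
  pc <- .positionContexts(codes)
  inExome <- rep(FALSE, length(codes))
  for (i in seq_along(exome)) {
    inExome[start(exome)[i]:end(exome)[i]] <- TRUE
  }
  wesKeep <- inExome[pc$pos]
  idxGenome <- split(pc$pos, pc$ctx)
  idxExome <- split(pc$pos[wesKeep], pc$ctx[wesKeep])
  ratio <- sum(wesKeep) / length(pc$pos)
  ctxOfSeq <- .universeContextKmer()
  kTrue <- nrow(truth$Hseq)

  withSeed(seed, {
    drawCohort <- function(n, prefix, index, burden) {
      ids <- sprintf("%s%03d", prefix, seq_len(n))
      W <- matrix(rgamma(n * kTrue, shape = exposureShape), n, kTrue)
      W <- W / rowSums(W)
      rownames(W) <- ids
      present <- as.integer(names(index))
      recs <- vector("list", n)
      for (j in seq_len(n)) {
        nMut <- rpois(1L, burden)
        if (nMut == 0L) nMut <- 1L # keep every sample usable
        p <- as.numeric(W[j, ] %*% truth$Hseq)
        drawn <- sample.int(.N_UNIVERSE, nMut, replace = TRUE, prob = p)
        for (round in seq_len(50L)) {
          absent <- !(ctxOfSeq[drawn] %in% present)
          if (!any(absent)) break
          drawn[absent] <- sample.int(.N_UNIVERSE, sum(absent), replace = TRUE, prob = p)
        }
        if (any(!(ctxOfSeq[drawn] %in% present))) {
          stop("drawn context absent from the genome after 50 redraws")
        }
        ctx <- ctxOfSeq[drawn]
        pos <- integer(nMut)
        for (cc in unique(ctx)) {
          at <- which(ctx == cc)
          cand <- index[[as.character(cc)]]
          pos[at] <- cand[sample.int(length(cand), length(at), replace = TRUE)]
        }
        centerCode <- codes[pos]
        altChar <- substr(.universe()$strings[drawn], 5L, 5L)
        pur <- centerCode %in% c(1L, 3L)
        altCode <- match(altChar, .BASES)
        altCode[pur] <- 5L - altCode[pur]
        recs[[j]] <- data.frame(
          sample_id = ids[j], chromosome = chrom, position = pos,
          reference_allele = .BASES[centerCode],
          mutated_allele = .BASES[altCode],
          seqIndex = drawn,
          stringsAsFactors = FALSE
        )
      }
      list(records = do.call(rbind, recs), W = W, ids = ids)
    }

    wgs <- drawCohort(nWgs, "WGS", idxGenome, burdenMean)
    wes <- drawCohort(nWes, "WES", idxExome, burdenMean * ratio)

    B <- matrix(runif(kTrue * nCoupledGenes, 0.5, 2.5), kTrue, nCoupledGenes)
    signal <- couplingStrength * (wes$W %*% B)
    coupled <- .softplus(4 * signal) +
      matrix(rnorm(nWes * nCoupledGenes, sd = noiseSd), nWes)
    control <- .softplus(matrix(rnorm(nWes * nControlGenes, 1, 0.5), nWes)) +
      matrix(rnorm(nWes * nControlGenes, sd = noiseSd), nWes)
    E <- pmax(cbind(coupled, control), 0)
    dimnames(E) <- list(wes$ids, c(
      sprintf("DDRL%03d", seq_len(nCoupledGenes)),
      sprintf("CTRL%03d", seq_len(nControlGenes))
    ))
    geneSets <- list(
      ddr_like = colnames(E)[seq_len(nCoupledGenes)],
      control_like = colnames(E)[nCoupledGenes + seq_len(nControlGenes)]
    )

    files <- NULL
    if (!is.null(dir)) {
      dir.create(dir, recursive = TRUE, showWarnings = FALSE)
      files <- list(
        wgs = file.path(dir, "wgs_mutations.tsv"),
        wes = file.path(dir, "wes_mutations.tsv"),
        expression = file.path(dir, "expression.tsv"),
        geneSets = c(
          ddr_like = file.path(dir, "geneset_ddr_like.txt"),
          control_like = file.path(dir, "geneset_control_like.txt")
        ),
        truth = file.path(dir, "truth.json")
      )
      write.table(wgs$records[, 1:5], files$wgs,
        sep = "\t", quote = FALSE, row.names = FALSE
      )
      write.table(wes$records[, 1:5], files$wes,
        sep = "\t", quote = FALSE, row.names = FALSE
      )
      write.table(
        data.frame(sample_id = rownames(E), E, check.names = FALSE),
        files$expression,
        sep = "\t", quote = FALSE, row.names = FALSE
      )
      writeLines(geneSets$ddr_like, files$geneSets[["ddr_like"]])
      writeLines(geneSets$control_like, files$geneSets[["control_like"]])
      write_json(
        list(
          patterns = truth$patterns,
          W_wgs = wgs$W, W_wes = wes$W, B = B,
          within_pattern_mass = truth$withinPatternMass
        ),
        files$truth,
        digits = NA, matrix = "rowmajor"
      )
    }
    list(
      wgs = wgs$records, wes = wes$records, expression = E,
      geneSets = geneSets,
      truth = list(W_wgs = wgs$W, W_wes = wes$W, B = B),
      files = files
    )
  })
}

#' The bundled small synthetic fixture
#'
#' A deterministic mini-dataset used throughout the test suites: a 200 kb
#' genome with a 25% exome, three planted signatures, and cohorts of 30
#' WGS-like and 30 WES-like samples with ~500 (WGS) mutations per sample
#' and expression coupled to the planted exposures. All files are written
#' to `dir` and read back through the standard file-based constructors, so
#' the whole FASTA/TSV round trip is exercised.
#'
#' @param seed integer seed; all internal seeds derive from it.
#' @param dir output directory (default: a session temporary directory).
#' @return list with `dataset` (a [MutationDataset-class]), `truth`,
#'   `cohort`, `genome` and `dir`.
#' @export
fixtureSmall <- function(seed = 1L, dir = tempfile("ddcat_fixture_")) {
  gen <- simulateGenome(
    length = 2e5, gcContent = 0.5, exomeFraction = 0.25,
    seed = seed, dir = dir
  )
  truth <- simulateTruth(
    kTrue = 3L, patternsPerSignature = 3L,
    withinPatternMass = 0.9, seed = seed + 1L
  )
  cohort <- simulateCohort(gen, truth,
    nWgs = 30L, nWes = 30L,
    burdenMean = 500, seed = seed + 2L, dir = dir
  )
  dataset <- buildDataset(
    genome = gen$files$fasta,
    wgs = cohort$files$wgs,
    wes = cohort$files$wes,
    expression = cohort$files$expression,
    geneSets = cohort$files$geneSets,
    exome = gen$files$bed,
    name = "fixture_small"
  )
  list(dataset = dataset, truth = truth, cohort = cohort, genome = gen, dir = dir)
}
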