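# Categorization fitness: held-out canonical correlation between inferred
# signature exposures and gene expression. CCA is ridge-regularized and
# solved as a generalized eigenproblem on the training covariance matrices;
# the statistic is the Pearson correlation of the first pair of canonical
# variates on the held-out fold, averaged over folds (and, for the fitness
# score, over the K values around K*).

# deterministic fold assignment: a shuffled 1..nFolds labelling of n samples
.foldAssignment <- function(n, nFolds, seed = NULL) {
  if (n < nFolds) stop("more folds than samples")
  withSeed(seed, sample(rep_len(seq_len(nFolds), n)))
}

# ridge-regularized CCA on training rows; returns first-pair weight vectors
.ccaFit <- function(X, Y, reg) {
  p <- ncol(X)
  q <- ncol(Y)
  n <- nrow(X)
  Cxx <- crossprod(X) / (n - 1) + diag(reg, p)
  Cyy <- crossprod(Y) / (n - 1) + diag(reg, q)
  Cxy <- crossprod(X, Y) / (n - 1)
  # eigenproblem on the smaller view
  if (p <= q) {
    Mx <- solve(Cxx, Cxy %*% solve(Cyy, t(Cxy)))
    a <- Re(eigen(Mx)$vectors[, 1L])
    b <- solve(Cyy, t(Cxy) %*% a)
  } else {
    My <- solve(Cyy, t(Cxy) %*% solve(Cxx, Cxy))
    b <- Re(eigen(My)$vectors[, 1L])
    a <- solve(Cxx, Cxy %*% b)
  }
  a <- a / sqrt(sum(a^2))
  b <- b / sqrt(sum(b^2))
  # orient so the training correlation is positive
  tr <- cor(X %*% a, Y %*% b)
  if (is.finite(tr) && tr < 0) b <- -b
  list(a = as.numeric(a), b = as.numeric(b))
}

#' Held-out canonical correlation between two views
#'
#' Cross-validated regularized CCA: in each fold the CCA weight vectors are
#' learned on the training rows (centred and scaled by training statistics,
#' with ridge `reg` added to both views' covariance matrices) and the
#' Pearson correlation of the first pair of canonical variates is computed
#' on the held-out rows. Columns that are constant in a training split are
#' dropped from both splits. The weights are oriented so the training
#' correlation is positive, so held-out correlations are signed.
#'
#' @param W samples x exposures view.
#' @param E samples x genes view (rows aligned to `W`).
#' @param nFolds number of folds (default 10).
#' @param reg ridge regularization added to both views (default 0.1).
#' @param seed optional seed for the fold shuffle.
#' @param folds optional precomputed fold assignment (overrides `seed`),
#'   used to keep folds identical across categorizations.
#' @return list with `meanCorrelation` and `foldCorrelations`.
#' @export
ccaTestCorrelation <- function(W, E, nFolds = 10L, reg = 0.1, seed = NULL,
                               folds = NULL) {
  W <- as.matrix(W)
  E <- as.matrix(E)
  n <- nrow(W)
  stopifnot(nrow(E) == n)
  if (n < 2L * nFolds) {
    stop("need at least 2 * nFolds samples")
  }
  if (is.null(folds)) folds <- .foldAssignment(n, nFolds, seed)
  rs <- vapply(seq_len(nFolds), function(f) {
    tr <- folds != f
    te <- !tr
    keepX <- apply(W[tr, , drop = FALSE], 2L, sd) > 0
    keepY <- apply(E[tr, , drop = FALSE], 2L, sd) > 0
    if (sum(keepX) < 1L || sum(keepY) < 1L) {
      return(NA_real_)
    }
    Xtr <- scale(W[tr, keepX, drop = FALSE])
    Ytr <- scale(E[tr, keepY, drop = FALSE])
    fit <- .ccaFit(Xtr, Ytr, reg)
    Xte <- scale(W[te, keepX, drop = FALSE],
      center = attr(Xtr, "scaled:center"), scale = attr(Xtr, "scaled:scale")
    )
    Yte <- scale(E[te, keepY, drop = FALSE],
      center = attr(Ytr, "scaled:center"), scale = attr(Ytr, "scaled:scale")
    )
    u <- Xte %*% fit$a
    v <- Yte %*% fit$b
    if (sd(u) == 0 || sd(v) == 0) {
      return(NA_real_)
    }
    cor(u, v)
  }, numeric(1L))
  list(
    meanCorrelation = mean(rs, na.rm = TRUE),
    foldCorrelations = rs
  )
}

#' Fitness-evaluation configuration
#'
#' Collects the knobs of the per-categorization fitness pipeline. The
#' defaults mirror the discovery protocol (10-fold CCA, K range of
#' half-width 2 around `K*`) with a lighter NMF effort (3 restarts) suited
#' to evaluating many categorizations inside the genetic algorithm;
#' [outOfSampleEvaluation()] uses the full 10-restart protocol instead.
#'
#' @param nmfRestarts,nmfMaxIter,nmfTol NMF effort per K.
#' @param nFolds,ccaReg CCA cross-validation folds and ridge strength.
#' @param kHalfWidth K range is `[K* - kHalfWidth, K* + kHalfWidth]`,
#'   clamped below at 1.
#' @param geneSet name of the dataset gene set used as the expression view
#'   (`NULL`: the first one).
#' @param foldSeed seed for the (dataset-level, shared) fold shuffle.
#' @return a named list.
#' @export
fitnessConfig <- function(nmfRestarts = 3L, nmfMaxIter = 500L, nmfTol = 1e-5,
                          nFolds = 10L, ccaReg = 0.1, kHalfWidth = 2L,
                          geneSet = NULL, foldSeed = 1L) {
  list(
    nmfRestarts = nmfRestarts, nmfMaxIter = nmfMaxIter, nmfTol = nmfTol,
    nFolds = nFolds, ccaReg = ccaReg, kHalfWidth = kHalfWidth,
    geneSet = geneSet, foldSeed = foldSeed
  )
}

.datasetExpressionView <- function(dataset, geneSet = NULL) {
  gs <- if (is.null(geneSet)) dataset@geneSets[[1L]] else dataset@geneSets[[geneSet]]
  if (is.null(gs)) stop("unknown gene set: ", geneSet)
  genes <- intersect(colnames(dataset@expression), gs)
  if (!length(genes)) stop("gene set shares no genes with the expression matrix")
  dataset@expression[, genes, drop = FALSE]
}

#' Fitness of a categorization on a dataset
#'
#' Runs the full scoring pipeline: build the WGS catalog under the
#' categorization, factorize its row-normalized counts by KL-NMF for each
#' `K` in the range around the dataset's `K*`, renormalize the signatures
#' from genome to exome opportunities, refit the WES samples' exposures by
#' NNLS, and score the held-out CCA correlation against the dataset's gene
#' expression. The fitness is the mean correlation over all K values and
#' folds.
#'
#' @param categorization a [MutationCategorization-class].
#' @param dataset a [MutationDataset-class] with `kStar` set (or pass
#'   `kRange`).
#' @param config a [fitnessConfig()] list.
#' @param kRange optional explicit integer vector of K values (overrides
#'   the `K*`-centred range).
#' @return list with `value` (the fitness), `perK` (named mean correlation
#'   per K) and `folds` (per-K fold correlations).
#' @export
categorizationFitness <- function(categorization, dataset,
                                  config = fitnessConfig(), kRange = NULL) {
  if (is.null(kRange)) {
    if (is.na(dataset@kStar)) {
      stop("dataset has no K*; run selectK() first or pass kRange")
    }
    kRange <- (dataset@kStar - config$kHalfWidth):(dataset@kStar + config$kHalfWidth)
    if (any(kRange < 1L)) {
      warning("K range clamped at 1")
      kRange <- kRange[kRange >= 1L]
    }
  }
  kRange <- sort(unique(as.integer(kRange)))

  wgsV <- normalizeCatalog(.datasetCatalog(dataset, categorization, "wgs"))
  wesCat <- .datasetCatalog(dataset, categorization, "wes")
  wesV <- normalizeCatalog(wesCat)
  U <- .datasetOpportunities(dataset, categorization)
  E <- .datasetExpressionView(dataset, config$geneSet)
  E <- E[rownames(wesV), , drop = FALSE]
  folds <- .foldAssignment(nrow(wesV), config$nFolds, config$foldSeed)

  kRange <- kRange[kRange <= min(dim(wgsV))]
  perK <- setNames(numeric(length(kRange)), kRange)
  foldCor <- list()
  for (i in seq_along(kRange)) {
    fit <- nmfKL(wgsV, kRange[i],
      nRestarts = config$nmfRestarts,
      maxIter = config$nmfMaxIter, tol = config$nmfTol
    )
    Hwes <- renormalizeSignatures(fit$H, U$wgs, U$wes)
    W <- nnlsExposures(wesV, Hwes)
    cc <- ccaTestCorrelation(W, E,
      nFolds = config$nFolds,
      reg = config$ccaReg, folds = folds
    )
    perK[i] <- cc$meanCorrelation
    foldCor[[as.character(kRange[i])]] <- cc$foldCorrelations
  }
  list(value = mean(perK), perK = perK, folds = foldCor)
}

#' Rank a population across datasets
#'
#' For each dataset, individuals are ranked 1 (worst) to S (best) by
#' fitness, with ties broken by stable individual order. The average
#' ranking ranks individuals by the mean of their per-dataset ranks (again
#' stable under ties); its top individual is the overall best.
#'
#' @param fitness individuals x datasets numeric matrix.
#' @return list with `perDataset` (S x D rank matrix), `average` (ranks
#'   1..S under the average ranking) and `best` (index of the top
#'   individual).
#' @export
rankPopulation <- function(fitness) {
  fitness <- as.matrix(fitness)
  if (anyNA(fitness)) stop("missing fitness scores")
  perDataset <- apply(fitness, 2L, function(f) rank(f, ties.method = "first"))
  perDataset <- matrix(as.numeric(perDataset),
    nrow(fitness), ncol(fitness),
    dimnames = dimnames(fitness)
  )
  avg <- rank(rowMeans(perDataset), ties.method = "first")
  list(
    perDataset = perDataset,
    average = avg,
    best = which.max(avg)
  )
}

#' Rank-power selection probabilities
#'
#' `p[i] = rank[i]^power / sum(rank^power)`: the higher the power, the more
#' selection mass concentrates on top-ranked individuals.
#'
#' @param ranks a permutation of `1:S` (1 = worst).
#' @param power positive exponent (default 5).
#' @return probability vector summing to one.
#' @examples
#' selectionProbabilities(1:3, power = 5) # c(1, 32, 243) / 276
#' @export
selectionProbabilities <- function(ranks, power = 5) {
  if (power <= 0) stop("'power' must be positive")
  if (!setequal(ranks, seq_along(ranks))) {
    stop("'ranks' must be a permutation of 1..S")
  }
  p <- ranks^power
  p / sum(p)
}
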