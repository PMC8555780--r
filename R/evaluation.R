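# Out-of-sample benchmarking of categorizations and comparison of
# discovered signatures against a reference catalog over the standard 96
# categories.

#' Cosine similarity
#'
#' @param a,b non-negative vectors of equal length, not all zero.
#' @return value in `[0, 1]` for non-negative inputs.
#' @examples
#' cosineSimilarity(c(1, 1, 0), c(1, 0, 0)) # 1 / sqrt(2)
#' @export
cosineSimilarity <- function(a, b) {
  stopifnot(length(a) == length(b))
  na <- sqrt(sum(a^2))
  nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0) stop("cosine similarity of a zero vector is undefined")
  sum(a * b) / (na * nb)
}

#' Transform a signature onto the standard categories
#'
#' `S' = S %*% T` with `T` the row-stochastic [transformationMatrix()];
#' probability mass is preserved except for mass on empty categories (zero
#' rows of `T`), in which case the result is renormalized with a warning.
#'
#' @param S signature row vector (or signatures x categories matrix) over
#'   the source categories.
#' @param T transformation matrix from [transformationMatrix()].
#' @return matrix of signatures over the standard categories.
#' @export
transformSignature <- function(S, T) {
  if (is.null(dim(S))) S <- matrix(S, nrow = 1L)
  stopifnot(ncol(S) == nrow(T))
  out <- S %*% T
  lost <- abs(rowSums(out) - rowSums(S)) > 1e-9
  if (any(lost)) {
    warning(
      sum(lost), " signature(s) had mass on empty categories; renormalized"
    )
    out[lost, ] <- out[lost, , drop = FALSE] / rowSums(out[lost, , drop = FALSE])
  }
  out
}

#' Read a reference signature matrix
#'
#' TSV with signatures in rows (first column `signature`) and the 96
#' standard categories as remaining columns, labelled `A[C>A]A` ...
#' `T[T>G]T`. Columns are reordered to the canonical standard order and
#' rows renormalized to sum to one if needed.
#'
#' @param path TSV path.
#' @return signatures x 96 row-stochastic matrix.
#' @export
readReferenceSignatures <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (colnames(df)[1L] != "signature") {
    stop("reference TSV must have 'signature' as its first column")
  }
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- df$signature
  std <- categoryLabels(standardCategorization())
  missing <- setdiff(std, colnames(m))
  if (length(missing)) {
    stop("reference is missing standard categories, e.g. ", missing[1L])
  }
  m <- m[, std, drop = FALSE]
  m / rowSums(m)
}

#' Match signatures to a reference catalog
#'
#' Transforms each signature onto the standard categories and reports, per
#' signature, all reference signatures with cosine similarity above the
#' threshold (sorted descending). When none passes, the single best match
#' is reported with `subThreshold = TRUE`.
#'
#' @param H signatures x categories matrix (rows of the discovered
#'   signature matrix).
#' @param T transformation matrix of `H`'s categorization.
#' @param reference signatures x 96 reference matrix (see
#'   [readReferenceSignatures()]).
#' @param threshold similarity cut-off (default 0.8).
#' @return data.frame with columns `signature`, `reference`, `similarity`,
#'   `subThreshold`.
#' @export
matchToReference <- function(H, T, reference, threshold = 0.8) {
  Ht <- transformSignature(H, T)
  sigNames <- rownames(H) %||% paste0("S", seq_len(nrow(Ht)))
  refNames <- rownames(reference) %||% paste0("Ref", seq_len(nrow(reference)))
  out <- lapply(seq_len(nrow(Ht)), function(i) {
    sims <- vapply(
      seq_len(nrow(reference)),
      function(j) cosineSimilarity(Ht[i, ], reference[j, ]),
      numeric(1L)
    )
    pass <- which(sims > threshold)
    if (length(pass)) {
      pass <- pass[order(sims[pass], decreasing = TRUE)]
      data.frame(
        signature = sigNames[i], reference = refNames[pass],
        similarity = sims[pass], subThreshold = FALSE
      )
    } else {
      j <- which.max(sims)
      data.frame(
        signature = sigNames[i], reference = refNames[j],
        similarity = sims[j], subThreshold = TRUE
      )
    }
  })
  do.call(rbind, out)
}

#' Rank reference signatures by average exposure prevalence
#'
#' Refits all reference signatures jointly to the row-normalized catalog by
#' NNLS and ranks them by mean exposure across samples, most prevalent
#' first. For an evaluation at order `K`, the top `K` signatures of this
#' ranking are used.
#'
#' @param reference signatures x categories row-stochastic matrix over the
#'   catalog's categories.
#' @param catalog a [MutationCatalog-class] (or counts matrix) built under
#'   the same categorization.
#' @return character vector of reference signature names, most prevalent
#'   first, with mean exposures as the `"meanExposure"` attribute.
#' @export
prevalenceRanking <- function(reference, catalog) {
  V <- normalizeCatalog(catalog)
  if (ncol(V) != ncol(reference)) {
    stop("catalog and reference live on different category spaces")
  }
  W <- nnlsExposures(V, reference)
  meanExp <- colMeans(W)
  ord <- order(meanExp, decreasing = TRUE)
  out <- (rownames(reference) %||% paste0("Ref", seq_len(nrow(reference))))[ord]
  attr(out, "meanExposure") <- meanExp[ord]
  out
}

#' Out-of-sample evaluation of a categorization
#'
#' For each `K` in `kList`: fit KL-NMF (best of `nRestarts`) to the
#' row-normalized WGS catalog, renormalize the signatures from genome to
#' exome opportunities, refit the held-out WES samples' exposures by NNLS,
#' and report (i) the KL reconstruction error of the refit against the WES
#' row-normalized catalog and (ii) the held-out CCA correlation against
#' each gene set.
#'
#' @param categorization a [MutationCategorization-class].
#' @param dataset a [MutationDataset-class]; its WES samples act as the
#'   test set.
#' @param kList integer vector of K values (e.g. `2:(max(kCosmic, kStar) + 2)`).
#' @param nRestarts NMF restarts (default 10, the reconstruction-error
#'   protocol).
#' @param nFolds,ccaReg,foldSeed CCA cross-validation settings.
#' @param seed seed for the NMF restarts.
#' @return data.frame with one row per (K, gene set): columns `K`,
#'   `geneSet`, `reconstructionError`, `correlation`.
#' @export
outOfSampleEvaluation <- function(categorization, dataset, kList,
                                  nRestarts = 10L, nFolds = 10L, ccaReg = 0.1,
                                  foldSeed = 1L, seed = NULL) {
  wgsV <- normalizeCatalog(.datasetCatalog(dataset, categorization, "wgs"))
  wesV <- normalizeCatalog(.datasetCatalog(dataset, categorization, "wes"))
  U <- .datasetOpportunities(dataset, categorization)
  folds <- .foldAssignment(nrow(wesV), nFolds, foldSeed)
  kList <- sort(unique(as.integer(kList)))
  if (any(kList > min(dim(wgsV)))) {
    stop("K exceeds the WGS catalog dimensions")
  }
  withSeed(seed, {
    rows <- list()
    for (K in kList) {
      fit <- nmfKL(wgsV, K, nRestarts = nRestarts)
      Hwes <- renormalizeSignatures(fit$H, U$wgs, U$wes)
      W <- nnlsExposures(wesV, Hwes)
      err <- klDivergence(wesV, W, Hwes)
      for (gs in names(dataset@geneSets)) {
        E <- .datasetExpressionView(dataset, gs)[rownames(wesV), , drop = FALSE]
        cc <- ccaTestCorrelation(W, E, nFolds = nFolds, reg = ccaReg, folds = folds)
        rows[[length(rows) + 1L]] <- data.frame(
          K = K, geneSet = gs,
          reconstructionError = as.numeric(err),
          correlation = cc$meanCorrelation
        )
      }
    }
    do.call(rbind, rows)
  })
}
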