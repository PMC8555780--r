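# Signature discovery: non-negative matrix factorization under generalized
# Kullback-Leibler divergence (multiplicative updates), NNLS exposure
# refitting, and a simplified cross-validation selector for the number of
# signatures ("cv2k_lite": masked-entry imputation with a one-standard-error
# parsimony rule).

.NMF_EPS <- 1e-12

#' Generalized Kullback-Leibler divergence of a factorization
#'
#' Computes `sum(V * log(V / WH) - V + WH)` with the convention
#' `0 * log(0) = 0`. When `WH` is zero where `V` is positive the divergence
#' is infinite; the returned value is then `Inf` with attribute
#' `"undefined" = TRUE`.
#'
#' @param V non-negative target matrix.
#' @param W,H factor matrices with `ncol(W) == nrow(H)`.
#' @param mask optional logical matrix; only `TRUE` entries contribute.
#' @return non-negative scalar.
#' @examples
#' klDivergence(matrix(c(1, 1), 1), matrix(1, 1, 1), matrix(c(2, 1), 1)) # 1 - log(2)
#' @export
klDivergence <- function(V, W, H, mask = NULL) {
  WH <- W %*% H
  pos <- V > 0
  if (!is.null(mask)) pos <- pos & mask
  bad <- pos & WH == 0
  term <- WH
  term[pos] <- V[pos] * log(V[pos] / WH[pos]) - V[pos] + WH[pos]
  if (!is.null(mask)) term[!mask] <- 0
  out <- sum(term[!bad])
  if (any(bad)) {
    out <- Inf
    attr(out, "undefined") <- TRUE
  }
  out
}

.nmfRun <- function(V, K, maxIter, tol, mask = NULL) {
  n <- nrow(V)
  m <- ncol(V)
  B <- if (is.null(mask)) NULL else (mask * 1)
  scale <- sqrt(mean(if (is.null(mask)) V else V[mask]) / K)
  W <- matrix(runif(n * K), n, K) * scale
  H <- matrix(runif(K * m), K, m) * scale
  obj <- Inf
  trace <- numeric(0)
  for (it in seq_len(maxIter)) {
    WH <- pmax(W %*% H, .NMF_EPS)
    R <- V / WH
    if (is.null(B)) {
      W <- W * ((R %*% t(H)) / pmax(rep(rowSums(H), each = n), .NMF_EPS))
      WH <- pmax(W %*% H, .NMF_EPS)
      R <- V / WH
      H <- H * ((t(W) %*% R) / pmax(rep(colSums(W), times = m), .NMF_EPS))
    } else {
      R <- R * B
      W <- W * ((R %*% t(H)) / pmax(B %*% t(H), .NMF_EPS))
      WH <- pmax(W %*% H, .NMF_EPS)
      R <- (V / WH) * B
      H <- H * ((t(W) %*% R) / pmax(t(W) %*% B, .NMF_EPS))
    }
    newObj <- klDivergence(V, W, pmax(H, 0), mask = mask)
    trace <- c(trace, newObj)
    if (is.finite(obj) && abs(obj - newObj) <= tol * max(abs(obj), .NMF_EPS)) {
      obj <- newObj
      break
    }
    obj <- newObj
  }
  list(W = W, H = H, error = obj, trace = trace, iterations = length(trace))
}

#' KL-divergence non-negative matrix factorization
#'
#' Factorizes a non-negative matrix `V ~ W %*% H` by multiplicative updates
#' minimizing the generalized Kullback-Leibler divergence. Several random
#' restarts are performed and the best (smallest final divergence) is
#' returned. After fitting, rows of `H` are normalized to sum to one with a
#' compensating rescale of `W`'s columns, which leaves `W %*% H` unchanged.
#'
#' An optional logical `mask` restricts the objective (and updates) to the
#' `TRUE` entries, which is used for held-out imputation in [selectK()].
#'
#' @param V non-negative matrix (samples x categories).
#' @param K factorization rank, `1 <= K <= min(dim(V))`.
#' @param nRestarts number of random initializations (default 10).
#' @param maxIter maximum multiplicative updates per restart.
#' @param tol relative objective-change stopping tolerance.
#' @param seed optional seed; `NULL` uses the current RNG stream.
#' @param mask optional logical matrix of observed entries.
#' @return list with `W` (n x K), `H` (K x m, row-stochastic), `error`
#'   (best final KL divergence), `trace` (objective per iteration of the
#'   best restart) and `restartErrors`.
#' @export
nmfKL <- function(V, K, nRestarts = 10L, maxIter = 2000L, tol = 1e-6,
                  seed = NULL, mask = NULL) {
  V <- as.matrix(V)
  .assertMatrixNonNegative(V, "V")
  K <- as.integer(K)
  if (K < 1L || K > min(dim(V))) {
    stop("K must lie in 1..min(dim(V))")
  }
  withSeed(seed, {
    best <- NULL
    errs <- numeric(nRestarts)
    for (r in seq_len(nRestarts)) {
      fit <- .nmfRun(V, K, maxIter, tol, mask)
      errs[r] <- fit$error
      if (is.null(best) || fit$error < best$error) best <- fit
    }
    rs <- rowSums(best$H)
    if (any(rs == 0)) rs[rs == 0] <- 1
    H <- best$H / rs
    W <- best$W * rep(rs, each = nrow(best$W))
    dimnames(W) <- list(rownames(V), NULL)
    dimnames(H) <- list(NULL, colnames(V))
    list(
      W = W, H = H, error = best$error, trace = best$trace,
      iterations = best$iterations, restartErrors = errs
    )
  })
}

#' Refit exposures by non-negative least squares
#'
#' For fixed signatures `H`, estimates each sample's exposures as
#' `argmin_{w >= 0} || V[j, ] - w %*% H ||_2` via Lawson-Hanson NNLS.
#'
#' @param V samples x categories matrix (rows aligned to `H`'s columns).
#' @param H signatures x categories matrix; must have no all-zero rows.
#' @return samples x signatures non-negative exposure matrix.
#' @export
nnlsExposures <- function(V, H) {
  V <- as.matrix(V)
  if (is.null(dim(H))) H <- matrix(H, nrow = 1L)
  stopifnot(ncol(V) == ncol(H))
  if (any(rowSums(abs(H)) == 0)) {
    stop("'H' contains all-zero signature rows")
  }
  A <- t(H)
  res <- vapply(
    seq_len(nrow(V)),
    function(j) {
      if (all(V[j, ] == 0)) {
        return(numeric(nrow(H)))
      }
      lsqnonneg(A, V[j, ])$x
    },
    numeric(nrow(H))
  )
  W <- if (is.matrix(res)) t(res) else matrix(res, ncol = 1L)
  dimnames(W) <- list(rownames(V), rownames(H))
  W
}

#' Choose the number of signatures by masked cross-validation
#'
#' A deliberately simple selector ("cv2k_lite"): for each repeat a random
#' fraction of matrix entries is hidden, a masked KL-NMF is fitted on the
#' remaining entries for every candidate `K`, and the KL imputation error
#' on the hidden entries is recorded. The chosen `K*` is the smallest
#' candidate whose mean error is within one standard error of the best mean
#' (parsimony rule). The full error curve is returned so an externally
#' determined `K*` can be substituted.
#'
#' @param V non-negative matrix.
#' @param kCandidates integer vector of candidate ranks.
#' @param maskFraction fraction of entries hidden per repeat (default 0.1).
#' @param nRepeats number of random maskings (default 5).
#' @param seed optional seed.
#' @param nRestarts,maxIter,tol passed to [nmfKL()] (lighter defaults here).
#' @return list with `kStar` and `errors` (candidates x repeats matrix).
#' @export
selectK <- function(V, kCandidates, maskFraction = 0.1, nRepeats = 5L,
                    seed = NULL, nRestarts = 2L, maxIter = 1000L, tol = 1e-5) {
  V <- as.matrix(V)
  kCandidates <- sort(unique(as.integer(kCandidates)))
  if (!length(kCandidates)) stop("no candidate K values")
  if (max(kCandidates) > min(dim(V))) {
    stop("candidate K exceeds min(dim(V))")
  }
  withSeed(seed, {
    errs <- matrix(
      NA_real_, length(kCandidates), nRepeats,
      dimnames = list(as.character(kCandidates), NULL)
    )
    nEntries <- length(V)
    for (r in seq_len(nRepeats)) {
      hidden <- sample.int(nEntries, max(1L, round(maskFraction * nEntries)))
      mask <- matrix(TRUE, nrow(V), ncol(V))
      mask[hidden] <- FALSE
      for (i in seq_along(kCandidates)) {
        fit <- nmfKL(V, kCandidates[i],
          nRestarts = nRestarts,
          maxIter = maxIter, tol = tol, mask = mask
        )
        errs[i, r] <- klDivergence(V, fit$W, fit$H, mask = !mask)
      }
    }
    means <- rowMeans(errs)
    bestI <- which.min(means)
    se <- sd(errs[bestI, ]) / sqrt(nRepeats)
    if (!is.finite(se)) se <- 0
    kStar <- kCandidates[which(means <= means[bestI] + se)[1L]]
    list(kStar = kStar, errors = errs, means = means, se = se)
  })
}
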