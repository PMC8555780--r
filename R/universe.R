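# Enumeration of the 7-mer mutation sequence universe and k-mer machinery.
#
# A mutation sequence is an 8-character string: positions 1-3 are the 5'
# flank, position 4 the original (pyrimidine-collapsed, so C or T) base,
# position 5 the new base, positions 6-8 the 3' flank. Internally bases are
# coded A=1, C=2, G=3, T=4 and sequences are addressed by a canonical index
#   idx = ((left * 2 + ref) * 3 + altRank) * 64 + right + 1
# where left/right are the base-4 big-endian flank codes (0..63), ref is 0
# for C and 1 for T, and altRank orders the three legal alternative bases
# alphabetically. The universe has 64 * 2 * 3 * 64 = 24,576 members.

.ddcat <- new.env(parent = emptyenv())

.BASES <- c("A", "C", "G", "T")
.N_UNIVERSE <- 24576L
.ALTS_C <- c(1L, 3L, 4L) # A, G, T
.ALTS_T <- c(1L, 2L, 3L) # A, C, G
# rank of alt code given ref (NA where alt == ref)
.ALT_RANK_C <- c(1L, NA, 2L, 3L)
.ALT_RANK_T <- c(1L, 2L, 3L, NA)

.universe <- function() {
  if (!is.null(.ddcat$universe)) {
    return(.ddcat$universe)
  }
  i <- 0:(.N_UNIVERSE - 1L)
  left <- i %/% 384L
  rem <- i %% 384L
  refb <- rem %/% 192L # 0 = C, 1 = T
  rem2 <- rem %% 192L
  altRank <- rem2 %/% 64L
  right <- rem2 %% 64L
  codes <- cbind(
    left %/% 16L + 1L,
    (left %/% 4L) %% 4L + 1L,
    left %% 4L + 1L,
    ifelse(refb == 0L, 2L, 4L),
    ifelse(refb == 0L, .ALTS_C[altRank + 1L], .ALTS_T[altRank + 1L]),
    right %/% 16L + 1L,
    (right %/% 4L) %% 4L + 1L,
    right %% 4L + 1L
  )
  storage.mode(codes) <- "integer"
  strings <- do.call(paste0, lapply(seq_len(8L), function(j) .BASES[codes[, j]]))
  .ddcat$universe <- list(codes = codes, strings = strings)
  .ddcat$universe
}

# codes: n x 8 integer matrix -> canonical universe index
.seqCodesToIndex <- function(codes) {
  if (is.null(dim(codes))) codes <- matrix(codes, nrow = 1L)
  refb <- as.integer(codes[, 4L] == 4L)
  bad <- !(codes[, 4L] %in% c(2L, 4L))
  if (any(bad)) {
    stop("original base (position 4) must be C or T after pyrimidine collapsing")
  }
  altRank <- ifelse(refb == 0L, .ALT_RANK_C[codes[, 5L]], .ALT_RANK_T[codes[, 5L]])
  if (anyNA(altRank)) {
    stop("alternative base (position 5) must differ from the original base")
  }
  left <- (codes[, 1L] - 1L) * 16L + (codes[, 2L] - 1L) * 4L + (codes[, 3L] - 1L)
  right <- (codes[, 6L] - 1L) * 16L + (codes[, 7L] - 1L) * 4L + (codes[, 8L] - 1L)
  as.integer(((left * 2L + refb) * 3L + (altRank - 1L)) * 64L + right + 1L)
}

#' Index of 8-character mutation sequences in the canonical universe
#'
#' Maps 8-character mutation sequence strings (flank, original base, new
#' base, flank; pyrimidine-collapsed) to their index in the canonical
#' enumeration of the 24,576-sequence universe.
#'
#' @param x character vector of 8-character sequences (e.g. `"TGTCTAAC"`).
#' @return integer vector of indices in `1:24576`.
#' @seealso [indexToSequence()]
#' @examples
#' sequenceIndex("TGTCTAAC")
#' @export
sequenceIndex <- function(x) {
  x <- toupper(as.character(x))
  if (any(nchar(x) != 8L)) {
    stop("mutation sequences must be 8 characters long")
  }
  codes <- matrix(match(unlist(strsplit(x, "", fixed = TRUE)), .BASES),
    ncol = 8L, byrow = TRUE
  )
  if (anyNA(codes)) {
    stop("mutation sequences may only contain A, C, G, T")
  }
  .seqCodesToIndex(codes)
}

#' @rdname sequenceIndex
#' @param i integer vector of universe indices.
#' @export
indexToSequence <- function(i) {
  i <- as.integer(i)
  if (any(is.na(i) | i < 1L | i > .N_UNIVERSE)) {
    stop("universe indices must lie in 1:", .N_UNIVERSE)
  }
  .universe()$strings[i]
}

#' The valid mutation sequence universe
#'
#' Returns all 24,576 valid 8-character mutation sequences in canonical
#' order: 64 left flanks x {C,T} original base x 3 alternative bases x 64
#' right flanks.
#'
#' @return character vector of length 24,576.
#' @export
mutationSequenceUniverse <- function() {
  .universe()$strings
}

# factorized views of the canonical index used by the fast pattern matcher:
# 64 left-flank code triples, the 6 (ref, alt) substitution combos, 64
# right-flank triples
.universeBlocks <- function() {
  if (!is.null(.ddcat$blocks)) {
    return(.ddcat$blocks)
  }
  f <- 0:63
  triple <- cbind(f %/% 16L + 1L, (f %/% 4L) %% 4L + 1L, f %% 4L + 1L)
  storage.mode(triple) <- "integer"
  .ddcat$blocks <- list(
    left = triple,
    right = triple,
    ref = c(2L, 2L, 2L, 4L, 4L, 4L),
    alt = c(1L, 3L, 4L, 1L, 2L, 3L)
  )
  .ddcat$blocks
}

## ---- 7-mer context machinery -------------------------------------------

.N_KMERS <- 16384L # 4^7

# codes: n x 7 matrix -> 7-mer index 1..16384 (lexicographic, A<C<G<T)
.kmerIndex <- function(codes) {
  if (is.null(dim(codes))) codes <- matrix(codes, nrow = 1L)
  k <- codes[, 1L] - 1L
  for (j in 2:7) k <- k * 4L + (codes[, j] - 1L)
  as.integer(k + 1L)
}

.kmerCodes <- function() {
  if (!is.null(.ddcat$kmerCodes)) {
    return(.ddcat$kmerCodes)
  }
  i <- 0:(.N_KMERS - 1L)
  K <- cbind(
    i %/% 4096L, (i %/% 1024L) %% 4L, (i %/% 256L) %% 4L, (i %/% 64L) %% 4L,
    (i %/% 16L) %% 4L, (i %/% 4L) %% 4L, i %% 4L
  ) + 1L
  storage.mode(K) <- "integer"
  .ddcat$kmerCodes <- K
  K
}

# For every 7-mer: the pyrimidine-collapsed representative (reverse
# complement when the central base is a purine) and the universe indices of
# the three single base substitutions at its centre.
.kmerMaps <- function() {
  if (!is.null(.ddcat$kmerMaps)) {
    return(.ddcat$kmerMaps)
  }
  K <- .kmerCodes()
  pur <- K[, 4L] %in% c(1L, 3L)
  Kc <- K
  Kc[pur, ] <- 5L - K[pur, 7:1, drop = FALSE]
  center <- Kc[, 4L]
  alt <- matrix(0L, .N_KMERS, 3L)
  for (j in 1:3) {
    alt[, j] <- ifelse(center == 2L, .ALTS_C[j], .ALTS_T[j])
  }
  altMap <- matrix(0L, .N_KMERS, 3L)
  for (j in 1:3) {
    altMap[, j] <- .seqCodesToIndex(cbind(
      Kc[, 1:3, drop = FALSE], center, alt[, j], Kc[, 5:7, drop = FALSE]
    ))
  }
  .ddcat$kmerMaps <- list(
    collapsed = .kmerIndex(Kc), # 7-mer -> collapsed 7-mer index
    altMap = altMap, # 7-mer x 3 -> universe index
    strings = do.call(paste0, lapply(1:7, function(j) .BASES[K[, j]]))
  )
  .ddcat$kmerMaps
}

# universe index -> collapsed 7-mer context index (positions 1-4, 6-8)
.universeContextKmer <- function() {
  if (!is.null(.ddcat$ctxKmer)) {
    return(.ddcat$ctxKmer)
  }
  codes <- .universe()$codes
  .ddcat$ctxKmer <- .kmerIndex(codes[, c(1:4, 6:8), drop = FALSE])
  .ddcat$ctxKmer
}
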