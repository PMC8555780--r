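# The degenerate category pattern language: an 8-symbol string over IUPAC
# codes where each symbol denotes a single base, a pair of bases, or the
# wildcard N. Position 4 (the original base) must be a clearly defined C or
# T and position 5 (the new base) a single base or pair disjoint from the
# original base. The all-wildcard "joker" pattern NNNNNNNN is the single
# exempt pattern; three-base IUPAC codes (B, D, H, V) are never allowed.

.IUPAC_SETS <- list(
  A = 1L, C = 2L, G = 3L, T = 4L,
  R = c(1L, 3L), Y = c(2L, 4L), S = c(2L, 3L),
  W = c(1L, 4L), K = c(3L, 4L), M = c(1L, 2L),
  N = 1:4
)

# reverse lookup: key "1-3" etc -> IUPAC letter
.IUPAC_CODE <- local({
  keys <- vapply(.IUPAC_SETS, function(s) paste(s, collapse = "-"), "")
  setNames(names(.IUPAC_SETS), keys)
})

#' A mutation category pattern
#'
#' An 8-symbol degenerate pattern over mutation sequences. `text` is the
#' canonical uppercase IUPAC form, `sets` a 4 x 8 logical membership matrix
#' (rows A, C, G, T), and `joker` flags the all-wildcard pattern.
#'
#' @name CategoryPattern-class
#' @aliases CategoryPattern
#' @exportClass CategoryPattern
setClass("CategoryPattern", representation(
  text = "character",
  sets = "matrix",
  joker = "logical"
))

#' Parse an 8-character IUPAC category pattern
#'
#' Validates and parses a category pattern. Flank symbols (positions 1-3 and
#' 6-8) may be single bases, two-base IUPAC codes, or `N`; position 4 must be
#' `C` or `T`; position 5 must be a single base or pair disjoint from
#' position 4. The joker pattern `NNNNNNNN` is accepted as a special case.
#' Three-base IUPAC codes (B, D, H, V) are rejected. Parsing is
#' case-insensitive; the canonical form is uppercase.
#'
#' @param text an 8-character string, or an already-parsed `CategoryPattern`
#'   (returned unchanged).
#' @return a [CategoryPattern-class] object.
#' @examples
#' parsePattern("NSTCTANN")
#' @export
parsePattern <- function(text) {
  if (is(text, "CategoryPattern")) {
    return(text)
  }
  if (!is.character(text) || length(text) != 1L) {
    stop("'text' must be a single character string")
  }
  text <- toupper(text)
  if (nchar(text) != 8L) {
    stop("category patterns must be 8 characters long: ", text)
  }
  chars <- strsplit(text, "", fixed = TRUE)[[1L]]
  if (any(chars %in% c("B", "D", "H", "V"))) {
    stop("three-base IUPAC codes (B, D, H, V) are not allowed: ", text)
  }
  bad <- setdiff(chars, names(.IUPAC_SETS))
  if (length(bad)) {
    stop("invalid pattern character(s) ", paste(bad, collapse = ", "), " in ", text)
  }
  sets <- matrix(FALSE, 4L, 8L, dimnames = list(.BASES, NULL))
  for (j in seq_len(8L)) {
    sets[.IUPAC_SETS[[chars[j]]], j] <- TRUE
  }
  joker <- all(sets)
  if (!joker) {
    if (sum(sets[, 4L]) != 1L || !(which(sets[, 4L]) %in% c(2L, 4L))) {
      stop(
        "position 4 (the original base) must be exactly C or T ",
        "in non-joker patterns: ", text
      )
    }
    if (!(sum(sets[, 5L]) %in% 1:2)) {
      stop(
        "position 5 (the new base) must be a single base or a pair ",
        "in non-joker patterns: ", text
      )
    }
    if (any(sets[, 4L] & sets[, 5L])) {
      stop(
        "position 5 (the new base) must be disjoint from the original ",
        "base: ", text
      )
    }
  }
  new("CategoryPattern", text = text, sets = sets, joker = joker)
}

setMethod("show", "CategoryPattern", function(object) {
  cat(
    "CategoryPattern", object@text,
    if (object@joker) "(joker)" else "",
    sprintf(
      "| size %d span %d reach %d\n",
      patternSize(object), patternSpan(object), patternReach(object)
    )
  )
})

#' Pattern size, span and reach
#'
#' The three assignment criteria of a category pattern. `patternSize()` is
#' the number of valid mutation sequences (of the 24,576-member universe)
#' matching the pattern; `patternSpan()` the inclusive number of positions
#' from the first to the last non-N symbol; `patternReach()` the largest
#' offset of any non-N symbol from the mutated site (flank position i
#' contributes `4 - i` on the left and `i - 5` on the right; positions 4-5
#' contribute 0). The joker has span and reach 0 and size 24,576.
#'
#' @param p a pattern string or [CategoryPattern-class].
#' @return an integer.
#' @examples
#' patternSize("NSTCTANN") # 128
#' patternSpan("NNNCTARC") # 5
#' patternReach("NNNCTARC") # 3
#' @export
patternSize <- function(p) {
  p <- parsePattern(p)
  s <- p@sets
  flank <- prod(colSums(s[, c(1:3, 6:8), drop = FALSE]))
  refs <- intersect(which(s[, 4L]), c(2L, 4L))
  pairs <- sum(vapply(refs, function(r) sum(s[, 5L]) - as.integer(s[r, 5L]), 0L))
  as.integer(flank * pairs)
}

#' @rdname patternSize
#' @export
patternSpan <- function(p) {
  p <- parsePattern(p)
  nonN <- which(colSums(p@sets) < 4L)
  if (!length(nonN)) {
    return(0L)
  }
  as.integer(diff(range(nonN)) + 1L)
}

.REACH_OFFSET <- c(3L, 2L, 1L, 0L, 0L, 1L, 2L, 3L)

#' @rdname patternSize
#' @export
patternReach <- function(p) {
  p <- parsePattern(p)
  nonN <- which(colSums(p@sets) < 4L)
  if (!length(nonN)) {
    return(0L)
  }
  max(.REACH_OFFSET[nonN])
}

#' Match mutation sequences against a category pattern
#'
#' A sequence matches a pattern iff each of its eight bases is a member of
#' the corresponding pattern symbol's base set (no mismatches allowed).
#'
#' @param x mutation sequences: 8-character strings or universe indices.
#' @param p a pattern string or [CategoryPattern-class].
#' @return logical vector.
#' @examples
#' patternMatches("TGTCTAAC", "NSTCTANN")
#' @export
patternMatches <- function(x, p) {
  p <- parsePattern(p)
  idx <- if (is.character(x)) sequenceIndex(x) else as.integer(x)
  codes <- .universe()$codes[idx, , drop = FALSE]
  m <- rep(TRUE, nrow(codes))
  for (j in seq_len(8L)) {
    m <- m & p@sets[codes[, j], j]
  }
  m
}

# match vector of a pattern over the full universe, exploiting the product
# structure of the canonical index: left flank (64) x substitution (6) x
# right flank (64), with the right flank varying fastest
.matchVector <- function(p) {
  blocks <- .universeBlocks()
  s <- p@sets
  leftOK <- s[blocks$left[, 1L], 1L] & s[blocks$left[, 2L], 2L] &
    s[blocks$left[, 3L], 3L]
  subOK <- s[blocks$ref, 4L] & s[blocks$alt, 5L]
  rightOK <- s[blocks$right[, 1L], 6L] & s[blocks$right[, 2L], 7L] &
    s[blocks$right[, 3L], 8L]
  rep(leftOK, each = 384L) &
    rep(rep(subOK, each = 64L), times = 64L) &
    rep(rightOK, times = 384L)
}

# lexicographic (size, span, reach) priority packed into one number;
# span <= 8 and reach <= 3 so the packing is collision-free
.patternKey <- function(p) {
  patternSize(p) * 100 + patternSpan(p) * 10 + patternReach(p)
}
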