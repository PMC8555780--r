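# Categorizations: ordered sets of category patterns together with the
# derived assignment of every valid mutation sequence to its best-matching
# category. Assignment follows three criteria applied lexicographically --
# smaller size, then smaller span, then smaller reach -- with residual ties
# broken uniformly at random and flagged as ambiguous.

#' Mutation categorization
#'
#' A set of `M` mutation categories plus the derived assignment table over
#' the 24,576-sequence universe. Pattern-based categorizations carry their
#' IUPAC patterns; direct categorizations (e.g. [randomCategorization()])
#' carry only the table. `conflictRate` is the fraction of sequences whose
#' best-matching category was not unique.
#'
#' @slot name identifier.
#' @slot patterns character vector of canonical IUPAC patterns (may be empty
#'   for direct table categorizations).
#' @slot labels category labels, length `M`.
#' @slot assignment integer vector of length 24,576 mapping each universe
#'   sequence to a category in `1:M`.
#' @slot ambiguous logical vector of length 24,576 flagging tie-broken
#'   assignments.
#' @slot conflictRate fraction of ambiguous assignments.
#'
#' @name MutationCategorization-class
#' @aliases MutationCategorization
#' @exportClass MutationCategorization
setClass("MutationCategorization", representation(
  name = "character",
  patterns = "character",
  labels = "character",
  assignment = "integer",
  ambiguous = "logical",
  conflictRate = "numeric"
))

setValidity("MutationCategorization", function(object) {
  msg <- character()
  if (length(object@assignment) != .N_UNIVERSE) {
    msg <- c(msg, sprintf("assignment must cover all %d sequences", .N_UNIVERSE))
  }
  M <- length(object@labels)
  if (M < 1L) msg <- c(msg, "at least one category required")
  if (length(object@patterns) && length(object@patterns) != M) {
    msg <- c(msg, "patterns and labels must have equal length")
  }
  if (any(object@assignment < 1L | object@assignment > M)) {
    msg <- c(msg, "assignment indices out of range")
  }
  if (length(object@ambiguous) != .N_UNIVERSE) {
    msg <- c(msg, "ambiguous flags must cover the universe")
  }
  if (length(msg)) msg else TRUE
})

#' @describeIn MutationCategorization-class number of categories
#' @param x,object a `MutationCategorization`.
#' @export
nCategories <- function(x) length(x@labels)

#' Accessors for MutationCategorization
#'
#' `categoryPatterns()` returns the IUPAC patterns (empty for direct table
#' categorizations), `categoryLabels()` the category labels,
#' `assignmentTable()` the integer sequence-to-category map over the
#' canonical universe, and `conflictRate()` the fraction of ambiguous
#' (tie-broken) assignments.
#'
#' @param x a [MutationCategorization-class].
#' @return see individual descriptions.
#' @name categorization-accessors
NULL

#' @rdname categorization-accessors
#' @export
categoryPatterns <- function(x) x@patterns

#' @rdname categorization-accessors
#' @export
categoryLabels <- function(x) x@labels

#' @rdname categorization-accessors
#' @export
assignmentTable <- function(x) x@assignment

#' @rdname categorization-accessors
#' @export
conflictRate <- function(x) x@conflictRate

setMethod("show", "MutationCategorization", function(object) {
  cat(
    "MutationCategorization '", object@name, "': ",
    nCategories(object), " categories",
    if (length(object@patterns)) "" else " (direct assignment table)",
    sprintf(", conflict rate %.4f\n", object@conflictRate),
    sep = ""
  )
  if (length(object@patterns)) {
    cat(
      "  patterns: ", paste(head(object@patterns, 4L), collapse = " "),
      if (length(object@patterns) > 4L) " ...", "\n",
      sep = ""
    )
  }
})

## ---- assignment table construction --------------------------------------

# Assignment from precomputed match columns M (universe x patterns) and
# priority keys. Two passes: the first finds each sequence's minimal
# matching key, the second counts the tied patterns at that key and records
# the winner (unique winners directly; key ties uniformly at random via the
# caller's RNG stream, flagged ambiguous). `tieCounts` gives per-pattern
# involvement in ambiguous ties (used by conflict resolution).
.assignFromMatches <- function(M, key) {
  n <- nrow(M)
  P <- ncol(M)
  groups <- split(seq_len(P), key)
  groups <- groups[order(as.numeric(names(groups)))]
  winner <- integer(n)
  amb <- logical(n)
  assigned <- logical(n)
  tieCounts <- numeric(P)
  for (g in groups) {
    if (length(g) == 1L) {
      newly <- !assigned & M[, g]
      winner[newly] <- g
    } else {
      sub <- M[, g, drop = FALSE]
      cnt <- rowSums(sub)
      newly <- !assigned & cnt > 0L
      if (!any(newly)) next
      winner[newly] <- g[max.col(sub[newly, , drop = FALSE] + 0,
        ties.method = "random"
      )]
      ambNew <- newly & cnt > 1L
      if (any(ambNew)) {
        amb[ambNew] <- TRUE
        tieCounts[g] <- tieCounts[g] + colSums(M[ambNew, g, drop = FALSE])
      }
    }
    assigned <- assigned | newly
  }
  if (!all(assigned)) {
    stop(
      sum(!assigned),
      " sequences match no pattern; include a joker category"
    )
  }
  list(
    assignment = winner,
    ambiguous = amb,
    conflictRate = mean(amb),
    tieCounts = tieCounts
  )
}

# Build the full assignment table for a list of patterns. Every sequence is
# assigned to the matching pattern with the smallest (size, span, reach)
# key; exact key ties are broken uniformly at random and flagged ambiguous.
.buildTable <- function(patterns, detail = FALSE) {
  ps <- lapply(patterns, parsePattern)
  if (!length(ps)) stop("at least one pattern required")
  M <- vapply(ps, .matchVector, logical(.N_UNIVERSE))
  key <- vapply(ps, .patternKey, 0)
  .assignFromMatches(M, key)
}

#' Create a categorization from a set of patterns
#'
#' Parses the patterns and builds the full assignment table over the
#' 24,576-sequence universe using the three assignment criteria (size, span,
#' reach, all "smaller wins") with uniform random tie-breaking.
#'
#' @param patterns character vector of 8-character IUPAC patterns.
#' @param name identifier stored with the object.
#' @param seed optional seed for the tie-breaking random stream; `NULL` uses
#'   the current RNG state.
#' @return a [MutationCategorization-class].
#' @examples
#' cat3 <- newCategorization(c("NSTCTANN", "NNNCTARC", "NNNNNNNN"),
#'   name = "toy", seed = 1
#' )
#' conflictRate(cat3)
#' @export
newCategorization <- function(patterns, name = "custom", seed = NULL) {
  ps <- lapply(patterns, parsePattern)
  canon <- vapply(ps, function(p) p@text, "")
  tab <- withSeed(seed, .buildTable(ps))
  new("MutationCategorization",
    name = name, patterns = canon, labels = canon,
    assignment = tab$assignment, ambiguous = tab$ambiguous,
    conflictRate = tab$conflictRate
  )
}

#' Assign a mutation sequence to its best-matching category
#'
#' Applies the three assignment criteria in order (category size, span,
#' reach; smaller wins at each step) among all patterns matching the
#' sequence. A residual tie is broken uniformly at random and flagged
#' ambiguous. For a categorization with a precomputed table the stored
#' assignment is returned.
#'
#' @param x an 8-character mutation sequence or universe index.
#' @param categorization a [MutationCategorization-class] or a character
#'   vector of patterns.
#' @return list with elements `category` (index), `label` and `ambiguous`.
#' @examples
#' assignSequence("TGTCTAAC", c("NSTCTANN", "NNNCTARC", "NNNNNNNN"))
#' @export
assignSequence <- function(x, categorization) {
  idx <- if (is.character(x)) sequenceIndex(x) else as.integer(x)
  stopifnot(length(idx) == 1L)
  if (is(categorization, "MutationCategorization")) {
    k <- categorization@assignment[idx]
    return(list(
      category = k,
      label = categorization@labels[k],
      ambiguous = categorization@ambiguous[idx]
    ))
  }
  ps <- lapply(categorization, parsePattern)
  hit <- which(vapply(ps, function(p) patternMatches(idx, p), logical(1L)))
  if (!length(hit)) {
    stop("sequence matches no pattern; include a joker category")
  }
  key <- vapply(ps[hit], .patternKey, 0)
  tiedSet <- hit[key == min(key)]
  k <- if (length(tiedSet) > 1L) tiedSet[sample.int(length(tiedSet), 1L)] else tiedSet
  list(
    category = k,
    label = vapply(ps, function(p) p@text, "")[k],
    ambiguous = length(tiedSet) > 1L
  )
}

## ---- baseline categorizations -------------------------------------------

#' The standard 96-category categorization
#'
#' The field's conventional categorization: the substitution plus one
#' flanking base on each side, i.e. patterns of the form `N N l REF ALT r N
#' N`. Categories are ordered by substitution class (C>A, C>G, C>T, T>A,
#' T>C, T>G), then 5' flank, then 3' flank, and labelled `"A[C>A]A"` style.
#' The 96 patterns partition the universe exactly, so the conflict rate is 0
#' and no joker is needed.
#'
#' @return a [MutationCategorization-class] with 96 categories.
#' @export
standardCategorization <- function() {
  if (!is.null(.ddcat$standardCat)) {
    return(.ddcat$standardCat)
  }
  u <- .universe()$codes
  refb <- as.integer(u[, 4L] == 4L)
  altRank <- ifelse(refb == 0L, .ALT_RANK_C[u[, 5L]], .ALT_RANK_T[u[, 5L]]) - 1L
  sub <- refb * 3L + altRank # 0..5
  assignment <- as.integer(sub * 16L + (u[, 3L] - 1L) * 4L + (u[, 6L] - 1L) + 1L)

  refs <- c("C", "C", "C", "T", "T", "T")
  alts <- c("A", "G", "T", "A", "C", "G")
  patterns <- character(96L)
  labels <- character(96L)
  k <- 0L
  for (s in 1:6) {
    for (l in .BASES) {
      for (r in .BASES) {
        k <- k + 1L
        patterns[k] <- paste0("NN", l, refs[s], alts[s], r, "NN")
        labels[k] <- paste0(l, "[", refs[s], ">", alts[s], "]", r)
      }
    }
  }
  .ddcat$standardCat <- new("MutationCategorization",
    name = "standard", patterns = patterns, labels = labels,
    assignment = assignment, ambiguous = rep(FALSE, .N_UNIVERSE),
    conflictRate = 0
  )
  .ddcat$standardCat
}

#' The two-flanking-base categorization (1536 categories)
#'
#' Patterns of the form `N l2 l1 REF ALT r1 r2 N`: the substitution with two
#' flanking bases on each side, giving 1536 exhaustive, pairwise disjoint
#' categories.
#'
#' @return a [MutationCategorization-class] with 1536 categories.
#' @export
twoFlankCategorization <- function() {
  u <- .universe()$codes
  refb <- as.integer(u[, 4L] == 4L)
  altRank <- ifelse(refb == 0L, .ALT_RANK_C[u[, 5L]], .ALT_RANK_T[u[, 5L]]) - 1L
  sub <- refb * 3L + altRank
  assignment <- as.integer(
    ((sub * 16L + (u[, 2L] - 1L) * 4L + (u[, 3L] - 1L)) * 16L +
      (u[, 6L] - 1L) * 4L + (u[, 7L] - 1L)) + 1L
  )
  refs <- c("C", "C", "C", "T", "T", "T")
  alts <- c("A", "G", "T", "A", "C", "G")
  patterns <- character(1536L)
  k <- 0L
  for (s in 1:6) {
    for (l2 in .BASES) {
      for (l1 in .BASES) {
        for (r1 in .BASES) {
          for (r2 in .BASES) {
            k <- k + 1L
            patterns[k] <- paste0("N", l2, l1, refs[s], alts[s], r1, r2, "N")
          }
        }
      }
    }
  }
  new("MutationCategorization",
    name = "two_flank", patterns = patterns, labels = patterns,
    assignment = assignment, ambiguous = rep(FALSE, .N_UNIVERSE),
    conflictRate = 0
  )
}

#' A uniformly random categorization
#'
#' Assigns each of the 24,576 valid mutation sequences uniformly at random
#' to one of `nCategories` labels. This is a direct assignment-table
#' categorization with no patterns; it serves as a negative baseline.
#'
#' @param seed integer seed (required for reproducibility; `NULL` uses the
#'   current RNG stream).
#' @param nCategories number of labels (default 96).
#' @return a [MutationCategorization-class].
#' @export
randomCategorization <- function(seed = NULL, nCategories = 96L) {
  assignment <- withSeed(seed, sample.int(nCategories, .N_UNIVERSE, replace = TRUE))
  new("MutationCategorization",
    name = if (is.null(seed)) "random" else paste0("random_seed", seed),
    patterns = character(0),
    labels = sprintf("RND%02d", seq_len(nCategories)),
    assignment = as.integer(assignment),
    ambiguous = rep(FALSE, .N_UNIVERSE),
    conflictRate = 0
  )
}

## ---- transformation matrix ----------------------------------------------

#' Transformation matrix onto the standard categories
#'
#' Builds the `M x 96` row-stochastic matrix `T` whose entry `T[i, j]` is
#' the fraction of universe sequences assigned to category `i` of
#' `categorization` that belong to standard category `j`. Rows of empty
#' categories (no assigned sequences) are all zero and reported in the
#' `"emptyCategories"` attribute. Transformed signatures `S' = S %*% T` live
#' on the standard 96 categories and can be compared to reference catalogs.
#'
#' @param categorization a [MutationCategorization-class].
#' @param reference the target categorization (default
#'   [standardCategorization()]).
#' @return numeric matrix with category labels as dimnames.
#' @export
transformationMatrix <- function(categorization, reference = standardCategorization()) {
  M <- nCategories(categorization)
  tab <- table(
    factor(categorization@assignment, levels = seq_len(M)),
    factor(reference@assignment, levels = seq_len(nCategories(reference)))
  )
  tab <- unclass(tab)
  rs <- rowSums(tab)
  Tm <- tab / ifelse(rs > 0, rs, 1)
  dimnames(Tm) <- list(categorization@labels, reference@labels)
  attr(Tm, "emptyCategories") <- which(rs == 0)
  Tm
}

## ---- serialization ------------------------------------------------------

#' Read and write categorizations as JSON
#'
#' The JSON carries the name, patterns, labels, conflict rate and the full
#' assignment table (plus ambiguity flags), so the round trip is exact even
#' though tie-breaking is random.
#'
#' @param categorization a [MutationCategorization-class].
#' @param path file path.
#' @return `readCategorization()` returns the reconstructed object;
#'   `writeCategorization()` returns `path` invisibly.
#' @export
writeCategorization <- function(categorization, path) {
  write_json(
    list(
      name = categorization@name,
      patterns = categorization@patterns,
      labels = categorization@labels,
      conflict_rate = categorization@conflictRate,
      assignment = categorization@assignment,
      ambiguous = as.integer(categorization@ambiguous)
    ),
    path,
    auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' @rdname writeCategorization
#' @export
readCategorization <- function(path) {
  x <- read_json(path, simplifyVector = TRUE)
  new("MutationCategorization",
    name = x$name,
    patterns = as.character(x$patterns %||% character(0)),
    labels = as.character(x$labels),
    assignment = as.integer(x$assignment),
    ambiguous = as.logical(x$ambiguous),
    conflictRate = as.numeric(x$conflict_rate)
  )
}

#' Export the full assignment table as TSV
#'
#' One row per universe sequence with columns `sequence`, `category_index`,
#' `category_label` and `ambiguous` (0/1).
#'
#' @inheritParams writeCategorization
#' @export
exportAssignmentTable <- function(categorization, path) {
  df <- data.frame(
    sequence = mutationSequenceUniverse(),
    category_index = categorization@assignment,
    category_label = categorization@labels[categorization@assignment],
    ambiguous = as.integer(categorization@ambiguous)
  )
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
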