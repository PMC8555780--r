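# Mutation catalogs: from a reference genome plus somatic mutation tables
# to a samples x categories count matrix, and the 7-mer opportunity
# machinery that renormalizes signatures between whole-genome and
# whole-exome regimes.

#' Mutation catalog
#'
#' A samples x categories count matrix built by assigning each usable
#' mutation record's 7-mer mutation sequence to its category.
#'
#' @slot counts non-negative integer matrix, samples in rows.
#' @slot categorizationName name of the categorization used.
#'
#' @name MutationCatalog-class
#' @aliases MutationCatalog
#' @exportClass MutationCatalog
setClass("MutationCatalog", representation(
  counts = "matrix",
  categorizationName = "character"
))

setValidity("MutationCatalog", function(object) {
  msg <- character()
  if (!is.numeric(object@counts)) msg <- c(msg, "counts must be numeric")
  if (any(object@counts < 0)) msg <- c(msg, "counts must be non-negative")
  if (is.null(rownames(object@counts))) msg <- c(msg, "counts must carry sample ids")
  if (length(msg)) msg else TRUE
})

#' @describeIn MutationCatalog-class the count matrix
#' @param x a `MutationCatalog`.
#' @export
catalogCounts <- function(x) x@counts

#' @describeIn MutationCatalog-class sample identifiers
#' @export
sampleIds <- function(x) rownames(x@counts)

setMethod("show", "MutationCatalog", function(object) {
  cat(
    "MutationCatalog: ", nrow(object@counts), " samples x ",
    ncol(object@counts), " categories (categorization '",
    object@categorizationName, "'), ",
    sum(object@counts), " mutations\n",
    sep = ""
  )
})

setMethod("dim", "MutationCatalog", function(x) dim(x@counts))

## ---- mutation tables ----------------------------------------------------

.MUTATION_COLUMNS <- c(
  sample_id = "sample_id", chromosome = "chromosome",
  position = "position", reference_allele = "reference_allele",
  mutated_allele = "mutated_allele"
)

#' Read a simple somatic mutation table
#'
#' Reads a TSV of single base substitutions with columns `sample_id`,
#' `chromosome`, `position` (1-based), `reference_allele`, `mutated_allele`.
#' Other dialects can be adapted with `columnMap`, a named character vector
#' mapping the canonical names to the file's column names. Records that are
#' not single-base substitutions (indels, MNVs, identical alleles) are
#' dropped; the tally is attached as attribute `"nonSnv"`.
#'
#' @param path TSV file path.
#' @param columnMap optional named character vector, e.g.
#'   `c(sample_id = "icgc_sample_id", ...)`.
#' @return data.frame with the canonical columns.
#' @export
readMutationTable <- function(path, columnMap = NULL) {
  df <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  map <- .MUTATION_COLUMNS
  if (!is.null(columnMap)) map[names(columnMap)] <- columnMap
  missing <- setdiff(unname(map), colnames(df))
  if (length(missing)) {
    stop("mutation table is missing column(s): ", paste(missing, collapse = ", "))
  }
  out <- data.frame(
    sample_id = as.character(df[[map["sample_id"]]]),
    chromosome = as.character(df[[map["chromosome"]]]),
    position = as.integer(df[[map["position"]]]),
    reference_allele = toupper(as.character(df[[map["reference_allele"]]])),
    mutated_allele = toupper(as.character(df[[map["mutated_allele"]]])),
    stringsAsFactors = FALSE
  )
  snv <- out$reference_allele %in% .BASES &
    out$mutated_allele %in% .BASES &
    out$reference_allele != out$mutated_allele
  attr(out, "nonSnv") <- sum(!snv)
  out[snv, , drop = FALSE]
}

## ---- sequence extraction ------------------------------------------------

.genomeAsCodes <- function(genome) {
  # genome: DNAStringSet or FASTA path -> list of integer code vectors
  # (NA for non-ACGT letters), cached per call site by the caller
  if (is.character(genome)) genome <- readDNAStringSet(genome)
  if (!is(genome, "DNAStringSet")) {
    stop("'genome' must be a DNAStringSet or a FASTA path")
  }
  nm <- names(genome)
  if (is.null(nm)) stop("genome sequences must be named")
  nm <- sub("\\s.*$", "", nm)
  out <- lapply(seq_along(genome), function(i) {
    match(strsplit(as.character(genome[[i]]), "", fixed = TRUE)[[1L]], .BASES)
  })
  names(out) <- nm
  out
}

#' Extract pyrimidine-collapsed mutation sequences from a genome
#'
#' For each single base substitution record, reads the +-3 base window
#' around the mutated position and forms the 8-character mutation sequence.
#' When the reference base is a purine (A or G) the 7-mer context is
#' reverse-complemented and the alternative base complemented, so that the
#' original base is always C or T. Records are rejected (with a reason) when
#' the window runs off the chromosome, contains an ambiguous base, the
#' chromosome is unknown, or the genome base disagrees with the record's
#' reference allele.
#'
#' @param genome a named [Biostrings::DNAStringSet] or FASTA path.
#' @param records data.frame as returned by [readMutationTable()].
#' @return `records` with two extra columns: `seqIndex` (universe index, NA
#'   for rejected records) and `reject` (reason, `""` for usable records).
#'   The reason tally is attached as attribute `"rejected"`.
#' @examples
#' g <- Biostrings::DNAStringSet(c(chr1 = "TGTCAACG"))
#' rec <- data.frame(
#'   sample_id = "s1", chromosome = "chr1", position = 4,
#'   reference_allele = "C", mutated_allele = "T"
#' )
#' extractMutationSequences(g, rec)$seqIndex == sequenceIndex("TGTCTAAC")
#' @export
extractMutationSequences <- function(genome, records) {
  codes <- .genomeAsCodes(genome)
  n <- nrow(records)
  seqIndex <- rep(NA_integer_, n)
  reject <- character(n)

  chromOk <- records$chromosome %in% names(codes)
  reject[!chromOk] <- "unknown_chromosome"

  for (chr in unique(records$chromosome[chromOk])) {
    g <- codes[[chr]]
    L <- length(g)
    sel <- which(records$chromosome == chr)
    pos <- records$position[sel]

    oob <- pos < 4L | pos > L - 3L
    reject[sel[oob]] <- "window_out_of_bounds"
    sel <- sel[!oob]
    pos <- pos[!oob]
    if (!length(sel)) next

    win <- matrix(g[outer(pos, -3:3, "+")], nrow = length(sel))
    hasN <- rowSums(is.na(win)) > 0L
    reject[sel[hasN]] <- "ambiguous_base_in_window"
    sel <- sel[!hasN]
    win <- win[!hasN, , drop = FALSE]
    if (!length(sel)) next

    refCode <- match(records$reference_allele[sel], .BASES)
    altCode <- match(records$mutated_allele[sel], .BASES)
    mismatch <- win[, 4L] != refCode
    reject[sel[mismatch]] <- "reference_mismatch"
    keep <- !mismatch
    sel <- sel[keep]
    win <- win[keep, , drop = FALSE]
    altCode <- altCode[keep]
    if (!length(sel)) next

    pur <- win[, 4L] %in% c(1L, 3L)
    if (any(pur)) {
      win[pur, ] <- 5L - win[pur, 7:1, drop = FALSE]
      altCode[pur] <- 5L - altCode[pur]
    }
    seqIndex[sel] <- .seqCodesToIndex(cbind(
      win[, 1:4, drop = FALSE], altCode, win[, 5:7, drop = FALSE]
    ))
  }
  out <- records
  out$seqIndex <- seqIndex
  out$reject <- reject
  attr(out, "rejected") <- table(reject[reject != ""])
  out
}

## ---- catalog construction -----------------------------------------------

#' Build a mutation catalog
#'
#' Counts each sample's usable mutation records per category by looking the
#' records' mutation sequences up in the categorization's precomputed
#' assignment table. Counts are conserved: the matrix total equals the
#' number of usable records.
#'
#' @param records data.frame with columns `sample_id` and `seqIndex` (as
#'   returned by [extractMutationSequences()]; rows with `NA` `seqIndex` are
#'   ignored), optionally deduplicated first with `dedup = TRUE` on columns
#'   (`sample_id`, `chromosome`, `position`, `reference_allele`,
#'   `mutated_allele`).
#' @param categorization a [MutationCategorization-class].
#' @param sampleOrder optional character vector fixing the row order (and
#'   including zero-mutation samples if desired).
#' @param dedup drop duplicate records before counting (default `FALSE`:
#'   duplicates are counted as-is).
#' @return a [MutationCatalog-class].
#' @export
buildCatalog <- function(records, categorization, sampleOrder = NULL, dedup = FALSE) {
  if (dedup) {
    keyCols <- intersect(
      c("sample_id", "chromosome", "position", "reference_allele", "mutated_allele"),
      colnames(records)
    )
    records <- records[!duplicated(records[keyCols]), , drop = FALSE]
  }
  usable <- records[!is.na(records$seqIndex), , drop = FALSE]
  if (!nrow(usable)) stop("no usable mutation records")
  samples <- sampleOrder %||% sort(unique(usable$sample_id))
  unknown <- setdiff(unique(usable$sample_id), samples)
  if (length(unknown)) {
    stop("records for samples outside 'sampleOrder': ", paste(unknown, collapse = ", "))
  }
  M <- nCategories(categorization)
  counts <- unclass(table(
    factor(usable$sample_id, levels = samples),
    factor(categorization@assignment[usable$seqIndex], levels = seq_len(M))
  ))
  dimnames(counts) <- list(samples, categorization@labels)
  new("MutationCatalog",
    counts = counts,
    categorizationName = categorization@name
  )
}

#' Row-normalize a catalog
#'
#' Divides each sample's counts by its total so rows sum to one. Samples
#' with zero mutations are an error (they cannot be normalized); the error
#' names them.
#'
#' @param x a [MutationCatalog-class] or counts matrix.
#' @return numeric row-stochastic matrix.
#' @export
normalizeCatalog <- function(x) {
  counts <- if (is(x, "MutationCatalog")) x@counts else x
  rs <- rowSums(counts)
  if (any(rs == 0)) {
    stop(
      "zero-mutation sample(s): ",
      paste(rownames(counts)[rs == 0], collapse = ", ")
    )
  }
  counts / rs
}

## ---- mutation opportunities ---------------------------------------------

# 7-mer counts over a genome (or over regions of it, where a position
# belongs to a region iff the central base does: regions are expanded by 3
# bases before windowed counting, which yields exactly the 7-mers centered
# inside them). Returns a vector over the 16,384 uncollapsed 7-mers.
.kmerCounts <- function(genome, regions = NULL) {
  if (is.character(genome)) genome <- readDNAStringSet(genome)
  names(genome) <- sub("\\s.*$", "", names(genome))
  km <- .kmerMaps()
  total <- setNames(numeric(.N_KMERS), km$strings)
  if (is.null(regions)) {
    for (i in seq_along(genome)) {
      oc <- oligonucleotideFrequency(genome[[i]], width = 7L)
      total <- total + oc[names(total)]
    }
    return(total)
  }
  if (is.character(regions)) regions <- rtracklayer::import(regions)
  for (chr in intersect(names(genome), as.character(unique(seqnames(regions))))) {
    rg <- regions[as.character(seqnames(regions)) == chr]
    if (!length(rg)) next
    subject <- genome[[chr]]
    st <- pmax(1L, start(rg) - 3L)
    en <- pmin(length(subject), end(rg) + 3L)
    v <- Views(subject, start = st, end = en)
    oc <- oligonucleotideFrequency(v, width = 7L)
    total <- total + colSums(oc)[names(total)]
  }
  total
}

# fold uncollapsed 7-mer counts into per-category opportunity counts
.opportunityFromKmers <- function(kmerCounts, categorization) {
  km <- .kmerMaps()
  M <- nCategories(categorization)
  assign3 <- categorization@assignment[as.vector(km$altMap)]
  w <- rep(as.numeric(kmerCounts), 3L)
  U <- vapply(
    split(w, factor(assign3, levels = seq_len(M))),
    sum, numeric(1L)
  )
  setNames(U, categorization@labels)
}

#' Count per-category mutation opportunities
#'
#' Every genomic position with a full, ambiguity-free 7-mer window (and,
#' when `regions` is given, whose central base lies inside the regions)
#' contributes three potential mutation sequences, one per alternative
#' base, after pyrimidine collapsing. The opportunity vector `U` counts
#' these per category, so `sum(U)` equals three times the number of
#' eligible positions. `U` lives in the same index space as the columns of
#' a signature matrix built under the same categorization.
#'
#' @param genome a named [Biostrings::DNAStringSet] or FASTA path.
#' @param categorization a [MutationCategorization-class].
#' @param regions optional `GRanges` or BED file path (0-based half-open on
#'   disk; imported as 1-based) restricting the central positions.
#' @return named numeric vector of length `nCategories(categorization)`.
#' @export
countOpportunities <- function(genome, categorization, regions = NULL) {
  kc <- .kmerCounts(genome, regions)
  if (sum(kc) == 0) {
    stop("no eligible positions (empty regions or all-ambiguous genome)")
  }
  .opportunityFromKmers(kc, categorization)
}

#' Renormalize signatures between opportunity regimes
#'
#' Rescales each signature's category probabilities by the ratio of
#' destination to source opportunity counts (`uDst[i] / uSrc[i]`) and
#' renormalizes the row to sum to one. This converts signatures learned
#' under one 7-mer opportunity regime (e.g. whole genome) to another (e.g.
#' exome). Categories unobservable in the source regime (`uSrc[i] == 0`
#' with signature mass present) get ratio 0 with a warning.
#'
#' @param H signatures x categories row-stochastic matrix.
#' @param uSrc,uDst opportunity vectors aligned to `H`'s columns.
#' @return row-stochastic matrix of the same shape.
#' @examples
#' renormalizeSignatures(matrix(c(0.5, 0.5), 1), c(1, 1), c(2, 1)) # 2/3, 1/3
#' @export
renormalizeSignatures <- function(H, uSrc, uDst) {
  if (is.null(dim(H))) H <- matrix(H, nrow = 1L)
  stopifnot(ncol(H) == length(uSrc), length(uSrc) == length(uDst))
  ratio <- ifelse(uSrc > 0, uDst / uSrc, 0)
  dead <- uSrc == 0 & uDst > 0 & colSums(H) > 0
  if (any(dead)) {
    warning(
      sum(dead), " categor(ies) unobservable in the source regime; ",
      "their mass is dropped"
    )
  }
  Hn <- H * rep(ratio, each = nrow(H))
  rs <- rowSums(Hn)
  if (any(rs == 0)) {
    stop("signature row(s) lost all mass under renormalization")
  }
  Hn / rs
}
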