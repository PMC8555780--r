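# A dataset bundle: WGS and WES mutation cohorts (stored as extracted
# mutation-sequence indices so catalogs under any categorization are a
# table lookup), the expression matrix over the WES samples, named gene
# sets, and the genome/exome 7-mer counts from which per-categorization
# opportunity vectors are folded.

#' Mutation + expression dataset bundle
#'
#' Holds everything the fitness and evaluation pipelines need: per-record
#' mutation sequence indices for the WGS and WES cohorts, the expression
#' matrix over the WES samples, gene sets, uncollapsed genome and exome
#' 7-mer counts, and (once computed) the dataset's `K*`.
#'
#' @slot name dataset identifier.
#' @slot wgs,wes data.frames with columns `sample_id`, `seqIndex`.
#' @slot expression samples x genes non-negative matrix, rownames matching
#'   the WES sample ids.
#' @slot geneSets named list of character vectors of gene ids.
#' @slot genomeKmers,exomeKmers numeric vectors of length 16,384.
#' @slot kStar optimal number of signatures (NA until computed).
#'
#' @name MutationDataset-class
#' @aliases MutationDataset
#' @exportClass MutationDataset
setClass("MutationDataset", representation(
  name = "character",
  wgs = "data.frame",
  wes = "data.frame",
  expression = "matrix",
  geneSets = "list",
  genomeKmers = "numeric",
  exomeKmers = "numeric",
  kStar = "numeric"
))

setValidity("MutationDataset", function(object) {
  msg <- character()
  for (slot in c("wgs", "wes")) {
    df <- slot(object, slot)
    if (!all(c("sample_id", "seqIndex") %in% colnames(df))) {
      msg <- c(msg, sprintf("'%s' needs columns sample_id, seqIndex", slot))
    }
  }
  if (!is.numeric(object@expression)) {
    msg <- c(msg, "expression must be numeric")
  } else if (any(object@expression < 0)) {
    msg <- c(msg, "expression must be non-negative")
  }
  wesSamples <- sort(unique(object@wes$sample_id))
  if (length(wesSamples) &&
    !identical(sort(rownames(object@expression)), wesSamples)) {
    msg <- c(msg, "expression rownames must match the WES sample ids")
  }
  if (length(object@genomeKmers) != .N_KMERS) {
    msg <- c(msg, "genomeKmers must have length 16384")
  }
  if (length(object@exomeKmers) != .N_KMERS) {
    msg <- c(msg, "exomeKmers must have length 16384")
  }
  if (length(msg)) msg else TRUE
})

setMethod("show", "MutationDataset", function(object) {
  cat(
    "MutationDataset '", object@name, "': ",
    length(unique(object@wgs$sample_id)), " WGS samples (",
    nrow(object@wgs), " mutations), ",
    length(unique(object@wes$sample_id)), " WES samples (",
    nrow(object@wes), " mutations), ",
    ncol(object@expression), " genes, gene sets: ",
    paste(names(object@geneSets), collapse = ", "),
    if (is.na(object@kStar)) ", K* not set" else sprintf(", K* = %d", object@kStar),
    "\n",
    sep = ""
  )
})

#' Read an expression matrix / gene set lists
#'
#' `readExpressionMatrix()` reads a TSV with samples in rows (first column
#' `sample_id`) and genes in columns. `readGeneSets()` reads plain-text
#' files of gene ids (one per line) into a named list.
#'
#' @param path TSV path.
#' @return numeric matrix with sample rownames.
#' @export
readExpressionMatrix <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (colnames(df)[1L] != "sample_id") {
    stop("expression TSV must have 'sample_id' as its first column")
  }
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- df$sample_id
  storage.mode(m) <- "double"
  m
}

#' @rdname readExpressionMatrix
#' @param paths named character vector of gene-list file paths.
#' @export
readGeneSets <- function(paths) {
  if (is.null(names(paths))) {
    stop("'paths' must be named (gene-set names)")
  }
  lapply(as.list(paths), function(p) readLines(p, warn = FALSE))
}

#' Assemble a dataset bundle from files or objects
#'
#' Extracts mutation sequences for both cohorts from the genome, reads the
#' expression matrix, and counts genome and exome 7-mers. The result feeds
#' [categorizationFitness()], [evolveCategorization()] and
#' [outOfSampleEvaluation()].
#'
#' @param genome named [Biostrings::DNAStringSet] or FASTA path.
#' @param wgs,wes mutation tables (data.frames or TSV paths, see
#'   [readMutationTable()]).
#' @param expression samples x genes matrix or TSV path (WES samples).
#' @param geneSets named list of gene-id character vectors (or named vector
#'   of file paths).
#' @param exome `GRanges` or BED path defining the exome.
#' @param name dataset identifier.
#' @return a [MutationDataset-class].
#' @export
buildDataset <- function(genome, wgs, wes, expression, geneSets, exome,
                         name = "dataset") {
  if (is.character(genome)) genome <- readDNAStringSet(genome)
  names(genome) <- sub("\\s.*$", "", names(genome))
  if (is.character(wgs)) wgs <- readMutationTable(wgs)
  if (is.character(wes)) wes <- readMutationTable(wes)
  if (is.character(expression)) expression <- readExpressionMatrix(expression)
  if (is.character(geneSets) || (is.character(geneSets[[1L]]) &&
    all(file.exists(unlist(geneSets))))) {
    geneSets <- readGeneSets(unlist(geneSets))
  }
  wgsX <- extractMutationSequences(genome, wgs)
  wesX <- extractMutationSequences(genome, wes)
  keepCols <- c("sample_id", "seqIndex")
  wgsDf <- wgsX[!is.na(wgsX$seqIndex), keepCols, drop = FALSE]
  wesDf <- wesX[!is.na(wesX$seqIndex), keepCols, drop = FALSE]
  expression <- expression[sort(unique(wesDf$sample_id)), , drop = FALSE]
  new("MutationDataset",
    name = name,
    wgs = wgsDf, wes = wesDf,
    expression = expression,
    geneSets = geneSets,
    genomeKmers = unname(.kmerCounts(genome)),
    exomeKmers = unname(.kmerCounts(genome, exome)),
    kStar = NA_real_
  )
}

# catalogs under an arbitrary categorization are a pure table lookup
.datasetCatalog <- function(dataset, categorization, cohort = c("wgs", "wes")) {
  cohort <- match.arg(cohort)
  buildCatalog(slot(dataset, cohort), categorization)
}

.datasetOpportunities <- function(dataset, categorization) {
  list(
    wgs = .opportunityFromKmers(dataset@genomeKmers, categorization),
    wes = .opportunityFromKmers(dataset@exomeKmers, categorization)
  )
}
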