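# Genetic algorithm over categorization space. Individuals are 96-category
# categorizations (95 degenerate patterns plus the joker) kept below a 1%
# assignment-conflict rate. Selection is rank-power based, per dataset and
# on the average ranking; the top two individuals of the average ranking
# pass unchanged (elitism); offspring arise by pattern crossover (up to 40%
# of categories from the lower-fitness parent) or by single-symbol
# expand/contract mutations.

#' Genetic algorithm configuration
#'
#' Defaults follow the published parameter choices: population size 40, 100
#' ancestors, 500 generations, crossover rate `q = 0.8`, per-category
#' mutation rate `m = 0.05`, selection strictness `power = 5`, interval
#' length concentration `c = 10`, and a 1% conflict-rate ceiling.
#'
#' @param populationSize population size `S` (>= 3).
#' @param nAncestors number of initial categorizations sampled, of which
#'   the top `S` by average ranking are kept.
#' @param nGenerations number of generations.
#' @param crossoverRate probability `q` of crossover (vs mutation) per
#'   offspring.
#' @param mutationRate per-category mutation probability `m`.
#' @param selectionPower rank-selection exponent.
#' @param concentration weight `c` on interval length 4 in ancestor
#'   category sampling.
#' @param conflictThreshold maximum tolerated ambiguous-assignment rate.
#' @param maxResolveRounds category replacements attempted before a
#'   categorization is rejected.
#' @param seed root seed for the whole run.
#' @param fitness a [fitnessConfig()] list.
#' @param kCandidates candidate K values for the per-dataset `K*` when not
#'   already set.
#' @return a named list.
#' @export
gaConfig <- function(populationSize = 40L, nAncestors = 100L,
                     nGenerations = 500L, crossoverRate = 0.8,
                     mutationRate = 0.05, selectionPower = 5,
                     concentration = 10, conflictThreshold = 0.01,
                     maxResolveRounds = 100L, seed = 1L,
                     fitness = fitnessConfig(), kCandidates = 2:6) {
  stopifnot(
    populationSize >= 3L, crossoverRate >= 0, crossoverRate <= 1,
    mutationRate >= 0, mutationRate <= 1, selectionPower > 0,
    concentration >= 1
  )
  list(
    populationSize = as.integer(populationSize),
    nAncestors = as.integer(nAncestors),
    nGenerations = as.integer(nGenerations),
    crossoverRate = crossoverRate,
    mutationRate = mutationRate,
    selectionPower = selectionPower,
    concentration = concentration,
    conflictThreshold = conflictThreshold,
    maxResolveRounds = as.integer(maxResolveRounds),
    seed = seed,
    fitness = fitness,
    kCandidates = kCandidates
  )
}

.JOKER <- "NNNNNNNN"
.SINGLE_CODES <- c("A", "C", "G", "T")
.PAIR_CODES <- c("R", "Y", "S", "W", "K", "M")

#' Sample a random category pattern
#'
#' Draws one ancestor-style category: an interval of `nSymbols` consecutive
#' non-N symbols covering the mutation (positions 4 and 5), all other
#' positions wildcards. `nSymbols` is drawn from \{3, ..., 7\} with weights
#' `(1, c, 1, 1, 1)` — concentrated on 4, the effective length of the
#' standard categories; the interval start is uniform among the legal
#' starts. Interval symbols are uniform over the 4 single bases and 6 base
#' pairs, subject to position 4 being exactly C or T and position 5 being
#' disjoint from it.
#'
#' @param concentration weight `c` on `nSymbols = 4`.
#' @return an 8-character IUPAC pattern string.
#' @export
sampleCategory <- function(concentration = 10) {
  nSymbols <- sample(3:7, 1L, prob = c(1, concentration, 1, 1, 1))
  lo <- max(1L, 6L - nSymbols)
  hi <- min(4L, 9L - nSymbols)
  start <- if (lo == hi) lo else sample(lo:hi, 1L)
  chars <- rep("N", 8L)
  refChar <- sample(c("C", "T"), 1L)
  for (p in start:(start + nSymbols - 1L)) {
    if (p == 4L) {
      chars[p] <- refChar
    } else if (p == 5L) {
      refCode <- match(refChar, .BASES)
      singles <- setdiff(.SINGLE_CODES, refChar)
      pairs <- .PAIR_CODES[vapply(
        .PAIR_CODES,
        function(cc) !(refCode %in% .IUPAC_SETS[[cc]]), logical(1L)
      )]
      chars[p] <- sample(c(singles, pairs), 1L)
    } else {
      chars[p] <- sample(c(.SINGLE_CODES, .PAIR_CODES), 1L)
    }
  }
  paste(chars, collapse = "")
}

#' Resolve assignment conflicts by category replacement
#'
#' While the ambiguous-assignment rate is at or above the threshold, the
#' non-joker category involved in the most ambiguous ties is replaced by a
#' freshly sampled category and the assignment table rebuilt. Residual
#' ambiguous sequences keep their uniformly random tied-winner assignment.
#' Fails (with an error) if `maxRounds` replacements do not reach the
#' threshold.
#'
#' @param patterns character vector of patterns including the joker.
#' @param config a [gaConfig()] list (threshold, concentration, rounds).
#' @param name name for the resulting categorization.
#' @return a [MutationCategorization-class] with
#'   `conflictRate < config$conflictThreshold`.
#' @export
resolveConflicts <- function(patterns, config = gaConfig(), name = "sampled") {
  ps <- lapply(patterns, parsePattern)
  patterns <- vapply(ps, function(p) p@text, "")
  jokerAt <- which(patterns == .JOKER)
  if (length(jokerAt) != 1L) {
    stop("patterns must include exactly one joker category")
  }
  # match columns and keys are kept up to date incrementally: a replacement
  # round only recomputes the replaced category's column
  M <- vapply(ps, .matchVector, logical(.N_UNIVERSE))
  key <- vapply(ps, .patternKey, 0)
  for (round in seq_len(config$maxResolveRounds)) {
    tab <- .assignFromMatches(M, key)
    if (tab$conflictRate < config$conflictThreshold) {
      return(new("MutationCategorization",
        name = name, patterns = patterns, labels = patterns,
        assignment = tab$assignment, ambiguous = tab$ambiguous,
        conflictRate = tab$conflictRate
      ))
    }
    ties <- tab$tieCounts
    ties[jokerAt] <- -1 # never replace the joker
    worst <- which.max(ties)
    p <- parsePattern(sampleCategory(config$concentration))
    patterns[worst] <- p@text
    M[, worst] <- .matchVector(p)
    key[worst] <- .patternKey(p)
    # duplicates introduced by the replacement stay ambiguous and will be
    # targeted in later rounds
  }
  stop(
    "conflict resolution did not reach a rate below ",
    config$conflictThreshold, " within ", config$maxResolveRounds, " rounds"
  )
}

#' Sample a conflict-resolved random categorization
#'
#' Draws 95 ancestor categories plus the joker and resolves conflicts until
#' the ambiguous-assignment rate is below the configured threshold.
#'
#' @param config a [gaConfig()] list.
#' @param seed optional seed; `NULL` uses the current RNG stream.
#' @param nCategories total number of categories including the joker.
#' @return a [MutationCategorization-class].
#' @export
sampleCategorization <- function(config = gaConfig(), seed = NULL,
                                 nCategories = 96L) {
  withSeed(seed, {
    patterns <- c(
      replicate(nCategories - 1L, sampleCategory(config$concentration)),
      .JOKER
    )
    resolveConflicts(patterns, config, name = "sampled")
  })
}

#' Crossover of two categorizations
#'
#' A fraction `u ~ Uniform(0, 0.4]` of the 95 non-joker categories is taken
#' from the lower-fitness parent and the rest from the higher-fitness
#' parent. Duplicate patterns are collapsed; if fewer than 95 unique
#' non-joker categories remain, fresh categories are sampled to fill up.
#' The joker is always included and conflicts are resolved.
#'
#' @param parentHi,parentLo [MutationCategorization-class] parents, `Hi`
#'   the better-ranked one.
#' @param config a [gaConfig()] list.
#' @return an offspring [MutationCategorization-class].
#' @export
gaCrossover <- function(parentHi, parentLo, config = gaConfig()) {
  hi <- setdiff(categoryPatterns(parentHi), .JOKER)
  lo <- setdiff(categoryPatterns(parentLo), .JOKER)
  nTotal <- length(hi)
  u <- runif(1L, 0, 0.4)
  nLo <- min(round(u * nTotal), length(lo))
  fromLo <- if (nLo > 0L) sample(lo, nLo) else character(0)
  fromHi <- sample(hi, nTotal - nLo)
  pool <- unique(c(fromLo, fromHi))
  while (length(pool) < nTotal) {
    pool <- unique(c(pool, sampleCategory(config$concentration)))
  }
  resolveConflicts(c(pool, .JOKER), config, name = "offspring")
}

# one symbol expand/contract move on a single pattern; returns the pattern
# unchanged if no position is eligible (cannot happen for non-joker
# patterns, which always carry a non-N position 5)
.mutatePattern <- function(text) {
  p <- parsePattern(text)
  if (p@joker) {
    return(text)
  }
  sets <- p@sets
  card <- colSums(sets)
  refCode <- which(sets[, 4L])
  eligible <- setdiff(which(card < 4L), 4L)
  if (!length(eligible)) {
    return(text)
  }
  pos <- if (length(eligible) == 1L) eligible else sample(eligible, 1L)
  cur <- which(sets[, pos])
  if (length(cur) == 1L) {
    # single -> pair containing it; position 5 must stay disjoint from ref
    partners <- setdiff(1:4, cur)
    if (pos == 5L) partners <- setdiff(partners, refCode)
    partner <- if (length(partners) == 1L) partners else sample(partners, 1L)
    newSet <- sort(c(cur, partner))
  } else {
    # pair -> one of its two bases
    newSet <- sample(cur, 1L)
  }
  chars <- strsplit(p@text, "", fixed = TRUE)[[1L]]
  chars[pos] <- .IUPAC_CODE[[paste(newSet, collapse = "-")]]
  paste(chars, collapse = "")
}

#' Mutate a categorization
#'
#' Each non-joker category is independently mutated with probability `m`: a
#' uniformly chosen eligible symbol (non-N, never position 4) is replaced
#' by an intersecting symbol — a single base becomes a pair containing it,
#' a pair becomes one of its two bases; position 5 targets stay disjoint
#' from the original base. Conflicts are resolved afterwards.
#'
#' @param categorization a [MutationCategorization-class].
#' @param config a [gaConfig()] list (`mutationRate`, conflict handling).
#' @return a [MutationCategorization-class].
#' @export
gaMutate <- function(categorization, config = gaConfig()) {
  patterns <- categoryPatterns(categorization)
  nonJoker <- patterns != .JOKER
  hit <- nonJoker & runif(length(patterns)) < config$mutationRate
  if (!any(hit)) {
    return(categorization)
  }
  patterns[hit] <- vapply(patterns[hit], .mutatePattern, "")
  resolveConflicts(patterns, config, name = "mutant")
}

## ---- generation loop ----------------------------------------------------

.individual <- function(categorization, fitness = NULL) {
  list(categorization = categorization, fitness = fitness)
}

.fitnessKey <- function(categorization) {
  paste(sort(categoryPatterns(categorization)), collapse = "|")
}

.evaluateIndividual <- function(ind, datasets, config, cache) {
  if (!is.null(ind$fitness)) {
    return(ind)
  }
  key <- .fitnessKey(ind$categorization)
  if (!is.null(cache[[key]])) {
    ind$fitness <- cache[[key]]
    return(ind)
  }
  ind$fitness <- vapply(
    datasets,
    function(d) categorizationFitness(ind$categorization, d, config$fitness)$value,
    numeric(1L)
  )
  cache[[key]] <- ind$fitness
  ind
}

.drawParentPair <- function(rankings, config) {
  # rankings: list of rank vectors (each per-dataset ranking plus the
  # average); a ranking is chosen uniformly, then parents by rank^power
  # without replacement within the pair
  rk <- rankings[[sample.int(length(rankings), 1L)]]
  p <- selectionProbabilities(rk, config$selectionPower)
  i <- sample.int(length(rk), 1L, prob = p)
  p2 <- p
  p2[i] <- 0
  j <- sample.int(length(rk), 1L, prob = p2 / sum(p2))
  # orient by rank in the chosen ranking (higher rank = fitter)
  if (rk[i] >= rk[j]) c(i, j) else c(j, i)
}

#' Produce the next GA generation
#'
#' The two top individuals of the average ranking are copied unchanged
#' (elitism). Each remaining offspring draws a ranking uniformly from the
#' per-dataset rankings plus the average ranking, draws a parent with
#' probability proportional to `rank^power`, and with probability `q`
#' crosses it with a second parent from the same ranking (drawn without
#' replacement), otherwise mutates it.
#'
#' @param population list of individuals (as returned by the internal
#'   evaluator; each has `$categorization` and `$fitness`).
#' @param ranking result of [rankPopulation()] on the population's fitness.
#' @param config a [gaConfig()] list.
#' @return list of `populationSize` individuals; offspring have no cached
#'   fitness yet.
#' @export
nextGeneration <- function(population, ranking, config) {
  S <- length(population)
  eliteIdx <- order(ranking$average, decreasing = TRUE)[1:2]
  rankings <- c(
    lapply(seq_len(ncol(ranking$perDataset)), function(d) ranking$perDataset[, d]),
    list(ranking$average)
  )
  offspring <- vector("list", S - 2L)
  for (o in seq_len(S - 2L)) {
    pair <- .drawParentPair(rankings, config)
    if (runif(1L) < config$crossoverRate) {
      child <- gaCrossover(
        population[[pair[1L]]]$categorization,
        population[[pair[2L]]]$categorization,
        config
      )
    } else {
      child <- gaMutate(population[[pair[1L]]]$categorization, config)
    }
    offspring[[o]] <- .individual(child)
  }
  c(population[eliteIdx], offspring)
}

#' Evolve a mutation categorization
#'
#' The full optimization loop: sample `nAncestors` conflict-resolved
#' categorizations, score them on every dataset, keep the top
#' `populationSize` by average ranking, then iterate [nextGeneration()] for
#' `nGenerations`, evaluating new offspring as they appear (fitness values
#' are cached by pattern multiset, so elites are never re-scored). Datasets
#' without a `K*` get one from [selectK()] on their standard-categorization
#' WGS catalog before the run starts; the same cross-validation folds are
#' reused for every individual so fitness values are comparable.
#'
#' @param datasets a [MutationDataset-class] or list of them.
#' @param config a [gaConfig()] list; all randomness flows from
#'   `config$seed`.
#' @return list with `best` (the top categorization of the final average
#'   ranking), `bestFitness` (its per-dataset fitness), `log` (per
#'   generation: best and mean fitness per dataset) and `population`.
#' @export
evolveCategorization <- function(datasets, config = gaConfig()) {
  if (is(datasets, "MutationDataset")) datasets <- list(datasets)
  stopifnot(length(datasets) >= 1L)
  set.seed(as.integer(config$seed))

  datasets <- lapply(datasets, function(d) {
    if (is.na(d@kStar)) {
      V <- normalizeCatalog(.datasetCatalog(d, standardCategorization(), "wgs"))
      cand <- config$kCandidates[config$kCandidates <= min(dim(V))]
      d@kStar <- selectK(V, cand)$kStar
    }
    d
  })

  cache <- new.env(parent = emptyenv())
  evalAll <- function(pop) {
    lapply(pop, .evaluateIndividual, datasets, config, cache)
  }
  fitnessMatrix <- function(pop) {
    do.call(rbind, lapply(pop, `[[`, "fitness"))
  }

  ancestors <- evalAll(lapply(
    seq_len(config$nAncestors),
    function(i) .individual(sampleCategorization(config))
  ))
  rk <- rankPopulation(fitnessMatrix(ancestors))
  keep <- order(rk$average, decreasing = TRUE)[seq_len(config$populationSize)]
  population <- ancestors[keep]

  log <- vector("list", config$nGenerations)
  for (gen in seq_len(config$nGenerations)) {
    fm <- fitnessMatrix(population)
    rk <- rankPopulation(fm)
    log[[gen]] <- data.frame(
      generation = gen,
      dataset = seq_len(ncol(fm)),
      bestFitness = fm[rk$best, ],
      maxMeanFitness = max(rowMeans(fm)),
      maxFitness = apply(fm, 2L, max),
      meanFitness = colMeans(fm)
    )
    population <- evalAll(nextGeneration(population, rk, config))
  }
  fm <- fitnessMatrix(population)
  rk <- rankPopulation(fm)
  list(
    best = population[[rk$best]]$categorization,
    bestFitness = fm[rk$best, ],
    log = do.call(rbind, log),
    population = population
  )
}
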