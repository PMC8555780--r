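test_that("ancestor categories follow the interval sampling scheme", {
  set.seed(12)
  pats <- replicate(2000, sampleCategory(10))
  parsed <- lapply(pats, parsePattern)
  # every emitted pattern is valid and non-joker, with non-N positions 4-5
  expect_true(all(vapply(parsed, function(p) !p@joker, logical(1))))
  nonN <- lapply(parsed, function(p) which(colSums(p@sets) < 4L))
  expect_true(all(vapply(nonN, function(x) all(c(4L, 5L) %in% x), logical(1))))
  # intervals are consecutive
  expect_true(all(vapply(nonN, function(x) all(diff(x) == 1L), logical(1))))
  # n_symbols concentrates on 4 with weight c / (c + 4)
  nsym <- lengths(nonN)
  expect_true(all(nsym >= 3L & nsym <= 7L))
  expect_lt(abs(mean(nsym == 4L) - 10 / 14), 0.04)
  # n_symbols = 5 intervals start at positions 1..4
  starts5 <- vapply(nonN[nsym == 5L], min, 0L)
  expect_setequal(unique(starts5), 1:4)
})

test_that("sampled categorizations keep conflicts below one percent", {
  cfg <- gaConfig()
  sc <- sampleCategorization(cfg, seed = 5)
  expect_identical(nCategories(sc), 96L)
  expect_identical(sum(categoryPatterns(sc) == "NNNNNNNN"), 1L)
  expect_lt(conflictRate(sc), 0.01)
  # all sequences assigned
  expect_identical(sum(tabulate(assignmentTable(sc), 96L)), 24576L)
  # deterministic under a fixed seed
  sc2 <- sampleCategorization(cfg, seed = 5)
  expect_identical(categoryPatterns(sc), categoryPatterns(sc2))
  expect_identical(assignmentTable(sc), assignmentTable(sc2))
})

test_that("conflict resolution replaces offending categories", {
  cfg <- gaConfig()
  # conflict-free input is returned unchanged
  clean <- c("NNTCTANN", "NNNNNNNN")
  set.seed(2)
  res <- resolveConflicts(clean, cfg)
  expect_identical(categoryPatterns(res), clean)
  # duplicated pattern: every matching sequence ties between the copies
  dup <- c("NSTCTANN", "NSTCTANN", "NNNNNNNN")
  set.seed(3)
  tab <- ddcat:::.buildTable(dup)
  expect_equal(tab$conflictRate, 128 / 24576)
  # a large duplicated category pushes the rate over the threshold and one
  # copy is replaced
  big <- c("NNNCTNNN", "NNNCTNNN", "NNNNNNNN")
  expect_equal(ddcat:::.buildTable(big)$conflictRate, 4096 / 24576)
  set.seed(4)
  fixed <- resolveConflicts(big, cfg)
  expect_lt(conflictRate(fixed), 0.01)
  expect_identical(sum(categoryPatterns(fixed) == "NNNCTNNN"), 1L)
  expect_error(resolveConflicts(c("NNTCTANN", "NNTCAANN"), cfg), "joker")
})

test_that("crossover mixes parents within the 40% bound and fills up", {
  cfg <- gaConfig()
  p1 <- sampleCategorization(cfg, seed = 61)
  p2 <- sampleCategorization(cfg, seed = 62)
  set.seed(63)
  for (i in 1:3) {
    child <- gaCrossover(p1, p2, cfg)
    expect_identical(nCategories(child), 96L)
    expect_lt(conflictRate(child), 0.01)
    kid <- setdiff(categoryPatterns(child), "NNNNNNNN")
    fromLo <- intersect(kid, setdiff(
      categoryPatterns(p2),
      categoryPatterns(p1)
    ))
    # categories certain to come from the lower-fitness parent obey the cap
    expect_lte(length(fromLo), ceiling(0.4 * 95))
  }
  # identical parents: offspring is a subset of the parent plus fill-ins
  set.seed(64)
  same <- gaCrossover(p1, p1, cfg)
  inherited <- intersect(categoryPatterns(same), categoryPatterns(p1))
  expect_gt(length(inherited), 90L)
})

test_that("the mutation operator makes single intersecting-symbol moves", {
  # 'A' at a flank expands to one of M, R, W
  set.seed(71)
  hits <- replicate(60, {
    m <- ddcat:::.mutatePattern("NNACTANN")
    chars <- strsplit(m, "")[[1]]
    changedAt <- which(chars != strsplit("NNACTANN", "")[[1]])
    list(m = m, at = changedAt, to = chars[changedAt])
  }, simplify = FALSE)
  for (h in hits) {
    expect_length(h$at, 1L)
    expect_true(h$at %in% c(3L, 5L, 6L)) # non-N positions excluding 4
    if (h$at == 3L) expect_true(h$to %in% c("M", "R", "W"))
    if (h$at == 5L) expect_true(h$to %in% c("K", "W", "Y")) # pairs with T, no C
    expect_no_error(parsePattern(h$m))
  }
  # a pair contracts to one of its bases: K (G/T) -> G or T
  set.seed(72)
  tos <- replicate(40, {
    m <- ddcat:::.mutatePattern("NNNCTKNN")
    substr(m, 6, 6)
  })
  expect_setequal(unique(tos[tos != "K"]), c("G", "T"))
  # joker and rate zero are no-ops
  expect_identical(ddcat:::.mutatePattern("NNNNNNNN"), "NNNNNNNN")
  cfg0 <- gaConfig(mutationRate = 0)
  sc <- sampleCategorization(cfg0, seed = 73)
  expect_identical(gaMutate(sc, cfg0), sc)
})

test_that("next generation applies elitism and restores population size", {
  cfg <- gaConfig(populationSize = 5, crossoverRate = 0)
  pop <- lapply(81:85, function(s) {
    ddcat:::.individual(sampleCategorization(cfg, seed = s), fitness = NULL)
  })
  fake <- matrix(c(0.5, 0.1, 0.4, 0.2, 0.3), 5) # individual 1 best, 2 worst
  for (i in 1:5) pop[[i]]$fitness <- fake[i, ]
  rk <- rankPopulation(fake)
  set.seed(86)
  nxt <- nextGeneration(pop, rk, cfg)
  expect_length(nxt, 5L)
  elitePatterns <- lapply(nxt[1:2], function(i) categoryPatterns(i$categorization))
  expect_true(identical(elitePatterns[[1]], categoryPatterns(pop[[1]]$categorization)))
  expect_true(identical(elitePatterns[[2]], categoryPatterns(pop[[3]]$categorization)))
  # elites keep their cached fitness; offspring are unevaluated
  expect_identical(nxt[[1]]$fitness, pop[[1]]$fitness)
  expect_true(all(vapply(nxt[3:5], function(i) is.null(i$fitness), logical(1))))
})

test_that("a tiny GA run completes, logs, and is reproducible", {
  ds <- ddcatDataset()
  cfg <- gaConfig(
    populationSize = 4, nAncestors = 5, nGenerations = 2, seed = 91,
    fitness = fitnessConfig(nmfRestarts = 2, nmfMaxIter = 300, kHalfWidth = 0)
  )
  res <- evolveCategorization(ds, cfg)
  expect_s4_class(res$best, "MutationCategorization")
  expect_identical(nCategories(res$best), 96L)
  expect_lt(conflictRate(res$best), 0.01)
  expect_identical(nrow(res$log), 2L)
  # elitism: the logged best fitness never decreases (single dataset)
  expect_true(all(diff(res$log$maxMeanFitness) >= 0))
  expect_gte(max(res$bestFitness), res$log$maxMeanFitness[1])
  res2 <- evolveCategorization(ds, cfg)
  expect_identical(res$log, res2$log)
  expect_identical(categoryPatterns(res$best), categoryPatterns(res2$best))
})
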