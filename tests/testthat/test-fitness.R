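test_that("held-out CCA finds planted coupling and nothing in noise", {
  set.seed(9)
  W <- matrix(rgamma(60 * 3, 2), 60)
  E <- W %*% matrix(runif(3 * 20), 3) + matrix(rnorm(60 * 20, sd = 0.01), 60)
  cc <- ccaTestCorrelation(W, E, seed = 1)
  expect_gt(cc$meanCorrelation, 0.95)
  expect_length(cc$foldCorrelations, 10L)

  # independent views: mean held-out correlation stays near zero
  nulls <- vapply(1:5, function(s) {
    set.seed(s)
    Wi <- matrix(rgamma(200 * 4, 2), 200)
    Ei <- matrix(rgamma(200 * 30, 2), 200)
    ccaTestCorrelation(Wi, Ei, seed = 100 + s)$meanCorrelation
  }, numeric(1))
  expect_lt(abs(mean(nulls)), 0.15)

  # fixed seed fixes folds and output
  cc2 <- ccaTestCorrelation(W, E, seed = 1)
  expect_identical(cc$foldCorrelations, cc2$foldCorrelations)
  expect_error(ccaTestCorrelation(W[1:10, ], E[1:10, ]), "2 \\* nFolds")
})

test_that("regularized CCA agrees with independent implementations", {
  set.seed(4)
  X <- scale(matrix(rnorm(50 * 3), 50))
  Y <- scale(matrix(rnorm(50 * 5), 50) + X[, 1])
  fit <- ddcat:::.ccaFit(X, Y, reg = 0.1)
  mine <- as.numeric(cor(X %*% fit$a, Y %*% fit$b))
  # as regularization vanishes, classical CCA (stats::cancor) is recovered
  fit0 <- ddcat:::.ccaFit(X, Y, reg = 1e-8)
  expect_equal(
    as.numeric(cor(X %*% fit0$a, Y %*% fit0$b)),
    cancor(X, Y)$cor[1], tolerance = 1e-4
  )
  # mixOmics ridge CCA finds the same leading canonical pair
  skip_if_not_installed("mixOmics")
  rc <- mixOmics::rcc(X, Y, lambda1 = 0.1, lambda2 = 0.1, method = "ridge")
  expect_equal(
    abs(as.numeric(cor(rc$variates$X[, 1], rc$variates$Y[, 1]))),
    abs(mine), tolerance = 1e-6
  )
})

test_that("rank-power selection probabilities follow the published rule", {
  expect_equal(selectionProbabilities(1:3, power = 1), c(1, 2, 3) / 6)
  expect_equal(selectionProbabilities(1:3, power = 5), c(1, 32, 243) / 276)
  p <- selectionProbabilities(1:10, power = 5)
  expect_equal(sum(p), 1)
  expect_true(all(diff(p) > 0))
  # large powers concentrate mass on the top rank
  expect_gt(selectionProbabilities(1:10, power = 50)[10], 0.99)
  expect_error(selectionProbabilities(1:3, power = 0), "positive")
  expect_error(selectionProbabilities(c(1, 1, 3), power = 2), "permutation")
})

test_that("population ranking averages per-dataset ranks with stable ties", {
  f1 <- matrix(c(0.1, 0.5, 0.3), 3)
  r1 <- rankPopulation(f1)
  expect_equal(unname(r1$average), c(1, 3, 2))
  expect_identical(r1$best, 2L)

  # two perfectly reversed datasets: all mean ranks tie, stable order breaks
  f2 <- cbind(c(0.1, 0.2, 0.3), c(0.3, 0.2, 0.1))
  r2 <- rankPopulation(f2)
  expect_equal(unname(rowMeans(r2$perDataset)), rep(2, 3))
  expect_equal(unname(r2$average), c(1, 2, 3)) # stable (first-wins) tie-break
  expect_error(rankPopulation(matrix(c(1, NA), 2)), "missing")
})

test_that("fitness separates coupled categorizations from random ones", {
  ds <- ddcatDataset()
  planted <- ddcatPlanted()
  cfg <- fitnessConfig()
  # a single-K range makes the fitness equal that K's fold mean
  set.seed(31)
  f1 <- categorizationFitness(planted, ds, cfg, kRange = 3)
  expect_equal(f1$value, unname(mean(f1$perK)))
  expect_length(f1$perK, 1L)

  # ordering planted >= standard > random, averaged over seeds
  fits <- vapply(1:3, function(s) {
    set.seed(40 + s)
    c(
      categorizationFitness(planted, ds, cfg, kRange = 3)$value,
      categorizationFitness(standardCategorization(), ds, cfg, kRange = 3)$value,
      categorizationFitness(randomCategorization(seed = s), ds, cfg, kRange = 3)$value
    )
  }, numeric(3))
  means <- rowMeans(fits)
  expect_gt(means[1], means[3]) # planted beats random decisively
  expect_gt(means[2], means[3]) # standard beats random
  expect_gte(means[1] + 0.05, means[2]) # planted at least on par with standard
})
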