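test_that("balanced bootstrap draws equal class counts with replacement", {
  set.seed(1)
  idx <- balancedBootstrapIndices(c(0, 0, 0, 1), 2)
  expect_length(idx, 4L)
  expect_identical(sum(idx <= 3), 2L)
  expect_identical(sum(idx == 4), 2L)
  # the study's 45/18 microarray case: 18 per class
  y <- rep(c(1, 0), c(45, 18))
  idx2 <- balancedBootstrapIndices(y, 18)
  expect_length(idx2, 36L)
  expect_identical(sum(y[idx2] == 0), 18L)
  expect_identical(sum(y[idx2] == 1), 18L)
  # 90:10 imbalance: composition is exact in every draw
  y2 <- rep(c(0, 1), c(90, 10))
  comps <- vapply(1:1000, function(s) {
    set.seed(s)
    d <- balancedBootstrapIndices(y2, 7)
    c(sum(y2[d] == 0), sum(y2[d] == 1), length(d))
  }, integer(3))
  expect_true(all(comps[1, ] == 7L & comps[2, ] == 7L & comps[3, ] == 14L))
  expect_error(balancedBootstrapIndices(rep(0, 5), 2), "both classes")
})

test_that("stratified folds keep every fold's class ratio within one", {
  for (s in 1:20) {
    set.seed(s)
    n <- sample(30:80, 1)
    y <- sample(0:1, n, replace = TRUE, prob = c(0.8, 0.2))
    if (sum(y) < 5) y[1:5] <- 1
    k <- 5
    folds <- modalFuse:::stratifiedFolds(y, k, s)
    perFold <- table(factor(folds, 1:k), y)
    expect_true(all(abs(perFold[, "1"] - sum(y == 1) / k) < 1))
    expect_true(all(abs(perFold[, "0"] - sum(y == 0) / k) < 1))
  }
})

test_that("Gini importance ranks a separating feature first, noise flat", {
  set.seed(5)
  n <- 60
  y <- rep(c(0, 1), each = n / 2)
  x <- cbind(matrix(rnorm(n * 9), n, 9), sep = y * 8 + rnorm(n, 0, 0.1))
  colnames(x) <- c(paste0("n", 1:9), "sep")
  f <- fitBalancedRF(x, y, ntree = 300)
  imp <- giniImportance(f)
  expect_identical(names(which.max(imp)), "sep")
  # pure noise: no feature dominates (3x the median), across seeds
  for (s in 1:20) {
    set.seed(400 + s)
    xn <- matrix(rnorm(80 * 8), 80, 8,
                 dimnames = list(NULL, paste0("f", 1:8)))
    yn <- rep(c(0, 1), each = 40)
    fn <- fitBalancedRF(xn, yn, ntree = 500)
    impn <- giniImportance(fn)
    expect_lt(max(impn), 3 * median(impn))
  }
})

test_that("subset-size picking follows the best and tolerance rules", {
  prof <- c(`1` = 0.90, `5` = 0.95, `10` = 0.96)
  expect_identical(pickSize(prof, "best"), 10L)
  expect_identical(pickSize(prof, "tolerance", 0.05), 5L)
  flat <- c(`1` = 0.9, `2` = 0.9)
  expect_identical(pickSize(flat, "best"), 1L)
  expect_identical(pickSize(flat, "tolerance", 0.05), 1L)
})

test_that("RFE recovers planted features and honours degenerate grids", {
  # 3 strong planted features among 30 noise: whatever size the picker
  # settles on, the chosen set must come from the planted features, the
  # full-data ranking must put all three on top, and chosen sets of size
  # >= 3 must contain all of them
  rankHits <- 0L
  for (s in 1:20) {
    set.seed(s)
    n <- 60
    y <- rep(c(0, 1), each = n / 2)
    x <- matrix(rnorm(n * 33), n, 33,
                dimnames = list(NULL, c(paste0("sig", 1:3),
                                        paste0("n", 1:30))))
    x[y == 1, 1:3] <- x[y == 1, 1:3] + 4
    prof <- runRFE(x, y, rfeConfig(subsetSizes = c(1, 2, 3, 5, 10),
                                   kFolds = 3, ntree = 100,
                                   pickRule = "best"), seed = s)
    if (prof$chosenSize <= 3)
      expect_true(all(prof$chosenFeatures %in% paste0("sig", 1:3)))
    else expect_true(all(paste0("sig", 1:3) %in% prof$chosenFeatures))
    if (setequal(prof$fullRanking[1:3], paste0("sig", 1:3)))
      rankHits <- rankHits + 1L
  }
  expect_gte(rankHits, 18L)
  # grid = total feature count: one profile entry, all features chosen
  set.seed(2)
  x2 <- matrix(rnorm(40 * 4), 40, 4,
               dimnames = list(NULL, paste0("f", 1:4)))
  y2 <- rep(c(0, 1), each = 20)
  prof2 <- runRFE(x2, y2, rfeConfig(subsetSizes = 4, kFolds = 4,
                                    ntree = 50), seed = 1)
  expect_length(prof2$meanAUC, 1L)
  expect_identical(prof2$chosenSize, 4L)
  expect_setequal(prof2$chosenFeatures, paste0("f", 1:4))
})

test_that("tolerance picking collapses to one perfectly separable feature", {
  set.seed(8)
  n <- 60
  y <- rep(c(0, 1), each = n / 2)
  x <- cbind(sep = y * 10 + rnorm(n, 0, 0.1),
             matrix(rnorm(n * 10), n, 10))
  colnames(x) <- c("sep", paste0("n", 1:10))
  prof <- runRFE(x, y, rfeConfig(subsetSizes = c(1, 2, 3, 5, 8),
                                 kFolds = 4, ntree = 100,
                                 pickRule = "tolerance",
                                 toleranceFraction = 0.05), seed = 3)
  expect_identical(prof$chosenSize, 1L)
  expect_identical(prof$chosenFeatures, "sep")
})

test_that("repeated selection is reproducible and keeps its accounting", {
  pair <- fixtureSmall()
  u <- mergeSeparate(list(pair$imaging, pair$molecular))
  cfg <- rfeConfig(subsetSizes = c(1, 2, 3, 5), kFolds = 3,
                   repetitions = 3, ntree = 60)
  r1 <- repeatSelection(u, config = cfg, seed = 6, scheme = "mean")
  r2 <- repeatSelection(u, config = cfg, seed = 6, scheme = "mean")
  expect_identical(r1$frequency, r2$frequency)
  expect_identical(r1$chosenSizes, r2$chosenSizes)
  # accounting identity: total counts = total chosen sizes
  expect_identical(sum(r1$frequency$count), sum(r1$chosenSizes))
  expect_true(all(r1$frequency$count <= cfg$repetitions))
  expect_true(all(diff(r1$frequency$count) <= 0))
})

test_that("repeated re-imputed selection recovers a planted molecular set", {
  cfg <- synthConfig(imagingControls = 60L, imagingCases = 15L,
                     imagingFeatures = 10L, imagingInformative = 0L,
                     molecularControls = 18L, molecularCases = 45L,
                     molecularFeatures = 40L, molecularInformative = 3L,
                     effectSize = 3)
  pair <- generateModalityPair(cfg, seed = 31L)
  u <- mergeSeparate(list(pair$imaging, pair$molecular))
  rs <- repeatSelection(u, config = rfeConfig(subsetSizes = c(1:6, 8, 10),
                                              kFolds = 5, repetitions = 10,
                                              ntree = 100,
                                              pickRule = "best"),
                        seed = 17, scheme = "normal")
  tab <- stats::setNames(rs$frequency$count, rs$frequency$feature)
  planted <- pair$truth$molecular
  for (f in planted) expect_gte(if (f %in% names(tab)) tab[[f]] else 0L, 8L)
  noise <- tab[!names(tab) %in% planted]
  expect_lte(if (length(noise)) max(noise) else 0L, 2L)
})

test_that("feature replication adds bit-identical suffixed copies", {
  pair <- fixtureSmall()
  u <- mergeSeparate(list(pair$imaging, pair$molecular))
  r <- replicateFeatures(u, "img", 10L)
  expect_identical(ncol(featureMatrix(r)),
                   ncol(featureMatrix(u)) + 60L)   # 6 x 10 copies
  expect_identical(featureMatrix(r)[, "img0001.rep7"],
                   featureMatrix(u)[, "img0001"])
  expect_identical(unname(featureModality(r)["img0003.rep2"]), "img")
  # the study's 31-feature block times 10 adds 310
  wide <- FeatureTable(matrix(rnorm(10 * 31), 10, 31,
                              dimnames = list(paste0("s", 1:10),
                                              paste0("d", 1:31))),
                       rep(c(0, 1), 5), "derm")
  rw <- replicateFeatures(wide, "derm", 10L)
  expect_identical(ncol(featureMatrix(rw)), 341L)
  d <- imputeUnified(r, "mean", seed = 1)
  expect_equal(unname(cor(featureMatrix(d)[, "img0002"],
                          featureMatrix(d)[, "img0002.rep4"])), 1)
})

test_that("importance-rank positions follow signal placement and add up", {
  cfg <- synthConfig(imagingControls = 30L, imagingCases = 10L,
                     imagingFeatures = 5L, imagingInformative = 5L,
                     molecularControls = 10L, molecularCases = 10L,
                     molecularFeatures = 20L, molecularInformative = 0L,
                     effectSize = 4)
  pair <- generateModalityPair(cfg, seed = 3L)
  u <- mergeSeparate(list(pair$imaging, pair$molecular))
  res <- importanceRankDensity(u, "normal", "img", repetitions = 10,
                               seed = 5, ntree = 150)
  expect_length(res$positions, 10L * 5L)
  # only the imaging features carry signal: they occupy the top ranks
  expect_lte(stats::quantile(res$positions, 0.9), 5)
  expect_error(importanceRankDensity(u, "mean", "nosuch", 2, 1),
               "absent")
})

test_that("rank positions are near-uniform when no feature informs", {
  cfg <- synthConfig(imagingControls = 16L, imagingCases = 8L,
                     imagingFeatures = 10L, imagingInformative = 0L,
                     molecularControls = 12L, molecularCases = 8L,
                     molecularFeatures = 20L, molecularInformative = 0L,
                     effectSize = 0, blockCorr = 0)
  pair <- generateModalityPair(cfg, seed = 13L)
  u <- mergeSeparate(list(pair$imaging, pair$molecular))
  res <- importanceRankDensity(u, "uniform", "gene", repetitions = 50,
                               seed = 7, ntree = 100)
  # all 30 features exchangeable: pooled positions of a 20-feature block
  # should be near-uniform on 1..30 (Kolmogorov-Smirnov distance < 0.1)
  pos <- res$positions
  ks <- max(abs(stats::ecdf(pos)(1:30) - (1:30) / 30))
  expect_lt(ks, 0.1)
})
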