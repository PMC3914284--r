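smallPair <- function() {
  a <- FeatureTable(matrix(c(1, 2, 3, 4, 5, 6), 3, 2,
                           dimnames = list(c("a1", "a2", "a3"),
                                           c("p", "q"))),
                    c(0, 0, 1), "imgm")
  b <- FeatureTable(matrix(c(7, 8, 9, 10, 11, 12), 2, 3,
                           dimnames = list(c("b1", "b2"),
                                           c("r", "s", "t"))),
                    c(0, 1), "molm")
  list(a = a, b = b)
}

test_that("merging separate tables yields the block-complement mask", {
  p <- smallPair()
  u <- mergeSeparate(list(p$a, p$b))
  expect_identical(dim(u), c(5L, 5L))
  m <- missingMask(u)
  for (i in 1:5) for (j in 1:5) {
    inBlockA <- i <= 3 && j <= 2
    inBlockB <- i > 3 && j > 2
    expect_identical(m[i, j], inBlockA || inBlockB)
  }
  expect_identical(classLabels(u), c(0L, 0L, 1L, 0L, 1L))
  expect_false(anyNA(classLabels(u)))
})

test_that("degenerate and invalid merges behave per contract", {
  p <- smallPair()
  empty <- FeatureTable(matrix(numeric(), 0, 2,
                               dimnames = list(NULL, c("u", "v"))),
                        integer(), "emptym")
  u <- mergeSeparate(list(p$a, empty))
  expect_identical(dim(u), c(3L, 4L))
  expect_true(all(is.na(featureMatrix(u)[, c("u", "v")])))
  dup <- FeatureTable(matrix(1:2, 2, 1,
                             dimnames = list(c("a1", "z"), "w")),
                      c(0, 1), "dupm")
  expect_error(mergeSeparate(list(p$a, dup)), "separate cohorts")
})

test_that("feature-name collisions are resolved by modality prefixes", {
  a <- FeatureTable(matrix(1:4, 2, 2, dimnames = list(c("a1", "a2"),
                                                      c("x", "y"))),
                    c(0, 1), "img")
  b <- FeatureTable(matrix(5:8, 2, 2, dimnames = list(c("b1", "b2"),
                                                      c("x", "z"))),
                    c(0, 1), "mol")
  u <- mergeSeparate(list(a, b))
  expect_setequal(featureNames(u), c("img.x", "img.y", "mol.x", "mol.z"))
})

test_that("mean imputation fills class-conditional means exactly", {
  a <- FeatureTable(matrix(c(1, 3, 5, 10, NA, 7), 3, 2,
                           dimnames = list(c("a1", "a2", "a3"),
                                           c("p", "q"))),
                    c(0, 0, 1), "A")
  b <- FeatureTable(matrix(c(4, 10), 2, 1,
                           dimnames = list(c("b1", "b2"), "r")),
                    c(0, 1), "B")
  u <- mergeSeparate(list(a, b))
  d <- imputeUnified(u, "mean", seed = 1)
  x <- featureMatrix(d)
  expect_identical(x["b1", "p"], 2)        # class 0 mean of {1, 3}
  expect_identical(x["b2", "p"], 5)        # class 1 observed {5}
  expect_identical(x["a2", "q"], 10)       # within-modality gap, class 0
  expect_identical(x["b2", "q"], 7)        # class 1 observed {7}
  expect_identical(x["a3", "r"], 10)       # class 1 observed {10}
  expect_identical(x["a1", "r"], 4)        # class 0 observed {4}
  # observed-cell conservation
  expect_identical(x[missingMask(u)], featureMatrix(u)[missingMask(u)])
  expect_true(all(missingMask(d)))
})

test_that("missing (feature, class) groups raise a named error", {
  a <- FeatureTable(matrix(c(1, 2), 2, 1,
                           dimnames = list(c("a1", "a2"), "p")),
                    c(0, 0), "A")
  b <- FeatureTable(matrix(c(4, 10), 2, 1,
                           dimnames = list(c("b1", "b2"), "r")),
                    c(0, 1), "B")
  u <- mergeSeparate(list(a, b))
  expect_error(imputeUnified(u, "mean", seed = 1), "class 1")
})

test_that("bootstrap imputation is closed over observed class values", {
  u <- randomUnified(11)
  d <- imputeUnified(u, "bootstrap", seed = 3)
  x <- featureMatrix(d); m <- missingMask(u); y <- classLabels(u)
  for (j in seq_len(ncol(x))) {
    for (cl in c(0L, 1L)) {
      miss <- !m[, j] & y == cl
      if (!any(miss)) next
      obs <- featureMatrix(u)[m[, j] & y == cl, j]
      expect_true(all(x[miss, j] %in% obs))
    }
  }
  # degenerate single observed value: every imputed cell equals it
  a <- FeatureTable(matrix(c(5, 5, 1, 2), 2, 2,
                           dimnames = list(c("a1", "a2"), c("p", "q"))),
                    c(0, 1), "A")
  b <- FeatureTable(matrix(c(4, 10), 2, 1,
                           dimnames = list(c("b1", "b2"), "r")),
                    c(0, 1), "B")
  d2 <- imputeUnified(mergeSeparate(list(a, b)), "bootstrap", seed = 9)
  expect_identical(featureMatrix(d2)["b1", "p"], 5)
  expect_identical(featureMatrix(d2)["b2", "p"], 5)
})

test_that("normal and uniform schemes match their stated distributions", {
  # one feature, one class, many missing cells: Monte-Carlo against the
  # stated parametric distribution
  n <- 10000L
  obs <- c(-2, -1, 0, 1, 2)   # m = 0, sd = sqrt(2.5)
  a <- FeatureTable(matrix(obs, 5, 1, dimnames = list(paste0("a", 1:5), "p")),
                    c(0, 0, 0, 0, 0), "A")
  filler <- FeatureTable(
    matrix(rnorm(2 * n), n, 2,
           dimnames = list(paste0("b", seq_len(n)), c("r", "s"))),
    rep(0L, n), "B")
  u <- mergeSeparate(list(a, filler))
  dn <- imputeUnified(u, "normal", seed = 5)
  drawsN <- featureMatrix(dn)[!missingMask(u)[, "p"], "p"]
  expect_lt(abs(mean(drawsN)), 4 * sqrt(2.5) / sqrt(n))
  expect_lt(abs(sd(drawsN) / sqrt(2.5) - 1), 0.05)
  du <- imputeUnified(u, "uniform", seed = 5)
  drawsU <- featureMatrix(du)[!missingMask(u)[, "p"], "p"]
  expect_true(all(drawsU >= -2 & drawsU <= 2))
  expect_lt(abs(mean(drawsU) - 0), 4 * (4 / sqrt(12)) / sqrt(n))
})

test_that("imputation streams are reproducible and repetition-varying", {
  u <- randomUnified(13)
  expect_gte(sum(!missingMask(u)), 20)
  # mean scheme: identical across repetitions
  m1 <- reimputeStream(u, "mean", seed = 2, repetition = 1)
  m2 <- reimputeStream(u, "mean", seed = 2, repetition = 2)
  expect_identical(featureMatrix(m1), featureMatrix(m2))
  for (s in c("normal", "uniform", "bootstrap")) {
    r1 <- reimputeStream(u, s, seed = 2, repetition = 1)
    r1b <- reimputeStream(u, s, seed = 2, repetition = 1)
    r2 <- reimputeStream(u, s, seed = 2, repetition = 2)
    expect_identical(featureMatrix(r1), featureMatrix(r1b))
    expect_false(identical(featureMatrix(r1), featureMatrix(r2)))
  }
})

test_that("imputed values are independent of the other class's values", {
  u <- randomUnified(17)
  y <- classLabels(u)
  d0 <- imputeUnified(u, "normal", seed = 4)
  # permute class-1 observed values within each column; class-0 fills must
  # be unchanged because each (feature, class) group has its own substream
  pert <- u
  x <- pert@features
  set.seed(99)
  for (j in seq_len(ncol(x))) {
    rows <- which(y == 1L & missingMask(u)[, j])
    if (length(rows) > 1L) x[rows, j] <- x[sample(rows), j]
  }
  pert@features <- x
  d1 <- imputeUnified(pert, "normal", seed = 4)
  miss0 <- !missingMask(u) & matrix(y == 0L, nrow(x), ncol(x))
  expect_identical(featureMatrix(d0)[miss0], featureMatrix(d1)[miss0])
})

test_that("mean scheme preserves class-conditional first moments exactly", {
  u <- randomUnified(19)
  d <- imputeUnified(u, "mean", seed = 1)
  y <- classLabels(u)
  for (j in seq_len(ncol(featureMatrix(u)))) {
    for (cl in c(0L, 1L)) {
      obs <- featureMatrix(u)[missingMask(u)[, j] & y == cl, j]
      full <- featureMatrix(d)[y == cl, j]
      expect_equal(mean(full), mean(obs), tolerance = 1e-12)
    }
  }
})
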