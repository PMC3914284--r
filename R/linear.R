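#' Principal-component scores and explained variance
#'
#' Thin wrapper around [stats::prcomp] returning per-sample scores on the
#' leading components and the fraction of total variance each explains.
#' Components beyond the matrix rank have zero variance and are flagged.
#'
#' @param x dense numeric matrix (samples x features); it is centred
#'   internally, scaling is left to the caller.
#' @param nComponents number of leading components to return.
#' @return list with `scores` (n x nComponents), `explained` (fractions,
#'   nonincreasing, sum <= 1), `allExplained` (all components), and
#'   `degenerate` (flags for zero-variance components among those
#'   returned).
#' @export
pcaScores <- function(x, nComponents = 2L) {
  x <- as.matrix(x)
  stopifnot(nComponents >= 1L, nComponents <= min(dim(x)))
  pr <- stats::prcomp(x, center = TRUE, scale. = FALSE)
  ev <- pr$sdev^2
  frac <- ev / sum(ev)
  k <- min(nComponents, ncol(pr$x))
  list(scores = pr$x[, seq_len(k), drop = FALSE],
       explained = frac[seq_len(k)], allExplained = frac,
       degenerate = ev[seq_len(k)] < .Machine$double.eps * max(ev))
}

# Pooled within-class scatter pieces shared by fitLDA / LOO prediction.
# Returns the shrunken covariance, class means, priors and the shrinkage
# intensity actually used.
.ldaMoments <- function(x, y, lambda) {
  n <- nrow(x); p <- ncol(x)
  i1 <- y == 1L; i0 <- !i1
  n1 <- sum(i1); n0 <- sum(i0)
  if (n1 < 2L || n0 < 2L) stop("each class needs >= 2 samples")
  m1 <- colMeans(x[i1, , drop = FALSE])
  m0 <- colMeans(x[i0, , drop = FALSE])
  xc <- x
  xc[i1, ] <- sweep(x[i1, , drop = FALSE], 2L, m1)
  xc[i0, ] <- sweep(x[i0, , drop = FALSE], 2L, m0)
  Sn <- crossprod(xc) / n
  mu <- mean(diag(Sn))
  if (identical(lambda, "auto")) {
    # Ledoit-Wolf-style intensity toward the scaled identity
    d2 <- sum(Sn * Sn) - 2 * mu * sum(diag(Sn)) + p * mu^2
    b2 <- (sum(rowSums(xc^2)^2) / n - sum(Sn * Sn)) / n
    lambda <- if (d2 <= .Machine$double.eps) 0 else min(1, max(0, b2 / d2))
  }
  stopifnot(is.numeric(lambda), lambda >= 0, lambda <= 1)
  # unbiased pooled estimate blended with the identity target
  S <- crossprod(xc) / (n - 2)
  sigma <- (1 - lambda) * S
  diag(sigma) <- diag(sigma) + lambda * mu
  list(sigma = sigma, m1 = m1, m0 = m0,
       priors = c(`0` = n0 / n, `1` = n1 / n), lambda = lambda)
}

#' Linear discriminant analysis with shrinkage for wide matrices
#'
#' Two-class LDA: the discriminant direction maximises the ratio of
#' between- to within-class variance. With more features than samples the
#' pooled within-class scatter is singular, so a diagonal-loading shrinkage
#' `(1 - lambda) * S + lambda * mean(diag(S)) * I` is applied; `lambda =
#' "auto"` picks the intensity by a Ledoit-Wolf-style estimate, `lambda =
#' 0` reproduces classical LDA on well-conditioned data.
#'
#' The `svdRatio` is the ratio of the between-group to the within-group
#' standard deviation along the discriminant axis; its square is the
#' canonical F-statistic.
#'
#' @param x dense numeric matrix (samples x features) with colnames.
#' @param y binary 0/1 labels.
#' @param lambda `"auto"` or a fixed shrinkage intensity in [0, 1].
#' @return an `ldaFit` list: `coefficients` (named, one per feature),
#'   `scores` (per-sample discriminant scores), `svdRatio`, `lambda`,
#'   `classMeans`, `priors`.
#' @export
fitLDA <- function(x, y, lambda = "auto") {
  x <- as.matrix(x); y <- as.integer(y)
  mom <- .ldaMoments(x, y, lambda)
  w <- tryCatch(solve(mom$sigma, mom$m1 - mom$m0), error = function(e)
    stop("within-class scatter is singular; set lambda > 0 ",
         "(shrinkage) for p >= n problems", call. = FALSE))
  names(w) <- colnames(x)
  z <- drop(x %*% w)
  n <- length(y)
  zbar <- mean(z)
  z1 <- mean(z[y == 1L]); z0 <- mean(z[y == 0L])
  between <- (sum(y == 1L) * (z1 - zbar)^2 + sum(y == 0L) * (z0 - zbar)^2)
  within <- sum((z - ifelse(y == 1L, z1, z0))^2)
  fstat <- (between / 1) / (within / (n - 2))
  structure(list(coefficients = w, scores = z,
                 svdRatio = sqrt(fstat), lambda = mom$lambda,
                 classMeans = rbind(`0` = mom$m0, `1` = mom$m1),
                 priors = mom$priors),
            class = "ldaFit")
}

#' @export
print.ldaFit <- function(x, ...) {
  cat(sprintf(
    "LDA fit: %d features, svd ratio %.3f (lambda = %.3g)\n",
    length(x$coefficients), x$svdRatio, x$lambda))
  invisible(x)
}

# Gaussian LDA class prediction for new rows given moments.
.ldaPredict <- function(mom, newx) {
  a1 <- solve(mom$sigma, mom$m1)
  a0 <- solve(mom$sigma, mom$m0)
  d1 <- drop(newx %*% a1) - 0.5 * sum(mom$m1 * a1) + log(mom$priors["1"])
  d0 <- drop(newx %*% a0) - 0.5 * sum(mom$m0 * a0) + log(mom$priors["0"])
  as.integer(d1 > d0)
}

#' Leave-one-out LDA accuracy for the positive class
#'
#' Fits `n` shrinkage-LDA models, each excluding one sample, predicts the
#' held-out sample with class priors estimated from the training part, and
#' reports the fraction of positive-class samples predicted correctly.
#'
#' @inheritParams fitLDA
#' @param positive label counted as positive (default 1, the disease
#'   class).
#' @return list with `accuracy` (positive-class fraction correct),
#'   `overall` (all-sample fraction correct) and `predicted` (per-sample
#'   LOO predictions).
#' @export
ldaLooAccuracy <- function(x, y, positive = 1L, lambda = "auto") {
  x <- as.matrix(x); y <- as.integer(y)
  n <- nrow(x)
  stopifnot(n >= 3L)
  if (!any(y == positive)) stop("positive class absent")
  pred <- integer(n)
  for (i in seq_len(n)) {
    mom <- .ldaMoments(x[-i, , drop = FALSE], y[-i], lambda)
    pred[i] <- .ldaPredict(mom, x[i, , drop = FALSE])
  }
  list(accuracy = perClassAccuracy(pred, y, positive),
       overall = mean(pred == y), predicted = pred)
}

#' Coefficient-stability indicators over repeated LDA fits
#'
#' Given the absolute discriminant coefficients of `R` re-imputed LDA runs,
#' ranks features two ways: `topMeans` — the `k` features with the largest
#' mean |coefficient|; `topFrequent` — the `k` features most often among
#' the `k` largest |coefficients| of a run. The stability indicator `si`
#' is the size of their intersection. Absolute values are used throughout
#' because the discriminant axis sign is arbitrary and flips across runs.
#' Frequency ties are broken by higher mean |coefficient|, then name.
#'
#' @param coefficientRuns R x p numeric matrix of coefficients (signs
#'   allowed; absolute values are taken), with feature colnames.
#' @param k list length (default 20, the study's biomarker-set size).
#' @return a `stabilityReport` list: `topMeans`, `topFrequent` (character
#'   vectors of length `min(k, p)`), `frequencies` (named counts), `si`
#'   (integer), `meanAbsCoef`.
#' @export
stabilityIndicators <- function(coefficientRuns, k = 20L) {
  m <- abs(as.matrix(coefficientRuns))
  stopifnot(nrow(m) >= 1L, ncol(m) >= 1L, !is.null(colnames(m)))
  p <- ncol(m)
  kk <- min(k, p)
  meanAbs <- colMeans(m)
  ordMeans <- order(-meanAbs, colnames(m))
  topMeans <- colnames(m)[ordMeans][seq_len(kk)]
  marks <- integer(p); names(marks) <- colnames(m)
  for (r in seq_len(nrow(m))) {
    top <- order(-m[r, ], colnames(m))[seq_len(kk)]
    marks[top] <- marks[top] + 1L
  }
  ordFreq <- order(-marks, -meanAbs, names(marks))
  topFrequent <- names(marks)[ordFreq][seq_len(kk)]
  structure(list(topMeans = topMeans, topFrequent = topFrequent,
                 frequencies = marks, si = length(intersect(topMeans,
                                                            topFrequent)),
                 meanAbsCoef = meanAbs, k = kk),
            class = "stabilityReport")
}

#' @export
print.stabilityReport <- function(x, ...) {
  cat(sprintf("Stability report (k = %d): si = %d\n", x$k, x$si))
  cat("  top-means:   ", paste(utils::head(x$topMeans, 8L),
                               collapse = ", "), "...\n")
  cat("  top-frequent:", paste(utils::head(x$topFrequent, 8L),
                               collapse = ", "), "...\n")
  invisible(x)
}
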