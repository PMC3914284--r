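#' Greedy removal set for highly correlated feature pairs
#'
#' Operates on an absolute-correlation matrix. While some retained pair
#' exceeds the cutoff, the offending pair with the highest correlation is
#' taken (ties by lowest index pair) and the member with the larger mean
#' absolute correlation over the currently retained features is removed
#' (exact ties: the lower column index). Among the retained features no
#' pair exceeds the cutoff.
#'
#' @param corr symmetric matrix of absolute pairwise correlations with unit
#'   diagonal, entries in [0, 1].
#' @param cutoff absolute-correlation threshold; a pair is offending when
#'   strictly above it.
#' @return integer vector of removed column indices (possibly empty), in
#'   removal order.
#' @export
findCorrelatedToRemove <- function(corr, cutoff = 0.75) {
  corr <- as.matrix(corr)
  p <- ncol(corr)
  if (p != nrow(corr) || max(abs(corr - t(corr))) > 1e-8)
    stop("corr must be a symmetric matrix")
  if (min(corr) < 0 || max(corr) > 1 + 1e-12)
    stop("corr entries must be absolute correlations in [0, 1]")
  stopifnot(cutoff > 0, cutoff <= 1)
  active <- rep(TRUE, p)
  removed <- integer()
  repeat {
    idx <- which(active)
    if (length(idx) < 2L) break
    sub <- corr[idx, idx, drop = FALSE]
    diag(sub) <- 0
    mx <- max(sub)
    if (mx <= cutoff) break
    hit <- which(sub == mx, arr.ind = TRUE)
    hit <- hit[hit[, 1L] < hit[, 2L], , drop = FALSE]
    hit <- hit[order(hit[, 1L], hit[, 2L]), , drop = FALSE][1L, ]
    a <- idx[hit[1L]]; b <- idx[hit[2L]]
    # mean |corr| over the other retained features
    meanCor <- function(i) mean(corr[i, setdiff(idx, i)])
    drop <- if (meanCor(a) > meanCor(b)) a
            else if (meanCor(b) > meanCor(a)) b
            else min(a, b)
    active[drop] <- FALSE
    removed <- c(removed, drop)
  }
  removed
}

#' Apply the colinearity filter to a feature table
#'
#' Computes absolute Pearson correlations on the in-scope feature block and
#' removes the [findCorrelatedToRemove] set; out-of-scope features are left
#' untouched. In the melanoma pipeline the scope is the molecular block:
#' microarray features are heavily covariant while the 31 image descriptors
#' are kept regardless. Constant columns have undefined correlations; they
#' are treated as correlation 0 and never removed for colinearity.
#'
#' @param x a [FeatureTable-class], [UnifiedTable-class] (dense), or plain
#'   numeric matrix.
#' @param cutoff absolute-correlation threshold (default 0.75).
#' @param scope for a UnifiedTable, the modality tag(s) to filter (default:
#'   all); for other inputs, optional character vector of feature names.
#' @return a list with `filtered` (same class as `x`), `removed` and
#'   `kept` feature names.
#' @export
applyColinearityFilter <- function(x, cutoff = 0.75, scope = NULL) {
  mat <- if (is(x, "FeatureTable") || is(x, "UnifiedTable"))
    featureMatrix(x) else as.matrix(x)
  if (anyNA(mat)) stop("colinearity filter requires a complete matrix")
  scopeNames <- colnames(mat)
  if (is(x, "UnifiedTable") && !is.null(scope))
    scopeNames <- names(featureModality(x))[featureModality(x) %in% scope]
  else if (!is.null(scope)) scopeNames <- intersect(colnames(mat), scope)
  if (length(scopeNames) == 0L) stop("empty filter scope")
  block <- mat[, scopeNames, drop = FALSE]
  suppressWarnings(corr <- abs(stats::cor(block)))
  corr[is.na(corr)] <- 0   # constant columns
  diag(corr) <- 1
  rm <- findCorrelatedToRemove(corr, cutoff)
  removed <- scopeNames[rm]
  keepNames <- setdiff(colnames(mat), removed)
  filtered <- if (is(x, "FeatureTable")) {
    FeatureTable(mat[, keepNames, drop = FALSE], classLabels(x),
                 modalityTag(x))
  } else if (is(x, "UnifiedTable")) {
    new("UnifiedTable", features = mat[, keepNames, drop = FALSE],
        mask = missingMask(x)[, keepNames, drop = FALSE],
        classLabels = classLabels(x),
        featureModality = featureModality(x)[keepNames],
        sampleModality = sampleModality(x))
  } else mat[, keepNames, drop = FALSE]
  list(filtered = filtered, removed = removed, kept = keepNames)
}
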