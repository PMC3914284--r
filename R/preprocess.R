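#' Drop zero-variance features
#'
#' Removes features whose observed values are all equal (variance zero over
#' non-missing cells). Feature order is otherwise preserved. For the
#' dermoscopy table this is the step that takes 32 raw descriptors down to
#' the informative 31.
#'
#' @param table a [FeatureTable-class].
#' @return the table without its constant features.
#' @export
dropZeroVariance <- function(table) {
  stopifnot(is(table, "FeatureTable"))
  x <- featureMatrix(table)
  nunique <- apply(x, 2L, function(v) length(unique(v[!is.na(v)])))
  keep <- nunique > 1L
  if (!any(keep)) stop("all features have zero variance; empty table")
  FeatureTable(x[, keep, drop = FALSE], classLabels(table),
               modalityTag(table))
}

#' Log2 ratios against a reference class
#'
#' Log2-transforms strictly positive intensities and subtracts, per gene,
#' the mean over the reference-class samples (log of the ratio to the
#' reference). Reference rows are dropped from the output and the remaining
#' categories are recoded to a binary class.
#'
#' @param expr numeric matrix, samples x genes, strictly positive
#'   intensities with rownames (sample IDs) and colnames (gene names).
#' @param categories factor/character per sample (e.g. "melanoma", "nevus",
#'   "normal").
#' @param referenceClass category used as the log-ratio reference and
#'   removed from the output.
#' @param positiveClass category coded 1 in the output (all other
#'   non-reference categories are coded 0).
#' @param modality modality tag for the returned table.
#' @return a [FeatureTable-class] of log2 ratios without the reference rows.
#' @export
logRatioVsReference <- function(expr, categories, referenceClass,
                                positiveClass, modality = "molecular") {
  expr <- as.matrix(expr)
  categories <- as.character(categories)
  stopifnot(length(categories) == nrow(expr))
  bad <- which(!is.na(expr) & expr <= 0, arr.ind = TRUE)
  if (nrow(bad) > 0L)
    stop(sprintf("nonpositive intensity at sample '%s', gene '%s'",
                 rownames(expr)[bad[1L, 1L]], colnames(expr)[bad[1L, 2L]]))
  ref <- categories == referenceClass
  if (!any(ref)) stop("no samples in reference class '", referenceClass, "'")
  lg <- log2(expr)
  refMean <- colMeans(lg[ref, , drop = FALSE])
  out <- sweep(lg[!ref, , drop = FALSE], 2L, refMean, "-")
  y <- as.integer(categories[!ref] == positiveClass)
  FeatureTable(out, y, modality)
}

#' Differential-expression prefilter parameters
#'
#' @param alpha Benjamini-Hochberg adjusted p-value threshold (inclusive).
#' @param minAbsLog2FC fold-change threshold in log2 units (inclusive;
#'   1.0 means 2-fold).
#' @param fcMode `"either"` keeps a gene if either class-group mean
#'   log-ratio meets the threshold; `"both"` requires both.
#' @return a classed parameter list.
#' @export
deFilterParams <- function(alpha = 0.001, minAbsLog2FC = 1,
                           fcMode = c("either", "both")) {
  stopifnot(alpha > 0, alpha <= 1, minAbsLog2FC >= 0)
  structure(list(alpha = alpha, minAbsLog2FC = minAbsLog2FC,
                 fcMode = match.arg(fcMode)),
            class = "deFilterParams")
}

# Vectorised per-gene Welch t-test, returning two-sided p-values.
welchP <- function(x, y) {
  g1 <- y == 1L
  n1 <- sum(g1); n0 <- sum(!g1)
  if (n1 < 2L || n0 < 2L) stop("each class needs >= 2 samples for the test")
  m1 <- colMeans(x[g1, , drop = FALSE])
  m0 <- colMeans(x[!g1, , drop = FALSE])
  v1 <- apply(x[g1, , drop = FALSE], 2L, stats::var)
  v0 <- apply(x[!g1, , drop = FALSE], 2L, stats::var)
  se2 <- v1 / n1 + v0 / n0
  tt <- (m1 - m0) / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v0 / n0)^2 / (n0 - 1))
  p <- 2 * stats::pt(abs(tt), df, lower.tail = FALSE)
  p[se2 == 0] <- 1  # identical constant groups carry no evidence
  p
}

#' Differential-expression prefilter
#'
#' Keeps genes that pass both gates on a log-ratio table: (i) per-gene
#' two-group location test with Benjamini-Hochberg adjusted p <= alpha, and
#' (ii) absolute class-group mean log2 ratio >= `minAbsLog2FC` (each group
#' mean is a contrast against the reference class absorbed during
#' [logRatioVsReference]). Both thresholds are inclusive.
#'
#' @param logRatios a [FeatureTable-class] of log2 ratios with binary class.
#' @param params a [deFilterParams] object.
#' @param method `"welch"` (default) for an ordinary Welch t-test, or
#'   `"moderated"` for limma's empirical-Bayes moderated t (needs limma).
#' @return the retained sub-table, with attribute `"report"` (data.frame of
#'   per-gene adjusted p and group means).
#' @export
dePrefilter <- function(logRatios, params = deFilterParams(),
                        method = c("welch", "moderated")) {
  stopifnot(is(logRatios, "FeatureTable"), inherits(params, "deFilterParams"))
  method <- match.arg(method)
  x <- featureMatrix(logRatios)
  y <- classLabels(logRatios)
  if (length(unique(y)) < 2L) stop("both class groups must be present")
  if (anyNA(x)) stop("prefilter requires a complete matrix")
  if (method == "moderated") {
    if (!requireNamespace("limma", quietly = TRUE))
      stop("method='moderated' requires the limma package")
    design <- cbind(Intercept = 1, disease = y)
    fit <- limma::eBayes(limma::lmFit(t(x), design))
    p <- fit$p.value[, "disease"]
  } else {
    p <- welchP(x, y)
  }
  padj <- stats::p.adjust(p, method = "BH")
  m1 <- colMeans(x[y == 1L, , drop = FALSE])
  m0 <- colMeans(x[y == 0L, , drop = FALSE])
  fcPass <- if (params$fcMode == "either")
    pmax(abs(m1), abs(m0)) >= params$minAbsLog2FC
  else pmin(abs(m1), abs(m0)) >= params$minAbsLog2FC
  keep <- padj <= params$alpha & fcPass
  report <- data.frame(feature = featureNames(logRatios), p = p,
                       padj = padj, meanDisease = m1, meanControl = m0,
                       kept = keep, row.names = NULL)
  out <- FeatureTable(x[, keep, drop = FALSE], y, modalityTag(logRatios))
  attr(out, "report") <- report
  out
}

#' Centre and scale a dense matrix
#'
#' Each column is shifted to mean 0 and divided by its sample standard
#' deviation. Constant columns become all-zero and are flagged rather than
#' producing NaN. The returned location/scale can be re-applied to new data.
#'
#' @param x dense numeric matrix.
#' @param center,scale optional precomputed location and scale vectors (as
#'   returned in a previous call) to apply instead of estimating.
#' @return a list with `scaled` (matrix), `center`, `scale` (per-feature),
#'   and `constant` (logical flags for sd-zero columns).
#' @export
centerScale <- function(x, center = NULL, scale = NULL) {
  x <- as.matrix(x)
  if (anyNA(x)) stop("centerScale requires a complete matrix")
  if (is.null(center)) center <- colMeans(x)
  if (is.null(scale)) scale <- apply(x, 2L, stats::sd)
  constant <- scale == 0 | is.na(scale)
  safe <- ifelse(constant, 1, scale)
  scaled <- sweep(sweep(x, 2L, center, "-"), 2L, safe, "/")
  scaled[, constant] <- 0
  list(scaled = scaled, center = center, scale = scale, constant = constant)
}
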