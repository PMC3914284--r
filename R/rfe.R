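#' Configuration for balanced-RF recursive feature elimination
#'
#' Defaults mirror the study design: subset-size grid 1..10 then 15..50 by
#' 5, 10-fold stratified CV, 50 repetitions, AUC as the selection metric,
#' and balanced (equal cases per class) bootstrap for every tree. For a
#' table with few features use e.g. `subsetSizes = c(1:10, 15, 20, 25, 30,
#' 31)` (the image-only grid).
#'
#' @param subsetSizes increasing integer vector of candidate subset sizes.
#' @param kFolds folds of the stratified CV.
#' @param repetitions repetitions of the whole CV in [repeatSelection].
#' @param pickRule `"best"` (smallest size attaining the maximum mean AUC)
#'   or `"tolerance"` (smallest size retaining `1 - toleranceFraction` of
#'   the maximum; the study's "95% tolerance" is `toleranceFraction =
#'   0.05`).
#' @param toleranceFraction fraction of the best AUC that may be sacrificed
#'   under `pickRule = "tolerance"`.
#' @param ntree trees per forest.
#' @param mtry features tried per split; `NULL` for `floor(sqrt(p))`.
#' @param balanced draw equal numbers per class into each tree's bag.
#' @param perClassN per-class bag size; `NULL` for the minority-class count.
#' @return a classed configuration list.
#' @export
rfeConfig <- function(subsetSizes = c(1:10, seq(15L, 50L, 5L)),
                      kFolds = 10L, repetitions = 50L,
                      pickRule = c("best", "tolerance"),
                      toleranceFraction = 0.05, ntree = 500L, mtry = NULL,
                      balanced = TRUE, perClassN = NULL) {
  subsetSizes <- sort(unique(as.integer(subsetSizes)))
  stopifnot(all(subsetSizes >= 1L), kFolds >= 2L, repetitions >= 1L,
            toleranceFraction >= 0, toleranceFraction < 1, ntree >= 1L)
  structure(list(subsetSizes = subsetSizes, kFolds = as.integer(kFolds),
                 repetitions = as.integer(repetitions),
                 pickRule = match.arg(pickRule),
                 toleranceFraction = toleranceFraction,
                 ntree = as.integer(ntree), mtry = mtry,
                 balanced = isTRUE(balanced), perClassN = perClassN),
            class = "rfeConfig")
}

#' Balanced bootstrap indices
#'
#' Draws, with replacement, exactly `perClassN` sample indices from each
#' class — the stratified bootstrap that each tree of a balanced random
#' forest is grown on. Uses the current RNG stream.
#'
#' @param classLabels binary 0/1 vector.
#' @param perClassN draws per class.
#' @return integer vector of `2 * perClassN` indices.
#' @export
balancedBootstrapIndices <- function(classLabels, perClassN) {
  classLabels <- as.integer(classLabels)
  stopifnot(perClassN >= 1L)
  i0 <- which(classLabels == 0L); i1 <- which(classLabels == 1L)
  if (length(i0) == 0L || length(i1) == 0L)
    stop("both classes must be non-empty")
  c(i0[sample.int(length(i0), perClassN, replace = TRUE)],
    i1[sample.int(length(i1), perClassN, replace = TRUE)])
}

#' Fit a balanced random forest
#'
#' A random forest whose per-tree bootstrap is stratified to contain an
#' equal number of cases per class (the balanced-RF treatment of class
#' imbalance), with per-feature Mean Decrease Gini importance. Uses the
#' current RNG stream; wrap in a seeded context for reproducibility.
#'
#' @param x numeric matrix (samples x features), no missing values.
#' @param y binary 0/1 labels.
#' @param ntree,mtry forest parameters; `mtry = NULL` means
#'   `floor(sqrt(p))`.
#' @param balanced if `FALSE`, an ordinary stratified bootstrap with the
#'   full class counts is used instead.
#' @param perClassN per-class bag size when balanced; defaults to the
#'   minority-class count.
#' @return a `randomForest` object.
#' @export
fitBalancedRF <- function(x, y, ntree = 500L, mtry = NULL, balanced = TRUE,
                          perClassN = NULL) {
  y <- as.integer(y)
  if (length(unique(y)) < 2L) stop("both classes must be present")
  if (anyNA(x)) stop("random forest requires a complete matrix")
  yf <- factor(y, levels = c(0L, 1L))
  counts <- table(yf)
  if (is.null(mtry)) mtry <- max(1L, floor(sqrt(ncol(x))))
  sampsize <- if (balanced) {
    n <- if (is.null(perClassN)) min(counts) else as.integer(perClassN)
    stats::setNames(c(n, n), levels(yf))
  } else stats::setNames(as.integer(counts), levels(yf))
  randomForest::randomForest(x = x, y = yf, ntree = ntree, mtry = mtry,
                             strata = yf, sampsize = sampsize,
                             replace = TRUE, keep.forest = TRUE)
}

#' Mean Decrease Gini importance of a fitted forest
#'
#' @param forest a `randomForest` object.
#' @return named non-negative numeric vector, one entry per feature.
#' @export
giniImportance <- function(forest) {
  imp <- forest$importance[, "MeanDecreaseGini"]
  stats::setNames(as.numeric(imp), rownames(forest$importance))
}

# Stratified fold assignment: within each class, shuffled indices are dealt
# to folds cyclically, so every fold's class ratio is within one sample of
# the global ratio.
stratifiedFolds <- function(y, k, seed) {
  y <- as.integer(y)
  folds <- integer(length(y))
  withSeed(seed, for (cl in unique(y)) {
    idx <- sample(which(y == cl))
    folds[idx] <- rep_len(seq_len(k), length(idx))
  })
  folds
}

#' Pick a subset size from a per-size performance profile
#'
#' `"best"` returns the smallest size attaining the maximum mean AUC;
#' `"tolerance"` the smallest size whose AUC is at least
#' `(1 - toleranceFraction)` times the maximum — the study's preference for
#' a subset that is "small enough without sacrificing too much
#' performance".
#'
#' @param profile named numeric vector of mean AUC per subset size (names
#'   are the sizes).
#' @param rule `"best"` or `"tolerance"`.
#' @param toleranceFraction see [rfeConfig].
#' @return the chosen size (integer).
#' @export
#' @examples
#' pickSize(c(`1` = 0.90, `5` = 0.95, `10` = 0.96), "tolerance", 0.05)  # 5
pickSize <- function(profile, rule = c("best", "tolerance"),
                     toleranceFraction = 0.05) {
  rule <- match.arg(rule)
  stopifnot(length(profile) >= 1L, !is.null(names(profile)))
  sizes <- as.integer(names(profile))
  ord <- order(sizes)
  sizes <- sizes[ord]; profile <- profile[ord]
  target <- if (rule == "best") max(profile)
            else (1 - toleranceFraction) * max(profile)
  sizes[which(profile >= target)[1L]]
}

#' One pass of recursive feature elimination with balanced random forests
#'
#' Within each stratified CV fold, a forest on the full feature set ranks
#' the features by Mean Decrease Gini; for every candidate subset size the
#' top-ranked features are refit and scored by held-out AUC. The per-size
#' AUCs are averaged across folds, a size is picked by the configured rule,
#' and the final feature set is the top `chosenSize` features of a forest
#' refit on all data. Importance for elimination is computed once per fold
#' on the full set and truncated per size (re-ranking at every size is not
#' performed).
#'
#' @param x numeric matrix (samples x features, complete), with colnames.
#' @param y binary 0/1 labels.
#' @param config an [rfeConfig].
#' @param seed integer seed; folds and forests draw from substreams of it.
#' @return a `selectionProfile` list: `sizes`, `meanAUC` (named by size),
#'   `foldAUC` (folds x sizes), `chosenSize`, `chosenFeatures`,
#'   `fullRanking` (features of the all-data forest, most important
#'   first).
#' @export
runRFE <- function(x, y, config = rfeConfig(), seed = 1L) {
  stopifnot(inherits(config, "rfeConfig"))
  y <- as.integer(y)
  p <- ncol(x)
  sizes <- config$subsetSizes[config$subsetSizes <= p]
  if (length(sizes) == 0L) stop("no subset size <= number of features")
  folds <- stratifiedFolds(y, config$kFolds, mixSeed(seed, "folds"))
  foldAUC <- matrix(NA_real_, config$kFolds, length(sizes),
                    dimnames = list(NULL, sizes))
  for (f in seq_len(config$kFolds)) {
    tr <- folds != f; te <- !tr
    if (length(unique(y[te])) < 2L || length(unique(y[tr])) < 2L) next
    full <- withSeed(mixSeed(seed, "rank", f),
      fitBalancedRF(x[tr, , drop = FALSE], y[tr], ntree = config$ntree,
                    mtry = config$mtry, balanced = config$balanced,
                    perClassN = config$perClassN))
    ranking <- order(-giniImportance(full))
    for (si in seq_along(sizes)) {
      keep <- ranking[seq_len(sizes[si])]
      fit <- withSeed(mixSeed(seed, "fit", f, sizes[si]),
        fitBalancedRF(x[tr, keep, drop = FALSE], y[tr],
                      ntree = config$ntree, mtry = config$mtry,
                      balanced = config$balanced,
                      perClassN = config$perClassN))
      prob <- stats::predict(fit, x[te, keep, drop = FALSE],
                             type = "prob")[, "1"]
      foldAUC[f, si] <- aucRank(prob, y[te])
    }
  }
  meanAUC <- colMeans(foldAUC, na.rm = TRUE)
  chosenSize <- pickSize(meanAUC, config$pickRule,
                         config$toleranceFraction)
  final <- withSeed(mixSeed(seed, "final"),
    fitBalancedRF(x, y, ntree = config$ntree, mtry = config$mtry,
                  balanced = config$balanced, perClassN = config$perClassN))
  fullRanking <- colnames(x)[order(-giniImportance(final))]
  structure(list(sizes = sizes, meanAUC = meanAUC, foldAUC = foldAUC,
                 chosenSize = chosenSize,
                 chosenFeatures = fullRanking[seq_len(chosenSize)],
                 fullRanking = fullRanking),
            class = "selectionProfile")
}

#' @export
print.selectionProfile <- function(x, ...) {
  cat("RFE selection profile\n  mean AUC by size:\n")
  print(round(x$meanAUC, 4))
  cat(sprintf("  chosen size: %d\n  features: %s\n", x$chosenSize,
              paste(utils::head(x$chosenFeatures, 10L), collapse = ", ")))
  invisible(x)
}

#' Repeated selection with per-repetition re-imputation
#'
#' Runs [runRFE] `config$repetitions` times and aggregates the chosen
#' feature sets into a frequency table — the selection-stability analysis
#' of the study design. When `x` is a block-sparse [UnifiedTable-class] and
#' a `scheme` is given, the table is re-imputed every repetition via
#' [reimputeStream] (stochastic schemes thus add imputation variation;
#' the mean scheme yields the identical table each time), then centred and
#' scaled.
#'
#' @param x a complete numeric matrix, a dense [UnifiedTable-class], or a
#'   block-sparse [UnifiedTable-class] together with `scheme`.
#' @param y binary labels; taken from the UnifiedTable when omitted.
#' @param config an [rfeConfig].
#' @param seed root seed; folds, forests, and imputations draw from
#'   derived substreams.
#' @param scheme imputation scheme for per-repetition re-imputation, or
#'   `NULL` if `x` is already dense.
#' @param conditionOnClass passed to [reimputeStream].
#' @param scale centre/scale each repetition's matrix before selection.
#' @return a `selectionStability` list: `frequency` (data.frame feature /
#'   count, descending), `chosenSizes`, `aucs` (AUC at the chosen size per
#'   repetition), `profiles` (per-repetition [runRFE] results),
#'   `repetitions`.
#' @export
repeatSelection <- function(x, y = NULL, config = rfeConfig(), seed = 1L,
                            scheme = NULL, conditionOnClass = TRUE,
                            scale = TRUE) {
  stopifnot(inherits(config, "rfeConfig"))
  isUnified <- is(x, "UnifiedTable")
  if (isUnified && is.null(y)) y <- classLabels(x)
  if (isUnified && is.null(scheme) && !all(missingMask(x)))
    stop("block-sparse UnifiedTable needs an imputation scheme")
  profiles <- vector("list", config$repetitions)
  for (rep in seq_len(config$repetitions)) {
    xr <- if (isUnified && !is.null(scheme))
      featureMatrix(reimputeStream(x, scheme, seed = seed,
                                   repetition = rep,
                                   conditionOnClass = conditionOnClass))
    else if (isUnified) featureMatrix(x) else as.matrix(x)
    if (scale) xr <- centerScale(xr)$scaled
    profiles[[rep]] <- runRFE(xr, y, config, seed = mixSeed(seed, "rep", rep))
  }
  feats <- unlist(lapply(profiles, `[[`, "chosenFeatures"))
  counts <- sort(table(feats), decreasing = TRUE)
  frequency <- data.frame(feature = names(counts),
                          count = as.integer(counts), row.names = NULL)
  structure(list(
    frequency = frequency,
    chosenSizes = vapply(profiles, `[[`, 0L, "chosenSize"),
    aucs = vapply(profiles, function(pr)
      unname(pr$meanAUC[as.character(pr$chosenSize)]), 0),
    profiles = profiles, repetitions = config$repetitions),
    class = "selectionStability")
}

#' @export
print.selectionStability <- function(x, ...) {
  cat(sprintf("Selection stability over %d repetitions\n", x$repetitions))
  cat(sprintf("  chosen sizes: median %.0f  AUC: median %.3f\n",
              stats::median(x$chosenSizes), stats::median(x$aucs)))
  cat("  top features:\n")
  print(utils::head(x$frequency, 10L))
  invisible(x)
}

#' Importance-rank positions of one modality across re-imputations
#'
#' For each repetition, the unified table is re-imputed, one balanced
#' forest is fit on the full dense table, features are sorted by
#' decreasing Mean Decrease Gini, and the 1-based rank positions of all
#' features of the given modality are recorded. The pooled positions are
#' the raw material of the rank-density comparison between modalities.
#'
#' @param unified a block-sparse [UnifiedTable-class].
#' @param scheme imputation scheme per repetition.
#' @param modality modality tag whose features are tracked.
#' @param repetitions number of repetitions.
#' @param seed root seed.
#' @param ntree trees per forest.
#' @param scale centre/scale each imputed table.
#' @return list with `positions` (integer vector of length
#'   `repetitions * nFeatures(modality)`) and `perRepetition` (matrix,
#'   repetitions x modality features).
#' @export
importanceRankDensity <- function(unified, scheme, modality,
                                  repetitions = 50L, seed = 1L,
                                  ntree = 500L, scale = TRUE) {
  stopifnot(is(unified, "UnifiedTable"))
  fm <- featureModality(unified)
  tracked <- names(fm)[fm == modality]
  if (length(tracked) == 0L) stop("modality '", modality, "' absent")
  y <- classLabels(unified)
  perRep <- matrix(NA_integer_, repetitions, length(tracked),
                   dimnames = list(NULL, tracked))
  for (rep in seq_len(repetitions)) {
    x <- featureMatrix(reimputeStream(unified, scheme, seed = seed,
                                      repetition = rep))
    if (scale) x <- centerScale(x)$scaled
    forest <- withSeed(mixSeed(seed, "rankrf", rep),
      fitBalancedRF(x, y, ntree = ntree))
    ord <- colnames(x)[order(-giniImportance(forest))]
    perRep[rep, ] <- match(tracked, ord)
  }
  list(positions = as.integer(perRep), perRepetition = perRep)
}

#' @rdname replicateFeatures
#' @export
setMethod("replicateFeatures", "UnifiedTable",
  function(x, modality, times) {
    stopifnot(times >= 1L)
    fm <- featureModality(x)
    block <- names(fm)[fm == modality]
    if (length(block) == 0L) return(x)
    newNames <- unlist(lapply(seq_len(times), function(t)
      paste0(block, ".rep", t)))
    feat <- cbind(x@features,
                  x@features[, rep(block, times), drop = FALSE])
    colnames(feat) <- c(names(fm), newNames)
    mask <- cbind(x@mask, x@mask[, rep(block, times), drop = FALSE])
    colnames(mask) <- colnames(feat)
    new("UnifiedTable", features = feat, mask = mask,
        classLabels = x@classLabels,
        featureModality = stats::setNames(
          c(fm, rep(modality, length(newNames))), colnames(feat)),
        sampleModality = x@sampleModality)
  })

#' @rdname replicateFeatures
#' @export
setMethod("replicateFeatures", "FeatureTable",
  function(x, modality, times) {
    stopifnot(times >= 1L, identical(modality, modalityTag(x)))
    m <- x@features
    if (ncol(m) == 0L) return(x)
    newNames <- unlist(lapply(seq_len(times), function(t)
      paste0(colnames(m), ".rep", t)))
    feat <- cbind(m, m[, rep(seq_len(ncol(m)), times), drop = FALSE])
    colnames(feat) <- c(colnames(m), newNames)
    FeatureTable(feat, x@classLabels, x@modality)
  })
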