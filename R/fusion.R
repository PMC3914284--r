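#' Merge separate modality tables into one block-sparse unified table
#'
#' Rows are the union of the cohorts, columns the union of the feature sets.
#' Because the cohorts share no samples, every cell outside a sample's own
#' modality block is missing; the class column is the only complete one.
#' If feature names collide across modalities, all feature names are
#' prefixed with their modality tag.
#'
#' @param tables list of two or more [FeatureTable-class] objects with
#'   disjoint sample-ID sets.
#' @return a [UnifiedTable-class] with `sum(rows)` samples and
#'   `sum(features)` features.
#' @export
#' @examples
#' pair <- fixtureSmall()
#' u <- mergeSeparate(list(pair$imaging, pair$molecular))
#' dim(u)
mergeSeparate <- function(tables) {
  stopifnot(is.list(tables), length(tables) >= 2L)
  for (t in tables) stopifnot(is(t, "FeatureTable"))
  ids <- unlist(lapply(tables, sampleIDs))
  if (anyDuplicated(ids))
    stop("sample IDs overlap across tables; the method is defined for ",
         "separate cohorts: ", paste(unique(ids[duplicated(ids)]),
                                     collapse = ", "))
  mods <- vapply(tables, modalityTag, "")
  if (anyDuplicated(mods)) stop("modality tags must be unique across tables")
  fnames <- lapply(tables, featureNames)
  if (anyDuplicated(unlist(fnames)))
    fnames <- lapply(seq_along(tables),
                     function(i) paste(mods[i], fnames[[i]], sep = "."))
  nr <- vapply(tables, function(t) nrow(featureMatrix(t)), 0L)
  nc <- vapply(tables, function(t) ncol(featureMatrix(t)), 0L)
  Ur <- sum(nr); Uf <- sum(nc)
  feat <- matrix(NA_real_, Ur, Uf,
                 dimnames = list(ids, unlist(fnames)))
  mask <- matrix(FALSE, Ur, Uf, dimnames = dimnames(feat))
  rowOff <- cumsum(c(0L, nr)); colOff <- cumsum(c(0L, nc))
  for (i in seq_along(tables)) {
    ri <- rowOff[i] + seq_len(nr[i])
    ci <- colOff[i] + seq_len(nc[i])
    block <- featureMatrix(tables[[i]])
    if (nr[i] > 0L && nc[i] > 0L) {
      feat[ri, ci] <- block
      mask[ri, ci] <- !is.na(block)
    }
  }
  new("UnifiedTable", features = feat, mask = mask,
      classLabels = unlist(lapply(tables, classLabels), use.names = FALSE),
      featureModality = stats::setNames(rep(mods, nc), colnames(feat)),
      sampleModality = stats::setNames(rep(mods, nr), ids))
}

.schemes <- c("mean", "normal", "uniform", "bootstrap")

# Draw `n` imputed values for one (feature, class) group under a scheme,
# given the observed values of that group. Assumes the RNG state is set.
.drawImputed <- function(scheme, obs, n) {
  m <- mean(obs)
  switch(scheme,
    mean = rep(m, n),
    normal = {
      s <- if (length(obs) > 1L) stats::sd(obs) else 0
      stats::rnorm(n, m, s)
    },
    uniform = stats::runif(n, min(obs), max(obs)),
    bootstrap = obs[sample.int(length(obs), n, replace = TRUE)])
}

#' Impute the missing block of a unified table
#'
#' Fills every missing cell from a distribution estimated on the observed
#' values of the *same feature* restricted to samples of the *same class*
#' (class-conditional imputation). Four schemes: `"mean"` (the observed
#' class mean, deterministic), `"normal"` (a draw from Normal(m, sd) with
#' m, sd the class-conditional mean and sample sd), `"uniform"` (a uniform
#' draw over the class-conditional observed range), `"bootstrap"` (a draw
#' with replacement from the class-conditional observed values). Draws are
#' not truncated to the observed range except trivially for bootstrap.
#'
#' Because the imputation is conditioned on the class it deliberately
#' biases the completed table toward class separability; downstream
#' accuracies on imputed data must be read with that in mind. A class-blind
#' control (`conditionOnClass = FALSE`) pools both classes and serves to
#' quantify the bias.
#'
#' The RNG substream of each (repetition, feature, class) group is derived
#' from `(seed, stream)` with [mixSeed], so imputed values are independent
#' of iteration order and of the other class's observed values, and
#' identical `(seed, stream)` pairs reproduce bitwise-identical tables.
#'
#' @param unified a [UnifiedTable-class].
#' @param scheme one of `"mean"`, `"normal"`, `"uniform"`, `"bootstrap"`.
#' @param seed integer root seed.
#' @param stream integer substream id; use the repetition number when
#'   re-imputing across repetitions (see [reimputeStream]).
#' @param conditionOnClass if `FALSE`, the per-feature distribution pools
#'   both classes (bias control).
#' @return a dense [UnifiedTable-class] (mask all observed). Observed cells
#'   are never modified.
#' @export
imputeUnified <- function(unified, scheme = .schemes, seed = 1L,
                          stream = 0L, conditionOnClass = TRUE) {
  stopifnot(is(unified, "UnifiedTable"))
  scheme <- match.arg(scheme)
  x <- unified@features
  mask <- unified@mask
  y <- unified@classLabels
  groups <- if (conditionOnClass) list(`0` = y == 0L, `1` = y == 1L)
            else list(`2` = rep(TRUE, length(y)))
  singletonNormal <- 0L
  withSeed(seed, for (j in seq_len(ncol(x))) {
    if (all(mask[, j])) next
    for (g in names(groups)) {
      rows <- groups[[g]]
      missIdx <- which(rows & !mask[, j])
      if (length(missIdx) == 0L) next
      obs <- x[rows & mask[, j], j]
      if (length(obs) == 0L)
        stop(sprintf(
          "feature '%s', class %s: no observed values to impute from",
          colnames(x)[j], g))
      if (scheme == "normal" && length(obs) == 1L)
        singletonNormal <- singletonNormal + 1L
      set.seed(mixSeed(seed, stream, j, as.integer(g)))
      x[missIdx, j] <- .drawImputed(scheme, obs, length(missIdx))
    }
  })
  if (singletonNormal > 0L)
    warning(singletonNormal, " (feature, class) group(s) had a single ",
            "observed value; normal-scheme sd taken as 0")
  new("UnifiedTable", features = x,
      mask = matrix(TRUE, nrow(x), ncol(x), dimnames = dimnames(x)),
      classLabels = y, featureModality = unified@featureModality,
      sampleModality = unified@sampleModality)
}

#' Re-impute a unified table for one repetition of a resampling run
#'
#' Deterministic function of `(seed, repetition)`: stochastic schemes
#' (normal/uniform/bootstrap) give a fresh imputed table per repetition,
#' while the mean scheme returns the identical table every time.
#'
#' @inheritParams imputeUnified
#' @param repetition 1-based repetition number.
#' @return a dense [UnifiedTable-class].
#' @export
reimputeStream <- function(unified, scheme = .schemes, seed = 1L,
                           repetition = 1L, conditionOnClass = TRUE) {
  scheme <- match.arg(scheme)
  stream <- if (scheme == "mean") 0L else as.integer(repetition)
  imputeUnified(unified, scheme, seed = seed, stream = stream,
                conditionOnClass = conditionOnClass)
}
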