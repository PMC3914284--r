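#' Configuration for the synthetic two-cohort generator
#'
#' Defaults emulate the melanoma study conditions: an imaging cohort of 972
#' controls vs 69 cases with 31 descriptors, and a molecular cohort of 18
#' controls vs 45 cases with 1701 genes — disjoint sample sets sharing only
#' the binary class. A small number of informative features per modality
#' carry a class mean shift of `effectSize` standard deviations; the
#' non-informative molecular features are organised in equicorrelated
#' blocks (pairwise correlation `blockCorr` within a block) to emulate gene
#' covariance and exercise the colinearity filter; the molecular block has
#' its own location and scale to emulate heterogeneous scales between
#' modalities.
#'
#' @param imagingControls,imagingCases,imagingFeatures,imagingInformative
#'   imaging-cohort sample and feature counts.
#' @param molecularControls,molecularCases,molecularFeatures,molecularInformative
#'   molecular-cohort sample and feature counts.
#' @param effectSize class mean shift on informative features, in units of
#'   the feature noise sd.
#' @param blockCorr within-block pairwise correlation of non-informative
#'   molecular features, in [0, 1).
#' @param blockSize features per equicorrelated molecular block.
#' @param noiseSd baseline feature noise standard deviation.
#' @param molecularScale,molecularOffset scale and location applied to the
#'   molecular block (scale heterogeneity between modalities).
#' @return a classed configuration list.
#' @export
synthConfig <- function(imagingControls = 972L, imagingCases = 69L,
                        imagingFeatures = 31L, imagingInformative = 3L,
                        molecularControls = 18L, molecularCases = 45L,
                        molecularFeatures = 1701L,
                        molecularInformative = 3L,
                        effectSize = 3, blockCorr = 0.9, blockSize = 5L,
                        noiseSd = 1, molecularScale = 2,
                        molecularOffset = 5) {
  cfg <- list(imagingControls = as.integer(imagingControls),
              imagingCases = as.integer(imagingCases),
              imagingFeatures = as.integer(imagingFeatures),
              imagingInformative = as.integer(imagingInformative),
              molecularControls = as.integer(molecularControls),
              molecularCases = as.integer(molecularCases),
              molecularFeatures = as.integer(molecularFeatures),
              molecularInformative = as.integer(molecularInformative),
              effectSize = effectSize, blockCorr = blockCorr,
              blockSize = as.integer(blockSize), noiseSd = noiseSd,
              molecularScale = molecularScale,
              molecularOffset = molecularOffset)
  stopifnot(cfg$imagingInformative <= cfg$imagingFeatures,
            cfg$molecularInformative <= cfg$molecularFeatures,
            cfg$blockCorr >= 0, cfg$blockCorr < 1, cfg$effectSize >= 0,
            cfg$noiseSd > 0, cfg$blockSize >= 1L)
  structure(cfg, class = "synthConfig")
}

# One modality: n x p Gaussian matrix, informative features shifted by
# effectSize * noiseSd in cases; optional equicorrelated blocks among the
# non-informative features via a shared-factor construction.
.synthModality <- function(nControl, nCase, p, nInf, effectSize, noiseSd,
                           blockCorr, blockSize, scaleF, offset, prefix,
                           idPrefix) {
  n <- nControl + nCase
  y <- c(rep(0L, nControl), rep(1L, nCase))
  x <- matrix(stats::rnorm(n * p, 0, noiseSd), n, p)
  if (blockCorr > 0 && p > nInf) {
    rest <- (nInf + 1L):p
    nBlocks <- length(rest) %/% blockSize
    for (b in seq_len(nBlocks)) {
      cols <- rest[(b - 1L) * blockSize + seq_len(blockSize)]
      shared <- stats::rnorm(n, 0, noiseSd)
      x[, cols] <- sqrt(blockCorr) * shared +
        sqrt(1 - blockCorr) * x[, cols]
    }
  }
  if (nInf > 0L)
    x[y == 1L, seq_len(nInf)] <- x[y == 1L, seq_len(nInf)] +
      effectSize * noiseSd
  x <- x * scaleF + offset
  dimnames(x) <- list(
    sprintf("%sS%04d", idPrefix, seq_len(n)),
    sprintf("%s%04d", prefix, seq_len(p)))
  informative <- if (nInf > 0L) colnames(x)[seq_len(nInf)] else character()
  list(table = FeatureTable(x, y, prefix), informative = informative)
}

#' Generate a pair of separate-modality cohorts with known ground truth
#'
#' Produces two [FeatureTable-class] objects with disjoint sample IDs, a
#' shared binary class, planted class-separating features, blockwise
#' molecular covariance and modality-specific location/scale — the
#' statistical skeleton of the melanoma two-cohort design, with the truth
#' recorded so recovery can be scored.
#'
#' @param config a [synthConfig].
#' @param seed integer seed; generation is a deterministic function of
#'   `(config, seed)`.
#' @return list with `imaging` and `molecular` ([FeatureTable-class]) and
#'   `truth` (list of informative feature names per modality).
#' @export
generateModalityPair <- function(config = synthConfig(), seed = 1L) {
  stopifnot(inherits(config, "synthConfig"))
  withSeed(seed, {
    img <- .synthModality(config$imagingControls, config$imagingCases,
                          config$imagingFeatures,
                          config$imagingInformative, config$effectSize,
                          config$noiseSd, 0, config$blockSize, 1, 0,
                          "img", "img")
    mol <- .synthModality(config$molecularControls, config$molecularCases,
                          config$molecularFeatures,
                          config$molecularInformative, config$effectSize,
                          config$noiseSd, config$blockCorr,
                          config$blockSize, config$molecularScale,
                          config$molecularOffset, "gene", "mol")
    list(imaging = img$table, molecular = mol$table,
         truth = list(imaging = img$informative,
                      molecular = mol$informative))
  })
}

#' Miniature deterministic fixture pair
#'
#' A small two-cohort pair (imaging 24 controls + 6 cases x 6 features,
#' molecular 8 controls + 4 cases x 40 features, 2 and 3 informative
#' features, effect size 3) generated with a fixed seed. Copies of the
#' fixture are shipped as plain CSV under `inst/extdata/`
#' (`synthetic_imaging_small.csv`, `synthetic_molecular_small.csv`);
#' regeneration is bitwise identical to the shipped files.
#'
#' @return as [generateModalityPair].
#' @export
fixtureSmall <- function() {
  generateModalityPair(
    synthConfig(imagingControls = 24L, imagingCases = 6L,
                imagingFeatures = 6L, imagingInformative = 2L,
                molecularControls = 8L, molecularCases = 4L,
                molecularFeatures = 40L, molecularInformative = 3L,
                effectSize = 3, blockCorr = 0.9, blockSize = 5L),
    seed = 42L)
}
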