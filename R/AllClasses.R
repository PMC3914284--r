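#' @import methods
NULL

#' FeatureTable: one modality of a separate-cohort study
#'
#' A samples-by-features numeric matrix from a single technological source
#' (e.g. dermoscopy image features, or microarray log ratios), together with
#' a binary class label per sample (0 = control/nevus, 1 = disease/melanoma)
#' and a modality tag. Sample IDs are the matrix rownames, feature names the
#' colnames; both must be unique. Missing values are allowed in the matrix.
#'
#' @slot features numeric matrix, samples in rows, features in columns.
#' @slot classLabels integer vector in {0, 1}, one per sample.
#' @slot modality single character tag naming the source modality.
#' @aliases FeatureTable-class
#' @exportClass FeatureTable
setClass("FeatureTable",
  representation(features = "matrix", classLabels = "integer",
                 modality = "character"))

setValidity("FeatureTable", function(object) {
  msg <- character()
  x <- object@features
  if (!is.numeric(x)) msg <- c(msg, "feature matrix must be numeric")
  if (nrow(x) > 0 && (is.null(rownames(x)) || anyDuplicated(rownames(x))))
    msg <- c(msg, "sample IDs (rownames) must be present and unique")
  if (ncol(x) > 0 && (is.null(colnames(x)) || anyDuplicated(colnames(x))))
    msg <- c(msg, "feature names (colnames) must be present and unique")
  if (length(object@classLabels) != nrow(x))
    msg <- c(msg, "classLabels length must equal the number of samples")
  if (!all(object@classLabels %in% c(0L, 1L)))
    msg <- c(msg, "classLabels must be coded 0 (control) / 1 (disease)")
  if (length(object@modality) != 1L || !nzchar(object@modality))
    msg <- c(msg, "modality must be a single non-empty string")
  if (length(msg)) msg else TRUE
})

#' Construct a FeatureTable
#'
#' @param features numeric matrix (samples x features); rownames are taken as
#'   sample IDs if `sampleIDs` is not given, colnames as feature names.
#' @param classLabels vector coercible to integer 0/1, one entry per sample.
#' @param modality single character tag for the source modality.
#' @param sampleIDs,featureNames optional overrides for the dimnames.
#' @return a validated [FeatureTable-class] object.
#' @export
#' @examples
#' m <- matrix(rnorm(8), 4, 2, dimnames = list(paste0("s", 1:4), c("a", "b")))
#' FeatureTable(m, c(0, 0, 1, 1), "demo")
FeatureTable <- function(features, classLabels, modality,
                         sampleIDs = NULL, featureNames = NULL) {
  features <- as.matrix(features)
  storage.mode(features) <- "double"
  if (!is.null(sampleIDs)) rownames(features) <- sampleIDs
  if (!is.null(featureNames)) colnames(features) <- featureNames
  new("FeatureTable", features = features,
      classLabels = as.integer(classLabels), modality = as.character(modality))
}

#' UnifiedTable: block-sparse merge of separate modalities
#'
#' The row-wise and column-wise concatenation of two or more FeatureTables
#' from disjoint sample cohorts. Before imputation, each sample has observed
#' values only in the feature block of its own modality (block-sparse
#' structure); the class column is the only complete column. After
#' imputation the mask is all-observed.
#'
#' @slot features numeric matrix ((sum of rows) x (sum of features)), NA
#'   where unobserved.
#' @slot mask logical matrix, TRUE where the cell is observed.
#' @slot classLabels integer 0/1 per sample (always complete).
#' @slot featureModality named character, source modality per feature.
#' @slot sampleModality named character, source modality per sample.
#' @aliases UnifiedTable-class
#' @exportClass UnifiedTable
setClass("UnifiedTable",
  representation(features = "matrix", mask = "matrix",
                 classLabels = "integer", featureModality = "character",
                 sampleModality = "character"))

setValidity("UnifiedTable", function(object) {
  msg <- character()
  x <- object@features
  if (!identical(dim(x), dim(object@mask)))
    msg <- c(msg, "mask and feature matrix dimensions differ")
  if (!is.logical(object@mask)) msg <- c(msg, "mask must be logical")
  if (any(is.na(x) & object@mask))
    msg <- c(msg, "cells flagged observed must not be NA")
  if (length(object@classLabels) != nrow(x) ||
      !all(object@classLabels %in% c(0L, 1L)))
    msg <- c(msg, "classLabels must be complete and coded 0/1")
  if (length(object@featureModality) != ncol(x))
    msg <- c(msg, "featureModality must map every feature")
  if (length(object@sampleModality) != nrow(x))
    msg <- c(msg, "sampleModality must map every sample")
  if (nrow(x) > 0 && (is.null(rownames(x)) || anyDuplicated(rownames(x))))
    msg <- c(msg, "sample IDs must be present and unique")
  if (ncol(x) > 0 && (is.null(colnames(x)) || anyDuplicated(colnames(x))))
    msg <- c(msg, "feature names must be present and unique")
  if (length(msg)) msg else TRUE
})
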