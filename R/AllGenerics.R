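# Accessor generics for the two containers. Slot access from user code is
# discouraged; these are the stable surface.

#' @rdname accessors
#' @param x a [FeatureTable-class] or [UnifiedTable-class] object.
#' @export
setGeneric("featureMatrix", function(x) standardGeneric("featureMatrix"))

#' @rdname accessors
#' @export
setGeneric("classLabels", function(x) standardGeneric("classLabels"))

#' @rdname accessors
#' @export
setGeneric("sampleIDs", function(x) standardGeneric("sampleIDs"))

#' @rdname accessors
#' @export
setGeneric("featureNames", function(x) standardGeneric("featureNames"))

#' @rdname accessors
#' @export
setGeneric("modalityTag", function(x) standardGeneric("modalityTag"))

#' @rdname accessors
#' @export
setGeneric("missingMask", function(x) standardGeneric("missingMask"))

#' @rdname accessors
#' @export
setGeneric("featureModality", function(x) standardGeneric("featureModality"))

#' @rdname accessors
#' @export
setGeneric("sampleModality", function(x) standardGeneric("sampleModality"))

#' Replicate the feature block of one modality
#'
#' Appends `times` identical copies of every feature column belonging to the
#' given modality, suffixing the copies to keep names unique. Used to probe
#' whether feature-count imbalance between modalities drives importance
#' rankings: if a small block is outranked only because it is small,
#' replicating it should close the gap.
#'
#' @param x a [FeatureTable-class] or [UnifiedTable-class] object.
#' @param modality modality tag whose block is replicated.
#' @param times number of extra copies (>= 1).
#' @return an object of the same class with `times * blockSize` extra
#'   features named `<name>.rep<t>`.
#' @export
setGeneric("replicateFeatures",
           function(x, modality, times) standardGeneric("replicateFeatures"))

#' Accessors for FeatureTable and UnifiedTable
#'
#' `featureMatrix` returns the numeric samples-by-features matrix;
#' `classLabels` the integer 0/1 class vector; `sampleIDs`/`featureNames`
#' the dimension names; `modalityTag` the tag of a single-modality table;
#' `missingMask` the logical observed-cell mask of a unified table;
#' `featureModality`/`sampleModality` the per-feature / per-sample source
#' modality maps.
#'
#' @name accessors
#' @rdname accessors
NULL

#' @rdname accessors
#' @export
setMethod("featureMatrix", "FeatureTable", function(x) x@features)

#' @rdname accessors
#' @export
setMethod("featureMatrix", "UnifiedTable", function(x) x@features)

#' @rdname accessors
#' @export
setMethod("classLabels", "FeatureTable", function(x) x@classLabels)

#' @rdname accessors
#' @export
setMethod("classLabels", "UnifiedTable", function(x) x@classLabels)

#' @rdname accessors
#' @export
setMethod("sampleIDs", "FeatureTable", function(x) rownames(x@features))

#' @rdname accessors
#' @export
setMethod("sampleIDs", "UnifiedTable", function(x) rownames(x@features))

#' @rdname accessors
#' @export
setMethod("featureNames", "FeatureTable", function(x) colnames(x@features))

#' @rdname accessors
#' @export
setMethod("featureNames", "UnifiedTable", function(x) colnames(x@features))

#' @rdname accessors
#' @export
setMethod("modalityTag", "FeatureTable", function(x) x@modality)

#' @rdname accessors
#' @export
setMethod("missingMask", "UnifiedTable", function(x) x@mask)

#' @rdname accessors
#' @export
setMethod("featureModality", "UnifiedTable", function(x) x@featureModality)

#' @rdname accessors
#' @export
setMethod("sampleModality", "UnifiedTable", function(x) x@sampleModality)

setMethod("dim", "FeatureTable", function(x) dim(x@features))
setMethod("dim", "UnifiedTable", function(x) dim(x@features))

setMethod("show", "FeatureTable", function(object) {
  n <- table(factor(object@classLabels, levels = c(0L, 1L)))
  cat(sprintf(
    "FeatureTable '%s': %d samples x %d features (%d control / %d disease)\n",
    object@modality, nrow(object@features), ncol(object@features),
    n[["0"]], n[["1"]]))
  if (anyNA(object@features))
    cat(sprintf("  %d missing cells\n", sum(is.na(object@features))))
})

setMethod("show", "UnifiedTable", function(object) {
  n <- table(factor(object@classLabels, levels = c(0L, 1L)))
  mods <- table(object@featureModality)
  cat(sprintf(
    "UnifiedTable: %d samples x %d features (%d control / %d disease)\n",
    nrow(object@features), ncol(object@features), n[["0"]], n[["1"]]))
  cat("  features per modality:",
      paste(sprintf("%s=%d", names(mods), mods), collapse = ", "), "\n")
  cat(sprintf("  observed cells: %.1f%%\n", 100 * mean(object@mask)))
})
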