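#' Read a modality feature table from delimited text
#'
#' Expects a header row; the first column holds sample IDs, one named column
#' holds the binary class, and every other column is a numeric feature.
#' Non-numeric feature cells are turned into missing values with a warning.
#' The missing sentinel on disk is the literal string `NA`; empty cells are
#' also accepted.
#'
#' @param path path to a delimited text file.
#' @param classColumn name of the class column. Its values must be codable
#'   to 0/1 (accepted: 0/1 numerics, or exactly two level strings, in which
#'   case `positiveClass` names the level coded 1).
#' @param modality modality tag to attach.
#' @param sep field delimiter (default comma).
#' @param positiveClass optional string naming the class level coded as 1.
#' @return a [FeatureTable-class].
#' @export
readFeatureTable <- function(path, classColumn = "class", modality,
                             sep = ",", positiveClass = NULL) {
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          colClasses = "character", check.names = FALSE,
                          na.strings = c("NA", ""), quote = "\"",
                          comment.char = "")
  if (ncol(df) < 2L) stop("file must have a sample-ID column plus data")
  ids <- df[[1L]]
  if (anyDuplicated(ids))
    stop("duplicate sample IDs in ", path, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  if (!classColumn %in% names(df)[-1L])
    stop("class column '", classColumn, "' not found in ", path)
  cls <- df[[classColumn]]
  if (anyNA(cls)) stop("class column contains missing values")
  ucls <- sort(unique(cls))
  if (all(ucls %in% c("0", "1"))) {
    y <- as.integer(cls)
  } else if (length(ucls) == 2L) {
    pos <- if (is.null(positiveClass)) ucls[2L] else positiveClass
    if (!pos %in% ucls) stop("positiveClass '", pos, "' not a class level")
    y <- as.integer(cls == pos)
  } else {
    stop("class column must be binary (found levels: ",
         paste(ucls, collapse = ", "), ")")
  }
  keep <- setdiff(names(df)[-1L], classColumn)
  feat <- as.matrix(df[keep])
  suppressWarnings(num <- matrix(as.numeric(feat), nrow(feat), ncol(feat),
                                 dimnames = list(ids, keep)))
  bad <- sum(!is.na(feat) & is.na(num))
  if (bad > 0L)
    warning(bad, " non-numeric feature cell(s) in ", path,
            " treated as missing")
  FeatureTable(num, y, modality)
}

#' Write a FeatureTable to delimited text
#'
#' Values are written with 17 significant digits so that
#' `readFeatureTable(writeFeatureTable(t))` round-trips to full double
#' precision. Missing cells are written as the literal `NA`.
#'
#' @param table a [FeatureTable-class].
#' @param path output path.
#' @param sep field delimiter (default comma).
#' @param classColumn name to give the class column on disk.
#' @return `path`, invisibly.
#' @export
writeFeatureTable <- function(table, path, sep = ",",
                              classColumn = "class") {
  stopifnot(is(table, "FeatureTable"))
  x <- featureMatrix(table)
  chr <- matrix("NA", nrow(x), ncol(x))
  ok <- !is.na(x)
  chr[ok] <- sprintf("%.17g", x[ok])
  out <- cbind(sample = sampleIDs(table), chr,
               matrix(as.character(classLabels(table)), ncol = 1))
  header <- c("sample", featureNames(table), classColumn)
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(paste(header, collapse = sep), con)
  writeLines(apply(out, 1L, paste, collapse = sep), con)
  invisible(path)
}

#' Read a fusion analysis configuration file
#'
#' A YAML file naming each modality table (path, class column, modality tag,
#' delimiter) plus a root seed, e.g.:
#' \preformatted{
#' seed: 11
#' tables:
#'   - path: imaging.csv
#'     class_column: class
#'     modality: imaging
#' }
#'
#' @param path path to the YAML file.
#' @return a list with elements `seed` and `tables`.
#' @export
readFusionConfig <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$tables) || length(cfg$tables) < 1L)
    stop("config must list at least one table")
  for (tab in cfg$tables)
    if (is.null(tab$path) || is.null(tab$modality))
      stop("each table entry needs 'path' and 'modality'")
  cfg$seed <- if (is.null(cfg$seed)) 1L else as.integer(cfg$seed)
  cfg
}
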