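## Real-data case study entry point: an externally supplied feature table
## with expert class labels (e.g. the UCI cardiotocography data, 2126
## records with 3- and 10-class label sets) is min-max scaled and run
## through the single- vs dual-measure benchmark against its labels.

#' Benchmark the framework on an externally supplied labelled dataset
#'
#' Reads a delimited feature table, extracts the known class column,
#' min-max scales every feature to [0, 1] and runs
#' [benchmarkSelection()] at k equal to the number of classes, scoring
#' each repetition's selected partition against the class labels. The
#' dataset is not shipped with the package; the caller supplies the file.
#'
#' @param path CSV/TSV file with continuous features and one class column.
#' @param labelColumn name or index of the class column.
#' @param config a [SeCoConfig-class]; its single \code{kRange} entry must
#'   equal the number of classes (defaults to a 500-run, top-decile
#'   configuration at the class count).
#' @param nReps benchmark repetitions (default 100).
#' @return Named list of two [BenchmarkResult-class] objects
#'   (\code{single}, \code{dual}).
#' @export
labelledCaseStudy <- function(path, labelColumn, config = NULL,
                              nReps = 100L) {
  if (!file.exists(path))
    stop(sprintf(
      "case-study dataset not found: %s (supply the file externally)",
      path), call. = FALSE)
  read <- readDataMatrix(path, labelColumn = labelColumn)
  if (is.null(read$labels))
    stop("a class label column is required", call. = FALSE)
  ref <- .as_label_vector(read$labels, "class labels")
  k <- max(ref)
  if (is.null(config))
    config <- secoConfig(kRange = k, nTotal = 500L, fractionF = 0.10,
                         masterSeed = 0L)
  x <- minMaxScale(read$data)
  benchmarkSelection(x, ref, k, config, nReps = nReps, method = "both")
}
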