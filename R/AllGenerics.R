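#' @name accessors
#' @title Accessors for SeCoClust objects
#'
#' @description Slot accessors: \code{clusterLabels} returns the cluster id
#' vector, \code{prototypes} the cluster-mean matrix, \code{wss} the
#' within-cluster sum of squares, \code{deltaSSQ} the separation score,
#' \code{runSeed} the RNG seed of a run, \code{nClusters} the cluster count,
#' \code{secoPoints} the (deltaSSQ, medCV) coordinate table of a map and
#' \code{treeEdges} the flow edge list of a partition tree.
#'
#' @param object a SeCoClust S4 object.
#' @return The slot value; see the class documentation for units.
#' @aliases clusterLabels prototypes wss deltaSSQ runSeed nClusters
#'   secoPoints treeEdges
#' @examples
#' x <- matrix(c(0, 0.1, 10, 10.1), ncol = 1)
#' fit <- fitKmeans(x, k = 2, seed = 1)
#' clusterLabels(fit)
#' wss(fit) + deltaSSQ(fit) # equals the total SSQ of x
NULL

#' @rdname accessors
#' @export
setGeneric("clusterLabels", function(object) standardGeneric("clusterLabels"))

#' @rdname accessors
#' @export
setGeneric("prototypes", function(object) standardGeneric("prototypes"))

#' @rdname accessors
#' @export
setGeneric("wss", function(object) standardGeneric("wss"))

#' @rdname accessors
#' @export
setGeneric("deltaSSQ", function(object) standardGeneric("deltaSSQ"))

#' @rdname accessors
#' @export
setGeneric("runSeed", function(object) standardGeneric("runSeed"))

#' @rdname accessors
#' @export
setGeneric("nClusters", function(object) standardGeneric("nClusters"))

#' @rdname accessors
#' @export
setGeneric("secoPoints", function(object) standardGeneric("secoPoints"))

#' @rdname accessors
#' @export
setGeneric("treeEdges", function(object) standardGeneric("treeEdges"))

#' @rdname accessors
#' @export
setMethod("clusterLabels", "ClusterSolution", function(object) object@labels)

#' @rdname accessors
#' @export
setMethod("clusterLabels", "ReferencePartition",
          function(object) object@labels)

#' @rdname accessors
#' @export
setMethod("prototypes", "ClusterSolution", function(object) object@prototypes)

#' @rdname accessors
#' @export
setMethod("prototypes", "ReferencePartition",
          function(object) object@prototypes)

#' @rdname accessors
#' @export
setMethod("wss", "ClusterSolution", function(object) object@wss)

#' @rdname accessors
#' @export
setMethod("wss", "ReferencePartition", function(object) object@wss)

#' @rdname accessors
#' @export
setMethod("deltaSSQ", "ClusterSolution", function(object) object@deltaSSQ)

#' @rdname accessors
#' @export
setMethod("runSeed", "ClusterSolution", function(object) object@seed)

#' @rdname accessors
#' @export
setMethod("nClusters", "ClusterSolution", function(object) object@k)

#' @rdname accessors
#' @export
setMethod("nClusters", "ReferencePartition", function(object) object@k)

#' @rdname accessors
#' @export
setMethod("secoPoints", "SeCoMap", function(object) object@points)

#' @rdname accessors
#' @export
setMethod("treeEdges", "PartitionTree", function(object) object@edges)

setMethod("show", "ClusterSolution", function(object) {
  cat(sprintf(
    "ClusterSolution: k = %d, n = %d\n  wss = %.6g, deltaSSQ = %.6g\n",
    object@k, length(object@labels), object@wss, object@deltaSSQ))
  cat(sprintf("  iterations: %d batch, %d online passes; seed = %s\n",
              object@nIter[1], object@nIter[2],
              ifelse(is.na(object@seed), "none", object@seed)))
})

setMethod("show", "ContingencyTable", function(object) {
  cat(sprintf("ContingencyTable: %d x %d, N = %d\n",
              nrow(object@counts), ncol(object@counts), object@nTotal))
  print(object@counts)
})

setMethod("show", "SeCoConfig", function(object) {
  cat(sprintf(
    "SeCoConfig: nTotal = %d, fractionF = %.3g, k in {%s}, masterSeed = %d\n",
    object@nTotal, object@fractionF,
    paste(object@kRange, collapse = ", "), object@masterSeed))
})

setMethod("show", "SeCoMap", function(object) {
  cat(sprintf("SeCoMap: %d retained solutions over k in {%s}\n",
              nrow(object@points),
              paste(sort(unique(object@points$k)), collapse = ", ")))
  med <- stats::aggregate(medCV ~ k, object@points, stats::median)
  cat("  median med(CV) by k:\n")
  for (i in seq_len(nrow(med)))
    cat(sprintf("    k = %2d: %.4f\n", med$k[i], med$medCV[i]))
})

setMethod("show", "MixtureSpec", function(object) {
  cat(sprintf("MixtureSpec: %d components in %d dimensions\n",
              nrow(object@means), ncol(object@means)))
  cat("  weights:", paste(signif(object@weights, 3), collapse = " "), "\n")
})

setMethod("show", "ReferencePartition", function(object) {
  cat(sprintf(
    "ReferencePartition: k = %d over %d observations, wss = %.6g\n",
    object@k, length(object@labels), object@wss))
})

setMethod("show", "PartitionTree", function(object) {
  cat(sprintf(
    "PartitionTree: k = %s; %d flow edges (%d visible at %.0f%%)\n",
    paste(range(object@kValues), collapse = " .. "),
    nrow(object@edges), sum(object@edges$visible),
    100 * object@minFraction))
})

setMethod("show", "BenchmarkResult", function(object) {
  cat(sprintf(
    "BenchmarkResult (%s measure): k = %d, %d repetitions\n",
    object@method, object@k, object@nReps))
  cat(sprintf("  accuracy %.4f (sd %.4f), mean CV %.4f, affinity %.4f\n",
              mean(object@accuracy), stats::sd(object@accuracy),
              mean(object@cv), object@affinity))
})
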