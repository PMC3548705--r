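#' @useDynLib SeCoClust, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @import methods
NULL

#' One converged k-means run
#'
#' Holds the labels, prototypes and sum-of-squares decomposition of a single
#' k-means fit: \code{wss} is the within-cluster sum of squares (the k-means
#' objective), \code{totalSSQ} the sum of squared distances of all points to
#' the global mean, and \code{deltaSSQ = totalSSQ - wss} the separation score
#' the SeCo framework ranks on.
#'
#' @slot k cluster count.
#' @slot labels integer vector of cluster ids in \code{1..k}, one per row of
#'   the data the solution was fitted to.
#' @slot prototypes \code{k x d} matrix of cluster means.
#' @slot wss within-cluster sum of squares (squared feature units).
#' @slot deltaSSQ total SSQ minus \code{wss}; larger means better separated.
#' @slot totalSSQ total sum of squares about the global data mean.
#' @slot nIter integer vector \code{c(batch, online)}: Lloyd iterations used
#'   and on-line refinement passes used.
#' @slot seed RNG seed the run was initialised from (\code{NA} when
#'   prototypes were supplied explicitly).
#' @slot runId position of the run within its ensemble (\code{NA} for
#'   standalone fits).
#'
#' @seealso [fitKmeans()], [runEnsemble()]
#' @export
setClass("ClusterSolution",
  slots = c(
    k = "integer",
    labels = "integer",
    prototypes = "matrix",
    wss = "numeric",
    deltaSSQ = "numeric",
    totalSSQ = "numeric",
    nIter = "integer",
    seed = "integer",
    runId = "integer"
  )
)

setValidity("ClusterSolution", function(object) {
  msg <- character()
  k <- object@k
  if (length(k) != 1L || k < 1L) msg <- c(msg, "k must be a positive integer")
  if (nrow(object@prototypes) != k)
    msg <- c(msg, "prototypes must have k rows")
  if (length(object@labels) &&
      !setequal(unique(object@labels), seq_len(k)))
    msg <- c(msg, "every cluster id in 1..k must appear at least once")
  if (object@wss < 0) msg <- c(msg, "wss must be nonnegative")
  if (object@deltaSSQ < -1e-8 * max(1, object@totalSSQ))
    msg <- c(msg, "deltaSSQ must be nonnegative")
  tol <- 1e-6 * max(1, object@totalSSQ)
  if (abs(object@wss + object@deltaSSQ - object@totalSSQ) > tol)
    msg <- c(msg, "wss + deltaSSQ must equal totalSSQ")
  if (length(msg)) msg else TRUE
})

#' Cross-tabulation of two partitions
#'
#' A \code{P x Q} contingency table of two cluster label vectors over the
#' same observations, the object the chi-square and Cramér's V statistics
#' are computed from.
#'
#' @slot counts \code{P x Q} nonnegative integer matrix of joint counts.
#' @slot rowTotals,colTotals marginal totals.
#' @slot nTotal number of observations.
#' @slot rowLevels,colLevels the sorted distinct labels indexing rows and
#'   columns.
#'
#' @seealso [contingencyTable()], [chiSquare()], [cramersV()]
#' @export
setClass("ContingencyTable",
  slots = c(
    counts = "matrix",
    rowTotals = "numeric",
    colTotals = "numeric",
    nTotal = "numeric",
    rowLevels = "integer",
    colLevels = "integer"
  )
)

setValidity("ContingencyTable", function(object) {
  msg <- character()
  if (any(object@counts < 0)) msg <- c(msg, "counts must be nonnegative")
  if (abs(sum(object@counts) - object@nTotal) > 0)
    msg <- c(msg, "counts must sum to nTotal")
  if (!isTRUE(all.equal(rowSums(object@counts), object@rowTotals,
                        check.attributes = FALSE)))
    msg <- c(msg, "rowTotals inconsistent with counts")
  if (!isTRUE(all.equal(colSums(object@counts), object@colTotals,
                        check.attributes = FALSE)))
    msg <- c(msg, "colTotals inconsistent with counts")
  if (length(msg)) msg else TRUE
})

#' Configuration of a SeCo ensemble analysis
#'
#' @slot nTotal ensemble size: number of random k-means initialisations per
#'   cluster number (default 500).
#' @slot fractionF top fraction of the ensemble, ranked by separation
#'   (deltaSSQ), retained for concordance scoring (default 0.10, the top
#'   decile).
#' @slot kRange inclusive set of cluster numbers to map.
#' @slot masterSeed integer master seed; run r of an ensemble uses seed
#'   \code{masterSeed + r}.
#'
#' @seealso [secoConfig()], [buildSeCoMap()]
#' @export
setClass("SeCoConfig",
  slots = c(
    nTotal = "integer",
    fractionF = "numeric",
    kRange = "integer",
    masterSeed = "integer"
  )
)

setValidity("SeCoConfig", function(object) {
  msg <- character()
  if (object@nTotal < 2L) msg <- c(msg, "nTotal must be at least 2")
  if (object@fractionF <= 0 || object@fractionF > 1)
    msg <- c(msg, "fractionF must be in (0, 1]")
  if (floor(object@nTotal * object@fractionF) < 2)
    msg <- c(msg, "floor(nTotal * fractionF) must be at least 2")
  if (length(object@kRange) < 1L || any(object@kRange < 1L))
    msg <- c(msg, "kRange must contain positive cluster numbers")
  if (length(msg)) msg else TRUE
})

#' Separation-concordance map
#'
#' Per cluster number k, the (deltaSSQ, med(CV)) coordinates of the retained
#' top-fraction solutions: deltaSSQ measures cluster separation and med(CV)
#' is each solution's median pairwise Cramér's V against the other retained
#' solutions, its stability score. Only retained solutions keep their label
#' vectors; every map point records its run seed so it can be re-materialised.
#'
#' @slot points data.frame with columns \code{k}, \code{runId}, \code{seed},
#'   \code{deltaSSQ}, \code{medCV}.
#' @slot solutions named list of retained [ClusterSolution-class] objects,
#'   names \code{"<k>:<runId>"}.
#' @slot config the [SeCoConfig-class] that produced the map.
#' @slot fingerprint list describing the input data (n, d, checksum).
#'
#' @seealso [buildSeCoMap()], [selectSolution()]
#' @export
setClass("SeCoMap",
  slots = c(
    points = "data.frame",
    solutions = "list",
    config = "SeCoConfig",
    fingerprint = "list"
  )
)

setValidity("SeCoMap", function(object) {
  msg <- character()
  need <- c("k", "runId", "seed", "deltaSSQ", "medCV")
  if (!all(need %in% names(object@points)))
    msg <- c(msg, "points must have columns k, runId, seed, deltaSSQ, medCV")
  else {
    if (any(object@points$medCV < -1e-12 | object@points$medCV > 1 + 1e-12))
      msg <- c(msg, "medCV must lie in [0, 1]")
    if (any(object@points$deltaSSQ < 0))
      msg <- c(msg, "deltaSSQ must be nonnegative")
  }
  if (length(msg)) msg else TRUE
})

#' Gaussian mixture specification
#'
#' Means, covariances and weights of a multivariate normal mixture, used to
#' generate synthetic benchmark data with known cohort structure.
#'
#' @slot means \code{m x d} matrix of component means.
#' @slot covariances list of \code{d x d} symmetric positive-definite
#'   covariance matrices.
#' @slot weights mixing weights, normalised to sum to 1.
#' @slot componentNames character labels for the components.
#'
#' @seealso [mixtureSpec()], [benchmarkMixture()], [sampleMixture()]
#' @export
setClass("MixtureSpec",
  slots = c(
    means = "matrix",
    covariances = "list",
    weights = "numeric",
    componentNames = "character"
  )
)

setValidity("MixtureSpec", function(object) {
  msg <- character()
  m <- nrow(object@means)
  if (length(object@covariances) != m)
    msg <- c(msg, "one covariance matrix per component required")
  if (length(object@weights) != m)
    msg <- c(msg, "one weight per component required")
  if (any(object@weights < 0)) msg <- c(msg, "weights must be nonnegative")
  if (abs(sum(object@weights) - 1) > 1e-8)
    msg <- c(msg, "weights must sum to 1")
  d <- ncol(object@means)
  for (i in seq_along(object@covariances)) {
    S <- object@covariances[[i]]
    if (!is.matrix(S) || any(dim(S) != d)) {
      msg <- c(msg, sprintf("covariance %d has wrong dimension", i))
      next
    }
    if (max(abs(S - t(S))) > 1e-8)
      msg <- c(msg, sprintf("covariance %d is not symmetric", i))
    else if (min(eigen(S, symmetric = TRUE,
                       only.values = TRUE)$values) <= 0)
      msg <- c(msg, sprintf("covariance %d is not positive-definite", i))
  }
  if (length(msg)) msg else TRUE
})

#' Reference partition for benchmarking
#'
#' The best-SSQ k-means solution over many runs on a large dataset, whose
#' prototypes are propagated to smaller datasets by iterating to convergence
#' from them; the resulting labels are the ground truth accuracy and
#' concordance are measured against.
#'
#' @slot prototypes \code{k x d} matrix of reference cluster means.
#' @slot labels reference labels of the source dataset.
#' @slot wss within-cluster SSQ of the source solution.
#' @slot k cluster count.
#' @slot sourceSeed master seed of the ensemble the partition was derived
#'   from.
#'
#' @seealso [deriveReferencePartition()], [projectReference()]
#' @export
setClass("ReferencePartition",
  slots = c(
    prototypes = "matrix",
    labels = "integer",
    wss = "numeric",
    k = "integer",
    sourceSeed = "integer"
  )
)

#' Membership flow between selected partitions at consecutive k
#'
#' Edges carry the contingency counts between the cohorts of the selected
#' solution at k and at k+1; edges moving less than \code{minFraction} of
#' their originating cohort are retained in the data but flagged invisible
#' for rendering.
#'
#' @slot kValues the consecutive cluster numbers of the levels.
#' @slot solutions list of the per-k [ClusterSolution-class] levels.
#' @slot edges data.frame with columns \code{kFrom}, \code{cohortFrom},
#'   \code{kTo}, \code{cohortTo}, \code{count}, \code{fraction},
#'   \code{visible}.
#' @slot minFraction visibility threshold on the flow fraction.
#'
#' @seealso [buildPartitionTree()]
#' @export
setClass("PartitionTree",
  slots = c(
    kValues = "integer",
    solutions = "list",
    edges = "data.frame",
    minFraction = "numeric"
  )
)

#' Result of the single- vs dual-measure benchmarking protocol
#'
#' Per repetition, a fresh ensemble is generated and one solution selected
#' either by best SSQ alone ("single") or by the SeCo dual measure
#' ("dual"); each selection is scored against the reference partition.
#'
#' @slot method \code{"single"} or \code{"dual"}.
#' @slot k cluster count benchmarked.
#' @slot cv per-repetition Cramér's V against the reference.
#' @slot accuracy per-repetition optimal-matching accuracy against the
#'   reference.
#' @slot affinity mean over rows of the modal cohort frequency across the
#'   selected partitions (how consistently each point lands in one cohort).
#' @slot nReps number of repetitions.
#' @slot config the [SeCoConfig-class] used per repetition.
#'
#' @seealso [benchmarkSelection()], [clusteringAffinity()]
#' @export
setClass("BenchmarkResult",
  slots = c(
    method = "character",
    k = "integer",
    cv = "numeric",
    accuracy = "numeric",
    affinity = "numeric",
    nReps = "integer",
    config = "SeCoConfig"
  )
)
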