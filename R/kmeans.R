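## k-means engine: random data-point seeding, batch Lloyd iteration to
## convergence, then on-line per-point refinement (the numerical core lives
## in src/kmeans_core.cpp).

.check_data_matrix <- function(x) {
  if (!is.matrix(x)) x <- as.matrix(x)
  if (!is.numeric(x)) stop("data must be a numeric matrix", call. = FALSE)
  if (nrow(x) < 1L || ncol(x) < 1L)
    stop("data must have at least one row and one column", call. = FALSE)
  if (!all(is.finite(x)))
    stop("data must contain only finite values", call. = FALSE)
  x
}

#' Total sum of squares about the global mean
#'
#' @param x numeric data matrix (rows are observations).
#' @return Sum of squared Euclidean distances of all rows to the column-mean
#'   vector — the quantity the separation score deltaSSQ is measured against.
#' @export
#' @examples
#' totalSSQ(matrix(c(0, 2), ncol = 1)) # 2
totalSSQ <- function(x) {
  x <- .check_data_matrix(x)
  sum(sweep(x, 2, colMeans(x))^2)
}

#' Seed prototypes with randomly selected data points
#'
#' Standard k-means initialisation: k distinct rows of the data sampled
#' uniformly without replacement.
#'
#' @param x numeric data matrix.
#' @param k number of prototypes, \code{1 <= k <= nrow(x)}.
#' @param seed integer seed making the draw reproducible; \code{NULL} uses
#'   the current RNG state.
#' @return A \code{k x d} matrix of starting prototypes.
#' @export
#' @examples
#' x <- matrix(rnorm(20), ncol = 2)
#' seedPrototypes(x, 3, seed = 42)
seedPrototypes <- function(x, k, seed = NULL) {
  x <- .check_data_matrix(x)
  k <- as.integer(k)
  if (k < 1L || k > nrow(x))
    stop(sprintf("k = %d must be between 1 and n = %d", k, nrow(x)),
         call. = FALSE)
  idx <- if (is.null(seed)) {
    sample.int(nrow(x), k)
  } else {
    withr::with_seed(as.integer(seed), sample.int(nrow(x), k))
  }
  x[idx, , drop = FALSE]
}

#' Assign each observation to its nearest prototype
#'
#' Squared-Euclidean nearest-prototype labelling; ties are broken by the
#' lowest prototype index so the assignment is deterministic.
#'
#' @param x numeric data matrix.
#' @param prototypes \code{k x d} matrix of prototypes.
#' @return Integer label vector in \code{1..k}, one entry per row of
#'   \code{x}.
#' @export
#' @examples
#' assignLabels(matrix(c(0, 10), ncol = 1), matrix(c(1, 9), ncol = 1))
assignLabels <- function(x, prototypes) {
  x <- .check_data_matrix(x)
  prototypes <- as.matrix(prototypes)
  if (ncol(prototypes) != ncol(x))
    stop("prototypes and data must have the same number of columns",
         call. = FALSE)
  if (!all(is.finite(prototypes)))
    stop("prototypes must be finite", call. = FALSE)
  .assign_nearest(x, prototypes)
}

#' Within-cluster sum of squares for given labels and prototypes
#'
#' @param x numeric data matrix.
#' @param labels integer labels in \code{1..k}.
#' @param prototypes \code{k x d} prototype matrix (need not be the cluster
#'   means).
#' @return Sum over clusters of squared distances of members to their
#'   prototype.
#' @export
#' @examples
#' withinSSQ(matrix(c(0, 2), ncol = 1), c(1L, 1L), matrix(1, ncol = 1)) # 2
withinSSQ <- function(x, labels, prototypes) {
  x <- .check_data_matrix(x)
  prototypes <- as.matrix(prototypes)
  labels <- as.integer(labels)
  if (length(labels) != nrow(x))
    stop("one label per observation required", call. = FALSE)
  if (any(labels < 1L) || any(labels > nrow(prototypes)))
    stop(sprintf(
      "labels reference cluster ids outside 1..%d", nrow(prototypes)),
      call. = FALSE)
  sum((x - prototypes[labels, , drop = FALSE])^2)
}

.new_solution <- function(core, x, seed = NA_integer_,
                          runId = NA_integer_) {
  tss <- totalSSQ(x)
  methods::new("ClusterSolution",
    k = nrow(core$prototypes),
    labels = as.integer(core$labels),
    prototypes = core$prototypes,
    wss = core$wss,
    deltaSSQ = max(0, tss - core$wss),
    totalSSQ = tss,
    nIter = c(core$n_batch, core$n_online),
    seed = as.integer(seed),
    runId = as.integer(runId)
  )
}

#' Fit k-means with batch iteration followed by on-line refinement
#'
#' Runs the standard batch (Lloyd) algorithm — assign to nearest prototype,
#' recompute means — until the labels stop changing, then refines the
#' converged solution with on-line passes: points are presented one at a
#' time in row order and moved to their nearest prototype, incrementally
#' updating both affected means, until a full pass makes no move. A cluster
#' emptied during a batch update is re-seeded at the point farthest from its
#' stale prototype so the solution always keeps k nonempty clusters.
#'
#' @param x numeric data matrix.
#' @param k number of clusters, \code{1 <= k <= nrow(x)}.
#' @param seed integer seed for the random data-point initialisation
#'   (ignored when \code{init} is given).
#' @param init optional explicit \code{k x d} starting prototype matrix.
#' @param maxBatchIter cap on Lloyd iterations (default 300).
#' @param maxOnlinePasses cap on on-line refinement passes (default 50).
#' @param runId optional ensemble run index recorded in the solution.
#' @return A [ClusterSolution-class] carrying labels, prototypes, \code{wss},
#'   \code{deltaSSQ} and the seed.
#' @export
#' @examples
#' x <- matrix(c(0, 0.1, 10, 10.1), ncol = 1)
#' fit <- fitKmeans(x, k = 2, seed = 7)
#' wss(fit) # 0.01: the two tight pairs
fitKmeans <- function(x, k, seed = NULL, init = NULL, maxBatchIter = 300L,
                      maxOnlinePasses = 50L, runId = NA_integer_) {
  x <- .check_data_matrix(x)
  if (is.null(init)) {
    init <- seedPrototypes(x, k, seed = seed)
  } else {
    init <- as.matrix(init)
    k <- nrow(init)
    if (ncol(init) != ncol(x))
      stop("init must have the same number of columns as the data",
           call. = FALSE)
  }
  core <- .kmeans_core(x, init, as.integer(maxBatchIter),
                       as.integer(maxOnlinePasses))
  .new_solution(core, x,
                seed = if (is.null(seed)) NA_integer_ else seed,
                runId = runId)
}

## exposes the per-iteration wss traces for diagnostics/tests
.fit_kmeans_trace <- function(x, init, maxBatchIter = 300L,
                              maxOnlinePasses = 50L) {
  x <- .check_data_matrix(x)
  .kmeans_core(x, as.matrix(init), as.integer(maxBatchIter),
               as.integer(maxOnlinePasses))
}

#' Serialise a cluster solution to JSON
#'
#' @param solution a [ClusterSolution-class].
#' @param path optional file to write to; when \code{NULL} the JSON string
#'   is returned.
#' @return The JSON string, invisibly when written to a file.
#' @export
solutionToJSON <- function(solution, path = NULL) {
  stopifnot(methods::is(solution, "ClusterSolution"))
  obj <- list(
    k = solution@k,
    labels = solution@labels,
    prototypes = solution@prototypes,
    wss = solution@wss,
    delta_ssq = solution@deltaSSQ,
    total_ssq = solution@totalSSQ,
    seed = solution@seed,
    run_id = solution@runId
  )
  txt <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA)
  if (is.null(path)) return(txt)
  writeLines(txt, path)
  invisible(txt)
}

#' Read a cluster solution back from JSON
#'
#' @param path file written by [solutionToJSON()].
#' @return A [ClusterSolution-class].
#' @export
solutionFromJSON <- function(path) {
  obj <- jsonlite::fromJSON(path)
  int_or_na <- function(v) {
    v <- suppressWarnings(as.integer(v))
    if (length(v) != 1L) NA_integer_ else v
  }
  obj$seed <- int_or_na(obj$seed)
  obj$run_id <- int_or_na(obj$run_id)
  methods::new("ClusterSolution",
    k = as.integer(obj$k),
    labels = as.integer(obj$labels),
    prototypes = as.matrix(obj$prototypes),
    wss = obj$wss,
    deltaSSQ = obj$delta_ssq,
    totalSSQ = obj$total_ssq,
    nIter = c(NA_integer_, NA_integer_),
    seed = as.integer(obj$seed),
    runId = as.integer(obj$run_id)
  )
}
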