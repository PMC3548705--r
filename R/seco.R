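## The SeCo procedure: ensemble generation, deltaSSQ ranking with
## fraction-f thresholding, concordance scoring, map assembly and
## dual-measure selection.

#' Configure a SeCo analysis
#'
#' @param kRange inclusive vector of cluster numbers to analyse.
#' @param nTotal ensemble size per cluster number; 500 random
#'   initialisations by default.
#' @param fractionF top fraction of the ensemble, ranked by separation
#'   (deltaSSQ), retained for stability scoring; the default 0.10 keeps the
#'   top decile, so 50 of 500 runs.
#' @param masterSeed integer master seed; ensemble run r uses seed
#'   \code{masterSeed + r}.
#' @return A validated [SeCoConfig-class].
#' @export
#' @examples
#' secoConfig(kRange = 2:10, masterSeed = 1)
secoConfig <- function(kRange, nTotal = 500L, fractionF = 0.10,
                       masterSeed = 0L) {
  methods::new("SeCoConfig",
    nTotal = as.integer(nTotal),
    fractionF = as.numeric(fractionF),
    kRange = as.integer(kRange),
    masterSeed = as.integer(masterSeed)
  )
}

#' Run an ensemble of independently seeded k-means fits
#'
#' Performs \code{nTotal} fits at a fixed k, run r seeded with
#' \code{masterSeed + r}; results are returned in seed order, so the
#' ensemble is reproducible and may be recomputed run-by-run.
#'
#' @param x numeric data matrix.
#' @param k cluster number.
#' @param config a [SeCoConfig-class]; only \code{nTotal} and
#'   \code{masterSeed} are used here.
#' @return List of \code{nTotal} [ClusterSolution-class] objects.
#' @export
runEnsemble <- function(x, k, config) {
  x <- .check_data_matrix(x)
  stopifnot(methods::is(config, "SeCoConfig"))
  lapply(seq_len(config@nTotal), function(r) {
    tryCatch(
      fitKmeans(x, k, seed = config@masterSeed + r, runId = r),
      error = function(e) stop(sprintf("ensemble run %d failed: %s", r,
                                       conditionMessage(e)), call. = FALSE)
    )
  })
}

#' Retain the top fraction of an ensemble by separation
#'
#' Solutions are sorted by deltaSSQ descending (ties broken by lower run
#' index) and the top \code{floor(m * fractionF)} retained.
#'
#' @param solutions list of [ClusterSolution-class] objects.
#' @param fractionF fraction in (0, 1]; must leave at least two solutions,
#'   otherwise the median pairwise concordance of the retained set is
#'   undefined.
#' @return The retained sublist, in decreasing deltaSSQ order.
#' @export
selectTopFraction <- function(solutions, fractionF) {
  if (length(solutions) == 0L)
    stop("no solutions supplied", call. = FALSE)
  m <- length(solutions)
  nKeep <- floor(m * fractionF)
  if (nKeep < 2L)
    stop(sprintf(
      "fractionF = %g of %d solutions keeps %d; at least 2 are required",
      fractionF, m, nKeep), call. = FALSE)
  dssq <- vapply(solutions, deltaSSQ, numeric(1))
  ord <- order(-dssq, seq_along(solutions))
  solutions[ord[seq_len(nKeep)]]
}

.data_fingerprint <- function(x) {
  list(n = nrow(x), d = ncol(x),
       checksum = format(sum(x) + sum(x * x), digits = 17))
}

#' Build a separation-concordance map
#'
#' For each cluster number k in the configuration: run the ensemble, retain
#' the top fraction by deltaSSQ, and score every retained solution by its
#' median pairwise Cramér's V against the other retained solutions. The
#' resulting (deltaSSQ, med(CV)) points, one per retained solution per k,
#' form the map.
#'
#' @param x numeric data matrix.
#' @param config a [SeCoConfig-class].
#' @param verbose print per-k progress (the seed range of each ensemble).
#' @return A [SeCoMap-class]; retained solutions keep their labels, and
#'   every map point records its run seed.
#' @export
#' @examples
#' x <- rbind(matrix(rnorm(40, 0), ncol = 2), matrix(rnorm(40, 6), ncol = 2))
#' map <- buildSeCoMap(x, secoConfig(kRange = 2, nTotal = 20,
#'                                   fractionF = 0.5, masterSeed = 1))
#' secoPoints(map)
buildSeCoMap <- function(x, config, verbose = FALSE) {
  x <- .check_data_matrix(x)
  stopifnot(methods::is(config, "SeCoConfig"))
  pts <- list()
  sols <- list()
  for (k in config@kRange) {
    if (k > nrow(x))
      stop(sprintf("k = %d exceeds the number of observations (%d)", k,
                   nrow(x)), call. = FALSE)
    if (verbose)
      message(sprintf(
        "INFO k = %d: ensemble of %d runs, seeds %d..%d", k,
        config@nTotal, config@masterSeed + 1L,
        config@masterSeed + config@nTotal))
    ens <- runEnsemble(x, k, config)
    kept <- selectTopFraction(ens, config@fractionF)
    med <- medianPairwiseConcordance(kept)
    pts[[as.character(k)]] <- data.frame(
      k = k,
      runId = vapply(kept, function(s) s@runId, 1L),
      seed = vapply(kept, runSeed, 1L),
      deltaSSQ = vapply(kept, deltaSSQ, numeric(1)),
      medCV = med
    )
    names(kept) <- sprintf("%d:%d", k,
                           vapply(kept, function(s) s@runId, 1L))
    sols <- c(sols, kept)
  }
  methods::new("SeCoMap",
    points = do.call(rbind, c(pts, list(make.row.names = FALSE))),
    solutions = sols,
    config = config,
    fingerprint = .data_fingerprint(x)
  )
}

.solution_key <- function(k, runId) sprintf("%d:%d", k, runId)

#' Select the most stable well-separated solution at a given k
#'
#' Implements the dual-measure rule: among the retained (top-fraction)
#' solutions, choose the one with the highest med(CV); ties are broken by
#' the larger deltaSSQ, then by the lower run index, so the choice is
#' deterministic and invariant to input ordering.
#'
#' @param map a [SeCoMap-class].
#' @param k cluster number to select at (defaults to the map's single k).
#' @return The selected [ClusterSolution-class].
#' @export
selectSolution <- function(map, k = NULL) {
  stopifnot(methods::is(map, "SeCoMap"))
  pts <- map@points
  if (is.null(k)) {
    ks <- unique(pts$k)
    if (length(ks) != 1L)
      stop("map covers several k; specify which one to select at",
           call. = FALSE)
    k <- ks
  }
  pts <- pts[pts$k == k, , drop = FALSE]
  if (nrow(pts) == 0L)
    stop(sprintf("map has no solutions at k = %d", k), call. = FALSE)
  ord <- order(-pts$medCV, -pts$deltaSSQ, pts$runId)
  best <- pts[ord[1L], ]
  map@solutions[[.solution_key(k, best$runId)]]
}

#' Select the best solution by separation alone
#'
#' The conventional single-measure rule: the solution with maximal deltaSSQ
#' (equivalently, minimal within-cluster SSQ); ties go to the lower run
#' index.
#'
#' @param solutions list of [ClusterSolution-class] objects.
#' @return The best-SSQ [ClusterSolution-class].
#' @export
selectSolutionSSQ <- function(solutions) {
  if (length(solutions) == 0L)
    stop("no solutions supplied", call. = FALSE)
  dssq <- vapply(solutions, deltaSSQ, numeric(1))
  solutions[[order(-dssq, seq_along(solutions))[1L]]]
}

#' Scatter plot of a SeCo map
#'
#' One panel with med(CV) on the x axis and deltaSSQ on the y axis, points
#' coloured by cluster number: the diagnostic view on which spread to the
#' left at a given k reveals unstable well-separated solutions.
#'
#' @param x a [SeCoMap-class].
#' @param y ignored.
#' @param ... further arguments passed to [graphics::plot()].
#' @return Invisibly, the plotted coordinate table.
#' @export
setMethod("plot", signature(x = "SeCoMap", y = "missing"),
  function(x, y, ...) {
    pts <- x@points
    ks <- sort(unique(pts$k))
    pal <- grDevices::hcl.colors(max(length(ks), 2L), "Dark 2")
    col <- pal[match(pts$k, ks)]
    graphics::plot(pts$medCV, pts$deltaSSQ, col = col, pch = 19,
                   xlab = "median internal Cramér's V",
                   ylab = expression(Delta * "SSQ"), ...)
    graphics::legend("bottomleft", legend = paste("k =", ks),
                     col = pal[seq_along(ks)], pch = 19, cex = 0.8)
    invisible(pts)
  })
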