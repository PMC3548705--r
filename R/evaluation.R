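## Accuracy and affinity evaluation against a reference partition, and the
## single- vs dual-measure benchmarking protocol.

## exact maximum-weight one-to-one matching of a square k x k profit
## matrix by dynamic programming over column subsets: f[mask] is the best
## total using the first popcount(mask) rows and the column set `mask`.
.best_assignment <- function(profit) {
  k <- nrow(profit)
  nmask <- bitwShiftL(1L, k)
  f <- rep(-Inf, nmask)
  from <- integer(nmask)
  f[1L] <- 0
  popcount <- integer(nmask)
  for (m in seq_len(nmask - 1L))
    popcount[m + 1L] <- popcount[bitwShiftR(m, 1) + 1L] + (m %% 2L)
  for (m in seq_len(nmask - 1L)) {
    r <- popcount[m + 1L]  # row to place next is r (0-based: row r+1 used)
    for (col in seq_len(k)) {
      bit <- bitwShiftL(1L, col - 1L)
      if (bitwAnd(m, bit) == 0L) next
      prev <- bitwXor(m, bit)
      cand <- f[prev + 1L] + profit[r, col]
      if (cand > f[m + 1L]) {
        f[m + 1L] <- cand
        from[m + 1L] <- col
      }
    }
  }
  # recover the row -> column assignment
  assign <- integer(k)
  m <- nmask - 1L
  for (r in rev(seq_len(k))) {
    col <- from[m + 1L]
    assign[r] <- col
    m <- bitwXor(m, bitwShiftL(1L, col - 1L))
  }
  list(assignment = assign, total = f[nmask])
}

#' Optimal one-to-one matching of clusters to reference cohorts
#'
#' Finds the cluster-to-reference assignment maximising the total matched
#' count in the contingency table (exact maximum-weight bipartite
#' matching). Both partitions must have the same number of clusters, since
#' the matching is one-to-one.
#'
#' @param labels,reference label vectors of equal length with equally many
#'   distinct labels.
#' @return Integer vector mapping each cluster id of \code{labels} (in
#'   sorted-level order) to a reference cohort id, with attribute
#'   \code{"matched"}: the total number of agreeing observations under the
#'   matching.
#' @export
matchClusters <- function(labels, reference) {
  a <- .as_label_vector(labels, "labels")
  b <- .as_label_vector(reference, "reference")
  if (length(a) != length(b))
    stop(sprintf("label vectors differ in length (%d vs %d)",
                 length(a), length(b)), call. = FALSE)
  P <- max(a)
  Q <- max(b)
  if (P != Q)
    stop(sprintf(
      "one-to-one matching needs a square table: %d clusters vs %d cohorts",
      P, Q), call. = FALSE)
  counts <- .joint_counts(a, b, P, Q)
  res <- .best_assignment(counts)
  structure(res$assignment, matched = res$total)
}

#' Clustering accuracy against a reference partition
#'
#' The proportion of correctly classified observations under the optimal
#' one-to-one relabelling of clusters to reference cohorts, so the measure
#' is invariant to how either partition numbers its clusters.
#'
#' @inheritParams matchClusters
#' @return Accuracy in \code{[0, 1]}.
#' @export
#' @examples
#' clusteringAccuracy(c(1, 1, 2, 2), c(2, 2, 1, 1)) # 1: a relabelling
#' clusteringAccuracy(c(1, 1, 2, 2), c(1, 2, 1, 2)) # 0.5
clusteringAccuracy <- function(labels, reference) {
  map <- matchClusters(labels, reference)
  attr(map, "matched") / length(.as_label_vector(reference))
}

## relabel a partition into the reference frame via the optimal matching
.align_to_reference <- function(labels, reference) {
  a <- .as_label_vector(labels)
  map <- matchClusters(a, reference)
  as.integer(map)[a]
}

#' Affinity of an ensemble of partitions
#'
#' How consistently each observation lands in the same cohort across a set
#' of selected partitions: every partition is aligned to a common frame by
#' the optimal cluster matching, then for each row the frequency of its
#' modal cohort across partitions is taken, and the mean over rows
#' returned. 1 means no observation ever swaps cohort.
#'
#' @param partitions list of label vectors (or [ClusterSolution-class]s) of
#'   equal length.
#' @param reference alignment frame; when \code{NULL} the first partition
#'   is used.
#' @return Affinity in \code{(0, 1]}.
#' @export
#' @examples
#' p <- c(1, 1, 1, 2, 2)
#' clusteringAffinity(list(p, p, p)) # 1
clusteringAffinity <- function(partitions, reference = NULL) {
  if (length(partitions) < 2L)
    stop("affinity needs at least two partitions", call. = FALSE)
  if (is.null(reference)) reference <- partitions[[1L]]
  ref <- .as_label_vector(reference, "reference")
  aligned <- vapply(partitions, .align_to_reference, ref,
                    FUN.VALUE = integer(length(ref)))
  m <- ncol(aligned)
  kmax <- max(aligned)
  modal <- vapply(seq_len(nrow(aligned)), function(i) {
    max(tabulate(aligned[i, ], nbins = kmax))
  }, numeric(1))
  mean(modal) / m
}

#' Benchmark single- against dual-measure solution selection
#'
#' Repeats the full selection pipeline: per repetition a fresh ensemble of
#' \code{nTotal} k-means runs is generated (repetition r offsets the master
#' seed by \code{r * nTotal}, so seed streams are disjoint), one solution
#' is selected with each rule — best SSQ alone ("single") or highest
#' med(CV) among the retained top fraction ("dual") — and scored against
#' the reference partition by Cramér's V and optimal-matching accuracy.
#' Affinity is computed over the selected partitions of all repetitions.
#'
#' @param x numeric data matrix.
#' @param reference reference label vector (e.g. from
#'   [projectReference()]).
#' @param k cluster count (accuracy requires it to equal the reference's
#'   cohort count).
#' @param config a [SeCoConfig-class]; its \code{nTotal}, \code{fractionF}
#'   and \code{masterSeed} drive every repetition.
#' @param nReps number of repetitions (100 in the full protocol).
#' @param method \code{"dual"}, \code{"single"} or \code{"both"}; with
#'   \code{"both"} the two rules share each repetition's ensemble, so they
#'   are compared on identical seed streams.
#' @return A [BenchmarkResult-class], or a named list of two (\code{single},
#'   \code{dual}) when \code{method = "both"}.
#' @export
benchmarkSelection <- function(x, reference, k, config, nReps = 100L,
                               method = c("both", "dual", "single")) {
  method <- match.arg(method)
  x <- .check_data_matrix(x)
  ref <- .as_label_vector(reference, "reference")
  if (length(ref) != nrow(x))
    stop("reference labels must cover every observation", call. = FALSE)
  nReps <- as.integer(nReps)
  want <- if (method == "both") c("single", "dual") else method
  sel <- list(single = vector("list", nReps),
              dual = vector("list", nReps))
  for (r in seq_len(nReps)) {
    cfg_r <- secoConfig(kRange = k, nTotal = config@nTotal,
                        fractionF = config@fractionF,
                        masterSeed = config@masterSeed + r * config@nTotal)
    ens <- runEnsemble(x, k, cfg_r)
    if ("single" %in% want)
      sel$single[[r]] <- selectSolutionSSQ(ens)
    if ("dual" %in% want) {
      kept <- selectTopFraction(ens, config@fractionF)
      med <- medianPairwiseConcordance(kept)
      ord <- order(-med, -vapply(kept, deltaSSQ, numeric(1)),
                   vapply(kept, function(s) s@runId, 1L))
      sel$dual[[r]] <- kept[[ord[1L]]]
    }
  }
  score <- function(solutions, meth) {
    labs <- lapply(solutions, clusterLabels)
    methods::new("BenchmarkResult",
      method = meth,
      k = as.integer(k),
      cv = vapply(labs, cramersV, numeric(1), labelsB = ref),
      accuracy = vapply(labs, clusteringAccuracy, numeric(1),
                        reference = ref),
      affinity = if (nReps >= 2L) clusteringAffinity(labs, ref) else 1,
      nReps = nReps,
      config = config
    )
  }
  out <- lapply(stats::setNames(want, want),
                function(m) score(sel[[m]], m))
  if (method == "both") out else out[[method]]
}

#' Sorted per-repetition concordance curve of a benchmark
#'
#' The data behind ordered-performance charts: the repetitionwise Cramér's
#' V values against the reference, sorted increasingly, with optional
#' per-rank percentile bootstrap confidence bounds.
#'
#' @param result a [BenchmarkResult-class].
#' @param conf confidence level for the bootstrap band, or \code{NULL} for
#'   none.
#' @param nBoot bootstrap resamples (default 1000).
#' @param seed seed for the bootstrap resampling.
#' @return data.frame with columns \code{rank}, \code{cv} and, with a band,
#'   \code{lower} and \code{upper}.
#' @export
concordanceCurve <- function(result, conf = NULL, nBoot = 1000L,
                             seed = 1L) {
  stopifnot(methods::is(result, "BenchmarkResult"))
  cv <- sort(result@cv)
  out <- data.frame(rank = seq_along(cv), cv = cv)
  if (!is.null(conf)) {
    alpha <- (1 - conf) / 2
    boot <- withr::with_seed(as.integer(seed), {
      vapply(seq_len(nBoot), function(b)
        sort(sample(result@cv, replace = TRUE)),
        numeric(length(cv)))
    })
    out$lower <- apply(boot, 1, stats::quantile, probs = alpha)
    out$upper <- apply(boot, 1, stats::quantile, probs = 1 - alpha)
  }
  out
}
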