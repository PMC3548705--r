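## Partition agreement statistics: contingency tables, chi-square,
## Cramér's V, the Hubert-Arabie adjusted Rand index, and median pairwise
## concordance over solution ensembles.

.as_label_vector <- function(labels, arg = "labels") {
  if (methods::is(labels, "ClusterSolution")) labels <- labels@labels
  labels <- as.integer(as.factor(labels))
  if (anyNA(labels)) stop(sprintf("%s contains missing values", arg),
                          call. = FALSE)
  labels
}

## fast joint counts for labels already coded 1..P and 1..Q
.joint_counts <- function(a, b, P, Q) {
  matrix(tabulate((b - 1L) * P + a, nbins = P * Q), nrow = P, ncol = Q)
}

## chi-square on a counts matrix; margins assumed positive
.chisq_counts <- function(counts) {
  n <- sum(counts)
  e <- outer(rowSums(counts), colSums(counts)) / n
  sum(counts^2 / e) - n
}

## Cramér's V for coded label vectors (hot path of the ensemble scoring)
.cv_coded <- function(a, b, P, Q) {
  counts <- .joint_counts(a, b, P, Q)
  n <- length(a)
  chi2 <- .chisq_counts(counts)
  v2 <- chi2 / (n * min(P - 1L, Q - 1L))
  sqrt(min(max(v2, 0), 1))
}

#' Cross-tabulate two partitions of the same observations
#'
#' @param labelsA,labelsB label vectors of equal length (any label coding;
#'   rows and columns of the table are indexed by the sorted distinct labels
#'   of each).
#' @return A [ContingencyTable-class] with joint counts and margins.
#' @export
#' @examples
#' contingencyTable(c(1, 1, 1, 2), c(1, 2, 1, 2))
contingencyTable <- function(labelsA, labelsB) {
  if (methods::is(labelsA, "ClusterSolution")) labelsA <- labelsA@labels
  if (methods::is(labelsB, "ClusterSolution")) labelsB <- labelsB@labels
  if (length(labelsA) != length(labelsB))
    stop(sprintf("label vectors differ in length (%d vs %d)",
                 length(labelsA), length(labelsB)), call. = FALSE)
  fa <- as.factor(labelsA)
  fb <- as.factor(labelsB)
  a <- as.integer(fa)
  b <- as.integer(fb)
  P <- nlevels(fa)
  Q <- nlevels(fb)
  counts <- .joint_counts(a, b, P, Q)
  dimnames(counts) <- list(levels(fa), levels(fb))
  methods::new("ContingencyTable",
    counts = counts,
    rowTotals = rowSums(counts),
    colTotals = colSums(counts),
    nTotal = length(a),
    rowLevels = seq_len(P),
    colLevels = seq_len(Q)
  )
}

#' Pearson chi-square statistic of a contingency table
#'
#' Expected counts are the usual independence products
#' \eqn{E_{pq} = r_p c_q / N}.
#'
#' @param table a [ContingencyTable-class], or a counts matrix.
#' @return The chi-square statistic (nonnegative).
#' @export
#' @examples
#' chiSquare(contingencyTable(c(1, 1, 2, 2), c(1, 1, 2, 2))) # 4
chiSquare <- function(table) {
  counts <- if (methods::is(table, "ContingencyTable")) table@counts
            else as.matrix(table)
  if (sum(counts) == 0) stop("table has no observations", call. = FALSE)
  if (any(rowSums(counts) == 0) || any(colSums(counts) == 0))
    stop("chi-square undefined for a table with a zero margin",
         call. = FALSE)
  .chisq_counts(counts)
}

#' Cramér's V concordance between two partitions
#'
#' \eqn{V = \sqrt{\chi^2 / (N \min(P-1, Q-1))}}: a normalised, symmetric
#' association index on \code{[0, 1]} that applies to partitions with
#' different cluster counts and is invariant to relabelling either side.
#'
#' @param labelsA,labelsB label vectors (or [ClusterSolution-class]s) of
#'   equal length; both must have at least two distinct labels.
#' @return Cramér's V in \code{[0, 1]}; 1 means the partitions determine
#'   each other.
#' @export
#' @examples
#' cramersV(c(1, 1, 2, 2), c(2, 2, 1, 1)) # 1: same partition relabelled
#' cramersV(c(1, 1, 2, 2), c(1, 2, 1, 2)) # 0: independent
cramersV <- function(labelsA, labelsB) {
  a <- .as_label_vector(labelsA, "labelsA")
  b <- .as_label_vector(labelsB, "labelsB")
  if (length(a) != length(b))
    stop(sprintf("label vectors differ in length (%d vs %d)",
                 length(a), length(b)), call. = FALSE)
  P <- max(a)
  Q <- max(b)
  if (P < 2L || Q < 2L)
    stop("Cramér's V is undefined when a partition has a single cluster",
         call. = FALSE)
  .cv_coded(a, b, P, Q)
}

#' Hubert-Arabie adjusted Rand index
#'
#' Chance-corrected pair-counting agreement between two partitions; 1 iff
#' they are identical up to relabelling, with expectation 0 under random
#' labellings with the same margins.
#'
#' @inheritParams cramersV
#' @return The adjusted Rand index (at most 1, may be negative).
#' @export
#' @examples
#' ariHA(c(1, 1, 2, 2), c(2, 2, 1, 1)) # 1
ariHA <- function(labelsA, labelsB) {
  a <- .as_label_vector(labelsA, "labelsA")
  b <- .as_label_vector(labelsB, "labelsB")
  if (length(a) != length(b))
    stop(sprintf("label vectors differ in length (%d vs %d)",
                 length(a), length(b)), call. = FALSE)
  counts <- .joint_counts(a, b, max(a), max(b))
  n <- length(a)
  sum_ij <- sum(choose(counts, 2))
  sum_a <- sum(choose(rowSums(counts), 2))
  sum_b <- sum(choose(colSums(counts), 2))
  expected <- sum_a * sum_b / choose(n, 2)
  max_index <- (sum_a + sum_b) / 2
  if (max_index == expected) return(1)  # degenerate: both partitions fixed
  (sum_ij - expected) / (max_index - expected)
}

#' Pairwise Cramér's V matrix over an ensemble of solutions
#'
#' @param solutions list of [ClusterSolution-class] objects (or label
#'   vectors) on the same observations.
#' @return Symmetric \code{m x m} matrix of pairwise Cramér's V values with
#'   unit diagonal.
#' @export
pairwiseConcordance <- function(solutions) {
  labs <- lapply(solutions, .as_label_vector)
  m <- length(labs)
  if (m < 2L)
    stop("at least two solutions are required", call. = FALSE)
  n <- length(labs[[1]])
  if (any(vapply(labs, length, 1L) != n))
    stop("all solutions must label the same observations", call. = FALSE)
  ks <- vapply(labs, max, 1L)
  cv <- diag(1, m)
  for (i in seq_len(m - 1L)) {
    for (j in seq(i + 1L, m)) {
      cv[i, j] <- cv[j, i] <- .cv_coded(labs[[i]], labs[[j]], ks[i], ks[j])
    }
  }
  cv
}

#' Median pairwise concordance of each solution in an ensemble
#'
#' Each solution's stability score med(CV) is the median of its Cramér's V
#' values against the other \code{m - 1} solutions (the self-pair is
#' excluded; it carries no information).
#'
#' @inheritParams pairwiseConcordance
#' @param overall logical; also return the median over all m(m-1)/2
#'   distinct pairs as an attribute \code{"overall"} (a secondary summary,
#'   never used for selection).
#' @return Numeric vector of per-solution med(CV) values in \code{[0, 1]}.
#' @export
medianPairwiseConcordance <- function(solutions, overall = FALSE) {
  cv <- pairwiseConcordance(solutions)
  m <- nrow(cv)
  med <- vapply(seq_len(m),
                function(i) stats::median(cv[i, -i]), numeric(1))
  if (overall)
    attr(med, "overall") <- stats::median(cv[upper.tri(cv)])
  med
}

#' Export a pairwise concordance matrix as TSV
#'
#' @param cv square concordance matrix, e.g. from [pairwiseConcordance()].
#' @param path output file.
#' @param ids solution identifiers used as header row and column.
#' @return The path, invisibly.
#' @export
writeConcordanceTSV <- function(cv, path, ids = seq_len(nrow(cv))) {
  df <- data.frame(id = ids, format(cv, digits = 17, trim = TRUE),
                   check.names = FALSE)
  names(df) <- c("id", ids)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
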