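## Partition tree: membership flow between selected solutions at
## consecutive cluster numbers.

#' Trace membership flow between partitions at consecutive k
#'
#' For each consecutive pair of levels, the flow from cohort p of the k
#' solution to cohort q of the k+1 solution is their joint count; the
#' fraction is the flow divided by the size of the originating cohort.
#' Edges moving less than \code{minFraction} of their source cohort are
#' kept in the edge list but flagged invisible, matching the usual
#' rendering rule that suppresses minor flows for clarity.
#'
#' @param solutions list of [ClusterSolution-class] objects (or label
#'   vectors) on identical observations, ordered by consecutive cluster
#'   numbers.
#' @param minFraction visibility threshold on the flow fraction (default
#'   0.10).
#' @param kValues optional integer vector of the cluster numbers; inferred
#'   from the solutions when omitted. Must be consecutive.
#' @return A [PartitionTree-class]; cohorts at each level are numbered in
#'   decreasing size order, stable across renders.
#' @export
#' @examples
#' a <- rep(1:2, each = 6)
#' b <- c(rep(1, 6), rep(2, 3), rep(3, 3)) # cohort 2 splits in two
#' tr <- buildPartitionTree(list(a, b), kValues = 2:3)
#' subset(treeEdges(tr), visible)
buildPartitionTree <- function(solutions, minFraction = 0.10,
                               kValues = NULL) {
  labs <- lapply(solutions, .as_label_vector)
  if (length(labs) < 2L)
    stop("a partition tree needs at least two levels", call. = FALSE)
  n <- length(labs[[1]])
  if (any(vapply(labs, length, 1L) != n))
    stop("all solutions must label the same observations", call. = FALSE)
  if (is.null(kValues)) kValues <- vapply(labs, max, 1L)
  kValues <- as.integer(kValues)
  if (any(diff(kValues) != 1L))
    stop("cluster numbers must be consecutive", call. = FALSE)

  # stable display order: renumber cohorts by decreasing size
  labs <- lapply(labs, function(l) {
    rank_by_size <- order(order(-tabulate(l), seq_len(max(l))))
    rank_by_size[l]
  })

  edges <- list()
  for (lev in seq_len(length(labs) - 1L)) {
    a <- labs[[lev]]
    b <- labs[[lev + 1L]]
    P <- max(a)
    Q <- max(b)
    counts <- .joint_counts(a, b, P, Q)
    src_size <- rowSums(counts)
    idx <- which(counts > 0, arr.ind = TRUE)
    frac <- counts[idx] / src_size[idx[, 1]]
    edges[[lev]] <- data.frame(
      kFrom = kValues[lev],
      cohortFrom = idx[, 1],
      kTo = kValues[lev + 1L],
      cohortTo = idx[, 2],
      count = counts[idx],
      fraction = frac,
      visible = frac >= minFraction
    )
  }
  edges <- do.call(rbind, c(edges, list(make.row.names = FALSE)))
  edges <- edges[order(edges$kFrom, edges$cohortFrom, edges$cohortTo), ]
  rownames(edges) <- NULL
  methods::new("PartitionTree",
    kValues = kValues,
    solutions = if (all(vapply(solutions, methods::is, TRUE,
                               "ClusterSolution"))) solutions else list(),
    edges = edges,
    minFraction = minFraction
  )
}

#' Export a partition tree edge list as TSV
#'
#' @param tree a [PartitionTree-class].
#' @param path output file.
#' @return The path, invisibly.
#' @export
writeTreeTSV <- function(tree, path) {
  stopifnot(methods::is(tree, "PartitionTree"))
  df <- tree@edges
  df$fraction <- format(df$fraction, digits = 17, trim = TRUE)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
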