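## Synthetic Gaussian-mixture benchmark: the canonical 10-component
## trivariate mixture, c-separation diagnostics, reference partitions and
## min-max scaling.

#' Construct a Gaussian mixture specification
#'
#' @param means \code{m x d} matrix of component means.
#' @param covariances list of m symmetric positive-definite \code{d x d}
#'   covariance matrices.
#' @param weights nonnegative mixing weights; normalised internally to sum
#'   to 1.
#' @param componentNames optional component labels (default C1..Cm).
#' @return A validated [MixtureSpec-class].
#' @export
mixtureSpec <- function(means, covariances, weights,
                        componentNames = NULL) {
  means <- as.matrix(means)
  if (is.null(componentNames))
    componentNames <- paste0("C", seq_len(nrow(means)))
  methods::new("MixtureSpec",
    means = means,
    covariances = lapply(covariances, as.matrix),
    weights = as.numeric(weights) / sum(weights),
    componentNames = componentNames
  )
}

#' The ten-component trivariate benchmark mixture
#'
#' The canonical synthetic benchmark of this package: ten anisotropic
#' trivariate normal cohorts, a mix of well-separated and strongly
#' overlapping components patterned on the principal separation axes of a
#' breast-cancer dataset. Mixing weights are proportional to the cohort
#' sizes of the original 1076-point realisation
#' (64, 42, 61, 32, 197, 131, 163, 97, 106, 183).
#'
#' @return The [MixtureSpec-class] of the benchmark generator.
#' @export
#' @examples
#' spec <- benchmarkMixture()
#' sum(spec@weights) # 1
benchmarkMixture <- function() {
  means <- matrix(c(
    -0.799, -1.011, -3.336,
    -0.441, -0.569, -2.331,
     0.649, -0.344, -4.154,
     1.077,  0.072, -2.815,
    -0.390, -0.242,  0.256,
    -1.358, -0.658,  1.639,
     1.261,  0.125,  0.862,
    -0.593,  3.024, -0.498,
     0.251, -0.539, -0.530,
     0.374, -0.267,  1.973), ncol = 3, byrow = TRUE)
  colnames(means) <- c("x", "y", "z")
  covs <- list(
    c(0.336,  0.044,  0.074,  0.044, 0.371,  0.210,  0.074,  0.210, 0.582),
    c(0.428,  0.060, -0.002,  0.060, 0.123,  0.157, -0.002,  0.157, 0.648),
    c(0.620,  0.023, -0.035,  0.023, 0.137,  0.070, -0.035,  0.070, 0.446),
    c(0.366, -0.002,  0.076, -0.002, 0.043,  0.104,  0.076,  0.104, 0.563),
    c(0.536,  0.013,  0.031,  0.013, 0.348, -0.117,  0.031, -0.117, 0.689),
    c(0.309, -0.060, -0.055, -0.060, 0.245, -0.013, -0.055, -0.013, 0.532),
    c(0.323,  0.017,  0.027,  0.017, 0.386, -0.060,  0.027, -0.060, 0.403),
    c(0.776,  0.033,  0.175,  0.033, 0.491,  0.003,  0.175,  0.003, 0.695),
    c(0.711, -0.025,  0.055, -0.025, 0.352, -0.081,  0.055, -0.081, 0.576),
    c(0.390, -0.097,  0.041, -0.097, 0.343, -0.014,  0.041, -0.014, 0.322))
  covs <- lapply(covs, matrix, nrow = 3, ncol = 3)
  sizes <- c(64, 42, 61, 32, 197, 131, 163, 97, 106, 183)
  mixtureSpec(means, covs, sizes)
}

#' Sample observations from a Gaussian mixture
#'
#' Each row draws a component index from the mixing weights, then a
#' multivariate normal deviate via the Cholesky factor of that component's
#' covariance.
#'
#' @param spec a [MixtureSpec-class].
#' @param n number of observations.
#' @param seed integer seed; \code{NULL} uses the current RNG state.
#' @return List with \code{data} (an \code{n x d} matrix) and
#'   \code{labels} (the true component index of each row).
#' @export
#' @examples
#' s <- sampleMixture(benchmarkMixture(), 100, seed = 1)
#' table(s$labels)
sampleMixture <- function(spec, n, seed = NULL) {
  stopifnot(methods::is(spec, "MixtureSpec"))
  n <- as.integer(n)
  if (n < 1L) stop("n must be positive", call. = FALSE)
  d <- ncol(spec@means)
  m <- nrow(spec@means)
  chols <- lapply(spec@covariances, chol)
  draw <- function() {
    comp <- sample.int(m, n, replace = TRUE, prob = spec@weights)
    z <- matrix(stats::rnorm(n * d), nrow = n, ncol = d)
    x <- matrix(0, n, d, dimnames = list(NULL, colnames(spec@means)))
    for (c in seq_len(m)) {
      rows <- which(comp == c)
      if (!length(rows)) next
      x[rows, ] <- sweep(z[rows, , drop = FALSE] %*% chols[[c]], 2,
                         spec@means[c, ], "+")
    }
    list(data = x, labels = comp)
  }
  if (is.null(seed)) draw() else withr::with_seed(as.integer(seed), draw())
}

#' c-separation between two mixture components
#'
#' Dasgupta's scale-normalised separation
#' \eqn{c_{ij} = \lVert\mu_i - \mu_j\rVert / \sqrt{d \cdot
#' \max(\lambda_{max}(\Sigma_i), \lambda_{max}(\Sigma_j))}}: values well
#' above 1 indicate little overlap between the components.
#'
#' @param spec a [MixtureSpec-class].
#' @param i,j distinct component indices.
#' @return The nonnegative c-separation index (symmetric in i and j).
#' @export
#' @examples
#' round(cSeparation(benchmarkMixture(), 5, 9), 4)
cSeparation <- function(spec, i, j) {
  stopifnot(methods::is(spec, "MixtureSpec"))
  if (i == j)
    stop("c-separation requires two distinct components", call. = FALSE)
  d <- ncol(spec@means)
  lmax <- function(S) max(eigen(S, symmetric = TRUE,
                                only.values = TRUE)$values)
  delta <- sqrt(sum((spec@means[i, ] - spec@means[j, ])^2))
  delta / sqrt(d * max(lmax(spec@covariances[[i]]),
                       lmax(spec@covariances[[j]])))
}

#' All pairwise c-separation indices of a mixture
#'
#' @param spec a [MixtureSpec-class].
#' @return Symmetric matrix of pairwise indices with zero diagonal, rows
#'   and columns named by component.
#' @export
cSeparationMatrix <- function(spec) {
  m <- nrow(spec@means)
  out <- matrix(0, m, m,
                dimnames = list(spec@componentNames, spec@componentNames))
  for (i in seq_len(m - 1L)) {
    for (j in seq(i + 1L, m)) {
      out[i, j] <- out[j, i] <- cSeparation(spec, i, j)
    }
  }
  out
}

#' Derive a reference partition from a large dataset
#'
#' Runs a full ensemble of k-means fits and keeps the solution with the
#' lowest within-cluster SSQ; its prototypes and labels serve as the
#' benchmark ground truth on the source data and can be projected onto
#' smaller datasets with [projectReference()].
#'
#' @param x numeric data matrix (the large source dataset).
#' @param k cluster count of the reference (default 10).
#' @param nRuns ensemble size (default 500).
#' @param masterSeed integer master seed for the ensemble.
#' @return A [ReferencePartition-class].
#' @export
deriveReferencePartition <- function(x, k = 10L, nRuns = 500L,
                                     masterSeed = 0L) {
  cfg <- secoConfig(kRange = k, nTotal = nRuns, fractionF = 1,
                    masterSeed = masterSeed)
  best <- selectSolutionSSQ(runEnsemble(x, k, cfg))
  methods::new("ReferencePartition",
    prototypes = best@prototypes,
    labels = best@labels,
    wss = best@wss,
    k = as.integer(k),
    sourceSeed = as.integer(masterSeed)
  )
}

#' Project a reference partition onto another dataset
#'
#' Iterates k-means to convergence (batch then on-line) starting from the
#' reference prototypes — no random seeding is involved, so the projection
#' is deterministic. On the source data of a converged reference this is a
#' no-op returning the reference labels.
#'
#' @param reference a [ReferencePartition-class].
#' @param x numeric data matrix with the same number of columns.
#' @return Integer label vector for the rows of \code{x}.
#' @export
projectReference <- function(reference, x) {
  stopifnot(methods::is(reference, "ReferencePartition"))
  x <- .check_data_matrix(x)
  if (ncol(x) != ncol(reference@prototypes))
    stop("data dimension does not match the reference prototypes",
         call. = FALSE)
  # call the engine directly: a dataset smaller than k cannot populate
  # every reference cluster, which is fine for a projected labelling
  core <- .kmeans_core(x, reference@prototypes, 300L, 50L)
  as.integer(core$labels)
}

#' Serialise a reference partition to JSON
#'
#' @param reference a [ReferencePartition-class].
#' @param path optional output file.
#' @return JSON string, invisibly when written to a file.
#' @export
referenceToJSON <- function(reference, path = NULL) {
  obj <- list(prototypes = reference@prototypes, k = reference@k,
              wss = reference@wss, source_seed = reference@sourceSeed)
  txt <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA)
  if (is.null(path)) return(txt)
  writeLines(txt, path)
  invisible(txt)
}

#' Min-max scale every column to [0, 1]
#'
#' The scaling applied to real datasets before clustering:
#' \code{(x - min) / (max - min)} per column. Idempotent on already scaled
#' data.
#'
#' @param x numeric data matrix.
#' @return The scaled matrix.
#' @export
#' @examples
#' minMaxScale(matrix(c(0, 5, 10), ncol = 1))
minMaxScale <- function(x) {
  x <- .check_data_matrix(x)
  lo <- apply(x, 2, min)
  hi <- apply(x, 2, max)
  const <- which(hi == lo)
  if (length(const)) {
    nm <- colnames(x)
    lab <- if (is.null(nm)) as.character(const) else nm[const]
    stop(sprintf("constant column(s) cannot be min-max scaled: %s",
                 paste(lab, collapse = ", ")), call. = FALSE)
  }
  sweep(sweep(x, 2, lo), 2, hi - lo, "/")
}
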