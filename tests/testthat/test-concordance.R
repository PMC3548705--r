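test_that("contingency tables cross-tabulate label vectors correctly", {
  ct <- contingencyTable(c(1, 1, 2, 2), c(1, 1, 2, 2))
  expect_equal(unname(ct@counts), diag(2, 2))
  ct2 <- contingencyTable(c(1, 1, 2, 2), c(2, 2, 1, 1))
  expect_equal(unname(ct2@counts), matrix(c(0, 2, 2, 0), 2))
  ct3 <- contingencyTable(c(1, 1, 1, 2), c(1, 2, 1, 2))
  expect_equal(unname(ct3@counts), matrix(c(2, 0, 1, 1), 2))
  expect_equal(ct3@rowTotals, c(3, 1), ignore_attr = TRUE)
  expect_equal(ct3@nTotal, 4)
  expect_error(contingencyTable(1:3, 1:4), "length")
})

test_that("chi-square matches hand values and the double-loop oracle", {
  expect_equal(chiSquare(matrix(c(2, 2, 2, 2), 2)), 0)
  expect_equal(chiSquare(diag(2, 2)), 4)
  tab <- contingencyTable(c(1, 1, 1, 2), c(1, 2, 1, 2))
  expect_equal(chiSquare(tab), chisq_oracle(tab@counts), tolerance = 1e-12)
  # independent cross-check against the stats implementation
  counts <- matrix(c(8, 3, 2, 9, 5, 6), 2)
  expect_equal(chiSquare(counts),
               unname(suppressWarnings(
                 stats::chisq.test(counts, correct = FALSE))$statistic),
               tolerance = 1e-10)
  expect_error(chiSquare(matrix(c(1, 1, 0, 0), 2)), "zero margin")
})

test_that("Cramér's V is normalised, symmetric and relabel-invariant", {
  a <- c(1, 1, 2, 2)
  expect_equal(cramersV(a, a), 1)
  expect_equal(cramersV(a, c(1, 2, 1, 2)), 0)
  b <- c(1, 2, 1, 2)
  v <- cramersV(c(1, 1, 1, 2), b)
  expect_equal(v, sqrt(chisq_oracle(
    contingencyTable(c(1, 1, 1, 2), b)@counts) / 4))
  expect_equal(cramersV(b, c(1, 1, 1, 2)), v)
  # relabelling either side changes nothing
  expect_equal(cramersV(3 - a, b), cramersV(a, b))
  expect_error(cramersV(rep(1, 4), a), "single cluster")
  for (s in 1:20) {
    x <- random_labels(40, 3, seed = s)
    y <- random_labels(40, 4, seed = s + 100)
    expect_gte(cramersV(x, y), 0)
    expect_lte(cramersV(x, y), 1)
    expect_equal(cramersV(x, y), cramers_v_oracle(x, y),
                 tolerance = 1e-12)
  }
})

test_that("V equals one exactly for permuted block-diagonal tables", {
  x <- random_labels(60, 4, seed = 9)
  perm <- c(3L, 1L, 4L, 2L)
  expect_equal(cramersV(x, perm[x]), 1)
})

test_that("adjusted Rand index agrees with pair counting and mclust", {
  expect_equal(ariHA(c(1, 1, 2, 2), c(2, 2, 1, 1)), 1)
  cases <- list(
    list(a = c(1, 1, 2, 2), b = c(1, 2, 1, 2)),
    list(a = seq_len(8), b = random_labels(8, 3, seed = 2)),
    list(a = random_labels(25, 3, seed = 5),
         b = random_labels(25, 4, seed = 6)))
  for (cs in cases) {
    expect_equal(ariHA(cs$a, cs$b), ari_pairs_oracle(cs$a, cs$b),
                 tolerance = 1e-12)
    expect_equal(ariHA(cs$a, cs$b),
                 mclust::adjustedRandIndex(cs$a, cs$b),
                 tolerance = 1e-12)
  }
})

test_that("V and ARI are strongly correlated over random partition pairs", {
  pairs <- 500
  v <- ari <- numeric(pairs)
  for (i in seq_len(pairs)) {
    k1 <- 2 + (i %% 5)
    k2 <- 2 + ((i * 7) %% 5)
    a <- random_labels(200, k1, seed = i)
    # correlate a noisy copy rather than an independent draw, spanning
    # the full agreement range
    noise <- random_labels(200, k2, seed = i + 10000)
    keep <- withr::with_seed(i + 20000,
                             runif(200) < (i %% 10) / 10)
    b <- ifelse(keep & k2 >= k1, a, noise)
    if (length(unique(b)) < 2) b <- noise
    v[i] <- cramersV(a, b)
    ari[i] <- ariHA(a, b)
  }
  expect_gt(stats::cor(v, ari), 0.9)
})

test_that("median pairwise concordance follows the median definition", {
  p1 <- rep(1:2, each = 4)
  expect_equal(medianPairwiseConcordance(list(p1, p1, p1)), rep(1, 3))
  # m = 2: each solution's score is their single pairwise V
  p2 <- c(1, 1, 1, 2, 1, 2, 2, 2)
  expect_equal(medianPairwiseConcordance(list(p1, p2)),
               rep(cramersV(p1, p2), 2))
  # constructed pairwise V values {1, 0.5, 0.5}: solution 1 pairs with
  # {1.0, 0.5}, so its median is 0.75
  p3 <- c(1, 1, 1, 2, 1, 2, 2, 2)
  stopifnot(isTRUE(all.equal(cramersV(p1, p3), 0.5)))
  med <- medianPairwiseConcordance(list(p1, p1, p3))
  expect_equal(med, c(0.75, 0.75, 0.5))
  expect_error(medianPairwiseConcordance(list(p1)), "at least two")
})

test_that("pairwise concordance matrices export as readable TSV", {
  sols <- list(rep(1:2, each = 4), c(1, 1, 1, 2, 1, 2, 2, 2),
               rep(1:2, 4))
  cv <- pairwiseConcordance(sols)
  expect_true(isSymmetric(cv))
  expect_equal(diag(cv), rep(1, 3))
  path <- withr::local_tempfile(fileext = ".tsv")
  writeConcordanceTSV(cv, path, ids = c("s1", "s2", "s3"))
  back <- utils::read.delim(path, check.names = FALSE)
  expect_equal(back$id, c("s1", "s2", "s3"))
  expect_equal(as.numeric(back[["s2"]]), cv[, 2], tolerance = 1e-15)
})
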