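test_that("prototype seeding draws distinct data rows reproducibly", {
  x <- withr::with_seed(1, matrix(rnorm(30), ncol = 3))
  # k = n returns every row in some order
  p <- seedPrototypes(x, 10, seed = 4)
  expect_equal(p[order(p[, 1]), ], x[order(x[, 1]), ])
  # k = 1 returns one data row
  p1 <- seedPrototypes(x, 1, seed = 9)
  expect_true(any(apply(x, 1, function(r) all(r == p1[1, ]))))
  # same seed, same draw
  expect_identical(seedPrototypes(x, 4, seed = 11),
                   seedPrototypes(x, 4, seed = 11))
  expect_error(seedPrototypes(x, 11, seed = 1), "k = 11.*n = 10")
})

test_that("nearest-prototype assignment is exact and ties go low", {
  protos <- matrix(c(0, 1, 2, 3), ncol = 2, byrow = TRUE)
  expect_identical(assignLabels(protos, protos), c(1L, 2L))
  # equidistant point between prototypes takes the lower index
  p <- matrix(c(0, 2, 4), ncol = 1)
  expect_identical(assignLabels(matrix(c(1, 3), ncol = 1), p)[1], 1L)
  expect_identical(assignLabels(matrix(3, ncol = 1), p)[1], 2L)
  expect_identical(
    assignLabels(matrix(c(0, 10), ncol = 1), matrix(c(1, 9), ncol = 1)),
    c(1L, 2L))
})

test_that("within-cluster SSQ matches hand computations", {
  x <- matrix(c(0, 2), ncol = 1)
  expect_equal(withinSSQ(x, c(1L, 1L), matrix(1, ncol = 1)), 2)
  # points at their prototypes give zero
  expect_equal(withinSSQ(x, c(1L, 2L), x), 0)
  # k = 1 at the mean recovers the total SSQ
  expect_equal(withinSSQ(x, c(1L, 1L), matrix(mean(x), ncol = 1)),
               totalSSQ(x))
  expect_error(withinSSQ(x, c(1L, 3L), matrix(1, ncol = 1)), "1\\.\\.1")
})

test_that("fitting k distinct points with k clusters is exact", {
  x <- matrix(c(0, 0, 5, 5, -3, 4), ncol = 2, byrow = TRUE)
  fit <- fitKmeans(x, 3, seed = 2)
  expect_equal(wss(fit), 0)
  expect_setequal(clusterLabels(fit), 1:3)
  expect_equal(deltaSSQ(fit), totalSSQ(x))
})

test_that("two separated pairs converge to the enumerated optimum", {
  x <- matrix(c(0, 0.1, 10, 10.1), ncol = 1)
  fit <- fitKmeans(x, 2, seed = 5)
  expect_equal(wss(fit), 0.01)
  expect_equal(sort(as.vector(prototypes(fit))), c(0.05, 10.05))
  expect_equal(wss(fit), best_partition_wss_oracle(x, 2))
})

test_that("batch and online wss traces never increase", {
  blobs <- make_blobs(n_per = 30, centers = rbind(c(0, 0), c(3, 1),
                                                  c(1, 4)), sd = 1.2,
                      seed = 3)
  for (s in 1:5) {
    init <- seedPrototypes(blobs$data, 3, seed = s)
    tr <- SeCoClust:::.fit_kmeans_trace(blobs$data, init)
    expect_true(all(diff(tr$batch_wss) <= 1e-9))
    expect_true(all(diff(c(tr$batch_wss[length(tr$batch_wss)],
                           tr$online_wss)) <= 1e-9))
  }
})

test_that("solution decomposition wss + deltaSSQ equals total SSQ", {
  blobs <- make_blobs(n_per = 25, sd = 1.5, seed = 8)
  for (k in 2:4) {
    fit <- fitKmeans(blobs$data, k, seed = k)
    expect_equal(wss(fit) + deltaSSQ(fit), totalSSQ(blobs$data),
                 tolerance = 1e-9)
  }
})

test_that("best of many seeds attains the exhaustive-partition optimum", {
  withr::with_seed(42, {
    x <- matrix(runif(9 * 2, 0, 10), ncol = 2)
  })
  opt <- best_partition_wss_oracle(x, 3)
  best <- min(vapply(1:200, function(s) wss(fitKmeans(x, 3, seed = s)),
                     numeric(1)))
  expect_equal(best, opt, tolerance = 1e-9)
})

test_that("row permutation with matching re-seed preserves wss", {
  blobs <- make_blobs(n_per = 20, sd = 0.8, seed = 12)
  x <- blobs$data
  init <- seedPrototypes(x, 2, seed = 31)
  fit1 <- fitKmeans(x, 2, init = init)
  perm <- withr::with_seed(7, sample.int(nrow(x)))
  fit2 <- fitKmeans(x[perm, ], 2, init = init)
  expect_equal(wss(fit2), wss(fit1), tolerance = 1e-9)
})

test_that("clusters emptied during batch updates are re-seeded, keeping k", {
  # two far groups plus an init that strands one prototype with no members
  x <- withr::with_seed(2, rbind(matrix(rnorm(40, 0, 0.2), ncol = 2),
                                 matrix(rnorm(40, 10, 0.2), ncol = 2)))
  init <- rbind(c(0, 0), c(10, 10), c(100, 100))
  fit <- fitKmeans(x, 3, init = init)
  expect_setequal(unique(clusterLabels(fit)), 1:3)
})

test_that("refined solutions are at least as good as batch-only Lloyd", {
  blobs <- make_blobs(n_per = 40, centers = rbind(c(0, 0), c(2, 2),
                                                  c(4, 0)), sd = 1.1,
                      seed = 21)
  for (s in 1:5) {
    init <- seedPrototypes(blobs$data, 3, seed = s)
    ours <- fitKmeans(blobs$data, 3, init = init)
    lloyd <- suppressWarnings(
      stats::kmeans(blobs$data, centers = init, iter.max = 300,
                    algorithm = "Lloyd"))
    expect_lte(wss(ours), lloyd$tot.withinss + 1e-9)
  }
})

test_that("solutions survive a JSON round trip", {
  blobs <- make_blobs(seed = 5)
  fit <- fitKmeans(blobs$data, 2, seed = 3)
  path <- withr::local_tempfile(fileext = ".json")
  solutionToJSON(fit, path)
  back <- solutionFromJSON(path)
  expect_identical(clusterLabels(back), clusterLabels(fit))
  expect_equal(prototypes(back), prototypes(fit), ignore_attr = TRUE)
  expect_equal(wss(back), wss(fit))
  expect_equal(runSeed(back), runSeed(fit))
})
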