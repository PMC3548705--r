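test_that("ensembles are seed-deterministic and ordered by run", {
  blobs <- make_blobs(n_per = 10, sd = 1, seed = 4)
  cfg <- secoConfig(kRange = 2, nTotal = 3, fractionF = 1, masterSeed = 7)
  ens1 <- runEnsemble(blobs$data, 2, cfg)
  ens2 <- runEnsemble(blobs$data, 2, cfg)
  expect_length(ens1, 3)
  expect_equal(vapply(ens1, runSeed, 1L), 8:10)
  expect_equal(vapply(ens1, deltaSSQ, numeric(1)),
               vapply(ens2, deltaSSQ, numeric(1)))
  expect_identical(lapply(ens1, clusterLabels),
                   lapply(ens2, clusterLabels))
})

test_that("top-fraction retention ranks by separation with stable ties", {
  blobs <- make_blobs(n_per = 15, sd = 2, seed = 6)
  cfg <- secoConfig(kRange = 3, nTotal = 20, fractionF = 0.5,
                    masterSeed = 1)
  ens <- runEnsemble(blobs$data, 3, cfg)
  kept <- selectTopFraction(ens, 0.5)
  expect_length(kept, 10)
  kept_d <- vapply(kept, deltaSSQ, numeric(1))
  all_d <- vapply(ens, deltaSSQ, numeric(1))
  # threshold correctness: worst retained >= best discarded
  expect_gte(min(kept_d), max(all_d[!seq_along(ens) %in%
                                      vapply(kept, function(s) s@runId, 1L)]))
  expect_true(all(diff(kept_d) <= 0))
  # f = 1 keeps everything, in deltaSSQ order
  expect_length(selectTopFraction(ens, 1), 20)
  expect_error(selectTopFraction(ens, 0.05), "at least 2")
  # exact ties at the cut go to the lower run index
  tie <- ens[1:4]
  for (i in seq_along(tie)) {
    tie[[i]]@deltaSSQ <- 5
    tie[[i]]@wss <- tie[[i]]@totalSSQ - 5
    tie[[i]]@runId <- i
  }
  expect_equal(vapply(selectTopFraction(tie, 0.5),
                      function(s) s@runId, 1L), 1:2)
})

test_that("a clean two-blob map is perfectly concordant", {
  blobs <- make_blobs(n_per = 20, sd = 0.3, seed = 2)
  map <- buildSeCoMap(blobs$data,
                      secoConfig(kRange = 2, nTotal = 20, fractionF = 0.5,
                                 masterSeed = 3))
  pts <- secoPoints(map)
  expect_equal(nrow(pts), 10)
  expect_equal(pts$medCV, rep(1, 10))
  expect_true(all(pts$k == 2))
})

test_that("the full pipeline is deterministic end to end", {
  blobs <- make_blobs(n_per = 15, centers = rbind(c(0, 0), c(4, 1),
                                                  c(2, 5)), sd = 1,
                      seed = 13)
  cfg <- secoConfig(kRange = 2:4, nTotal = 12, fractionF = 0.5,
                    masterSeed = 99)
  map1 <- buildSeCoMap(blobs$data, cfg)
  map2 <- buildSeCoMap(blobs$data, cfg)
  expect_equal(secoPoints(map1), secoPoints(map2))
  sel1 <- selectSolution(map1, 3)
  sel2 <- selectSolution(map2, 3)
  expect_identical(clusterLabels(sel1), clusterLabels(sel2))
})

test_that("dual-measure selection applies its tie rules in order", {
  mk <- function(medCV, deltaSSQ, runId) {
    data.frame(k = 3, runId = runId, seed = runId, deltaSSQ = deltaSSQ,
               medCV = medCV)
  }
  pts <- rbind(mk(0.9, 5, 1), mk(0.99, 3, 2), mk(0.99, 4, 3))
  sols <- list(`3:1` = "a", `3:2` = "b", `3:3` = "c")
  map <- methods::new("SeCoMap", points = pts, solutions = sols,
                      config = secoConfig(kRange = 3, nTotal = 10,
                                          masterSeed = 0, fractionF = 0.3),
                      fingerprint = list())
  # highest medCV wins; among the 0.99 pair the larger deltaSSQ wins
  expect_identical(selectSolution(map, 3), "c")
  # reordering the points changes nothing
  map@points <- pts[c(3, 1, 2), ]
  expect_identical(selectSolution(map, 3), "c")
  # all medCV equal reduces to separation-only selection
  pts2 <- rbind(mk(0.5, 5, 1), mk(0.5, 3, 2), mk(0.5, 4, 3))
  map@points <- pts2
  expect_identical(selectSolution(map, 3), "a")
})

test_that("separation-only selection minimises wss with run-order ties", {
  blobs <- make_blobs(n_per = 10, sd = 1.5, seed = 17)
  cfg <- secoConfig(kRange = 2, nTotal = 8, fractionF = 0.5,
                    masterSeed = 40)
  ens <- runEnsemble(blobs$data, 2, cfg)
  best <- selectSolutionSSQ(ens)
  expect_equal(wss(best), min(vapply(ens, wss, numeric(1))))
  expect_identical(selectSolutionSSQ(ens[3]), ens[[3]])
})

test_that("tightening the retained fraction does not destabilise the map", {
  # trend check on moderate benchmark samples: the minimum med(CV) of the
  # retained set should not decrease on average as f tightens 0.7 -> 0.1
  sam <- sampleMixture(benchmarkMixture(), 2000, seed = 55)
  fractions <- c(0.7, 0.3, 0.1)
  min_med <- matrix(NA_real_, 5, length(fractions))
  for (s in 1:5) {
    for (k in c(8, 10)) {
      ens <- runEnsemble(sam$data, k,
                         secoConfig(kRange = k, nTotal = 60,
                                    masterSeed = 1000 * s + k))
      for (fi in seq_along(fractions)) {
        kept <- selectTopFraction(ens, fractions[fi])
        m <- min(medianPairwiseConcordance(kept))
        min_med[s, fi] <- min(min_med[s, fi], m, na.rm = TRUE)
      }
    }
  }
  avg <- colMeans(min_med)
  expect_true(all(diff(avg) >= -1e-9))
})
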