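test_that("the paired t map matches the textbook statistic", {
  set.seed(60)
  a <- array(rnorm(5 * 3 * 4), c(5, 3, 4))
  b <- array(rnorm(5 * 3 * 4), c(5, 3, 4))
  tm <- pairedTMap(a, b)
  for (ch in 1:3) for (tb in 1:4) {
    ref <- t.test(a[, ch, tb], b[, ch, tb], paired = TRUE)$statistic
    expect_equal(tm@t[ch, tb], unname(ref), tolerance = 1e-12)
  }
  expect_equal(tm@df, 4)
})

test_that("degenerate paired differences yield zero t with a warning", {
  a <- array(1, c(4, 2, 2)); b <- array(0, c(4, 2, 2))
  expect_warning(tm <- pairedTMap(a, b), "zero-variance")
  expect_true(all(tm@t == 0))
  expect_warning(tm2 <- pairedTMap(a, a), "zero-variance")
  expect_true(all(tm2@t == 0))
})

test_that("chain-graph clustering matches the hand enumeration", {
  adj <- chainAdjacency(5)
  tm <- matrix(0, 5, 4)
  tm[1, 1] <- 3; tm[2, 1] <- 3.5; tm[2, 2] <- 2.8; tm[4, 3] <- 3.2
  cl <- formClusters(tm, adj, minNeighbors = 0, df = 10)
  canon <- canonicalClusters(cl, 5)
  expect_length(canon, 2)
  expect_equal(canon[[1]]$lin, sort(c(1, 2, 7)))   # {A1, B1, B2}
  expect_equal(canon[[1]]$sumT, 3 + 3.5 + 2.8)
  expect_equal(canon[[2]]$lin, 14)                 # {D3}
  # with four required neighbors no chain sample survives
  expect_length(formClusters(tm, adj, minNeighbors = 4, df = 10), 0)
  # subthreshold map forms no clusters
  expect_length(formClusters(matrix(0.5, 5, 4), adj, minNeighbors = 0,
                             df = 10), 0)
})

test_that("cluster forming matches a brute-force graph oracle exactly", {
  skip_if_not_installed("igraph")
  set.seed(61)
  adjs <- list(chainAdjacency(6), sensorAdjacency(sensorLayout(6), k = 2))
  tcrit <- qt(1 - 0.05 / 2, 9)
  for (rep_ in 1:200) {
    adj <- adjs[[(rep_ %% 2) + 1]]
    nCh <- 6; nT <- sample(2:5, 1)
    tm <- matrix(rnorm(nCh * nT, sd = 1.8), nCh, nT)
    for (minNb in c(0, 2)) {
      got <- canonicalClusters(
        formClusters(tm, adj, minNeighbors = minNb, df = 9), nCh)
      want <- canonicalClusters(
        bruteforceClusters(tm, adj, tcrit, minNeighbors = minNb), nCh)
      expect_identical(lapply(got, `[[`, "lin"), lapply(want, `[[`, "lin"))
      expect_equal(lapply(got, `[[`, "sumT"), lapply(want, `[[`, "sumT"))
    }
  }
})

test_that("Monte-Carlo p values are the plain proportion of extremes", {
  arr <- nullArrays(62, 8, 10, 12)
  arr$a[, 1:4, 5:9] <- arr$a[, 1:4, 5:9] + 2
  adj <- sensorAdjacency(sensorLayout(10), k = 4)
  res <- clusterPermutationTest(arr$a, arr$b, adj, nPermutations = 300,
                                seed = 7, minNeighbors = 0)
  for (cl in clusters(res)) {
    manual <- if (cl$sign > 0) mean(res@maxDistribution >= cl$sumT)
              else mean(res@minDistribution <= cl$sumT)
    expect_equal(cl$p, manual, tolerance = 1e-12)
  }
  resPlus <- clusterPermutationTest(arr$a, arr$b, adj, nPermutations = 300,
                                    seed = 7, minNeighbors = 0,
                                    plusOne = TRUE)
  cl1 <- clusters(resPlus)[[1]]
  manual1 <- if (cl1$sign > 0) (sum(resPlus@maxDistribution >= cl1$sumT) + 1) / 301
             else (sum(resPlus@minDistribution <= cl1$sumT) + 1) / 301
  expect_equal(cl1$p, manual1, tolerance = 1e-12)
})

test_that("a planted effect is detected with matching sign and location", {
  arr <- nullArrays(63, 10, 12, 15)
  adj <- sensorAdjacency(sensorLayout(12), k = 4)
  arr$a[, 1:5, 6:12] <- arr$a[, 1:5, 6:12] - 2.5
  res <- clusterPermutationTest(arr$a, arr$b, adj, nPermutations = 400,
                                seed = 8, minNeighbors = 0)
  lead <- clusters(res)[[1]]
  expect_equal(lead$sign, -1L)
  expect_true(lead$significant)
  expect_lt(lead$p, 0.025)
  expect_lt(lead$cohenD, 0)
  expect_true(any(lead$members[, "channel"] %in% 1:5))
})

test_that("the permutation test is deterministic and exchangeable", {
  arr <- nullArrays(64, 6, 8, 10)
  adj <- sensorAdjacency(sensorLayout(8), k = 3)
  r1 <- clusterPermutationTest(arr$a, arr$b, adj, nPermutations = 200,
                               seed = 5, minNeighbors = 0)
  r2 <- clusterPermutationTest(arr$a, arr$b, adj, nPermutations = 200,
                               seed = 5, minNeighbors = 0)
  expect_identical(r1@maxDistribution, r2@maxDistribution)
  expect_identical(lapply(clusters(r1), `[[`, "sumT"),
                   lapply(clusters(r2), `[[`, "sumT"))
  # permuting the subject order leaves the observed clusters unchanged
  ord <- c(3, 1, 6, 2, 5, 4)
  r3 <- clusterPermutationTest(arr$a[ord, , ], arr$b[ord, , ], adj,
                               nPermutations = 200, seed = 5,
                               minNeighbors = 0)
  expect_equal(canonicalClusters(clusters(r1), 8),
               canonicalClusters(clusters(r3), 8))
})

test_that("input contracts are enforced", {
  adj <- sensorAdjacency(sensorLayout(4), k = 2)
  a <- array(rnorm(2 * 4 * 3), c(2, 4, 3))
  expect_error(clusterPermutationTest(a[1, , , drop = FALSE],
                                      a[1, , , drop = FALSE], adj,
                                      nPermutations = 100), "2 subjects")
  expect_error(clusterPermutationTest(a, a, adj, nPermutations = 10),
               "nPermutations")
  expect_error(formClusters(matrix(0, 6, 3), adj, df = 5), "cover")
})

test_that("adjacency structures are symmetric, loop-free and serializable", {
  adj <- sensorAdjacency(sensorLayout(20), k = 5)
  nb <- neighborList(adj)
  labs <- channelLabels(adj)
  for (ch in labs) {
    expect_false(ch %in% nb[[ch]])
    for (other in nb[[ch]]) expect_true(ch %in% nb[[other]])
  }
  f <- file.path(tempdir(), "adj.json")
  writeAdjacency(adj, f)
  back <- readAdjacency(f)
  expect_identical(neighborList(back), nb)
  unlink(f)
  expect_error(adjacencyFromList(list(A = "B", B = "C", C = "B")),
               "symmetric")
})
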