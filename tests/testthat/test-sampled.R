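test_that("sampling the worked example finds both attractors with unbiased sizes", {
  F <- network(fixtureF())
  set.seed(901)
  sd1 <- sampleDecomposition(F, q = 1000)
  expect_length(attractors(sd1), 2L)
  keys <- vapply(attractors(sd1), canonicalKey, character(1))
  est <- hits(sd1) / 1000
  truth <- c("100" = 5 / 8, "110" = 3 / 8)[keys]
  se <- sqrt(truth * (1 - truth) / 1000)
  expect_true(all(abs(est - truth) < 5 * se))
})

test_that("degenerate sampling cases behave", {
  onePoint <- BooleanNetwork(list(c(0, 1), c(1, 0)), list(2, 1))  # 4-cycle
  set.seed(902)
  sdA <- sampleDecomposition(onePoint, q = 50)
  expect_length(attractors(sdA), 1L)
  expect_equal(hits(sdA) / 50, 1)
  expect_equal(sampledBasinCoherence(onePoint, sdA, 1), 1)
  expect_equal(exactAttractorCoherence(onePoint, sdA, 1), 1)
  sdB <- sampleDecomposition(network(fixtureG()), q = 1)
  expect_length(attractors(sdB), 1L)
  expect_equal(hits(sdB), 1L)
  expect_error(sampleDecomposition(onePoint, q = 0), ">= 1")
})

test_that("sampled basin coherence estimates converge to the exhaustive value", {
  F <- network(fixtureF())
  set.seed(903)
  sd1 <- sampleDecomposition(F, q = 600)
  i100 <- match("100", vapply(attractors(sd1), canonicalKey, character(1)))
  est <- sampledBasinCoherence(F, sd1, i100)
  se <- sqrt(2 / 3 * (1 / 3) / hits(sd1)[i100])
  expect_lt(abs(est - 2 / 3), 5 * se)
  G <- network(fixtureG())
  sdG <- sampleDecomposition(G, q = 600)
  i111 <- match("111", vapply(attractors(sdG), canonicalKey, character(1)))
  expect_lt(abs(sampledBasinCoherence(G, sdG, i111) - 4 / 9), 0.15)
})

test_that("attractor coherence from sampling is exact, not estimated", {
  G <- network(fixtureG())
  set.seed(904)
  sdG <- sampleDecomposition(G, q = 40)
  keys <- vapply(attractors(sdG), canonicalKey, character(1))
  expect_equal(exactAttractorCoherence(G, sdG, match("111", keys)), 2 / 3)
  expect_equal(exactAttractorCoherence(G, sdG, match("000", keys)), 1)
  F <- network(fixtureF())
  sdF <- sampleDecomposition(F, q = 40)
  kF <- vapply(attractors(sdF), canonicalKey, character(1))
  expect_equal(exactAttractorCoherence(F, sdF, match("100", kF)), 1 / 3)
  # random networks: sampled-exact equals exhaustive for every attractor found
  for (net in randomTestNetworks(5, nNodes = 7, inDegree = 2, seed = 905)) {
    d <- basinDecomposition(net)
    sdN <- sampleDecomposition(net, q = 150)
    for (i in seq_along(attractors(sdN))) {
      key <- canonicalKey(attractors(sdN)[[i]])
      expect_equal(exactAttractorCoherence(net, sdN, i),
                   attractorCoherence(net, d, key), tolerance = 1e-12)
    }
  }
})

test_that("sampled size estimates track the exhaustive decomposition", {
  set.seed(906)
  for (net in randomTestNetworks(4, nNodes = 8, inDegree = 2, seed = 907)) {
    d <- basinDecomposition(net)
    truthByKey <- stats::setNames(basinSizes(d) / 2^nNodes(net),
                                  vapply(attractors(d), canonicalKey,
                                         character(1)))
    q <- 800
    sdN <- sampleDecomposition(net, q = q)
    for (i in seq_along(attractors(sdN))) {
      s <- truthByKey[[canonicalKey(attractors(sdN)[[i]])]]
      expect_lt(abs(hits(sdN)[i] / q - s), 5 * sqrt(s * (1 - s) / q) + 1e-9)
    }
  }
})

test_that("sampled records mirror the exhaustive record layout", {
  F <- network(fixtureF())
  set.seed(908)
  sdF <- sampleDecomposition(F, q = 300)
  rec <- sampledRecords(F, sdF, networkId = "F")
  expect_equal(nrow(rec), 2L)
  expect_false(any(rec$exact_flag))
  expect_setequal(rec$attractor_key, c("100", "110"))
  expect_equal(sum(rec$relative_basin_size), 1)
})

test_that("detection probability follows 1 - (1 - b)^q", {
  expect_equal(100 * detectionProbability(0.01, 1000), 99.996, tolerance = 5e-4)
  expect_equal(detectionProbability(1, 17), 1)
  expect_equal(detectionProbability(0.5, 1), 0.5)
  expect_error(detectionProbability(0, 10), "\\(0, 1\\]")
  expect_error(detectionProbability(1.2, 10), "\\(0, 1\\]")
})

test_that("discovery frequency of a small basin matches the detection formula", {
  F <- network(fixtureF())     # the 110 attractor holds b = 3/8 of the space
  q <- 2L
  pTheory <- detectionProbability(3 / 8, q)
  set.seed(909)
  reps <- 400
  foundCount <- 0L
  for (r in seq_len(reps)) {
    sdF <- sampleDecomposition(F, q = q)
    keys <- vapply(attractors(sdF), canonicalKey, character(1))
    foundCount <- foundCount + ("110" %in% keys)
  }
  se <- sqrt(pTheory * (1 - pTheory) / reps)
  expect_lt(abs(foundCount / reps - pTheory), 4 * se)
})
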