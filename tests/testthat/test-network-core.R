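test_that("synchronous steps of the worked examples match hand evaluation", {
  F <- network(fixtureF())
  expect_equal(synchronousStep(F, "000"), c(0L, 0L, 1L))
  expect_equal(synchronousStep(F, "100"), c(1L, 0L, 0L))  # fixed point
  G <- network(fixtureG())
  expect_equal(synchronousStep(G, "110"), c(1L, 1L, 1L))
  expect_equal(synchronousStep(G, "111"), c(1L, 1L, 1L))  # fixed point
  expect_error(synchronousStep(F, c(0, 1)), "length N")
})

test_that("exhaustive decomposition reproduces the worked examples", {
  dF <- basinDecomposition(network(fixtureF()))
  expect_equal(vapply(attractors(dF), canonicalKey, character(1)),
               c("100", "110"))
  expect_equal(basinSizes(dF), c(5, 3))
  expect_true(all(vapply(attractors(dF), period, integer(1)) == 1L))
  dG <- basinDecomposition(network(fixtureG()))
  expect_equal(vapply(attractors(dG), canonicalKey, character(1)),
               c("000", "111"))
  expect_equal(basinSizes(dG), c(5, 3))
})

test_that("the 1-node negation network has one period-2 attractor", {
  net <- BooleanNetwork(list(c(1, 0)), list(1))
  d <- basinDecomposition(net)
  expect_length(attractors(d), 1L)
  expect_equal(period(attractors(d)[[1]]), 2L)
  expect_equal(basinSizes(d), 2)
})

test_that("attractor cycles advance correctly and basins cover the space", {
  for (net in randomTestNetworks(6, nNodes = 6, inDegree = 2, seed = 401)) {
    d <- basinDecomposition(net)
    expect_equal(sum(basinSizes(d)), 2^nNodes(net))
    for (a in attractors(d)) {
      sts <- attractorStates(a)
      for (r in seq_len(nrow(sts))) {
        nxt <- synchronousStep(net, sts[r, ])
        expect_equal(nxt, sts[(r %% nrow(sts)) + 1L, ])
      }
    }
  }
})

test_that("decomposition agrees with a naive per-trajectory oracle", {
  for (net in randomTestNetworks(8, nNodes = 5, inDegree = 2, seed = 402)) {
    d <- basinDecomposition(net)
    o <- naiveDecomposition(net)
    expect_equal(length(attractors(d)), length(o$cycles))
    expect_equal(sort(basinSizes(d)), sort(o$basinSizes))
    # same partition of states, up to attractor relabelling
    expect_equal(length(unique(paste(assignment(d), o$assignment))),
                 length(attractors(d)))
  }
})

test_that("rebuilding a decomposition is deterministic", {
  net <- randomTestNetworks(1, nNodes = 8, inDegree = 3, seed = 403)[[1]]
  d1 <- basinDecomposition(net)
  d2 <- basinDecomposition(net)
  expect_identical(assignment(d1), assignment(d2))
  expect_identical(basinSizes(d1), basinSizes(d2))
})

test_that("node relabelling preserves attractor count and basin-size multiset", {
  net <- randomTestNetworks(1, nNodes = 6, inDegree = 2, seed = 404)[[1]]
  d <- basinDecomposition(net)
  perm <- c(3L, 1L, 6L, 2L, 5L, 4L)      # new position of each old node
  inv <- order(perm)
  permNet <- BooleanNetwork(rules(net)[inv],
                            lapply(regulators(net)[inv],
                                   function(r) perm[r]))
  dp <- basinDecomposition(permNet)
  expect_equal(length(attractors(dp)), length(attractors(d)))
  expect_equal(sort(basinSizes(dp)), sort(basinSizes(d)))
})

test_that("networks above the exhaustive limit are redirected to sampling", {
  net <- randomTestNetworks(1, nNodes = 6, inDegree = 2, seed = 405)[[1]]
  expect_error(basinDecomposition(net, maxNodes = 5),
               "sampleDecomposition")
})

test_that("strong connectivity matches the igraph oracle", {
  ring <- BooleanNetwork(list(c(0, 1), c(0, 1), c(0, 1)),
                         list(3, 1, 2))
  expect_true(isStronglyConnected(ring))
  oneWay <- BooleanNetwork(list(c(0, 1), c(0, 1)), list(1, 1))
  expect_false(isStronglyConnected(oneWay))
  F <- network(fixtureF())                # complete wiring
  expect_true(isStronglyConnected(F))
  set.seed(406)
  for (i in 1:25) {
    net <- randomNetwork(6, 2, requireStrongConnectivity = FALSE,
                         allowSelfInputs = TRUE)
    edges <- do.call(rbind, lapply(seq_len(nNodes(net)), function(j)
      cbind(regulators(net)[[j]], j)))
    g <- igraph::graph_from_edgelist(edges, directed = TRUE)
    expect_equal(isStronglyConnected(net),
                 igraph::is_connected(g, mode = "strong"))
  }
})

test_that("rule files round-trip through read and write", {
  F <- network(fixtureF())
  path <- tempfile(fileext = ".bnet")
  on.exit(unlink(path))
  writeBooleanNetwork(F, path)
  back <- readBooleanNetwork(path)
  expect_identical(nodeNames(back), nodeNames(F))
  for (m in 0:7)
    expect_equal(synchronousStep(back, m), synchronousStep(F, m))
  # NODE = EXPR dialect with keywords
  net <- readBooleanNetwork(text = c("a = a OR b", "b = NOT a AND b"))
  expect_equal(regulators(net), list(c(1L, 2L), c(1L, 2L)))
  expect_equal(synchronousStep(net, c(1, 0)), c(1L, 0L))
  expect_error(readBooleanNetwork(text = "a, a | q"), "undefined node")
})
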