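# printed stratification of the 5-input NCFs by layer structure
table5 <- list(
  list(L = c(5),          w = 31, a = 15 / 16, zeta = 0.0303, S = 0.3125),
  list(L = c(3, 2),       w = 29, a = 13 / 16, zeta = 0.0850, S = 0.6875),
  list(L = c(2, 1, 2),    w = 27, a = 11 / 16, zeta = 0.1318, S = 0.9375),
  list(L = c(2, 3),       w = 25, a = 9 / 16,  zeta = 0.1709, S = 1.0625),
  list(L = c(1, 1, 3),    w = 23, a = 7 / 16,  zeta = 0.2021, S = 1.1875),
  list(L = c(1, 1, 1, 2), w = 21, a = 5 / 16,  zeta = 0.2256, S = 1.3125),
  list(L = c(1, 2, 2),    w = 19, a = 3 / 16,  zeta = 0.2412, S = 1.3125),
  list(L = c(1, 4),       w = 17, a = 1 / 16,  zeta = 0.2490, S = 1.1875))

test_that("canonical 5-input NCFs reproduce the printed bias and sensitivity table", {
  for (row in table5) {
    f <- canonicalNCF(row$L)
    b <- biasProfile(f)
    expect_equal(hammingWeight(f), row$w)
    expect_equal(unname(b["absBias"]), row$a)
    expect_equal(round(unname(b["stdBias"]), 4), row$zeta)
    expect_equal(averageSensitivity(f), row$S)
    expect_equal(layers(layerStructure(f)), as.integer(row$L))
  }
})

test_that("bias identities hold: 4*zeta = 1 - a^2 and the OR5 profile", {
  b <- biasProfile(canonicalNCF(c(5)))
  expect_equal(unname(b["p"]), 31 / 32)
  expect_equal(unname(b["absBias"]), 15 / 16)
  set.seed(601)
  for (i in 1:50) {
    f <- randomNondegenerateFunction(sample(1:5, 1))
    b <- biasProfile(f)
    expect_equal(4 * b[["stdBias"]], 1 - b[["absBias"]]^2, tolerance = 1e-12)
  }
  b1 <- biasProfile(BooleanFunction(c(0, 1)))   # 1-input identity
  expect_equal(unname(b1), c(0.5, 0, 0.25))
})

test_that("average sensitivity matches brute force and rejects arity 0", {
  and2 <- BooleanFunction(c(0, 0, 0, 1))
  expect_equal(averageSensitivity(and2), 1)
  expect_error(averageSensitivity(BooleanFunction(1)), "arity-0")
  # brute force over all inputs x flips on random functions
  set.seed(602)
  for (i in 1:10) {
    k <- sample(2:4, 1)
    f <- randomNondegenerateFunction(k)
    grid <- as.matrix(expand.grid(rep(list(0:1), k)))[, k:1, drop = FALSE]
    brute <- mean(apply(grid, 1, function(x)
      sum(vapply(seq_len(k), function(i2) {
        y <- x; y[i2] <- 1 - y[i2]
        evaluate(f, x) != evaluate(f, y)
      }, logical(1)))))
    expect_equal(averageSensitivity(f), brute)
  }
})

test_that("canalizing variables match the textbook examples and a brute-force oracle", {
  and3 <- BooleanFunction(c(0, 0, 0, 0, 0, 0, 0, 1))
  cv <- canalizingVariables(and3)
  expect_equal(sort(unique(cv$position)), 1:3)
  expect_true(all(cv$canalizingInput == 0L & cv$canalizedOutput == 0L))
  g <- BooleanFunction(c(0, 0, 0, 0, 0, 1, 1, 1))      # x & (y | z)
  cvg <- canalizingVariables(g)
  expect_equal(unique(cvg$position), 1L)
  expect_equal(nrow(canalizingVariables(BooleanFunction(c(0, 1, 1, 0)))), 0L)
  expect_error(canalizingVariables(BooleanFunction(c(1, 1, 1, 1))), "constant")
  set.seed(603)
  for (i in 1:25) {
    k <- sample(2:4, 1)
    f <- randomNondegenerateFunction(k)
    got <- as.matrix(canalizingVariables(f))
    dimnames(got) <- NULL
    want <- naiveCanalizingTriples(f)
    if (is.null(want)) expect_equal(nrow(got), 0L)
    else expect_equal(got[order(got[, 1], got[, 2]), , drop = FALSE],
                      want[order(want[, 1], want[, 2]), , drop = FALSE])
  }
})

test_that("layer structures follow the iterative peeling definition", {
  expect_equal(layers(layerStructure(BooleanFunction(c(0, 0, 0, 0, 0, 0, 0, 1)))),
               3L)                                      # x & y & z
  expect_equal(layers(layerStructure(BooleanFunction(c(0, 0, 0, 0, 0, 1, 1, 1)))),
               c(1L, 2L))                               # x & (y | z)
  xor2 <- layerStructure(BooleanFunction(c(0, 1, 1, 0)))
  expect_equal(layers(xor2), integer(0))
  expect_equal(canalizingDepth(xor2), 0L)
  expect_false(isNCF(xor2))
  expect_error(layerStructure(BooleanFunction(c(0, 0, 1, 1, 1, 1, 1, 1))),
               "essential")
})

test_that("layer-structure enumeration counts 2^(n-2) compositions", {
  expect_equal(enumerateLayerStructures(3), list(3L, c(1L, 2L)))
  expect_equal(length(enumerateLayerStructures(2)), 1L)
  for (n in 2:7) {
    ls <- enumerateLayerStructures(n)
    expect_length(ls, 2^(n - 2))
    expect_true(all(vapply(ls, function(L)
      sum(L) == n && L[length(L)] >= 2, logical(1))))
    expect_false(anyDuplicated(vapply(ls, paste, character(1),
                                      collapse = "-")) > 0)
  }
  expect_error(enumerateLayerStructures(1), ">= 2")
})

test_that("canonical NCFs invert through the peeling algorithm for n = 2..7", {
  for (n in 2:7) for (L in enumerateLayerStructures(n)) {
    f <- canonicalNCF(L, n)
    ls <- layerStructure(f)
    expect_equal(layers(ls), as.integer(L))
    expect_true(isNCF(ls))
  }
  expect_equal(truthTable(canonicalNCF(c(2))), c(0L, 1L, 1L, 1L))  # A | B
  expect_error(canonicalNCF(c(2, 1)), "final layer")
  expect_error(canonicalNCF(c(1, 2), n = 4), "composition")
})

test_that("NCFs sharing a layer structure share absolute bias and sensitivity", {
  set.seed(604)
  for (n in 3:5) for (L in enumerateLayerStructures(n)) {
    ref <- functionProfile(canonicalNCF(L, n))
    for (i in 1:20) {
      f <- randomNCFWithLayerStructure(L)
      b <- biasProfile(f)
      expect_equal(unname(b["absBias"]), ref$abs_bias)
      expect_equal(averageSensitivity(f), ref$sensitivity)
    }
  }
})

test_that("function profiles serialise the expected columns", {
  pr <- functionProfile(canonicalNCF(c(1, 4)))
  expect_equal(pr$layer_structure, "1-4")
  expect_equal(pr$depth, 5L)
  expect_true(pr$is_ncf)
  prDeg <- functionProfile(BooleanFunction(c(0, 0, 1, 1)))  # degenerate
  expect_true(is.na(prDeg$layer_structure))
})
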