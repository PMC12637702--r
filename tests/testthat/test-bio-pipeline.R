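test_that("source nodes are identified: self-copies and constants", {
  chain <- readBooleanNetwork(text = c("s, s", "a, s & b", "b, a"))
  expect_equal(findSourceNodes(chain), 1L)
  expect_equal(findSourceNodes(network(fixtureF())), integer(0))
  expect_equal(findSourceNodes(network(fixtureG())), integer(0))
  withConst <- readBooleanNetwork(text = c("c, 1", "a, c | b", "b, a"))
  expect_equal(findSourceNodes(withConst), 1L)
})

test_that("fixing sources propagates constants and drops inessential inputs", {
  net <- readBooleanNetwork(text = c("s, s", "a, s & b", "b, !a"))
  hi <- reducedNetwork(fixSources(net, 1))
  expect_equal(nodeNames(hi), c("a", "b"))
  expect_equal(truthTable(rules(hi)[[1]]), c(0L, 1L))     # a = b
  lo <- reducedNetwork(fixSources(net, 0))
  expect_equal(arity(rules(lo)[[1]]), 0L)                 # a = 0 constant
  expect_equal(truthTable(rules(lo)[[1]]), 0L)
  expect_error(fixSources(net, c(0, 1)), "one bit")
})

test_that("reduced dynamics equal the full dynamics on non-source coordinates", {
  set.seed(1001)
  cohort <- syntheticCohort(3, sizeRange = c(4, 5), inDegree = 2,
                            nSources = 2)
  for (net in cohort) {
    src <- findSourceNodes(net)
    expect_length(src, 2L)
    nonSrc <- setdiff(seq_len(nNodes(net)), src)
    for (cfg in list(c(0L, 0L), c(1L, 0L), c(1L, 1L))) {
      red <- reducedNetwork(fixSources(net, cfg))
      full <- integer(nNodes(net))
      full[src] <- cfg
      start <- sample(c(0L, 1L), length(nonSrc), replace = TRUE)
      full[nonSrc] <- start
      x <- start
      for (t in 1:12) {
        x <- synchronousStep(red, x)
        full <- synchronousStep(net, full)
        expect_equal(x, full[nonSrc])
        expect_equal(full[src], cfg)    # sources really are constant
      }
    }
  }
})

test_that("null models preserve wiring and non-degeneracy", {
  set.seed(1002)
  net <- randomNetwork(7, 2)
  nulls <- nullModels(net, 20)
  for (nm in nulls) {
    expect_identical(regulators(nm), regulators(net))
    expect_identical(lengths(regulators(nm)), lengths(regulators(net)))
    expect_true(all(vapply(rules(nm), isNonDegenerate, logical(1))))
  }
  # rules do vary across nulls
  tts <- vapply(nulls, function(nm) paste(unlist(lapply(rules(nm), truthTable)),
                                          collapse = ""), character(1))
  expect_gt(length(unique(tts)), 1L)
})

test_that("a planted biological-vs-null coherence shift is detected", {
  set.seed(1003)
  cohort <- syntheticCohort(12, sizeRange = c(12, 12), inDegree = 3,
                            ruleClass = "ncf")
  cmp <- pairedStabilityComparison(cohort, R = 8)
  expect_gt(mean(cmp@perModel$difference), 0)
  expect_lt(cmp@pairedP, 0.01)
  expect_equal(nrow(cmp@perModel), 12L)
})

test_that("identical biological and null coherences give a null result", {
  fake <- new("NullModelComparison",
              perModel = data.frame(model = 1:5, coherence_bio = rep(0.7, 5),
                                    coherence_null_mean = rep(0.7, 5),
                                    difference = rep(0, 5)),
              shapiroP = NA_real_, pairedP = 0.5, signP = NA_real_,
              nSignPairs = 0L)
  expect_gte(fake@pairedP, 0.5)
  # and through the real pipeline: exchangeable cohort, many repetitions
  # should reject at about the nominal rate
  set.seed(1004)
  reps <- 120
  rejections <- 0L
  for (r in seq_len(reps)) {
    cohort <- syntheticCohort(5, sizeRange = c(5, 5), inDegree = 2,
                              plantedEffect = 0)
    cmp <- pairedStabilityComparison(cohort, R = 4)
    rejections <- rejections + (cmp@pairedP < 0.05)
  }
  rate <- rejections / reps
  expect_lt(abs(rate - 0.05), 3 * sqrt(0.05 * 0.95 / reps) + 0.02)
})

test_that("sign-test tail probabilities match the binomial brute force", {
  set.seed(1005)
  cohort <- syntheticCohort(4, sizeRange = c(5, 6), inDegree = 2,
                            ruleClass = "ncf")
  cmp <- pairedStabilityComparison(cohort, R = 3)
  recs <- do.call(rbind, lapply(seq_along(cohort), function(j)
    attractorRecords(cohort[[j]], networkId = j)))
  dpsi <- recs$basin_coherence - recs$attractor_coherence
  nz <- dpsi[dpsi != 0]
  expect_equal(cmp@nSignPairs, length(nz))
  brute <- sum(stats::dbinom(sum(nz > 0):length(nz), length(nz), 0.5))
  expect_equal(cmp@signP, brute, tolerance = 1e-12)
  # the printed-style reference case: 8 positives out of 8 pairs
  expect_equal(stats::binom.test(8, 8, alternative = "greater")$p.value,
               1 / 256, tolerance = 1e-12)
  expect_error(pairedStabilityComparison(cohort[1:2], R = 2), "at least 3")
})

test_that("a directory of rule files is analysed end to end", {
  set.seed(1006)
  dir <- tempfile("models")
  dir.create(dir)
  on.exit(unlink(dir, recursive = TRUE))
  cohort <- syntheticCohort(4, sizeRange = c(5, 6), inDegree = 2,
                            ruleClass = "ncf")
  for (j in seq_along(cohort))
    writeBooleanNetwork(cohort[[j]], file.path(dir, paste0("m", j, ".bnet")))
  out <- analyzeModelDirectory(dir, R = 3)
  expect_equal(nrow(out$manifest), 4L)
  expect_true(all(out$manifest$analysis == "exact"))
  expect_s4_class(out$comparison, "NullModelComparison")
})
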