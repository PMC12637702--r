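# Worked-example fixtures and synthetic model cohorts. The two 3-node
# networks F and G have identical basin structure (fixed-point basins of
# sizes 5 and 3, basin coherences 2/3 and 4/9, network coherence 14/24) but
# sharply different attractor coherences (1/3 and 1/3 versus 1 and 2/3),
# which is exactly the distinction the coherence gap quantifies.

.fixture <- function(name, net, expected) {
  d <- basinDecomposition(net)
  keys <- vapply(attractors(d), canonicalKey, character(1))
  ord <- match(expected$attractors, keys)
  stopifnot(!anyNA(ord),
            identical(basinSizes(d)[ord], expected$basinSizes),
            all(abs(vapply(ord, function(i) basinCoherence(net, d, i),
                           numeric(1)) - expected$basinCoherence) < 1e-12),
            all(abs(vapply(ord, function(i) attractorCoherence(net, d, i),
                           numeric(1)) - expected$attractorCoherence) < 1e-12),
            abs(networkCoherence(net, d) - expected$networkCoherence) < 1e-12)
  new("Fixture", name = name, network = net, expected = expected)
}

#' Worked-example networks F and G
#'
#' Two 3-node networks with identical basin structure but different attractor
#' coherence. `fixtureF` uses rules
#' `(x1 | x2 | x3, x1 & (x2 | x3), !x1 & !x2 & !x3)`: its fixed points 100
#' and 110 both have attractor coherence 1/3. `fixtureG` uses
#' `(x1 & (x2 | x3), x1 & (x2 | x3), x1 | (x2 & x3))`: its fixed points 000
#' and 111 have attractor coherence 1 and 2/3. Both networks have basins of
#' sizes 5 and 3 with basin coherences 2/3 and 4/9 and network coherence
#' 14/24. The expected table is re-verified by exhaustive decomposition every
#' time the fixture is constructed.
#'
#' @return A [Fixture-class].
#' @examples
#' expectedValues(fixtureG())$attractorCoherence
#' @export
fixtureF <- function() {
  net <- readBooleanNetwork(text = c(
    "targets, factors",
    "x1, x1 | x2 | x3",
    "x2, x1 & (x2 | x3)",
    "x3, !x1 & !x2 & !x3"))
  .fixture("F", net, list(
    attractors = c("100", "110"),
    basinSizes = c(5, 3),
    basinCoherence = c(2 / 3, 4 / 9),
    attractorCoherence = c(1 / 3, 1 / 3),
    networkCoherence = 14 / 24))
}

#' @rdname fixtureF
#' @export
fixtureG <- function() {
  net <- readBooleanNetwork(text = c(
    "targets, factors",
    "x1, x1 & (x2 | x3)",
    "x2, x1 & (x2 | x3)",
    "x3, x1 | (x2 & x3)"))
  .fixture("G", net, list(
    attractors = c("000", "111"),
    basinSizes = c(5, 3),
    basinCoherence = c(2 / 3, 4 / 9),
    attractorCoherence = c(1, 2 / 3),
    networkCoherence = 14 / 24))
}

#' @describeIn fixtureF The fixture's [BooleanNetwork-class].
#' @param x A [Fixture-class].
#' @export
network <- function(x) x@network

#' @describeIn fixtureF The fixture's verified expected values.
#' @export
expectedValues <- function(x) x@expected

#' @export
setMethod("show", "Fixture", function(object) {
  cat(sprintf("Fixture %s: %d-node network, attractors %s\n", object@name,
              nNodes(object@network),
              paste(object@expected$attractors, collapse = ", ")))
})

#' Synthetic model cohort
#'
#' Generates random model cohorts for end-to-end pipeline tests without any
#' external download. `plantedEffect` controls the expected biological-vs-null
#' coherence shift: it is the per-rule probability of drawing a (coherence
#' enhancing) nested canalizing rule instead of a uniform non-degenerate one,
#' so 0 makes the cohort exchangeable with its null models and 1 gives fully
#' nested canalizing models. `nSources` self-copy source nodes can be
#' appended to exercise the fixed-source machinery.
#'
#' @param nModels Number of models.
#' @param sizeRange Inclusive range of (non-source) network sizes.
#' @param inDegree Regulators per non-source node.
#' @param ruleClass `"ncf"` or `"random"`; the cohort's base rule class when
#'   `plantedEffect` is not used.
#' @param plantedEffect Per-rule probability of an NCF rule (overrides
#'   `ruleClass` mixing; `NULL` uses `ruleClass` for every rule).
#' @param nSources Number of self-copy source nodes appended to each model.
#' @return List of [BooleanNetwork-class] objects.
#' @examples
#' set.seed(1); cohort <- syntheticCohort(3, c(5, 6))
#' @export
syntheticCohort <- function(nModels, sizeRange = c(6, 10), inDegree = 2L,
                            ruleClass = "random", plantedEffect = NULL,
                            nSources = 0L) {
  nModels <- .checkCount(nModels, "nModels")
  nSources <- .checkCount(nSources, "nSources", min = 0)
  lapply(seq_len(nModels), function(j) {
    nChoices <- seq.int(sizeRange[1], sizeRange[2])
    n <- nChoices[sample.int(length(nChoices), 1L)]
    regs <- randomWiring(n, inDegree)
    tts <- lapply(regs, function(r) {
      k <- length(r)
      useNCF <- if (is.null(plantedEffect)) ruleClass == "ncf"
                else stats::runif(1) < plantedEffect
      if (useNCF) .rndCanalizedTT(k, k) else .rndNondegTT(k)
    })
    if (nSources > 0L) {
      core <- n
      for (s in seq_len(nSources)) {
        idx <- core + s
        regs[[idx]] <- idx            # self-copy source
        tts[[idx]] <- c(0L, 1L)
        # wire the source into one random core rule (as its least significant
        # input, XOR-ed in) so that the fixed configuration matters
        tgt <- sample(core, 1L)
        regs[[tgt]] <- c(regs[[tgt]], idx)
        tt2 <- tts[[tgt]][rep(seq_along(tts[[tgt]]), each = 2L)]
        flip <- seq(2L, length(tt2), by = 2L)
        tt2[flip] <- 1L - tt2[flip]
        tts[[tgt]] <- tt2
      }
    }
    BooleanNetwork(tts, regs)
  })
}

#' Export fixtures as rule files with expected-value sidecars
#'
#' Writes every named fixture as a BoolNet-format `.bnet` file plus a JSON
#' sidecar of its verified expected values, exercising the reader/writer
#' round trip.
#'
#' @param dir Output directory (created if needed).
#' @return Invisibly, the written file paths.
#' @export
exportFixtures <- function(dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- character()
  for (fx in list(fixtureF(), fixtureG())) {
    bnet <- file.path(dir, paste0(fx@name, ".bnet"))
    writeBooleanNetwork(fx@network, bnet)
    side <- file.path(dir, paste0(fx@name, ".expected.json"))
    jsonlite::write_json(fx@expected, side, auto_unbox = TRUE, digits = NA)
    paths <- c(paths, bnet, side)
  }
  invisible(paths)
}
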