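# Pipeline for curated biological models: source-node fixing, matched random
# null models, and the cohort-level paired stability tests.

#' Source nodes of a network
#'
#' Source nodes are variables whose value never changes: self-copy nodes
#' (`x_i = x_i`) and nodes with no essential inputs (constant-carrying
#' zero-input rules). Holding the M source nodes fixed splits the full state
#' transition graph into 2^M independent subgraphs; analysing the reduced
#' fixed-source networks removes the artificial attractor inflation this
#' fragmentation causes.
#'
#' @param net A [BooleanNetwork-class].
#' @return Integer vector of source-node indices.
#' @examples
#' findSourceNodes(network(fixtureF()))  # none
#' @export
findSourceNodes <- function(net) {
  which(vapply(seq_len(nNodes(net)), function(i) {
    f <- net@rules[[i]]
    regs <- net@regulators[[i]]
    if (!length(essentialInputs(f))) return(TRUE)   # constant (incl. arity 0)
    identical(regs, i) && identical(f@truthTable, c(0L, 1L))  # x_i = x_i
  }, logical(1)))
}

# restrict a rule to non-fixed regulators after substituting fixed values,
# then drop newly inessential inputs; returns list(tt, regs)
.reduceRule <- function(f, regs, fixedValues) {
  k <- f@arity
  fixedPos <- which(!is.na(fixedValues[regs]))
  tt <- f@truthTable
  if (length(fixedPos)) {
    tt <- .ttRestrict(tt, k, fixedPos, fixedValues[regs[fixedPos]])
    regs <- regs[-fixedPos]
    k <- length(regs)
  }
  ess <- essentialInputs(new("BooleanFunction", arity = as.integer(k),
                             truthTable = tt))
  if (length(ess) < k) {
    drop <- setdiff(seq_len(k), ess)
    tt <- .ttRestrict(tt, k, drop, rep(0L, length(drop)))
    regs <- regs[ess]
  }
  list(tt = tt, regs = regs)
}

#' Hold source nodes at a fixed configuration
#'
#' Substitutes the given constants into every downstream rule, drops inputs
#' that became inessential, and returns the reduced network over the
#' non-source nodes. Coherence computed on the reduced network perturbs only
#' the N - M non-source coordinates. Rules that reduce to constants are kept
#' as arity-0 nodes (their value settles in one step).
#'
#' @param net A [BooleanNetwork-class].
#' @param configuration 0/1 vector, one value per source node (in
#'   [findSourceNodes()] order).
#' @return A [FixedSourceNetwork-class].
#' @examples
#' net <- readBooleanNetwork(text = c("s, s", "a, s & b", "b, !a"))
#' reducedNetwork(fixSources(net, 1))
#' @export
fixSources <- function(net, configuration) {
  src <- findSourceNodes(net)
  if (length(configuration) != length(src))
    stop("configuration must assign one bit to each of the ", length(src),
         " source node(s)", call. = FALSE)
  configuration <- as.integer(configuration)
  if (length(src) && !all(configuration %in% c(0L, 1L)))
    stop("configuration entries must be 0 or 1", call. = FALSE)
  fixedValues <- rep(NA_integer_, nNodes(net))
  fixedValues[src] <- configuration
  keep <- setdiff(seq_len(nNodes(net)), src)
  reduced <- lapply(keep, function(i)
    .reduceRule(net@rules[[i]], net@regulators[[i]], fixedValues))
  newIndex <- match(seq_len(nNodes(net)), keep)
  red <- BooleanNetwork(lapply(reduced, `[[`, "tt"),
                        lapply(reduced, function(r) newIndex[r$regs]),
                        nodeNames = net@nodeNames[keep])
  new("FixedSourceNetwork", parent = "network", sourceNodes = src,
      configuration = configuration, reduced = red)
}

#' @describeIn fixSources The reduced [BooleanNetwork-class] over non-source
#'   nodes.
#' @param x A [FixedSourceNetwork-class].
#' @export
reducedNetwork <- function(x) x@reduced

#' @export
setMethod("show", "FixedSourceNetwork", function(object) {
  cat(sprintf("FixedSourceNetwork: %d source node(s) held at %s; %d-node reduced network\n",
              length(object@sourceNodes),
              paste(object@configuration, collapse = ""),
              nNodes(object@reduced)))
})

# network coherence of a possibly source-carrying model: fix sources and
# average the reduced-network coherence over up to maxConfigs configurations
# (all of them when 2^M <= maxConfigs, else sampled without replacement)
.modelCoherence <- function(net, maxConfigs = 16L, maxNodes = 22L) {
  src <- findSourceNodes(net)
  m <- length(src)
  if (!m) {
    return(networkCoherence(net, basinDecomposition(net, maxNodes = maxNodes)))
  }
  configs <- if (2^m <= maxConfigs) 0:(2^m - 1L)
             else sample(0:(2^m - 1L), maxConfigs)
  mean(vapply(configs, function(cf) {
    bits <- as.integer(bitwAnd(bitwShiftR(cf, (m - 1L):0L), 1L))
    red <- reducedNetwork(fixSources(net, bits))
    networkCoherence(red, basinDecomposition(red, maxNodes = maxNodes))
  }, numeric(1)))
}

#' Matched random null models
#'
#' Null models preserve the wiring diagram exactly but redraw every rule of
#' arity at least 1 as a uniform non-degenerate function of the same arity
#' (arity-0 constants are kept). Comparing a model against its nulls isolates
#' the contribution of the regulatory logic from the topology.
#'
#' @param net A [BooleanNetwork-class].
#' @param R Number of null models.
#' @return List of R [BooleanNetwork-class] objects.
#' @examples
#' set.seed(1)
#' nulls <- nullModels(network(fixtureF()), R = 3)
#' identical(regulators(nulls[[1]]), regulators(network(fixtureF())))
#' @export
nullModels <- function(net, R) {
  R <- .checkCount(R, "R")
  lapply(seq_len(R), function(r) {
    tts <- lapply(net@rules, function(f)
      if (f@arity == 0L) f@truthTable else .rndNondegTT(f@arity))
    BooleanNetwork(tts, net@regulators, net@nodeNames)
  })
}

#' Paired biological-vs-null stability comparison
#'
#' For every model, computes its network coherence (fixing source nodes and
#' averaging over up to `maxConfigs` source configurations) and the mean
#' coherence of R matched null models, then tests the cohort of paired
#' differences: a Shapiro-Wilk normality check, a one-sided paired t-test
#' with alternative "biological coherence exceeds null coherence", and an
#' exact sign test on the per-attractor basin-minus-attractor coherence pairs
#' of the models.
#'
#' @param models List of [BooleanNetwork-class] objects (at least 3).
#' @param R Null models per biological model (study default 100).
#' @param maxConfigs Source configurations analysed per model (default 16).
#' @param maxNodes Exhaustive-size limit forwarded to
#'   [basinDecomposition()].
#' @return A [NullModelComparison-class].
#' @examples
#' set.seed(1)
#' cohort <- syntheticCohort(4, sizeRange = c(5, 6), ruleClass = "ncf")
#' pairedStabilityComparison(cohort, R = 3)
#' @export
pairedStabilityComparison <- function(models, R = 100L, maxConfigs = 16L,
                                      maxNodes = 22L) {
  if (length(models) < 3L)
    stop("at least 3 models are required for the cohort tests", call. = FALSE)
  R <- .checkCount(R, "R")
  bio <- numeric(length(models))
  nullMean <- numeric(length(models))
  psiPairs <- list()
  for (j in seq_along(models)) {
    net <- models[[j]]
    bio[j] <- .modelCoherence(net, maxConfigs, maxNodes)
    nullMean[j] <- mean(vapply(nullModels(net, R), .modelCoherence,
                               numeric(1), maxConfigs = maxConfigs,
                               maxNodes = maxNodes))
    if (!length(findSourceNodes(net)) && nNodes(net) <= maxNodes) {
      rec <- attractorRecords(net, networkId = j)
      psiPairs[[length(psiPairs) + 1L]] <-
        rec$basin_coherence - rec$attractor_coherence
    }
  }
  diffs <- bio - nullMean
  shapiroP <- if (stats::sd(diffs) > 0) stats::shapiro.test(diffs)$p.value
              else NA_real_
  pairedP <- if (stats::sd(diffs) > 0)
    stats::t.test(diffs, alternative = "greater")$p.value else 0.5
  dpsi <- unlist(psiPairs)
  nz <- dpsi[dpsi != 0]
  signP <- if (length(nz))
    stats::binom.test(sum(nz > 0), length(nz),
                      alternative = "greater")$p.value else NA_real_
  new("NullModelComparison",
      perModel = data.frame(model = seq_along(models), coherence_bio = bio,
                            coherence_null_mean = nullMean,
                            difference = diffs),
      shapiroP = shapiroP, pairedP = pairedP, signP = signP,
      nSignPairs = length(nz))
}

#' @export
setMethod("show", "NullModelComparison", function(object) {
  cat(sprintf("NullModelComparison over %d models\n", nrow(object@perModel)))
  cat(sprintf("  mean paired difference: %.4f\n",
              mean(object@perModel$difference)))
  cat(sprintf("  Shapiro-Wilk p = %.3g; one-sided paired t-test p = %.3g; sign test p = %.3g (n = %d)\n",
              object@shapiroP, object@pairedP, object@signP,
              object@nSignPairs))
})

#' Analyse a directory of rule files
#'
#' Reads every BoolNet-style rule file in a directory and runs the paired
#' null-model comparison on the models that fit the exhaustive limit after
#' source fixing. A manifest of model name, size and source count is attached.
#'
#' @param dir Directory of `.bnet`/`.txt` rule files.
#' @param R Null models per biological model.
#' @param maxExactN Largest parent-model size analysed exhaustively.
#' @param maxConfigs Source configurations analysed per model.
#' @return List with elements `manifest` (data frame) and `comparison`
#'   (a [NullModelComparison-class]).
#' @export
analyzeModelDirectory <- function(dir, R = 100L, maxExactN = 20L,
                                  maxConfigs = 16L) {
  files <- list.files(dir, pattern = "\\.(bnet|txt)$", full.names = TRUE)
  if (!length(files))
    stop("no .bnet/.txt rule files found in ", dir, call. = FALSE)
  nets <- lapply(files, readBooleanNetwork)
  manifest <- data.frame(
    model = basename(files),
    n_nodes = vapply(nets, nNodes, integer(1)),
    n_sources = vapply(nets, function(x) length(findSourceNodes(x)),
                       integer(1)))
  manifest$analysis <- ifelse(manifest$n_nodes <= maxExactN, "exact",
                              "sampled")
  exact <- nets[manifest$analysis == "exact"]
  comparison <- if (length(exact) >= 3L)
    pairedStabilityComparison(exact, R = R, maxConfigs = maxConfigs,
                              maxNodes = maxExactN) else NULL
  list(manifest = manifest, comparison = comparison)
}
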