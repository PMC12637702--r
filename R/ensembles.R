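# Random-network ensembles: wiring generation, rule-class dispatch, and the
# pooled per-attractor coherence analysis behind the ensemble comparisons.

#' Random wiring diagram
#'
#' Each node receives `inDegree` distinct regulators drawn uniformly
#' (self-inputs excluded by default); candidate wirings are resampled until
#' the regulator-to-target digraph is strongly connected, up to a retry cap.
#'
#' @param nNodes Number of nodes.
#' @param inDegree Regulators per node (at most `nNodes`).
#' @param requireStrongConnectivity Resample until strongly connected.
#' @param allowSelfInputs Whether a node may regulate itself.
#' @param maxTries Retry cap for the strong-connectivity rejection loop.
#' @return List of integer regulator vectors, one per node.
#' @examples
#' set.seed(1); lengths(randomWiring(12, 3))
#' @export
randomWiring <- function(nNodes, inDegree, requireStrongConnectivity = TRUE,
                         allowSelfInputs = FALSE, maxTries = 10000L) {
  n <- .checkCount(nNodes, "nNodes")
  k <- .checkCount(inDegree, "inDegree")
  if (k > n || (!allowSelfInputs && k > n - 1L))
    stop("in-degree exceeds the number of available regulators", call. = FALSE)
  for (try in seq_len(maxTries)) {
    regs <- lapply(seq_len(n), function(i) {
      pool <- if (allowSelfInputs) seq_len(n) else setdiff(seq_len(n), i)
      sort(sample(pool, k))
    })
    if (!requireStrongConnectivity || .stronglyConnectedRegs(regs, n))
      return(regs)
  }
  stop("no strongly connected wiring found for nNodes = ", n, ", inDegree = ",
       k, " within ", maxTries, " tries", call. = FALSE)
}

# one truth table for the given rule class (raw vector; hot path)
.rndRuleTT <- function(ruleClass, k, depth = NA_integer_,
                       layerStructure = integer()) {
  switch(ruleClass,
         random = .rndNondegTT(k),
         depth = if (depth == 0L) .rndNonCanalizingTT(k)
                 else .rndCanalizedTT(k, depth),
         ncf = .rndCanalizedTT(k, k),
         `ncf-layer` = truthTable(randomNCFWithLayerStructure(layerStructure)),
         stop("unknown rule class: ", ruleClass, call. = FALSE))
}

#' Random Boolean network of a given rule class
#'
#' Combines [randomWiring()] with per-node rules of the requested class
#' ("random" non-degenerate, exact canalizing "depth", "ncf", or "ncf-layer"
#' with a fixed layer structure).
#'
#' @inheritParams randomWiring
#' @param ruleClass One of `"random"`, `"depth"`, `"ncf"`, `"ncf-layer"`.
#' @param depth Exact canalizing depth for `ruleClass = "depth"`.
#' @param layerStructure Layer structure for `ruleClass = "ncf-layer"`.
#' @return A [BooleanNetwork-class].
#' @examples
#' set.seed(1); randomNetwork(8, 3, ruleClass = "ncf")
#' @export
randomNetwork <- function(nNodes, inDegree, ruleClass = "random",
                          depth = NA_integer_, layerStructure = integer(),
                          requireStrongConnectivity = TRUE,
                          allowSelfInputs = FALSE) {
  regs <- randomWiring(nNodes, inDegree, requireStrongConnectivity,
                       allowSelfInputs)
  tts <- lapply(regs, function(r)
    .rndRuleTT(ruleClass, length(r), depth, layerStructure))
  BooleanNetwork(tts, regs)
}

#' Specify a random-network ensemble
#'
#' Defaults follow the reference study conditions: 10,000 networks of 12
#' nodes with in-degree 3, strongly connected wirings and non-degenerate
#' rules. Reduced `size` values reproduce the comparisons at desk scale.
#'
#' @param nNodes Nodes per network.
#' @param inDegree Regulators per node.
#' @param ruleClass `"random"`, `"depth"`, `"ncf"` or `"ncf-layer"`.
#' @param depth Exact canalizing depth (rule class `"depth"`).
#' @param layerStructure Integer composition (rule class `"ncf-layer"`).
#' @param size Number of networks in the ensemble.
#' @param seed RNG seed; the ensemble is deterministic given the spec.
#' @param requireStrongConnectivity,allowSelfInputs Wiring options.
#' @return An [EnsembleSpec-class].
#' @examples
#' ensembleSpec(ruleClass = "ncf", size = 100, seed = 7)
#' @export
ensembleSpec <- function(nNodes = 12L, inDegree = 3L, ruleClass = "random",
                         depth = NA_integer_, layerStructure = integer(),
                         size = 10000L, seed = 1L,
                         requireStrongConnectivity = TRUE,
                         allowSelfInputs = FALSE) {
  new("EnsembleSpec", nNodes = as.integer(nNodes),
      inDegree = as.integer(inDegree), ruleClass = ruleClass,
      depth = as.integer(depth), layerStructure = as.integer(layerStructure),
      size = as.integer(size), seed = as.integer(seed),
      requireStrongConnectivity = requireStrongConnectivity,
      allowSelfInputs = allowSelfInputs)
}

# fast per-network analysis used by runEnsemble: regulator lists + raw truth
# tables in, one record row per attractor out
.analyzeRaw <- function(regs, tts, n, networkId) {
  states <- 0:(2L^n - 1L)
  succ <- integer(length(states))
  for (i in seq_len(n)) {
    idx <- integer(length(states))
    for (r in regs[[i]])
      idx <- idx * 2L + bitwAnd(bitwShiftR(states, n - r), 1L)
    succ <- succ + tts[[i]][idx + 1L] * bitwShiftL(1L, n - i)
  }
  d <- .decomposeSucc(succ, n)
  psi <- .coherencePerState(d$assignment, n)
  nA <- length(d$attractorStates)
  basinCoh <- as.numeric(rowsum(psi, d$assignment)[, 1L]) / d$basinSizes
  attrCoh <- vapply(d$attractorStates, function(cs) mean(psi[cs + 1L]),
                    numeric(1))
  keys <- vapply(d$attractorStates, function(cs)
    .keyOfBits(.bitsOfCodes(cs[1L], n)[1L, ]), character(1))
  data.frame(network_id = rep(networkId, nA), attractor_key = keys,
             period = lengths(d$attractorStates),
             relative_basin_size = d$basinSizes / 2^n,
             basin_coherence = basinCoh, attractor_coherence = attrCoh,
             exact_flag = rep(TRUE, nA), stringsAsFactors = FALSE)
}

#' Run a random-network ensemble analysis
#'
#' Generates `size` networks according to the spec, exhaustively decomposes
#' each one, emits one record per attractor (relative basin size, basin
#' coherence, attractor coherence), pools the records, and summarises them by
#' the binned conditional-coherence curves: AUC:BC, AUC:AC, the coherence gap,
#' percent above the 0.5 baseline, the relative drop, and the mean rule
#' sensitivity and standardized bias across the ensemble. Deterministic given
#' the spec's seed.
#'
#' @param spec An [EnsembleSpec-class].
#' @param nBins,policy Passed to [coherenceCurves()].
#' @return An [EnsembleResult-class].
#' @examples
#' res <- runEnsemble(ensembleSpec(size = 100, seed = 7))
#' res@summary[["auc_bc"]]
#' @export
runEnsemble <- function(spec, nBins = 1000L, policy = "interpolate") {
  stopifnot(is(spec, "EnsembleSpec"))
  validObject(spec)
  n <- spec@nNodes
  set.seed(spec@seed)
  recs <- vector("list", spec@size)
  sensSum <- 0; biasSum <- 0; nRules <- 0L
  for (b in seq_len(spec@size)) {
    regs <- randomWiring(n, spec@inDegree, spec@requireStrongConnectivity,
                         spec@allowSelfInputs)
    tts <- lapply(regs, function(r)
      .rndRuleTT(spec@ruleClass, length(r), spec@depth, spec@layerStructure))
    for (tt in tts) {
      f <- new("BooleanFunction", arity = spec@inDegree, truthTable = tt)
      sensSum <- sensSum + averageSensitivity(f)
      p <- mean(tt)
      biasSum <- biasSum + p * (1 - p)
      nRules <- nRules + 1L
    }
    recs[[b]] <- .analyzeRaw(regs, tts, n, networkId = b)
  }
  records <- do.call(rbind, recs)
  curves <- coherenceCurves(records, nBins = nBins, policy = policy)
  summ <- c(auc_bc = curves@aucBC, auc_ac = curves@aucAC,
            delta_auc = curves@deltaAUC,
            pct_above_baseline_bc = percentAboveBaseline(curves@aucBC),
            pct_above_baseline_ac = percentAboveBaseline(curves@aucAC),
            relative_drop = if (curves@aucBC != 0.5)
              100 * curves@deltaAUC / (curves@aucBC - 0.5) else NA_real_,
            mean_sensitivity = sensSum / nRules,
            mean_std_bias = biasSum / nRules,
            max_gap = curves@maxGap, excluded = as.numeric(curves@excluded),
            n_records = nrow(records))
  new("EnsembleResult", spec = spec, records = records, curves = curves,
      summary = summ)
}

#' @export
setMethod("show", "EnsembleSpec", function(object) {
  extra <- switch(object@ruleClass,
                  depth = sprintf(" (depth %d)", object@depth),
                  `ncf-layer` = sprintf(" (%s)", paste(object@layerStructure,
                                                       collapse = ", ")),
                  "")
  cat(sprintf("EnsembleSpec: %d networks, %d nodes, in-degree %d, rules %s%s, seed %d\n",
              object@size, object@nNodes, object@inDegree, object@ruleClass,
              extra, object@seed))
})

#' @export
setMethod("show", "EnsembleResult", function(object) {
  show(object@spec)
  cat(sprintf("  %d attractor records; AUC:BC %.4f (+%.1f%%), AUC:AC %.4f, gap %.4f\n",
              nrow(object@records), object@summary[["auc_bc"]],
              object@summary[["pct_above_baseline_bc"]],
              object@summary[["auc_ac"]], object@summary[["delta_auc"]]))
})
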