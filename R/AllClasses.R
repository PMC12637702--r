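#' @import methods
NULL

#' Boolean update function
#'
#' A `BooleanFunction` is the truth table of a k-input Boolean update rule.
#' The table is stored MSB-first: entry `m + 1` gives the output
#' `f(x1, ..., xk)` where `x1` is the most significant bit of `m`. With this
#' convention the Hamming weight of the rule is simply the popcount of the
#' table.
#'
#' @slot arity Number of inputs, an integer `k >= 0`.
#' @slot truthTable Integer vector of `2^k` entries, each 0 or 1.
#'
#' @seealso [BooleanFunction()] for construction, [evaluate()],
#'   [essentialInputs()], [layerStructure()].
#' @export
setClass("BooleanFunction",
  representation(arity = "integer", truthTable = "integer"),
  validity = function(object) {
    msgs <- character()
    if (length(object@arity) != 1L || is.na(object@arity) || object@arity < 0L)
      msgs <- c(msgs, "arity must be a single non-negative integer")
    else if (length(object@truthTable) != 2L^object@arity)
      msgs <- c(msgs, sprintf("truth table must have 2^%d = %d entries, got %d",
                              object@arity, 2L^object@arity, length(object@truthTable)))
    if (anyNA(object@truthTable) || !all(object@truthTable %in% c(0L, 1L)))
      msgs <- c(msgs, "truth table entries must be 0 or 1")
    if (length(msgs)) msgs else TRUE
  })

#' Boolean network
#'
#' A synchronously updated Boolean network of N named nodes. Each node `i`
#' carries an ordered list of regulator indices (the wiring diagram) and a
#' [BooleanFunction-class] whose arity equals the regulator count.
#'
#' @slot nodeNames Character vector of N distinct node identifiers.
#' @slot regulators List of integer vectors; `regulators[[i]]` gives the
#'   ordered input nodes of rule `i`.
#' @slot rules List of [BooleanFunction-class] objects, one per node.
#'
#' @seealso [BooleanNetwork()], [synchronousStep()], [basinDecomposition()].
#' @export
setClass("BooleanNetwork",
  representation(nodeNames = "character", regulators = "list", rules = "list"),
  validity = function(object) {
    n <- length(object@nodeNames)
    msgs <- character()
    if (anyDuplicated(object@nodeNames))
      msgs <- c(msgs, "node names must be distinct")
    if (length(object@regulators) != n || length(object@rules) != n)
      msgs <- c(msgs, "regulators and rules must have one entry per node")
    else {
      for (i in seq_len(n)) {
        regs <- object@regulators[[i]]
        if (length(regs) && (anyNA(regs) || any(regs < 1L) || any(regs > n)))
          msgs <- c(msgs, sprintf("node %d has regulator indices outside 1..%d", i, n))
        f <- object@rules[[i]]
        if (!is(f, "BooleanFunction"))
          msgs <- c(msgs, sprintf("rule %d is not a BooleanFunction", i))
        else if (f@arity != length(regs))
          msgs <- c(msgs, sprintf("rule %d has arity %d but %d regulators",
                                  i, f@arity, length(regs)))
      }
    }
    if (length(msgs)) msgs else TRUE
  })

#' Attractor of a Boolean network
#'
#' A periodic orbit of the synchronous dynamics: a fixed point (period 1) or a
#' limit cycle. States are stored in cycle order starting from the canonical
#' state (the lexicographically smallest member), so that two attractors are
#' identical iff their canonical keys agree, regardless of phase.
#'
#' @slot stateBits Integer matrix (period x N) of the cycle's states, one row
#'   per state, columns in node order.
#' @slot stateCodes Numeric vector of the MSB-first integer encodings of the
#'   rows (exact for N <= 53; `NA` beyond).
#' @slot canonicalKey Character bitstring of the canonical state.
#' @export
setClass("Attractor",
  representation(stateBits = "matrix", stateCodes = "numeric",
                 canonicalKey = "character"),
  validity = function(object) {
    msgs <- character()
    if (!nrow(object@stateBits))
      msgs <- c(msgs, "attractor must contain at least one state")
    if (length(object@stateCodes) != nrow(object@stateBits))
      msgs <- c(msgs, "stateCodes length must equal the period")
    if (length(msgs)) msgs else TRUE
  })

#' Exhaustive basin decomposition
#'
#' The full classification of a network's `2^N` states: the list of attractors,
#' the map assigning every state to its attractor, and the basin sizes. Basin
#' sizes always sum to `2^N`.
#'
#' @slot nNodes Network size N.
#' @slot attractors List of [Attractor-class] objects.
#' @slot assignment Integer vector of length `2^N`; entry `m + 1` is the
#'   attractor index of the state with code `m`.
#' @slot basinSizes Numeric vector of basin sizes, parallel to `attractors`.
#' @export
setClass("BasinDecomposition",
  representation(nNodes = "integer", attractors = "list",
                 assignment = "integer", basinSizes = "numeric"),
  validity = function(object) {
    msgs <- character()
    if (length(object@assignment) != 2^object@nNodes)
      msgs <- c(msgs, "assignment must cover all 2^N states")
    if (sum(object@basinSizes) != 2^object@nNodes)
      msgs <- c(msgs, "basin sizes must sum to 2^N")
    if (length(object@basinSizes) != length(object@attractors))
      msgs <- c(msgs, "one basin size per attractor required")
    if (length(msgs)) msgs else TRUE
  })

#' Monte-Carlo basin decomposition
#'
#' Result of sampling q random initial states and iterating each to its
#' attractor. Hit counts give unbiased relative-basin-size estimates; the
#' attractor list contains every attractor reached by at least one sample.
#' Trajectory resolutions are memoised in `memo` and reused by
#' [sampledBasinCoherence()] and [exactAttractorCoherence()].
#'
#' @slot nNodes Network size N.
#' @slot attractors List of discovered [Attractor-class] objects.
#' @slot hits Integer vector of per-attractor sample counts (sums to q).
#' @slot q Number of sampled initial states.
#' @slot initialStates Integer matrix (q x N) of sampled start states.
#' @slot initialAssignment Integer vector mapping each sample to its attractor.
#' @slot memo Environment caching state -> attractor-key resolutions.
#' @slot registry Environment mapping attractor keys to [Attractor-class]
#'   objects (may grow beyond `attractors` during neighbour resolution).
#' @slot stepCap Safety cap on per-trajectory steps.
#' @export
setClass("SampledDecomposition",
  representation(nNodes = "integer", attractors = "list", hits = "integer",
                 q = "integer", initialStates = "matrix",
                 initialAssignment = "integer", memo = "environment",
                 registry = "environment", stepCap = "numeric"),
  validity = function(object) {
    msgs <- character()
    if (sum(object@hits) != object@q)
      msgs <- c(msgs, "hit counts must sum to q")
    if (length(object@hits) != length(object@attractors))
      msgs <- c(msgs, "one hit count per discovered attractor required")
    if (length(msgs)) msgs else TRUE
  })

#' Binned conditional-coherence curves
#'
#' Conditional means of basin and attractor coherence given relative basin
#' size, on `nBins` equal subintervals of (0, 1], together with the areas
#' under both curves (AUC:BC, AUC:AC) and the coherence gap
#' `deltaAUC = AUC:BC - AUC:AC`. Ensembles whose basin-size support has an
#' empty run of at least 0.02 are flagged `excluded`.
#'
#' @slot nBins Number of subintervals (default 1000).
#' @slot binMeansBasin,binMeansAttractor Per-bin conditional means; `NA` marks
#'   an empty bin.
#' @slot aucBC,aucAC,deltaAUC Area-under-curve scalars.
#' @slot maxGap Longest run of empty bins as a fraction of [0, 1].
#' @slot excluded `TRUE` iff `maxGap >= 0.02`.
#' @slot policy Empty-bin policy used for the AUC ("interpolate" or
#'   "renormalize").
#' @export
setClass("CoherenceCurves",
  representation(nBins = "integer", binMeansBasin = "numeric",
                 binMeansAttractor = "numeric", aucBC = "numeric",
                 aucAC = "numeric", deltaAUC = "numeric", maxGap = "numeric",
                 excluded = "logical", policy = "character"),
  validity = function(object) {
    msgs <- character()
    if (length(object@binMeansBasin) != object@nBins ||
        length(object@binMeansAttractor) != object@nBins)
      msgs <- c(msgs, "bin mean vectors must have nBins entries")
    if (!isTRUE(all.equal(object@deltaAUC, object@aucBC - object@aucAC)))
      msgs <- c(msgs, "deltaAUC must equal aucBC - aucAC")
    if (object@excluded != (object@maxGap >= 0.02))
      msgs <- c(msgs, "excluded flag must equal (maxGap >= 0.02)")
    if (length(msgs)) msgs else TRUE
  })

#' Random-ensemble specification
#'
#' Parameters of one ensemble of random Boolean networks: size-N networks with
#' fixed in-degree and a rule class that is one of uniformly random
#' non-degenerate functions (`"random"`), functions of exact canalizing depth
#' k (`"depth"`), nested canalizing functions (`"ncf"`), or NCFs with a fixed
#' layer structure (`"ncf-layer"`).
#'
#' @slot nNodes Nodes per network (study default 12).
#' @slot inDegree Regulators per node.
#' @slot ruleClass One of "random", "depth", "ncf", "ncf-layer".
#' @slot depth Exact canalizing depth (rule class "depth" only).
#' @slot layerStructure Integer composition (rule class "ncf-layer" only).
#' @slot size Number of networks (study default 10000).
#' @slot seed RNG seed making the ensemble reproducible.
#' @slot requireStrongConnectivity Resample wirings until strongly connected.
#' @slot allowSelfInputs Whether a node may regulate itself.
#' @export
setClass("EnsembleSpec",
  representation(nNodes = "integer", inDegree = "integer",
                 ruleClass = "character", depth = "integer",
                 layerStructure = "integer", size = "integer",
                 seed = "integer", requireStrongConnectivity = "logical",
                 allowSelfInputs = "logical"),
  validity = function(object) {
    msgs <- character()
    if (object@inDegree < 1L || object@inDegree > object@nNodes)
      msgs <- c(msgs, "in-degree must lie in 1..nNodes")
    if (!object@ruleClass %in% c("random", "depth", "ncf", "ncf-layer"))
      msgs <- c(msgs, "unknown rule class")
    if (object@ruleClass == "depth" &&
        (is.na(object@depth) || object@depth < 0L || object@depth > object@inDegree))
      msgs <- c(msgs, "canalizing depth must lie in 0..inDegree")
    if (object@ruleClass == "ncf-layer" &&
        sum(object@layerStructure) != object@inDegree)
      msgs <- c(msgs, "layer structure must be a composition of the in-degree")
    if (length(msgs)) msgs else TRUE
  })

#' Random-ensemble result
#'
#' Pooled per-attractor records of an ensemble run, the binned coherence
#' curves computed from them, and summary statistics (AUCs, coherence gap,
#' percent above the 0.5 baseline, relative drop, mean rule sensitivity and
#' mean standardized bias).
#'
#' @slot spec The [EnsembleSpec-class] that generated the ensemble.
#' @slot records Pooled attractor records (one row per attractor).
#' @slot curves The [CoherenceCurves-class] over the pooled records.
#' @slot summary Named numeric vector of ensemble summaries.
#' @export
setClass("EnsembleResult",
  representation(spec = "EnsembleSpec", records = "data.frame",
                 curves = "CoherenceCurves", summary = "numeric"))

#' Fixed-source reduction of a network
#'
#' A biological model with its M source nodes held at a constant
#' configuration: the reduced (N - M)-node network obtained by substituting
#' the constants and dropping inputs that became inessential.
#'
#' @slot parent Name/id of the parent model.
#' @slot sourceNodes Indices of the source nodes in the parent.
#' @slot configuration Integer vector of fixed source values.
#' @slot reduced The reduced [BooleanNetwork-class] over non-source nodes.
#' @export
setClass("FixedSourceNetwork",
  representation(parent = "character", sourceNodes = "integer",
                 configuration = "integer", reduced = "BooleanNetwork"),
  validity = function(object) {
    if (length(object@configuration) != length(object@sourceNodes))
      "configuration must assign one bit per source node" else TRUE
  })

#' Biological-vs-null stability comparison
#'
#' Per-model network coherences against the mean coherence of matched random
#' null models (same wiring, redrawn non-degenerate rules), with cohort-level
#' tests: a normality check on the paired differences, a one-sided paired
#' location test (biological > null), and an exact sign test on per-attractor
#' basin-vs-attractor coherence pairs.
#'
#' @slot perModel Data frame: model, coherence_bio, coherence_null_mean,
#'   difference.
#' @slot shapiroP Shapiro-Wilk normality p-value of the differences.
#' @slot pairedP One-sided paired t-test p-value (alternative: bio > null).
#' @slot signP Exact one-sided sign-test p-value on psiB - psiA pairs.
#' @slot nSignPairs Number of non-tied psiB/psiA pairs entering the sign test.
#' @export
setClass("NullModelComparison",
  representation(perModel = "data.frame", shapiroP = "numeric",
                 pairedP = "numeric", signP = "numeric",
                 nSignPairs = "integer"))

#' Named worked-example fixture
#'
#' A network bundled with its exact expected attractors, basin sizes and
#' coherences. The expected table is re-verified by exhaustive decomposition
#' when the fixture is constructed, so any drift fails loudly.
#'
#' @slot name Fixture name.
#' @slot network The [BooleanNetwork-class].
#' @slot expected Named list of exact expected values.
#' @export
setClass("Fixture",
  representation(name = "character", network = "BooleanNetwork",
                 expected = "list"))

#' Canalizing layer structure
#'
#' The ordered tuple (k1, ..., kr) produced by iterative peeling of canalizing
#' variables: the first layer holds all variables canalizing in f, the next
#' all variables that become canalizing once the first layer's non-canalizing
#' values are substituted, and so on. The canalizing depth is the sum of the
#' layer sizes; a function is nested canalizing (NCF) when the depth equals
#' its arity.
#'
#' @slot layers Integer vector (k1, ..., kr), possibly empty.
#' @slot depth Sum of the layer sizes.
#' @slot arity Arity of the classified function.
#' @slot isNCF `TRUE` iff depth equals arity.
#' @export
setClass("LayerStructure",
  representation(layers = "integer", depth = "integer", arity = "integer",
                 isNCF = "logical"),
  validity = function(object) {
    msgs <- character()
    if (length(object@layers) && any(object@layers < 1L))
      msgs <- c(msgs, "all layer sizes must be >= 1")
    if (object@depth != sum(object@layers))
      msgs <- c(msgs, "depth must equal the sum of layer sizes")
    if (object@depth > object@arity)
      msgs <- c(msgs, "depth cannot exceed arity")
    if (object@isNCF && object@arity >= 2L &&
        object@layers[length(object@layers)] < 2L)
      msgs <- c(msgs, "the final layer of an NCF with arity >= 2 must have size >= 2")
    if (length(msgs)) msgs else TRUE
  })
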