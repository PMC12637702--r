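# Monte-Carlo basin analysis for networks beyond the exhaustive limit:
# random initial states are iterated to their attractor (visited-set cycle
# detection), giving unbiased basin-size and basin-coherence estimates,
# while attractor coherence stays exact for every discovered attractor.

# iterate bits to an attractor; memoises every visited state's key in `memo`
# (key -> attractor key) and registers new attractors in `registry`
# (key -> Attractor). Returns the attractor key.
.resolveState <- function(ruleList, regList, bits, memo, registry, stepCap) {
  path <- character(0)
  pathBits <- list()
  pos <- new.env(hash = TRUE, parent = emptyenv())  # key -> index in path
  repeat {
    key <- .keyOfBits(bits)
    hit <- memo[[key]]
    if (!is.null(hit)) {
      for (k in path) memo[[k]] <- hit
      return(hit)
    }
    at <- pos[[key]]
    if (!is.null(at)) {                       # new cycle closed
      cycBits <- do.call(rbind, pathBits[at:length(pathBits)])
      cycKeys <- path[at:length(path)]
      rot <- match(min(cycKeys), cycKeys)     # lexicographic = numeric order
      ord <- c(rot:length(cycKeys), seq_len(rot - 1L))
      canon <- cycKeys[rot]
      if (is.null(registry[[canon]])) {
        n <- ncol(cycBits)
        codes <- if (n <= 53L) .codeOfBits(cycBits[ord, , drop = FALSE])
                 else rep(NA_real_, length(ord))
        registry[[canon]] <- new("Attractor",
                                 stateBits = cycBits[ord, , drop = FALSE],
                                 stateCodes = codes, canonicalKey = canon)
      }
      for (k in path) memo[[k]] <- canon
      return(canon)
    }
    path <- c(path, key)
    pathBits[[length(path)]] <- bits
    pos[[key]] <- length(path)
    if (length(path) > stepCap)
      stop("trajectory exceeded the step cap of ", stepCap, call. = FALSE)
    bits <- .stepBits(ruleList, regList, bits)
  }
}

#' Monte-Carlo basin decomposition
#'
#' Draws `q` initial states uniformly with replacement, iterates each to its
#' attractor, and deduplicates attractors by canonical key. The fraction of
#' samples reaching an attractor is an unbiased estimate of its relative
#' basin size; an attractor of relative basin size b is discovered with
#' probability [detectionProbability()]`(b, q)`.
#'
#' @param net A [BooleanNetwork-class] (any size; trajectories only need the
#'   transient, not the full state space).
#' @param q Number of sampled initial states (study default 1000).
#' @param stepCap Defensive per-trajectory step limit.
#' @return A [SampledDecomposition-class].
#' @examples
#' set.seed(1)
#' sd <- sampleDecomposition(network(fixtureF()), q = 200)
#' hits(sd) / 200                   # near 5/8 and 3/8
#' @export
sampleDecomposition <- function(net, q = 1000L, stepCap = 1e6) {
  q <- .checkCount(q, "q")
  n <- nNodes(net)
  memo <- new.env(hash = TRUE, parent = emptyenv())
  registry <- new.env(hash = TRUE, parent = emptyenv())
  starts <- matrix(sample(c(0L, 1L), q * n, replace = TRUE), nrow = q)
  keys <- character(q)
  for (j in seq_len(q))
    keys[j] <- .resolveState(net@rules, net@regulators, starts[j, ],
                             memo, registry, stepCap)
  hitTab <- sort(table(keys), decreasing = TRUE)
  attrKeys <- names(hitTab)
  new("SampledDecomposition", nNodes = n,
      attractors = lapply(attrKeys, function(k) registry[[k]]),
      hits = as.integer(hitTab), q = q, initialStates = starts,
      initialAssignment = match(keys, attrKeys), memo = memo,
      registry = registry, stepCap = stepCap)
}

#' @describeIn sampleDecomposition Per-attractor sample counts; `hits(x) / q`
#'   estimates the relative basin sizes.
#' @param x A [SampledDecomposition-class].
#' @export
hits <- function(x) x@hits

#' @export
setMethod("show", "SampledDecomposition", function(object) {
  cat(sprintf("SampledDecomposition (%d nodes, q = %d): %d attractor(s) discovered\n",
              object@nNodes, object@q, length(object@attractors)))
  cat("  size estimates:",
      paste(signif(utils::head(object@hits, 10) / object@q, 3), collapse = ", "),
      "\n")
})

#' Sampled basin-coherence estimate
#'
#' Mean coherence of the sampled initial states that landed in the given
#' attractor's basin: for each such state, every single-bit neighbour is
#' itself iterated to its attractor (reusing the decomposition's memo) and
#' the fraction staying in the basin is averaged. An unbiased estimator of
#' the exact basin coherence.
#'
#' @param net The [BooleanNetwork-class] that was sampled.
#' @param sampled A [SampledDecomposition-class] of `net`.
#' @param attractor Attractor index, [Attractor-class], or canonical key.
#' @return A fraction in `[0, 1]`.
#' @export
sampledBasinCoherence <- function(net, sampled, attractor) {
  i <- .attractorIndex(sampled, attractor)
  key <- canonicalKey(sampled@attractors[[i]])
  members <- which(sampled@initialAssignment == i)
  if (!length(members))
    stop("no sampled state landed in this basin; its coherence estimate is ",
         "undefined", call. = FALSE)
  n <- sampled@nNodes
  mean(vapply(members, function(j) {
    bits <- sampled@initialStates[j, ]
    same <- 0L
    for (b in seq_len(n)) {
      nb <- bits; nb[b] <- 1L - nb[b]
      same <- same + (.resolveState(net@rules, net@regulators, nb,
                                    sampled@memo, sampled@registry,
                                    sampled@stepCap) == key)
    }
    same / n
  }, numeric(1)))
}

#' Exact attractor coherence from a sampled decomposition
#'
#' The attractor's cycle states are known exactly, so its coherence is exact
#' regardless of q: every single-bit perturbation of every cycle state is
#' iterated to its attractor and compared by canonical key.
#'
#' @inheritParams sampledBasinCoherence
#' @return A fraction in `[0, 1]`, equal to the exhaustive
#'   [attractorCoherence()] whenever both can be computed.
#' @export
exactAttractorCoherence <- function(net, sampled, attractor) {
  i <- .attractorIndex(sampled, attractor)
  a <- sampled@attractors[[i]]
  key <- canonicalKey(a)
  n <- sampled@nNodes
  mean(apply(a@stateBits, 1L, function(bits) {
    same <- 0L
    for (b in seq_len(n)) {
      nb <- bits; nb[b] <- 1L - nb[b]
      same <- same + (.resolveState(net@rules, net@regulators, nb,
                                    sampled@memo, sampled@registry,
                                    sampled@stepCap) == key)
    }
    same / n
  }))
}

#' Per-attractor records from a sampled decomposition
#'
#' The sampled analogue of [attractorRecords()]: relative basin sizes and
#' basin coherences are Monte-Carlo estimates (`exact_flag = FALSE` semantics
#' apply to those columns), while periods and attractor coherences are exact.
#'
#' @inheritParams sampledBasinCoherence
#' @param networkId Identifier stored in the `network_id` column.
#' @return Data frame in the same layout as [attractorRecords()], with
#'   `exact_flag = FALSE`.
#' @export
sampledRecords <- function(net, sampled, networkId = "net") {
  nA <- length(sampled@attractors)
  data.frame(
    network_id = rep(networkId, nA),
    attractor_key = vapply(sampled@attractors, canonicalKey, character(1)),
    period = vapply(sampled@attractors, period, integer(1)),
    relative_basin_size = sampled@hits / sampled@q,
    basin_coherence = vapply(seq_len(nA), function(i)
      sampledBasinCoherence(net, sampled, i), numeric(1)),
    attractor_coherence = vapply(seq_len(nA), function(i)
      exactAttractorCoherence(net, sampled, i), numeric(1)),
    exact_flag = rep(FALSE, nA), stringsAsFactors = FALSE)
}

#' Attractor detection probability under random sampling
#'
#' Probability that at least one of q uniform random initial states falls in
#' a basin of relative size b: `p(b, q) = 1 - (1 - b)^q`. With q = 1000, an
#' attractor whose basin covers 1% of the state space is found with
#' probability 99.996%.
#'
#' @param b Relative basin size in (0, 1].
#' @param q Number of sampled initial states.
#' @return Probability in (0, 1].
#' @examples
#' detectionProbability(0.01, 1000)
#' @export
detectionProbability <- function(b, q) {
  q <- .checkCount(q, "q")
  if (any(b <= 0 | b > 1))
    stop("relative basin size must lie in (0, 1]", call. = FALSE)
  1 - (1 - b)^q
}
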