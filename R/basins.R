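# Exhaustive state-space decomposition. States are MSB-first integer codes
# 0..2^N-1; the successor map is built per node by vectorised truth-table
# lookup over all states, and basins are found by iterated squaring of the
# successor map (N squarings compose it 2^N times, past any transient).

# 0-based successor codes for all 2^N states
.successorMap <- function(ruleList, regList, n) {
  states <- 0:(2L^n - 1L)
  succ <- integer(length(states))
  for (i in seq_along(ruleList)) {
    regs <- regList[[i]]
    idx <- integer(length(states))
    for (r in regs)
      idx <- idx * 2L + bitwAnd(bitwShiftR(states, n - r), 1L)
    succ <- succ + ruleList[[i]]@truthTable[idx + 1L] * bitwShiftL(1L, n - i)
  }
  succ
}

# raw decomposition from a successor map: list(assignment, basinSizes,
# attractorStates = list of 0-based code vectors in cycle order starting at
# the canonical (smallest) state)
.decomposeSucc <- function(succ, n) {
  s <- succ + 1L                       # 1-based
  for (i in seq_len(n)) s <- s[s]      # now succ^(2^n): on-cycle for every state
  onCycle <- unique(s)
  attrOf <- integer(length(succ))
  cycles <- list()
  seen <- logical(length(succ))
  for (y in onCycle) {
    if (seen[y]) next
    cyc <- y
    z <- succ[y] + 1L
    while (z != y) { cyc <- c(cyc, z); z <- succ[z] + 1L }
    rot <- which.min(cyc)
    cyc <- c(cyc[rot:length(cyc)], cyc[seq_len(rot - 1L)])
    cycles[[length(cycles) + 1L]] <- cyc - 1L
    attrOf[cyc] <- length(cycles)
    seen[cyc] <- TRUE
  }
  assignment <- attrOf[s]
  list(assignment = assignment,
       basinSizes = tabulate(assignment, nbins = length(cycles)),
       attractorStates = cycles)
}

.makeAttractor <- function(codes, n) {
  bits <- .bitsOfCodes(codes, n)
  new("Attractor", stateBits = bits,
      stateCodes = as.numeric(codes),
      canonicalKey = .keyOfBits(bits[1L, ]))
}

#' Exhaustive basin decomposition of a Boolean network
#'
#' Computes the full state transition graph of the `2^N` states, identifies
#' every attractor (the periodic orbits of the synchronous dynamics) and
#' assigns each state to the attractor its trajectory reaches. Basin sizes
#' always sum to `2^N`.
#'
#' @param net A [BooleanNetwork-class].
#' @param maxNodes Exhaustive-size limit (default 22, about 4M states);
#'   larger networks raise an error pointing at [sampleDecomposition()].
#' @return A [BasinDecomposition-class].
#' @examples
#' d <- basinDecomposition(network(fixtureF()))
#' basinSizes(d)   # 5 and 3
#' @export
basinDecomposition <- function(net, maxNodes = 22L) {
  n <- nNodes(net)
  if (n > maxNodes)
    stop("network has ", n, " nodes, above the exhaustive limit of ", maxNodes,
         "; use sampleDecomposition() for Monte-Carlo analysis", call. = FALSE)
  succ <- .successorMap(net@rules, net@regulators, n)
  d <- .decomposeSucc(succ, n)
  new("BasinDecomposition", nNodes = n,
      attractors = lapply(d$attractorStates, .makeAttractor, n = n),
      assignment = d$assignment, basinSizes = as.numeric(d$basinSizes))
}

#' @describeIn basinDecomposition List of [Attractor-class] objects.
#' @param x A [BasinDecomposition-class] (or [SampledDecomposition-class]).
#' @export
attractors <- function(x) x@attractors

#' @describeIn basinDecomposition Basin sizes, parallel to `attractors(x)`.
#' @export
basinSizes <- function(x) x@basinSizes

#' @describeIn basinDecomposition State-to-attractor index map (entry `m + 1`
#'   classifies the state with code `m`).
#' @export
assignment <- function(x) x@assignment

#' @describeIn basinDecomposition Period of an [Attractor-class].
#' @param a An [Attractor-class].
#' @export
period <- function(a) nrow(a@stateBits)

#' @describeIn basinDecomposition Canonical identity key of an
#'   [Attractor-class] (bitstring of its lexicographically smallest state).
#' @export
canonicalKey <- function(a) a@canonicalKey

#' @describeIn basinDecomposition States of an [Attractor-class] as a
#'   period-by-N 0/1 matrix in cycle order.
#' @export
attractorStates <- function(a) a@stateBits

#' @export
setMethod("show", "Attractor", function(object) {
  cat(sprintf("Attractor of period %d: %s%s\n", period(object),
              object@canonicalKey,
              if (period(object) > 1) " (canonical state)" else " (fixed point)"))
})

#' @export
setMethod("show", "BasinDecomposition", function(object) {
  cat(sprintf("BasinDecomposition of a %d-node network: %d attractor(s)\n",
              object@nNodes, length(object@attractors)))
  cat("  basin sizes:",
      paste(utils::head(object@basinSizes, 10), collapse = ", "), "\n")
})

# locate an attractor argument (index, Attractor, or canonical key) in a
# decomposition; errors if absent
.attractorIndex <- function(decomp, attractor) {
  keys <- vapply(decomp@attractors, canonicalKey, character(1))
  if (is(attractor, "Attractor")) attractor <- attractor@canonicalKey
  if (is.character(attractor)) {
    i <- match(attractor, keys)
    if (is.na(i)) stop("attractor ", attractor, " is not part of this ",
                       "decomposition", call. = FALSE)
    return(i)
  }
  i <- as.integer(attractor)
  if (i < 1L || i > length(keys))
    stop("attractor index out of range", call. = FALSE)
  i
}
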