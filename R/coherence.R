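# Coherence metrics. The coherence of a state is the fraction of its N
# single-bit-flip neighbours that lie in the same basin of attraction;
# basin / attractor / network coherence average this over a basin, over an
# attractor's cycle states, and over the whole state space.

# per-state coherence vector for all 2^N states, from the assignment map
.coherencePerState <- function(assignment, n) {
  states <- 0:(2L^n - 1L)
  same <- numeric(length(states))
  for (i in seq_len(n)) {
    nb <- bitwXor(states, bitwShiftL(1L, n - i))
    same <- same + (assignment[nb + 1L] == assignment)
  }
  same / n
}

#' State, basin, attractor and network coherence
#'
#' `stateCoherence` returns `psi_x`, the fraction of the N single-bit
#' neighbours of `x` assigned to the same attractor as `x`; each perturbed
#' state is classified by following the deterministic dynamics to its
#' attractor, as encoded in the decomposition's assignment map.
#'
#' @param net A [BooleanNetwork-class].
#' @param decomposition A [BasinDecomposition-class] of `net`.
#' @param x State (0/1 vector, bitstring, or MSB-first code).
#' @return A fraction in `[0, 1]`.
#' @examples
#' F <- network(fixtureF()); d <- basinDecomposition(F)
#' stateCoherence(F, d, "100")     # 1/3
#' basinCoherence(F, d, 1)         # 2/3
#' attractorCoherence(F, d, 1)     # 1/3
#' networkCoherence(F, d)          # 14/24
#' @export
stateCoherence <- function(net, decomposition, x) {
  n <- nNodes(net)
  bits <- .asStateBits(x, n)
  code <- .codeOfBits(bits)
  a <- decomposition@assignment
  own <- a[code + 1L]
  nb <- bitwXor(as.integer(code), bitwShiftL(1L, n - seq_len(n)))
  mean(a[nb + 1L] == own)
}

#' @rdname stateCoherence
#' @param attractor Attractor index, [Attractor-class], or canonical key.
#' @return `basinCoherence`: the unweighted mean of `stateCoherence` over all
#'   states assigned to the attractor.
#' @export
basinCoherence <- function(net, decomposition, attractor) {
  i <- .attractorIndex(decomposition, attractor)
  n <- nNodes(net)
  psi <- .coherencePerState(decomposition@assignment, n)
  mean(psi[decomposition@assignment == i])
}

#' @rdname stateCoherence
#' @return `attractorCoherence`: the mean of `stateCoherence` over the cycle
#'   states of the attractor only.
#' @export
attractorCoherence <- function(net, decomposition, attractor) {
  i <- .attractorIndex(decomposition, attractor)
  codes <- decomposition@attractors[[i]]@stateCodes
  mean(vapply(codes, function(cd) stateCoherence(net, decomposition, cd),
              numeric(1)))
}

#' @rdname stateCoherence
#' @return `networkCoherence`: the mean coherence over all `2^N` states,
#'   equivalently the basin-size-weighted mean of the basin coherences.
#' @export
networkCoherence <- function(net, decomposition) {
  mean(.coherencePerState(decomposition@assignment, nNodes(net)))
}

#' Per-attractor coherence records of one network
#'
#' One row per attractor: relative basin size, basin coherence, attractor
#' coherence, period. These rows are the unit of analysis pooled across an
#' ensemble (each record is one attractor) and feed [coherenceCurves()].
#'
#' @param net A [BooleanNetwork-class].
#' @param decomposition A [BasinDecomposition-class] of `net`; computed on
#'   the fly when missing.
#' @param networkId Identifier stored in the `network_id` column.
#' @return Data frame with columns `network_id`, `attractor_key`, `period`,
#'   `relative_basin_size`, `basin_coherence`, `attractor_coherence`,
#'   `exact_flag`.
#' @examples
#' attractorRecords(network(fixtureF()))
#' @export
attractorRecords <- function(net, decomposition = basinDecomposition(net),
                             networkId = "net") {
  n <- nNodes(net)
  asg <- decomposition@assignment
  psi <- .coherencePerState(asg, n)
  nA <- length(decomposition@attractors)
  basinCoh <- as.numeric(rowsum(psi, asg)[, 1L]) / decomposition@basinSizes
  attrCoh <- vapply(decomposition@attractors, function(a)
    mean(psi[a@stateCodes + 1L]), numeric(1))
  data.frame(network_id = rep(networkId, nA),
             attractor_key = vapply(decomposition@attractors, canonicalKey,
                                    character(1)),
             period = vapply(decomposition@attractors, period, integer(1)),
             relative_basin_size = decomposition@basinSizes / 2^n,
             basin_coherence = basinCoh,
             attractor_coherence = attrCoh,
             exact_flag = rep(TRUE, nA),
             stringsAsFactors = FALSE)
}

#' Read and write pooled attractor-record tables
#'
#' Tab-separated serialisation of the per-attractor records produced by
#' [attractorRecords()], [sampledRecords()] or [runEnsemble()].
#'
#' @param records Attractor-record data frame.
#' @param file Path of the TSV file.
#' @return `readAttractorRecords`: the records data frame.
#' @export
writeAttractorRecords <- function(records, file) {
  utils::write.table(records, file, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(file)
}

#' @rdname writeAttractorRecords
#' @export
readAttractorRecords <- function(file) {
  utils::read.table(file, header = TRUE, sep = "\t",
                    colClasses = c(attractor_key = "character"))
}
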