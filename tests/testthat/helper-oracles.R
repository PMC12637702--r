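# Independent oracles used across the suite. These deliberately avoid the
# package's vectorised successor-map/squaring machinery: states are iterated
# one by one with plain list bookkeeping, so agreement is a genuine
# two-route check.

# brute-force decomposition: follow each state's trajectory with a visited
# list until a repeat, classify cycles by their smallest member
naiveDecomposition <- function(net) {
  n <- nNodes(net)
  nStates <- 2^n
  attractorOf <- rep(NA_integer_, nStates)
  cycleKeys <- character(0)
  cycles <- list()
  for (m in 0:(nStates - 1)) {
    bits <- as.integer(bitwAnd(bitwShiftR(m, (n - 1):0), 1))
    path <- integer(0)
    repeat {
      code <- sum(bits * 2^((n - 1):0))
      if (!is.na(attractorOf[code + 1])) break
      if (code %in% path) {
        cyc <- path[which(path == code):length(path)]
        key <- as.character(min(cyc))
        if (!key %in% cycleKeys) {
          cycleKeys <- c(cycleKeys, key)
          cycles[[length(cycles) + 1]] <- sort(cyc)
        }
        attractorOf[path + 1] <- match(key, cycleKeys)
        break
      }
      path <- c(path, code)
      bits <- synchronousStep(net, bits)
    }
    if (length(path) && anyNA(attractorOf[path + 1])) {
      code <- sum(bits * 2^((n - 1):0))
      attractorOf[path + 1] <- attractorOf[code + 1]
    }
  }
  list(assignment = attractorOf, cycles = cycles,
       basinSizes = tabulate(attractorOf, nbins = length(cycles)))
}

# per-state coherence straight from the definition
naiveStateCoherence <- function(net, naive, code) {
  n <- nNodes(net)
  own <- naive$assignment[code + 1]
  mean(vapply(seq_len(n), function(i) {
    naive$assignment[bitwXor(code, 2^(n - i)) + 1] == own
  }, logical(1)))
}

# all (position, input, output) canalizing triples by direct testing
naiveCanalizingTriples <- function(f) {
  k <- arity(f)
  out <- NULL
  grid <- as.matrix(expand.grid(rep(list(0:1), k)))[, k:1, drop = FALSE]
  vals <- apply(grid, 1, function(x) evaluate(f, x))
  for (i in seq_len(k)) for (a in 0:1) {
    sel <- vals[grid[, i] == a]
    if (length(unique(sel)) == 1)
      out <- rbind(out, c(i, a, sel[1]))
  }
  out
}

# a small assortment of random networks for property loops
randomTestNetworks <- function(nNets, nNodes, inDegree, seed) {
  set.seed(seed)
  lapply(seq_len(nNets), function(i)
    randomNetwork(nNodes, inDegree, allowSelfInputs = TRUE,
                  requireStrongConnectivity = FALSE))
}
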