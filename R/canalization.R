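# Canalization analytics: bias, sensitivity, canalizing variables, layer
# structure, and the canonical nested canalizing representatives.

#' Bias profile of a Boolean function
#'
#' The bias p is the fraction of ones in the truth table. Two derived metrics
#' are reported: the absolute bias `a(p) = |2p - 1|` (0 for unbiased, 1 for
#' maximally biased rules) and the standardized bias `zeta(p) = p(1 - p)`
#' (0.25 for unbiased, 0 for maximally biased rules). They satisfy the
#' identity `4 zeta = 1 - a^2`.
#'
#' @param f A [BooleanFunction-class].
#' @return Named numeric vector with elements `p`, `absBias`, `stdBias`.
#' @examples
#' biasProfile(canonicalNCF(c(5)))    # 5-input OR: p = 31/32
#' @export
biasProfile <- function(f) {
  p <- sum(f@truthTable) / length(f@truthTable)
  c(p = p, absBias = abs(2 * p - 1), stdBias = p * (1 - p))
}

#' Average sensitivity of a Boolean function
#'
#' The expected number of the n single-input flips that change the output,
#' averaged over all `2^n` inputs:
#' `S(f) = 2^-n * sum_x sum_i 1[f(x) != f(x + e_i)]`.
#' The mean rule sensitivity of a network is the standard proxy for its
#' dynamical regime (ordered < 1, critical ~ 1, chaotic > 1).
#'
#' @param f A [BooleanFunction-class] with `arity >= 1`.
#' @return The average sensitivity, a scalar in `[0, arity]`.
#' @examples
#' averageSensitivity(canonicalNCF(c(5)))  # 0.3125
#' @export
averageSensitivity <- function(f) {
  k <- f@arity
  if (k == 0L)
    stop("average sensitivity is undefined for arity-0 functions", call. = FALSE)
  tt <- f@truthTable
  m <- 0:(length(tt) - 1L)
  s <- 0
  for (i in seq_len(k))
    s <- s + mean(tt != tt[bitwXor(m, bitwShiftL(1L, k - i)) + 1L])
  s
}

#' Canalizing variables of a Boolean function
#'
#' Variable `x_i` is canalizing if some fixed value `a` forces the output to a
#' constant `b` regardless of the other inputs. All such (position, canalizing
#' input, canalized output) triples are returned; a variable of a 1-input
#' function canalizes with both its values.
#'
#' @param f A non-constant [BooleanFunction-class].
#' @return Data frame with columns `position`, `canalizingInput`,
#'   `canalizedOutput` (zero rows for non-canalizing functions).
#' @examples
#' canalizingVariables(BooleanFunction(c(0, 1, 1, 0)))  # XOR: none
#' @export
canalizingVariables <- function(f) {
  tt <- f@truthTable
  if (all(tt == tt[1L]))
    stop("canalizing variables are undefined for constant functions", call. = FALSE)
  k <- f@arity
  out <- list()
  for (i in seq_len(k)) for (a in c(0L, 1L)) {
    slice <- .ttSlice(tt, k, i, a)
    if (all(slice == slice[1L]))
      out[[length(out) + 1L]] <- c(i, a, slice[1L])
  }
  res <- do.call(rbind, out)
  if (is.null(res)) res <- matrix(integer(), ncol = 3L)
  res <- as.data.frame(res)
  names(res) <- c("position", "canalizingInput", "canalizedOutput")
  res
}

# restrict tt over k inputs by fixing positions `pos` to values `val`
.ttRestrict <- function(tt, k, pos, val) {
  m <- 0:(length(tt) - 1L)
  keep <- rep(TRUE, length(tt))
  for (j in seq_along(pos))
    keep <- keep & bitwAnd(bitwShiftR(m, k - pos[j]), 1L) == val[j]
  tt[keep]
}

#' Canalizing layer structure of a Boolean function
#'
#' Iterative peeling: all currently canalizing variables form a layer; their
#' non-canalizing values are substituted, and the procedure repeats on the
#' restricted function until it becomes constant or non-canalizing. The depth
#' is the total number of peeled variables; a function is nested canalizing
#' (NCF) when its depth equals its arity.
#'
#' Degenerate or constant functions are rejected: reduce them to their
#' [essentialInputs()] first.
#'
#' @param f A non-degenerate [BooleanFunction-class].
#' @return A [LayerStructure-class].
#' @examples
#' layers(layerStructure(BooleanFunction(c(0, 0, 0, 0, 0, 0, 0, 1))))  # AND3: 3
#' layers(layerStructure(BooleanFunction(c(0, 0, 0, 0, 0, 1, 1, 1))))  # x&(y|z): 1 2
#' @export
layerStructure <- function(f) {
  if (!isNonDegenerate(f))
    stop("layer structure requires a non-degenerate, non-constant function; ",
         "restrict the function to its essential inputs first", call. = FALSE)
  tt <- f@truthTable
  k <- f@arity
  sizes <- integer()
  while (k > 0L) {
    cv <- canalizingVariables(BooleanFunction(tt))
    if (!nrow(cv)) break
    cv <- cv[!duplicated(cv$position), , drop = FALSE]
    sizes <- c(sizes, nrow(cv))
    tt <- .ttRestrict(tt, k, cv$position, 1L - cv$canalizingInput)
    k <- k - nrow(cv)
    if (all(tt == tt[1L])) break
  }
  new("LayerStructure", layers = sizes, depth = sum(sizes),
      arity = f@arity, isNCF = sum(sizes) == f@arity)
}

#' @describeIn layerStructure Layer sizes (k1, ..., kr) of a
#'   [LayerStructure-class].
#' @param x A [LayerStructure-class].
#' @export
layers <- function(x) x@layers

#' @describeIn layerStructure Canalizing depth (sum of layer sizes).
#' @export
canalizingDepth <- function(x) x@depth

#' @describeIn layerStructure Whether the depth covers the arity (an NCF).
#' @export
isNCF <- function(x) x@isNCF

#' @export
setMethod("show", "LayerStructure", function(object) {
  cat(sprintf("LayerStructure (%s): depth %d of arity %d%s\n",
              paste(object@layers, collapse = ", "), object@depth,
              object@arity, if (object@isNCF) " [NCF]" else ""))
})

#' Enumerate the layer structures of n-input NCFs
#'
#' All compositions (k1, ..., kr) of n whose last part is at least 2; there
#' are exactly `2^(n-2)` of them, ordered by the Hamming weight of their
#' canonical representative (most biased first, matching the usual
#' stratification tables).
#'
#' @param n Arity, at least 2.
#' @return List of integer vectors, each a valid layer structure.
#' @examples
#' enumerateLayerStructures(3)  # (3), (1, 2)
#' @export
enumerateLayerStructures <- function(n) {
  n <- .checkCount(n, "n", min = 2)
  compose <- function(m) {
    if (m == 0L) return(list(integer()))
    out <- list()
    for (first in seq_len(m))
      out <- c(out, lapply(compose(m - first), function(rest) c(first, rest)))
    out
  }
  comps <- Filter(function(kk) kk[length(kk)] >= 2L, compose(n))
  w <- vapply(comps, function(kk) {
    h <- hammingWeight(canonicalNCF(kk))
    min(h, 2^n - h)
  }, numeric(1))
  comps[order(w)]
}

# general canalized truth-table builder; layerVars: list of index vectors,
# aVals: per-variable canalizing inputs (indexed by position), bVals: one
# canalized output per layer (must alternate); core: list(vars, tt) or NULL
# (NULL means the fall-through output is the complement of the last layer's)
.canalizedTT <- function(n, layerVars, aVals, bVals, core = NULL) {
  m <- 0:(2L^n - 1L)
  bit <- function(v) bitwAnd(bitwShiftR(m, n - v), 1L)
  res <- rep(NA_integer_, length(m))
  active <- rep(TRUE, length(m))
  for (j in seq_along(layerVars)) {
    fired <- rep(FALSE, length(m))
    for (v in layerVars[[j]]) fired <- fired | bit(v) == aVals[v]
    fired <- active & fired
    res[fired] <- bVals[j]
    active <- active & !fired
  }
  if (is.null(core)) {
    res[active] <- 1L - bVals[length(bVals)]
  } else {
    idx <- 0L
    for (v in core$vars) idx <- idx * 2L + bit(v)
    res[active] <- core$tt[idx[active] + 1L]
  }
  res
}

#' Canonical NCF representative of a layer structure
#'
#' Builds the alternating or/and representative: the first layer's variables
#' are joined by `|`, the next layer's by `&`, and so on, e.g. structure
#' (3, 2) over 5 inputs gives `A | B | C | (D & E)`. All NCFs sharing a layer
#' structure share this representative's absolute bias and average
#' sensitivity.
#'
#' @param structure Integer vector (k1, ..., kr) with last part >= 2 (or the
#'   trivial structure `1` for arity 1).
#' @param n Arity; defaults to `sum(structure)`.
#' @return A [BooleanFunction-class].
#' @examples
#' canonicalNCF(c(3, 2))  # A | B | C | (D & E)
#' @export
canonicalNCF <- function(structure, n = sum(structure)) {
  kk <- as.integer(structure)
  if (!length(kk) || any(kk < 1L) || sum(kk) != n)
    stop("structure must be a composition of n with positive parts", call. = FALSE)
  if (n >= 2L && kk[length(kk)] < 2L)
    stop("the final layer of an NCF with arity >= 2 must have size >= 2",
         call. = FALSE)
  ends <- cumsum(kk)
  layerVars <- mapply(function(a, b) seq.int(a, b), ends - kk + 1L, ends,
                      SIMPLIFY = FALSE)
  bVals <- rep_len(c(1L, 0L), length(kk))
  aVals <- integer(n)
  for (j in seq_along(layerVars)) aVals[layerVars[[j]]] <- bVals[j]
  BooleanFunction(.canalizedTT(n, layerVars, aVals, bVals))
}

#' One-row analytic profile of a Boolean function
#'
#' Collects arity, Hamming weight, bias metrics, average sensitivity and
#' canalizing layer structure into a single serialisable row (layer fields are
#' `NA` for degenerate or constant functions).
#'
#' @param f A [BooleanFunction-class].
#' @return One-row data frame with columns `arity`, `hamming_weight`, `p`,
#'   `abs_bias`, `std_bias`, `sensitivity`, `layer_structure` (dash-joined),
#'   `depth`, `is_ncf`.
#' @examples
#' functionProfile(canonicalNCF(c(1, 4)))
#' @export
functionProfile <- function(f) {
  b <- biasProfile(f)
  sens <- if (f@arity >= 1L) averageSensitivity(f) else NA_real_
  if (isNonDegenerate(f)) {
    ls <- layerStructure(f)
    lsStr <- paste(ls@layers, collapse = "-")
    depth <- ls@depth
    ncf <- ls@isNCF
  } else {
    lsStr <- NA_character_; depth <- NA_integer_; ncf <- NA
  }
  data.frame(arity = f@arity, hamming_weight = hammingWeight(f),
             p = unname(b["p"]), abs_bias = unname(b["absBias"]),
             std_bias = unname(b["stdBias"]), sensitivity = sens,
             layer_structure = lsStr, depth = depth, is_ncf = ncf,
             stringsAsFactors = FALSE)
}
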