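# Random Boolean-rule generators. All draw from R's global RNG so that a
# single set.seed() call makes any downstream analysis reproducible.

# uniform truth table, rejection-sampled until non-degenerate
.rndNondegTT <- function(k) {
  k <- as.integer(k)
  repeat {
    tt <- sample(c(0L, 1L), 2L^k, replace = TRUE)
    if (any(tt != tt[1L]) &&
        isNonDegenerate(new("BooleanFunction", arity = k, truthTable = tt)))
      return(tt)
  }
}

# non-degenerate with no canalizing variable (the "core" of a canalized rule)
.rndNonCanalizingTT <- function(k) {
  if (k < 2L)
    stop("no non-canalizing non-degenerate function exists for arity < 2",
         call. = FALSE)
  repeat {
    tt <- .rndNondegTT(k)
    if (!nrow(canalizingVariables(new("BooleanFunction", arity = k,
                                      truthTable = tt))))
      return(tt)
  }
}

# standard-monomial-form draw: the canalized outputs b_1..b_k are iid coin
# flips (for an NCF the last two are tied), so runs of equal outputs define
# the layers and every layer structure is equally likely; variables are
# assigned by a uniform permutation and canalizing inputs drawn uniformly.
.rndCanalizedTT <- function(n, k) {
  stopifnot(k >= 1L, k <= n)
  if (k == n) {
    b <- if (n == 1L) sample(c(0L, 1L), 1L)
         else {
           bb <- sample(c(0L, 1L), n - 1L, replace = TRUE)
           c(bb, bb[n - 1L])
         }
  } else {
    b <- sample(c(0L, 1L), k, replace = TRUE)
  }
  runs <- rle(b)
  perm <- sample.int(n)
  ends <- cumsum(runs$lengths)
  layerVars <- mapply(function(a, e) perm[seq.int(a, e)],
                      ends - runs$lengths + 1L, ends, SIMPLIFY = FALSE)
  aVals <- integer(n)
  aVals[perm[seq_len(k)]] <- sample(c(0L, 1L), k, replace = TRUE)
  core <- if (k < n)
    list(vars = perm[(k + 1L):n], tt = .rndNonCanalizingTT(n - k))
  else NULL
  .canalizedTT(n, layerVars, aVals, runs$values, core)
}

#' Random non-degenerate Boolean function
#'
#' Uniform over all truth tables of the given arity, rejection-sampled until
#' every input is essential and the function is non-constant (the rule class
#' of the "random" ensembles and of the null models).
#'
#' @param arity Number of inputs, at least 1.
#' @return A [BooleanFunction-class].
#' @examples
#' set.seed(1); randomNondegenerateFunction(3)
#' @export
randomNondegenerateFunction <- function(arity) {
  k <- .checkCount(arity, "arity")
  new("BooleanFunction", arity = k, truthTable = .rndNondegTT(k))
}

#' Random Boolean function with exact canalizing depth
#'
#' Builds canalizing layers for `depth` variables (uniform layer composition
#' via the standard monomial form, uniform canalizing inputs and output
#' polarity) around a uniformly drawn non-canalizing, non-degenerate core on
#' the remaining variables. The resulting layer structure has depth exactly
#' `depth`; `depth = arity` yields an NCF. `depth = arity - 1` is infeasible
#' (a single remaining variable is always canalizing) and is rejected.
#'
#' @param arity Number of inputs.
#' @param depth Exact canalizing depth, in `0..arity` excluding `arity - 1`.
#' @return A [BooleanFunction-class].
#' @examples
#' set.seed(1)
#' canalizingDepth(layerStructure(randomFunctionWithDepth(4, 2)))  # 2
#' @export
randomFunctionWithDepth <- function(arity, depth) {
  n <- .checkCount(arity, "arity")
  k <- .checkCount(depth, "depth", min = 0)
  if (k > n) stop("depth cannot exceed arity", call. = FALSE)
  if (n >= 2L && k == n - 1L)
    stop("exact depth arity - 1 is infeasible: the last remaining variable ",
         "is always canalizing", call. = FALSE)
  if (k == 0L) {
    if (n < 2L)
      stop("every non-degenerate 1-input function is canalizing", call. = FALSE)
    return(new("BooleanFunction", arity = n, truthTable = .rndNonCanalizingTT(n)))
  }
  new("BooleanFunction", arity = n, truthTable = .rndCanalizedTT(n, k))
}

#' Random nested canalizing function
#'
#' Draws an NCF via the standard monomial form: every layer structure of the
#' arity is equally likely, and variable-to-layer assignment, canalizing
#' inputs and output polarity are uniform.
#'
#' @param arity Number of inputs.
#' @return A [BooleanFunction-class] whose canalizing depth equals its arity.
#' @examples
#' set.seed(1); isNCF(layerStructure(randomNCF(3)))
#' @export
randomNCF <- function(arity) {
  n <- .checkCount(arity, "arity")
  new("BooleanFunction", arity = n, truthTable = .rndCanalizedTT(n, n))
}

#' Random NCF with a fixed layer structure
#'
#' Uniform over variable-to-layer assignments, canalizing input values and
#' output polarity, conditioned on the exact layer structure.
#'
#' @param structure Integer composition (k1, ..., kr) with last part >= 2 (or
#'   `1` for arity 1).
#' @return A [BooleanFunction-class] with `layerStructure()` equal to
#'   `structure`.
#' @examples
#' set.seed(1)
#' layers(layerStructure(randomNCFWithLayerStructure(c(1, 2, 2))))
#' @export
randomNCFWithLayerStructure <- function(structure) {
  kk <- as.integer(structure)
  n <- sum(kk)
  if (!length(kk) || any(kk < 1L) || (n >= 2L && kk[length(kk)] < 2L))
    stop("invalid layer structure: parts must be positive and the last ",
         "part >= 2", call. = FALSE)
  perm <- sample.int(n)
  ends <- cumsum(kk)
  layerVars <- mapply(function(a, e) perm[seq.int(a, e)],
                      ends - kk + 1L, ends, SIMPLIFY = FALSE)
  b1 <- sample(c(0L, 1L), 1L)
  bVals <- if (b1 == 1L) rep_len(c(1L, 0L), length(kk))
           else rep_len(c(0L, 1L), length(kk))
  aVals <- integer(n)
  aVals[perm] <- sample(c(0L, 1L), n, replace = TRUE)
  new("BooleanFunction", arity = n,
      truthTable = .canalizedTT(n, layerVars, aVals, bVals))
}
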