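#' Construct a Boolean function from its truth table
#'
#' @param truthTable Vector of `2^k` zeros and ones, MSB-first: entry `m + 1`
#'   is the output for the input whose bits (x1 most significant) encode `m`.
#'   A length-1 table defines a constant (arity-0) function.
#' @return A [BooleanFunction-class].
#' @examples
#' and3 <- BooleanFunction(c(0, 0, 0, 0, 0, 0, 0, 1))
#' evaluate(and3, c(1, 1, 1))
#' @export
BooleanFunction <- function(truthTable) {
  tt <- as.integer(truthTable)
  k <- log2(length(tt))
  if (length(tt) < 1L || k != round(k))
    stop("truth table length must be a power of two", call. = FALSE)
  new("BooleanFunction", arity = as.integer(k), truthTable = tt)
}

#' @describeIn BooleanFunction Number of inputs of a Boolean function.
#' @param f A [BooleanFunction-class].
#' @export
arity <- function(f) f@arity

#' @describeIn BooleanFunction The stored truth table (MSB-first).
#' @export
truthTable <- function(f) f@truthTable

#' @describeIn BooleanFunction Number of ones in the truth table.
#' @export
hammingWeight <- function(f) sum(f@truthTable)

#' Evaluate a Boolean function on one input vector
#'
#' Looks up the truth-table entry whose MSB-first bits are the inputs.
#'
#' @param f A [BooleanFunction-class].
#' @param inputs Binary vector of length `arity(f)`.
#' @return 0 or 1.
#' @export
setGeneric("evaluate", function(f, inputs) standardGeneric("evaluate"))

#' @rdname evaluate
#' @export
setMethod("evaluate", "BooleanFunction", function(f, inputs) {
  if (length(inputs) != f@arity)
    stop("expected ", f@arity, " inputs, got ", length(inputs), call. = FALSE)
  if (anyNA(inputs) || !all(inputs %in% c(0, 1)))
    stop("inputs must be 0 or 1", call. = FALSE)
  f@truthTable[.codeOfBits(as.integer(inputs)) + 1L]
})

# truth-table entries where input position i (1-based, MSB-first) equals a
.ttSlice <- function(tt, k, i, a) {
  m <- 0:(length(tt) - 1L)
  tt[bitwAnd(bitwShiftR(m, k - i), 1L) == a]
}

#' Essential inputs of a Boolean function
#'
#' Input position `i` is essential iff two input vectors differing only at
#' position `i` give different outputs. A function is non-degenerate when all
#' its declared inputs are essential and it is non-constant; random-network
#' generation and the null-model pipeline require non-degenerate rules, which
#' excludes e.g. `x | y` declared as a 3-input rule.
#'
#' @param f A [BooleanFunction-class].
#' @return `essentialInputs`: integer vector of essential positions.
#' @examples
#' or2as3 <- BooleanFunction(c(0, 0, 1, 1, 1, 1, 1, 1)) # x1 | x2 with dummy x3
#' essentialInputs(or2as3)
#' isNonDegenerate(or2as3)
#' @export
essentialInputs <- function(f) {
  k <- f@arity
  if (k == 0L) return(integer())
  tt <- f@truthTable
  which(vapply(seq_len(k), function(i)
    any(.ttSlice(tt, k, i, 0L) != .ttSlice(tt, k, i, 1L)), logical(1)))
}

#' @rdname essentialInputs
#' @return `isNonDegenerate`: `TRUE` iff all inputs are essential and the
#'   function is non-constant.
#' @export
isNonDegenerate <- function(f) {
  tt <- f@truthTable
  if (all(tt == tt[1L])) return(FALSE)
  length(essentialInputs(f)) == f@arity
}

#' @export
setMethod("show", "BooleanFunction", function(object) {
  cat(sprintf("BooleanFunction with %d input(s), truth table %s\n",
              object@arity, paste(object@truthTable, collapse = "")))
})
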