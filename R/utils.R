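# Internal bit/state helpers. State codes are MSB-first: node 1 is the most
# significant bit, so the all-zero state has code 0 and "100" (3 nodes) code 4.

# bits (vector or matrix rows) -> integer code; exact only for N <= 53
.codeOfBits <- function(bits) {
  if (is.matrix(bits)) {
    n <- ncol(bits)
    as.numeric(bits %*% 2^((n - 1L):0L))
  } else {
    n <- length(bits)
    sum(bits * 2^((n - 1L):0L))
  }
}

# codes -> integer matrix of bits, one row per code
.bitsOfCodes <- function(codes, n) {
  out <- matrix(0L, nrow = length(codes), ncol = n)
  for (j in seq_len(n))
    out[, j] <- as.integer(bitwAnd(bitwShiftR(as.integer(codes), n - j), 1L))
  out
}

.keyOfBits <- function(bits) paste(bits, collapse = "")

.bitsOfKey <- function(key) as.integer(strsplit(key, "", fixed = TRUE)[[1]])

# parse a user-facing state: integer code, 0/1 vector, or "0101" string
.asStateBits <- function(x, n) {
  if (is.character(x) && length(x) == 1L) x <- .bitsOfKey(x)
  if (length(x) == 1L && n > 1L)  # a single number is read as an MSB-first code
    x <- as.integer(bitwAnd(bitwShiftR(as.integer(x), (n - 1L):0L), 1L))
  if (length(x) != n)
    stop("state must have length N = ", n, call. = FALSE)
  if (anyNA(x) || !all(x %in% c(0, 1)))
    stop("state entries must be 0 or 1", call. = FALSE)
  as.integer(x)
}

.checkCount <- function(x, name, min = 1) {
  if (length(x) != 1L || is.na(x) || x < min)
    stop(name, " must be a single number >= ", min, call. = FALSE)
  as.integer(x)
}

#' Unweighted rolling-window mean
#'
#' Presentation utility mirroring the rolling means (window 50 or 500) used to
#' visualise coherence against basin size: the input is first ordered by `by`
#' (typically relative basin size) and a centred moving average of `x` is
#' returned in that order.
#'
#' @param x Numeric vector to smooth.
#' @param window Window width in observations.
#' @param by Optional ranking variable; the result is ordered by rank of `by`.
#' @return Data frame with the ordered `by`, ordered `x` and the rolling mean
#'   (`NA` where the centred window is incomplete).
#' @examples
#' rollingMean(runif(100), window = 10)
#' @export
rollingMean <- function(x, window, by = NULL) {
  stopifnot(window >= 1, window <= length(x))
  ord <- if (is.null(by)) seq_along(x) else order(by)
  xs <- x[ord]
  rm <- stats::filter(xs, rep(1 / window, window), sides = 2)
  data.frame(by = if (is.null(by)) ord else by[ord], x = xs,
             rollingMean = as.numeric(rm))
}
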