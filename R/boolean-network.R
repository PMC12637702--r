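#' Construct a Boolean network
#'
#' Assembles a synchronously updated Boolean network from truth tables and
#' regulator lists. Regulators may be given as indices or node names.
#'
#' @param rules List of [BooleanFunction-class] objects (or raw truth-table
#'   vectors), one per node.
#' @param regulators List of regulator index (or name) vectors, one per node,
#'   ordered to match each rule's inputs.
#' @param nodeNames Optional node identifiers; defaults to `x1, x2, ...`.
#' @return A [BooleanNetwork-class].
#' @examples
#' # 1-node negation: a period-2 attractor covering the whole state space
#' BooleanNetwork(list(c(1, 0)), list(1))
#' @export
BooleanNetwork <- function(rules, regulators, nodeNames = NULL) {
  n <- length(rules)
  if (is.null(nodeNames)) nodeNames <- paste0("x", seq_len(n))
  rules <- lapply(rules, function(r)
    if (is(r, "BooleanFunction")) r else BooleanFunction(r))
  regulators <- lapply(regulators, function(r) {
    if (is.character(r)) r <- match(r, nodeNames)
    as.integer(r)
  })
  new("BooleanNetwork", nodeNames = as.character(nodeNames),
      regulators = regulators, rules = rules)
}

#' @describeIn BooleanNetwork Number of nodes.
#' @param net A [BooleanNetwork-class].
#' @export
nNodes <- function(net) length(net@nodeNames)

#' @describeIn BooleanNetwork Node identifiers.
#' @export
nodeNames <- function(net) net@nodeNames

#' @describeIn BooleanNetwork Per-node regulator index lists (the wiring
#'   diagram).
#' @export
regulators <- function(net) net@regulators

#' @describeIn BooleanNetwork Per-node update rules.
#' @export
rules <- function(net) net@rules

#' @export
setMethod("show", "BooleanNetwork", function(object) {
  cat(sprintf("BooleanNetwork with %d nodes: %s\n", nNodes(object),
              paste(utils::head(object@nodeNames, 8), collapse = ", ")))
  degs <- lengths(object@regulators)
  cat(sprintf("  in-degrees: min %d, max %d\n",
              if (length(degs)) min(degs) else 0L,
              if (length(degs)) max(degs) else 0L))
})

#' One synchronous update step
#'
#' Applies `F(x) = (f1(x), ..., fN(x))`: every rule is evaluated on its
#' regulators' values in `x` and all nodes update simultaneously.
#'
#' @param net A [BooleanNetwork-class].
#' @param x State: a length-N 0/1 vector, a bitstring like `"100"`, or an
#'   MSB-first integer code.
#' @return Integer 0/1 vector of length N, the successor state.
#' @examples
#' synchronousStep(network(fixtureF()), "100")  # fixed point
#' @export
synchronousStep <- function(net, x) {
  bits <- .asStateBits(x, nNodes(net))
  .stepBits(net@rules, net@regulators, bits)
}

.stepBits <- function(ruleList, regList, bits) {
  out <- integer(length(bits))
  for (i in seq_along(out)) {
    f <- ruleList[[i]]
    regs <- regList[[i]]
    idx <- 0L
    for (r in regs) idx <- idx * 2L + bits[r]
    out[i] <- f@truthTable[idx + 1L]
  }
  out
}

# strong connectivity of the regulator->target digraph via forward/backward
# reachability from node 1 (boolean matrix fixpoint; N is small)
.stronglyConnectedRegs <- function(regList, n) {
  if (n == 1L) return(TRUE)
  adj <- matrix(FALSE, n, n)   # adj[i, j]: edge j -> i (j regulates i)
  for (i in seq_len(n)) adj[i, regList[[i]]] <- TRUE
  reach <- function(a) {
    r <- logical(n); r[1L] <- TRUE
    repeat {
      nr <- r | (a %*% r > 0)
      if (all(nr == r)) return(r)
      r <- nr
    }
  }
  all(reach(adj)) && all(reach(t(adj)))
}

#' Strong connectivity of the wiring diagram
#'
#' `TRUE` iff the directed graph with an edge from every regulator to its
#' target has a single strongly connected component covering all nodes (the
#' wiring constraint imposed on all random ensembles).
#'
#' @param net A [BooleanNetwork-class].
#' @return Logical scalar.
#' @export
isStronglyConnected <- function(net) {
  .stronglyConnectedRegs(net@regulators, nNodes(net))
}

# ---- BoolNet-style rule files ----------------------------------------------

.exprToR <- function(expr) {
  e <- expr
  e <- gsub("(?i)\\bAND\\b", "&", e, perl = TRUE)
  e <- gsub("(?i)\\bOR\\b", "|", e, perl = TRUE)
  e <- gsub("(?i)\\bNOT\\b", "!", e, perl = TRUE)
  e
}

.exprVars <- function(exprR) {
  toks <- regmatches(exprR, gregexpr("[A-Za-z._][A-Za-z0-9._]*", exprR))[[1]]
  unique(toks)
}

#' Read and write BoolNet-style rule files
#'
#' `readBooleanNetwork` parses the `targets, factors` format (operators `&`,
#' `|`, `!`, parentheses, constants `0`/`1`) as well as the `NODE = EXPR`
#' dialect with `AND`/`OR`/`NOT` keywords. A node's regulators are the
#' variables of its expression in order of first appearance; each rule's truth
#' table is built by evaluating the expression over all regulator
#' assignments.
#'
#' `writeBooleanNetwork` emits the `targets, factors` format, preserving node
#' order; non-constant rules are written in disjunctive normal form, so a
#' written file re-reads to a network with identical dynamics.
#'
#' @param file Path to a rule file (or, for `text`, the content directly).
#' @param text Optional character vector of lines, used instead of `file`.
#' @return `readBooleanNetwork`: a [BooleanNetwork-class].
#' @examples
#' net <- readBooleanNetwork(text = c("targets, factors",
#'                                    "a, a | b", "b, !a & b"))
#' nodeNames(net)
#' @export
readBooleanNetwork <- function(file, text = NULL) {
  lines <- if (is.null(text)) readLines(file) else text
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  lines <- lines[!grepl("^(?i)targets\\s*,\\s*factors$", lines, perl = TRUE)]
  eq <- grepl("=", lines, fixed = TRUE) & !grepl(",", lines, fixed = TRUE)
  targets <- character(length(lines))
  exprs <- character(length(lines))
  for (i in seq_along(lines)) {
    parts <- if (eq[i]) strsplit(lines[i], "=", fixed = TRUE)[[1]]
             else regmatches(lines[i], regexpr(",", lines[i]), invert = TRUE)[[1]]
    if (length(parts) != 2L)
      stop("cannot parse rule line: ", lines[i], call. = FALSE)
    targets[i] <- trimws(parts[1])
    exprs[i] <- .exprToR(trimws(parts[2]))
  }
  if (anyDuplicated(targets))
    stop("duplicate target node: ", targets[anyDuplicated(targets)], call. = FALSE)
  regs <- list(); tts <- list()
  for (i in seq_along(targets)) {
    vars <- .exprVars(exprs[i])
    if (length(bad <- setdiff(vars, targets)))
      stop("rule for ", targets[i], " references undefined node(s): ",
           paste(bad, collapse = ", "), call. = FALSE)
    k <- length(vars)
    parsed <- parse(text = exprs[i])[[1]]
    tt <- integer(2L^k)
    for (m in seq_len(2L^k) - 1L) {
      env <- list2env(stats::setNames(
        as.list(as.logical(bitwAnd(bitwShiftR(m, (k - 1L):0L), 1L))), vars))
      tt[m + 1L] <- as.integer(eval(parsed, envir = env))
    }
    regs[[i]] <- match(vars, targets)
    tts[[i]] <- tt
  }
  BooleanNetwork(tts, regs, targets)
}

#' @rdname readBooleanNetwork
#' @param net A [BooleanNetwork-class] to serialise.
#' @return `writeBooleanNetwork`: the file path, invisibly.
#' @export
writeBooleanNetwork <- function(net, file) {
  n <- nNodes(net)
  lines <- c("targets, factors")
  for (i in seq_len(n)) {
    f <- net@rules[[i]]
    regNames <- net@nodeNames[net@regulators[[i]]]
    k <- f@arity
    tt <- f@truthTable
    expr <- if (k == 0L || all(tt == tt[1L])) {
      as.character(tt[1L])
    } else {
      ones <- which(tt == 1L) - 1L
      terms <- vapply(ones, function(m) {
        bits <- bitwAnd(bitwShiftR(m, (k - 1L):0L), 1L)
        paste(ifelse(bits == 1L, regNames, paste0("!", regNames)),
              collapse = " & ")
      }, character(1))
      if (length(terms) == 1L) terms else paste0("(", terms, ")", collapse = " | ")
    }
    lines <- c(lines, paste0(net@nodeNames[i], ", ", expr))
  }
  writeLines(lines, file)
  invisible(file)
}
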