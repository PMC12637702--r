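# Binned conditional-coherence curves: E[psiB | s] and E[psiA | s] on
# n equal subintervals of (0, 1], their AUCs, and the coherence gap.

.binFill <- function(v, policy) {
  occ <- which(!is.na(v))
  if (policy == "renormalize") return(v)
  stats::approx(occ, v[occ], xout = seq_along(v), rule = 2)$y
}

.binAUC <- function(v, policy) {
  if (policy == "renormalize") mean(v, na.rm = TRUE) else mean(.binFill(v, policy))
}

#' Binned conditional-coherence curves and their AUCs
#'
#' Pools per-attractor records, bins them by relative basin size into `nBins`
#' equal subintervals of (0, 1] (bin b covers ((b-1)/nBins, b/nBins]), and
#' computes the empirical conditional means of basin and attractor coherence
#' per bin. The areas under the two curves (AUC:BC, AUC:AC) approximate the
#' basin-size-uniformised expected coherences, with 0.5 the fully-random
#' baseline; their difference is the coherence gap.
#'
#' Empty bins are filled by linear interpolation between the nearest occupied
#' bins (clamped at the ends); `policy = "renormalize"` averages occupied bins
#' only. Ensembles whose longest empty run reaches 0.02 of the size axis are
#' flagged `excluded`, since their conditional means are unreliable over a
#' non-negligible size range.
#'
#' @param records Data frame with columns `relative_basin_size`,
#'   `basin_coherence`, `attractor_coherence` (e.g. pooled
#'   [attractorRecords()] rows).
#' @param nBins Number of subintervals (default 1000).
#' @param policy Empty-bin policy, `"interpolate"` (default) or
#'   `"renormalize"`.
#' @return A [CoherenceCurves-class].
#' @examples
#' recs <- runEnsemble(ensembleSpec(size = 50, seed = 1))@records
#' coherenceCurves(recs)
#' @export
coherenceCurves <- function(records, nBins = 1000L,
                            policy = c("interpolate", "renormalize")) {
  policy <- match.arg(policy)
  nBins <- .checkCount(nBins, "nBins")
  if (!nrow(records))
    stop("cannot bin an empty record set", call. = FALSE)
  s <- records$relative_basin_size
  if (any(s <= 0 | s > 1))
    stop("relative basin sizes must lie in (0, 1]", call. = FALSE)
  bin <- pmin(ceiling(s * nBins), nBins)
  bb <- rep(NA_real_, nBins); ba <- rep(NA_real_, nBins)
  mb <- rowsum(cbind(records$basin_coherence, records$attractor_coherence,
                     1), bin)
  idx <- as.integer(rownames(mb))
  bb[idx] <- mb[, 1] / mb[, 3]
  ba[idx] <- mb[, 2] / mb[, 3]
  gaps <- rle(is.na(bb))
  maxGap <- if (any(gaps$values)) max(gaps$lengths[gaps$values]) / nBins else 0
  aucBC <- .binAUC(bb, policy)
  aucAC <- .binAUC(ba, policy)
  new("CoherenceCurves", nBins = nBins, binMeansBasin = bb,
      binMeansAttractor = ba, aucBC = aucBC, aucAC = aucAC,
      deltaAUC = aucBC - aucAC, maxGap = maxGap,
      excluded = maxGap >= 0.02, policy = policy)
}

#' @describeIn coherenceCurves Area under the basin-coherence curve.
#' @param curves A [CoherenceCurves-class].
#' @export
aucBC <- function(curves) curves@aucBC

#' @describeIn coherenceCurves Area under the attractor-coherence curve.
#' @export
aucAC <- function(curves) curves@aucAC

#' Coherence gap and derived comparisons
#'
#' `coherenceGap` returns `deltaAUC = AUC:BC - AUC:AC`, the coherence gap;
#' `percentAboveBaseline` expresses an AUC as a percentage above the
#' fully-random baseline of 0.5; `relativeDrop` expresses the gap relative to
#' the basin curve's excess over baseline,
#' `100 * deltaAUC / (AUC:BC - 0.5)`. Curves flagged excluded (basin-size
#' support gap >= 0.02) are refused.
#'
#' @param curves A [CoherenceCurves-class].
#' @return A scalar (percentages on the 0-100 scale).
#' @examples
#' percentAboveBaseline(0.75)  # 50
#' @export
coherenceGap <- function(curves) {
  if (curves@excluded)
    stop("curves are excluded: the basin-size distribution has a gap of ",
         signif(curves@maxGap, 3), " >= 0.02", call. = FALSE)
  curves@deltaAUC
}

#' @rdname coherenceGap
#' @param auc An AUC scalar (or [CoherenceCurves-class], whose AUC:BC is used).
#' @export
percentAboveBaseline <- function(auc) {
  if (is(auc, "CoherenceCurves")) auc <- auc@aucBC
  100 * (auc - 0.5) / 0.5
}

#' @rdname coherenceGap
#' @export
relativeDrop <- function(curves) {
  gap <- coherenceGap(curves)
  if (curves@aucBC == 0.5)
    stop("relative drop is undefined when AUC:BC equals the 0.5 baseline",
         call. = FALSE)
  100 * gap / (curves@aucBC - 0.5)
}

#' @rdname coherenceCurves
#' @param file Path of the JSON file to write.
#' @export
writeCoherenceCurves <- function(curves, file) {
  jsonlite::write_json(
    list(n_bins = curves@nBins,
         bin_means_basin = curves@binMeansBasin,
         bin_means_attractor = curves@binMeansAttractor,
         auc_bc = curves@aucBC, auc_ac = curves@aucAC,
         delta_auc = curves@deltaAUC, max_gap = curves@maxGap,
         excluded = curves@excluded, policy = curves@policy),
    file, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(file)
}

#' @export
setMethod("show", "CoherenceCurves", function(object) {
  cat(sprintf(paste0("CoherenceCurves (%d bins, %s): AUC:BC = %.4f, ",
                     "AUC:AC = %.4f, gap = %.4f%s\n"),
              object@nBins, object@policy, object@aucBC, object@aucAC,
              object@deltaAUC,
              if (object@excluded) sprintf(" [excluded: gap %.3f]", object@maxGap)
              else ""))
})
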