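#' @include model.R
NULL

# Integrated gradients along the straight-line path from an all-zeros
# epigenomic background X0 to the real input X: the attribution of signal
# s_t at bin i is the path integral of (dy/dgamma)(dgamma/dalpha), which for
# the straight line reduces to (X - X0) times the path-averaged gradient.
# The target scalar y is the sum of the selected output pixels (upper
# triangle only, to avoid double counting the symmetric matrix).  The graph
# adjacency and positional-encoding rows are held fixed along the path:
# they are not epigenomic inputs.

.regionScalarMask <- function(sample, targetRegion) {
  n <- ncol(sample@X)
  w <- sample@bandBp / sample@resolution
  band <- .bandMaskCached(n, w)
  upper <- outer(seq_len(n), seq_len(n), "<=")
  if (is.character(targetRegion) && identical(targetRegion, "band")) {
    sel <- band > 0 & upper
  } else {
    if (!is.matrix(targetRegion) || !all(dim(targetRegion) == c(n, n)))
      stop("targetRegion must be 'band' or an n x n logical matrix")
    sel <- (targetRegion | t(targetRegion)) & band > 0 & upper
  }
  if (!any(sel)) stop("empty target region")
  sel * 1
}

#' Integrated-gradients attribution of an output region
#'
#' Attributes the summed model output over a target region to every input
#' dimension X[s, i], using a Riemann-midpoint discretization of the path
#' integral from the all-zeros baseline.  The completeness diagnostic
#' |sum(A) - (y(X) - y(X0))| is returned with the result.
#'
#' @param model an \linkS4class{ImputationModel}.
#' @param sample a \linkS4class{WindowSample}.
#' @param targetRegion "band" (the full prediction band) or an n x n logical
#'   matrix selecting output pixels (symmetrized, intersected with the band).
#' @param steps path-discretization count.
#' @return an \linkS4class{AttributionMap}.
#' @export
integratedGradients <- function(model, sample, targetRegion = "band",
                                steps = 300) {
  sel <- .regionScalarMask(sample, targetRegion)
  X <- sample@X
  gradSum <- X * 0
  for (s in seq_len(steps)) {
    alpha <- (s - 0.5) / steps
    fw <- .forwardFull(model, sample, X = alpha * X)
    bk <- .backward(model, fw, sel)
    gradSum <- gradSum + bk$dX
  }
  A <- X * gradSum / steps
  yX <- sum(.forwardFull(model, sample, X = X)$out * sel)
  y0 <- sum(.forwardFull(model, sample, X = X * 0)$out * sel)
  yDiff <- yX - y0
  new("AttributionMap", A = A, featureNames = sample@featureNames,
      steps = steps, yDiff = yDiff,
      completenessGap = abs(sum(A) - yDiff))
}

#' Per-feature overall importance by whole-map attribution
#'
#' Attributes the entire prediction band to all features for each sample and
#' reports, per signal, the mean over samples of the summed absolute
#' attribution, together with the positive and negative attribution mass.
#'
#' @param model an \linkS4class{ImputationModel}.
#' @param samples list of \linkS4class{WindowSample}s.
#' @param steps path-discretization count.
#' @return data.frame with columns feature, importance, positive, negative.
#' @export
featureImportance <- function(model, samples, steps = 300) {
  if (!length(samples)) stop("need at least one sample")
  mats <- lapply(samples, function(sm)
    attributionMatrix(integratedGradients(model, sm, "band", steps = steps)))
  abs_ <- Reduce(`+`, lapply(mats, function(A) rowSums(abs(A)))) / length(mats)
  pos <- Reduce(`+`, lapply(mats, function(A) rowSums(pmax(A, 0)))) / length(mats)
  neg <- Reduce(`+`, lapply(mats, function(A) rowSums(pmin(A, 0)))) / length(mats)
  data.frame(feature = samples[[1]]@featureNames, importance = abs_,
             positive = pos, negative = neg, row.names = NULL)
}

# pixel set of a structure call inside a window, at the window resolution
.callRegionMask <- function(sample, callSet, which = 1, squareBp = 10000) {
  res <- sample@resolution
  n <- ncol(sample@X)
  off <- sample@startBp / res
  cres <- callSet@resolution
  df <- callSet@calls[which, , drop = FALSE]
  mask <- matrix(FALSE, n, n)
  if (df$kind == "loop") {
    half <- squareBp / res / 2
    p <- floor((df$anchor1_start + df$anchor1_end) / 2 * cres / res) - off
    q <- floor((df$anchor2_start + df$anchor2_end) / 2 * cres / res) - off
    if (p + half < 1 || p - half + 1 > n || q + half < 1 || q - half + 1 > n)
      stop("coordinate error: call lies outside the window")
    ri <- max(1, p - half + 1):min(n, p + half)
    rj <- max(1, q - half + 1):min(n, q + half)
    mask[ri, rj] <- TRUE
  } else {
    a1 <- df$anchor1_start * cres / res - off + 1
    a2 <- df$anchor1_end * cres / res - off
    e1 <- df$anchor2_start * cres / res - off + 1
    e2 <- df$anchor2_end * cres / res - off
    ri <- max(1, a1):min(n, a2)
    rj <- max(1, e1):min(n, e2)
    if (!length(ri) || !length(rj) || a2 < 1 || a1 > n || e2 < 1 || e1 > n)
      stop("coordinate error: call lies outside the window")
    mask[ri, rj] <- TRUE
  }
  mask
}

#' Attribute a called structure to the input features
#'
#' The target region is the call's pixel set: the 10 kb x 10 kb square at a
#' loop's anchor pair (the training-mask convention) or a stripe's
#' anchor-by-extent pixel band.  Attribution values are signed: a feature
#' with a peak can still contribute negatively to a structure.
#'
#' @param model an \linkS4class{ImputationModel}.
#' @param sample the \linkS4class{WindowSample} overlapping the call.
#' @param callSet a \linkS4class{StructureCallSet}.
#' @param which row index of the call within `callSet`.
#' @param steps path-discretization count.
#' @return an \linkS4class{AttributionMap}.
#' @export
attributeStructure <- function(model, sample, callSet, which = 1,
                               steps = 300) {
  mask <- .callRegionMask(sample, callSet, which)
  integratedGradients(model, sample, targetRegion = mask, steps = steps)
}
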