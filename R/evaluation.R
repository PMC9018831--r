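#' @include structures.R
NULL

# diagonal-strip representation: strips[i, c] = M[i, i + (c - D - 1)] for
# offsets -D..D, with 0 outside the matrix.  Lets the 2D box filter and all
# per-stratum statistics run in O(n * band) without densifying the map.
.diagStrips <- function(map, D) {
  n <- nrow(map@matrix)
  tr <- .sparseTriplets(map@matrix)
  S <- matrix(0, n, 2 * D + 1)
  if (nrow(tr)) {
    d <- tr$j - tr$i
    keep <- d <= D
    i <- c(tr$i[keep], tr$j[keep & d > 0])
    dd <- c(d[keep], -d[keep & d > 0])
    x <- c(tr$x[keep], tr$x[keep & d > 0])
    S[cbind(i, dd + D + 1)] <- x
  }
  S
}

# (2h+1)^2 uniform filter in full-matrix coordinates, applied in strip space
# with zero padding and a constant divisor
.boxFilterStrips <- function(S, h) {
  n <- nrow(S); W <- ncol(S)
  T <- matrix(0, n, W)
  for (b in -h:h) {
    cs <- max(1, 1 - b):min(W, W - b)
    T[, cs] <- T[, cs] + S[, cs + b, drop = FALSE]
  }
  F <- matrix(0, n, W)
  for (a in -h:h) {
    rs <- max(1, 1 - a):min(n, n - a)
    cs <- max(1, 1 + a):min(W, W + a)
    F[rs, cs] <- F[rs, cs] + T[rs + a, cs - a, drop = FALSE]
  }
  F / (2 * h + 1)^2
}

.checkSameGrid <- function(a, b) {
  if (nrow(a@matrix) != nrow(b@matrix) || a@resolution != b@resolution ||
      a@offsetBin != b@offsetBin)
    stop("grid mismatch: maps must share extent, resolution and offset")
}

#' Stratum-adjusted correlation coefficient between two contact maps
#'
#' Both maps are smoothed with a (2h+1)^2 uniform kernel, a Pearson
#' correlation r_k is computed for every distance stratum, and the SCC is
#' the variance-weighted aggregate sum(w_k r_k) / sum(w_k) with
#' w_k = N_k sqrt(var_a,k var_b,k); zero-variance strata are skipped.
#'
#' @param mapA,mapB \linkS4class{ContactMap}s on the same grid.
#' @param h smoothing half-width in bins.
#' @param maxDistanceBp maximum genomic distance included.
#' @return an \linkS4class{SCCReport}.
#' @export
scc <- function(mapA, mapB, h = 5, maxDistanceBp = 200000) {
  .checkSameGrid(mapA, mapB)
  n <- nrow(mapA@matrix)
  res <- mapA@resolution
  D <- min(floor(maxDistanceBp / res), n - 1)
  Dp <- D + 2 * h
  Fa <- .boxFilterStrips(.diagStrips(mapA, Dp), h)
  Fb <- .boxFilterStrips(.diagStrips(mapB, Dp), h)
  rows <- lapply(0:D, function(d) {
    idx <- seq_len(n - d)
    x <- Fa[idx, d + Dp + 1]
    y <- Fb[idx, d + Dp + 1]
    N <- length(x)
    va <- if (N > 1) stats::var(x) else 0
    vb <- if (N > 1) stats::var(y) else 0
    if (N < 2 || va == 0 || vb == 0)
      return(data.frame(d = d, r = NA_real_, N = N, w = 0))
    data.frame(d = d, r = stats::cor(x, y), N = N, w = N * sqrt(va * vb))
  })
  strata <- do.call(rbind, rows)
  ok <- strata$w > 0
  val <- if (any(ok)) sum(strata$w[ok] * strata$r[ok]) / sum(strata$w[ok])
         else NA_real_
  new("SCCReport", strata = strata, scc = val, h = h,
      maxDistanceBp = maxDistanceBp)
}

#' Distance-stratified Pearson correlation
#'
#' Pearson r per distance stratum on the unsmoothed values; strata where
#' either map is constant are reported as NA.
#'
#' @param mapA,mapB \linkS4class{ContactMap}s on the same grid.
#' @param maxDistanceBp maximum genomic distance.
#' @return data.frame with columns d (bins), distance_bp, r, N.
#' @export
distanceStratifiedPearson <- function(mapA, mapB, maxDistanceBp = 200000) {
  .checkSameGrid(mapA, mapB)
  n <- nrow(mapA@matrix)
  res <- mapA@resolution
  D <- min(floor(maxDistanceBp / res), n - 1)
  Sa <- .diagStrips(mapA, D)
  Sb <- .diagStrips(mapB, D)
  rows <- lapply(0:D, function(d) {
    idx <- seq_len(n - d)
    x <- Sa[idx, d + D + 1]
    y <- Sb[idx, d + D + 1]
    r <- if (length(x) > 1 && stats::sd(x) > 0 && stats::sd(y) > 0)
      stats::cor(x, y) else NA_real_
    data.frame(d = d, distance_bp = d * res, r = r, N = length(x))
  })
  do.call(rbind, rows)
}

#' Per-fragment Spearman correlation between two O/E maps
#'
#' The chromosome is split into mutually exclusive fragments (250 kb by
#' default; trailing partial fragments are dropped); within each fragment
#' both maps are smoothed with a 5 x 5 uniform kernel and Spearman's rho is
#' computed over the band pixels (upper triangle).  Fragments where either
#' smoothed map is constant carry an undefined flag.
#'
#' @param pred,obs O/E-state \linkS4class{ContactMap}s at 200 bp on the
#'   same grid.
#' @param fragmentBp fragment length in bp.
#' @param bandBp maximum pixel distance included.
#' @param h smoothing half-width (2 = the 5 x 5 kernel).
#' @return data.frame with columns fragment, start_bp, rho, defined.
#' @export
fragmentSpearman <- function(pred, obs, fragmentBp = 250000,
                             bandBp = 200000, h = 2) {
  .checkSameGrid(pred, obs)
  if (!pred@state %in% c("oe", "log_oe") || !obs@state %in% c("oe", "log_oe"))
    stop("fragmentSpearman expects O/E-normalized maps")
  res <- pred@resolution
  if (fragmentBp %% res != 0)
    stop("fragmentBp must be a multiple of the resolution")
  n <- nrow(pred@matrix)
  nf <- fragmentBp / res
  nFrag <- floor(n / nf)
  if (nFrag < 1) stop("map shorter than one fragment")
  w <- min(floor(bandBp / res), nf - 1)
  fullP <- contactMatrix(pred)
  fullO <- contactMatrix(obs)
  sel <- which(upper.tri(matrix(0, nf, nf), diag = TRUE) &
                 abs(outer(seq_len(nf), seq_len(nf), "-")) <= w)
  rows <- lapply(seq_len(nFrag), function(k) {
    bins <- (k - 1) * nf + seq_len(nf)
    P <- .boxBlur(as.matrix(fullP[bins, bins]), h)
    O <- .boxBlur(as.matrix(fullO[bins, bins]), h)
    x <- P[sel]; y <- O[sel]
    defined <- stats::sd(x) > 0 && stats::sd(y) > 0
    rho <- if (defined) stats::cor(x, y, method = "spearman") else NA_real_
    data.frame(fragment = k, start_bp = (k - 1) * fragmentBp, rho = rho,
               defined = defined)
  })
  do.call(rbind, rows)
}

# dense (2h+1)^2 uniform blur; the divisor is the count of in-matrix pixels
# so the filter is a true mean at the edges (a constant map stays constant)
.boxBlur <- function(M, h) {
  n <- nrow(M); m <- ncol(M)
  out <- matrix(0, n, m)
  cnt <- matrix(0, n, m)
  for (a in -h:h) for (b in -h:h) {
    rs <- max(1, 1 - a):min(n, n - a)
    cs <- max(1, 1 - b):min(m, m - b)
    out[rs, cs] <- out[rs, cs] + M[rs + a, cs + b, drop = FALSE]
    cnt[rs, cs] <- cnt[rs, cs] + 1
  }
  out / cnt
}

#' A/B compartment calling from the leading eigenvector
#'
#' Bins are split by the sign of the first eigenvector of the O/E matrix
#' (optionally of its correlation matrix); the sign group with the higher
#' mean H3K27ac is labeled "A".  The labeling is therefore invariant to the
#' arbitrary sign of the eigenvector.
#'
#' @param map O/E-state \linkS4class{ContactMap} (e.g. at 250 kb).
#' @param h3k27ac numeric vector of per-bin H3K27ac signal.
#' @param useCorrelation eigendecompose the correlation matrix of the O/E
#'   map instead of the O/E map itself.
#' @return character vector of "A"/"B" labels per bin.
#' @export
callCompartments <- function(map, h3k27ac, useCorrelation = FALSE) {
  if (!map@state %in% c("oe", "log_oe"))
    stop("callCompartments expects an O/E-normalized map")
  n <- nrow(map@matrix)
  if (n < 2) stop("need at least 2 bins")
  if (length(h3k27ac) != n) stop("h3k27ac must have one value per bin")
  M <- as.matrix(contactMatrix(map))
  if (max(M) - min(M) < 1e-12)
    stop("degenerate eigenproblem: constant contact matrix")
  if (useCorrelation) {
    M <- suppressWarnings(stats::cor(M))
    M[!is.finite(M)] <- 0
  } else {
    # remove the rank-one overall-intensity component: the leading
    # eigenvector of a strictly positive matrix is single-signed
    # (Perron-Frobenius) and carries no plaid information
    M <- M - mean(M)
  }
  ev <- eigen((M + t(M)) / 2, symmetric = TRUE)$vectors[, 1]
  grp <- ev >= 0
  if (all(grp) || all(!grp)) {
    # no sign split: single compartment, labeled by H3K27ac against nothing
    return(rep("A", n))
  }
  aIsPos <- mean(h3k27ac[grp]) >= mean(h3k27ac[!grp])
  ifelse(grp == aIsPos, "A", "B")
}

#' Annotate fragment scores with conservation, compartment and timing
#'
#' Conservation tiers by phastCons rank (top 10%, top 10-50%, rest);
#' replication timing early iff the repli-seq value is strictly positive;
#' compartment labels from \code{\link{callCompartments}} (or given
#' directly).
#'
#' @param scores data.frame from \code{\link{fragmentSpearman}}.
#' @param phastcons numeric per-fragment conservation scores.
#' @param h3k27ac numeric per-fragment H3K27ac signal.
#' @param compartments either a character vector of per-fragment "A"/"B"
#'   labels or an O/E \linkS4class{ContactMap} at the fragment resolution.
#' @param repliseq numeric per-fragment two-stage repli-seq signal.
#' @return `scores` with extra columns conservation, compartment, timing.
#' @export
annotateFragments <- function(scores, phastcons, h3k27ac, compartments,
                              repliseq) {
  nF <- nrow(scores)
  stopifnot(length(phastcons) == nF, length(repliseq) == nF)
  if (is(compartments, "ContactMap"))
    compartments <- callCompartments(compartments, h3k27ac)
  stopifnot(length(compartments) == nF)
  r <- rank(-phastcons, ties.method = "first")
  n10 <- ceiling(0.1 * nF)
  n50 <- ceiling(0.5 * nF)
  tier <- ifelse(r <= n10, "top10", ifelse(r <= n50, "top10_50", "rest"))
  tier[is.na(phastcons)] <- NA
  scores$conservation <- tier
  scores$compartment <- compartments
  scores$timing <- ifelse(is.na(repliseq), NA,
                          ifelse(repliseq > 0, "early", "late"))
  scores
}

#' One-sided Welch t test between two score groups
#'
#' Tests whether group A has a larger mean than group B (one-sided,
#' unequal-variance).
#'
#' @param valuesA,valuesB numeric score vectors (each of length >= 2).
#' @return data.frame with t, df and p.
#' @export
groupTest <- function(valuesA, valuesB) {
  if (length(valuesA) < 2 || length(valuesB) < 2)
    stop("each group needs at least 2 values")
  tt <- stats::t.test(valuesA, valuesB, alternative = "greater",
                      var.equal = FALSE)
  data.frame(t = unname(tt$statistic), df = unname(tt$parameter),
             p = tt$p.value)
}

#' Filter an eQTL-TSS pair table to model-addressable bin pairs
#'
#' Positions are binned at 200 bp; pairs separated by `maxDistanceBp` or
#' more are dropped, and bin pairs reported in more than one tissue are
#' dropped entirely (tissue-specific pairs only).  Malformed rows are
#' rejected with their line numbers logged.
#'
#' @param pairs data.frame with columns chrom, variant_pos, tss_pos, tissue
#'   (see \code{\link{readEqtlPairs}}).
#' @param resolution bin width in bp.
#' @param maxDistanceBp distance cutoff (strictly-less-than).
#' @return data.frame with chrom, variant_bin, tss_bin, tissue, distance_bp.
#' @export
filterEqtlPairs <- function(pairs, resolution = 200, maxDistanceBp = 180000) {
  if (!nrow(pairs))
    return(data.frame(chrom = character(), variant_bin = numeric(),
                      tss_bin = numeric(), tissue = character(),
                      distance_bp = numeric()))
  bad <- !is.finite(suppressWarnings(as.numeric(pairs$variant_pos))) |
    !is.finite(suppressWarnings(as.numeric(pairs$tss_pos))) |
    is.na(pairs$tissue) | !nzchar(as.character(pairs$tissue))
  if (any(bad))
    message("rejected malformed rows: ", paste(which(bad), collapse = ", "))
  pairs <- pairs[!bad, , drop = FALSE]
  vb <- binIndex(as.numeric(pairs$variant_pos), resolution)
  tb <- binIndex(as.numeric(pairs$tss_pos), resolution)
  dist <- abs(as.numeric(pairs$variant_pos) - as.numeric(pairs$tss_pos))
  keep <- dist < maxDistanceBp
  out <- data.frame(chrom = pairs$chrom[keep],
                    variant_bin = vb[keep], tss_bin = tb[keep],
                    tissue = as.character(pairs$tissue)[keep],
                    distance_bp = dist[keep])
  key <- paste(out$chrom, pmin(out$variant_bin, out$tss_bin),
               pmax(out$variant_bin, out$tss_bin))
  nTissues <- tapply(out$tissue, key, function(t) length(unique(t)))
  out <- out[nTissues[key] == 1, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Pile up a contact map at eQTL-TSS bin pairs
#'
#' Delegates to \code{\link{pileup}} at the (variant_bin, tss_bin) pixels;
#' the center score is the mean of the central 5 x 5 block.
#'
#' @param map a \linkS4class{ContactMap} at the pairs' bin resolution.
#' @param pairs filtered pair table from \code{\link{filterEqtlPairs}}.
#' @param side odd pile-up side length in pixels.
#' @return a \linkS4class{PileupResult}.
#' @export
eqtlPileup <- function(map, pairs, side = 101) {
  centers <- cbind(pmin(pairs$variant_bin, pairs$tss_bin),
                   pmax(pairs$variant_bin, pairs$tss_bin))
  pileup(map, centers, side = side)
}
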