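#' @include preprocess.R
NULL

#' Pool a 200-bp contact map to a coarser resolution
#'
#' Raw maps are pooled by block sums over the stored upper triangle (total
#' contacts conserved); O/E and log maps by the mean over the full symmetric
#' block.
#'
#' @param map a \linkS4class{ContactMap} at 200-bp resolution.
#' @param targetResolution coarse resolution in bp (default 1 kb).
#' @return a \linkS4class{ContactMap} at the coarse resolution.
#' @export
poolContacts <- function(map, targetResolution = 1000) {
  res <- map@resolution
  if (res != 200)
    stop("poolContacts expects a 200-bp map (got ", res, " bp)")
  if (targetResolution %% res != 0)
    stop("targetResolution must be a multiple of the map resolution")
  f <- targetResolution / res
  n <- nrow(map@matrix)
  nC <- ceiling(n / f)
  tr <- .sparseTriplets(map@matrix)
  I <- (tr$i - 1) %/% f + 1
  J <- (tr$j - 1) %/% f + 1
  if (map@state == "raw") {
    x <- tr$x
  } else {
    # full-block mean: off-diagonal fine pixels in a diagonal coarse block
    # appear twice in the symmetric matrix
    wgt <- ifelse(I == J & tr$i != tr$j, 2, 1)
    x <- tr$x * wgt / f^2
  }
  up <- sparseMatrix(i = I, j = J, x = x, dims = c(nC, nC))
  ContactMap(up, chrom = map@chrom, resolution = targetResolution,
             offsetBin = map@offsetBin %/% f, state = map@state)
}

# expected (stratum-mean) value per distance, over the full extent
.strataMeans <- function(upper) {
  n <- nrow(upper)
  tr <- .sparseTriplets(upper)
  d <- tr$j - tr$i
  sums <- numeric(n)
  if (nrow(tr)) {
    agg <- tapply(tr$x, d, sum)
    sums[as.integer(names(agg)) + 1] <- agg
  }
  sums / (n - (0:(n - 1)))
}

# sum of the matrix over a set of (rowOffset, colOffset) pixels around each
# pixel, with zero padding outside the matrix
.shiftSum <- function(M, offsets) {
  n <- nrow(M)
  out <- matrix(0, n, n)
  for (k in seq_len(nrow(offsets))) {
    a <- offsets[k, 1]; b <- offsets[k, 2]
    ri <- max(1, 1 - a):min(n, n - a)
    ci <- max(1, 1 - b):min(n, n - b)
    out[ri, ci] <- out[ri, ci] + M[ri + a, ci + b, drop = FALSE]
  }
  out
}

# Background regions around a candidate pixel.  The in-line backgrounds are
# four directional single-width rays (left/right along the row, up/down
# along the column) rather than two pooled 3-wide strips: a pixel on or at
# the end of a stripe ridge has at least one ray riding on the ridge, so
# the fold test rejects it, whereas pooled strips dilute the ridge with its
# flanks and let stripe pixels through as spurious loops.
.loopBackgroundOffsets <- function(radius = 5, core = 2) {
  g <- expand.grid(a = -radius:radius, b = -radius:radius)
  cheb <- pmax(abs(g$a), abs(g$b))
  list(
    donut = as.matrix(g[cheb > core & cheb <= radius, ]),
    lowerLeft = as.matrix(g[g$a >= 1 & g$a <= radius & g$b <= -1 &
                              g$b >= -radius & cheb > core, ]),
    left = as.matrix(g[g$a == 0 & g$b < -core & g$b >= -radius, ]),
    right = as.matrix(g[g$a == 0 & g$b > core & g$b <= radius, ]),
    up = as.matrix(g[g$b == 0 & g$a < -core & g$a >= -radius, ]),
    down = as.matrix(g[g$b == 0 & g$a > core & g$a <= radius, ])
  )
}

# single-linkage clusters of pixel coordinates under Chebyshev distance <= gap
.clusterPixels <- function(ij, gap = 2) {
  k <- nrow(ij)
  cl <- seq_len(k)
  if (k > 1) {
    dch <- pmax(abs(outer(ij[, 1], ij[, 1], "-")),
                abs(outer(ij[, 2], ij[, 2], "-")))
    adj <- dch <= gap
    repeat {
      newCl <- apply(adj, 1, function(row) min(cl[row]))
      if (all(newCl == cl)) break
      cl <- newCl
    }
  }
  cl
}

#' Call chromatin loops on a 1-kb contact map
#'
#' Donut-style multi-background caller: a pixel is a loop candidate when its
#' observed count exceeds `fold` times each of four local background
#' estimates (donut, lower-left, horizontal and vertical regions of radius
#' `radius` pixels, excluding a `core`-pixel core), with a
#' Benjamini-Hochberg-adjusted Poisson upper-tail probability (against the
#' most conservative background) at most `fdr`.  Candidates within 2 pixels
#' are merged by single linkage and each merged cluster is reported by its
#' maximal pixel.
#'
#' @param map raw-count \linkS4class{ContactMap} (typically at 1 kb).
#' @param fdr BH-adjusted significance threshold.
#' @param minDistanceBp,maxDistanceBp genomic distance limits of calls.
#' @param fold minimal observed/background ratio against every background.
#' @param radius background radius in pixels.
#' @param core excluded core half-width in pixels.
#' @return a \linkS4class{StructureCallSet} of loops (scores = donut fold).
#' @export
callLoops <- function(map, fdr = 0.1, minDistanceBp = 10000,
                      maxDistanceBp = 200000, fold = 1.75, radius = 5,
                      core = 2) {
  if (map@state != "raw")
    stop("callLoops requires a raw-count map (expContacts() for log maps)")
  n <- nrow(map@matrix)
  if (n <= 2 * radius + 1)
    stop("map narrower than the maximum background radius")
  res <- map@resolution
  M <- as.matrix(contactMatrix(map))
  expd <- .strataMeans(map@matrix)
  E <- matrix(expd[abs(outer(seq_len(n), seq_len(n), "-")) + 1], n, n)
  offs <- .loopBackgroundOffsets(radius, core)
  lamb <- lapply(offs, function(o) {
    so <- .shiftSum(M, o)
    se <- .shiftSum(E, o)
    ifelse(se > 0, so / se, Inf) * E
  })
  dmin <- ceiling(minDistanceBp / res)
  dmax <- floor(maxDistanceBp / res)
  ij <- which(upper.tri(M), arr.ind = TRUE)
  d <- ij[, 2] - ij[, 1]
  interior <- ij[, 1] > radius & ij[, 2] > radius &
    ij[, 1] <= n - radius & ij[, 2] <= n - radius
  cand <- d >= dmin & d <= dmax & interior & M[ij] > 0
  ij <- ij[cand, , drop = FALSE]
  if (!nrow(ij)) return(StructureCallSet(map@chrom, res))
  obs <- M[ij]
  lamMat <- vapply(lamb, function(L) L[ij], numeric(nrow(ij)))
  lamMat <- matrix(lamMat, nrow = nrow(ij))
  lamMax <- apply(lamMat, 1, max)
  passFold <- rowSums(obs >= fold * lamMat) == ncol(lamMat) &
    is.finite(lamMax) & lamMax > 0
  pval <- rep(1, nrow(ij))
  ok <- passFold & obs > 0
  pval[ok] <- stats::pgamma(lamMax[ok], shape = obs[ok], lower.tail = TRUE)
  qval <- stats::p.adjust(pval, method = "BH")
  hit <- passFold & qval <= fdr
  ij <- ij[hit, , drop = FALSE]
  if (!nrow(ij)) return(StructureCallSet(map@chrom, res))
  obs <- obs[hit]
  donutFold <- obs / lamMat[hit, 1]
  cl <- .clusterPixels(ij, gap = 2)
  keep <- vapply(split(seq_along(cl), cl), function(idx)
    idx[which.max(obs[idx])], numeric(1))
  loopCallSet(map@chrom, res,
              anchor1 = ij[keep, 1] - 1 + map@offsetBin,
              anchor2 = ij[keep, 2] - 1 + map@offsetBin,
              score = donutFold[keep])
}

#' Call architectural stripes on a 1-kb contact map
#'
#' For each anchor bin the caller scans the O/E values along its row
#' (vertical stripes: anchor at the smaller coordinate extending right) and
#' its column (horizontal stripes: the converse); contiguous runs of at
#' least `minLengthPx` pixels exceeding `fold` times the per-pixel median of
#' the `flank` flanking rows/columns on each side are reported, and
#' overlapping runs from adjacent anchors are merged (keeping the
#' strongest).
#'
#' @param map raw-count \linkS4class{ContactMap} (typically at 1 kb).
#' @param minLengthPx minimal run length in pixels.
#' @param fold minimal O/E ratio over the flanking median.
#' @param flank number of flanking rows/columns on each side.
#' @param minOffsetPx first diagonal offset scanned.
#' @param maxDistanceBp maximal scanned genomic distance from the anchor.
#' @return a \linkS4class{StructureCallSet} of stripes (score = mean fold).
#' @export
callStripes <- function(map, minLengthPx = 10, fold = 2, flank = 3,
                        minOffsetPx = 2, maxDistanceBp = 200000) {
  if (map@state != "raw")
    stop("callStripes requires a raw-count map")
  n <- nrow(map@matrix)
  if (n <= 2 * flank + 1)
    stop("map narrower than the flanking width")
  res <- map@resolution
  raw <- as.matrix(contactMatrix(map))
  expd <- .strataMeans(map@matrix)
  E <- matrix(expd[abs(outer(seq_len(n), seq_len(n), "-")) + 1], n, n)
  OE <- matrix(0, n, n)
  OE[E > 0] <- raw[E > 0] / E[E > 0]
  dmax <- min(floor(maxDistanceBp / res), n - 1)
  runs <- list()
  scanAnchor <- function(a, orient) {
    js <- if (orient == "vertical") (a + minOffsetPx):min(n, a + dmax)
          else (a - minOffsetPx):max(1, a - dmax)
    js <- js[js >= 1 & js <= n]
    if (length(js) < minLengthPx) return(NULL)
    fl <- setdiff((a - flank):(a + flank), a)
    fl <- fl[fl >= 1 & fl <= n]
    if (length(fl) < 2) return(NULL)
    v <- if (orient == "vertical") OE[a, js] else OE[js, a]
    Mfl <- if (orient == "vertical") OE[fl, js, drop = FALSE]
           else t(OE[js, fl, drop = FALSE])
    med <- apply(Mfl, 2, stats::median)
    pass <- v > 0 & (v >= fold * med)
    r <- rle(pass)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1
    out <- NULL
    for (k in which(r$values & r$lengths >= minLengthPx)) {
      idx <- starts[k]:ends[k]
      jj <- js[idx]
      sc <- mean(ifelse(med[idx] > 0, v[idx] / med[idx], fold * 2))
      out <- rbind(out, data.frame(anchor = a, orientation = orient,
                                   from = min(jj), to = max(jj), score = sc))
    }
    out
  }
  for (a in seq_len(n)) {
    runs[[length(runs) + 1]] <- scanAnchor(a, "vertical")
    runs[[length(runs) + 1]] <- scanAnchor(a, "horizontal")
  }
  runs <- do.call(rbind, runs)
  if (is.null(runs) || !nrow(runs)) return(StructureCallSet(map@chrom, res))
  # merge overlapping runs from adjacent anchors (same orientation)
  merged <- NULL
  for (orient in unique(runs$orientation)) {
    sub <- runs[runs$orientation == orient, , drop = FALSE]
    sub <- sub[order(sub$anchor), , drop = FALSE]
    grp <- .clusterPixels(cbind(sub$anchor, 0), gap = 1)
    for (gI in unique(grp)) {
      gg <- sub[grp == gI, , drop = FALSE]
      ovl <- rep(1L, nrow(gg))  # within an anchor cluster, merge extent overlaps
      if (nrow(gg) > 1) {
        lo <- gg$from; hi <- gg$to
        ovlM <- outer(lo, hi, "<=") & outer(hi, lo, ">=")
        ovl <- .clusterFromAdj(ovlM)
      }
      for (oI in unique(ovl)) {
        gsub <- gg[ovl == oI, , drop = FALSE]
        best <- which.max(gsub$score)
        merged <- rbind(merged, data.frame(
          anchor = gsub$anchor[best], orientation = orient,
          from = min(gsub$from), to = max(gsub$to),
          score = gsub$score[best]))
      }
    }
  }
  a0 <- merged$anchor - 1 + map@offsetBin
  StructureCallSet(map@chrom, res, data.frame(
    kind = "stripe",
    anchor1_start = a0, anchor1_end = a0 + 1,
    anchor2_start = merged$from - 1 + map@offsetBin,
    anchor2_end = merged$to + map@offsetBin,
    orientation = merged$orientation, score = merged$score))
}

.clusterFromAdj <- function(adj) {
  cl <- seq_len(nrow(adj))
  repeat {
    newCl <- apply(adj, 1, function(row) min(cl[row]))
    if (all(newCl == cl)) break
    cl <- newCl
  }
  cl
}

#' Match two call sets for Venn-style overlap counts
#'
#' Greedy one-to-one matching: loops match when both anchor midpoints agree
#' within `toleranceBp`; stripes match on anchor midpoint and orientation.
#' Ties are broken by smallest anchor distance, then genomic order, so the
#' counts are deterministic.
#'
#' @param setA,setB \linkS4class{StructureCallSet}s of the same kind.
#' @param toleranceBp anchor-midpoint tolerance in bp.
#' @return list with counts a_only, both, b_only and the matched index pairs.
#' @export
matchCalls <- function(setA, setB, toleranceBp = 5000) {
  dfA <- setA@calls; dfB <- setB@calls
  kinds <- unique(c(dfA$kind, dfB$kind))
  if (length(kinds) > 1) stop("cannot match calls of mixed kinds")
  midsA1 <- (dfA$anchor1_start + dfA$anchor1_end) / 2 * setA@resolution
  midsB1 <- (dfB$anchor1_start + dfB$anchor1_end) / 2 * setB@resolution
  if (!nrow(dfA) || !nrow(dfB)) {
    return(list(a_only = nrow(dfA), both = 0, b_only = nrow(dfB),
                pairs = cbind(integer(), integer())))
  }
  if (kinds == "loop") {
    midsA2 <- (dfA$anchor2_start + dfA$anchor2_end) / 2 * setA@resolution
    midsB2 <- (dfB$anchor2_start + dfB$anchor2_end) / 2 * setB@resolution
    d1 <- abs(outer(midsA1, midsB1, "-"))
    d2 <- abs(outer(midsA2, midsB2, "-"))
    okM <- d1 <= toleranceBp & d2 <= toleranceBp
    dist <- pmax(d1, d2)
  } else {
    d1 <- abs(outer(midsA1, midsB1, "-"))
    okM <- d1 <= toleranceBp &
      outer(dfA$orientation, dfB$orientation, "==")
    dist <- d1
  }
  cand <- which(okM, arr.ind = TRUE)
  if (nrow(cand)) {
    ord <- order(dist[cand], cand[, 1], cand[, 2])
    cand <- cand[ord, , drop = FALSE]
  }
  usedA <- logical(nrow(dfA)); usedB <- logical(nrow(dfB))
  pairs <- NULL
  for (k in seq_len(nrow(cand))) {
    a <- cand[k, 1]; b <- cand[k, 2]
    if (!usedA[a] && !usedB[b]) {
      usedA[a] <- TRUE; usedB[b] <- TRUE
      pairs <- rbind(pairs, c(a, b))
    }
  }
  both <- sum(usedA)
  list(a_only = nrow(dfA) - both, both = both, b_only = nrow(dfB) - both,
       pairs = if (is.null(pairs)) cbind(integer(), integer()) else pairs)
}

#' Pile up square regions around a set of pixels
#'
#' Extracts a `side` x `side` submatrix centered at each pixel, drops
#' regions clipped at the map edges, and averages the rest elementwise.
#'
#' @param map a \linkS4class{ContactMap} (any state).
#' @param centers 2-column matrix of 0-based (bin1, bin2) pixel coordinates
#'   at the map's resolution.
#' @param side odd submatrix side length in pixels.
#' @return a \linkS4class{PileupResult}.
#' @export
pileup <- function(map, centers, side = 101) {
  if (side %% 2 == 0) stop("side must be odd")
  centers <- as.matrix(centers)
  n <- nrow(map@matrix)
  half <- (side - 1) / 2
  full <- contactMatrix(map)
  acc <- matrix(0, side, side)
  used <- 0
  for (k in seq_len(nrow(centers))) {
    i <- centers[k, 1] + 1 - map@offsetBin
    j <- centers[k, 2] + 1 - map@offsetBin
    if (i - half < 1 || j - half < 1 || i + half > n || j + half > n) next
    acc <- acc + as.matrix(full[(i - half):(i + half), (j - half):(j + half)])
    used <- used + 1
  }
  if (used == 0) stop("no usable centers (all regions clipped at edges)")
  m <- acc / used
  c0 <- half + 1
  new("PileupResult", matrix = m, nRegions = used,
      centerScore = mean(m[(c0 - 2):(c0 + 2), (c0 - 2):(c0 + 2)]))
}
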