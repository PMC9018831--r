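#' @include core_data.R
NULL

#' Interpolate a coarse contact map onto a finer grid
#'
#' Bilinear interpolation on bin centers: the value at a fine-bin center is
#' the separable linear interpolation of the four surrounding coarse-bin
#' centers (clamped at the map edges), so values at coarse-bin centers are
#' preserved exactly.  Output is clamped at 0 and keeps the input state.
#'
#' @param map a \linkS4class{ContactMap} at a coarse resolution.
#' @param targetResolution fine resolution in bp; must divide the coarse one.
#' @param maxDistanceBp if not NULL, only pixels within this genomic distance
#'   of the diagonal are materialized (band-limited output).
#' @param method "bilinear" (default) or "nearest".
#' @return a \linkS4class{ContactMap} at `targetResolution`.
#' @export
interpolateContacts <- function(map, targetResolution = 200,
                                maxDistanceBp = NULL,
                                method = c("bilinear", "nearest")) {
  method <- match.arg(method)
  R <- map@resolution
  r <- targetResolution
  if (R %% r != 0)
    stop("coarse resolution (", R, ") must be an integer multiple of the target (", r, ")")
  f <- R / r
  if (f == 1) return(map)
  nC <- nrow(map@matrix)
  nF <- nC * f
  # interpolation weights: fine center (i+0.5)r at coarse coordinate u
  i <- seq_len(nF) - 1
  u <- ((i + 0.5) * r) / R - 0.5
  lo <- pmin(pmax(floor(u), 0), nC - 1)
  hi <- pmin(lo + 1, nC - 1)
  wHi <- pmin(pmax(u - lo, 0), 1)
  if (method == "nearest") {
    lo <- pmin(pmax(round(u), 0), nC - 1)
    hi <- lo
    wHi <- rep(0, nF)
  }
  W <- sparseMatrix(i = c(seq_len(nF), seq_len(nF)), j = c(lo + 1, hi + 1),
                    x = c(ifelse(hi == lo, 1, 1 - wHi),
                          ifelse(hi == lo, 0, wHi)), dims = c(nF, nC))
  full <- contactMatrix(map)
  fine <- W %*% full %*% Matrix::t(W)
  fine <- drop0(fine)
  fine@x <- pmax(fine@x, 0)
  up <- Matrix::triu(fine)
  if (!is.null(maxDistanceBp)) {
    tr <- .sparseTriplets(up)
    keep <- (tr$j - tr$i) * r <= maxDistanceBp
    up <- sparseMatrix(i = tr$i[keep], j = tr$j[keep], x = tr$x[keep],
                       dims = c(nF, nF))
  }
  ContactMap(up, chrom = map@chrom, resolution = r,
             offsetBin = map@offsetBin * f, state = map@state,
             totalContacts = if (map@state == "raw") NA_real_ else NA_real_)
}

#' Observed/expected normalization by distance stratum
#'
#' Divides each entry by the mean of its distance stratum d = |i - j|,
#' computed over the map's extent (structural zeros included in the mean);
#' strata with zero mean are left at 0.
#'
#' @param map a raw-state \linkS4class{ContactMap}.
#' @return a \linkS4class{ContactMap} with state "oe".
#' @export
oeNormalize <- function(map) {
  if (map@state != "raw")
    stop("oeNormalize expects a raw-state map (got '", map@state, "')")
  n <- nrow(map@matrix)
  tr <- .sparseTriplets(map@matrix)
  if (!nrow(tr)) stop("empty map: nothing to normalize")
  d <- tr$j - tr$i
  sums <- numeric(n)                       # index: d + 1
  agg <- tapply(tr$x, d, sum)
  sums[as.integer(names(agg)) + 1] <- agg
  counts <- n - (0:(n - 1))
  means <- sums / counts
  newx <- ifelse(means[d + 1] > 0, tr$x / means[d + 1], 0)
  up <- sparseMatrix(i = tr$i, j = tr$j, x = newx, dims = c(n, n))
  ContactMap(up, chrom = map@chrom, resolution = map@resolution,
             offsetBin = map@offsetBin, state = "oe")
}

#' log1p / expm1 transforms of a contact map
#'
#' `logContacts` maps raw counts to log1p space (state "raw" -> "log",
#' "oe" -> "log_oe"); `expContacts` inverts it.
#'
#' @param map a \linkS4class{ContactMap}.
#' @return a transformed \linkS4class{ContactMap}.
#' @export
logContacts <- function(map) {
  if (!map@state %in% c("raw", "oe"))
    stop("logContacts expects state raw or oe")
  m <- map@matrix
  m@x <- log1p(m@x)
  ContactMap(m, chrom = map@chrom, resolution = map@resolution,
             offsetBin = map@offsetBin,
             state = if (map@state == "raw") "log" else "log_oe")
}

#' @rdname logContacts
#' @export
expContacts <- function(map) {
  if (!map@state %in% c("log", "log_oe"))
    stop("expContacts expects state log or log_oe")
  m <- map@matrix
  m@x <- pmax(expm1(m@x), 0)   # predictions may dip below 0 in log space
  ContactMap(m, chrom = map@chrom, resolution = map@resolution,
             offsetBin = map@offsetBin,
             state = if (map@state == "log") "raw" else "oe")
}

#' Sinusoidal positional encoding of bin order
#'
#' Transformer-style encoding: row pairs (sin, cos) at geometrically spaced
#' wavelengths.  Deterministic and independent of any contact or epigenomic
#' data; it only encodes node order along the genome.
#'
#' @param nBins number of bins.
#' @param encodingDim even number of rows.
#' @return encodingDim x nBins matrix with entries in [-1, 1].
#' @export
positionalEncoding <- function(nBins, encodingDim = 8) {
  if (encodingDim %% 2 != 0) stop("encodingDim must be even")
  pos <- seq_len(nBins) - 1
  out <- matrix(0, encodingDim, nBins)
  half <- encodingDim / 2
  for (k in seq_len(half)) {
    freq <- 1 / 10000^((k - 1) / half)
    out[2 * k - 1, ] <- sin(pos * freq)
    out[2 * k, ] <- cos(pos * freq)
  }
  rownames(out) <- paste0("pos", seq_len(encodingDim))
  out
}

#' Build the contact graph for one window
#'
#' Adjacency = the window's interpolated O/E contact values with entries
#' below `edgeThreshold` zeroed (optionally sparsified to the top-k
#' neighbours per node), plus identity self-loops.  Node features are the
#' epigenomic feature matrix stacked on the positional encoding.
#'
#' @param fineMap \linkS4class{ContactMap} at the window resolution covering
#'   exactly the window.
#' @param X m x n feature matrix (n = window bins).
#' @param encodingDim positional-encoding rows to append.
#' @param edgeThreshold zero adjacency entries strictly below this value.
#' @param topK if not NULL, keep only each node's top-k off-diagonal edges
#'   (union over both endpoints, so the matrix stays symmetric).
#' @return a \linkS4class{ChromGraph}.
#' @export
buildGraph <- function(fineMap, X, encodingDim = 8, edgeThreshold = 0,
                       topK = NULL) {
  n <- nrow(fineMap@matrix)
  if (ncol(X) != n)
    stop("dimension mismatch: X has ", ncol(X), " columns but the map has ",
         n, " bins")
  full <- contactMatrix(fineMap)
  Matrix::diag(full) <- 0
  full <- drop0(full)
  if (edgeThreshold > 0 && length(full@x)) {
    full@x[full@x < edgeThreshold] <- 0
    full <- drop0(full)
  }
  if (!is.null(topK) && length(full@x)) {
    tr <- .sparseTriplets(Matrix::triu(full))
    keep <- logical(nrow(tr))
    for (node in unique(c(tr$i, tr$j))) {
      idx <- which(tr$i == node | tr$j == node)
      if (length(idx) > topK)
        idx <- idx[order(tr$x[idx], decreasing = TRUE)[seq_len(topK)]]
      keep[idx] <- TRUE
    }
    up <- sparseMatrix(i = tr$i[keep], j = tr$j[keep], x = tr$x[keep],
                       dims = c(n, n))
    full <- up + Matrix::t(up)
  }
  adj <- full + Diagonal(n)
  feats <- rbind(X, positionalEncoding(n, encodingDim))
  new("ChromGraph", nNodes = n, adjacency = as(adj, "CsparseMatrix"),
      nodeFeatures = as.matrix(feats))
}

#' Sliding-window coordinates along a chromosome
#'
#' Windows start at 0, step, 2*step, ... while start + window fits; when the
#' last regular window does not reach the chromosome end, one extra window
#' right-aligned at the end is appended so coverage is complete.
#'
#' @param chromLengthBp chromosome length in bp.
#' @param windowBp window width (multiple of stepBp and of resolution).
#' @param stepBp step length.
#' @param resolution bin width in bp.
#' @param shortChrom what to do when the chromosome is shorter than one
#'   window: "truncate" returns a single flagged truncated window, "empty"
#'   returns no windows.
#' @return data.frame with columns start, end, truncated, rightAligned.
#' @export
extractWindows <- function(chromLengthBp, windowBp = 250000, stepBp = 50000,
                           resolution = 200,
                           shortChrom = c("truncate", "empty")) {
  shortChrom <- match.arg(shortChrom)
  if (windowBp %% stepBp != 0) stop("windowBp must be a multiple of stepBp")
  if (windowBp %% resolution != 0)
    stop("windowBp must be a multiple of the resolution")
  if (chromLengthBp < windowBp) {
    if (shortChrom == "empty")
      return(data.frame(start = numeric(), end = numeric(),
                        truncated = logical(), rightAligned = logical()))
    return(data.frame(start = 0, end = chromLengthBp, truncated = TRUE,
                      rightAligned = FALSE))
  }
  starts <- seq(0, chromLengthBp - windowBp, by = stepBp)
  rightAligned <- rep(FALSE, length(starts))
  if (max(starts) + windowBp < chromLengthBp) {
    starts <- c(starts, chromLengthBp - windowBp)
    rightAligned <- c(rightAligned, TRUE)
  }
  data.frame(start = starts, end = starts + windowBp,
             truncated = FALSE, rightAligned = rightAligned)
}

#' Binomial downsampling of a raw contact map
#'
#' Thins every count independently with rate targetTotal / totalContacts,
#' so the expected output total equals targetTotal.
#'
#' @param map raw \linkS4class{ContactMap} with integer counts.
#' @param targetTotal desired expected total (<= current total).
#' @param seed RNG seed.
#' @return a raw \linkS4class{ContactMap}.
#' @export
downsampleContacts <- function(map, targetTotal, seed) {
  if (map@state != "raw") stop("downsampling requires a raw map")
  tot <- sum(map@matrix@x)
  if (targetTotal > tot)
    stop("targetTotal (", targetTotal, ") exceeds total contacts (", tot, ")")
  rate <- if (tot > 0) targetTotal / tot else 0
  if (rate == 1 || tot == 0) return(map)
  m <- map@matrix
  if (any(abs(m@x - round(m@x)) > 1e-8))
    stop("downsampling requires integer counts")
  withr::with_seed(seed, {
    m@x <- as.numeric(stats::rbinom(length(m@x), size = round(m@x), prob = rate))
  })
  m <- drop0(m)
  ContactMap(m, chrom = map@chrom, resolution = map@resolution,
             offsetBin = map@offsetBin, state = "raw")
}

#' Aggregate a surrogate contact map from several cell types
#'
#' Each input map is binomially thinned to targetTotal / k contacts (equal
#' proportions) and the thinned maps are summed entrywise, mirroring the
#' construction of a surrogate Hi-C map from unmatched cell lines.
#'
#' @param maps list of >= 2 raw \linkS4class{ContactMap}s on the same grid.
#' @param targetTotal expected total of the aggregate.
#' @param seed RNG seed.
#' @return a raw \linkS4class{ContactMap}.
#' @export
aggregateSurrogate <- function(maps, targetTotal, seed) {
  if (length(maps) < 2) stop("need at least 2 maps to aggregate")
  dims <- vapply(maps, function(m) nrow(m@matrix), numeric(1))
  ress <- vapply(maps, function(m) m@resolution, numeric(1))
  if (length(unique(dims)) > 1 || length(unique(ress)) > 1)
    stop("mismatched grids: all maps must share dimension and resolution")
  k <- length(maps)
  per <- targetTotal / k
  acc <- NULL
  withr::with_seed(seed, {
    for (m in maps) {
      tot <- sum(m@matrix@x)
      thin <- if (tot == 0) m else {
        seedI <- sample.int(.Machine$integer.max, 1)
        downsampleContacts(m, min(per, tot), seed = seedI)
      }
      acc <- if (is.null(acc)) thin@matrix else acc + thin@matrix
    }
  })
  ContactMap(acc, chrom = maps[[1]]@chrom, resolution = ress[1],
             offsetBin = maps[[1]]@offsetBin, state = "raw")
}

#' Stitch per-window predictions into a chromosome-scale band map
#'
#' Where k windows overlap a pixel the stitched value is their mean (or
#' median); pixels beyond the band are absent.
#'
#' @param samples list of \linkS4class{WindowSample}s from one chromosome
#'   sharing one bandBp.
#' @param predictions list of n x n predicted matrices, parallel to samples.
#' @param chromLengthBp chromosome length; inferred from the windows if NULL.
#' @param method "mean" or "median" across overlapping windows.
#' @param state state label of the stitched map ("log" for model output).
#' @return a band-limited \linkS4class{ContactMap} at the window resolution.
#' @export
stitchPredictions <- function(samples, predictions, chromLengthBp = NULL,
                              method = c("mean", "median"), state = "log") {
  method <- match.arg(method)
  bands <- unique(vapply(samples, function(s) s@bandBp, numeric(1)))
  if (length(bands) > 1) stop("inconsistent bandBp across windows")
  res <- samples[[1]]@resolution
  w <- bands / res
  if (is.null(chromLengthBp))
    chromLengthBp <- max(vapply(samples, function(s) s@startBp + s@windowBp,
                                numeric(1)))
  nCh <- ceiling(chromLengthBp / res)
  winBp <- samples[[1]]@windowBp
  steps <- diff(sort(unique(vapply(samples, function(s) s@startBp, numeric(1)))))
  K <- if (length(steps)) ceiling(winBp / min(steps)) + 1 else 1
  stack <- array(NA_real_, dim = c(nCh, w + 1, K))
  for (s in seq_along(samples)) {
    sm <- samples[[s]]
    pred <- predictions[[s]]
    n <- ncol(sm@X)
    off <- sm@startBp / res
    layer <- ((s - 1) %% K) + 1
    for (d in 0:w) {
      if (d >= n) break
      idx <- seq_len(n - d)
      stack[off + idx, d + 1, layer] <- pred[cbind(idx, idx + d)]
    }
  }
  agg <- if (method == "mean") {
    apply(stack, c(1, 2), function(v) mean(v, na.rm = TRUE))
  } else {
    apply(stack, c(1, 2), function(v) stats::median(v, na.rm = TRUE))
  }
  ij <- which(!is.nan(agg) & !is.na(agg), arr.ind = TRUE)
  i <- ij[, 1]; d <- ij[, 2] - 1
  keep <- i + d <= nCh
  up <- sparseMatrix(i = i[keep], j = (i + d)[keep], x = agg[ij][keep],
                     dims = c(nCh, nCh))
  ContactMap(up, chrom = samples[[1]]@chrom, resolution = res,
             offsetBin = 0, state = state)
}

#' Build model-ready window samples from Hi-C and tracks
#'
#' Runs the full preprocessing chain: interpolation of the input Hi-C to the
#' target resolution within the band, per-chromosome O/E normalization,
#' sliding-window extraction, graph construction with positional encoding,
#' and (when a target map is given) band-masked log1p count targets.
#'
#' @param hic input raw \linkS4class{ContactMap} (coarse resolution).
#' @param tracks list of \linkS4class{BinTrack}s covering the chromosome.
#' @param chromLengthBp chromosome length in bp.
#' @param windowBp,stepBp,bandBp sliding-window geometry.
#' @param truth optional target raw \linkS4class{ContactMap} at `resolution`
#'   (e.g. Micro-C); targets are log1p counts restricted to the band.
#' @param resolution fine bin width (200).
#' @param encodingDim positional-encoding rows.
#' @param edgeThreshold graph edge threshold on interpolated O/E values.
#' @return list of \linkS4class{WindowSample}s.
#' @export
makeWindowSamples <- function(hic, tracks, chromLengthBp,
                              windowBp = 250000, stepBp = 50000,
                              bandBp = 200000, truth = NULL,
                              resolution = 200, encodingDim = 8,
                              edgeThreshold = 0) {
  fine <- interpolateContacts(hic, resolution,
                              maxDistanceBp = bandBp + windowBp / 10)
  fineOE <- oeNormalize(fine)
  wins <- extractWindows(chromLengthBp, windowBp, stepBp, resolution)
  n <- windowBp / resolution
  w <- bandBp / resolution
  featNames <- vapply(tracks, featureName, character(1))
  Xall <- do.call(rbind, lapply(tracks, trackValues))
  rownames(Xall) <- featNames
  oeFull <- contactMatrix(fineOE)
  truthFull <- if (!is.null(truth)) contactMatrix(truth) else NULL
  bandM <- .bandMask(n, w)
  lapply(seq_len(nrow(wins)), function(k) {
    s <- wins$start[k]
    bins <- (s / resolution) + seq_len(n)
    X <- Xall[, bins, drop = FALSE]
    winMap <- ContactMap(Matrix::triu(oeFull[bins, bins]),
                         chrom = hic@chrom, resolution = resolution,
                         offsetBin = s / resolution, state = "oe")
    graph <- buildGraph(winMap, X, encodingDim = encodingDim,
                        edgeThreshold = edgeThreshold)
    Y <- NULL
    if (!is.null(truthFull)) {
      Y <- as.matrix(truthFull[bins, bins])
      Y <- log1p(Y) * bandM
    }
    new("WindowSample", chrom = hic@chrom, startBp = s, windowBp = windowBp,
        bandBp = bandBp, resolution = resolution, X = as.matrix(X),
        featureNames = featNames, graph = graph, Y = Y)
  })
}

# band mask: 1 where |i - j| <= w
.bandMask <- function(n, w) {
  d <- abs(outer(seq_len(n), seq_len(n), "-"))
  (d <= w) * 1
}
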