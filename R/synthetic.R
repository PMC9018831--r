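#' @include evaluation.R
NULL

#' Define a synthetic benchmark chromosome
#'
#' Builds the full specification of a seeded synthetic region: expected
#' contacts decay as (1+d)^-alpha, modulated by alternating compartment
#' blocks (plaid), with planted Gaussian loop foci and stripe ridges whose
#' amplitudes are expressed as fold over the local decay.  Counts are
#' Poisson-sampled at the stated depth; a degraded Hi-C surrogate is derived
#' by binomial thinning plus 1-kb pooling; matched epigenomic tracks carry
#' peaks at the planted anchors.  Loop and stripe placements are drawn once
#' from the spec's seed (or given explicitly).
#'
#' @param seed mandatory RNG seed.
#' @param lengthBp region length in bp.
#' @param resolution fine bin width (200 bp).
#' @param alpha distance-decay exponent.
#' @param diagIntensity expected count at distance 0.
#' @param nLoops,nStripes number of planted structures.
#' @param loopFold,loopSigma loop peak fold over local decay and Gaussian
#'   width in fine pixels.
#' @param loopDistanceBp range of anchor separations.
#' @param stripeFold,stripeExtentBp stripe ridge fold and extent range.
#' @param compartmentBlockBp alternating A/B block length.
#' @param compartmentRatio same-compartment multiplier (cross-compartment
#'   contacts are divided by it).
#' @param hicDepthFraction fraction of the depth kept in the Hi-C surrogate.
#' @param hicResolution Hi-C bin width in bp.
#' @param trackNoise track background mean.
#' @param trackPeakAmp track peak height as fold over background.
#' @param truthBandBp maximum genomic distance materialized in the truth map.
#' @param loops,stripes explicit placement data.frames (override random
#'   placement); loops: anchor1, anchor2 (fine bins), fold, sigma; stripes:
#'   anchor, orientation, extentBins, fold.
#' @return a \linkS4class{SyntheticSpec}.
#' @export
syntheticSpec <- function(seed, lengthBp = 1.3e6, resolution = 200,
                          alpha = 1, diagIntensity = 100,
                          nLoops = 20, nStripes = 10,
                          loopFold = 8, loopSigma = 1.5,
                          loopDistanceBp = c(10000, 18000),
                          stripeFold = 10, stripeExtentBp = c(15000, 25000),
                          compartmentBlockBp = 260000,
                          compartmentRatio = 1.25,
                          hicDepthFraction = 0.01, hicResolution = 1000,
                          trackNoise = 0.5, trackPeakAmp = 8,
                          truthBandBp = 26000,
                          loops = NULL, stripes = NULL) {
  if (missing(seed)) stop("seed is mandatory")
  nb <- lengthBp / resolution
  margin <- 100                    # keep anchors away from the region ends
  minSepPx <- 25000 / resolution   # pairwise anchor separation
  withr::with_seed(seed, {
    if (is.null(loops)) {
      dRange <- loopDistanceBp / resolution
      a1 <- numeric(0); a2 <- numeric(0)
      tries <- 0
      while (length(a1) < nLoops && tries < 5000) {
        tries <- tries + 1
        d <- round(stats::runif(1, dRange[1], dRange[2]))
        p <- round(stats::runif(1, margin, nb - margin - d))
        if (!length(a1) ||
            min(pmax(abs(a1 - p), abs(a2 - (p + d)))) >= minSepPx) {
          a1 <- c(a1, p); a2 <- c(a2, p + d)
        }
      }
      loops <- data.frame(anchor1 = a1, anchor2 = a2,
                          fold = rep(loopFold, length(a1)),
                          sigma = rep(loopSigma, length(a1)))
    }
    if (is.null(stripes)) {
      eRange <- stripeExtentBp / resolution
      an <- numeric(0); ori <- character(0); ext <- numeric(0)
      tries <- 0
      while (length(an) < nStripes && tries < 5000) {
        tries <- tries + 1
        e <- round(stats::runif(1, eRange[1], eRange[2]))
        o <- sample(c("vertical", "horizontal"), 1)
        p <- round(stats::runif(1, margin + e, nb - margin - e))
        farFromStripes <- !length(an) || min(abs(an - p)) >= minSepPx
        farFromLoops <- !nrow(loops) ||
          min(abs(c(loops$anchor1, loops$anchor2) - p)) >= minSepPx / 2
        if (farFromStripes && farFromLoops) {
          an <- c(an, p); ori <- c(ori, o); ext <- c(ext, e)
        }
      }
      stripes <- data.frame(anchor = an, orientation = ori,
                            extentBins = ext,
                            fold = rep(stripeFold, length(an)))
    }
  })
  new("SyntheticSpec", lengthBp = lengthBp, resolution = resolution,
      alpha = alpha, diagIntensity = diagIntensity, loops = loops,
      stripes = stripes, compartmentBlockBp = compartmentBlockBp,
      compartmentRatio = compartmentRatio,
      hicDepthFraction = hicDepthFraction, hicResolution = hicResolution,
      trackNoise = trackNoise, trackPeakAmp = trackPeakAmp, seed = seed)
}

#' Compartment block labels of a synthetic spec
#'
#' @param spec a \linkS4class{SyntheticSpec}.
#' @param resolution bin width of the returned label vector.
#' @return character vector of "A"/"B" per bin (alternating blocks, A first).
#' @export
compartmentBlocks <- function(spec, resolution = spec@resolution) {
  nb <- ceiling(spec@lengthBp / resolution)
  blockBins <- spec@compartmentBlockBp / resolution
  blk <- ((seq_len(nb) - 1) %/% blockBins) %% 2
  ifelse(blk == 0, "A", "B")
}

.truthBandBp <- function(spec) {
  # stored with the generator defaults; kept as a function so explicit
  # loop/stripe extents can widen it
  need <- 26000
  if (nrow(spec@loops))
    need <- max(need, (max(spec@loops$anchor2 - spec@loops$anchor1) + 30) *
                  spec@resolution)
  if (nrow(spec@stripes))
    need <- max(need, (max(spec@stripes$extentBins) + 30) * spec@resolution)
  min(need, spec@lengthBp - spec@resolution)
}

#' Generate the ground-truth fine contact map
#'
#' Expected intensity = distance decay x compartment plaid, plus Gaussian
#' loop foci and stripe ridges at (fold-1) times the local base; counts are
#' Poisson-sampled unless `noise = FALSE` (expected-value mode).  The map is
#' materialized within a band wide enough to contain every planted
#' structure.
#'
#' @param spec a \linkS4class{SyntheticSpec}.
#' @param noise Poisson-sample counts (TRUE) or return the expectation.
#' @return a raw \linkS4class{ContactMap} at the fine resolution.
#' @export
generateTruth <- function(spec, noise = TRUE) {
  res <- spec@resolution
  nb <- spec@lengthBp / res
  D <- floor(.truthBandBp(spec) / res)
  lab <- as.numeric(compartmentBlocks(spec) == "A")
  S <- matrix(0, nb, D + 1)
  for (d in 0:D) {
    i <- seq_len(nb - d)
    base <- spec@diagIntensity * (1 + d)^(-spec@alpha)
    same <- lab[i] == lab[i + d]
    S[i, d + 1] <- base * ifelse(same, spec@compartmentRatio,
                                 1 / spec@compartmentRatio)
  }
  addAt <- function(i, j, amount) {
    d <- j - i
    ok <- i >= 1 & j <= nb & d >= 0 & d <= D & i <= nb
    if (any(ok)) {
      idx <- cbind(i[ok], d[ok] + 1)
      S[idx] <<- S[idx] + amount[ok]
    }
  }
  if (nrow(spec@loops)) for (k in seq_len(nrow(spec@loops))) {
    lp <- spec@loops[k, ]
    rad <- ceiling(4 * lp$sigma)
    off <- expand.grid(di = -rad:rad, dj = -rad:rad)
    i <- lp$anchor1 + 1 + off$di
    j <- lp$anchor2 + 1 + off$dj
    d <- pmax(j - i, 0)
    base <- spec@diagIntensity * (1 + d)^(-spec@alpha)
    g <- exp(-(off$di^2 + off$dj^2) / (2 * lp$sigma^2))
    addAt(i, j, (lp$fold - 1) * base * g)
  }
  ridgeStart <- 10                       # ridge begins 2 kb from the anchor
  sigmaS <- 1
  if (nrow(spec@stripes)) for (k in seq_len(nrow(spec@stripes))) {
    st <- spec@stripes[k, ]
    along <- ridgeStart:st$extentBins
    for (dw in -3:3) {
      g <- exp(-dw^2 / (2 * sigmaS^2))
      if (st$orientation == "vertical") {
        i <- rep(st$anchor + 1 + dw, length(along))
        j <- st$anchor + 1 + along
      } else {
        i <- st$anchor + 1 - along
        j <- rep(st$anchor + 1 + dw, length(along))
      }
      d <- pmax(j - i, 0)
      base <- spec@diagIntensity * (1 + d)^(-spec@alpha)
      addAt(i, j, (st$fold - 1) * base * g)
    }
  }
  if (noise)
    S <- withr::with_seed(spec@seed,
      matrix(stats::rpois(length(S), lambda = S), nrow(S), ncol(S)))
  ij <- which(S != 0, arr.ind = TRUE)
  i <- ij[, 1]; d <- ij[, 2] - 1
  keep <- i + d <= nb
  up <- sparseMatrix(i = i[keep], j = (i + d)[keep], x = S[ij][keep],
                     dims = c(nb, nb))
  ContactMap(up, chrom = "chrS", resolution = res, state = "raw")
}

#' Degrade the truth map into a lower-resolution Hi-C surrogate
#'
#' Binomial thinning to `depthFraction` of the contacts followed by
#' block-sum pooling to `coarseResolution`.
#'
#' @param truth raw truth \linkS4class{ContactMap} at 200 bp.
#' @param depthFraction fraction of contacts kept, in (0, 1].
#' @param coarseResolution output bin width in bp.
#' @param seed RNG seed for the thinning.
#' @return a raw \linkS4class{ContactMap} at `coarseResolution`.
#' @export
degradeToHic <- function(truth, depthFraction, coarseResolution = 1000,
                         seed) {
  if (truth@state != "raw") stop("truth map must be raw counts")
  if (depthFraction <= 0 || depthFraction > 1)
    stop("depthFraction must be in (0, 1]")
  thinned <- if (depthFraction == 1) truth else
    downsampleContacts(truth, round(depthFraction * sum(truth@matrix@x)),
                       seed = seed)
  poolContacts(thinned, coarseResolution)
}

# Gaussian bump track helper
.addPeaks <- function(vals, centers, height, sigma = 2) {
  nb <- length(vals)
  for (c0 in centers) {
    lo <- max(1, c0 - 4 * sigma); hi <- min(nb, c0 + 4 * sigma)
    idx <- lo:hi
    vals[idx] <- vals[idx] + height * exp(-(idx - c0)^2 / (2 * sigma^2))
  }
  vals
}

#' Generate the matched synthetic epigenomic tracks (6-epi set)
#'
#' Construction rules couple tracks to the planted structures: ATAC-seq and
#' CTCF peak at every loop and stripe anchor; H3K4me1 peaks flank the
#' anchors; H3K4me3 peaks at loop anchors; H3K27ac peaks at stripe anchors
#' and is elevated in A blocks; H3K27me3 is elevated over the B (repressive)
#' blocks.  Background is gamma-distributed noise; every track is
#' normalized by its genome-wide mean.
#'
#' @param spec a \linkS4class{SyntheticSpec}.
#' @return named list of six normalized \linkS4class{BinTrack}s.
#' @export
generateTracks <- function(spec) {
  nb <- spec@lengthBp / spec@resolution
  lab <- compartmentBlocks(spec)
  anchorsLoop <- c(spec@loops$anchor1, spec@loops$anchor2) + 1
  anchorsStripe <- spec@stripes$anchor + 1
  allAnchors <- c(anchorsLoop, anchorsStripe)
  amp <- spec@trackPeakAmp * spec@trackNoise
  bg <- function() stats::rgamma(nb, shape = 2, scale = spec@trackNoise / 2)
  withr::with_seed(spec@seed + 1, {
    vals <- list(
      `ATAC-seq` = .addPeaks(bg(), allAnchors, amp),
      CTCF = .addPeaks(bg(), allAnchors, amp),
      H3K4me1 = .addPeaks(bg(), c(allAnchors - 5, allAnchors + 5), amp * 0.7),
      H3K4me3 = .addPeaks(bg(), anchorsLoop, amp * 0.8),
      H3K27ac = .addPeaks(bg() + (lab == "A") * spec@trackNoise,
                          anchorsStripe, amp),
      H3K27me3 = bg() + (lab == "B") * spec@trackNoise * 3
    )
  })
  tracks <- lapply(names(vals), function(f) {
    tr <- BinTrack(vals[[f]], chrom = "chrS", resolution = spec@resolution,
                   feature = f)
    normalizeTrack(tr, mean(tr@values))
  })
  names(tracks) <- names(vals)
  tracks
}

#' Ground-truth structure calls of a synthetic spec
#'
#' @param spec a \linkS4class{SyntheticSpec}.
#' @param resolution anchor resolution of the returned calls (1 kb).
#' @return list with elements `loops` and `stripes`
#'   (\linkS4class{StructureCallSet}s).
#' @export
truthStructures <- function(spec, resolution = 1000) {
  f <- resolution / spec@resolution
  lps <- if (nrow(spec@loops))
    loopCallSet("chrS", resolution,
                anchor1 = spec@loops$anchor1 %/% f,
                anchor2 = spec@loops$anchor2 %/% f,
                score = spec@loops$fold)
  else StructureCallSet("chrS", resolution)
  sts <- if (nrow(spec@stripes)) {
    a <- spec@stripes$anchor %/% f
    ext <- ceiling(spec@stripes$extentBins / f)
    from <- ifelse(spec@stripes$orientation == "vertical", a, a - ext)
    to <- ifelse(spec@stripes$orientation == "vertical", a + ext, a)
    StructureCallSet("chrS", resolution, data.frame(
      kind = "stripe", anchor1_start = a, anchor1_end = a + 1,
      anchor2_start = from, anchor2_end = to,
      orientation = spec@stripes$orientation, score = spec@stripes$fold))
  } else StructureCallSet("chrS", resolution)
  list(loops = lps, stripes = sts)
}

#' Generate a complete train/tune/test window dataset
#'
#' Generates the truth map, the degraded Hi-C, and the tracks; runs the
#' preprocessing pipeline; and splits the windows into train/tune/test
#' deterministically under the seed.  Returns the planted structures as
#' 1-kb call sets alongside.
#'
#' @param spec a \linkS4class{SyntheticSpec}.
#' @param splitFractions train/tune/test fractions summing to 1.
#' @param windowBp,stepBp,bandBp window geometry for the desk-scale model.
#' @param nWindows keep only the first n windows (NULL = all).
#' @param seed split/shuffle seed (defaults to the spec seed).
#' @return list(train, tune, test, samples, truth, hic, tracks, truthLoops,
#'   truthStripes, spec).
#' @export
makeDataset <- function(spec, splitFractions = c(0.7, 0.15, 0.15),
                        windowBp = 50000, stepBp = 12500, bandBp = 20000,
                        nWindows = NULL, seed = spec@seed) {
  if (abs(sum(splitFractions) - 1) > 1e-8)
    stop("splitFractions must sum to 1")
  truth <- generateTruth(spec)
  hic <- degradeToHic(truth, spec@hicDepthFraction, spec@hicResolution,
                      seed = spec@seed + 2)
  tracks <- generateTracks(spec)
  samples <- makeWindowSamples(hic, tracks, spec@lengthBp,
                               windowBp = windowBp, stepBp = stepBp,
                               bandBp = bandBp, truth = truth,
                               resolution = spec@resolution)
  if (!is.null(nWindows)) {
    if (nWindows > length(samples))
      stop("nWindows exceeds the available windows (", length(samples), ")")
    samples <- samples[seq_len(nWindows)]
  }
  N <- length(samples)
  if (N < sum(splitFractions > 0))
    stop("too few windows for the requested split")
  withr::with_seed(seed + 3, ord <- sample(N))
  nTr <- round(splitFractions[1] * N)
  nTu <- round(splitFractions[2] * N)
  nTr <- min(nTr, N); nTu <- min(nTu, N - nTr)
  ts <- truthStructures(spec)
  list(train = samples[sort(ord[seq_len(nTr)])],
       tune = if (nTu > 0) samples[sort(ord[nTr + seq_len(nTu)])] else list(),
       test = if (N - nTr - nTu > 0)
         samples[sort(ord[(nTr + nTu + 1):N])] else list(),
       samples = samples, truth = truth, hic = hic, tracks = tracks,
       truthLoops = ts$loops, truthStripes = ts$stripes, spec = spec)
}
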