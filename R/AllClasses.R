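#' @import methods
#' @importFrom Matrix Matrix sparseMatrix triu t drop0 rowSums colSums Diagonal
NULL

#' BinTrack: one epigenomic feature binned over a region
#'
#' Holds one signal track (e.g. ATAC-seq or a histone mark) averaged into
#' fixed-width bins (200 bp by default) over a contiguous region of one
#' chromosome.  Coordinates are 0-based half-open; bin index =
#' floor(position / resolution).
#'
#' @slot chrom chromosome name.
#' @slot startBin index of the first bin at this resolution.
#' @slot resolution bin width in bp.
#' @slot values numeric vector, one finite value per bin.
#' @slot feature feature label, e.g. "ATAC-seq".
#' @slot normalized TRUE once values are observed / genome-wide mean.
#' @exportClass BinTrack
setClass("BinTrack",
  representation(
    chrom = "character", startBin = "numeric", resolution = "numeric",
    values = "numeric", feature = "character", normalized = "logical"
  ),
  prototype(resolution = 200, normalized = FALSE)
)

setValidity("BinTrack", function(object) {
  msg <- NULL
  if (length(object@resolution) != 1 || object@resolution <= 0)
    msg <- c(msg, "resolution must be a single positive number")
  if (any(!is.finite(object@values)))
    msg <- c(msg, "values must all be finite")
  if (length(object@chrom) != 1 || !nzchar(object@chrom))
    msg <- c(msg, "chrom must be a single non-empty string")
  if (is.null(msg)) TRUE else msg
})

#' ContactMap: sparse symmetric binned contact matrix
#'
#' Stores the upper triangle (including the diagonal) of a symmetric
#' non-negative contact matrix; symmetry is enforced at the accessor, which
#' mirrors on access.  `state` tracks the normalization applied: "raw"
#' counts, "oe" (observed/expected by distance stratum), "log" (log1p of
#' raw counts) or "log_oe".
#'
#' @slot chrom chromosome name.
#' @slot resolution bin width in bp.
#' @slot offsetBin index of the first bin covered by the matrix.
#' @slot matrix upper-triangular sparse matrix (CsparseMatrix).
#' @slot state one of "raw", "oe", "log", "log_oe".
#' @slot totalContacts sum of stored raw counts (diagonal counted once);
#'   NA for non-raw states.
#' @exportClass ContactMap
setClass("ContactMap",
  representation(
    chrom = "character", resolution = "numeric", offsetBin = "numeric",
    matrix = "CsparseMatrix", state = "character", totalContacts = "numeric"
  ),
  prototype(offsetBin = 0, state = "raw", totalContacts = NA_real_)
)

setValidity("ContactMap", function(object) {
  msg <- NULL
  m <- object@matrix
  if (nrow(m) != ncol(m)) msg <- c(msg, "matrix must be square")
  if (!object@state %in% c("raw", "oe", "log", "log_oe"))
    msg <- c(msg, "state must be one of raw, oe, log, log_oe")
  x <- m@x
  if (length(x) && any(!is.finite(x))) msg <- c(msg, "entries must be finite")
  if (object@state == "raw" && length(x) && any(x < 0))
    msg <- c(msg, "raw entries must be non-negative")
  if (length(object@resolution) != 1 || object@resolution <= 0)
    msg <- c(msg, "resolution must be positive")
  if (is.null(msg)) TRUE else msg
})

#' StructureCallSet: loop and stripe calls on a binned contact map
#'
#' A set of structural calls at one resolution.  Loops carry two bin-interval
#' anchors (anchor1 genomically left of anchor2); stripes carry an anchor
#' interval plus an extent interval and an orientation ("vertical": anchor at
#' the smaller coordinate extending right; "horizontal": the converse).
#'
#' @slot chrom chromosome name.
#' @slot resolution bin width in bp of the anchor coordinates.
#' @slot calls data.frame with columns kind, anchor1_start, anchor1_end,
#'   anchor2_start, anchor2_end, orientation, score (half-open bin intervals).
#' @exportClass StructureCallSet
setClass("StructureCallSet",
  representation(chrom = "character", resolution = "numeric", calls = "data.frame")
)

.callColumns <- c("kind", "anchor1_start", "anchor1_end",
                  "anchor2_start", "anchor2_end", "orientation", "score")

setValidity("StructureCallSet", function(object) {
  msg <- NULL
  df <- object@calls
  if (!all(.callColumns %in% names(df)))
    msg <- c(msg, paste("calls must have columns:", paste(.callColumns, collapse = ", ")))
  else if (nrow(df)) {
    if (!all(df$kind %in% c("loop", "stripe"))) msg <- c(msg, "kind must be loop or stripe")
    if (!all(df$orientation %in% c("na", "horizontal", "vertical")))
      msg <- c(msg, "orientation must be na, horizontal or vertical")
    if (any(df$anchor1_start > df$anchor1_end)) msg <- c(msg, "anchor1 interval reversed")
    lp <- df$kind == "loop"
    if (any(lp & df$anchor1_start > df$anchor2_start))
      msg <- c(msg, "loop anchors must be ordered anchor1 <= anchor2")
  }
  if (is.null(msg)) TRUE else msg
})

#' ChromGraph: contact graph over 200-bp nodes
#'
#' Nodes are fixed-width genomic bins; weighted edges are (thresholded)
#' interpolated O/E contacts, with identity self-loops always added so the
#' symmetric-normalized graph convolution is well defined.
#'
#' @slot nNodes number of nodes.
#' @slot adjacency sparse symmetric non-negative matrix with positive diagonal.
#' @slot nodeFeatures (features + positional encoding) x nodes matrix.
#' @exportClass ChromGraph
setClass("ChromGraph",
  representation(nNodes = "numeric", adjacency = "CsparseMatrix",
                 nodeFeatures = "matrix")
)

setValidity("ChromGraph", function(object) {
  msg <- NULL
  a <- object@adjacency
  if (nrow(a) != object@nNodes || ncol(a) != object@nNodes)
    msg <- c(msg, "adjacency must be nNodes x nNodes")
  if (length(a@x) && any(!is.finite(a@x) | a@x < 0))
    msg <- c(msg, "adjacency must be finite and non-negative")
  if (any(Matrix::diag(a) <= 0)) msg <- c(msg, "self-loops required: diagonal must be > 0")
  if (ncol(object@nodeFeatures) != object@nNodes)
    msg <- c(msg, "nodeFeatures must have one column per node")
  if (is.null(msg)) TRUE else msg
})

#' WindowSample: one sliding-window training/inference unit
#'
#' A 250-kb (by default) window holding the feature matrix X (signals x
#' bins), the contact graph built from the input Hi-C, and optionally the
#' target matrix Y restricted to the prediction band.
#'
#' @slot chrom chromosome name.
#' @slot startBp window start in bp (0-based).
#' @slot windowBp window width in bp.
#' @slot bandBp maximum predicted genomic distance in bp.
#' @slot resolution bin width in bp (200).
#' @slot X m x n feature matrix (epigenomic signals only).
#' @slot featureNames names of the m rows of X.
#' @slot graph ChromGraph over the window's bins.
#' @slot Y optional n x n target matrix (symmetric, zero outside the band).
#' @exportClass WindowSample
setClass("WindowSample",
  representation(
    chrom = "character", startBp = "numeric", windowBp = "numeric",
    bandBp = "numeric", resolution = "numeric", X = "matrix",
    featureNames = "character", graph = "ChromGraph", Y = "ANY"
  ),
  prototype(resolution = 200, Y = NULL)
)

setValidity("WindowSample", function(object) {
  msg <- NULL
  n <- object@windowBp / object@resolution
  if (ncol(object@X) != n) msg <- c(msg, "X must have windowBp/resolution columns")
  if (any(!is.finite(object@X))) msg <- c(msg, "X must be finite")
  if (!is.null(object@Y)) {
    if (!all(dim(object@Y) == c(n, n))) msg <- c(msg, "Y must be n x n")
    if (any(!is.finite(object@Y))) msg <- c(msg, "Y must be finite")
  }
  if (length(object@featureNames) != nrow(object@X))
    msg <- c(msg, "featureNames must match rows of X")
  if (is.null(msg)) TRUE else msg
})

#' ImputationModel: parameters of the conv/GCN imputation network
#'
#' Parameters of the mapping from a window's feature matrix to its predicted
#' contact matrix: a 1D-convolutional stack over the genomic axis, a
#' graph-convolutional stack over the contact graph, and two output heads
#' (a fully connected per-bin contact-profile head and an inner-product loop
#' head) whose outputs are summed.
#'
#' @slot params named list of parameter matrices/vectors.
#' @slot config named list of hyperparameters (layer sizes, band, lr, seed).
#' @exportClass ImputationModel
setClass("ImputationModel",
  representation(params = "list", config = "list")
)

setValidity("ImputationModel", function(object) {
  ok <- all(vapply(object@params, function(p) all(is.finite(p)), logical(1)))
  if (!ok) "all parameter tensors must be finite" else TRUE
})

#' TrainState: bookkeeping for the sequential two-phase training
#'
#' @slot phase "loop" or "profile"; the loop head is trained first, then the
#'   profile head on the residual map with the loop head frozen.
#' @slot epoch epochs completed in the current phase.
#' @slot history data.frame of per-epoch phase and MSE.
#' @slot opt Adam optimizer state.
#' @slot seed RNG seed used for this phase.
#' @exportClass TrainState
setClass("TrainState",
  representation(phase = "character", epoch = "numeric", history = "data.frame",
                 opt = "list", seed = "numeric")
)

#' AttributionMap: integrated-gradients attribution of an output region
#'
#' @slot A m x n attribution matrix (signal x bin), same layout as the input
#'   feature matrix; positional-encoding rows are excluded.
#' @slot featureNames names of the m rows.
#' @slot steps path-discretization step count.
#' @slot yDiff y(X) - y(X0), the attributed output difference.
#' @slot completenessGap |sum(A) - yDiff| (absolute), a self-diagnostic.
#' @exportClass AttributionMap
setClass("AttributionMap",
  representation(A = "matrix", featureNames = "character", steps = "numeric",
                 yDiff = "numeric", completenessGap = "numeric")
)

#' PileupResult: averaged submatrix around a set of centers
#'
#' @slot matrix mean submatrix with odd side length.
#' @slot nRegions number of (non-clipped) regions aggregated.
#' @slot centerScore mean of the central 5 x 5 block.
#' @exportClass PileupResult
setClass("PileupResult",
  representation(matrix = "matrix", nRegions = "numeric", centerScore = "numeric")
)

setValidity("PileupResult", function(object) {
  msg <- NULL
  if (nrow(object@matrix) %% 2 == 0) msg <- c(msg, "side length must be odd")
  if (any(!is.finite(object@matrix))) msg <- c(msg, "matrix must be finite")
  if (object@nRegions < 1) msg <- c(msg, "nRegions must be >= 1")
  if (is.null(msg)) TRUE else msg
})

#' SCCReport: stratum-adjusted correlation coefficient report
#'
#' @slot strata data.frame with per-stratum distance (bins), Pearson r,
#'   stratum size N and weight w.
#' @slot scc the weighted aggregate, sum(w r) / sum(w).
#' @slot h smoothing half-width (bins).
#' @slot maxDistanceBp maximum genomic distance included.
#' @exportClass SCCReport
setClass("SCCReport",
  representation(strata = "data.frame", scc = "numeric", h = "numeric",
                 maxDistanceBp = "numeric")
)

#' SyntheticSpec: parameters of the synthetic benchmark generator
#'
#' Defines a synthetic chromosome: exponential-family distance decay
#' (expected contact proportional to (1+d)^-alpha), alternating compartment
#' blocks with a plaid affinity ratio, planted Gaussian loop foci and stripe
#' ridges, Poisson count noise at a stated depth, a degraded lower-depth
#' coarser Hi-C surrogate, and matched epigenomic tracks whose peaks
#' co-locate with the planted anchors.
#'
#' @slot lengthBp region length in bp.
#' @slot resolution fine bin width in bp (200).
#' @slot alpha distance-decay exponent.
#' @slot diagIntensity expected count at distance 0 in the fine map.
#' @slot loops data.frame: anchor1, anchor2 (fine-bin indices), fold, sigma.
#' @slot stripes data.frame: anchor (fine bin), orientation, extentBins, fold.
#' @slot compartmentBlockBp length of alternating A/B blocks.
#' @slot compartmentRatio same-compartment contact multiplier (cross-block
#'   contacts are divided by it).
#' @slot hicDepthFraction fraction of the fine-map depth kept in the
#'   degraded Hi-C surrogate.
#' @slot hicResolution bin width of the degraded Hi-C (1000).
#' @slot trackNoise background noise level of the synthetic tracks.
#' @slot trackPeakAmp peak amplitude (fold over background) of track peaks.
#' @slot seed mandatory RNG seed.
#' @exportClass SyntheticSpec
setClass("SyntheticSpec",
  representation(
    lengthBp = "numeric", resolution = "numeric", alpha = "numeric",
    diagIntensity = "numeric", loops = "data.frame", stripes = "data.frame",
    compartmentBlockBp = "numeric", compartmentRatio = "numeric",
    hicDepthFraction = "numeric", hicResolution = "numeric",
    trackNoise = "numeric", trackPeakAmp = "numeric", seed = "numeric"
  )
)

setValidity("SyntheticSpec", function(object) {
  msg <- NULL
  if (length(object@seed) != 1 || is.na(object@seed))
    msg <- c(msg, "seed is mandatory")
  if (object@lengthBp <= 0 || object@resolution <= 0)
    msg <- c(msg, "lengthBp and resolution must be positive")
  if (object@diagIntensity <= 0) msg <- c(msg, "diagIntensity must be positive")
  nb <- object@lengthBp / object@resolution
  if (nrow(object@loops)) {
    if (any(object@loops$fold <= 0)) msg <- c(msg, "loop amplitudes must be > 0")
    if (any(object@loops$anchor1 < 0 | object@loops$anchor2 >= nb))
      msg <- c(msg, "loop anchors must lie within the region")
  }
  if (nrow(object@stripes)) {
    if (any(object@stripes$fold <= 0)) msg <- c(msg, "stripe amplitudes must be > 0")
    if (any(object@stripes$anchor < 0 | object@stripes$anchor >= nb))
      msg <- c(msg, "stripe anchors must lie within the region")
  }
  if (object@hicDepthFraction <= 0 || object@hicDepthFraction > 1)
    msg <- c(msg, "hicDepthFraction must be in (0, 1]")
  if (is.null(msg)) TRUE else msg
})

#' RunConfig: resolved run configuration
#'
#' @slot features character vector of epigenomic feature names.
#' @slot windowBp,stepBp,bandBp sliding-window geometry in bp.
#' @slot model named list of model hyperparameters.
#' @slot caller named list of loop/stripe caller thresholds.
#' @slot seed RNG seed (NA until set; stochastic commands require it).
#' @exportClass RunConfig
setClass("RunConfig",
  representation(features = "character", windowBp = "numeric", stepBp = "numeric",
                 bandBp = "numeric", model = "list", caller = "list",
                 seed = "numeric")
)
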