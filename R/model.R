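#' @include preprocess.R
NULL

# The imputation network maps a window's feature matrix X (m signals x n
# bins) to an n x n contact matrix: a 1D convolutional stack extracts local
# patterns along the genome, a graph-convolutional stack extracts spatial
# patterns over the contact graph, their per-bin outputs are concatenated,
# and two output heads are summed -- a fully connected head emitting each
# bin's contact profile over offsets -w..w, and an inner-product head whose
# low-rank embeddings capture focal loops.  Forward, backprop and Adam are
# implemented directly with BLAS matrix ops; gradients are checked against
# numerical differentiation in the test suite.

.bandCache <- new.env(parent = emptyenv())

.bandMaskCached <- function(n, w) {
  key <- paste(n, w)
  if (is.null(.bandCache[[key]])) .bandCache[[key]] <- .bandMask(n, w)
  .bandCache[[key]]
}

.profIndexCached <- function(n, w) {
  key <- paste("idx", n, w)
  if (is.null(.bandCache[[key]])) {
    i <- rep(seq_len(n), times = 2 * w + 1)
    c0 <- rep(seq_len(2 * w + 1), each = n)
    j <- i + (c0 - w - 1)
    valid <- j >= 1 & j <= n
    .bandCache[[key]] <- list(i = i[valid], j = j[valid], c = c0[valid])
  }
  .bandCache[[key]]
}

.heInit <- function(nr, nc, fanIn) matrix(stats::rnorm(nr * nc, sd = sqrt(2 / fanIn)), nr, nc)

#' Construct an (untrained) imputation model
#'
#' @param nFeatures number m of epigenomic input signals.
#' @param bandBp maximum predicted genomic distance in bp.
#' @param featureNames expected feature labels (length m); used to give
#'   informative errors on feature mismatch.
#' @param resolution bin width in bp.
#' @param convChannels channels of the two 1D conv layers.
#' @param convKernels kernel widths (bins, odd) of the conv layers.
#' @param gcnUnits units of the two graph-conv layers.
#' @param embedDim loop-head embedding dimension.
#' @param encodingDim positional-encoding rows fed to the graph stack.
#' @param lr Adam learning rate.
#' @param seed mandatory RNG seed for initialization.
#' @return an \linkS4class{ImputationModel}.
#' @export
imputationModel <- function(nFeatures, bandBp = 200000,
                            featureNames = NULL, resolution = 200,
                            convChannels = c(32, 64), convKernels = c(11, 5),
                            gcnUnits = c(64, 64), embedDim = 64,
                            encodingDim = 8, lr = 1e-3, seed) {
  if (missing(seed)) stop("seed is mandatory for model initialization")
  if (any(convKernels %% 2 == 0)) stop("conv kernels must be odd")
  m <- nFeatures; p <- encodingDim
  c1 <- convChannels[1]; c2 <- convChannels[2]
  k1 <- convKernels[1]; k2 <- convKernels[2]
  g1 <- gcnUnits[1]; g2 <- gcnUnits[2]
  w <- bandBp / resolution
  h <- c2 + g2
  params <- withr::with_seed(seed, list(
    Wc1 = .heInit(c1, m * k1, m * k1), bc1 = numeric(c1),
    Wc2 = .heInit(c2, c1 * k2, c1 * k2), bc2 = numeric(c2),
    Wg1 = .heInit(m + p, g1, m + p), bg1 = numeric(g1),
    Wg2 = .heInit(g1, g2, g1), bg2 = numeric(g2),
    Wp = .heInit(h, 2 * w + 1, h) * 0.1, bp = numeric(2 * w + 1),
    We = .heInit(h, embedDim, h) * 0.1, be = numeric(embedDim)
  ))
  config <- list(nFeatures = m, bandBp = bandBp, resolution = resolution,
                 featureNames = featureNames, convChannels = convChannels,
                 convKernels = convKernels, gcnUnits = gcnUnits,
                 embedDim = embedDim, encodingDim = encodingDim, lr = lr,
                 seed = seed)
  new("ImputationModel", params = params, config = config)
}

# symmetric normalization D^{-1/2} A D^{-1/2} of a self-looped adjacency
.normalizedAdj <- function(adj) {
  deg <- Matrix::rowSums(adj)
  if (any(deg <= 0)) stop("internal error: zero-degree node after self-loops")
  dh <- 1 / sqrt(deg)
  Diagonal(x = dh) %*% adj %*% Diagonal(x = dh)
}

#' One graph-convolution layer
#'
#' Computes sigma(D^{-1/2} A D^{-1/2} H W + b) with A the self-looped
#' adjacency, D its degree matrix and sigma = ReLU.
#'
#' @param H n x h hidden matrix.
#' @param adjacency self-looped sparse adjacency (n x n).
#' @param W h x h' weight matrix.
#' @param b optional length-h' bias.
#' @param activation apply the ReLU nonlinearity (TRUE).
#' @return n x h' matrix.
#' @export
gcnLayer <- function(H, adjacency, W, b = NULL, activation = TRUE) {
  if (ncol(H) != nrow(W)) stop("dimension mismatch between H and W")
  if (nrow(H) != nrow(adjacency)) stop("dimension mismatch between H and adjacency")
  Ahat <- .normalizedAdj(adjacency)
  Z <- as.matrix(Ahat %*% H) %*% W
  if (!is.null(b)) Z <- sweep(Z, 2, b, "+")
  if (activation) pmax(Z, 0) else Z
}

.im2col <- function(X, k) {
  cin <- nrow(X); n <- ncol(X); pad <- (k - 1) / 2
  Xp <- cbind(matrix(0, cin, pad), X, matrix(0, cin, pad))
  out <- matrix(0, cin * k, n)
  for (t in seq_len(k))
    out[((t - 1) * cin + 1):(t * cin), ] <- Xp[, t:(t + n - 1), drop = FALSE]
  out
}

.col2im <- function(dCol, cin, k, n) {
  pad <- (k - 1) / 2
  dXp <- matrix(0, cin, n + 2 * pad)
  for (t in seq_len(k)) {
    rows <- ((t - 1) * cin + 1):(t * cin)
    dXp[, t:(t + n - 1)] <- dXp[, t:(t + n - 1)] + dCol[rows, , drop = FALSE]
  }
  dXp[, (pad + 1):(pad + n), drop = FALSE]
}

# full forward pass; X overrides the sample's feature matrix (used by the
# integrated-gradients path); returns all caches needed for backprop
.forwardFull <- function(model, sample, X = NULL) {
  p <- model@params; cfg <- model@config
  if (is.null(X)) X <- sample@X
  m <- cfg$nFeatures
  if (nrow(X) != m) {
    exp <- if (!is.null(cfg$featureNames))
      paste(cfg$featureNames, collapse = ", ") else paste(m, "features")
    stop("configuration error: model expects ", m, " features (", exp,
         ") but got ", nrow(X))
  }
  n <- ncol(X)
  w <- cfg$bandBp / cfg$resolution
  k1 <- cfg$convKernels[1]; k2 <- cfg$convKernels[2]
  Ahat <- .normalizedAdj(sample@graph@adjacency)
  # conv path
  C1col <- .im2col(X, k1)
  Z1 <- p$Wc1 %*% C1col + p$bc1
  C1 <- pmax(Z1, 0)
  C2col <- .im2col(C1, k2)
  Z2 <- p$Wc2 %*% C2col + p$bc2
  C2 <- pmax(Z2, 0)
  # graph path: epigenomic rows follow X, positional rows stay fixed
  pe <- sample@graph@nodeFeatures[-seq_len(nrow(sample@X)), , drop = FALSE]
  H0 <- t(rbind(X, pe))
  AH0 <- as.matrix(Ahat %*% H0)
  Zg1 <- sweep(AH0 %*% p$Wg1, 2, p$bg1, "+")
  G1 <- pmax(Zg1, 0)
  AG1 <- as.matrix(Ahat %*% G1)
  Zg2 <- sweep(AG1 %*% p$Wg2, 2, p$bg2, "+")
  G2 <- pmax(Zg2, 0)
  H <- cbind(t(C2), G2)
  # profile head
  P <- sweep(H %*% p$Wp, 2, p$bp, "+")
  idx <- .profIndexCached(n, w)
  Mp <- matrix(0, n, n)
  Mp[cbind(idx$i, idx$j)] <- P[cbind(idx$i, idx$c)]
  band <- .bandMaskCached(n, w)
  Sp <- (Mp + t(Mp)) / 2 * band
  # loop head
  E <- sweep(H %*% p$We, 2, p$be, "+")
  IP <- tcrossprod(E)
  Ml <- pmax(IP, 0) * band
  list(out = Sp + Ml, profile = Sp, loop = Ml, X = X, n = n, w = w,
       band = band, idx = idx, Ahat = Ahat, C1col = C1col, Z1 = Z1, C1 = C1,
       C2col = C2col, Z2 = Z2, C2 = C2, H0 = H0, AH0 = AH0, Zg1 = Zg1,
       G1 = G1, AG1 = AG1, Zg2 = Zg2, G2 = G2, H = H, P = P, E = E, IP = IP)
}

# backprop of a scalar loss with d loss / d out = dOut (n x n, any shape).
# heads: which output paths to propagate ("profile", "loop").
# Returns parameter grads and dX.
.backward <- function(model, fw, dOut, heads = c("profile", "loop")) {
  p <- model@params; cfg <- model@config
  m <- cfg$nFeatures
  n <- fw$n
  c2 <- cfg$convChannels[2]
  dH <- matrix(0, n, ncol(fw$H))
  g <- list()
  if ("loop" %in% heads) {
    Gl <- dOut * (fw$IP > 0) * fw$band
    dE <- (Gl + t(Gl)) %*% fw$E
    g$We <- crossprod(fw$H, dE)
    g$be <- colSums(dE)
    dH <- dH + dE %*% t(p$We)
  } else {
    g$We <- p$We * 0; g$be <- p$be * 0
  }
  if ("profile" %in% heads) {
    Gp <- dOut * fw$band
    Gs <- (Gp + t(Gp)) / 2
    dP <- matrix(0, n, ncol(fw$P))
    dP[cbind(fw$idx$i, fw$idx$c)] <- Gs[cbind(fw$idx$i, fw$idx$j)]
    g$Wp <- crossprod(fw$H, dP)
    g$bp <- colSums(dP)
    dH <- dH + dP %*% t(p$Wp)
  } else {
    g$Wp <- p$Wp * 0; g$bp <- p$bp * 0
  }
  dC2 <- t(dH[, seq_len(c2), drop = FALSE])
  dG2 <- dH[, (c2 + 1):ncol(dH), drop = FALSE]
  # graph path
  dZg2 <- dG2 * (fw$Zg2 > 0)
  g$Wg2 <- crossprod(fw$AG1, dZg2)
  g$bg2 <- colSums(dZg2)
  dG1 <- as.matrix(fw$Ahat %*% dZg2) %*% t(p$Wg2)
  dZg1 <- dG1 * (fw$Zg1 > 0)
  g$Wg1 <- crossprod(fw$AH0, dZg1)
  g$bg1 <- colSums(dZg1)
  dH0 <- as.matrix(fw$Ahat %*% dZg1) %*% t(p$Wg1)
  dXg <- t(dH0)[seq_len(m), , drop = FALSE]
  # conv path
  dZ2 <- dC2 * (fw$Z2 > 0)
  g$Wc2 <- tcrossprod(dZ2, fw$C2col)
  g$bc2 <- rowSums(dZ2)
  dC1col <- crossprod(p$Wc2, dZ2)
  dC1 <- .col2im(dC1col, cfg$convChannels[1], cfg$convKernels[2], n)
  dZ1 <- dC1 * (fw$Z1 > 0)
  g$Wc1 <- tcrossprod(dZ1, fw$C1col)
  g$bc1 <- rowSums(dZ1)
  dXcol <- crossprod(p$Wc1, dZ1)
  dXc <- .col2im(dXcol, m, cfg$convKernels[1], n)
  list(grads = g[names(model@params)], dX = dXc + dXg)
}

#' Forward pass of the imputation model on one window
#'
#' The output is the sum of the symmetrized contact-profile head and the
#' non-negative inner-product loop head, exactly zero outside the band.
#'
#' @param model an \linkS4class{ImputationModel}.
#' @param sample a \linkS4class{WindowSample} with matching feature count.
#' @return n x n symmetric predicted matrix (log1p-count space).
#' @export
modelForward <- function(model, sample) .forwardFull(model, sample)$out

#' @rdname modelForward
#' @return for `modelComponents`, a list with elements `profile`, `loop`
#'   and `out` (their sum).
#' @export
modelComponents <- function(model, sample) {
  fw <- .forwardFull(model, sample)
  list(profile = fw$profile, loop = fw$loop, out = fw$out)
}

# ---- Adam -----------------------------------------------------------------

.adamInit <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0), t = 0)
}

.adamStep <- function(params, grads, st, lr, update = names(params),
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  st$t <- st$t + 1
  for (nm in update) {
    st$m[[nm]] <- beta1 * st$m[[nm]] + (1 - beta1) * grads[[nm]]
    st$v[[nm]] <- beta2 * st$v[[nm]] + (1 - beta2) * grads[[nm]]^2
    mh <- st$m[[nm]] / (1 - beta1^st$t)
    vh <- st$v[[nm]] / (1 - beta2^st$t)
    params[[nm]] <- params[[nm]] - lr * mh / (sqrt(vh) + eps)
  }
  list(params = params, state = st)
}

# ---- training -------------------------------------------------------------

#' Training mask for loop regions
#'
#' Builds the symmetric boolean mask of 10 kb x 10 kb squares (50 x 50 bins
#' at 200 bp) centered at each loop's anchor pair, clipped to the window and
#' intersected with the prediction band.
#'
#' @param sample a \linkS4class{WindowSample}.
#' @param loopCalls a \linkS4class{StructureCallSet} of loops (anchors at
#'   <= 1-kb precision).
#' @param squareBp side length of the training square (10,000 bp).
#' @return n x n logical matrix (possibly all-FALSE).
#' @export
loopTrainingMask <- function(sample, loopCalls, squareBp = 10000) {
  res <- sample@resolution
  n <- ncol(sample@X)
  w <- sample@bandBp / res
  half <- squareBp / res / 2               # 25 bins at defaults
  mask <- matrix(FALSE, n, n)
  df <- loopCalls@calls[loopCalls@calls$kind == "loop", , drop = FALSE]
  if (nrow(df)) {
    cres <- loopCalls@resolution
    off <- sample@startBp / res
    p <- floor((df$anchor1_start + df$anchor1_end) / 2 * cres / res) - off
    q <- floor((df$anchor2_start + df$anchor2_end) / 2 * cres / res) - off
    for (k in seq_along(p)) {
      ri <- max(1, p[k] - half + 1):min(n, p[k] + half)
      rj <- max(1, q[k] - half + 1):min(n, q[k] + half)
      if (p[k] + half < 1 || p[k] - half + 1 > n) next
      if (q[k] + half < 1 || q[k] - half + 1 > n) next
      mask[ri, rj] <- TRUE
      mask[rj, ri] <- TRUE
    }
  }
  mask & (.bandMaskCached(n, w) > 0)
}

.maskedMSE <- function(pred, target, mask) {
  nm <- sum(mask)
  if (nm == 0) return(0)
  sum(((pred - target) * mask)^2) / nm
}

#' Phase 1: train the loop branch on loop regions
#'
#' Minimizes the MSE between the model output and the target restricted to
#' the union of 10 kb x 10 kb squares centered at the given loops.  By
#' default the shared trunk and the loop head are updated; the profile head
#' is never updated in this phase.
#'
#' @param model an \linkS4class{ImputationModel}.
#' @param dataset list of \linkS4class{WindowSample}s with targets.
#' @param loopCalls \linkS4class{StructureCallSet} of training loops.
#' @param epochs training epochs.
#' @param seed RNG seed (window shuffling).
#' @param freezeTrunk update only the loop head.
#' @return list(model, state) with a \linkS4class{TrainState} in phase "loop".
#' @export
trainLoopBranch <- function(model, dataset, loopCalls, epochs = 40, seed,
                            freezeTrunk = FALSE) {
  if (missing(seed)) stop("seed is mandatory")
  masks <- lapply(dataset, loopTrainingMask, loopCalls = loopCalls)
  useful <- vapply(masks, any, logical(1))
  if (!any(useful)) stop("no loops overlap the dataset windows")
  upd <- c("We", "be",
           if (!freezeTrunk) c("Wc1", "bc1", "Wc2", "bc2",
                               "Wg1", "bg1", "Wg2", "bg2"))
  params <- model@params
  opt <- .adamInit(params)
  hist <- data.frame(phase = character(), epoch = numeric(), mse = numeric())
  lr <- model@config$lr
  withr::with_seed(seed, {
    for (ep in seq_len(epochs)) {
      ord <- sample(which(useful))
      mses <- numeric(0)
      for (k in ord) {
        sm <- dataset[[k]]
        model@params <- params
        fw <- .forwardFull(model, sm)
        msk <- masks[[k]]
        nm <- sum(msk)
        dOut <- 2 * (fw$out - sm@Y) * msk / nm
        bk <- .backward(model, fw, dOut, heads = c("profile", "loop"))
        stp <- .adamStep(params, bk$grads, opt, lr, update = upd)
        params <- stp$params; opt <- stp$state
        mses <- c(mses, .maskedMSE(fw$out, sm@Y, msk))
      }
      hist <- rbind(hist, data.frame(phase = "loop", epoch = ep,
                                     mse = mean(mses)))
    }
  })
  model@params <- params
  state <- new("TrainState", phase = "loop", epoch = epochs, history = hist,
               opt = list(), seed = seed)
  list(model = model, state = state)
}

#' Phase 2: train the profile branch on the residual map
#'
#' Requires phase 1 to have run.  The target for the profile head is the
#' residual map: the observed target minus the loop-head output of the
#' phase-1 model, computed once and held fixed.  The loop-head parameters
#' are never updated; by default the shared trunk is frozen too, since
#' fine-tuning it would silently move the loop component that the residual
#' was computed against.
#'
#' @param model model returned by \code{\link{trainLoopBranch}}.
#' @param dataset list of \linkS4class{WindowSample}s with targets.
#' @param epochs training epochs.
#' @param seed RNG seed.
#' @param state the \linkS4class{TrainState} from phase 1.
#' @param freezeTrunk update only the profile head (TRUE, default); FALSE
#'   also fine-tunes the conv/GCN trunk through the profile path.
#' @return list(model, state) with the state in phase "profile".
#' @export
trainProfileBranch <- function(model, dataset, epochs = 25, seed, state,
                               freezeTrunk = TRUE) {
  if (missing(seed)) stop("seed is mandatory")
  if (missing(state) || !is(state, "TrainState") || state@phase != "loop")
    stop("state error: the loop branch must be trained first (phase order)")
  upd <- c("Wp", "bp",
           if (!freezeTrunk) c("Wc1", "bc1", "Wc2", "bc2",
                               "Wg1", "bg1", "Wg2", "bg2"))
  params <- model@params
  opt <- .adamInit(params)
  hist <- state@history
  lr <- model@config$lr
  # residual targets are computed once from the phase-1 model and then held
  # fixed: the loop component subtracted from the observed map is the frozen
  # phase-1 output, not a moving target
  resids <- lapply(dataset, function(sm) {
    fw <- .forwardFull(model, sm)
    sm@Y - fw$loop
  })
  withr::with_seed(seed, {
    for (ep in seq_len(epochs)) {
      ord <- sample(seq_along(dataset))
      mses <- numeric(0)
      for (k in ord) {
        sm <- dataset[[k]]
        model@params <- params
        fw <- .forwardFull(model, sm)
        nb <- sum(fw$band)
        dOut <- 2 * (fw$profile - resids[[k]]) * fw$band / nb
        bk <- .backward(model, fw, dOut, heads = "profile")
        stp <- .adamStep(params, bk$grads, opt, lr, update = upd)
        params <- stp$params; opt <- stp$state
        mses <- c(mses, sum(((fw$out - sm@Y) * fw$band)^2) / nb)
      }
      hist <- rbind(hist, data.frame(phase = "profile", epoch = ep,
                                     mse = mean(mses)))
    }
  })
  model@params <- params
  st <- new("TrainState", phase = "profile", epoch = epochs, history = hist,
            opt = list(), seed = seed)
  list(model = model, state = st)
}

#' Band-masked MSE of a model over a dataset
#'
#' @param model an \linkS4class{ImputationModel}.
#' @param dataset list of \linkS4class{WindowSample}s with targets.
#' @return mean over windows of the band-restricted MSE.
#' @export
bandMSE <- function(model, dataset) {
  mean(vapply(dataset, function(sm) {
    fw <- .forwardFull(model, sm)
    sum(((fw$out - sm@Y) * fw$band)^2) / sum(fw$band)
  }, numeric(1)))
}

#' Impute a high-resolution contact map
#'
#' Composes the full pipeline: preprocessing of the input Hi-C and tracks
#' into windows, per-window forward passes, and mean-stitching of the
#' overlapping predictions into a chromosome-scale band map in the model's
#' output space (log1p contacts).
#'
#' @param model a trained \linkS4class{ImputationModel}.
#' @param hic input raw \linkS4class{ContactMap}.
#' @param tracks list of \linkS4class{BinTrack}s; feature names must match
#'   the model's expected feature list.
#' @param chromLengthBp chromosome length in bp.
#' @param windowBp,stepBp sliding-window geometry.
#' @return a band-limited \linkS4class{ContactMap} (state "log").
#' @export
impute <- function(model, hic, tracks, chromLengthBp,
                   windowBp = 250000, stepBp = windowBp / 4) {
  cfg <- model@config
  have <- vapply(tracks, featureName, character(1))
  if (!is.null(cfg$featureNames)) {
    missing <- setdiff(cfg$featureNames, have)
    if (length(missing))
      stop("configuration error: missing required track(s): ",
           paste(missing, collapse = ", "))
    tracks <- tracks[match(cfg$featureNames, have)]
  }
  samples <- makeWindowSamples(hic, tracks, chromLengthBp,
                               windowBp = windowBp, stepBp = stepBp,
                               bandBp = cfg$bandBp,
                               resolution = cfg$resolution,
                               encodingDim = cfg$encodingDim)
  preds <- lapply(samples, function(sm) modelForward(model, sm))
  stitchPredictions(samples, preds, chromLengthBp = chromLengthBp,
                    state = "log")
}
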