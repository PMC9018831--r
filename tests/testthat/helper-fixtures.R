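# Shared fixture builders and independent brute-force oracles.  The oracles
# are deliberately written as plain dense-matrix loops, independent of the
# package's strip/sparse implementations.

randomSymmetricMap <- function(n, resolution = 1000, density = 0.2,
                               seed = 1, state = "raw", chrom = "chr1") {
  withr::with_seed(seed, {
    m <- matrix(0, n, n)
    up <- which(upper.tri(m, diag = TRUE))
    nz <- sample(up, round(density * length(up)))
    m[nz] <- rpois(length(nz), 5) + 1
  })
  m[lower.tri(m)] <- t(m)[lower.tri(m)]
  ContactMap(m, chrom = chrom, resolution = resolution, state = state)
}

tinyWindowSample <- function(n = 30, m = 3, w = 8, seed = 3,
                             encodingDim = 4, withY = FALSE) {
  withr::with_seed(seed, {
    X <- matrix(abs(rnorm(m * n)), m, n)
    adjm <- matrix(rpois(n * n, 0.3), n, n)
  })
  feats <- c("ATAC-seq", "CTCF", "H3K27ac", "H3K4me1", "H3K4me3",
             "H3K27me3")[seq_len(m)]
  rownames(X) <- feats
  adjm <- adjm + t(adjm); diag(adjm) <- 0
  fm <- ContactMap(adjm, "chr1", 200, state = "oe")
  g <- buildGraph(fm, X, encodingDim = encodingDim)
  Y <- NULL
  if (withY) {
    withr::with_seed(seed + 1, Y <- matrix(rnorm(n * n), n, n))
    Y <- (Y + t(Y)) / 2
    d <- abs(outer(seq_len(n), seq_len(n), "-"))
    Y[d > w] <- 0
  }
  new("WindowSample", chrom = "chr1", startBp = 0, windowBp = n * 200,
      bandBp = w * 200, resolution = 200, X = X, featureNames = feats,
      graph = g, Y = Y)
}

tinyModel <- function(sample, seed = 11, jitter = TRUE, bandBp = sample@bandBp) {
  model <- imputationModel(
    nFeatures = nrow(sample@X), bandBp = bandBp,
    featureNames = sample@featureNames, convChannels = c(4, 5),
    convKernels = c(5, 3), gcnUnits = c(6, 7), embedDim = 4,
    encodingDim = nrow(sample@graph@nodeFeatures) - nrow(sample@X),
    seed = seed)
  if (jitter)  # move biases off the ReLU kink so losses are smooth
    model@params <- withr::with_seed(seed + 1,
      lapply(model@params, function(p) p + rnorm(length(p), 0, 0.05)))
  model
}

# ---- oracles --------------------------------------------------------------

# dense GCN propagation oracle
denseGcnOracle <- function(H, A, W, activation = TRUE) {
  A <- as.matrix(A)
  d <- rowSums(A)
  Ahat <- diag(1 / sqrt(d)) %*% A %*% diag(1 / sqrt(d))
  Z <- Ahat %*% H %*% W
  if (activation) pmax(Z, 0) else Z
}

# dense box-filter; zero padding with a constant divisor (the SCC
# convention) or a true mean over in-matrix pixels (renorm = TRUE, the
# fragment-smoothing convention)
denseBoxFilterOracle <- function(M, h, renorm = FALSE) {
  n <- nrow(M)
  out <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    s <- 0; cnt <- 0
    for (a in -h:h) for (b in -h:h) {
      ii <- i + a; jj <- j + b
      if (ii >= 1 && ii <= n && jj >= 1 && jj <= n) {
        s <- s + M[ii, jj]; cnt <- cnt + 1
      }
    }
    out[i, j] <- s / if (renorm) cnt else (2 * h + 1)^2
  }
  out
}

# brute-force SCC oracle over dense matrices
sccOracle <- function(A, B, h, maxD) {
  As <- denseBoxFilterOracle(A, h)
  Bs <- denseBoxFilterOracle(B, h)
  n <- nrow(A)
  num <- 0; den <- 0
  strata <- data.frame()
  for (d in 0:min(maxD, n - 1)) {
    x <- sapply(seq_len(n - d), function(i) As[i, i + d])
    y <- sapply(seq_len(n - d), function(i) Bs[i, i + d])
    if (length(x) < 2 || var(x) == 0 || var(y) == 0) next
    r <- cor(x, y)
    w <- length(x) * sqrt(var(x) * var(y))
    num <- num + w * r; den <- den + w
  }
  num / den
}

# brute-force per-diagonal Pearson oracle
stratPearsonOracle <- function(A, B, maxD) {
  n <- nrow(A)
  sapply(0:min(maxD, n - 1), function(d) {
    x <- sapply(seq_len(n - d), function(i) A[i, i + d])
    y <- sapply(seq_len(n - d), function(i) B[i, i + d])
    if (length(x) < 2 || sd(x) == 0 || sd(y) == 0) NA_real_ else cor(x, y)
  })
}

# numerical gradient of a scalar function of the feature matrix
numericGradX <- function(f, X, eps = 1e-6) {
  G <- X * 0
  for (ii in seq_along(X)) {
    X2 <- X; X2[ii] <- X2[ii] + eps
    X3 <- X; X3[ii] <- X3[ii] - eps
    G[ii] <- (f(X2) - f(X3)) / (2 * eps)
  }
  G
}
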