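test_that("interpolation of a constant map is constant and preserves centers", {
  m <- matrix(3, 4, 4)
  map <- ContactMap(m, "chr1", 1000)
  fine <- interpolateContacts(map, 200)
  expect_equal(nBins(fine), 20)
  expect_true(all(abs(as.matrix(contactMatrix(fine)) - 3) < 1e-12))

  # coarse-bin centers preserved exactly for a non-constant map
  rmap <- randomSymmetricMap(6, resolution = 1000, density = 0.8, seed = 2)
  fine <- interpolateContacts(rmap, 200)
  coarse <- as.matrix(contactMatrix(rmap))
  fineM <- as.matrix(contactMatrix(fine))
  # fine center of coarse bin i sits at fine index 5*(i-1)+3 (factor 5, odd)
  for (i in 1:6) for (j in 1:6)
    expect_equal(fineM[5 * (i - 1) + 3, 5 * (j - 1) + 3], coarse[i, j],
                 tolerance = 1e-12)
})

test_that("bilinear interpolation matches the closed form between centers", {
  # 2x2 coarse map [[4,0],[0,4]] at 1000 bp; along the line between the two
  # diagonal centers values interpolate linearly in each axis
  m <- matrix(c(4, 0, 0, 4), 2, 2)
  map <- ContactMap(m, "chr1", 1000)
  fine <- interpolateContacts(map, 200)
  fm <- as.matrix(contactMatrix(fine))
  # coarse centers at fine coords (3,3) and (8,8) (1-based, factor 5)
  expect_equal(fm[3, 3], 4)
  expect_equal(fm[8, 8], 4)
  expect_equal(fm[3, 8], 0)
  # closed-form bilinear at intermediate fine bin k between centers:
  # weight w = (k-3)/5 along each axis
  for (k in 3:8) {
    w <- (k - 3) / 5
    expect_equal(fm[k, k], 4 * (1 - w)^2 + 4 * w^2, tolerance = 1e-12)
  }
})

test_that("interpolation at the input resolution is the identity", {
  rmap <- randomSymmetricMap(10, resolution = 1000, seed = 3)
  out <- interpolateContacts(rmap, 1000)
  expect_identical(as.matrix(contactMatrix(out)),
                   as.matrix(contactMatrix(rmap)))
  expect_error(interpolateContacts(rmap, 300), "multiple")
})

test_that("O/E normalization gives unit stratum means", {
  rmap <- randomSymmetricMap(40, resolution = 200, density = 0.6, seed = 4)
  oe <- oeNormalize(rmap)
  expect_equal(contactState(oe), "oe")
  full <- as.matrix(contactMatrix(oe))
  n <- nrow(full)
  for (d in 0:10) {
    vals <- sapply(seq_len(n - d), function(i) full[i, i + d])
    if (sum(vals) > 0) expect_equal(mean(vals), 1, tolerance = 1e-12)
  }
})

test_that("O/E divides by the extent mean including structural zeros", {
  # stratum d=1 entries {2,4}, others 0, n=4: mean over extent = 6/3 = 2
  m <- matrix(0, 4, 4)
  m[1, 2] <- 2; m[2, 3] <- 4
  map <- ContactMap(m, "chr1", 200)
  oe <- oeNormalize(map)
  full <- as.matrix(contactMatrix(oe))
  expect_equal(full[1, 2], 2 / 2)
  expect_equal(full[2, 3], 4 / 2)
  # constant map -> all ones
  cmap <- ContactMap(matrix(5, 6, 6), "chr1", 200)
  expect_true(all(abs(as.matrix(contactMatrix(oeNormalize(cmap))) - 1) < 1e-12))
  empty <- ContactMap(matrix(0, 4, 4), "chr1", 200)
  expect_error(oeNormalize(empty), "empty")
  expect_error(oeNormalize(oeNormalize(map)), "raw")
})

test_that("positional encoding is deterministic, bounded and data-free", {
  pe <- positionalEncoding(100, 8)
  expect_equal(dim(pe), c(8, 100))
  # bin 0: sin rows are 0, cos rows are 1
  expect_equal(unname(pe[seq(1, 8, 2), 1]), rep(0, 4))
  expect_equal(unname(pe[seq(2, 8, 2), 1]), rep(1, 4))
  expect_true(all(pe >= -1 & pe <= 1))
  expect_identical(pe, positionalEncoding(100, 8))
  expect_error(positionalEncoding(10, 7), "even")
})

test_that("graph construction adds self-loops and respects thresholds", {
  n <- 12
  X <- matrix(1, 2, n)
  zero <- ContactMap(matrix(0, n, n), "chr1", 200, state = "oe")
  g <- buildGraph(zero, X, encodingDim = 4)
  expect_equal(as.matrix(adjacencyMatrix(g)), diag(n))
  expect_equal(nrow(nodeFeatures(g)), 2 + 4)

  rmap <- randomSymmetricMap(n, resolution = 200, density = 0.5, seed = 6,
                             state = "oe")
  g2 <- buildGraph(rmap, X, encodingDim = 4, edgeThreshold = 0)
  A <- as.matrix(adjacencyMatrix(g2))
  M <- as.matrix(contactMatrix(rmap)); diag(M) <- 0
  # support = map support plus diagonal
  expect_identical(A != 0, (M != 0) | diag(n) > 0)
  # node degree = row sum of thresholded map + 1
  expect_equal(Matrix::rowSums(adjacencyMatrix(g2)), rowSums(M) + 1,
               ignore_attr = TRUE)
  expect_error(buildGraph(rmap, X[, 1:5]), "mismatch")
})

test_that("window extraction follows the sliding-window contract", {
  w <- extractWindows(1e6, 250000, 50000)
  expect_equal(nrow(w), 16)
  expect_equal(w$start[1:3], c(0, 50000, 100000))
  expect_equal(250000 / 200, 1250)   # bins per window at defaults
  # length == window -> exactly one window
  w1 <- extractWindows(250000, 250000, 50000)
  expect_equal(nrow(w1), 1)
  # non-multiple length appends one right-aligned window
  w2 <- extractWindows(1.02e6, 250000, 50000)
  expect_equal(w2$start[nrow(w2)], 1.02e6 - 250000)
  expect_true(w2$rightAligned[nrow(w2)])
  # short chromosome: truncated or empty per config
  ws <- extractWindows(100000, 250000, 50000)
  expect_true(ws$truncated)
  expect_equal(nrow(extractWindows(100000, 250000, 50000,
                                   shortChrom = "empty")), 0)
  expect_error(extractWindows(1e6, 250000, 60000), "multiple")
})

test_that("windows tile the diagonal band completely", {
  L <- 8e5; win <- 250000; band <- 200000
  w <- extractWindows(L, win, 50000)
  covered <- rep(FALSE, L / 200)
  for (k in seq_len(nrow(w))) {
    bins <- (w$start[k] / 200 + 1):(w$end[k] / 200)
    covered[bins] <- TRUE
  }
  expect_true(all(covered))
})

test_that("binomial downsampling matches expectation and is seeded", {
  rmap <- randomSymmetricMap(30, resolution = 1000, density = 0.8, seed = 8)
  tot <- totalContacts(rmap)
  expect_identical(downsampleContacts(rmap, tot, seed = 1)@matrix,
                   rmap@matrix)
  expect_error(downsampleContacts(rmap, tot + 1, seed = 1), "exceeds")
  # determinism
  d1 <- downsampleContacts(rmap, round(tot / 10), seed = 42)
  d2 <- downsampleContacts(rmap, round(tot / 10), seed = 42)
  expect_identical(d1@matrix, d2@matrix)
  # mean over 100 seeds within 3 SE of the target
  target <- round(tot / 10)
  tots <- vapply(1:100, function(s)
    sum(downsampleContacts(rmap, target, seed = s)@matrix@x), numeric(1))
  p <- target / tot
  se <- sqrt(tot * p * (1 - p)) / sqrt(100)
  expect_lt(abs(mean(tots) - target), 3 * se)
})

test_that("single-entry downsampling is Binomial(size, rate)", {
  m <- matrix(0, 3, 3); m[1, 2] <- 100
  map <- ContactMap(m, "chr1", 1000)
  draws <- vapply(1:400, function(s)
    sum(downsampleContacts(map, 50, seed = s)@matrix@x), numeric(1))
  # Binomial(100, .5): mean 50, var 25
  expect_lt(abs(mean(draws) - 50), 3 * sqrt(25 / 400))
  expect_lt(abs(var(draws) - 25), 10)
})

test_that("surrogate aggregation has linear expectation in equal proportions", {
  maps <- lapply(1:4, function(s)
    randomSymmetricMap(20, resolution = 1000, density = 0.7, seed = s))
  target <- 1000
  agg <- aggregateSurrogate(maps, target, seed = 5)
  # repeated seeds: total within 3 SE of target
  tots <- vapply(1:60, function(s)
    totalContacts(aggregateSurrogate(maps, target, seed = s)), numeric(1))
  expect_lt(abs(mean(tots) - target), 3 * sd(tots) / sqrt(60))
  # k identical maps at full depth reproduce k x the original in expectation
  tot1 <- totalContacts(maps[[1]])
  agg2 <- aggregateSurrogate(list(maps[[1]], maps[[1]]), 2 * tot1, seed = 1)
  expect_equal(totalContacts(agg2), 2 * tot1)
  # an empty map contributes zero without erroring
  empty <- ContactMap(matrix(0, 20, 20), "chr1", 1000)
  agg3 <- aggregateSurrogate(list(maps[[1]], empty), tot1, seed = 2)
  expect_true(totalContacts(agg3) <= tot1)
  expect_error(aggregateSurrogate(maps[1], 10, seed = 1), "at least 2")
  bad <- randomSymmetricMap(10, resolution = 1000, seed = 9)
  expect_error(aggregateSurrogate(list(maps[[1]], bad), 10, seed = 1),
               "grids")
})

test_that("stitching averages overlapping windows within the band", {
  sm1 <- tinyWindowSample(n = 20, w = 5, seed = 1)
  p1 <- matrix(1, 20, 20)
  # single window: output equals the window prediction inside the band
  st <- stitchPredictions(list(sm1), list(p1), chromLengthBp = 20 * 200)
  full <- as.matrix(contactMatrix(st))
  expect_equal(full[1, 3], 1)
  expect_equal(full[1, 10], 0)  # beyond band: absent
  # two overlapping windows with values a and b -> (a+b)/2 in the overlap
  sm2 <- tinyWindowSample(n = 20, w = 5, seed = 2)
  sm2@startBp <- 10 * 200
  p2 <- matrix(3, 20, 20)
  st2 <- stitchPredictions(list(sm1, sm2), list(p1, p2),
                           chromLengthBp = 30 * 200)
  f2 <- as.matrix(contactMatrix(st2))
  expect_equal(f2[2, 4], 1)          # only window 1
  expect_equal(f2[12, 14], 2)        # overlap: mean of 1 and 3
  expect_equal(f2[25, 27], 3)        # only window 2
  # equal values stay equal under averaging
  st3 <- stitchPredictions(list(sm1, sm2), list(p1, p1 * 1),
                           chromLengthBp = 30 * 200)
  expect_equal(as.matrix(contactMatrix(st3))[12, 14], 1)
  sm3 <- tinyWindowSample(n = 20, w = 7, seed = 3)
  expect_error(stitchPredictions(list(sm1, sm3), list(p1, p1)), "band")
})

test_that("log/exp contact transforms invert each other and clamp at zero", {
  rmap <- randomSymmetricMap(15, resolution = 200, seed = 10)
  lg <- logContacts(rmap)
  expect_equal(contactState(lg), "log")
  back <- expContacts(lg)
  expect_equal(as.matrix(contactMatrix(back)),
               as.matrix(contactMatrix(rmap)), tolerance = 1e-12)
})
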