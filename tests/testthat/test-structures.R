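test_that("pooling block-sums raw maps and conserves totals", {
  cmap <- ContactMap(matrix(2, 10, 10), "chr1", 200)
  pooled <- poolContacts(cmap, 1000)
  expect_equal(resolutionBp(pooled), 1000)
  expect_equal(nBins(pooled), 2)
  # constant raw c pools to 25c off-diagonal
  expect_equal(as.matrix(contactMatrix(pooled))[1, 2], 50)
  expect_equal(totalContacts(pooled), totalContacts(cmap))

  # a single nonzero pixel lands in exactly one coarse pixel
  m <- matrix(0, 10, 10); m[2, 7] <- 3
  one <- poolContacts(ContactMap(m, "chr1", 200), 1000)
  expect_equal(sum(one@matrix != 0), 1)
  expect_equal(as.matrix(contactMatrix(one))[1, 2], 3)

  rmap <- randomSymmetricMap(25, resolution = 200, density = 0.5, seed = 3)
  expect_equal(totalContacts(poolContacts(rmap, 1000)), totalContacts(rmap))
  expect_error(poolContacts(poolContacts(rmap, 1000), 1000), "200")
})

test_that("pooling O/E maps takes full-block means", {
  oeM <- oeNormalize(randomSymmetricMap(25, resolution = 200, density = 0.9,
                                        seed = 4))
  pooled <- poolContacts(oeM, 1000)
  full <- as.matrix(contactMatrix(oeM))
  coarse <- as.matrix(contactMatrix(pooled))
  expect_equal(coarse[1, 2], mean(full[1:5, 6:10]), tolerance = 1e-12)
  expect_equal(coarse[2, 2], mean(full[6:10, 6:10]), tolerance = 1e-12)
})

test_that("a constant map yields no loop or stripe calls", {
  cmap <- ContactMap(matrix(5, 60, 60), "chr1", 1000)
  expect_equal(length(callLoops(cmap, maxDistanceBp = 40000)), 0)
  expect_equal(length(callStripes(cmap, maxDistanceBp = 40000)), 0)
  tiny <- ContactMap(matrix(5, 8, 8), "chr1", 1000)
  expect_error(callLoops(tiny), "narrower")
})

# shared planted-loop fixture: exponential decay + Gaussian foci.  The base
# depth is high enough that Poisson fluctuations cannot reach the caller's
# fold threshold, so the planted foci are the only expected calls.
plantedLoopMap <- function(n = 200, centers, amp = 8, sigma = 1,
                           base = 300, seed = 21, res = 1000) {
  d <- abs(outer(seq_len(n), seq_len(n), "-"))
  mu <- base * exp(-d / 25)
  for (k in seq_len(nrow(centers))) {
    g <- exp(-((row(mu) - centers[k, 1])^2 +
                 (col(mu) - centers[k, 2])^2) / (2 * sigma^2))
    mu <- mu + (amp - 1) * base * exp(-d / 25) * g
  }
  withr::with_seed(seed, cnt <- matrix(rpois(n * n, mu), n, n))
  cnt[lower.tri(cnt)] <- t(cnt)[lower.tri(cnt)]
  ContactMap(cnt, "chr1", res)
}

test_that("planted Gaussian foci are called within one pixel, no extras", {
  centers <- cbind(c(30, 60, 95, 130, 170), c(45, 78, 110, 148, 185))
  map <- plantedLoopMap(centers = centers, seed = 21)
  calls <- callLoops(map, maxDistanceBp = 60000)
  df <- structureCalls(calls)
  expect_equal(nrow(df), 5)
  for (k in seq_len(5)) {
    dist <- pmax(abs(df$anchor1_start + 1 - centers[k, 1]),
                 abs(df$anchor2_start + 1 - centers[k, 2]))
    expect_lte(min(dist), 1)
  }
})

test_that("foci one pixel apart merge into a single call", {
  centers <- cbind(c(60, 61), c(90, 91))
  map <- plantedLoopMap(centers = centers, seed = 22, n = 150)
  calls <- callLoops(map, maxDistanceBp = 60000)
  expect_equal(length(calls), 1)
})

test_that("loop calling is translation-equivariant", {
  centers <- cbind(c(50, 100), c(70, 125))
  map1 <- plantedLoopMap(centers = centers, seed = 23, n = 160)
  k <- 7
  map2 <- plantedLoopMap(centers = centers + k, seed = 23, n = 160)
  c1 <- structureCalls(callLoops(map1, maxDistanceBp = 60000))
  c2 <- structureCalls(callLoops(map2, maxDistanceBp = 60000))
  expect_equal(nrow(c1), nrow(c2))
  # planted centers shift by k; the Poisson noise field does not shift with
  # them, so allow the 1-pixel localization slack of the caller
  expect_true(all(abs(sort(c2$anchor1_start) - sort(c1$anchor1_start) - k) <= 1))
  expect_true(all(abs(sort(c2$anchor2_start) - sort(c1$anchor2_start) - k) <= 1))
})

test_that("planted stripes are called with the right anchor and orientation", {
  n <- 200
  d <- abs(outer(seq_len(n), seq_len(n), "-"))
  mu <- 60 * exp(-d / 25)
  a <- 80                      # vertical stripe: row a extending right
  ridge <- (row(mu) == a) & (col(mu) > a + 1) & (col(mu) <= a + 30)
  mu[ridge] <- mu[ridge] * 4
  mu[t(ridge)] <- mu[t(ridge)] * 4
  withr::with_seed(31, cnt <- matrix(rpois(n * n, mu), n, n))
  cnt[lower.tri(cnt)] <- t(cnt)[lower.tri(cnt)]
  map <- ContactMap(cnt, "chr1", 1000)
  calls <- callStripes(map, maxDistanceBp = 60000)
  df <- structureCalls(calls)
  df <- df[df$orientation == "vertical", , drop = FALSE]
  expect_gte(nrow(df), 1)
  best <- which.max(df$score)
  expect_lte(abs(df$anchor1_start[best] + 1 - a), 1)
  expect_gte(df$anchor2_end[best] - df$anchor2_start[best], 25)
})

test_that("runs shorter than the minimum length are not called", {
  n <- 150
  d <- abs(outer(seq_len(n), seq_len(n), "-"))
  mu <- 60 * exp(-d / 25)
  a <- 70
  ridge <- (row(mu) == a) & (col(mu) > a + 1) & (col(mu) <= a + 6)  # 5 px
  mu[ridge] <- mu[ridge] * 4
  mu[t(ridge)] <- mu[t(ridge)] * 4
  withr::with_seed(32, cnt <- matrix(rpois(n * n, mu), n, n))
  cnt[lower.tri(cnt)] <- t(cnt)[lower.tri(cnt)]
  calls <- callStripes(ContactMap(cnt, "chr1", 1000), minLengthPx = 10,
                       maxDistanceBp = 60000)
  df <- structureCalls(calls)
  expect_false(any(abs(df$anchor1_start + 1 - a) <= 1 &
                     df$orientation == "vertical"))
})

test_that("call matching is greedy one-to-one with bp tolerance", {
  a <- loopCallSet("chr1", 1000, anchor1 = c(100, 300), anchor2 = c(200, 450))
  # identical sets
  m <- matchCalls(a, a, toleranceBp = 5000)
  expect_equal(m$both, 2); expect_equal(m$a_only, 0); expect_equal(m$b_only, 0)
  # disjoint far-apart sets
  b <- loopCallSet("chr1", 1000, anchor1 = 700, anchor2 = 900)
  m2 <- matchCalls(a, b, toleranceBp = 5000)
  expect_equal(m2$both, 0); expect_equal(m2$a_only, 2); expect_equal(m2$b_only, 1)
  # +4 kb shift on both anchors still matches at 5 kb tolerance
  sh <- loopCallSet("chr1", 1000, anchor1 = 104, anchor2 = 204)
  m3 <- matchCalls(loopCallSet("chr1", 1000, 100, 200), sh, toleranceBp = 5000)
  expect_equal(m3$both, 1)
  # +6 kb does not
  sh2 <- loopCallSet("chr1", 1000, anchor1 = 106, anchor2 = 206)
  m4 <- matchCalls(loopCallSet("chr1", 1000, 100, 200), sh2, toleranceBp = 5000)
  expect_equal(m4$both, 0)
  # stripes must share orientation
  s1 <- StructureCallSet("chr1", 1000, data.frame(
    kind = "stripe", anchor1_start = 50, anchor1_end = 51,
    anchor2_start = 52, anchor2_end = 70, orientation = "vertical", score = 1))
  s2 <- StructureCallSet("chr1", 1000, data.frame(
    kind = "stripe", anchor1_start = 50, anchor1_end = 51,
    anchor2_start = 30, anchor2_end = 49, orientation = "horizontal", score = 1))
  expect_equal(matchCalls(s1, s2, 5000)$both, 0)
  expect_error(matchCalls(a, s1), "mixed")
})

test_that("pileup averages regions, drops clipped ones, and is symmetric", {
  rmap <- randomSymmetricMap(60, resolution = 1000, density = 0.9, seed = 9)
  full <- as.matrix(contactMatrix(rmap))
  # one center (0-based bins) -> pileup equals that submatrix
  p1 <- pileup(rmap, cbind(30, 40), side = 11)
  expect_equal(pileupMatrix(p1), full[26:36, 36:46], ignore_attr = TRUE)
  expect_equal(p1@nRegions, 1)
  # two centers -> elementwise mean
  p2 <- pileup(rmap, rbind(c(30, 40), c(20, 35)), side = 11)
  expect_equal(pileupMatrix(p2), (full[26:36, 36:46] + full[16:26, 31:41]) / 2,
               ignore_attr = TRUE)
  # center score = mean of central 5x5
  expect_equal(centerScore(p2), mean(pileupMatrix(p2)[4:8, 4:8]))
  # clipped regions are dropped
  p3 <- pileup(rmap, rbind(c(2, 5), c(30, 40)), side = 11)
  expect_equal(p3@nRegions, 1)
  expect_error(pileup(rmap, cbind(2, 5), side = 11), "no usable")
  expect_error(pileup(rmap, cbind(30, 40), side = 10), "odd")
  # symmetric center set on a symmetric map gives a symmetric pileup
  p4 <- pileup(rmap, rbind(c(25, 40), c(40, 25)), side = 9)
  expect_equal(pileupMatrix(p4), t(pileupMatrix(p4)), tolerance = 1e-12)
})

test_that("pileup at planted loop centers is centrally enriched", {
  centers <- cbind(c(40, 90, 140), c(60, 115, 160))
  map <- plantedLoopMap(centers = centers, seed = 25)
  oe <- oeNormalize(map)
  p <- pileup(oe, centers - 1, side = 21)
  m <- pileupMatrix(p)
  outer_ring <- m[c(1:3, 19:21), c(1:3, 19:21)]
  expect_gt(centerScore(p), mean(outer_ring))
})
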