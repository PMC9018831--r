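test_that("SCC matches the brute-force oracle and its invariances", {
  mapA <- randomSymmetricMap(60, resolution = 200, density = 0.5, seed = 1)
  mapB <- randomSymmetricMap(60, resolution = 200, density = 0.5, seed = 2)
  A <- as.matrix(contactMatrix(mapA))
  B <- as.matrix(contactMatrix(mapB))
  rep <- scc(mapA, mapB, h = 2, maxDistanceBp = 30 * 200)
  expect_equal(sccValue(rep), sccOracle(A, B, h = 2, maxD = 30),
               tolerance = 1e-12)
  # self-correlation is exactly 1
  expect_equal(sccValue(scc(mapA, mapA, h = 2, maxDistanceBp = 4000)), 1,
               tolerance = 1e-12)
  # symmetric in its arguments
  expect_equal(sccValue(scc(mapA, mapB, h = 2, maxDistanceBp = 4000)),
               sccValue(scc(mapB, mapA, h = 2, maxDistanceBp = 4000)),
               tolerance = 1e-12)
  # invariant to scaling either map by c > 0
  mapC <- ContactMap(contactMatrix(mapA) * 3, "chr1", 200)
  expect_equal(sccValue(scc(mapC, mapB, h = 2, maxDistanceBp = 4000)),
               sccValue(scc(mapA, mapB, h = 2, maxDistanceBp = 4000)),
               tolerance = 1e-12)
  expect_error(scc(mapA, randomSymmetricMap(50, resolution = 200)), "grid")
})

test_that("distance-stratified Pearson matches the per-diagonal oracle", {
  mapA <- randomSymmetricMap(80, resolution = 200, density = 0.6, seed = 3)
  mapB <- randomSymmetricMap(80, resolution = 200, density = 0.6, seed = 4)
  df <- distanceStratifiedPearson(mapA, mapB, maxDistanceBp = 40 * 200)
  oracle <- stratPearsonOracle(as.matrix(contactMatrix(mapA)),
                               as.matrix(contactMatrix(mapB)), 40)
  expect_equal(df$r, oracle, tolerance = 1e-12)
  # identical maps: r = 1 at every defined stratum
  dfSame <- distanceStratifiedPearson(mapA, mapA, maxDistanceBp = 8000)
  expect_true(all(abs(dfSame$r[!is.na(dfSame$r)] - 1) < 1e-12))
  # anti-correlation: log-space negation
  lg <- logContacts(mapA)
  neg <- ContactMap(-as.matrix(contactMatrix(lg)) , "chr1", 200,
                    state = "log")
  dfNeg <- distanceStratifiedPearson(lg, neg, maxDistanceBp = 8000)
  expect_true(all(abs(dfNeg$r[!is.na(dfNeg$r)] + 1) < 1e-12))
})

test_that("fragment Spearman is rank-invariant and matches rank-Pearson", {
  raw <- randomSymmetricMap(100, resolution = 200, density = 0.8, seed = 5)
  oe <- oeNormalize(raw)
  scores <- fragmentSpearman(oe, oe, fragmentBp = 5000, bandBp = 4000)
  expect_true(all(scores$rho == 1))
  # monotone transform leaves rho at 1 (rank invariance of the correlation
  # step; smoothing disabled so the transform commutes with the pipeline)
  cubed <- ContactMap(contactMatrix(oe)^3, "chr1", 200, state = "oe")
  s2 <- fragmentSpearman(oe, cubed, fragmentBp = 5000, bandBp = 4000, h = 0)
  expect_true(all(abs(s2$rho - 1) < 1e-12))
  # equals rank-then-Pearson on the same smoothed band pixels
  other <- oeNormalize(randomSymmetricMap(100, resolution = 200,
                                          density = 0.8, seed = 6))
  s3 <- fragmentSpearman(oe, other, fragmentBp = 5000, bandBp = 4000)
  nf <- 25
  fullP <- as.matrix(contactMatrix(oe))[1:nf, 1:nf]
  fullO <- as.matrix(contactMatrix(other))[1:nf, 1:nf]
  Ps <- denseBoxFilterOracle(fullP, 2, renorm = TRUE)
  Os <- denseBoxFilterOracle(fullO, 2, renorm = TRUE)
  sel <- which(upper.tri(Ps, diag = TRUE) &
                 abs(outer(1:nf, 1:nf, "-")) <= 20)
  expect_equal(s3$rho[1], cor(rank(Ps[sel]), rank(Os[sel])),
               tolerance = 1e-12)
  # constant fragments carry the undefined flag
  flat <- ContactMap(matrix(1, 100, 100), "chr1", 200, state = "oe")
  s4 <- fragmentSpearman(flat, oe, fragmentBp = 5000, bandBp = 4000)
  expect_true(all(!s4$defined))
  expect_error(fragmentSpearman(oe, oe, fragmentBp = 5100), "multiple")
  expect_error(fragmentSpearman(raw, oe, fragmentBp = 5000), "O/E")
})

test_that("compartments recover a 2-block checkerboard and obey the rules", {
  n <- 20
  lab <- rep(c(TRUE, FALSE), each = 10)
  M <- ifelse(outer(lab, lab, "=="), 2, 0.5)
  map <- ContactMap(M, "chr1", 250000, state = "oe")
  h3 <- ifelse(lab, 5, 1)
  out <- callCompartments(map, h3)
  expect_equal(out, ifelse(lab, "A", "B"))
  # H3K27ac higher in the other block flips the labels
  out2 <- callCompartments(map, ifelse(lab, 1, 5))
  expect_equal(out2, ifelse(lab, "B", "A"))
  # sign-flip invariance: permuting block order must relabel consistently
  perm <- c(11:20, 1:10)
  mapP <- ContactMap(M[perm, perm], "chr1", 250000, state = "oe")
  outP <- callCompartments(mapP, h3[perm])
  expect_equal(outP, out[perm])
  expect_error(callCompartments(ContactMap(matrix(1, 5, 5), "chr1", 250000,
                                           state = "oe"), rep(1, 5)),
               "degenerate")
  expect_error(callCompartments(map, h3[1:3]), "per bin")
})

test_that("fragment annotation tiers, timing and compartments", {
  scores <- data.frame(fragment = 1:10, start_bp = (0:9) * 250000,
                       rho = seq(0.9, 0.5, length.out = 10), defined = TRUE)
  phast <- 10:1  # distinct, fragment 1 highest
  rep0 <- c(1, 1, -1, 0, 1, -1, 1, -1, 1, -1)
  comp <- rep(c("A", "B"), 5)
  ann <- annotateFragments(scores, phast, h3k27ac = rep(1, 10),
                           compartments = comp, repliseq = rep0)
  expect_equal(sum(ann$conservation == "top10"), 1)
  expect_equal(ann$conservation[1], "top10")
  expect_equal(sum(ann$conservation == "top10_50"), 4)
  # repli-seq 0 is late (strictly positive = early)
  expect_equal(ann$timing[4], "late")
  expect_equal(ann$timing[1], "early")
  # all-positive repli-seq -> all early
  ann2 <- annotateFragments(scores, phast, rep(1, 10), comp, rep(2, 10))
  expect_true(all(ann2$timing == "early"))
  expect_equal(ann$compartment, comp)
})

test_that("one-sided Welch test behaves at the null and under separation", {
  # identical groups: p ~ 0.5
  x <- seq(-1, 1, length.out = 20)
  expect_equal(groupTest(x, x)$p, 0.5, tolerance = 1e-12)
  # strong separation: p below 1e-10
  withr::with_seed(8, {
    a <- rnorm(50, 0.9, 0.01)
    b <- rnorm(50, 0.5, 0.01)
  })
  expect_lt(groupTest(a, b)$p, 1e-10)
  # equal n and variances: reversing the groups flips p to 1 - p
  withr::with_seed(9, {
    g1 <- rnorm(30); g2 <- rnorm(30)
  })
  expect_equal(groupTest(g1, g2)$p + groupTest(g2, g1)$p, 1,
               tolerance = 1e-9)
  expect_error(groupTest(1, c(1, 2)), "at least 2")
})

test_that("high-SNR fragments score higher rho and the test detects it", {
  # the mechanism behind the conservation/compartment/timing contrasts:
  # two groups of fragments with different signal-to-noise, compared by
  # fragment Spearman and the one-sided test
  n <- 50; nf <- 25
  withr::with_seed(10, {
    base <- matrix(rpois(nf * nf, 20), nf, nf)
    base[lower.tri(base)] <- t(base)[lower.tri(base)]
    rhoHigh <- replicate(n, {
      noisy <- base + matrix(rpois(nf * nf, 2), nf, nf)
      noisy[lower.tri(noisy)] <- t(noisy)[lower.tri(noisy)]
      cor(base[upper.tri(base)], noisy[upper.tri(noisy)], method = "spearman")
    })
    rhoLow <- replicate(n, {
      noisy <- matrix(rpois(nf * nf, 20), nf, nf) +
        matrix(rpois(nf * nf, 2), nf, nf)
      cor(base[upper.tri(base)], noisy[upper.tri(noisy)], method = "spearman")
    })
  })
  res <- groupTest(rhoHigh, rhoLow)
  expect_lt(res$p, 0.01)
})

test_that("eQTL filtering drops distant and multi-tissue pairs exactly", {
  pairs <- data.frame(
    chrom = "chr1",
    variant_pos = c(1000, 5000, 200000, 9000, 9000, 50000),
    tss_pos = c(101000, 190000, 15000, 9100, 9100, 49000),
    gene = paste0("g", 1:6),
    tissue = c("lung", "lung", "lung", "lung", "pancreas", "liver"))
  out <- filterEqtlPairs(pairs)
  # pair 2 is 185 kb apart -> dropped; pair 3 is 185 kb -> dropped
  # pairs 4 and 5 share a bin pair in two tissues -> both dropped
  expect_equal(out$distance_bp, c(100000, 1000))
  expect_true(all(out$distance_bp < 180000))
  expect_equal(out$variant_bin, binIndex(c(1000, 50000), 200))
  # kept pair at 100,000 bp; empty input gives empty output
  expect_equal(nrow(filterEqtlPairs(pairs[0, ])), 0)
  # malformed rows are rejected with a log message
  bad <- pairs; bad$variant_pos[1] <- NA
  expect_message(filterEqtlPairs(bad), "rejected")
})

test_that("eQTL table round trip and pileup delegation", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("chrom\tvariant_pos\ttss_pos\tgene\ttissue",
               "chr1\t10000\t25000\tg1\tlung"), path)
  tab <- readEqtlPairs(path)
  expect_equal(tab$variant_pos, 10000)
  rmap <- randomSymmetricMap(300, resolution = 200, density = 0.3, seed = 11)
  prs <- filterEqtlPairs(tab)
  p <- eqtlPileup(rmap, prs, side = 21)
  full <- as.matrix(contactMatrix(rmap))
  expect_equal(pileupMatrix(p), full[(51 - 10):(51 + 10), (126 - 10):(126 + 10)],
               ignore_attr = TRUE)
  expect_error(eqtlPileup(rmap, prs, side = 100), "odd")
})
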