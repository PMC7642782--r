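## Build a MergedDataset directly from vectors (for statistic oracles).
mergedFrom <- function(h, k, l, side, I, sigma = 1,
                       cell = unitCell(30, 30, 40), sg = "P41212") {
  sgO <- spaceGroup(sg)
  d <- dSpacing(cell, cbind(h, k, l))
  rf <- data.frame(h = h, k = k, l = l, side = side, intensity = I,
                   sigma = sigma, nmeas = 2L, d = d)
  new("MergedDataset", cell = cell, spacegroup = sgO, reflections = rf,
      provenance = list())
}

test_that("half splitting is disjoint, exhaustive and seeded", {
  ds <- fixCoarseSim()
  sp <- splitHalf(ds, seed = 5)
  expect_length(intersect(sp$a, sp$b), 0)
  expect_setequal(c(sp$a, sp$b), crystals(ds)$id)
  expect_equal(abs(length(sp$a) - length(sp$b)) <= 1, TRUE)
  expect_identical(splitHalf(ds, seed = 5), splitHalf(ds, seed = 5))
  expect_error(splitHalf(subsetPatterns(ds, crystals(ds)$id[1]), 1),
               "at least 2")
})

test_that("R_split reproduces hand arithmetic and its invariances", {
  m1 <- mergedFrom(c(3, 4), c(1, 2), c(2, 1), 1L, c(10, 20))
  m2 <- mergedFrom(c(3, 4), c(1, 2), c(2, 1), 1L, c(12, 18))
  expect_equal(rSplit(m1, m2)$overall, 100 / sqrt(2) * 4 / 30,
               tolerance = 1e-12)
  expect_equal(rSplit(m1, m1)$overall, 0)
  ## scale invariance
  m1k <- mergedFrom(c(3, 4), c(1, 2), c(2, 1), 1L, 7 * c(10, 20))
  m2k <- mergedFrom(c(3, 4), c(1, 2), c(2, 1), 1L, 7 * c(12, 18))
  expect_equal(rSplit(m1k, m2k)$overall, rSplit(m1, m2)$overall)
  ## swapped halves give the same value
  expect_equal(rSplit(m2, m1)$overall, rSplit(m1, m2)$overall)
})

test_that("CC_1/2 and CC* behave on identical, noisy and null data", {
  set.seed(8)
  n <- 60
  h <- sample(2:9, n, TRUE); k <- sample(1:6, n, TRUE); l <- sample(1:9, n, TRUE)
  key <- !duplicated(paste(h, k, l)); h <- h[key]; k <- k[key]; l <- l[key]
  I <- runif(length(h), 10, 100)
  mA <- mergedFrom(h, k, l, 1L, I)
  expect_equal(ccHalf(mA, mA)$cc12, 1)
  expect_equal(ccHalf(mA, mA)$ccStar, 1)
  ## independent pure noise: |CC| small (null oracle at large n)
  set.seed(9)
  nn <- 6000
  hh <- rep(1:200, length.out = nn) + 0L
  ## build unique triples covering many indices
  trip <- unique(data.frame(h = sample(1:30, nn, TRUE),
                            k = sample(0:20, nn, TRUE),
                            l = sample(1:30, nn, TRUE)))
  trip <- trip[seq_len(min(4000, nrow(trip))), ]
  nA <- mergedFrom(trip$h, trip$k, trip$l, 1L, rnorm(nrow(trip)),
                   cell = unitCell(100, 100, 100), sg = "P1")
  nB <- mergedFrom(trip$h, trip$k, trip$l, 1L, rnorm(nrow(trip)),
                   cell = unitCell(100, 100, 100), sg = "P1")
  expect_lt(abs(ccHalf(nA, nB)$cc12), 0.05)
  ## CC* >= CC_1/2 on (0, 1)
  for (cc in c(0.1, 0.5, 0.9, 0.99))
    expect_gte(sqrt(2 * cc / (1 + cc)), cc)
})

test_that("CC_ano correlates Bijvoet differences between halves", {
  h <- c(3, 4, 5, 6); k <- c(1, 2, 1, 2); l <- c(2, 1, 4, 3)
  I <- c(100, 80, 60, 40)
  dI <- c(5, -4, 3, -2)
  mk <- function(I, dI) {
    mergedFrom(rep(h, 2), rep(k, 2), rep(l, 2),
               rep(c(1L, -1L), each = 4),
               c(I + dI / 2, I - dI / 2))
  }
  mA <- mk(I, dI)
  expect_equal(ccAno(mA, mA)$overall, 1)
  ## null: f'' = 0 simulation gives |CC_ano| ~ 0
  ds0 <- fixCached("friedelSim", function()
    simulateDataset(coarseConfig(nPatterns = 400, fDoublePrime = 0),
                    seed = 61))
  hv <- mergeHalves(ds0, mergeConfig(model = "unity"), seed = 3)
  expect_lt(abs(ccAno(hv$a, hv$b)$overall), 0.1)
  ## anomalous data: CC_ano grows with the number of patterns (averaged
  ## over split seeds; the small-subset estimate is noisy)
  ds <- fixDefaultSim()
  ids <- crystals(ds)$id
  ccAt <- function(n) mean(sapply(1:2, function(s) {
    hv <- mergeHalves(subsetPatterns(ds, ids[seq_len(n)]),
                      mergeConfig(model = "unity"), seed = s)
    ccAno(hv$a, hv$b)$overall
  }))
  expect_gt(ccAt(length(ids)), ccAt(80))
})

test_that("completeness and redundancy match the enumeration oracle", {
  cell <- unitCell(30, 30, 40)
  sg <- spaceGroup("P41212")
  theo <- generateHkl(cell, sg, 5)
  ## merged set equal to the full theoretical list (both Bijvoet sides)
  rows <- do.call(rbind, lapply(seq_len(nrow(theo)), function(i) {
    if (theo$centric[i]) data.frame(h = theo$h[i], k = theo$k[i],
                                    l = theo$l[i], side = 1L)
    else data.frame(h = theo$h[i], k = theo$k[i], l = theo$l[i],
                    side = c(1L, -1L))
  }))
  m <- mergedFrom(rows$h, rows$k, rows$l, rows$side,
                  runif(nrow(rows), 5, 50), cell = cell)
  scheme <- shellScheme(5, max(theo$d), 4)
  cr <- completenessRedundancy(m, scheme)
  expect_equal(cr$overall$completeness, 100)
  expect_equal(cr$overall$redundancy, 2)   # nmeas = 2 in mergedFrom
  expect_equal(sum(cr$shells$nTheoretical), nrow(rows))
  ## dropping half the records halves completeness
  half <- m
  half@reflections <- half@reflections[seq(1, nrow(rows), by = 2), ]
  crH <- completenessRedundancy(half, scheme)
  expect_equal(crH$overall$completeness, 100 * ceiling(nrow(rows) / 2) /
                 nrow(rows), tolerance = 1e-12)
})

test_that("shell schemes are equal-volume and exhaustive", {
  sc <- shellScheme(2.65, 40, 10)
  expect_length(sc$edges, 11)
  expect_true(all(diff(sc$edges) < 0))
  v <- diff(sc$edges^-3)
  expect_equal(max(v) / min(v), 1, tolerance = 1e-9)
  d <- runif(500, 2.65, 40)
  idx <- sfxsad:::shellIndex(sc, d)
  expect_true(all(idx >= 1 & idx <= 10))
})

test_that("the quality report assembles coherent overall statistics", {
  ds <- fixCoarseSim()
  rep <- qualityReport(ds, mergeConfig(model = "xsphere"), seed = 2,
                       nShells = 6)
  ov <- overallStats(rep)
  sh <- shellTable(rep)
  expect_equal(nrow(sh), 6)
  expect_true(ov$completeness > 95 && ov$completeness <= 100)
  expect_gt(ov$redundancy, 5)
  expect_gt(ov$cc12, 0.9)
  expect_true(ov$rSplit > 0 && ov$rSplit < 50)
  expect_true(abs(ov$ccAno) <= 1)
  expect_gt(ov$meanIsig, 1)
  ## statistics invariant under pattern-id relabeling
  ds2 <- ds
  cr <- crystals(ds); obs <- observations(ds)
  newIds <- setNames(rev(cr$id) + 1000L, cr$id)
  cr$id <- as.integer(newIds[as.character(cr$id)])
  obs$pattern_id <- as.integer(newIds[as.character(obs$pattern_id)])
  ds2@crystals <- cr[order(cr$id), ]; rownames(ds2@crystals) <- NULL
  ds2@observations <- obs
  m1 <- runMerge(ds, mergeConfig(model = "unity"))
  m2 <- runMerge(ds2, mergeConfig(model = "unity"))
  expect_equal(rSplit(m1, m2)$overall, 0, tolerance = 1e-9)
})
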