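test_that("Bijvoet differences follow the sqrt-truncation convention", {
  cell <- unitCell(30, 30, 40)
  mk <- function(iP, iM, sP = 2, sM = 2) {
    rf <- data.frame(h = c(3, 3), k = c(1, 1), l = c(2, 2),
                     side = c(1L, -1L), intensity = c(iP, iM),
                     sigma = c(sP, sM), nmeas = 4L,
                     d = dSpacing(cell, c(3, 1, 2)))
    new("MergedDataset", cell = cell, spacegroup = spaceGroup("P41212"),
        reflections = rf, provenance = list())
  }
  d1 <- bijvoetDifferences(mk(100, 64))
  expect_equal(d1$dFobs, 10 - 8)
  expect_equal(d1$sigDF, sqrt((2 / 20)^2 + (2 / 16)^2))
  ## negative merged intensity: that side truncates to F = 0, the
  ## reflection is retained with an inflated sigma
  d2 <- bijvoetDifferences(mk(100, -5))
  expect_equal(d2$dFobs, 10)
  expect_equal(d2$sigDF, sqrt((2 / 20)^2 + 2))
})

test_that("f'' = 0 noise-free data give identically zero differences", {
  cfg <- coarseConfig(nPatterns = 40, fDoublePrime = 0, noise = FALSE,
                      scaleSdLog = 0, bJitter = 0, cellJitter = 0,
                      spotSigma = 0)
  ds <- simulateDataset(cfg, seed = 71)
  m <- runMerge(ds, mergeConfig(model = "xsphere", iterations = 0,
                                pushRes = Inf, outlierNsigma = Inf,
                                minMeasurements = 1))
  diffs <- bijvoetDifferences(m)
  expect_gt(nrow(diffs), 10)
  expect_lt(max(abs(diffs$dFobs)), 1e-8)
})

test_that("the Bijvoet-ratio estimator reproduces published arithmetic", {
  expect_equal(bijvoetRatioEstimate(0, 1.51, 1000), 0)
  ## thaumatin-like composition at the two photon energies
  expect_equal(bijvoetRatioEstimate(17, 1.51, 1558), 3.2, tolerance = 0.3 / 3.2)
  expect_equal(bijvoetRatioEstimate(17, 0.95, 1558), 2.0, tolerance = 0.3 / 2.0)
  ## linear in f''
  expect_equal(bijvoetRatioEstimate(17, 0.95, 1558) /
                 bijvoetRatioEstimate(17, 1.51, 1558), 0.95 / 1.51,
               tolerance = 1e-12)
  expect_error(bijvoetRatioEstimate(5, 1.5, 0), "> 0")
})

test_that("the anomalous difference map peaks at the anomalous sites", {
  ## single-S toy model with exact calculated differences as coefficients
  cell <- unitCell(20, 20, 28)
  sg <- spaceGroup("P41212")
  atoms <- data.frame(element = c("S", "C", "C", "O"),
                      x = c(0.31, 0.12, 0.55, 0.82),
                      y = c(0.17, 0.71, 0.33, 0.06),
                      z = c(0.43, 0.22, 0.61, 0.87),
                      occ = 1, biso = 5,
                      fp = 0, fpp = c(1.51, 0, 0, 0),
                      anomalous = c(TRUE, FALSE, FALSE, FALSE))
  model <- structureModel(cell, sg, atoms)
  hkl <- generateHkl(cell, sg, 1.4)
  hkl <- hkl[!hkl$centric, ]
  ma <- modelAnomalous(model, as.matrix(hkl[, c("h", "k", "l")]))
  diffs <- data.frame(h = ma$h, k = ma$k, l = ma$l, d = ma$d,
                      dFobs = ma$dFcalc, phi = ma$phi)
  map <- anomalousDifferenceMap(diffs, sg, cell)
  ## global grid maximum within one grid step of a symmetry image of the
  ## sulfur site
  v <- mapValues(map)
  w <- which(v == max(v), arr.ind = TRUE)[1, ]
  frac <- (w - 1) / dim(v)
  ops <- symOps(sg)
  sims <- t(sapply(seq_along(ops$rotations), function(i)
    (ops$rotations[[i]] %*% c(0.31, 0.17, 0.43) + ops$translations[[i]]) %% 1))
  dmin <- min(apply(sims, 1, function(s) {
    dd <- abs(s - frac); dd <- pmin(dd, 1 - dd)
    sqrt(sum((dd * cellLengths(cell))^2))
  }))
  expect_lt(dmin, 1.5 * max(cellLengths(cell) / dim(v)))
  ## S_ano at the exact site exceeds the phasing-feasibility threshold on
  ## exact data
  expect_gt(as.numeric(sAno(map, model)), 10)
  ## rms normalization: doubling the coefficients changes nothing
  diffs2 <- diffs; diffs2$dFobs <- 2 * diffs2$dFobs
  map2 <- anomalousDifferenceMap(diffs2, sg, cell)
  expect_equal(as.numeric(sAno(map2, model)), as.numeric(sAno(map, model)),
               tolerance = 1e-9)
  expect_equal(map2@rms, 2 * map@rms, tolerance = 1e-9)
  ## all-zero coefficients give an identically zero map
  diffs0 <- diffs; diffs0$dFobs <- 0
  map0 <- anomalousDifferenceMap(diffs0, sg, cell)
  expect_true(all(mapValues(map0) == 0))
  expect_error(anomalousDifferenceMap(diffs[0, ], sg, cell), "empty")
})

test_that("S_ano discriminates signal from the f''-free noise floor", {
  ds <- fixDefaultSim()
  model <- groundTruth(ds)$model
  m <- runMerge(ds, mergeConfig(model = "xsphere"))
  diffs <- bijvoetDifferences(m, model)
  map <- anomalousDifferenceMap(diffs, ds@spacegroup, ds@cell)
  expect_gt(as.numeric(sAno(map, model)), 10)
  ## same conditions but f'' = 0: noise floor below 3
  ds0 <- fixCached("defaultNull", function()
    simulateDataset(simConfig(nPatterns = 400, fDoublePrime = 0),
                    seed = 103))
  model0 <- groundTruth(ds0)$model
  m0 <- runMerge(ds0, mergeConfig(model = "xsphere"))
  diffs0 <- bijvoetDifferences(m0, model0)
  map0 <- anomalousDifferenceMap(diffs0, ds0@spacegroup, ds0@cell)
  expect_lt(abs(as.numeric(sAno(map0, model0))), 3)
})

test_that("model-versus-data anomalous correlation behaves across regimes", {
  ds <- fixDefaultSim()
  model <- groundTruth(ds)$model
  m <- runMerge(ds, mergeConfig(model = "xsphere"))
  diffs <- bijvoetDifferences(m, model)
  ## exact agreement gives 1
  ideal <- diffs; ideal$dFobs <- ideal$dFcalc
  expect_equal(ccAnoModelVsData(ideal)$overall, 1)
  ## real merge: positive and substantial
  expect_gt(ccAnoModelVsData(diffs)$overall, 0.3)
  ## pure noise: near zero
  noise <- diffs; noise$dFobs <- rnorm(nrow(noise))
  expect_lt(abs(ccAnoModelVsData(noise)$overall), 0.1)
  ## inflating high-resolution noise makes CC decline with resolution
  ramp <- diffs
  w <- 1 / ramp$d
  ramp$dFobs <- ramp$dFcalc + rnorm(nrow(ramp)) *
    mean(abs(ramp$dFcalc)) * 5 * (w / max(w))^3
  sc <- shellScheme(min(ramp$d), max(ramp$d), 4)
  shells <- ccAnoModelVsData(ramp, sc)$shells
  expect_gt(shells[1], shells[4])
})

test_that("the subsampling study locates the threshold crossing", {
  ds <- fixDefaultSim()
  model <- groundTruth(ds)$model
  ## a single size reduces to one full evaluation
  one <- subsampleStudy(ds, nrow(crystals(ds)), mergeConfig(), model,
                        seed = 2)
  expect_equal(nrow(curveTable(one)), 1)
  cur <- fixCached("studyDefault", function()
    subsampleStudy(ds, c(50, 100, 200, 400), mergeConfig(), model,
                   seed = 2))
  tb <- curveTable(cur)
  ## monotone growth with size
  expect_gt(cor(tb$nImages, tb$sAno, method = "spearman"), 0.9)
  ## sqrt-n scaling: log-log slope 0.5 +- 0.15
  slope <- coef(lm(log(tb$sAno) ~ log(tb$nImages)))[2]
  expect_equal(as.numeric(slope), 0.5, tolerance = 0.15 / 0.5)
  if (cur@status == "crossed") {
    expect_true(cur@crossing >= 50 && cur@crossing <= 400)
    i <- findInterval(cur@crossing, tb$nImages)
    expect_true(tb$sAno[i] <= 10 && tb$sAno[i + 1] >= 10)
  }
})

test_that("true sulfur sites dominate the anomalous map peaks", {
  ds <- fixDefaultSim()
  model <- groundTruth(ds)$model
  m <- runMerge(ds, mergeConfig(model = "xsphere"))
  diffs <- bijvoetDifferences(m, model)
  map <- anomalousDifferenceMap(diffs, ds@spacegroup, ds@cell)
  s <- sAno(map, model)
  heights <- attr(s, "heights")
  ## every true site stands clearly above the map noise
  expect_true(all(heights > 5))
})
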