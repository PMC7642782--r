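test_that("crystal sampling honors jitter, spreads and determinism", {
  cell <- unitCell(58.5, 58.5, 151.25)
  cr0 <- sampleCrystals(5, cell, cellJitter = 0, scaleSdLog = 0,
                        bJitter = 0, profileJitterLog = 0, seed = 1)
  expect_true(all(cr0$a == 58.5 & cr0$c == 151.25))
  expect_true(all(cr0$scale == 1 & cr0$bFactor == 0))
  ## orientations orthonormal with det +1
  for (i in 1:5) {
    O <- matrix(as.numeric(cr0[i, 2:10]), 3, 3, byrow = TRUE)
    expect_equal(crossprod(O), diag(3), tolerance = 1e-12)
    expect_equal(det(O), 1, tolerance = 1e-12)
  }
  cr <- sampleCrystals(1e4, cell, cellJitter = 0.002, seed = 2)
  expect_equal(sd(cr$c) / mean(cr$c), 0.002, tolerance = 0.0002 / 0.002)
  expect_identical(sampleCrystals(20, cell, seed = 3),
                   sampleCrystals(20, cell, seed = 3))
})

test_that("excitation error vanishes on the Ewald sphere and follows the Taylor law", {
  lam <- 2.713
  onSphere <- function(theta2, phi) {
    ## a point q with |k0 + q| = 1/lambda
    s <- c(sin(theta2) * cos(phi), sin(theta2) * sin(phi), cos(theta2)) / lam
    s - c(0, 0, 1 / lam)
  }
  q <- rbind(onSphere(0.4, 1.0), onSphere(1.2, -2.0), c(0, 0, -2 / lam))
  expect_lt(max(abs(excitationError(wavelength = lam, q = q))), 1e-12)
  qx <- 0.01 / lam
  r <- excitationError(wavelength = lam, q = c(qx, 0, 0))
  expect_equal(r, lam * qx^2 / 2, tolerance = 0.01)
  ## matrix route: cell+orientation equals direct q computation
  cell <- unitCell(30, 30, 40)
  r2 <- excitationError(cell, diag(3), c(1, 2, 3), lam)
  q2 <- as.numeric(cellRecipMatrix(cell) %*% c(1, 2, 3))
  expect_equal(r2, excitationError(wavelength = lam, q = q2))
})

test_that("spherical-cap partiality has the exact endpoints and shape", {
  R <- 2e-3
  expect_equal(partialityCap(-R, R), 1)
  expect_equal(partialityCap(R, R), 0)
  expect_equal(partialityCap(0, R), 0.5)
  expect_equal(partialityCap(R / 2, R), 0.15625)
  r <- seq(-2 * R, 2 * R, length.out = 201)
  p <- partialityCap(r, R)
  expect_true(all(p >= 0 & p <= 1))
  expect_true(all(diff(p) <= 1e-15))
  expect_error(partialityCap(0, -1), "> 0")
})

test_that("detector projection is exact and invertible on the sphere", {
  beam <- beamGeometry(2.713, 95)
  expect_equal(as.numeric(projectToDetector(beam, c(0, 0, 0))), c(0, 0))
  ## round trip for an on-sphere q
  lam <- beam@wavelength
  s <- c(sin(0.6) * cos(0.3), sin(0.6) * sin(0.3), cos(0.6)) / lam
  q <- s - c(0, 0, 1 / lam)
  xy <- projectToDetector(beam, q)
  expect_equal(as.numeric(unprojectFromDetector(beam, xy)), q,
               tolerance = 1e-10)
  ## Bragg-radius oracle: d = 2.65 A at lambda = 2.713 A, D = 95 mm
  d <- 2.65
  theta <- asin(lam / (2 * d))
  qv <- c(sin(2 * theta), 0, cos(2 * theta)) / lam - c(0, 0, 1 / lam)
  expect_equal(1 / sqrt(sum(qv^2)), d, tolerance = 1e-12)
  xy2 <- projectToDetector(beam, qv)
  expect_equal(sqrt(sum(xy2^2)), 95 * tan(2 * theta), tolerance = 1e-10)
  expect_error(projectToDetector(beam, c(0, 0, -2 / lam)), "toward")
})

test_that("single-pattern simulation matches its defining contract", {
  cfg <- coarseConfig(noise = FALSE, scaleSdLog = 0, bJitter = 0,
                      cellJitter = 0, partialityMode = "ones",
                      sigmaBg = 0, photonScale = 1)
  cell <- simCell <- unitCell(30, 30, 40)
  sg <- spaceGroup("P41212")
  model <- toyStructureModel(cell, sg, 20, 3, bIso = 10, seed = 9)
  cr <- sampleCrystals(1, cell, cellJitter = 0, scaleSdLog = 0, bJitter = 0,
                       profileJitterLog = 0, seed = 21)
  beam <- beamGeometry(cfg$wavelength, 95, extent = 260)
  obs <- simulatePattern(cr[1, ], model, beam, dmin = 3, config = cfg)
  expect_gt(nrow(obs), 5)
  ## p forced to 1, scale 1, B 0, no noise: intensity == |F|^2 exactly
  sf <- structureFactors(model, as.matrix(obs[, c("h", "k", "l")]))
  expect_equal(obs$intensity, Mod(sf$fPlus)^2, tolerance = 1e-10)
  ## doubling the scale doubles every intensity
  cr2 <- cr; cr2$scale <- 2
  obs2 <- simulatePattern(cr2[1, ], model, beam, dmin = 3, config = cfg)
  expect_equal(obs2$intensity, 2 * obs$intensity, tolerance = 1e-12)
  ## emitted set equals the brute-force predicate on the full sphere
  fs <- sfxsad:::.fullSphereHkl(cell, sg, 3)
  O <- matrix(as.numeric(cr[1, 2:10]), 3, 3, byrow = TRUE)
  r <- excitationError(cell, O, fs$hkl, beam@wavelength)
  qlab <- t(O %*% (cellRecipMatrix(cell) %*% t(fs$hkl)))
  sz <- qlab[, 3] + 1 / beam@wavelength
  keep <- abs(r) < cr$profileRadius[1] & sz > 0
  xy <- matrix(NA_real_, nrow(fs$hkl), 2)
  xy[keep, ] <- projectToDetector(beam, qlab[keep, , drop = FALSE])
  keep[keep] <- abs(xy[keep, 1]) <= beam@extent &
    abs(xy[keep, 2]) <= beam@extent
  expect_equal(nrow(obs), sum(keep))
  expect_setequal(paste(obs$h, obs$k, obs$l),
                  paste(fs$hkl[keep, 1], fs$hkl[keep, 2], fs$hkl[keep, 3]))
})

test_that("dataset simulation is deterministic and applies the hit filter", {
  cfg <- coarseConfig(nPatterns = 0)
  expect_equal(nrow(observations(simulateDataset(cfg, seed = 1))), 0)
  cfg2 <- coarseConfig(nPatterns = 25)
  d1 <- simulateDataset(cfg2, seed = 4)
  d2 <- simulateDataset(cfg2, seed = 4)
  expect_identical(observations(d1), observations(d2))
  expect_identical(crystals(d1), crystals(d2))
  ## raising the hit threshold drops exactly the low-count patterns
  cfg3 <- coarseConfig(nPatterns = 40, minPeaks = 0)
  all40 <- simulateDataset(cfg3, seed = 6)
  counts <- crystals(all40)$nObs
  thr <- as.integer(stats::quantile(counts, 0.5))
  cfgThr <- coarseConfig(nPatterns = 40, minPeaks = thr)
  kept <- simulateDataset(cfgThr, seed = 6)
  expect_setequal(crystals(kept)$id, crystals(all40)$id[counts >= thr])
  expect_equal(kept@meta$nDropped, sum(counts < thr))
})

test_that("observations respect the resolution and excitation-error bounds", {
  ds <- fixCoarseSim()
  obs <- observations(ds)
  cr <- crystals(ds)
  expect_true(all(obs$d >= ds@dmin))
  Rj <- cr$profileRadius[match(obs$pattern_id, cr$id)]
  expect_true(all(abs(obs$r) < Rj))
  expect_true(all(obs$partiality >= 0 & obs$partiality <= 1))
  expect_true(all(obs$sigma > 0))
})

test_that("multiplicity grows linearly with pattern count", {
  n1 <- 60; n2 <- 180
  cfgA <- coarseConfig(nPatterns = n1)
  cfgB <- coarseConfig(nPatterns = n2)
  mult <- function(ds) {
    m <- runMerge(ds, mergeConfig(model = "unity", iterations = 0,
                                  pushRes = Inf, outlierNsigma = Inf,
                                  minMeasurements = 1))
    mean(reflections(m)$nmeas)
  }
  m1 <- mult(simulateDataset(cfgA, seed = 31))
  m2 <- mult(simulateDataset(cfgB, seed = 32))
  expect_equal(m2 / m1, n2 / n1, tolerance = 0.10)
})

test_that("Bijvoet intensity asymmetry propagates from f'' to the observations", {
  ## population mean of I+ - I- over Bijvoet pairs matches |F+|^2 - |F-|^2
  cfg <- coarseConfig(nPatterns = 250, noise = FALSE, scaleSdLog = 0,
                      bJitter = 0, cellJitter = 0, spotSigma = 0,
                      partialityMode = "ones", photonScale = 1)
  ds <- simulateDataset(cfg, seed = 33)
  m <- runMerge(ds, mergeConfig(model = "unity", iterations = 0,
                                pushRes = Inf, outlierNsigma = Inf,
                                minMeasurements = 1))
  tr <- groundTruth(ds)$f2
  rf <- reflections(m)
  i <- match(paste(rf$h, rf$k, rf$l), paste(tr$h, tr$k, tr$l))
  itrue <- ifelse(rf$side > 0, tr$iPlus[i], tr$iMinus[i])
  expect_equal(rf$intensity, itrue, tolerance = 1e-10)
  ## with f'' > 0 the merged Bijvoet differences match the model's
  bt <- sfxsad:::.bijvoetTable(m)
  j <- match(paste(bt$h, bt$k, bt$l), paste(tr$h, tr$k, tr$l))
  expect_equal(bt$iPlus - bt$iMinus, tr$iPlus[j] - tr$iMinus[j],
               tolerance = 1e-8)
  expect_gt(mean(abs(bt$iPlus - bt$iMinus)), 0)
})
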