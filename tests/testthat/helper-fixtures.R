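## Shared fixtures, built once per test run and cached.

.fixCache <- new.env(parent = emptyenv())

fixCached <- function(key, builder) {
  if (!exists(key, envir = .fixCache)) assign(key, builder(), envir = .fixCache)
  get(key, envir = .fixCache)
}

## Small, fast simulation conditions: tetragonal toy cell, coarse resolution.
## Used wherever the test checks mechanics rather than the default study
## conditions.
coarseConfig <- function(...) {
  simConfig(cell = c(30, 30, 40, 90, 90, 90), dmin = 3,
            nAtoms = 30, nSulfur = 4, extent = 260, ...)
}

fixCoarseSim <- function() fixCached("coarse", function()
  simulateDataset(coarseConfig(nPatterns = 300), seed = 101))

fixCoarseNoiseFree <- function() fixCached("coarseNF", function()
  simulateDataset(coarseConfig(nPatterns = 60, noise = FALSE,
                               scaleSdLog = 0, bJitter = 0,
                               cellJitter = 0, spotSigma = 0),
                  seed = 102))

## Default-condition simulation at reduced pattern count (thaumatin-like
## cell, 2.65 A, weak-signal noise defaults).
fixDefaultSim <- function() fixCached("default", function()
  simulateDataset(simConfig(nPatterns = 400), seed = 103))

## A tiny P1 model for structure-factor oracle tests.
fixTinyModel <- function() {
  cell <- unitCell(10, 12, 14)
  atoms <- data.frame(element = c("C", "S"),
                      x = c(0.1, 0), y = c(0.2, 0), z = c(0.3, 0),
                      occ = 1, biso = 0, fp = 0, fpp = c(0, 1.51),
                      anomalous = c(FALSE, TRUE))
  structureModel(cell, "P1", atoms)
}

## Brute-force triclinic d-spacing via the classical closed-form formula
## (independent of the package's reciprocal-matrix route).
oracleDSpacing <- function(a, b, c, al, be, ga, h, k, l) {
  alr <- al * pi / 180; ber <- be * pi / 180; gar <- ga * pi / 180
  ca <- cos(alr); cb <- cos(ber); cg <- cos(gar)
  sa <- sin(alr); sb <- sin(ber); sg <- sin(gar)
  V <- a * b * c * sqrt(1 - ca^2 - cb^2 - cg^2 + 2 * ca * cb * cg)
  s11 <- (b * c * sa)^2
  s22 <- (a * c * sb)^2
  s33 <- (a * b * sg)^2
  s12 <- a * b * c^2 * (ca * cb - cg)
  s23 <- a^2 * b * c * (cb * cg - ca)
  s13 <- a * b^2 * c * (cg * ca - cb)
  d2inv <- (s11 * h^2 + s22 * k^2 + s33 * l^2 +
              2 * s12 * h * k + 2 * s23 * k * l + 2 * s13 * h * l) / V^2
  1 / sqrt(d2inv)
}

## Direct-summation structure factor for a P1 model (independent oracle).
oracleSfP1 <- function(atoms, cell, hkl) {
  d <- oracleDSpacing(cell@a, cell@b, cell@c, cell@alpha, cell@beta,
                      cell@gamma, hkl[1], hkl[2], hkl[3])
  stol <- 1 / (2 * d)
  F <- 0 + 0i
  for (i in seq_len(nrow(atoms))) {
    f0 <- sum(sfxsad:::.f0Coefs[[atoms$element[i]]]$a *
                exp(-sfxsad:::.f0Coefs[[atoms$element[i]]]$b * stol^2)) +
      sfxsad:::.f0Coefs[[atoms$element[i]]]$c
    f <- complex(real = f0 + atoms$fp[i], imaginary = atoms$fpp[i])
    ph <- 2 * pi * sum(hkl * c(atoms$x[i], atoms$y[i], atoms$z[i]))
    F <- F + atoms$occ[i] * f * exp(-atoms$biso[i] * stol^2) *
      exp(complex(imaginary = ph))
  }
  F
}

## Construct a minimal StillDataset directly from an observation table
## (cell/sg/beam fixed): used for hand-built merge fixtures.
handDataset <- function(obs, cell = unitCell(30, 30, 40),
                        sg = "P41212", profileRadius = 2e-3,
                        wavelength = 2.713, distance = 95) {
  ids <- sort(unique(obs$pattern_id))
  n <- length(ids)
  cr <- data.frame(id = ids,
                   o11 = 1, o12 = 0, o13 = 0, o21 = 0, o22 = 1, o23 = 0,
                   o31 = 0, o32 = 0, o33 = 1,
                   a = cell@a, b = cell@b, c = cell@c,
                   profileRadius = profileRadius,
                   nObs = as.integer(table(factor(obs$pattern_id,
                                                  levels = ids))))
  need <- c("partiality", "r", "x", "y")
  for (nm in need) if (is.null(obs[[nm]]))
    obs[[nm]] <- switch(nm, partiality = 1, r = 0, x = 0, y = 0)
  if (is.null(obs$d))
    obs$d <- dSpacing(cell, as.matrix(obs[, c("h", "k", "l")]))
  new("StillDataset", beam = beamGeometry(wavelength, distance),
      cell = cell, spacegroup = spaceGroup(sg), dmin = min(obs$d),
      crystals = cr, observations = obs, truth = list(), meta = list())
}
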