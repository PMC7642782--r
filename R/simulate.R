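## Synthetic still-diffraction data with ground truth: the desk-scale
## stand-in for raw serial-crystallography data.  Each pattern comes from a
## freshly drawn crystal (random orientation, jittered cell, own scale, B
## factor and profile radius); reflections close enough to the Ewald sphere
## are recorded as partial intensities with counting-like noise and
## projected onto a flat detector.

#' Simulation configuration
#'
#' Returns the default desk-scale study conditions: a thaumatin-like
#' tetragonal crystal form (P4(1)2(1)2, cell 58.5 x 58.5 x 151.25 A),
#' 2.713 A radiation (4.57 keV, sulfur f'' = 1.51 e-), ~95 mm detector
#' distance, 2.65 A resolution cutoff, 0.2% unit-cell jitter and a toy
#' 100-atom model with 10 sulfurs.  Any field can be overridden by name.
#'
#' @param ... named overrides of the defaults listed below
#' @return a list of class `SimConfig`
#' @section Fields:
#' \describe{
#'   \item{spacegroup, cell, dmin}{crystal form and resolution limit (A)}
#'   \item{nPatterns}{number of patterns to generate}
#'   \item{wavelength, distance, distanceTrue, pixel, center, extent}{beam
#'     and detector geometry (A, mm); `distance` is the header (assumed)
#'     distance, `distanceTrue` the one actually used for projection, so a
#'     deliberate miscalibration is `distanceTrue != distance`}
#'   \item{nAtoms, nSulfur, bIso, fPrime, fDoublePrime, modelSeed}{toy
#'     structure model (see [toyStructureModel()])}
#'   \item{cellJitter}{fractional standard deviation of the cell lengths}
#'   \item{scaleSdLog, bJitter}{spread of per-crystal log-scale and B (A^2)}
#'   \item{profileRadius, profileJitterLog}{median reflection profile radius
#'     (1/A) and its log-normal spread}
#'   \item{sigmaBg}{background noise level (counts)}
#'   \item{spotSigma}{spot centroid noise (mm)}
#'   \item{photonScale}{counts per squared structure-factor unit}
#'   \item{noise}{logical; FALSE gives noise-free intensities and spots}
#'   \item{partialityMode}{"xsphere" (spherical-cap partiality) or "ones"
#'     (force p = 1, for validation)}
#'   \item{minPeaks}{crystal-hit threshold: patterns with fewer observations
#'     are dropped}
#' }
#' @export
simConfig <- function(...) {
  cfg <- list(
    spacegroup = "P41212",
    cell = c(58.5, 58.5, 151.25, 90, 90, 90),
    dmin = 2.65,
    nPatterns = 2000,
    wavelength = 2.713,
    distance = 95,
    distanceTrue = NA_real_,       # defaults to `distance`
    pixel = 0.075,
    center = c(0, 0),
    extent = 180,
    nAtoms = 100,
    nSulfur = 10,
    bIso = 20,
    fPrime = 0,
    fDoublePrime = 1.51,
    modelSeed = 42,
    cellJitter = 0.002,
    scaleSdLog = 0.3,
    bJitter = 5,
    profileRadius = 2e-3,
    profileJitterLog = 0.2,
    sigmaBg = 15,
    spotSigma = 0.01,
    photonScale = 0.01,
    noise = TRUE,
    partialityMode = "xsphere",
    minPeaks = 10)
  ov <- list(...)
  bad <- setdiff(names(ov), names(cfg))
  if (length(bad)) stop("unknown SimConfig field(s): ", paste(bad, collapse = ", "))
  cfg[names(ov)] <- ov
  if (is.na(cfg$distanceTrue)) cfg$distanceTrue <- cfg$distance
  stopifnot(cfg$dmin > 0, cfg$nPatterns >= 0, cfg$wavelength > 0,
            cfg$distance > 0, cfg$distanceTrue > 0, cfg$cellJitter >= 0,
            cfg$scaleSdLog >= 0, cfg$bJitter >= 0, cfg$profileRadius > 0,
            cfg$profileJitterLog >= 0, cfg$sigmaBg >= 0, cfg$spotSigma >= 0,
            cfg$photonScale > 0, cfg$minPeaks >= 0,
            cfg$partialityMode %in% c("xsphere", "ones"))
  class(cfg) <- c("SimConfig", "list")
  cfg
}

simBeam <- function(cfg)
  beamGeometry(cfg$wavelength, cfg$distance, cfg$pixel, cfg$center, cfg$extent)

simCell <- function(cfg)
  unitCell(cfg$cell[1], cfg$cell[2], cfg$cell[3],
           cfg$cell[4], cfg$cell[5], cfg$cell[6])

#' Sample per-crystal states
#'
#' Orientations are uniform on the rotation group (random unit
#' quaternions); cell lengths are the reference lengths multiplied by
#' independent Gaussian factors with fractional spread `cellJitter`;
#' linear scales and profile radii are log-normal; B offsets are Gaussian.
#'
#' @param n number of crystals (>= 1)
#' @param cell reference [UnitCell-class]
#' @param cellJitter fractional standard deviation of cell lengths (>= 0)
#' @param scaleSdLog standard deviation of log scale
#' @param bJitter standard deviation of the per-crystal B offset (A^2)
#' @param profileRadius median profile radius (1/A)
#' @param profileJitterLog standard deviation of log profile radius
#' @param seed RNG seed (NULL uses the current RNG stream)
#' @return data.frame: id, o11..o33 (row-major rotation matrix), a, b, c,
#'   scale, bFactor, profileRadius
#' @export
sampleCrystals <- function(n, cell, cellJitter = 0.002, scaleSdLog = 0.3,
                           bJitter = 5, profileRadius = 2e-3,
                           profileJitterLog = 0.2, seed = NULL) {
  stopifnot(n >= 1, cellJitter >= 0, scaleSdLog >= 0, bJitter >= 0,
            profileRadius > 0, profileJitterLog >= 0)
  withSeed(seed, {
    O <- randomRotations(n)
    colnames(O) <- c("o11", "o12", "o13", "o21", "o22", "o23",
                     "o31", "o32", "o33")
    len <- cellLengths(cell)
    fac <- matrix(1 + rnorm(3 * n) * cellJitter, n, 3)
    out <- data.frame(id = seq_len(n), O,
                      a = len[1] * fac[, 1], b = len[2] * fac[, 2],
                      c = len[3] * fac[, 3],
                      scale = exp(rnorm(n) * scaleSdLog),
                      bFactor = rnorm(n) * bJitter,
                      profileRadius = profileRadius *
                        exp(rnorm(n) * profileJitterLog))
    out
  })
}

#' Excitation error of reflections
#'
#' Signed distance of a reciprocal-lattice point from the Ewald sphere:
#' r = |k0 + q| - 1/lambda with k0 = (0, 0, 1/lambda) and q the lab-frame
#' reciprocal vector.  r = 0 exactly on the sphere, negative inside.
#'
#' @param cell a [UnitCell-class] (ignored when `q` is supplied)
#' @param orientation 3x3 rotation matrix (crystal-to-lab)
#' @param hkl Miller indices (vector or n x 3 matrix)
#' @param wavelength X-ray wavelength (Angstrom)
#' @param q optional n x 3 matrix of lab-frame reciprocal vectors; when
#'   given, `cell`/`orientation`/`hkl` are not used
#' @return numeric vector of excitation errors (1/Angstrom)
#' @export
excitationError <- function(cell, orientation, hkl, wavelength, q = NULL) {
  if (is.null(q)) {
    H <- asHklMatrix(hkl)
    q <- t(orientation %*% (cellRecipMatrix(cell) %*% t(H)))
  }
  if (is.null(dim(q))) q <- matrix(q, ncol = 3)
  k0inv <- 1 / wavelength
  s <- q
  s[, 3] <- s[, 3] + k0inv
  sqrt(rowSums(s^2)) - k0inv
}

#' Spherical-cap partiality
#'
#' Models a reflection as a sphere of radius R in reciprocal space cut by
#' the Ewald sphere: with t = clamp(r/R, -1, 1) the recorded fraction is
#' the cap volume fraction p = (2 - 3t + t^3)/4.  p = 1 at r = -R (fully
#' inside), 1/2 at r = 0, 0 at r = +R; monotonically non-increasing in r.
#'
#' @param r excitation error (1/Angstrom, vectorized)
#' @param profileRadius profile radius R (1/Angstrom, > 0)
#' @return partiality between 0 and 1
#' @export
partialityCap <- function(r, profileRadius) {
  if (any(profileRadius <= 0)) stop("profile radius must be > 0")
  t <- pmin(1, pmax(-1, r / profileRadius))
  (2 - 3 * t + t^3) / 4
}

#' Project reciprocal vectors onto the detector
#'
#' The diffracted ray direction is (k0 + q)/|k0 + q|; its intersection with
#' the detector plane z = distance, offset by the beam center, is the spot
#' position in mm.
#'
#' @param beam a [BeamGeometry-class]
#' @param q n x 3 matrix (or length-3 vector) of lab-frame reciprocal
#'   vectors
#' @param distance optional override of the projection distance (mm)
#' @return n x 2 matrix of spot positions (mm)
#' @export
projectToDetector <- function(beam, q, distance = NULL) {
  if (is.null(dim(q))) q <- matrix(q, ncol = 3)
  D <- if (is.null(distance)) beam@distance else distance
  s <- q
  s[, 3] <- s[, 3] + 1 / beam@wavelength
  if (any(s[, 3] <= 0))
    stop("diffracted ray does not travel toward the detector")
  cbind(x = D * s[, 1] / s[, 3] + beam@center[1],
        y = D * s[, 2] / s[, 3] + beam@center[2])
}

#' Recover on-sphere reciprocal vectors from spot positions
#'
#' Inverse of [projectToDetector()] under the elastic (on-Ewald-sphere)
#' assumption: the unit ray through the spot is scaled to 1/lambda and k0
#' subtracted.  Exact for reflections in diffracting condition.
#'
#' @param beam a [BeamGeometry-class]
#' @param xy n x 2 matrix (or length-2 vector) of spot positions (mm)
#' @param distance optional assumed distance (mm); defaults to the beam's
#' @return n x 3 matrix of reciprocal vectors (1/Angstrom)
#' @export
unprojectFromDetector <- function(beam, xy, distance = NULL) {
  if (is.null(dim(xy))) xy <- matrix(xy, ncol = 2)
  D <- if (is.null(distance)) beam@distance else distance
  u <- cbind(xy[, 1] - beam@center[1], xy[, 2] - beam@center[2], D)
  u <- u / sqrt(rowSums(u^2))
  u <- u / beam@wavelength
  u[, 3] <- u[, 3] - 1 / beam@wavelength
  colnames(u) <- c("qx", "qy", "qz")
  u
}

## |q| of an on-sphere reflection whose spot lies at radius rho from the
## beam center when the detector is at distance D
qMagFromRadius <- function(rho, D, wavelength)
  2 * sin(atan(rho / D) / 2) / wavelength

## Precompute everything pattern-independent: unique reflection list, true
## Bijvoet intensities, full-sphere expansion with ASU lookup.
.simPrecompute <- function(model, dmin) {
  cell <- model@cell
  sg <- model@spacegroup
  uniq <- generateHkl(cell, sg, dmin)
  sf <- structureFactors(model, as.matrix(uniq[, c("h", "k", "l")]))
  uniq$iPlus <- Mod(sf$fPlus)^2
  uniq$iMinus <- Mod(sf$fMinus)^2
  fs <- .fullSphereHkl(cell, sg, dmin)
  m <- mapToAsu(sg, fs$hkl)
  idx <- match(.hklKey(m$asu), .hklKey(as.matrix(uniq[, c("h", "k", "l")])))
  iTrue <- ifelse(m$friedel > 0, uniq$iPlus[idx], uniq$iMinus[idx])
  list(cell = cell, sg = sg, dmin = dmin, uniq = uniq,
       fullH = fs$hkl, d = fs$d, stol2 = 1 / (4 * fs$d^2), iTrue = iTrue)
}

## One pattern.  `cr` is a one-row slice of a sampleCrystals() frame; RNG
## state is the caller's.
.simOnePattern <- function(pre, cr, cfg, beam) {
  Bj <- cellRecipMatrix(unitCell(cr$a, cr$b, cr$c,
                                 pre$cell@alpha, pre$cell@beta, pre$cell@gamma))
  O <- rotationFromRow(cr[c("o11", "o12", "o13", "o21", "o22", "o23",
                            "o31", "o32", "o33")])
  q <- O %*% (Bj %*% t(pre$fullH))               # 3 x n lab frame
  k0inv <- 1 / cfg$wavelength
  sz <- q[3, ] + k0inv
  r <- sqrt(q[1, ]^2 + q[2, ]^2 + sz^2) - k0inv
  sel <- which(abs(r) < cr$profileRadius & sz > 0)
  if (!length(sel)) return(NULL)
  r <- r[sel]; sz <- sz[sel]
  D <- cfg$distanceTrue
  x <- D * q[1, sel] / sz + cfg$center[1]
  y <- D * q[2, sel] / sz + cfg$center[2]
  on <- abs(x) <= cfg$extent & abs(y) <= cfg$extent
  if (!any(on)) return(NULL)
  sel <- sel[on]; r <- r[on]; x <- x[on]; y <- y[on]
  p <- if (cfg$partialityMode == "ones") rep(1, length(sel))
       else partialityCap(r, cr$profileRadius)
  stol2 <- pre$stol2[sel]
  i0 <- cfg$photonScale * cr$scale * exp(-2 * cr$bFactor * stol2) *
    p * pre$iTrue[sel]
  sigma <- pmax(sqrt(i0 + cfg$sigmaBg^2), 1e-6)
  if (cfg$noise) {
    i0 <- i0 + rnorm(length(i0)) * sigma
    if (cfg$spotSigma > 0) {
      x <- x + rnorm(length(x)) * cfg$spotSigma
      y <- y + rnorm(length(y)) * cfg$spotSigma
    }
  }
  data.frame(pattern_id = cr$id, h = pre$fullH[sel, 1], k = pre$fullH[sel, 2],
             l = pre$fullH[sel, 3], intensity = i0, sigma = sigma,
             partiality = p, r = r, x = x, y = y, d = pre$d[sel])
}

#' Simulate one still pattern
#'
#' Convenience single-pattern front end to the simulator: every reflection
#' with |r| < profileRadius, d >= dmin and a spot inside the detector is
#' recorded with intensity scale * exp(-2 B stol^2) * p * |F|^2 plus
#' Gaussian noise of variance (I + sigmaBg^2).
#'
#' @param crystal one-row data.frame as returned by [sampleCrystals()]
#' @param model a [StructureModel-class]
#' @param beam a [BeamGeometry-class] (its `distance` is used for
#'   projection)
#' @param dmin resolution cutoff (Angstrom)
#' @param config a [simConfig()] list controlling noise and partiality mode
#' @param seed optional RNG seed
#' @return data.frame of observations (see [StillDataset-class])
#' @export
simulatePattern <- function(crystal, model, beam, dmin,
                            config = simConfig(), seed = NULL) {
  cfg <- config
  cfg$wavelength <- beam@wavelength
  cfg$distanceTrue <- beam@distance
  cfg$center <- beam@center
  cfg$extent <- beam@extent
  pre <- .simPrecompute(model, dmin)
  withSeed(seed, .simOnePattern(pre, crystal, cfg, beam))
}

#' Simulate a still-diffraction dataset
#'
#' Draws `nPatterns` crystals, simulates each pattern, applies the
#' crystal-hit filter (at least `minPeaks` observations) and assembles a
#' [StillDataset-class] with its ground-truth sidecar.  Deterministic for a
#' fixed seed.
#'
#' @param config a [simConfig()] list
#' @param seed integer seed driving all randomness (crystal draws and
#'   noise); the toy model uses `config$modelSeed` so that the same ground
#'   truth can be shared across datasets
#' @param model optional [StructureModel-class] overriding the toy model
#' @return a [StillDataset-class]
#' @export
simulateDataset <- function(config = simConfig(), seed = 1, model = NULL) {
  cfg <- config
  cell <- simCell(cfg)
  sg <- spaceGroup(cfg$spacegroup)
  if (is.null(model))
    model <- toyStructureModel(cell, sg, cfg$nAtoms, cfg$nSulfur, cfg$bIso,
                               cfg$fPrime, cfg$fDoublePrime, cfg$modelSeed)
  beam <- simBeam(cfg)
  if (cfg$nPatterns == 0) {
    emptyCr <- data.frame(id = integer(), o11 = numeric(), o12 = numeric(),
                          o13 = numeric(), o21 = numeric(), o22 = numeric(),
                          o23 = numeric(), o31 = numeric(), o32 = numeric(),
                          o33 = numeric(), a = numeric(), b = numeric(),
                          c = numeric(), profileRadius = numeric(),
                          nObs = integer())
    emptyObs <- data.frame(pattern_id = integer(), h = integer(),
                           k = integer(), l = integer(), intensity = numeric(),
                           sigma = numeric(), partiality = numeric(),
                           r = numeric(), x = numeric(), y = numeric(),
                           d = numeric())
    return(new("StillDataset", beam = beam, cell = cell, spacegroup = sg,
               dmin = cfg$dmin, crystals = emptyCr, observations = emptyObs,
               truth = list(distance = cfg$distanceTrue, model = model),
               meta = list(seed = seed, nDropped = 0L, config = cfg)))
  }
  crFull <- sampleCrystals(cfg$nPatterns, cell, cfg$cellJitter,
                           cfg$scaleSdLog, cfg$bJitter, cfg$profileRadius,
                           cfg$profileJitterLog, seed = childSeed(seed, 1))
  pre <- .simPrecompute(model, cfg$dmin)
  obsList <- withSeed(childSeed(seed, 2), {
    lapply(seq_len(nrow(crFull)), function(i)
      .simOnePattern(pre, crFull[i, ], cfg, beam))
  })
  nObs <- vapply(obsList, function(o) if (is.null(o)) 0L else nrow(o), 0L)
  hit <- nObs >= cfg$minPeaks
  obs <- if (any(hit)) as.data.frame(rbindlist(obsList[hit]))
         else data.frame(pattern_id = integer(), h = integer(), k = integer(),
                         l = integer(), intensity = numeric(),
                         sigma = numeric(), partiality = numeric(),
                         r = numeric(), x = numeric(), y = numeric(),
                         d = numeric())
  crVis <- crFull[hit, c("id", "o11", "o12", "o13", "o21", "o22", "o23",
                         "o31", "o32", "o33", "a", "b", "c", "profileRadius")]
  crVis$nObs <- nObs[hit]
  rownames(crVis) <- NULL
  sites <- as.matrix(anomalousSites(model)[, c("x", "y", "z")])
  truth <- list(distance = cfg$distanceTrue,
                crystals = crFull, f2 = pre$uniq, sites = sites,
                model = model, seed = seed)
  new("StillDataset", beam = beam, cell = cell, spacegroup = sg,
      dmin = cfg$dmin, crystals = crVis, observations = obs, truth = truth,
      meta = list(seed = seed, nDropped = sum(!hit), config = cfg))
}

#' Subset a dataset to selected patterns
#'
#' @param dataset a [StillDataset-class]
#' @param ids pattern ids to keep
#' @return a [StillDataset-class] restricted to `ids`
#' @export
subsetPatterns <- function(dataset, ids) {
  cr <- dataset@crystals
  obs <- dataset@observations
  initialize(dataset,
             crystals = cr[cr$id %in% ids, , drop = FALSE],
             observations = obs[obs$pattern_id %in% ids, , drop = FALSE])
}
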