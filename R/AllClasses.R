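## Central S4 containers.  Large per-observation tables are plain data.frames
## held in slots: reflection lists at desk scale run to 10^5-10^6 rows and a
## row-per-object representation would be prohibitively slow.

#' Unit cell
#'
#' Lengths in Angstrom, angles in degrees.  Validity enforces positive
#' lengths, angles in (0, 180) and a positive-definite metric.
#'
#' @slot a,b,c cell edge lengths (Angstrom)
#' @slot alpha,beta,gamma cell angles (degrees)
#' @export
setClass("UnitCell",
  representation(a = "numeric", b = "numeric", c = "numeric",
                 alpha = "numeric", beta = "numeric", gamma = "numeric"))

setValidity("UnitCell", function(object) {
  len <- c(object@a, object@b, object@c)
  ang <- c(object@alpha, object@beta, object@gamma)
  if (length(len) != 3L || any(!is.finite(len)) || any(len <= 0))
    return("cell lengths must be finite and > 0")
  if (length(ang) != 3L || any(!is.finite(ang)) || any(ang <= 0 | ang >= 180))
    return("cell angles must lie in (0, 180) degrees")
  ca <- cos(ang * pi / 180)
  disc <- 1 - sum(ca^2) + 2 * prod(ca)
  if (disc <= 0)
    return("cell angles give a non-positive-definite metric")
  TRUE
})

#' Construct a unit cell
#'
#' @param a,b,c cell edge lengths in Angstrom
#' @param alpha,beta,gamma cell angles in degrees (default 90)
#' @return a [UnitCell-class] object
#' @examples
#' unitCell(58.5, 58.5, 151.25)
#' @export
unitCell <- function(a, b, c, alpha = 90, beta = 90, gamma = 90) {
  new("UnitCell", a = as.numeric(a), b = as.numeric(b), c = as.numeric(c),
      alpha = as.numeric(alpha), beta = as.numeric(beta),
      gamma = as.numeric(gamma))
}

#' Space group
#'
#' Hard-coded symmetry for the three groups used throughout the package:
#' P1, P4(1)2(1)2 (no. 92) and C222(1) (no. 20).  Rotations act on
#' fractional coordinates as x' = R x + t; reflection equivalents are
#' h' = h R (row vector times matrix).
#'
#' @slot symbol short Hermann-Mauguin style symbol ("P1", "P41212", "C2221")
#' @slot number IT space-group number (1, 92, 20)
#' @slot rotations list of 3x3 rotation matrices of the symmetry operators
#' @slot translations list of length-3 translation vectors
#' @slot centering list of lattice-centering translation vectors
#' @slot laueRot list of unique rotation parts used for intensity merging
#' @export
setClass("SpaceGroup",
  representation(symbol = "character", number = "integer",
                 rotations = "list", translations = "list",
                 centering = "list", laueRot = "list"))

setValidity("SpaceGroup", function(object) {
  n <- length(object@rotations)
  if (n < 1L || length(object@translations) != n)
    return("rotations/translations must be non-empty parallel lists")
  idOk <- any(vapply(object@rotations, function(R) all(R == diag(3)), TRUE) &
              vapply(object@translations, function(t) all(t %% 1 == 0), TRUE))
  if (!idOk) return("identity operator missing")
  ## closure of rotation parts under composition, modulo lattice translations
  keys <- vapply(object@laueRot, function(R) paste(as.integer(R), collapse = ","), "")
  for (R1 in object@laueRot) for (R2 in object@laueRot) {
    if (!(paste(as.integer(R1 %*% R2), collapse = ",") %in% keys))
      return("laue rotations not closed under composition")
  }
  TRUE
})

#' Structure model
#'
#' Atoms with fractional coordinates, occupancies, isotropic displacement
#' parameters and complex scattering corrections (f', f'').  Atoms flagged
#' `anomalous` define the anomalous substructure used for phased anomalous
#' difference maps and S_ano.
#'
#' @slot cell a [UnitCell-class]
#' @slot spacegroup a [SpaceGroup-class]
#' @slot atoms data.frame with columns element, x, y, z (fractional), occ,
#'   biso (Angstrom^2), fp, fpp (electrons), anomalous (logical)
#' @export
setClass("StructureModel",
  representation(cell = "UnitCell", spacegroup = "SpaceGroup",
                 atoms = "data.frame"))

setValidity("StructureModel", function(object) {
  at <- object@atoms
  need <- c("element", "x", "y", "z", "occ", "biso", "fp", "fpp", "anomalous")
  if (!all(need %in% names(at))) return("atoms lacks required columns")
  if (nrow(at) < 1L) return("model must contain at least one atom")
  if (any(at$occ < 0 | at$occ > 1)) return("occupancies must lie in [0, 1]")
  if (any(at$biso < 0)) return("b_iso must be >= 0")
  if (any(at$fpp < 0)) return("f'' must be >= 0")
  TRUE
})

#' Beam and detector geometry
#'
#' @slot wavelength X-ray wavelength (Angstrom)
#' @slot distance sample-to-detector distance (mm)
#' @slot pixel pixel size (mm)
#' @slot center beam center on the detector (mm, mm)
#' @slot extent detector half-width (mm); spots with |x| or |y| beyond this
#'   fall off the detector
#' @export
setClass("BeamGeometry",
  representation(wavelength = "numeric", distance = "numeric",
                 pixel = "numeric", center = "numeric", extent = "numeric"))

setValidity("BeamGeometry", function(object) {
  if (object@wavelength <= 0) return("wavelength must be > 0")
  if (object@distance <= 0) return("detector distance must be > 0")
  if (object@pixel <= 0) return("pixel size must be > 0")
  if (length(object@center) != 2L) return("beam center must have length 2")
  if (object@extent <= 0) return("detector extent must be > 0")
  TRUE
})

#' Construct a beam/detector geometry
#'
#' @param wavelength X-ray wavelength in Angstrom
#' @param distance sample-to-detector distance in mm
#' @param pixel pixel size in mm
#' @param center beam center (mm, mm)
#' @param extent detector half-width in mm
#' @return a [BeamGeometry-class]
#' @export
beamGeometry <- function(wavelength, distance, pixel = 0.075,
                         center = c(0, 0), extent = 180) {
  new("BeamGeometry", wavelength = as.numeric(wavelength),
      distance = as.numeric(distance), pixel = as.numeric(pixel),
      center = as.numeric(center), extent = as.numeric(extent))
}

#' Synthetic still-diffraction dataset
#'
#' One pattern per crystal; observations are partial Bragg intensities.
#' The `truth` slot is a ground-truth sidecar (true detector distance,
#' per-crystal scales/B factors, true squared structure factors, anomalous
#' sites) written only by the simulator; analysis code never reads it except
#' where an oracle is explicitly documented (e.g. index assignment in the
#' detector-distance scan).
#'
#' @slot beam a [BeamGeometry-class]; `distance` is the *assumed* (header)
#'   distance, which may deliberately differ from `truth$distance`
#' @slot cell reference [UnitCell-class]
#' @slot spacegroup a [SpaceGroup-class]
#' @slot dmin resolution cutoff of the simulation (Angstrom)
#' @slot crystals data.frame, one row per retained pattern: id, orientation
#'   (o11..o33), jittered cell lengths a, b, c, profileRadius, nObs
#' @slot observations data.frame: pattern_id, h, k, l, intensity, sigma,
#'   partiality, r (excitation error, 1/Angstrom), x, y (mm), d (Angstrom)
#' @slot truth list (ground-truth sidecar); empty for datasets read from a
#'   stream file without their sidecar
#' @slot meta list (seed, dropped-pattern count, config echo)
#' @export
setClass("StillDataset",
  representation(beam = "BeamGeometry", cell = "UnitCell",
                 spacegroup = "SpaceGroup", dmin = "numeric",
                 crystals = "data.frame", observations = "data.frame",
                 truth = "list", meta = "list"))

setValidity("StillDataset", function(object) {
  obs <- object@observations
  cr <- object@crystals
  need <- c("pattern_id", "h", "k", "l", "intensity", "sigma", "partiality",
            "r", "x", "y", "d")
  if (nrow(obs) > 0) {
    if (!all(need %in% names(obs))) return("observations lacks required columns")
    if (!all(obs$pattern_id %in% cr$id))
      return("every observation must reference a crystal")
    if (any(obs$sigma <= 0)) return("observation sigmas must be > 0")
    if (any(obs$partiality < 0 | obs$partiality > 1))
      return("partialities must lie in [0, 1]")
  }
  TRUE
})

#' Merged reflection dataset
#'
#' Symmetry-reduced mean intensities with uncertainties; Bijvoet mates are
#' kept separate (`side` = +1 for the I+ record of an asymmetric-unit
#' reflection, -1 for I-).
#'
#' @slot cell a [UnitCell-class]
#' @slot spacegroup a [SpaceGroup-class]
#' @slot reflections data.frame: h, k, l (ASU indices), side (+1/-1),
#'   intensity, sigma, nmeas, d
#' @slot provenance list (merge configuration, input sizes, seed)
#' @export
setClass("MergedDataset",
  representation(cell = "UnitCell", spacegroup = "SpaceGroup",
                 reflections = "data.frame", provenance = "list"))

setValidity("MergedDataset", function(object) {
  rf <- object@reflections
  need <- c("h", "k", "l", "side", "intensity", "sigma", "nmeas", "d")
  if (!all(need %in% names(rf))) return("reflections lacks required columns")
  if (nrow(rf) > 0) {
    if (any(rf$nmeas < 1)) return("nmeas must be >= 1")
    if (any(rf$sigma[rf$nmeas >= 2] <= 0))
      return("sigma must be > 0 for nmeas >= 2")
    if (anyDuplicated(paste(rf$h, rf$k, rf$l, rf$side)))
      return("at most one record per (asu hkl, friedel side)")
  }
  TRUE
})

#' Real-space anomalous difference Fourier map
#'
#' The grid covers exactly one unit cell; values are stored in units of the
#' map root-mean-square density.  The Fourier coefficients used for the
#' synthesis are retained so that peak heights at arbitrary fractional
#' coordinates can be evaluated by direct summation rather than grid
#' interpolation.
#'
#' @slot values 3D array of rms-normalized map values
#' @slot rms raw map rms before normalization
#' @slot cell a [UnitCell-class]
#' @slot spacing requested grid spacing (Angstrom)
#' @slot coeffH integer matrix of full-sphere Miller indices
#' @slot coeffF complex vector of full-sphere coefficients
#' @export
setClass("MapGrid",
  representation(values = "array", rms = "numeric", cell = "UnitCell",
                 spacing = "numeric", coeffH = "matrix", coeffF = "complex"))

setValidity("MapGrid", function(object) {
  if (length(dim(object@values)) != 3L) return("values must be a 3D array")
  if (length(object@coeffF) > 0 && any(Mod(object@coeffF) > 0) &&
      object@rms <= 0)
    return("rms must be > 0 for nonzero coefficients")
  TRUE
})

#' Detector-distance scan result
#'
#' @slot table data.frame: distance (mm), sdA, sdB, sdC (Angstrom, spread of
#'   fitted cell lengths over indexed patterns), rate (indexed fraction)
#' @slot optimal optimal distance in mm (argmin of sdC; ties go to the
#'   smaller distance)
#' @slot step grid step in mm
#' @export
setClass("DistanceScanResult",
  representation(table = "data.frame", optimal = "numeric", step = "numeric"))

setValidity("DistanceScanResult", function(object) {
  tb <- object@table
  if (!all(c("distance", "sdA", "sdB", "sdC", "rate") %in% names(tb)))
    return("table lacks required columns")
  if (!isTRUE(all.equal(min(abs(object@optimal - tb$distance)), 0)))
    return("optimal distance must be a member of the candidate grid")
  if (nrow(tb) >= 3) {
    st <- diff(tb$distance)
    if (max(abs(st - mean(st))) > 1e-9) return("grid spacing must be uniform")
  }
  TRUE
})

#' Data-quality report
#'
#' Overall and per-shell half-dataset statistics in the style of SFX
#' data-collection tables.
#'
#' @slot overall named list: rSplit (%), cc12, ccStar, ccAno, meanIsig,
#'   completeness (%), redundancy, nUnique, nObs
#' @slot shells data.frame with the same statistics per resolution shell
#' @slot meta list (shell scheme, seed, merge configuration)
#' @export
setClass("QualityReport",
  representation(overall = "list", shells = "data.frame", meta = "list"))

#' S_ano versus image-count curve
#'
#' @slot curve data.frame: nImages, sAno
#' @slot threshold S_ano level regarded as sufficient for phasing (default 10)
#' @slot crossing interpolated image count at which the curve crosses the
#'   threshold (NA if never crossed)
#' @slot status "crossed", "below_range" (already above threshold at the
#'   smallest size) or "not_reached"
#' @export
setClass("SanoCurve",
  representation(curve = "data.frame", threshold = "numeric",
                 crossing = "numeric", status = "character"))

setValidity("SanoCurve", function(object) {
  n <- object@curve$nImages
  if (length(n) > 1 && any(diff(n) <= 0))
    return("nImages must be strictly increasing")
  TRUE
})
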