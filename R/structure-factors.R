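## Direct-summation structure factors with anomalous contributions.
##
## F(h) = sum_ops sum_atoms occ * f * exp(-B stol^2) * exp(2 pi i h.(Rx + t))
## with f = f0 + f' + i f''.  F(-h) is computed with the SAME complex f;
## this sign convention is what breaks Friedel's law when f'' > 0.

#' Construct a structure model
#'
#' @param cell a [UnitCell-class]
#' @param spacegroup a [SpaceGroup-class] or symbol
#' @param atoms data.frame with columns element, x, y, z (fractional
#'   coordinates), and optionally occ (default 1), biso (default 0), fp
#'   (default 0), fpp (default 0), anomalous (default `fpp > 0`)
#' @return a [StructureModel-class]
#' @export
structureModel <- function(cell, spacegroup, atoms) {
  if (is.character(spacegroup)) spacegroup <- spaceGroup(spacegroup)
  at <- as.data.frame(atoms)
  if (is.null(at$occ)) at$occ <- 1
  if (is.null(at$biso)) at$biso <- 0
  if (is.null(at$fp)) at$fp <- 0
  if (is.null(at$fpp)) at$fpp <- 0
  if (is.null(at$anomalous)) at$anomalous <- at$fpp > 0
  new("StructureModel", cell = cell, spacegroup = spacegroup, atoms = at)
}

.sfOneSide <- function(model, H, stol) {
  at <- model@atoms
  sg <- model@spacegroup
  n <- nrow(H); nat <- nrow(at)
  ## n x nat complex: occ * f(stol) * Debye-Waller
  fmat <- matrix(0 + 0i, n, nat)
  for (el in unique(at$element)) {
    idx <- which(at$element == el)
    f0v <- .f0(el, stol)
    for (j in idx)
      fmat[, j] <- complex(real = f0v + at$fp[j], imaginary = at$fpp[j])
  }
  dw <- exp(-outer(stol^2, at$biso))
  fmat <- fmat * dw * rep(at$occ, each = n)
  xyz <- t(as.matrix(at[, c("x", "y", "z")]))       # 3 x nat
  F <- complex(n)
  tp <- 2 * pi
  for (s in seq_along(sg@rotations)) {
    X <- H %*% sg@rotations[[s]]                    # n x 3, h' = h R
    ph <- X %*% xyz                                 # n x nat
    tph <- as.numeric(H %*% sg@translations[[s]])   # n, phase from h.t
    contrib <- rowSums(fmat * exp(complex(imaginary = tp * ph)))
    F <- F + contrib * exp(complex(imaginary = tp * tph))
  }
  cent <- complex(n)
  for (v in sg@centering)
    cent <- cent + exp(complex(imaginary = tp * as.numeric(H %*% v)))
  F * cent
}

#' Structure factors with separated Bijvoet mates
#'
#' Computes F(h) and F(-h) for each requested Miller triple by direct
#' summation over all atoms and symmetry operators, using the same complex
#' scattering factor for both mates so that f'' > 0 breaks Friedel's law.
#'
#' @param model a [StructureModel-class]
#' @param hkl length-3 vector or n x 3 matrix of Miller indices
#' @return data.frame: h, k, l, d, fPlus (complex F(h)), fMinus (complex
#'   F(-h))
#' @export
structureFactors <- function(model, hkl) {
  H <- asHklMatrix(hkl)
  d <- dSpacing(model@cell, H)
  stol <- 1 / (2 * d)
  fp <- .sfOneSide(model, H, stol)
  fm <- .sfOneSide(model, -H, stol)
  data.frame(h = H[, 1], k = H[, 2], l = H[, 3], d = d,
             fPlus = fp, fMinus = fm)
}

#' Model phases and calculated anomalous differences
#'
#' For each reflection returns |F+|, |F-|, the anomalous difference
#' amplitude |F+| - |F-| and the phase of the Bijvoet-averaged structure
#' factor (F+ + conj(F-))/2, the standard phase for anomalous difference
#' Fourier synthesis.
#'
#' @param model a [StructureModel-class]
#' @param hkl Miller indices (vector or matrix)
#' @return data.frame: h, k, l, d, fPlusAbs, fMinusAbs, dFcalc, phi (radians)
#' @export
modelAnomalous <- function(model, hkl) {
  sf <- structureFactors(model, hkl)
  fav <- (sf$fPlus + Conj(sf$fMinus)) / 2
  data.frame(h = sf$h, k = sf$k, l = sf$l, d = sf$d,
             fPlusAbs = Mod(sf$fPlus), fMinusAbs = Mod(sf$fMinus),
             dFcalc = Mod(sf$fPlus) - Mod(sf$fMinus), phi = Arg(fav))
}

#' Random toy protein-like structure model
#'
#' Builds a reproducible random model of light atoms (C, N, O in roughly
#' protein-like proportions) plus a sulfur substructure, with uniform
#' fractional coordinates.  This is the synthetic stand-in for a refined
#' protein model; it defines the ground-truth intensities and the anomalous
#' sites of a simulated dataset.
#'
#' @param cell a [UnitCell-class]
#' @param spacegroup a [SpaceGroup-class] or symbol
#' @param nAtoms total number of atoms
#' @param nSulfur number of sulfur (anomalous) sites among them
#' @param bIso isotropic displacement parameter for all atoms (Angstrom^2)
#' @param fPrime,fDoublePrime anomalous corrections applied to the sulfur
#'   atoms (electrons); defaults to f'' = 1.51 e-, the sulfur value at
#'   4.57 keV
#' @param seed RNG seed making the model reproducible
#' @return a [StructureModel-class]
#' @export
toyStructureModel <- function(cell, spacegroup, nAtoms = 100, nSulfur = 10,
                              bIso = 20, fPrime = 0, fDoublePrime = 1.51,
                              seed = 42) {
  stopifnot(nAtoms >= 1, nSulfur >= 0, nSulfur <= nAtoms)
  if (is.character(spacegroup)) spacegroup <- spaceGroup(spacegroup)
  withSeed(seed, {
    nLight <- nAtoms - nSulfur
    el <- c(sample(c("C", "N", "O"), nLight, replace = TRUE,
                   prob = c(0.62, 0.19, 0.19)), rep("S", nSulfur))
    atoms <- data.frame(
      element = el,
      x = runif(nAtoms), y = runif(nAtoms), z = runif(nAtoms),
      occ = 1, biso = bIso,
      fp = ifelse(el == "S", fPrime, 0),
      fpp = ifelse(el == "S", fDoublePrime, 0),
      anomalous = el == "S")
    structureModel(cell, spacegroup, atoms)
  })
}
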