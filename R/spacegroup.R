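## Hard-coded symmetry for the three space groups handled by the package.
## A general symmetry engine is out of scope: P1, P4(1)2(1)2 and C222(1)
## cover triclinic controls plus the tetragonal (thaumatin-like) and
## orthorhombic (A2A-like) crystal forms used throughout.

sgRot <- function(...) matrix(c(...), nrow = 3, byrow = TRUE)

.sgTable <- local({
  p1 <- list(symbol = "P1", number = 1L,
             rotations = list(diag(3)),
             translations = list(c(0, 0, 0)),
             centering = list(c(0, 0, 0)))
  ## IT no. 92, standard setting
  p41212 <- list(symbol = "P41212", number = 92L,
    rotations = list(
      diag(3),
      diag(c(-1, -1, 1)),
      sgRot(0, -1, 0,  1, 0, 0,  0, 0, 1),
      sgRot(0, 1, 0,  -1, 0, 0,  0, 0, 1),
      diag(c(-1, 1, -1)),
      diag(c(1, -1, -1)),
      sgRot(0, 1, 0,  1, 0, 0,  0, 0, -1),
      sgRot(0, -1, 0,  -1, 0, 0,  0, 0, -1)),
    translations = list(
      c(0, 0, 0), c(0, 0, 1/2),
      c(1/2, 1/2, 1/4), c(1/2, 1/2, 3/4),
      c(1/2, 1/2, 1/4), c(1/2, 1/2, 3/4),
      c(0, 0, 0), c(0, 0, 1/2)),
    centering = list(c(0, 0, 0)))
  ## IT no. 20
  c2221 <- list(symbol = "C2221", number = 20L,
    rotations = list(
      diag(3), diag(c(-1, -1, 1)), diag(c(-1, 1, -1)), diag(c(1, -1, -1))),
    translations = list(
      c(0, 0, 0), c(0, 0, 1/2), c(0, 0, 1/2), c(0, 0, 0)),
    centering = list(c(0, 0, 0), c(1/2, 1/2, 0)))
  list(P1 = p1, P41212 = p41212, C2221 = c2221)
})

normalizeSgSymbol <- function(symbol) {
  s <- toupper(gsub("[^A-Za-z0-9]", "", symbol))
  if (s %in% c("P1")) return("P1")
  if (s %in% c("P41212", "P4121")) return("P41212")
  if (s %in% c("C2221", "C2221")) return("C2221")
  stop("unsupported space group: ", symbol,
       " (supported: P1, P41212, C2221)")
}

#' Construct a space group
#'
#' Supported symbols: `"P1"`, `"P41212"` (no. 92) and `"C2221"` (no. 20).
#' Symmetry operators are stored explicitly; centering translations are kept
#' separate from the primitive operator list.
#'
#' @param symbol space-group symbol
#' @return a [SpaceGroup-class]
#' @examples
#' spaceGroup("P41212")
#' @export
spaceGroup <- function(symbol) {
  e <- .sgTable[[normalizeSgSymbol(symbol)]]
  laue <- unique(lapply(e$rotations, function(R) R))
  new("SpaceGroup", symbol = e$symbol, number = e$number,
      rotations = e$rotations, translations = e$translations,
      centering = e$centering, laueRot = laue)
}

sgFromNumber <- function(number) {
  sym <- switch(as.character(number), "1" = "P1", "92" = "P41212",
                "20" = "C2221",
                stop("unsupported space-group number: ", number))
  spaceGroup(sym)
}

## lexicographic ranking key of a Miller triple; supports |index| < 2048
.hklKey <- function(H) {
  (H[, 1] + 2048) * 4096^2 + (H[, 2] + 2048) * 4096 + (H[, 3] + 2048)
}

.hklUnkey <- function(key) {
  l <- key %% 4096; key <- (key - l) / 4096
  k <- key %% 4096; key <- (key - k) / 4096
  cbind(h = key - 2048, k = k - 2048, l = l - 2048)
}

#' Map reflections to the asymmetric unit
#'
#' The canonical representative of a reflection orbit is the lexicographic
#' maximum over the images of both h and -h under the Laue rotations.  The
#' Friedel flag records whether the representative was reached through the
#' inversion (-1) or not (+1); ties between the two branches (centric
#' reflections) resolve to +1.
#'
#' @param spacegroup a [SpaceGroup-class]
#' @param hkl length-3 vector or n x 3 matrix of Miller indices
#' @return list with elements `asu` (n x 3 integer matrix), `friedel`
#'   (+1/-1) and `centric` (logical: -h lies in the Laue orbit of h)
#' @export
mapToAsu <- function(spacegroup, hkl) {
  H <- asHklMatrix(hkl)
  if (any(rowSums(abs(H)) == 0)) stop("cannot map the (0,0,0) triple")
  bestP <- rep(-Inf, nrow(H)); bestM <- rep(-Inf, nrow(H))
  for (R in spacegroup@laueRot) {
    img <- H %*% R                      # h' = h R (row-vector convention)
    bestP <- pmax(bestP, .hklKey(img))
    bestM <- pmax(bestM, .hklKey(-img))
  }
  plus <- bestP >= bestM
  asu <- .hklUnkey(ifelse(plus, bestP, bestM))
  storage.mode(asu) <- "integer"
  list(asu = asu, friedel = ifelse(plus, 1L, -1L), centric = bestP == bestM)
}

## lattice-centering test: h.v must be integral for all centering vectors
.centeringAllowed <- function(spacegroup, H) {
  ok <- rep(TRUE, nrow(H))
  for (v in spacegroup@centering) {
    if (all(v == 0)) next
    ph <- H %*% v
    ok <- ok & (abs(ph - round(ph)) < 1e-9)
  }
  ok
}

## every lattice point (full sphere) with d >= dmin, absences removed
.fullSphereHkl <- function(cell, spacegroup, dmin) {
  len <- cellLengths(cell)
  hmax <- pmax(0L, floor(len / dmin))
  g <- as.matrix(expand.grid(h = -hmax[1]:hmax[1], k = -hmax[2]:hmax[2],
                             l = -hmax[3]:hmax[3]))
  g <- g[rowSums(abs(g)) > 0, , drop = FALSE]
  g <- g[.centeringAllowed(spacegroup, g), , drop = FALSE]
  d <- dSpacing(cell, g)
  keep <- d >= dmin
  list(hkl = g[keep, , drop = FALSE], d = d[keep])
}

#' Enumerate unique reflections to a resolution limit
#'
#' Returns the asymmetric-unit-unique Miller triples with d >= `dmin`,
#' reduced under the Laue rotations and Friedel pairing.  Centering-forbidden
#' reflections (e.g. h+k odd in C-centered lattices) are excluded.  Centric
#' reflections (those whose Friedel mate is Laue-equivalent to themselves,
#' so only one Bijvoet side exists) are flagged; acentric entries stand for
#' two separately-merged Bijvoet mates.
#'
#' @param cell a [UnitCell-class]
#' @param spacegroup a [SpaceGroup-class]
#' @param dmin resolution limit in Angstrom (> 0)
#' @return data.frame: h, k, l (ASU indices), d, centric
#' @export
generateHkl <- function(cell, spacegroup, dmin) {
  stopifnot(dmin > 0)
  fs <- .fullSphereHkl(cell, spacegroup, dmin)
  if (nrow(fs$hkl) == 0)
    return(data.frame(h = integer(), k = integer(), l = integer(),
                      d = numeric(), centric = logical()))
  m <- mapToAsu(spacegroup, fs$hkl)
  key <- .hklKey(m$asu)
  first <- !duplicated(key)
  out <- data.frame(h = m$asu[first, 1], k = m$asu[first, 2],
                    l = m$asu[first, 3], d = fs$d[first],
                    centric = m$centric[first])
  out[order(-out$d, out$h, out$k, out$l), , drop = FALSE]
}
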