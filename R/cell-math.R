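## Cell geometry: orthogonalization, reciprocal basis, d-spacings.

#' Orthogonalization matrix of a unit cell
#'
#' Columns are the cell basis vectors a, b, c in a Cartesian frame with a
#' along x and b in the xy plane.  Fractional coordinates map to Cartesian
#' Angstrom as `M %*% x`.
#'
#' @param cell a [UnitCell-class]
#' @return 3x3 numeric matrix
#' @export
cellOrthMatrix <- function(cell) {
  stopifnot(is(cell, "UnitCell"))
  ang <- cellAngles(cell) * pi / 180
  ca <- cos(ang); sa <- sin(ang)
  v <- sqrt(1 - sum(ca^2) + 2 * prod(ca))
  matrix(c(cell@a, cell@b * ca[3], cell@c * ca[2],
           0,      cell@b * sa[3], cell@c * (ca[1] - ca[2] * ca[3]) / sa[3],
           0,      0,              cell@c * v / sa[3]),
         nrow = 3, byrow = TRUE)
}

#' Reciprocal-basis matrix of a unit cell
#'
#' Returns B such that the reciprocal vector of Miller triple h (as a
#' column) is `q = B %*% h`, with |q| = 1/d in 1/Angstrom.
#'
#' @param cell a [UnitCell-class]
#' @return 3x3 numeric matrix
#' @export
cellRecipMatrix <- function(cell) {
  t(solve(cellOrthMatrix(cell)))
}

asHklMatrix <- function(hkl) {
  if (is.null(dim(hkl))) hkl <- matrix(hkl, ncol = 3, byrow = FALSE,
                                       dimnames = NULL)
  if (ncol(hkl) != 3L) stop("hkl must be a length-3 vector or an n x 3 matrix")
  storage.mode(hkl) <- "double"
  hkl
}

#' Resolution (d-spacing) of reflections
#'
#' d = 1/|d*| with d*^2 taken from the reciprocal metric tensor; valid for
#' arbitrary (triclinic) cells.
#'
#' @param cell a [UnitCell-class]
#' @param hkl length-3 integer vector or n x 3 matrix of Miller indices
#' @return numeric vector of d-spacings in Angstrom
#' @examples
#' dSpacing(unitCell(58.5, 58.5, 151.25), c(0, 0, 2))  # 75.625
#' @export
dSpacing <- function(cell, hkl) {
  H <- asHklMatrix(hkl)
  if (any(rowSums(abs(H)) == 0))
    stop("d-spacing undefined for the (0,0,0) triple")
  B <- cellRecipMatrix(cell)
  q <- B %*% t(H)
  1 / sqrt(colSums(q * q))
}
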