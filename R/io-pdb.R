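## Structure models as minimal PDB ATOM/HETATM records (via bio3d).
## Anomalous corrections are not representable in PDB; they are supplied
## by the caller and applied per element.

#' Read a structure model from a PDB file
#'
#' Occupancy and B-factor columns are honored; coordinates are converted
#' from orthogonal Angstrom to fractional using the supplied cell.  f'/f''
#' are assigned per element via `anomalous` (they are experiment
#' parameters, not part of the file).
#'
#' @param path PDB file
#' @param cell a [UnitCell-class]
#' @param spacegroup a [SpaceGroup-class] or symbol
#' @param anomalous named list, e.g. `list(S = c(fp = 0, fpp = 1.51))`
#' @return a [StructureModel-class]
#' @export
readPdbModel <- function(path, cell, spacegroup,
                         anomalous = list(S = c(fp = 0, fpp = 1.51))) {
  if (!file.exists(path)) stop("no such PDB file: ", path)
  pdb <- bio3d::read.pdb(path)
  at <- pdb$atom
  el <- trimws(at$elesy)
  el[!nzchar(el)] <- substr(trimws(at$elety[!nzchar(el)]), 1, 1)
  xyzOrth <- rbind(at$x, at$y, at$z)
  frac <- t(solve(cellOrthMatrix(cell)) %*% xyzOrth)
  fp <- numeric(nrow(at)); fpp <- numeric(nrow(at))
  for (e in names(anomalous)) {
    sel <- toupper(el) == toupper(e)
    fp[sel] <- anomalous[[e]][["fp"]]
    fpp[sel] <- anomalous[[e]][["fpp"]]
  }
  atoms <- data.frame(element = toupper(el), x = frac[, 1], y = frac[, 2],
                      z = frac[, 3], occ = at$o, biso = at$b,
                      fp = fp, fpp = fpp, anomalous = fpp > 0)
  structureModel(cell, spacegroup, atoms)
}

#' Write a structure model as a PDB file
#'
#' Fractional coordinates are orthogonalized with the model cell; element,
#' occupancy and B-factor are written per PDB v3.3 columns.
#'
#' @param model a [StructureModel-class]
#' @param path output path
#' @return `path`, invisibly
#' @export
writePdbModel <- function(model, path) {
  at <- model@atoms
  M <- cellOrthMatrix(model@cell)
  orth <- t(M %*% t(as.matrix(at[, c("x", "y", "z")])))
  n <- nrow(at)
  bio3d::write.pdb(file = path,
                   xyz = as.numeric(t(orth)),
                   type = rep("ATOM", n),
                   eleno = seq_len(n),
                   elety = at$element,
                   resid = rep("UNK", n),
                   chain = rep("A", n),
                   resno = seq_len(n),
                   o = at$occ, b = at$biso,
                   elesy = at$element)
  invisible(path)
}
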