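#' @name sfxsad-accessors
#' @title Accessors for sfxsad classes
#' @description Accessor generics for the package's S4 containers.
#' @param x an sfxsad object
#' @param object an sfxsad object
NULL

#' @rdname sfxsad-accessors
#' @export
setGeneric("cellLengths", function(x) standardGeneric("cellLengths"))
#' @rdname sfxsad-accessors
#' @export
setGeneric("cellAngles", function(x) standardGeneric("cellAngles"))
#' @rdname sfxsad-accessors
#' @export
setGeneric("cellVolume", function(x) standardGeneric("cellVolume"))
#' @rdname sfxsad-accessors
#' @export
setGeneric("sgSymbol", function(x) standardGeneric("sgSymbol"))
#' @rdname sfxsad-accessors
#' @export
setGeneric("symOps", function(x) standardGeneric("symOps"))
#' @rdname sfxsad-accessors
#' @export
setGeneric("laueOps", function(x) standardGeneric("laueOps"))
#' @rdname sfxsad-accessors
#' @export
setGeneric("atoms", function(x) standardGeneric("atoms"))
#' @rdname sfxsad-accessors
#' @export
setGeneric("anomalousSites", function(x) standardGeneric("anomalousSites"))
#' @rdname sfxsad-accessors
#' @export
setGeneric("observations", function(x) standardGeneric("observations"))
#' @rdname sfxsad-accessors
#' @export
setGeneric("crystals", function(x) standardGeneric("crystals"))
#' @rdname sfxsad-accessors
#' @export
setGeneric("groundTruth", function(x) standardGeneric("groundTruth"))
#' @rdname sfxsad-accessors
#' @export
setGeneric("beamOf", function(x) standardGeneric("beamOf"))
#' @rdname sfxsad-accessors
#' @export
setGeneric("reflections", function(x) standardGeneric("reflections"))
#' @rdname sfxsad-accessors
#' @export
setGeneric("provenance", function(x) standardGeneric("provenance"))
#' @rdname sfxsad-accessors
#' @export
setGeneric("mapValues", function(x) standardGeneric("mapValues"))
#' @rdname sfxsad-accessors
#' @export
setGeneric("mapRms", function(x) standardGeneric("mapRms"))
#' @rdname sfxsad-accessors
#' @export
setGeneric("shellTable", function(x) standardGeneric("shellTable"))
#' @rdname sfxsad-accessors
#' @export
setGeneric("overallStats", function(x) standardGeneric("overallStats"))
#' @rdname sfxsad-accessors
#' @export
setGeneric("scanTable", function(x) standardGeneric("scanTable"))
#' @rdname sfxsad-accessors
#' @export
setGeneric("optimalDistance", function(x) standardGeneric("optimalDistance"))
#' @rdname sfxsad-accessors
#' @export
setGeneric("curveTable", function(x) standardGeneric("curveTable"))
#' @rdname sfxsad-accessors
#' @export
setGeneric("thresholdCrossing", function(x) standardGeneric("thresholdCrossing"))

setMethod("cellLengths", "UnitCell", function(x) c(a = x@a, b = x@b, c = x@c))
setMethod("cellAngles", "UnitCell",
          function(x) c(alpha = x@alpha, beta = x@beta, gamma = x@gamma))
setMethod("cellVolume", "UnitCell", function(x) {
  ca <- cos(cellAngles(x) * pi / 180)
  x@a * x@b * x@c * sqrt(1 - sum(ca^2) + 2 * prod(ca))
})

setMethod("sgSymbol", "SpaceGroup", function(x) x@symbol)
setMethod("symOps", "SpaceGroup", function(x)
  list(rotations = x@rotations, translations = x@translations,
       centering = x@centering))
setMethod("laueOps", "SpaceGroup", function(x) x@laueRot)

setMethod("cellLengths", "StructureModel", function(x) cellLengths(x@cell))
setMethod("atoms", "StructureModel", function(x) x@atoms)
setMethod("anomalousSites", "StructureModel",
          function(x) x@atoms[x@atoms$anomalous, , drop = FALSE])

setMethod("observations", "StillDataset", function(x) x@observations)
setMethod("crystals", "StillDataset", function(x) x@crystals)
setMethod("groundTruth", "StillDataset", function(x) x@truth)
setMethod("beamOf", "StillDataset", function(x) x@beam)

setMethod("reflections", "MergedDataset", function(x) x@reflections)
setMethod("provenance", "MergedDataset", function(x) x@provenance)

setMethod("mapValues", "MapGrid", function(x) x@values)
setMethod("mapRms", "MapGrid", function(x) x@rms)

setMethod("shellTable", "QualityReport", function(x) x@shells)
setMethod("overallStats", "QualityReport", function(x) x@overall)

setMethod("scanTable", "DistanceScanResult", function(x) x@table)
setMethod("optimalDistance", "DistanceScanResult", function(x) x@optimal)

setMethod("curveTable", "SanoCurve", function(x) x@curve)
setMethod("thresholdCrossing", "SanoCurve", function(x) x@crossing)

## show methods -------------------------------------------------------------

setMethod("show", "UnitCell", function(object) {
  cat(sprintf("UnitCell: a=%.4g b=%.4g c=%.4g  alpha=%.4g beta=%.4g gamma=%.4g\n",
              object@a, object@b, object@c,
              object@alpha, object@beta, object@gamma))
})

setMethod("show", "SpaceGroup", function(object) {
  cat(sprintf("SpaceGroup %s (no. %d): %d symops, %d laue rotations, %d centering vector(s)\n",
              object@symbol, object@number, length(object@rotations),
              length(object@laueRot), length(object@centering)))
})

setMethod("show", "StructureModel", function(object) {
  at <- object@atoms
  cat(sprintf("StructureModel: %d atoms (%s), %d anomalous site(s), %s\n",
              nrow(at),
              paste(sprintf("%s:%d", names(table(at$element)),
                            as.integer(table(at$element))), collapse = " "),
              sum(at$anomalous), object@spacegroup@symbol))
  show(object@cell)
})

setMethod("show", "BeamGeometry", function(object) {
  cat(sprintf("BeamGeometry: lambda=%.4g A, distance=%.4g mm, pixel=%.3g mm, extent=+-%.4g mm\n",
              object@wavelength, object@distance, object@pixel, object@extent))
})

setMethod("show", "StillDataset", function(object) {
  cat(sprintf("StillDataset: %d pattern(s), %d observation(s), dmin=%.3g A, %s\n",
              nrow(object@crystals), nrow(object@observations), object@dmin,
              object@spacegroup@symbol))
  show(object@beam)
  if (length(object@truth))
    cat(sprintf("  ground truth attached (true distance %.4g mm)\n",
                object@truth$distance))
})

setMethod("show", "MergedDataset", function(object) {
  rf <- object@reflections
  cat(sprintf("MergedDataset: %d records (%d I+, %d I-), %s, d range %.3g-%.3g A\n",
              nrow(rf), sum(rf$side > 0), sum(rf$side < 0),
              object@spacegroup@symbol,
              if (nrow(rf)) max(rf$d) else NA, if (nrow(rf)) min(rf$d) else NA))
})

setMethod("show", "MapGrid", function(object) {
  dm <- dim(object@values)
  cat(sprintf("MapGrid: %d x %d x %d grid, %d coefficients, rms=%.4g (values in rms units)\n",
              dm[1], dm[2], dm[3], length(object@coeffF), object@rms))
})

setMethod("show", "DistanceScanResult", function(object) {
  cat(sprintf("DistanceScanResult: %d candidate distances (step %.4g mm), optimum %.4f mm\n",
              nrow(object@table), object@step, object@optimal))
})

setMethod("show", "QualityReport", function(object) {
  ov <- object@overall
  cat("QualityReport (overall, highest shell in parentheses)\n")
  hs <- object@shells[nrow(object@shells), ]
  fmt <- function(v, vs, digits = 3)
    sprintf(paste0("%.", digits, "f (%.", digits, "f)"), v, vs)
  cat(sprintf("  Resolution (A)      %.2f-%.2f (%.2f-%.2f)\n",
              ov$dMax, ov$dMin, hs$dMax, hs$dMin))
  cat(sprintf("  Completeness (%%)    %s\n", fmt(ov$completeness, hs$completeness, 1)))
  cat(sprintf("  Redundancy          %s\n", fmt(ov$redundancy, hs$redundancy, 1)))
  cat(sprintf("  CC_1/2              %s\n", fmt(ov$cc12, hs$cc12)))
  cat(sprintf("  CC*                 %s\n", fmt(ov$ccStar, hs$ccStar)))
  cat(sprintf("  CC_ano              %s\n", fmt(ov$ccAno, hs$ccAno)))
  cat(sprintf("  <I/sigma(I)>        %s\n", fmt(ov$meanIsig, hs$meanIsig, 2)))
  cat(sprintf("  R_split (%%)         %s\n", fmt(ov$rSplit, hs$rSplit, 2)))
  cat(sprintf("  Unique reflections  %d\n", ov$nUnique))
})

setMethod("show", "SanoCurve", function(object) {
  cat(sprintf("SanoCurve: %d sizes, threshold %.3g, crossing at n = %s (%s)\n",
              nrow(object@curve), object@threshold,
              if (is.na(object@crossing)) "NA" else
                sprintf("%.0f", object@crossing), object@status))
})
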