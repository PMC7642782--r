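#' Published image counts of de novo phasing serial-crystallography studies
#'
#' Minimal image counts reported by published sulfur-SAD serial
#' crystallography studies of the two model systems handled by this
#' package, together with their beam energies and sulfur f'' values.  The
#' table supports back-of-envelope comparisons, e.g. the image-count
#' reduction between facilities or photon energies for the same sample.
#'
#' @return data.frame: sample, facility, photonEnergyKeV, fDoublePrime,
#'   nImages, resolutionA
#' @examples
#' tb <- sadStudyImageCounts()
#' ## tenfold reduction for the membrane-protein target:
#' tb$nImages[tb$sample == "A2A" & tb$facility == "LCLS"] /
#'   tb$nImages[tb$sample == "A2A" & tb$facility == "SwissFEL"]
#' @export
sadStudyImageCounts <- function() {
  data.frame(
    sample = c("A2A", "A2A", "thaumatin", "thaumatin"),
    facility = c("SwissFEL", "LCLS", "SwissFEL", "SwissFEL"),
    photonEnergyKeV = c(4.57, 6.0, 4.57, 6.06),
    fDoublePrime = c(1.51, NA, 1.51, 0.95),
    nImages = c(50000, 500000, 20000, 50000),
    resolutionA = c(2.65, 2.5, 2.65, 1.95))
}
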