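## Anomalous-signal extraction: Bijvoet differences, the Bijvoet-ratio
## estimate, phased anomalous difference Fourier maps, S_ano and the
## image-count subsampling study.

#' Observed (and calculated) Bijvoet differences from a merged dataset
#'
#' Amplitudes are taken as F = sqrt(max(I, 0)) per Bijvoet side (no
#' French-Wilson treatment); delta_F_obs = F+ - F-.  Sigma follows
#' first-order propagation, sigma_F = sigma_I / (2F) for F > 0 and
#' sqrt(sigma_I) for truncated sides (an inflated placeholder that keeps
#' the reflection usable).  When a model is supplied, the calculated
#' anomalous differences |F+| - |F-| and the Bijvoet-averaged model phase
#' are attached.
#'
#' @param merged a [MergedDataset-class] with separated Bijvoet sides
#' @param model optional [StructureModel-class] supplying delta_F_calc and
#'   phases
#' @return data.frame: h, k, l, d, dFobs, sigDF, and with a model dFcalc,
#'   phi (radians)
#' @export
bijvoetDifferences <- function(merged, model = NULL) {
  b <- .bijvoetTable(merged)
  fP <- sqrt(pmax(b$iPlus, 0)); fM <- sqrt(pmax(b$iMinus, 0))
  sP <- ifelse(fP > 0, b$sPlus / (2 * fP), sqrt(abs(b$sPlus)))
  sM <- ifelse(fM > 0, b$sMinus / (2 * fM), sqrt(abs(b$sMinus)))
  out <- data.frame(h = b$h, k = b$k, l = b$l, d = b$d,
                    dFobs = fP - fM, sigDF = sqrt(sP^2 + sM^2))
  if (!is.null(model)) {
    ma <- modelAnomalous(model, as.matrix(b[, c("h", "k", "l")]))
    out$dFcalc <- ma$dFcalc
    out$phi <- ma$phi
  }
  out
}

#' Expected Bijvoet ratio of a crystal (percent)
#'
#' Rule-of-thumb estimate of <|delta F|>/<F> for an anomalous substructure
#' of `nAnom` sites with imaginary scattering correction `fDoublePrime` in
#' a structure of `nTotalNonH` non-hydrogen atoms of effective normal
#' scattering power `zEff` electrons:
#' 100 * sqrt(2 nAnom) * f'' / (sqrt(nTotalNonH) * zEff).
#'
#' @param nAnom number of anomalous scatterers
#' @param fDoublePrime imaginary anomalous correction (electrons)
#' @param nTotalNonH total non-hydrogen atom count
#' @param zEff effective scattering power per atom (electrons; default 6.7,
#'   a protein-average value)
#' @return Bijvoet ratio in percent
#' @examples
#' bijvoetRatioEstimate(17, 1.51, 1558)   # thaumatin-like at 4.57 keV
#' @export
bijvoetRatioEstimate <- function(nAnom, fDoublePrime, nTotalNonH,
                                 zEff = 6.7) {
  stopifnot(nAnom >= 0, fDoublePrime >= 0)
  if (nTotalNonH <= 0) stop("nTotalNonH must be > 0")
  if (nAnom == 0) return(0)
  100 * sqrt(2 * nAnom) * fDoublePrime / (sqrt(nTotalNonH) * zEff)
}

## Expand ASU anomalous difference coefficients to the full sphere.
## Coefficients transform like structure factors, C(hR) = C(h) e^{-2pi i h.t},
## and Friedel completion C(-h) = conj(C(h)) keeps the map real.
.expandCoeffs <- function(spacegroup, H, C) {
  rot <- spacegroup@rotations
  trs <- spacegroup@translations
  n <- nrow(H)
  outH <- vector("list", 2 * length(rot))
  outC <- vector("list", 2 * length(rot))
  for (s in seq_along(rot)) {
    Hs <- H %*% rot[[s]]
    Cs <- C * exp(complex(imaginary = -2 * pi * as.numeric(H %*% trs[[s]])))
    outH[[2 * s - 1]] <- Hs;  outC[[2 * s - 1]] <- Cs
    outH[[2 * s]] <- -Hs;     outC[[2 * s]] <- Conj(Cs)
  }
  allH <- do.call(rbind, outH)
  allC <- do.call(c, outC)
  keep <- !duplicated(.hklKey(allH))
  list(H = allH[keep, , drop = FALSE], C = allC[keep])
}

## S_ano by direct Fourier summation at exact fractional coordinates,
## normalized by the Parseval rms of the synthesis
.sAnoDirect <- function(spacegroup, cell, H, C, sites) {
  ex <- .expandCoeffs(spacegroup, H, C)
  V <- cellVolume(cell)
  rms <- sqrt(sum(Mod(ex$C)^2)) / V
  if (rms == 0) return(list(heights = rep(0, nrow(sites)), rms = 0))
  ph <- ex$H %*% t(sites)                  # nCoeff x nSites
  heights <- vapply(seq_len(nrow(sites)), function(j)
    Re(sum(ex$C * exp(complex(imaginary = -2 * pi * ph[, j])))) / V,
    numeric(1))
  list(heights = heights / rms, rms = rms)
}

#' Phased anomalous difference Fourier map
#'
#' Fourier synthesis with coefficients dF * exp(i(phi - pi/2)) on the
#' asymmetric-unit reflections, expanded to the full sphere by the
#' space-group operators and Friedel completion, evaluated by FFT on a
#' grid covering one unit cell.  Output values are in units of the map
#' rms; positive peaks at anomalous-scatterer positions measure the
#' anomalous signal.
#'
#' @param diffs data.frame from [bijvoetDifferences()] with model phases
#'   (columns h, k, l, dFobs — or `dF` — and phi)
#' @param spacegroup a [SpaceGroup-class]
#' @param cell a [UnitCell-class]
#' @param spacing target grid spacing (Angstrom); the grid is chosen fine
#'   enough for the data (at least d_min/3 sampling) and alias-free
#' @param dFColumn which column holds the difference amplitudes
#' @return a [MapGrid-class]
#' @export
anomalousDifferenceMap <- function(diffs, spacegroup, cell, spacing = NULL,
                                   dFColumn = "dFobs") {
  if (!nrow(diffs)) stop("empty coefficient set")
  if (!all(c("phi", dFColumn) %in% names(diffs)))
    stop("diffs must carry model phases (phi) and ", dFColumn)
  H <- as.matrix(diffs[, c("h", "k", "l")])
  dF <- diffs[[dFColumn]]
  C <- complex(modulus = abs(dF),
               argument = diffs$phi - pi / 2 + ifelse(dF < 0, pi, 0))
  ex <- .expandCoeffs(spacegroup, H, C)
  dmin <- min(dSpacing(cell, H))
  if (is.null(spacing)) spacing <- dmin / 3
  spacing <- min(spacing, dmin / 3)
  len <- cellLengths(cell)
  hmax <- apply(abs(ex$H), 2, max)
  dims <- pmax(ceiling(len / spacing), 2 * hmax + 2)
  dims <- as.integer(2 * ceiling(dims / 2))
  A <- array(0i, dims)
  idx <- sweep(ex$H, 2, dims, "%%") + 1
  A[cbind(idx[, 1], idx[, 2], idx[, 3])] <- ex$C
  V <- cellVolume(cell)
  rho <- Re(fft(A)) / V                    # rho(x) = (1/V) sum C e^{-2pi i hx}
  rms <- sqrt(mean(rho^2))
  vals <- if (rms > 0) rho / rms else rho
  new("MapGrid", values = vals, rms = rms, cell = cell, spacing = spacing,
      coeffH = ex$H, coeffF = ex$C)
}

#' Anomalous signal strength S_ano
#'
#' Mean height of the phased anomalous difference Fourier map at the
#' anomalous-scatterer positions, in map-rms units, evaluated by direct
#' Fourier summation at the exact fractional coordinates (not grid
#' interpolation).  Values of ~10 or more indicate that SAD phasing is
#' typically feasible.
#'
#' @param map a [MapGrid-class] from [anomalousDifferenceMap()]
#' @param sites n x 3 matrix of fractional coordinates (or a
#'   [StructureModel-class], whose anomalous sites are used)
#' @return mean site height in rms units; the per-site heights are
#'   attached as attribute `"heights"`
#' @export
sAno <- function(map, sites) {
  if (is(sites, "StructureModel"))
    sites <- as.matrix(anomalousSites(sites)[, c("x", "y", "z")])
  if (is.null(dim(sites))) sites <- matrix(sites, ncol = 3)
  if (!nrow(sites)) stop("need at least one site")
  V <- cellVolume(map@cell)
  rms <- sqrt(sum(Mod(map@coeffF)^2)) / V
  if (rms == 0) return(structure(0, heights = rep(0, nrow(sites))))
  ph <- map@coeffH %*% t(sites)
  heights <- vapply(seq_len(nrow(sites)), function(j)
    Re(sum(map@coeffF * exp(complex(imaginary = -2 * pi * ph[, j])))) / V,
    numeric(1)) / rms
  structure(mean(heights), heights = heights)
}

#' Model-versus-data anomalous correlation
#'
#' Pearson correlation between the observed and the calculated anomalous
#' difference amplitudes, |dF_obs| vs |dF_calc|, overall and per
#' resolution shell.
#'
#' @param diffs data.frame from [bijvoetDifferences()] with a model
#' @param scheme optional [shellScheme()]
#' @return list: `overall`, `shells` (numeric vector or NULL)
#' @export
ccAnoModelVsData <- function(diffs, scheme = NULL) {
  if (is.null(diffs$dFcalc))
    stop("diffs must carry dFcalc (supply a model to bijvoetDifferences)")
  x <- abs(diffs$dFobs); y <- abs(diffs$dFcalc)
  list(overall = safeCor(x, y),
       shells = .perShell(scheme, diffs$d,
                          function(ii) safeCor(x[ii], y[ii])))
}

#' S_ano as a function of the number of merged images
#'
#' Draws a seeded random ordering of the patterns, merges nested subsets
#' of increasing size, and computes S_ano for each; the image count at
#' which the curve crosses the phasing-feasibility threshold is estimated
#' by linear interpolation between the bracketing sizes.
#'
#' @param dataset a [StillDataset-class]
#' @param sizes increasing image counts (each <= number of patterns)
#' @param config a [mergeConfig()]
#' @param model a [StructureModel-class] supplying phases and sites
#' @param seed seed for the pattern ordering
#' @param threshold S_ano level to locate (default 10)
#' @return a [SanoCurve-class]
#' @export
subsampleStudy <- function(dataset, sizes, config = mergeConfig(),
                           model = NULL, seed = 1, threshold = 10) {
  if (is.null(model)) model <- dataset@truth$model
  if (is.null(model)) stop("a structure model is required for phases")
  sizes <- sort(unique(as.integer(sizes)))
  ids <- dataset@crystals$id
  if (any(sizes > length(ids)))
    stop("subsample sizes exceed the number of patterns")
  ord <- withSeed(seed, sample(ids))
  sites <- as.matrix(anomalousSites(model)[, c("x", "y", "z")])
  sA <- vapply(sizes, function(n) {
    sub <- subsetPatterns(dataset, ord[seq_len(n)])
    merged <- runMerge(sub, config)
    diffs <- bijvoetDifferences(merged, model)
    if (!nrow(diffs)) return(NA_real_)
    C <- complex(modulus = abs(diffs$dFobs),
                 argument = diffs$phi - pi / 2 + ifelse(diffs$dFobs < 0, pi, 0))
    .sAnoDirect(dataset@spacegroup, dataset@cell,
                as.matrix(diffs[, c("h", "k", "l")]), C, sites)$heights |>
      mean()
  }, numeric(1))
  curve <- data.frame(nImages = sizes, sAno = sA)
  cross <- NA_real_; status <- "not_reached"
  fin <- which(is.finite(sA))
  if (length(fin)) {
    above <- sA >= threshold
    if (isTRUE(above[fin[1]])) {
      status <- "below_range"; cross <- sizes[fin[1]]
    } else {
      for (i in head(fin, -1)) {
        i2 <- fin[fin > i][1]
        if (!isTRUE(above[i]) && isTRUE(above[i2])) {
          cross <- sizes[i] + (threshold - sA[i]) *
            (sizes[i2] - sizes[i]) / (sA[i2] - sA[i])
          status <- "crossed"
          break
        }
      }
    }
  }
  new("SanoCurve", curve = curve, threshold = threshold,
      crossing = cross, status = status)
}
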