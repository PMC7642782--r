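## Detector-distance optimization.  The statistic mirrors the serial-
## crystallography practice of indexing the same data at a grid of assumed
## distances and choosing the distance that minimizes the spread of the
## per-pattern unit-cell estimates; index assignment itself is taken from
## the simulator's stored Miller indices (an "oracle indexer"), isolating
## the geometry statistic from any particular autoindexing algorithm.

.familyOf <- function(spacegroup) {
  switch(sgSymbol(spacegroup),
         P41212 = "tetragonal", C2221 = "orthorhombic", P1 = "orthorhombic")
}

.cellDesign <- function(h, k, l, family) {
  switch(family,
         tetragonal = cbind(hk = h^2 + k^2, l2 = l^2),
         orthorhombic = cbind(h2 = h^2, k2 = k^2, l2 = l^2),
         stop("unsupported lattice family: ", family))
}

#' Fit cell lengths of one pattern from spot positions
#'
#' Recomputes |q| for every observation from its spot position at an
#' assumed detector distance (elastic unprojection), then solves the linear
#' least-squares problem d*^2 = (h^2+k^2)/a^2 + l^2/c^2 (tetragonal) or
#' h^2/a^2 + k^2/b^2 + l^2/c^2 (orthorhombic) for the reciprocal squared
#' lengths.  A pattern counts as indexed when all fitted reciprocal squares
#' are positive and the rms relative residual is below `gate`.
#'
#' @param obs data.frame with columns h, k, l, x, y (one pattern); when an
#'   `r` column (the predicted excitation error carried by the stream
#'   record for each reflection) is present it is used for the exact
#'   off-sphere correction
#' @param assumedDistance detector distance used for unprojection (mm)
#' @param beam a [BeamGeometry-class]
#' @param family "tetragonal" or "orthorhombic"
#' @param gate rms relative residual below which the fit counts as indexed
#' @param profileRadius optional profile radius R of the pattern (1/A),
#'   used as a fallback when no per-reflection excitation errors are
#'   available.  Spots sit off the Ewald sphere by their excitation error
#'   r, and the elastic unprojection obeys exactly
#'   q_hat^2 = (q^2 - r^2)/(1 + lambda r); with the recorded r the
#'   inversion q^2 = q_hat^2 (1 + lambda r) + r^2 is exact, while with r
#'   only known to be uniform in (-R, R) the unbiased estimate is
#'   (q_hat^2 + R^2/3)/(1 + lambda^2 R^2/3).  Without either correction
#'   the recovered detector distance is systematically shifted by the
#'   order of 100 micrometres.
#' @return list: a, b, c (Angstrom; NA when not indexable), residual,
#'   indexed
#' @export
fitCellLengths <- function(obs, assumedDistance, beam,
                           family = c("tetragonal", "orthorhombic"),
                           gate = 1e-3, profileRadius = NULL) {
  family <- match.arg(family)
  X <- .cellDesign(obs$h, obs$k, obs$l, family)
  if (nrow(X) < ncol(X) || qr(X)$rank < ncol(X))
    stop("rank-deficient reflection set: cannot fit ", ncol(X),
         " cell parameters")
  rho <- sqrt((obs$x - beam@center[1])^2 + (obs$y - beam@center[2])^2)
  yv <- qMagFromRadius(rho, assumedDistance, beam@wavelength)^2
  if (!is.null(obs$r)) {
    yv <- yv * (1 + beam@wavelength * obs$r) + obs$r^2
  } else if (!is.null(profileRadius)) {
    yv <- (yv + profileRadius^2 / 3) /
      (1 + beam@wavelength^2 * profileRadius^2 / 3)
  }
  beta <- solve(crossprod(X), crossprod(X, yv))
  fit <- as.numeric(X %*% beta)
  residual <- sqrt(mean(((fit - yv) / yv)^2))
  if (any(beta <= 0))
    return(list(a = NA_real_, b = NA_real_, c = NA_real_,
                residual = residual, indexed = FALSE))
  len <- 1 / sqrt(beta)
  out <- if (family == "tetragonal") c(len[1], len[1], len[2])
         else c(len[1], len[2], len[3])
  list(a = out[1], b = out[2], c = out[3], residual = residual,
       indexed = residual < gate)
}

## Fit all patterns at one distance; returns a data.frame.  `prep` comes
## from .scanPrep (pre-split observations with fixed design matrices).
.fitAll <- function(prep, distance, wavelength, gate) {
  res <- lapply(prep, function(p) {
    yv <- qMagFromRadius(p$rho, distance, wavelength)^2 *
      (1 + wavelength * p$r) + p$r^2
    beta <- tryCatch(solve(p$xtx, crossprod(p$X, yv)),
                     error = function(e) NULL)
    if (is.null(beta))
      return(c(NA_real_, NA_real_, NA_real_, Inf))
    fit <- as.numeric(p$X %*% beta)
    residual <- sqrt(mean(((fit - yv) / yv)^2))
    if (any(beta <= 0)) return(c(NA_real_, NA_real_, NA_real_, residual))
    len <- 1 / sqrt(beta)
    if (length(len) == 2L) len <- c(len[1], len[1], len[2])
    c(len, residual)
  })
  m <- do.call(rbind, res)
  data.frame(a = m[, 1], b = m[, 2], c = m[, 3], residual = m[, 4],
             indexed = is.finite(m[, 4]) & m[, 4] < gate & !is.na(m[, 1]))
}

.scanPrep <- function(dataset, family) {
  obs <- dataset@observations
  beam <- dataset@beam
  rho <- sqrt((obs$x - beam@center[1])^2 + (obs$y - beam@center[2])^2)
  sp <- split(data.frame(h = obs$h, k = obs$k, l = obs$l, rho = rho,
                         r = obs$r),
              obs$pattern_id)
  lapply(sp, function(o) {
    X <- .cellDesign(o$h, o$k, o$l, family)
    list(X = X, xtx = crossprod(X), rho = o$rho, r = o$r)
  })
}

#' Scan candidate detector distances
#'
#' For every distance on a uniform grid, all patterns are refit and the
#' standard deviation of each fitted cell length over indexed patterns is
#' recorded together with the indexed fraction.  The optimal distance is
#' the argmin of the c-length standard deviation (ties resolve to the
#' smaller distance).
#'
#' @param dataset a [StillDataset-class]
#' @param center center of the scan grid (mm); defaults to the header
#'   distance
#' @param halfRange half-width of the grid (mm)
#' @param step grid increment (mm); default 0.020 (20 micrometres)
#' @param gate residual gate for counting a pattern as indexed
#' @return a [DistanceScanResult-class]
#' @export
distanceScan <- function(dataset, center = NULL, halfRange = 0.5,
                         step = 0.020, gate = 1e-3) {
  stopifnot(step > 0)
  if (is.null(center)) center <- dataset@beam@distance
  distances <- seq(center - halfRange, center + halfRange, by = step)
  if (length(distances) < 3) stop("scan grid must cover at least 3 points")
  family <- .familyOf(dataset@spacegroup)
  prep <- .scanPrep(dataset, family)
  if (!length(prep)) stop("dataset has no patterns to scan")
  rows <- lapply(distances, function(D) {
    f <- .fitAll(prep, D, dataset@beam@wavelength, gate)
    idx <- f$indexed
    data.frame(distance = D,
               sdA = if (sum(idx) >= 2) sd(f$a[idx]) else NA_real_,
               sdB = if (sum(idx) >= 2) sd(f$b[idx]) else NA_real_,
               sdC = if (sum(idx) >= 2) sd(f$c[idx]) else NA_real_,
               rate = mean(idx))
  })
  tab <- do.call(rbind, rows)
  if (all(tab$rate == 0)) stop("no pattern indexed at any candidate distance")
  best <- which.min(tab$sdC)        # ties: which.min takes the first, i.e.
                                    # the smaller distance on an ascending grid
  new("DistanceScanResult", table = tab, optimal = tab$distance[best],
      step = step)
}

#' Reprocess observation geometry at an assumed detector distance
#'
#' Emulates re-indexing at a different distance: each pattern's cell is
#' refit at the assumed distance, d-spacings are recomputed from the fitted
#' cell, and the excitation error is re-estimated from the radial offset
#' between the observed spot and the fitted lattice point,
#' r = 2 (d*_fit - |q_spot|) / (lambda d*_fit), the first-order relation
#' between radial displacement and Ewald-sphere offset for a still.
#' Patterns that fail the fit keep their stored geometry.
#'
#' @param dataset a [StillDataset-class]
#' @param distance assumed distance (mm)
#' @param gate residual gate (as in [distanceScan()])
#' @return a [StillDataset-class] with updated r and d columns
#' @export
reprocessAtDistance <- function(dataset, distance, gate = 1e-3) {
  family <- .familyOf(dataset@spacegroup)
  obs <- dataset@observations
  beam <- dataset@beam
  rho <- sqrt((obs$x - beam@center[1])^2 + (obs$y - beam@center[2])^2)
  qhat <- qMagFromRadius(rho, distance, beam@wavelength)
  newR <- obs$r
  newD <- obs$d
  for (pid in unique(obs$pattern_id)) {
    ii <- which(obs$pattern_id == pid)
    o <- obs[ii, ]
    f <- tryCatch(fitCellLengths(o, distance, beam, family, gate),
                  error = function(e) NULL)
    if (is.null(f) || !f$indexed) next
    dstar <- sqrt((o$h^2) / f$a^2 + (o$k^2) / f$b^2 + (o$l^2) / f$c^2)
    newR[ii] <- 2 * (dstar - qhat[ii]) / (beam@wavelength * dstar)
    newD[ii] <- 1 / dstar
  }
  obs$r <- newR
  obs$d <- newD
  initialize(dataset, observations = obs)
}
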