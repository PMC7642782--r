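## Half-dataset and per-shell data-quality statistics.

#' Resolution shell scheme
#'
#' `nShells` shells between `dMax` and `dMin`, with boundaries equally
#' spaced in d*^3 (equal reciprocal-space volume per shell).
#'
#' @param dMin high-resolution limit (Angstrom)
#' @param dMax low-resolution limit (Angstrom)
#' @param nShells number of shells (default 10)
#' @return list of class `ShellScheme` with element `edges` (d in
#'   Angstrom, decreasing, length nShells + 1)
#' @export
shellScheme <- function(dMin, dMax, nShells = 10) {
  stopifnot(dMin > 0, dMax > dMin, nShells >= 1)
  s3 <- seq(1 / dMax^3, 1 / dMin^3, length.out = nShells + 1)
  structure(list(edges = s3^(-1 / 3), nShells = as.integer(nShells),
                 dMin = dMin, dMax = dMax),
            class = c("ShellScheme", "list"))
}

## shell index of d-spacings (1 = lowest resolution); values outside the
## scheme clamp to the end shells
shellIndex <- function(scheme, d) {
  i <- findInterval(1 / d^3, seq(1 / scheme$dMax^3, 1 / scheme$dMin^3,
                                 length.out = scheme$nShells + 1),
                    rightmost.closed = TRUE)
  pmin(pmax(i, 1L), scheme$nShells)
}

#' Split a dataset into two half datasets by pattern
#'
#' Patterns are shuffled with a seeded permutation and assigned
#' alternately, giving two disjoint sets whose union is the full dataset.
#' All half-set statistics (R_split, CC_1/2, CC_ano) are defined over such
#' crystal-wise splits.
#'
#' @param dataset a [StillDataset-class] with >= 2 patterns
#' @param seed RNG seed for the shuffle
#' @return list with integer vectors `a` and `b` of pattern ids
#' @export
splitHalf <- function(dataset, seed = 1) {
  ids <- dataset@crystals$id
  if (length(ids) < 2) stop("need at least 2 patterns to split")
  perm <- withSeed(seed, sample(ids))
  list(a = sort(perm[seq(1, length(perm), by = 2)]),
       b = sort(perm[seq(2, length(perm), by = 2)]))
}

#' Merge the two halves of a dataset
#'
#' @param dataset a [StillDataset-class]
#' @param config a [mergeConfig()]
#' @param seed seed for the pattern split
#' @return list: `a`, `b` ([MergedDataset-class]), `split` (the id sets)
#' @export
mergeHalves <- function(dataset, config = mergeConfig(), seed = 1) {
  sp <- splitHalf(dataset, seed)
  list(a = runMerge(subsetPatterns(dataset, sp$a), config),
       b = runMerge(subsetPatterns(dataset, sp$b), config),
       split = sp)
}

## join two merged datasets on (asu hkl, side)
.joinHalves <- function(half1, half2) {
  r1 <- half1@reflections; r2 <- half2@reflections
  k1 <- .hklKey(as.matrix(r1[, c("h", "k", "l")])) * 2 + (r1$side > 0)
  k2 <- .hklKey(as.matrix(r2[, c("h", "k", "l")])) * 2 + (r2$side > 0)
  i <- match(k1, k2)
  ok <- !is.na(i)
  data.frame(h = r1$h[ok], k = r1$k[ok], l = r1$l[ok], side = r1$side[ok],
             d = r1$d[ok], I1 = r1$intensity[ok], I2 = r2$intensity[i[ok]])
}

.perShell <- function(scheme, d, fun) {
  if (is.null(scheme)) return(NULL)
  idx <- shellIndex(scheme, d)
  vapply(seq_len(scheme$nShells), function(s) fun(which(idx == s)),
         numeric(1))
}

#' R_split between two half-dataset merges
#'
#' R_split = 100 * 2^(-1/2) * sum|I1 - I2| / (0.5 * sum(I1 + I2)) over the
#' common (ASU, Friedel side) records; the overall value pools sums over
#' all common reflections rather than averaging shells.
#'
#' @param half1,half2 [MergedDataset-class] objects
#' @param scheme optional [shellScheme()] for per-shell values
#' @return list: `overall` (%), `shells` (numeric vector or NULL)
#' @export
rSplit <- function(half1, half2, scheme = NULL) {
  j <- .joinHalves(half1, half2)
  if (!nrow(j)) stop("no common reflections between halves")
  rs <- function(ii) {
    den <- 0.5 * sum(j$I1[ii] + j$I2[ii])
    if (length(ii) == 0 || den == 0) return(NA_real_)
    100 / sqrt(2) * sum(abs(j$I1[ii] - j$I2[ii])) / den
  }
  list(overall = rs(seq_len(nrow(j))),
       shells = .perShell(scheme, j$d, rs))
}

#' CC_1/2 and CC* between two half-dataset merges
#'
#' Pearson correlation of the two half intensities; CC* =
#' sqrt(2 CC / (1 + CC)) extrapolates to the full dataset (undefined and
#' reported NA for CC <= 0).
#'
#' @inheritParams rSplit
#' @return list: `cc12`, `ccStar` (overall), `shells` data.frame or NULL
#' @export
ccHalf <- function(half1, half2, scheme = NULL) {
  j <- .joinHalves(half1, half2)
  ccs <- function(ii) safeCor(j$I1[ii], j$I2[ii])
  star <- function(cc) {
    if (is.na(cc) || 2 * cc / (1 + cc) < 0) return(NA_real_)
    sqrt(2 * cc / (1 + cc))
  }
  cc <- ccs(seq_len(nrow(j)))
  shells <- NULL
  if (!is.null(scheme)) {
    v <- .perShell(scheme, j$d, ccs)
    shells <- data.frame(cc12 = v, ccStar = vapply(v, star, numeric(1)))
  }
  list(cc12 = cc, ccStar = star(cc), shells = shells)
}

## per-merge Bijvoet difference table: acentric reflections with both sides
.bijvoetTable <- function(merged) {
  rf <- merged@reflections
  key <- .hklKey(as.matrix(rf[, c("h", "k", "l")]))
  pos <- rf$side > 0
  i <- match(key[pos], key[!pos])
  ok <- !is.na(i)
  p <- which(pos)[ok]; m <- which(!pos)[i[ok]]
  data.frame(h = rf$h[p], k = rf$k[p], l = rf$l[p], d = rf$d[p],
             iPlus = rf$intensity[p], sPlus = rf$sigma[p],
             iMinus = rf$intensity[m], sMinus = rf$sigma[m])
}

#' Anomalous correlation between half datasets (CC_ano)
#'
#' Pearson correlation of the Bijvoet intensity differences (I+ - I-)
#' computed independently in each half, over acentric reflections with
#' both Bijvoet sides present in both halves.
#'
#' @inheritParams rSplit
#' @return list: `overall`, `shells` (numeric vector or NULL)
#' @export
ccAno <- function(half1, half2, scheme = NULL) {
  b1 <- .bijvoetTable(half1); b2 <- .bijvoetTable(half2)
  k1 <- .hklKey(as.matrix(b1[, c("h", "k", "l")]))
  k2 <- .hklKey(as.matrix(b2[, c("h", "k", "l")]))
  i <- match(k1, k2); ok <- !is.na(i)
  d1 <- b1$iPlus[ok] - b1$iMinus[ok]
  d2 <- b2$iPlus[i[ok]] - b2$iMinus[i[ok]]
  dd <- b1$d[ok]
  list(overall = safeCor(d1, d2),
       shells = .perShell(scheme, dd, function(ii) safeCor(d1[ii], d2[ii])))
}

#' Completeness and redundancy of a merged dataset
#'
#' Completeness compares the observed unique (ASU, Friedel side) records
#' against the theoretical count from [generateHkl()] (centric reflections
#' contribute one record, acentric two); redundancy is total measurements
#' over observed uniques.
#'
#' @param merged a [MergedDataset-class]
#' @param scheme a [shellScheme()]
#' @return list: `overall` (completeness %, redundancy) and `shells`
#'   data.frame (completeness, redundancy, nUnique, nTheoretical)
#' @export
completenessRedundancy <- function(merged, scheme) {
  theo <- generateHkl(merged@cell, merged@spacegroup, scheme$dMin)
  theo <- theo[theo$d <= scheme$dMax + 1e-9, , drop = FALSE]
  nTheo <- ifelse(theo$centric, 1L, 2L)
  rf <- merged@reflections
  inR <- rf$d >= scheme$dMin - 1e-9 & rf$d <= scheme$dMax + 1e-9
  rf <- rf[inR, , drop = FALSE]
  idxT <- shellIndex(scheme, theo$d)
  idxO <- shellIndex(scheme, rf$d)
  shT <- vapply(seq_len(scheme$nShells),
                function(s) sum(nTheo[idxT == s]), numeric(1))
  shO <- vapply(seq_len(scheme$nShells),
                function(s) sum(idxO == s), numeric(1))
  shM <- vapply(seq_len(scheme$nShells),
                function(s) sum(rf$nmeas[idxO == s]), numeric(1))
  shells <- data.frame(
    completeness = 100 * shO / pmax(shT, 1),
    redundancy = ifelse(shO > 0, shM / shO, NA_real_),
    nUnique = shO, nTheoretical = shT)
  list(overall = list(completeness = 100 * nrow(rf) / sum(nTheo),
                      redundancy = if (nrow(rf)) sum(rf$nmeas) / nrow(rf)
                                   else NA_real_),
       shells = shells)
}

#' Full data-quality report
#'
#' Merges the dataset (full and as two halves), then assembles the overall
#' and per-shell statistics reported for SFX datasets: R_split, CC_1/2,
#' CC*, CC_ano, mean I/sigma, completeness and redundancy.
#'
#' @param dataset a [StillDataset-class]
#' @param config a [mergeConfig()]
#' @param seed seed for the half split
#' @param nShells number of resolution shells
#' @return a [QualityReport-class]
#' @export
qualityReport <- function(dataset, config = mergeConfig(), seed = 1,
                          nShells = 10) {
  full <- runMerge(dataset, config)
  rf <- full@reflections
  scheme <- shellScheme(dataset@dmin, max(rf$d), nShells)
  halves <- mergeHalves(dataset, config, seed)
  rs <- rSplit(halves$a, halves$b, scheme)
  cch <- ccHalf(halves$a, halves$b, scheme)
  cca <- ccAno(halves$a, halves$b, scheme)
  cr <- completenessRedundancy(full, scheme)
  isig <- rf$intensity / rf$sigma
  idx <- shellIndex(scheme, rf$d)
  shIsig <- vapply(seq_len(nShells), function(s) {
    v <- isig[idx == s & is.finite(isig)]
    if (length(v)) mean(v) else NA_real_
  }, numeric(1))
  shN <- vapply(seq_len(nShells), function(s) sum(idx == s), numeric(1))
  edges <- scheme$edges
  shells <- data.frame(
    dMax = edges[-length(edges)], dMin = edges[-1],
    rSplit = rs$shells, cc12 = cch$shells$cc12, ccStar = cch$shells$ccStar,
    ccAno = cca$shells, meanIsig = shIsig,
    completeness = cr$shells$completeness,
    redundancy = cr$shells$redundancy, nUnique = shN)
  overall <- list(
    dMax = max(rf$d), dMin = dataset@dmin,
    rSplit = rs$overall, cc12 = cch$cc12, ccStar = cch$ccStar,
    ccAno = cca$overall, meanIsig = mean(isig[is.finite(isig)]),
    completeness = cr$overall$completeness,
    redundancy = cr$overall$redundancy,
    nUnique = nrow(rf), nObs = nrow(dataset@observations))
  new("QualityReport", overall = overall, shells = shells,
      meta = list(scheme = scheme, seed = seed, config = config))
}
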