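## The package's minimal stream dialect: a plain-text per-pattern container
## of indexed reflections (the stand-in for serial-crystallography stream
## output), plus a JSON-lines ground-truth sidecar.  Numeric fields are
## written at %.6g and the format round-trips at that precision.

.streamMagic <- "SFXSAD-STREAM 1"

#' Write a still dataset as a stream file
#'
#' Ground truth is never written into the stream itself; pass `truthPath`
#' to store it as a JSON-lines sidecar.
#'
#' @param dataset a [StillDataset-class]
#' @param path output stream path
#' @param truthPath optional path for the ground-truth sidecar
#' @return `path`, invisibly
#' @export
writeStream <- function(dataset, path, truthPath = NULL) {
  beam <- dataset@beam
  len <- cellLengths(dataset@cell); ang <- cellAngles(dataset@cell)
  con <- file(path, "w")
  on.exit(close(con))
  w <- function(...) cat(..., "\n", sep = "", file = con)
  w(.streamMagic)
  w("cell ", paste(num6(c(len, ang)), collapse = " "))
  w("spacegroup ", sgSymbol(dataset@spacegroup))
  w("wavelength ", num6(beam@wavelength))
  w("distance ", num6(beam@distance))
  w("pixel ", num6(beam@pixel))
  w("center ", paste(num6(beam@center), collapse = " "))
  w("extent ", num6(beam@extent))
  w("dmin ", num6(dataset@dmin))
  w("seed ", if (is.null(dataset@meta$seed)) "NA" else
      format(dataset@meta$seed))
  w("npatterns ", nrow(dataset@crystals))
  cr <- dataset@crystals
  obs <- dataset@observations
  sp <- split(seq_len(nrow(obs)), factor(obs$pattern_id, levels = cr$id))
  for (i in seq_len(nrow(cr))) {
    w("begin chunk")
    w("pattern ", cr$id[i])
    w("orientation ", paste(num6(as.numeric(cr[i, c(
      "o11", "o12", "o13", "o21", "o22", "o23", "o31", "o32", "o33")])),
      collapse = " "))
    w("cell_lengths ", paste(num6(c(cr$a[i], cr$b[i], cr$c[i])),
                             collapse = " "))
    w("profile_radius ", num6(cr$profileRadius[i]))
    ii <- sp[[i]]
    w("reflections ", length(ii))
    if (length(ii)) {
      o <- obs[ii, ]
      lines <- paste(o$h, o$k, o$l, num6(o$intensity), num6(o$sigma),
                     num6(o$partiality), num6(o$r), num6(o$x), num6(o$y))
      writeLines(lines, con)
    }
    w("end chunk")
  }
  if (!is.null(truthPath)) writeTruthSidecar(dataset, truthPath)
  invisible(path)
}

.parseErr <- function(lineNo, msg) stop("stream parse error at line ",
                                        lineNo, ": ", msg, call. = FALSE)

.headerVal <- function(lines, key, lineOffset = 0) {
  hit <- grep(paste0("^", key, " "), lines)
  if (!length(hit)) .parseErr(lineOffset + 1, paste0("missing header '", key, "'"))
  strsplit(sub(paste0("^", key, " +"), "", lines[hit[1]]), " +")[[1]]
}

#' Read a stream file
#'
#' @param path stream file path
#' @param truthPath optional sidecar path; when given, the ground truth is
#'   re-attached to the returned dataset
#' @return a [StillDataset-class] (truth empty unless `truthPath` given)
#' @export
readStream <- function(path, truthPath = NULL) {
  if (!file.exists(path)) stop("no such stream file: ", path)
  lines <- readLines(path)
  if (!length(lines) || lines[1] != .streamMagic)
    .parseErr(1, "not an sfxsad stream file")
  chunkStarts <- which(lines == "begin chunk")
  headEnd <- if (length(chunkStarts)) chunkStarts[1] - 1 else length(lines)
  head <- lines[seq_len(headEnd)]
  cellv <- as.numeric(.headerVal(head, "cell"))
  cell <- unitCell(cellv[1], cellv[2], cellv[3], cellv[4], cellv[5], cellv[6])
  sg <- spaceGroup(.headerVal(head, "spacegroup"))
  beam <- beamGeometry(as.numeric(.headerVal(head, "wavelength")),
                       as.numeric(.headerVal(head, "distance")),
                       as.numeric(.headerVal(head, "pixel")),
                       as.numeric(.headerVal(head, "center")),
                       as.numeric(.headerVal(head, "extent")))
  dmin <- as.numeric(.headerVal(head, "dmin"))
  seed <- suppressWarnings(as.numeric(.headerVal(head, "seed")))
  crList <- list(); obsList <- list()
  i <- headEnd + 1
  while (i <= length(lines)) {
    if (lines[i] == "") { i <- i + 1; next }
    if (lines[i] != "begin chunk") .parseErr(i, "expected 'begin chunk'")
    need <- function(j, what) if (j > length(lines))
      .parseErr(length(lines), paste0("truncated chunk: missing ", what))
    need(i + 1, "pattern id")
    pid <- suppressWarnings(as.integer(sub("^pattern +", "", lines[i + 1])))
    if (is.na(pid)) .parseErr(i + 1, "bad pattern id")
    need(i + 2, "orientation")
    ori <- suppressWarnings(as.numeric(strsplit(
      sub("^orientation +", "", lines[i + 2]), " +")[[1]]))
    if (length(ori) != 9 || anyNA(ori)) .parseErr(i + 2, "bad orientation")
    need(i + 3, "cell_lengths")
    cl <- suppressWarnings(as.numeric(strsplit(
      sub("^cell_lengths +", "", lines[i + 3]), " +")[[1]]))
    if (length(cl) != 3 || anyNA(cl)) .parseErr(i + 3, "bad cell lengths")
    need(i + 4, "profile radius")
    pr <- suppressWarnings(as.numeric(sub("^profile_radius +", "",
                                          lines[i + 4])))
    if (is.na(pr)) .parseErr(i + 4, "bad profile radius")
    need(i + 5, "reflection count")
    nref <- suppressWarnings(as.integer(sub("^reflections +", "",
                                            lines[i + 5])))
    if (is.na(nref)) .parseErr(i + 5, "bad reflection count")
    if (i + 5 + nref + 1 > length(lines))
      .parseErr(length(lines), "truncated chunk: reflection records")
    if (lines[i + 5 + nref + 1] != "end chunk")
      .parseErr(i + 5 + nref + 1, "expected 'end chunk'")
    crList[[length(crList) + 1]] <- c(pid, ori, cl, pr)
    if (nref > 0) {
      recs <- strsplit(lines[(i + 6):(i + 5 + nref)], " +")
      nf <- lengths(recs)
      if (any(nf != 9))
        .parseErr(i + 5 + which(nf != 9)[1], "malformed reflection record")
      m <- matrix(suppressWarnings(as.numeric(unlist(recs))),
                  nrow = nref, byrow = TRUE)
      if (anyNA(m))
        .parseErr(i + 6, "malformed reflection record")
      obsList[[length(obsList) + 1]] <- cbind(pid, m)
    }
    i <- i + 5 + nref + 2
  }
  crM <- do.call(rbind, crList)
  cr <- if (is.null(crM)) {
    data.frame(id = integer(), o11 = numeric(), o12 = numeric(),
               o13 = numeric(), o21 = numeric(), o22 = numeric(),
               o23 = numeric(), o31 = numeric(), o32 = numeric(),
               o33 = numeric(), a = numeric(), b = numeric(), c = numeric(),
               profileRadius = numeric(), nObs = integer())
  } else {
    d <- as.data.frame(crM)
    names(d) <- c("id", "o11", "o12", "o13", "o21", "o22", "o23",
                  "o31", "o32", "o33", "a", "b", "c", "profileRadius")
    d$id <- as.integer(d$id)
    d
  }
  obsM <- do.call(rbind, obsList)
  obs <- if (is.null(obsM)) {
    data.frame(pattern_id = integer(), h = integer(), k = integer(),
               l = integer(), intensity = numeric(), sigma = numeric(),
               partiality = numeric(), r = numeric(), x = numeric(),
               y = numeric(), d = numeric())
  } else {
    d <- as.data.frame(obsM)
    names(d) <- c("pattern_id", "h", "k", "l", "intensity", "sigma",
                  "partiality", "r", "x", "y")
    d$pattern_id <- as.integer(d$pattern_id)
    d$h <- as.integer(d$h); d$k <- as.integer(d$k); d$l <- as.integer(d$l)
    d$d <- dSpacing(cell, as.matrix(d[, c("h", "k", "l")]))
    d
  }
  cr$nObs <- as.integer(table(factor(obs$pattern_id, levels = cr$id)))
  ds <- new("StillDataset", beam = beam, cell = cell, spacegroup = sg,
            dmin = dmin, crystals = cr, observations = obs, truth = list(),
            meta = list(seed = seed))
  if (!is.null(truthPath)) ds@truth <- readTruthSidecar(truthPath)
  ds
}

#' Write the ground-truth sidecar
#'
#' JSON-lines: one record for the scalar truth (true detector distance,
#' seed), one for the per-crystal truth (scales, B factors, radii, cells),
#' one for the true squared structure factors and one for the anomalous
#' sites.
#'
#' @param dataset a [StillDataset-class] with attached truth
#' @param path output path
#' @return `path`, invisibly
#' @export
writeTruthSidecar <- function(dataset, path) {
  tr <- dataset@truth
  if (!length(tr)) stop("dataset carries no ground truth")
  con <- file(path, "w")
  on.exit(close(con))
  wl <- function(x) writeLines(toJSON(x, auto_unbox = TRUE, digits = NA), con)
  wl(list(type = "meta", distance = tr$distance, seed = tr$seed))
  crt <- tr$crystals
  wl(c(list(type = "crystals"),
       as.list(crt[, c("id", "a", "b", "c", "scale", "bFactor",
                       "profileRadius")])))
  f2 <- tr$f2
  wl(c(list(type = "f2"),
       as.list(f2[, c("h", "k", "l", "d", "centric", "iPlus", "iMinus")])))
  s <- tr$sites
  wl(list(type = "sites", x = s[, 1], y = s[, 2], z = s[, 3]))
  invisible(path)
}

#' Read a ground-truth sidecar
#'
#' @param path sidecar path
#' @return truth list (distance, crystals, f2, sites)
#' @export
readTruthSidecar <- function(path) {
  if (!file.exists(path)) stop("no such sidecar: ", path)
  recs <- lapply(readLines(path), fromJSON)
  types <- vapply(recs, `[[`, "", "type")
  getRec <- function(ty) recs[[match(ty, types)]]
  meta <- getRec("meta")
  crj <- getRec("crystals")
  cr <- data.frame(id = crj$id, a = crj$a, b = crj$b, c = crj$c,
                   scale = crj$scale, bFactor = crj$bFactor,
                   profileRadius = crj$profileRadius)
  fj <- getRec("f2")
  f2 <- data.frame(h = fj$h, k = fj$k, l = fj$l, d = fj$d,
                   centric = fj$centric, iPlus = fj$iPlus, iMinus = fj$iMinus)
  sj <- getRec("sites")
  list(distance = meta$distance, seed = meta$seed, crystals = cr, f2 = f2,
       sites = cbind(x = sj$x, y = sj$y, z = sj$z))
}
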