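## CCP4-style binary map output (standard 1024-byte header + float32 grid).

#' Write a map grid in CCP4 map format
#'
#' Writes the rms-normalized map values as MODE 2 (float32) with the
#' standard 256-word header, axis order X, Y, Z, covering one unit cell.
#'
#' @param map a [MapGrid-class]
#' @param path output path
#' @return `path`, invisibly
#' @export
writeCcp4Map <- function(map, path) {
  dm <- dim(map@values)
  len <- cellLengths(map@cell); ang <- cellAngles(map@cell)
  vals <- as.numeric(map@values)
  con <- file(path, "wb")
  on.exit(close(con))
  wInt <- function(x) writeBin(as.integer(x), con, size = 4, endian = "little")
  wFlt <- function(x) writeBin(as.numeric(x), con, size = 4, endian = "little")
  wInt(dm)                       # 1-3   NC NR NS
  wInt(2)                        # 4     MODE float32
  wInt(c(0, 0, 0))               # 5-7   start
  wInt(dm)                       # 8-10  intervals
  wFlt(c(len, ang))              # 11-16 cell
  wInt(c(1, 2, 3))               # 17-19 axis order
  wFlt(c(min(vals), max(vals), mean(vals)))  # 20-22
  wInt(1)                        # 23    ISPG (written as P1 grid)
  wInt(0)                        # 24    NSYMBT
  wInt(rep(0, 52 - 25 + 1))      # 25-52 reserved
  writeChar("MAP ", con, nchars = 4, eos = NULL)     # 53
  wInt(16708)                    # 54    little-endian machine stamp
  wFlt(sd(vals))                 # 55    RMS
  wInt(0)                        # 56    NLABL
  wInt(rep(0, 200))              # 57-256 labels
  wFlt(vals)
  invisible(path)
}

#' Table of map heights at site positions
#'
#' @param map a [MapGrid-class]
#' @param sites n x 3 matrix of fractional coordinates or a
#'   [StructureModel-class]
#' @return data.frame: x, y, z, height (rms units)
#' @export
siteHeights <- function(map, sites) {
  if (is(sites, "StructureModel"))
    sites <- as.matrix(anomalousSites(sites)[, c("x", "y", "z")])
  h <- attr(sAno(map, sites), "heights")
  data.frame(x = sites[, 1], y = sites[, 2], z = sites[, 3], height = h)
}
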