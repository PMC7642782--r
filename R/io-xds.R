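## XDS_ASCII-style merged reflection files: the interchange format for
## merged intensities with Bijvoet mates as signed-index records.

#' Write a merged dataset in XDS_ASCII style
#'
#' I+ records are written as (h, k, l), I- records as (-h, -k, -l);
#' FRIEDEL'S_LAW=FALSE.  Space-group numbers follow the package's three
#' groups (1, 92, 20).
#'
#' @param merged a non-empty [MergedDataset-class]
#' @param path output path
#' @return `path`, invisibly
#' @export
writeXdsAscii <- function(merged, path) {
  rf <- merged@reflections
  if (!nrow(rf)) stop("refusing to write an empty merged dataset")
  len <- cellLengths(merged@cell); ang <- cellAngles(merged@cell)
  con <- file(path, "w")
  on.exit(close(con))
  w <- function(...) cat(..., "\n", sep = "", file = con)
  w("!FORMAT=XDS_ASCII    MERGE=TRUE    FRIEDEL'S_LAW=FALSE")
  w("!SPACE_GROUP_NUMBER=", merged@spacegroup@number)
  w("!UNIT_CELL_CONSTANTS=", paste(sprintf("%10.4f", c(len, ang)),
                                   collapse = ""))
  w("!NUMBER_OF_ITEMS_IN_EACH_DATA_RECORD=5")
  w("!ITEM_H=1")
  w("!ITEM_K=2")
  w("!ITEM_L=3")
  w("!ITEM_IOBS=4")
  w("!ITEM_SIGMA(IOBS)=5")
  w("!END_OF_HEADER")
  sgn <- ifelse(rf$side > 0, 1L, -1L)
  writeLines(sprintf("%6d%6d%6d %.4e %.4e", sgn * rf$h, sgn * rf$k,
                     sgn * rf$l, rf$intensity, rf$sigma), con)
  w("!END_OF_DATA")
  invisible(path)
}

#' Read an XDS_ASCII-style reflection file
#'
#' Records are mapped back to (ASU, Friedel side) using the header space
#' group; `nmeas` is not stored in the format and is set to 1.
#'
#' @param path file path
#' @return a [MergedDataset-class]
#' @export
readXdsAscii <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  hEnd <- match("!END_OF_HEADER", lines)
  if (is.na(hEnd)) stop("not an XDS_ASCII file (no !END_OF_HEADER): ", path)
  head <- lines[seq_len(hEnd)]
  sgLine <- grep("^!SPACE_GROUP_NUMBER=", head, value = TRUE)
  cellLine <- grep("^!UNIT_CELL_CONSTANTS=", head, value = TRUE)
  if (!length(sgLine) || !length(cellLine))
    stop("XDS_ASCII header lacks space group or cell: ", path)
  sg <- sgFromNumber(as.integer(sub("^!SPACE_GROUP_NUMBER= *", "", sgLine[1])))
  cv <- as.numeric(strsplit(trimws(
    sub("^!UNIT_CELL_CONSTANTS=", "", cellLine[1])), " +")[[1]])
  cell <- unitCell(cv[1], cv[2], cv[3], cv[4], cv[5], cv[6])
  dEnd <- match("!END_OF_DATA", lines)
  if (is.na(dEnd)) dEnd <- length(lines) + 1
  body <- lines[(hEnd + 1):(dEnd - 1)]
  body <- body[nzchar(trimws(body))]
  m <- matrix(as.numeric(unlist(strsplit(trimws(body), " +"))),
              nrow = length(body), byrow = TRUE)
  H <- m[, 1:3, drop = FALSE]
  asu <- mapToAsu(sg, H)
  side <- ifelse(asu$centric, 1L, asu$friedel)
  rf <- data.frame(h = asu$asu[, 1], k = asu$asu[, 2], l = asu$asu[, 3],
                   side = side, intensity = m[, 4], sigma = m[, 5],
                   nmeas = 1L,
                   d = dSpacing(cell, asu$asu))
  ## collapse duplicates defensively (should not occur in our own files)
  keyS <- .hklKey(asu$asu) * 2 + (side > 0)
  rf <- rf[!duplicated(keyS), , drop = FALSE]
  rownames(rf) <- NULL
  new("MergedDataset", cell = cell, spacegroup = sg, reflections = rf,
      provenance = list(source = path))
}
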