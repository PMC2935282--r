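## CCP4/MRC density-map input/output (mode 2, float32), enough for a mask
## or density grid over one unit cell to round-trip and open in standard
## map viewers. Axis order is fixed to X, Y, Z (MAPC/MAPR/MAPS = 1/2/3);
## files with a different axis order are reported, not silently permuted.

#' Write a DensityGrid as a CCP4/MRC map
#'
#' Mode-2 (float32) map covering exactly one unit cell, axis order X/Y/Z,
#' with header statistics (min/max/mean/rms) filled.
#'
#' @param grid a \linkS4class{DensityGrid}.
#' @param path output path.
#' @return invisibly, the path.
#' @export
writeCCP4Map <- function(grid, path) {
  n <- dim(grid@values)
  v <- as.vector(grid@values)
  con <- file(path, "wb")
  on.exit(close(con))
  wi <- function(x) writeBin(as.integer(x), con, size = 4, endian = "little")
  wf <- function(x) writeBin(as.numeric(x), con, size = 4, endian = "little")
  wi(n)                        # NC NR NS
  wi(2)                        # MODE 2 = float32
  wi(c(0, 0, 0))               # start offsets
  wi(n)                        # sampling MX MY MZ
  wf(cellLengths(grid@cell))   # CELLA
  wf(cellAngles(grid@cell))    # CELLB
  wi(c(1, 2, 3))               # MAPC MAPR MAPS
  wf(c(min(v), max(v), mean(v)))  # DMIN DMAX DMEAN
  wi(1)                        # ISPG (P1)
  wi(0)                        # NSYMBT
  wi(rep(0, 25))               # EXTRA (words 25-49)
  wf(c(0, 0, 0))               # ORIGIN (words 50-52)
  writeChar("MAP ", con, 4, eos = NULL)           # word 53
  writeBin(as.integer(c(0x44, 0x41, 0, 0)), con, size = 1)  # MACHST
  wf(sd(v))                    # RMS
  wi(0)                        # NLABL
  writeBin(raw(800), con)      # labels
  wf(v)
  invisible(path)
}

#' Read a CCP4/MRC map into a DensityGrid
#'
#' Only mode-2 maps with axis order X/Y/Z covering one unit cell are
#' accepted; anything else is reported as an error rather than silently
#' permuted.
#'
#' @param path file path.
#' @return a \linkS4class{DensityGrid}.
#' @export
readCCP4Map <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  ri <- function(k) readBin(con, "integer", k, size = 4, endian = "little")
  rf <- function(k) readBin(con, "numeric", k, size = 4, endian = "little")
  n <- ri(3)
  mode <- ri(1)
  if (mode != 2) .stopf("unsupported map mode %d (only mode 2 supported)", mode)
  ri(3)            # start offsets
  m <- ri(3)       # sampling
  if (!all(m == n)) .stopf("map does not cover exactly one unit cell")
  len <- rf(3)
  ang <- rf(3)
  axes <- ri(3)
  if (!all(axes == c(1, 2, 3)))
    .stopf("axis order %s not supported (expected 1 2 3); refusing to permute",
           paste(axes, collapse = " "))
  rf(3); ri(1)
  nsym <- ri(1)
  ri(25)
  rf(3)   # origin
  readChar(con, 4, useBytes = TRUE)
  readBin(con, "integer", 4, size = 1)
  rf(1); ri(1)
  readBin(con, "raw", 800)
  if (nsym > 0) readBin(con, "raw", nsym)
  v <- rf(prod(n))
  cell <- unitCell(len[1], len[2], len[3], ang[1], ang[2], ang[3])
  densityGrid(cell, values = array(v, dim = n))
}
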