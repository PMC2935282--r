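## PDB coordinate input/output. Reads CRYST1 and ATOM/HETATM records;
## ANISOU records are read but ignored (with a notice). Elements missing
## from columns 77-78 are inferred from the atom-name columns per PDB v3
## conventions.

.elementFromName <- function(name) {
  ## columns 13-16; a two-character element is right-justified into 13-14
  c12 <- substr(name, 1, 2)
  first <- substr(name, 1, 1)
  if (first != " " && !grepl("[0-9]", first) &&
      .normElement(c12) %in% names(.vdwRadii) && substr(name, 2, 2) != " ")
    return(.normElement(c12))
  nm <- gsub("[0-9' ]", "", name)
  .normElement(substr(nm, 1, 1))
}

#' Read a PDB coordinate file
#'
#' Parses CRYST1 (cell) and ATOM/HETATM (coordinates, occupancy, B factor,
#' element) records. Symmetry defaults to P1 unless operators are
#' supplied. ANISOU records are ignored with a notice. Waters (residue
#' HOH/WAT) are flagged in the \code{water} column.
#'
#' @param path file path.
#' @param symmetry operator list (see \code{\link{symOp}}); default P1.
#' @param radii optional named per-element vdW radius overrides.
#' @return a \linkS4class{CrystalModel}.
#' @export
readPDB <- function(path, symmetry = list(symOp()), radii = NULL) {
  lines <- readLines(path, warn = FALSE)
  rec <- substr(lines, 1, 6)
  cr <- lines[rec == "CRYST1"]
  if (length(cr) < 1) .stopf("missing CRYST1 record in '%s'", path)
  cell <- unitCell(as.numeric(substr(cr[1], 7, 15)),
                   as.numeric(substr(cr[1], 16, 24)),
                   as.numeric(substr(cr[1], 25, 33)),
                   as.numeric(substr(cr[1], 34, 40)),
                   as.numeric(substr(cr[1], 41, 47)),
                   as.numeric(substr(cr[1], 48, 54)))
  nAniso <- sum(rec == "ANISOU")
  if (nAniso > 0)
    message(sprintf("readPDB: ignoring %d ANISOU record(s)", nAniso))
  sel <- which(rec %in% c("ATOM  ", "HETATM"))
  if (length(sel) == 0) .stopf("no ATOM/HETATM records in '%s'", path)
  parse1 <- function(i) {
    ln <- lines[i]
    xyz <- suppressWarnings(c(as.numeric(substr(ln, 31, 38)),
                              as.numeric(substr(ln, 39, 46)),
                              as.numeric(substr(ln, 47, 54))))
    if (any(is.na(xyz)))
      .stopf("unparseable ATOM record at line %d of '%s'", i, path)
    occ <- suppressWarnings(as.numeric(substr(ln, 55, 60)))
    b <- suppressWarnings(as.numeric(substr(ln, 61, 66)))
    el <- trimws(substr(ln, 77, 78))
    if (el == "") el <- .elementFromName(substr(ln, 13, 16))
    res <- trimws(substr(ln, 18, 20))
    data.frame(element = .normElement(el), x = xyz[1], y = xyz[2],
               z = xyz[3], occ = ifelse(is.na(occ), 1, occ),
               b = ifelse(is.na(b), 0, b),
               water = res %in% c("HOH", "WAT"))
  }
  at <- do.call(rbind, lapply(sel, parse1))
  at$radius <- vdwRadius(at$element)
  if (!is.null(radii)) {
    hit <- at$element %in% names(radii)
    at$radius[hit] <- radii[at$element[hit]]
  }
  crystalModel(cell, at, symmetry = symmetry,
               id = basename(path))
}

#' Write a CrystalModel as a PDB file
#'
#' Emits CRYST1 plus HETATM records (one residue per atom; waters as HOH).
#'
#' @param model a \linkS4class{CrystalModel}.
#' @param path output path.
#' @return invisibly, the path.
#' @export
writePDB <- function(model, path) {
  cell <- model@cell
  at <- model@atoms
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("CRYST1%9.3f%9.3f%9.3f%7.2f%7.2f%7.2f P 1           1",
                     cell@a, cell@b, cell@c, cell@alpha, cell@beta,
                     cell@gamma), con)
  for (i in seq_len(nrow(at))) {
    el <- at$element[i]
    res <- if (isTRUE(at$water[i])) "HOH" else "LIG"
    name <- sprintf("%-4s", paste0(substr(el, 1, 2), i %% 100))
    writeLines(sprintf(
      "HETATM%5d %-4s %-3s A%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
      i, name, res, i, at$x[i], at$y[i], at$z[i], at$occ[i], at$b[i],
      toupper(el)), con)
  }
  writeLines("END", con)
  invisible(path)
}
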