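## Reflection-data input/output: a whitespace-columnar text dialect and a
## minimal mmCIF reflection loop. The text round trip preserves indices,
## amplitudes and flags bit-exactly.

#' Write a ReflectionSet to a reflection file
#'
#' The "text" dialect writes a commented header line plus whitespace
#' columns h k l (and whichever of fobs, sigobs, free, fcalc, phic are
#' filled). The "mmcif" dialect writes a \code{loop_} with
#' \code{_refln.index_h/k/l}, \code{_refln.F_meas_au},
#' \code{_refln.F_meas_sigma_au}, \code{_refln.status} (o/f) and, when
#' \eqn{F_c} is present, \code{_refln.F_calc_au} and
#' \code{_refln.phase_calc}.
#'
#' @param refl a \linkS4class{ReflectionSet}.
#' @param path output path.
#' @param format "text" or "mmcif".
#' @return invisibly, the path.
#' @export
writeReflections <- function(refl, path, format = c("text", "mmcif")) {
  format <- match.arg(format)
  df <- data.frame(h = refl@hkl[, 1], k = refl@hkl[, 2], l = refl@hkl[, 3])
  if (length(refl@fobs)) df$fobs <- refl@fobs
  if (length(refl@sigobs)) df$sigobs <- refl@sigobs
  if (length(refl@free)) df$free <- as.integer(refl@free)
  if (length(refl@fc)) {
    df$fcalc <- Mod(refl@fc)
    df$phic <- Arg(refl@fc) * 180 / pi
  }
  if (format == "text") {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(paste("#", paste(names(df), collapse = " ")), con)
    write.table(format(df, digits = 10, trim = TRUE, scientific = FALSE),
                con, quote = FALSE, row.names = FALSE, col.names = FALSE)
  } else {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(c("data_reflections", "loop_", "_refln.index_h",
                 "_refln.index_k", "_refln.index_l"), con)
    tags <- character()
    cols <- list(df$h, df$k, df$l)
    if (!is.null(df$fobs)) { tags <- c(tags, "_refln.F_meas_au")
                             cols <- c(cols, list(df$fobs)) }
    if (!is.null(df$sigobs)) { tags <- c(tags, "_refln.F_meas_sigma_au")
                               cols <- c(cols, list(df$sigobs)) }
    if (!is.null(df$free)) { tags <- c(tags, "_refln.status")
                             cols <- c(cols, list(ifelse(df$free == 1, "f", "o"))) }
    if (!is.null(df$fcalc)) { tags <- c(tags, "_refln.F_calc_au",
                                        "_refln.phase_calc")
                              cols <- c(cols, list(df$fcalc, df$phic)) }
    writeLines(tags, con)
    body <- do.call(paste, lapply(cols, function(x)
      if (is.numeric(x)) format(x, digits = 10, trim = TRUE,
                                scientific = FALSE) else x))
    writeLines(body, con)
  }
  invisible(path)
}

#' Read a reflection file
#'
#' Accepts the columnar text dialect written by
#' \code{\link{writeReflections}} (header comment naming the columns, or
#' bare h k l F [sigma] [free] columns) and the mmCIF reflection-loop
#' dialect with arbitrary column order. Duplicate Miller indices and
#' non-numeric fields are errors.
#'
#' @param path file path.
#' @param cell a \linkS4class{UnitCell} for resolution bookkeeping.
#' @return a \linkS4class{ReflectionSet}.
#' @export
readReflections <- function(path, cell) {
  lines <- readLines(path, warn = FALSE)
  if (any(grepl("^\\s*loop_", lines))) return(.readReflnCif(lines, cell))
  header <- NULL
  if (length(lines) && grepl("^#", lines[1])) {
    header <- strsplit(trimws(sub("^#", "", lines[1])), "\\s+")[[1]]
    lines <- lines[-1]
  }
  lines <- lines[nzchar(trimws(lines))]
  df <- read.table(text = lines, header = FALSE, colClasses = "numeric")
  if (is.null(header)) {
    header <- c("h", "k", "l", "fobs", "sigobs", "free")[seq_len(ncol(df))]
  }
  if (ncol(df) != length(header))
    .stopf("reflection file has %d columns but header names %d",
           ncol(df), length(header))
  names(df) <- header
  .reflFromDF(df, cell)
}

.reflFromDF <- function(df, cell) {
  need <- c("h", "k", "l")
  if (!all(need %in% names(df))) .stopf("reflection data must have h, k, l")
  hkl <- as.matrix(df[, need])
  if (anyDuplicated(hkl)) .stopf("duplicate Miller index in reflection data")
  refl <- reflectionSet(cell, hkl,
                        fobs = if (!is.null(df$fobs)) df$fobs else numeric(),
                        sigobs = if (!is.null(df$sigobs)) df$sigobs else numeric(),
                        free = if (!is.null(df$free)) df$free > 0 else logical())
  if (!is.null(df$fcalc)) {
    ph <- if (!is.null(df$phic)) df$phic * pi / 180 else 0
    refl@fc <- complex(modulus = df$fcalc, argument = ph)
  }
  refl
}

.readReflnCif <- function(lines, cell) {
  lines <- trimws(lines)
  loopAt <- which(lines == "loop_")[1]
  if (is.na(loopAt)) .stopf("no loop_ in mmCIF reflection file")
  i <- loopAt + 1
  tags <- character()
  while (i <= length(lines) && grepl("^_", lines[i])) {
    tags <- c(tags, lines[i]); i <- i + 1
  }
  body <- lines[i:length(lines)]
  body <- body[nzchar(body) & !grepl("^(#|data_|_|loop_)", body)]
  df <- read.table(text = body, header = FALSE, colClasses = "character")
  if (ncol(df) != length(tags))
    .stopf("mmCIF loop has %d tags but %d columns", length(tags), ncol(df))
  names(df) <- tags
  pick <- function(tag) {
    v <- df[[tag]]
    if (is.null(v)) return(NULL)
    num <- suppressWarnings(as.numeric(v))
    if (any(is.na(num))) .stopf("non-numeric field in mmCIF column %s", tag)
    num
  }
  out <- data.frame(h = pick("_refln.index_h"), k = pick("_refln.index_k"),
                    l = pick("_refln.index_l"))
  if (!is.null(df[["_refln.F_meas_au"]])) out$fobs <- pick("_refln.F_meas_au")
  if (!is.null(df[["_refln.F_meas_sigma_au"]]))
    out$sigobs <- pick("_refln.F_meas_sigma_au")
  if (!is.null(df[["_refln.status"]]))
    out$free <- as.integer(df[["_refln.status"]] == "f")
  if (!is.null(df[["_refln.F_calc_au"]])) {
    out$fcalc <- pick("_refln.F_calc_au")
    if (!is.null(df[["_refln.phase_calc"]]))
      out$phic <- pick("_refln.phase_calc")
  }
  .reflFromDF(out, cell)
}
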