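## Plain-text profile I/O (tolerant reader for depth-by-time count tables),
## deterministic writer, and the synthetic-observation generator used by the
## recovery tests.

sniffDelimiter <- function(lines) {
  if (any(grepl("\t", lines, fixed = TRUE))) "\t"
  else if (any(grepl(",", lines, fixed = TRUE))) ","
  else "[[:space:]]+"
}

splitFields <- function(line, delim) {
  if (delim == "[[:space:]]+") {
    strsplit(trimws(line), delim)[[1]]
  } else {
    trimws(strsplit(line, delim, fixed = TRUE)[[1]])
  }
}

#' Read a depth-by-time tracer profile from a plain-text table
#'
#' Reads a numeric matrix of tracer counts with layers in rows (interface
#' first) and time points in columns. The delimiter (tab, comma or
#' whitespace) is sniffed, an optional header row and an optional depth-label
#' first column are detected and stripped, and all remaining cells must parse
#' as non-negative numbers.
#'
#' @param path file to read.
#' @param dtMin,layerHeightMm physical metadata attached to the result
#'   (defaults: 5-minute frames, 0.073 mm layers).
#' @param orientation `"auto"` (default: if the table is wider than tall it
#'   is transposed so that layers end up in rows), `"layers-in-rows"` or
#'   `"layers-in-columns"`.
#' @return a [profileSeries()].
#' @export
readProfile <- function(path, dtMin = 5, layerHeightMm = 0.073,
                        orientation = c("auto", "layers-in-rows",
                                        "layers-in-columns")) {
  orientation <- match.arg(orientation)
  if (!file.exists(path)) stopIO("cannot read profile: no such file '%s'", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines))
    return(profileSeries(matrix(numeric(0), nrow = 0, ncol = 0),
                         dtMin, layerHeightMm))
  delim <- sniffDelimiter(lines)
  rows <- lapply(lines, splitFields, delim = delim)

  isNum <- function(x) !is.na(suppressWarnings(as.numeric(x)))
  ## header row: any non-numeric token in the first row
  header <- !all(isNum(rows[[1]]))
  if (header) rows <- rows[-1]
  if (!length(rows)) stopIO("profile file '%s' contains no data rows", path)
  ## depth-label column: any non-numeric leading token in the data rows, or a
  ## header one field longer than the data rows
  firstTok <- vapply(rows, `[`, character(1), 1L)
  labels <- !all(isNum(firstTok))
  if (labels) rows <- lapply(rows, `[`, -1L)

  widths <- lengths(rows)
  if (length(unique(widths)) != 1L)
    stopIO("ragged rows in '%s': row %d has %d fields, expected %d",
           path, which(widths != widths[1])[1] + header, widths[widths != widths[1]][1],
           widths[1])
  m <- matrix(NA_real_, nrow = length(rows), ncol = widths[1])
  for (i in seq_along(rows)) {
    v <- suppressWarnings(as.numeric(rows[[i]]))
    if (anyNA(v))
      stopIO("non-numeric cell at row %d, column %d of '%s'",
             i + header, which(is.na(v))[1] + labels, path)
    m[i, ] <- v
  }
  if (any(m < 0))
    stopIO("negative count at row %d of '%s'", which(rowSums(m < 0) > 0)[1] + header,
           path)
  if (orientation == "layers-in-columns" ||
      (orientation == "auto" && nrow(m) < ncol(m))) m <- t(m)
  profileSeries(m, dtMin = dtMin, layerHeightMm = layerHeightMm)
}

#' Write a profile as a tab-delimited plain-text table
#'
#' Deterministic formatting: integer-valued cells are written verbatim,
#' fractional cells with six decimal places. Repeated writes of the same
#' series are byte-identical.
#'
#' @param series a [profileSeries()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeProfile <- function(series, path) {
  m <- profileCounts(series)
  ok <- tryCatch({
    con <- file(path, open = "wb")
    TRUE
  }, error = function(e) FALSE)
  if (!ok) stopIO("cannot open '%s' for writing", path)
  on.exit(close(con))
  fmtCell <- function(x)
    ifelse(x == round(x), sprintf("%d", as.integer(round(x))),
           sprintf("%.6f", x))
  if (nrow(m) > 0 && ncol(m) > 0) {
    txt <- apply(m, 1, function(row) paste(fmtCell(row), collapse = "\t"))
    writeLines(txt, con, sep = "\n")
  }
  invisible(path)
}

#' Generate a synthetic observed dataset with known truth
#'
#' Stands in for the imaging experiment: forward-simulates the lattice model
#' under known parameters and optionally thins every count binomially with
#' detection probability `pDetect`, mimicking luminophores missed by the
#' camera/threshold. The generating truth is returned alongside so recovery
#' tests can compare fitted against true values.
#'
#' @param params a [modelParams()] (the truth).
#' @param config a [simConfig()]; its seed drives both the simulation and the
#'   thinning.
#' @param pDetect detection probability in (0, 1]; 1 disables noise.
#' @return list with `series` (a [profileSeries()]) and `truth`
#'   (list of `params`, `config`, `pDetect`).
#' @export
generateSynthetic <- function(params, config, pDetect = 1) {
  if (length(pDetect) != 1L || !is.finite(pDetect) || pDetect <= 0 || pDetect > 1)
    stopUsage("'pDetect' must be a single value in (0, 1]")
  series <- simulateProfile(params, config)
  if (pDetect < 1) {
    m <- profileCounts(series)
    thinned <- matrix(rbinom(length(m), size = as.integer(m), prob = pDetect),
                      nrow = nrow(m))
    series <- profileSeries(thinned, dtMin = series@dtMin,
                            layerHeightMm = series@layerHeightMm)
  }
  list(series = series,
       truth = list(params = params, config = config, pDetect = pDetect))
}
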