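.readTSVBody <- function(path) {
  lines <- readLines(path)
  meta <- grep("^#", lines, value = TRUE)
  body <- lines[!grepl("^\\s*(#|$)", lines)]
  if (length(body) < 1L) stop("empty table: ", path)
  tab <- utils::read.table(text = body, header = TRUE, sep = "\t",
                           na.strings = c("NA", ""), stringsAsFactors = FALSE,
                           check.names = FALSE)
  list(meta = meta, tab = tab)
}

.numericColumn <- function(tab, col, path) {
  if (!col %in% names(tab)) return(rep(NA_real_, nrow(tab)))
  x <- tab[[col]]
  if (is.numeric(x)) return(as.numeric(x))
  v <- suppressWarnings(as.numeric(x))
  bad <- which(!is.na(x) & is.na(v))
  if (length(bad))
    stop("non-numeric value '", x[bad[1]], "' in column '", col, "' at data row ",
         bad[1], " of ", path)
  v
}

#' Construct a PeakTable
#'
#' @param residue integer residue ids.
#' @param dH,dN chemical shifts (ppm).
#' @param intensity peak intensities (>= 0, NA for missing/overlapped peaks).
#' @param sidechain logical; TRUE for Asn/Gln/Arg side-chain N-H peaks.
#' @return a [PeakTable-class].
#' @export
PeakTable <- function(residue, dH, dN, intensity = NA_real_,
                      sidechain = FALSE) {
  d <- data.frame(residue = as.integer(residue), dH = as.numeric(dH),
                  dN = as.numeric(dN),
                  intensity = as.numeric(rep_len(intensity, length(residue))),
                  sidechain = rep_len(as.logical(sidechain), length(residue)))
  new("PeakTable", data = d[order(d$sidechain, d$residue), , drop = FALSE])
}

#' Read an NMR peak table (TSV)
#'
#' Expects a tab-separated table with header columns `residue`, `dH`, `dN`,
#' `intensity` and optionally `sidechain` (0/1 or TRUE/FALSE). Lines starting
#' with `#` are metadata/comments. Empty cells are kept as missing (NA), never
#' as zero. Duplicated residue ids (within the backbone or the side-chain
#' group) and non-numeric shifts are errors.
#'
#' @param path input TSV file.
#' @return a [PeakTable-class].
#' @export
readPeakTable <- function(path) {
  if (!file.exists(path)) stop("peak table not found: ", path)
  tab <- .readTSVBody(path)$tab
  need <- c("residue", "dH", "dN", "intensity")
  if (!all(need %in% names(tab)))
    stop("peak table ", path, " must have header columns ",
         paste(need, collapse = ", "))
  sidechain <- if ("sidechain" %in% names(tab))
    as.logical(.numericColumn(tab, "sidechain", path)) else FALSE
  res <- as.integer(.numericColumn(tab, "residue", path))
  dup <- res[duplicated(data.frame(res, rep_len(sidechain, length(res))))]
  if (length(dup)) stop("duplicated residue ", dup[1], " in ", path)
  PeakTable(res, .numericColumn(tab, "dH", path), .numericColumn(tab, "dN", path),
            .numericColumn(tab, "intensity", path), sidechain)
}

#' Write a PeakTable as TSV
#'
#' Inverse of [readPeakTable()]; missing values are written as empty cells.
#'
#' @param x a [PeakTable-class].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writePeakTable <- function(x, path) {
  stopifnot(is(x, "PeakTable"))
  d <- x@data
  d$sidechain <- as.integer(d$sidechain)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(names(d), collapse = "\t"), con)
  writeLines(do.call(paste, c(lapply(d, .fmtTSV), sep = "\t")), con)
  invisible(path)
}

# exact (%.17g) but compact numeric formatting; integers stay integers,
# NA becomes an empty cell
.fmtTSV <- function(x) {
  out <- if (is.integer(x)) sprintf("%d", x) else sprintf("%.17g", x)
  out[is.na(x)] <- ""
  out
}

#' Construct a RelaxationDataset
#'
#' @param residue integer residue ids.
#' @param R1,R2 relaxation rates (1/s, > 0).
#' @param NOE heteronuclear 1H-15N NOE (dimensionless).
#' @param R1rho rotating-frame rate (1/s), NA when not measured.
#' @param eR1,eR2,eNOE,eR1rho uncertainties (> 0 or NA).
#' @param fieldMHz spectrometer 1H frequency (MHz).
#' @param truth optional data.frame of generating parameters (synthetic data).
#' @return a [RelaxationDataset-class].
#' @export
RelaxationDataset <- function(residue, R1, R2, NOE, R1rho = NA_real_,
                              eR1 = NA_real_, eR2 = NA_real_, eNOE = NA_real_,
                              eR1rho = NA_real_, fieldMHz = 500,
                              truth = data.frame()) {
  n <- length(residue)
  d <- data.frame(residue = as.integer(residue), R1 = as.numeric(R1),
                  R2 = as.numeric(R2), NOE = as.numeric(NOE),
                  R1rho = as.numeric(rep_len(R1rho, n)),
                  eR1 = as.numeric(rep_len(eR1, n)),
                  eR2 = as.numeric(rep_len(eR2, n)),
                  eNOE = as.numeric(rep_len(eNOE, n)),
                  eR1rho = as.numeric(rep_len(eR1rho, n)))
  new("RelaxationDataset", data = d[order(d$residue), , drop = FALSE],
      fieldMHz = fieldMHz, truth = truth)
}

#' Read a 15N relaxation table (TSV)
#'
#' Tab-separated columns `residue`, `R1`, `R2`, `NOE` and optionally `R1rho`
#' plus error columns `eR1`, `eR2`, `eNOE`, `eR1rho`. The spectrometer field is
#' taken from a metadata line `# field_MHz <value>`; it is required. Negative
#' or zero rates are errors; absent columns become all-NA.
#'
#' @param path input TSV file.
#' @return a [RelaxationDataset-class].
#' @export
readRelaxationTable <- function(path) {
  if (!file.exists(path)) stop("relaxation table not found: ", path)
  parsed <- .readTSVBody(path)
  fm <- grep("^#\\s*field_MHz\\b", parsed$meta, value = TRUE)
  if (!length(fm))
    stop("relaxation table ", path, " must carry a '# field_MHz <MHz>' metadata line")
  field <- as.numeric(sub("^#\\s*field_MHz\\s+", "", fm[1]))
  if (is.na(field) || field <= 0) stop("invalid field_MHz value in ", path)
  tab <- parsed$tab
  need <- c("residue", "R1", "R2", "NOE")
  if (!all(need %in% names(tab)))
    stop("relaxation table ", path, " must have header columns ",
         paste(need, collapse = ", "))
  g <- function(col) .numericColumn(tab, col, path)
  RelaxationDataset(as.integer(g("residue")), g("R1"), g("R2"), g("NOE"),
                    g("R1rho"), g("eR1"), g("eR2"), g("eNOE"), g("eR1rho"),
                    fieldMHz = field)
}

#' Write a RelaxationDataset as TSV
#'
#' Inverse of [readRelaxationTable()]; emits the `# field_MHz` metadata line.
#'
#' @param x a [RelaxationDataset-class].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeRelaxationTable <- function(x, path) {
  stopifnot(is(x, "RelaxationDataset"))
  d <- x@data
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# field_MHz %.10g", x@fieldMHz), con)
  writeLines(paste(names(d), collapse = "\t"), con)
  writeLines(do.call(paste, c(lapply(d, .fmtTSV), sep = "\t")), con)
  invisible(path)
}

#' Write a residue-indexed matrix as TSV
#'
#' Residue ids become the row and column headers. Full double precision is
#' used so that [readMatrixTSV()] round-trips exactly.
#'
#' @param m numeric matrix with residue-id dimnames, or a
#'   [DistanceFluctuation-class] / [FluctuationDifference-class] /
#'   [StrainSeries-class] object.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeMatrixTSV <- function(m, path) {
  if (is(m, "DistanceFluctuation") || is(m, "FluctuationDifference") ||
      is(m, "StrainSeries")) m <- values(m)
  stopifnot(is.matrix(m), !is.null(rownames(m)))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(c("residue", colnames(m)), collapse = "\t"), con)
  body <- vapply(seq_len(nrow(m)), function(i) {
    v <- ifelse(is.na(m[i, ]), "NA", sprintf("%.17g", m[i, ]))
    paste(c(rownames(m)[i], v), collapse = "\t")
  }, character(1))
  writeLines(body, con)
  invisible(path)
}

#' Read a residue-indexed matrix written by [writeMatrixTSV()]
#'
#' @param path input TSV file.
#' @return numeric matrix with the stored dimnames.
#' @export
readMatrixTSV <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                           row.names = 1)
  as.matrix(tab)
}

#' Write a report as versioned JSON
#'
#' Reports are plain lists; a `schema_version` field is added. Round-trips
#' through [readReportJSON()].
#'
#' @param report a named list.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeReportJSON <- function(report, path) {
  stopifnot(is.list(report))
  if (is.null(report$schema_version)) report$schema_version <- "1.0"
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null", na = "null")
  invisible(path)
}

#' Read a JSON report written by [writeReportJSON()]
#'
#' @param path input file.
#' @return the report list.
#' @export
readReportJSON <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}
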