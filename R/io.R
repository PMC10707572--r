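# Delimited-text readers/writers for spectra, titrations, EEMs and result
# tables. Dialect: UTF-8 text, delimiter auto-detected among tab / comma /
# semicolon, '#' starts a comment, one optional header row. Wavelengths are
# always nm on disk; concentrations always molar in the data model.

detect_delimiter <- function(lines) {
  cand <- c("\t", ",", ";")
  counts <- vapply(cand, function(d)
    max(lengths(strsplit(lines, d, fixed = TRUE))), numeric(1))
  if (all(counts <= 1)) stop("could not detect a delimiter (tab/comma/semicolon)",
                             call. = FALSE)
  cand[which.max(counts)]
}

# Read a delimited file into a numeric matrix, reporting the 1-based file
# line number of any malformed row. Returns list(data, header) where header
# is the character vector of an optional non-numeric first row (or NULL).
read_delimited_numeric <- function(path, min_cols = 2L) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- readLines(path, warn = FALSE, encoding = "UTF-8")
  keep <- !grepl("^\\s*(#|$)", raw)
  if (!any(keep)) stop("file contains no data rows: ", path, call. = FALSE)
  lines <- raw[keep]
  line_no <- which(keep)
  delim <- detect_delimiter(lines)
  fields <- strsplit(trimws(lines), delim, fixed = TRUE)
  fields <- lapply(fields, trimws)
  header <- NULL
  first_num <- suppressWarnings(as.numeric(fields[[1]]))
  if (anyNA(first_num)) {            # treat as header row
    header <- fields[[1]]
    fields <- fields[-1]
    line_no <- line_no[-1]
    if (length(fields) == 0L)
      stop("file contains a header but no data rows: ", path, call. = FALSE)
  }
  ncols <- length(fields[[1]])
  if (ncols < min_cols)
    stop(sprintf("expected at least %d columns, found %d (line %d)",
                 min_cols, ncols, line_no[1]), call. = FALSE)
  out <- matrix(NA_real_, nrow = length(fields), ncol = ncols)
  for (i in seq_along(fields)) {
    row <- suppressWarnings(as.numeric(fields[[i]]))
    if (length(row) != ncols || anyNA(row))
      stop(sprintf("malformed row at line %d of %s", line_no[i], path),
           call. = FALSE)
    out[i, ] <- row
  }
  list(data = out, header = header)
}

#' Read a two-column spectrum file
#'
#' Expects delimited text with columns (wavelength_nm, value); `#` starts a
#' comment and one header row is allowed. Rows are sorted by wavelength;
#' duplicated wavelengths are an error.
#'
#' @param path path to the file.
#' @param kind signal kind of the values column (see [spectrum()]).
#' @param label optional label; defaults to the file name.
#' @return a validated [spectrum()].
#' @export
read_spectrum <- function(path, kind, label = basename(path)) {
  parsed <- read_delimited_numeric(path, min_cols = 2L)
  if (ncol(parsed$data) != 2L)
    stop("a spectrum file must have exactly 2 columns, found ",
         ncol(parsed$data), call. = FALSE)
  spectrum(parsed$data[, 1], parsed$data[, 2], kind = kind, label = label)
}

#' Write a spectrum to a two-column TSV file
#' @param s a [spectrum()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_spectrum <- function(s, path) {
  stopifnot(inherits(s, "spectrum"))
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(sprintf("# kind: %s", s$kind), con)
  writeLines("wavelength_nm\tvalue", con)
  writeLines(sprintf("%.10g\t%.10g", s$wavelengths_nm, s$values), con)
  invisible(path)
}

#' Read a wide-format titration table
#'
#' First column is wavelength (nm); each remaining column is one spectrum at
#' one quencher concentration. Concentrations are taken from
#' `quencher_concs_M` when supplied, otherwise parsed from the numeric header
#' row (columns 2..k).
#'
#' @param path path to the file.
#' @param temperature_K temperature of the titration (Kelvin).
#' @param protein_conc_M protein concentration (mol/L).
#' @param quencher_concs_M optional concentrations (mol/L), one per spectrum
#'   column, strictly increasing from 0.
#' @param kind signal kind of the spectra (default emission).
#' @param path_length_cm cuvette path length (cm).
#' @param excitation_absorbances,emission_absorbances optional per-point
#'   absorbances for inner-filter correction.
#' @return a validated [titration_series()].
#' @export
read_titration <- function(path, temperature_K, protein_conc_M,
                           quencher_concs_M = NULL, kind = "emission_au",
                           path_length_cm = 1,
                           excitation_absorbances = NULL,
                           emission_absorbances = NULL) {
  parsed <- read_delimited_numeric(path, min_cols = 2L)
  ncols <- ncol(parsed$data)
  if (is.null(quencher_concs_M)) {
    if (is.null(parsed$header))
      stop("quencher concentrations must be supplied or present as a header",
           call. = FALSE)
    quencher_concs_M <- suppressWarnings(as.numeric(parsed$header[-1]))
    if (anyNA(quencher_concs_M))
      stop("header columns 2..k are not numeric concentrations", call. = FALSE)
  }
  if (length(quencher_concs_M) != ncols - 1L)
    stop(sprintf("declared %d concentrations but file has %d spectrum columns",
                 length(quencher_concs_M), ncols - 1L), call. = FALSE)
  wl <- parsed$data[, 1]
  spectra <- lapply(seq_len(ncols - 1L), function(j)
    spectrum(wl, parsed$data[, j + 1L], kind = kind,
             label = sprintf("[Q]=%.3g M", quencher_concs_M[j])))
  titration_series(temperature_K = temperature_K,
                   protein_conc_M = protein_conc_M,
                   quencher_concs_M = quencher_concs_M,
                   spectra = spectra, path_length_cm = path_length_cm,
                   excitation_absorbances = excitation_absorbances,
                   emission_absorbances = emission_absorbances)
}

#' Write a titration series as a wide TSV table
#' @param series a [titration_series()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_titration <- function(series, path) {
  stopifnot(inherits(series, "titration_series"))
  mat <- vapply(series$spectra, function(s) s$values,
                numeric(length(series$spectra[[1]]$values)))
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(sprintf("# temperature_K: %g; protein_conc_M: %g",
                     series$temperature_K, series$protein_conc_M), con)
  writeLines(paste(c("wavelength_nm",
                     sprintf("%.10g", series$quencher_concs_M)),
                   collapse = "\t"), con)
  wl <- series$spectra[[1]]$wavelengths_nm
  body <- apply(cbind(wl, mat), 1L, function(r)
    paste(sprintf("%.10g", r), collapse = "\t"))
  writeLines(body, con)
  invisible(path)
}

#' Read an excitation-emission matrix file
#'
#' Matrix TSV/CSV: the first row holds emission wavelengths (first cell is a
#' corner label or excitation header), the first column holds excitation
#' wavelengths.
#'
#' @param path path to the file.
#' @return a validated [eem()].
#' @export
read_eem <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- readLines(path, warn = FALSE, encoding = "UTF-8")
  raw <- raw[!grepl("^\\s*(#|$)", raw)]
  if (length(raw) < 3L) stop("EEM file too short: ", path, call. = FALSE)
  delim <- detect_delimiter(raw)
  fields <- lapply(strsplit(raw, delim, fixed = TRUE), trimws)
  first <- fields[[1]]
  em <- suppressWarnings(as.numeric(first[-1]))
  if (anyNA(em)) stop("EEM first row must end in numeric emission wavelengths",
                      call. = FALSE)
  body <- fields[-1]
  ex <- numeric(length(body))
  mat <- matrix(NA_real_, nrow = length(body), ncol = length(em))
  for (i in seq_along(body)) {
    row <- suppressWarnings(as.numeric(body[[i]]))
    if (length(row) != length(em) + 1L || anyNA(row))
      stop(sprintf("malformed EEM row %d in %s", i + 1L, path), call. = FALSE)
    ex[i] <- row[1]
    mat[i, ] <- row[-1]
  }
  eem(ex, em, mat)
}

#' Write an EEM as a matrix TSV file
#' @param x an [eem()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_eem <- function(x, path) {
  stopifnot(inherits(x, "eem"))
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(paste(c("ex_nm", sprintf("%.10g", x$emission_nm)),
                   collapse = "\t"), con)
  body <- vapply(seq_along(x$excitation_nm), function(i)
    paste(sprintf("%.10g", c(x$excitation_nm[i], x$intensities[i, ])),
          collapse = "\t"), character(1))
  writeLines(body, con)
  invisible(path)
}

#' Write a result object (or data frame) as a flat TSV table
#'
#' Results are flattened with their `as.data.frame` method into a long
#' parameter table; values round-trip through [read_result_table()] at full
#' double precision (well beyond 6 significant digits).
#'
#' @param result a fitted result object with an `as.data.frame` method, or a
#'   data frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_result_table <- function(result, path) {
  df <- as.data.frame(result)
  utils::write.table(format(df, digits = 15, scientific = NA, trim = TRUE),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read back a table written by [write_result_table()]
#' @param path path to the file.
#' @return a data frame with numeric columns re-typed.
#' @export
read_result_table <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, check.names = FALSE)
  for (j in seq_along(df)) {
    num <- suppressWarnings(as.numeric(df[[j]]))
    if (!anyNA(num)) df[[j]] <- num
  }
  df
}
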