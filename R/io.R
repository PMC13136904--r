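#' Read a three-column SAXS .dat file
#'
#' Parses the ASCII dialect used by synchrotron reduction pipelines and the
#' small-angle scattering databank: optional comment/header lines (leading
#' '#' or any non-numeric content) followed by 2-3 numeric columns
#' (Q, I, optionally sigma).  The Q unit is auto-detected - a maximum Q
#' below 1 suggests inverse Angstroms and is converted to nm^-1 - unless
#' `unit_hint` overrides the heuristic.  Rows with negative intensity are
#' kept and their count attached as attribute `n_negative`.
#'
#' @param path File path.
#' @param unit_hint `NULL` (auto), `"nm^-1"`, or `"A^-1"`.
#' @return A [saxs_profile()].
#' @export
read_saxs_dat <- function(path, unit_hint = NULL) {
  lines <- readLines(path, warn = FALSE)
  rows <- lapply(lines, function(l) {
    toks <- strsplit(trimws(l), "[,;[:space:]]+")[[1]]
    if (length(toks) < 2) return(NULL)
    vals <- suppressWarnings(as.numeric(toks))
    if (any(is.na(vals))) return(NULL)
    vals
  })
  rows <- Filter(Negate(is.null), rows)
  if (length(rows) < 10) stop("fewer than 10 numeric data rows in ", path)
  ncols <- vapply(rows, length, integer(1))
  nc <- min(ncols)
  m <- do.call(rbind, lapply(rows, function(r) r[seq_len(min(nc, 3))]))
  q <- m[, 1]
  if (any(diff(q) <= 0)) stop("non-monotone Q grid in ", path)
  unit <- if (!is.null(unit_hint)) {
    match.arg(unit_hint, c("nm^-1", "A^-1"))
  } else if (max(q) < 1) "A^-1" else "nm^-1"
  # sigma lives on the intensity axis, so only q needs unit conversion
  sigma <- if (ncol(m) >= 3 && all(m[, 3] > 0)) m[, 3] else NULL
  prof <- saxs_profile(q, m[, 2], sigma = sigma, q_unit = unit)
  attr(prof, "n_negative") <- sum(m[, 2] < 0)
  prof
}

#' Write a SAXS profile as a three-column .dat file
#'
#' @param profile A [saxs_profile()].
#' @param path Output path.
#' @param comment Optional header comment.
#' @return The path, invisibly.
#' @export
write_saxs_dat <- function(profile, path, comment = NULL) {
  stopifnot(inherits(profile, "saxs_profile"))
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(comment)) writeLines(paste("#", comment), con)
  writeLines("# Q(nm^-1)  I(Q)  sigma", con)
  sig <- if (is.null(profile$sigma)) rep(NA, length(profile$q)) else profile$sigma
  for (i in seq_along(profile$q)) {
    if (is.na(sig[i])) {
      writeLines(sprintf("%.8e %.8e", profile$q[i], profile$intensity[i]), con)
    } else {
      writeLines(sprintf("%.8e %.8e %.8e", profile$q[i], profile$intensity[i],
                         sig[i]), con)
    }
  }
  invisible(path)
}

#' Read a CD melting matrix (or single spectrum) from delimited text
#'
#' Expected layout: a header row of temperatures (its first field may be a
#' label such as "wavelength"), then one row per wavelength with the
#' wavelength in the first column and ellipticities (mdeg) in the remaining
#' columns.  A two-column file without a numeric header is read as a single
#' [cd_spectrum()].  Ragged rows are an error rather than silently repaired.
#'
#' @param path File path.
#' @return A [cd_melting_matrix()] or, for two-column input, a
#'   [cd_spectrum()].
#' @export
read_cd_matrix <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) < 2) stop("too few rows in ", path)
  tok <- function(l) strsplit(trimws(l), "[,;\t[:space:]]+")[[1]]
  widths <- vapply(lines, function(l) length(tok(l)), integer(1))
  if (length(unique(widths[-1])) > 1) stop("ragged rows in ", path)
  body_width <- widths[2]
  parse_row <- function(l) {
    v <- suppressWarnings(as.numeric(tok(l)))
    if (any(is.na(v))) stop("non-numeric data row in ", path)
    v
  }
  first <- tok(lines[1])
  first_num <- suppressWarnings(as.numeric(first))
  first_is_data <- !any(is.na(first_num)) && length(first) == body_width
  if (body_width == 2) {
    # single spectrum; tolerate a one-line label header
    data_lines <- if (first_is_data) lines else lines[-1]
    m <- do.call(rbind, lapply(data_lines, parse_row))
    return(cd_spectrum(m[, 1], m[, 2]))
  }
  # melting matrix: first line must be the temperature header (optionally
  # prefixed by a label for the wavelength column)
  temps <- first_num[!is.na(first_num)]
  if (length(temps) != body_width - 1)
    stop("header width does not match data rows in ", path)
  m <- do.call(rbind, lapply(lines[-1], parse_row))
  cd_melting_matrix(m[, 1], temps, m[, -1, drop = FALSE])
}

#' Write a CD melting matrix as delimited text
#'
#' @param d A [cd_melting_matrix()] or [cd_spectrum()].
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_cd_matrix <- function(d, path) {
  if (inherits(d, "cd_spectrum")) {
    utils::write.table(data.frame(wavelength = d$wavelengths,
                                  ellipticity = d$ellipticity),
                       path, row.names = FALSE, col.names = TRUE, quote = FALSE)
    return(invisible(path))
  }
  stopifnot(inherits(d, "cd_melting_matrix"))
  header <- paste(c("wavelength", format(d$temperatures, trim = TRUE)),
                  collapse = "\t")
  body <- vapply(seq_along(d$wavelengths), function(i) {
    paste(c(format(d$wavelengths[i], trim = TRUE),
            format(d$ellipticity[i, ], trim = TRUE, digits = 10)),
          collapse = "\t")
  }, character(1))
  writeLines(c(header, body), path)
  invisible(path)
}
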