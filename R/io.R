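# Readers and writers: two-column kinetic traces, time-explicit ASCII and
# long-CSV spectro-temporal matrices, component spectra and JSON results.
# All numeric payloads round-trip at full double precision.

.fmt <- function(x) sprintf("%.17g", x)

#' Write a kinetic trace to a two-column text file
#'
#' Format: '#'-prefixed comment lines carrying the metadata, then one
#' `time_ns deltaA` pair per line.
#'
#' @param trace A [kinetic_trace()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_kinetic_trace <- function(trace, path) {
  stopifnot(inherits(trace, "kinetic_trace"))
  lines <- c(
    "# kinetic trace: time_ns deltaA",
    sprintf("# wavelength_nm %s", .fmt(trace$wavelength_nm)),
    sprintf("# temperature_K %s", .fmt(trace$temperature_K)),
    paste(.fmt(trace$times), .fmt(trace$deltaA))
  )
  writeLines(lines, path)
  invisible(path)
}

#' Read a kinetic trace from a two-column text file
#'
#' @param path File with two whitespace- or comma-separated numeric columns
#'   (time in ns, deltaA); '#' lines are comments. Metadata comments written
#'   by [write_kinetic_trace()] are recovered.
#' @return A [kinetic_trace()].
#' @export
read_kinetic_trace <- function(path) {
  lines <- readLines(path)
  meta <- list(wavelength_nm = NA_real_, temperature_K = NA_real_)
  for (key in names(meta)) {
    hit <- grep(paste0("^#\\s*", key, "\\s"), lines, value = TRUE)
    if (length(hit)) {
      meta[[key]] <- suppressWarnings(as.numeric(sub(".*\\s", "", hit[1])))
    }
  }
  data_idx <- which(!grepl("^\\s*(#|$)", lines))
  if (!length(data_idx)) {
    stop("parse error: no data lines in ", path, call. = FALSE)
  }
  parse_row <- function(i) {
    fields <- strsplit(trimws(lines[i]), "[,[:space:]]+")[[1]]
    vals <- suppressWarnings(as.numeric(fields))
    if (length(vals) != 2 || anyNA(vals)) {
      stop("parse error at line ", i, ": expected two numeric columns",
           call. = FALSE)
    }
    vals
  }
  m <- t(vapply(data_idx, parse_row, numeric(2)))
  kinetic_trace(m[, 1], m[, 2], wavelength_nm = meta$wavelength_nm,
                temperature_K = meta$temperature_K)
}

#' Write a spectro-temporal matrix (time-explicit ASCII or long CSV)
#'
#' Time-explicit dialect: a header line carrying the IRF metadata, the line
#' `Time explicit`, the line `Intervalnr <n>`, a row with the `n` delay
#' values, then one row per wavelength (`wavelength value1 ... valueN`).
#' Long-CSV dialect: '#' IRF comments, a `wavelength_nm,time_ps,deltaA`
#' header and one row per matrix cell.
#'
#' @param tam A [ta_matrix()].
#' @param path Output file path.
#' @param dialect `"matrix"` (time-explicit, default) or `"csv"` (long).
#' @return `path`, invisibly.
#' @export
write_ta_matrix <- function(tam, path, dialect = c("matrix", "csv")) {
  stopifnot(inherits(tam, "ta_matrix"))
  dialect <- match.arg(dialect)
  if (dialect == "matrix") {
    lines <- c(
      sprintf("TA matrix t0_ps=%s fwhm_ps=%s", .fmt(tam$irf$t0),
              .fmt(tam$irf$fwhm)),
      "Time explicit",
      sprintf("Intervalnr %d", length(tam$times)),
      paste(.fmt(tam$times), collapse = "\t"),
      vapply(seq_along(tam$wavelengths), function(i) {
        paste(c(.fmt(tam$wavelengths[i]), .fmt(tam$deltaA[i, ])),
              collapse = "\t")
      }, character(1))
    )
    writeLines(lines, path)
  } else {
    grid <- expand.grid(ti = seq_along(tam$times),
                        wi = seq_along(tam$wavelengths))
    lines <- c(
      sprintf("# t0_ps %s", .fmt(tam$irf$t0)),
      sprintf("# fwhm_ps %s", .fmt(tam$irf$fwhm)),
      "wavelength_nm,time_ps,deltaA",
      sprintf("%s,%s,%s", .fmt(tam$wavelengths[grid$wi]),
              .fmt(tam$times[grid$ti]),
              .fmt(tam$deltaA[cbind(grid$wi, grid$ti)]))
    )
    writeLines(lines, path)
  }
  invisible(path)
}

#' Read a spectro-temporal matrix
#'
#' Accepts both dialects written by [write_ta_matrix()]; the dialect is
#' detected from the file content. Malformed headers or rows raise parse
#' errors naming the offending line.
#'
#' @param path Input file path.
#' @return A [ta_matrix()].
#' @export
read_ta_matrix <- function(path) {
  lines <- readLines(path)
  if (any(grepl("^wavelength_nm,time_ps,deltaA$", lines))) {
    return(.read_ta_csv(lines, path))
  }
  if (length(lines) < 5) {
    stop("parse error: time-explicit file needs a header, 'Time explicit', ",
         "'Intervalnr', a time row and at least one wavelength row",
         call. = FALSE)
  }
  irf <- list(t0 = 0, fwhm = 0.4)
  for (key in c("t0", "fwhm")) {
    m <- regmatches(lines[1],
                    regexpr(paste0(key, "_ps=([-0-9.eE+]+)"), lines[1]))
    if (length(m)) irf[[key]] <- as.numeric(sub(".*=", "", m))
  }
  if (!grepl("^\\s*Time explicit\\s*$", lines[2])) {
    stop("parse error at line 2: expected 'Time explicit'", call. = FALSE)
  }
  if (!grepl("^\\s*Intervalnr\\s+\\d+\\s*$", lines[3])) {
    stop("parse error at line 3: expected 'Intervalnr <n>'", call. = FALSE)
  }
  n <- as.integer(sub(".*?(\\d+).*", "\\1", lines[3]))
  times <- suppressWarnings(as.numeric(strsplit(trimws(lines[4]),
                                                "[,[:space:]]+")[[1]]))
  if (length(times) != n || anyNA(times)) {
    stop("parse error at line 4: expected ", n, " numeric time points",
         call. = FALSE)
  }
  rows <- lines[-(1:4)]
  rows <- rows[nzchar(trimws(rows))]
  wl <- numeric(length(rows))
  dA <- matrix(NA_real_, length(rows), n)
  for (i in seq_along(rows)) {
    vals <- suppressWarnings(as.numeric(strsplit(trimws(rows[i]),
                                                 "[,[:space:]]+")[[1]]))
    if (length(vals) != n + 1 || anyNA(vals)) {
      stop("parse error at line ", i + 4, ": expected a wavelength plus ", n,
           " values", call. = FALSE)
    }
    wl[i] <- vals[1]
    dA[i, ] <- vals[-1]
  }
  ta_matrix(wl, times, dA, irf)
}

# long-CSV dialect reader
.read_ta_csv <- function(lines, path) {
  irf <- list(t0 = 0, fwhm = 0.4)
  for (key in c("t0", "fwhm")) {
    hit <- grep(paste0("^#\\s*", key, "_ps\\s"), lines, value = TRUE)
    if (length(hit)) irf[[key]] <- as.numeric(sub(".*\\s", "", hit[1]))
  }
  hdr <- which(grepl("^wavelength_nm,time_ps,deltaA$", lines))[1]
  body <- lines[-seq_len(hdr)]
  body <- body[nzchar(trimws(body)) & !grepl("^#", body)]
  parts <- strsplit(body, ",")
  bad <- which(lengths(parts) != 3)[1]
  if (!is.na(bad)) {
    stop("parse error at line ", hdr + bad, ": expected three CSV fields",
         call. = FALSE)
  }
  m <- matrix(suppressWarnings(as.numeric(unlist(parts))), ncol = 3,
              byrow = TRUE)
  if (anyNA(m)) {
    stop("parse error: non-numeric CSV payload in ", path, call. = FALSE)
  }
  wl <- sort(unique(m[, 1]))
  tt <- sort(unique(m[, 2]))
  dA <- matrix(NA_real_, length(wl), length(tt))
  dA[cbind(match(m[, 1], wl), match(m[, 2], tt))] <- m[, 3]
  if (anyNA(dA)) {
    stop("parse error: CSV does not cover the full wavelength x time grid",
         call. = FALSE)
  }
  ta_matrix(wl, tt, dA, irf)
}

#' Write component spectra (DADS/SADS) to CSV
#'
#' '#' comments carry the kind and lifetimes; columns are `wavelength_nm`
#' followed by one column per kinetic component.
#'
#' @param cs A [component_spectra()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_component_spectra <- function(cs, path) {
  stopifnot(inherits(cs, "component_spectra"))
  cols <- colnames(cs$spectra)
  if (is.null(cols)) cols <- paste0("component", seq_along(cs$lifetimes))
  lines <- c(
    sprintf("# kind %s", cs$kind),
    sprintf("# lifetimes %s", paste(.fmt(cs$lifetimes), collapse = " ")),
    sprintf("# fixed %s", paste(as.integer(cs$fixed), collapse = " ")),
    paste(c("wavelength_nm", cols), collapse = ","),
    vapply(seq_along(cs$wavelengths), function(i) {
      paste(.fmt(c(cs$wavelengths[i], cs$spectra[i, ])), collapse = ",")
    }, character(1))
  )
  writeLines(lines, path)
  invisible(path)
}

#' Read component spectra written by [write_component_spectra()]
#' @param path Input file path.
#' @return A [component_spectra()].
#' @export
read_component_spectra <- function(path) {
  lines <- readLines(path)
  grab <- function(key) {
    hit <- grep(paste0("^#\\s*", key, "\\s"), lines, value = TRUE)
    if (!length(hit)) stop("parse error: missing '# ", key, "' header in ",
                           path, call. = FALSE)
    strsplit(sub(paste0("^#\\s*", key, "\\s+"), "", hit[1]), "\\s+")[[1]]
  }
  kind <- grab("kind")
  lifetimes <- as.numeric(grab("lifetimes"))
  fixed <- as.logical(as.integer(grab("fixed")))
  hdr <- which(grepl("^wavelength_nm,", lines))[1]
  if (is.na(hdr)) stop("parse error: missing column header in ", path,
                       call. = FALSE)
  cols <- strsplit(lines[hdr], ",")[[1]][-1]
  body <- lines[-seq_len(hdr)]
  body <- body[nzchar(trimws(body))]
  m <- matrix(suppressWarnings(as.numeric(unlist(strsplit(body, ",")))),
              nrow = length(body), byrow = TRUE)
  if (anyNA(m) || ncol(m) != length(cols) + 1) {
    stop("parse error: malformed spectra rows in ", path, call. = FALSE)
  }
  sp <- m[, -1, drop = FALSE]
  colnames(sp) <- cols
  component_spectra(kind, lifetimes, fixed, sp, m[, 1])
}

#' Write an analysis result as JSON
#'
#' Serializes a named list (fit parameters, extraction results, lifetimes,
#' branching fractions, ...) with full numeric precision and stable key
#' order, so identical inputs give byte-identical files.
#'
#' @param x Named list (classed objects are unclassed; matrices dropped).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_results_json <- function(x, path) {
  clean <- function(v) {
    if (is.list(v)) {
      v <- lapply(unclass(v), clean)
      v[!vapply(v, is.null, logical(1))]
    } else if (is.matrix(v)) {
      NULL
    } else if (is.numeric(v)) {
      ifelse(is.finite(v), v, NA_real_) * 1  # JSON has no Inf
    } else {
      v
    }
  }
  jsonlite::write_json(clean(x), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  invisible(path)
}

#' Read a JSON results file
#' @param path Input file path.
#' @return Named list.
#' @export
read_results_json <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}
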