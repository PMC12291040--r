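#' Construct a single MS/MS spectrum record
#'
#' A `spectrum_record` holds one analyte's centroided MS/MS peak list
#' together with its precursor m/z, retention time (minutes) and an
#' optional drug-class label.
#'
#' @param analyte_id character scalar identifying the analyte.
#' @param precursor_mz precursor mass-to-charge ratio (Th), > 0.
#' @param rt_min retention time in minutes, >= 0.
#' @param peaks two-column numeric matrix (or data.frame) of fragment
#'   m/z and intensity; m/z > 0, intensities >= 0.
#' @param class_label drug-class label; `""` for unknowns.
#' @param ce_range_tag collision-energy ramp tag, e.g. `"10-30V"`.
#' @return an object of class `spectrum_record`.
#' @export
spectrum_record <- function(analyte_id, precursor_mz, rt_min, peaks,
                            class_label = "", ce_range_tag = "10-30V") {
  peaks <- as.matrix(peaks)
  if (ncol(peaks) != 2L) stop("peaks must have two columns (mz, intensity)")
  storage.mode(peaks) <- "double"
  colnames(peaks) <- c("mz", "intensity")
  if (!is.numeric(precursor_mz) || length(precursor_mz) != 1L ||
      is.na(precursor_mz) || precursor_mz <= 0) {
    stop("precursor_mz must be a single positive number (record ",
         sQuote(analyte_id), ")")
  }
  if (!is.numeric(rt_min) || length(rt_min) != 1L || is.na(rt_min) ||
      rt_min < 0) {
    stop("rt_min must be a single non-negative number (record ",
         sQuote(analyte_id), ")")
  }
  if (nrow(peaks) && (anyNA(peaks) || any(peaks[, 1L] <= 0) ||
                      any(peaks[, 2L] < 0))) {
    stop("peaks must have mz > 0 and intensity >= 0 (record ",
         sQuote(analyte_id), ")")
  }
  structure(
    list(analyte_id = as.character(analyte_id),
         class_label = as.character(class_label),
         precursor_mz = as.numeric(precursor_mz),
         rt_min = as.numeric(rt_min),
         peaks = peaks,
         ce_range_tag = as.character(ce_range_tag)),
    class = "spectrum_record")
}

#' @export
print.spectrum_record <- function(x, ...) {
  cat(sprintf("<spectrum_record> %s  class=%s  precursor=%.4f Th  RT=%.2f min  %d peaks (%s)\n",
              x$analyte_id,
              if (nzchar(x$class_label)) x$class_label else "?",
              x$precursor_mz, x$rt_min, nrow(x$peaks), x$ce_range_tag))
  invisible(x)
}

#' Parse spectral input files into spectrum records
#'
#' Reads centroided MS/MS peak lists from MGF (`BEGIN IONS`/`END IONS`
#' blocks with `PEPMASS`, `RTINSECONDS` and an optional `CLASS=` user
#' field), MSP (`Name:`, `PrecursorMZ:`, `RT:` in minutes, `Comment:
#' class=...`, `Num Peaks:`) or a long-format CSV peak list with columns
#' `analyte_id,class,precursor_mz,rt_min,fragment_mz,intensity`.
#'
#' Retention times in MGF `RTINSECONDS` are converted to minutes; MSP
#' `RT:` values are taken to be minutes already.
#'
#' @param path path to the input file.
#' @param format one of `"mgf"`, `"msp"`, `"csv_peaks"`.
#' @return list of [spectrum_record()] objects (empty list for an empty
#'   file).
#' @export
parse_spectra <- function(path, format = c("mgf", "msp", "csv_peaks")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  switch(format,
         mgf = .parse_mgf(path),
         msp = .parse_msp(path),
         csv_peaks = .parse_csv_peaks(path))
}

.num_or_fail <- function(x, what, where) {
  v <- suppressWarnings(as.numeric(x))
  if (is.na(v)) stop("non-numeric ", what, " ", sQuote(x), " in ", where)
  v
}

.parse_mgf <- function(path) {
  lines <- trimws(readLines(path, warn = FALSE))
  records <- list()
  i <- 1L; n <- length(lines); rec_idx <- 0L
  while (i <= n) {
    if (!nzchar(lines[i]) || startsWith(lines[i], "#")) { i <- i + 1L; next }
    if (lines[i] != "BEGIN IONS") {
      stop("malformed MGF: expected BEGIN IONS at line ", i,
           ", got ", sQuote(lines[i]))
    }
    rec_idx <- rec_idx + 1L
    meta <- list(TITLE = sprintf("spectrum_%d", rec_idx))
    peaks <- NULL
    i <- i + 1L
    while (i <= n && lines[i] != "END IONS") {
      ln <- lines[i]
      if (!nzchar(ln)) { i <- i + 1L; next }
      if (grepl("^[A-Za-z][A-Za-z0-9_]*=", ln)) {
        key <- sub("=.*$", "", ln)
        meta[[toupper(key)]] <- sub("^[^=]*=", "", ln)
      } else {
        parts <- strsplit(ln, "[ \t]+")[[1]]
        if (length(parts) < 2L) {
          stop("malformed MGF peak line in record ", rec_idx,
               " (line ", i, "): ", sQuote(ln))
        }
        mz <- .num_or_fail(parts[1L], "m/z",
                           sprintf("record %d line %d", rec_idx, i))
        it <- .num_or_fail(parts[2L], "intensity",
                           sprintf("record %d line %d", rec_idx, i))
        peaks <- rbind(peaks, c(mz, it))
      }
      i <- i + 1L
    }
    if (i > n) stop("malformed MGF: record ", rec_idx, " has no END IONS")
    if (is.null(meta$PEPMASS)) {
      stop("MGF record ", rec_idx, " (", meta$TITLE, ") has no PEPMASS")
    }
    pep <- strsplit(trimws(meta$PEPMASS), "[ \t]+")[[1]][1L]
    rt_min <- if (!is.null(meta$RTINSECONDS)) {
      .num_or_fail(meta$RTINSECONDS, "RTINSECONDS",
                   sprintf("record %d", rec_idx)) / 60
    } else 0
    records[[rec_idx]] <- spectrum_record(
      analyte_id = meta$TITLE,
      precursor_mz = .num_or_fail(pep, "PEPMASS", sprintf("record %d", rec_idx)),
      rt_min = rt_min,
      peaks = if (is.null(peaks)) matrix(numeric(), 0L, 2L) else peaks,
      class_label = if (!is.null(meta$CLASS)) meta$CLASS else "")
    i <- i + 1L
  }
  records
}

.parse_msp <- function(path) {
  lines <- readLines(path, warn = FALSE)
  records <- list()
  i <- 1L; n <- length(lines); rec_idx <- 0L
  while (i <= n) {
    ln <- trimws(lines[i])
    if (!nzchar(ln)) { i <- i + 1L; next }
    if (!grepl("^Name:", ln, ignore.case = TRUE)) {
      stop("malformed MSP: expected 'Name:' at line ", i, ", got ", sQuote(ln))
    }
    rec_idx <- rec_idx + 1L
    name <- trimws(sub("^Name:", "", ln, ignore.case = TRUE))
    precursor <- NA_real_; rt <- 0; klass <- ""; num_peaks <- NA_integer_
    i <- i + 1L
    while (i <= n && !grepl("^Num Peaks:", trimws(lines[i]), ignore.case = TRUE)) {
      fl <- trimws(lines[i])
      if (grepl("^PrecursorMZ:", fl, ignore.case = TRUE)) {
        precursor <- .num_or_fail(trimws(sub("^PrecursorMZ:", "", fl,
                                             ignore.case = TRUE)),
                                  "PrecursorMZ", sQuote(name))
      } else if (grepl("^(RT|RetentionTime):", fl, ignore.case = TRUE)) {
        rt <- .num_or_fail(trimws(sub("^(RT|RetentionTime):", "", fl,
                                      ignore.case = TRUE)),
                           "RT", sQuote(name))
      } else if (grepl("^Comment:", fl, ignore.case = TRUE)) {
        cm <- regmatches(fl, regexpr("class=[^ ;]+", fl, ignore.case = TRUE))
        if (length(cm)) klass <- sub("^class=", "", cm, ignore.case = TRUE)
      }
      i <- i + 1L
    }
    if (i > n) stop("MSP record ", sQuote(name), " has no 'Num Peaks:' line")
    num_peaks <- as.integer(.num_or_fail(
      trimws(sub("^Num Peaks:", "", trimws(lines[i]), ignore.case = TRUE)),
      "Num Peaks", sQuote(name)))
    i <- i + 1L
    peaks <- NULL
    while (i <= n && nzchar(trimws(lines[i]))) {
      parts <- strsplit(trimws(lines[i]), "[ \t;]+")[[1]]
      if (length(parts) < 2L || length(parts) %% 2L != 0L) {
        stop("malformed MSP peak line in record ", sQuote(name),
             " (line ", i, "): ", sQuote(trimws(lines[i])))
      }
      vals <- vapply(parts, .num_or_fail, numeric(1L),
                     what = "peak value", where = sQuote(name))
      peaks <- rbind(peaks, matrix(vals, ncol = 2L, byrow = TRUE))
      i <- i + 1L
    }
    npk <- if (is.null(peaks)) 0L else nrow(peaks)
    if (npk != num_peaks) {
      stop("MSP record ", sQuote(name), ": 'Num Peaks: ", num_peaks,
           "' but ", npk, " peaks read")
    }
    if (is.na(precursor)) {
      stop("MSP record ", sQuote(name), " has no PrecursorMZ")
    }
    records[[rec_idx]] <- spectrum_record(
      analyte_id = name, precursor_mz = precursor, rt_min = rt,
      peaks = if (is.null(peaks)) matrix(numeric(), 0L, 2L) else peaks,
      class_label = klass)
  }
  records
}

.parse_csv_peaks <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("analyte_id", "class", "precursor_mz", "rt_min",
            "fragment_mz", "intensity")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols)) {
    stop("csv_peaks file lacks column(s): ", paste(missing_cols, collapse = ", "))
  }
  if (!nrow(df)) return(list())
  ids <- unique(df$analyte_id)
  lapply(ids, function(id) {
    block <- df[df$analyte_id == id, , drop = FALSE]
    spectrum_record(
      analyte_id = id,
      precursor_mz = block$precursor_mz[1L],
      rt_min = block$rt_min[1L],
      peaks = cbind(block$fragment_mz, block$intensity),
      class_label = as.character(block$class[1L]))
  })
}

#' Write spectrum records to an MGF file
#'
#' Inverse of [parse_spectra()] for the MGF dialect; used by the
#' synthetic-panel generator so fixtures round-trip through the parser.
#'
#' @param records list of [spectrum_record()] objects.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_mgf <- function(records, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (r in records) {
    writeLines(c("BEGIN IONS",
                 paste0("TITLE=", r$analyte_id),
                 paste0("PEPMASS=", format(r$precursor_mz, digits = 15)),
                 paste0("RTINSECONDS=", format(r$rt_min * 60, digits = 15)),
                 if (nzchar(r$class_label)) paste0("CLASS=", r$class_label),
                 paste(format(r$peaks[, 1L], digits = 15, trim = TRUE),
                       format(r$peaks[, 2L], digits = 15, trim = TRUE)),
                 "END IONS", ""), con)
  }
  invisible(path)
}
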