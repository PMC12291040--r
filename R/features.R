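.FEATURE_COLS <- c("precursor_mz", "rt_min", "frag1_mz", "frag2_mz",
                   "frag3_mz", "nl1", "nl2", "nl3")

#' Extract the 8-variable feature vector from one spectrum
#'
#' Fragments with relative intensity (intensity divided by the base-peak
#' intensity) at or above `rel_intensity_threshold` are ranked by
#' descending intensity; the top three fill the fragment slots.  Each
#' fragment's neutral loss is the absolute difference between a
#' reference m/z and the fragment m/z.  The reference is either the
#' base peak (so the top-ranked fragment has a neutral loss of exactly
#' 0 when it is the base peak) or the precursor ion, the usual chemical
#' convention.  Intensity ties are broken by lower m/z, then input
#' order, so the matrix is deterministic.
#'
#' Fewer than three surviving fragments leave the remaining slots
#' missing (`NA`), never silently zero; downstream imputation is an
#' explicit, separate step (see [autoscale_fit()]).
#'
#' @param record a [spectrum_record()].
#' @param rel_intensity_threshold minimum relative intensity (fraction
#'   of the base peak) for a fragment to enter the ranking; the
#'   comparison is inclusive (`>=`).  Default 0.10.
#' @param nl_reference `"base_peak"` or `"precursor"`: the reference ion
#'   for neutral-loss computation.
#' @param include_base_peak if `FALSE` the base peak itself is excluded
#'   from the ranked fragment slots (its neutral loss in base-peak mode
#'   is identically 0, which makes the matrix column constant; see the
#'   package vignette).
#' @return named numeric vector of length 8 (`precursor_mz, rt_min,
#'   frag1_mz, frag2_mz, frag3_mz, nl1, nl2, nl3`), `NA` for missing
#'   slots, with attribute `missing_mask` (logical, length 6) covering
#'   the fragment/neutral-loss slots.
#' @export
extract_features <- function(record,
                             rel_intensity_threshold = 0.10,
                             nl_reference = c("base_peak", "precursor"),
                             include_base_peak = TRUE) {
  nl_reference <- match.arg(nl_reference)
  stopifnot(inherits(record, "spectrum_record"))
  pk <- record$peaks
  if (!nrow(pk)) stop("empty peak list for record ", sQuote(record$analyte_id))
  if (all(pk[, "intensity"] == 0)) {
    stop("all-zero intensities for record ", sQuote(record$analyte_id))
  }
  ord <- order(-pk[, "intensity"], pk[, "mz"], seq_len(nrow(pk)))
  base_i <- ord[1L]
  base_int <- pk[base_i, "intensity"]
  rel <- pk[, "intensity"] / base_int
  keep <- rel >= rel_intensity_threshold
  if (!include_base_peak) keep[base_i] <- FALSE
  surv <- ord[keep[ord]]
  ref_mz <- switch(nl_reference,
                   base_peak = pk[base_i, "mz"],
                   precursor = record$precursor_mz)
  frag <- rep(NA_real_, 3L)
  nl <- rep(NA_real_, 3L)
  k <- min(3L, length(surv))
  if (k > 0L) {
    frag[seq_len(k)] <- pk[surv[seq_len(k)], "mz"]
    nl[seq_len(k)] <- abs(ref_mz - frag[seq_len(k)])
  }
  out <- c(record$precursor_mz, record$rt_min, frag, nl)
  names(out) <- .FEATURE_COLS
  attr(out, "missing_mask") <- is.na(c(frag, nl))
  out
}

#' Build the n x 8 feature matrix from spectrum records
#'
#' Applies [extract_features()] to every record and stacks the results,
#' preserving row order.  Records whose extraction fails are collected
#' and reported together.
#'
#' @param records non-empty list of [spectrum_record()] objects.
#' @param ... passed to [extract_features()].
#' @return a `feature_matrix`: list with `values` (n x 8 numeric matrix,
#'   `NA` = missing), `missing_mask` (n x 8 logical), `analyte_id` and
#'   `class_label` character vectors.
#' @export
build_matrix <- function(records, ...) {
  if (!length(records)) stop("no records to build a matrix from")
  rows <- vector("list", length(records))
  failures <- character()
  for (i in seq_along(records)) {
    fv <- tryCatch(extract_features(records[[i]], ...), error = function(e) e)
    if (inherits(fv, "error")) {
      failures <- c(failures, sprintf("%s (%s)", records[[i]]$analyte_id,
                                      conditionMessage(fv)))
    } else rows[[i]] <- fv
  }
  if (length(failures)) {
    stop("feature extraction failed for: ", paste(failures, collapse = "; "))
  }
  values <- do.call(rbind, rows)
  rownames(values) <- NULL
  feature_matrix(values,
                 analyte_id = vapply(records, `[[`, "", "analyte_id"),
                 class_label = vapply(records, `[[`, "", "class_label"))
}

#' Construct a feature matrix object
#'
#' @param values n x 8 numeric matrix with the fixed column order
#'   `precursor_mz, rt_min, frag1_mz, frag2_mz, frag3_mz, nl1, nl2, nl3`;
#'   `NA` marks missing fragment/neutral-loss slots.
#' @param analyte_id,class_label character vectors of length n.
#' @return object of class `feature_matrix`.
#' @export
feature_matrix <- function(values, analyte_id = NULL, class_label = NULL) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (ncol(values) != 8L) stop("a feature matrix has exactly 8 columns")
  colnames(values) <- .FEATURE_COLS
  n <- nrow(values)
  if (is.null(analyte_id)) analyte_id <- sprintf("sample_%d", seq_len(n))
  if (is.null(class_label)) class_label <- rep("", n)
  stopifnot(length(analyte_id) == n, length(class_label) == n)
  structure(list(values = values,
                 missing_mask = is.na(values),
                 analyte_id = as.character(analyte_id),
                 class_label = as.character(class_label)),
            class = "feature_matrix")
}

#' @export
print.feature_matrix <- function(x, ...) {
  tab <- table(factor(x$class_label, exclude = NULL))
  cat(sprintf("<feature_matrix> %d analytes x 8 variables; %d missing cells\n",
              nrow(x$values), sum(x$missing_mask)))
  cat("classes:", paste(sprintf("%s (%d)", names(tab), tab), collapse = ", "),
      "\n")
  invisible(x)
}

#' @export
dim.feature_matrix <- function(x) dim(x$values)

#' @export
as.data.frame.feature_matrix <- function(x, ...) {
  data.frame(analyte_id = x$analyte_id, class = x$class_label,
             x$values, stringsAsFactors = FALSE)
}

#' Subset a feature matrix by row
#' @param x a `feature_matrix`.
#' @param i row index vector.
#' @param ... ignored.
#' @export
`[.feature_matrix` <- function(x, i, ...) {
  feature_matrix(x$values[i, , drop = FALSE],
                 analyte_id = x$analyte_id[i],
                 class_label = x$class_label[i])
}

#' Write a feature matrix to CSV
#'
#' Header `analyte_id,class,precursor_mz,rt_min,frag1_mz,frag2_mz,
#' frag3_mz,nl1,nl2,nl3`; missing cells are written blank.  Dot decimal,
#' UTF-8, full double precision so write/read round-trips losslessly.
#'
#' @param x a `feature_matrix`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(x, path) {
  df <- as.data.frame(x)
  num <- vapply(df, is.numeric, logical(1L))
  df[num] <- lapply(df[num], function(col)
    ifelse(is.na(col), "", format(col, digits = 17, trim = TRUE,
                                  scientific = FALSE)))
  utils::write.csv(df, path, row.names = FALSE, quote = TRUE, na = "")
  invisible(path)
}

#' Read a feature matrix from CSV
#'
#' Parses a feature-table CSV in the dialect written by
#' [write_feature_table()] (the same 8 variable columns used by
#' published screening feature tables, plus analyte and class columns).
#' Blank or `NA` cells are flagged missing; numbers are parsed with dot
#' decimal regardless of locale.
#'
#' @param path CSV path.
#' @return a `feature_matrix`.
#' @export
read_feature_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  need <- c("analyte_id", "class", .FEATURE_COLS)
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols)) {
    stop("feature table lacks required column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  vals <- sapply(.FEATURE_COLS, function(cn) {
    raw <- trimws(df[[cn]])
    blank <- !nzchar(raw) | toupper(raw) == "NA"
    v <- suppressWarnings(as.numeric(raw))
    bad <- !blank & is.na(v)
    if (any(bad)) {
      stop("non-numeric value ", sQuote(raw[which(bad)[1L]]),
           " in column ", sQuote(cn))
    }
    v
  })
  if (!is.matrix(vals)) vals <- matrix(vals, ncol = 8L)
  feature_matrix(vals, analyte_id = df$analyte_id, class_label = df$class)
}
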