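#' Build a resolved pipeline configuration
#'
#' Defaults follow the conventions of published UPLC-HRMS/MS screening
#' workflows: 10 percent relative-intensity threshold for fragment
#' selection, 75/25 Kennard-Stone split, 95 percent confidence limits,
#' modeling floor of four analytes per class.  The neutral-loss
#' reference defaults to the precursor ion at the pipeline level so the
#' matrix is full rank (see the package vignette for why the base-peak
#' reference with the base peak in slot 1 yields a constant column).
#'
#' @param ... named overrides of the defaults.
#' @param file optional YAML file of overrides (flags in `...` win).
#' @return object of class `run_config` (a named list).
#' @export
run_config <- function(..., file = NULL) {
  cfg <- list(threshold = 0.10, nl_reference = "precursor",
              include_base_peak = TRUE,
              fraction = 0.75, train_count = NULL,
              alpha = 0.05, rule = "chi2", classes_min = 4L,
              cv_scheme = "auto", A_max = 5L, q_method = "moment_chi2",
              seed = 7L)
  if (!is.null(file)) {
    if (!file.exists(file)) stop("config file not found: ", file)
    fromfile <- yaml::read_yaml(file)
    cfg[names(fromfile)] <- fromfile
  }
  dots <- list(...)
  bad <- setdiff(names(dots), names(cfg))
  if (length(bad)) stop("unknown config key(s): ", paste(bad, collapse = ", "))
  cfg[names(dots)] <- dots
  stopifnot(cfg$threshold > 0, cfg$threshold <= 1,
            cfg$fraction > 0, cfg$fraction <= 1,
            cfg$alpha > 0, cfg$alpha < 1, cfg$classes_min >= 2)
  structure(cfg, class = "run_config")
}

#' Run the full screening workflow
#'
#' Build (or load) the feature matrix, Kennard-Stone split it, fit
#' per-class SIMCA models on the training rows, validate on training
#' and test rows, optionally screen unknown spectra, and write every
#' artifact with a stable filename plus a manifest of content hashes.
#' The pipeline contains no randomness, so rerunning with identical
#' inputs and configuration reproduces identical hashes.
#'
#' The modeling floor (`classes_min`) is applied to the full-panel
#' class sizes, as screening panels do: a class with at least
#' `classes_min` analytes overall is modeled on whatever training rows
#' the split assigns it.
#'
#' @param input a `feature_matrix`, a path to a feature-table CSV, or a
#'   path to an MGF/MSP spectra file.
#' @param outdir output directory (created if needed).
#' @param config a [run_config()].
#' @param format input format when `input` is a spectra path
#'   (`"mgf"`, `"msp"`, `"csv_peaks"`); `"table"` for a feature-table
#'   CSV (the default guesses from the extension).
#' @param pc_counts optional named vector fixing the per-class
#'   component counts (skips cross-validated selection) — the workflow
#'   used to re-run a published panel whose PC counts are reported.
#' @param classes optional character vector restricting which classes
#'   are modeled (default: every class at or above the floor).
#' @param screen optional spectra file (or `feature_matrix`) of
#'   unknowns to classify against the fitted panel.
#' @return invisibly, a list with `matrix`, `split`, `fit`, `report`,
#'   `predictions` (or `NULL`), and `manifest` (data.frame of files and
#'   MD5 hashes).
#' @export
run_pipeline <- function(input, outdir, config = run_config(),
                         format = NULL, pc_counts = NULL, classes = NULL,
                         screen = NULL) {
  stopifnot(inherits(config, "run_config"))
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  message("resolved config: ",
          paste(names(config), vapply(config, function(v)
            paste(format(v), collapse = ","), ""), sep = "=", collapse = " "))

  load_features <- function(src, fmt) {
    if (inherits(src, "feature_matrix")) return(src)
    if (is.null(fmt)) {
      fmt <- if (grepl("\\.mgf$", src, ignore.case = TRUE)) "mgf"
      else if (grepl("\\.msp$", src, ignore.case = TRUE)) "msp"
      else "table"
    }
    if (fmt == "table") return(read_feature_table(src))
    build_matrix(parse_spectra(src, fmt),
                 rel_intensity_threshold = config$threshold,
                 nl_reference = config$nl_reference,
                 include_base_peak = config$include_base_peak)
  }

  message("stage: build-matrix")
  fm <- load_features(input, format)
  write_feature_table(fm, file.path(outdir, "matrix.csv"))

  message("stage: split")
  split <- kennard_stone_split(autoscale_fit(fm)$scaled,
                               train_fraction = config$fraction,
                               n_train = config$train_count)
  train <- fm[split$train]
  test <- fm[split$test]
  write_feature_table(train, file.path(outdir, "train.csv"))
  write_feature_table(test, file.path(outdir, "test.csv"))

  message("stage: fit")
  sizes <- table(fm$class_label[nzchar(fm$class_label)])
  eligible <- if (is.null(classes)) names(sizes)[sizes >= config$classes_min]
  else classes
  if (!length(eligible)) stop("no class reaches the modeling floor")
  fit <- simca(train, A = pc_counts, A_max = config$A_max,
               alpha = config$alpha, rule = config$rule,
               classes = eligible, cv_scheme = config$cv_scheme,
               q_method = config$q_method)
  write_models_json(fit, file.path(outdir, "models.json"))

  message("stage: validate")
  report <- rbind(validate_models(fit, train, set = "train"),
                  validate_models(fit, test, set = "test"))
  utils::write.csv(report, file.path(outdir, "report.csv"),
                   row.names = FALSE)

  predictions <- NULL
  if (!is.null(screen)) {
    message("stage: screen")
    unknowns <- load_features(screen, NULL)
    predictions <- predict(fit, unknowns)
    write_predictions_csv(predictions, file.path(outdir, "predictions.csv"))
  }

  files <- c("matrix.csv", "train.csv", "test.csv", "models.json",
             "report.csv", if (!is.null(predictions)) "predictions.csv")
  manifest <- data.frame(file = files,
                         md5 = unname(tools::md5sum(file.path(outdir, files))),
                         stringsAsFactors = FALSE)
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  message("wrote ", length(files) + 1L, " artifacts to ", outdir)
  invisible(list(matrix = fm, split = split, fit = fit, report = report,
                 predictions = predictions, manifest = manifest))
}

#' Write a predictions table
#'
#' One row per sample: the combined distance and verdict per class
#' model, then `accepted_classes`, a semicolon-separated (possibly
#' empty) list of accepting classes.
#'
#' @param pred a `simca_pred` from [predict.simca()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_predictions_csv <- function(pred, path) {
  wide <- data.frame(sample_id = rownames(pred$accepted),
                     stringsAsFactors = FALSE)
  for (k in colnames(pred$accepted)) {
    dk <- pred$distances[pred$distances$class_label == k, ]
    wide[[paste0("d_", k)]] <- dk$d
    wide[[paste0("accepted_", k)]] <- dk$accepted
  }
  wide$accepted_classes <- unname(pred$accepted_classes)
  utils::write.csv(wide, path, row.names = FALSE)
  invisible(path)
}
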