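#' Serialize a fitted SIMCA panel to JSON
#'
#' Writes the full numeric state of every class model (scaling means
#' and sds, loadings, eigenvalues, critical limits, acceptance-rule
#' parameters, alpha) at full double precision, so a panel re-read
#' with [read_models_json()] reproduces predictions bit-for-bit across
#' sessions.
#'
#' @param object a `simca` fit.
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_models_json <- function(object, path) {
  ser_class <- function(m) {
    list(class_label = m$class_label,
         A = m$A, alpha = m$alpha, rule = m$rule, q_method = m$q_method,
         n_train = m$n_train,
         center = unname(m$pca$scaling$center),
         scale = unname(m$pca$scaling$scale),
         missing_policy = m$pca$scaling$missing_policy,
         loadings = unname(m$pca$loadings),
         eigenvalues = m$pca$eigenvalues,
         eigenvalues_all = m$pca$eigenvalues_all,
         q_mean = m$pca$q_mean, q_var = m$pca$q_var,
         t2_crit = m$t2_crit, q_crit = m$q_crit,
         h0 = m$h0, q0 = m$q0, nh = m$nh, nq = m$nq,
         d_threshold = m$d_threshold)
  }
  payload <- list(format = "simcascreen-models",
                  version = 1L,
                  settings = object$settings,
                  excluded = object$excluded,
                  models = lapply(object$models, ser_class))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Read a SIMCA panel from JSON
#'
#' @param path JSON path written by [write_models_json()].
#' @return a `simca` object usable with [predict.simca()] and friends.
#' @export
read_models_json <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  payload <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(payload$format) || payload$format != "simcascreen-models") {
    stop("not a simcascreen model file: ", path)
  }
  de_class <- function(s) {
    p <- length(s$center)
    P <- matrix(unlist(s$loadings), nrow = p)
    rownames(P) <- .FEATURE_COLS[seq_len(p)]
    scaling <- structure(list(center = as.numeric(s$center),
                              scale = as.numeric(s$scale),
                              missing_policy = s$missing_policy),
                         class = "scaling_params")
    pca <- structure(list(scaling = scaling, loadings = P,
                          eigenvalues = as.numeric(s$eigenvalues),
                          eigenvalues_all = as.numeric(s$eigenvalues_all),
                          A = as.integer(s$A), n_train = as.integer(s$n_train),
                          scores = NULL, t2_train = NULL, q_train = NULL,
                          q_mean = s$q_mean, q_var = s$q_var),
                     class = "pca_model")
    structure(list(class_label = s$class_label, pca = pca,
                   A = as.integer(s$A), alpha = s$alpha, rule = s$rule,
                   q_method = s$q_method, t2_crit = s$t2_crit,
                   q_crit = s$q_crit, h0 = s$h0, q0 = s$q0,
                   nh = s$nh, nq = s$nq, d_threshold = s$d_threshold,
                   n_train = as.integer(s$n_train)),
              class = "simca_class")
  }
  models <- lapply(payload$models, de_class)
  names(models) <- vapply(models, `[[`, "", "class_label")
  info <- do.call(rbind, lapply(models, function(m)
    data.frame(class = m$class_label, n_train = m$n_train, A = m$A,
               cv_efficiency = NA_real_, d_threshold = m$d_threshold,
               stringsAsFactors = FALSE)))
  rownames(info) <- NULL
  structure(list(models = models, classes = info,
                 excluded = as.character(payload$excluded),
                 settings = payload$settings,
                 call = quote(read_models_json())),
            class = "simca")
}
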