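#' Fit autoscaling parameters and scale a matrix
#'
#' Missing cells are imputed (per `missing_policy`) before column means
#' and standard deviations (n-1 denominator) are computed; each scaled
#' column then has mean 0 and standard deviation 1.  Constant columns
#' cannot be autoscaled and raise an error naming the column.
#'
#' @param x a `feature_matrix` or numeric matrix (`NA` = missing).
#' @param missing_policy `"mean_impute"` (default: missing cells take
#'   the column mean of the observed values, so they scale to exactly
#'   0) or `"zero_fill"` (missing cells take 0 before scaling, matching
#'   pipelines that enter absent fragments as null data).
#' @return list with `params` (a `scaling_params`: `center`, `scale`,
#'   `missing_policy`) and `scaled` (the scaled numeric matrix, no
#'   `NA`s).
#' @export
autoscale_fit <- function(x, missing_policy = c("mean_impute", "zero_fill")) {
  missing_policy <- match.arg(missing_policy)
  v <- if (inherits(x, "feature_matrix")) x$values else as.matrix(x)
  if (nrow(v) < 2L) stop("autoscaling needs at least 2 rows")
  filled <- .impute(v, missing_policy)
  center <- colMeans(filled)
  scale <- apply(filled, 2L, stats::sd)
  if (any(scale <= 0 | !is.finite(scale))) {
    bad <- colnames(v)[scale <= 0 | !is.finite(scale)]
    if (is.null(bad)) bad <- which(scale <= 0 | !is.finite(scale))
    stop("constant column(s) cannot be autoscaled: ",
         paste(bad, collapse = ", "))
  }
  params <- structure(list(center = center, scale = scale,
                           missing_policy = missing_policy),
                      class = "scaling_params")
  list(params = params, scaled = autoscale_apply(params, filled))
}

.impute <- function(v, missing_policy) {
  if (!anyNA(v)) return(v)
  for (j in seq_len(ncol(v))) {
    na <- is.na(v[, j])
    if (any(na)) {
      fill <- switch(missing_policy,
                     zero_fill = 0,
                     mean_impute = {
                       if (all(na)) stop("column ", j, " entirely missing")
                       mean(v[!na, j])
                     })
      v[which(na), j] <- unname(fill)
    }
  }
  names(v) <- NULL  # element names picked up by subscript assignment
  v
}

#' Apply fitted scaling parameters to new rows
#'
#' @param params a `scaling_params` from [autoscale_fit()].
#' @param x matrix or `feature_matrix` of new rows; missing cells are
#'   imputed with the params' own policy (at the training column mean
#'   for `"mean_impute"`).
#' @return scaled numeric matrix.
#' @export
autoscale_apply <- function(params, x) {
  v <- if (inherits(x, "feature_matrix")) x$values else as.matrix(x)
  if (ncol(v) != length(params$center)) stop("column count mismatch")
  if (anyNA(v)) {
    for (j in seq_len(ncol(v))) {
      na <- is.na(v[, j])
      v[na, j] <- if (params$missing_policy == "zero_fill") 0 else
        params$center[j]
    }
  }
  sweep(sweep(v, 2L, params$center, "-"), 2L, params$scale, "/")
}

#' Invert autoscaling
#' @param params a `scaling_params`.
#' @param scaled scaled matrix.
#' @return matrix on the original scale.
#' @export
autoscale_invert <- function(params, scaled) {
  sweep(sweep(as.matrix(scaled), 2L, params$scale, "*"), 2L,
        params$center, "+")
}
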