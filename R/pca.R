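#' Fit a PCA model with outlier-diagnostic state
#'
#' Principal components from the singular value decomposition of the
#' (auto)scaled data matrix.  Score variances ("eigenvalues") use the
#' n-1 denominator, `lambda_a = s_a^2 / (n - 1)`.  The sign of each
#' loading vector is fixed so its largest-magnitude element is
#' positive, making loading plots reproducible across platforms.
#'
#' The model stores its own scaling parameters, the training Q-residual
#' moments, and the full eigenvalue spectrum, so projections and
#' critical limits for new samples need nothing but the model object.
#'
#' @param x numeric matrix or `feature_matrix` of training rows.
#' @param A number of components to retain, `1 <= A <= min(n - 1,
#'   ncol)`.
#' @param scale `"autoscale"` (default) to fit scaling parameters on
#'   `x`, or `"none"` when `x` is already scaled.
#' @param missing_policy passed to [autoscale_fit()].
#' @return object of class `pca_model`: `scaling`, `loadings` (p x A,
#'   orthonormal columns), `eigenvalues` (length A, descending),
#'   `eigenvalues_all`, `A`, `n_train`, `scores` (training scores),
#'   `q_mean`, `q_var` (training Q moments), `t2_train`, `q_train`.
#' @export
pca_fit <- function(x, A, scale = c("autoscale", "none"),
                    missing_policy = "mean_impute") {
  scale <- match.arg(scale)
  if (scale == "autoscale") {
    sc <- autoscale_fit(x, missing_policy)
    params <- sc$params
    xs <- sc$scaled
  } else {
    xs <- if (inherits(x, "feature_matrix")) x$values else as.matrix(x)
    if (anyNA(xs)) stop("scale = \"none\" requires a complete matrix")
    params <- structure(list(center = rep(0, ncol(xs)),
                             scale = rep(1, ncol(xs)),
                             missing_policy = missing_policy),
                        class = "scaling_params")
  }
  n <- nrow(xs); p <- ncol(xs)
  A <- as.integer(A)
  if (A < 1L || A > min(n - 1L, p)) {
    stop("A must be between 1 and min(n - 1, p) = ", min(n - 1L, p))
  }
  sv <- svd(xs, nu = 0L, nv = min(n - 1L, p))
  ev_all <- sv$d[seq_len(min(n - 1L, p))]^2 / (n - 1)
  P <- sv$v[, seq_len(A), drop = FALSE]
  # sign convention: largest |loading| element positive per component
  for (a in seq_len(A)) {
    m <- which.max(abs(P[, a]))
    if (P[m, a] < 0) P[, a] <- -P[, a]
  }
  rownames(P) <- colnames(xs)
  scores <- xs %*% P
  E <- xs - scores %*% t(P)
  q_train <- rowSums(E^2)
  lambda <- ev_all[seq_len(A)]
  t2_train <- rowSums(sweep(scores^2, 2L, lambda, "/"))
  structure(list(scaling = params,
                 loadings = P,
                 eigenvalues = lambda,
                 eigenvalues_all = ev_all,
                 A = A, n_train = n,
                 scores = scores,
                 t2_train = t2_train,
                 q_train = q_train,
                 q_mean = mean(q_train),
                 q_var = stats::var(q_train)),
            class = "pca_model")
}

#' @export
print.pca_model <- function(x, ...) {
  expl <- 100 * sum(x$eigenvalues) / sum(x$eigenvalues_all)
  cat(sprintf("<pca_model> %d components, n = %d, %.1f%% variance explained\n",
              x$A, x$n_train, expl))
  invisible(x)
}

#' Project new samples onto a PCA model
#'
#' Applies the model's own scaling, computes scores `t = x_s P`,
#' Hotelling distance `T2 = sum_a t_a^2 / lambda_a` (the Mahalanobis
#' distance from the center of the score space) and the Q residual
#' `Q = ||x_s - t P'||^2` (the variance left unexplained by the
#' component model).
#'
#' @param model a `pca_model`.
#' @param x new rows (matrix or `feature_matrix`) with the same
#'   variables as the training data.
#' @return list with `scores` (n x A), `t2`, `q` (numeric vectors).
#' @export
pca_project <- function(model, x) {
  xs <- autoscale_apply(model$scaling, x)
  if (ncol(xs) != nrow(model$loadings)) stop("variable count mismatch")
  scores <- xs %*% model$loadings
  E <- xs - scores %*% t(model$loadings)
  list(scores = scores,
       t2 = rowSums(sweep(scores^2, 2L, model$eigenvalues, "/")),
       q = rowSums(E^2))
}

#' Critical limits for Hotelling T2 and Q residuals
#'
#' The T2 limit uses the F distribution,
#' `T2_crit = A (n - 1) / (n - A) * F_{1 - alpha}(A, n - A)`.
#' The Q limit is, by default, the moment-matched scaled chi-square
#' (Nomikos-MacGregor): with `m = mean(Q_train)` and `v = var(Q_train)`,
#' `Q_crit = g * chisq_{1 - alpha}(h)` where `g = v / (2 m)` and
#' `h = 2 m^2 / v`.  This stays well-behaved at the very small
#' per-class sample sizes common in one-class screening panels.  The
#' Jackson-Mudholkar limit (from the discarded eigenvalues) is
#' available via `q_method = "jackson_mudholkar"`.
#'
#' Degenerate cases: `var(Q_train) = 0` gives `Q_crit = mean(Q_train)`;
#' a full-rank model (all Q effectively 0) gives `Q_crit = 0`.
#'
#' @param model a `pca_model`.
#' @param alpha significance level; limits are at confidence `1 -
#'   alpha` (default 0.05, the conventional 95 percent level).
#' @param q_method `"moment_chi2"` (default) or `"jackson_mudholkar"`.
#' @return list with `t2` and `q` critical values.
#' @export
critical_limits <- function(model, alpha = 0.05,
                            q_method = c("moment_chi2", "jackson_mudholkar")) {
  q_method <- match.arg(q_method)
  A <- model$A; n <- model$n_train
  if (n <= A) stop("critical limits need n_train > A")
  t2_crit <- A * (n - 1) / (n - A) * stats::qf(1 - alpha, A, n - A)
  m <- model$q_mean; v <- model$q_var
  if (q_method == "moment_chi2" || length(model$eigenvalues_all) <= A) {
    q_crit <- if (!is.finite(v) || v <= .Machine$double.eps * max(m, 1)) m
    else (v / (2 * m)) * stats::qchisq(1 - alpha, 2 * m^2 / v)
  } else {
    disc <- model$eigenvalues_all[-seq_len(A)]
    th1 <- sum(disc); th2 <- sum(disc^2); th3 <- sum(disc^3)
    if (th1 <= 0) {
      q_crit <- 0
    } else {
      h0 <- 1 - 2 * th1 * th3 / (3 * th2^2)
      if (!is.finite(h0) || h0 == 0) h0 <- 1e-3
      z <- stats::qnorm(1 - alpha)
      q_crit <- th1 * (z * sqrt(2 * th2 * h0^2) / th1 +
                         1 + th2 * h0 * (h0 - 1) / th1^2)^(1 / h0)
    }
  }
  list(t2 = t2_crit, q = max(q_crit, 0))
}

#' Influence table: the numbers behind the influence plot
#'
#' Per-row T2 and Q with their critical limits and an outlier flag
#' (`TRUE` iff T2 or Q exceeds its limit), i.e. the numeric backing of
#' the T2-vs-Q influence plot used for outlier screening.
#'
#' @param model a `pca_model`.
#' @param x rows to diagnose (default: the training scores' own data
#'   cannot be recovered, so `x` is required).
#' @param alpha significance level for the limits.
#' @param ids optional row identifiers.
#' @inheritParams critical_limits
#' @return data.frame with columns `id, t2, q, t2_limit, q_limit,
#'   outlier`.
#' @export
influence_table <- function(model, x, alpha = 0.05, ids = NULL,
                            q_method = "moment_chi2") {
  pr <- pca_project(model, x)
  lim <- critical_limits(model, alpha, q_method)
  n <- length(pr$t2)
  if (is.null(ids)) {
    ids <- if (inherits(x, "feature_matrix")) x$analyte_id
    else sprintf("row_%d", seq_len(n))
  }
  data.frame(id = ids, t2 = pr$t2, q = pr$q,
             t2_limit = lim$t2, q_limit = lim$q,
             outlier = pr$t2 > lim$t2 | pr$q > lim$q,
             stringsAsFactors = FALSE)
}
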