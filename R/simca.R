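#' Fit one SIMCA class model
#'
#' A SIMCA class model is a PCA model of the class's training rows
#' (class-local autoscaling by default) plus an acceptance rule turning
#' the Hotelling T2 (score distance) and Q residual (orthogonal
#' distance) of a projected sample into a single accept/reject verdict:
#'
#' * `rule = "chi2"` (default): the scaled sum
#'   `c = Nh * T2/T2_0 + Nq * Q/Q_0` is treated as chi-square with
#'   `Nh + Nq` degrees of freedom, where `T2_0`, `Q_0` are the training
#'   means and `Nh`, `Nq` are moment-matched degrees of freedom
#'   (`N = 2 mean^2 / var`, clamped to `[1, 250]`).  A sample is
#'   accepted when `c` is at or below the `1 - alpha` chi-square
#'   quantile.  The reported distance is normalised,
#'   `d = sqrt(c / (Nh + Nq))`, so the acceptance threshold
#'   `d_threshold = sqrt(qchisq(1 - alpha, Nh + Nq) / (Nh + Nq))` is
#'   close to 1 and comparable across classes.
#' * `rule = "box"`: accept iff `T2 <= T2_crit` and `Q <= Q_crit`
#'   (their `1 - alpha` critical limits); the reported distance is
#'   `d = max(T2/T2_crit, Q/Q_crit)` with `d_threshold = 1`.
#'
#' @param x training rows of ONE class (`feature_matrix` or matrix).
#' @param A number of principal components (`A < n` rows).
#' @param class_label label stored in the model.
#' @param alpha significance level for limits and threshold (default
#'   0.05).
#' @param rule `"chi2"` or `"box"` (see Details).
#' @param scaling `"class"` for class-local autoscaling (the SIMCA
#'   convention) or `"global"` when `x` is already globally scaled.
#' @param q_method Q-limit method, see [critical_limits()].
#' @param ref_distances how the rule's reference moments are computed
#'   from the class training data: `"loo"` (default) uses leave-one-out
#'   distances, which describe genuinely new samples and keep the
#'   acceptance region calibrated at small n; `"resubstitution"` uses
#'   the training rows' own distances (used inside cross-validated
#'   component selection, where the held-out rejections must carry the
#'   overfitting penalty).
#' @return object of class `simca_class`.
#' @export
fit_class <- function(x, A, class_label = "class", alpha = 0.05,
                      rule = c("chi2", "box"),
                      scaling = c("class", "global"),
                      q_method = "moment_chi2",
                      ref_distances = c("loo", "resubstitution")) {
  rule <- match.arg(rule)
  scaling <- match.arg(scaling)
  ref_distances <- match.arg(ref_distances)
  v <- if (inherits(x, "feature_matrix")) x$values else as.matrix(x)
  n <- nrow(v)
  if (A >= n) stop("A (", A, ") must be smaller than the class size (", n, ")")
  if (n < 4L) {
    warning("class ", sQuote(class_label), " has only ", n,
            " training rows; models below 4 analytes are unreliable")
  }
  pca <- pca_fit(x, A, scale = if (scaling == "class") "autoscale" else "none")
  lim <- critical_limits(pca, alpha, q_method)
  # Reference moments for the acceptance rule come from leave-one-out
  # distances: each training row projected on the model of the others.
  # Resubstitution distances shrink sharply at small n (the scaling and
  # the component plane are fit to the same few rows), which would make
  # the acceptance region far too tight for genuinely new samples.
  dd <- if (ref_distances == "loo") .loo_distances(v, A, scaling)
  else list(h = pca$t2_train, q = pca$q_train)
  h <- dd$h; q <- dd$q
  h0 <- mean(h)
  q0 <- mean(q)
  nh <- .moment_df(h)
  # full-rank class models leave no orthogonal residual: drop the Q term
  q_degenerate <- q0 <= .Machine$double.eps * 8
  nq <- if (q_degenerate) 0 else .moment_df(q)
  dof <- nh + nq
  # the acceptance quantile uses an F form rather than the asymptotic
  # chi-square: the reference moments are themselves estimated from n
  # training distances, and at the small class sizes typical of
  # screening panels the estimation uncertainty fattens the tail of
  # the combined distance appreciably (F(dof, n-1) -> chi2(dof)/dof as
  # n grows)
  d_threshold <- switch(rule,
                        chi2 = sqrt(stats::qf(1 - alpha, dof,
                                              max(n - 1, 1))),
                        box = 1)
  structure(list(class_label = class_label, pca = pca, A = as.integer(A),
                 alpha = alpha, rule = rule, q_method = q_method,
                 t2_crit = lim$t2, q_crit = lim$q,
                 h0 = h0, q0 = q0, nh = nh, nq = nq,
                 d_threshold = d_threshold, n_train = n),
            class = "simca_class")
}

# cross-validated score/orthogonal distances of class training rows:
# leave-one-out up to 30 rows, 10-fold (contiguous, deterministic)
# above; falls back to resubstitution when n is too small for refits
.loo_distances <- function(v, A, scaling) {
  n <- nrow(v)
  scale_mode <- if (scaling == "class") "autoscale" else "none"
  k <- if (n <= 30L) n else 10L
  if (A <= n - ceiling(n / k) - 1L) {
    out <- tryCatch({
      fold <- rep_len(seq_len(k), n)
      h <- numeric(n); q <- numeric(n)
      for (f in seq_len(k)) {
        hold <- fold == f
        m_f <- pca_fit(v[!hold, , drop = FALSE], A, scale = scale_mode)
        pr <- pca_project(m_f, v[hold, , drop = FALSE])
        h[hold] <- pr$t2; q[hold] <- pr$q
      }
      list(h = h, q = q)
    }, error = function(e) NULL)
    if (!is.null(out)) return(out)
  }
  m <- pca_fit(v, A, scale = scale_mode)
  list(h = m$t2_train, q = m$q_train)
}

# moment-matched chi-square degrees of freedom, clamped for stability
.moment_df <- function(z) {
  m <- mean(z); v <- stats::var(z)
  if (!is.finite(v) || v <= .Machine$double.eps * max(m^2, 1)) return(250)
  min(max(2 * m^2 / v, 1), 250)
}

#' @export
print.simca_class <- function(x, ...) {
  cat(sprintf("<simca_class> %s: n = %d, A = %d, rule = %s, d_threshold = %.3f\n",
              x$class_label, x$n_train, x$A, x$rule, x$d_threshold))
  invisible(x)
}

#' Distances of samples to one SIMCA class model
#'
#' @param model a `simca_class`.
#' @param x rows to evaluate.
#' @param ids optional sample identifiers.
#' @return data.frame `sample_id, class_label, t2, q, s, q_red, d,
#'   d_threshold, accepted`; `s = T2/T2_crit` and `q_red = Q/Q_crit`
#'   are the reduced distances, `d` is the rule's combined distance and
#'   `accepted` is `d <= d_threshold`.
#' @export
class_distance <- function(model, x, ids = NULL) {
  pr <- pca_project(model$pca, x)
  n <- length(pr$t2)
  if (is.null(ids)) {
    ids <- if (inherits(x, "feature_matrix")) x$analyte_id
    else sprintf("row_%d", seq_len(n))
  }
  s <- pr$t2 / model$t2_crit
  q_red <- if (model$q_crit > 0) pr$q / model$q_crit
  else ifelse(pr$q <= sqrt(.Machine$double.eps), 0, Inf)
  d <- switch(model$rule,
              chi2 = {
                cc <- model$nh * pr$t2 / model$h0 +
                  if (model$nq > 0) model$nq * pr$q / model$q0 else 0
                sqrt(cc / (model$nh + model$nq))
              },
              box = pmax(s, q_red))
  data.frame(sample_id = ids, class_label = model$class_label,
             t2 = pr$t2, q = pr$q, s = s, q_red = q_red, d = d,
             d_threshold = model$d_threshold,
             accepted = d <= model$d_threshold,
             stringsAsFactors = FALSE)
}

#' Cross-validated selection of the component count
#'
#' For each candidate component count `A`, the class training rows are
#' split into cancellation groups (five contiguous venetian-blind
#' groups after sorting by analyte id when the class has at least 8
#' rows, else leave-one-out).  Per fold, a class model is fit on the
#' in-fold rows; cross-validated sensitivity is pooled over the
#' held-out class rows and specificity is the mean over folds of the
#' rejection rate of all other-class training rows projected onto the
#' fold model.  Efficiency is the geometric mean of the two, and the
#' smallest `A` attaining the maximum efficiency is selected
#' (parsimony tie-break).
#'
#' @param x_class training rows of the target class.
#' @param x_other training rows of all other classes.
#' @param A_max largest component count to try (capped at the smallest
#'   fold training size minus 1 and at the variable count).
#' @param cv_scheme `"auto"` (five groups when the class has >= 8 rows,
#'   else leave-one-out), `"five_groups"`, or `"loo"`.
#' @param alpha,rule,q_method passed to [fit_class()].
#' @param ids analyte ids of the class rows (used only to order the
#'   venetian-blind assignment deterministically).
#' @return list with `A` (selected), `table` (data.frame `A,
#'   sensitivity, specificity, efficiency`) and `scheme`.
#' @export
select_components <- function(x_class, x_other, A_max = 5,
                              cv_scheme = c("auto", "five_groups", "loo"),
                              alpha = 0.05, rule = "chi2",
                              q_method = "moment_chi2", ids = NULL) {
  cv_scheme <- match.arg(cv_scheme)
  vc <- if (inherits(x_class, "feature_matrix")) x_class$values
  else as.matrix(x_class)
  vo <- if (inherits(x_other, "feature_matrix")) x_other$values
  else as.matrix(x_other)
  n <- nrow(vc)
  if (n < 4L) stop("component selection needs a class of at least 4 rows")
  if (is.null(ids)) {
    ids <- if (inherits(x_class, "feature_matrix")) x_class$analyte_id
    else sprintf("row_%d", seq_len(n))
  }
  if (cv_scheme == "auto") cv_scheme <- if (n >= 8L) "five_groups" else "loo"
  k <- if (cv_scheme == "five_groups") 5L else n
  # contiguous venetian-blind fold assignment after sorting by id
  ord <- order(ids)
  fold <- integer(n)
  fold[ord] <- rep_len(seq_len(k), n)
  min_train <- min(tabulate(fold, k))  # smallest held-out count
  min_fit <- n - max(tabulate(fold, k))
  A_max <- min(A_max, min_fit - 1L, ncol(vc))
  if (A_max < 1L) stop("A_max < 1 after fold-size capping")
  res <- data.frame(A = seq_len(A_max), sensitivity = NA_real_,
                    specificity = NA_real_, efficiency = NA_real_)
  for (A in seq_len(A_max)) {
    acc_in <- logical(0)
    spec_folds <- numeric(0)
    for (f in seq_len(k)) {
      hold <- fold == f
      # fold models use resubstitution reference moments: the held-out
      # rejections then carry the overfitting penalty that makes CV
      # efficiency peak at the true dimensionality (an LOO-corrected
      # reference inside the fold would calibrate every A equally well
      # and flatten the comparison)
      m <- fit_class(vc[!hold, , drop = FALSE], A, alpha = alpha,
                     rule = rule, q_method = q_method,
                     ref_distances = "resubstitution")
      acc_in <- c(acc_in, class_distance(m, vc[hold, , drop = FALSE])$accepted)
      if (nrow(vo)) {
        spec_folds <- c(spec_folds, mean(!class_distance(m, vo)$accepted))
      }
    }
    sens <- mean(acc_in)
    spec <- if (length(spec_folds)) mean(spec_folds) else 1
    res$sensitivity[A] <- sens
    res$specificity[A] <- spec
    res$efficiency[A] <- sqrt(sens * spec)
  }
  best <- which(res$efficiency >= max(res$efficiency) - 1e-12)[1L]
  list(A = res$A[best], table = res, scheme = cv_scheme)
}

#' Fit per-class SIMCA models
#'
#' The main fitting function: one PCA-based one-class model per drug
#' class, each able to accept or reject any sample independently (soft
#' classification — a sample may be claimed by zero, one, or several
#' classes).  Component counts are selected per class by
#' cross-validated maximum efficiency ([select_components()]) unless
#' supplied.
#'
#' @param x a `feature_matrix`, or a numeric matrix/data.frame of
#'   feature rows.
#' @param class class labels (defaults to `x$class_label` for a
#'   `feature_matrix`).
#' @param A `NULL` for cross-validated selection, a single count used
#'   for all classes, or a named vector of per-class counts (classes
#'   absent from the vector fall back to CV).
#' @param A_max upper bound for CV component selection.
#' @param alpha significance level (default 0.05: 95 percent
#'   confidence limits).
#' @param rule acceptance rule, `"chi2"` or `"box"`; see
#'   [fit_class()].
#' @param classes_min minimum class size to model (default 4, the
#'   conventional floor for one-class panels); smaller classes are
#'   skipped with a message and their samples still count as non-target
#'   in validation.
#' @param classes optional explicit character vector of classes to
#'   model, overriding the size floor.
#' @param cv_scheme CV scheme for component selection, see
#'   [select_components()].
#' @param q_method Q-limit method, see [critical_limits()].
#' @return object of class `simca`: list with `models` (named list of
#'   `simca_class`), `classes` (summary data.frame), `excluded`,
#'   `settings`, `call`.
#' @seealso [predict.simca()], [validate_models()], [coomans_table()]
#' @examples
#' set.seed(1)
#' fm <- generate_feature_matrix(
#'   means = rbind(a = rep(0, 8), b = rep(6, 8)),
#'   n_per_class = 20, seed = 1)
#' fit <- simca(fm, A = 2)
#' fit
#' predict(fit, fm[1:3])
#' @export
simca <- function(x, class = NULL, A = NULL, A_max = 5, alpha = 0.05,
                  rule = c("chi2", "box"), classes_min = 4L,
                  classes = NULL, cv_scheme = "auto",
                  q_method = "moment_chi2") {
  rule <- match.arg(rule)
  cl <- match.call()
  if (inherits(x, "feature_matrix")) {
    v <- x$values
    if (is.null(class)) class <- x$class_label
    ids <- x$analyte_id
  } else {
    v <- as.matrix(x)
    ids <- rownames(v)
    if (is.null(ids)) ids <- sprintf("row_%d", seq_len(nrow(v)))
    if (is.null(class)) stop("class labels required for a plain matrix")
  }
  class <- as.character(class)
  stopifnot(length(class) == nrow(v))
  sizes <- table(class[nzchar(class)])
  if (is.null(classes)) {
    classes <- names(sizes)[sizes >= classes_min]
    excluded <- names(sizes)[sizes < classes_min]
  } else {
    excluded <- setdiff(names(sizes), classes)
  }
  if (!length(classes)) stop("no class reaches the modeling floor of ",
                             classes_min, " analytes")
  if (length(excluded)) {
    message("classes below the modeling floor (kept as non-target only): ",
            paste(excluded, collapse = ", "))
  }
  a_for <- function(k) {
    if (is.null(A)) return(NULL)
    if (length(A) == 1L && is.null(names(A))) return(as.integer(A))
    if (k %in% names(A)) return(as.integer(A[[k]]))
    NULL
  }
  models <- list()
  info <- list()
  for (k in sort(classes)) {
    in_k <- class == k
    if (sum(in_k) < 2L) {
      message("class ", sQuote(k), " has fewer than 2 rows here; skipped")
      excluded <- union(excluded, k)
      next
    }
    Ak <- a_for(k)
    cv_eff <- NA_real_
    if (is.null(Ak) && sum(in_k) < 4L) {
      # too few rows for cross-validation: fall back to a 1-component model
      Ak <- 1L
      message("class ", sQuote(k), ": ", sum(in_k),
              " rows, skipping CV and using A = 1")
    }
    if (!is.null(Ak)) Ak <- min(Ak, sum(in_k) - 1L)
    if (is.null(Ak)) {
      sel <- select_components(v[in_k, , drop = FALSE],
                               v[!in_k & nzchar(class), , drop = FALSE],
                               A_max = A_max, cv_scheme = cv_scheme,
                               alpha = alpha, rule = rule,
                               q_method = q_method, ids = ids[in_k])
      Ak <- sel$A
      cv_eff <- sel$table$efficiency[sel$A]
    }
    models[[k]] <- fit_class(v[in_k, , drop = FALSE], Ak, class_label = k,
                             alpha = alpha, rule = rule, q_method = q_method)
    info[[k]] <- data.frame(class = k, n_train = sum(in_k), A = Ak,
                            cv_efficiency = cv_eff,
                            d_threshold = models[[k]]$d_threshold,
                            stringsAsFactors = FALSE)
  }
  structure(list(models = models,
                 classes = do.call(rbind, unname(info)),
                 excluded = excluded,
                 settings = list(alpha = alpha, rule = rule,
                                 classes_min = classes_min,
                                 cv_scheme = cv_scheme, A_max = A_max,
                                 q_method = q_method),
                 call = cl),
            class = "simca")
}

#' @export
print.simca <- function(x, ...) {
  cat(sprintf("SIMCA class models (%d classes, rule = %s, alpha = %g)\n",
              length(x$models), x$settings$rule, x$settings$alpha))
  print(x$classes, row.names = FALSE)
  if (length(x$excluded)) {
    cat("not modeled (below floor):", paste(x$excluded, collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
summary.simca <- function(object, ...) {
  s <- object$classes
  s$t2_crit <- vapply(object$models[s$class], `[[`, 0, "t2_crit")
  s$q_crit <- vapply(object$models[s$class], `[[`, 0, "q_crit")
  structure(list(classes = s, settings = object$settings,
                 excluded = object$excluded), class = "summary.simca")
}

#' @export
print.summary.simca <- function(x, ...) {
  cat(sprintf("SIMCA panel: %d class models (rule = %s, alpha = %g, CV = %s)\n",
              nrow(x$classes), x$settings$rule, x$settings$alpha,
              x$settings$cv_scheme))
  print(x$classes, row.names = FALSE, digits = 4)
  if (length(x$excluded)) {
    cat("not modeled (below floor):", paste(x$excluded, collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
coef.simca <- function(object, ...) {
  lapply(object$models, function(m) m$pca$loadings)
}

#' Residual Q values of samples under each class model
#' @param object a `simca` fit.
#' @param newdata rows to evaluate (required).
#' @param ... ignored.
#' @return matrix (samples x classes) of Q residuals.
#' @export
residuals.simca <- function(object, newdata, ...) {
  sapply(object$models, function(m) pca_project(m$pca, newdata)$q)
}

#' Classify samples against every SIMCA class model
#'
#' Soft classification: each class model issues an independent
#' accept/reject verdict, so a sample may be claimed by several
#' classes, exactly one, or none (a "none" verdict flags a substance
#' outside all modeled classes).
#'
#' @param object a `simca` fit.
#' @param newdata rows to classify (`feature_matrix` or matrix).
#' @param ... ignored.
#' @return object of class `simca_pred`: `distances` (long data.frame,
#'   one row per sample x class, from [class_distance()]), `accepted`
#'   (samples x classes logical matrix) and `accepted_classes`
#'   (per-sample semicolon-separated list, possibly empty).
#' @export
predict.simca <- function(object, newdata, ...) {
  if (!length(object$models)) stop("no class models to predict with")
  n <- if (inherits(newdata, "feature_matrix")) nrow(newdata$values)
  else nrow(as.matrix(newdata))
  ids <- if (inherits(newdata, "feature_matrix")) newdata$analyte_id
  else {
    rn <- rownames(as.matrix(newdata))
    if (is.null(rn)) sprintf("row_%d", seq_len(n)) else rn
  }
  dists <- do.call(rbind, lapply(object$models, class_distance,
                                 x = newdata, ids = ids))
  rownames(dists) <- NULL
  acc <- vapply(object$models, function(m)
    dists$accepted[dists$class_label == m$class_label], logical(n))
  if (n == 1L) acc <- matrix(acc, 1L, dimnames = list(NULL, names(object$models)))
  rownames(acc) <- ids
  structure(list(distances = dists, accepted = acc,
                 accepted_classes = apply(acc, 1L, function(z)
                   paste(colnames(acc)[z], collapse = ";"))),
            class = "simca_pred")
}

#' @rdname predict.simca
#' @param models a `simca` fit.
#' @param samples rows to classify.
#' @export
classify <- function(models, samples) predict(models, samples)

#' @export
print.simca_pred <- function(x, ...) {
  cat(sprintf("<simca_pred> %d samples x %d class models\n",
              nrow(x$accepted), ncol(x$accepted)))
  out <- data.frame(sample_id = rownames(x$accepted),
                    accepted_classes = ifelse(nzchar(x$accepted_classes),
                                              x$accepted_classes, "(none)"),
                    stringsAsFactors = FALSE)
  print(utils::head(out, 20L), row.names = FALSE)
  if (nrow(out) > 20L) cat("... (", nrow(out) - 20L, " more)\n", sep = "")
  invisible(x)
}

#' Sensitivity, specificity and efficiency per class
#'
#' For each class model c on a labeled sample set: TP = true-c samples
#' accepted by c, FN = true-c rejected, TN = non-c rejected, FP = non-c
#' accepted; sensitivity = TP/(TP+FN), specificity = TN/(TN+FP),
#' efficiency = sqrt(sensitivity x specificity) — the geometric-mean
#' criterion used both for component selection and validation
#' reporting.  Samples whose true class has no model count only as
#' non-target for the other models.
#'
#' @param object a `simca` fit.
#' @param x labeled rows.
#' @param labels true class labels (defaults to `x$class_label`).
#' @param set label for the `set` column (e.g. `"train"`, `"test"`).
#' @return data.frame of class `simca_report` with columns `class, set,
#'   TP, FN, TN, FP, sensitivity, specificity, efficiency`.  A class
#'   with no target samples in `x` gets `NA` sensitivity.
#' @export
validate_models <- function(object, x, labels = NULL, set = "test") {
  if (is.null(labels)) {
    if (!inherits(x, "feature_matrix")) stop("labels required")
    labels <- x$class_label
  }
  labels <- as.character(labels)
  pred <- predict(object, x)
  out <- lapply(names(object$models), function(k) {
    acc <- pred$accepted[, k]
    is_k <- labels == k
    TP <- sum(acc & is_k); FN <- sum(!acc & is_k)
    FP <- sum(acc & !is_k); TN <- sum(!acc & !is_k)
    sens <- if (TP + FN > 0) TP / (TP + FN) else NA_real_
    spec <- if (TN + FP > 0) TN / (TN + FP) else NA_real_
    data.frame(class = k, set = set, TP = TP, FN = FN, TN = TN, FP = FP,
               sensitivity = sens, specificity = spec,
               efficiency = sqrt(sens * spec), stringsAsFactors = FALSE)
  })
  structure(do.call(rbind, out), class = c("simca_report", "data.frame"))
}

#' Coomans distance table for two class models
#'
#' The numeric backing of a Coomans plot: each sample's combined
#' distance to two class models, the two acceptance thresholds, and the
#' quadrant the thresholds assign — `accepted_by_both`, `only_a`,
#' `only_b` or `neither`.  Quadrants agree with [predict.simca()]
#' verdicts by construction (one definition of acceptance everywhere).
#'
#' @param object a `simca` fit (or a `simca_class` for `model_a` with
#'   `model_b` given).
#' @param class_a,class_b the two class labels to compare.
#' @param x rows to place on the plot.
#' @param ids optional sample identifiers.
#' @return data.frame `sample_id, d_a, d_b, threshold_a, threshold_b,
#'   quadrant`.
#' @export
coomans_table <- function(object, class_a, class_b, x, ids = NULL) {
  ma <- object$models[[class_a]]
  mb <- object$models[[class_b]]
  if (is.null(ma) || is.null(mb)) {
    stop("both classes must have fitted models: ",
         class_a, ", ", class_b)
  }
  da <- class_distance(ma, x, ids = ids)
  db <- class_distance(mb, x, ids = ids)
  quadrant <- ifelse(da$accepted & db$accepted, "accepted_by_both",
                     ifelse(da$accepted, "only_a",
                            ifelse(db$accepted, "only_b", "neither")))
  data.frame(sample_id = da$sample_id, d_a = da$d, d_b = db$d,
             threshold_a = ma$d_threshold, threshold_b = mb$d_threshold,
             quadrant = quadrant, stringsAsFactors = FALSE)
}

#' Plot method: Coomans plot or per-class distance plot
#'
#' With two class labels, draws the Coomans plot (distance to model a
#' vs distance to model b, threshold lines splitting the plane into the
#' four acceptance regions).  With one class label, draws that model's
#' combined distance per sample with its acceptance threshold.
#'
#' @param x a `simca` fit.
#' @param newdata rows to plot.
#' @param classes one or two class labels (default: first one).
#' @param labels optional true labels used to colour points.
#' @param ... passed to [plot()].
#' @export
plot.simca <- function(x, newdata, classes = names(x$models)[1L],
                       labels = NULL, ...) {
  if (is.null(labels) && inherits(newdata, "feature_matrix")) {
    labels <- newdata$class_label
  }
  col <- if (is.null(labels)) "grey30" else as.integer(factor(labels)) + 1L
  if (length(classes) >= 2L) {
    ct <- coomans_table(x, classes[1L], classes[2L], newdata)
    plot(ct$d_a, ct$d_b, col = col, pch = 19,
         xlab = paste("distance to", classes[1L]),
         ylab = paste("distance to", classes[2L]),
         main = "Coomans plot", ...)
    graphics::abline(v = ct$threshold_a[1L], h = ct$threshold_b[1L],
                     lty = 2)
  } else {
    cd <- class_distance(x$models[[classes[1L]]], newdata)
    plot(seq_len(nrow(cd)), cd$d, col = col, pch = 19,
         xlab = "sample", ylab = "combined distance",
         main = paste("SIMCA model:", classes[1L]), ...)
    graphics::abline(h = cd$d_threshold[1L], lty = 2)
  }
  invisible(x)
}

#' Simulate samples from fitted class models
#'
#' Draws samples from each class model's Gaussian picture of its class:
#' scores from independent normals with the model score variances,
#' residuals isotropic in the orthogonal complement with the training
#' mean Q, back-transformed through the class scaling.  Useful for
#' generative checks of a fitted panel.
#'
#' @param object a `simca` fit.
#' @param nsim samples per class.
#' @param seed optional RNG seed.
#' @param ... ignored.
#' @return a `feature_matrix` with class labels set to the generating
#'   class.
#' @export
simulate.simca <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  out <- lapply(object$models, function(m) {
    P <- m$pca$loadings
    p <- nrow(P); A <- ncol(P)
    t <- matrix(stats::rnorm(nsim * A), nsim, A) %*%
      diag(sqrt(m$pca$eigenvalues), A)
    z <- matrix(stats::rnorm(nsim * p), nsim, p)
    Eperp <- z - (z %*% P) %*% t(P)
    if (p > A && m$q0 > 0) {
      Eperp <- Eperp * sqrt(m$q0 / (p - A))
    } else Eperp[] <- 0
    autoscale_invert(m$pca$scaling, t %*% t(P) + Eperp)
  })
  feature_matrix(do.call(rbind, out),
                 class_label = rep(names(object$models), each = nsim))
}
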