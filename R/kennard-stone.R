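#' Kennard-Stone maximin training/test split
#'
#' Deterministic sample-set partitioning in Euclidean distance
#' (normally on the autoscaled matrix): the two most distant samples
#' seed the training set, then each step adds the candidate whose
#' minimum distance to the already-selected set is largest, until
#' `ceiling(train_fraction * n)` samples (or `n_train`, if given) are
#' selected.  The remainder is the test set.  Ties are broken by lowest
#' row index, so the split is fully reproducible.
#'
#' @param x numeric matrix (rows = samples) or `feature_matrix`
#'   (autoscaled internally with mean imputation in that case).
#' @param train_fraction fraction of samples for the training set;
#'   default 0.75.
#' @param n_train optional absolute training-set size, overriding
#'   `train_fraction` (useful to reproduce a published split size
#'   exactly).
#' @return object of class `ks_split`: list with `train`, `test`
#'   (disjoint row indices covering all rows) and `selection_order`
#'   (the order Kennard-Stone picked training samples).
#' @export
kennard_stone_split <- function(x, train_fraction = 0.75, n_train = NULL) {
  if (inherits(x, "feature_matrix")) x <- autoscale_fit(x)$scaled
  x <- as.matrix(x)
  n <- nrow(x)
  if (n < 2L) stop("need at least 2 rows to split")
  if (is.null(n_train)) {
    stopifnot(train_fraction > 0, train_fraction <= 1)
    n_train <- ceiling(train_fraction * n)
  }
  n_train <- as.integer(n_train)
  stopifnot(n_train >= 2L, n_train <= n)
  D <- as.matrix(stats::dist(x))
  # seed pair: maximum pairwise distance, ties by lowest (i, j)
  up <- which(upper.tri(D), arr.ind = TRUE)
  dv <- D[up]
  mx <- max(dv)
  cand <- up[dv >= mx - 0, , drop = FALSE]
  cand <- cand[order(cand[, 1L], cand[, 2L]), , drop = FALSE]
  sel <- sort(as.integer(unname(c(cand[1L, 1L], cand[1L, 2L]))))
  mind <- pmin(D[, sel[1L]], D[, sel[2L]])
  mind[sel] <- -Inf
  while (length(sel) < n_train) {
    nxt <- as.integer(which.max(mind))  # lowest index wins ties
    sel <- c(sel, nxt)
    mind <- pmin(mind, D[, nxt])
    mind[nxt] <- -Inf
  }
  sel <- unname(sel)
  structure(list(train = sort(sel),
                 test = setdiff(seq_len(n), sel),
                 selection_order = sel),
            class = "ks_split")
}

#' @export
print.ks_split <- function(x, ...) {
  cat(sprintf("<ks_split> %d train / %d test (Kennard-Stone)\n",
              length(x$train), length(x$test)))
  invisible(x)
}
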