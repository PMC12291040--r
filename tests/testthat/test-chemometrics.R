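test_that("autoscaling centers, scales, imputes and inverts", {
  x <- cbind(a = c(1, 2, 3), b = c(10, 30, 20), c = c(0, 5, 1))
  sc <- autoscale_fit(x)
  expect_equal(sc$scaled[, "a"], c(-1, 0, 1))
  expect_true(all(abs(colMeans(sc$scaled)) < 1e-9))
  expect_equal(apply(sc$scaled, 2, sd), c(a = 1, b = 1, c = 1))
  expect_equal(autoscale_invert(sc$params, sc$scaled), x, tolerance = 1e-12)

  xm <- x; xm[2, 2] <- NA
  expect_equal(unname(autoscale_fit(xm, "mean_impute")$scaled[2, 2]), 0)
  z <- autoscale_fit(xm, "zero_fill")
  expect_equal(z$params$center[["b"]], mean(c(10, 0, 20)))

  xc <- x; xc[, 3] <- 7
  expect_error(autoscale_fit(xc), "c")
  expect_error(autoscale_fit(x[1, , drop = FALSE]), "2 rows")
})

test_that("Kennard-Stone picks the extreme pair then maximin points", {
  x <- matrix(c(0, 1, 2, 10), ncol = 1)
  sp <- kennard_stone_split(x, train_fraction = 0.5)
  expect_identical(sp$train, c(1L, 4L))
  expect_identical(sp$test, c(2L, 3L))
  expect_identical(sp$selection_order[1:2], c(1L, 4L))

  all_in <- kennard_stone_split(x, train_fraction = 1.0)
  expect_identical(sort(all_in$selection_order), 1:4)
  expect_length(all_in$test, 0L)
})

test_that("Kennard-Stone equals the brute-force maximin oracle", {
  set.seed(101)
  for (i in 1:60) {
    n <- sample(4:12, 1)
    x <- matrix(rnorm(n * sample(2:8, 1)), nrow = n)
    n_train <- sample(2:(n - 1), 1)
    sp <- kennard_stone_split(x, n_train = n_train)
    expect_identical(sp$selection_order, as.integer(ks_oracle(x, n_train)))
    expect_identical(sort(c(sp$train, sp$test)), seq_len(n))
  }
  # duplicate rows are allowed; ties resolve to the lowest index
  xd <- rbind(c(0, 0), c(0, 0), c(5, 5), c(5, 5))
  expect_identical(kennard_stone_split(xd, n_train = 3)$selection_order[1:2],
                   c(1L, 3L))
})

test_that("PCA reproduces variance structure with fixed sign convention", {
  set.seed(7)
  x <- matrix(rnorm(40 * 8), 40, 8)
  sc <- autoscale_fit(x)
  full <- pca_fit(sc$scaled, 8, scale = "none")
  # full-rank reconstruction and trace conservation on autoscaled data
  rec <- full$scores %*% t(full$loadings)
  expect_lt(max(abs(rec - sc$scaled)), 1e-8)
  expect_equal(sum(full$eigenvalues_all), 8, tolerance = 1e-6)
  expect_true(all(diff(full$eigenvalues_all) <= 1e-10))
  # orthonormal loadings, uncorrelated scores, positive sign convention
  G <- crossprod(full$loadings)
  expect_lt(max(abs(G - diag(8))), 1e-8)
  cv <- cov(full$scores)
  expect_lt(max(abs(cv - diag(diag(cv)))), 1e-8)
  for (a in 1:8) {
    expect_gt(full$loadings[which.max(abs(full$loadings[, a])), a], 0)
  }
  expect_error(pca_fit(sc$scaled, 9, scale = "none"), "between 1")
})

test_that("PC1 separates two synthetic clusters", {
  fm <- gaussian_classes(30, sep = 10, seed = 2)
  m <- pca_fit(fm, 2)
  s1 <- pca_project(m, fm)$scores[, 1]
  lab <- fm$class_label == "class_2"
  agree <- max(mean((s1 > 0) == lab), mean((s1 < 0) == lab))
  expect_gte(agree, 0.95)
})

test_that("projection reproduces training scores, zero Q at full rank, and the T2 identity", {
  set.seed(8)
  x <- matrix(rnorm(25 * 8), 25, 8)
  m <- pca_fit(x, 3)
  pr <- pca_project(m, x)
  expect_lt(max(abs(pr$scores - m$scores)), 1e-10)
  expect_equal(pr$t2, m$t2_train, tolerance = 1e-10)
  # mean training T2 equals A(n-1)/n under the n-1 eigenvalue convention
  expect_equal(mean(pr$t2), 3 * 24 / 25, tolerance = 1e-6)
  mfull <- pca_fit(x, 8)
  expect_lt(max(pca_project(mfull, x)$q), 1e-8)
  # the training mean projects to the origin
  center <- matrix(colMeans(x), 1)
  pm <- pca_project(m, center)
  expect_lt(max(abs(pm$scores)), 1e-10)
  expect_lt(pm$t2, 1e-12)
  # row-order invariance
  perm <- sample(25)
  prp <- pca_project(m, x[perm, ])
  expect_equal(prp$t2, pr$t2[perm])
  expect_equal(prp$q, pr$q[perm])
})

test_that("critical limits calibrate to alpha on large Gaussian training sets", {
  set.seed(123)
  x <- matrix(rnorm(2000 * 8), 2000, 8)
  m <- pca_fit(x, 3)
  lim <- critical_limits(m, alpha = 0.05)
  se2 <- 2 * sqrt(0.05 * 0.95 / 2000)
  expect_lt(abs(mean(m$t2_train > lim$t2) - 0.05), se2)
  expect_lt(abs(mean(m$q_train > lim$q) - 0.05), se2)
  # Jackson-Mudholkar alternative lands in the same neighbourhood
  lim_jm <- critical_limits(m, alpha = 0.05, q_method = "jackson_mudholkar")
  expect_lt(abs(mean(m$q_train > lim_jm$q) - 0.05), 2 * se2)
  # A = n - 1 edge: limits exist (single denominator df), A = n errors
  edge <- critical_limits(pca_fit(matrix(rnorm(32), 4, 8), 3), 0.05)
  expect_true(is.finite(edge$t2) && edge$t2 > 0)
  expect_error(pca_fit(matrix(rnorm(32), 4, 8), 4), "between 1")
})

test_that("influence tables flag outliers consistently with the limit comparisons", {
  set.seed(9)
  x <- matrix(rnorm(60 * 8), 60, 8)
  m <- pca_fit(x, 3)
  far <- matrix(rnorm(5 * 8), 5, 8); far[1, 2] <- 20
  tab <- influence_table(m, rbind(x[1:5, ], far))
  expect_identical(tab$outlier, tab$t2 > tab$t2_limit | tab$q > tab$q_limit)
  expect_true(tab$outlier[6])
  inlier <- tab[tab$t2 < tab$t2_limit & tab$q < tab$q_limit, ]
  expect_true(all(!inlier$outlier))
})
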