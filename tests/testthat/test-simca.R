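test_that("a class model accepts its own kind and the class mean exactly", {
  set.seed(21)
  x <- matrix(rnorm(200 * 8, mean = 5), 200, 8)
  m <- fit_class(x, 3, "g")
  cd_train <- class_distance(m, x)
  # training acceptance close to the nominal 1 - alpha
  expect_gte(mean(cd_train$accepted), 1 - 2 * 0.05)
  # the class training mean is at distance zero
  cd0 <- class_distance(m, matrix(colMeans(x), 1))
  expect_lt(cd0$d, 1e-8)
  expect_true(cd0$accepted)
  # verdicts equal the distance comparison by definition
  expect_identical(cd_train$accepted, cd_train$d <= cd_train$d_threshold)
  expect_error(fit_class(x[1:3, ], 3, "g"), "smaller than")
  expect_warning(fit_class(x[1:3, ], 1, "tiny"), "unreliable")
})

test_that("shrinking alpha loosens the acceptance region monotonically", {
  set.seed(22)
  x <- matrix(rnorm(60 * 8), 60, 8)
  probe <- matrix(rnorm(300 * 8, sd = 1.4), 300, 8)
  for (rule in c("chi2", "box")) {
    m05 <- fit_class(x, 2, "g", alpha = 0.05, rule = rule)
    m50 <- fit_class(x, 2, "g", alpha = 0.5, rule = rule)
    m01 <- fit_class(x, 2, "g", alpha = 0.01, rule = rule)
    a05 <- class_distance(m05, probe)$accepted
    a50 <- class_distance(m50, probe)$accepted
    a01 <- class_distance(m01, probe)$accepted
    expect_true(all(a50 <= a05))   # alpha = 0.5 tightens: more rejections
    expect_true(all(a05 <= a01))   # alpha = 0.01 loosens: never fewer accepts
  }
})

test_that("component selection caps folds for tiny classes and breaks ties small", {
  set.seed(23)
  x4 <- matrix(rnorm(4 * 8), 4, 8)
  other <- matrix(rnorm(10 * 8, mean = 30), 10, 8)
  sel <- suppressWarnings(select_components(x4, other, A_max = 5))
  expect_identical(sel$scheme, "loo")
  expect_lte(max(sel$table$A), 2L)
  # saturated efficiency at every A resolves to the smallest A
  tight <- matrix(rnorm(12 * 8, sd = 0.05), 12, 8)
  far <- matrix(rnorm(40 * 8, mean = 50), 40, 8)
  sel2 <- select_components(tight, far, A_max = 3)
  expect_identical(sel2$scheme, "five_groups")
  expect_identical(sel2$A, sel2$table$A[which.max(sel2$table$efficiency)])
  if (max(abs(diff(sel2$table$efficiency))) < 1e-12) {
    expect_identical(sel2$A, 1L)
  }
  expect_error(select_components(x4[1:3, ], other), "at least 4")
})

test_that("selection recovers the latent dimension on rank-2 fixtures", {
  hits <- 0L
  for (seed in 1:10) {
    pair <- make_rank2_pair(seed)
    sel <- select_components(pair$x_class, pair$x_other, A_max = 4)
    hits <- hits + (sel$A == 2L)
  }
  expect_gte(hits, 9L)
})

test_that("simca fits one model per eligible class and predicts softly", {
  fm <- gaussian_classes(30, n_classes = 3, sep = 12, seed = 4)
  fit <- simca(fm, A = 2)
  expect_s3_class(fit, "simca")
  expect_setequal(names(fit$models), c("class_1", "class_2", "class_3"))
  pred <- predict(fit, fm)
  expect_identical(dim(pred$accepted), c(90L, 3L))
  # soft classification: membership claims are independent per class
  own <- pred$accepted[cbind(seq_len(90), match(fm$class_label,
                                                colnames(pred$accepted)))]
  expect_gte(mean(own), 0.9)
  far <- feature_matrix(matrix(1e3, 2, 8))
  pf <- predict(fit, far)
  expect_identical(unname(pf$accepted_classes), c("", ""))
  expect_error(predict(structure(list(models = list()), class = "simca"),
                       fm), "no class models")
  # floor: classes under 4 analytes are kept only as non-target
  labs <- fm$class_label; labs[fm$class_label == "class_3"][1:28] <- "class_1"
  suppressMessages(fit2 <- simca(feature_matrix(fm$values, class_label = labs),
                                 A = 2))
  expect_false("class_3" %in% names(fit2$models))
  expect_true("class_3" %in% fit2$excluded)
})

test_that("overlapping classes can both claim one sample", {
  means <- rbind(a = rep(0, 8), b = c(1, rep(0, 7)))
  fm <- generate_feature_matrix(means, n_per_class = 60, seed = 9)
  fit <- simca(fm, A = 2)
  pred <- predict(fit, fm)
  expect_gt(sum(rowSums(pred$accepted) == 2L), 0L)
})

test_that("validation counts match a brute-force confusion oracle", {
  fm <- gaussian_classes(25, n_classes = 3, sep = 12, seed = 6)
  fit <- simca(fm, A = 2)
  rep <- validate_models(fit, fm, set = "train")
  pred <- predict(fit, fm)
  for (k in names(fit$models)) {
    oracle <- confusion_oracle(pred$accepted[, k], fm$class_label, k)
    row <- rep[rep$class == k, ]
    expect_identical(c(TP = row$TP, FN = row$FN, TN = row$TN, FP = row$FP),
                     oracle)
    expect_equal(row$sensitivity, oracle["TP"] / (oracle["TP"] + oracle["FN"]),
                 ignore_attr = TRUE)
    expect_equal(row$efficiency,
                 sqrt(row$sensitivity * row$specificity))
  }
  # removing non-target samples leaves target sensitivity unchanged
  keep <- fm$class_label != "class_3"
  rep2 <- validate_models(fit, fm[which(keep)], set = "train")
  expect_equal(rep2$sensitivity[rep2$class == "class_1"],
               rep$sensitivity[rep$class == "class_1"])
})

test_that("degenerate all-accept models give specificity 0 and efficiency 0", {
  fm <- gaussian_classes(20, n_classes = 2, sep = 3, seed = 13)
  fit <- simca(fm, A = 2, alpha = 1e-12)  # limits so wide everything passes
  rep <- validate_models(fit, fm)
  expect_true(all(rep$sensitivity == 1))
  expect_true(all(rep$specificity == 0))
  expect_true(all(rep$efficiency == 0))
})

test_that("Coomans quadrants agree with classify() on every sample", {
  fm <- gaussian_classes(30, n_classes = 2, sep = 8, seed = 5)
  fit <- simca(fm, A = 2)
  ct <- coomans_table(fit, "class_1", "class_2", fm)
  pred <- classify(fit, fm)
  want <- ifelse(pred$accepted[, "class_1"] & pred$accepted[, "class_2"],
                 "accepted_by_both",
                 ifelse(pred$accepted[, "class_1"], "only_a",
                        ifelse(pred$accepted[, "class_2"], "only_b",
                               "neither")))
  expect_identical(ct$quadrant, unname(want))
  # the class-1 training mean sits at d_a = 0
  mean1 <- matrix(colMeans(fm$values[fm$class_label == "class_1", ]), 1)
  c0 <- coomans_table(fit, "class_1", "class_2", mean1)
  expect_lt(c0$d_a, 1e-8)
  expect_true(c0$quadrant %in% c("only_a", "accepted_by_both"))
  expect_error(coomans_table(fit, "class_1", "nope", fm), "fitted")
})

test_that("heavily overlapping classes put most samples in the shared quadrant", {
  means <- rbind(a = rep(0, 8), b = c(0.5, rep(0, 7)))
  fm <- generate_feature_matrix(means, n_per_class = 80, seed = 14)
  fit <- simca(fm, A = 2)
  ct <- coomans_table(fit, "a", "b", fm)
  expect_gt(mean(ct$quadrant == "accepted_by_both"), 0.5)
})

test_that("JSON serialization reproduces predictions across sessions", {
  fm <- gaussian_classes(20, n_classes = 2, sep = 10, seed = 8)
  fit <- simca(fm, A = 2)
  path <- tempfile(fileext = ".json")
  write_models_json(fit, path)
  back <- read_models_json(path)
  p1 <- predict(fit, fm)
  p2 <- predict(back, fm)
  expect_equal(p1$distances$d, p2$distances$d, tolerance = 1e-12)
  expect_identical(p1$accepted, p2$accepted)
  expect_error(read_models_json(tempfile()), "not found")
})

test_that("model methods print, summarise, simulate and expose coefficients", {
  fm <- gaussian_classes(50, n_classes = 2, sep = 10, seed = 10)
  fit <- simca(fm, A = 2)
  expect_output(print(fit), "SIMCA class models")
  expect_output(print(summary(fit)), "t2_crit|q_crit")
  expect_named(coef(fit), c("class_1", "class_2"))
  expect_identical(dim(coef(fit)$class_1), c(8L, 2L))
  r <- residuals(fit, fm)
  expect_identical(dim(r), c(100L, 2L))
  sim <- simulate(fit, nsim = 40, seed = 99)
  expect_s3_class(sim, "feature_matrix")
  # simulated samples look like their class to the fitted panel
  rep <- validate_models(fit, sim)
  expect_true(all(rep$sensitivity > 0.8))
  pdf(NULL)
  plot(fit, fm, classes = c("class_1", "class_2"))
  plot(fit, fm, classes = "class_1")
  dev.off()
  expect_output(print(predict(fit, fm[1:3])), "simca_pred")
})
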