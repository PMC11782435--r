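# Canonical projection, cost-sensitive SVM, cross-validation, NLR and the
# cost-matrix search.

make_feature_cloud <- function(n_per_class = 50, sep = c(4, 0, 0, 0),
                               seed = 1) {
  set.seed(seed)
  x <- rbind(matrix(rnorm(n_per_class * 4), ncol = 4),
             matrix(rnorm(n_per_class * 4), ncol = 4) +
               matrix(sep, n_per_class, 4, byrow = TRUE))
  colnames(x) <- c("tau_ms", "lambda", "dtau_ms", "dlambda")
  list(x = x, labels = factor(rep(c("Bone", "Crossing"), each = n_per_class),
                              levels = c("Bone", "Crossing")))
}

test_that("axis-aligned separation loads c1 on the separating feature", {
  d <- make_feature_cloud(sep = c(4, 0, 0, 0), seed = 2)
  proj <- canonical_projection(d$x, d$labels)
  expect_gt(abs(proj$W["tau_ms", "c1"]), 0.9)
  # unit norms and orthogonality of the two canonical directions
  expect_equal(sum(proj$W[, 1]^2), 1, tolerance = 1e-10)
  expect_equal(sum(proj$W[, 2]^2), 1, tolerance = 1e-10)
  expect_lt(abs(sum(proj$W[, 1] * proj$W[, 2])), 1e-10)
})

test_that("four-point worked Fisher example puts c1 on the first axis", {
  x <- rbind(c(0, 0, 0, 0), c(1, 0, 0, 0), c(4, 0, 0, 0), c(5, 0, 0, 0))
  colnames(x) <- c("tau_ms", "lambda", "dtau_ms", "dlambda")
  # degenerate zero-variance features force the ridge path
  lab <- factor(c("Bone", "Bone", "Crossing", "Crossing"),
                levels = c("Bone", "Crossing"))
  x5 <- x[c(1, 2, 1, 2, 1, 3, 4, 3, 4, 3), ]
  lab5 <- rep(lab[c(1, 3)], each = 5)
  proj <- suppressWarnings(canonical_projection(x5, lab5))
  expect_equal(abs(proj$W["tau_ms", "c1"]), 1, tolerance = 1e-6)
})

test_that("identical class means are rejected", {
  d <- make_feature_cloud(sep = c(0, 0, 0, 0), seed = 3)
  x <- rbind(d$x[1:10, ], d$x[1:10, ])
  lab <- factor(rep(c("Bone", "Crossing"), each = 10),
                levels = c("Bone", "Crossing"))
  expect_error(canonical_projection(x, lab), "identical class means")
})

test_that("Fisher direction matches an independent discriminant analysis", {
  skip_if_not_installed("MASS")
  d <- make_feature_cloud(sep = c(2, 1, -1, 0.5), seed = 4)
  proj <- canonical_projection(d$x, d$labels)
  ld <- MASS::lda(scale(d$x), d$labels)$scaling[, 1]
  ld <- ld / sqrt(sum(ld^2))
  expect_equal(abs(sum(ld * proj$W[, 1])), 1, tolerance = 1e-6)
})

test_that("separable clusters are classified without training errors", {
  d <- make_feature_cloud(sep = c(8, 0, 0, 0), seed = 5)
  proj <- canonical_projection(d$x, d$labels)
  xy <- predict(proj, d$x)
  for (s in c(1, 2, 3.5)) {
    rule <- train_weighted_classifier(xy, d$labels,
                                      cost_matrix(sigma_CB = s))
    expect_true(all(predict(rule, xy) == d$labels))
  }
  # symmetric weights reproduce the unweighted rule
  r1 <- train_weighted_classifier(xy, d$labels, cost_matrix(1, 1))
  r2 <- train_weighted_classifier(xy, d$labels, cost_matrix(2, 2))
  expect_equal(as.character(predict(r1, xy)), as.character(predict(r2, xy)))
  expect_error(train_weighted_classifier(xy[d$labels == "Bone", ],
                                         d$labels[d$labels == "Bone"]),
               "both classes")
})

test_that("raising the false-negative weight does not increase training FN", {
  set.seed(6)
  d <- simulate_overlapping_classes(n = 400, pos_frac = 0.2, separation = 1.5)
  fn_count <- function(s) {
    rule <- train_weighted_classifier(d$x, d$labels, cost_matrix(sigma_CB = s))
    p <- predict(rule, d$x)
    sum(d$labels == "Crossing" & p == "Bone")
  }
  expect_lte(fn_count(3.5), fn_count(1))
})

test_that("stratified cross-validation predicts each record exactly once", {
  d <- make_feature_cloud(n_per_class = 50, sep = c(8, 0, 0, 0), seed = 7)
  proj <- canonical_projection(d$x, d$labels)
  xy <- predict(proj, d$x)
  cv <- kfold_cv(xy, d$labels, k = 5, seed = 1)
  expect_false(anyNA(cv$predictions))
  expect_equal(sort(unique(cv$folds)), 1:5)
  expect_equal(as.vector(table(cv$folds)), rep(20, 5))
  n <- cv$counts
  expect_equal(n$TP + n$TN + n$FP + n$FN, 100)
  # perfectly separable: no errors anywhere
  expect_equal(n$FP, 0)
  expect_equal(n$FN, 0)
  expect_equal(cv$accuracy, 1)
  expect_equal(cv$mean_fold_accuracy, 1)
})

test_that("NLR and accuracy follow their closed forms", {
  expect_equal(nlr(confusion_counts(TP = 90, TN = 80, FP = 20, FN = 10)),
               0.125)
  expect_equal(nlr(confusion_counts(TP = 50, TN = 80, FP = 20, FN = 0)), 0)
  expect_equal(nlr(confusion_counts(TP = 25, TN = 25, FP = 25, FN = 25)), 1)
  expect_error(nlr(confusion_counts(TP = 0, TN = 10, FP = 1, FN = 0)),
               "TP \\+ FN")
  expect_error(nlr(confusion_counts(TP = 5, TN = 0, FP = 1, FN = 2)), "TN")
  expect_equal(accuracy_metric(confusion_counts(TP = 1000, TN = 507,
                                                FP = 55, FN = 29)),
               1507 / 1591)
  expect_equal(accuracy_metric(confusion_counts(10, 10, 0, 0)), 1)
  expect_equal(accuracy_metric(confusion_counts(25, 25, 25, 25)), 0.5)
  expect_error(accuracy_metric(confusion_counts(0, 0, 0, 0)), "total")
})

test_that("metrics agree with brute-force recounts of random predictions", {
  set.seed(8)
  for (i in 1:20) {
    truth <- factor(sample(c("Bone", "Crossing"), 60, replace = TRUE,
                           prob = c(0.7, 0.3)), levels = c("Bone", "Crossing"))
    pred <- factor(sample(c("Bone", "Crossing"), 60, replace = TRUE),
                   levels = c("Bone", "Crossing"))
    tp <- sum(truth == "Crossing" & pred == "Crossing")
    tn <- sum(truth == "Bone" & pred == "Bone")
    fp <- sum(truth == "Bone" & pred == "Crossing")
    fn <- sum(truth == "Crossing" & pred == "Bone")
    cc <- confusion_counts(tp, tn, fp, fn)
    expect_equal(accuracy_metric(cc), mean(truth == pred))
    if (tp + fn > 0 && tn > 0)
      expect_equal(nlr(cc), (fn / (tp + fn)) / (tn / (fp + tn)))
  }
})

test_that("cost search ties break to sigma_CB = 1 on separable data", {
  d <- make_feature_cloud(n_per_class = 40, sep = c(8, 0, 0, 0), seed = 9)
  proj <- canonical_projection(d$x, d$labels)
  xy <- predict(proj, d$x)
  res <- optimize_cost_matrix(xy, d$labels, k = 5, seed = 1,
                              sigma_grid = seq(1, 3, by = 0.5))
  expect_true(all(res$grid$nlr == 0))
  expect_equal(res$cost$sigma_CB, 1)
})

test_that("cost search reduces FN on imbalanced overlapping data, sharing folds", {
  set.seed(10)
  d <- simulate_overlapping_classes(n = 500, pos_frac = 0.15, separation = 1.5)
  res <- optimize_cost_matrix(d$x, d$labels, k = 5, seed = 7,
                              sigma_grid = seq(1, 6, by = 0.5))
  g <- res$grid
  expect_lte(g$FN[g$sigma_CB == 3.5], g$FN[g$sigma_CB == 1])
  expect_lte(min(g$nlr), g$nlr[g$sigma_CB == 1])
  # the sigma = 1 cell reproduces the unweighted classifier exactly
  cv1 <- kfold_cv(d$x, d$labels, cost_matrix(1, 1), folds = res$folds)
  expect_equal(g$FN[g$sigma_CB == 1], cv1$counts$FN)
  expect_equal(g$FP[g$sigma_CB == 1], cv1$counts$FP)
  expect_identical(res$cv_unweighted$counts, cv1$counts)
  # monotone cost response up to CV noise: FN non-increasing, FP
  # non-decreasing along the grid (allow single-count jitter)
  expect_true(all(diff(g$FN) <= 1))
  expect_true(all(diff(g$FP) >= -1))
  expect_lte(g$FN[nrow(g)], g$FN[1])
  expect_gte(g$FP[nrow(g)], g$FP[1])
})

test_that("one-way ANOVA matches hand computation and the t-test identity", {
  g <- factor(rep(c("a", "b"), each = 3))
  v <- c(1, 2, 3, 4, 5, 6)
  res <- anova_oneway(v, g)
  expect_equal(res$F, 13.5)  # MSB = 13.5, MSW = 1
  tt <- t.test(v ~ g, var.equal = TRUE)
  expect_equal(res$F, unname(tt$statistic)^2)
  expect_equal(anova_oneway(c(1, 2, 3, 1, 2, 3), g)$F, 0)
  expect_error(anova_oneway(1:5, factor(rep("a", 5))), "two groups")
})

test_that("the full classifier separates a strong-effect synthetic database", {
  exp <- generate_database(generator_config(seed = 7, n_plates = 6))
  ft <- truth_features(exp)
  cls <- classify_impacts(ft, seed = 7, sigma_grid = seq(1, 4, by = 0.5))
  expect_s3_class(cls, "crossing_classifier")
  expect_gte(cls$accuracy, 0.90)
  expect_lt(cls$anova$tau_ms$p, 0.001)
  # tau is higher and lambda lower for Crossing impacts
  expect_gt(mean(ft$tau_ms[ft$label == "Crossing"]),
            mean(ft$tau_ms[ft$label == "Bone"]))
  expect_lt(mean(ft$lambda[ft$label == "Crossing"]),
            mean(ft$lambda[ft$label == "Bone"]))
  expect_output(print(cls), "accuracy")
  expect_output(summary(cls), "ANOVA")
})
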