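#' Canonical projection of the impact features
#'
#' Projects the four standardized features (`tau`, `lambda`, `dtau`,
#' `dlambda`) onto two canonical variables: `c1` is the Fisher two-class
#' discriminant direction (maximising between-class over within-class
#' scatter), and — since a two-class discriminant analysis yields a single
#' axis — `c2` is defined as the direction of maximal residual variance
#' orthogonal to `c1` in the standardized feature space.
#'
#' @param x Numeric matrix or `data.frame` with columns `tau_ms`, `lambda`,
#'   `dtau_ms`, `dlambda` (any 4 numeric columns are accepted, in order).
#' @param labels Factor with levels `Bone`, `Crossing`; both classes must
#'   have at least 5 records.
#' @param ridge Ridge added to a computationally singular within-class
#'   covariance (with a warning).
#' @return Object of class `canonical_projection`: `center`, `scale`
#'   (per-feature standardization constants), `W` (4 x 2 weight matrix,
#'   unit-norm columns `c1`, `c2`).
#' @export
canonical_projection <- function(x, labels, ridge = 1e-6) {
  x <- as.matrix(as.data.frame(x)[, seq_len(4L)])
  storage.mode(x) <- "double"
  labels <- droplevels(as.factor(labels))
  if (nlevels(labels) != 2L)
    stop("canonical_projection: need exactly two classes")
  if (any(table(labels) < 5L))
    stop("canonical_projection: need at least 5 records per class")
  ctr <- colMeans(x)
  scl <- apply(x, 2L, sd)
  if (any(scl == 0)) scl[scl == 0] <- 1
  xs <- scale(x, ctr, scl)
  g <- split(seq_len(nrow(xs)), labels)
  m1 <- colMeans(xs[g[[1L]], , drop = FALSE])
  m2 <- colMeans(xs[g[[2L]], , drop = FALSE])
  dm <- m2 - m1
  if (sqrt(sum(dm^2)) < 1e-10)
    stop("canonical_projection: identical class means, no discriminant axis")
  n1 <- length(g[[1L]]); n2 <- length(g[[2L]])
  Sw <- ((n1 - 1) * cov(xs[g[[1L]], , drop = FALSE]) +
         (n2 - 1) * cov(xs[g[[2L]], , drop = FALSE])) / (n1 + n2 - 2)
  w1 <- tryCatch(solve(Sw, dm), error = function(e) {
    warning("canonical_projection: singular within-class scatter, ",
            "ridge-regularized")
    solve(Sw + diag(ridge, ncol(xs)), dm)
  })
  w1 <- w1 / sqrt(sum(w1^2))
  # residual variance orthogonal to c1
  proj <- xs - (xs %*% w1) %*% t(w1)
  eig <- eigen(cov(proj), symmetric = TRUE)
  w2 <- eig$vectors[, 1L]
  w2 <- w2 - sum(w2 * w1) * w1
  w2 <- w2 / sqrt(sum(w2^2))
  W <- cbind(c1 = w1, c2 = w2)
  rownames(W) <- colnames(x)
  structure(list(center = ctr, scale = scl, W = W,
                 classes = levels(labels)),
            class = "canonical_projection")
}

#' @export
print.canonical_projection <- function(x, ...) {
  cat("Canonical projection (Fisher discriminant + orthogonal variance axis)\n")
  print(round(x$W, 4))
  invisible(x)
}

#' Apply a canonical projection
#'
#' @param object A [canonical_projection()].
#' @param newdata Matrix or `data.frame` with the same 4 feature columns.
#' @param ... Unused.
#' @return n x 2 matrix with columns `c1`, `c2`.
#' @export
predict.canonical_projection <- function(object, newdata, ...) {
  x <- as.matrix(as.data.frame(newdata)[, seq_len(4L)])
  storage.mode(x) <- "double"
  scale(x, object$center, object$scale) %*% object$W
}

#' Misclassification cost matrix
#'
#' 2 x 2 weights `sigma[l, m]` penalising a record of true class `l`
#' classified as `m` (C = Crossing, B = Bone); the diagonal (correct
#' classification) is zero. A missed crossing (`sigma_CB`) is the costly
#' error for the surgeon, so `sigma_CB > sigma_BC` is the useful regime.
#'
#' @param sigma_CB Weight of a false negative (Crossing classified Bone).
#' @param sigma_BC Weight of a false positive (Bone classified Crossing).
#' @return Object of class `cost_matrix`.
#' @export
cost_matrix <- function(sigma_CB = 1, sigma_BC = 1) {
  if (sigma_CB < 0 || sigma_BC < 0)
    stop("cost_matrix: weights must be nonnegative")
  structure(list(sigma_BB = 0, sigma_CB = sigma_CB,
                 sigma_BC = sigma_BC, sigma_CC = 0),
            class = "cost_matrix")
}

#' @export
print.cost_matrix <- function(x, ...) {
  cat("Misclassification cost matrix [[sigma_BB, sigma_CB], [sigma_BC, sigma_CC]]:\n")
  cat(sprintf("  [[%g, %g], [%g, %g]]\n",
              x$sigma_BB, x$sigma_CB, x$sigma_BC, x$sigma_CC))
  invisible(x)
}

#' Train a cost-weighted soft-margin linear classifier
#'
#' Linear-kernel soft-margin SVM in which training errors on true-Crossing
#' records are weighted by `sigma_CB` and on true-Bone records by
#' `sigma_BC` (class weights on the hinge loss). With
#' `sigma_CB = sigma_BC = 1` this is the standard soft-margin SVM.
#'
#' @param x Numeric matrix of predictors (e.g. the canonical variables).
#' @param labels Factor with levels `Bone`, `Crossing` (both present).
#' @param cost A [cost_matrix()].
#' @param C Margin penalty of the SVM (default 1).
#' @return Object of class `linear_rule`: the fitted classifier with
#'   `weights` and `bias` oriented so a positive score predicts Crossing.
#' @export
train_weighted_classifier <- function(x, labels, cost = cost_matrix(),
                                      C = 1) {
  x <- as.matrix(x)
  labels <- factor(labels, levels = c("Bone", "Crossing"))
  if (length(unique(labels[!is.na(labels)])) < 2L)
    stop("train_weighted_classifier: both classes must be present")
  wts <- c(Bone = cost$sigma_BC, Crossing = cost$sigma_CB)
  fit <- e1071::svm(x, labels, kernel = "linear", cost = C,
                    class.weights = wts, scale = FALSE)
  w <- drop(t(fit$coefs) %*% fit$SV)
  b <- -fit$rho
  # orient the reported hyperplane so that score > 0 => Crossing
  dv <- drop(x %*% w + b)
  if (mean(dv[labels == "Crossing"]) < mean(dv[labels == "Bone"])) {
    w <- -w; b <- -b
  }
  structure(list(svm = fit, weights = w, bias = b, C = C, cost = cost),
            class = "linear_rule")
}

#' @export
predict.linear_rule <- function(object, newdata, ...) {
  predict(object$svm, as.matrix(newdata))
}

#' @export
print.linear_rule <- function(x, ...) {
  cat("Weighted soft-margin linear classifier\n")
  cat(sprintf("  weights: (%s), bias %.4f (score > 0 => Crossing)\n",
              paste(sprintf("%.4f", x$weights), collapse = ", "), x$bias))
  cat(sprintf("  cost weights: sigma_CB = %g, sigma_BC = %g, C = %g\n",
              x$cost$sigma_CB, x$cost$sigma_BC, x$C))
  invisible(x)
}

#' Confusion counts
#'
#' The positive event is an impact classified as Crossing: TP = Crossing
#' classified Crossing, FN = Crossing classified Bone, FP = Bone classified
#' Crossing, TN = Bone classified Bone.
#'
#' @param TP,TN,FP,FN Nonnegative counts.
#' @return Object of class `confusion_counts`.
#' @export
confusion_counts <- function(TP, TN, FP, FN) {
  v <- c(TP = TP, TN = TN, FP = FP, FN = FN)
  if (any(v < 0)) stop("confusion_counts: counts must be nonnegative")
  structure(as.list(v), class = "confusion_counts")
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat(sprintf("Confusion counts: TP %d, TN %d, FP %d, FN %d (n = %d)\n",
              x$TP, x$TN, x$FP, x$FN, x$TP + x$TN + x$FP + x$FN))
  cat(sprintf("  accuracy %.4f", accuracy_metric(x)))
  nl <- tryCatch(nlr(x), error = function(e) NA_real_)
  if (is.finite(nl)) cat(sprintf(", NLR %.4f", nl))
  cat("\n")
  invisible(x)
}

count_predictions <- function(truth, pred) {
  confusion_counts(
    TP = sum(truth == "Crossing" & pred == "Crossing"),
    TN = sum(truth == "Bone" & pred == "Bone"),
    FP = sum(truth == "Bone" & pred == "Crossing"),
    FN = sum(truth == "Crossing" & pred == "Bone"))
}

#' Classification accuracy
#'
#' `(TP + TN) / (TP + TN + FP + FN)`.
#'
#' @param counts A [confusion_counts()].
#' @return Fraction in [0, 1].
#' @export
#' @examples
#' accuracy_metric(confusion_counts(TP = 90, TN = 80, FP = 20, FN = 10))
accuracy_metric <- function(counts) {
  total <- counts$TP + counts$TN + counts$FP + counts$FN
  if (total == 0) stop("accuracy undefined: total count is zero")
  (counts$TP + counts$TN) / total
}

#' Negative likelihood ratio
#'
#' `NLR = (FN / (TP + FN)) / (TN / (FP + TN))` — the ratio of the
#' false-negative rate to specificity. Minimising it favours catching every
#' Crossing while preserving true Bone calls.
#'
#' @param counts A [confusion_counts()].
#' @return Nonnegative scalar.
#' @export
#' @examples
#' nlr(confusion_counts(TP = 90, TN = 80, FP = 20, FN = 10))  # 0.125
nlr <- function(counts) {
  if (counts$TP + counts$FN == 0)
    stop("NLR undefined: no true Crossing records (TP + FN = 0)")
  if (counts$FP + counts$TN == 0)
    stop("NLR undefined: no true Bone records (FP + TN = 0)")
  if (counts$TN == 0)
    stop("NLR undefined: TN = 0 (zero specificity)")
  (counts$FN / (counts$TP + counts$FN)) / (counts$TN / (counts$FP + counts$TN))
}

#' Stratified fold assignment
#'
#' @param labels Factor of class labels; each class count must be >= `k`.
#' @param k Number of folds.
#' @param seed Integer seed for the fold draw.
#' @return Integer vector of fold ids in 1..k.
#' @export
make_folds <- function(labels, k = 5L, seed = 1L) {
  if (k < 2L) stop("make_folds: k must be >= 2")
  if (any(table(labels) < k))
    stop("make_folds: each class must have at least k records")
  set.seed(seed)
  folds <- integer(length(labels))
  for (cl in levels(as.factor(labels))) {
    idx <- which(labels == cl)
    folds[idx] <- sample(rep_len(seq_len(k), length(idx)))
  }
  folds
}

#' Cross-validated evaluation of the weighted classifier
#'
#' Stratified k-fold cross-validation: each record is predicted exactly
#' once by a classifier trained on the other k-1 folds. Reports the pooled
#' confusion counts over all validation folds (primary) and the per-fold
#' accuracies with their mean.
#'
#' @inheritParams train_weighted_classifier
#' @param k Number of folds (default 5).
#' @param seed Seed for the stratified fold draw (ignored when `folds`
#'   given).
#' @param folds Optional precomputed fold assignment (from [make_folds()]),
#'   allowing several cost matrices to share identical folds.
#' @return Object of class `cv_result`: `counts` ([confusion_counts()]),
#'   `accuracy` (pooled), `per_fold_accuracy`, `mean_fold_accuracy`,
#'   `predictions` (factor, one per record), `folds`.
#' @export
kfold_cv <- function(x, labels, cost = cost_matrix(), k = 5L, seed = 1L,
                     C = 1, folds = NULL) {
  x <- as.matrix(x)
  labels <- factor(labels, levels = c("Bone", "Crossing"))
  if (is.null(folds)) folds <- make_folds(labels, k, seed)
  k <- max(folds)
  pred <- factor(rep(NA_character_, length(labels)),
                 levels = c("Bone", "Crossing"))
  per_fold <- numeric(k)
  for (f in seq_len(k)) {
    tr <- folds != f
    if (length(unique(labels[tr])) < 2L)
      stop("kfold_cv: a training split lost a class; use stratified folds")
    rule <- train_weighted_classifier(x[tr, , drop = FALSE], labels[tr],
                                      cost, C)
    p <- predict(rule, x[!tr, , drop = FALSE])
    pred[!tr] <- p
    per_fold[f] <- mean(p == labels[!tr])
  }
  counts <- count_predictions(labels, pred)
  structure(list(counts = counts, accuracy = accuracy_metric(counts),
                 per_fold_accuracy = per_fold,
                 mean_fold_accuracy = mean(per_fold),
                 predictions = pred, folds = folds, cost = cost),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("%d-fold cross-validation (sigma_CB = %g, sigma_BC = %g)\n",
              max(x$folds), x$cost$sigma_CB, x$cost$sigma_BC))
  print(x$counts)
  cat(sprintf("  mean per-fold accuracy %.4f\n", x$mean_fold_accuracy))
  invisible(x)
}

#' Tune the cost matrix by minimising the cross-validated NLR
#'
#' Grid search over the false-negative weight `sigma_CB` (with
#' `sigma_BC = 1` fixed: only the ratio matters), evaluating each candidate
#' by stratified k-fold cross-validation on identical folds and picking the
#' candidate with the smallest pooled negative likelihood ratio; ties go to
#' the smallest `sigma_CB`. Candidates with zero TN get an infinite NLR.
#'
#' @inheritParams kfold_cv
#' @param sigma_grid Candidate `sigma_CB` values (default 1 to 10 by 0.25).
#' @return Object of class `cost_search`: `cost` (optimal [cost_matrix()]),
#'   `cv_best` (the cv_result at the optimum), `cv_unweighted` (at
#'   `sigma_CB = 1`), `grid` (`data.frame` of counts, accuracy, NLR per
#'   candidate), `folds`.
#' @export
optimize_cost_matrix <- function(x, labels, k = 5L, seed = 1L,
                                 sigma_grid = seq(1, 10, by = 0.25), C = 1) {
  labels <- factor(labels, levels = c("Bone", "Crossing"))
  folds <- make_folds(labels, k, seed)
  cvs <- vector("list", length(sigma_grid))
  grid <- data.frame(sigma_CB = sigma_grid, TP = NA, TN = NA, FP = NA,
                     FN = NA, accuracy = NA, nlr = NA)
  for (i in seq_along(sigma_grid)) {
    cv <- kfold_cv(x, labels, cost_matrix(sigma_CB = sigma_grid[i]),
                   C = C, folds = folds)
    cvs[[i]] <- cv
    cc <- cv$counts
    grid[i, c("TP", "TN", "FP", "FN")] <- c(cc$TP, cc$TN, cc$FP, cc$FN)
    grid$accuracy[i] <- cv$accuracy
    grid$nlr[i] <- tryCatch(nlr(cc), error = function(e) Inf)
  }
  best <- which(grid$nlr <= min(grid$nlr) + 1e-12)[1L]  # grid ascending => smallest sigma
  i1 <- which(sigma_grid == 1)
  structure(list(cost = cost_matrix(sigma_CB = sigma_grid[best]),
                 cv_best = cvs[[best]],
                 cv_unweighted = if (length(i1)) cvs[[i1]] else NULL,
                 grid = grid, folds = folds),
            class = "cost_search")
}

#' @export
print.cost_search <- function(x, ...) {
  cat("Cost-matrix search (minimum cross-validated NLR)\n")
  cat(sprintf("  optimal sigma_CB = %g (NLR %.4f, accuracy %.4f)\n",
              x$cost$sigma_CB,
              tryCatch(nlr(x$cv_best$counts), error = function(e) NA),
              x$cv_best$accuracy))
  if (!is.null(x$cv_unweighted))
    cat(sprintf("  unweighted (sigma_CB = 1): NLR %.4f, accuracy %.4f, FN %d\n",
                tryCatch(nlr(x$cv_unweighted$counts), error = function(e) NA),
                x$cv_unweighted$accuracy, x$cv_unweighted$counts$FN))
  invisible(x)
}

#' One-way ANOVA between two impact classes
#'
#' Classical one-way fixed-effects ANOVA of an indicator between the Bone
#' and Crossing groups (equal-variance F test; for two groups F equals the
#' squared pooled-variance t statistic).
#'
#' @param values Numeric indicator values (e.g. per-impact `tau`).
#' @param groups Factor with two levels, each with at least 2 records.
#' @return List with `F`, `p`, `df` (numerator, denominator).
#' @export
anova_oneway <- function(values, groups) {
  groups <- droplevels(as.factor(groups))
  if (nlevels(groups) < 2L)
    stop("anova_oneway: need at least two groups")
  if (any(table(groups) < 2L))
    stop("anova_oneway: each group needs at least 2 records")
  ft <- oneway.test(values ~ groups, var.equal = TRUE)
  list(F = unname(ft$statistic), p = unname(ft$p.value),
       df = unname(ft$parameter))
}

#' Fit the Bone/Crossing impact classifier
#'
#' The end-to-end classification stage: projects the four impact features
#' onto the canonical variables `(c1, c2)`, evaluates a cost-sensitive
#' soft-margin linear SVM by stratified 5-fold cross-validation, and
#' (optionally) tunes the false-negative cost `sigma_CB` by minimising the
#' cross-validated negative likelihood ratio.
#'
#' @param features Feature `data.frame` from [build_feature_table()]
#'   (columns `tau_ms`, `lambda`, `dtau_ms`, `dlambda`, `label`).
#' @param k Folds. @param seed Fold seed.
#' @param sigma_grid Candidate `sigma_CB` grid; set `optimize = FALSE` to
#'   evaluate a fixed `cost` instead.
#' @param optimize Tune the cost matrix (default) or use `cost` as given.
#' @param cost [cost_matrix()] used when `optimize = FALSE`.
#' @param C Margin penalty.
#' @return Object of class `crossing_classifier`: `projection`, `search`
#'   (when tuned), `cv` (the reported [kfold_cv()] result), `counts`,
#'   `accuracy`, `per_fold_accuracy`, `nlr`, `sigma` (cost matrix),
#'   `anova` (per-indicator F/p between classes), `features`.
#' @export
classify_impacts <- function(features, k = 5L, seed = 1L,
                             sigma_grid = seq(1, 10, by = 0.25),
                             optimize = TRUE, cost = cost_matrix(), C = 1) {
  labels <- factor(features$label, levels = c("Bone", "Crossing"))
  fx <- features[, c("tau_ms", "lambda", "dtau_ms", "dlambda")]
  proj <- canonical_projection(fx, labels)
  xy <- predict(proj, fx)
  if (optimize) {
    search <- optimize_cost_matrix(xy, labels, k = k, seed = seed,
                                   sigma_grid = sigma_grid, C = C)
    cv <- search$cv_best
    cost <- search$cost
  } else {
    search <- NULL
    cv <- kfold_cv(xy, labels, cost, k = k, seed = seed, C = C)
  }
  an <- lapply(fx, function(v) anova_oneway(v, labels))
  structure(list(projection = proj, search = search, cv = cv,
                 counts = cv$counts, accuracy = cv$accuracy,
                 per_fold_accuracy = cv$per_fold_accuracy,
                 nlr = tryCatch(nlr(cv$counts), error = function(e) NA_real_),
                 sigma = cost, anova = an, features = features,
                 seed = seed, k = k),
            class = "crossing_classifier")
}

#' @export
print.crossing_classifier <- function(x, ...) {
  cat("Bone/Crossing impact classifier (cost-sensitive linear SVM)\n")
  print(x$sigma)
  print(x$counts)
  cat(sprintf("  mean per-fold accuracy %.4f over %d folds\n",
              x$cv$mean_fold_accuracy, x$k))
  invisible(x)
}

#' @export
summary.crossing_classifier <- function(object, ...) {
  cat("Bone/Crossing impact classifier\n\n")
  print(object$projection)
  cat("\n")
  print(object$sigma)
  print(object$counts)
  cat(sprintf("  per-fold accuracy: %s (mean %.4f)\n",
              paste(sprintf("%.3f", object$per_fold_accuracy), collapse = ", "),
              object$cv$mean_fold_accuracy))
  cat("  one-way ANOVA between classes:\n")
  for (nm in names(object$anova))
    cat(sprintf("    %-8s F = %8.2f, p = %.3g\n", nm,
                object$anova[[nm]]$F, object$anova[[nm]]$p))
  invisible(object)
}

#' Plot the classified database in canonical-variable space
#'
#' @param x A `crossing_classifier`.
#' @param ... Passed to [plot()].
#' @export
plot.crossing_classifier <- function(x, ...) {
  fx <- x$features[, c("tau_ms", "lambda", "dtau_ms", "dlambda")]
  xy <- predict(x$projection, fx)
  lab <- x$features$label
  plot(xy, col = ifelse(lab == "Crossing", 2, 1),
       pch = ifelse(lab == "Crossing", 4, 1),
       xlab = "c1", ylab = "c2", ...)
  legend("topright", legend = c("Bone", "Crossing"), col = c(1, 2),
         pch = c(1, 4), bty = "n")
  invisible(x)
}

#' Fraction of Crossing impacts detected within a tolerance window
#'
#' A crossing-labelled impact counts as detected if the classifier predicts
#' Crossing at that impact or within `window` impacts of it on the same
#' plate.
#'
#' @param features Feature `data.frame` (with `plate_id`, `impact_index`,
#'   `label`).
#' @param predictions Factor of predicted labels, aligned with `features`
#'   rows.
#' @param window Impact-index tolerance (default 1).
#' @return Fraction in [0, 1].
#' @export
crossing_detection_rate <- function(features, predictions, window = 1L) {
  stopifnot(nrow(features) == length(predictions))
  hits <- 0L; total <- 0L
  for (pid in unique(features$plate_id)) {
    sel <- features$plate_id == pid
    idx <- features$impact_index[sel]
    truth <- features$label[sel]
    pred <- predictions[sel]
    pred_idx <- idx[pred == "Crossing"]
    for (i in idx[truth == "Crossing"]) {
      total <- total + 1L
      if (any(abs(pred_idx - i) <= window)) hits <- hits + 1L
    }
  }
  if (total == 0L) stop("no crossing-labelled impacts in features")
  hits / total
}
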