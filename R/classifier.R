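#' Linear discriminant analysis with pooled-covariance shrinkage
#'
#' Fits a two-class Fisher discriminant: class means, pooled within-class
#' covariance regularised by a scalar ridge (`ridge * mean(diag(S))` added
#' to the diagonal), and the discriminant direction
#' `w = S^-1 (mu_pos - mu_neg)`. Scores are signed distances along `w`,
#' higher scores indicating the positive (symptomatic) class; the default
#' decision threshold is the score of the midpoint between class means,
#' shifted by the log prior ratio.
#'
#' @param x Numeric matrix or data frame of features.
#' @param y Class labels; the positive class is `"symptomatic"` when
#'   present, otherwise the rarer class.
#' @param ridge Scalar shrinkage intensity (fraction of the mean diagonal
#'   added to the pooled covariance). `ridge = 0` fails on singular fits
#'   with an error suggesting shrinkage.
#' @param prior Two-element class prior (negative, positive).
#' @return An object of class `tfhrv_lda`.
#' @export
lda_fit <- function(x, y, ridge = 1e-6, prior = c(0.5, 0.5)) {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  y <- droplevels(as_label_factor(y))
  if (nlevels(y) != 2L) abort("lda_fit needs exactly two classes")
  pos <- y == levels(y)[2]
  n0 <- sum(!pos)
  n1 <- sum(pos)
  if (n0 < 2L || n1 < 2L) abort("each class needs at least 2 observations")
  mu0 <- colMeans(x[!pos, , drop = FALSE])
  mu1 <- colMeans(x[pos, , drop = FALSE])
  s <- ((n0 - 1) * cov(x[!pos, , drop = FALSE]) +
        (n1 - 1) * cov(x[pos, , drop = FALSE])) / (n0 + n1 - 2)
  if (ridge > 0) {
    s <- s + diag(ridge * mean(diag(s)), ncol(x))
  }
  w <- tryCatch(
    solve(s, mu1 - mu0),
    error = function(e) {
      abort(paste("pooled covariance is singular; set ridge > 0",
                  "to shrink the fit"))
    }
  )
  threshold <- sum(w * (mu0 + mu1) / 2) + log(prior[1] / prior[2])
  structure(
    list(features = colnames(x), mu0 = mu0, mu1 = mu1, cov = s, w = w,
         threshold = threshold, levels = levels(y), prior = prior,
         ridge = ridge),
    class = "tfhrv_lda"
  )
}

#' @rdname lda_fit
#' @param object A fitted `tfhrv_lda`.
#' @param newdata Feature matrix or data frame to score.
#' @param type `"score"` for the continuous discriminant score or
#'   `"class"` for thresholded labels.
#' @param ... Unused.
#' @export
predict.tfhrv_lda <- function(object, newdata,
                              type = c("score", "class"), ...) {
  type <- match.arg(type)
  if (is.data.frame(newdata) && !is.null(object$features)) {
    newdata <- newdata[, object$features, drop = FALSE]
  }
  sc <- as.matrix(newdata) %*% object$w
  sc <- drop(sc)
  if (type == "score") return(sc)
  factor(ifelse(sc > object$threshold, object$levels[2], object$levels[1]),
         levels = object$levels)
}

#' @export
tidy.tfhrv_lda <- function(x, ...) {
  tibble(feature = x$features %||% paste0("V", seq_along(x$w)),
         weight = unname(x$w),
         mean_negative = unname(x$mu0), mean_positive = unname(x$mu1))
}

#' @export
glance.tfhrv_lda <- function(x, ...) {
  tibble(n_features = length(x$w), ridge = x$ridge,
         threshold = x$threshold)
}

#' ROC analysis of classifier scores
#'
#' Threshold-sweep ROC over the unique score values; the area under the
#' curve is the trapezoidal integral (identical to the normalised
#' Mann-Whitney U statistic). The operating point maximises Youden's
#' J = Se + Sp - 1; sensitivity, specificity and the confusion counts are
#' reported at that point, treating symptomatic patients as positives.
#'
#' @param scores Numeric classifier scores, higher = more positive.
#' @param labels Class labels.
#' @param positive Positive class name (defaults to `"symptomatic"` when
#'   present, otherwise the rarer class).
#' @return A list of class `roc_report`: `curve` tibble (`threshold`,
#'   `fpr`, `tpr`), `auc`, `se`, `sp`, `threshold`, and confusion counts
#'   `tp`, `fp`, `tn`, `fn`.
#' @export
roc_metrics <- function(scores, labels, positive = NULL) {
  y <- droplevels(as_label_factor(labels, positive = positive))
  if (nlevels(y) != 2L) abort("roc_metrics needs both classes present")
  if (length(unique(scores)) == 1L) {
    warn("constant scores produce a degenerate ROC; AUC = 0.5")
    n1 <- sum(y == levels(y)[2])
    n0 <- sum(y == levels(y)[1])
    return(structure(
      list(curve = tibble(threshold = scores[1], fpr = c(0, 1),
                          tpr = c(0, 1)),
           auc = 0.5, se = 1, sp = 0, threshold = scores[1],
           tp = n1, fp = n0, tn = 0L, fn = 0L),
      class = "roc_report"
    ))
  }
  r <- pROC::roc(response = y, predictor = scores,
                 levels = levels(y), direction = "<", quiet = TRUE)
  curve <- tibble(threshold = r$thresholds, fpr = 1 - r$specificities,
                  tpr = r$sensitivities) |>
    arrange(.data$fpr, .data$tpr)
  best <- pROC::coords(r, "best", best.method = "youden",
                       ret = c("threshold", "sensitivity", "specificity"),
                       transpose = FALSE)
  best <- best[1, ]
  thr <- best$threshold
  pos <- y == levels(y)[2]
  pred_pos <- scores > thr
  structure(
    list(curve = curve, auc = as.numeric(pROC::auc(r)),
         se = best$sensitivity, sp = best$specificity, threshold = thr,
         tp = sum(pred_pos & pos), fp = sum(pred_pos & !pos),
         tn = sum(!pred_pos & !pos), fn = sum(!pred_pos & pos)),
    class = "roc_report"
  )
}

#' @export
glance.roc_report <- function(x, ...) {
  tibble(auc = x$auc, se = x$se, sp = x$sp, threshold = x$threshold,
         tp = x$tp, fp = x$fp, tn = x$tn, fn = x$fn)
}

#' Stratified train/test split of a feature cohort
#'
#' Draws `floor(fraction * n)` training rows from each class; the
#' remaining rows form the test set, so the split is disjoint and
#' exhaustive.
#'
#' @param data Feature tibble with a `label` column.
#' @param fraction Training fraction in (0, 1).
#' @param seed Integer seed.
#' @return A list with tibbles `train` and `test`.
#' @export
split_train_test <- function(data, fraction = 0.75, seed = 1L) {
  if (fraction <= 0 || fraction >= 1) {
    abort("fraction must lie strictly between 0 and 1")
  }
  y <- as_label_factor(data$label)
  if (any(table(droplevels(y)) < 2L)) abort("each class needs >= 2 rows")
  withr::local_seed(derive_seed(seed, "split"))
  tr <- unlist(lapply(levels(droplevels(y)), function(lv) {
    idx <- which(y == lv)
    sample(idx, floor(fraction * length(idx)))
  }))
  if (length(tr) == nrow(data)) abort("training fraction leaves no test set")
  list(train = data[sort(tr), , drop = FALSE],
       test = data[-sort(tr), , drop = FALSE])
}

# stratified fold assignment; guarantees both classes in every fold
stratified_folds <- function(y, folds) {
  assign <- integer(length(y))
  for (lv in levels(droplevels(y))) {
    idx <- sample(which(y == lv))
    assign[idx] <- rep_len(seq_len(folds), length(idx))
  }
  assign
}

#' Repeated stratified cross-validation of the LDA classifier
#'
#' Runs stratified k-fold cross-validation `repeats` times with fresh fold
#' assignments. Within each repeat, out-of-fold scores are pooled into a
#' single ROC; the report carries the per-repeat AUC, sensitivity and
#' specificity (mean and SD across repeats), a vertically averaged ROC on
#' a common 101-point FPR grid, the pooled operating threshold of the
#' last-repeat ROC, and confusion counts at the global operating point.
#'
#' @param data Feature tibble with a `label` column.
#' @param features Feature columns to use (default: all).
#' @param folds,repeats Cross-validation layout.
#' @param ridge Shrinkage passed to [lda_fit()].
#' @param seed Integer seed.
#' @return An object of class `cv_report`.
#' @export
repeated_cv <- function(data, features = NULL, folds = 5L, repeats = 10L,
                        ridge = 1e-6, seed = 1L) {
  feats <- features %||% feature_columns(data)
  y <- droplevels(as_label_factor(data$label))
  if (any(table(y) < folds)) {
    abort("each class needs at least `folds` observations")
  }
  x <- as.matrix(data[, feats, drop = FALSE])
  withr::local_seed(derive_seed(seed, "cv"))
  per_repeat <- vector("list", repeats)
  rocs <- vector("list", repeats)
  all_scores <- numeric(0)
  all_labels <- character(0)
  for (r in seq_len(repeats)) {
    fold <- stratified_folds(y, folds)
    scores <- numeric(length(y))
    for (f in seq_len(folds)) {
      te <- fold == f
      fit <- lda_fit(x[!te, , drop = FALSE], y[!te], ridge = ridge)
      scores[te] <- as.matrix(x[te, , drop = FALSE]) %*% fit$w
    }
    rm <- roc_metrics(scores, y)
    per_repeat[[r]] <- tibble(repeat_id = r, auc = rm$auc, se = rm$se,
                              sp = rm$sp, threshold = rm$threshold)
    rocs[[r]] <- rm
    all_scores <- c(all_scores, scores)
    all_labels <- c(all_labels, as.character(y))
  }
  metrics <- list_rbind(per_repeat)
  fpr_grid <- seq(0, 1, length.out = 101L)
  tpr_mat <- vapply(rocs, function(rm) {
    cv <- rm$curve
    vapply(fpr_grid, function(f) max(cv$tpr[cv$fpr <= f + 1e-12], 0),
           numeric(1))
  }, numeric(101L))
  pooled <- roc_metrics(all_scores, all_labels)
  structure(
    list(
      metrics = metrics,
      roc = tibble(fpr = fpr_grid, tpr = rowMeans(tpr_mat)),
      pooled = pooled,
      auc_mean = mean(metrics$auc), auc_sd = sd(metrics$auc),
      se_mean = mean(metrics$se), se_sd = sd(metrics$se),
      sp_mean = mean(metrics$sp), sp_sd = sd(metrics$sp),
      folds = folds, repeats = repeats, features = feats
    ),
    class = "cv_report"
  )
}

#' @export
tidy.cv_report <- function(x, ...) x$metrics

#' @export
glance.cv_report <- function(x, ...) {
  tibble(auc_mean = x$auc_mean, auc_sd = x$auc_sd,
         se_mean = x$se_mean, se_sd = x$se_sd,
         sp_mean = x$sp_mean, sp_sd = x$sp_sd,
         folds = x$folds, repeats = x$repeats,
         n_features = length(x$features))
}

#' @export
print.cv_report <- function(x, ...) {
  cat(sprintf(
    "<cv_report> %d-fold CV x %d repeats on %d features\n  AUC %.3f +/- %.3f | Se %.3f +/- %.3f | Sp %.3f +/- %.3f\n",
    x$folds, x$repeats, length(x$features),
    x$auc_mean, x$auc_sd, x$se_mean, x$se_sd, x$sp_mean, x$sp_sd
  ))
  invisible(x)
}

#' @describeIn repeated_cv Mean ROC curve with the chance diagonal.
#' @param object A `cv_report`.
#' @param ... Unused.
#' @export
autoplot.cv_report <- function(object, ...) {
  ggplot(object$roc, aes(.data$fpr, .data$tpr)) +
    geom_abline(slope = 1, intercept = 0, linetype = 2,
                colour = "grey60") +
    geom_line(colour = "firebrick") +
    coord_equal() +
    labs(x = "false positive rate", y = "true positive rate",
         title = sprintf("mean ROC (AUC %.3f +/- %.3f)",
                         object$auc_mean, object$auc_sd)) +
    theme_minimal()
}
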