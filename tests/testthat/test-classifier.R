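two_clouds <- function(n, d = 6, seed = 1) {
  set.seed(seed)
  tibble::tibble(
    patient_id = as.character(1:n),
    label = rep(c("symptomatic", "asymptomatic"), each = n / 2),
    x1 = rnorm(n) + ifelse(rep(c(TRUE, FALSE), each = n / 2), d, 0),
    x2 = rnorm(n)
  )
}

test_that("separable clouds are classified perfectly at the midpoint", {
  d <- two_clouds(60)
  fit <- lda_fit(d[, c("x1", "x2")], d$label)
  pred <- predict(fit, d[, c("x1", "x2")], type = "class")
  expect_equal(as.character(pred), d$label)
})

test_that("isotropic classes give a Fisher direction along the mean gap", {
  set.seed(4)
  n <- 2000
  y <- rep(c("symptomatic", "asymptomatic"), each = n / 2)
  mu <- c(1.5, -0.7, 0.4)
  x <- matrix(rnorm(n * 3), n, 3)
  x[y == "symptomatic", ] <- sweep(x[y == "symptomatic", ], 2, mu, "+")
  fit <- lda_fit(x, y)
  cosine <- sum(fit$w * mu) / sqrt(sum(fit$w^2) * sum(mu^2))
  expect_gt(cosine, 0.999)
})

test_that("end-to-end AUC is invariant to affine feature rescaling", {
  d <- two_clouds(80, d = 1.5, seed = 9)
  fit1 <- lda_fit(d[, c("x1", "x2")], d$label)
  a1 <- tfhrv:::fast_auc(predict(fit1, d[, c("x1", "x2")]),
                         d$label == "symptomatic")
  d2 <- dplyr::mutate(d, x1 = 100 * x1 - 3, x2 = 0.01 * x2 + 7)
  fit2 <- lda_fit(d2[, c("x1", "x2")], d2$label)
  a2 <- tfhrv:::fast_auc(predict(fit2, d2[, c("x1", "x2")]),
                         d2$label == "symptomatic")
  expect_lt(abs(a1 - a2), 1e-9)
})

test_that("singular fits fail without shrinkage and agree with MASS", {
  d <- two_clouds(40, d = 2, seed = 3)
  d$x3 <- d$x1                       # collinear
  expect_error(lda_fit(d[, c("x1", "x2", "x3")], d$label, ridge = 0),
               "ridge|singular|shrink")
  fit <- lda_fit(d[, c("x1", "x2")], d$label, ridge = 0)
  m <- MASS::lda(as.matrix(d[, c("x1", "x2")]), grouping = d$label)
  ours <- predict(fit, d[, c("x1", "x2")], type = "class")
  theirs <- predict(m, as.matrix(d[, c("x1", "x2")]))$class
  expect_gte(mean(as.character(ours) == as.character(theirs)), 0.97)
})

test_that("roc metrics agree with pairwise concordance and Mann-Whitney", {
  r <- roc_metrics(c(0.9, 0.8, 0.3, 0.1),
                   c("symptomatic", "symptomatic",
                     "asymptomatic", "asymptomatic"))
  expect_equal(r$auc, 1)
  expect_equal(r$se, 1)
  expect_equal(r$sp, 1)

  r2 <- roc_metrics(c(0.9, 0.3, 0.8, 0.1),
                    c("symptomatic", "symptomatic",
                      "asymptomatic", "asymptomatic"))
  expect_equal(r2$auc, concordance_auc(c(0.9, 0.3), c(0.8, 0.1)))
  expect_equal(r2$auc, 0.75)

  set.seed(5)
  scores <- rnorm(60)
  labels <- sample(rep(c("symptomatic", "asymptomatic"), each = 30))
  r3 <- roc_metrics(scores, labels)
  u <- wilcox.test(scores[labels == "symptomatic"],
                   scores[labels == "asymptomatic"],
                   exact = FALSE)$statistic
  expect_equal(r3$auc, unname(u) / (30 * 30), tolerance = 1e-12)
  expect_equal(r3$tp + r3$fn, 30)
  expect_equal(r3$tn + r3$fp, 30)

  expect_warning(flat <- roc_metrics(rep(1, 10),
                                     rep(c("symptomatic", "asymptomatic"),
                                         5)),
                 "degenerate")
  expect_equal(flat$auc, 0.5)
})

test_that("stratified splits partition the cohort with fixed class counts", {
  co <- simulate_cohort(cohort_spec(seed = 3))
  std <- standardize_features(co)
  bal <- adasyn_balance(std, n_synthetic = 55, seed = 2)
  sp <- split_train_test(bal, 0.75, seed = 8)
  expect_equal(nrow(sp$train), 119L)
  expect_equal(nrow(sp$test), 41L)
  expect_equal(as.integer(table(sp$train$label)), c(60L, 59L))
  expect_equal(as.integer(table(sp$test$label)), c(21L, 20L))
  expect_setequal(c(sp$train$patient_id, sp$test$patient_id),
                  bal$patient_id)
  expect_length(intersect(sp$train$patient_id, sp$test$patient_id), 0L)
  expect_error(split_train_test(bal, 1.0, seed = 1), "between 0 and 1")
})

test_that("repeated CV hits the separable and permutation-null bounds", {
  d <- two_clouds(60, d = 8, seed = 2)
  cv <- repeated_cv(d, folds = 5, repeats = 4, seed = 3)
  expect_true(all(cv$metrics$auc == 1))

  set.seed(10)
  n <- 160
  null <- tibble::tibble(
    patient_id = as.character(1:n),
    label = sample(rep(c("symptomatic", "asymptomatic"), each = n / 2)),
    x1 = rnorm(n), x2 = rnorm(n), x3 = rnorm(n)
  )
  cv0 <- repeated_cv(null, folds = 5, repeats = 5, seed = 4)
  expect_lt(abs(cv0$auc_mean - 0.5), 0.07)
})

test_that("single-feature CV recovers the closed-form Gaussian AUC", {
  co <- simulate_cohort(cohort_spec(
    n_symptomatic = 300, n_asymptomatic = 300, n_features = 1,
    informative = 1, shift = 2, seed = 11
  ))
  cv <- repeated_cv(co, folds = 5, repeats = 10, seed = 3)
  expect_lt(abs(cv$auc_mean - pnorm(2 / sqrt(2))), 0.04)
})

test_that("cv reports are deterministic and degenerate SDs vanish", {
  d <- two_clouds(40, d = 1, seed = 6)
  a <- repeated_cv(d, folds = 4, repeats = 3, seed = 5)
  b <- repeated_cv(d, folds = 4, repeats = 3, seed = 5)
  expect_identical(a$metrics, b$metrics)
  one <- repeated_cv(d, folds = 4, repeats = 1, seed = 5)
  expect_true(is.na(one$auc_sd) || one$auc_sd == 0)
  g <- glance(a)
  expect_named(g, c("auc_mean", "auc_sd", "se_mean", "se_sd", "sp_mean",
                    "sp_sd", "folds", "repeats", "n_features"))
})
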