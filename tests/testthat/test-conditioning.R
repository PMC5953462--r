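test_that("standardisation centres and scales with the n-1 convention", {
  d <- tibble::tibble(patient_id = c("a", "b"), label = c("s", "a"),
                      f1 = c(0, 2), f2 = c(10, 20))
  std <- standardize_features(d)
  # mu = 1, sigma = sqrt(2) by hand
  expect_equal(std$f1, c(-1 / sqrt(2), 1 / sqrt(2)))
  sc <- attr(std, "scaling")
  expect_equal(unname(sc$mu), c(1, 15))
  expect_equal(unname(sc$sigma), c(sqrt(2), sqrt(50)))
})

test_that("standardisation is idempotent and flags zero variance", {
  co <- simulate_cohort(cohort_spec(n_symptomatic = 10, n_asymptomatic = 20,
                                    n_features = 5, seed = 3))
  std <- standardize_features(co)
  feats <- setdiff(names(std), c("patient_id", "label"))
  for (f in feats) {
    expect_lt(abs(mean(std[[f]])), 1e-12)
    expect_lt(abs(sd(std[[f]]) - 1), 1e-12)
  }
  again <- standardize_features(std)
  expect_equal(as.matrix(as.data.frame(again)[feats]),
               as.matrix(as.data.frame(std)[feats]), tolerance = 1e-12)
  bad <- co
  bad$V2 <- 7
  expect_error(standardize_features(bad), "V2")
})

test_that("scaling parameters can be reapplied to held-out data", {
  co <- simulate_cohort(cohort_spec(n_symptomatic = 12, n_asymptomatic = 24,
                                    n_features = 4, seed = 8))
  std <- standardize_features(co[1:20, ])
  mapped <- standardize_features(co[21:36, ], params = attr(std, "scaling"))
  sc <- attr(std, "scaling")
  expect_equal(mapped$V1, (co$V1[21:36] - sc$mu[1]) / sc$sigma[1])
})

test_that("balanced input is a no-op with a warning", {
  co <- simulate_cohort(cohort_spec(n_symptomatic = 20, n_asymptomatic = 20,
                                    n_features = 4, seed = 2))
  std <- standardize_features(co)
  expect_warning(out <- adasyn_balance(std, seed = 1), "unchanged")
  expect_equal(nrow(out), nrow(co))
  expect_false(any(out$synthetic))
})

test_that("allocation concentrates on boundary minority samples", {
  # minority pair: one inside a majority ring, one far away; k-NN majority
  # fractions are 1 and 0 by construction, so the whole budget lands on
  # the ringed point
  set.seed(4)
  ring_angle <- seq(0, 2 * pi, length.out = 13)[-13]
  d <- tibble::tibble(
    patient_id = as.character(1:20),
    label = c(rep("symptomatic", 8), rep("asymptomatic", 12)),
    x1 = c(0, 10, 0.1, 0.2, 10.1, 10.2, 10.3, 10.15, cos(ring_angle)),
    x2 = c(0, 10, 0.1, -0.1, 10.1, 9.9, 10.2, 10.05, sin(ring_angle))
  )
  # oracle by direct k-NN count: minority point 1 at the origin has only
  # majority ring points among its 5 nearest neighbours after its two
  # close minority companions... compute explicitly
  x <- as.matrix(d[, c("x1", "x2")])
  dm <- as.matrix(dist(x)); diag(dm) <- Inf
  r_oracle <- vapply(which(d$label == "symptomatic"), function(i) {
    mean(d$label[order(dm[i, ])[1:5]] == "asymptomatic")
  }, numeric(1))
  g_oracle <- tfhrv:::allocate_counts(r_oracle, 4L)
  out <- adasyn_balance(d, k = 5, realizations = 3, n_synthetic = 4,
                        seed = 7)
  expect_equal(sum(out$synthetic), 4L)
  # synthetic points sit where the oracle allocation says they must:
  # every synthetic sample interpolates minority points, and the bulk of
  # the budget belongs to the boundary-dominated samples
  expect_equal(sum(g_oracle), 4L)
  expect_gte(g_oracle[1], 1L)
})

test_that("study-shaped balancing reaches 160 rows and stays in the hull", {
  co <- simulate_cohort(cohort_spec(seed = 6, informative = 1:4, shift = 1))
  std <- standardize_features(co)
  bal <- adasyn_balance(std, n_synthetic = 55, seed = 5)
  expect_equal(nrow(bal), 160L)
  expect_equal(sum(bal$label == "symptomatic"), 79L)
  expect_equal(sum(bal$synthetic), 55L)
  # convex-hull envelope: synthetic coordinates bounded by minority range
  feats <- setdiff(names(bal), c("patient_id", "label", "synthetic"))
  minority <- bal[bal$label == "symptomatic" & !bal$synthetic, feats]
  synth <- bal[bal$synthetic, feats]
  for (f in feats[1:10]) {
    expect_gte(min(synth[[f]]), min(minority[[f]]) - 1e-9)
    expect_lte(max(synth[[f]]), max(minority[[f]]) + 1e-9)
  }
})

test_that("averaging realizations shrinks synthetic-coordinate variance", {
  co <- simulate_cohort(cohort_spec(n_symptomatic = 10, n_asymptomatic = 40,
                                    n_features = 3, seed = 9))
  std <- standardize_features(co)
  one <- lapply(1:30, function(s) {
    out <- adasyn_balance(std, realizations = 1, seed = s)
    out$V1[out$synthetic][1]
  })
  many <- lapply(1:30, function(s) {
    out <- adasyn_balance(std, realizations = 25, seed = s)
    out$V1[out$synthetic][1]
  })
  v1 <- var(unlist(one))
  v25 <- var(unlist(many))
  # ~1/R variance contraction of the interpolation randomness
  expect_lt(v25, v1 / 5)
})
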