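#' Standardise a feature matrix
#'
#' Centres and scales every feature column to zero mean and unit sample
#' standard deviation (n - 1 denominator) over all rows. The scaling
#' parameters are returned so held-out data can be mapped onto the same
#' scale.
#'
#' @param data Feature tibble (`patient_id`, `label`, numeric features).
#' @param params Optional scaling tibble (`feature`, `mu`, `sigma`) from a
#'   previous call, applied instead of re-estimating.
#' @return The standardised tibble with the scaling attached as attribute
#'   `"scaling"`.
#' @export
standardize_features <- function(data, params = NULL) {
  feats <- feature_columns(data)
  if (nrow(data) < 2L) abort("standardisation needs at least 2 rows")
  x <- as.matrix(data[, feats, drop = FALSE])
  if (any(!is.finite(x))) abort("feature matrix contains missing values")
  if (is.null(params)) {
    mu <- colMeans(x)
    sigma <- apply(x, 2, sd)
    zero <- sigma <= .Machine$double.eps
    if (any(zero)) {
      abort(sprintf("zero-variance feature(s): %s",
                    paste(feats[zero], collapse = ", ")))
    }
    params <- tibble(feature = feats, mu = mu, sigma = sigma)
  } else {
    params <- params[match(feats, params$feature), ]
    if (any(is.na(params$mu))) abort("params do not cover all features")
  }
  z <- sweep(sweep(x, 2, params$mu), 2, params$sigma, "/")
  out <- data
  out[, feats] <- as_tibble(as.data.frame(z))
  attr(out, "scaling") <- params
  out
}

# largest-remainder rounding of w * total to non-negative integers summing
# to total
allocate_counts <- function(w, total) {
  if (total <= 0L) return(integer(length(w)))
  if (sum(w) <= 0) w <- rep(1, length(w))
  raw <- w / sum(w) * total
  g <- floor(raw)
  rem <- total - sum(g)
  if (rem > 0) {
    idx <- order(raw - g, decreasing = TRUE)[seq_len(rem)]
    g[idx] <- g[idx] + 1L
  }
  as.integer(g)
}

#' Balance classes by averaged adaptive synthetic oversampling
#'
#' Generates synthetic minority-class (symptomatic) samples with the
#' ADASYN scheme: each minority sample receives a share of the synthetic
#' budget proportional to the fraction of majority samples among its k
#' nearest neighbours (so generation concentrates near the class
#' boundary), and each synthetic point is a convex interpolation between a
#' minority sample and one of its k nearest minority neighbours. Because
#' individual realizations are random, the generator is run `realizations`
#' times under a fixed minority-visit order and the synthetic block is the
#' element-wise mean over realizations at matched generation index.
#'
#' @param data Standardised feature tibble with exactly two label classes.
#' @param k Neighbour count for the density ratios and interpolation.
#' @param realizations Number of averaged ADASYN runs.
#' @param n_synthetic Synthetic sample budget G; defaults to the majority
#'   minus minority class size. `G = 0` is a no-op with a warning.
#' @param seed Integer seed.
#' @return The input tibble with synthetic minority rows appended and a
#'   logical `synthetic` column.
#' @export
adasyn_balance <- function(data, k = 5L, realizations = 50L,
                           n_synthetic = NULL, seed = 1L) {
  parts <- feature_matrix_parts(data)
  y <- droplevels(parts$y)
  if (nlevels(y) != 2L) abort("adasyn_balance needs exactly two classes")
  counts <- table(y)
  minority <- names(counts)[which.min(counts)]
  majority <- setdiff(names(counts), minority)
  g_total <- as.integer(n_synthetic %||% (max(counts) - min(counts)))
  out <- mutate(data, synthetic = FALSE)
  if (g_total <= 0L) {
    warn("non-positive synthetic budget; returning data unchanged")
    return(out)
  }
  if (min(counts) < k + 1L) {
    abort("minority class too small for the k-NN neighbourhood")
  }
  x <- parts$x
  min_idx <- which(y == minority)
  d <- as.matrix(dist(x))
  diag(d) <- Inf

  # density ratios: majority fraction among the k nearest neighbours of
  # each minority sample (deterministic given the data)
  r <- vapply(min_idx, function(i) {
    nn <- order(d[i, ])[seq_len(k)]
    mean(y[nn] == majority)
  }, numeric(1))
  g <- allocate_counts(r, g_total)

  # k nearest minority neighbours of each minority sample
  nn_min <- lapply(min_idx, function(i) {
    cand <- setdiff(min_idx, i)
    cand[order(d[i, cand])][seq_len(min(k, length(cand)))]
  })

  withr::local_seed(derive_seed(seed, "balance"))
  acc <- matrix(0, g_total, ncol(x))
  for (r_i in seq_len(realizations)) {
    row <- 0L
    for (j in seq_along(min_idx)) {
      if (g[j] == 0L) next
      xi <- x[min_idx[j], ]
      for (cc in seq_len(g[j])) {
        nb <- x[sample(nn_min[[j]], 1L), ]
        u <- runif(1L)
        row <- row + 1L
        acc[row, ] <- acc[row, ] + xi + u * (nb - xi)
      }
    }
  }
  synth <- acc / realizations
  colnames(synth) <- parts$features
  synth_tbl <- bind_cols(
    tibble(patient_id = sprintf("SYN%03d", seq_len(g_total)),
           label = minority, synthetic = TRUE),
    as_tibble(as.data.frame(synth))
  )
  bind_rows(out, synth_tbl[, names(out)])
}
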