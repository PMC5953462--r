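#' ReliefF feature weights
#'
#' Classic ReliefF for numeric attributes and two classes. Every instance
#' serves as an update centre: for each centre, the k nearest same-class
#' neighbours (hits) and k nearest other-class neighbours (misses) are
#' found by Euclidean distance, and each feature weight accumulates the
#' range-normalised absolute difference to misses minus the same quantity
#' to hits, divided by `m * k`. Weights therefore lie in \[-1, 1\], with
#' large positive weights marking features that separate the classes.
#'
#' @param x Numeric matrix or data frame of features (rows = instances).
#' @param y Class labels (two classes, each larger than `k`).
#' @param k Neighbour count, or a vector of neighbour counts whose weights
#'   are averaged (neighbour orderings are computed once).
#' @return Named numeric vector of feature weights.
#' @export
relieff_weights <- function(x, y, k = 10L) {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  y <- droplevels(as_label_factor(y))
  if (nlevels(y) != 2L) abort("relieff_weights needs exactly two classes")
  ks <- as.integer(k)
  if (any(table(y) <= max(ks))) {
    abort("each class must be larger than the neighbour count k")
  }
  n <- nrow(x)
  p <- ncol(x)
  rng <- apply(x, 2, function(v) diff(range(v)))
  rng[rng <= .Machine$double.eps] <- 1
  d <- as.matrix(dist(x))
  diag(d) <- Inf

  w <- matrix(0, length(ks), p)
  for (i in seq_len(n)) {
    same <- which(y == y[i])
    other <- which(y != y[i])
    hit_ord <- same[order(d[i, same])]
    miss_ord <- other[order(d[i, other])]
    # per-neighbour normalised feature differences, in neighbour order
    dh <- abs(sweep(x[hit_ord[seq_len(max(ks))], , drop = FALSE], 2, x[i, ])) |>
      sweep(2, rng, "/")
    dm <- abs(sweep(x[miss_ord[seq_len(max(ks))], , drop = FALSE], 2, x[i, ])) |>
      sweep(2, rng, "/")
    ch <- apply(dh, 2, cumsum)
    cm <- apply(dm, 2, cumsum)
    for (j in seq_along(ks)) {
      kk <- ks[j]
      w[j, ] <- w[j, ] + (cm[kk, ] - ch[kk, ]) / (n * kk)
    }
  }
  setNames(colMeans(w), colnames(x) %||% paste0("V", seq_len(p)))
}

#' Bootstrap ReliefF filter stage
#'
#' Runs ReliefF on repeated class-stratified subsamples of the training
#' set, averages weights over a range of neighbour counts within each
#' subsample, takes the per-feature median across subsamples as the final
#' relevance weight, and retains the top fraction of features (ties at the
#' retention boundary broken by original feature order).
#'
#' @param data Standardised training feature tibble.
#' @param realizations Number of bootstrap subsamples.
#' @param sample_fraction Fraction of each class drawn per subsample.
#' @param k_range Neighbour counts averaged within each subsample.
#' @param retain_fraction Fraction of features kept (count =
#'   `ceiling(retain_fraction * M)`).
#' @param seed Integer seed.
#' @return A list of class `relieff_filter`: `weights` tibble (`feature`,
#'   `weight`, `retained`) and `retained` (character vector, original
#'   feature order).
#' @export
filter_stage <- function(data, realizations = 50L, sample_fraction = 0.6,
                         k_range = 10:19, retain_fraction = 0.75,
                         seed = 1L) {
  parts <- feature_matrix_parts(data)
  y <- droplevels(parts$y)
  per_class <- floor(table(y) * sample_fraction)
  if (any(per_class <= max(k_range))) {
    abort("subsample smaller than the largest neighbour count")
  }
  withr::local_seed(derive_seed(seed, "filter"))
  wmat <- matrix(NA_real_, realizations, ncol(parts$x))
  for (r in seq_len(realizations)) {
    idx <- unlist(lapply(levels(y), function(lv) {
      sample(which(y == lv), per_class[[lv]])
    }))
    wmat[r, ] <- relieff_weights(parts$x[idx, , drop = FALSE], y[idx],
                                 k = k_range)
  }
  med <- apply(wmat, 2, median)
  m_keep <- ceiling(retain_fraction * length(med))
  ord <- order(-med, seq_along(med))
  retained_idx <- sort(ord[seq_len(m_keep)])
  weights <- tibble(feature = parts$features, weight = med,
                    retained = seq_along(med) %in% retained_idx)
  structure(
    list(weights = weights, retained = parts$features[retained_idx]),
    class = "relieff_filter"
  )
}
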