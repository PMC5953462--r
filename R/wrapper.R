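# sequential floating forward selection with an LDA black box, scored by
# AUC on a held-out inner split; tol guards against cycling, as does the
# iteration cap
sffs_lda <- function(xtr, ytr, xte, yte, tol = 1e-4, ridge = 1e-6,
                     max_size = ncol(xtr)) {
  p <- ncol(xtr)
  pos_te <- is_positive(yte)
  score_set <- function(sel) {
    if (!length(sel)) return(0.5)
    fit <- lda_fit(xtr[, sel, drop = FALSE], ytr, ridge = ridge)
    fast_auc(drop(xte[, sel, drop = FALSE] %*% fit$w), pos_te)
  }
  sel <- integer(0)
  best <- 0.5
  iter <- 0L
  repeat {
    iter <- iter + 1L
    if (iter > 2L * p || length(sel) >= max_size) break
    cand <- setdiff(seq_len(p), sel)
    if (!length(cand)) break
    gains <- vapply(cand, function(f) score_set(c(sel, f)), numeric(1))
    j <- which.max(gains)
    if (gains[j] <= best + tol) break
    sel <- c(sel, cand[j])
    best <- gains[j]
    # conditional backward exclusion (never the feature just added)
    while (length(sel) > 2L) {
      inner <- sel[-length(sel)]
      drops <- vapply(seq_along(inner),
                      function(i) score_set(sel[-i]), numeric(1))
      i <- which.max(drops)
      if (drops[i] > best + tol) {
        sel <- sel[-i]
        best <- drops[i]
      } else break
    }
  }
  sel
}

#' Floating LDA wrapper stage: feature appearance counts
#'
#' Repeats a sequential floating forward selection (with conditional
#' backward exclusion) on random stratified 75/25 inner splits of the
#' training set. Each realization trains LDA candidates on the inner 75%
#' and scores them by AUC on the inner 25%; the features selected in each
#' realization increment their appearance count. Degenerate inner splits
#' (a single class on either side) are redrawn and logged.
#'
#' @param data Training feature tibble, typically restricted to the
#'   filter-retained features.
#' @param features Feature columns to search over (default: all).
#' @param realizations Number of wrapper realizations.
#' @param inner_fraction Inner training fraction of each realization.
#' @param tol Minimum AUC improvement to accept an add/remove step.
#' @param ridge Shrinkage passed to [lda_fit()].
#' @param seed Integer seed.
#' @return A list of class `wrapper_counts`: `counts` tibble (`feature`,
#'   `count`), `realizations`, and `redraws` (number of redrawn splits).
#' @export
wrapper_stage <- function(data, features = NULL, realizations = 50L,
                          inner_fraction = 0.75, tol = 1e-4,
                          ridge = 1e-6, seed = 1L) {
  feats <- features %||% feature_columns(data)
  x <- as.matrix(data[, feats, drop = FALSE])
  y <- droplevels(as_label_factor(data$label))
  withr::local_seed(derive_seed(seed, "wrapper"))
  counts <- setNames(integer(length(feats)), feats)
  redraws <- 0L
  for (r in seq_len(realizations)) {
    repeat {
      tr <- unlist(lapply(levels(y), function(lv) {
        idx <- which(y == lv)
        sample(idx, floor(inner_fraction * length(idx)))
      }))
      te <- setdiff(seq_along(y), tr)
      ok <- nlevels(droplevels(y[tr])) == 2L &&
        nlevels(droplevels(y[te])) == 2L
      if (ok) break
      redraws <- redraws + 1L
    }
    sel <- sffs_lda(x[tr, , drop = FALSE], y[tr],
                    x[te, , drop = FALSE], y[te],
                    tol = tol, ridge = ridge)
    counts[sel] <- counts[sel] + 1L
  }
  structure(
    list(counts = tibble(feature = feats, count = unname(counts)),
         realizations = realizations, redraws = redraws),
    class = "wrapper_counts"
  )
}

#' Optimise the appearance-count threshold L
#'
#' For every candidate threshold L, the features appearing more than L
#' times across wrapper realizations form a candidate set (these sets are
#' nested and shrink as L grows). Each distinct set is scored by the mean
#' AUC of repeated stratified cross-validation on the training data, with
#' the same CV partitions shared across L values. The chosen L maximises
#' the mean AUC; among thresholds within `tie_tol` of the maximum, the one
#' giving the fewest features wins.
#'
#' @param counts A `wrapper_counts` object (or its `counts` tibble).
#' @param data Training feature tibble.
#' @param folds,repeats Cross-validation layout for scoring.
#' @param tie_tol AUC window treated as a tie.
#' @param ridge Shrinkage passed to [lda_fit()].
#' @param seed Integer seed (shared by all candidate evaluations).
#' @return A list of class `threshold_choice`: `L`, `features`, and the
#'   evaluation `grid` (`L`, `n_features`, `auc_mean`, `auc_sd`).
#' @export
optimize_threshold <- function(counts, data, folds = 5L, repeats = 10L,
                               tie_tol = 0.005, ridge = 1e-6, seed = 1L) {
  if (inherits(counts, "wrapper_counts")) {
    realizations <- counts$realizations
    counts <- counts$counts
  } else {
    realizations <- max(counts$count)
  }
  ls <- 0:(realizations - 1L)
  sets <- lapply(ls, function(l) counts$feature[counts$count > l])
  keep <- lengths(sets) > 0L
  ls <- ls[keep]
  sets <- sets[keep]
  if (!length(sets)) abort("no features pass any threshold")
  sig <- vapply(sets, paste, character(1), collapse = "\r")
  first <- !duplicated(sig)
  eval_cache <- setNames(vector("list", sum(first)), sig[first])
  for (s in sig[first]) {
    feats <- sets[[match(s, sig)]]
    cv <- repeated_cv(data, features = feats, folds = folds,
                      repeats = repeats, ridge = ridge, seed = seed)
    eval_cache[[s]] <- c(auc_mean = cv$auc_mean, auc_sd = cv$auc_sd)
  }
  grid <- tibble(
    L = ls,
    n_features = lengths(sets),
    auc_mean = vapply(sig, function(s) eval_cache[[s]][["auc_mean"]],
                      numeric(1)),
    auc_sd = vapply(sig, function(s) eval_cache[[s]][["auc_sd"]],
                    numeric(1))
  )
  best_auc <- max(grid$auc_mean)
  tied <- which(grid$auc_mean >= best_auc - tie_tol)
  pick <- tied[which.min(grid$n_features[tied])]
  structure(
    list(L = grid$L[pick], features = sets[[pick]], grid = grid),
    class = "threshold_choice"
  )
}

#' @export
print.threshold_choice <- function(x, ...) {
  cat(sprintf("<threshold_choice> L = %d keeping %d features\n",
              x$L, length(x$features)))
  invisible(x)
}
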