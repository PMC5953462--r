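#' Study configuration
#'
#' Collects the tunable parameters of every pipeline stage with the
#' defaults used throughout: the SPWVD kernel, the respiratory tracker,
#' class balancing (50 averaged ADASYN realizations), the bootstrap
#' ReliefF filter (50 subsamples of 60%, neighbour counts 10-19, top 75%
#' retained), the floating LDA wrapper (50 realizations of stratified
#' 75/25 inner splits), the appearance-count threshold search, and the
#' repeated 5-fold cross-validated LDA. A single master seed fans out to
#' per-stage seeds so stages can be re-run in isolation.
#'
#' @param kernel An [spwvd_kernel()].
#' @param lf_band Fixed LF band in Hz.
#' @param artifact_tolerance Tolerance for the automatic RR artifact rule,
#'   or `NULL` to skip correction (the default).
#' @param balance_k,balance_realizations,balance_G ADASYN parameters; `G`
#'   defaults to majority minus minority size.
#' @param split_fraction Training fraction of the cohort split.
#' @param filter_realizations,filter_fraction,filter_k_range,filter_retain
#'   Bootstrap ReliefF parameters.
#' @param wrapper_realizations,wrapper_inner_fraction,wrapper_tol Floating
#'   wrapper parameters.
#' @param cv_folds,cv_repeats Cross-validation layout.
#' @param tie_tol AUC tie window of the threshold search.
#' @param ridge LDA shrinkage.
#' @param seed Master seed.
#' @return A list of class `study_config`.
#' @export
study_config <- function(kernel = spwvd_kernel(),
                         lf_band = c(0.04, 0.15),
                         artifact_tolerance = NULL,
                         balance_k = 5L, balance_realizations = 50L,
                         balance_G = NULL,
                         split_fraction = 0.75,
                         filter_realizations = 50L, filter_fraction = 0.6,
                         filter_k_range = 10:19, filter_retain = 0.75,
                         wrapper_realizations = 50L,
                         wrapper_inner_fraction = 0.75,
                         wrapper_tol = 1e-4,
                         cv_folds = 5L, cv_repeats = 10L,
                         tie_tol = 0.005, ridge = 1e-6, seed = 1L) {
  structure(as.list(environment()), class = "study_config")
}

#' Extract the 60 HRV features of one recording
#'
#' End-to-end single-recording pipeline: (optional) artifact correction,
#' spline resampling of RR to 4 Hz, zero-phase high-pass at 0.03 Hz, SPWVD
#' of the RR series; EDR construction and its SPWVD; respiratory-frequency
#' tracking and the respiration-centred HF band; LF and HF band powers,
#' normalised indices, and one-minute window averages.
#'
#' @param beats A `beat_series`.
#' @param segmentation One-row segmentation tibble.
#' @param config A [study_config()].
#' @return A tibble of 60 rows (`feature`, `marker`, `window`, `value`,
#'   `flagged`); intermediate products are attached as attribute
#'   `"intermediates"` (`band_series`, `fr`).
#' @export
extract_recording_features <- function(beats, segmentation,
                                       config = study_config()) {
  if (!is.null(config$artifact_tolerance)) {
    beats <- correct_rr_artifacts(beats, config$artifact_tolerance)
  }
  rr <- resample_uniform(beats, "rr") |> highpass_rr()
  tfd_rr <- spwvd(rr, kernel = config$kernel)
  edr <- edr_series(beats)
  tfd_edr <- spwvd(edr, kernel = config$kernel)
  fr <- track_resp_frequency(tfd_edr)
  hf_band <- hf_band_from_fr(fr)
  # the RR and EDR grids can differ by one sample at either end (the RR
  # channel only exists from the second beat); align the band on RR time
  hf_band_rr <- tibble(
    time_s = tfd_rr$time_s,
    lower_hz = approx(hf_band$time_s, hf_band$lower_hz,
                      xout = tfd_rr$time_s, rule = 2)$y,
    upper_hz = approx(hf_band$time_s, hf_band$upper_hz,
                      xout = tfd_rr$time_s, rule = 2)$y
  )
  lf <- band_power(tfd_rr, config$lf_band)
  hf <- band_power(tfd_rr, hf_band_rr)
  bp <- normalized_series(lf, hf)
  windows <- define_windows(segmentation)
  feats <- extract_features(bp, windows)
  attr(feats, "intermediates") <- list(band_series = bp, fr = fr)
  feats
}

#' Extract a cohort feature matrix from a manifest
#'
#' The manifest is a tibble (or CSV path) with columns `patient_id`,
#' `beats_path`, `segmentation_path` and `label`. Each recording runs
#' through [extract_recording_features()]; failures are logged per patient
#' without aborting the cohort.
#'
#' @param manifest Manifest tibble or path to a manifest CSV.
#' @param config A [study_config()].
#' @return A wide feature tibble (`patient_id`, `label`, 60 feature
#'   columns); per-patient failures are recorded in attribute
#'   `"failures"`.
#' @export
run_extraction <- function(manifest, config = study_config()) {
  if (is.character(manifest)) {
    manifest <- readr::read_csv(manifest, show_col_types = FALSE,
                                progress = FALSE)
  }
  need <- c("patient_id", "beats_path", "segmentation_path", "label")
  if (!all(need %in% names(manifest))) {
    abort(sprintf("manifest needs columns: %s", paste(need, collapse = ", ")))
  }
  failures <- list()
  rows <- vector("list", nrow(manifest))
  for (i in seq_len(nrow(manifest))) {
    rec <- manifest[i, ]
    rows[[i]] <- tryCatch(
      {
        beats <- read_beats(rec$beats_path, patient_id = rec$patient_id,
                            label = rec$label)
        seg <- read_segmentation(rec$segmentation_path)
        feats <- extract_recording_features(beats, seg, config)
        wide <- setNames(as.list(feats$value), feats$feature)
        bind_cols(tibble(patient_id = rec$patient_id, label = rec$label),
                  as_tibble(wide))
      },
      error = function(e) {
        failures[[rec$patient_id]] <<- conditionMessage(e)
        warn(sprintf("patient %s failed: %s", rec$patient_id,
                     conditionMessage(e)))
        NULL
      }
    )
  }
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows)) abort("no recording could be processed")
  out <- list_rbind(rows)
  attr(out, "failures") <- failures
  out
}

#' Run the full classification study on a feature matrix
#'
#' Orchestrates the analysis end to end: standardisation over the full
#' cohort, ADASYN class balancing averaged over realizations, a stratified
#' 75/25 train/test split, bootstrap ReliefF filtering, the floating LDA
#' wrapper with appearance-count thresholding optimised by
#' cross-validated AUC, repeated cross-validation on the training set, and
#' a final evaluation of the held-out test set. The test set is scored
#' both at the training-derived operating threshold and at its own
#' ROC-optimal point.
#'
#' @param data Raw feature tibble (`patient_id`, `label`, features) as
#'   produced by [run_extraction()] or [simulate_cohort()].
#' @param config A [study_config()].
#' @return An object of class `study_result` with elements `filter`
#'   (ReliefF stage), `wrapper` (appearance counts), `threshold`
#'   (chosen L, final feature set, AUC grid), `cv` (training
#'   `cv_report`), `test` (held-out metrics), `scaling`, `config` and
#'   `seed`.
#' @export
run_study <- function(data, config = study_config()) {
  stopifnot(inherits(config, "study_config"))
  seed <- config$seed
  std <- standardize_features(data)
  balanced <- adasyn_balance(std, k = config$balance_k,
                             realizations = config$balance_realizations,
                             n_synthetic = config$balance_G, seed = seed)
  split <- split_train_test(balanced, fraction = config$split_fraction,
                            seed = seed)
  filt <- filter_stage(split$train,
                       realizations = config$filter_realizations,
                       sample_fraction = config$filter_fraction,
                       k_range = config$filter_k_range,
                       retain_fraction = config$filter_retain, seed = seed)
  wrap <- wrapper_stage(split$train, features = filt$retained,
                        realizations = config$wrapper_realizations,
                        inner_fraction = config$wrapper_inner_fraction,
                        tol = config$wrapper_tol, ridge = config$ridge,
                        seed = seed)
  thr <- optimize_threshold(wrap, split$train, folds = config$cv_folds,
                            repeats = config$cv_repeats,
                            tie_tol = config$tie_tol,
                            ridge = config$ridge, seed = seed)
  cv <- repeated_cv(split$train, features = thr$features,
                    folds = config$cv_folds, repeats = config$cv_repeats,
                    ridge = config$ridge, seed = seed)

  final_fit <- lda_fit(split$train[, thr$features, drop = FALSE],
                       split$train$label, ridge = config$ridge)
  test_scores <- predict(final_fit, split$test)
  test_pos <- is_positive(split$test$label)
  thr_train <- cv$pooled$threshold
  pred_pos <- test_scores > thr_train
  test_roc <- roc_metrics(test_scores, split$test$label)
  test <- list(
    auc = test_roc$auc,
    fixed_threshold = list(
      threshold = thr_train,
      se = sum(pred_pos & test_pos) / sum(test_pos),
      sp = sum(!pred_pos & !test_pos) / sum(!test_pos),
      tp = sum(pred_pos & test_pos), fp = sum(pred_pos & !test_pos),
      tn = sum(!pred_pos & !test_pos), fn = sum(!pred_pos & test_pos)
    ),
    reoptimized = glance(test_roc),
    n_train = nrow(split$train), n_test = nrow(split$test)
  )
  structure(
    list(filter = filt, wrapper = wrap, threshold = thr, cv = cv,
         test = test, fit = final_fit,
         scaling = attr(std, "scaling"), config = config, seed = seed),
    class = "study_result"
  )
}

#' @export
print.study_result <- function(x, ...) {
  cat(sprintf(
    paste0("<study_result>\n  filter retained %d features; wrapper L = %d",
           " -> %d features\n  training CV: AUC %.3f +/- %.3f | Se %.3f",
           " +/- %.3f | Sp %.3f +/- %.3f\n  held-out test (n = %d):",
           " AUC %.3f\n"),
    length(x$filter$retained), x$threshold$L, length(x$threshold$features),
    x$cv$auc_mean, x$cv$auc_sd, x$cv$se_mean, x$cv$se_sd,
    x$cv$sp_mean, x$cv$sp_sd, x$test$n_test, x$test$auc
  ))
  invisible(x)
}

#' @export
glance.study_result <- function(x, ...) {
  tibble(
    L = x$threshold$L, n_selected = length(x$threshold$features),
    cv_auc_mean = x$cv$auc_mean, cv_auc_sd = x$cv$auc_sd,
    cv_se_mean = x$cv$se_mean, cv_se_sd = x$cv$se_sd,
    cv_sp_mean = x$cv$sp_mean, cv_sp_sd = x$cv$sp_sd,
    test_auc = x$test$auc,
    test_se = x$test$fixed_threshold$se,
    test_sp = x$test$fixed_threshold$sp
  )
}

#' @export
tidy.study_result <- function(x, ...) {
  left_join(x$filter$weights, x$wrapper$counts, by = "feature") |>
    mutate(count = ifelse(is.na(.data$count), 0L, .data$count),
           selected = .data$feature %in% x$threshold$features)
}

#' @describeIn optimize_threshold Mean AUC (+/- SD ribbon) against the
#'   appearance-count threshold.
#' @param object A `threshold_choice`.
#' @param ... Unused.
#' @export
autoplot.threshold_choice <- function(object, ...) {
  ggplot(object$grid, aes(.data$L, .data$auc_mean)) +
    geom_ribbon(aes(ymin = .data$auc_mean - .data$auc_sd,
                    ymax = .data$auc_mean + .data$auc_sd),
                fill = "grey80") +
    geom_line() +
    geom_vline(xintercept = object$L, linetype = 2, colour = "firebrick") +
    labs(x = "appearance-count threshold L", y = "mean AUC") +
    theme_minimal()
}
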