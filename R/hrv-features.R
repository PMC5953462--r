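#' Normalised spectral index series
#'
#' Combines aligned LF and HF band-power series into the full marker set:
#' total power `TP = LF + HF`, normalised powers `LFnu = 100 * LF / TP`
#' and `HFnu = 100 * HF / TP` (so `LFnu + HFnu = 100` wherever defined),
#' and the sympathovagal balance `LFHF = LF / HF`. Because the underlying
#' distribution may swing negative locally, instants where `TP <= 0` are
#' masked rather than clipped; instants with `HF <= 0` additionally mask
#' `LFHF` so no infinities propagate.
#'
#' @param lf,hf Band-power tibbles from [band_power()], on identical time
#'   grids.
#' @return A tibble of class `band_power_series` with columns `time_s`,
#'   `lf`, `hf`, `tp`, `lfnu`, `hfnu`, `lfhf` and `masked`; the count of
#'   invalid-power instants is attached as attribute `"n_invalid"`.
#' @export
normalized_series <- function(lf, hf) {
  if (nrow(lf) != nrow(hf) || max(abs(lf$time_s - hf$time_s)) > 1e-9) {
    abort("LF and HF series must share the same time grid")
  }
  tp <- lf$power + hf$power
  invalid <- tp <= 0
  masked <- lf$masked | hf$masked | invalid
  lfnu <- ifelse(invalid, NA_real_, 100 * lf$power / tp)
  hfnu <- ifelse(invalid, NA_real_, 100 * hf$power / tp)
  lfhf <- ifelse(invalid | hf$power <= 0, NA_real_, lf$power / hf$power)
  structure(
    tibble(time_s = lf$time_s, lf = lf$power, hf = hf$power, tp = tp,
           lfnu = lfnu, hfnu = hfnu, lfhf = lfhf, masked = masked),
    class = c("band_power_series", "tbl_df", "tbl", "data.frame"),
    n_invalid = sum(invalid)
  )
}

window_labels <- c("WU1", "WU2", "EX1", "EX2", "EX3", "PE",
                   "AR1", "AR2", "AR3", "PR1", "PR2", "PR3")

hrv_markers <- c("LF", "LFnu", "HF", "HFnu", "LFHF")

#' Canonical names of the extracted feature set
#'
#' Five spectral markers averaged in each of the twelve one-minute protocol
#' windows, named `<MARKER>_<WINDOW>` (e.g. `LFnu_EX2`).
#'
#' @return Character vector of 60 feature names, marker-major.
#' @export
feature_names <- function() {
  as.vector(t(outer(hrv_markers, window_labels, paste, sep = "_")))
}

#' Protocol windows for feature averaging
#'
#' Lays out the twelve one-minute analysis windows over a segmented test:
#' two warm-up minutes from warm-up start, the first three exercise
#' minutes, the last minute before peak effort (PE), three active-recovery
#' minutes from the peak, and three passive-recovery minutes from the end
#' of active recovery. When incremental exercise lasts less than four
#' minutes, EX3 and PE overlap; this is permitted with a warning so that
#' short tests remain comparable.
#'
#' @param seg A one-row segmentation tibble (see [read_segmentation()]).
#' @return A tibble (`window`, `start_s`, `end_s`) of class
#'   `segment_windows` with twelve rows in canonical order.
#' @export
define_windows <- function(seg) {
  seg <- validate_segmentation(seg)
  wu0 <- seg$warmup_start_s
  ex0 <- seg$exercise_start_s
  pk <- seg$peak_effort_s
  ar_end <- seg$active_rec_end_s
  pr_end <- seg$passive_rec_end_s

  if (ex0 - wu0 < 120) abort("warm-up phase shorter than its two windows")
  if (pk - ex0 < 180) {
    abort("incremental-exercise phase shorter than its three windows")
  }
  if (ar_end - pk < 180) {
    abort("active-recovery phase shorter than its three windows")
  }
  if (pr_end - ar_end < 180) {
    abort("passive-recovery phase shorter than its three windows")
  }
  if (pk - ex0 < 240) {
    warn(sprintf(
      "exercise phase lasts %.0f s (< 4 min): EX3 and PE overlap by %.0f s",
      pk - ex0, 240 - (pk - ex0)
    ))
  }
  starts <- c(wu0, wu0 + 60, ex0, ex0 + 60, ex0 + 120, pk - 60,
              pk, pk + 60, pk + 120, ar_end, ar_end + 60, ar_end + 120)
  structure(
    tibble(window = window_labels, start_s = starts, end_s = starts + 60),
    class = c("segment_windows", "tbl_df", "tbl", "data.frame")
  )
}

#' Window-averaged HRV features
#'
#' Averages each marker series over the unmasked samples of each protocol
#' window, yielding the 60 named features for one recording. Windows with
#' more than half of their samples masked are flagged; a window with no
#' valid samples for some marker is an error (the patient should be
#' excluded upstream).
#'
#' @param bp A `band_power_series`.
#' @param windows A `segment_windows` tibble from [define_windows()].
#' @return A tibble with columns `feature`, `marker`, `window`, `value`
#'   and `flagged`.
#' @export
extract_features <- function(bp, windows) {
  marker_cols <- c(LF = "lf", LFnu = "lfnu", HF = "hf", HFnu = "hfnu",
                   LFHF = "lfhf")
  rows <- pmap(windows, function(window, start_s, end_s) {
    sel <- bp$time_s >= start_s & bp$time_s < end_s
    if (!any(sel)) {
      abort(sprintf("window %s lies outside the series support", window))
    }
    frac_masked <- mean(bp$masked[sel])
    vals <- map_dbl(marker_cols, function(col) {
      v <- bp[[col]][sel & !bp$masked]
      v <- v[is.finite(v)]
      if (!length(v)) {
        abort(sprintf("window %s fully masked; no valid samples", window))
      }
      mean(v)
    })
    tibble(feature = paste(names(marker_cols), window, sep = "_"),
           marker = names(marker_cols), window = window,
           value = unname(vals), flagged = frac_masked > 0.5)
  })
  out <- list_rbind(rows)
  out$window <- factor(out$window, levels = window_labels)
  out[order(match(out$marker, hrv_markers), out$window), ] |>
    mutate(window = as.character(.data$window))
}

#' Compare features between symptomatic and asymptomatic groups
#'
#' Two-sided Mann-Whitney U test per feature. The exact null distribution
#' is enumerated when both groups have at most 8 observations and no ties;
#' otherwise the tie-corrected normal approximation is used. Significance
#' is flagged at p < 0.05.
#'
#' @param data Feature tibble with a `label` column and numeric feature
#'   columns.
#' @param alpha Significance level.
#' @return A tibble (`feature`, `statistic`, `p.value`, `significant`)
#'   sorted by p-value.
#' @export
compare_groups <- function(data, alpha = 0.05) {
  y <- as_label_factor(data$label)
  if (nlevels(droplevels(y)) != 2L) {
    abort("compare_groups needs exactly two label groups")
  }
  if (any(table(y) < 2L)) abort("each group needs at least 2 observations")
  feats <- feature_columns(data)
  pos <- is_positive(y)
  res <- map(feats, function(f) {
    a <- data[[f]][pos]
    b <- data[[f]][!pos]
    exact <- length(a) <= 8L && length(b) <= 8L && !anyDuplicated(c(a, b))
    wt <- suppressWarnings(wilcox.test(a, b, exact = exact))
    tibble(feature = f, statistic = unname(wt$statistic),
           p.value = wt$p.value)
  })
  list_rbind(res) |>
    mutate(significant = .data$p.value < alpha) |>
    arrange(.data$p.value)
}
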