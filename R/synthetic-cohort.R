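#' Specification of a synthetic feature cohort
#'
#' Describes a Gaussian class-conditional feature cohort with a planted set
#' of class-informative columns, used to validate the conditioning,
#' selection and classification stages against known ground truth. Defaults
#' mirror a study-shaped cohort: 24 symptomatic vs 81 asymptomatic patients
#' and 60 features.
#'
#' @param n_symptomatic,n_asymptomatic Class sizes (positive counts).
#' @param n_features Number of feature columns.
#' @param informative Integer indices of class-informative columns (subset
#'   of `1:n_features`).
#' @param shift Mean shift (in within-class SD units) applied to the
#'   informative columns of the symptomatic class; must be finite.
#' @param rho Common within-class correlation between features (0 gives
#'   independent features).
#' @param seed Integer seed.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_symptomatic = 24, n_asymptomatic = 81,
                        n_features = 60, informative = integer(0),
                        shift = 0, rho = 0, seed = 1L) {
  if (n_symptomatic <= 0 || n_asymptomatic <= 0 || n_features <= 0) {
    abort("class sizes and feature count must be positive")
  }
  informative <- as.integer(informative)
  if (length(informative) > n_features ||
      (length(informative) && (min(informative) < 1L ||
                               max(informative) > n_features))) {
    abort("informative indices must be a subset of 1:n_features")
  }
  if (!is.finite(shift)) abort("shift must be finite")
  if (rho < 0 || rho >= 1) abort("rho must lie in [0, 1)")
  structure(
    list(n_symptomatic = n_symptomatic, n_asymptomatic = n_asymptomatic,
         n_features = n_features, informative = informative,
         shift = shift, rho = rho, seed = as.integer(seed)),
    class = "cohort_spec"
  )
}

#' Simulate a feature cohort with planted informative columns
#'
#' Draws Gaussian class-conditional features with unit within-class
#' variance. Informative columns have their symptomatic-class mean shifted
#' by `shift` SD units; all other columns are pure noise. With one
#' informative column of shift `d` and unit variances, the theoretical
#' single-feature AUC is `pnorm(d / sqrt(2))`.
#'
#' @param spec A [cohort_spec()].
#' @return A tibble with columns `patient_id`, `label` and `n_features`
#'   feature columns named `V1..Vk`; the planted informative feature names
#'   are attached as attribute `"informative"`.
#' @export
simulate_cohort <- function(spec = cohort_spec()) {
  stopifnot(inherits(spec, "cohort_spec"))
  withr::local_seed(spec$seed)
  n <- spec$n_symptomatic + spec$n_asymptomatic
  p <- spec$n_features
  x <- matrix(rnorm(n * p), n, p)
  if (spec$rho > 0) {
    # equicorrelated noise via a shared latent factor
    z <- rnorm(n)
    x <- sqrt(1 - spec$rho) * x + sqrt(spec$rho) * z
  }
  lab <- c(rep("symptomatic", spec$n_symptomatic),
           rep("asymptomatic", spec$n_asymptomatic))
  if (length(spec$informative)) {
    x[lab == "symptomatic", spec$informative] <-
      x[lab == "symptomatic", spec$informative] + spec$shift
  }
  colnames(x) <- paste0("V", seq_len(p))
  out <- bind_cols(
    tibble(patient_id = sprintf("P%03d", seq_len(n)), label = lab),
    as_tibble(x)
  )
  attr(out, "informative") <- paste0("V", spec$informative)
  out
}
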