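# Synthetic-cohort configuration.
#
# Defaults encode the study conditions of a large adult cardiac-surgery
# cohort monitored at 15-s resolution: phase durations (lognormal around the
# cohort medians, IQRs as dispersion), per channel-by-phase BP levels and
# between-patient level spread, AR(1) fluctuation dynamics whose (ar,
# innovation SD) pairs are obtained by inverting SD1 = sigma*sqrt(1-rho),
# SD2 = sigma*sqrt(1+rho) at the cohort's median Poincare descriptors, and
# covariate/outcome distributions with 30-day mortality ~2.7% and in-hospital
# renal failure ~2.85%.

#' Default per channel-by-phase BP dynamics
#'
#' One row per admissible (channel, phase) cell: the phase pressure level
#' (mmHg) and its between-patient SD, and the within-series AR(1) dynamics
#' (`ar`, `innovation_sd` in mmHg).
#'
#' @return A data frame with columns `channel`, `phase`, `level_mmhg`,
#'   `level_sd`, `ar`, `innovation_sd`.
#' @export
default_bp_dynamics <- function() {
  data.frame(
    channel = c("MAP", "MAP", "MAP", "SBP", "SBP"),
    phase = c("pre_bypass", "bypass", "post_bypass", "pre_bypass", "post_bypass"),
    level_mmhg = c(78, 57, 70, 111, 100),
    level_sd = c(7.4, 6.7, 5.9, 9.6, 7.4),
    ar = c(0.754, 0.899, 0.616, 0.953, 0.947),
    innovation_sd = c(10.75, 3.83, 10.74, 6.19, 5.42),
    stringsAsFactors = FALSE
  )
}

default_covariate_config <- function() {
  list(
    age_mean = 68, age_sd = 11.9, age_min = 19, age_max = 95,
    male_prop = 0.696,
    surgery_props = c(CABG = 0.4749, valve = 0.2975,
                      CABG_valve = 0.1966, other = 0.0310),
    sts_mm_median = 0.015, sts_mm_sdlog = 0.9,
    sts_renal_median = 0.03, sts_renal_sdlog = 0.9,
    sts_age_slope = 0.25,          # added to meanlog per decade above 68
    sts_score_cor = 0.7,           # latent correlation between the two scores
    vaso_median = 0.63, vaso_sdlog = 1.0,
    missing_sts_rate = c(mm = 0.259, renal = 0.276)
  )
}

default_outcome_coefficients <- function() {
  list(
    mortality_30d = list(
      target_prevalence = 0.027,
      sts_score = "sts_mm_score",
      terms = c(age_per10 = 0.35, sts_logit = 0.9, surgery_valve = 0.3,
                surgery_CABG_valve = 0.9, surgery_other = 1.3,
                log1p_vaso = 0.25)
    ),
    renal_failure = list(
      target_prevalence = 0.0285,
      sts_score = "sts_renal_score",
      terms = c(age_per10 = 0.30, sts_logit = 0.9, surgery_valve = 0.4,
                surgery_CABG_valve = 0.9, surgery_other = 0.6,
                log1p_vaso = 0.10)
    )
  )
}

#' Configuration for the synthetic cardiac-surgery cohort generator
#'
#' All defaults encode the emulated study conditions (see the methods
#' vignette). Outcome term names may be any of the built-in covariate terms
#' (`age_per10`, `sts_logit`, `surgery_valve`, `surgery_CABG_valve`,
#' `surgery_other`, `log1p_vaso`) or any BP-variability feature column name
#' (e.g. `cv_map_post`), which couples the outcome to the generated series;
#' the default coupling is zero. When `target_prevalence` is set for an
#' outcome, the intercept is calibrated by root finding so the expected
#' marginal prevalence matches it.
#'
#' @param n_patients number of patients (>= 1).
#' @param seed integer master seed; all stage/patient/channel substreams are
#'   derived from it via [hash_seed()].
#' @param phase_duration_medians named vector, minutes per phase.
#' @param phase_duration_sdlog lognormal dispersion of durations per phase.
#' @param bp_dynamics data frame as from [default_bp_dynamics()].
#' @param ar_coefficient optional scalar in (-1, 1) overriding `ar` in every
#'   dynamics cell.
#' @param innovation_sd optional scalar (mmHg) overriding `innovation_sd` in
#'   every cell.
#' @param dropout_rate i.i.d. per-sample missingness fraction in `[0, 1)`.
#' @param sample_interval_s sampling cadence, seconds.
#' @param covariates list as from `default_covariate_config()` (partial lists
#'   are merged over the defaults).
#' @param outcome_coefficients list as from
#'   `default_outcome_coefficients()`.
#' @param prop_no_cpb fraction of patients operated without cardiopulmonary
#'   bypass (excluded downstream).
#' @param prop_under_age fraction below the adult age cut-off.
#' @param prop_inadequate fraction with an artificially truncated recording
#'   (inadequate monitoring data).
#' @return An object of class `bpv_sim_config`.
#' @export
#' @examples
#' cfg <- sim_config(n_patients = 50, seed = 7)
#' cfg
sim_config <- function(n_patients = 500,
                       seed = 1L,
                       phase_duration_medians = c(pre_bypass = 126.0,
                                                  bypass = 79.3,
                                                  post_bypass = 76.5),
                       phase_duration_sdlog = c(pre_bypass = 0.263,
                                                bypass = 0.333,
                                                post_bypass = 0.239),
                       bp_dynamics = default_bp_dynamics(),
                       ar_coefficient = NULL,
                       innovation_sd = NULL,
                       dropout_rate = 0.02,
                       sample_interval_s = 15,
                       covariates = list(),
                       outcome_coefficients = default_outcome_coefficients(),
                       prop_no_cpb = 0.154,
                       prop_under_age = 0,
                       prop_inadequate = 0.0025) {
  if (!is.numeric(n_patients) || n_patients < 1) stop("n_patients must be >= 1")
  cov <- default_covariate_config()
  cov[names(covariates)] <- covariates
  if (abs(sum(cov$surgery_props) - 1) > 1e-6) {
    stop("surgery-category proportions must sum to 1")
  }
  if (!is.null(ar_coefficient)) {
    if (abs(ar_coefficient) >= 1) stop("ar_coefficient must lie in (-1, 1)")
    bp_dynamics$ar <- ar_coefficient
  }
  if (!is.null(innovation_sd)) {
    if (innovation_sd <= 0) stop("innovation_sd must be positive")
    bp_dynamics$innovation_sd <- innovation_sd
  }
  if (any(abs(bp_dynamics$ar) >= 1)) stop("ar coefficients must lie in (-1, 1)")
  if (dropout_rate < 0 || dropout_rate >= 1) stop("dropout_rate must be in [0, 1)")
  stopifnot(all(bpv_phases %in% names(phase_duration_medians)),
            all(bpv_phases %in% names(phase_duration_sdlog)),
            all(phase_duration_medians > 0))
  if (any(bp_dynamics$level_mmhg < 20 | bp_dynamics$level_mmhg > 250)) {
    stop("BP levels must be physiologic (20-250 mmHg)")
  }
  structure(
    list(n_patients = as.integer(n_patients), seed = as.integer(seed),
         phase_duration_medians = phase_duration_medians,
         phase_duration_sdlog = phase_duration_sdlog,
         bp_dynamics = bp_dynamics,
         dropout_rate = dropout_rate,
         sample_interval_s = sample_interval_s,
         covariates = cov,
         outcome_coefficients = outcome_coefficients,
         prop_no_cpb = prop_no_cpb,
         prop_under_age = prop_under_age,
         prop_inadequate = prop_inadequate),
    class = "bpv_sim_config"
  )
}

#' @export
print.bpv_sim_config <- function(x, ...) {
  cat(sprintf("<bpv_sim_config> %d patients, seed %d\n", x$n_patients, x$seed))
  cat(sprintf("  phase medians (min): pre %.1f / bypass %.1f / post %.1f\n",
              x$phase_duration_medians[["pre_bypass"]],
              x$phase_duration_medians[["bypass"]],
              x$phase_duration_medians[["post_bypass"]]))
  cat(sprintf("  dropout %.1f%%, no-CPB %.1f%%, cadence %g s\n",
              100 * x$dropout_rate, 100 * x$prop_no_cpb, x$sample_interval_s))
  cat(sprintf("  outcomes: %s\n",
              paste(names(x$outcome_coefficients), collapse = ", ")))
  invisible(x)
}
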