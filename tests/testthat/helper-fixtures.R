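# Shared fixtures: small, fast study configurations and hand-built cohorts.
# Unit tests use short phase durations so series stay small; the acceptance
# tests use the full default study conditions.

tiny_cfg <- function(n = 60, seed = 42, ...) {
  sim_config(n_patients = n, seed = seed,
             phase_duration_medians = c(pre_bypass = 15, bypass = 8,
                                        post_bypass = 8),
             ...)
}

# random lag-1 cloud with controllable correlation structure
random_cloud <- function(n = 50, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  base <- rnorm(n + 1, 100, 15) + cumsum(rnorm(n + 1, 0, 2))
  lag1_cloud(base)
}

# grid helper: samples every 15 s on [0, total_s)
grid_15s <- function(total_s) seq(0, total_s - 1e-9, by = 15)

# hand-built 5-patient cohort for exclusion-funnel tests:
#   P1 adequate, P2 no CPB, P3 short bypass MAP series (inadequate),
#   P4 adequate, P5 adequate
manual_cohort <- function() {
  mk_samples <- function(pid, total_s, channels = c("MAP", "SBP"),
                         value = 80) {
    do.call(rbind, lapply(channels, function(ch) {
      t <- grid_15s(total_s)
      data.frame(patient_id = pid, channel = ch,
                 time_s = t, value_mmhg = value + sin(t / 60),
                 stringsAsFactors = FALSE)
    }))
  }
  records <- data.frame(
    patient_id = paste0("P", 1:5),
    age = c(65, 70, 55, 60, 72),
    sex = "M",
    surgery_category = "CABG",
    sts_mm_score = 0.02, sts_renal_score = 0.03,
    vasopressor_dose = 0.5,
    cpb_used = c(TRUE, FALSE, TRUE, TRUE, TRUE),
    bypass_start_s = c(1200, NA, 1200, 1200, 1200),
    bypass_end_s = c(2400, NA, 1500, 2400, 2400),
    outcome_mortality_30d = c(0, 0, 0, 1, 0),
    outcome_renal_failure = c(0, 0, 0, 0, 1),
    stringsAsFactors = FALSE
  )
  samples <- rbind(
    mk_samples("P1", 3600),
    mk_samples("P2", 3600),
    mk_samples("P3", 1650),   # bypass [1200, 1500): 20 MAP samples, ok;
    mk_samples("P4", 3600),   # but post-bypass [1500, 1650) only 10 -> short
    mk_samples("P5", 3600)
  )
  list(records = records, samples = samples)
}
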