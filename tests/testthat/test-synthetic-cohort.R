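# Synthetic cohort generator: series structure, AR(1) moments, outcome
# assignment, determinism, covariate targets.

test_that("phase sample counts are exact without dropout and SBP skips bypass", {
  cfg <- sim_config(n_patients = 1, seed = 3, dropout_rate = 0)
  ser <- generate_bp_series(
    list(patient_id = "P1", cpb_used = TRUE,
         durations_min = c(pre_bypass = 10, bypass = 10, post_bypass = 10)),
    cfg, seed = 5)
  expect_equal(length(ser$MAP.pre_bypass), 40)       # 600 s / 15 s
  expect_equal(length(ser$MAP.bypass), 40)
  expect_equal(length(ser$MAP.post_bypass), 40)
  expect_null(ser$SBP.bypass)                        # forced by construction
  # no SBP sample time falls inside [bypass_start, bypass_end)
  sbp_t <- c(ser$SBP.pre_bypass$time_s, ser$SBP.post_bypass$time_s)
  expect_false(any(sbp_t >= 600 & sbp_t < 1200))
  # contiguous global grid across phases
  expect_equal(ser$MAP.bypass$time_s[1], 600)
  expect_equal(ser$MAP.post_bypass$time_s[1], 1200)
})

test_that("generator rejects non-physiologic inputs", {
  cfg <- sim_config(n_patients = 1, seed = 3)
  spec <- list(patient_id = "P1", cpb_used = TRUE,
               durations_min = c(pre_bypass = 10, bypass = -1,
                                 post_bypass = 10))
  expect_error(generate_bp_series(spec, cfg, 1), "positive")
  spec2 <- list(patient_id = "P1", cpb_used = TRUE,
                durations_min = c(pre_bypass = 10, bypass = 10,
                                  post_bypass = 10),
                levels = c(MAP.pre_bypass = 300))
  expect_error(generate_bp_series(spec2, cfg, 1), "physiologic")
})

test_that("AR(1) series recover their stationary moments", {
  # closed form: stationary SD = innovation_sd / sqrt(1 - ar^2) = 5.0
  cfg <- sim_config(n_patients = 1, seed = 8, ar_coefficient = 0.8,
                    innovation_sd = 3, dropout_rate = 0)
  ser <- generate_bp_series(
    list(patient_id = "P1", cpb_used = TRUE,
         durations_min = c(pre_bypass = 2500, bypass = 10, post_bypass = 10)),
    cfg, seed = 123)
  v <- ser$MAP.pre_bypass$value_mmhg
  expect_equal(length(v), 10000)
  expect_lt(abs(sd(v) - 5) / 5, 0.05)
  # lag-1 autocorrelation close to the AR coefficient
  r1 <- cor(v[-length(v)], v[-1])
  expect_lt(abs(r1 - 0.8), 0.02)
  # sample mean near the configured level, AR(1)-correct standard error
  se_mean <- 5 * sqrt((1 + 0.8) / (1 - 0.8)) / sqrt(length(v))
  expect_lt(abs(mean(v) - 78), 4 * se_mean)
})

test_that("outcome assignment is calibrated and deterministic", {
  # slopes zero, intercept 0 -> prevalence ~ 0.5
  x <- data.frame(z = rnorm(10000))
  y0 <- assign_outcomes(x, c("(Intercept)" = 0, z = 0), seed = 21)
  expect_lt(abs(mean(y0) - 0.5), 3 * sqrt(0.25 / 10000))

  # intercept log(0.027/0.973), slopes zero, n = 1e5 -> prevalence ~ 2.7%
  xx <- data.frame(z = rnorm(1e5))
  y1 <- assign_outcomes(xx, c("(Intercept)" = log(0.027 / 0.973), z = 0),
                        seed = 22)
  expect_lt(abs(mean(y1) - 0.027), 3 * sqrt(0.027 * 0.973 / 1e5))

  # same seed -> identical labels; different seed -> different
  y2 <- assign_outcomes(xx, c("(Intercept)" = log(0.027 / 0.973), z = 0),
                        seed = 22)
  expect_identical(as.integer(y1), as.integer(y2))

  expect_error(assign_outcomes(data.frame(z = c(1, Inf)),
                               c("(Intercept)" = 0, z = 1), seed = 1),
               "non-finite")
  expect_error(assign_outcomes(x, c("(Intercept)" = 0, nope = 1), seed = 1),
               "conformable")
})

test_that("cohorts are byte-identical under the same config", {
  cfg <- tiny_cfg(n = 40, seed = 77)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(a$records, b$records)
  expect_identical(a$samples, b$samples)
  expect_identical(a$truth, b$truth)
  c2 <- generate_cohort(tiny_cfg(n = 40, seed = 78))
  expect_false(identical(a$samples, c2$samples))
})

test_that("covariate and structural fractions hit their targets", {
  # covariate-only checks: short series keep this fast
  props <- c(CABG = 0.475, valve = 0.30, CABG_valve = 0.195, other = 0.03)
  cfg <- sim_config(n_patients = 10000, seed = 15,
                    phase_duration_medians = c(pre_bypass = 3, bypass = 2,
                                               post_bypass = 2),
                    covariates = list(surgery_props = props,
                                      missing_sts_rate = c(mm = 0.25,
                                                           renal = 0.25)))
  coh <- generate_cohort(cfg)
  n <- nrow(coh$records)
  for (cat in names(props)) {
    p_hat <- mean(coh$records$surgery_category == cat)
    expect_lt(abs(p_hat - props[[cat]]),
              3 * sqrt(props[[cat]] * (1 - props[[cat]]) / n))
  }
  miss <- mean(is.na(coh$records$sts_mm_score))
  expect_lt(abs(miss - 0.25), 3 * sqrt(0.25 * 0.75 / n))
  # age range respected, scores within [0, 1]
  expect_true(all(coh$records$age >= 19 & coh$records$age <= 95))
  sts <- coh$truth$sts_true$sts_mm_score
  expect_true(all(sts > 0 & sts < 1))
})

test_that("generated outcomes are calibrated against the stored truth", {
  cfg <- sim_config(n_patients = 8000, seed = 31,
                    phase_duration_medians = c(pre_bypass = 3, bypass = 2,
                                               post_bypass = 2))
  coh <- generate_cohort(cfg)
  # truth slopes echo the configured coefficients
  gen <- cfg$outcome_coefficients$mortality_30d$terms
  stored <- coh$truth$coefficients$mortality_30d
  expect_equal(stored[names(gen)], gen)
  # marginal prevalence near the calibration target
  p_bar <- mean(coh$truth$p$p_mortality_30d)
  expect_lt(abs(p_bar - 0.027), 1e-6)   # intercept calibrated by root finding
  obs <- mean(coh$records$outcome_mortality_30d)
  expect_lt(abs(obs - 0.027), 4 * sqrt(0.027 * 0.973 / 8000))
  # bin-level calibration: observed event fraction tracks true probability
  p <- coh$truth$p$p_mortality_30d
  y <- coh$records$outcome_mortality_30d
  bins <- cut(p, quantile(p, seq(0, 1, 0.25)), include.lowest = TRUE)
  for (b in levels(bins)) {
    i <- bins == b
    exp_p <- mean(p[i])
    se <- sqrt(exp_p * (1 - exp_p) / sum(i))
    expect_lt(abs(mean(y[i]) - exp_p), 4 * se + 1e-3)
  }
})

test_that("no-CPB and truncated-recording patients appear at their rates", {
  cfg <- sim_config(n_patients = 2000, seed = 55,
                    phase_duration_medians = c(pre_bypass = 6, bypass = 5,
                                               post_bypass = 5),
                    prop_no_cpb = 0.10, prop_inadequate = 0.01)
  coh <- generate_cohort(cfg)
  n_nocpb <- sum(!coh$records$cpb_used)
  expect_lt(abs(n_nocpb - 200), 3 * sqrt(2000 * 0.1 * 0.9))
  expect_true(all(is.na(coh$records$bypass_start_s[!coh$records$cpb_used])))
  # truncated patients have almost no pre-bypass MAP
  flags <- coh$truth$flags
  short_ids <- flags$patient_id[flags$inadequate & !flags$no_cpb]
  if (length(short_ids)) {
    s <- coh$samples[coh$samples$patient_id == short_ids[1] &
                       coh$samples$channel == "MAP" &
                       coh$samples$phase == "pre_bypass", ]
    expect_lte(nrow(s), 5)
  }
})

test_that("cohort CSV round trip preserves records and samples", {
  dir <- file.path(tempdir(), "bpv_csv_test")
  coh <- generate_cohort(tiny_cfg(n = 15, seed = 91))
  write_cohort_csv(coh, dir)
  back <- read_cohort_csv(dir)
  expect_equal(nrow(back$records), 15)
  expect_equal(nrow(back$samples), nrow(coh$samples))
  expect_equal(back$samples$value_mmhg, round(coh$samples$value_mmhg, 6))
  expect_true(file.exists(file.path(dir, "truth.csv")))
  # generating coefficients echoed as header comments
  hdr <- readLines(file.path(dir, "truth.csv"), n = 2)
  expect_true(all(grepl("^#", hdr)))
  unlink(dir, recursive = TRUE)
})
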