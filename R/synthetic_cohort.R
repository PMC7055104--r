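# Synthetic cohort generation: phase-structured AR(1) BP series, Table-style
# covariates, and Bernoulli outcomes from a logistic truth model.

#' Generate one patient's phase-segmented BP series
#'
#' MAP is emitted for all three phases, SBP for pre- and post-bypass only
#' (no SBP samples inside the bypass interval, by construction). Each
#' (channel, phase) series is a stationary AR(1) fluctuation around the
#' patient's phase level, restarted independently at phase boundaries, on a
#' global 15-s grid; i.i.d. dropout removes samples.
#'
#' @param patient_spec list with `patient_id`, `cpb_used` (logical),
#'   `durations_min` (named vector over phases, minutes; for non-CPB
#'   patients a single `total` entry), and optionally `levels`: either a
#'   data frame with `channel`, `phase`, `level_mmhg` or a named numeric
#'   vector keyed `"<channel>.<phase>"` (defaults to the configured cell
#'   levels).
#' @param cfg a [sim_config()] object.
#' @param seed integer substream seed for this patient (the per-channel
#'   streams are derived from it, so adding a channel does not perturb the
#'   others).
#' @return Named list of [bp_series] (`"MAP.pre_bypass"`, ...,
#'   `"SBP.post_bypass"`).
#' @export
#' @examples
#' cfg <- sim_config(n_patients = 1, seed = 1, dropout_rate = 0)
#' ser <- generate_bp_series(
#'   list(patient_id = "P1", cpb_used = TRUE,
#'        durations_min = c(pre_bypass = 10, bypass = 10, post_bypass = 10)),
#'   cfg, seed = hash_seed(1, "patient", 1))
#' length(ser$MAP.pre_bypass)  # 40 samples: 600 s / 15 s
generate_bp_series <- function(patient_spec, cfg, seed) {
  dt <- cfg$sample_interval_s
  dyn <- cfg$bp_dynamics
  dyn_key <- paste(dyn$channel, dyn$phase, sep = ".")
  dyn_level <- dyn$level_mmhg
  dyn_ar <- dyn$ar
  dyn_innov <- dyn$innovation_sd
  lv <- patient_spec$levels
  lv_key <- NULL
  if (!is.null(lv)) {
    if (is.data.frame(lv)) {
      lv_key <- stats::setNames(lv$level_mmhg,
                                paste(lv$channel, lv$phase, sep = "."))
    } else {
      lv_key <- lv   # named numeric vector keyed "<channel>.<phase>"
    }
  }
  cpb <- isTRUE(patient_spec$cpb_used)
  dur <- patient_spec$durations_min
  if (any(dur <= 0)) stop("phase durations must be positive")

  if (cpb) {
    pre_s <- dur[["pre_bypass"]] * 60
    byp_s <- dur[["bypass"]] * 60
    post_s <- dur[["post_bypass"]] * 60
    bounds <- list(pre_bypass = c(0, pre_s),
                   bypass = c(pre_s, pre_s + byp_s),
                   post_bypass = c(pre_s + byp_s, pre_s + byp_s + post_s))
  } else {
    total_s <- sum(dur) * 60
    bounds <- list(pre_bypass = c(0, total_s))
  }

  out <- list()
  for (ch in c("MAP", "SBP")) {
    phases <- names(bounds)
    if (ch == "SBP") phases <- setdiff(phases, "bypass")
    set.seed(hash_seed(seed, ch))
    for (ph in phases) {
      cell <- paste(ch, ph, sep = ".")
      j <- match(cell, dyn_key)
      if (is.na(j)) stop(sprintf("no dynamics cell for %s/%s", ch, ph))
      level <- dyn_level[j]
      if (!is.null(lv_key) && cell %in% names(lv_key)) {
        level <- unname(lv_key[[cell]])
      }
      if (level < 20 || level > 250) {
        stop(sprintf("non-physiologic BP level %.1f mmHg for %s/%s",
                     level, ch, ph))
      }
      b <- bounds[[ph]]
      k0 <- ceiling(b[1] / dt)
      k1 <- floor((b[2] - 1e-9) / dt)
      if (k1 < k0) {
        out[[cell]] <- new_bp_series(patient_spec$patient_id, ch, ph,
                                     numeric(0), numeric(0))
        next
      }
      tt <- (k0:k1) * dt
      n <- length(tt)
      sd_stat <- dyn_innov[j] / sqrt(1 - dyn_ar[j]^2)
      innov <- stats::rnorm(n, 0, dyn_innov[j])
      x0 <- stats::rnorm(1, 0, sd_stat)
      dev <- as.numeric(stats::filter(innov, dyn_ar[j], method = "recursive",
                                      init = x0))
      vals <- pmax(level + dev, 5)   # floor far below physiologic range
      if (cfg$dropout_rate > 0) {
        keep <- stats::runif(n) >= cfg$dropout_rate
        tt <- tt[keep]
        vals <- vals[keep]
      }
      out[[cell]] <- new_bp_series(patient_spec$patient_id, ch, ph, tt, vals)
    }
  }
  out
}

#' Draw binary outcome labels from a logistic model
#'
#' `label ~ Bernoulli(plogis(intercept + X beta))`. Coefficient names must
#' match columns of `covariates`; an optional `"(Intercept)"` entry is the
#' intercept.
#'
#' @param covariates data frame or matrix of numeric covariates.
#' @param coefficients named numeric vector.
#' @param seed integer substream seed.
#' @return Integer 0/1 vector with attributes `lp` (linear predictor) and
#'   `p` (event probability).
#' @export
#' @examples
#' x <- data.frame(z = rnorm(100))
#' y <- assign_outcomes(x, c("(Intercept)" = 0, z = 1), seed = 1)
assign_outcomes <- function(covariates, coefficients, seed) {
  X <- as.matrix(as.data.frame(covariates))
  icpt <- if ("(Intercept)" %in% names(coefficients)) {
    coefficients[["(Intercept)"]]
  } else 0
  slopes <- coefficients[setdiff(names(coefficients), "(Intercept)")]
  if (length(slopes)) {
    missing_cols <- setdiff(names(slopes), colnames(X))
    if (length(missing_cols)) {
      stop("coefficients not conformable with covariates: ",
           paste(missing_cols, collapse = ", "))
    }
    lp <- icpt + drop(X[, names(slopes), drop = FALSE] %*% slopes)
  } else {
    lp <- rep(icpt, nrow(X))
  }
  if (any(!is.finite(lp))) stop("non-finite linear predictor")
  p <- stats::plogis(lp)
  labels <- with_seed(seed, stats::rbinom(length(p), 1L, p))
  attr(labels, "lp") <- lp
  attr(labels, "p") <- p
  labels
}

# built-in outcome-model covariate terms derivable from patient records
builtin_outcome_terms <- function(records, sts_true) {
  data.frame(
    age_per10 = (records$age - 68) / 10,
    sts_logit_mm = stats::qlogis(sts_true$sts_mm_score),
    sts_logit_renal = stats::qlogis(sts_true$sts_renal_score),
    surgery_valve = as.numeric(records$surgery_category == "valve"),
    surgery_CABG_valve = as.numeric(records$surgery_category == "CABG_valve"),
    surgery_other = as.numeric(records$surgery_category == "other"),
    log1p_vaso = log1p(records$vasopressor_dose)
  )
}

#' Generate a complete synthetic cohort
#'
#' Draws covariates, phase durations and per-patient BP levels, generates
#' the phase-structured series for every patient, and assigns outcome labels
#' from the configured logistic truth model (intercepts calibrated to the
#' target marginal prevalences over the realised covariates). Fully
#' reproducible from `cfg$seed`.
#'
#' @param cfg a [sim_config()] object.
#' @return An object of class `bpv_cohort`: `records` (one row per patient),
#'   `samples` (long series table: `patient_id`, `channel`, `phase`,
#'   `time_s`, `value_mmhg`), `truth` (generating coefficients, linear
#'   predictors, event probabilities, true STS scores, structural flags) and
#'   `cfg`.
#' @export
#' @examples
#' coh <- generate_cohort(sim_config(
#'   n_patients = 20, seed = 3,
#'   phase_duration_medians = c(pre_bypass = 10, bypass = 6, post_bypass = 6)))
#' coh
generate_cohort <- function(cfg) {
  stopifnot(inherits(cfg, "bpv_sim_config"))
  n <- cfg$n_patients
  cov <- cfg$covariates
  ids <- sprintf("P%05d", seq_len(n))

  covs <- with_seed(hash_seed(cfg$seed, "covariates"), {
    age <- pmin(pmax(stats::rnorm(n, cov$age_mean, cov$age_sd),
                     cov$age_min), cov$age_max)
    male <- stats::rbinom(n, 1, cov$male_prop)
    surgery <- sample(names(cov$surgery_props), n, replace = TRUE,
                      prob = cov$surgery_props)
    z_mm <- stats::rnorm(n)
    z_re <- cov$sts_score_cor * z_mm +
      sqrt(1 - cov$sts_score_cor^2) * stats::rnorm(n)
    age_shift <- cov$sts_age_slope * (age - 68) / 10
    sts_mm <- pmin(pmax(exp(log(cov$sts_mm_median) + age_shift +
                              cov$sts_mm_sdlog * z_mm), 1e-3), 0.95)
    sts_renal <- pmin(pmax(exp(log(cov$sts_renal_median) + age_shift +
                                 cov$sts_renal_sdlog * z_re), 1e-3), 0.95)
    vaso <- pmin(exp(log(cov$vaso_median) + cov$vaso_sdlog * stats::rnorm(n)), 30)
    miss_mm <- stats::runif(n) < cov$missing_sts_rate[["mm"]]
    miss_renal <- stats::runif(n) < cov$missing_sts_rate[["renal"]]
    list(age = age, male = male, surgery = surgery, sts_mm = sts_mm,
         sts_renal = sts_renal, vaso = vaso, miss_mm = miss_mm,
         miss_renal = miss_renal)
  })

  struct <- with_seed(hash_seed(cfg$seed, "structure"), {
    no_cpb <- stats::runif(n) < cfg$prop_no_cpb
    under_age <- stats::runif(n) < cfg$prop_under_age
    inadequate <- stats::runif(n) < cfg$prop_inadequate
    dur <- sapply(bpv_phases, function(ph) {
      exp(log(cfg$phase_duration_medians[[ph]]) +
            cfg$phase_duration_sdlog[[ph]] * stats::rnorm(n))
    })
    list(no_cpb = no_cpb, under_age = under_age, inadequate = inadequate,
         dur = matrix(dur, nrow = n,
                      dimnames = list(NULL, bpv_phases)))
  })
  if (cfg$prop_under_age > 0) {
    covs$age[struct$under_age] <- stats::runif(sum(struct$under_age), 15, 18)
  }

  dyn <- cfg$bp_dynamics
  cellkey <- paste(dyn$channel, dyn$phase, sep = ".")
  level_mat <- with_seed(hash_seed(cfg$seed, "levels"), {
    m <- matrix(stats::rnorm(n * nrow(dyn)), nrow = n)
    sweep(sweep(m, 2, dyn$level_sd, "*"), 2, dyn$level_mmhg, "+")
  })
  level_mat <- pmin(pmax(level_mat, 25), 240)
  colnames(level_mat) <- cellkey

  # series generation (per patient, per-channel substreams); channel and
  # phase accumulate as integer codes, decoded once at the end
  acc_n <- integer(n); acc_ch <- vector("list", n)
  acc_ph <- vector("list", n); acc_t <- vector("list", n)
  acc_v <- vector("list", n)
  for (i in seq_len(n)) {
    cpb <- !struct$no_cpb[i]
    dmin <- struct$dur[i, ]
    spec <- list(
      patient_id = ids[i], cpb_used = cpb,
      durations_min = if (cpb) dmin else c(total = sum(dmin[c(1, 3)])),
      levels = level_mat[i, ]
    )
    ser <- generate_bp_series(spec, cfg, hash_seed(cfg$seed, "patient", ids[i]))
    if (struct$inadequate[i]) {
      # truncated recording: keep only the first few pre-bypass MAP samples
      s <- ser$MAP.pre_bypass
      keep <- seq_len(min(5L, length(s$time_s)))
      ser$MAP.pre_bypass <- bp_series(ids[i], "MAP", "pre_bypass",
                                      s$time_s[keep], s$value_mmhg[keep])
    }
    ns <- vapply(ser, function(s) length(s$time_s), integer(1))
    acc_n[i] <- sum(ns)
    acc_ch[[i]] <- rep(match(vapply(ser, `[[`, "", "channel"), bpv_channels), ns)
    acc_ph[[i]] <- rep(match(vapply(ser, `[[`, "", "phase"), bpv_phases), ns)
    acc_t[[i]] <- unlist(lapply(ser, `[[`, "time_s"), use.names = FALSE)
    acc_v[[i]] <- unlist(lapply(ser, `[[`, "value_mmhg"), use.names = FALSE)
  }
  samples <- data.frame(
    patient_id = rep(ids, acc_n),
    channel = bpv_channels[unlist(acc_ch, use.names = FALSE)],
    phase = bpv_phases[unlist(acc_ph, use.names = FALSE)],
    time_s = unlist(acc_t, use.names = FALSE),
    value_mmhg = unlist(acc_v, use.names = FALSE),
    stringsAsFactors = FALSE
  )

  pre_s <- struct$dur[, "pre_bypass"] * 60
  byp_s <- struct$dur[, "bypass"] * 60
  records <- data.frame(
    patient_id = ids,
    age = covs$age,
    sex = ifelse(covs$male == 1, "M", "F"),
    surgery_category = covs$surgery,
    sts_mm_score = ifelse(covs$miss_mm, NA_real_, covs$sts_mm),
    sts_renal_score = ifelse(covs$miss_renal, NA_real_, covs$sts_renal),
    vasopressor_dose = covs$vaso,
    cpb_used = !struct$no_cpb,
    bypass_start_s = ifelse(struct$no_cpb, NA_real_, pre_s),
    bypass_end_s = ifelse(struct$no_cpb, NA_real_, pre_s + byp_s),
    stringsAsFactors = FALSE
  )

  sts_true <- data.frame(patient_id = ids, sts_mm_score = covs$sts_mm,
                         sts_renal_score = covs$sts_renal,
                         stringsAsFactors = FALSE)
  terms_df <- builtin_outcome_terms(records, sts_true)

  # outcome-coefficient names outside the built-in vocabulary refer to BPV
  # feature columns and couple the outcome to the generated series
  all_term_names <- unique(unlist(lapply(cfg$outcome_coefficients,
                                         function(o) names(o$terms))))
  builtin <- c("age_per10", "sts_logit", "surgery_valve", "surgery_CABG_valve",
               "surgery_other", "log1p_vaso")
  feat_terms <- setdiff(all_term_names, builtin)
  if (length(feat_terms)) {
    feats <- cohort_features_for_truth(records, samples)
    for (ft in feat_terms) {
      if (!ft %in% names(feats)) {
        stop("unknown outcome coefficient term: ", ft)
      }
      v <- feats[[ft]][match(ids, feats$patient_id)]
      v[is.na(v)] <- stats::median(v, na.rm = TRUE)
      terms_df[[ft]] <- v
    }
  }

  truth_coef <- list()
  lp_df <- data.frame(patient_id = ids, stringsAsFactors = FALSE)
  p_df <- lp_df
  for (oc in names(cfg$outcome_coefficients)) {
    spec <- cfg$outcome_coefficients[[oc]]
    beta <- spec$terms
    # sts_logit resolves to the outcome's matched score
    des <- terms_df
    if ("sts_logit" %in% names(beta)) {
      des$sts_logit <- if (identical(spec$sts_score, "sts_renal_score")) {
        des$sts_logit_renal
      } else des$sts_logit_mm
    }
    lp0 <- if (length(beta)) {
      drop(as.matrix(des[, names(beta), drop = FALSE]) %*% beta)
    } else rep(0, n)
    icpt <- if (!is.null(spec$target_prevalence)) {
      stats::uniroot(function(c0) mean(stats::plogis(c0 + lp0)) -
                       spec$target_prevalence,
                     c(-40, 20), tol = 1e-10)$root
    } else spec$intercept %||% 0
    coefs <- c("(Intercept)" = icpt, beta)
    y <- assign_outcomes(des[, names(beta), drop = FALSE], coefs,
                         hash_seed(cfg$seed, "outcome", oc))
    records[[paste0("outcome_", oc)]] <- as.integer(y)
    truth_coef[[oc]] <- coefs
    lp_df[[paste0("lp_", oc)]] <- attr(y, "lp")
    p_df[[paste0("p_", oc)]] <- attr(y, "p")
  }

  structure(
    list(records = records, samples = samples,
         truth = list(coefficients = truth_coef, lp = lp_df, p = p_df,
                      sts_true = sts_true,
                      flags = data.frame(patient_id = ids,
                                         no_cpb = struct$no_cpb,
                                         under_age = struct$under_age,
                                         inadequate = struct$inadequate,
                                         stringsAsFactors = FALSE)),
         cfg = cfg),
    class = "bpv_cohort"
  )
}

# features used only to couple outcomes to the series inside the generator
cohort_features_for_truth <- function(records, samples) {
  split_samples <- split_samples_by_patient(samples)
  cores <- lapply(seq_len(nrow(records)), function(i) {
    rec <- records[i, ]
    if (!isTRUE(rec$cpb_used)) return(NULL)
    s <- split_samples[[rec$patient_id]]
    if (is.null(s)) return(NULL)
    seg <- try(segment_phases(s, rec), silent = TRUE)
    if (inherits(seg, "try-error")) return(NULL)
    patient_bpv_core(seg, min_samples = 20, max_gap = 30)
  })
  cores <- cores[!vapply(cores, is.null, logical(1))]
  if (!length(cores)) return(NULL)
  data.frame(patient_id = vapply(cores, `[[`, "", "patient_id"),
             do.call(rbind, lapply(cores, `[[`, "values")),
             stringsAsFactors = FALSE, check.names = FALSE)
}

#' @export
print.bpv_cohort <- function(x, ...) {
  cat(sprintf("<bpv_cohort> %d patients, %s samples (seed %d)\n",
              nrow(x$records), format(nrow(x$samples), big.mark = ","),
              x$cfg$seed))
  for (oc in names(x$truth$coefficients)) {
    col <- paste0("outcome_", oc)
    cat(sprintf("  %s: %d events (%.2f%%)\n", oc, sum(x$records[[col]]),
                100 * mean(x$records[[col]])))
  }
  invisible(x)
}

#' Write a synthetic cohort to long-format CSV files
#'
#' Writes `series.csv` (`patient_id`, `channel`, `phase`, `time_s`,
#' `value_mmhg`), `covariates.csv` (one row per patient) and `truth.csv`
#' (per-patient linear predictors and event probabilities, with the
#' generating coefficients echoed as `#` header comments).
#'
#' @param cohort a `bpv_cohort`.
#' @param dir output directory (created if absent).
#' @return Invisibly, the written file paths.
#' @export
write_cohort_csv <- function(cohort, dir) {
  stopifnot(inherits(cohort, "bpv_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  f_series <- file.path(dir, "series.csv")
  f_cov <- file.path(dir, "covariates.csv")
  f_truth <- file.path(dir, "truth.csv")
  utils::write.csv(round_numeric(cohort$samples), f_series, row.names = FALSE)
  utils::write.csv(round_numeric(cohort$records), f_cov, row.names = FALSE)
  truth <- merge(cohort$truth$lp, cohort$truth$p, by = "patient_id")
  con <- file(f_truth, "w")
  for (oc in names(cohort$truth$coefficients)) {
    b <- cohort$truth$coefficients[[oc]]
    writeLines(sprintf("# %s: %s", oc,
                       paste(sprintf("%s=%.6g", names(b), b), collapse = " ")),
               con)
  }
  utils::write.csv(round_numeric(truth), con, row.names = FALSE)
  close(con)
  invisible(c(f_series, f_cov, f_truth))
}

#' Read cohort CSV files written by [write_cohort_csv()] or external tools
#'
#' @param dir directory containing `series.csv` and `covariates.csv`.
#' @return A list with `records` and `samples` data frames.
#' @export
read_cohort_csv <- function(dir) {
  samples <- utils::read.csv(file.path(dir, "series.csv"),
                             stringsAsFactors = FALSE)
  records <- utils::read.csv(file.path(dir, "covariates.csv"),
                             stringsAsFactors = FALSE)
  need_s <- c("patient_id", "channel", "time_s", "value_mmhg")
  if (!all(need_s %in% names(samples))) {
    stop("series.csv must have columns: ", paste(need_s, collapse = ", "))
  }
  if (!"patient_id" %in% names(records)) {
    stop("covariates.csv must have a patient_id column")
  }
  list(records = records, samples = samples)
}

# fixed decimal precision for written numeric output (platform-stable
# golden files)
round_numeric <- function(df, digits = 6) {
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], round, digits = digits)
  df
}
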