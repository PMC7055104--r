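# Publication-shaped model suite: univariable BPV models, the STS-score
# models, and covariate-adjusted BPV models, each evaluated by C-statistic
# and Hosmer-Lemeshow calibration.

# adjustment covariates: age, surgery category, matched STS score (imputed,
# log-odds scale, with missingness indicator), vasopressor-inotrope dose
build_adjustment_design <- function(records, sts_col) {
  rec <- impute_missing_sts(records, score_cols = sts_col)
  sc <- pmin(pmax(rec[[sts_col]], 1e-4), 1 - 1e-4)
  data.frame(
    age_per10 = (rec$age - 68) / 10,
    surgery_valve = as.numeric(rec$surgery_category == "valve"),
    surgery_CABG_valve = as.numeric(rec$surgery_category == "CABG_valve"),
    surgery_other = as.numeric(rec$surgery_category == "other"),
    sts_logit = stats::qlogis(sc),
    sts_missing = rec[[paste0(sts_col, "_missing")]],
    log1p_vaso = log1p(rec$vasopressor_dose)
  )
}

suite_row <- function(outcome, model_type, variable, channel = NA, phase = NA,
                      metric = NA) {
  data.frame(outcome = outcome, model = model_type, variable = variable,
             channel = channel, phase = phase, metric = metric,
             n = NA_integer_, n_events = NA_integer_,
             estimate = NA_real_, se = NA_real_, exposure_p = NA_real_,
             auc = NA_real_, auc_lo = NA_real_, auc_hi = NA_real_,
             hl_chi2 = NA_real_, hl_df = NA_integer_, hl_p = NA_real_,
             converged = NA, n_iterations = NA_integer_,
             note = "", stringsAsFactors = FALSE)
}

# evaluate one model specification, folding fit warnings (e.g. separation
# diagnostics) into the row's note instead of emitting them
run_spec <- function(row, expr) {
  wmsg <- character(0)
  res <- tryCatch(
    withCallingHandlers(expr, warning = function(w) {
      wmsg <<- c(wmsg, conditionMessage(w))
      invokeRestart("muffleWarning")
    }),
    error = function(err) {
      row$note <- conditionMessage(err)
      row
    })
  if (length(wmsg) && !nzchar(res$note)) {
    res$note <- paste(unique(wmsg), collapse = "; ")
  }
  res
}

fill_fit <- function(row, fit, term, score_for_auc, y, hl_groups) {
  row$n <- fit$n
  row$n_events <- sum(y)
  row$converged <- fit$converged
  row$n_iterations <- fit$iterations
  if (!is.na(term) && term %in% names(fit$coefficients)) {
    row$estimate <- fit$coefficients[[term]]
    row$se <- fit$se[[term]]
    row$exposure_p <- wald_p(fit, term)
  }
  cs <- c_statistic(score_for_auc, y)
  row$auc <- cs$auc
  row$auc_lo <- cs$ci[1]
  row$auc_hi <- cs$ci[2]
  hl <- tryCatch(hosmer_lemeshow(fit$fitted, y, groups = hl_groups),
                 error = function(e) NULL)
  if (!is.null(hl)) {
    row$hl_chi2 <- hl$chi2
    row$hl_df <- hl$df
    row$hl_p <- hl$p_value
  }
  row
}

#' Run the full logistic model suite over the analysis cohort
#'
#' For each outcome: (a) univariable models, one per BP-variability exposure
#' (CV/SD1/SD2 per channel and phase); (b) an STS-score-only model; (c) an
#' STS model adjusted to age, surgery category and vasopressor dose; (d) per
#' exposure, the BPV parameter adjusted to age, surgery category, STS score
#' and vasopressor dose. Missing STS scores are median-imputed with a
#' retained missingness indicator; scores enter on the log-odds scale.
#'
#' The reported C-statistic is that of the exposure itself (natural
#' increasing orientation) for univariable models — so a protective exposure
#' can score below 0.5 — and of the fitted probabilities for multivariable
#' models. Per-specification failures are caught and reported as rows with
#' missing cells, not errors.
#'
#' @param features BPV feature rows from [compute_cohort_bpv()].
#' @param records patient records (must contain the outcome columns).
#' @param outcomes outcome names; column `outcome_<name>` must exist.
#'   Mortality-type outcomes use `sts_mm_score`, renal ones
#'   `sts_renal_score` (see `sts_map`).
#' @param models which model families to run.
#' @param sts_map named list mapping outcome name to its STS score column.
#' @param hl_groups Hosmer-Lemeshow group count.
#' @param exposures exposure columns (default the 15 CV/SD1/SD2 cells).
#' @return Data frame of class `bpv_model_suite`, one row per fitted model.
#' @export
run_model_suite <- function(features, records,
                            outcomes = c("mortality_30d", "renal_failure"),
                            models = c("univariable", "sts_only",
                                       "sts_adjusted", "adjusted"),
                            sts_map = list(mortality_30d = "sts_mm_score",
                                           renal_failure = "sts_renal_score"),
                            hl_groups = 10,
                            exposures = bpv_exposure_names()) {
  dat <- merge(records, features, by = "patient_id", sort = TRUE)
  exposures <- intersect(exposures, names(dat))
  rows <- list()
  add <- function(r) rows[[length(rows) + 1]] <<- r

  parse_exposure <- function(e) {
    parts <- strsplit(e, "_", fixed = TRUE)[[1]]
    list(metric = parts[1], channel = toupper(parts[2]),
         phase = c(pre = "pre_bypass", bypass = "bypass",
                   post = "post_bypass")[[parts[3]]])
  }

  for (oc in outcomes) {
    ycol <- paste0("outcome_", oc)
    if (!ycol %in% names(dat)) stop("missing outcome column: ", ycol)
    sts_col <- sts_map[[oc]] %||% "sts_mm_score"
    adj_full <- build_adjustment_design(dat, sts_col)

    if ("univariable" %in% models) {
      for (e in exposures) {
        pe <- parse_exposure(e)
        row <- suite_row(oc, "univariable", e, pe$channel, pe$phase, pe$metric)
        add(run_spec(row, {
          ok <- !is.na(dat[[e]]) & !is.na(dat[[ycol]])
          x <- dat[[e]][ok]
          y <- dat[[ycol]][ok]
          fit <- fit_logistic_irls(matrix(x, dimnames = list(NULL, e)), y)
          fill_fit(row, fit, e, score_for_auc = x, y = y, hl_groups)
        }))
      }
    }

    if ("sts_only" %in% models) {
      row <- suite_row(oc, "sts_only", sts_col)
      add(run_spec(row, {
        ok <- !is.na(dat[[ycol]])
        X <- adj_full[ok, c("sts_logit", "sts_missing"), drop = FALSE]
        y <- dat[[ycol]][ok]
        fit <- fit_logistic_irls(X, y)
        fill_fit(row, fit, "sts_logit", score_for_auc = fit$fitted, y = y,
                 hl_groups)
      }))
    }

    if ("sts_adjusted" %in% models) {
      row <- suite_row(oc, "sts_adjusted", sts_col)
      add(run_spec(row, {
        ok <- !is.na(dat[[ycol]])
        X <- adj_full[ok, , drop = FALSE]
        y <- dat[[ycol]][ok]
        fit <- fit_logistic_irls(X, y)
        fill_fit(row, fit, "sts_logit", score_for_auc = fit$fitted, y = y,
                 hl_groups)
      }))
    }

    if ("adjusted" %in% models) {
      for (e in exposures) {
        pe <- parse_exposure(e)
        row <- suite_row(oc, "adjusted", e, pe$channel, pe$phase, pe$metric)
        add(run_spec(row, {
          ok <- !is.na(dat[[e]]) & !is.na(dat[[ycol]])
          X <- cbind(stats::setNames(data.frame(dat[[e]][ok]), e),
                     adj_full[ok, , drop = FALSE])
          y <- dat[[ycol]][ok]
          fit <- fit_logistic_irls(X, y)
          fill_fit(row, fit, e, score_for_auc = fit$fitted, y = y, hl_groups)
        }))
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("bpv_model_suite", class(out))
  out
}

#' @export
print.bpv_model_suite <- function(x, ...) {
  cat(sprintf("<bpv_model_suite> %d model rows\n", nrow(x)))
  cols <- intersect(c("outcome", "model", "variable", "n", "auc", "auc_lo",
                      "auc_hi", "exposure_p", "hl_p", "note"), names(x))
  show <- as.data.frame(x)[, cols, drop = FALSE]
  num <- vapply(show, is.numeric, logical(1))
  show[num] <- lapply(show[num], signif, digits = 3)
  print.data.frame(show)
  invisible(x)
}
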