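# Cohort pipeline: phase segmentation, exclusion funnel, per-patient BPV
# feature rows, outcome-stratified descriptive comparisons.

# split a long samples table into light per-patient column lists (much
# cheaper than split.data.frame on multi-million-row cohorts)
split_samples_by_patient <- function(samples) {
  pid <- samples$patient_id
  n <- length(pid)
  starts <- which(c(TRUE, pid[-1] != pid[-n]))
  block_ids <- pid[starts]
  if (anyDuplicated(block_ids)) {
    # non-contiguous patients (externally sorted data): generic split
    idx <- split(seq_len(n), pid)
  } else {
    ends <- c(starts[-1] - 1L, n)
    idx <- mapply(seq.int, starts, ends, SIMPLIFY = FALSE)
    names(idx) <- block_ids
  }
  lapply(idx, function(i) {
    list(patient_id = samples$patient_id[i[1]],
         channel = samples$channel[i],
         time_s = samples$time_s[i],
         value_mmhg = samples$value_mmhg[i])
  })
}

#' Segment one patient's raw samples into surgical phases
#'
#' Half-open convention: pre-bypass = `time < bypass_start`; bypass =
#' `bypass_start <= time < bypass_end`; post-bypass = `time >= bypass_end`.
#' SBP samples falling inside the bypass interval are dropped (attribute
#' `n_sbp_dropped` counts them).
#'
#' @param samples data frame for one patient with columns `channel`,
#'   `time_s`, `value_mmhg` (a `patient_id` column is used if present).
#' @param record one-row data frame (or list) with `cpb_used`,
#'   `bypass_start_s`, `bypass_end_s` and optionally `patient_id`.
#' @return Named list of [bp_series] (`"MAP.pre_bypass"`, ...), with
#'   attribute `n_sbp_dropped`.
#' @export
segment_phases <- function(samples, record) {
  if (!isTRUE(record$cpb_used)) {
    stop("patient did not undergo cardiopulmonary bypass; no phases to segment")
  }
  bs <- record$bypass_start_s
  be <- record$bypass_end_s
  if (!is.finite(bs) || !is.finite(be) || bs >= be) {
    stop("bypass interval must satisfy bypass_start < bypass_end")
  }
  pid <- record$patient_id %||% (samples$patient_id[1] %||% "unknown")
  t_all <- samples$time_s
  if (!length(t_all) || bs < min(t_all) || be > max(t_all)) {
    cond <- simpleError(
      sprintf("bypass interval [%.0f, %.0f) outside recording span; patient %s flagged inadequate",
              bs, be, pid))
    class(cond) <- c("bpv_inadequate", class(cond))
    stop(cond)
  }
  n_sbp_dropped <- 0L
  out <- list()
  for (ch in bpv_channels) {
    ci <- samples$channel == ch
    tt <- samples$time_s[ci]
    vv <- samples$value_mmhg[ci]
    if (is.unsorted(tt, strictly = FALSE)) {
      o <- order(tt)
      tt <- tt[o]
      vv <- vv[o]
    }
    # 0 = pre-bypass, 1 = bypass, 2 = post-bypass under [start, end)
    code <- findInterval(tt, c(bs, be))
    if (ch == "SBP") {
      n_sbp_dropped <- sum(code == 1L)
      keep <- code != 1L
      tt <- tt[keep]
      vv <- vv[keep]
      code <- code[keep]
    }
    if (any(!is.finite(vv) | vv <= 0)) {
      stop("pressure values must be finite and positive")
    }
    if (anyDuplicated(tt)) stop("sample times must be strictly increasing")
    phases <- if (ch == "SBP") setdiff(bpv_phases, "bypass") else bpv_phases
    for (p in phases) {
      idx <- code == match(p, bpv_phases) - 1L
      out[[paste(ch, p, sep = ".")]] <- new_bp_series(pid, ch, p, tt[idx],
                                                      vv[idx])
    }
  }
  attr(out, "n_sbp_dropped") <- n_sbp_dropped
  out
}

#' Apply the cohort exclusion funnel
#'
#' Sequential first-matching criteria, mirroring a patient-selection flow
#' chart: (1) age at or below the adult cut-off, (2) surgery without
#' cardiopulmonary bypass, (3) inadequate BP data (any of the three MAP
#' phase series shorter than `min_phase_samples`, or a bypass interval
#' outside the recording span). Each excluded patient carries exactly one
#' reason code.
#'
#' @param cohort a `bpv_cohort`, or a list with `records` and `samples`.
#' @param min_phase_samples minimum MAP samples per phase for adequacy
#'   (default 20, i.e. 5 min of 15-s samples).
#' @param min_age adult age cut-off in years (retain age > 18 by default).
#' @return A list of class `bpv_analysis_cohort`: `records` (retained),
#'   `series` (per retained patient, the segmented [bp_series] list), and
#'   `log` (class `bpv_exclusion_log`).
#' @export
apply_exclusions <- function(cohort, min_phase_samples = 20, min_age = 18) {
  records <- cohort$records
  samples <- cohort$samples
  split_samples <- split_samples_by_patient(samples)
  n <- nrow(records)
  reason <- character(n)
  series <- vector("list", n)
  names(series) <- records$patient_id
  for (i in seq_len(n)) {
    rec <- records[i, ]
    s <- split_samples[[rec$patient_id]]
    if (!is.na(rec$age) && rec$age <= min_age) {
      reason[i] <- "under_age"
    } else if (!isTRUE(rec$cpb_used)) {
      reason[i] <- "no_cpb"
    } else {
      seg <- tryCatch(segment_phases(s, rec), error = function(e) e)
      if (inherits(seg, "error")) {
        reason[i] <- "inadequate_bp_data"
      } else {
        map_n <- vapply(bpv_phases, function(p) {
          length(seg[[paste("MAP", p, sep = ".")]]$time_s)
        }, integer(1))
        if (any(map_n < min_phase_samples)) {
          reason[i] <- "inadequate_bp_data"
        } else {
          reason[i] <- "retained"
          series[[i]] <- seg
        }
      }
    }
  }
  retained <- reason == "retained"
  counts <- c(initial = n,
              under_age = sum(reason == "under_age"),
              no_cpb = sum(reason == "no_cpb"),
              inadequate_bp_data = sum(reason == "inadequate_bp_data"),
              retained = sum(retained))
  log <- structure(
    list(counts = counts,
         reasons = data.frame(patient_id = records$patient_id,
                              reason = reason, stringsAsFactors = FALSE)),
    class = "bpv_exclusion_log")
  structure(list(records = records[retained, , drop = FALSE],
                 series = series[retained],
                 log = log),
            class = "bpv_analysis_cohort")
}

#' @export
print.bpv_exclusion_log <- function(x, ...) {
  cat("<bpv_exclusion_log>\n")
  cat(sprintf("  initial:            %d\n", x$counts[["initial"]]))
  cat(sprintf("  under age:          %d\n", x$counts[["under_age"]]))
  cat(sprintf("  no CPB:             %d\n", x$counts[["no_cpb"]]))
  cat(sprintf("  inadequate BP data: %d\n", x$counts[["inadequate_bp_data"]]))
  cat(sprintf("  retained:           %d\n", x$counts[["retained"]]))
  invisible(x)
}

#' @export
print.bpv_analysis_cohort <- function(x, ...) {
  cat(sprintf("<bpv_analysis_cohort> %d retained patients\n", nrow(x$records)))
  print(x$log)
  invisible(x)
}

#' Per-patient BP-variability feature row
#'
#' One row with CV, SD1, SD2 and SD1/SD2 per admissible (channel, phase)
#' cell (the SBP-bypass cell is structurally absent), plus per-cell sample
#' counts. Cells from series shorter than `min_samples` are `NA`; degenerate
#' cells (constant series) carry `cv = sd1 = sd2 = 0` with `NA` ratio.
#'
#' @param phase_series named list of [bp_series] as from [segment_phases()].
#' @param min_samples minimum series length for any descriptor (default 20).
#' @param max_gap lag-1 pairing gap rule in seconds (see [lag1_cloud()]).
#' @return One-row data frame with columns `patient_id`,
#'   `<metric>_<channel>_<phase>` for metric in cv/sd1/sd2/ratio, and
#'   `n_<channel>_<phase>` counts.
#' @export
compute_patient_bpv <- function(phase_series, min_samples = 20, max_gap = 30) {
  core <- patient_bpv_core(phase_series, min_samples, max_gap)
  row <- c(list(patient_id = core$patient_id), as.list(core$values))
  as.data.frame(row, stringsAsFactors = FALSE, check.names = FALSE)
}

# numeric feature vector for one patient (shared by compute_patient_bpv and
# the vectorised cohort path)
patient_bpv_core <- function(phase_series, min_samples, max_gap) {
  nonempty <- which(vapply(phase_series, function(s) length(s$time_s) > 0,
                           logical(1)))
  pid <- if (length(nonempty)) phase_series[[nonempty[1]]]$patient_id
  else NA_character_
  cells <- bpv_cells()
  vals <- numeric(0)
  for (k in seq_len(nrow(cells))) {
    ch <- cells$channel[k]
    ph <- cells$phase[k]
    s <- phase_series[[paste(ch, ph, sep = ".")]]
    n <- if (is.null(s)) 0L else length(s$time_s)
    cvv <- sd1 <- sd2 <- ratio <- NA_real_
    if (n >= min_samples) {
      # same formulas as cv_bp()/poincare_sd(), inlined for the cohort loop
      v <- s$value_mmhg
      m <- mean(v)
      sdv <- stats::sd(v)
      cvv <- if (m > 0) sdv / m else NA_real_
      gap_ok <- diff(s$time_s) <= max_gap
      x <- v[-n][gap_ok]
      y <- v[-1][gap_ok]
      if (length(x) >= 2) {
        sd1 <- stats::sd((x - y) / sqrt(2))
        sd2 <- stats::sd((x + y) / sqrt(2))
        ratio <- if (sd2 > 0) sd1 / sd2 else NA_real_
      }
    }
    cell <- c(cvv, sd1, sd2, ratio, n)
    names(cell) <- vapply(c("cv", "sd1", "sd2", "ratio", "n"),
                          feature_name, "", ch, ph)
    vals <- c(vals, cell)
  }
  list(patient_id = pid, values = vals)
}

#' BPV feature rows for every retained patient
#'
#' @param analysis_cohort a `bpv_analysis_cohort` from [apply_exclusions()].
#' @param min_samples,max_gap passed to [compute_patient_bpv()].
#' @return Data frame, one row per retained patient.
#' @export
compute_cohort_bpv <- function(analysis_cohort, min_samples = 20, max_gap = 30) {
  stopifnot(inherits(analysis_cohort, "bpv_analysis_cohort"))
  cores <- lapply(analysis_cohort$series, patient_bpv_core,
                  min_samples = min_samples, max_gap = max_gap)
  if (!length(cores)) return(NULL)
  mat <- do.call(rbind, lapply(cores, `[[`, "values"))
  out <- data.frame(patient_id = vapply(cores, `[[`, "", "patient_id"),
                    mat, stringsAsFactors = FALSE, check.names = FALSE)
  rownames(out) <- NULL
  out
}

# the 15 modelled exposure columns: {cv, sd1, sd2} x {sbp pre/post, map
# pre/bypass/post}
bpv_exposure_names <- function() {
  cells <- bpv_cells()
  unlist(lapply(c("cv", "sd1", "sd2"), function(m) {
    feature_name(m, cells$channel, cells$phase)
  }), use.names = FALSE)
}

fmt_median_iqr <- function(x) {
  q <- stats::quantile(x, c(0.25, 0.5, 0.75), na.rm = TRUE, names = FALSE,
                       type = 7)
  sprintf("%.3g (%.3g, %.3g)", q[2], q[1], q[3])
}

#' Outcome-stratified descriptive comparison table
#'
#' For each variable: median (IQR) by stratum with a two-sided Mann-Whitney
#' U test for continuous variables (exact when both groups have <= 8
#' observations and no ties, tie-corrected normal approximation otherwise),
#' or n (%) with a chi-square test (Fisher's exact when any expected cell
#' count is below 5) for categorical ones. Shapiro-Wilk normality p-values
#' are reported alongside continuous variables (on a subsample of at most
#' 5000, the test's supported range).
#'
#' @param data data frame of per-patient variables (e.g. records merged with
#'   BPV features).
#' @param outcome name of the 0/1 outcome column to stratify by.
#' @param variables variables to summarise; defaults to every column except
#'   identifiers and outcome columns.
#' @return Data frame of class `bpv_descriptive_table` with one row per
#'   variable (or per categorical level): summaries per stratum, the test
#'   used, its p-value, and the Shapiro-Wilk p.
#' @export
descriptive_comparison <- function(data, outcome, variables = NULL) {
  stopifnot(outcome %in% names(data))
  y <- data[[outcome]]
  if (!all(y %in% c(0, 1, NA))) stop("outcome must be binary 0/1")
  if (is.null(variables)) {
    variables <- setdiff(names(data),
                         c("patient_id", outcome,
                           grep("^outcome_", names(data), value = TRUE)))
  }
  rows <- list()
  for (v in variables) {
    x <- data[[v]]
    ok <- !is.na(x) & !is.na(y)
    x0 <- x[ok & y == 0]
    x1 <- x[ok & y == 1]
    if (!length(x0) || !length(x1)) {
      rows[[length(rows) + 1]] <- data.frame(
        variable = v, type = NA_character_, overall = NA_character_,
        no_event = NA_character_, event = NA_character_, test = "none",
        p_value = NA_real_, shapiro_p = NA_real_, flag = "empty_stratum",
        stringsAsFactors = FALSE)
      next
    }
    if (is.numeric(x) && length(unique(x[ok])) > 5) {
      exact <- min(length(x0), length(x1)) <= 8 &&
        !any(duplicated(c(x0, x1)))
      p <- suppressWarnings(
        stats::wilcox.test(x1, x0, exact = exact, correct = TRUE)$p.value)
      sw <- tryCatch({
        xs <- x[ok]
        if (length(xs) > 5000) xs <- xs[seq(1, length(xs), length.out = 5000)]
        stats::shapiro.test(xs)$p.value
      }, error = function(e) NA_real_)
      rows[[length(rows) + 1]] <- data.frame(
        variable = v, type = "continuous",
        overall = fmt_median_iqr(x[ok]),
        no_event = fmt_median_iqr(x0), event = fmt_median_iqr(x1),
        test = if (exact) "mann_whitney_exact" else "mann_whitney",
        p_value = p, shapiro_p = sw, flag = "",
        stringsAsFactors = FALSE)
    } else {
      tab <- table(factor(x[ok]), factor(y[ok], levels = c(0, 1)))
      expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
      use_fisher <- any(expected < 5)
      p <- tryCatch({
        if (use_fisher) stats::fisher.test(tab)$p.value
        else stats::chisq.test(tab, correct = FALSE)$p.value
      }, error = function(e) NA_real_)
      for (lev in rownames(tab)) {
        n0 <- tab[lev, "0"]; n1 <- tab[lev, "1"]
        rows[[length(rows) + 1]] <- data.frame(
          variable = paste0(v, ": ", lev), type = "categorical",
          overall = sprintf("%d (%.1f%%)", n0 + n1,
                            100 * (n0 + n1) / sum(tab)),
          no_event = sprintf("%d (%.1f%%)", n0, 100 * n0 / sum(tab[, "0"])),
          event = sprintf("%d (%.1f%%)", n1, 100 * n1 / sum(tab[, "1"])),
          test = if (use_fisher) "fisher_exact" else "chi_square",
          p_value = p, shapiro_p = NA_real_, flag = "",
          stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("bpv_descriptive_table", class(out))
  out
}
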