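# End-to-end orchestration: simulate -> segment/exclude -> features ->
# describe -> model, with a flat config file, fixed-precision outputs and a
# reproducibility manifest.

pipeline_config_defaults <- function() {
  list(
    n_patients = 500, seed = 1,
    pre_bypass_minutes = 126.0, bypass_minutes = 79.3,
    post_bypass_minutes = 76.5,
    dropout_rate = 0.02,
    ar_coefficient = NULL, innovation_sd = NULL,
    prop_no_cpb = 0.154, prop_under_age = 0, prop_inadequate = 0.0025,
    min_phase_samples = 20, max_gap_s = 30, hl_groups = 10,
    coupling_outcome = NULL, coupling_term = NULL, coupling_value = NULL,
    plot_patients = 2
  )
}

#' Read and validate a flat pipeline configuration file
#'
#' YAML file of flat `key: value` pairs; unknown keys are rejected before
#' any stage runs. Keys and defaults: see `pipeline_config_defaults` in the
#' package sources and the methods vignette. The optional
#' `coupling_outcome` / `coupling_term` / `coupling_value` triple adds a
#' BPV-feature term (e.g. `cv_map_post`) to one outcome's generating
#' coefficients, for positive-control runs.
#'
#' @param config path to a YAML file, or a named list of overrides.
#' @return Validated config list (defaults filled in).
#' @export
read_pipeline_config <- function(config = list()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (!is.list(config)) stop("config must be a file path or a named list")
  defaults <- pipeline_config_defaults()
  unknown <- setdiff(names(config), names(defaults))
  if (length(unknown)) {
    stop("unknown config keys: ", paste(unknown, collapse = ", "))
  }
  out <- defaults
  out[names(config)] <- config
  if (!is.null(out$coupling_term) &&
      (is.null(out$coupling_outcome) || is.null(out$coupling_value))) {
    stop("coupling_term requires coupling_outcome and coupling_value")
  }
  out
}

config_to_sim <- function(cf, seed = NULL) {
  oc <- default_outcome_coefficients()
  if (!is.null(cf$coupling_term)) {
    if (!cf$coupling_outcome %in% names(oc)) {
      stop("coupling_outcome must be one of: ",
           paste(names(oc), collapse = ", "))
    }
    oc[[cf$coupling_outcome]]$terms[cf$coupling_term] <- cf$coupling_value
  }
  sim_config(
    n_patients = cf$n_patients,
    seed = seed %||% cf$seed,
    phase_duration_medians = c(pre_bypass = cf$pre_bypass_minutes,
                               bypass = cf$bypass_minutes,
                               post_bypass = cf$post_bypass_minutes),
    dropout_rate = cf$dropout_rate,
    ar_coefficient = cf$ar_coefficient,
    innovation_sd = cf$innovation_sd,
    prop_no_cpb = cf$prop_no_cpb,
    prop_under_age = cf$prop_under_age,
    prop_inadequate = cf$prop_inadequate,
    outcome_coefficients = oc
  )
}

write_table <- function(df, path) {
  utils::write.csv(round_numeric(as.data.frame(df)), path, row.names = FALSE)
  path
}

#' Run the whole analysis pipeline end to end
#'
#' Simulates a cohort from the configuration, applies the exclusion funnel,
#' computes per-patient BPV features, builds outcome-stratified descriptive
#' tables, runs the model suite, renders a markdown summary with
#' Poincare-plot figures for example patients, and writes a reproducibility
#' manifest (config hash, seed, stage timings, output checksums, package
#' version) last. Two runs with the same config produce byte-identical CSV
#' and markdown outputs.
#'
#' @param config path to a YAML config file or a named list (see
#'   [read_pipeline_config()]).
#' @param out_dir output directory (created if needed).
#' @param seed optional integer overriding the config seed.
#' @return Invisibly, a list with the in-memory stage results and the
#'   manifest.
#' @export
run_pipeline <- function(config = list(), out_dir, seed = NULL) {
  cf <- read_pipeline_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  timings <- list()
  clock <- function(stage, expr) {
    t0 <- Sys.time()
    val <- expr
    timings[[stage]] <<- round(as.numeric(difftime(Sys.time(), t0,
                                                   units = "secs")), 3)
    val
  }
  files <- character(0)

  cohort <- clock("simulate", generate_cohort(config_to_sim(cf, seed)))
  files <- c(files, write_cohort_csv(cohort, out_dir))

  analysis <- clock("exclude", apply_exclusions(
    cohort, min_phase_samples = cf$min_phase_samples))
  files <- c(files,
             write_table(analysis$log$reasons,
                         file.path(out_dir, "exclusion_log.csv")),
             write_table(analysis$records,
                         file.path(out_dir, "analysis_records.csv")))

  features <- clock("features", compute_cohort_bpv(
    analysis, min_samples = cf$min_phase_samples, max_gap = cf$max_gap_s))
  files <- c(files, write_table(features,
                                file.path(out_dir, "bpv_features.csv")))

  dat <- merge(analysis$records, features, by = "patient_id", sort = TRUE)
  outcomes <- sub("^outcome_", "",
                  grep("^outcome_", names(analysis$records), value = TRUE))
  descr <- clock("describe", {
    lapply(stats::setNames(outcomes, outcomes), function(oc) {
      descriptive_comparison(dat, paste0("outcome_", oc),
                             variables = c("age", "sex", "surgery_category",
                                           "sts_mm_score", "sts_renal_score",
                                           "vasopressor_dose",
                                           bpv_exposure_names()))
    })
  })
  for (oc in outcomes) {
    files <- c(files, write_table(descr[[oc]],
                                  file.path(out_dir,
                                            sprintf("descriptive_%s.csv", oc))))
  }

  suite <- clock("model", run_model_suite(features, analysis$records,
                                          outcomes = outcomes,
                                          hl_groups = cf$hl_groups))
  files <- c(files, write_table(suite, file.path(out_dir, "model_suite.csv")))

  plots <- clock("plots", {
    ids <- utils::head(analysis$records$patient_id, cf$plot_patients)
    ok <- character(0)
    for (pid in ids) {
      f <- file.path(out_dir, sprintf("poincare_%s.png", pid))
      res <- tryCatch({
        grDevices::png(f, width = 600, height = 600)
        on.exit(grDevices::dev.off(), add = TRUE)
        plot_poincare(analysis$series[[pid]]$MAP.pre_bypass,
                      max_gap = cf$max_gap_s,
                      main = sprintf("Poincaré plot, %s, MAP pre-bypass",
                                     pid))
        ok <- c(ok, f)
        f
      }, error = function(e) NULL)
    }
    ok
  })

  report <- file.path(out_dir, "report.md")
  writeLines(render_report_md(cohort, analysis, descr, suite, cf), report)
  files <- c(files, report)

  manifest <- list(
    package = "bpvpoincare",
    package_version = as.character(utils::packageVersion("bpvpoincare")),
    seed = seed %||% cf$seed,
    config = cf[!vapply(cf, is.null, logical(1))],
    config_hash = hash_seed(paste(deparse(cf), collapse = "")),
    stage_seconds = timings,
    files = stats::setNames(lapply(files, file_content_hash),
                            basename(files))
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(list(cohort = cohort, analysis = analysis, features = features,
                 descriptives = descr, suite = suite, manifest = manifest))
}

md_table <- function(df, digits = 3) {
  df <- as.data.frame(df)
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(x) signif(x, digits))
  cells <- vapply(df, function(col) format(col, trim = TRUE),
                  FUN.VALUE = character(nrow(df)))
  cells <- matrix(cells, nrow = nrow(df))
  header <- paste0("| ", paste(names(df), collapse = " | "), " |")
  sep <- paste0("|", paste(rep("---", ncol(df)), collapse = "|"), "|")
  body <- apply(cells, 1, function(r) paste0("| ", paste(r, collapse = " | "), " |"))
  c(header, sep, body)
}

render_report_md <- function(cohort, analysis, descr, suite, cf) {
  out <- c("# Blood pressure variability pipeline report", "",
           sprintf("Synthetic cohort of %d patients (seed %d).",
                   nrow(cohort$records), cohort$cfg$seed), "",
           "## Exclusion funnel", "")
  cts <- analysis$log$counts
  out <- c(out, sprintf("- initial: %d", cts[["initial"]]),
           sprintf("- under age: %d", cts[["under_age"]]),
           sprintf("- no CPB: %d", cts[["no_cpb"]]),
           sprintf("- inadequate BP data: %d", cts[["inadequate_bp_data"]]),
           sprintf("- retained: %d", cts[["retained"]]), "")
  for (oc in names(descr)) {
    col <- paste0("outcome_", oc)
    out <- c(out, sprintf("## Outcome: %s", oc), "",
             sprintf("%d events / %d patients (%.2f%%)",
                     sum(analysis$records[[col]]), nrow(analysis$records),
                     100 * mean(analysis$records[[col]])), "",
             "### Descriptive comparison (first rows)", "",
             md_table(utils::head(descr[[oc]][, c("variable", "no_event",
                                                  "event", "test", "p_value")],
                                  12)), "")
  }
  out <- c(out, "## Model suite", "",
           md_table(suite[, c("outcome", "model", "variable", "n", "auc",
                              "auc_lo", "auc_hi", "exposure_p", "hl_p")]),
           "")
  out
}
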