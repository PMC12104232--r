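#' Default pipeline configuration
#'
#' Structure-level dosimetric configuration (which structures are targets
#' with which prescription, which are serial/parallel OARs and which summary
#' feeds their comparisons), radiobiological parameters, and convention
#' switches.
#'
#' @param prescription_gy prescription for the primary target PTV (Gy).
#' @param params radiobiological parameters, see [radiobio_params()].
#' @param gamma_mode NTCP fractionation convention, see [ntcp()].
#' @param pooling correlation pooling mode, see [correlation_matrix()].
#' @return named list used by [run_pipeline()].
#' @export
pipeline_config <- function(prescription_gy = 70, params = radiobio_params(),
                            gamma_mode = "per_fraction",
                            pooling = "pooled") {
  list(
    structures = list(
      PTVnx = list(class = "target", prescription_gy = prescription_gy),
      SpinalCord = list(class = "serial", summary = "dmax"),
      Parotid_L = list(class = "parallel", summary = "dmean"),
      Parotid_R = list(class = "parallel", summary = "dmean"),
      OpticNerve_L = list(class = "serial", summary = "dmax"),
      OpticNerve_R = list(class = "serial", summary = "dmax")),
    params = params, gamma_mode = gamma_mode, pooling = pooling)
}

# The gold-standard evaluation set: standard OARs plus the standard PTV.
standard_eval_set <- function(patient) {
  structure_set(c(list(patient$ptv_standard), patient$standard$masks),
                "standard")
}

#' Run the full variability -> dosimetry -> prognosis analysis on a cohort
#'
#' Reproduces the analysis sequence on a (synthetic or loaded) cohort:
#' geometric inter-observer metrics per structure, dose metrics of every
#' observer plan evaluated on the gold-standard structures, radiobiological
#' endpoints and their deltas versus the standard plan, paired
#' observer-vs-standard tests, and the Spearman correlation / predictor
#' selection between geometric metrics and coverage/control deltas.
#'
#' @param cohort a `cohort` from [generate_cohort()].
#' @param config a [pipeline_config()].
#' @param x_metrics geometric metric specs (`"label:metric"`) correlated
#'   against the deltas; default volume difference, Dice and HD95 of the
#'   primary target.
#' @return list of data.frames: `geometry`, `dose`, `radbio` (all
#'   metric-record tables), `paired_tests`, `correlations`, `predictors`,
#'   plus the `config` echo.
#' @export
run_pipeline <- function(cohort, config = pipeline_config(),
                         x_metrics = c("GTVnx:dV_cc", "GTVnx:DSC",
                                       "GTVnx:HD95_mm")) {
  parts <- lapply(cohort$patients, analyze_patient, config = config)
  finalize_results(parts, cohort$manifest$ptv_label, config, x_metrics,
                   obs_ids = names(cohort$patients[[1]]$sets))
}

#' Generate and analyse a synthetic cohort patient by patient
#'
#' Equivalent to `run_pipeline(generate_cohort(...))` — same stream seeds,
#' same tables — but each patient's volumetric data is discarded as soon as
#' its metric rows are extracted, so cohort size is not limited by memory.
#'
#' @inheritParams generate_cohort
#' @inheritParams run_pipeline
#' @param target_label,margin_mm see [generate_cohort()].
#' @return the same result list as [run_pipeline()].
#' @export
run_study <- function(n_patients, observers, dose_mod = dose_model(),
                      seed = 1L, grid = default_grid(),
                      target_label = "GTVnx", margin_mm = 3,
                      config = pipeline_config(),
                      x_metrics = c("GTVnx:dV_cc", "GTVnx:DSC",
                                    "GTVnx:HD95_mm")) {
  parts <- vector("list", n_patients)
  obs_ids <- vapply(observers, function(o) o$observer_id, character(1))
  for (p in seq_len(n_patients)) {
    pt <- build_patient(p, seed, observers, dose_mod, grid, target_label,
                        margin_mm)
    parts[[p]] <- analyze_patient(pt, config)
    rm(pt)
  }
  finalize_results(parts, sub("^GTV", "PTV", target_label), config,
                   x_metrics, obs_ids = obs_ids)
}

# All metric rows for one patient: geometry, dose-on-standard, radiobiology.
analyze_patient <- function(pt, config) {
  pid <- pt$patient_id
  eval_set <- standard_eval_set(pt)
  geometry <- list(); dose_rows <- list(); radbio <- list()
  # geometric IOV per structure
  for (lb in names(pt$standard$masks)) {
    masks <- lapply(pt$sets, function(s) s$masks[[lb]])
    geometry[[length(geometry) + 1L]] <-
      group_report(masks, pt$standard$masks[[lb]],
                   observer_ids = names(pt$sets), patient_id = pid)
  }
  # dose metrics on gold-standard structures (standard plan included as its
  # own row set, so deltas and paired tests can be formed)
  std_rows <- map_plan_to_standard(pt$dose_standard, eval_set,
                                   config$structures, "standard", pid)
  dose_rows[[length(dose_rows) + 1L]] <- std_rows
  std_end <- plan_endpoints(pt$dose_standard, eval_set, config$params,
                            config$gamma_mode)
  radbio[[length(radbio) + 1L]] <- data.frame(
    patient_id = pid, observer_id = "standard", std_end,
    stringsAsFactors = FALSE)
  for (oid in names(pt$sets)) {
    orows <- map_plan_to_standard(pt$doses[[oid]], eval_set,
                                  config$structures, oid, pid)
    deltas <- delta_rows(orows, std_rows, config$structures, pid, oid)
    dose_rows[[length(dose_rows) + 1L]] <- rbind(orows, deltas)
    oend <- plan_endpoints(pt$doses[[oid]], eval_set, config$params,
                           config$gamma_mode)
    radbio[[length(radbio) + 1L]] <- data.frame(
      patient_id = pid, observer_id = oid, oend, stringsAsFactors = FALSE)
    radbio[[length(radbio) + 1L]] <- cbind(
      endpoint_deltas(oend, std_end, oid, pid),
      model = NA, summary_dose_gy = NA, eud_gy = NA, probability = NA)[
        , c("patient_id", "observer_id", "structure_label", "model",
            "summary_dose_gy", "eud_gy", "probability", "metric_name",
            "value", "units")]
  }
  list(geometry = geometry, dose_rows = dose_rows, radbio = radbio)
}

finalize_results <- function(parts, ptv_label, config, x_metrics, obs_ids) {
  geometry <- do.call(rbind, unlist(lapply(parts, `[[`, "geometry"),
                                    recursive = FALSE))
  dose_rows <- unlist(lapply(parts, `[[`, "dose_rows"), recursive = FALSE)
  radbio <- unlist(lapply(parts, `[[`, "radbio"), recursive = FALSE)
  dose_tab <- do.call(rbind, dose_rows)
  radbio_tab <- do.call(rbind, lapply(radbio, function(d) {
    for (col in c("metric_name", "value", "units"))
      if (is.null(d[[col]])) d[[col]] <- NA
    d[, c("patient_id", "observer_id", "structure_label", "model",
          "summary_dose_gy", "eud_gy", "probability", "metric_name",
          "value", "units")]
  }))
  records <- rbind(
    geometry,
    dose_tab[, c("patient_id", "observer_id", "structure_label",
                 "metric_name", "value", "units")],
    radbio_tab[!is.na(radbio_tab$metric_name),
               c("patient_id", "observer_id", "structure_label",
                 "metric_name", "value", "units")])
  y_metrics <- c(paste0(ptv_label, ":dPDC_pct"), paste0(ptv_label, ":dTCP"))
  correlations <- correlation_matrix(records, x_metrics, y_metrics,
                                     pooling = config$pooling)
  predictors <- select_predictors(correlations)
  paired <- paired_test_table(records, obs_ids)
  list(geometry = geometry, dose = dose_tab, radbio = radbio_tab,
       records = records, paired_tests = paired,
       correlations = correlations, predictors = predictors,
       config = config)
}

# Observer-vs-standard delta rows for the dose table: dPDC for targets,
# dDdiff on the configured summary metric for OARs.
delta_rows <- function(obs_rows, std_rows, structures, patient_id,
                       observer_id) {
  out <- list()
  for (lb in unique(obs_rows$structure_label)) {
    cfg <- structures[[lb]]
    o <- obs_rows[obs_rows$structure_label == lb, ]
    s <- std_rows[std_rows$structure_label == lb, ]
    if (identical(cfg$class, "target")) {
      out[[length(out) + 1L]] <- metric_record(
        patient_id, observer_id, lb, "dPDC_pct",
        o$value[o$metric_name == "PDC_pct"] -
          s$value[s$metric_name == "PDC_pct"])
    } else {
      met <- oar_summary_metric(cfg)
      out[[length(out) + 1L]] <- metric_record(
        patient_id, observer_id, lb, "dDdiff_pct",
        delta_d_diff(o$value[o$metric_name == met],
                     s$value[s$metric_name == met]))
    }
  }
  do.call(rbind, out)
}

# Paired observer-vs-standard comparisons per (structure, metric) across
# patients, for metrics that exist for both the observers and the standard.
paired_test_table <- function(records, obs_ids) {
  paired_metrics <- c("PDC_pct", "Dmax_gy", "Dmean_gy", "D1cc_gy")
  out <- list()
  for (lb in unique(records$structure_label)) {
    for (met in paired_metrics) {
      std <- records[records$structure_label == lb &
                       records$metric_name == met &
                       records$observer_id == "standard", ]
      if (nrow(std) < 3) next
      std <- std[order(std$patient_id), ]
      for (oid in obs_ids) {
        ob <- records[records$structure_label == lb &
                        records$metric_name == met &
                        records$observer_id == oid, ]
        ob <- ob[order(ob$patient_id), ]
        if (nrow(ob) != nrow(std)) next
        pc <- paired_compare(ob$value, std$value)
        out[[length(out) + 1L]] <- data.frame(
          structure_label = lb, metric_name = met, observer_id = oid,
          test = pc$test, statistic = pc$statistic, p = pc$p_value,
          n = pc$n, stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, out)
}

#' Summarise pipeline outputs as mean +/- SD tables
#'
#' Per (structure, metric, observer): the arithmetic mean and sample SD
#' across patients, with the conventional significance markers (`*` for
#' p < 0.05, `**` for p < 0.01 from the paired tests) attached where a
#' paired test exists — markers are presentation only, full p-values stay
#' in `paired_tests`.
#'
#' @param results output of [run_pipeline()].
#' @return data.frame: `structure_label`, `metric_name`, `observer_id`,
#'   `mean`, `sd`, `n`, `signif`.
#' @export
cohort_report <- function(results) {
  rec <- results$records
  key <- interaction(rec$structure_label, rec$metric_name, rec$observer_id,
                     drop = TRUE)
  parts <- split(rec, key)
  out <- do.call(rbind, lapply(parts, function(d) {
    data.frame(structure_label = d$structure_label[1],
               metric_name = d$metric_name[1],
               observer_id = d$observer_id[1],
               mean = mean(d$value), sd = sd(d$value), n = nrow(d),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  pt <- results$paired_tests
  out$signif <- ""
  if (!is.null(pt) && nrow(pt)) {
    idx <- match(paste(out$structure_label, out$metric_name, out$observer_id),
                 paste(pt$structure_label, pt$metric_name, pt$observer_id))
    pv <- pt$p[idx]
    out$signif[!is.na(pv) & pv < 0.05] <- "*"
    out$signif[!is.na(pv) & pv < 0.01] <- "**"
  }
  out[order(out$structure_label, out$metric_name, out$observer_id), ]
}

#' Write pipeline outputs as CSV files plus a JSON manifest
#'
#' @param results output of [run_pipeline()].
#' @param cohort the analysed cohort (its manifest is embedded).
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_results <- function(results, cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write.csv(results$geometry, file.path(dir, "metrics.csv"),
            row.names = FALSE)
  write.csv(results$dose, file.path(dir, "dose_metrics.csv"),
            row.names = FALSE)
  write.csv(results$radbio, file.path(dir, "radbio.csv"), row.names = FALSE)
  write.csv(results$correlations, file.path(dir, "corr.csv"),
            row.names = FALSE)
  write.csv(results$predictors, file.path(dir, "predictors.csv"),
            row.names = FALSE)
  write.csv(cohort_report(results), file.path(dir, "report.csv"),
            row.names = FALSE)
  jsonlite::write_json(
    list(cohort = cohort$manifest,
         pooling = results$config$pooling,
         gamma_mode = results$config$gamma_mode),
    file.path(dir, "manifest.json"), auto_unbox = TRUE, digits = NA,
    pretty = TRUE)
  invisible(dir)
}
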