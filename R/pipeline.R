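# One-command orchestration: cohort (or sweep bundles) -> per-cell features ->
# gain statistics -> population report, with QC logging and deterministic
# outputs under a required seed.

#' Full feature extraction for one trace-level cell record
#'
#' Passive features from the hyperpolarizing steps, capacitance from the
#' voltage-clamp step, excitability from the square family, gain statistics
#' from the sinusoid families, and session QC. A protocol kind missing for a
#' requested feature yields `NA` for that feature plus a note; it is not a
#' hard error.
#'
#' @param record a [cell_record()].
#' @param drift_max_mv,semilunar_rin QC thresholds, see [qc_cell()].
#' @return one-row data.frame (a cell feature row) with attribute `notes`.
#' @export
compute_cell_features <- function(record, drift_max_mv = RMP_DRIFT_MAX_MV,
                                  semilunar_rin = SEMILUNAR_RIN_MOHM) {
  notes <- character(0)
  grab <- function(expr, what) {
    tryCatch(expr, error = function(e) {
      notes <<- c(notes, sprintf("%s skipped: %s", what, conditionMessage(e)))
      NA_real_
    })
  }
  steps <- sweeps_of_kind(record, "hyperpol_step")
  r_in <- grab(as.numeric(measure_input_resistance(steps)), "input resistance")
  tau_m <- grab(as.numeric(measure_time_constant(steps)), "time constant")
  rmp <- grab(measure_rmp(steps), "resting potential")
  vc <- sweeps_of_kind(record, "vc_step")
  c_m <- grab(measure_capacitance(vc[[1]]), "capacitance")
  exc <- tryCatch(measure_excitability(sweeps_of_kind(record, "square_family")),
                  error = function(e) {
                    notes <<- c(notes, sprintf("excitability skipped: %s",
                                               conditionMessage(e)))
                    list(ap_threshold = NA_real_, peak_dvdt = NA_real_,
                         max_rate = NA_real_)
                  })
  io <- tryCatch(cell_io_features(record),
                 error = function(e) {
                   notes <<- c(notes, sprintf("io features skipped: %s",
                                              conditionMessage(e)))
                   list(asl = NA_real_, var = NA_real_,
                        offset_norm = NA_real_, incomplete = TRUE)
                 })
  qc <- tryCatch(qc_cell(record, list(r_in = r_in), drift_max_mv, semilunar_rin),
                 error = function(e) {
                   notes <<- c(notes, sprintf("qc skipped: %s",
                                              conditionMessage(e)))
                   list(rmp_drift = NA_real_, passed = FALSE,
                        excluded_as_semilunar = FALSE,
                        reasons = "qc not computable")
                 })
  notes <- c(notes, qc$reasons)
  row <- data.frame(
    cell_id = record$cell_id, age_days = record$age_days,
    r_in = r_in, tau_m = tau_m, c_m = c_m, rmp = rmp,
    ap_threshold = exc$ap_threshold, peak_dvdt = exc$peak_dvdt,
    max_rate = exc$max_rate,
    asl = io$asl, var = io$var, offset_norm = io$offset_norm,
    incomplete = isTRUE(io$incomplete), qc_passed = qc$passed,
    rmp_drift = qc$rmp_drift,
    excluded_as_semilunar = qc$excluded_as_semilunar,
    stringsAsFactors = FALSE)
  attr(row, "notes") <- notes
  row
}

#' Assemble and validate a pipeline configuration
#'
#' @param config named list or path to a JSON file. Recognized fields:
#'   `seed` (required), `cohort` (list of [cohort_spec()] arguments for a
#'   synthetic run), `input_bundles` (paths of csv_json bundles for a
#'   trace-level run), `stat` (clustering statistic: `asl`, `var` or
#'   `offset_norm`), `out_dir`, `qc` (`drift_max_mv`, `semilunar_rin`),
#'   `n_boot`.
#' @return normalized `gc_pipeline_config` list.
#' @export
pipeline_config <- function(config) {
  if (is.character(config) && length(config) == 1L)
    config <- jsonlite::fromJSON(config, simplifyVector = TRUE)
  if (!is.list(config)) stopf("config must be a list or a JSON path")
  if (is.null(config$seed)) stopf("config validation: seed is required")
  config$seed <- as.integer(config$seed)
  config$stat <- match.arg(config$stat %||% "asl",
                           c("asl", "var", "offset_norm"))
  if (is.null(config$cohort) && is.null(config$input_bundles))
    stopf("config needs either a synthetic cohort spec or input bundles")
  config$qc <- utils::modifyList(list(drift_max_mv = RMP_DRIFT_MAX_MV,
                                      semilunar_rin = SEMILUNAR_RIN_MOHM),
                                 config$qc %||% list())
  config$n_boot <- config$n_boot %||% 120
  config$out_dir <- config$out_dir %||% stop("config validation: out_dir is required")
  structure(config, class = "gc_pipeline_config")
}

format_num <- function(x) {
  # fixed 12-significant-digit formatting keeps report bytes reproducible
  ifelse(is.na(x), "NA", formatC(x, digits = 12, format = "g"))
}

write_table <- function(df, path) {
  num <- vapply(df, is.numeric, logical(1)) & !vapply(df, is.integer, logical(1))
  df[num] <- lapply(df[num], format_num)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
}

#' Run the full analysis pipeline
#'
#' Synthetic route: generate the cohort, extract curve-level features.
#' Bundle route: read each bundle and run [compute_cell_features()]. Then:
#' QC filtering with an exclusion log, Gaussian comparison, K-means S/L
#' labeling, Ward clustering on the seven intrinsic parameters, age-binned
#' group probabilities, mean-variance parabola and per-group correlations.
#' Writes `features.csv`, `per_frequency.csv` (synthetic route),
#' `age_probabilities.csv`, `report.json` and `exclusions.log` under
#' `out_dir`. Outputs are byte-identical across reruns with the same
#' config+seed.
#'
#' @param config see [pipeline_config()].
#' @return invisibly, a list with the feature table, labels, and all fitted
#'   summaries.
#' @export
run_pipeline <- function(config) {
  cfg <- if (inherits(config, "gc_pipeline_config")) config
         else pipeline_config(config)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(cfg$seed)
  notes <- list()
  per_freq <- NULL
  if (!is.null(cfg$cohort)) {
    ch <- cfg$cohort
    ch$seed <- NULL  # the pipeline seed governs everything
    spec <- do.call(cohort_spec, c(ch, list(seed = cfg$seed)))
    cohort <- generate_cohort(spec)
    rows <- cohort_features(cohort)
    per_freq <- do.call(rbind, lapply(seq_along(cohort$cells), function(i) {
      pf <- pool_features(cohort$cells[[i]]$curves)$per_frequency
      cbind(cell_id = rows$cell_id[i], pf)
    }))
  } else {
    cohort <- NULL
    recs <- lapply(cfg$input_bundles, read_cell_bundle)
    feats <- lapply(recs, compute_cell_features,
                    drift_max_mv = cfg$qc$drift_max_mv,
                    semilunar_rin = cfg$qc$semilunar_rin)
    notes <- lapply(feats, attr, "notes")
    names(notes) <- vapply(recs, `[[`, character(1), "cell_id")
    rows <- do.call(rbind, feats)
  }
  # QC + completeness filter, logged once per excluded cell
  excl <- character(0)
  usable <- rows$qc_passed & !rows$incomplete &
    !is.na(rows[[cfg$stat]]) & !is.na(rows$r_in)
  for (i in which(!usable)) {
    why <- c(if (!rows$qc_passed[i]) "failed QC",
             if (rows$incomplete[i]) "incomplete io statistics",
             if (is.na(rows[[cfg$stat]][i])) sprintf("missing %s", cfg$stat))
    extra <- notes[[rows$cell_id[i]]]
    excl <- c(excl, sprintf("%s: %s", rows$cell_id[i],
                            paste(unique(c(why, extra)), collapse = "; ")))
  }
  ana <- rows[usable, , drop = FALSE]
  if (nrow(ana) < 20)
    stopf("only %d usable cells after QC; population inference needs >= 20",
          nrow(ana))
  values <- ana[[cfg$stat]]
  gauss <- compare_gaussians(values, n_boot = cfg$n_boot)
  km <- kmeans_two(values, seed = cfg$seed)
  labels <- km$labels
  ward <- ward_cluster_seven(ana, labels)
  agep <- age_group_probabilities(ana, labels)
  parab <- tryCatch(mean_variance_parabola(ana, cfg$stat),
                    error = function(e) NULL)
  corrs <- group_correlations(ana, labels)
  ana$label <- as.character(labels)
  # ---- reports
  write_table(ana, file.path(cfg$out_dir, "features.csv"))
  if (!is.null(per_freq))
    write_table(per_freq, file.path(cfg$out_dir, "per_frequency.csv"))
  write_table(agep, file.path(cfg$out_dir, "age_probabilities.csv"))
  writeLines(if (length(excl)) excl else "no exclusions",
             file.path(cfg$out_dir, "exclusions.log"))
  report <- list(
    config = list(seed = cfg$seed, stat = cfg$stat, n_cells = nrow(rows),
                  n_analyzed = nrow(ana), qc = cfg$qc),
    gaussian_comparison = list(
      one = gauss$one_comp[c("mu", "sigma", "sse")],
      two = gauss$two_comp[c("mu", "sigma", "sse")],
      f_stat = gauss$f_stat, f_p = gauss$f_p, lrt_stat = gauss$lrt_stat,
      p_value = gauss$p_value, preferred = gauss$preferred),
    kmeans = list(centers = as.list(km$centers),
                  mean_dist = as.list(km$mean_dist),
                  n = as.list(table(labels)),
                  separation_p = km$separation_p),
    ward_seven = list(agreement = ward$agreement),
    parabola = if (!is.null(parab))
      list(coefficients = as.list(parab$coefficients),
           adjusted_r2 = parab$adjusted_r2, p_value = parab$p_value),
    correlations = corrs,
    exclusions = excl)
  jsonlite::write_json(report, file.path(cfg$out_dir, "report.json"),
                       auto_unbox = TRUE, digits = 10, pretty = TRUE,
                       null = "null", na = "null")
  invisible(list(features = ana, all_rows = rows, labels = labels,
                 gaussian = gauss, kmeans = km, ward = ward,
                 age_probabilities = agep, parabola = parab,
                 correlations = corrs, exclusions = excl, cohort = cohort))
}
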