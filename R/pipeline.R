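variant_kinds <- function(variant) {
  switch(variant,
         GM = "GRAYSCALE",
         DM = "DEA",
         DSM = c("DEA", "SSD"),
         DSNM = c("DEA", "SSD", "NRD"),
         stop("unknown model variant: ", variant, call. = FALSE))
}

#' Compute the feature maps of one patient
#'
#' Crops the frame to the ROI bounding box and runs the requested
#' estimators on the gated region. `GRAYSCALE` reconstructs the B-mode
#' image from the same RF frame and crops its ROI — the comparison variant
#' for display-processed images.
#'
#' @param frame An [rf_frame()].
#' @param roi An [roi_mask()] congruent with the frame.
#' @param kinds Subset of `c("DEA", "SSD", "NRD", "GRAYSCALE")`.
#' @param Ng Unused here; accepted for convenience.
#' @param smooth_len,dynamic_range_db B-mode reconstruction parameters.
#' @return Named list of [feature_map()]s.
#' @export
compute_patient_maps <- function(frame, roi, kinds = c("DEA", "SSD", "NRD"),
                                 smooth_len = 5L, dynamic_range_db = 60) {
  cr <- crop_roi(frame$samples, roi)
  maps <- list()
  if ("DEA" %in% kinds) {
    maps$DEA <- compute_dea_map(cr$values, cr$mask, c = frame$c, fs = frame$fs)
  }
  if ("SSD" %in% kinds) maps$SSD <- compute_ssd_map(cr$values, cr$mask)
  if ("NRD" %in% kinds) maps$NRD <- compute_nrd_map(cr$values, cr$mask)
  if ("GRAYSCALE" %in% kinds) {
    bm <- reconstruct_bmode(frame, smooth_len = smooth_len,
                            dynamic_range_db = dynamic_range_db)
    px <- if (bm$converted) bm$pixels else bm$pixels  # linear frames keep ROI coordinates
    crb <- crop_roi(px, roi)
    maps$GRAYSCALE <- grayscale_map(crb$values, crb$mask)
  }
  maps
}

#' Build a cohort feature table
#'
#' Computes the requested feature maps for every patient and extracts the
#' per-map 345-feature radiomics vectors, returning the wide patients x
#' features table used by [rank_by_src()] and the classifiers.
#'
#' @param cohort A [simulate_cohort()] / [read_cohort()] tibble.
#' @param kinds Map kinds to include (order fixed internally).
#' @param Ng Gray levels for quantization.
#' @param wavelet Wavelet family.
#' @param ... Passed to [compute_patient_maps()].
#' @return Tibble: `patient_id`, `label`, then `345 * length(kinds)`
#'   feature columns.
#' @export
cohort_feature_table <- function(cohort, kinds = c("DEA", "SSD", "NRD"),
                                 Ng = 64L, wavelet = "haar", ...) {
  rows <- purrr::map(seq_len(nrow(cohort)), function(i) {
    maps <- compute_patient_maps(cohort$frame[[i]], cohort$roi[[i]], kinds = kinds, ...)
    fv <- extract_patient_features(maps, Ng = Ng, wavelet = wavelet)
    tibble::tibble(patient_id = cohort$patient_id[i], label = cohort$label[i],
                   name = fv$name, value = fv$value)
  })
  dplyr::bind_rows(rows) |>
    tidyr::pivot_wider(id_cols = c("patient_id", "label"),
                       names_from = "name", values_from = "value")
}

default_config <- function() {
  list(
    data = list(source = "synthetic", n_per_class = 20L),
    variants = c("GM", "DM", "DSM", "DSNM"),
    ng = 64L, wavelet = "haar",
    omp = list(tol = 1e-6),
    svm = list(C = 0.8, gamma = 1),
    k_max = 15L,
    n_boot = 2000L,
    bmode = list(smooth_len = 5L, dynamic_range_db = 60),
    seed = 1L
  )
}

#' Run the full analysis pipeline
#'
#' Simulate (or load) a two-class RF cohort, compute the feature maps of
#' each model variant, extract radiomics features, rank them by sparse
#' representation coefficients, sweep the top-k SVM classifier under
#' LOOCV, and report per-variant performance. Variants: `GM` (grayscale
#' B-mode), `DM` (DEA), `DSM` (DEA + SSD), `DSNM` (DEA + SSD + NRD).
#'
#' @param config Named list (missing entries fall back to defaults shown
#'   in the vignette) or path to a JSON file with the same structure.
#' @param out_dir Optional directory; when given, feature tables,
#'   rankings, per-variant reports, curves and `summary.csv` are written
#'   there, each stamped with the config hash.
#' @return Object of class `pipeline_run`: list with `summary` (one row
#'   per variant), `reports`, `sweeps`, `rankings`, `tables`,
#'   `config`, `config_hash`.
#' @export
run_pipeline <- function(config = list(), out_dir = NULL) {
  if (is.character(config)) config <- jsonlite::read_json(config, simplifyVector = TRUE)
  cfg <- utils::modifyList(default_config(), config)
  cfg$variants <- match.arg(cfg$variants, c("GM", "DM", "DSM", "DSNM"),
                            several.ok = TRUE)
  config_hash <- rlang::hash(cfg)
  t0 <- Sys.time()
  logs <- list()
  log_stage <- function(stage, msg) {
    logs[[length(logs) + 1L]] <<- list(
      stage = stage, message = msg,
      elapsed_s = round(as.numeric(difftime(Sys.time(), t0, units = "secs")), 2))
    message(sprintf("[%s] %s", stage, msg))
  }
  set.seed(cfg$seed)
  cohort <- if (identical(cfg$data$source, "synthetic")) {
    args <- cfg$data
    args$source <- NULL
    args$base_seed <- cfg$seed
    do.call(cohort_spec, args) |> simulate_cohort()
  } else {
    read_cohort(cfg$data$manifest)
  }
  all_kinds <- unique(unlist(lapply(cfg$variants, variant_kinds)))
  log_stage("maps", sprintf("computing %s for %d patients",
                            paste(all_kinds, collapse = "/"), nrow(cohort)))
  map_sets <- purrr::map(seq_len(nrow(cohort)), function(i) {
    compute_patient_maps(cohort$frame[[i]], cohort$roi[[i]], kinds = all_kinds,
                         smooth_len = cfg$bmode$smooth_len,
                         dynamic_range_db = cfg$bmode$dynamic_range_db)
  })
  log_stage("features", "extracting radiomics vectors")
  feats_by_kind <- purrr::map(stats::setNames(all_kinds, all_kinds), function(kd) {
    rows <- purrr::map(seq_len(nrow(cohort)), function(i) {
      fv <- extract_map_features(map_sets[[i]][[kd]], Ng = cfg$ng, wavelet = cfg$wavelet)
      tibble::tibble(patient_id = cohort$patient_id[i], label = cohort$label[i],
                     name = fv$name, value = fv$value)
    })
    dplyr::bind_rows(rows)
  })
  results <- purrr::map(stats::setNames(cfg$variants, cfg$variants), function(v) {
    kinds <- variant_kinds(v)
    tab <- dplyr::bind_rows(feats_by_kind[kinds]) |>
      tidyr::pivot_wider(id_cols = c("patient_id", "label"),
                         names_from = "name", values_from = "value")
    log_stage(v, sprintf("%d features: ranking + LOOCV sweep",
                         length(feature_columns(tab))))
    ranking <- rank_by_src(tab, tol = cfg$omp$tol)
    sweep <- sweep_feature_count(tab, ranking, k_max = cfg$k_max,
                                 C = cfg$svm$C, gamma = cfg$svm$gamma)
    report <- evaluate_model(tab, ranking, k = sweep$best_k,
                             C = cfg$svm$C, gamma = cfg$svm$gamma,
                             n_boot = cfg$n_boot)
    list(table = tab, ranking = ranking, sweep = sweep, report = report)
  })
  summary <- purrr::imap_dfr(results, function(r, v) {
    dplyr::bind_cols(tibble::tibble(model = v,
                                    n_features = length(feature_columns(r$table))),
                     glance(r$report))
  })
  log_stage("done", "pipeline complete")
  run <- structure(list(summary = summary,
                        reports = purrr::map(results, "report"),
                        sweeps = purrr::map(results, "sweep"),
                        rankings = purrr::map(results, "ranking"),
                        tables = purrr::map(results, "table"),
                        cohort = cohort, logs = logs,
                        config = cfg, config_hash = config_hash),
                   class = "pipeline_run")
  if (!is.null(out_dir)) write_pipeline_run(run, out_dir)
  run
}

#' @export
print.pipeline_run <- function(x, ...) {
  cat(sprintf("<pipeline_run> %d patients, config %s\n",
              nrow(x$cohort), substr(x$config_hash, 1, 8)))
  print(as.data.frame(x$summary), digits = 4)
  invisible(x)
}

#' @exportS3Method generics::glance
glance.pipeline_run <- function(x, ...) x$summary

write_pipeline_run <- function(run, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  stamp <- function(df) dplyr::mutate(df, config_hash = run$config_hash)
  readr::write_csv(stamp(run$summary), file.path(out_dir, "summary.csv"))
  for (v in names(run$tables)) {
    readr::write_csv(run$tables[[v]], file.path(out_dir, sprintf("features_%s.csv", v)))
    readr::write_csv(stamp(tibble::as_tibble(run$rankings[[v]])),
                     file.path(out_dir, sprintf("ranking_%s.csv", v)))
    readr::write_csv(stamp(run$sweeps[[v]]$metrics),
                     file.path(out_dir, sprintf("sweep_%s.csv", v)))
    rep <- run$reports[[v]]
    readr::write_csv(stamp(rep$roc$points), file.path(out_dir, sprintf("roc_%s.csv", v)))
    readr::write_csv(stamp(rep$prc$points), file.path(out_dir, sprintf("prc_%s.csv", v)))
    jsonlite::write_json(
      c(as.list(glance(rep)), list(config_hash = run$config_hash)),
      file.path(out_dir, sprintf("report_%s.json", v)),
      auto_unbox = TRUE, digits = NA)
  }
  jsonlite::write_json(run$config, file.path(out_dir, "config.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  writeLines(vapply(run$logs, function(l) {
    jsonlite::toJSON(c(l, list(config_hash = run$config_hash)), auto_unbox = TRUE)
  }, character(1)), file.path(out_dir, "logs.jsonl"))
  invisible(out_dir)
}

#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @importFrom rlang .data
#' @importFrom Rcpp sourceCpp
#' @useDynLib rfrad, .registration = TRUE
NULL
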