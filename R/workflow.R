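#' Pipeline configuration
#'
#' Bundles the inputs and stage parameters of a full run. Exactly one
#' data source is used: file paths (`spectra_path`/`metadata_path`) or a
#' simulation block (`simulate`).
#'
#' @param spectra_path,metadata_path CSV inputs for [read_spectra()], or
#'   `NULL` when simulating.
#' @param simulate a [sim_config()], or `NULL` when reading files.
#' @param preprocess a [preprocess_config()] for the quantitative
#'   calibration (default first derivative).
#' @param qualify_preprocess pretreatment for the qualitative
#'   discrimination stage (default SNV, see [qualify_pipeline()]).
#' @param n_pcs principal components for the qualitative stage.
#' @param n_intervals,combo_sizes,max_lv synergy-interval search
#'   parameters.
#' @param responses freshness indices to calibrate, subset of
#'   `c("hu", "yi", "wr")`.
#' @param output_dir directory for report files, or `NULL` to skip
#'   writing.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(spectra_path = NULL, metadata_path = NULL,
                            simulate = NULL,
                            preprocess = preprocess_config(),
                            qualify_preprocess = preprocess_config("snv"),
                            n_pcs = 13, n_intervals = 25,
                            combo_sizes = c(2, 3), max_lv = 15,
                            responses = c("hu", "yi", "wr"),
                            output_dir = NULL) {
  from_files <- !is.null(spectra_path) || !is.null(metadata_path)
  if (from_files == !is.null(simulate))
    stop("exactly one of file paths / simulate block must be given")
  if (from_files && (is.null(spectra_path) || is.null(metadata_path)))
    stop("both spectra_path and metadata_path are required")
  if (!all(responses %in% c("hu", "yi", "wr")))
    stop("responses must be a subset of hu, yi, wr")
  structure(list(spectra_path = spectra_path, metadata_path = metadata_path,
                 simulate = simulate, preprocess = preprocess,
                 qualify_preprocess = qualify_preprocess,
                 n_pcs = n_pcs, n_intervals = n_intervals,
                 combo_sizes = combo_sizes, max_lv = max_lv,
                 responses = responses, output_dir = output_dir),
            class = "pipeline_config")
}

load_pipeline_data <- function(cfg) {
  if (!is.null(cfg$simulate)) {
    sim <- generate_dataset(cfg$simulate)
    responses <- with(sim$truth$indices,
                      data.frame(hu = haugh_unit, yi = yolk_index,
                                 wr = weight_loss))
    list(spectra = sim$spectra, responses = responses, truth = sim$truth)
  } else {
    s <- read_spectra(cfg$spectra_path, cfg$metadata_path)
    list(spectra = s, responses = NULL, truth = NULL)
  }
}

#' Run the qualitative (storage-day discrimination) analysis
#'
#' Simulate-or-load, split by the every-third rule, pretreat, PCA on the
#' calibration set, discriminant analysis, per-day count table. With
#' `output_dir` set, writes `qualify_counts.csv` (per-day correct/total)
#' and `qualify_report.json`.
#'
#' @param cfg a [pipeline_config()].
#' @return The [qualify_pipeline()] report.
#' @export
run_qualitative <- function(cfg) {
  stopifnot(inherits(cfg, "pipeline_config"))
  dat <- load_pipeline_data(cfg)
  split <- make_split(dat$spectra)
  rep <- qualify_pipeline(dat$spectra, cfg$qualify_preprocess, cfg$n_pcs,
                          split)
  if (!is.null(cfg$output_dir)) {
    dir.create(cfg$output_dir, showWarnings = FALSE, recursive = TRUE)
    write.csv(rep$per_day,
              file.path(cfg$output_dir, "qualify_counts.csv"),
              row.names = FALSE)
    jsonlite::write_json(
      list(n_pcs = rep$n_pcs, per_day = rep$per_day,
           train_accuracy_pct = rep$train_accuracy,
           test_accuracy_pct = rep$test_accuracy),
      file.path(cfg$output_dir, "qualify_report.json"),
      auto_unbox = TRUE, digits = NA, dataframe = "columns")
  }
  rep
}

#' Run the quantitative (Si-PLS calibration) analysis
#'
#' For each requested freshness index: synergy-interval search on the
#' calibration set, evaluation on the prediction set. Responses come from
#' the simulation truth (simulated runs) or from a destructive table
#' joined by `sample_id` (`destructive_path` CSV with the
#' [freshness_indices()] columns). A failure in one response is reported
#' and the remaining responses still complete. With `output_dir` set,
#' writes `quantify_summary.csv` (one row per response: effective region,
#' latent variables, RMSEP, R(t)) and per-response search tables.
#'
#' @param cfg a [pipeline_config()].
#' @param destructive_path optional CSV of destructive measurements for
#'   file-based runs.
#' @return List of class `quantify_report`: per-response `sipls_eval`
#'   results plus a `summary` data.frame.
#' @export
run_quantitative <- function(cfg, destructive_path = NULL) {
  stopifnot(inherits(cfg, "pipeline_config"))
  dat <- load_pipeline_data(cfg)
  s <- dat$spectra
  resp <- dat$responses
  if (is.null(resp)) {
    if (is.null(destructive_path))
      stop("file-based quantitative runs need destructive_path")
    d <- freshness_indices(read.csv(destructive_path))
    d <- d[match(s$sample_ids, d$sample_id), ]
    resp <- data.frame(hu = d$haugh_unit, yi = d$yolk_index,
                       wr = d$weight_loss)
  }
  split <- make_split(s)
  sp <- apply_preprocess(s, cfg$preprocess,
                         calibration_indices = split$calibration)
  Xc <- sp$absorbance[split$calibration, , drop = FALSE]
  Xp <- sp$absorbance[split$prediction, , drop = FALSE]
  results <- list()
  rows <- list()
  for (r in cfg$responses) {
    res <- tryCatch({
      yc <- resp[[r]][split$calibration]
      yp <- resp[[r]][split$prediction]
      fit <- sipls(Xc, yc, s$grid, n_intervals = cfg$n_intervals,
                   sizes = cfg$combo_sizes, max_lv = cfg$max_lv)
      ev <- evaluate_sipls(fit, Xc, yc, Xp, yp)
      ev$search <- fit
      ev
    }, error = function(e) {
      warning("response '", r, "' failed: ", conditionMessage(e))
      NULL
    })
    results[[r]] <- res
    if (!is.null(res))
      rows[[r]] <- data.frame(
        response = r,
        effective_region_nm = format_regions(res$selected_regions,
                                             s$grid$unit),
        n_lv = res$chosen_lv, rmsep = res$rmsep, r_t = res$r_prediction)
  }
  summary <- do.call(rbind, rows)
  rownames(summary) <- NULL
  if (!is.null(cfg$output_dir)) {
    dir.create(cfg$output_dir, showWarnings = FALSE, recursive = TRUE)
    write.csv(summary, file.path(cfg$output_dir, "quantify_summary.csv"),
              row.names = FALSE)
    for (r in names(results)) if (!is.null(results[[r]]))
      write.csv(results[[r]]$search$table,
                file.path(cfg$output_dir,
                          paste0("quantify_search_", r, ".csv")),
                row.names = FALSE)
  }
  structure(list(results = results, summary = summary),
            class = "quantify_report")
}

#' @export
print.quantify_report <- function(x, ...) {
  cat("<quantify_report>\n")
  print(x$summary, row.names = FALSE)
  invisible(x)
}
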