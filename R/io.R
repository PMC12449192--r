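#' Read and write the shared pigment CSV dialect
#'
#' The pigments dialect has header
#' `strain,replicate,time_min,phase,dd,dt,vx,ax,zx[,fx][,chl_a,chlide_a]`,
#' UTF-8, `.` decimal separator. Unknown extra columns are preserved with a
#' warning; missing required columns raise an error naming the column, and
#' time must be strictly increasing within each strain x replicate.
#'
#' @param path File path.
#' @return A tibble (readers) or the input, invisibly (writers).
#' @name pigments_csv
NULL

PIGMENTS_REQUIRED <- c("strain", "replicate", "time_min", "phase",
                       "dd", "dt", "vx", "ax", "zx")
PIGMENTS_OPTIONAL <- c("fx", "chl_a", "chlide_a")
FLUOR_REQUIRED <- c("strain", "replicate", "time_min", "fm_prime")

check_dialect <- function(df, required, optional, what) {
  miss <- setdiff(required, names(df))
  if (length(miss) > 0) {
    stop(what, " table is missing required column(s): ",
         paste(miss, collapse = ", "))
  }
  extra <- setdiff(names(df), c(required, optional))
  if (length(extra) > 0) {
    warning(what, " table has unknown column(s), preserved: ",
            paste(extra, collapse = ", "))
  }
  mono <- df |>
    dplyr::group_by(.data$strain, .data$replicate) |>
    dplyr::summarise(ok = !is.unsorted(.data$time_min, strictly = TRUE),
                     .groups = "drop")
  if (!all(mono$ok)) {
    bad <- mono[!mono$ok, ]
    stop(what, " table has non-monotone time for ",
         paste(bad$strain, bad$replicate, sep = "/", collapse = ", "))
  }
  df
}

#' @rdname pigments_csv
#' @export
read_pigments_csv <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  check_dialect(df, PIGMENTS_REQUIRED, PIGMENTS_OPTIONAL, "pigments")
}

#' @rdname pigments_csv
#' @param x Table to write.
#' @export
write_pigments_csv <- function(x, path) {
  check_dialect(tibble::as_tibble(x), PIGMENTS_REQUIRED, PIGMENTS_OPTIONAL,
                "pigments")
  readr::write_csv(x, path, progress = FALSE)
  invisible(x)
}

#' Read and write the shared fluorescence CSV dialect
#'
#' Header `strain,replicate,time_min,fm_prime`; same conventions as the
#' pigments dialect.
#'
#' @param path File path.
#' @param x Table to write.
#' @return A tibble (reader) or the input, invisibly (writer).
#' @name fluorescence_csv
NULL

#' @rdname fluorescence_csv
#' @export
read_fluorescence_csv <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  check_dialect(df, FLUOR_REQUIRED, character(0), "fluorescence")
}

#' @rdname fluorescence_csv
#' @export
write_fluorescence_csv <- function(x, path) {
  check_dialect(tibble::as_tibble(x), FLUOR_REQUIRED, character(0),
                "fluorescence")
  readr::write_csv(x, path, progress = FALSE)
  invisible(x)
}

#' Write a results table as CSV
#'
#' Plain CSV writer used for quenching, rates, model-comparison and stats
#' tables.
#'
#' @param x Data frame.
#' @param path File path.
#' @export
write_results_csv <- function(x, path) {
  readr::write_csv(tibble::as_tibble(x), path, progress = FALSE)
  invisible(x)
}

#' Read a run configuration (JSON or YAML)
#'
#' A flat document holding scenario parameter overrides plus run-level
#' settings. Recognized top-level keys: every [scenario_params()] field,
#' `genotypes`, `days`, `hl_min`, `ll_min`, `hl_irradiance`,
#' `ll_irradiance`, `include_hl_endpoint`, `out_dir`, `verbose`. Unknown
#' keys are rejected so typos cannot silently change a run.
#'
#' @param path Path ending in `.json`, `.yaml` or `.yml`.
#' @return Named list of settings.
#' @export
read_run_config <- function(path) {
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else {
    stop("config must be a .json or .yaml/.yml file")
  }
  allowed <- c(names(scenario_params()), "genotypes", "days", "hl_min",
               "ll_min", "hl_irradiance", "ll_irradiance",
               "include_hl_endpoint", "out_dir", "verbose")
  unknown <- setdiff(names(cfg), allowed)
  if (length(unknown) > 0) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  }
  cfg
}

#' Run the full analysis pipeline on a synthetic dataset
#'
#' Executes simulate -> pigment metrics -> quenching -> recovery kinetics ->
#' pool correlation -> group statistics, writing every table as CSV into
#' `out_dir` together with the resolved configuration (for provenance) and
#' a plain-text log. Fully deterministic under a fixed seed and config.
#'
#' @param config Named list of settings as from [read_run_config()]
#'   (default: empty, i.e. all package defaults).
#' @param seed Integer seed overriding the config seed.
#' @param out_dir Output directory (created if needed).
#' @param verbose Print progress lines.
#' @return Invisibly, a list with all result tables.
#' @export
run_pipeline <- function(config = list(), seed = NULL, out_dir = tempfile("xq_run_"),
                         verbose = FALSE) {
  run_keys <- c("genotypes", "days", "hl_min", "ll_min", "hl_irradiance",
                "ll_irradiance", "include_hl_endpoint", "out_dir", "verbose")
  par_cfg <- config[setdiff(names(config), run_keys)]
  if (!is.null(seed)) par_cfg$seed <- as.integer(seed)
  params <- do.call(scenario_params, par_cfg)
  genotypes <- config$genotypes %||% c("wt", "vde_ko", "zep2_ko", "zep3_ko")
  regime <- light_regime(
    days = config$days %||% 5,
    hl_min = config$hl_min %||% 360,
    ll_min = config$ll_min %||% 1080,
    hl_irradiance = config$hl_irradiance %||% 1100,
    ll_irradiance = config$ll_irradiance %||% 25,
    hl_threshold = params$hl_threshold
  )
  include_hl <- config$include_hl_endpoint %||% TRUE

  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(out_dir, "run.log")
  log_line <- function(...) {
    msg <- paste0(format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"), " ", ...)
    cat(msg, "\n", file = log_path, append = TRUE, sep = "")
    if (verbose) message(msg)
  }
  log_line("pipeline start; seed = ", params$seed)

  resolved <- c(unclass(params),
                list(genotypes = genotypes,
                     include_hl_endpoint = include_hl,
                     days = config$days %||% 5))
  jsonlite::write_json(resolved, file.path(out_dir, "resolved_config.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)

  ds <- generate_dataset(params, genotypes, regime)
  write_pigments_csv(ds$pigments, file.path(out_dir, "pigments.csv"))
  write_fluorescence_csv(ds$fluorescence, file.path(out_dir, "fluorescence.csv"))
  log_line("simulated ", length(genotypes), " genotypes x ",
           params$n_replicates, " replicates")

  metrics <- pool_sums(ds$pigments)
  write_results_csv(metrics, file.path(out_dir, "pigment_metrics.csv"))

  quench <- compute_quenching(ds$fluorescence)
  write_results_csv(quench, file.path(out_dir, "quenching.csv"))
  log_line("metrics and quenching computed")

  rates <- fit_recovery_kinetics(ds$pigments, quench)
  write_results_csv(rates, file.path(out_dir, "rates.csv"))
  if (length(genotypes) >= 2 && "wt" %in% genotypes) {
    rate_summary <- compare_rates(rates, reference = "wt",
                                  seed = params$seed)
    write_results_csv(rate_summary, file.path(out_dir, "rate_summary.csv"))
  }
  log_line("recovery kinetics fitted")

  corr_strains <- intersect(c("wt", "zep2_ko"), unique(ds$pigments$strain))
  if (length(corr_strains) == 0) corr_strains <- unique(ds$pigments$strain)
  pig_corr <- dplyr::filter(ds$pigments, .data$strain %in% corr_strains)
  qe_corr <- dplyr::filter(quench, .data$strain %in% corr_strains)
  pools <- build_delta_pools(pig_corr, include_hl_endpoint = include_hl)
  pool_models <- fit_pool_models(qe_corr, pools)
  write_results_csv(pool_models, file.path(out_dir, "pool_models.csv"))
  log_line("best pool: ", select_best_pool(pool_models))

  mutants <- setdiff(unique(ds$pigments$strain), "wt")
  stats_tbl <- NULL
  if ("wt" %in% unique(ds$pigments$strain) && length(mutants) > 0) {
    stats_tbl <- dplyr::bind_rows(lapply(mutants, function(m) {
      dplyr::bind_rows(
        welch_tests(metrics, "total", m),
        welch_tests(metrics, "deepoxidized", m)
      )
    }))
    write_results_csv(stats_tbl, file.path(out_dir, "group_stats.csv"))
  }
  log_line("pipeline done")

  invisible(list(dataset = ds, metrics = metrics, quenching = quench,
                 rates = rates, pool_models = pool_models,
                 group_stats = stats_tbl, out_dir = out_dir))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
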