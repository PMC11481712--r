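# Scenario configuration, orchestration of deterministic and stochastic
# runs, reproducible manifests and result export.

#' Scenario configuration
#'
#' A flat, human-editable `key: value` document. Recognised keys (defaults
#' in parentheses): `schema_version` (1), `nuclide` (I-131),
#' `absorption_type` (F), `amad` (5), `gsd` (2.5), `density`,
#' `shape_factor`, `scenario` (worker), `commitment_years` (50), `n`
#' (1000), `seed` (1), `s_table` (synthetic | path to CSV),
#' `s_magnitude` (1e-15).
#'
#' @param path path to a config file, or NULL to start from defaults.
#' @param ... overrides of individual keys.
#' @return a `scenario_config` list; every default is made explicit so the
#'   manifest can echo the full configuration.
#' @export
scenario_config <- function(path = NULL, ...) {
  defaults <- list(
    schema_version = 1, nuclide = "I-131", absorption_type = "F",
    amad = 5, gsd = 2.5, density = NA, shape_factor = NA,
    scenario = "worker", commitment_years = 50, n = 1000, seed = 1,
    s_table = "synthetic", s_magnitude = 1e-15
  )
  cfg <- defaults
  if (!is.null(path)) {
    lines <- readLines(path, warn = FALSE)
    lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
    for (ln in lines) {
      kv <- strsplit(ln, ":", fixed = TRUE)[[1]]
      if (length(kv) < 2) stop("malformed config line: '", ln, "'")
      key <- trimws(kv[1])
      val <- trimws(paste(kv[-1], collapse = ":"))
      if (!key %in% names(defaults)) stop("unknown config key '", key, "'")
      num <- suppressWarnings(as.numeric(val))
      cfg[[key]] <- if (!is.na(num)) num else val
    }
  }
  overrides <- list(...)
  bad <- setdiff(names(overrides), names(defaults))
  if (length(bad)) stop("unknown config key(s): ", paste(bad, collapse = ", "))
  cfg[names(overrides)] <- overrides
  if (cfg$n < 1) stop("n must be >= 1")
  if (cfg$commitment_years <= 0) stop("commitment_years must be positive")
  if (!identical(cfg$scenario, "worker")) {
    stop("only the bundled 'worker' scenario is configurable by file")
  }
  structure(cfg, class = "scenario_config")
}

config_tau_days <- function(config) config$commitment_years * 365.25

config_s_pair <- function(config) {
  if (identical(config$s_table, "synthetic")) {
    generate_synthetic_s_table(
      seed = stage_seed(config$seed, "s_table"),
      sources = unique(source_region_map()$source_region),
      targets = names(tissue_weights()),
      magnitude = config$s_magnitude
    )
  } else {
    read_s_table(config$s_table)
  }
}

config_aerosol <- function(config) {
  aerosol_spec(amad = config$amad, gsd = config$gsd,
               density = if (is.na(config$density)) NULL else config$density,
               shape_factor = if (is.na(config$shape_factor)) NULL else
                 config$shape_factor)
}

run_manifest <- function(config, outputs = character(0)) {
  files <- list.files(system.file("extdata", package = "hrtmdose"),
                      full.names = TRUE)
  sums <- tools::md5sum(files)
  names(sums) <- basename(names(sums))
  list(
    config = unclass(config),
    seed = config$seed,
    stage_seeds = sapply(c("lhs", "propagate", "s_table", "sensitivity"),
                         function(s) stage_seed(config$seed, s)),
    table_checksums = sums,
    package_version = as.character(utils::packageVersion("hrtmdose")),
    r_version = R.version.string,
    timestamp = format(Sys.time(), tz = "UTC"),
    outputs = outputs
  )
}

#' Deterministic dose-coefficient run
#'
#' Validates the configuration, evaluates the deterministic committed
#' effective dose coefficient chain at reference parameter values, and
#' returns the result together with a reproducibility manifest (config
#' echo, bundled-table checksums, seeds, versions).
#'
#' @param config a [scenario_config()].
#' @return a `deterministic_run`: list with `result`
#'   (a `dose_coefficient_result`) and `manifest`.
#' @export
run_deterministic <- function(config = scenario_config()) {
  s_pair <- config_s_pair(config)
  result <- deterministic_cedc(
    aerosol = config_aerosol(config),
    scenario = worker_scenario(),
    s_pair = s_pair,
    nuclide = config$nuclide,
    tau = config_tau_days(config)
  )
  structure(list(result = result, manifest = run_manifest(config)),
            class = "deterministic_run")
}

#' Stochastic uncertainty and sensitivity run
#'
#' The full stochastic pipeline: latin-hypercube design over the eighteen
#' uncertain parameters, propagation through the deterministic chain,
#' summary statistics, distribution characterisation, uncertainty factor
#' around the deterministic central estimate, and random-forest + Shapley
#' sensitivity ranking. All stages derive their seeds from the config seed.
#'
#' @param config a [scenario_config()] with `n >= 2`.
#' @param attribution_rows number of design rows to compute Shapley
#'   attributions on (capped at n; attributions are the slow part).
#' @return a `stochastic_run`: list with `cedc` (the sample), `summary`,
#'   `fits`, `uf`, `sensitivity` (importance report), `model`, `design`,
#'   `deterministic` and `manifest`. When the sample is degenerate the
#'   fitting/sensitivity stages are skipped with a recorded message.
#' @export
run_stochastic <- function(config = scenario_config(), attribution_rows = 250) {
  if (config$n < 2) stop("stochastic run needs n >= 2")
  s_pair <- config_s_pair(config)
  aerosol <- config_aerosol(config)
  tau <- config_tau_days(config)

  design <- lhs_design(reference_parameter_table(), n = config$n,
                       seed = stage_seed(config$seed, "lhs"))
  cedc <- propagate(design, aerosol = aerosol, s_pair = s_pair,
                    nuclide = config$nuclide, tau = tau)
  summ <- summarize_cedc(cedc)

  deterministic <- deterministic_cedc(
    aerosol = aerosol, scenario = worker_scenario(), s_pair = s_pair,
    nuclide = config$nuclide, tau = tau
  )

  notes <- character(0)
  fits <- NULL
  uf <- NULL
  sens <- NULL
  model <- NULL
  if (summ$sd == 0) {
    notes <- c(notes, paste(
      "sample is degenerate (zero spread): distribution fitting and",
      "sensitivity ranking refused"))
  } else {
    fits <- best_fit_distribution(cedc)
    uf <- uncertainty_factor(deterministic$E, summ$q2.5, summ$q97.5)
    scaled <- minmax_scale(as.numeric(cedc))
    model <- fit_ensemble(design, scaled,
                          ensemble_config(seed = stage_seed(config$seed,
                                                            "sensitivity")))
    rows <- seq_len(min(attribution_rows, nrow(design)))
    sens <- importance_report(model, design[rows, , drop = FALSE])
  }

  structure(list(cedc = cedc, summary = summ, fits = fits, uf = uf,
                 sensitivity = sens, model = model, design = design,
                 deterministic = deterministic, notes = notes,
                 manifest = run_manifest(config)),
            class = "stochastic_run")
}

#' @export
print.stochastic_run <- function(x, ...) {
  cat("<stochastic dose-coefficient run> n =", x$summary$n, "\n")
  print(x$summary)
  if (length(x$notes)) cat("note:", x$notes, "\n")
  if (!is.null(x$fits)) {
    cat("best-fit family:", x$fits$family[1], "\n")
  }
  if (!is.null(x$uf)) print(x$uf)
  if (!is.null(x$sensitivity)) {
    cat("top features:",
        paste(head(x$sensitivity$feature, 3), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Export run results to files
#'
#' Writes the run outputs with stable column order: the dose-coefficient
#' sample and design matrix as CSV, and the summary / fit ranking / UF /
#' sensitivity blocks as JSON.
#'
#' @param run a `stochastic_run` or `deterministic_run`.
#' @param dir output directory (created if missing).
#' @param formats subset of `c("csv", "json")`.
#' @return invisibly, the paths written.
#' @export
export_results <- function(run, dir, formats = c("csv", "json")) {
  bad <- setdiff(formats, c("csv", "json"))
  if (length(bad)) stop("unknown format(s): ", paste(bad, collapse = ", "))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  wjson <- function(obj, file) {
    p <- file.path(dir, file)
    jsonlite::write_json(obj, p, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
    paths <<- c(paths, p)
  }
  wcsv <- function(df, file) {
    p <- file.path(dir, file)
    write.csv(df, p, row.names = FALSE)
    paths <<- c(paths, p)
  }

  if (inherits(run, "deterministic_run")) {
    if ("json" %in% formats) {
      wjson(list(E_Sv_per_Bq = run$result$E,
                 h_M = as.list(run$result$h_M),
                 h_F = as.list(run$result$h_F),
                 tau_days = run$result$tau_days,
                 manifest = run$manifest), "deterministic.json")
    }
    if ("csv" %in% formats) {
      dep <- run$result$deposition
      wcsv(data.frame(region = c(hd_regions, "exhaled", "not_inhaled"),
                      fraction = unlist(dep[c(hd_regions, "exhaled",
                                              "not_inhaled")])),
           "deposition.csv")
    }
    return(invisible(paths))
  }

  if ("csv" %in% formats) {
    wcsv(data.frame(cedc_Sv_per_Bq = as.numeric(run$cedc)), "cedc.csv")
    wcsv(as.data.frame(unclass(run$design)), "design.csv")
    if (!is.null(run$sensitivity)) {
      att <- attr(run$sensitivity, "attributions")
      wcsv(as.data.frame(att$phi), "attributions.csv")
    }
  }
  if ("json" %in% formats) {
    wjson(unclass(run$summary), "summary.json")
    if (!is.null(run$fits)) {
      wjson(list(ranking = as.data.frame(unclass(run$fits)[
        c("family", "D", "p", "accepted")])), "fits.json")
    }
    if (!is.null(run$uf)) wjson(unclass(run$uf), "uf.json")
    if (!is.null(run$sensitivity)) {
      wjson(list(metrics = run$model$metrics,
                 ntree = run$model$ntree,
                 importance = as.data.frame(unclass(run$sensitivity)[
                   c("feature", "impurity_importance", "mean_abs_shap")])),
            "sensitivity.json")
    }
    wjson(run$manifest, "manifest.json")
  }
  invisible(paths)
}
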