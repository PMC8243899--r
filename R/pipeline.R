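# End-to-end pipeline: cohort (simulated or from CSVs) -> panels -> per-
# category trajectory model selection (optionally sex-stratified) ->
# diagnostics -> cross-tabs -> association -> descriptive outputs, all
# written into a run directory with a JSON manifest.

#' Default pipeline configuration
#'
#' Returns the configuration list [run_pipeline()] consumes, with every field
#' at its default. Fields: \code{n_patients}, \code{seed}, \code{calibration}
#' ("total"), \code{input_dir} (read cohort CSVs instead of simulating),
#' \code{categories}, \code{strata}, \code{groups} and \code{orders} (grid
#' bounds), \code{min_prop}, \code{n_restarts}, \code{n_boot},
#' \code{usd_rate}, \code{windows}, \code{make_plots}, \code{out_dir}.
#'
#' @param ... Named overrides of the defaults.
#' @return A named list.
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    n_patients = 1000L, seed = 1L, calibration = "total", input_dir = NULL,
    categories = c("total", "medical", "long_term_care"),
    strata = c("all", "male", "female"),
    groups = 2:8, orders = 0:5, min_prop = 0.05,
    n_restarts = 5L, n_boot = 200L,
    usd_rate = 92, windows = c(60L, 12L),
    make_plots = TRUE, out_dir = NULL
  )
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown)) stop("unknown config field(s): ",
                            paste(unknown, collapse = ", "), call. = FALSE)
  cfg[names(dots)] <- dots
  cfg
}

.write_csv <- function(x, path) {
  utils::write.csv(x, path, row.names = FALSE)
  path
}

#' Run the full expenditure-trajectory pipeline
#'
#' Executes, per stratum and expenditure category: panel construction,
#' trajectory-model selection over the configured grid, classification
#' diagnostics and labelling; then cross-tabulates the three category pairs,
#' writes descriptive outputs (summary table in USD, concentration curve,
#' per-group monthly trends), fits both association models on the
#' total-expenditure assignment, and records everything in
#' \code{manifest.json}. Identical configuration (including seed) reproduces
#' byte-identical CSV outputs.
#'
#' @param config A [pipeline_config()] list or the path of a YAML file with
#'   the same fields.
#' @param out_dir Output directory (overrides \code{config$out_dir}).
#' @return The manifest list, invisibly; side effect: files under
#'   \code{out_dir}.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = NULL) {
  if (is.character(config)) config <- do.call(pipeline_config,
                                              yaml::read_yaml(config))
  out_dir <- out_dir %||% config$out_dir %||%
    stop("no output directory given", call. = FALSE)
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  manifest <- list(package_version = as.character(utils::packageVersion("eoltraj")),
                   config = config[setdiff(names(config), "out_dir")],
                   files = character(0))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      manifest$failed_stage <- name
      jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                           auto_unbox = TRUE, pretty = TRUE, force = TRUE)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  # --- cohort -----------------------------------------------------------
  cohort <- stage("cohort", {
    if (!is.null(config$input_dir)) {
      list(claims = utils::read.csv(file.path(config$input_dir, "claims.csv"),
                                    colClasses = c(billing_month = "character")),
           patients = utils::read.csv(file.path(config$input_dir, "patients.csv")),
           truth = NULL)
    } else {
      generate_cohort(default_calibration(config$calibration,
                                          n_patients = config$n_patients,
                                          seed = config$seed))
    }
  })
  files <- character(0)
  if (!is.null(cohort$truth))
    files <- c(files, .write_csv(cohort$truth, file.path(out_dir, "truth.csv")))

  panel <- stage("panel", build_panel(cohort$claims, cohort$patients,
                                      max(config$windows)))
  lp <- log_transform(panel)

  # --- descriptives -----------------------------------------------------
  stage("descriptives", {
    summ <- panel_summary(panel, config$windows)
    summ_usd <- summ
    summ_usd[c("mean", "sd", "min", "max")] <-
      lapply(summ[c("mean", "sd", "min", "max")],
             function(z) round(to_usd(z, config$usd_rate)))
    files <- c(files,
               .write_csv(summ_usd, file.path(out_dir, "summary_usd.csv")))
    tot <- rowSums(panel$values[, , "total"])
    pc <- pareto_curve(tot)
    files <- c(files,
               .write_csv(pc$curve, file.path(out_dir, "pareto_curve.csv")),
                .write_csv(pc$queries, file.path(out_dir, "pareto_queries.csv")))
  })

  # --- per stratum / category model selection ---------------------------
  sex <- cohort$patients$sex
  strata_rows <- list(all = rep(TRUE, nrow(cohort$patients)),
                      male = sex == "male", female = sex == "female")
  assignments <- list()
  for (st in config$strata) {
    rows <- strata_rows[[st]]
    ids <- panel$patient_ids[rows]
    for (cat in config$categories) {
      tag <- paste0(st, "_", gsub("_", "", cat))
      sel <- stage(paste0("select_", tag),
                   gbtm_grid(lp$values[rows, , cat],
                             groups = config$groups, orders = config$orders,
                             min_prop = config$min_prop,
                             n_restarts = config$n_restarts,
                             seed = config$seed))
      fit <- sel$best
      labels <- label_trajectories(fit)
      files <- c(files, .write_csv(sel$grid,
                                   file.path(out_dir, paste0("grid_", tag, ".csv"))))
      jsonlite::write_json(
        list(groups = fit$groups, orders = fit$orders, pi = fit$pi,
             beta = fit$beta, sigma = fit$sigma, loglik = fit$loglik,
             bic = gbtm_bic(fit), labels = labels),
        file.path(out_dir, paste0("model_", tag, ".json")),
        auto_unbox = TRUE, digits = NA, pretty = TRUE)
      files <- c(files, file.path(out_dir, paste0("model_", tag, ".json")))
      asg <- data.frame(patient_id = ids, group = fit$assignment,
                        label = labels[fit$assignment],
                        stringsAsFactors = FALSE)
      files <- c(files, .write_csv(asg,
                                   file.path(out_dir, paste0("assignments_", tag, ".csv"))))
      diag <- stage(paste0("diagnose_", tag),
                    adequacy_report(fit, n_boot = config$n_boot,
                                    seed = config$seed))
      jsonlite::write_json(c(list(pass = diag$pass), as.list(diag$table)),
                           file.path(out_dir, paste0("diagnostics_", tag, ".json")),
                           auto_unbox = TRUE, digits = NA, pretty = TRUE)
      files <- c(files, file.path(out_dir, paste0("diagnostics_", tag, ".json")))
      if (st == "all") {
        assignments[[cat]] <-
          stats::setNames(asg$group, asg$patient_id)
        trend <- monthly_trend(panel, stats::setNames(asg$group, asg$patient_id))
        files <- c(files, .write_csv(trend[trend$category == cat, ],
                                     file.path(out_dir, paste0("trend_", tag, ".csv"))))
        if (isTRUE(config$make_plots)) {
          grDevices::png(file.path(out_dir, paste0("trajectories_", tag, ".png")),
                         width = 900, height = 600)
          plot(fit, y = lp$values[rows, , cat], labels = labels,
               main = paste("Fitted trajectories:", cat))
          grDevices::dev.off()
        }
      }
    }
  }

  # --- cross-tabs -------------------------------------------------------
  stage("crosstabs", {
    pairs <- if (length(assignments) >= 2L)
      utils::combn(names(assignments), 2L, simplify = FALSE) else list()
    for (pr in pairs) {
      ct <- cross_tabulate(assignments[[pr[1]]], assignments[[pr[2]]],
                           pr[1], pr[2])
      df <- as.data.frame(ct)
      files <- c(files, .write_csv(df,
                                    file.path(out_dir, paste0("crosstab_", pr[1], "_vs_",
                                                              pr[2], ".csv"))))
    }
  })

  # --- association ------------------------------------------------------
  stage("association", {
    if (!is.null(assignments$total) &&
        any(grepl("^dx_", names(cohort$patients)))) {
      asg <- assignments$total[panel$patient_ids]
      # guard against complete separation in small cohorts: a flag with an
      # empty outcome-group cell cannot enter the regression
      pats <- cohort$patients
      flags <- grep("^(dx|svc)_", names(pats), value = TRUE)
      sep <- flags[vapply(flags, function(f) {
        tab <- table(factor(pats[[f]], levels = 0:1), asg)
        any(tab == 0L)
      }, logical(1))]
      if (length(sep)) {
        manifest$excluded_covariates <- sep
        pats <- pats[setdiff(names(pats), sep)]
      }
      for (m in 1:2) {
        res <- suppressWarnings(fit_trajectory_multinom(pats, asg, model = m))
        files <- c(files, .write_csv(or_table(res),
                                      file.path(out_dir, paste0("association_model", m, ".csv"))))
      }
    }
  })

  manifest$files <- sort(basename(files))
  manifest$seed <- config$seed
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, force = TRUE)
  invisible(manifest)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
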