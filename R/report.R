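#' Run the full analysis pipeline and write a report bundle
#'
#' Orchestrates the package's analyses on one record set (read from a CSV
#' or generated from a preset scenario) and writes one output file per
#' requested analysis, a machine-readable manifest enumerating every
#' design-decision flag in effect, and a run log. Identical configuration
#' and seed give byte-identical CSV outputs.
#'
#' @param cfg A list (or path to a JSON/YAML file holding one) with fields:
#'   `input` (record CSV path) or `scenario` (list with `country`,
#'   `age_group`, `method`, optional `n_deaths`); `age_group`;
#'   `design_mode`; `analyses` (subset of `csmf_table`,
#'   `cause_comparison`, `accuracy`, `projections`, `sweep`,
#'   `demographics`); `projections` (ids, default A, B, E); `n_boot`
#'   (default 200); `seed` (required); `out_dir`.
#' @return Invisibly, a list with the per-analysis results and the paths
#'   written.
#' @export
run_full_analysis <- function(cfg) {
  if (is.character(cfg) && length(cfg) == 1) cfg <- read_run_config(cfg)
  stopifnot(is.list(cfg))
  if (is.null(cfg$seed)) stop("cfg$seed is required")
  if (is.null(cfg$out_dir)) stop("cfg$out_dir is required")
  analyses <- cfg$analyses
  if (is.null(analyses))
    analyses <- c("csmf_table", "cause_comparison", "accuracy",
                  "projections", "sweep", "demographics")
  if (!length(analyses)) stop("at least one analysis must be requested")
  n_boot <- if (is.null(cfg$n_boot)) 200 else cfg$n_boot
  proj_ids <- if (is.null(cfg$projections)) c("A", "B", "E") else cfg$projections
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(cfg$out_dir, "run.log")
  log_lines <- character(0)
  say <- function(...) {
    msg <- sprintf(...)
    message(msg)
    log_lines <<- c(log_lines, msg)
  }

  if (!is.null(cfg$input)) {
    say("reading records from %s", cfg$input)
    rs <- read_va_records(cfg$input, cfg$age_group,
                          if (is.null(cfg$design_mode)) "weighted_clustered"
                          else cfg$design_mode)
  } else if (!is.null(cfg$scenario)) {
    sc <- cfg$scenario
    say("generating preset scenario %s/%s/%s (seed %d)",
        sc$country, sc$age_group, sc$method, cfg$seed)
    pre <- preset_scenario(sc$country, sc$age_group, sc$method,
                           n_deaths = sc$n_deaths, seed = cfg$seed)
    rs <- generate_study(pre, seed = cfg$seed)
  } else stop("cfg must name an input file or a scenario")

  results <- list()
  paths <- character(0)
  wr <- function(df, name) {
    p <- file.path(cfg$out_dir, name)
    utils::write.csv(df, p, row.names = FALSE)
    paths <<- c(paths, p)
    p
  }
  status <- character(0)
  run_one <- function(name, fun) {
    res <- tryCatch({fun(); "ok"}, error = function(e) {
      say("analysis %s FAILED: %s", name, conditionMessage(e))
      paste("error:", conditionMessage(e))
    })
    status[[name]] <<- res
  }

  if ("csmf_table" %in% analyses) run_one("csmf_table", function() {
    tabs <- lapply(c("population", "community", "facility"), function(role) {
      v <- if (role == "population") weighted_csmf(rs) else weighted_csmf(rs, role)
      data.frame(role = role, as.data.frame(v))
    })
    results$csmf_table <<- do.call(rbind, tabs)
    wr(results$csmf_table, "csmf_table.csv")
    say("csmf_table written")
  })
  if ("cause_comparison" %in% analyses) run_one("cause_comparison", function() {
    results$cause_comparison <<- suppressMessages(
      compare_all_causes(rs, n_boot = n_boot, seed = cfg$seed))
    wr(as.data.frame(results$cause_comparison), "cause_comparison.csv")
    say("cause_comparison written")
  })
  if ("accuracy" %in% analyses) run_one("accuracy", function() {
    est <- csmf_accuracy_ci(rs, "facility", "community",
                            n_boot = n_boot, seed = cfg$seed)
    results$accuracy <<- est
    jsonlite::write_json(
      list(estimate = est$estimate, lower = est$lower, upper = est$upper,
           n_boot = est$n_boot, seed = est$seed),
      file.path(cfg$out_dir, "accuracy.json"), auto_unbox = TRUE, digits = NA)
    paths <<- c(paths, file.path(cfg$out_dir, "accuracy.json"))
    say("accuracy written")
  })
  if ("projections" %in% analyses) run_one("projections", function() {
    rows <- lapply(proj_ids, function(id) {
      pr <- suppressMessages(
        project_csmf(rs, id, n_boot = n_boot, seed = cfg$seed))
      results$projections[[id]] <<- pr
      acc <- pr$accuracy
      data.frame(projection = id, n_deaths = nrow(rs),
                 pct_facility = 100 * pr$p_facility,
                 accuracy = if (inherits(acc, "interval_estimate")) acc$estimate else acc,
                 lower = if (inherits(acc, "interval_estimate")) acc$lower else NA,
                 upper = if (inherits(acc, "interval_estimate")) acc$upper else NA)
    })
    wr(do.call(rbind, rows), "projections.csv")
    say("projections written (%s)", paste(proj_ids, collapse = ","))
  })
  if ("sweep" %in% analyses) run_one("sweep", function() {
    sw <- facility_fraction_sweep(weighted_csmf(rs, "community"),
                                  weighted_csmf(rs, "facility"))
    results$sweep <<- sw
    wr(sw, "sweep.csv")
    say("sweep written")
  })
  if ("demographics" %in% analyses) run_one("demographics", function() {
    dem_factors <- intersect(c("age_band", "mother_education", "sex",
                               "born_in_facility", "wealth_quintile",
                               if (rs_age_group(rs) == "neonate") "anc_formal"),
                             names(rs))
    results$demographics <<- demographic_table(rs, dem_factors)
    wr(results$demographics, "demographics.csv")
    say("demographics written")
  })

  manifest <- list(
    seed = cfg$seed,
    n_boot = n_boot,
    analyses = analyses,
    projections = proj_ids,
    n_records = nrow(rs),
    design_mode = rs_design_mode(rs),
    status = as.list(status),
    decisions = list(
      accuracy_reference = "community (place comparison); observed population (projections)",
      aggregation = "soft",
      fisher_trigger = "any zero raw cell or expected raw count < 5",
      bootstrap = "PSU percentile bootstrap, weights not rescaled",
      multinomial_ridge = 1e-4,
      rf = "500 trees, min node 1, mtry floor(sqrt(p))"),
    outputs = basename(paths))
  jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  writeLines(log_lines, log_path)
  failed <- grepl("^error", unlist(status))
  if (any(failed))
    stop("analysis failure(s): ", paste(names(status)[failed], collapse = ", "))
  invisible(list(results = results, paths = paths, manifest = manifest))
}

#' @keywords internal
read_run_config <- function(path) {
  if (grepl("\\.ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("yaml package required to read YAML configs")
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
}
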