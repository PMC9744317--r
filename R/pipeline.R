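# Config-driven orchestration: simulate or ingest -> variable coding ->
# path model + nested confounding -> rGE report -> machine-readable bundle.

#' Prepare a person-level table for analysis
#'
#' Applies the survey coding rules to a raw cohort table: recodes education
#' category labels to years (with an optional wave-fallback column for the
#' child), builds the additive involvement scales from their binary items,
#' applies listwise deletion in the order of the sample-selection cascade
#' (child education, parental education, PGS, involvement), and standardizes
#' the analysis columns.  Every filter step and its remaining n is recorded
#' in `attr(, "filter_log")`.
#'
#' @param cohort A `cohort_table` from [simulate_cohort()] or any data frame
#'   with compatible columns (labels `child_edu_label` (+ optional
#'   `child_edu_label_w4` fallback), `father_edu_label`, `mother_edu_label`
#'   or ready-made `*_years` columns; involvement items
#'   `father_school_1..3`, `father_leisure_1..5` or ready-made counts;
#'   `pgs`, `PC*`, controls, `household_id`, `person_id`).
#' @return Data frame with raw `*_years` / `*_count` columns, standardized
#'   analysis columns (`child_edu`, `father_edu`, `mother_edu`,
#'   `school_inv`, `leisure_inv`, `mother_school_inv`, `mother_leisure_inv`,
#'   `age`, `pgs`), binary controls as 0/1, genetic PCs, and a refreshed
#'   `sibling` flag.
#' @export
prepare_cohort <- function(cohort) {
  d <- as.data.frame(cohort)
  log <- data.frame(step = "input rows", n = nrow(d))
  note <- function(step, n) rbind(log, data.frame(step = step, n = n))

  req <- c("household_id", "person_id", "pgs", "age", "female",
           "father_resident", "mother_resident", "enrolled")
  miss <- setdiff(req, names(d))
  if (length(miss)) stop("missing required column(s): ",
                         paste(miss, collapse = ", "))

  if (!"child_edu_years" %in% names(d)) {
    if (!"child_edu_label" %in% names(d))
      stop("missing required column(s): child_edu_label or child_edu_years")
    lab <- d$child_edu_label
    if ("child_edu_label_w4" %in% names(d))
      lab <- coalesce_waves(lab, d$child_edu_label_w4)
    d$child_edu_years <- recode_child_education(lab)
  }
  d <- d[!is.na(d$child_edu_years), , drop = FALSE]
  log <- note("child education reported", nrow(d))

  for (p in c("father", "mother")) {
    ycol <- paste0(p, "_edu_years")
    if (!ycol %in% names(d)) {
      lcol <- paste0(p, "_edu_label")
      if (!lcol %in% names(d))
        stop("missing required column(s): ", lcol, " or ", ycol)
      d[[ycol]] <- recode_parent_education(d[[lcol]])
    }
  }
  d <- d[!is.na(d$father_edu_years) & !is.na(d$mother_edu_years), , drop = FALSE]
  log <- note("parental education reported", nrow(d))

  d <- d[!is.na(d$pgs), , drop = FALSE]
  log <- note("education PGS available", nrow(d))

  if (!"school_inv_count" %in% names(d)) {
    sc <- paste0("father_school_", 1:3)
    lc <- paste0("father_leisure_", 1:5)
    miss <- setdiff(c(sc, lc), names(d))
    if (length(miss)) stop("missing involvement item column(s): ",
                           paste(miss, collapse = ", "))
    d$school_inv_count <- build_involvement_scale(d[sc], "school")
    d$leisure_inv_count <- build_involvement_scale(d[lc], "leisure")
  }
  if (!"mother_school_count" %in% names(d)) {
    miss <- setdiff(c("mother_school", "mother_leisure"), names(d))
    if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "))
    d$mother_school_count <- d$mother_school
    d$mother_leisure_count <- d$mother_leisure
  }
  d <- d[!is.na(d$school_inv_count) & !is.na(d$leisure_inv_count) &
           !is.na(d$mother_school_count) & !is.na(d$mother_leisure_count), ,
         drop = FALSE]
  log <- note("parental involvement complete", nrow(d))

  if (nrow(d) < 10) stop("fewer than 10 complete rows after filtering")

  hh_n <- table(d$household_id)
  d$sibling <- as.vector(hh_n[as.character(d$household_id)]) >= 2

  d$child_edu <- standardize(d$child_edu_years)
  d$father_edu <- standardize(d$father_edu_years)
  d$mother_edu <- standardize(d$mother_edu_years)
  d$school_inv <- standardize(d$school_inv_count)
  d$leisure_inv <- standardize(d$leisure_inv_count)
  d$mother_school_inv <- standardize(d$mother_school_count)
  d$mother_leisure_inv <- standardize(d$mother_leisure_count)
  d$age_years <- d$age
  d$age <- standardize(d$age_years)
  d$pgs <- standardize(d$pgs)

  attr(d, "filter_log") <- log
  class(d) <- c("analysis_table", "data.frame")
  d
}

#' Descriptive statistics table
#'
#' Mean/SD/min/max for the continuous analysis variables (on their raw
#' scales) and yes/no counts for the binary indicators.
#'
#' @param prepared An [prepare_cohort()] result.
#' @return List with `continuous` and `binary` data frames.
#' @export
cohort_descriptives <- function(prepared) {
  cont <- c(`Years of education child` = "child_edu_years",
            `Years of education father` = "father_edu_years",
            `Years of education mother` = "mother_edu_years",
            `PGS education child (z)` = "pgs",
            `Father's school-specific involvement` = "school_inv_count",
            `Father's leisure involvement` = "leisure_inv_count",
            `Mother's school-specific involvement` = "mother_school_count",
            `Mother's leisure involvement` = "mother_leisure_count",
            `Age first interview` = "age_years")
  cont <- cont[unname(cont) %in% names(prepared)]
  ct <- do.call(rbind, lapply(names(cont), function(nm) {
    x <- prepared[[cont[[nm]]]]
    data.frame(variable = nm, mean = mean(x), sd = stats::sd(x),
               min = min(x), max = max(x))
  }))
  bins <- c(`Enrolled in education` = "enrolled",
            `Live with father at first wave` = "father_resident",
            `Live with mother at first wave` = "mother_resident")
  bt <- do.call(rbind, lapply(names(bins), function(nm) {
    x <- prepared[[bins[[nm]]]]
    data.frame(variable = nm, yes_n = sum(x == 1), yes_pct = 100 * mean(x == 1),
               no_n = sum(x == 0), no_pct = 100 * mean(x == 0))
  }))
  list(continuous = ct, binary = bt)
}

#' Run configuration
#'
#' Assemble (and validate) the configuration of a full pipeline run.
#' Exactly one input mode is used: `"simulate"` (a [sim_config()] /
#' [scenario_config()], seed mandatory) or `"ingest"` (a delimited text
#' file plus an optional column mapping from the package's canonical names
#' to the file's).
#'
#' @param mode `"simulate"` or `"ingest"`.
#' @param sim A `sim_config`, or a list of [sim_config()] arguments, or a
#'   scenario name for [scenario_config()].
#' @param input For ingest mode: `list(path =, columns =, sep =)` where
#'   `columns` maps canonical column names to file column names.
#' @param control_placement Passed to [path_spec()].
#' @param bootstrap `list(B =, enabled =)` for the mediation/confounding
#'   resampling intervals.
#' @param conf Confidence level used throughout.
#' @param seed Integer master seed (mandatory in simulate mode; also drives
#'   the bootstrap).
#' @return Object of class `run_config`.
#' @export
run_config <- function(mode = c("simulate", "ingest"),
                       sim = "passive",
                       input = NULL,
                       control_placement = "outcome",
                       bootstrap = list(B = 1000, enabled = TRUE),
                       conf = 0.95,
                       seed = 1L) {
  mode <- match.arg(mode)
  if (mode == "simulate") {
    if (length(seed) != 1 || is.na(seed)) stop("seed is mandatory in simulate mode")
    if (is.character(sim)) sim <- scenario_config(sim, seed = seed)
    else if (is.list(sim) && !inherits(sim, "sim_config")) {
      sim$seed <- seed
      sim <- do.call(sim_config, sim)
    } else if (inherits(sim, "sim_config")) {
      sim$seed <- seed
      validate_sim_config(sim)
    } else stop("sim must be a scenario name, an argument list, or a sim_config")
  } else {
    if (is.null(input$path)) stop("ingest mode requires input$path")
  }
  if (is.null(bootstrap$B)) bootstrap$B <- 1000
  if (is.null(bootstrap$enabled)) bootstrap$enabled <- TRUE
  structure(list(mode = mode, sim = if (mode == "simulate") sim else NULL,
                 input = input, control_placement = control_placement,
                 bootstrap = bootstrap, conf = conf, seed = as.integer(seed)),
            class = "run_config")
}

#' Read a run configuration from a YAML file
#'
#' @param path YAML file with fields matching [run_config()] arguments.
#' @return A validated `run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  known <- c("mode", "sim", "input", "control_placement", "bootstrap",
             "conf", "seed")
  unknown <- setdiff(names(y), known)
  if (length(unknown)) stop("unknown config field(s): ",
                            paste(unknown, collapse = ", "))
  do.call(run_config, y)
}

.ingest_cohort <- function(input) {
  sep <- if (is.null(input$sep)) "\t" else input$sep
  d <- utils::read.table(input$path, header = TRUE, sep = sep,
                         stringsAsFactors = FALSE, check.names = FALSE)
  if (!is.null(input$columns)) {
    for (canon in names(input$columns)) {
      filecol <- input$columns[[canon]]
      if (!filecol %in% names(d))
        stop("ingest: mapped column '", filecol, "' (for '", canon,
             "') not found in ", input$path)
      names(d)[names(d) == filecol] <- canon
    }
  }
  d
}

#' Run the full analysis pipeline
#'
#' simulate (or ingest) -> variable coding and filtering -> nested path
#' models with mediation decomposition and genetic/social confounding ->
#' gene-environment correlation report.  All randomness (simulation and
#' bootstrap) derives from the single seed in the configuration; the same
#' configuration and seed reproduce the bundle exactly.
#'
#' @param config A [run_config()].
#' @return Object of class `report_bundle` with elements `descriptives`,
#'   `mediation`, `confounding`, `rge`, `filter_log` and `meta`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE))
  }
  raw <- stage("input", switch(config$mode,
    simulate = simulate_cohort(config$sim),
    ingest = .ingest_cohort(config$input)))
  prepared <- stage("coding", prepare_cohort(raw))
  n_pcs <- sum(grepl("^PC[0-9]+$", names(prepared)))
  spec <- path_spec(pcs = if (n_pcs) paste0("PC", seq_len(n_pcs)) else character(0),
                    control_placement = config$control_placement)

  desc <- stage("descriptives", cohort_descriptives(prepared))
  nested <- stage("path_model", fit_nested_suite(prepared, spec))
  med <- stage("mediation", decompose_effects(nested$M3, conf = config$conf))

  boot <- NULL
  if (isTRUE(config$bootstrap$enabled) && config$bootstrap$B >= 200) {
    statfun <- function(d) {
      ns <- fit_nested_suite(d, spec)
      dec <- decompose_effects(ns$M3)
      c(indirect_school = unname(dec$indirect["school"]),
        indirect_leisure = unname(dec$indirect["leisure"]),
        indirect_pgs = unname(dec$indirect["pgs"]),
        total = dec$total,
        genetic_school_pct = ns$confounding$percent_reduction[1],
        genetic_leisure_pct = ns$confounding$percent_reduction[2],
        social_pgs_pct = ns$confounding$percent_reduction[3])
    }
    boot <- stage("bootstrap",
      cluster_bootstrap(prepared, statfun, cluster = spec$cluster,
                        B = config$bootstrap$B,
                        seed = config$seed + 1000L, conf = config$conf))
  }
  rge <- stage("rge", rge_report(prepared, conf = config$conf))

  meta <- list(seed = config$seed, mode = config$mode,
               package_version = as.character(utils::packageVersion("rgepath")),
               control_placement = config$control_placement,
               n_children = nrow(prepared),
               n_households = length(unique(prepared$household_id)),
               bootstrap_B = if (is.null(boot)) 0L else boot$B)
  structure(list(descriptives = desc, mediation = med,
                 confounding = nested$confounding, nested = nested,
                 rge = rge, bootstrap = boot,
                 filter_log = attr(prepared, "filter_log"), meta = meta),
            class = "report_bundle")
}

#' @export
print.report_bundle <- function(x, ...) {
  cat(sprintf("Report bundle (%s mode, seed %d): %d children, %d households\n",
              x$meta$mode, x$meta$seed, x$meta$n_children, x$meta$n_households))
  print(x$mediation)
  cat("\n")
  tab <- x$confounding
  tab$percent_reduction <- round(tab$percent_reduction, 1)
  print(tab, row.names = FALSE)
  cat("\n")
  print(x$rge)
  invisible(x)
}

.bundle_as_list <- function(bundle) {
  list(
    descriptives_continuous = bundle$descriptives$continuous,
    descriptives_binary = bundle$descriptives$binary,
    mediation = bundle$mediation$table,
    mediation_total = bundle$mediation$total,
    mediation_reduced_form = bundle$mediation$reduced_form,
    confounding = bundle$confounding,
    rge = bundle$rge$table,
    rge_n = list(individuals = bundle$rge$n_individuals,
                 families = bundle$rge$n_families,
                 pairs = bundle$rge$n_pairs),
    filter_log = bundle$filter_log,
    meta = bundle$meta
  )
}

.summary_lines <- function(bundle) {
  med <- bundle$mediation
  conf <- bundle$confounding
  pm <- med$proportion_mediated
  lines <- c(
    sprintf("The total effect of father's education on child's education is %.3f.",
            med$total),
    sprintf("Father's school-specific involvement mediates %.1f%% of the intergenerational transmission (%.3f of the total effect of %.3f).",
            pm["school"], med$indirect["school"], med$total),
    sprintf("Father's leisure involvement mediates %.1f%% (%.3f of %.3f).",
            pm["leisure"], med$indirect["leisure"], med$total),
    sprintf("The education PGS mediates %.2f%% (%.3f of %.3f).",
            pm["pgs"], med$indirect["pgs"], med$total),
    sprintf("The association between father's school-specific involvement and children's educational attainment moves from %.3f to %.3f when the child's education PGS is added, which implies %.1f%% genetic confounding.",
            conf$before[1], conf$after[1], conf$percent_reduction[1]),
    sprintf("The association between father's leisure involvement and children's educational attainment moves from %.3f to %.3f (%.1f%% genetic confounding).",
            conf$before[2], conf$after[2], conf$percent_reduction[2]),
    sprintf("Once father involvement is added, the education PGS coefficient moves from %.3f to %.3f, which implies %.1f%% social confounding.",
            conf$before[3], conf$after[3], conf$percent_reduction[3])
  )
  rt <- bundle$rge$table
  wf <- function(v) if (is.na(v)) "not estimated (no sibling pairs)" else sprintf("%.3f", v)
  c(lines,
    sprintf("Correlated effects: school %.3f, leisure %.3f; between-family betas: school %.3f, leisure %.3f; within-family correlations: school %s, leisure %s.",
            rt$correlated_effects[1], rt$correlated_effects[2],
            rt$between_beta[1], rt$between_beta[2],
            wf(rt$within_corr[1]), wf(rt$within_corr[2])))
}

#' Persist a report bundle
#'
#' Writes one CSV per table (descriptives, mediation, confounding, rGE,
#' filter log), a JSON copy of the whole bundle holding the unrounded
#' numbers, and a human-readable plain-text summary.  All files are UTF-8,
#' comma-delimited with '.' decimals; within-family cells without sibling
#' pairs are written as empty (missing), never as zero.
#'
#' @param bundle A [run_pipeline()] result.
#' @param dir Output directory (created if needed).
#' @return Character vector of the files written, invisibly.
#' @export
write_report <- function(bundle, dir) {
  stopifnot(inherits(bundle, "report_bundle"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(dir)) stop("cannot create output directory ", dir)
  files <- character(0)
  wcsv <- function(df, name) {
    path <- file.path(dir, name)
    utils::write.csv(df, path, row.names = FALSE, fileEncoding = "UTF-8", na = "")
    files <<- c(files, path)
  }
  wcsv(bundle$descriptives$continuous, "descriptives_continuous.csv")
  wcsv(bundle$descriptives$binary, "descriptives_binary.csv")
  wcsv(bundle$mediation$table, "mediation.csv")
  wcsv(bundle$confounding, "confounding.csv")
  wcsv(bundle$rge$table, "rge.csv")
  wcsv(bundle$filter_log, "filter_log.csv")

  json_path <- file.path(dir, "bundle.json")
  jsonlite::write_json(.bundle_as_list(bundle), json_path, auto_unbox = TRUE,
                       digits = NA, dataframe = "rows", na = "null")
  files <- c(files, json_path)

  sum_path <- file.path(dir, "summary.txt")
  writeLines(.summary_lines(bundle), sum_path, useBytes = TRUE)
  files <- c(files, sum_path)
  invisible(files)
}

#' Read back a persisted report bundle
#'
#' Reads the JSON written by [write_report()] into the same list-of-tables
#' structure (the machine-readable half of the bundle).
#'
#' @param dir Directory written by [write_report()].
#' @return Named list mirroring the JSON bundle.
#' @export
read_report <- function(dir) {
  jsonlite::fromJSON(file.path(dir, "bundle.json"), simplifyDataFrame = TRUE)
}
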