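# Orchestration: sessionize -> metrics -> classify -> prompts -> analyze,
# with a plain-text + CSV report bundle. The pipeline is a pure function of
# its inputs and settings: re-running it reproduces every output file
# bit for bit (no clocks, no RNG).

#' Run the full engagement-analytics pipeline
#'
#' Reads a visit log (plus optionally psychosocial measures and a catalog),
#' reconstructs sessions, computes per-user and cohort metrics, classifies
#' users, detects prompt triggers, runs the attrition tests and
#' usage-outcome correlations, and writes a report bundle of CSV files and
#' a `report.txt` with the run settings. Any stage failure aborts with the
#' stage name.
#'
#' @param visits_path CSV or JSONL visit log (see [read_visits()]).
#' @param out_dir Output directory, created if needed.
#' @param psychosocial_path Optional psychosocial CSV; when given, change
#'   scores and correlations are included.
#' @param catalog_path Optional catalog CSV; defaults to the built-in
#'   program catalog.
#' @param access Optional access-window tibble; defaults to first-visit
#'   anchoring.
#' @param timeout_minutes Inactivity timeout (default 30).
#' @return Invisibly, a list with every computed table and the paths
#'   written.
#' @export
run_pipeline <- function(visits_path, out_dir,
                         psychosocial_path = NULL, catalog_path = NULL,
                         access = NULL, timeout_minutes = 30) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
        call. = FALSE
      )
    })
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  catalog <- stage(
    "catalog",
    if (is.null(catalog_path)) default_catalog() else read_catalog(catalog_path)
  )
  visits <- stage("validate", read_visits(visits_path, catalog = catalog))

  paths <- list()
  emit <- function(name, tb) {
    p <- file.path(out_dir, paste0(name, ".csv"))
    readr::write_csv(tb, p, na = "")
    paths[[name]] <<- p
    tb
  }

  if (nrow(visits) == 0) {
    writeLines(
      c(
        "engagement-analytics report",
        paste0("package: microengage ", package_version_string()),
        "users: 0",
        "page visits: 0",
        paste0("inactivity timeout (minutes): ", timeout_minutes),
        "note: empty visit log; no statistics computed"
      ),
      file.path(out_dir, "report.txt")
    )
    return(invisible(list(
      visits = visits, report = file.path(out_dir, "report.txt"),
      paths = paths
    )))
  }

  sv <- stage("sessionize", sessionize(visits, timeout_minutes))
  sessions <- emit("sessions", session_table(sv))
  summary <- stage(
    "metrics",
    summarize_usage(visits[, VISIT_COLUMNS],
      catalog = catalog, access = access,
      timeout_minutes = timeout_minutes
    )
  )
  emit("user_monthly", summary$monthly)
  emit("user_overall", summary$overall)
  emit("cohort_monthly", cohort_table(summary))
  classification <- stage("classify", classify_users(summary))
  emit("classification", classification)
  emit("crosstab", crosstab_groups(classification))
  emit("attrition_tests", stage("analyze", attrition_tests(summary)))
  emit("triggers_congrats", stage("prompts", congrats_triggers(sv)))
  emit(
    "triggers_exercise",
    stage("prompts", exercise_triggers(sv, catalog))
  )

  correlations <- NULL
  if (!is.null(psychosocial_path)) {
    psych <- stage("psychosocial", read_psychosocial(psychosocial_path))
    correlations <- stage(
      "analyze",
      usage_outcome_correlations(summary, psych)
    )
    emit("correlations", correlations)
  }

  report <- file.path(out_dir, "report.txt")
  status_counts <- table(classification$status)
  writeLines(
    c(
      "engagement-analytics report",
      paste0("package: microengage ", package_version_string()),
      paste0("users: ", nrow(summary$overall)),
      paste0("page visits: ", nrow(visits)),
      paste0("inactivity timeout (minutes): ", timeout_minutes),
      paste0("activity denominator (components): ", summary$denominator),
      paste0(
        "status counts: ",
        paste(names(status_counts), as.integer(status_counts),
          sep = "=", collapse = ", "
        )
      ),
      paste0("files: ", paste(names(paths), collapse = ", "))
    ),
    report
  )
  invisible(list(
    visits = visits, sessions = sessions, summary = summary,
    classification = classification, correlations = correlations,
    report = report, paths = paths
  ))
}

package_version_string <- function() {
  as.character(utils::packageVersion("microengage"))
}

#' Write the files of a synthetic cohort
#'
#' Convenience used by simulation studies: writes the visit log, the
#' psychosocial table and the ground truth of a generated cohort.
#'
#' @param cohort A `synthetic_cohort`.
#' @param dir Output directory, created if needed.
#' @return Named list of paths, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list(
    visits = file.path(dir, "visits.csv"),
    psychosocial = file.path(dir, "psychosocial.csv"),
    truth = file.path(dir, "ground_truth.json")
  )
  write_visits(cohort$visits, paths$visits)
  write_psychosocial(cohort$psychosocial, paths$psychosocial)
  truth <- cohort$truth
  truth$sessions <- within(as.data.frame(truth$sessions), {
    start <- format_timestamp(start)
    observed_end <- format_timestamp(observed_end)
    true_end <- format_timestamp(true_end)
  })
  jsonlite::write_json(
    list(
      seed = cohort$seed,
      users = as.data.frame(truth$users),
      sessions = truth$sessions
    ),
    paths$truth,
    auto_unbox = TRUE, digits = NA, na = "null"
  )
  invisible(paths)
}
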