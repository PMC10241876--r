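# End-to-end analysis and report assembly: exclusions -> schedules ->
# demographic parameters -> jackknife SEs -> Tukey letters, plus the
# stage-duration and reproductive summaries, rendered tables and schedule
# plots. The analysis path is fully deterministic; all randomness lives in
# the simulator.

#' Run the full life-table analysis
#'
#' @param cohorts Named list of [cohort_study] objects, or `NULL` to read
#'   from `individuals`/`fecundity` CSV paths.
#' @param individuals,fecundity CSV paths (used when `cohorts` is NULL).
#' @param age_origin Age origin for the schedules.
#' @param jackknife_unit Deletion unit for the jackknife.
#' @param alpha Significance level for all letter displays.
#' @param out_dir Optional output directory; when given, schedule, parameter
#'   and summary CSVs plus a JSON results bundle are written there.
#' @return An `analysis_report`: per-treatment `schedules`, `params`,
#'   `jackknife`, cross-treatment `comparisons` (one per parameter),
#'   `stage_summary`, `repro_summary`, and a `provenance` block.
#' @export
run_analysis <- function(cohorts = NULL, individuals = NULL, fecundity = NULL,
                         age_origin = c("egg", "adult_emergence"),
                         jackknife_unit = c("individual", "female"),
                         alpha = 0.05, out_dir = NULL) {
  age_origin <- match.arg(age_origin)
  jackknife_unit <- match.arg(jackknife_unit)
  if (is.null(cohorts)) {
    if (is.null(individuals) || is.null(fecundity)) {
      stop("provide either `cohorts` or both CSV paths")
    }
    cohorts <- read_cohort_csv(individuals, fecundity)
  }
  if (inherits(cohorts, "cohort_study")) cohorts <- list(cohorts)
  cohorts <- lapply(cohorts, apply_exclusions)
  names(cohorts) <- vapply(cohorts, function(co) co$treatment, character(1))
  for (co in cohorts) {
    if (nrow(co$individuals) == 0L) {
      stop("treatment '", co$treatment, "': empty cohort after exclusions")
    }
    cen <- census_quantities(co)
    if (cen$NF == 0L) {
      stop("treatment '", co$treatment,
           "': no adult females; demographic parameters undefined")
    }
  }
  message(sprintf("[cohortlife] %d treatment(s): %s", length(cohorts),
                  paste(names(cohorts), collapse = ", ")))

  schedules <- lapply(cohorts, build_schedule, age_origin = age_origin)
  params <- lapply(schedules, demographic_params)
  jack <- lapply(cohorts, jackknife_parameters, unit = jackknife_unit,
                 age_origin = age_origin)
  for (tr in names(jack)) {
    message(sprintf("[cohortlife] %s: n=%d records, %d ages, rm=%.4f (%d iter)",
                    tr, nrow(cohorts[[tr]]$individuals),
                    length(schedules[[tr]]$ages), params[[tr]]$rm,
                    params[[tr]]$solver$iterations))
  }
  comparisons <- NULL
  if (length(cohorts) >= 2) {
    comparisons <- lapply(stats::setNames(nm = .jk_params), function(par) {
      compare_treatments(lapply(jack, `[[`, par), alpha = alpha)
    })
  } else {
    message("[cohortlife] single treatment: comparison section empty")
  }
  stage_summary <- stage_duration_summary(cohorts, alpha = alpha)
  repro_summary <- reproductive_summary(cohorts, alpha = alpha)

  report <- structure(
    list(treatments = names(cohorts), cohorts = cohorts,
         schedules = schedules, params = params, jackknife = jack,
         comparisons = comparisons, stage_summary = stage_summary,
         repro_summary = repro_summary,
         provenance = list(
           package_version = as.character(utils::packageVersion("cohortlife")),
           age_origin = age_origin, jackknife_unit = jackknife_unit,
           alpha = alpha, timestamp = format(Sys.time(), tz = "UTC"))),
    class = "analysis_report")
  if (!is.null(out_dir)) write_report(report, out_dir)
  report
}

#' @export
print.analysis_report <- function(x, ...) {
  cat(sprintf("<analysis_report> %d treatment(s): %s\n",
              length(x$treatments), paste(x$treatments, collapse = ", ")))
  print(render_tables(x)$params)
  invisible(x)
}

.fmt_cell <- function(est, se, letter = "", digits = 3, se_digits = 4) {
  if (is.na(est)) return("")
  if (is.na(se)) return(sprintf("%.*f%s", digits, est, letter))
  sprintf("%.*f ± %.*f%s", digits, est, se_digits, se, letter)
}

.summary_table <- function(summaries) {
  do.call(rbind, lapply(summaries, function(sm) {
    cells <- vapply(seq_len(nrow(sm$groups)), function(i) {
      g <- sm$groups[i, ]
      sprintf("%s(%d)", .fmt_cell(g$mean, g$se, g$letter, 1, 2), g$n)
    }, character(1))
    data.frame(variable = sm$variable,
               treatment = sm$groups$treatment, cell = cells,
               test = sm$test, statistic = round(sm$statistic, 2),
               df = paste(sm$df, collapse = ","), p = signif(sm$p, 3),
               stringsAsFactors = FALSE)
  }))
}

#' Render the report as formatted tables
#'
#' Estimate-and-error cells are formatted the way life-table papers print
#' them (`"0.139 ± 0.0044a"`): durations to 1 decimal place, the four
#' demographic parameters to 3, letters appended. Rendering is formatting
#' only; every number comes from the report's raw fields.
#'
#' @param report An `analysis_report`.
#' @return List of data frames: `params` (one row per treatment), `stages`,
#'   `reproduction` (long format, one row per variable x treatment).
#' @export
render_tables <- function(report) {
  stopifnot(inherits(report, "analysis_report"))
  letters_of <- function(par) {
    if (is.null(report$comparisons)) {
      return(stats::setNames(rep("", length(report$treatments)),
                             report$treatments))
    }
    tab <- report$comparisons[[par]]$table
    stats::setNames(tab$letter, tab$treatment)
  }
  params <- do.call(rbind, lapply(report$treatments, function(tr) {
    jk <- report$jackknife[[tr]]
    row <- data.frame(treatment = tr, stringsAsFactors = FALSE)
    for (par in .jk_params) {
      lt <- letters_of(par)[tr]
      if (is.na(lt)) lt <- ""
      row[[par]] <- .fmt_cell(jk[[par]]$theta_jack, jk[[par]]$se, lt)
    }
    row
  }))
  list(params = params,
       stages = .summary_table(report$stage_summary),
       reproduction = .summary_table(report$repro_summary))
}

#' Write the report's files to a directory
#'
#' Emits `schedule_<treatment>.csv` (x, lx, mx at full precision),
#' `params.csv`, `stage_summary.csv`, `repro_summary.csv` and a
#' machine-readable `results.json` with the unrounded numbers.
#'
#' @param report An `analysis_report`.
#' @param out_dir Output directory (created if missing).
#' @return Invisibly, the paths written.
#' @export
write_report <- function(report, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character()
  for (tr in report$treatments) {
    p <- file.path(out_dir, paste0("schedule_", gsub("[^A-Za-z0-9_-]", "_", tr),
                                   ".csv"))
    export_schedule(report$schedules[[tr]], p)
    paths <- c(paths, p)
  }
  tabs <- render_tables(report)
  for (nm in names(tabs)) {
    p <- file.path(out_dir, paste0(
      c(params = "params", stages = "stage_summary",
        reproduction = "repro_summary")[nm], ".csv"))
    con <- file(p, open = "wb")
    utils::write.csv(tabs[[nm]], con, row.names = FALSE, eol = "\n")
    close(con)
    paths <- c(paths, p)
  }
  bundle <- list(
    provenance = report$provenance,
    parameters = lapply(report$jackknife, function(jk) {
      lapply(jk, function(e) list(estimate = e$theta_jack, se = e$se,
                                  theta_all = e$theta_all, n = e$n_used))
    }),
    comparisons = if (is.null(report$comparisons)) NULL else
      lapply(report$comparisons, function(cmp) cmp$table))
  p <- file.path(out_dir, "results.json")
  jsonlite::write_json(bundle, p, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  paths <- c(paths, p)
  invisible(paths)
}

#' Plot survival and fecundity curves
#'
#' One panel per treatment: lx on the left axis (0-1), mx on the right axis,
#' against age in days. The underlying numbers are always written as a CSV
#' next to the figures so downstream checks never inspect pixels.
#'
#' @param schedules Named list of `life_schedule` objects.
#' @param out_dir Output directory.
#' @param format `"png"` or `"svg"`.
#' @return Invisibly, the paths written (CSV first).
#' @export
plot_schedules <- function(schedules, out_dir, format = c("png", "svg")) {
  format <- match.arg(format)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (inherits(schedules, "life_schedule")) {
    schedules <- list(schedule = schedules)
  }
  rows <- do.call(rbind, lapply(names(schedules), function(tr) {
    cbind(treatment = tr, export_schedule(schedules[[tr]]))
  }))
  csv <- file.path(out_dir, "schedule_curves.csv")
  con <- file(csv, open = "wb")
  utils::write.csv(rows, con, row.names = FALSE, eol = "\n")
  close(con)
  paths <- csv
  for (tr in names(schedules)) {
    sc <- schedules[[tr]]
    p <- file.path(out_dir, paste0("curves_", gsub("[^A-Za-z0-9_-]", "_", tr),
                                   ".", format))
    if (format == "png") grDevices::png(p, 800, 500) else
      grDevices::svg(p, 8, 5)
    op <- graphics::par(mar = c(4.5, 4.5, 2.5, 4.5))
    graphics::plot(sc$ages, sc$lx, type = "s", ylim = c(0, 1), col = "black",
                   xlab = "Age (days)", ylab = expression(l[x]), main = tr)
    graphics::par(new = TRUE)
    graphics::plot(sc$ages, sc$mx, type = "h", col = "firebrick", axes = FALSE,
                   xlab = "", ylab = "")
    graphics::axis(4, col.axis = "firebrick")
    graphics::mtext(expression(m[x]), side = 4, line = 3, col = "firebrick")
    graphics::par(op)
    grDevices::dev.off()
    paths <- c(paths, p)
  }
  invisible(paths)
}
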