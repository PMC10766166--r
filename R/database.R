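new_sdtm_database <- function(study_ids, datasets, directives, codelists_by_study,
                              config = list(), report = empty_report(),
                              n_source_values = NA_integer_) {
  structure(
    list(study_ids = study_ids, datasets = datasets, directives = directives,
         codelists_by_study = codelists_by_study, config = config,
         report = report, n_source_values = n_source_values),
    class = "sdtm_database"
  )
}

#' @export
print.sdtm_database <- function(x, ...) {
  cat(sprintf("<sdtm_database> %s\n", paste(x$study_ids, collapse = " + ")))
  for (d in names(x$datasets)) {
    cat(sprintf("  %-8s %4d rows x %d variables\n", d, nrow(x$datasets[[d]]), ncol(x$datasets[[d]])))
  }
  if (nrow(x$report)) cat(sprintf("  %d row-level error(s) in the run report\n", nrow(x$report)))
  invisible(x)
}

#' Tidy summaries of an SDTM database
#'
#' `tidy()` returns one row per domain dataset (row, variable and subject
#' counts); `glance()` returns a one-row overview of the whole database.
#'
#' @param x An `sdtm_database`.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.sdtm_database <- function(x, ...) {
  purrr::list_rbind(imap(x$datasets, function(ds, d) {
    tibble(domain = d, class = classify_domain(d), n_rows = nrow(ds),
           n_variables = ncol(ds), n_subjects = n_distinct(ds$USUBJID))
  }))
}

#' @rdname tidy.sdtm_database
#' @export
glance.sdtm_database <- function(x, ...) {
  subjects <- unique(unlist(map(x$datasets, ~ .x$USUBJID)))
  tibble(
    n_studies = length(x$study_ids),
    n_domains = length(x$datasets),
    n_rows = sum(map_int(x$datasets, nrow)),
    n_subjects = length(subjects),
    n_errors = nrow(x$report)
  )
}

#' Plot the shape of an SDTM database
#'
#' Bar chart of row counts per domain dataset, filled by SDTM observation
#' class — a quick visual check that a conversion produced the expected
#' domains in the expected proportions.
#'
#' @param object An `sdtm_database`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.sdtm_database <- function(object, ...) {
  df <- tidy.sdtm_database(object)
  ggplot2::ggplot(df, ggplot2::aes(x = stats::reorder(.data$domain, -.data$n_rows),
                                   y = .data$n_rows, fill = .data$class)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "SDTM domain", y = "Rows", fill = "Class",
                  title = paste(object$study_ids, collapse = " + ")) +
    ggplot2::theme_minimal()
}

#' Write an SDTM database to disk
#'
#' Writes one RFC 4180 CSV per domain (`<DOMAIN>.csv`, UTF-8, header row =
#' the ordered variable list), the Define-XML 2.0 document (`define.xml`),
#' and a plain-text run report listing row counts and any row-level errors.
#'
#' @param db An `sdtm_database`.
#' @param dir Output directory (created if absent).
#' @return Invisibly, the paths written.
#' @export
write_sdtm <- function(db, dir) {
  stopifnot(inherits(db, "sdtm_database"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character()
  for (d in names(db$datasets)) {
    p <- file.path(dir, paste0(d, ".csv"))
    readr::write_csv(db$datasets[[d]], p, na = "")
    paths <- c(paths, p)
  }
  define_path <- file.path(dir, "define.xml")
  writeLines(write_define(db), define_path, useBytes = TRUE)
  report_path <- file.path(dir, "run-report.txt")
  writeLines(format_run_report(db), report_path)
  invisible(c(paths, define_path, report_path))
}

format_run_report <- function(db) {
  lines <- c(
    sprintf("SDTM conversion report: %s", paste(db$study_ids, collapse = " + ")),
    sprintf("domains: %d, rows: %d, row-level errors: %d",
            length(db$datasets), sum(map_int(db$datasets, nrow)), nrow(db$report)),
    map_chr(names(db$datasets), ~ sprintf("  %s: %d rows", .x, nrow(db$datasets[[.x]])))
  )
  if (nrow(db$report)) {
    lines <- c(lines, "errors:",
               sprintf("  [%s] %s subject=%s oid=%s: %s",
                       db$report$kind, db$report$domain, db$report$subject_key,
                       db$report$oid, db$report$detail))
  }
  lines
}
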