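# ---- value annotation and normalization ------------------------------------

# Join the long record table with the directive table and normalize every
# value: dates to ISO 8601, coded values through their code list, everything
# else trimmed. Row-level failures (unmapped codes, bad dates) abort the
# value, not the run; they are returned as an error table for the run report.
annotate_values <- function(records, directives, codelists, dialect = "auto") {
  vals <- records |>
    inner_join(directives, by = c(item_oid = "source_oid")) |>
    filter(!is.na(.data$value), nzchar(str_trim(.data$value)))
  if (nrow(vals) == 0) {
    return(list(values = vals |> mutate(norm = character(0)), errors = empty_report()))
  }
  is_date <- vals$data_type == "date" | grepl("DTC$", vals$variable) |
    (!is.na(vals$testcode) & grepl("(DATE|DTC)$", vals$testcode))
  errors <- list()
  norm <- character(nrow(vals))
  keep <- logical(nrow(vals))
  for (i in seq_len(nrow(vals))) {
    res <- tryCatch({
      if (is_date[i]) {
        iso8601_one(vals$value[i], dialect)
      } else if (!is.na(vals$codelist_ref[i])) {
        cl <- codelists[[vals$codelist_ref[i]]]
        if (is.null(cl)) {
          stop_sdtm("sdtm_config_error", sprintf("codelist %s not supplied", vals$codelist_ref[i]))
        }
        recode(vals$value[i], cl, subject_key = vals$subject_key[i])
      } else {
        str_trim(vals$value[i])
      }
    }, sdtmbridge_error = function(e) e)
    if (inherits(res, "condition")) {
      errors[[length(errors) + 1L]] <- tibble(
        kind = class(res)[1], domain = vals$domain[i], subject_key = vals$subject_key[i],
        oid = vals$item_oid[i], raw = vals$value[i], detail = conditionMessage(res)
      )
    } else {
      norm[i] <- res
      keep[i] <- TRUE
    }
  }
  vals$norm <- norm
  list(values = vals[keep, ],
       errors = if (length(errors)) purrr::list_rbind(errors) else empty_report())
}

empty_report <- function() {
  tibble(kind = character(), domain = character(), subject_key = character(),
         oid = character(), raw = character(), detail = character())
}

# Grouping key for one logical record: all directives sharing
# (domain, testcode) for a given (subject, repeat) populate one row.
# Special-purpose domains are subject-level (repeat and testcode ignored).
with_record_key <- function(values) {
  cls <- unname(classify_domain_vec(values$domain))
  mutate(values,
         .class = cls,
         .key_repeat = ifelse(cls == "special_purpose", 1L, .data$repeat_key),
         .key_test = ifelse(cls == "special_purpose", "", .data$testcode))
}

classify_domain_vec <- function(domain) {
  u <- unique(domain)
  stats::setNames(classify_domain(u), u)[domain]
}

# Two source fields competing for the same logical cell is a mapping defect.
# Identical values from the *same* field repeated at the subject level
# collapse silently (a vertical study restates sex at every visit).
screen_collisions <- function(values) {
  if (nrow(values) == 0) {
    return(list(values = values, errors = empty_report()))
  }
  grouped <- values |>
    group_by(.data$subject_key, .data$domain, .data$.key_repeat, .data$.key_test, .data$variable) |>
    summarise(
      n_oid = n_distinct(.data$item_oid), n_val = n_distinct(.data$norm),
      oids = paste(unique(.data$item_oid), collapse = ", "),
      .groups = "drop"
    )
  bad <- filter(grouped, .data$n_oid > 1 | .data$n_val > 1)
  errors <- if (nrow(bad)) {
    tibble(kind = "sdtm_collision", domain = bad$domain, subject_key = bad$subject_key,
           oid = bad$oids, raw = NA_character_,
           detail = sprintf("source fields %s compete for %s.%s", bad$oids, bad$domain, bad$variable))
  } else {
    empty_report()
  }
  clean <- values |>
    anti_join(bad, by = c("subject_key", "domain", ".key_repeat", ".key_test", "variable")) |>
    distinct(.data$subject_key, .data$domain, .data$.key_repeat, .data$.key_test,
             .data$variable, .keep_all = TRUE)
  list(values = clean, errors = errors)
}

abort_on_collision <- function(screened) {
  if (nrow(screened$errors)) {
    e <- screened$errors[1, ]
    stop_sdtm("sdtm_collision", e$detail, oids = e$oid)
  }
  screened$values
}

# ---- row constructors by domain class --------------------------------------

rows_special <- function(values, study_id) {
  if (nrow(values) == 0) return(NULL)
  values |>
    select(".subject" = "subject_key", "variable", "norm") |>
    tidyr::pivot_wider(names_from = "variable", values_from = "norm") |>
    mutate(USUBJID = make_usubjid(study_id, .data$.subject),
           .key_repeat = 1L, .key_test = "", .oid = "")
}

rows_keyed <- function(values, topic_var, topic_value = function(tc) tc) {
  # findings/interventions/events share one shape: rows keyed by
  # (subject, repeat, testcode), each directive filling its own variable
  values |>
    group_by(".subject" = .data$subject_key, .data$.key_repeat, .data$.key_test) |>
    summarise(
      .oid = min(.data$item_oid),
      data = list(stats::setNames(.data$norm, .data$variable)),
      .groups = "drop"
    ) |>
    mutate(!!topic_var := map_chr(.data$.key_test, topic_value)) |>
    tidyr::unnest_wider("data")
}

rows_supp <- function(values, study_id, domain, qlabels = c()) {
  too_long <- unique(values$testcode[nchar(values$testcode) > 8])
  if (length(too_long)) {
    stop_sdtm("sdtm_name_length",
              sprintf("QNAM token %s exceeds the 8-character SDTM name limit", too_long[1]))
  }
  values |>
    mutate(
      .subject = .data$subject_key,
      .oid = .data$item_oid,
      RDOMAIN = sub("^SUPP", "", domain),
      IDVAR = "", IDVARVAL = "",
      QNAM = .data$testcode,
      QLABEL = map_chr(.data$testcode, ~ unname(qlabels[.x] %||% .x)),
      QVAL = .data$norm
    ) |>
    select(".subject", ".key_repeat", ".key_test", ".oid",
           "RDOMAIN", "IDVAR", "IDVARVAL", "QNAM", "QLABEL", "QVAL")
}

# ---- exported builder surface ----------------------------------------------

#' Build findings-domain rows (horizontal to vertical pivot)
#'
#' Findings domains (LB, VS) are vertical: one row per measurement, keyed by
#' the test code. A horizontal source record holding k annotated test codes
#' therefore yields k rows, and directives that share a test code (e.g. an
#' `LBORRES` field and an `LBDTC` field both coded `CREAT`) fill different
#' variables of the same row.
#'
#' @param records Long record tibble (`subject_key`, `group_oid`,
#'   `repeat_key`, `item_oid`, `value`), e.g. `study$records`.
#' @param directives Directive tibble for a single findings domain.
#' @param codelists Named list of code lists for recoding.
#' @param study_id Study identifier used to derive `USUBJID`.
#' @param dialect Date dialect passed to [to_iso8601()].
#' @param test_labels Optional named vector mapping test codes to `--TEST`
#'   labels; when omitted no `--TEST` column is emitted.
#' @return Tibble of rows with SDTM columns plus internal ordering columns
#'   (prefixed `.`) consumed by [assign_seq()].
#' @export
build_findings_rows <- function(records, directives, codelists, study_id = "STUDY",
                                dialect = "auto", test_labels = NULL) {
  check_one_domain(directives, "findings")
  domain <- directives$domain[1]
  ann <- annotate_values(records, directives, codelists, dialect)
  propagate_first_error(ann$errors)
  values <- abort_on_collision(screen_collisions(with_record_key(ann$values)))
  if (nrow(values) == 0) return(NULL)
  rows <- rows_keyed(values, paste0(domain, "TESTCD"))
  if (!is.null(test_labels)) {
    rows[[paste0(domain, "TEST")]] <-
      map_chr(rows$.key_test, ~ unname(test_labels[.x] %||% .x))
  }
  finalize_domain(rows, domain, study_id)
}

#' Build interventions-domain rows
#'
#' Interventions domains (CM) key rows on the treatment: the annotation's
#' test code token names the treatment, `--TRT` carries it (or a configured
#' display label), occurrence flags are recoded through the NY code list and
#' start dates are ISO-normalized. Directives sharing a test code fill one
#' row.
#'
#' @inheritParams build_findings_rows
#' @param trt_labels Optional named vector mapping treatment codes to
#'   display labels for `--TRT`.
#' @return Tibble of rows with SDTM columns plus internal ordering columns.
#' @export
build_interventions_rows <- function(records, directives, codelists, study_id = "STUDY",
                                     dialect = "auto", trt_labels = NULL) {
  check_one_domain(directives, "interventions")
  build_topic_rows(records, directives, codelists, study_id, dialect, trt_labels, "TRT")
}

build_events_rows <- function(records, directives, codelists, study_id = "STUDY",
                              dialect = "auto", term_labels = NULL) {
  check_one_domain(directives, "events")
  build_topic_rows(records, directives, codelists, study_id, dialect, term_labels, "TERM")
}

build_topic_rows <- function(records, directives, codelists, study_id, dialect, labels, suffix) {
  domain <- directives$domain[1]
  ann <- annotate_values(records, directives, codelists, dialect)
  propagate_first_error(ann$errors)
  values <- abort_on_collision(screen_collisions(with_record_key(ann$values)))
  if (nrow(values) == 0) return(NULL)
  topic <- function(tc) unname((labels %||% c())[tc] %||% tc)
  rows <- rows_keyed(values, paste0(domain, suffix), topic)
  finalize_domain(rows, domain, study_id)
}

#' Build supplemental-qualifier rows
#'
#' Variables with no slot in a standard domain are stored as supplemental
#' qualifiers: one `QNAM`/`QVAL` row per (subject, repeat, test code) with
#' `RDOMAIN` naming the parent domain. Rows link at subject level
#' (`IDVAR`/`IDVARVAL` empty). `QNAM` tokens are limited to 8 characters by
#' the SDTM naming rule.
#'
#' @inheritParams build_findings_rows
#' @param qlabels Named vector mapping `QNAM` tokens to `QLABEL` text.
#' @return Tibble of rows with SDTM columns plus internal ordering columns.
#' @export
build_supplemental_rows <- function(records, directives, codelists, study_id = "STUDY",
                                    dialect = "auto", qlabels = c()) {
  check_one_domain(directives, "supplemental")
  domain <- directives$domain[1]
  ann <- annotate_values(records, directives, codelists, dialect)
  propagate_first_error(ann$errors)
  values <- abort_on_collision(screen_collisions(with_record_key(ann$values)))
  if (nrow(values) == 0) return(NULL)
  rows <- rows_supp(values, study_id, domain, qlabels)
  finalize_domain(rows, domain, study_id)
}

check_one_domain <- function(directives, expected_class) {
  if (nrow(directives) == 0) stop_sdtm("sdtm_config_error", "no directives supplied")
  if (n_distinct(directives$domain) != 1) {
    stop_sdtm("sdtm_config_error", "directives must share a single target domain")
  }
  cls <- classify_domain(directives$domain[1])
  if (cls != expected_class) {
    stop_sdtm("sdtm_config_error",
              sprintf("domain %s is %s, not %s", directives$domain[1], cls, expected_class))
  }
  validate_directives(directives)
}

propagate_first_error <- function(errors) {
  if (nrow(errors)) {
    stop_sdtm(errors$kind[1], errors$detail[1])
  }
}

# add identifiers and hand over to SEQ assignment
finalize_domain <- function(rows, domain, study_id) {
  rows$STUDYID <- study_id
  rows$DOMAIN <- domain
  if (!"USUBJID" %in% names(rows)) {
    rows$USUBJID <- make_usubjid(study_id, rows$.subject)
  }
  cls <- classify_domain(domain)
  if (cls %in% c("findings", "interventions", "events")) {
    rows <- assign_seq(rows, domain)
  }
  rows
}

#' Assign SDTM sequence numbers
#'
#' Numbers each subject's rows 1..n in a deterministic order: source repeat
#' key, then test code alphabetically, then source field oid. Running twice
#' on the same input gives the identical assignment.
#'
#' @param rows Row tibble from one of the `build_*_rows()` functions (must
#'   carry `USUBJID` and the internal `.key_repeat`, `.key_test`, `.oid`
#'   ordering columns).
#' @param domain Domain code; the sequence variable is named `<domain>SEQ`.
#' @return The rows, sorted, with the `--SEQ` column populated.
#' @export
assign_seq <- function(rows, domain) {
  seq_var <- paste0(domain, "SEQ")
  rows |>
    arrange(.data$USUBJID, .data$.key_repeat, .data$.key_test, .data$.oid) |>
    group_by(.data$USUBJID) |>
    mutate(!!seq_var := as.character(row_number())) |>
    ungroup()
}

#' Derive the unique subject identifier
#'
#' `USUBJID` is the study identifier and the within-study subject key joined
#' with a hyphen, which keeps subjects from independently converted studies
#' globally unique after integration.
#'
#' @param study_id Nonempty study identifier.
#' @param subject_key Nonempty within-study subject key(s).
#' @return Character vector of `USUBJID` values.
#' @examples
#' make_usubjid("COHORTA", "001")
#' @export
make_usubjid <- function(study_id, subject_key) {
  if (!is_string(study_id) || !nzchar(study_id)) {
    stop_sdtm("sdtm_validation_error", "study_id must be nonempty")
  }
  subject_key <- as.character(subject_key)
  if (length(subject_key) == 0 || any(is.na(subject_key) | !nzchar(subject_key))) {
    stop_sdtm("sdtm_validation_error", "subject_key must be nonempty")
  }
  paste(study_id, subject_key, sep = "-")
}

# ---- dataset assembly ------------------------------------------------------

# SUPP-- datasets use the SDTMIG fixed column sequence; other domains put
# the identifier block first and the qualifier variables alphabetically.
order_variables <- function(domain, vars) {
  if (startsWith(domain, "SUPP")) {
    fixed <- c("STUDYID", "RDOMAIN", "USUBJID", "IDVAR", "IDVARVAL", "QNAM", "QLABEL", "QVAL")
    return(c(intersect(fixed, vars), sort(setdiff(vars, fixed))))
  }
  lead <- c("STUDYID", "DOMAIN", "USUBJID", paste0(domain, "SEQ"))
  c(intersect(lead, vars), sort(setdiff(vars, lead)))
}

as_dataset <- function(rows, domain) {
  rows <- select(rows, -dplyr::starts_with("."))
  if (startsWith(domain, "SUPP")) rows$DOMAIN <- NULL
  rows <- rows[, order_variables(domain, names(rows)), drop = FALSE]
  mutate(rows, across(dplyr::everything(), na_to_blank))
}

domain_sort <- function(domains) {
  cls_rank <- c(special_purpose = 1, interventions = 2, events = 2, findings = 2, supplemental = 3)
  rank <- cls_rank[classify_domain_vec(domains)]
  domains[order(rank, domains)]
}

#' Convert an annotated study to an SDTM database
#'
#' Runs the full conversion for one study: extracts (or accepts) the mapping
#' directives, normalizes and recodes every annotated value, pivots
#' horizontal records into vertical findings rows, builds interventions,
#' events, supplemental and demographics datasets, assigns `--SEQ`, and
#' collects row-level problems (unmapped codes, unparseable dates, mapping
#' collisions) into a run report instead of aborting.
#'
#' @param study An [odm_study()] object.
#' @param directives Directive tibble; defaults to [study_directives()] of
#'   the study. Must be nonempty.
#' @param codelists Named list of code lists; defaults to the study's own.
#' @param config Optional list: `date_dialect` (default `"auto"`),
#'   `qlabels`, `trt_labels`, `test_labels` (named character vectors).
#' @return An `sdtm_database` object: named list of domain datasets plus the
#'   directive/code-list metadata needed to write Define-XML, and the run
#'   report (`$report`).
#' @export
convert_study <- function(study, directives = NULL, codelists = NULL, config = list()) {
  stopifnot(inherits(study, "odm_study"))
  directives <- directives %||% study_directives(study)
  codelists <- codelists %||% study$codelists
  if (nrow(directives) == 0) {
    stop_sdtm("sdtm_config_error", sprintf("study %s has no annotated fields to map", study$study_id))
  }
  missing_src <- setdiff(directives$source_oid, study$items$oid)
  if (length(missing_src)) {
    stop_sdtm("sdtm_config_error",
              sprintf("directive source oid %s not found in study", missing_src[1]))
  }
  validate_directives(directives)
  dialect <- config$date_dialect %||% "auto"

  ann <- annotate_values(study$records, directives, codelists, dialect)
  screened <- screen_collisions(with_record_key(ann$values))
  values <- screened$values
  report <- bind_rows(ann$errors, screened$errors)

  datasets <- list()
  for (domain in unique(values$domain)) {
    dv <- filter(values, .data$domain == !!domain)
    cls <- classify_domain(domain)
    rows <- switch(
      cls,
      special_purpose = rows_special(dv, study$study_id),
      findings = {
        r <- rows_keyed(dv, paste0(domain, "TESTCD"))
        if (!is.null(config$test_labels)) {
          r[[paste0(domain, "TEST")]] <- map_chr(r$.key_test, ~ unname(config$test_labels[.x] %||% .x))
        }
        r
      },
      interventions = rows_keyed(dv, paste0(domain, "TRT"),
                                 function(tc) unname((config$trt_labels %||% c())[tc] %||% tc)),
      events = rows_keyed(dv, paste0(domain, "TERM"),
                          function(tc) unname((config$trt_labels %||% c())[tc] %||% tc)),
      supplemental = rows_supp(dv, study$study_id, domain, config$qlabels %||% c())
    )
    if (is.null(rows) || nrow(rows) == 0) next
    rows <- finalize_domain(rows, domain, study$study_id)
    datasets[[domain]] <- as_dataset(rows, domain)
  }
  datasets <- datasets[domain_sort(names(datasets))]

  new_sdtm_database(
    study_ids = study$study_id,
    datasets = datasets,
    directives = stats::setNames(list(directives), study$study_id),
    codelists_by_study = stats::setNames(list(codelists), study$study_id),
    config = config,
    report = report,
    n_source_values = nrow(ann$values) + nrow(ann$errors)
  )
}
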