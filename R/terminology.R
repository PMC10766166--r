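#' Construct a code list
#'
#' A code list maps the raw codes a source database used (e.g. `1`/`2` or
#' `0`/`1` for sex) to CDISC submission values (`M`/`F`). Lists of kind
#' `"ct"` target a named CDISC controlled-terminology code list (e.g. `SEX`,
#' `NY`) and their submission values are checked against the built-in CT
#' subset; lists of kind `"custom"` carry study-specific values such as
#' Oxford-classification lesion scores (`M0`/`M1`, `T0`/`T1`/`T2`).
#'
#' @param oid Identifier, unique among a study's code lists.
#' @param entries Named character vector: names are source codes, values are
#'   submission values.
#' @param kind `"ct"` or `"custom"`.
#' @param ct_name For `kind = "ct"`, the controlled-terminology code-list
#'   name (e.g. `"SEX"`).
#' @return A `sdtm_codelist` object.
#' @examples
#' codelist("CL.SEX", c(`1` = "M", `2` = "F"), kind = "ct", ct_name = "SEX")
#' @export
codelist <- function(oid, entries, kind = c("custom", "ct"), ct_name = NULL) {
  kind <- match.arg(kind)
  if (!is_string(oid) || !nzchar(oid)) {
    stop_sdtm("sdtm_config_error", "code list oid must be a nonempty string")
  }
  entries <- stats::setNames(as.character(entries), names(entries))
  if (length(entries) == 0 || is.null(names(entries)) || any(!nzchar(names(entries)))) {
    stop_sdtm("sdtm_config_error", sprintf("code list %s must have named, nonempty entries", oid))
  }
  if (anyDuplicated(names(entries))) {
    stop_sdtm("sdtm_config_error", sprintf("code list %s has duplicate source codes", oid))
  }
  if (kind == "ct") {
    if (!is_string(ct_name)) {
      stop_sdtm("sdtm_config_error", sprintf("code list %s of kind 'ct' needs a ct_name", oid))
    }
    allowed <- builtin_ct()[[ct_name]]
    if (!is.null(allowed) && !all(entries %in% allowed)) {
      bad <- setdiff(unique(entries), allowed)
      stop_sdtm("sdtm_config_error",
                sprintf("code list %s maps to value(s) %s outside CT list %s (%s)",
                        oid, paste(bad, collapse = ", "), ct_name, paste(allowed, collapse = "/")))
    }
  }
  structure(
    list(oid = oid, kind = kind, entries = entries,
         ct_name = if (kind == "ct") ct_name else NULL),
    class = "sdtm_codelist"
  )
}

#' @export
print.sdtm_codelist <- function(x, ...) {
  cat(sprintf("<sdtm_codelist> %s (%s%s): %s\n", x$oid, x$kind,
              if (!is.null(x$ct_name)) paste0(" ", x$ct_name) else "",
              paste(sprintf("%s=%s", names(x$entries), x$entries), collapse = ", ")))
  invisible(x)
}

#' Built-in controlled-terminology subset
#'
#' The minimal CT code lists the converter relies on for validation: `SEX`
#' (M/F/U) and `NY` (Y/N). The full CT catalog is versioned and external;
#' any further lists come from configuration.
#'
#' @return Named list of allowed submission-value vectors.
#' @export
builtin_ct <- function() {
  list(SEX = c("M", "F", "U"), NY = c("Y", "N"))
}

#' Recode a raw source value through a code list
#'
#' Looks up the raw value (after trimming surrounding whitespace) in the
#' code list and returns its submission value. This is how sources that
#' coded male/female as 1/2 and as 0/1 both land on `M`/`F`.
#'
#' @param raw Character vector of raw source codes.
#' @param codelist A `sdtm_codelist`.
#' @param subject_key Optional subject identifier(s) included in the error
#'   condition for audit logging.
#' @return Character vector of submission values.
#' @examples
#' sex <- codelist("CL.SEX", c(`1` = "M", `2` = "F"), kind = "ct", ct_name = "SEX")
#' recode("1", sex)
#' @export
recode <- function(raw, codelist, subject_key = NULL) {
  stopifnot(inherits(codelist, "sdtm_codelist"))
  key <- str_trim(as.character(raw))
  hit <- match(key, names(codelist$entries))
  if (anyNA(hit)) {
    i <- which(is.na(hit))[1]
    stop_sdtm(
      "sdtm_unmapped_code",
      sprintf("value %s is not in code list %s", dQuote(key[i], q = FALSE), codelist$oid),
      codelist_oid = codelist$oid,
      raw_value = key[i],
      subject_key = if (!is.null(subject_key)) as.character(subject_key)[min(i, length(subject_key))] else NA_character_
    )
  }
  unname(codelist$entries[hit])
}

#' Normalize a date string to ISO 8601
#'
#' Source databases store dates in divergent dialects; SDTM `--DTC`
#' variables require ISO 8601. Supported dialects: `"slash"`
#' (`YYYY/MM/DD`), `"hyphen"` (`YYYY-MM-DD`), `"compact"` (`YYYYMMDD`), and
#' `"auto"` which tries all three. Reduced-precision inputs (year-month or
#' year only) yield `YYYY-MM` / `YYYY`. Dates are calendar-validated, so
#' impossible dates like `2021/02/30` are rejected.
#'
#' @param raw Character vector of date strings.
#' @param dialect One of `"auto"`, `"slash"`, `"hyphen"`, `"compact"`.
#' @return Character vector of ISO 8601 dates.
#' @examples
#' to_iso8601("1985/03/12", "slash")
#' to_iso8601("1985/03", "slash")
#' @export
to_iso8601 <- function(raw, dialect = c("auto", "slash", "hyphen", "compact")) {
  dialect <- match.arg(dialect)
  map_chr(as.character(raw), iso8601_one, dialect = dialect)
}

iso8601_one <- function(x, dialect) {
  x <- str_trim(x)
  if (is.na(x) || !nzchar(x)) stop_sdtm("sdtm_date_error", "empty date string", raw_value = x)
  pats <- list(
    slash   = "^(\\d{4})(?:/(\\d{1,2})(?:/(\\d{1,2}))?)?$",
    hyphen  = "^(\\d{4})(?:-(\\d{1,2})(?:-(\\d{1,2}))?)?$",
    compact = "^(\\d{4})(\\d{2})?(\\d{2})?$"
  )
  tried <- if (dialect == "auto") c("hyphen", "slash", "compact") else dialect
  for (d in tried) {
    m <- regmatches(x, regexec(pats[[d]], x))[[1]]
    if (length(m) == 0) next
    y <- m[2]
    mo <- if (length(m) >= 3 && nzchar(m[3])) m[3] else NA
    dy <- if (length(m) >= 4 && nzchar(m[4])) m[4] else NA
    return(validate_iso_parts(x, y, mo, dy))
  }
  stop_sdtm("sdtm_date_error",
            sprintf("date %s does not match the %s dialect", dQuote(x, q = FALSE), dialect),
            raw_value = x)
}

validate_iso_parts <- function(raw, y, mo, dy) {
  if (is.na(mo)) return(y)
  mo_i <- as.integer(mo)
  if (mo_i < 1 || mo_i > 12) {
    stop_sdtm("sdtm_date_error", sprintf("date %s has impossible month", dQuote(raw, q = FALSE)), raw_value = raw)
  }
  if (is.na(dy)) return(sprintf("%s-%02d", y, mo_i))
  iso <- sprintf("%s-%02d-%02d", y, mo_i, as.integer(dy))
  if (is.na(as.Date(iso, format = "%Y-%m-%d"))) {
    stop_sdtm("sdtm_date_error", sprintf("date %s is not a valid calendar date", dQuote(raw, q = FALSE)), raw_value = raw)
  }
  iso
}

#' Load code lists from a YAML configuration
#'
#' The configuration is a YAML document with a top-level `codelists`
#' sequence; each element has `oid`, `kind` (`ct` or `custom`), optional
#' `ct_name`, and an `entries` mapping from source code to submission value.
#' An example ships with the package (`system.file("extdata",
#' "codelists-example.yaml", package = "sdtmbridge")`).
#'
#' @param config Path to a YAML file, or a YAML string.
#' @return Named list of `sdtm_codelist` objects, keyed by oid.
#' @export
load_codelists <- function(config) {
  # keep Y/N/Yes/No literal: submission values must never collapse to logicals
  handlers <- list("bool#yes" = function(x) x, "bool#no" = function(x) x)
  parsed <- tryCatch(
    if (is_string(config) && file.exists(config)) {
      yaml::read_yaml(config, handlers = handlers)
    } else {
      yaml::yaml.load(config, handlers = handlers)
    },
    error = function(e) stop_sdtm("sdtm_config_error", sprintf("cannot parse code-list config: %s", conditionMessage(e)))
  )
  entries <- parsed[["codelists"]]
  if (is.null(entries) || length(entries) == 0) {
    stop_sdtm("sdtm_config_error", "config has no 'codelists' sequence")
  }
  lists <- map(entries, function(e) {
    if (is.null(e$oid) || is.null(e$entries)) {
      stop_sdtm("sdtm_config_error", "each code list needs 'oid' and 'entries'")
    }
    ent <- stats::setNames(as.character(unlist(e$entries)), names(e$entries))
    codelist(e$oid, ent, kind = e$kind %||% "custom", ct_name = e$ct_name)
  })
  oids <- map_chr(lists, "oid")
  if (anyDuplicated(oids)) {
    stop_sdtm("sdtm_config_error",
              sprintf("duplicate code list oid %s in config", oids[duplicated(oids)][1]))
  }
  stats::setNames(lists, oids)
}
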