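#' Parse SDTM mapping annotations
#'
#' A mapping annotation is the dot-separated metadata triple attached to a
#' source field: `DOMAIN.VARIABLE` for variables with a unique meaning per
#' subject (e.g. `DM.SEX`), or `DOMAIN.VARIABLE.TESTCODE` for variables that
#' hold many kinds of values distinguished by a short test code (e.g.
#' `LB.LBORRES.CREAT` for serum creatinine, `VS.VSORRES.SYSBP` for systolic
#' blood pressure). Supplemental-qualifier targets use a `SUPP` + parent
#' domain code with variable `QNAM` (e.g. `SUPPMH.QNAM.OPE`).
#'
#' The parser tolerates the variation seen in hand-entered annotations: an
#' optional leading `IT.` prefix (the ItemDef OID convention), stray
#' whitespace around the dot separators, and lower-case entry. Tokens are
#' upper-cased; the canonical rendering (see [render_annotation()]) never
#' carries the `IT.` prefix.
#'
#' @param text Character vector of raw annotation strings.
#' @return A tibble with one row per annotation and columns `domain`,
#'   `variable`, `testcode` (`NA` for two-token annotations).
#' @examples
#' parse_annotation("IT.VS.VSORRES. SYSBP")
#' parse_annotation(c("DM.SEX", "LB.LBORRES.CREAT"))
#' @export
parse_annotation <- function(text) {
  if (!is.character(text) || length(text) == 0) {
    stop_sdtm("sdtm_annotation_error", "annotation must be a character vector")
  }
  purrr::map(text, parse_annotation_one) |> purrr::list_rbind()
}

parse_annotation_one <- function(txt) {
  if (is.na(txt) || !nzchar(str_trim(txt))) {
    stop_sdtm("sdtm_annotation_error", "empty annotation string")
  }
  tokens <- str_to_upper(str_trim(strsplit(txt, ".", fixed = TRUE)[[1]]))
  tokens <- tokens[nzchar(tokens)]
  if (length(tokens) >= 3 && tokens[[1]] == "IT") {
    tokens <- tokens[-1]
  }
  if (length(tokens) < 2 || length(tokens) > 3) {
    stop_sdtm(
      "sdtm_annotation_error",
      sprintf("annotation %s must have 2 or 3 dot-separated tokens (DOMAIN.VARIABLE[.TESTCODE])", dQuote(txt, q = FALSE))
    )
  }
  domain <- tokens[[1]]
  variable <- tokens[[2]]
  testcode <- if (length(tokens) == 3) tokens[[3]] else NA_character_
  if (!grepl("^[A-Z]{2}$", domain) && !grepl("^SUPP[A-Z]{2}$", domain)) {
    stop_sdtm("sdtm_annotation_error",
              sprintf("annotation %s: %s is not a 2-letter or SUPP-- domain code", dQuote(txt, q = FALSE), domain))
  }
  if (!grepl("^[A-Z][A-Z0-9]*$", variable)) {
    stop_sdtm("sdtm_annotation_error",
              sprintf("annotation %s: variable token %s is not alphanumeric", dQuote(txt, q = FALSE), variable))
  }
  if (!is.na(testcode) && !grepl("^[A-Z0-9]+$", testcode)) {
    stop_sdtm("sdtm_annotation_error",
              sprintf("annotation %s: test code token %s is not alphanumeric", dQuote(txt, q = FALSE), testcode))
  }
  tibble(domain = domain, variable = variable, testcode = testcode)
}

#' Render a mapping directive in canonical form
#'
#' The canonical rendering is `DOMAIN.VARIABLE` or `DOMAIN.VARIABLE.TESTCODE`
#' with no `IT.` prefix and no whitespace; `parse_annotation()` is the left
#' inverse of this function.
#'
#' @param directives A data frame with columns `domain`, `variable`,
#'   `testcode` (as returned by [parse_annotation()] or [study_directives()]).
#' @return Character vector of canonical annotation strings.
#' @export
render_annotation <- function(directives) {
  ifelse(
    is.na(directives$testcode),
    paste(directives$domain, directives$variable, sep = "."),
    paste(directives$domain, directives$variable, directives$testcode, sep = ".")
  )
}

# closed world of implemented parent domains
.sdtm_domain_classes <- c(
  DM = "special_purpose",
  LB = "findings",
  VS = "findings",
  CM = "interventions",
  MH = "events"
)

#' Classify an SDTM domain code
#'
#' Maps each implemented domain code to its SDTM observation class:
#' `DM` is special-purpose, `LB`/`VS` are findings (vertical, one row per
#' measurement keyed by `--TESTCD`), `CM` is interventions, `MH` is events,
#' and `SUPP--` codes are supplemental qualifiers. The world is closed: codes
#' the dataset builder does not implement are rejected rather than guessed
#' at.
#'
#' @param domain Character vector of domain codes (e.g. `"LB"`, `"SUPPDM"`).
#' @return Character vector of classes: one of `special_purpose`, `findings`,
#'   `interventions`, `events`, `supplemental`.
#' @examples
#' classify_domain(c("LB", "SUPPDM"))
#' @export
classify_domain <- function(domain) {
  vapply(domain, function(d) {
    if (!is_string(d)) stop_sdtm("sdtm_unsupported_domain", "domain code must be a string")
    if (grepl("^SUPP[A-Z]{2}$", d)) {
      parent <- sub("^SUPP", "", d)
      if (!parent %in% names(.sdtm_domain_classes)) {
        stop_sdtm("sdtm_unsupported_domain",
                  sprintf("supplemental domain %s refers to unimplemented parent domain %s", d, parent))
      }
      return("supplemental")
    }
    if (!d %in% names(.sdtm_domain_classes)) {
      stop_sdtm("sdtm_unsupported_domain", sprintf("domain code %s is not implemented", d))
    }
    .sdtm_domain_classes[[d]]
  }, character(1), USE.NAMES = FALSE)
}

#' Extract mapping directives from a parsed study
#'
#' Collects the annotated items of an ODM study into a directive table: one
#' row per source field carrying an SDTM mapping triple, joined with the
#' field's code-list reference and declared data type. Fields without an
#' annotation are ignored (they are simply not mapped). Each directive's
#' domain must be classifiable and the structural rules of its class are
#' enforced: findings/interventions/events and supplemental targets need a
#' test code, special-purpose targets must not have one, and supplemental
#' variables must be `QNAM`.
#'
#' @param study An `odm_study` object from [parse_odm()] or
#'   [generate_study()].
#' @return A tibble with columns `source_oid`, `source_name`, `domain`,
#'   `variable`, `testcode`, `codelist_ref`, `data_type`.
#' @export
study_directives <- function(study) {
  stopifnot(inherits(study, "odm_study"))
  annotated <- filter(study$items, !is.na(.data$sdtm_annotation))
  if (nrow(annotated) == 0) {
    return(tibble(
      source_oid = character(), source_name = character(),
      domain = character(), variable = character(), testcode = character(),
      codelist_ref = character(), data_type = character()
    ))
  }
  parsed <- parse_annotation(annotated$sdtm_annotation)
  out <- bind_cols(
    tibble(source_oid = annotated$oid, source_name = annotated$name),
    parsed,
    tibble(codelist_ref = annotated$codelist_ref, data_type = annotated$data_type)
  )
  validate_directives(out)
  out
}

# structural rules shared by study_directives() and convert_study()
validate_directives <- function(directives) {
  cls <- classify_domain(directives$domain)
  needs_tc <- cls %in% c("findings", "interventions", "events", "supplemental")
  missing_tc <- directives[needs_tc & is.na(directives$testcode), ]
  if (nrow(missing_tc) > 0) {
    stop_sdtm("sdtm_config_error",
              sprintf("directive %s requires a test code token", render_annotation(missing_tc)[1]))
  }
  stray_tc <- directives[cls == "special_purpose" & !is.na(directives$testcode), ]
  if (nrow(stray_tc) > 0) {
    stop_sdtm("sdtm_config_error",
              sprintf("special-purpose directive %s must not carry a test code", render_annotation(stray_tc)[1]))
  }
  supp_bad <- directives[cls == "supplemental" & directives$variable != "QNAM", ]
  if (nrow(supp_bad) > 0) {
    stop_sdtm("sdtm_config_error",
              sprintf("supplemental directive %s must use variable QNAM", render_annotation(supp_bad)[1]))
  }
  invisible(directives)
}
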