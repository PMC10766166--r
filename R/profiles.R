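#' Construct a cohort profile
#'
#' A cohort profile describes one source database well enough to synthesize
#' realistic exports from it: its structure (vertical with repeated
#' measurements, or horizontal without), its date dialect, its item
#' templates (local variable name, data type, local code list, SDTM mapping
#' annotation) and its code lists. Profiles exist so that every stage of the
#' pipeline can be exercised without access to patient data.
#'
#' @param study_id Study identifier.
#' @param structure `"vertical_repeating"` or `"horizontal"`.
#' @param date_dialect `"slash"`, `"hyphen"` or `"compact"` — the dialect
#'   the cohort's dates are generated in.
#' @param items Tibble with columns `oid`, `name`, `group_oid`, `repeating`,
#'   `data_type`, `codelist_ref`, `sdtm_annotation`, `value_kind`.
#' @param codelists Named list of [codelist()] objects.
#' @param n_sites Number of sites (descriptive only).
#' @param qlabels Named vector of `QLABEL` texts keyed by `QNAM`.
#' @return A `cohort_profile` object.
#' @export
cohort_profile <- function(study_id, structure = c("horizontal", "vertical_repeating"),
                           date_dialect = c("slash", "hyphen", "compact"),
                           items, codelists = list(), n_sites = 1L, qlabels = c()) {
  structure_kind <- match.arg(structure)
  date_dialect <- match.arg(date_dialect)
  items <- as_tibble(items)
  if (structure_kind == "vertical_repeating" && !any(items$repeating)) {
    stop_sdtm("sdtm_config_error",
              "a vertical_repeating profile needs at least one repeating item group")
  }
  if (structure_kind == "horizontal" && any(items$repeating)) {
    stop_sdtm("sdtm_config_error", "a horizontal profile cannot have repeating groups")
  }
  annotated <- compact_chr(items$sdtm_annotation)
  if (length(annotated)) parse_annotation(annotated) # must all parse
  unresolved <- setdiff(compact_chr(items$codelist_ref), names(codelists))
  if (length(unresolved)) {
    stop_sdtm("sdtm_config_error", sprintf("profile codelist_ref %s unresolved", unresolved[1]))
  }
  structure(
    list(study_id = study_id, structure = structure_kind, date_dialect = date_dialect,
         items = items, codelists = codelists, n_sites = as.integer(n_sites),
         config = list(date_dialect = date_dialect, qlabels = qlabels)),
    class = "cohort_profile"
  )
}

#' @export
print.cohort_profile <- function(x, ...) {
  cat(sprintf("<cohort_profile> %s: %s, %d items (%d annotated), %d code lists, dates '%s'\n",
              x$study_id, x$structure, nrow(x$items),
              length(compact_chr(x$items$sdtm_annotation)), length(x$codelists), x$date_dialect))
  invisible(x)
}

sanitize_oid <- function(name) {
  gsub("^_|_$", "", gsub("[^A-Za-z0-9]+", "_", name))
}

oxford_codelists <- function(identity = FALSE) {
  mk <- function(letter, max_score) {
    vals <- paste0(letter, 0:max_score)
    src <- if (identity) vals else as.character(0:max_score)
    codelist(paste0("CL.OX", letter), stats::setNames(vals, src), kind = "custom")
  }
  out <- list(mk("M", 1), mk("E", 1), mk("S", 1), mk("T", 2))
  stats::setNames(out, map_chr(out, "oid"))
}

default_qlabels <- c(
  OPE = "Tonsillectomy", OPEDATE = "Date of Tonsillectomy",
  M = "Oxford Mesangial Hypercellularity", E = "Oxford Endocapillary Hypercellularity",
  S = "Oxford Segmental Glomerulosclerosis", T = "Oxford Tubular Atrophy/Interstitial Fibrosis",
  FAMHIST = "Family History of Kidney Disease", PULSEN = "Number of Steroid Pulse Therapies"
)

profile_items_from_map <- function(cohort_col, coded_refs) {
  km <- key_item_map()
  rows <- km[!is.na(km[[cohort_col]]), ]
  tibble(
    oid = sanitize_oid(rows[[cohort_col]]),
    name = rows[[cohort_col]],
    data_type = dplyr::case_when(
      startsWith(rows$value_kind, "date") ~ "date",
      startsWith(rows$value_kind, "int") ~ "integer",
      startsWith(rows$value_kind, "num") ~ "float",
      TRUE ~ "code"
    ),
    codelist_ref = dplyr::case_when(
      rows$value_kind == "sex" ~ coded_refs[["sex"]],
      rows$value_kind == "ny" ~ coded_refs[["ny"]],
      rows$value_kind == "oxford_m" ~ "CL.OXM",
      rows$value_kind == "oxford_e" ~ "CL.OXE",
      rows$value_kind == "oxford_s" ~ "CL.OXS",
      rows$value_kind == "oxford_t" ~ "CL.OXT",
      TRUE ~ NA_character_
    ),
    sdtm_annotation = rows$annotation,
    value_kind = rows$value_kind
  )
}

filler_items <- function(n, prefix) {
  if (n <= 0) {
    return(tibble(oid = character(), name = character(), data_type = character(),
                  codelist_ref = character(), sdtm_annotation = character(),
                  value_kind = character()))
  }
  nm <- sprintf("%s_extra_%02d", prefix, seq_len(n))
  tibble(oid = nm, name = nm,
         data_type = rep(c("text", "float"), length.out = n),
         codelist_ref = NA_character_, sdtm_annotation = NA_character_,
         value_kind = rep(c("text_note", "num_filler"), length.out = n))
}

extra_supp_items <- function(famhist_name, pulse_name, ny_ref) {
  tibble(
    oid = sanitize_oid(c(famhist_name, pulse_name)),
    name = c(famhist_name, pulse_name),
    data_type = c("code", "integer"),
    codelist_ref = c(ny_ref, NA_character_),
    sdtm_annotation = c("SUPPDM.QNAM.FAMHIST", "SUPPCM.QNAM.PULSEN"),
    value_kind = c("ny", "int_pulse")
  )
}

#' Built-in cohort profiles
#'
#' Three profiles emulating the structural divergence typical of
#' independently designed cohort databases: cohort A is vertical with
#' repeated measurements (its laboratory and vital-sign fields live in a
#' repeating item group), cohorts B and C are horizontal snapshots. The
#' shared clinical items of [key_item_map()] are embedded verbatim with each
#' cohort's local variable names and availability; the cohorts differ in
#' how they code categorical values (sex 1/2 vs 0/1, yes/no flags 1/0 vs
#' 1/2 vs Y/N, Oxford scores numeric vs literal) and in their date dialects
#' (slash, hyphen, compact). Cohorts A and C additionally carry a
#' family-history item (supplemental qualifier of DM) and a steroid-pulse
#' count (supplemental qualifier of CM). Unannotated filler fields bring the
#' item counts to 20, 18 and 40 — desk-scale stand-ins for real cohorts
#' whose databases hold tens to hundreds of items.
#'
#' @return Named list of three `cohort_profile` objects (`A`, `B`, `C`).
#' @export
builtin_profiles <- function() {
  # cohort A: vertical, slash dates, sex 1/2, flags 1/0, Oxford numeric
  cls_a <- c(
    stats::setNames(list(
      codelist("CL.SEX", c(`1` = "M", `2` = "F"), kind = "ct", ct_name = "SEX"),
      codelist("CL.NY", c(`1` = "Y", `0` = "N"), kind = "ct", ct_name = "NY")
    ), c("CL.SEX", "CL.NY")),
    oxford_codelists()
  )
  items_a <- bind_rows(
    profile_items_from_map("cohort_a", c(sex = "CL.SEX", ny = "CL.NY")),
    extra_supp_items("fam_hist", "pulse_num", "CL.NY"),
    filler_items(1, "a")
  )
  repeating_kinds <- c("num_sbp", "num_creat", "num_egfr", "num_uprot")
  items_a <- items_a |>
    mutate(repeating = .data$value_kind %in% repeating_kinds,
           group_oid = ifelse(.data$repeating, "IG.VISITS", "IG.BASE"))

  # cohort B: horizontal, hyphen dates, sex 0/1, flags 1/2
  cls_b <- c(
    stats::setNames(list(
      codelist("CL.SEX", c(`0` = "M", `1` = "F"), kind = "ct", ct_name = "SEX"),
      codelist("CL.NY", c(`1` = "Y", `2` = "N"), kind = "ct", ct_name = "NY")
    ), c("CL.SEX", "CL.NY")),
    oxford_codelists()
  )
  items_b <- bind_rows(
    profile_items_from_map("cohort_b", c(sex = "CL.SEX", ny = "CL.NY")),
    filler_items(4, "b")
  ) |>
    mutate(repeating = FALSE, group_oid = "IG.MAIN")

  # cohort C: horizontal, compact dates, literal codes for flags and Oxford
  cls_c <- c(
    stats::setNames(list(
      codelist("CL.SEX", c(`1` = "M", `2` = "F"), kind = "ct", ct_name = "SEX"),
      codelist("CL.NY", c(Y = "Y", N = "N"), kind = "ct", ct_name = "NY")
    ), c("CL.SEX", "CL.NY")),
    oxford_codelists(identity = TRUE)
  )
  items_c <- bind_rows(
    profile_items_from_map("cohort_c", c(sex = "CL.SEX", ny = "CL.NY")),
    extra_supp_items("fhx_kidney", "pulse_therapy_n", "CL.NY"),
    filler_items(19, "c")
  ) |>
    mutate(repeating = FALSE, group_oid = "IG.MAIN")

  list(
    A = cohort_profile("COHORTA", "vertical_repeating", "slash", items_a, cls_a,
                       n_sites = 6, qlabels = default_qlabels),
    B = cohort_profile("COHORTB", "horizontal", "hyphen", items_b, cls_b,
                       n_sites = 6, qlabels = default_qlabels),
    C = cohort_profile("COHORTC", "horizontal", "compact", items_c, cls_c,
                       n_sites = 42, qlabels = default_qlabels)
  )
}
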