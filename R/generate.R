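format_date_dialect <- function(d, dialect) {
  format(d, switch(dialect, slash = "%Y/%m/%d", hyphen = "%Y-%m-%d", compact = "%Y%m%d"))
}

random_date <- function(from, to) {
  as.Date(from) + sample.int(as.integer(as.Date(to) - as.Date(from)), 1L)
}

# one synthetic raw value for an item template; ranges are desk-scale
# plausibility, not fitted clinical distributions
gen_value <- function(kind, codelist, dialect) {
  switch(
    kind,
    sex = ,
    ny = ,
    oxford_m = ,
    oxford_e = ,
    oxford_s = ,
    oxford_t = sample(names(codelist$entries), 1L),
    date_birth = format_date_dialect(random_date("1940-01-01", "1990-12-31"), dialect),
    date_biopsy = format_date_dialect(random_date("1995-01-01", "2015-12-31"), dialect),
    date_treat = format_date_dialect(random_date("2000-01-01", "2016-12-31"), dialect),
    num_sbp = as.character(round(stats::runif(1, 90, 180))),
    num_creat = sprintf("%.2f", stats::runif(1, 0.4, 3.0)),
    num_egfr = sprintf("%.1f", stats::runif(1, 15, 120)),
    num_uprot = sprintf("%.2f", stats::runif(1, 0.05, 6)),
    int_age = as.character(sample(18:80, 1L)),
    int_pulse = as.character(sample(0:3, 1L)),
    text_note = sprintf("note %02d", sample.int(99, 1L)),
    num_filler = sprintf("%.1f", stats::runif(1, 0, 100)),
    stop_sdtm("sdtm_config_error", sprintf("unknown value template %s", kind))
  )
}

#' Generate a synthetic ODM study from a cohort profile
#'
#' Draws per-subject values for every item template in the profile: coded
#' items from the profile's own local code lists (so conversion never meets
#' an unmapped code), dates in the cohort's dialect, numeric labs from
#' plausible uniform ranges. Vertical profiles emit 1-3 repeats of their
#' repeating item groups per subject. About 5% of values are missing
#' (the field is simply absent from the export). Deterministic for a fixed
#' seed.
#'
#' @param profile A [cohort_profile()].
#' @param n_subjects Number of subjects (>= 1).
#' @param seed Integer seed.
#' @param missing_rate Probability that any one value is absent
#'   (default 0.05).
#' @param max_repeats Upper bound of the per-subject repeat count for
#'   repeating groups (default 3).
#' @return An [odm_study()] object.
#' @examples
#' study <- generate_study(builtin_profiles()$B, n_subjects = 5, seed = 1)
#' @export
generate_study <- function(profile, n_subjects, seed = 1L, missing_rate = 0.05,
                           max_repeats = 3L) {
  stopifnot(inherits(profile, "cohort_profile"))
  if (!is.numeric(n_subjects) || n_subjects < 1) {
    stop_sdtm("sdtm_config_error", "n_subjects must be >= 1")
  }
  n_subjects <- as.integer(n_subjects)
  items <- profile$items
  withr::with_seed(as.integer(seed), {
    recs <- list()
    for (s in seq_len(n_subjects)) {
      subject <- sprintf("%03d", s)
      groups <- distinct(items, .data$group_oid, .data$repeating)
      for (gi in seq_len(nrow(groups))) {
        g_items <- items[items$group_oid == groups$group_oid[gi], ]
        n_rep <- if (groups$repeating[gi]) sample.int(max_repeats, 1L) else 1L
        for (rk in seq_len(n_rep)) {
          for (ii in seq_len(nrow(g_items))) {
            if (stats::runif(1) < missing_rate) next
            it <- g_items[ii, ]
            cl <- if (!is.na(it$codelist_ref)) profile$codelists[[it$codelist_ref]] else NULL
            recs[[length(recs) + 1L]] <- tibble(
              subject_key = subject, group_oid = it$group_oid, repeat_key = rk,
              item_oid = it$oid, value = gen_value(it$value_kind, cl, profile$date_dialect)
            )
          }
        }
      }
    }
    odm_study(
      profile$study_id,
      select(items, "oid", "name", "data_type", "codelist_ref", "sdtm_annotation",
             "group_oid", "repeating"),
      profile$codelists,
      if (length(recs)) purrr::list_rbind(recs) else NULL
    )
  })
}
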