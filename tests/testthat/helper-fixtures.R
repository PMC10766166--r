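# Fixtures are built in code; nothing is read from disk.

mk_items <- function(...) {
  rows <- list(...)
  purrr::list_rbind(purrr::map(rows, function(r) {
    tibble::tibble(
      oid = r[[1]], name = r[[1]],
      data_type = r[[2]],
      codelist_ref = if (length(r) >= 3 && !is.na(r[[3]])) r[[3]] else NA_character_,
      sdtm_annotation = if (length(r) >= 4 && !is.na(r[[4]])) r[[4]] else NA_character_,
      group_oid = if (length(r) >= 5) r[[5]] else "IG.MAIN",
      repeating = if (length(r) >= 6) r[[6]] else FALSE
    )
  }))
}

mk_records <- function(...) {
  rows <- list(...)
  purrr::list_rbind(purrr::map(rows, function(r) {
    tibble::tibble(subject_key = r[[1]], group_oid = if (length(r) >= 5) r[[5]] else "IG.MAIN",
                   repeat_key = as.integer(if (length(r) >= 4) r[[4]] else 1L),
                   item_oid = r[[2]], value = r[[3]])
  }))
}

sex_list_12 <- function() codelist("CL.SEX", c(`1` = "M", `2` = "F"), kind = "ct", ct_name = "SEX")
sex_list_01 <- function() codelist("CL.SEX", c(`0` = "M", `1` = "F"), kind = "ct", ct_name = "SEX")
ny_list_10 <- function() codelist("CL.NY", c(`1` = "Y", `0` = "N"), kind = "ct", ct_name = "NY")

# A reduced cohort-A-style study: sex, biopsy date, creatinine, eGFR,
# systolic BP, tonsillectomy flag and Oxford M score.
tiny_study <- function(study_id = "T1") {
  items <- mk_items(
    list("sex", "code", "CL.SEX", "DM.SEX"),
    list("date_bx", "date", NA, "LB.LBDTC.BIOPSY"),
    list("creatinine", "float", NA, "LB.LBORRES.CREAT"),
    list("egfr", "float", NA, "LB.LBORRES.EGFR"),
    list("sbp", "float", NA, "VS.VSORRES.SYSBP"),
    list("tonsillectomy", "code", "CL.NY", "SUPPMH.QNAM.OPE"),
    list("ox_m", "code", "CL.OXM", "SUPPMH.QNAM.M")
  )
  cls <- list(
    CL.SEX = sex_list_12(),
    CL.NY = ny_list_10(),
    CL.OXM = codelist("CL.OXM", c(`0` = "M0", `1` = "M1"), kind = "custom")
  )
  records <- mk_records(
    list("001", "sex", "1"),
    list("001", "date_bx", "2005/04/01"),
    list("001", "creatinine", "0.8"),
    list("001", "egfr", "75"),
    list("001", "sbp", "128"),
    list("001", "tonsillectomy", "1"),
    list("001", "ox_m", "1"),
    list("002", "sex", "2"),
    list("002", "creatinine", "1.2"),
    list("002", "sbp", "141")
  )
  odm_study(study_id, items, cls, records)
}

# conservation accounting: non-missing annotated source values
n_annotated_values <- function(study, directives = study_directives(study)) {
  vals <- dplyr::inner_join(study$records, directives, by = c(item_oid = "source_oid"))
  sum(!is.na(vals$value) & nzchar(trimws(vals$value)))
}

# populated cells in the variables the directives target (QVAL for SUPP--)
n_mapped_cells <- function(db) {
  dirs <- dplyr::bind_rows(db$directives)
  total <- 0L
  for (d in names(db$datasets)) {
    ds <- db$datasets[[d]]
    vars <- if (startsWith(d, "SUPP")) "QVAL" else {
      unique(dirs$variable[dirs$domain == d])
    }
    vars <- intersect(vars, names(ds))
    for (v in vars) total <- total + sum(nzchar(ds[[v]]))
  }
  total
}

# naive findings-pivot oracle: enumerate the expected
# (USUBJID, testcode, variable, value) tuples straight from the records
naive_findings_tuples <- function(study, directives = study_directives(study),
                                  dialect = "auto") {
  fin <- directives[classify_domain(directives$domain) == "findings", ]
  vals <- dplyr::inner_join(study$records, fin, by = c(item_oid = "source_oid"))
  vals <- vals[!is.na(vals$value) & nzchar(trimws(vals$value)), ]
  norm <- vapply(seq_len(nrow(vals)), function(i) {
    if (vals$data_type[i] == "date" || grepl("DTC$", vals$variable[i])) {
      to_iso8601(vals$value[i], dialect)
    } else if (!is.na(vals$codelist_ref[i])) {
      recode(vals$value[i], study$codelists[[vals$codelist_ref[i]]])
    } else {
      trimws(vals$value[i])
    }
  }, character(1))
  dplyr::count(
    tibble::tibble(
      usubjid = make_usubjid(study$study_id, vals$subject_key),
      domain = vals$domain, testcode = vals$testcode,
      variable = vals$variable, value = norm
    ),
    usubjid, domain, testcode, variable, value
  )
}

recovered_findings_tuples <- function(db) {
  dirs <- dplyr::bind_rows(db$directives)
  out <- list()
  for (d in unique(dirs$domain[classify_domain(dirs$domain) == "findings"])) {
    ds <- db$datasets[[d]]
    if (is.null(ds)) next
    tc <- ds[[paste0(d, "TESTCD")]]
    for (v in intersect(unique(dirs$variable[dirs$domain == d]), names(ds))) {
      keep <- nzchar(ds[[v]])
      out[[length(out) + 1L]] <- tibble::tibble(
        usubjid = ds$USUBJID[keep], domain = d, testcode = tc[keep],
        variable = v, value = ds[[v]][keep]
      )
    }
  }
  dplyr::count(purrr::list_rbind(out), usubjid, domain, testcode, variable, value)
}

# directive sets reconstructed from the key-item mapping ledger alone
ledger_directives <- function() {
  km <- key_item_map()
  mk <- function(col) {
    rows <- km[!is.na(km[[col]]), ]
    parsed <- parse_annotation(rows$annotation)
    dplyr::bind_cols(
      tibble::tibble(source_oid = rows[[col]], source_name = rows[[col]]),
      parsed,
      tibble::tibble(codelist_ref = NA_character_, data_type = "text")
    )
  }
  list(A = mk("cohort_a"), B = mk("cohort_b"), C = mk("cohort_c"))
}
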