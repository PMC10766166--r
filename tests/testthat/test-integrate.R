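test_that("integrating a single database is the identity up to SEQ renumbering", {
  db <- convert_study(tiny_study(), config = list(date_dialect = "slash"))
  merged <- integrate_studies(list(db))
  expect_identical(names(merged$datasets), names(db$datasets))
  for (d in names(db$datasets)) {
    expect_identical(merged$datasets[[d]], db$datasets[[d]], info = d)
  }
})

test_that("per-domain row counts are conserved across integration", {
  dbs <- purrr::map(c("S1", "S2", "S3"), function(id) {
    convert_study(tiny_study(study_id = id), config = list(date_dialect = "slash"))
  })
  merged <- integrate_studies(dbs)
  for (d in names(merged$datasets)) {
    expect_equal(nrow(merged$datasets[[d]]),
                 sum(purrr::map_int(dbs, ~ if (is.null(.x$datasets[[d]])) 0L else nrow(.x$datasets[[d]]))),
                 info = d)
  }
  expect_equal(nrow(merged$datasets$DM), 6L)
})

test_that("variables are unioned and missing cells stay empty", {
  a <- convert_study(tiny_study("SA"), config = list(date_dialect = "slash"))
  items <- mk_items(list("sex", "code", "CL.SEX", "DM.SEX"),
                    list("age", "integer", NA, "DM.AGE"))
  s <- odm_study("SB", items, list(CL.SEX = sex_list_01()),
                 mk_records(list("001", "sex", "0"), list("001", "age", "44")))
  b <- convert_study(s)
  merged <- integrate_studies(list(a, b))
  dm <- merged$datasets$DM
  expect_true("AGE" %in% names(dm))
  expect_equal(dm$AGE[dm$USUBJID == "SB-001"], "44")
  expect_true(all(dm$AGE[dm$STUDYID == "SA"] == ""))
})

test_that("a shared USUBJID across inputs aborts integration", {
  db <- convert_study(tiny_study("SAME"), config = list(date_dialect = "slash"))
  err <- tryCatch(integrate_studies(list(db, db)), sdtm_integration_error = function(e) e)
  expect_s3_class(err, "sdtm_integration_error")
  expect_match(conditionMessage(err), "SAME-001")
})

test_that("common_items is the exact triple intersection", {
  specs <- ledger_directives()
  report <- common_items(specs)
  expect_s3_class(report, "common_item_report")
  # single study: intersection identity
  solo <- common_items(specs["A"])
  expect_equal(nrow(solo$triples), nrow(dplyr::distinct(specs$A, domain, variable, testcode)))
  # disjoint studies: empty intersection
  x <- specs$A[specs$A$domain == "DM", ]
  y <- specs$A[specs$A$domain == "LB", ]
  expect_equal(nrow(common_items(list(X = x, Y = y))$triples), 0L)
})

test_that("common_items is order-invariant and monotone non-increasing", {
  specs <- ledger_directives()
  n_abc <- nrow(common_items(specs)$triples)
  n_cba <- nrow(common_items(rev(specs))$triples)
  expect_equal(n_abc, n_cba)
  n_ab <- nrow(common_items(specs[c("A", "B")])$triples)
  expect_true(n_abc <= n_ab)
  expect_true(n_ab <= nrow(common_items(specs["A"])$triples))
})

test_that("consistency checking compares code lists by submission-value image", {
  mk_spec <- function(ref) tibble::tibble(
    source_oid = "sex", source_name = "sex", domain = "DM", variable = "SEX",
    testcode = NA_character_, codelist_ref = ref, data_type = "code"
  )
  # sources coded 1/2 and 0/1 both land on M/F: compatible
  none <- check_metadata_consistency(
    list(A = mk_spec("CL.SEX"), B = mk_spec("CL.SEX")),
    list(A = list(CL.SEX = sex_list_12()), B = list(CL.SEX = sex_list_01()))
  )
  expect_equal(nrow(none), 0L)
  # custom lists with different images: one finding
  mk_ox <- function(vals) list(CL.OXM = codelist("CL.OXM", vals, kind = "custom"))
  spec_m <- tibble::tibble(source_oid = "m", source_name = "m", domain = "SUPPMH",
                           variable = "QNAM", testcode = "M",
                           codelist_ref = "CL.OXM", data_type = "code")
  found <- check_metadata_consistency(
    list(A = spec_m, B = spec_m),
    list(A = mk_ox(c(`0` = "M0", `1` = "M1")), B = mk_ox(c(`0` = "M0", `1` = "M1", `2` = "M2")))
  )
  expect_equal(nrow(found), 1L)
  expect_equal(found$check, "codelist_image")
  # identical specs: consistent
  same <- check_metadata_consistency(
    list(A = spec_m, B = spec_m),
    list(A = mk_ox(c(`0` = "M0", `1` = "M1")), B = mk_ox(c(`0` = "M0", `1` = "M1")))
  )
  expect_equal(nrow(same), 0L)
})

test_that("differing data types for a shared item are flagged", {
  mk <- function(type) tibble::tibble(
    source_oid = "age", source_name = "age", domain = "DM", variable = "AGE",
    testcode = NA_character_, codelist_ref = NA_character_, data_type = type
  )
  f <- check_metadata_consistency(list(A = mk("integer"), B = mk("text")),
                                  list(A = list(), B = list()))
  expect_equal(f$check, "data_type")
})
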