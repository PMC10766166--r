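test_that("one horizontal record with k test codes pivots into k findings rows", {
  s <- tiny_study()
  d <- study_directives(s)
  lb <- build_findings_rows(s$records, d[d$domain == "LB" & d$variable == "LBORRES", ],
                            s$codelists, study_id = "T1")
  one <- lb[lb$USUBJID == "T1-001", ]
  expect_equal(nrow(one), 2L)
  expect_setequal(one$LBTESTCD, c("CREAT", "EGFR"))
  expect_equal(one$LBORRES[one$LBTESTCD == "CREAT"], "0.8")
})

test_that("a date-only findings mapping emits its own row with --ORRES empty", {
  s <- tiny_study()
  d <- study_directives(s)
  lb <- build_findings_rows(s$records, d[d$domain == "LB", ], s$codelists, study_id = "T1",
                            dialect = "slash")
  biopsy <- lb[lb$LBTESTCD == "BIOPSY", ]
  expect_equal(nrow(biopsy), 1L)
  expect_equal(biopsy$LBDTC, "2005-04-01")
  expect_true(is.na(biopsy$LBORRES) | !nzchar(biopsy$LBORRES))
})

test_that("vertical repeats of one vital-sign field become sequential rows", {
  items <- mk_items(list("sbp", "float", NA, "VS.VSORRES.SYSBP", "IG.V", TRUE))
  records <- mk_records(
    list("001", "sbp", "120", 1, "IG.V"),
    list("001", "sbp", "131", 2, "IG.V")
  )
  s <- odm_study("A", items, records = records)
  vs <- build_findings_rows(s$records, study_directives(s), s$codelists, study_id = "A")
  expect_equal(nrow(vs), 2L)
  expect_equal(vs$VSTESTCD, c("SYSBP", "SYSBP"))
  expect_equal(vs$VSSEQ, c("1", "2"))
  expect_equal(vs$VSORRES, c("120", "131"))
})

test_that("interventions directives sharing a treatment code fill one row", {
  items <- mk_items(
    list("psl_flag", "code", "CL.NY", "CM.CMOCCUR.PSL"),
    list("psl_start", "date", NA, "CM.CMSTDTC.PSL"),
    list("ras_flag", "code", "CL.NY", "CM.CMOCCUR.RAS")
  )
  records <- mk_records(
    list("001", "psl_flag", "1"),
    list("001", "psl_start", "2005/04/01"),
    list("001", "ras_flag", "0")
  )
  s <- odm_study("A", items, list(CL.NY = ny_list_10()), records)
  cm <- build_interventions_rows(s$records, study_directives(s), s$codelists,
                                 study_id = "A", dialect = "slash")
  expect_equal(nrow(cm), 2L)
  psl <- cm[cm$CMTRT == "PSL", ]
  expect_equal(psl$CMOCCUR, "Y")
  expect_equal(psl$CMSTDTC, "2005-04-01")
  expect_equal(cm$CMOCCUR[cm$CMTRT == "RAS"], "N")
})

test_that("two source fields competing for one cell raise a collision error", {
  items <- mk_items(
    list("flag_a", "code", "CL.NY", "CM.CMOCCUR.PSL"),
    list("flag_b", "code", "CL.NY", "CM.CMOCCUR.PSL")
  )
  records <- mk_records(list("001", "flag_a", "1"), list("001", "flag_b", "0"))
  s <- odm_study("A", items, list(CL.NY = ny_list_10()), records)
  err <- tryCatch(
    build_interventions_rows(s$records, study_directives(s), s$codelists),
    sdtm_collision = function(e) e
  )
  expect_s3_class(err, "sdtm_collision")
  expect_match(conditionMessage(err), "flag_a")
  expect_match(conditionMessage(err), "flag_b")
})

test_that("supplemental qualifiers carry RDOMAIN, QNAM and recoded QVAL", {
  s <- tiny_study()
  d <- study_directives(s)
  supp <- build_supplemental_rows(s$records, d[d$domain == "SUPPMH", ], s$codelists,
                                  study_id = "T1", qlabels = c(OPE = "Tonsillectomy"))
  ope <- supp[supp$QNAM == "OPE", ]
  expect_equal(ope$RDOMAIN, "MH")
  expect_equal(ope$QVAL, "Y")
  expect_equal(ope$QLABEL, "Tonsillectomy")
  expect_equal(ope$IDVAR, "")
  m <- supp[supp$QNAM == "M", ]
  expect_equal(m$QVAL, "M1") # custom Oxford list
})

test_that("QNAM tokens longer than 8 characters violate the SDTM name rule", {
  items <- mk_items(list("x", "text", NA, "SUPPMH.QNAM.OPEDATEXX"))
  records <- mk_records(list("001", "x", "v"))
  s <- odm_study("A", items, records = records)
  expect_error(
    build_supplemental_rows(s$records, study_directives(s), s$codelists),
    class = "sdtm_name_length"
  )
})

test_that("sequence numbers restart per subject and are deterministic", {
  items <- mk_items(
    list("creat", "float", NA, "LB.LBORRES.CREAT"),
    list("egfr", "float", NA, "LB.LBORRES.EGFR")
  )
  records <- mk_records(
    list("002", "creat", "1.0"),
    list("001", "creat", "0.9"),
    list("001", "egfr", "80")
  )
  s <- odm_study("A", items, records = records)
  r1 <- build_findings_rows(s$records, study_directives(s), s$codelists, study_id = "A")
  r2 <- build_findings_rows(s$records, study_directives(s), s$codelists, study_id = "A")
  expect_identical(r1, r2)
  expect_equal(r1$LBSEQ[r1$USUBJID == "A-001"], c("1", "2"))
  expect_equal(r1$LBSEQ[r1$USUBJID == "A-002"], "1")
})

test_that("usubjid derivation is prefix-injective and rejects empty parts", {
  expect_equal(make_usubjid("COHORTA", "001"), "COHORTA-001")
  expect_equal(length(unique(make_usubjid("S", sprintf("%03d", 1:50)))), 50L)
  expect_error(make_usubjid("", "001"), class = "sdtm_validation_error")
  expect_error(make_usubjid("S", ""), class = "sdtm_validation_error")
})

test_that("a study mapped only to DM yields a single one-row-per-subject dataset", {
  items <- mk_items(list("sex", "code", "CL.SEX", "DM.SEX"))
  records <- mk_records(list("001", "sex", "1"), list("002", "sex", "2"), list("003", "sex", "1"))
  s <- odm_study("S", items, list(CL.SEX = sex_list_12()), records)
  db <- convert_study(s)
  expect_named(db$datasets, "DM")
  expect_equal(nrow(db$datasets$DM), 3L)
  expect_equal(db$datasets$DM$SEX, c("M", "F", "M"))
  expect_equal(anyDuplicated(db$datasets$DM$USUBJID), 0L)
})

test_that("converting a study with no annotated fields is a configuration error", {
  items <- mk_items(list("note", "text"))
  s <- odm_study("S", items, records = mk_records(list("001", "note", "hi")))
  expect_error(convert_study(s), class = "sdtm_config_error")
})

test_that("a reduced cohort-A-style study produces exactly DM, VS, LB and SUPPMH", {
  db <- convert_study(tiny_study(), config = list(date_dialect = "slash"))
  expect_setequal(names(db$datasets), c("DM", "VS", "LB", "SUPPMH"))
  expect_equal(nrow(db$report), 0L)
  # DM cardinality: one row per subject with at least one DM value
  expect_equal(nrow(db$datasets$DM), 2L)
})

test_that("row-level recode and date failures land in the run report, not an abort", {
  items <- mk_items(
    list("sex", "code", "CL.SEX", "DM.SEX"),
    list("dt", "date", NA, "LB.LBDTC.BIOPSY")
  )
  records <- mk_records(
    list("001", "sex", "9"),            # unmapped code
    list("001", "dt", "2021/02/30"),    # impossible date
    list("002", "sex", "2")
  )
  s <- odm_study("S", items, list(CL.SEX = sex_list_12()), records)
  db <- convert_study(s, config = list(date_dialect = "slash"))
  expect_equal(nrow(db$report), 2L)
  expect_setequal(db$report$kind, c("sdtm_unmapped_code", "sdtm_date_error"))
  expect_equal(nrow(db$datasets$DM), 1L) # the clean subject survives
})

test_that("events-class domains build like interventions with an MHTERM topic", {
  items <- mk_items(
    list("gn_flag", "code", "CL.NY", "MH.MHOCCUR.GN"),
    list("gn_date", "date", NA, "MH.MHSTDTC.GN")
  )
  records <- mk_records(list("001", "gn_flag", "1"), list("001", "gn_date", "2003/01/15"))
  s <- odm_study("S", items, list(CL.NY = ny_list_10()), records)
  db <- convert_study(s, config = list(date_dialect = "slash"))
  expect_named(db$datasets, "MH")
  expect_equal(db$datasets$MH$MHTERM, "GN")
  expect_equal(db$datasets$MH$MHOCCUR, "Y")
  expect_equal(db$datasets$MH$MHSTDTC, "2003-01-15")
})

test_that("dataset variables start with the identifier block", {
  db <- convert_study(tiny_study(), config = list(date_dialect = "slash"))
  expect_equal(names(db$datasets$LB)[1:4], c("STUDYID", "DOMAIN", "USUBJID", "LBSEQ"))
  expect_equal(names(db$datasets$SUPPMH),
               c("STUDYID", "RDOMAIN", "USUBJID", "IDVAR", "IDVARVAL", "QNAM", "QLABEL", "QVAL"))
  expect_true(all(db$datasets$LB$DOMAIN == "LB"))
})
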