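minimal_odm <- function() {
  paste0(
    '<ODM xmlns="http://www.cdisc.org/ns/odm/v1.3" FileOID="F1" FileType="Snapshot" ODMVersion="1.3.2">',
    '<Study OID="ST.MINI"><GlobalVariables><StudyName>MINI</StudyName>',
    '<StudyDescription>d</StudyDescription><ProtocolName>MINI</ProtocolName></GlobalVariables>',
    '<MetaDataVersion OID="MDV.1" Name="m">',
    '<ItemGroupDef OID="IG.MAIN" Name="IG.MAIN" Repeating="No"><ItemRef ItemOID="age" Mandatory="No"/></ItemGroupDef>',
    '<ItemDef OID="age" Name="age" DataType="integer"/>',
    "</MetaDataVersion></Study>",
    '<ClinicalData StudyOID="ST.MINI" MetaDataVersionOID="MDV.1">',
    '<SubjectData SubjectKey="001"><StudyEventData StudyEventOID="SE.1"><FormData FormOID="FM.1">',
    '<ItemGroupData ItemGroupOID="IG.MAIN" ItemGroupRepeatKey="1"><ItemData ItemOID="age" Value="42"/></ItemGroupData>',
    "</FormData></StudyEventData></SubjectData></ClinicalData></ODM>"
  )
}

test_that("a minimal ODM document parses into one item and one record", {
  s <- parse_odm(minimal_odm())
  expect_s3_class(s, "odm_study")
  expect_equal(s$study_id, "MINI")
  expect_equal(nrow(s$items), 1L)
  expect_equal(s$items$data_type, "integer")
  expect_equal(nrow(s$records), 1L)
  expect_equal(s$records$value, "42")
})

test_that("repeat keys become distinct records", {
  xml <- sub(
    "</ItemGroupData>",
    paste0("</ItemGroupData>",
           '<ItemGroupData ItemGroupOID="IG.MAIN" ItemGroupRepeatKey="2">',
           '<ItemData ItemOID="age" Value="43"/></ItemGroupData>'),
    minimal_odm(), fixed = TRUE
  )
  s <- parse_odm(xml)
  expect_equal(s$records$repeat_key, c(1L, 2L))
  expect_equal(s$records$value, c("42", "43"))
})

test_that("undeclared item oids in clinical data are an integrity error", {
  xml <- sub('ItemData ItemOID="age"', 'ItemData ItemOID="IT.MISSING"', minimal_odm(), fixed = TRUE)
  err <- tryCatch(parse_odm(xml), sdtm_integrity_error = function(e) e)
  expect_s3_class(err, "sdtm_integrity_error")
  expect_match(conditionMessage(err), "IT.MISSING", fixed = TRUE)
})

test_that("malformed XML and foreign namespaces are rejected", {
  expect_error(parse_odm("<ODM><unclosed>"), class = "sdtm_parse_error")
  other_ns <- sub("/v1.3", "/v1.2", minimal_odm(), fixed = TRUE)
  expect_error(parse_odm(other_ns), class = "sdtm_validation_error")
})

test_that("vendor-extension elements are ignored with a warning", {
  xml <- sub(
    "</MetaDataVersion>",
    '<x:Custom xmlns:x="http://example.org/vendor">z</x:Custom></MetaDataVersion>',
    minimal_odm(), fixed = TRUE
  )
  expect_warning(s <- parse_odm(xml), "vendor")
  expect_equal(nrow(s$items), 1L)
})

test_that("SDTM annotations are read from IT. oids and from SDTM aliases", {
  via_alias <- sub(
    '<ItemDef OID="age" Name="age" DataType="integer"/>',
    '<ItemDef OID="age" Name="age" DataType="integer"><Alias Context="SDTM" Name="DM.AGE"/></ItemDef>',
    minimal_odm(), fixed = TRUE
  )
  expect_equal(parse_odm(via_alias)$items$sdtm_annotation, "DM.AGE")
  via_oid <- gsub('"age"', '"IT.DM.AGE"', minimal_odm(), fixed = TRUE)
  expect_equal(parse_odm(via_oid)$items$sdtm_annotation, "IT.DM.AGE")
  expect_equal(parse_annotation(parse_odm(via_oid)$items$sdtm_annotation)$variable, "AGE")
})

test_that("write then parse is the identity on every component", {
  for (prof in builtin_profiles()) {
    s <- generate_study(prof, n_subjects = 4, seed = 11)
    s2 <- parse_odm(write_odm(s))
    expect_identical(s2$study_id, s$study_id)
    expect_identical(s2$items, s$items)
    expect_identical(s2$codelists, s$codelists)
    expect_identical(s2$records, s$records)
  }
})

test_that("the XML carries exactly one ItemData element per record value", {
  s <- generate_study(builtin_profiles()$A, n_subjects = 6, seed = 3)
  doc <- xml2::read_xml(write_odm(s))
  n_itemdata <- length(xml2::xml_find_all(
    doc, "//odm:ItemData", c(odm = "http://www.cdisc.org/ns/odm/v1.3")
  ))
  expect_equal(n_itemdata, nrow(s$records))
})

test_that("a study with no records serializes to metadata only", {
  items <- mk_items(list("sex", "code", "CL.SEX", "DM.SEX"))
  s <- odm_study("EMPTY", items, list(CL.SEX = sex_list_12()))
  doc <- xml2::read_xml(write_odm(s))
  ns <- c(odm = "http://www.cdisc.org/ns/odm/v1.3")
  expect_equal(length(xml2::xml_find_all(doc, "//odm:MetaDataVersion", ns)), 1L)
  expect_equal(length(xml2::xml_find_all(doc, "//odm:ClinicalData", ns)), 0L)
})

test_that("structural invariants are enforced at construction", {
  items <- mk_items(list("a", "text"), list("a", "text"))
  expect_error(odm_study("S", items), class = "sdtm_validation_error")
  coded <- mk_items(list("c", "code", "CL.GONE"))
  expect_error(odm_study("S", coded, list()), class = "sdtm_validation_error")
  ok <- mk_items(list("a", "text"))
  expect_error(odm_study("", ok), class = "sdtm_validation_error")
  expect_error(odm_study("S", ok, records = mk_records(list("001", "zzz", "1"))),
               class = "sdtm_integrity_error")
})
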