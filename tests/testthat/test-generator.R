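test_that("generation is deterministic: same seed, byte-identical ODM", {
  p <- builtin_profiles()$A
  x1 <- write_odm(generate_study(p, n_subjects = 10, seed = 7))
  x2 <- write_odm(generate_study(p, n_subjects = 10, seed = 7))
  expect_identical(x1, x2)
  x3 <- write_odm(generate_study(p, n_subjects = 10, seed = 8))
  expect_false(identical(x1, x3))
})

test_that("the requested number of subjects is generated", {
  s <- generate_study(builtin_profiles()$B, n_subjects = 5, seed = 1)
  expect_equal(dplyr::n_distinct(s$records$subject_key), 5L)
  expect_error(generate_study(builtin_profiles()$B, n_subjects = 0, seed = 1),
               class = "sdtm_config_error")
})

test_that("repeat keys form a 1..k prefix per subject and repeating group", {
  s <- generate_study(builtin_profiles()$A, n_subjects = 8, seed = 3)
  reps <- s$records[s$records$group_oid == "IG.VISITS", ]
  for (sk in unique(reps$subject_key)) {
    ks <- sort(unique(reps$repeat_key[reps$subject_key == sk]))
    expect_identical(ks, seq_len(max(ks)), info = sk)
    expect_true(max(ks) <= 3)
  }
  # horizontal cohorts never repeat
  sb <- generate_study(builtin_profiles()$B, n_subjects = 8, seed = 3)
  expect_true(all(sb$records$repeat_key == 1L))
})

test_that("profiles embed the ledger's local names and per-cohort availability", {
  p <- builtin_profiles()
  a_ann <- p$A$items$sdtm_annotation
  expect_true("SUPPMH.QNAM.OPEDATE" %in% a_ann)
  expect_equal(p$A$items$name[match("SUPPMH.QNAM.OPEDATE", a_ann)], "tonsillectomy_dt")
  # cohort B collects no serum creatinine
  expect_false("LB.LBORRES.CREAT" %in% p$B$items$sdtm_annotation)
  expect_true("LB.LBORRES.CREAT" %in% p$C$items$sdtm_annotation)
  # all three cohorts collect systolic blood pressure
  for (prof in p) {
    expect_true("VS.VSORRES.SYSBP" %in% prof$items$sdtm_annotation)
  }
  expect_equal(purrr::map_int(p, ~ nrow(.x$items)), c(A = 20L, B = 18L, C = 40L))
  expect_equal(p$A$structure, "vertical_repeating")
  expect_equal(p$B$structure, "horizontal")
  expect_equal(p$C$structure, "horizontal")
})

test_that("profile invariants are enforced", {
  items <- mk_items(list("x", "text"))
  items$value_kind <- "text_note"
  expect_error(
    cohort_profile("P", "vertical_repeating", "slash", items),
    class = "sdtm_config_error"
  )
  bad_ann <- items
  bad_ann$sdtm_annotation <- "nonsense"
  expect_error(cohort_profile("P", "horizontal", "slash", bad_ann),
               class = "sdtm_annotation_error")
})

test_that("every generated study converts without unmapped-code errors", {
  p <- builtin_profiles()
  for (nm in names(p)) {
    db <- convert_study(generate_study(p[[nm]], n_subjects = 6, seed = 17),
                        config = p[[nm]]$config)
    expect_equal(nrow(db$report), 0L, info = nm)
  }
})

test_that("converted and integrated profiles exercise every implemented dataset shape", {
  p <- builtin_profiles()
  dbs <- purrr::map(p, ~ convert_study(generate_study(.x, n_subjects = 6, seed = 29),
                                       config = .x$config))
  merged <- integrate_studies(unname(dbs))
  classes <- unique(classify_domain(names(merged$datasets)))
  expect_setequal(classes, c("special_purpose", "findings", "interventions", "supplemental"))
  # the events class is reachable through SUPPMH's parent-domain taxonomy
  expect_equal(classify_domain(sub("^SUPP", "", "SUPPMH")), "events")
})
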