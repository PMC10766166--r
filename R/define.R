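DEF_NS <- "http://www.cdisc.org/ns/def/v2.0"

dataset_label <- function(domain) {
  labels <- c(DM = "Demographics", CM = "Concomitant Medications",
              LB = "Laboratory Test Results", VS = "Vital Signs",
              MH = "Medical History")
  if (startsWith(domain, "SUPP")) {
    return(sprintf("Supplemental Qualifiers for %s", sub("^SUPP", "", domain)))
  }
  unname(labels[domain] %||% domain)
}

dataset_class_label <- function(domain) {
  switch(classify_domain(domain),
         special_purpose = "SPECIAL PURPOSE",
         findings = "FINDINGS",
         interventions = "INTERVENTIONS",
         events = "EVENTS",
         supplemental = "RELATIONSHIP")
}

dataset_structure <- function(domain) {
  switch(classify_domain(domain),
         special_purpose = "One record per subject",
         findings = "One record per test per observation per subject",
         interventions = "One record per treatment per subject",
         events = "One record per event per subject",
         supplemental = "One record per supplemental qualifier per subject")
}

variable_data_type <- function(variable) {
  if (grepl("SEQ$", variable)) return("integer")
  if (grepl("(DTC|STDTC|ENDTC)$", variable) || variable == "BRTHDTC") return("date")
  "text"
}

# one row per directive, with the submission-value image of its code list
merged_directive_meta <- function(db) {
  purrr::list_rbind(imap(db$directives, function(dir, study) {
    cls <- db$codelists_by_study[[study]]
    dir |>
      mutate(
        study = study,
        image = map(.data$codelist_ref, function(ref) {
          if (is.na(ref)) NULL else sort(unique(unname(cls[[ref]]$entries)))
        }),
        ct_name = map_chr(.data$codelist_ref, function(ref) {
          if (is.na(ref)) NA_character_ else (cls[[ref]]$ct_name %||% NA_character_)
        })
      )
  }))
}

# Define-XML code lists carry submission values (what is IN the SDTM data),
# not the per-study source codes, so differently coded sources share one list
define_codelists <- function(meta) {
  coded <- filter(meta, !map_lgl(.data$image, is.null))
  if (nrow(coded) == 0) return(tibble(oid = character(), name = character(), values = list()))
  coded |>
    mutate(cl_oid = ifelse(!is.na(.data$ct_name), paste0("CL.", .data$ct_name),
                           paste0("CL.", .data$domain, ".", .data$variable))) |>
    group_by(oid = .data$cl_oid) |>
    summarise(name = first(ifelse(is.na(.data$ct_name), .data$cl_oid, .data$ct_name)),
              values = list(sort(unique(unlist(.data$image)))), .groups = "drop")
}

#' Write a Define-XML 2.0 metadata document
#'
#' Emits the data-definition document for an SDTM database: one
#' `ItemGroupDef` per domain dataset (with label, structure and class), one
#' `ItemDef` per variable with OID `IT.<DOMAIN>.<VARIABLE>` mirroring the
#' mapping-annotation syntax, value-level metadata (`def:ValueListDef` with
#' per-test-code ItemDefs `IT.<DOMAIN>.<VARIABLE>.<TESTCODE>`) for findings
#' domains, and code lists enumerating the submission values present in the
#' data.
#'
#' @param db An `sdtm_database` with at least one dataset.
#' @return The Define-XML document as a string.
#' @export
write_define <- function(db) {
  stopifnot(inherits(db, "sdtm_database"))
  if (length(db$datasets) == 0) {
    stop_sdtm("sdtm_validation_error", "cannot write Define-XML for an empty database")
  }
  meta <- merged_directive_meta(db)
  cls_tbl <- define_codelists(meta)
  cl_oid_for <- function(domain, variable, testcode) {
    hits <- meta |>
      filter(.data$domain == !!domain, .data$variable == !!variable,
             (is.na(!!testcode) | is.na(.data$testcode) | .data$testcode == !!testcode),
             !map_lgl(.data$image, is.null))
    if (nrow(hits) == 0) return(NA_character_)
    if (!is.na(hits$ct_name[1])) paste0("CL.", hits$ct_name[1]) else paste0("CL.", domain, ".", variable)
  }

  study_label <- paste(db$study_ids, collapse = "+")
  doc <- xml2::xml_new_root(
    "ODM", xmlns = ODM_NS, `xmlns:def` = DEF_NS,
    FileOID = paste0("DEFINE.", study_label),
    FileType = "Snapshot", ODMVersion = "1.3.2",
    CreationDateTime = "2019-01-01T00:00:00"
  )
  st <- xml2::xml_add_child(doc, "Study", OID = paste0("ST.", study_label))
  gv <- xml2::xml_add_child(st, "GlobalVariables")
  xml2::xml_add_child(gv, "StudyName", study_label)
  xml2::xml_add_child(gv, "StudyDescription", paste("SDTM database:", study_label))
  xml2::xml_add_child(gv, "ProtocolName", study_label)
  mdv <- xml2::xml_add_child(st, "MetaDataVersion", OID = "MDV.DEFINE.1",
                             Name = "Define metadata",
                             `def:DefineVersion` = "2.0.0",
                             `def:StandardName` = "SDTM-IG",
                             `def:StandardVersion` = "3.2")

  # value-level metadata for findings domains only
  findings_vl <- meta |>
    filter(classify_domain_vec(.data$domain) == "findings", !is.na(.data$testcode)) |>
    distinct(.data$domain, .data$variable, .data$testcode)
  vl_groups <- findings_vl |> distinct(.data$domain, .data$variable)
  for (i in seq_len(nrow(vl_groups))) {
    d <- vl_groups$domain[i]; v <- vl_groups$variable[i]
    vld <- xml2::xml_add_child(mdv, "def:ValueListDef", OID = sprintf("VL.%s.%s", d, v))
    tcs <- sort(findings_vl$testcode[findings_vl$domain == d & findings_vl$variable == v])
    for (k in seq_along(tcs)) {
      xml2::xml_add_child(vld, "ItemRef", ItemOID = sprintf("IT.%s.%s.%s", d, v, tcs[k]),
                          OrderNumber = as.character(k), Mandatory = "No")
    }
  }

  for (d in names(db$datasets)) {
    ds <- db$datasets[[d]]
    igd <- xml2::xml_add_child(
      mdv, "ItemGroupDef", OID = paste0("IG.", d), Name = d,
      Repeating = if (classify_domain(d) %in% c("findings", "interventions", "events", "supplemental")) "Yes" else "No",
      IsReferenceData = "No", SASDatasetName = d,
      Domain = if (startsWith(d, "SUPP")) sub("^SUPP", "", d) else d,
      Purpose = "Tabulation",
      `def:Structure` = dataset_structure(d),
      `def:Class` = dataset_class_label(d)
    )
    desc <- xml2::xml_add_child(igd, "Description")
    xml2::xml_add_child(desc, "TranslatedText", dataset_label(d), `xml:lang` = "en")
    for (k in seq_along(names(ds))) {
      xml2::xml_add_child(igd, "ItemRef", ItemOID = sprintf("IT.%s.%s", d, names(ds)[k]),
                          OrderNumber = as.character(k), Mandatory = "No")
    }
  }

  for (d in names(db$datasets)) {
    ds <- db$datasets[[d]]
    for (v in names(ds)) {
      it <- xml2::xml_add_child(mdv, "ItemDef", OID = sprintf("IT.%s.%s", d, v),
                                Name = v, DataType = variable_data_type(v))
      has_vl <- nrow(vl_groups) > 0 && any(vl_groups$domain == d & vl_groups$variable == v)
      cl_oid <- cl_oid_for(d, v, NA_character_)
      if (!has_vl && !is.na(cl_oid)) {
        xml2::xml_add_child(it, "CodeListRef", CodeListOID = cl_oid)
      }
      if (has_vl) {
        xml2::xml_add_child(it, "def:ValueListRef", ValueListOID = sprintf("VL.%s.%s", d, v))
      }
    }
  }
  # value-level ItemDefs
  for (i in seq_len(nrow(findings_vl))) {
    d <- findings_vl$domain[i]; v <- findings_vl$variable[i]; tc <- findings_vl$testcode[i]
    it <- xml2::xml_add_child(mdv, "ItemDef", OID = sprintf("IT.%s.%s.%s", d, v, tc),
                              Name = sprintf("%s (%s)", v, tc),
                              DataType = variable_data_type(v))
    cl_oid <- cl_oid_for(d, v, tc)
    if (!is.na(cl_oid)) xml2::xml_add_child(it, "CodeListRef", CodeListOID = cl_oid)
  }

  for (i in seq_len(nrow(cls_tbl))) {
    cl <- xml2::xml_add_child(mdv, "CodeList", OID = cls_tbl$oid[i],
                              Name = cls_tbl$name[i], DataType = "text")
    for (v in cls_tbl$values[[i]]) {
      xml2::xml_add_child(cl, "EnumeratedItem", CodedValue = v)
    }
  }

  as.character(doc)
}

#' Read the dataset/variable inventory back out of a Define-XML document
#'
#' Utility for cross-checking a Define document against the CSVs it
#' describes: returns the (domain, variable) pairs declared by the
#' `ItemGroupDef`/`ItemRef` elements.
#'
#' @param xml_text Define-XML as a string or file path.
#' @return Tibble with columns `domain` and `variable`, in declaration order.
#' @export
read_define_variables <- function(xml_text) {
  doc <- xml2::read_xml(xml_text)
  ns <- c(odm = ODM_NS, def = DEF_NS)
  igds <- xml2::xml_find_all(doc, ".//odm:ItemGroupDef", ns)
  purrr::list_rbind(map(igds, function(g) {
    refs <- xml2::xml_find_all(g, "./odm:ItemRef", ns)
    oids <- xml2::xml_attr(refs, "ItemOID")
    tibble(domain = xml2::xml_attr(g, "Name"),
           variable = sub(sprintf("^IT\\.%s\\.", xml2::xml_attr(g, "Name")), "", oids))
  }))
}
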