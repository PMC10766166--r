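ODM_NS <- "http://www.cdisc.org/ns/odm/v1.3"

#' Construct an ODM study object
#'
#' In-memory representation of one study's ODM export: the item metadata
#' (with optional SDTM mapping annotations), the code lists, and the
#' clinical data as a long table of per-subject, per-repeat field values.
#' Records are canonically ordered by subject, item group, repeat key and
#' item oid, so that the write/parse round trip is the identity.
#'
#' @param study_id Nonempty study identifier; it prefixes every `USUBJID`.
#' @param items Tibble with columns `oid`, `name`, `data_type` (one of
#'   text/integer/float/date/code), `codelist_ref`, `sdtm_annotation`
#'   (`NA` where absent), and `group_oid` (the item group the field
#'   belongs to) plus logical `repeating`.
#' @param codelists Named list of [codelist()] objects.
#' @param records Tibble with columns `subject_key`, `group_oid`,
#'   `repeat_key` (positive integer, 1 for non-repeating groups),
#'   `item_oid`, `value`.
#' @return An `odm_study` object.
#' @export
odm_study <- function(study_id, items, codelists = list(), records = NULL) {
  if (!is_string(study_id) || !nzchar(study_id)) {
    stop_sdtm("sdtm_validation_error", "study_id must be a nonempty string")
  }
  items <- as_tibble(items)
  needed <- c("oid", "name", "data_type", "codelist_ref", "sdtm_annotation", "group_oid", "repeating")
  missing_cols <- setdiff(needed, names(items))
  if (length(missing_cols)) {
    stop_sdtm("sdtm_validation_error",
              sprintf("items is missing column(s): %s", paste(missing_cols, collapse = ", ")))
  }
  if (anyDuplicated(items$oid)) {
    stop_sdtm("sdtm_validation_error",
              sprintf("duplicate item oid %s", items$oid[duplicated(items$oid)][1]))
  }
  bad_type <- setdiff(unique(items$data_type), c("text", "integer", "float", "date", "code"))
  if (length(bad_type)) {
    stop_sdtm("sdtm_validation_error", sprintf("unknown data_type %s", bad_type[1]))
  }
  no_ref <- items$data_type == "code" & is.na(items$codelist_ref)
  if (any(no_ref)) {
    stop_sdtm("sdtm_validation_error",
              sprintf("coded item %s has no codelist_ref", items$oid[no_ref][1]))
  }
  unresolved <- setdiff(compact_chr(items$codelist_ref), names(codelists))
  if (length(unresolved)) {
    stop_sdtm("sdtm_validation_error",
              sprintf("codelist_ref %s does not resolve to a declared code list", unresolved[1]))
  }
  if (is.null(records)) {
    records <- tibble(subject_key = character(), group_oid = character(),
                      repeat_key = integer(), item_oid = character(), value = character())
  }
  records <- as_tibble(records)
  records$repeat_key <- as.integer(records$repeat_key)
  if (nrow(records)) {
    undeclared <- setdiff(unique(records$item_oid), items$oid)
    if (length(undeclared)) {
      stop_sdtm("sdtm_integrity_error",
                sprintf("ItemData references undeclared item oid %s", dQuote(undeclared[1], q = FALSE)),
                oid = undeclared[1])
    }
    if (any(records$repeat_key < 1L)) {
      stop_sdtm("sdtm_validation_error", "repeat_key must be a positive integer")
    }
    dup <- records |>
      count(.data$subject_key, .data$group_oid, .data$repeat_key, .data$item_oid) |>
      filter(n > 1)
    if (nrow(dup)) {
      stop_sdtm("sdtm_integrity_error",
                sprintf("duplicate value for item %s (subject %s, group %s, repeat %d)",
                        dup$item_oid[1], dup$subject_key[1], dup$group_oid[1], dup$repeat_key[1]))
    }
    records <- arrange(records, .data$subject_key, .data$group_oid, .data$repeat_key, .data$item_oid)
  }
  structure(
    list(study_id = study_id, items = items, codelists = codelists, records = records),
    class = "odm_study"
  )
}

#' @export
print.odm_study <- function(x, ...) {
  n_ann <- sum(!is.na(x$items$sdtm_annotation))
  cat(sprintf("<odm_study> %s: %d items (%d SDTM-annotated), %d code lists, %d values across %d subjects\n",
              x$study_id, nrow(x$items), n_ann, length(x$codelists),
              nrow(x$records), n_distinct(x$records$subject_key)))
  invisible(x)
}

#' Parse a CDISC ODM 1.3 document
#'
#' Reads an ODM 1.3 export carrying study metadata (ItemDefs, ItemGroupDefs,
#' CodeLists) and clinical data (SubjectData/ItemGroupData/ItemData).
#' SDTM mapping annotations are picked up from two conventions: the ItemDef
#' OID itself when it begins with `IT.`, otherwise an ODM `Alias` element
#' with `Context="SDTM"`. Blank `ItemData` values are treated as absent.
#' Elements in foreign (vendor-extension) namespaces are ignored with a
#' warning. Only the ODM 1.3 namespace is accepted.
#'
#' @param xml_text ODM XML as a string, or a path to an XML file.
#' @return An [odm_study()] object.
#' @export
parse_odm <- function(xml_text) {
  doc <- tryCatch(
    xml2::read_xml(xml_text),
    error = function(e) stop_sdtm("sdtm_parse_error", sprintf("malformed XML: %s", conditionMessage(e)))
  )
  root_ns <- xml2::xml_ns(doc)
  if (!ODM_NS %in% unclass(root_ns)) {
    actual <- unclass(root_ns)[["d1"]] %||% "<none>"
    stop_sdtm("sdtm_validation_error",
              sprintf("document namespace %s is not ODM 1.3 (%s); other ODM versions are not supported",
                      actual, ODM_NS))
  }
  ns <- c(odm = ODM_NS)
  foreign <- xml2::xml_find_all(doc, sprintf("//*[namespace-uri() != '%s']", ODM_NS))
  if (length(foreign) > 0) {
    warn(sprintf("ignoring %d element(s) in vendor-extension namespaces", length(foreign)))
  }
  studies <- xml2::xml_find_all(doc, "./odm:Study", ns)
  if (length(studies) != 1) {
    stop_sdtm("sdtm_validation_error", sprintf("expected exactly one Study element, found %d", length(studies)))
  }
  study <- studies[[1]]
  study_oid <- xml2::xml_attr(study, "OID")
  study_id <- sub("^ST\\.", "", study_oid)

  mdv <- xml2::xml_find_first(study, "./odm:MetaDataVersion", ns)
  if (is.na(xml2::xml_name(mdv))) {
    stop_sdtm("sdtm_validation_error", "Study has no MetaDataVersion")
  }

  # item group membership and repeating flag
  group_defs <- xml2::xml_find_all(mdv, "./odm:ItemGroupDef", ns)
  membership <- purrr::list_rbind(map(group_defs, function(g) {
    refs <- xml2::xml_find_all(g, "./odm:ItemRef", ns)
    tibble(
      item_oid = xml2::xml_attr(refs, "ItemOID"),
      group_oid = xml2::xml_attr(g, "OID"),
      repeating = identical(xml2::xml_attr(g, "Repeating"), "Yes")
    )
  }))

  item_defs <- xml2::xml_find_all(mdv, "./odm:ItemDef", ns)
  items <- purrr::list_rbind(map(item_defs, function(it) {
    oid <- xml2::xml_attr(it, "OID")
    clref <- xml2::xml_find_first(it, "./odm:CodeListRef", ns)
    clref <- if (is.na(xml2::xml_name(clref))) NA_character_ else xml2::xml_attr(clref, "CodeListOID")
    alias <- xml2::xml_find_first(it, "./odm:Alias[@Context='SDTM']", ns)
    annotation <- if (!is.na(xml2::xml_name(alias))) {
      xml2::xml_attr(alias, "Name")
    } else if (startsWith(oid, "IT.")) {
      oid
    } else {
      NA_character_
    }
    odm_type <- xml2::xml_attr(it, "DataType")
    data_type <- if (!is.na(clref)) "code" else switch(
      odm_type, integer = "integer", float = "float", date = "date", "text"
    )
    tibble(oid = oid, name = xml2::xml_attr(it, "Name"),
           data_type = data_type, codelist_ref = clref, sdtm_annotation = annotation)
  }))
  if (nrow(items) == 0) {
    items <- tibble(oid = character(), name = character(), data_type = character(),
                    codelist_ref = character(), sdtm_annotation = character())
  }
  if (nrow(membership)) {
    items <- left_join(items, membership, by = c(oid = "item_oid"))
  } else {
    items$group_oid <- NA_character_
    items$repeating <- FALSE
  }
  items$group_oid <- ifelse(is.na(items$group_oid), "IG.DEFAULT", items$group_oid)
  items$repeating <- ifelse(is.na(items$repeating), FALSE, items$repeating)

  cl_nodes <- xml2::xml_find_all(mdv, "./odm:CodeList", ns)
  codelists <- map(cl_nodes, function(cl) {
    cl_items <- xml2::xml_find_all(cl, "./odm:CodeListItem", ns)
    coded <- xml2::xml_attr(cl_items, "CodedValue")
    decoded <- map_chr(cl_items, function(ci) {
      xml2::xml_text(xml2::xml_find_first(ci, "./odm:Decode/odm:TranslatedText", ns))
    })
    ct_alias <- xml2::xml_find_first(cl, "./odm:Alias[@Context='CT']", ns)
    ct_name <- if (is.na(xml2::xml_name(ct_alias))) NULL else xml2::xml_attr(ct_alias, "Name")
    codelist(xml2::xml_attr(cl, "OID"),
             stats::setNames(decoded, coded),
             kind = if (is.null(ct_name)) "custom" else "ct",
             ct_name = ct_name)
  })
  codelists <- stats::setNames(codelists, map_chr(codelists, "oid"))

  subj_nodes <- xml2::xml_find_all(doc, "./odm:ClinicalData/odm:SubjectData", ns)
  records <- purrr::list_rbind(map(subj_nodes, function(sd) {
    igs <- xml2::xml_find_all(sd, ".//odm:ItemGroupData", ns)
    purrr::list_rbind(map(igs, function(ig) {
      idata <- xml2::xml_find_all(ig, "./odm:ItemData", ns)
      rk <- xml2::xml_attr(ig, "ItemGroupRepeatKey")
      tibble(
        subject_key = xml2::xml_attr(sd, "SubjectKey"),
        group_oid = xml2::xml_attr(ig, "ItemGroupOID"),
        repeat_key = if (is.na(rk)) 1L else as.integer(rk),
        item_oid = xml2::xml_attr(idata, "ItemOID"),
        value = xml2::xml_attr(idata, "Value")
      )
    }))
  }))
  if (!is.null(records) && nrow(records)) {
    records <- filter(records, !is.na(.data$value), nzchar(str_trim(.data$value)))
  }
  odm_study(study_id, items, codelists, records)
}

#' Serialize a study to CDISC ODM 1.3 XML
#'
#' Writes the study metadata (item groups, item definitions with their SDTM
#' annotations as `Alias Context="SDTM"` elements, code lists) and the
#' clinical data. `parse_odm(write_odm(s))` reproduces `s` field for field.
#'
#' @param study An [odm_study()] object.
#' @param file Optional path; when given the XML is also written there.
#' @return The XML document as a string, invisibly when `file` is given.
#' @export
write_odm <- function(study, file = NULL) {
  stopifnot(inherits(study, "odm_study"))
  # re-validate via the constructor so callers cannot serialize a corrupted study
  study <- odm_study(study$study_id, study$items, study$codelists, study$records)

  doc <- xml2::xml_new_root(
    "ODM", xmlns = ODM_NS,
    FileOID = paste0("ODM.", study$study_id),
    FileType = "Snapshot",
    ODMVersion = "1.3.2",
    CreationDateTime = "2019-01-01T00:00:00"
  )
  st <- xml2::xml_add_child(doc, "Study", OID = paste0("ST.", study$study_id))
  gv <- xml2::xml_add_child(st, "GlobalVariables")
  xml2::xml_add_child(gv, "StudyName", study$study_id)
  xml2::xml_add_child(gv, "StudyDescription", paste("Export of", study$study_id))
  xml2::xml_add_child(gv, "ProtocolName", study$study_id)
  mdv <- xml2::xml_add_child(st, "MetaDataVersion", OID = "MDV.1", Name = "Metadata")

  groups <- distinct(study$items, .data$group_oid, .data$repeating)
  for (gi in seq_len(nrow(groups))) {
    g <- xml2::xml_add_child(mdv, "ItemGroupDef",
                             OID = groups$group_oid[gi], Name = groups$group_oid[gi],
                             Repeating = if (groups$repeating[gi]) "Yes" else "No")
    in_group <- study$items$oid[study$items$group_oid == groups$group_oid[gi]]
    for (oid in in_group) {
      xml2::xml_add_child(g, "ItemRef", ItemOID = oid, Mandatory = "No")
    }
  }

  for (i in seq_len(nrow(study$items))) {
    row <- study$items[i, ]
    odm_type <- switch(row$data_type, code = "text", text = "text",
                       integer = "integer", float = "float", date = "date")
    it <- xml2::xml_add_child(mdv, "ItemDef", OID = row$oid, Name = row$name, DataType = odm_type)
    if (!is.na(row$codelist_ref)) {
      xml2::xml_add_child(it, "CodeListRef", CodeListOID = row$codelist_ref)
    }
    if (!is.na(row$sdtm_annotation) && !startsWith(row$oid, "IT.")) {
      xml2::xml_add_child(it, "Alias", Context = "SDTM", Name = row$sdtm_annotation)
    }
  }

  for (cl in study$codelists) {
    node <- xml2::xml_add_child(mdv, "CodeList", OID = cl$oid, Name = cl$oid, DataType = "text")
    for (j in seq_along(cl$entries)) {
      ci <- xml2::xml_add_child(node, "CodeListItem", CodedValue = names(cl$entries)[j])
      dec <- xml2::xml_add_child(ci, "Decode")
      xml2::xml_add_child(dec, "TranslatedText", cl$entries[[j]], `xml:lang` = "en")
    }
    if (cl$kind == "ct") {
      xml2::xml_add_child(node, "Alias", Context = "CT", Name = cl$ct_name)
    }
  }

  if (nrow(study$records)) {
    cd <- xml2::xml_add_child(doc, "ClinicalData",
                              StudyOID = paste0("ST.", study$study_id),
                              MetaDataVersionOID = "MDV.1")
    by_subject <- split(study$records, study$records$subject_key)
    for (sk in names(by_subject)) {
      sd <- xml2::xml_add_child(cd, "SubjectData", SubjectKey = sk)
      se <- xml2::xml_add_child(sd, "StudyEventData", StudyEventOID = "SE.1")
      fd <- xml2::xml_add_child(se, "FormData", FormOID = "FM.1")
      recs <- by_subject[[sk]]
      grp <- split(recs, list(recs$group_oid, recs$repeat_key), drop = TRUE)
      # split() orders by factor level; restore canonical (group, repeat) order
      ord <- order(map_chr(grp, ~ .x$group_oid[1]), map_int(grp, ~ .x$repeat_key[1]))
      for (g in grp[ord]) {
        ig <- xml2::xml_add_child(fd, "ItemGroupData",
                                  ItemGroupOID = g$group_oid[1],
                                  ItemGroupRepeatKey = as.character(g$repeat_key[1]))
        for (k in seq_len(nrow(g))) {
          xml2::xml_add_child(ig, "ItemData", ItemOID = g$item_oid[k], Value = g$value[k])
        }
      }
    }
  }

  out <- as.character(doc)
  if (!is.null(file)) {
    writeLines(out, file, useBytes = TRUE)
    return(invisible(out))
  }
  out
}
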