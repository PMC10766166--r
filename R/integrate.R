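#' Integrate several converted studies into one SDTM database
#'
#' Concatenates the domain datasets of independently converted studies:
#' per domain, rows are stacked and the variable sets unioned (cells a study
#' did not collect stay empty), `--SEQ` is reassigned within each subject,
#' and the Define metadata is carried over so a single merged Define-XML can
#' be regenerated. Subjects must be globally unique, which the study-prefixed
#' `USUBJID` guarantees unless two inputs share a study id.
#'
#' @param dbs List of `sdtm_database` objects (at least one).
#' @return One merged `sdtm_database`.
#' @export
integrate_studies <- function(dbs) {
  if (!is.list(dbs) || length(dbs) < 1 || !all(map_lgl(dbs, inherits, "sdtm_database"))) {
    stop_sdtm("sdtm_config_error", "integrate_studies() needs a list of at least one sdtm_database")
  }
  all_subjects <- purrr::list_rbind(imap(dbs, function(db, i) {
    tibble(input = i, usubjid = unique(unlist(map(db$datasets, ~ .x$USUBJID))))
  }))
  dup <- all_subjects |> count(.data$usubjid) |> filter(n > 1)
  if (nrow(dup)) {
    stop_sdtm("sdtm_integration_error",
              sprintf("USUBJID %s occurs in more than one input database", dup$usubjid[1]),
              usubjid = dup$usubjid[1])
  }

  domains <- domain_sort(unique(unlist(map(dbs, ~ names(.x$datasets)))))
  datasets <- stats::setNames(map(domains, function(d) {
    parts <- purrr::compact(map(dbs, ~ .x$datasets[[d]]))
    merged <- bind_rows(parts) |>
      mutate(across(dplyr::everything(), na_to_blank))
    merged <- merged[, order_variables(d, names(merged)), drop = FALSE]
    seq_var <- paste0(d, "SEQ")
    if (seq_var %in% names(merged)) {
      merged <- merged |>
        group_by(.data$USUBJID) |>
        mutate(!!seq_var := as.character(row_number())) |>
        ungroup()
    }
    merged
  }), domains)

  new_sdtm_database(
    study_ids = unlist(map(dbs, "study_ids")),
    datasets = datasets,
    directives = purrr::list_flatten(map(dbs, "directives")),
    codelists_by_study = purrr::list_flatten(map(dbs, "codelists_by_study")),
    config = dbs[[1]]$config,
    report = bind_rows(map(dbs, "report")),
    n_source_values = sum(map_int(dbs, ~ .x$n_source_values %||% NA_integer_))
  )
}

#' Items common to all input studies
#'
#' Before integration the mapping metadata of each study must agree on the
#' items collected by every study. This computes the exact intersection of
#' the (domain, variable, testcode) triples across the per-study directive
#' sets, together with each study's local source-field names for the shared
#' items — the shape of a key-item mapping ledger.
#'
#' @param specs Named list of per-study directive tibbles (from
#'   [study_directives()]), or of `sdtm_database` objects.
#' @return A `common_item_report`: list with `triples` (tibble of shared
#'   triples plus one source-name column per study) and `per_study_counts`.
#' @export
common_items <- function(specs) {
  specs <- as_directive_sets(specs)
  if (length(specs) < 1) stop_sdtm("sdtm_config_error", "at least one study is required")
  triple_sets <- map(specs, function(d) {
    distinct(d, .data$domain, .data$variable, .data$testcode)
  })
  shared <- reduce(triple_sets, function(a, b) {
    inner_join(a, b, by = c("domain", "variable", "testcode"))
  }) |>
    arrange(.data$domain, .data$variable, .data$testcode)
  for (study in names(specs)) {
    names_by_triple <- specs[[study]] |>
      group_by(.data$domain, .data$variable, .data$testcode) |>
      summarise(src = paste(.data$source_name, collapse = "; "), .groups = "drop")
    shared <- left_join(shared, names_by_triple, by = c("domain", "variable", "testcode")) |>
      rename(!!study := "src")
  }
  structure(
    list(
      triples = shared,
      per_study_counts = map_int(triple_sets, nrow)
    ),
    class = "common_item_report"
  )
}

as_directive_sets <- function(specs) {
  if (inherits(specs, "sdtm_database")) specs <- list(specs)
  out <- list()
  for (i in seq_along(specs)) {
    s <- specs[[i]]
    if (inherits(s, "sdtm_database")) {
      for (study in names(s$directives)) out[[study]] <- s$directives[[study]]
    } else {
      nm <- names(specs)[i] %||% paste0("study", i)
      if (!"source_name" %in% names(s)) s$source_name <- s$source_oid
      out[[if (nzchar(nm)) nm else paste0("study", i)]] <- s
    }
  }
  out
}

#' @export
print.common_item_report <- function(x, ...) {
  cat(sprintf("<common_item_report> %d triples common to %d studies (per-study mapped items: %s)\n",
              nrow(x$triples), length(x$per_study_counts),
              paste(sprintf("%s=%d", names(x$per_study_counts), x$per_study_counts), collapse = ", ")))
  print(x$triples)
  invisible(x)
}

#' @rdname tidy.sdtm_database
#' @export
tidy.common_item_report <- function(x, ...) x$triples

#' @rdname tidy.sdtm_database
#' @export
glance.common_item_report <- function(x, ...) {
  tibble(n_common = nrow(x$triples),
         n_studies = length(x$per_study_counts),
         min_mapped = min(x$per_study_counts),
         max_mapped = max(x$per_study_counts))
}

#' Plot which shared items each study collects under which local name
#'
#' Tile plot of the common-item triples against the input studies; tiles are
#' labelled with each study's local variable name for the shared item.
#'
#' @param object A `common_item_report`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.common_item_report <- function(object, ...) {
  studies <- names(object$per_study_counts)
  df <- object$triples |>
    mutate(item = render_annotation(object$triples)) |>
    tidyr::pivot_longer(dplyr::all_of(studies), names_to = "study", values_to = "source_name")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$study, y = .data$item)) +
    ggplot2::geom_tile(fill = "grey90", colour = "white") +
    ggplot2::geom_text(ggplot2::aes(label = .data$source_name), size = 3) +
    ggplot2::labs(x = NULL, y = NULL, title = "Common items across studies") +
    ggplot2::theme_minimal()
}

#' Check metadata consistency across studies
#'
#' For every item common to all studies, verifies that the studies agree on
#' what ends up in the integrated data: the submission-value images of their
#' code lists (sources coded 1/2 and 0/1 for sex are compatible because both
#' recode to M/F) and the declared data types. Disagreements are returned as
#' findings, not raised as errors.
#'
#' @param specs Named list of per-study directive tibbles or
#'   `sdtm_database` objects (at least two studies).
#' @param codelists_by_study Named list (study -> named list of code lists);
#'   inferred automatically when `specs` are databases.
#' @return Tibble of findings: `domain`, `variable`, `testcode`, `check`,
#'   `detail`. Zero rows means the metadata are consistent.
#' @export
check_metadata_consistency <- function(specs, codelists_by_study = NULL) {
  if (is.null(codelists_by_study)) {
    dbs <- if (inherits(specs, "sdtm_database")) list(specs) else specs
    if (all(map_lgl(dbs, inherits, "sdtm_database"))) {
      codelists_by_study <- purrr::list_flatten(map(dbs, "codelists_by_study"))
    } else {
      stop_sdtm("sdtm_config_error", "codelists_by_study is required when specs are directive tables")
    }
  }
  specs <- as_directive_sets(specs)
  if (length(specs) < 2) stop_sdtm("sdtm_config_error", "consistency checking needs at least two studies")
  shared <- common_items(specs)$triples
  findings <- list()
  for (i in seq_len(nrow(shared))) {
    tr <- shared[i, c("domain", "variable", "testcode")]
    per_study <- imap(specs, function(dir, study) {
      hit <- dir |>
        filter(.data$domain == tr$domain, .data$variable == tr$variable,
               (is.na(tr$testcode) & is.na(.data$testcode)) |
                 (!is.na(tr$testcode) & !is.na(.data$testcode) & .data$testcode == tr$testcode))
      ref <- hit$codelist_ref[1]
      image <- if (is.na(ref)) character(0) else {
        sort(unique(unname(codelists_by_study[[study]][[ref]]$entries)))
      }
      list(type = hit$data_type[1], image = image)
    })
    images <- map(per_study, "image")
    if (length(unique(map_chr(images, paste, collapse = "|"))) > 1) {
      findings[[length(findings) + 1L]] <- bind_cols(tr, tibble(
        check = "codelist_image",
        detail = paste(sprintf("%s={%s}", names(per_study),
                               map_chr(images, paste, collapse = ",")), collapse = " vs ")
      ))
    }
    types <- map_chr(per_study, "type")
    if (n_distinct(types) > 1) {
      findings[[length(findings) + 1L]] <- bind_cols(tr, tibble(
        check = "data_type",
        detail = paste(sprintf("%s=%s", names(per_study), types), collapse = " vs ")
      ))
    }
  }
  if (length(findings)) {
    purrr::list_rbind(findings)
  } else {
    tibble(domain = character(), variable = character(), testcode = character(),
           check = character(), detail = character())
  }
}
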