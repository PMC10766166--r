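#' @importFrom rlang %||% abort warn .data
#' @importFrom tibble tibble as_tibble
#' @importFrom dplyr mutate filter select arrange group_by ungroup summarise
#'   across bind_rows bind_cols left_join inner_join anti_join distinct
#'   row_number n n_distinct first rename relocate pull slice count
#' @importFrom purrr map map_chr map_int map_lgl map2 pmap imap keep discard
#'   list_rbind reduce walk iwalk
#' @importFrom stringr str_detect str_trim str_split str_to_upper str_pad
NULL

# all package conditions share the "sdtmbridge_error" class so callers can
# catch anything the pipeline raises with one handler
stop_sdtm <- function(class, message, ...) {
  rlang::abort(message, class = c(class, "sdtmbridge_error"), ...)
}

# empty cells are stored as "" (not NA) so CSV serialization is unambiguous
blank_to_na <- function(x) ifelse(!is.na(x) & nzchar(str_trim(x)), x, NA_character_)
na_to_blank <- function(x) ifelse(is.na(x), "", x)

is_string <- function(x) is.character(x) && length(x) == 1L && !is.na(x)

compact_chr <- function(x) x[!is.na(x)]
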