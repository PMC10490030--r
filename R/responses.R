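#' Load FFQ responses
#'
#' Reads respondent answers to an FFQ instrument from delimited text. The
#' native layout is long: one row per respondent x item with columns
#' `respondent_id`, `sex` ("female"/"male"), `item_id`,
#' `servings_per_week` (nonnegative; fractions allowed). A wide layout (one
#' column per item id, plus `respondent_id` and `sex`) is read with
#' `wide = TRUE`.
#'
#' Under the default strict policy every instrument item must be answered by
#' every respondent; under the permissive policy missing items are scored as
#' 0 servings with a warning, and the per-respondent `completeness` fraction
#' records how much of the instrument was answered.
#'
#' @param source path to a comma- or tab-delimited text file.
#' @param instrument the `ffq_instrument` the responses answer.
#' @param strict if `TRUE` (default), missing respondent x item cells are an
#'   error; if `FALSE` they become 0 servings with a warning.
#' @param wide read the wide (one column per item) layout.
#' @param delim delimiter; `NULL` auto-detects comma vs tab.
#' @return an `ffq_responses` tibble (long layout) with columns
#'   `respondent_id`, `sex`, `item_id`, `servings_per_week`, plus a
#'   `completeness` tibble attribute (respondent_id, completeness in
#'   \[0, 1\]).
#' @export
load_responses <- function(source, instrument, strict = TRUE, wide = FALSE,
                           delim = NULL) {
  if (!file.exists(source)) {
    rlang::abort(sprintf("responses file not found: %s", source),
                 class = "tocointake_io_error")
  }
  if (is.null(delim)) {
    header <- readLines(source, n = 1L)
    delim <- if (grepl("\t", header, fixed = TRUE)) "\t" else ","
  }
  raw <- readr::read_delim(source, delim = delim, show_col_types = FALSE,
                           progress = FALSE)
  if (wide) {
    id_cols <- intersect(c("respondent_id", "sex"), names(raw))
    raw <- tidyr::pivot_longer(raw, cols = -dplyr::all_of(id_cols),
                               names_to = "item_id",
                               values_to = "servings_per_week")
  }
  as_ffq_responses(raw, instrument, strict = strict)
}

#' Validate a data frame of FFQ responses
#'
#' @param data long-format responses (see [load_responses()]).
#' @inheritParams load_responses
#' @return an `ffq_responses` tibble.
#' @export
as_ffq_responses <- function(data, instrument, strict = TRUE) {
  required <- c("respondent_id", "sex", "item_id", "servings_per_week")
  missing <- setdiff(required, names(data))
  if (length(missing)) {
    rlang::abort(sprintf("responses table is missing column(s): %s",
                         paste(missing, collapse = ", ")),
                 class = "tocointake_schema_error")
  }
  resp <- tibble::as_tibble(data)[required]
  resp$respondent_id <- as.character(resp$respondent_id)
  resp$item_id <- as.character(resp$item_id)
  resp$sex <- as.character(resp$sex)

  bad_sex <- setdiff(unique(resp$sex), c("female", "male"))
  if (length(bad_sex)) {
    rlang::abort(sprintf("sex must be 'female' or 'male'; found: %s",
                         paste(bad_sex, collapse = ", ")),
                 class = "tocointake_validation_error")
  }
  unknown <- setdiff(unique(resp$item_id), instrument$item_id)
  if (length(unknown)) {
    rlang::abort(sprintf("unknown item_id(s): %s",
                         paste(unknown, collapse = ", ")),
                 class = "tocointake_validation_error")
  }
  if (anyDuplicated(resp[c("respondent_id", "item_id")])) {
    rlang::abort("duplicate respondent_id x item_id rows",
                 class = "tocointake_validation_error")
  }
  v <- resp$servings_per_week
  if (any(is.na(v)) || any(v < 0) || any(!is.finite(v))) {
    rlang::abort("servings_per_week must be finite and >= 0",
                 class = "tocointake_validation_error")
  }
  sex_per_resp <- dplyr::distinct(resp, .data$respondent_id, .data$sex)
  if (anyDuplicated(sex_per_resp$respondent_id)) {
    rlang::abort("inconsistent sex within a respondent",
                 class = "tocointake_validation_error")
  }

  n_items <- nrow(instrument)
  completeness <- resp |>
    dplyr::count(.data$respondent_id, name = "n_answered") |>
    dplyr::mutate(completeness = .data$n_answered / n_items) |>
    dplyr::select("respondent_id", "completeness")

  incomplete <- completeness$respondent_id[completeness$completeness < 1]
  if (length(incomplete)) {
    if (strict) {
      missing_items <- resp |>
        dplyr::filter(.data$respondent_id == incomplete[[1L]]) |>
        dplyr::pull("item_id")
      rlang::abort(sprintf(
        "strict policy: respondent '%s' is missing item(s): %s",
        incomplete[[1L]],
        paste(setdiff(instrument$item_id, missing_items), collapse = ", ")
      ), class = "tocointake_validation_error")
    }
    rlang::warn(sprintf(
      "%d respondent(s) with missing items scored as 0 servings",
      length(incomplete)
    ))
    resp <- resp |>
      tidyr::complete(
        tidyr::nesting(!!rlang::sym("respondent_id"), !!rlang::sym("sex")),
        item_id = instrument$item_id,
        fill = list(servings_per_week = 0)
      ) |>
      dplyr::select(dplyr::all_of(required))
  }
  structure(resp, completeness = completeness,
            class = c("ffq_responses", class(tibble::tibble())))
}

#' Write FFQ responses to delimited text
#'
#' @param responses an `ffq_responses` tibble (long layout).
#' @param path output path.
#' @param delim delimiter (default comma).
#' @return `path`, invisibly.
#' @export
write_responses <- function(responses, path, delim = ",") {
  readr::write_delim(tibble::as_tibble(responses), path, delim = delim,
                     progress = FALSE)
  invisible(path)
}
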