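#' Convert weekly servings to daily portions
#'
#' Reported usual servings per week are normalised to portions per day by
#' dividing by the recall period (7 days).
#'
#' @param servings_per_week nonnegative numeric vector; fractions allowed.
#' @param recall_period_days divisor, default 7.
#' @return portions per day.
#' @export
#' @examples
#' daily_portions(c(7, 3.5, 0))
daily_portions <- function(servings_per_week, recall_period_days = 7) {
  if (any(servings_per_week < 0, na.rm = TRUE)) {
    rlang::abort("servings_per_week must be >= 0",
                 class = "tocointake_domain_error")
  }
  servings_per_week / recall_period_days
}

#' Daily isoform intake from one item
#'
#' Componentwise scalar product: daily portions of an item times the isoform
#' content of one portion.
#'
#' @param portions_per_day nonnegative scalar.
#' @param per_portion one-row tibble of per-portion contents (mg), as
#'   returned by [content_per_portion()].
#' @return one-row tibble of daily intakes (mg/day).
#' @export
item_daily_intake <- function(portions_per_day, per_portion) {
  if (portions_per_day < 0) {
    rlang::abort("portions_per_day must be >= 0",
                 class = "tocointake_domain_error")
  }
  dplyr::mutate(per_portion, dplyr::across(dplyr::everything(),
                                           ~ .x * portions_per_day))
}

# Per-item per-portion content table for a whole instrument: one row per
# item over isoform_cols(). Accumulation downstream keeps instrument order.
instrument_portion_contents <- function(instrument, db) {
  contents <- purrr::map(seq_len(nrow(instrument)), function(i) {
    content_per_portion(instrument[i, ], db)
  })
  dplyr::bind_cols(instrument["item_id"], dplyr::bind_rows(contents),
                   instrument["group"])
}

#' Daily vitamin E isoform intake per respondent
#'
#' The scoring engine: for every respondent, daily intake of each isoform is
#' the sum over instrument items of
#' `servings_per_week / 7 x content per portion of the item`, where the
#' per-portion content is the unweighted mean of the item's member foods'
#' composition scaled by the portion size. Tocopherol and tocotrienol sums,
#' their total, and alpha-tocopherol equivalents are appended.
#'
#' @param responses an `ffq_responses` tibble (or any data frame with
#'   columns `respondent_id`, `sex`, `item_id`, `servings_per_week`).
#' @param instrument the `ffq_instrument` answered.
#' @param db a `composition_db` resolving every member food.
#' @param weights a [conversion_weights()] object for the alpha-TE column.
#' @param report_added_as_alpha if `TRUE`, manufacturer-added vitamin E is
#'   folded into the reported `alpha_t` column (default `FALSE`: it stays in
#'   `added_vit_e`). Independently of this flag it enters `alpha_te` when
#'   `weights` says so.
#' @return an `intake_table`: one row per respondent with columns
#'   `respondent_id`, `sex`, the nine columns of [isoform_cols()] (mg/day),
#'   `sum_tocopherols`, `sum_tocotrienols`, `total_isoforms`, `alpha_te`.
#' @export
#' @examples
#' inst <- builtin_instrument()
#' db <- make_fixture_db(seed = 1, instrument = inst)
#' resp <- tibble::tibble(
#'   respondent_id = "r1", sex = "female",
#'   item_id = inst$item_id, servings_per_week = 1
#' )
#' compute_intake(resp, inst, db)
compute_intake <- function(responses, instrument, db,
                           weights = conversion_weights(),
                           report_added_as_alpha = FALSE) {
  by_group <- intake_by_group(responses, instrument, db)
  out <- by_group |>
    dplyr::group_by(.data$respondent_id, .data$sex) |>
    dplyr::summarise(dplyr::across(dplyr::all_of(isoform_cols()), sum),
                     .groups = "drop")
  out <- add_intake_sums(out, weights)
  if (report_added_as_alpha) {
    # reporting fold only: alpha_te already counts added_vit_e per `weights`
    out$alpha_t <- out$alpha_t + out$added_vit_e
  }
  # preserve respondent order of first appearance in the responses
  out <- out[match(unique(as.character(responses$respondent_id)),
                   out$respondent_id), ]
  structure(out, class = c("intake_table", class(tibble::tibble())))
}

#' Daily intake broken down by food group
#'
#' Same computation as [compute_intake()] but partitioned by the instrument's
#' food groups; the group rows of one respondent sum to that respondent's
#' daily intake.
#'
#' @inheritParams compute_intake
#' @return tibble with one row per respondent x food group, isoform columns
#'   in mg/day.
#' @export
intake_by_group <- function(responses, instrument, db) {
  stopifnot(is.data.frame(responses))
  missing <- setdiff(c("respondent_id", "sex", "item_id",
                       "servings_per_week"), names(responses))
  if (length(missing)) {
    rlang::abort(sprintf("responses are missing column(s): %s",
                         paste(missing, collapse = ", ")),
                 class = "tocointake_schema_error")
  }
  recall <- attr(instrument, "recall_period_days") %||% 7
  contents <- instrument_portion_contents(instrument, db)

  scored <- responses |>
    dplyr::inner_join(contents, by = "item_id") |>
    dplyr::mutate(
      portions_per_day = daily_portions(.data$servings_per_week, recall),
      dplyr::across(dplyr::all_of(isoform_cols()),
                    ~ .x * .data$portions_per_day),
      item_id = factor(.data$item_id, levels = instrument$item_id)
    ) |>
    dplyr::arrange(.data$respondent_id, .data$item_id)

  unknown <- setdiff(unique(as.character(responses$item_id)),
                     instrument$item_id)
  if (length(unknown)) {
    rlang::abort(sprintf("unknown item_id(s): %s",
                         paste(unknown, collapse = ", ")),
                 class = "tocointake_validation_error")
  }

  scored |>
    dplyr::group_by(.data$respondent_id, .data$sex, .data$group) |>
    dplyr::summarise(dplyr::across(dplyr::all_of(isoform_cols()), sum),
                     .groups = "drop")
}

#' Write / read a per-respondent intake table
#'
#' Delimited-text writers and readers for the intake table, plus a JSON
#' alternative. Values are written at full precision by default; set
#' `report_decimals` to round for presentation.
#'
#' @param intake an `intake_table`.
#' @param path file path.
#' @param delim delimiter (default comma).
#' @param report_decimals if non-`NULL`, round all mass columns to this many
#'   decimals in the written file (presentation only; in-memory values stay
#'   full precision).
#' @return `path` (write) or a tibble (read).
#' @export
write_intake <- function(intake, path, delim = ",", report_decimals = NULL) {
  out <- tibble::as_tibble(intake)
  if (!is.null(report_decimals)) {
    num <- names(out)[vapply(out, is.numeric, logical(1))]
    out <- dplyr::mutate(out, dplyr::across(dplyr::all_of(num),
                                            ~ round(.x, report_decimals)))
  }
  if (grepl("\\.json$", path)) {
    jsonlite::write_json(out, path, digits = NA)
  } else {
    readr::write_delim(out, path, delim = delim, progress = FALSE)
  }
  invisible(path)
}

#' @rdname write_intake
#' @export
read_intake <- function(path, delim = NULL) {
  if (!file.exists(path)) {
    rlang::abort(sprintf("intake file not found: %s", path),
                 class = "tocointake_io_error")
  }
  if (grepl("\\.json$", path)) {
    out <- tibble::as_tibble(jsonlite::fromJSON(path))
  } else {
    if (is.null(delim)) {
      header <- readLines(path, n = 1L)
      delim <- if (grepl("\t", header, fixed = TRUE)) "\t" else ","
    }
    out <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                             progress = FALSE)
  }
  structure(out, class = c("intake_table", class(tibble::tibble())))
}
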