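#' Built-in dietary reference intake frameworks for vitamin E
#'
#' Three adult reference frameworks, each keyed to the metric it is defined
#' on:
#' * **NIPH-NIH-NRI** (Polish): adequate intake in alpha-tocopherol
#'   equivalents, 10 mg/day men, 8 mg/day women; UL 300 mg/day.
#' * **NIH** (US): RDA in alpha-tocopherol, 15 mg/day both sexes;
#'   UL 1000 mg/day.
#' * **EFSA** (European): adequate intake in alpha-tocopherol, 13 mg/day
#'   men, 11 mg/day women; UL 300 mg/day.
#'
#' @return tibble with columns `framework`, `metric` (`"alpha_t"` or
#'   `"alpha_te"`), `reference_type` (`"AI"`/`"RDA"`), `sex`, `threshold`
#'   (mg/day), `ul` (mg/day).
#' @export
#' @examples
#' builtin_frameworks()
builtin_frameworks <- function() {
  frameworks <- tibble::tribble(
    ~framework,     ~metric,    ~reference_type, ~sex,     ~threshold, ~ul,
    "NIPH-NIH-NRI", "alpha_te", "AI",            "male",   10,         300,
    "NIPH-NIH-NRI", "alpha_te", "AI",            "female", 8,          300,
    "NIH",          "alpha_t",  "RDA",           "male",   15,         1000,
    "NIH",          "alpha_t",  "RDA",           "female", 15,         1000,
    "EFSA",         "alpha_t",  "AI",            "male",   13,         300,
    "EFSA",         "alpha_t",  "AI",            "female", 11,         300
  )
  as_dri_frameworks(frameworks)
}

#' Validate a table of DRI frameworks
#'
#' User-defined frameworks can be supplied as a data frame (or loaded from
#' delimited text with [load_frameworks()]) with one row per framework x sex.
#'
#' @param data data frame with the columns of [builtin_frameworks()].
#' @return validated `dri_frameworks` tibble.
#' @export
as_dri_frameworks <- function(data) {
  required <- c("framework", "metric", "reference_type", "sex", "threshold",
                "ul")
  missing <- setdiff(required, names(data))
  if (length(missing)) {
    rlang::abort(sprintf("frameworks table is missing column(s): %s",
                         paste(missing, collapse = ", ")),
                 class = "tocointake_schema_error")
  }
  fw <- tibble::as_tibble(data)[required]
  if (any(fw$threshold <= 0) || any(fw$ul < fw$threshold)) {
    rlang::abort("thresholds must be > 0 and ul >= threshold",
                 class = "tocointake_validation_error")
  }
  bad_sex <- setdiff(unique(fw$sex), c("female", "male"))
  if (length(bad_sex)) {
    rlang::abort("sex must be 'female' or 'male'",
                 class = "tocointake_validation_error")
  }
  bad_metric <- setdiff(unique(fw$metric), c("alpha_t", "alpha_te"))
  if (length(bad_metric)) {
    rlang::abort("metric must be 'alpha_t' or 'alpha_te'",
                 class = "tocointake_validation_error")
  }
  structure(fw, class = c("dri_frameworks", class(tibble::tibble())))
}

#' Load DRI frameworks from delimited text
#'
#' @param path comma- or tab-delimited file with the columns of
#'   [builtin_frameworks()].
#' @return a `dri_frameworks` tibble.
#' @export
load_frameworks <- function(path) {
  if (!file.exists(path)) {
    rlang::abort(sprintf("frameworks file not found: %s", path),
                 class = "tocointake_io_error")
  }
  header <- readLines(path, n = 1L)
  delim <- if (grepl("\t", header, fixed = TRUE)) "\t" else ","
  as_dri_frameworks(readr::read_delim(path, delim = delim,
                                      show_col_types = FALSE,
                                      progress = FALSE))
}

#' Classify intakes against DRI frameworks
#'
#' Each respondent's intake on a framework's metric (alpha-tocopherol or
#' alpha-TE, mg/day) is compared with the sex-specific reference value.
#' Intake at or above the threshold is adequate (boundary counts as
#' adequate); intake strictly above the UL flags `ul_exceeded`.
#'
#' @param intake an `intake_table` (needs `respondent_id`, `sex`, and the
#'   metric columns named by the frameworks).
#' @param frameworks a `dri_frameworks` tibble; default
#'   [builtin_frameworks()].
#' @return tibble with one row per respondent x framework: `respondent_id`,
#'   `sex`, `framework`, `metric`, `value` (mg/day), `status`
#'   (`"adequate"`/`"inadequate"`), `ul_exceeded`.
#' @export
classify_adequacy <- function(intake, frameworks = builtin_frameworks()) {
  stopifnot(is.data.frame(intake))
  frameworks <- as_dri_frameworks(frameworks)
  metrics <- unique(frameworks$metric)
  missing <- setdiff(c("respondent_id", "sex", metrics), names(intake))
  if (length(missing)) {
    rlang::abort(sprintf("intake table is missing column(s): %s",
                         paste(missing, collapse = ", ")),
                 class = "tocointake_schema_error")
  }
  bad_sex <- setdiff(unique(as.character(intake$sex)), c("female", "male"))
  if (length(bad_sex)) {
    rlang::abort(sprintf("unknown sex value(s): %s",
                         paste(bad_sex, collapse = ", ")),
                 class = "tocointake_domain_error")
  }
  long <- intake |>
    dplyr::select("respondent_id", "sex", dplyr::all_of(metrics)) |>
    tidyr::pivot_longer(dplyr::all_of(metrics), names_to = "metric",
                        values_to = "value")
  long |>
    dplyr::inner_join(frameworks, by = c("sex", "metric"),
                      relationship = "many-to-many") |>
    dplyr::mutate(
      status = ifelse(.data$value >= .data$threshold, "adequate",
                      "inadequate"),
      ul_exceeded = .data$value > .data$ul
    ) |>
    dplyr::select("respondent_id", "sex", "framework", "metric", "value",
                  "status", "ul_exceeded") |>
    dplyr::arrange(match(.data$framework, frameworks$framework))
}

#' Group-level adequacy percentages
#'
#' Summarises per-respondent classifications into the share of the group
#' with adequate and inadequate intake, and the share exceeding the UL, per
#' framework. Percentages are kept at full precision; round only for
#' presentation.
#'
#' @param classified output of [classify_adequacy()].
#' @return tibble with one row per framework: `framework`, `metric`, `n`,
#'   `pct_adequate`, `pct_inadequate`, `pct_ul_exceeded`.
#' @export
adequacy_summary <- function(classified) {
  if (!is.data.frame(classified) || nrow(classified) == 0L) {
    rlang::abort("classify_adequacy() results required (nonempty)",
                 class = "tocointake_domain_error")
  }
  classified |>
    dplyr::group_by(.data$framework, .data$metric) |>
    dplyr::summarise(
      n = dplyr::n(),
      pct_adequate = 100 * mean(.data$status == "adequate"),
      pct_inadequate = 100 * mean(.data$status == "inadequate"),
      pct_ul_exceeded = 100 * mean(.data$ul_exceeded),
      .groups = "drop"
    )
}
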