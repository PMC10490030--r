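#' Load a food-composition table
#'
#' Reads a delimited text table of per-food vitamin E isoform contents and
#' validates it. One row per food; contents are mg per 100 g edible portion.
#' Required columns: `food_id`, `name`, `group` (one of [food_groups()]),
#' the eight isoform columns of [isoform_cols()] and `added_vit_e`.
#'
#' Rows whose isoform contents are all zero are retained: many legitimate
#' foods carry no measurable vitamin E. Missing (blank/NA) cells are an error
#' by default because silently zeroing them biases intake estimates downward;
#' set `blank_as_zero = TRUE` to map them to 0 with a warning.
#'
#' @param source path to a comma- or tab-delimited UTF-8 text file.
#' @param delim field delimiter; `NULL` (default) auto-detects comma vs tab
#'   from the header line.
#' @param blank_as_zero permissive handling of missing content cells.
#' @param provenance free-text metadata (source, version) recorded on the
#'   returned object.
#' @return a `composition_db`: a tibble of validated food records with a
#'   `provenance` attribute.
#' @export
load_composition <- function(source, delim = NULL, blank_as_zero = FALSE,
                             provenance = source) {
  if (!file.exists(source)) {
    rlang::abort(sprintf("composition file not found: %s", source),
                 class = "tocointake_io_error")
  }
  if (is.null(delim)) {
    header <- readLines(source, n = 1L)
    delim <- if (grepl("\t", header, fixed = TRUE)) "\t" else ","
  }
  raw <- readr::read_delim(source, delim = delim, show_col_types = FALSE,
                           progress = FALSE)
  as_composition_db(raw, blank_as_zero = blank_as_zero,
                    provenance = provenance)
}

#' Validate a data frame as a composition database
#'
#' @param data a data frame with the composition schema (see
#'   [load_composition()]).
#' @inheritParams load_composition
#' @return a validated `composition_db` tibble.
#' @export
as_composition_db <- function(data, blank_as_zero = FALSE,
                              provenance = "in-memory") {
  required <- c("food_id", "name", "group", isoform_cols())
  missing <- setdiff(required, names(data))
  if (length(missing)) {
    rlang::abort(
      sprintf("composition table is missing column(s): %s",
              paste(missing, collapse = ", ")),
      class = "tocointake_schema_error"
    )
  }
  db <- tibble::as_tibble(data)[required]
  db$food_id <- as.character(db$food_id)
  db$name <- as.character(db$name)
  db$group <- as.character(db$group)

  na_cells <- vapply(db[isoform_cols()], function(v) sum(is.na(v)), integer(1))
  if (any(na_cells > 0)) {
    if (blank_as_zero) {
      rlang::warn(sprintf(
        "%d missing content cell(s) set to 0 (blank_as_zero = TRUE)",
        sum(na_cells)
      ))
      db <- dplyr::mutate(db, dplyr::across(
        dplyr::all_of(isoform_cols()), ~ tidyr::replace_na(.x, 0)
      ))
    } else {
      rlang::abort(
        sprintf("missing content cells in column(s): %s (set blank_as_zero = TRUE to map blanks to 0)",
                paste(names(na_cells)[na_cells > 0], collapse = ", ")),
        class = "tocointake_validation_error"
      )
    }
  }
  check_isoform_values(db, id_col = "food_id")

  dup <- db$food_id[duplicated(db$food_id)]
  if (length(dup)) {
    rlang::abort(sprintf("duplicate food_id: %s",
                         paste(unique(dup), collapse = ", ")),
                 class = "tocointake_validation_error")
  }
  bad_group <- setdiff(unique(db$group), food_groups())
  if (length(bad_group)) {
    rlang::abort(sprintf("unknown food group(s): %s",
                         paste(bad_group, collapse = ", ")),
                 class = "tocointake_validation_error")
  }
  structure(db, provenance = provenance,
            class = c("composition_db", class(tibble::tibble())))
}

#' Write a composition database to delimited text
#'
#' @param db a `composition_db`.
#' @param path output file path.
#' @param delim field delimiter (default comma).
#' @return `path`, invisibly.
#' @export
write_composition <- function(db, path, delim = ",") {
  readr::write_delim(tibble::as_tibble(db), path, delim = delim,
                     progress = FALSE)
  invisible(path)
}

#' Per-portion isoform content of an FFQ line item
#'
#' An FFQ item pools one or more member foods; its content in one portion is
#' the unweighted mean of the member foods' per-100 g contents, scaled by the
#' portion mass: `mean(content per 100 g) * portion_g / 100`, componentwise.
#' Volume portions (mL) are treated numerically as grams (density 1).
#'
#' @param item one row of an FFQ instrument (a data frame with `portion_g`
#'   and a `member_food_ids` list column), or a list with those fields.
#' @param db a `composition_db` resolving every member food id.
#' @return one-row tibble of per-portion contents (mg) over [isoform_cols()].
#' @export
content_per_portion <- function(item, db) {
  if (is.data.frame(item)) {
    stopifnot(nrow(item) == 1L)
    portion_g <- item$portion_g[[1L]]
    members <- item$member_food_ids[[1L]]
  } else {
    portion_g <- item$portion_g
    members <- item$member_food_ids
  }
  if (!is.numeric(portion_g) || length(portion_g) != 1L || portion_g <= 0) {
    rlang::abort("portion_g must be a single positive number",
                 class = "tocointake_domain_error")
  }
  if (length(members) == 0L) {
    rlang::abort("FFQ item has an empty member food list",
                 class = "tocointake_definition_error")
  }
  unresolved <- setdiff(members, db$food_id)
  if (length(unresolved)) {
    rlang::abort(sprintf("food id(s) not in composition database: %s",
                         paste(unresolved, collapse = ", ")),
                 class = "tocointake_lookup_error")
  }
  rows <- db[match(members, db$food_id), isoform_cols()]
  per100 <- colMeans(rows)
  tibble::as_tibble(as.list(per100 * portion_g / 100))
}

#' Generate a synthetic composition database
#'
#' Deterministic (for a fixed seed) generator of realistic composition
#' fixtures. Contents are drawn from log-normal distributions whose scales
#' differ by food group the way real composition tables do: fats and
#' nuts/oilseeds are tocopherol-rich (tens of mg/100 g alpha- and gamma-T),
#' cereals carry most of the tocotrienols, vegetables and fruit are low
#' (fractions of a mg). When an `instrument` is supplied, one food row is
#' generated per member food id of the instrument so that every item
#' resolves; otherwise `n_items` generic foods are spread across all eight
#' groups.
#'
#' @param seed integer seed; the generator is a pure function of
#'   `(seed, n_items, instrument)`.
#' @param n_items number of foods when no instrument is given (>= 1).
#' @param instrument optionally, an FFQ instrument whose member foods the
#'   database must cover.
#' @return a `composition_db`.
#' @export
#' @examples
#' db <- make_fixture_db(seed = 1, n_items = 16)
#' dplyr::count(db, group)
make_fixture_db <- function(seed = 1L, n_items = 67L, instrument = NULL) {
  if (is.null(instrument) && n_items < 1) {
    rlang::abort("n_items must be >= 1", class = "tocointake_domain_error")
  }
  if (!is.null(instrument)) {
    foods <- instrument |>
      dplyr::select("group", "member_food_ids") |>
      tidyr::unnest("member_food_ids") |>
      dplyr::rename(food_id = "member_food_ids") |>
      dplyr::distinct(.data$food_id, .keep_all = TRUE)
  } else {
    groups <- rep(food_groups(), length.out = n_items)
    foods <- tibble::tibble(
      food_id = sprintf("food_%03d", seq_len(n_items)),
      group = sort(groups)
    )
  }

  # per-group median content (mg/100 g) for the dominant isoforms; the
  # remaining isoforms sit two orders of magnitude lower
  profile <- list(
    "vegetables"                  = c(alpha_t = 0.8, gamma_t = 0.3),
    "fruit and fruit products"    = c(alpha_t = 0.6, gamma_t = 0.2),
    "legumes and legume products" = c(alpha_t = 0.3, gamma_t = 1.5),
    "nuts and oilseeds"           = c(alpha_t = 8, gamma_t = 5, beta_t = 0.3),
    "fats"                        = c(alpha_t = 12, gamma_t = 13, delta_t = 1.5),
    "cereals"                     = c(alpha_t = 0.5, beta_t3 = 6,
                                      alpha_t3 = 2.4, gamma_t3 = 2.4,
                                      delta_t3 = 0.5),
    "fish and fish products"      = c(alpha_t = 1.5, gamma_t = 0.3),
    "snacks and others"           = c(alpha_t = 2.5, gamma_t = 4.5,
                                      gamma_t3 = 0.4)
  )

  withr::with_seed(as.integer(seed), {
    content <- purrr::map_dfr(foods$group, function(g) {
      med <- rep(0.01, 8)
      names(med) <- isoform_cols(added = FALSE)
      med[names(profile[[g]])] <- profile[[g]]
      amt <- stats::setNames(
        stats::rlnorm(8, meanlog = log(med), sdlog = 0.5), names(med)
      )
      tibble::as_tibble_row(as.list(round(amt, 4)))
    })
    # a few processed foods carry manufacturer-added vitamin E
    added <- ifelse(
      foods$group %in% c("fats", "snacks and others") &
        stats::runif(nrow(foods)) < 0.3,
      round(stats::rlnorm(nrow(foods), log(2), 0.4), 4), 0
    )
  })

  db <- dplyr::bind_cols(
    foods["food_id"],
    tibble::tibble(name = gsub("_", " ", foods$food_id), group = foods$group),
    content,
    tibble::tibble(added_vit_e = added)
  )
  as_composition_db(db, provenance = sprintf("synthetic (seed %d)", seed))
}
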