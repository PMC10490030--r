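#' Vitamin E isoform column names
#'
#' The eight naturally occurring vitamin E isoforms — the four tocopherols
#' (alpha, beta, gamma, delta) and the four tocotrienols — plus, optionally,
#' manufacturer-added vitamin E. Every table in this package that carries
#' isoform amounts (composition per 100 g, per-portion content, daily intake)
#' uses these column names, always in mg.
#'
#' @param added if `TRUE` (default) include `added_vit_e`, the column holding
#'   vitamin E added to a product by the manufacturer, carried separately from
#'   the natural isoforms.
#' @return character vector of column names.
#' @export
#' @examples
#' isoform_cols()
#' isoform_cols(added = FALSE)
isoform_cols <- function(added = TRUE) {
  base <- c(
    "alpha_t", "beta_t", "gamma_t", "delta_t",
    "alpha_t3", "beta_t3", "gamma_t3", "delta_t3"
  )
  if (added) c(base, "added_vit_e") else base
}

tocopherol_cols <- function() isoform_cols(added = FALSE)[1:4]
tocotrienol_cols <- function() isoform_cols(added = FALSE)[5:8]

#' The eight food groups of the vitamin E FFQ
#'
#' Closed set of product categories used by the instrument and the
#' composition database.
#'
#' @return character vector of the 8 group labels.
#' @export
food_groups <- function() {
  c(
    "vegetables", "fruit and fruit products", "legumes and legume products",
    "nuts and oilseeds", "fats", "cereals", "fish and fish products",
    "snacks and others"
  )
}

# Check that isoform columns of a data frame are finite and >= 0.
# Returns NULL invisibly or aborts with the offending ids/fields.
check_isoform_values <- function(data, id_col = "food_id",
                                 cols = isoform_cols(),
                                 what = "content") {
  cols <- intersect(cols, names(data))
  for (col in cols) {
    v <- data[[col]]
    if (!is.numeric(v)) {
      rlang::abort(sprintf("column '%s' must be numeric", col),
                   class = "tocointake_validation_error")
    }
    bad <- which(!is.finite(v) | v < 0)
    if (length(bad)) {
      ids <- if (id_col %in% names(data)) data[[id_col]][bad] else bad
      rlang::abort(
        sprintf(
          "negative or non-finite %s in column '%s' for: %s",
          what, col, paste(utils::head(ids, 5), collapse = ", ")
        ),
        class = "tocointake_validation_error"
      )
    }
  }
  invisible(NULL)
}

#' Activity weights for the alpha-tocopherol-equivalent conversion
#'
#' Builds the vector of dimensionless activity coefficients used to express a
#' mixture of vitamin E isoforms as mg of alpha-tocopherol equivalents
#' (alpha-TE). Defaults are the conventional coefficients: 1.0 alpha-T,
#' 0.4 beta-T, 0.1 gamma-T, 0.01 delta-T, 0.3 alpha-T3, 0.05 beta-T3,
#' 0.01 gamma-T3. Delta-tocotrienol carries weight 0 by default (it is absent
#' from the conventional formula); supply `delta_t3 = 0.01` or any other
#' value to adopt a different convention.
#'
#' @param ... named weight overrides, e.g. `delta_t3 = 0.01`.
#' @param fold_added_as_alpha if `TRUE` (default), manufacturer-added vitamin
#'   E contributes to alpha-TE with weight 1.0 (it is added as
#'   alpha-tocopherol or an ester thereof); if `FALSE` it is ignored.
#' @return an object of class `conversion_weights`: a named numeric vector
#'   over [isoform_cols()] with the fold-in flag as an attribute.
#' @export
#' @examples
#' conversion_weights()
#' conversion_weights(delta_t3 = 0.01)
conversion_weights <- function(..., fold_added_as_alpha = TRUE) {
  w <- c(
    alpha_t = 1.0, beta_t = 0.4, gamma_t = 0.1, delta_t = 0.01,
    alpha_t3 = 0.3, beta_t3 = 0.05, gamma_t3 = 0.01, delta_t3 = 0.0
  )
  dots <- list(...)
  if (length(dots)) {
    bad <- setdiff(names(dots), names(w))
    if (length(bad) || is.null(names(dots)) || any(names(dots) == "")) {
      rlang::abort(
        sprintf("unknown weight name(s): %s", paste(bad, collapse = ", ")),
        class = "tocointake_domain_error"
      )
    }
    w[names(dots)] <- vapply(dots, as.numeric, numeric(1))
  }
  if (any(w < 0) || any(!is.finite(w))) {
    rlang::abort("weights must be finite and >= 0",
                 class = "tocointake_domain_error")
  }
  w <- c(w, added_vit_e = if (isTRUE(fold_added_as_alpha)) 1.0 else 0.0)
  structure(w,
    fold_added_as_alpha = isTRUE(fold_added_as_alpha),
    class = c("conversion_weights", "numeric")
  )
}

#' Alpha-tocopherol equivalents of isoform amounts
#'
#' Weighted sum of isoform amounts (mg) with the activity coefficients in
#' `weights`. Works row-wise on any data frame carrying the isoform columns,
#' so the same function converts a per-100 g composition row or a per-day
#' intake row.
#'
#' @param data a data frame with the columns of [isoform_cols()]
#'   (`added_vit_e` optional, treated as 0 when absent).
#' @param weights a [conversion_weights()] object.
#' @return numeric vector, one alpha-TE value (mg) per row of `data`.
#' @export
#' @examples
#' # 1 mg of each isoform, nothing added: 1 + 0.4 + 0.1 + 0.01 + 0.3 + 0.05 + 0.01
#' alpha_te(tibble::as_tibble(as.list(stats::setNames(rep(1, 8), isoform_cols(FALSE)))))
alpha_te <- function(data, weights = conversion_weights()) {
  stopifnot(is.data.frame(data))
  te <- rep(0, nrow(data))
  for (col in names(weights)) {
    if (col %in% names(data)) {
      check_isoform_values(data, cols = col, what = "amount")
      te <- te + unname(weights[[col]]) * data[[col]]
    }
  }
  te
}

# Append sum_tocopherols, sum_tocotrienols, total_isoforms, alpha_te columns
# to a table holding the isoform columns. Internal: used by intake and synth.
add_intake_sums <- function(data, weights = conversion_weights()) {
  data$sum_tocopherols <- rowSums(data[tocopherol_cols()])
  data$sum_tocotrienols <- rowSums(data[tocotrienol_cols()])
  data$total_isoforms <- data$sum_tocopherols + data$sum_tocotrienols
  data$alpha_te <- alpha_te(data, weights)
  data
}
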