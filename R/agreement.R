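#' Bland-Altman limits-of-agreement analysis
#'
#' Quantifies agreement between two methods measuring the same quantity on
#' the same subjects (here, two dietary assessment methods). For paired
#' values a (method A, e.g. FFQ) and b (method B, e.g. 1-day record):
#' differences `d = a - b`; bias = mean(d); SD of differences with the n-1
#' denominator; limits of agreement `bias +/- k * SD` (k = 1.96 bounds ~95%
#' of differences under normality). The Bland-Altman index is the percentage
#' of pairs strictly beyond the limits; points exactly on a limit count as
#' within. Agreement is called good when the index does not exceed
#' `index_threshold` (5% conventionally; 10% as a laxer published
#' alternative).
#'
#' @param data data frame of paired measurements.
#' @param a,b columns of `data` (tidy-eval) holding methods A and B, mg/day.
#' @param k limit multiplier, default 1.96.
#' @param index_threshold good-agreement cutoff on the index, in percent.
#' @param variable optional label of the quantity compared.
#' @return a `bland_altman` object; see [tidy.bland_altman()] for the
#'   per-pair table and [glance.bland_altman()] for the one-row summary.
#' @export
#' @examples
#' d <- tibble::tibble(ffq = c(10, 12, 9, 14), record = c(11, 10, 9, 15))
#' ba <- bland_altman(d, ffq, record)
#' glance(ba)
bland_altman <- function(data, a, b, k = 1.96, index_threshold = 5,
                         variable = NULL) {
  stopifnot(is.data.frame(data))
  av <- dplyr::pull(data, {{ a }})
  bv <- dplyr::pull(data, {{ b }})
  keep <- stats::complete.cases(av, bv)
  av <- av[keep]
  bv <- bv[keep]
  n <- length(av)
  if (n < 2L) {
    rlang::abort("Bland-Altman analysis needs at least 2 complete pairs",
                 class = "tocointake_domain_error")
  }
  d <- av - bv
  mean_diff <- mean(d)
  sd_diff <- stats::sd(d)
  lower_loa <- mean_diff - k * sd_diff
  upper_loa <- mean_diff + k * sd_diff
  if (sd_diff == 0) {
    rlang::warn("zero variance of differences; Bland-Altman index set to 0")
    n_outside <- 0L
  } else {
    n_outside <- sum(d < lower_loa | d > upper_loa)
  }
  index <- ba_index_pct(n_outside, n)
  structure(
    list(
      n = n, mean_diff = mean_diff, sd_diff = sd_diff,
      lower_loa = lower_loa, upper_loa = upper_loa,
      n_outside = n_outside, n_within = n - n_outside,
      ba_index_pct = index,
      good_agreement = index <= index_threshold,
      k = k, index_threshold = index_threshold,
      variable = variable %||% "value",
      pairs = tibble::tibble(a = av, b = bv, mean = (av + bv) / 2, diff = d)
    ),
    class = "bland_altman"
  )
}

#' Bland-Altman index from counts
#'
#' The index is the percentage of pairs beyond the limits of agreement:
#' `100 * n_outside / n`.
#'
#' @param n_outside pairs strictly beyond the limits.
#' @param n total pairs.
#' @return percentage in \[0, 100\].
#' @export
#' @examples
#' ba_index_pct(27, 447)
ba_index_pct <- function(n_outside, n) {
  stopifnot(n > 0, n_outside >= 0, n_outside <= n)
  100 * n_outside / n
}

#' @export
print.bland_altman <- function(x, ...) {
  cat(sprintf("Bland-Altman agreement (%s), n = %d\n", x$variable, x$n))
  cat(sprintf("  bias %.3f, SD of differences %.3f\n", x$mean_diff,
              x$sd_diff))
  cat(sprintf("  limits of agreement [%.3f, %.3f] (k = %g)\n", x$lower_loa,
              x$upper_loa, x$k))
  cat(sprintf("  %d of %d within limits; index %.2f%% (%s agreement at %g%%)\n",
              x$n_within, x$n, x$ba_index_pct,
              if (x$good_agreement) "good" else "poor", x$index_threshold))
  invisible(x)
}

#' Per-pair Bland-Altman plot data
#'
#' @param x a `bland_altman` object.
#' @param ... unused.
#' @return tibble with one row per pair: `a`, `b`, `mean` ((a+b)/2), `diff`
#'   (a-b), plus the constant reference lines `bias`, `lower_loa`,
#'   `upper_loa`.
#' @export
tidy.bland_altman <- function(x, ...) {
  dplyr::mutate(x$pairs, bias = x$mean_diff, lower_loa = x$lower_loa,
                upper_loa = x$upper_loa)
}

#' One-row Bland-Altman summary
#'
#' @param x a `bland_altman` object.
#' @param ... unused.
#' @return one-row tibble: `variable`, `n`, `mean_diff`, `sd_diff`,
#'   `lower_loa`, `upper_loa`, `n_within`, `n_outside`, `ba_index_pct`,
#'   `good_agreement`.
#' @export
glance.bland_altman <- function(x, ...) {
  tibble::tibble(
    variable = x$variable, n = x$n, mean_diff = x$mean_diff,
    sd_diff = x$sd_diff, lower_loa = x$lower_loa, upper_loa = x$upper_loa,
    n_within = x$n_within, n_outside = x$n_outside,
    ba_index_pct = x$ba_index_pct, good_agreement = x$good_agreement
  )
}

#' Export Bland-Altman plot data to delimited text
#'
#' @param x a `bland_altman` object.
#' @param path output path.
#' @param delim delimiter.
#' @return `path`, invisibly.
#' @export
write_ba_plot_data <- function(x, path, delim = ",") {
  readr::write_delim(tidy(x), path, delim = delim, progress = FALSE)
  invisible(path)
}

#' Bland-Altman plot
#'
#' Scatter of per-pair difference against per-pair mean with horizontal
#' reference lines at the bias (solid) and both limits of agreement
#' (dashed).
#'
#' @param object a `bland_altman` object.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.bland_altman <- function(object, ...) {
  ggplot2::ggplot(object$pairs, ggplot2::aes(x = .data$mean,
                                             y = .data$diff)) +
    ggplot2::geom_point(alpha = 0.5) +
    ggplot2::geom_hline(yintercept = object$mean_diff) +
    ggplot2::geom_hline(yintercept = c(object$lower_loa, object$upper_loa),
                        linetype = "dashed") +
    ggplot2::labs(
      x = "Mean of the two methods (mg/day)",
      y = "Difference, method A - method B (mg/day)",
      title = sprintf("Bland-Altman: %s (index %.1f%%)", object$variable,
                      object$ba_index_pct)
    ) +
    ggplot2::theme_minimal()
}

#' Spearman rank correlation between two methods
#'
#' Rho on average (mid-)ranks with a two-sided p-value from the
#' t-approximation, the standard choice at cohort sample sizes.
#'
#' @inheritParams bland_altman
#' @return one-row tibble: `rho`, `p_value`, `n`.
#' @export
spearman_correlation <- function(data, a, b) {
  av <- dplyr::pull(data, {{ a }})
  bv <- dplyr::pull(data, {{ b }})
  keep <- stats::complete.cases(av, bv)
  av <- av[keep]
  bv <- bv[keep]
  if (length(av) < 3L) {
    rlang::abort("Spearman correlation needs at least 3 complete pairs",
                 class = "tocointake_domain_error")
  }
  if (stats::sd(av) == 0 || stats::sd(bv) == 0) {
    rlang::warn("constant series: Spearman rho undefined")
    return(tibble::tibble(rho = NA_real_, p_value = NA_real_,
                          n = length(av)))
  }
  ct <- suppressWarnings(
    stats::cor.test(av, bv, method = "spearman", exact = FALSE)
  )
  tibble::tibble(rho = unname(ct$estimate), p_value = ct$p.value,
                 n = length(av))
}

#' Mann-Whitney U test between two samples
#'
#' U computed from joint midranks (`U = #\{a > b\} + 0.5 * #\{a = b\}` over
#' all cross pairs); two-sided p-value from the normal approximation with
#' tie and continuity corrections.
#'
#' @param values_a,values_b numeric samples.
#' @return one-row tibble: `u_statistic`, `p_value`, `n_a`, `n_b`.
#' @export
mann_whitney_test <- function(values_a, values_b) {
  values_a <- values_a[!is.na(values_a)]
  values_b <- values_b[!is.na(values_b)]
  if (!length(values_a) || !length(values_b)) {
    rlang::abort("both samples must be nonempty",
                 class = "tocointake_domain_error")
  }
  wt <- suppressWarnings(
    stats::wilcox.test(values_a, values_b, exact = FALSE, correct = TRUE)
  )
  tibble::tibble(u_statistic = unname(wt$statistic), p_value = wt$p.value,
                 n_a = length(values_a), n_b = length(values_b))
}

#' Shapiro-Wilk normality gate
#'
#' Tests normality of a series and flags whether downstream comparisons
#' should take the nonparametric path (p <= alpha).
#'
#' @param values numeric sample, 3 <= n <= 5000.
#' @param alpha rejection level, default 0.05.
#' @return one-row tibble: `statistic`, `p_value`, `n`, `nonparametric`.
#' @export
normality_gate <- function(values, alpha = 0.05) {
  values <- values[!is.na(values)]
  n <- length(values)
  if (n < 3L || n > 5000L) {
    rlang::abort("Shapiro-Wilk requires 3 <= n <= 5000",
                 class = "tocointake_domain_error")
  }
  sw <- stats::shapiro.test(values)
  tibble::tibble(statistic = unname(sw$statistic), p_value = sw$p.value,
                 n = n, nonparametric = sw$p.value <= alpha)
}

#' Method-comparison report across intake variables
#'
#' Runs the full agreement battery — Bland-Altman limits and index, Spearman
#' rank correlation, Mann-Whitney U — for each intake variable shared by two
#' aligned intake tables (the eight isoforms, the tocopherol and tocotrienol
#' sums, and alpha-TE by default). Tables are joined on `respondent_id`.
#'
#' @param intake_a,intake_b intake tables from the two methods (e.g.
#'   [compute_intake()] output and a 1-day-record table).
#' @param variables intake columns to compare.
#' @param k,index_threshold passed to [bland_altman()].
#' @return tibble with one row per variable: bias, SD, both limits,
#'   `n_within`, `within_label` ("x out of n"), `ba_index_pct`,
#'   `good_agreement`, `rho`, `rho_p`, `u_statistic`, `u_p`.
#' @export
agreement_report <- function(intake_a, intake_b,
                             variables = c(isoform_cols(added = FALSE),
                                           "sum_tocopherols",
                                           "sum_tocotrienols", "alpha_te"),
                             k = 1.96, index_threshold = 5) {
  joined <- dplyr::inner_join(
    tibble::as_tibble(intake_a), tibble::as_tibble(intake_b),
    by = "respondent_id", suffix = c("_a", "_b")
  )
  if (nrow(joined) < 2L) {
    rlang::abort("fewer than 2 respondents shared between the two tables",
                 class = "tocointake_domain_error")
  }
  purrr::map_dfr(variables, function(v) {
    a <- joined[[paste0(v, "_a")]]
    b <- joined[[paste0(v, "_b")]]
    ba <- bland_altman(tibble::tibble(a = a, b = b), a, b, k = k,
                       index_threshold = index_threshold, variable = v)
    sp <- spearman_correlation(tibble::tibble(a = a, b = b), a, b)
    mw <- mann_whitney_test(a, b)
    glance(ba) |>
      dplyr::mutate(
        within_label = sprintf("%d out of %d", .data$n_within, .data$n),
        rho = sp$rho, rho_p = sp$p_value,
        u_statistic = mw$u_statistic, u_p = mw$p_value
      )
  })
}

#' Write an agreement report to delimited text
#'
#' Columns mirror the shape of a published method-comparison table:
#' variable, bias, both limits of agreement, "x out of n" within-limits
#' count, and the index in percent, plus the rank statistics.
#'
#' @param report output of [agreement_report()].
#' @param path output path.
#' @param delim delimiter.
#' @return `path`, invisibly.
#' @export
write_agreement <- function(report, path, delim = ",") {
  readr::write_delim(report, path, delim = delim, progress = FALSE)
  invisible(path)
}
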