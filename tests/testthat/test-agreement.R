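test_that("limits of agreement follow the bias +/- k*SD construction", {
  set.seed(31)
  d <- tibble::tibble(a = stats::rnorm(50, 10, 3),
                      b = stats::rnorm(50, 10, 3))
  ba <- bland_altman(d, a, b)
  diffs <- d$a - d$b
  expect_equal(ba$mean_diff, mean(diffs))
  expect_equal(ba$sd_diff, stats::sd(diffs))  # n-1 denominator
  expect_equal(ba$lower_loa, ba$mean_diff - 1.96 * ba$sd_diff)
  expect_equal(ba$upper_loa, ba$mean_diff + 1.96 * ba$sd_diff)
  expect_equal(ba$ba_index_pct, 100 * ba$n_outside / ba$n)
  # vectorised count equals a scalar recount
  recount <- 0L
  for (x in diffs) {
    if (x < ba$lower_loa || x > ba$upper_loa) recount <- recount + 1L
  }
  expect_equal(ba$n_outside, recount)
})

test_that("one difference in twenty beyond the limits gives index 5", {
  # 19 tight differences and one extreme outlier
  d <- tibble::tibble(
    a = c(rep(c(10, 10.5), 9), 10.2, 60),
    b = c(rep(c(10.2, 10.1), 9), 10.4, 10)
  )
  ba <- bland_altman(d, a, b)
  expect_equal(ba$n, 20L)
  expect_equal(ba$n_outside, 1L)
  expect_equal(ba$ba_index_pct, 5.0)
  expect_true(ba$good_agreement)
})

test_that("points exactly on a limit count as within", {
  # differences alternate -1/+1; with k = 1/sd the limits fall exactly on
  # +/-1, so every point sits on a boundary
  n <- 20
  d <- tibble::tibble(a = rep(c(0, 2), n / 2), b = rep(1, n))
  ba <- bland_altman(d, a, b, k = 1 / stats::sd(d$a - d$b))
  expect_equal(ba$lower_loa, -1)
  expect_equal(ba$upper_loa, 1)
  expect_equal(ba$n_outside, 0L)
  expect_equal(ba$ba_index_pct, 0)
})

test_that("swapping methods reflects bias and limits, keeps the index", {
  set.seed(8)
  d <- tibble::tibble(a = stats::rlnorm(80, 2, 0.4),
                      b = stats::rlnorm(80, 2, 0.5))
  ab <- bland_altman(d, a, b)
  ba <- bland_altman(d, b, a)
  expect_equal(ba$mean_diff, -ab$mean_diff)
  expect_equal(ba$sd_diff, ab$sd_diff)
  expect_equal(ba$lower_loa, -ab$upper_loa)
  expect_equal(ba$upper_loa, -ab$lower_loa)
  expect_equal(ba$ba_index_pct, ab$ba_index_pct)
})

test_that("degenerate agreement inputs are handled explicitly", {
  expect_error(bland_altman(tibble::tibble(a = 1, b = 2), a, b),
               class = "tocointake_domain_error")
  expect_warning(
    ba <- bland_altman(tibble::tibble(a = rep(1, 5), b = rep(1, 5)), a, b),
    "zero variance"
  )
  expect_equal(ba$ba_index_pct, 0)
})

test_that("plot data mirrors the fitted agreement object", {
  d <- tibble::tibble(a = c(1, 2, 3), b = c(2, 2, 2))
  ba <- bland_altman(d, a, b)
  td <- tidy(ba)
  expect_equal(nrow(td), 3L)
  expect_equal(td$mean, (d$a + d$b) / 2)
  expect_equal(td$diff, d$a - d$b)
  expect_equal(unique(td$bias), ba$mean_diff)
  expect_equal(unique(td$lower_loa), ba$lower_loa)
  expect_equal(unique(td$upper_loa), ba$upper_loa)

  path <- withr::local_tempfile(fileext = ".csv")
  write_ba_plot_data(ba, path)
  back <- readr::read_csv(path, show_col_types = FALSE)
  expect_equal(tibble::as_tibble(back), td)

  gl <- glance(ba)
  expect_equal(gl$n_within + gl$n_outside, gl$n)
  p <- autoplot(ba)
  expect_s3_class(p, "ggplot")
})

test_that("Spearman rho is exact on monotone data and matches midrank Pearson", {
  d <- tibble::tibble(a = c(1, 2, 5, 9), b = c(2, 4, 6, 20))
  expect_equal(spearman_correlation(d, a, b)$rho, 1.0)
  d_rev <- dplyr::mutate(d, b = rev(b))
  expect_equal(spearman_correlation(d_rev, a, b)$rho, -1.0)

  # ties: rho equals Pearson correlation of midranks (independent oracle)
  set.seed(5)
  x <- sample(1:4, 30, replace = TRUE)
  y <- x + sample(0:2, 30, replace = TRUE)
  got <- spearman_correlation(tibble::tibble(a = x, b = y), a, b)$rho
  expect_equal(got, stats::cor(rank(x), rank(y)), tolerance = 1e-12)
})

test_that("Spearman is invariant under strictly increasing transforms", {
  set.seed(6)
  d <- tibble::tibble(a = stats::rlnorm(40), b = stats::rlnorm(40))
  base <- spearman_correlation(d, a, b)
  trans <- spearman_correlation(
    dplyr::mutate(d, a = log(a), b = exp(b / 10)), a, b
  )
  expect_equal(trans$rho, base$rho)
  expect_equal(trans$p_value, base$p_value)
})

test_that("constant series yield an undefined rho with a warning", {
  d <- tibble::tibble(a = rep(1, 5), b = 1:5)
  expect_warning(out <- spearman_correlation(d, a, b), "constant")
  expect_true(is.na(out$rho))
})

test_that("Mann-Whitney U matches exhaustive pair counting", {
  # identical samples: U = n_a * n_b / 2
  expect_equal(mann_whitney_test(1:6, 1:6)$u_statistic, 18)
  # complete separation: U = n_a * n_b or 0
  expect_equal(mann_whitney_test(11:15, 1:5)$u_statistic, 25)
  expect_equal(mann_whitney_test(1:5, 11:15)$u_statistic, 0)

  set.seed(9)
  for (i in 1:5) {
    a <- sample(1:8, 7, replace = TRUE)
    b <- sample(1:8, 5, replace = TRUE)
    u_oracle <- 0
    for (x in a) for (y in b) {
      u_oracle <- u_oracle + (x > y) + 0.5 * (x == y)
    }
    expect_equal(mann_whitney_test(a, b)$u_statistic, u_oracle)
  }
})

test_that("the normality gate routes clearly non-normal data to ranks", {
  set.seed(12)
  unif <- stats::runif(447)
  gate <- normality_gate(unif)
  expect_true(gate$nonparametric)

  norm <- stats::rnorm(100)
  gate2 <- normality_gate(norm)
  expect_false(gate2$nonparametric)

  expect_error(normality_gate(c(1, 2)), class = "tocointake_domain_error")
})

test_that("the agreement report covers all intake variables coherently", {
  cohort <- gen_cohort(synth_config(n_respondents = 40), seed = 21)
  rep <- agreement_report(cohort$ffq_intake, cohort$record_intake)
  expect_equal(rep$variable,
               c(isoform_cols(added = FALSE), "sum_tocopherols",
                 "sum_tocotrienols", "alpha_te"))
  expect_equal(rep$lower_loa, rep$mean_diff - 1.96 * rep$sd_diff)
  expect_equal(rep$upper_loa, rep$mean_diff + 1.96 * rep$sd_diff)
  expect_equal(rep$ba_index_pct, 100 * rep$n_outside / rep$n)
  expect_equal(rep$within_label,
               sprintf("%d out of %d", rep$n_within, rep$n))
  expect_true(all(rep$rho >= -1 & rep$rho <= 1))

  path <- withr::local_tempfile(fileext = ".csv")
  write_agreement(rep, path)
  expect_true(file.exists(path))
})
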