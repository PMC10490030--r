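test_that("weekly servings normalise to daily portions", {
  expect_equal(daily_portions(7), 1.0)
  expect_equal(daily_portions(3.5), 0.5)
  expect_equal(daily_portions(0), 0)
  expect_error(daily_portions(-1), class = "tocointake_domain_error")
})

test_that("item intake is linear in portions per day", {
  per_portion <- content_per_portion(tiny_instrument()[1, ], tiny_db())
  half <- item_daily_intake(0.5, per_portion)
  expect_equal(half$alpha_t, 1.25)
  expect_true(all(unlist(item_daily_intake(0, per_portion)) == 0))
  expect_equal(unlist(item_daily_intake(2, per_portion)),
               unlist(half) * 4)
  expect_error(item_daily_intake(-0.1, per_portion),
               class = "tocointake_domain_error")
})

test_that("single-item chained arithmetic: 7 servings/week of a 30 g portion", {
  inst <- as_ffq_instrument(tibble::tibble(
    item_id = "x", label = "X", group = "nuts and oilseeds",
    portion_g = 30, unit = "g", household_measure = "2 tablespoons",
    member_food_ids = list("food_x")
  ))
  db <- as_composition_db(tibble::tibble(
    food_id = "food_x", name = "x", group = "nuts and oilseeds",
    alpha_t = 25, beta_t = 0, gamma_t = 0, delta_t = 0,
    alpha_t3 = 0, beta_t3 = 0, gamma_t3 = 0, delta_t3 = 0, added_vit_e = 0
  ))
  resp <- tibble::tibble(respondent_id = "r1", sex = "male",
                         item_id = "x", servings_per_week = 7)
  out <- compute_intake(resp, inst, db)
  expect_equal(out$alpha_t, 7.5)
  expect_equal(out$alpha_te, 7.5)
  expect_equal(out$sum_tocopherols, 7.5)
  expect_equal(out$sum_tocotrienols, 0)
})

test_that("an all-zero response yields an all-zero intake", {
  out <- compute_intake(tiny_responses(servings = c(0, 0, 0)),
                        tiny_instrument(), tiny_db())
  mass_cols <- setdiff(names(out), c("respondent_id", "sex"))
  expect_true(all(unlist(out[mass_cols]) == 0))
})

test_that("intake matches a brute-force double-loop rescoring", {
  inst <- builtin_instrument()
  db <- make_fixture_db(seed = 11, instrument = inst)
  set.seed(42)
  resp <- tibble::tibble(
    respondent_id = rep(sprintf("r%02d", 1:5), each = nrow(inst)),
    sex = rep(c("female", "male", "female", "male", "female"),
              each = nrow(inst)),
    item_id = rep(inst$item_id, times = 5),
    servings_per_week = round(stats::rgamma(5 * nrow(inst), 1.5, 0.5), 2)
  )
  out <- compute_intake(resp, inst, db)
  oracle <- brute_force_intake(resp, inst, db)
  for (rid in names(oracle)) {
    got <- unlist(out[out$respondent_id == rid, isoform_cols()])
    expect_equal(got, oracle[[rid]], tolerance = 1e-12)
  }
})

test_that("the pipeline is homogeneous in servings", {
  inst <- tiny_instrument()
  db <- tiny_db()
  base <- tiny_responses(servings = c(2, 5, 1.5))
  out1 <- compute_intake(base, inst, db)
  for (c_scale in c(0.5, 2, 3.7)) {
    scaled <- base
    scaled$servings_per_week <- scaled$servings_per_week * c_scale
    out2 <- compute_intake(scaled, inst, db)
    mass_cols <- setdiff(names(out1), c("respondent_id", "sex"))
    expect_equal(unlist(out2[mass_cols]), unlist(out1[mass_cols]) * c_scale)
  }
})

test_that("group breakdown reconciles with the daily totals", {
  inst <- builtin_instrument()
  db <- make_fixture_db(seed = 7, instrument = inst)
  cohort <- gen_cohort(synth_config(n_respondents = 8), db = db, seed = 7)
  daily <- cohort$ffq_intake
  by_grp <- intake_by_group(cohort$responses, inst, db)
  regrouped <- by_grp |>
    dplyr::group_by(respondent_id) |>
    dplyr::summarise(dplyr::across(dplyr::all_of(isoform_cols()), sum))
  joined <- dplyr::inner_join(
    daily, regrouped, by = "respondent_id", suffix = c("", ".grp")
  )
  for (col in isoform_cols()) {
    expect_equal(joined[[paste0(col, ".grp")]], joined[[col]],
                 tolerance = 1e-9)
  }
})

test_that("intake sums satisfy their defining identities", {
  cohort <- gen_cohort(synth_config(n_respondents = 12), seed = 9)
  x <- cohort$ffq_intake
  expect_equal(x$sum_tocopherols,
               x$alpha_t + x$beta_t + x$gamma_t + x$delta_t)
  expect_equal(x$sum_tocotrienols,
               x$alpha_t3 + x$beta_t3 + x$gamma_t3 + x$delta_t3)
  expect_equal(x$total_isoforms, x$sum_tocopherols + x$sum_tocotrienols)
  expect_true(all(x$alpha_te >= x$alpha_t))
})

test_that("alpha-TE applies the activity coefficients", {
  row <- function(...) {
    v <- stats::setNames(rep(0, 9), isoform_cols())
    over <- c(...)
    v[names(over)] <- over
    tibble::as_tibble_row(as.list(v))
  }
  expect_equal(alpha_te(row(alpha_t = 1)), 1.0)
  # 1 mg of each natural isoform: 1 + 0.4 + 0.1 + 0.01 + 0.3 + 0.05 + 0.01
  ones <- row(alpha_t = 1, beta_t = 1, gamma_t = 1, delta_t = 1,
              alpha_t3 = 1, beta_t3 = 1, gamma_t3 = 1, delta_t3 = 1)
  expect_equal(alpha_te(ones), 1.87)
  # delta-tocotrienol is outside the conventional formula
  expect_equal(alpha_te(row(delta_t3 = 5)), 0.0)
  # ... unless a weight is supplied
  expect_equal(alpha_te(row(delta_t3 = 5), conversion_weights(delta_t3 = 0.01)),
               0.05)
  # added vitamin E folds in at weight 1 by default, 0 when disabled
  expect_equal(alpha_te(row(added_vit_e = 2)), 2.0)
  expect_equal(
    alpha_te(row(added_vit_e = 2),
             conversion_weights(fold_added_as_alpha = FALSE)),
    0.0
  )
})

test_that("alpha-TE is linear and monotone in each component", {
  w <- conversion_weights()
  set.seed(1)
  for (i in 1:5) {
    a <- tibble::as_tibble_row(as.list(stats::setNames(
      stats::runif(9, 0, 10), isoform_cols())))
    b <- tibble::as_tibble_row(as.list(stats::setNames(
      stats::runif(9, 0, 10), isoform_cols())))
    expect_equal(alpha_te(a + b, w), alpha_te(a, w) + alpha_te(b, w))
    expect_gte(alpha_te(a + b, w), alpha_te(a, w))
  }
})

test_that("intake tables round-trip through text and JSON writers", {
  out <- compute_intake(tiny_responses(), tiny_instrument(), tiny_db())
  csv <- withr::local_tempfile(fileext = ".csv")
  write_intake(out, csv)
  expect_equal(tibble::as_tibble(read_intake(csv)),
               tibble::as_tibble(out), ignore_attr = TRUE,
               tolerance = 1e-12)
  js <- withr::local_tempfile(fileext = ".json")
  write_intake(out, js)
  expect_equal(tibble::as_tibble(read_intake(js)),
               tibble::as_tibble(out), ignore_attr = TRUE,
               tolerance = 1e-6)
  # presentation rounding applies only to the written file
  csv2 <- withr::local_tempfile(fileext = ".csv")
  write_intake(out, csv2, report_decimals = 1)
  rounded <- read_intake(csv2)
  expect_equal(rounded$alpha_t, round(out$alpha_t, 1))
})
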