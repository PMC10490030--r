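# Tiny in-code fixtures shared across test files.

# 3-item instrument over 2 groups, with one pooled item.
tiny_instrument <- function() {
  as_ffq_instrument(tibble::tibble(
    item_id = c("oil_a", "nuts_ab", "veg_c"),
    label = c("Oil A", "Nuts A/B", "Vegetable C"),
    group = c("fats", "nuts and oilseeds", "vegetables"),
    portion_g = c(10, 30, 100),
    unit = "g",
    household_measure = c("1 tablespoon", "2 tablespoons", "2/3 cup"),
    member_food_ids = list("oil_a", c("nut_a", "nut_b"), "veg_c")
  ))
}

# Composition for the tiny instrument, hand-picked round numbers (mg/100 g).
tiny_db <- function() {
  as_composition_db(tibble::tibble(
    food_id = c("oil_a", "nut_a", "nut_b", "veg_c"),
    name = c("oil a", "nut a", "nut b", "vegetable c"),
    group = c("fats", "nuts and oilseeds", "nuts and oilseeds",
              "vegetables"),
    alpha_t = c(25, 20, 10, 1),
    beta_t = c(0.5, 0.2, 0.4, 0),
    gamma_t = c(40, 10, 30, 0.5),
    delta_t = c(1, 0.5, 0.1, 0),
    alpha_t3 = c(0.2, 0, 0, 0),
    beta_t3 = c(0, 0.1, 0.3, 0),
    gamma_t3 = c(0.1, 0, 0.2, 0),
    delta_t3 = c(0, 0.05, 0.05, 0),
    added_vit_e = c(2, 0, 0, 0)
  ))
}

tiny_responses <- function(servings = c(7, 3.5, 0),
                           respondent_id = "r1", sex = "female") {
  tibble::tibble(
    respondent_id = respondent_id, sex = sex,
    item_id = c("oil_a", "nuts_ab", "veg_c"),
    servings_per_week = servings
  )
}

# Independent brute-force scorer: plain nested loops over
# (respondent, item, isoform), no dplyr, no package arithmetic helpers.
brute_force_intake <- function(responses, instrument, db) {
  iso <- c("alpha_t", "beta_t", "gamma_t", "delta_t",
           "alpha_t3", "beta_t3", "gamma_t3", "delta_t3", "added_vit_e")
  ids <- unique(responses$respondent_id)
  out <- list()
  for (rid in ids) {
    rows <- responses[responses$respondent_id == rid, ]
    total <- setNames(rep(0, length(iso)), iso)
    for (j in seq_len(nrow(instrument))) {
      item <- instrument[j, ]
      hit <- rows$servings_per_week[rows$item_id == item$item_id]
      if (length(hit) == 0 || hit == 0) next
      members <- item$member_food_ids[[1]]
      for (k in iso) {
        per100 <- 0
        for (m in members) per100 <- per100 + db[[k]][db$food_id == m]
        per100 <- per100 / length(members)
        per_portion <- per100 * item$portion_g / 100
        total[k] <- total[k] + (hit / 7) * per_portion
      }
    }
    out[[rid]] <- total
  }
  out
}
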