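# The built-in semiquantitative vitamin E FFQ: 41 line items over 8 food
# groups, each with a standard portion (g or mL) and a household measure.
# Pooled rows ("Almonds/sunflower seeds") expand to member foods through
# member_food_ids; scoring averages the members' composition.

builtin_items <- function() {
  it <- function(item_id, label, group, portion_g, unit, measure, members) {
    tibble::tibble(
      item_id = item_id, label = label, group = group,
      portion_g = portion_g, unit = unit, household_measure = measure,
      member_food_ids = list(members)
    )
  }
  dplyr::bind_rows(
    # vegetables
    it("veg_brassicas", "Broccoli/brussels sprouts/kale/asparagus/leeks",
       "vegetables", 100, "g", "2/3 cup; 2 handfuls of leaves",
       c("broccoli", "brussels_sprouts", "kale", "asparagus", "leeks")),
    it("veg_roots", "Carrots/parsley root", "vegetables", 100, "g",
       "2/3 cup", c("carrots", "parsley_root")),
    it("veg_peas_tomatoes", "Green peas/tomatoes", "vegetables", 100, "g",
       "2/3 cup", c("green_peas", "tomatoes")),
    it("veg_mixed", "Beetroot/beet greens/pumpkin/red peppers/turnip",
       "vegetables", 100, "g", "2/3 cup; 2 handfuls of leaves",
       c("beetroot", "beet_greens", "pumpkin", "red_peppers", "turnip")),
    it("veg_leafy", "Lettuce/romaine lettuce/spinach/chicory/rucola",
       "vegetables", 100, "g", "2/3 cup; 2 handfuls",
       c("lettuce", "romaine_lettuce", "spinach", "chicory", "rucola")),
    it("corn", "Corn", "vegetables", 20, "g", "1 tablespoon", "corn"),
    it("veg_juice", "Carrot juice/multivegetable juices", "vegetables",
       200, "mL", "1 cup", c("carrot_juice", "multivegetable_juice")),
    it("veg_other", "Other vegetables", "vegetables", 100, "g",
       "2/3 cup; 2 handfuls of leaves", "other_vegetables"),
    # fruit and fruit products
    it("kiwifruit", "Kiwifruit", "fruit and fruit products", 100, "g",
       "2/3 cup", "kiwifruit"),
    it("berries", "Raspberries/blackberries/blueberries",
       "fruit and fruit products", 100, "g", "2/3 cup",
       c("raspberries", "blackberries", "blueberries")),
    it("avocado", "Avocado", "fruit and fruit products", 70, "g",
       "1/2 medium piece", "avocado"),
    it("fruit_other", "Other fruit", "fruit and fruit products", 100, "g",
       "2/3 cup", "other_fruit"),
    # legumes and legume products
    it("legume_seeds", "Peas/lentils - dry seeds",
       "legumes and legume products", 15, "g", "1 tablespoon",
       c("dry_peas", "dry_lentils")),
    it("hummus", "Hummus", "legumes and legume products", 10, "g",
       "1 teaspoon", "hummus"),
    # nuts and oilseeds
    it("pumpkin_seeds", "Pumpkin seeds", "nuts and oilseeds", 30, "g",
       "2 tablespoons", "pumpkin_seeds"),
    it("linseeds", "Linseeds", "nuts and oilseeds", 30, "g",
       "2 tablespoons", "linseeds"),
    it("pistachios_pecans", "Pistachios/pecans", "nuts and oilseeds", 30,
       "g", "2 tablespoons", c("pistachios", "pecans")),
    it("almonds_sunflower", "Almonds/sunflower seeds", "nuts and oilseeds",
       30, "g", "2 tablespoons", c("almonds", "sunflower_seeds")),
    it("almond_drink", "Almond drink", "nuts and oilseeds", 200, "mL",
       "1 cup", "almond_drink"),
    it("hazelnuts", "Hazelnuts", "nuts and oilseeds", 30, "g",
       "2 tablespoons", "hazelnuts"),
    it("peanuts", "Peanuts", "nuts and oilseeds", 30, "g",
       "2 tablespoons", "peanuts"),
    it("pine_nuts", "Pine nuts", "nuts and oilseeds", 30, "g",
       "2 tablespoons", "pine_nuts"),
    it("nuts_other", "Other nuts, e.g., walnuts, cashews",
       "nuts and oilseeds", 30, "g", "2 tablespoons",
       c("walnuts", "cashews")),
    # fats
    it("canola_oil", "Canola oil", "fats", 10, "g", "1 tablespoon",
       "canola_oil"),
    it("sunflower_oil", "Sunflower oil", "fats", 10, "g", "1 tablespoon",
       "sunflower_oil"),
    it("olive_oil", "Olive oil", "fats", 10, "g", "1 tablespoon",
       "olive_oil"),
    it("grapeseed_oil", "Grape-seed oil", "fats", 10, "g", "1 tablespoon",
       "grapeseed_oil"),
    it("peanut_oil", "Peanut oil", "fats", 10, "g", "1 tablespoon",
       "peanut_oil"),
    it("wheat_germ_oil", "Wheat germ oil", "fats", 10, "g", "1 tablespoon",
       "wheat_germ_oil"),
    it("soybean_oil", "Soybean oil", "fats", 10, "g", "1 tablespoon",
       "soybean_oil"),
    it("coconut_oil", "Coconut oil", "fats", 10, "g", "1 tablespoon",
       "coconut_oil"),
    it("margarine", "Margarine", "fats", 10, "g", "1 tablespoon",
       "margarine"),
    it("mayonnaise", "Mayonnaise", "fats", 10, "g", "1 tablespoon",
       "mayonnaise"),
    it("pesto", "Pesto", "fats", 10, "g", "1 teaspoon", "pesto"),
    it("eggs", "Eggs", "fats", 50, "g", "1 piece", "eggs"),
    # cereals: bread portion 35 g (other cereal products 75 g; see vignette)
    it("wholegrain_cereals",
       "Wholemeal bread, whole wheat pasta/brown rice/cornflakes",
       "cereals", 35, "g", "1 slice or cup of dry product",
       c("wholemeal_bread", "whole_wheat_pasta", "brown_rice", "cornflakes")),
    # fish and fish products
    it("fresh_fish", "Fresh fish, e.g., salmon, trout, mackerel, herring",
       "fish and fish products", 100, "g", "1 piece",
       c("salmon", "trout", "mackerel", "herring")),
    it("canned_fish_oil",
       "Canned fish in oil, e.g., mackerel, tuna, herring, sardines",
       "fish and fish products", 150, "g", "1 medium can",
       c("canned_mackerel_in_oil", "canned_tuna_in_oil",
         "canned_herring_in_oil", "canned_sardines_in_oil")),
    it("fish_other",
       "Other fish, e.g., canned fish in water/in tomatoes, flounder, carp, fish fingers",
       "fish and fish products", 150, "g", "1 medium can",
       c("canned_fish_in_water", "canned_fish_in_tomatoes", "flounder",
         "carp", "fish_fingers")),
    # snacks and others
    it("dark_chocolate", "Dark chocolate", "snacks and others", 5, "g",
       "1 cube", "dark_chocolate"),
    it("chips_crackers", "Chips/crackers/nachos", "snacks and others", 10,
       "g", "1 handful", c("chips", "crackers", "nachos"))
  )
}

#' The built-in vitamin E FFQ instrument
#'
#' Returns the packaged 41-item semiquantitative FFQ covering the 8 food
#' groups of [food_groups()]. Each item carries its standard portion size
#' (100 g for most vegetables and fruit, 30 g nuts and seeds, 10 g oils,
#' 200 mL juices and almond drink, ...), a household measure, and the list of
#' member foods it pools. Respondents report usual servings per week;
#' fractional values are allowed.
#'
#' @return an `ffq_instrument`: a tibble of items with a
#'   `recall_period_days` attribute (7; servings are asked per week).
#' @export
#' @examples
#' inst <- builtin_instrument()
#' nrow(inst)
#' dplyr::n_distinct(inst$group)
builtin_instrument <- function() {
  as_ffq_instrument(builtin_items())
}

#' Validate a data frame as an FFQ instrument
#'
#' @param items tibble with columns `item_id`, `label`, `group`, `portion_g`,
#'   `unit` ("g" or "mL"), `household_measure`, `member_food_ids`
#'   (list column).
#' @param recall_period_days divisor used to normalise reported servings to
#'   portions per day (default 7: servings are reported per week).
#' @return an `ffq_instrument` tibble.
#' @export
as_ffq_instrument <- function(items, recall_period_days = 7) {
  required <- c("item_id", "label", "group", "portion_g", "unit",
                "household_measure", "member_food_ids")
  missing <- setdiff(required, names(items))
  if (length(missing)) {
    rlang::abort(sprintf("instrument is missing column(s): %s",
                         paste(missing, collapse = ", ")),
                 class = "tocointake_schema_error")
  }
  items <- tibble::as_tibble(items)[required]
  if (anyDuplicated(items$item_id)) {
    rlang::abort("duplicate item_id in instrument",
                 class = "tocointake_validation_error")
  }
  if (any(items$portion_g <= 0 | !is.finite(items$portion_g))) {
    rlang::abort("portion_g must be positive and finite",
                 class = "tocointake_validation_error")
  }
  if (any(!nzchar(items$label))) {
    rlang::abort("item labels must be nonempty",
                 class = "tocointake_validation_error")
  }
  bad_group <- setdiff(unique(items$group), food_groups())
  if (length(bad_group)) {
    rlang::abort(sprintf("unknown food group(s): %s",
                         paste(bad_group, collapse = ", ")),
                 class = "tocointake_validation_error")
  }
  structure(items, recall_period_days = recall_period_days,
            class = c("ffq_instrument", class(tibble::tibble())))
}

#' Write / read an FFQ instrument as YAML
#'
#' Round-trippable structured-text serialisation for user-modified
#' instruments; [load_instrument()] re-validates on read.
#'
#' @param instrument an `ffq_instrument`.
#' @param path file path.
#' @return `path` (write) or an `ffq_instrument` (load).
#' @export
write_instrument <- function(instrument, path) {
  payload <- list(
    recall_period_days = attr(instrument, "recall_period_days"),
    items = purrr::pmap(instrument, function(item_id, label, group,
                                             portion_g, unit,
                                             household_measure,
                                             member_food_ids) {
      list(item_id = item_id, label = label, group = group,
           portion_g = portion_g, unit = unit,
           household_measure = household_measure,
           member_food_ids = as.list(member_food_ids))
    })
  )
  yaml::write_yaml(payload, path)
  invisible(path)
}

#' @rdname write_instrument
#' @export
load_instrument <- function(path) {
  if (!file.exists(path)) {
    rlang::abort(sprintf("instrument file not found: %s", path),
                 class = "tocointake_io_error")
  }
  payload <- yaml::read_yaml(path)
  items <- purrr::map_dfr(payload$items, function(x) {
    tibble::tibble(
      item_id = x$item_id, label = x$label, group = x$group,
      portion_g = as.numeric(x$portion_g), unit = x$unit,
      household_measure = x$household_measure,
      member_food_ids = list(unlist(x$member_food_ids))
    )
  })
  as_ffq_instrument(items,
                    recall_period_days = payload$recall_period_days %||% 7)
}
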