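# Label -> trait lookup for the 51 calibration dishes (17 per trait).

food_trait_entries <- function() {
  block <- c("Roasted meat", "Stir-fried pork with bamboo shoots",
             "Chicken thigh block", "Sweet and sour pork ribs",
             "Braised beans with potatoes", "Potato grilled pork ribs",
             "Eggplant chunks", "Pork meatballs", "Mushroom and chicken",
             "Halogen pig's feet", "Radish flank", "Fried yam block",
             "Fried chicken wings", "Tomato scrambled eggs",
             "Konjac roast duck", "Steak", "French fries")
  slice <- c("Vinegar cabbage", "Shredded pork with Beijing sauce",
             "Bean sprouts salad", "Fried lettuce silk",
             "Green pepper shredded pork", "Fried pork with garlic sprouts",
             "Stir-fried pork with mushrooms", "Shredded onion",
             "Sausage slices", "Sliced ham", "Shredded chicken",
             "Vegetable salad", "Cold noodles", "Needle mushroom with sauce",
             "Dried fish fillet", "Sliced carrot", "Potato silk")
  grain <- c("Cucumber salad", "Chicken diced", "Stir-fried lotus root diced",
             "Stir-fried pork with lettuce diced", "Shrimp corn",
             "Cowpea fleshy foam", "Fried diced chicken", "Spicy chicken",
             "Bean curd butyl", "Beef granules", "Ham fried rice",
             "Carrot dices", "Mushroom butyl", "Green pepper corn",
             "Groundnut kernels", "Pea", "Bamboo butyl")
  data.frame(
    food = c(block, slice, grain),
    trait = rep(trait_classes(), times = c(length(block), length(slice),
                                           length(grain))),
    stringsAsFactors = FALSE
  )
}

#' Registered foods and their trait classes
#'
#' The 51 dishes in the shipped calibration vocabulary with their
#' morphology trait (17 per trait).
#'
#' @return Data frame with columns `food` and `trait`.
#' @export
food_traits <- function() food_trait_entries()

#' Look up the trait of a food label
#'
#' Case-insensitive lookup in the shipped 51-dish vocabulary.
#'
#' @param label Food name.
#' @return The trait code, or `NA_character_` for an unknown label.
#' @examples
#' lookup_trait("French fries")  # block_thick_bar
#' lookup_trait("Pea")           # grain_granule
#' @export
lookup_trait <- function(label) {
  tab <- food_trait_entries()
  hit <- match(tolower(label), tolower(tab$food))
  if (is.na(hit)) NA_character_ else tab$trait[hit]
}
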