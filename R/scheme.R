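#' Regulatory scheme for the front-of-pack "high in" symbol
#'
#' A `fop_scheme` bundles every regulatory constant the classifier needs:
#' the daily values (DVs) used to express thresholds, the three tier
#' fractions, the small-reference-amount cutoff, the per-category reference
#' amounts, the set of mixed-dish categories assessed at the higher tier,
#' optional per-category densities (for g <-> mL conversion), and declarative
#' exemption rules. All of it is data, never code, so regulation-sourced
#' constants can be swapped without touching the package.
#'
#' The shipped defaults follow Canadian labelling practice: DVs of 2300 mg
#' sodium, 20 g saturated fat and 100 g total sugars; tiers of 15 % of the DV
#' for most foods, 30 % for mixed dishes (frozen meals, pizzas) and 10 % for
#' categories whose reference amount is at most 30 g (or 30 mL); and a
#' threshold comparison on the larger of the label serving size and the
#' reference amount. Reference amounts per category are illustrative
#' placeholders in the style of Health Canada's Table of Reference Amounts.
#'
#' @param daily_values named numeric: DV per nutrient of concern
#'   (`sodium` in mg, `saturated_fat` and `total_sugar` in g).
#' @param tier_fractions named numeric with entries `default`,
#'   `small_reference_amount` and `mixed_dish`, each in (0, 1].
#' @param small_ra_cutoff reference-amount cutoff (same number for g and mL)
#'   at or below which the small-reference-amount tier applies.
#' @param reference_amounts tibble with columns `category`, `amount`, `unit`
#'   ("g" or "mL"), one row per registered category.
#' @param mixed_dish_categories character vector of category ids assessed at
#'   the mixed-dish tier; must be a subset of the registered categories.
#' @param densities optional named numeric (g per mL) per category, used to
#'   convert a label serving declared in the other unit family than the
#'   category's reference amount.
#' @param exemption_rules list of rules created by [exemption_rule()].
#' @return An object of class `fop_scheme`.
#' @seealso [default_scheme()], [read_scheme()], [classify()]
#' @export
fop_scheme <- function(daily_values = c(sodium = 2300, saturated_fat = 20, total_sugar = 100),
                       tier_fractions = c(default = 0.15,
                                          small_reference_amount = 0.10,
                                          mixed_dish = 0.30),
                       small_ra_cutoff = 30,
                       reference_amounts,
                       mixed_dish_categories = character(),
                       densities = NULL,
                       exemption_rules = list()) {
  scheme <- structure(
    list(
      daily_values = daily_values,
      tier_fractions = tier_fractions,
      small_ra_cutoff = small_ra_cutoff,
      reference_amounts = tibble::as_tibble(reference_amounts),
      mixed_dish_categories = mixed_dish_categories,
      densities = densities,
      exemption_rules = exemption_rules
    ),
    class = "fop_scheme"
  )
  validate_scheme(scheme)
}

#' @export
print.fop_scheme <- function(x, ...) {
  cat("<fop_scheme>\n")
  cat("  daily values:",
      paste(names(x$daily_values), x$daily_values, sep = "=", collapse = ", "), "\n")
  cat("  tiers:",
      paste(names(x$tier_fractions), x$tier_fractions, sep = "=", collapse = ", "),
      sprintf("(small-RA cutoff %s)\n", x$small_ra_cutoff))
  cat("  categories:", nrow(x$reference_amounts),
      sprintf("(%d mixed-dish)\n", length(x$mixed_dish_categories)))
  cat("  exemption rules:", length(x$exemption_rules), "\n")
  invisible(x)
}

validate_scheme <- function(scheme) {
  nutrients <- fop_nutrients()
  if (!all(nutrients %in% names(scheme$daily_values))) {
    stop("daily_values must name all of: ", paste(nutrients, collapse = ", "),
         call. = FALSE)
  }
  if (any(scheme$daily_values[nutrients] <= 0)) {
    stop("all daily values must be > 0", call. = FALSE)
  }
  tf <- scheme$tier_fractions
  need <- c("default", "small_reference_amount", "mixed_dish")
  if (!all(need %in% names(tf))) {
    stop("tier_fractions must name: ", paste(need, collapse = ", "), call. = FALSE)
  }
  if (any(tf[need] <= 0 | tf[need] > 1)) {
    stop("tier fractions must lie in (0, 1]", call. = FALSE)
  }
  ra <- scheme$reference_amounts
  if (!all(c("category", "amount", "unit") %in% names(ra))) {
    stop("reference_amounts needs columns category, amount, unit", call. = FALSE)
  }
  if (anyDuplicated(ra$category)) {
    stop("duplicate category in reference_amounts", call. = FALSE)
  }
  if (any(ra$amount <= 0)) stop("reference amounts must be > 0", call. = FALSE)
  if (!all(ra$unit %in% c("g", "mL"))) {
    stop("reference amount units must be 'g' or 'mL'", call. = FALSE)
  }
  bad <- setdiff(scheme$mixed_dish_categories, ra$category)
  if (length(bad)) {
    stop("mixed-dish categories not registered: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  for (rule in scheme$exemption_rules) {
    stopifnot(is.list(rule), !is.null(rule$rule_id), !is.null(rule$attribute),
              rule$comparator %in% c(">=", ">", "<=", "<", "=="))
  }
  scheme
}

# the three nutrients the symbol covers, in canonical order
fop_nutrients <- function() c("sodium", "saturated_fat", "total_sugar")

# column of the products table holding each nutrient's per-serving amount
fop_nutrient_cols <- function() {
  c(sodium = "sodium_mg", saturated_fat = "saturated_fat_g",
    total_sugar = "total_sugar_g")
}

#' Declarative exemption rule
#'
#' An exemption removes the symbol requirement for products matching a simple
#' predicate on an `exemption_*` attribute (e.g. yoghurts whose calcium
#' content reaches 15 % of the DV). Rules are evaluated independently and any
#' match exempts the product.
#'
#' @param rule_id short unique identifier.
#' @param applies_to character vector of category ids the rule covers.
#' @param attribute name of the exemption attribute (matched against the
#'   products table column `exemption_<attribute>`).
#' @param comparator one of `">="`, `">"`, `"<="`, `"<"`, `"=="`.
#' @param threshold numeric value the attribute is compared against.
#' @return A list describing the rule, for use in [fop_scheme()].
#' @export
exemption_rule <- function(rule_id, applies_to, attribute, comparator, threshold) {
  stopifnot(is.character(rule_id), length(rule_id) == 1,
            comparator %in% c(">=", ">", "<=", "<", "=="),
            is.numeric(threshold))
  list(rule_id = rule_id, applies_to = applies_to, attribute = attribute,
       comparator = comparator, threshold = threshold)
}

#' Default illustrative scheme (15 Canadian processed-food categories)
#'
#' Registers the fifteen monitored categories with placeholder reference
#' amounts in the style of Health Canada's Table of Reference Amounts, the
#' Canadian labelling DVs, the three-tier threshold structure, and one
#' illustrative exemption (yoghurts and dairy desserts with calcium at or
#' above 15 % of the DV). The reference amounts and the calcium cutoff are
#' editable config, not regulation text.
#'
#' @return A `fop_scheme`.
#' @export
default_scheme <- function() {
  ra <- tibble::tribble(
    ~category,                          ~amount, ~unit,
    "rte_breakfast_cereals",                 30, "g",
    "sliced_breads",                         50, "g",
    "luncheon_meats",                        55, "g",
    "ready_to_serve_soups",                 250, "mL",
    "pizzas",                               140, "g",
    "granola_bars",                          30, "g",
    "frozen_meals",                         250, "g",
    "pasta_sauces",                         125, "mL",
    "yoghurts_dairy_desserts",              175, "g",
    "sausages",                              75, "g",
    "cookies",                               30, "g",
    "crackers",                              20, "g",
    "salty_snacks",                          50, "g",
    "processed_cheeses",                     30, "g",
    "flavoured_milks_plant_beverages",      250, "mL"
  )
  fop_scheme(
    reference_amounts = ra,
    mixed_dish_categories = c("frozen_meals", "pizzas"),
    densities = c(ready_to_serve_soups = 1.0, pasta_sauces = 1.05,
                  flavoured_milks_plant_beverages = 1.03),
    exemption_rules = list(
      exemption_rule("yoghurt_high_calcium",
                     applies_to = "yoghurts_dairy_desserts",
                     attribute = "calcium_pct_dv",
                     comparator = ">=", threshold = 15)
    )
  )
}

#' Read or write a scheme as YAML
#'
#' The on-disk form mirrors the `fop_scheme` fields one-to-one so a scheme
#' round-trips exactly.
#'
#' @param path file path to a YAML scheme file.
#' @return `read_scheme()` returns a `fop_scheme`; `write_scheme()` returns
#'   `path` invisibly.
#' @export
read_scheme <- function(path) {
  raw <- yaml::read_yaml(path)
  fop_scheme(
    daily_values = unlist(raw$daily_values),
    tier_fractions = unlist(raw$tier_fractions),
    small_ra_cutoff = raw$small_ra_cutoff,
    reference_amounts = tibble::tibble(
      category = vapply(raw$reference_amounts, `[[`, "", "category"),
      amount = vapply(raw$reference_amounts, function(r) as.numeric(r$amount), 0),
      unit = vapply(raw$reference_amounts, `[[`, "", "unit")
    ),
    mixed_dish_categories = as.character(unlist(raw$mixed_dish_categories %||% list())),
    densities = if (length(raw$densities)) unlist(raw$densities) else NULL,
    exemption_rules = lapply(raw$exemption_rules %||% list(), function(r) {
      exemption_rule(r$rule_id, as.character(unlist(r$applies_to)),
                     r$attribute, r$comparator, as.numeric(r$threshold))
    })
  )
}

#' @rdname read_scheme
#' @param scheme a `fop_scheme`.
#' @export
write_scheme <- function(scheme, path) {
  out <- list(
    daily_values = as.list(scheme$daily_values),
    tier_fractions = as.list(scheme$tier_fractions),
    small_ra_cutoff = scheme$small_ra_cutoff,
    reference_amounts = lapply(seq_len(nrow(scheme$reference_amounts)), function(i) {
      as.list(scheme$reference_amounts[i, ])
    }),
    mixed_dish_categories = as.list(scheme$mixed_dish_categories),
    densities = as.list(scheme$densities %||% list()),
    exemption_rules = scheme$exemption_rules
  )
  yaml::write_yaml(out, path)
  invisible(path)
}
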