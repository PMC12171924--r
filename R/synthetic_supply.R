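#' Specify one synthetic food category
#'
#' Defines the generative model for a category of the synthetic supply:
#' nutrient amounts per serving are drawn from lognormal marginals
#' parameterised by method of moments from the target mean/SD (guaranteeing
#' non-negativity and right skew, the shape nutrient contents show in
#' practice); sales volumes are heavy-tailed lognormal; and each product is
#' independently missing from the sales table with probability
#' `1 - match_probability`, emulating an incomplete label-to-sales match.
#'
#' @param category category id (must be registered in the scheme used
#'   downstream).
#' @param n_products number of products (>= 1).
#' @param serving_sizes numeric vector: a discrete set of label serving
#'   sizes sampled uniformly, or a named `c(min = , max = )` pair for a
#'   continuous uniform range.
#' @param serving_unit `"g"` or `"mL"`.
#' @param nutrients named list mapping each of `energy_kj`, `total_fat_g`,
#'   `saturated_fat_g`, `total_sugar_g`, `fibre_g`, `protein_g`, `sodium_mg`
#'   to a `c(mean, sd)` target per serving. SD 0 gives a constant.
#' @param correlation optional exchangeable inter-nutrient correlation in
#'   \[0, 1), implemented through a Gaussian copula; default 0 (independent).
#' @param sales `c(meanlog, sdlog)` of the lognormal sales-kg distribution.
#' @param match_probability probability that a product's code appears in the
#'   sales table (default 0.79).
#' @param exemption_attributes optional named list mapping an attribute
#'   (e.g. `calcium_pct_dv`) to a lognormal `c(mean, sd)` target.
#' @return An object of class `category_spec`.
#' @export
category_spec <- function(category, n_products, serving_sizes,
                          serving_unit = "g", nutrients,
                          correlation = 0,
                          sales = c(meanlog = 6.5, sdlog = 1.4),
                          match_probability = 0.79,
                          exemption_attributes = NULL) {
  stopifnot(n_products >= 1, match_probability >= 0, match_probability <= 1,
            correlation >= 0, correlation < 1)
  need <- product_nutrient_cols()
  missing_nut <- setdiff(need, names(nutrients))
  if (length(missing_nut)) {
    stop("nutrient targets missing for: ", paste(missing_nut, collapse = ", "),
         call. = FALSE)
  }
  for (nut in need) {
    tgt <- nutrients[[nut]]
    if (length(tgt) != 2 || tgt[2] < 0) {
      stop("nutrient target for ", nut, " must be c(mean, sd) with sd >= 0",
           call. = FALSE)
    }
    if (tgt[1] <= 0 && tgt[2] > 0) {
      stop("infeasible lognormal moments for ", nut,
           ": positive SD requires a positive mean", call. = FALSE)
    }
  }
  structure(list(category = category, n_products = as.integer(n_products),
                 serving_sizes = serving_sizes, serving_unit = serving_unit,
                 nutrients = nutrients, correlation = correlation,
                 sales = sales, match_probability = match_probability,
                 exemption_attributes = exemption_attributes),
            class = "category_spec")
}

#' Specify a whole synthetic supply
#'
#' @param categories list of [category_spec()] objects with unique ids.
#' @return An object of class `supply_spec`.
#' @export
supply_spec <- function(categories) {
  ids <- vapply(categories, `[[`, "", "category")
  if (anyDuplicated(ids)) stop("category ids must be unique", call. = FALSE)
  structure(list(categories = categories), class = "supply_spec")
}

# lognormal method-of-moments: mean m > 0, sd s >= 0
lnorm_moments <- function(m, s) {
  sigma2 <- log(1 + (s / m)^2)
  list(meanlog = log(m) - sigma2 / 2, sdlog = sqrt(sigma2))
}

#' Generate a synthetic label + sales supply
#'
#' Draws every category of the spec in order, fully reproducibly from the
#' seed: serving sizes, the seven per-serving nutrients (lognormal marginals,
#' optional Gaussian-copula correlation), exemption attributes, heavy-tailed
#' sales volumes, and the Bernoulli label-to-sales match. Sales dollars are
#' derived from kilograms through a lognormal price per kg, and units from an
#' assumed pack of eight servings; both are carried for completeness, while
#' all weighted statistics downstream use kilograms.
#'
#' @param spec a [supply_spec()].
#' @param seed integer seed; the same seed reproduces the tables exactly.
#' @return A list with `products` (label tibble, CSV-ready) and `sales`
#'   (sales tibble covering the matched subset).
#' @export
generate_supply <- function(spec, seed) {
  stopifnot(inherits(spec, "supply_spec"))
  withr::with_seed(as.integer(seed), {
    prod_list <- list()
    sales_list <- list()
    for (i in seq_along(spec$categories)) {
      cs <- spec$categories[[i]]
      g <- generate_category(cs, code_prefix = sprintf("P%02d", i))
      prod_list[[i]] <- g$products
      sales_list[[i]] <- g$sales
    }
    products <- dplyr::bind_rows(prod_list)
    sales <- dplyr::bind_rows(sales_list)
    list(products = products, sales = sales)
  })
}

generate_category <- function(cs, code_prefix) {
  n <- cs$n_products
  serving <- if (!is.null(names(cs$serving_sizes)) &&
                 all(c("min", "max") %in% names(cs$serving_sizes))) {
    round(stats::runif(n, cs$serving_sizes[["min"]], cs$serving_sizes[["max"]]))
  } else if (length(cs$serving_sizes) == 1) {
    rep(cs$serving_sizes, n)
  } else {
    sample(cs$serving_sizes, n, replace = TRUE)
  }

  nut_cols <- product_nutrient_cols()
  k <- length(nut_cols)
  # Gaussian copula: exchangeable correlation across nutrients
  z <- matrix(stats::rnorm(n * k), n, k)
  if (cs$correlation > 0) {
    R <- matrix(cs$correlation, k, k); diag(R) <- 1
    z <- z %*% chol(R)
  }
  u <- stats::pnorm(z)

  products <- tibble::tibble(
    product_code = sprintf("%s%05d", code_prefix, seq_len(n)),
    category = cs$category,
    brand = sprintf("Brand %s", sample(LETTERS, n, replace = TRUE)),
    serving_size = serving,
    serving_unit = cs$serving_unit
  )
  for (j in seq_along(nut_cols)) {
    tgt <- cs$nutrients[[nut_cols[j]]]
    products[[nut_cols[j]]] <- if (tgt[2] == 0) rep(tgt[1], n) else {
      lm <- lnorm_moments(tgt[1], tgt[2])
      stats::qlnorm(u[, j], lm$meanlog, lm$sdlog)
    }
  }
  for (attr_name in names(cs$exemption_attributes %||% list())) {
    tgt <- cs$exemption_attributes[[attr_name]]
    lm <- lnorm_moments(tgt[1], tgt[2])
    products[[paste0("exemption_", attr_name)]] <- stats::rlnorm(n, lm$meanlog, lm$sdlog)
  }

  sales_kg <- stats::rlnorm(n, cs$sales[["meanlog"]], cs$sales[["sdlog"]])
  price_per_kg <- stats::rlnorm(n, log(8), 0.4)
  matched <- stats::rbinom(n, 1, cs$match_probability) == 1
  sales_cad <- sales_kg * price_per_kg
  sales_units <- pmax(1, round(sales_kg * 1000 / (serving * 8)))
  sales <- tibble::tibble(
    product_code = products$product_code[matched],
    sales_kg = sales_kg[matched],
    sales_cad = sales_cad[matched],
    sales_units = sales_units[matched]
  )
  list(products = products, sales = sales)
}

#' Boundary fixture: products placed at known multiples of their threshold
#'
#' Builds a small label table for one category in which product *i*'s
#' target-nutrient amount at basis is exactly `threshold * (1 + f_i)`, so the
#' flag status of every product — at baseline and under any uniform
#' reduction — is analytically known. The serving size equals the category's
#' reference amount, making the basis equal the serving and the per-serving
#' amount exact. All other nutrients are 0.
#'
#' @param scheme a [fop_scheme()].
#' @param category registered category id.
#' @param fractions numeric vector in (-1, 1): signed offsets from threshold.
#' @param nutrient target nutrient (default `"sodium"`).
#' @return A products tibble, one row per fraction.
#' @export
generate_boundary_fixture <- function(scheme, category, fractions,
                                      nutrient = "sodium") {
  nutrient <- match.arg(nutrient, fop_nutrients())
  stopifnot(all(fractions > -1), all(fractions < 1))
  ra <- scheme$reference_amounts
  idx <- match(category, ra$category)
  if (is.na(idx)) stop("unregistered category: ", category, call. = FALSE)
  tier <- select_tier(category, scheme)
  threshold <- tier * scheme$daily_values[[nutrient]]
  n <- length(fractions)
  out <- tibble::tibble(
    product_code = sprintf("BF%03d", seq_len(n)),
    category = category,
    brand = "Boundary",
    serving_size = ra$amount[idx],
    serving_unit = ra$unit[idx]
  )
  for (col in product_nutrient_cols()) out[[col]] <- 0
  out[[fop_nutrient_cols()[[nutrient]]]] <- threshold * (1 + fractions)
  out
}

#' Uniform unit sales for a products table
#'
#' Convenience for fixtures: a sales table matching every product with equal
#' weight, so weighted and unweighted statistics coincide.
#'
#' @param products a products tibble.
#' @param kg_each sales kg per product (default 1).
#' @return A sales tibble.
#' @export
uniform_sales <- function(products, kg_each = 1) {
  tibble::tibble(product_code = products$product_code,
                 sales_kg = kg_each, sales_cad = kg_each * 8,
                 sales_units = 1L)
}

#' Default synthetic supply specification (15 categories)
#'
#' Encodes the fifteen monitored categories with illustrative per-serving
#' nutrient targets of realistic magnitude for the Canadian packaged-food
#' supply: sodium-dense soups, luncheon meats, processed cheeses and pizzas;
#' sugar-dense cookies, sweetened beverages and breakfast cereals;
#' saturated-fat-dense sausages, pizzas and frozen meals. Serving sizes sit
#' at or near each category's reference amount; sales are heavy-tailed; the
#' label-to-sales match probability is 0.79 throughout. Yoghurts carry a
#' calcium exemption attribute. These targets are the package's own
#' assumptions, not measurements.
#'
#' @return A [supply_spec()] compatible with [default_scheme()].
#' @export
default_supply_spec <- function() {
  nut <- function(energy, fat, satfat, sugar, fibre, protein, sodium_mg,
                  energy_sd = energy * 0.25, fat_sd = fat * 0.4,
                  satfat_sd, sugar_sd, fibre_sd = fibre * 0.5,
                  protein_sd = protein * 0.35, sodium_sd) {
    list(energy_kj = c(energy, energy_sd),
         total_fat_g = c(fat, fat_sd),
         saturated_fat_g = c(satfat, satfat_sd),
         total_sugar_g = c(sugar, sugar_sd),
         fibre_g = c(fibre, fibre_sd),
         protein_g = c(protein, protein_sd),
         sodium_mg = c(sodium_mg, sodium_sd))
  }
  supply_spec(list(
    category_spec("rte_breakfast_cereals", 380, c(30, 30, 40),
                  nutrients = nut(480, 1.5, 0.5, 8, 2.5, 3, 140,
                                  satfat_sd = 0.4, sugar_sd = 3, sodium_sd = 60)),
    category_spec("sliced_breads", 300, 50,
                  nutrients = nut(560, 2, 0.4, 3, 2, 5, 365,
                                  satfat_sd = 0.3, sugar_sd = 1.5, sodium_sd = 40)),
    category_spec("luncheon_meats", 330, c(55, 55, 60),
                  nutrients = nut(420, 5, 1.5, 1, 0.3, 10, 600,
                                  satfat_sd = 1, sugar_sd = 0.7, sodium_sd = 150)),
    category_spec("ready_to_serve_soups", 360, 250, serving_unit = "mL",
                  nutrients = nut(420, 3, 0.8, 4, 1.5, 4, 650,
                                  satfat_sd = 0.6, sugar_sd = 2, sodium_sd = 180)),
    category_spec("pizzas", 250, 140,
                  nutrients = nut(1450, 13, 6.8, 5, 2.5, 16, 850,
                                  satfat_sd = 1.4, sugar_sd = 2, sodium_sd = 200)),
    category_spec("granola_bars", 330, c(30, 35),
                  nutrients = nut(590, 5, 1, 7, 1.8, 2.5, 80,
                                  satfat_sd = 0.7, sugar_sd = 2.5, sodium_sd = 40)),
    category_spec("frozen_meals", 380, c(250, 300),
                  nutrients = nut(1500, 10, 5, 6, 3.5, 18, 800,
                                  satfat_sd = 2.5, sugar_sd = 3, sodium_sd = 250)),
    category_spec("pasta_sauces", 300, 125, serving_unit = "mL",
                  nutrients = nut(330, 2.5, 0.5, 6, 1.8, 2, 420,
                                  satfat_sd = 0.4, sugar_sd = 2.5, sodium_sd = 120)),
    category_spec("yoghurts_dairy_desserts", 420, 175,
                  nutrients = nut(620, 3.5, 1.8, 12, 0.2, 6, 90,
                                  satfat_sd = 1.2, sugar_sd = 5, sodium_sd = 40),
                  exemption_attributes = list(calcium_pct_dv = c(13, 6))),
    category_spec("sausages", 300, c(75, 100),
                  nutrients = nut(1000, 20, 6, 1.5, 0.3, 12, 550,
                                  satfat_sd = 2, sugar_sd = 1, sodium_sd = 150)),
    category_spec("cookies", 520, c(30, 30, 45),
                  nutrients = nut(620, 6.5, 2.2, 11.5, 1, 1.8, 90,
                                  satfat_sd = 0.8, sugar_sd = 2, sodium_sd = 40)),
    category_spec("crackers", 330, 20,
                  nutrients = nut(380, 3.5, 0.8, 1, 0.8, 1.8, 150,
                                  satfat_sd = 0.5, sugar_sd = 0.6, sodium_sd = 60)),
    category_spec("salty_snacks", 460, 50,
                  nutrients = nut(1050, 13, 1.8, 1.5, 2, 3, 330,
                                  satfat_sd = 1, sugar_sd = 1, sodium_sd = 100)),
    category_spec("processed_cheeses", 232, 30,
                  nutrients = nut(340, 5.5, 1.8, 1, 0, 4.5, 440,
                                  satfat_sd = 0.8, sugar_sd = 0.6, sodium_sd = 120)),
    category_spec("flavoured_milks_plant_beverages", 240, 250,
                  serving_unit = "mL",
                  nutrients = nut(800, 4, 1.5, 20, 0.5, 7, 120,
                                  satfat_sd = 1, sugar_sd = 6, sodium_sd = 50))
  ))
}
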