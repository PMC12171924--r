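#' Basis amount for the threshold comparison
#'
#' The regulation compares nutrient content at the larger of the label
#' serving size and the category's reference amount. Both quantities must be
#' in the same unit family; a serving declared in the other family is first
#' converted through an explicit density (g per mL) — without one the
#' comparison is refused rather than guessed.
#'
#' @param serving_size label serving size (numeric, in `serving_unit`).
#' @param reference_amount category reference amount (in `reference_unit`).
#' @param serving_unit,reference_unit `"g"` or `"mL"`.
#' @param density optional g-per-mL density used when the units differ.
#' @return Numeric basis amount expressed in `reference_unit`. Vectorised.
#' @export
basis_amount <- function(serving_size, reference_amount,
                         serving_unit = "g", reference_unit = serving_unit,
                         density = NULL) {
  serving <- convert_serving(serving_size, serving_unit, reference_unit, density)
  pmax(serving, reference_amount)
}

# convert a serving between unit families via density (g per mL)
convert_serving <- function(serving_size, from_unit, to_unit, density) {
  same <- from_unit == to_unit
  if (all(same)) return(serving_size)
  if (is.null(density) || any(is.na(density[!same]))) {
    stop("serving unit differs from reference-amount unit and no density ",
         "is configured for the conversion", call. = FALSE)
  }
  density <- rep_len(density, length(serving_size))
  out <- serving_size
  g_to_ml <- !same & from_unit == "g"
  ml_to_g <- !same & from_unit == "mL"
  out[g_to_ml] <- serving_size[g_to_ml] / density[g_to_ml]
  out[ml_to_g] <- serving_size[ml_to_g] * density[ml_to_g]
  out
}

#' Select the threshold tier for a category
#'
#' Mixed-dish categories are assessed at the 30 % tier; otherwise a category
#' whose reference amount is less than or equal to the small-RA cutoff
#' (boundary inclusive) takes the 10 % tier; all remaining categories take
#' the default 15 % tier. The branches are evaluated in that order and are
#' exhaustive and mutually exclusive, so exactly one tier is assigned.
#'
#' @param category character vector of registered category ids.
#' @param scheme a [fop_scheme()].
#' @return Numeric vector of tier fractions.
#' @export
select_tier <- function(category, scheme) {
  ra <- scheme$reference_amounts
  idx <- match(category, ra$category)
  if (anyNA(idx)) {
    stop("unregistered category: ",
         paste(unique(category[is.na(idx)]), collapse = ", "), call. = FALSE)
  }
  tf <- scheme$tier_fractions
  ifelse(category %in% scheme$mixed_dish_categories,
         tf[["mixed_dish"]],
         ifelse(ra$amount[idx] <= scheme$small_ra_cutoff,
                tf[["small_reference_amount"]],
                tf[["default"]]))
}

#' Rescale a per-serving nutrient amount to the basis amount
#'
#' Linear rescaling: `amount * basis / serving_size`. When the basis equals
#' the serving the amount is returned unchanged (exactly, with no
#' floating-point round trip).
#'
#' @param nutrient_per_serving amount per label serving.
#' @param serving_size label serving size (> 0, same unit family as basis).
#' @param basis basis amount from [basis_amount()].
#' @return Numeric amount at basis. Vectorised.
#' @export
amount_at_basis <- function(nutrient_per_serving, serving_size, basis) {
  if (any(!is.finite(serving_size) | serving_size <= 0)) {
    stop("serving_size must be > 0", call. = FALSE)
  }
  ifelse(basis == serving_size,
         nutrient_per_serving,
         nutrient_per_serving * basis / serving_size)
}

#' Classify products against the "high in" symbol rules
#'
#' For each product: exemption rules are evaluated first (any match exempts
#' and empties the flagged set); the tier fraction and basis amount are
#' resolved from the category; and each nutrient of concern (sodium,
#' saturated fat, total sugar) is flagged when its amount at basis meets or
#' exceeds `tier_fraction * DV` (inclusive ">=" comparison, on exact stored
#' values with no label rounding). Every intermediate quantity is recorded in
#' the verdict for audit.
#'
#' A missing nutrient value is handled by `missing_policy`: `"strict"` stops
#' with the product code; `"lenient"` (default) records an `NA` flag for
#' that nutrient, which never counts towards `n_flagged`.
#'
#' `classify()` takes a single product (one-row tibble or named list);
#' `classify_products()` is the vectorised form; `classify_supply()` runs on
#' the matched products of an [merge_by_code()] supply, order-stable.
#'
#' @param product one product record (one-row tibble or named list).
#' @param scheme a [fop_scheme()].
#' @param missing_policy `"lenient"` or `"strict"`.
#' @return A verdict tibble with one row per product: `product_code`,
#'   `category`, `exempted`, `exemption_rule_id`, `tier_fraction`,
#'   `basis_amount`, `basis_unit`, per-nutrient `<nutrient>_at_basis`,
#'   `<nutrient>_threshold`, `<nutrient>_flagged`, plus `n_flagged` and
#'   `any_flagged`.
#' @export
classify <- function(product, scheme, missing_policy = c("lenient", "strict")) {
  if (!is.data.frame(product)) product <- tibble::as_tibble(product)
  stopifnot(nrow(product) == 1)
  classify_products(product, scheme, missing_policy)
}

#' @rdname classify
#' @param products tibble of product records.
#' @export
classify_products <- function(products, scheme,
                              missing_policy = c("lenient", "strict")) {
  missing_policy <- match.arg(missing_policy)
  n <- nrow(products)
  nutrients <- fop_nutrients()
  if (n == 0) return(empty_verdicts())

  ra <- scheme$reference_amounts
  idx <- match(products$category, ra$category)
  if (anyNA(idx)) {
    stop("no reference amount configured for category: ",
         paste(unique(products$category[is.na(idx)]), collapse = ", "),
         call. = FALSE)
  }
  ra_amount <- ra$amount[idx]
  ra_unit <- ra$unit[idx]
  dens <- if (is.null(scheme$densities)) rep(NA_real_, n) else
    unname(scheme$densities[products$category])

  tier <- select_tier(products$category, scheme)
  serving_in_ra_unit <- convert_serving(products$serving_size,
                                        products$serving_unit, ra_unit, dens)
  basis <- pmax(serving_in_ra_unit, ra_amount)

  ex <- evaluate_exemptions(products, scheme)
  out <- tibble::tibble(
    product_code = products$product_code,
    category = products$category,
    exempted = as.logical(ex),
    exemption_rule_id = attr(ex, "rule_id"),
    tier_fraction = tier,
    basis_amount = basis,
    basis_unit = ra_unit
  )

  cols <- fop_nutrient_cols()
  n_flagged <- integer(n)
  for (nut in nutrients) {
    per_serving <- products[[cols[[nut]]]]
    at_basis <- amount_at_basis(per_serving, serving_in_ra_unit, basis)
    threshold <- tier * scheme$daily_values[[nut]]
    if (missing_policy == "strict" && anyNA(per_serving)) {
      stop("missing ", nut, " for product(s): ",
           paste(utils::head(products$product_code[is.na(per_serving)], 5),
                 collapse = ", "), call. = FALSE)
    }
    flagged <- at_basis >= threshold          # NA propagates under lenient
    flagged[out$exempted] <- FALSE            # exemption empties the flagged set
    out[[paste0(nut, "_at_basis")]] <- at_basis
    out[[paste0(nut, "_threshold")]] <- threshold
    out[[paste0(nut, "_flagged")]] <- flagged
    n_flagged <- n_flagged + ifelse(is.na(flagged), 0L, as.integer(flagged))
  }
  out$n_flagged <- n_flagged
  out$any_flagged <- n_flagged > 0L
  out
}

#' @rdname classify
#' @param supply an `fop_supply`.
#' @export
classify_supply <- function(supply, scheme,
                            missing_policy = c("lenient", "strict")) {
  classify_products(supply$matched, scheme, missing_policy)
}

empty_verdicts <- function() {
  nutrients <- fop_nutrients()
  out <- tibble::tibble(
    product_code = character(), category = character(),
    exempted = logical(), exemption_rule_id = character(),
    tier_fraction = numeric(), basis_amount = numeric(), basis_unit = character()
  )
  for (nut in nutrients) {
    out[[paste0(nut, "_at_basis")]] <- numeric()
    out[[paste0(nut, "_threshold")]] <- numeric()
    out[[paste0(nut, "_flagged")]] <- logical()
  }
  out$n_flagged <- integer()
  out$any_flagged <- logical()
  out
}

# evaluate exemption rules; any match exempts. Returns logical vector with a
# "rule_id" attribute giving the first matching rule per product (NA if none).
evaluate_exemptions <- function(products, scheme) {
  n <- nrow(products)
  exempted <- rep(FALSE, n)
  rule_id <- rep(NA_character_, n)
  for (rule in scheme$exemption_rules) {
    col <- paste0("exemption_", rule$attribute)
    if (!col %in% names(products)) next
    val <- products[[col]]
    hit <- products$category %in% rule$applies_to & !is.na(val) &
      switch(rule$comparator,
             ">=" = val >= rule$threshold,
             ">"  = val >  rule$threshold,
             "<=" = val <= rule$threshold,
             "<"  = val <  rule$threshold,
             "==" = val == rule$threshold)
    rule_id[hit & !exempted] <- rule$rule_id
    exempted <- exempted | hit
  }
  structure(exempted, rule_id = rule_id)
}
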