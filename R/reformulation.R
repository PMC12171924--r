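#' Reformulation scenario
#'
#' A scenario reduces exactly one nutrient of concern by a uniform fraction
#' across a scope of categories (default: all), modelling industry
#' reformulation. Reductions apply to the per-serving amount; since the
#' threshold comparison rescales linearly, this is equivalent to reducing
#' the amount at basis.
#'
#' @param nutrient one of `"sodium"`, `"saturated_fat"`, `"total_sugar"`.
#' @param reduction fraction in \[0, 1); the study grid is 0.05/0.10/0.15.
#' @param scope character vector of category ids, or `NULL` for all.
#' @return An object of class `fop_scenario`.
#' @export
fop_scenario <- function(nutrient, reduction, scope = NULL) {
  nutrient <- match.arg(nutrient, fop_nutrients())
  stopifnot(is.numeric(reduction), length(reduction) == 1,
            reduction >= 0, reduction < 1)
  structure(list(nutrient = nutrient, reduction = reduction, scope = scope),
            class = "fop_scenario")
}

#' Apply a reformulation scenario to product records
#'
#' Pure transformation: the target nutrient's per-serving amount is
#' multiplied by `1 - reduction` for in-scope products; every other field
#' (and every out-of-scope product) is untouched, and the input is never
#' modified.
#'
#' @param products a products tibble or an `fop_supply` (both the matched
#'   and unmatched products are then transformed).
#' @param scenario an [fop_scenario()].
#' @return An object of the same shape as `products`.
#' @export
apply_scenario <- function(products, scenario) {
  stopifnot(inherits(scenario, "fop_scenario"))
  if (inherits(products, "fop_supply")) {
    products$matched <- apply_scenario(products$matched, scenario)
    products$unmatched_products <- apply_scenario(products$unmatched_products, scenario)
    return(products)
  }
  col <- fop_nutrient_cols()[[scenario$nutrient]]
  in_scope <- if (is.null(scenario$scope)) rep(TRUE, nrow(products)) else
    products$category %in% scenario$scope
  products[[col]][in_scope] <- products[[col]][in_scope] * (1 - scenario$reduction)
  products
}

#' Percentage-point change between two prevalences
#'
#' `before - after`, both expressed on the 0–100 percentage scale. A drop
#' from 70 % to 48 % is a 22 percentage-point (pp) change.
#'
#' @param before,after percentages in \[0, 100\]. Vectorised.
#' @return Percentage points.
#' @export
pp_change <- function(before, after) {
  if (any(before < 0 | before > 100 | after < 0 | after > 100, na.rm = TRUE)) {
    stop("percentages must lie in [0, 100]", call. = FALSE)
  }
  before - after
}

#' Reformulation scenario grid (per-category prevalence shifts)
#'
#' For each target nutrient and each reduction on the grid (a baseline
#' reduction of 0 is always included), every in-scope product is reformulated,
#' the whole supply is re-classified, and the per-category and overall
#' prevalence of the symbol for that nutrient is tabulated together with the
#' percentage-point change from baseline. Prevalences are unweighted product
#' fractions over matched products; nothing is rounded in computation.
#'
#' @param supply an `fop_supply`.
#' @param scheme a [fop_scheme()].
#' @param nutrients target nutrients (default all three).
#' @param reductions reduction grid (default `c(0.05, 0.10, 0.15)`).
#' @param missing_policy passed to [classify_products()].
#' @return A tibble with columns `nutrient`, `category` (including
#'   `"(overall)"`), `reduction`, `n`, `prevalence_pct`, `baseline_pct`,
#'   `pp_change`.
#' @export
run_scenario_grid <- function(supply, scheme,
                              nutrients = fop_nutrients(),
                              reductions = c(0.05, 0.10, 0.15),
                              missing_policy = "lenient") {
  nutrients <- match.arg(nutrients, fop_nutrients(), several.ok = TRUE)
  reductions <- sort(unique(c(0, reductions)))
  products <- supply$matched

  prev_for <- function(verdicts, nutrient) {
    fl <- verdicts[[paste0(nutrient, "_flagged")]] %in% TRUE
    by_cat <- tibble::tibble(category = verdicts$category, flagged = fl) |>
      dplyr::group_by(.data$category) |>
      dplyr::summarise(n = dplyr::n(),
                       prevalence_pct = 100 * mean(.data$flagged),
                       .groups = "drop")
    dplyr::bind_rows(by_cat,
                     tibble::tibble(category = "(overall)",
                                    n = length(fl),
                                    prevalence_pct = 100 * mean(fl)))
  }

  rows <- list()
  for (nut in nutrients) {
    for (r in reductions) {
      sc <- fop_scenario(nut, r)
      v <- classify_products(apply_scenario(products, sc), scheme,
                             missing_policy = missing_policy)
      p <- prev_for(v, nut)
      p$nutrient <- nut
      p$reduction <- r
      rows[[length(rows) + 1]] <- p
    }
  }
  out <- dplyr::bind_rows(rows)
  base <- out[out$reduction == 0,
              c("nutrient", "category", "prevalence_pct")]
  names(base)[3] <- "baseline_pct"
  out <- dplyr::left_join(out, base, by = c("nutrient", "category"))
  out$pp_change <- pp_change(out$baseline_pct, out$prevalence_pct)
  dplyr::select(out, "nutrient", "category", "reduction", "n",
                "prevalence_pct", "baseline_pct", "pp_change")
}

#' Per-product deflagging detail for one scenario
#'
#' @param supply an `fop_supply`.
#' @param scheme a [fop_scheme()].
#' @param scenario an [fop_scenario()].
#' @return Tibble: `product_code`, `category`, `flagged_baseline`,
#'   `flagged_scenario`, `deflagged`.
#' @export
scenario_deflags <- function(supply, scheme, scenario) {
  col <- paste0(scenario$nutrient, "_flagged")
  v0 <- classify_products(supply$matched, scheme)
  v1 <- classify_products(apply_scenario(supply$matched, scenario), scheme)
  tibble::tibble(
    product_code = v0$product_code,
    category = v0$category,
    flagged_baseline = v0[[col]] %in% TRUE,
    flagged_scenario = v1[[col]] %in% TRUE,
    deflagged = (v0[[col]] %in% TRUE) & !(v1[[col]] %in% TRUE)
  )
}

#' Minimum reduction that removes a nutrient's symbol
#'
#' For a product flagged for `nutrient` at baseline: the exact closed-form
#' reduction at which the amount at basis reaches the threshold is
#' `1 - threshold / amount_at_basis`. Because the comparison is inclusive
#' (amounts exactly at threshold are flagged), that reduction itself still
#' flags; the reported grid value is the smallest multiple of `step` whose
#' scenario strictly unflags the nutrient. A product at exactly the
#' threshold has closed form 0 and deflags at any positive reduction.
#'
#' @param product one product record (one-row tibble or named list).
#' @param scheme a [fop_scheme()].
#' @param nutrient target nutrient.
#' @param step grid resolution (default 0.001).
#' @param max_reduction largest reduction considered achievable (default
#'   0.15, the top of the study grid).
#' @return A one-row tibble: `product_code`, `nutrient`, `closed_form`,
#'   `grid_reduction` (`NA` if no grid point at or below `max_reduction`
#'   unflags), `achievable`.
#' @export
minimum_deflag_reduction <- function(product, scheme, nutrient,
                                     step = 0.001, max_reduction = 0.15) {
  nutrient <- match.arg(nutrient, fop_nutrients())
  if (!is.data.frame(product)) product <- tibble::as_tibble(product)
  stopifnot(nrow(product) == 1)
  v <- classify_products(product, scheme)
  if (!isTRUE(v[[paste0(nutrient, "_flagged")]])) {
    stop("product ", product$product_code, " is not flagged for ", nutrient,
         " at baseline", call. = FALSE)
  }
  amount <- v[[paste0(nutrient, "_at_basis")]]
  threshold <- v[[paste0(nutrient, "_threshold")]]
  closed <- 1 - threshold / amount
  grid <- seq(0, max_reduction, by = step)
  unflags <- amount * (1 - grid) < threshold
  grid_reduction <- if (any(unflags)) grid[which(unflags)[1]] else NA_real_
  tibble::tibble(product_code = v$product_code, nutrient = nutrient,
                 closed_form = closed, grid_reduction = grid_reduction,
                 achievable = !is.na(grid_reduction))
}
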