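#' Sales-weighted mean
#'
#' `sum(w * x) / sum(w)`, the category average in which each product
#' contributes proportionally to its sales volume, approximating what the
#' population actually buys. With all weights equal it reduces to the
#' arithmetic mean. A zero total weight leaves the mean undefined and is
#' reported as `NA` (missing), never 0.
#'
#' @param values numeric vector of per-product amounts.
#' @param weights non-negative weights (sales in kg), same length.
#' @return The weighted mean, or `NA` when `sum(weights) == 0`.
#' @export
weighted_mean <- function(values, weights) {
  stopifnot(length(values) == length(weights))
  if (any(weights < 0, na.rm = TRUE)) stop("weights must be >= 0", call. = FALSE)
  sw <- sum(weights)
  if (!isTRUE(sw > 0)) return(NA_real_)
  sum(weights * values) / sw
}

#' Sales-weighted standard deviation
#'
#' Frequency-weight population form
#' `sqrt( sum(w * (x - m)^2) / sum(w) )` around the weighted mean `m`,
#' with no reliability correction. Invariant to rescaling all weights by a
#' constant. A single product has no spread: the SD is reported as 0 and
#' carries the attribute `single = TRUE` as a flag.
#'
#' @inheritParams weighted_mean
#' @return The weighted SD (0, flagged, for a single observation).
#' @export
weighted_sd <- function(values, weights) {
  stopifnot(length(values) == length(weights))
  if (length(values) == 1) return(structure(0, single = TRUE))
  m <- weighted_mean(values, weights)
  if (is.na(m)) return(NA_real_)
  sqrt(sum(weights * (values - m)^2) / sum(weights))
}

#' Per-category nutritional portrait (weighted by sales)
#'
#' Sales-weighted mean and SD of each per-serving nutrient, per category —
#' the "what the population buys" portrait. Values are per label serving
#' (the label-facing quantity) by default; `per_100 = TRUE` rescales each
#' product to per-100 g (or per-100 mL) before averaging, for cross-category
#' comparisons.
#'
#' @param supply an `fop_supply` from [merge_by_code()]; only matched
#'   products enter weighted statistics.
#' @param weighting `"sales_kg"` (default) or `"unweighted"`.
#' @param per_100 rescale amounts to per-100 g/mL before averaging.
#' @return A tibble: one row per category with `n_products` and
#'   `<nutrient>_mean` / `<nutrient>_sd` columns.
#' @export
category_summary <- function(supply, weighting = c("sales_kg", "unweighted"),
                             per_100 = FALSE) {
  weighting <- match.arg(weighting)
  x <- supply$matched
  cols <- product_nutrient_cols()
  if (per_100) {
    for (col in cols) x[[col]] <- x[[col]] / x$serving_size * 100
  }
  w <- if (weighting == "sales_kg") x$sales_kg else rep(1, nrow(x))
  x$.w <- w
  x |>
    dplyr::group_by(.data$category) |>
    dplyr::group_modify(function(d, key) {
      out <- tibble::tibble(n_products = nrow(d))
      for (col in cols) {
        stem <- sub("_(kj|g|mg)$", "", col)
        out[[paste0(stem, "_mean")]] <- weighted_mean(d[[col]], d$.w)
        out[[paste0(stem, "_sd")]] <- as.numeric(weighted_sd(d[[col]], d$.w))
      }
      out
    }) |>
    dplyr::ungroup()
}

#' Symbol prevalence per nutrient and flagged-nutrient distribution
#'
#' For each category and overall: the fraction of products flagged per
#' nutrient, the fraction flagged for at least one nutrient, and the
#' distribution of products over 0/1/2/3 flagged nutrients. The default is
#' unweighted product counts (the regulation's burden is per product); a
#' sales-weighted variant is available by passing per-product weights.
#'
#' @param verdicts verdict tibble from [classify_products()].
#' @param weights optional non-negative per-product weights (e.g. sales kg);
#'   `NULL` (default) gives unweighted product fractions.
#' @return A tibble with one row per category plus an `"(overall)"` row:
#'   `n`, per-nutrient prevalence fractions, `any_symbol`, and `p_flagged_0`
#'   .. `p_flagged_3` (summing to 1).
#' @export
prevalence_table <- function(verdicts, weights = NULL) {
  if (nrow(verdicts) == 0) stop("no verdicts to tabulate", call. = FALSE)
  if (is.null(weights)) weights <- rep(1, nrow(verdicts))
  stopifnot(length(weights) == nrow(verdicts))
  verdicts$.w <- weights

  one_group <- function(d) {
    sw <- sum(d$.w)
    out <- tibble::tibble(n = nrow(d))
    for (nut in fop_nutrients()) {
      fl <- d[[paste0(nut, "_flagged")]]
      out[[nut]] <- sum(d$.w * (fl %in% TRUE)) / sw
    }
    out$any_symbol <- sum(d$.w * (d$n_flagged > 0)) / sw
    for (k in 0:3) {
      out[[paste0("p_flagged_", k)]] <- sum(d$.w * (d$n_flagged == k)) / sw
    }
    out
  }
  by_cat <- verdicts |>
    dplyr::group_by(.data$category) |>
    dplyr::group_modify(function(d, key) one_group(d)) |>
    dplyr::ungroup()
  overall <- one_group(verdicts)
  overall$category <- "(overall)"
  dplyr::bind_rows(by_cat, overall)
}
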