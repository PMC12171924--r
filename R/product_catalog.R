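#' Load a product-label table
#'
#' Reads the label database CSV into a validated tibble. Required columns:
#' `product_code`, `category`, `brand`, `serving_size`, `serving_unit`, and
#' the seven per-serving nutrients `energy_kj`, `total_fat_g`,
#' `saturated_fat_g`, `total_sugar_g`, `fibre_g`, `protein_g`, `sodium_mg`.
#' Optional `exemption_*` columns carry attributes used by exemption rules.
#'
#' Unit canonicalisation happens here and never downstream: sodium is stored
#' in mg and mass nutrients in g. A file whose sodium column is declared in
#' grams (column `sodium_g`) is converted to mg on load; energy declared in
#' kcal (`energy_kcal`) is converted to kJ.
#'
#' Row-level validation requires `serving_size > 0`, all nutrient amounts
#' non-negative, `serving_unit` in g/mL and, when a scheme is supplied, a
#' registered category. Invalid rows are never silently dropped: with
#' `on_invalid = "error"` (default) loading aborts naming the offending
#' product codes; with `"warn"` the invalid rows are removed, a warning is
#' raised and the removed rows are attached as `attr(x, "problems")`.
#'
#' @param path CSV file path (UTF-8, header required).
#' @param scheme optional [fop_scheme()]; when given, categories are checked
#'   against its registry.
#' @param on_invalid `"error"` or `"warn"`.
#' @return A tibble of validated product records.
#' @export
load_products <- function(path, scheme = NULL, on_invalid = c("error", "warn")) {
  on_invalid <- match.arg(on_invalid)
  x <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)

  # alternate-unit columns accepted at load, converted to canonical units
  if (!"sodium_mg" %in% names(x) && "sodium_g" %in% names(x)) {
    x$sodium_mg <- x$sodium_g * 1000
    x$sodium_g <- NULL
  }
  if (!"energy_kj" %in% names(x) && "energy_kcal" %in% names(x)) {
    x$energy_kj <- x$energy_kcal * 4.184
    x$energy_kcal <- NULL
  }

  required <- c("product_code", "category", "brand", "serving_size",
                "serving_unit", product_nutrient_cols())
  missing_cols <- setdiff(required, names(x))
  if (length(missing_cols)) {
    stop("products file is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  x$product_code <- normalise_code(x$product_code)
  validate_products(x, scheme = scheme, on_invalid = on_invalid)
}

# per-serving nutrient columns in canonical units
product_nutrient_cols <- function() {
  c("energy_kj", "total_fat_g", "saturated_fat_g", "total_sugar_g",
    "fibre_g", "protein_g", "sodium_mg")
}

#' Validate product records
#'
#' @param products tibble of product records.
#' @inheritParams load_products
#' @return The validated tibble (invalid rows removed under `"warn"`).
#' @export
validate_products <- function(products, scheme = NULL,
                              on_invalid = c("error", "warn")) {
  on_invalid <- match.arg(on_invalid)
  probs <- character(nrow(products))
  bad_serving <- !is.finite(products$serving_size) | products$serving_size <= 0
  probs[bad_serving] <- "serving_size must be > 0"
  bad_unit <- !products$serving_unit %in% c("g", "mL")
  probs[bad_unit & probs == ""] <- "serving_unit must be 'g' or 'mL'"
  for (col in product_nutrient_cols()) {
    neg <- !is.na(products[[col]]) & products[[col]] < 0
    probs[neg & probs == ""] <- paste0("negative ", col)
  }
  if (!is.null(scheme)) {
    unreg <- !products$category %in% scheme$reference_amounts$category
    probs[unreg & probs == ""] <- "category not registered in scheme"
  }
  bad <- probs != ""
  if (any(bad)) {
    report <- tibble::tibble(product_code = products$product_code[bad],
                             problem = probs[bad])
    msg <- paste0(nrow(report), " invalid product row(s): ",
                  paste(utils::head(paste0(report$product_code, " (",
                                           report$problem, ")"), 5),
                        collapse = "; "),
                  if (nrow(report) > 5) " ..." else "")
    if (on_invalid == "error") stop(msg, call. = FALSE)
    warning(msg, call. = FALSE)
    products <- products[!bad, ]
    attr(products, "problems") <- report
  }
  products
}

#' Write product records back to CSV in canonical units
#'
#' @param products tibble of product records.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_products <- function(products, path) {
  readr::write_csv(products, path, progress = FALSE)
  invisible(path)
}

#' Load a sales table
#'
#' Columns: `product_code`, `sales_kg`, `sales_cad`, `sales_units`. All three
#' measures must be non-negative. Product codes are normalised (trimmed,
#' upper-cased) identically to the label side. Duplicate codes are permitted
#' here (interpreted as period slices) and are summed during the merge.
#'
#' @param path CSV file path.
#' @return A tibble of sales records.
#' @export
load_sales <- function(path) {
  x <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  required <- c("product_code", "sales_kg", "sales_cad", "sales_units")
  missing_cols <- setdiff(required, names(x))
  if (length(missing_cols)) {
    stop("sales file is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  x$product_code <- normalise_code(x$product_code)
  for (col in c("sales_kg", "sales_cad", "sales_units")) {
    if (any(!is.na(x[[col]]) & x[[col]] < 0)) {
      stop("negative values in sales column ", col, call. = FALSE)
    }
  }
  x
}

# product codes are opaque strings; trim and upper-case only
normalise_code <- function(code) toupper(trimws(as.character(code)))

#' Merge label and sales databases by product code
#'
#' Exact-key join on the normalised product code. The label table must be
#' unique per code (duplicates are a hard error); duplicate sales rows per
#' code are first aggregated by summation of all three measures. Label
#' products without sales are retained as `unmatched_products` — usable for
#' unweighted analyses but excluded from all sales-weighted statistics.
#'
#' @param products tibble from [load_products()].
#' @param sales tibble from [load_sales()].
#' @return An object of class `fop_supply`: a list with `matched` (products
#'   joined with their sales columns), `unmatched_products`,
#'   `unmatched_sales_codes`, and `match_counts` per category.
#' @export
merge_by_code <- function(products, sales) {
  products$product_code <- normalise_code(products$product_code)
  sales$product_code <- normalise_code(sales$product_code)
  dup <- unique(products$product_code[duplicated(products$product_code)])
  if (length(dup)) {
    stop("duplicate product codes in label table: ",
         paste(utils::head(dup, 5), collapse = ", "),
         if (length(dup) > 5) " ..." else "", call. = FALSE)
  }
  sales_agg <- sales |>
    dplyr::group_by(.data$product_code) |>
    dplyr::summarise(sales_kg = sum(.data$sales_kg),
                     sales_cad = sum(.data$sales_cad),
                     sales_units = sum(.data$sales_units),
                     .groups = "drop")
  matched <- dplyr::inner_join(products, sales_agg, by = "product_code")
  unmatched_products <- products[!products$product_code %in% sales_agg$product_code, ]
  unmatched_sales_codes <- setdiff(sales_agg$product_code, products$product_code)
  match_counts <- products |>
    dplyr::mutate(matched = .data$product_code %in% sales_agg$product_code) |>
    dplyr::group_by(.data$category) |>
    dplyr::summarise(n_products = dplyr::n(),
                     n_matched = sum(.data$matched), .groups = "drop")
  structure(
    list(matched = matched,
         unmatched_products = unmatched_products,
         unmatched_sales_codes = unmatched_sales_codes,
         match_counts = match_counts),
    class = "fop_supply"
  )
}

#' @export
print.fop_supply <- function(x, ...) {
  cat("<fop_supply>\n")
  cat(sprintf("  %d label products, %d matched to sales, %d unmatched\n",
              nrow(x$matched) + nrow(x$unmatched_products),
              nrow(x$matched), nrow(x$unmatched_products)))
  cat(sprintf("  %d sales codes without a label record\n",
              length(x$unmatched_sales_codes)))
  cat(sprintf("  %d categories\n", nrow(x$match_counts)))
  invisible(x)
}

#' Market coverage of the sales match
#'
#' The share of the label database for which sales could be matched. On the
#' default `product_count` basis the per-category coverage is
#' matched/total products and the overall figure is the unweighted mean of
#' the per-category coverages. On the `sales_kg` basis, coverage is the share
#' of total sales-table kilograms captured by matched codes; since unmatched
#' sales codes carry no category, only the overall figure is defined on that
#' basis and per-category values are reported as missing.
#'
#' A registered category with zero products has undefined coverage, reported
#' as `NA` (never 0) and excluded from the overall mean.
#'
#' @param supply an `fop_supply` from [merge_by_code()].
#' @param basis `"product_count"` (default) or `"sales_kg"`.
#' @param sales for `basis = "sales_kg"`, the original sales tibble (needed
#'   for the unmatched kilograms in the denominator).
#' @param scheme optional [fop_scheme()]; registered categories absent from
#'   the data are then included with `NA` coverage.
#' @return A list with `by_category` (tibble: category, n_products,
#'   n_matched, coverage) and `overall` (a single fraction in \[0, 1\]).
#' @export
market_coverage <- function(supply, basis = c("product_count", "sales_kg"),
                            sales = NULL, scheme = NULL) {
  basis <- match.arg(basis)
  by_cat <- supply$match_counts
  if (!is.null(scheme)) {
    missing_cats <- setdiff(scheme$reference_amounts$category, by_cat$category)
    if (length(missing_cats)) {
      by_cat <- dplyr::bind_rows(
        by_cat,
        tibble::tibble(category = missing_cats, n_products = 0L, n_matched = 0L))
    }
  }
  if (basis == "product_count") {
    by_cat$coverage <- ifelse(by_cat$n_products > 0,
                              by_cat$n_matched / by_cat$n_products, NA_real_)
    overall <- mean(by_cat$coverage, na.rm = TRUE)
  } else {
    if (is.null(sales)) {
      stop("sales table required for basis = 'sales_kg'", call. = FALSE)
    }
    by_cat$coverage <- NA_real_
    total_kg <- sum(sales$sales_kg)
    overall <- if (total_kg > 0) sum(supply$matched$sales_kg) / total_kg else NA_real_
  }
  list(by_category = dplyr::arrange(by_cat, .data$category), overall = overall)
}
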