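scheme <- default_scheme()

write_fixture_csv <- function(df) {
  path <- withr::local_tempfile(fileext = ".csv", .local_envir = parent.frame())
  readr::write_csv(df, path, progress = FALSE)
  path
}

test_that("loader validates rows and canonicalises units", {
  good <- make_product("sliced_breads", 35, product_code = "abc-1",
                       sodium_mg = 450)
  p <- load_products(write_fixture_csv(good), scheme = scheme)
  expect_equal(p$sodium_mg, 450)
  expect_equal(p$product_code, "ABC-1")  # trimmed and upper-cased

  zero_serving <- make_product("sliced_breads", 0, product_code = "Z1")
  expect_error(load_products(write_fixture_csv(zero_serving)), "Z1")

  neg <- make_product("cookies", 30, product_code = "N1", total_sugar_g = -2)
  expect_error(load_products(write_fixture_csv(neg)), "negative total_sugar_g")

  no_col <- good[, setdiff(names(good), "sodium_mg")]
  expect_error(load_products(write_fixture_csv(no_col)), "sodium_mg")

  unreg <- make_product("not_a_category", 30, product_code = "U1")
  expect_error(load_products(write_fixture_csv(unreg), scheme = scheme),
               "category")

  # warn policy reports and drops, never silently
  mixed_rows <- dplyr::bind_rows(good, zero_serving)
  expect_warning(kept <- load_products(write_fixture_csv(mixed_rows),
                                       on_invalid = "warn"), "Z1")
  expect_equal(nrow(kept), 1)
  expect_equal(attr(kept, "problems")$product_code, "Z1")
})

test_that("sodium declared in grams is stored as mg x1000, round-trips", {
  raw <- make_product("sliced_breads", 50, product_code = "G1")
  raw$sodium_g <- 0.45
  raw$sodium_mg <- NULL
  p <- load_products(write_fixture_csv(raw))
  expect_equal(p$sodium_mg, 450)

  # round-trip in canonical form: write then re-read is identical
  out <- withr::local_tempfile(fileext = ".csv")
  write_products(p, out)
  p2 <- load_products(out)
  expect_equal(as.data.frame(p2), as.data.frame(p))
})

test_that("merge is an exact-key join with summed duplicate sales", {
  products <- dplyr::bind_rows(lapply(1:5, function(i) {
    make_product("cookies", 30, product_code = paste0("P", i))
  }))
  sales <- tibble::tibble(product_code = paste0("P", 1:4),
                          sales_kg = c(10, 2, 3, 7),
                          sales_cad = c(1, 2, 3, 4), sales_units = 1:4)
  sup <- merge_by_code(products, sales)
  expect_equal(nrow(sup$matched), 4)
  expect_equal(nrow(sup$unmatched_products), 1)
  expect_equal(sup$unmatched_products$product_code, "P5")

  # duplicate sales rows for one code are summed (period slices)
  sales_dup <- dplyr::bind_rows(sales,
    tibble::tibble(product_code = "P2", sales_kg = 3, sales_cad = 1,
                   sales_units = 2L))
  sup2 <- merge_by_code(products, sales_dup)
  expect_equal(sup2$matched$sales_kg[sup2$matched$product_code == "P2"], 5)

  # empty sales table: everything unmatched
  sup3 <- merge_by_code(products, sales[0, ])
  expect_equal(nrow(sup3$matched), 0)
  expect_equal(nrow(sup3$unmatched_products), 5)

  # label table must be unique per code
  expect_error(merge_by_code(dplyr::bind_rows(products, products[1, ]), sales),
               "duplicate")

  # codes normalised identically on both sides
  sales_messy <- sales
  sales_messy$product_code <- paste0(" p", 1:4, " ")
  expect_equal(nrow(merge_by_code(products, sales_messy)$matched), 4)
})

test_that("merge is idempotent on its matched set", {
  set.seed(7)
  products <- random_products(40)
  sales <- uniform_sales(products[1:25, ], kg_each = 3)
  sup <- merge_by_code(products, sales)
  again <- merge_by_code(sup$matched[names(products)], sales)
  expect_equal(again$matched, sup$matched)
  expect_equal(length(again$unmatched_sales_codes), 0)
})

test_that("market coverage averages per-category fractions", {
  # two categories with coverages 0.70 and 0.90 -> overall 0.80
  p1 <- dplyr::bind_rows(lapply(1:10, function(i) {
    make_product("cookies", 30, product_code = paste0("C", i))
  }))
  p2 <- dplyr::bind_rows(lapply(1:10, function(i) {
    make_product("sliced_breads", 50, product_code = paste0("B", i))
  }))
  products <- dplyr::bind_rows(p1, p2)
  sales <- uniform_sales(dplyr::bind_rows(p1[1:7, ], p2[1:9, ]))
  cov <- market_coverage(merge_by_code(products, sales))
  expect_equal(sort(cov$by_category$coverage), c(0.7, 0.9))
  expect_equal(cov$overall, 0.8)

  # all matched -> 1; invariant to input row order
  cov_full <- market_coverage(merge_by_code(products, uniform_sales(products)))
  expect_equal(cov_full$overall, 1)
  shuffled <- products[sample(nrow(products)), ]
  cov_shuf <- market_coverage(merge_by_code(shuffled, sales))
  expect_equal(cov_shuf$overall, cov$overall)
  expect_equal(dplyr::arrange(cov_shuf$by_category, category),
               dplyr::arrange(cov$by_category, category))

  # a registered category with zero products is missing, not 0
  cov_reg <- market_coverage(merge_by_code(products, sales), scheme = scheme)
  pizzas <- cov_reg$by_category[cov_reg$by_category$category == "pizzas", ]
  expect_true(is.na(pizzas$coverage))
  expect_equal(cov_reg$overall, 0.8)  # NA categories excluded from the mean

  # sales_kg basis: share of sales-table kilograms captured by the match
  sales_extra <- dplyr::bind_rows(
    sales, tibble::tibble(product_code = "GHOST", sales_kg = 4,
                          sales_cad = 1, sales_units = 1L))
  cov_kg <- market_coverage(merge_by_code(products, sales_extra),
                            basis = "sales_kg", sales = sales_extra)
  expect_equal(cov_kg$overall, 16 / 20)
})
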