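scheme <- default_scheme()

test_that("basis amount is the larger of serving size and reference amount", {
  expect_equal(basis_amount(35, 50), 50)
  expect_equal(basis_amount(50, 50), 50)
  expect_equal(basis_amount(75, 50), 75)
  # unit mismatch without a density is refused, with one it converts
  expect_error(basis_amount(100, 250, serving_unit = "g",
                            reference_unit = "mL"), "density")
  expect_equal(basis_amount(200, 250, serving_unit = "g",
                            reference_unit = "mL", density = 1), 250)
  expect_equal(basis_amount(300, 250, serving_unit = "g",
                            reference_unit = "mL", density = 1), 300)
})

test_that("tier selection: mixed dish, small reference amount, default", {
  expect_equal(select_tier("frozen_meals", scheme), 0.30)
  expect_equal(select_tier("pizzas", scheme), 0.30)
  expect_equal(select_tier("cookies", scheme), 0.10)        # RA 30 g, inclusive
  expect_equal(select_tier("sliced_breads", scheme), 0.15)  # RA 50 g > cutoff
  expect_error(select_tier("nope", scheme), "unregistered")
  # exactly one tier per product, always one of the three configured values
  tiers <- select_tier(scheme$reference_amounts$category, scheme)
  expect_true(all(tiers %in% scheme$tier_fractions))
  expect_equal(length(tiers), nrow(scheme$reference_amounts))
})

test_that("amount at basis rescales linearly", {
  expect_equal(amount_at_basis(300, 50, 75), 450)
  expect_identical(amount_at_basis(123.456, 50, 50), 123.456)  # exact identity
  expect_equal(amount_at_basis(0, 50, 75), 0)
  expect_error(amount_at_basis(300, 0, 75), "serving_size")
})

test_that("classification flags nutrients at or above tier x DV", {
  # serving = RA = 55 g (luncheon meats), default tier: threshold 0.15 x 2300
  p <- make_product("luncheon_meats", 55, sodium_mg = 400)
  v <- classify(p, scheme)
  expect_equal(v$sodium_threshold, 345)
  expect_true(v$sodium_flagged)
  expect_equal(v$n_flagged, 1L)
  expect_equal(v$basis_amount, 55)

  # all three nutrients zero -> nothing flagged
  v0 <- classify(make_product("luncheon_meats", 55), scheme)
  expect_equal(v0$n_flagged, 0L)
  expect_false(v0$any_flagged)

  # a small serving is scaled up to the reference amount before comparison
  v_sc <- classify(make_product("luncheon_meats", 27.5, sodium_mg = 200), scheme)
  expect_equal(v_sc$sodium_at_basis, 400)
  expect_true(v_sc$sodium_flagged)
})

test_that("exemption rules short-circuit to an empty flagged set", {
  yog <- make_product("yoghurts_dairy_desserts", 175, total_sugar_g = 25,
                      exemption_calcium_pct_dv = 20)
  v <- classify(yog, scheme)
  expect_true(v$exempted)
  expect_equal(v$exemption_rule_id, "yoghurt_high_calcium")
  expect_false(v$total_sugar_flagged)
  expect_equal(v$n_flagged, 0L)
  # same product below the calcium cutoff is flagged for sugar
  yog$exemption_calcium_pct_dv <- 10
  v2 <- classify(yog, scheme)
  expect_false(v2$exempted)
  expect_true(v2$total_sugar_flagged)
})

test_that("missing nutrient values follow the configured policy", {
  p <- make_product("sliced_breads", 50, sodium_mg = NA, total_sugar_g = 20)
  v <- classify(p, scheme, missing_policy = "lenient")
  expect_true(is.na(v$sodium_flagged))
  expect_true(v$total_sugar_flagged)
  expect_equal(v$n_flagged, 1L)  # NA never counts towards the flagged set
  expect_error(classify(p, scheme, missing_policy = "strict"), "P1")
})

test_that("verdicts are order-stable and empty input yields empty output", {
  set.seed(11)
  prods <- random_products(50)
  v <- classify_products(prods, scheme)
  expect_equal(v$product_code, prods$product_code)
  expect_equal(nrow(classify_products(prods[0, ], scheme)), 0)
})

test_that("monotonicity: raising one nutrient never unflags it", {
  set.seed(21)
  prods <- random_products(200)
  v1 <- classify_products(prods, scheme)
  for (nut in c("sodium", "saturated_fat", "total_sugar")) {
    col <- fopscan:::fop_nutrient_cols()[[nut]]
    bumped <- prods
    bumped[[col]] <- bumped[[col]] * 1.5 + 1
    v2 <- classify_products(bumped, scheme)
    was <- v1[[paste0(nut, "_flagged")]] %in% TRUE & !v1$exempted
    still <- v2[[paste0(nut, "_flagged")]] %in% TRUE
    expect_true(all(still[was]))
  }
})

test_that("verdicts are invariant to a common rescaling of DVs and amounts", {
  set.seed(31)
  prods <- random_products(150)
  v1 <- classify_products(prods, scheme)
  k <- 3.7
  scaled_scheme <- scheme
  scaled_scheme$daily_values <- scheme$daily_values * k
  scaled_prods <- prods
  for (col in unname(fopscan:::fop_nutrient_cols())) {
    scaled_prods[[col]] <- scaled_prods[[col]] * k
  }
  v2 <- classify_products(scaled_prods, scaled_scheme)
  for (nut in c("sodium", "saturated_fat", "total_sugar")) {
    expect_equal(v2[[paste0(nut, "_flagged")]], v1[[paste0(nut, "_flagged")]])
  }
  expect_equal(v2$n_flagged, v1$n_flagged)
})

test_that("a scheme round-trips through YAML", {
  path <- withr::local_tempfile(fileext = ".yaml")
  write_scheme(scheme, path)
  back <- read_scheme(path)
  expect_equal(back$daily_values, scheme$daily_values)
  expect_equal(back$tier_fractions, scheme$tier_fractions)
  expect_equal(back$reference_amounts, scheme$reference_amounts)
  expect_equal(back$mixed_dish_categories, scheme$mixed_dish_categories)
  expect_equal(back$densities, scheme$densities)
  expect_equal(back$exemption_rules, scheme$exemption_rules)
  # and the round-tripped scheme classifies identically
  set.seed(41)
  prods <- random_products(100)
  expect_equal(classify_products(prods, back), classify_products(prods, scheme))
})
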