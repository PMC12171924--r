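# Independent straight-line re-implementation of the classification rules,
# written directly from the rule text with an explicit per-product loop and
# no shared code with the package internals. Used as the equivalence oracle.
oracle_classify <- function(products, scheme) {
  n <- nrow(products)
  res <- data.frame(product_code = products$product_code,
                    tier = NA_real_, exempted = FALSE,
                    sodium_flagged = NA, saturated_fat_flagged = NA,
                    total_sugar_flagged = NA)
  dv <- scheme$daily_values
  for (i in seq_len(n)) {
    cat_i <- products$category[i]
    ra_row <- scheme$reference_amounts[scheme$reference_amounts$category == cat_i, ]
    ra <- ra_row$amount
    ra_unit <- ra_row$unit

    # tier: mixed dish 30 %; else RA <= cutoff 10 %; else 15 %
    if (cat_i %in% scheme$mixed_dish_categories) {
      tier <- scheme$tier_fractions[["mixed_dish"]]
    } else if (ra <= scheme$small_ra_cutoff) {
      tier <- scheme$tier_fractions[["small_reference_amount"]]
    } else {
      tier <- scheme$tier_fractions[["default"]]
    }

    # serving in the reference-amount unit (explicit density if units differ)
    serving <- products$serving_size[i]
    if (products$serving_unit[i] != ra_unit) {
      d <- scheme$densities[[cat_i]]
      serving <- if (products$serving_unit[i] == "g") serving / d else serving * d
    }
    basis <- max(serving, ra)   # highest of serving size and reference amount

    # exemptions first: any matching rule empties the flagged set
    exempted <- FALSE
    for (rule in scheme$exemption_rules) {
      col <- paste0("exemption_", rule$attribute)
      if (!cat_i %in% rule$applies_to || !col %in% names(products)) next
      val <- products[[col]][i]
      if (is.na(val)) next
      hit <- switch(rule$comparator,
                    ">=" = val >= rule$threshold, ">" = val > rule$threshold,
                    "<=" = val <= rule$threshold, "<" = val < rule$threshold,
                    "==" = val == rule$threshold)
      if (hit) exempted <- TRUE
    }

    amounts <- c(sodium = products$sodium_mg[i],
                 saturated_fat = products$saturated_fat_g[i],
                 total_sugar = products$total_sugar_g[i])
    for (nut in names(amounts)) {
      at_basis <- amounts[[nut]] * basis / serving
      if (basis == serving) at_basis <- amounts[[nut]]
      flag <- if (is.na(at_basis)) NA else at_basis >= tier * dv[[nut]]
      if (exempted) flag <- FALSE
      res[[paste0(nut, "_flagged")]][i] <- flag
    }
    res$tier[i] <- tier
    res$exempted[i] <- exempted
  }
  res
}
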