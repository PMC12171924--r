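# fixture builders shared across test files

make_product <- function(category, serving_size, serving_unit = "g",
                         product_code = "P1", brand = "Test",
                         energy_kj = 0, total_fat_g = 0, saturated_fat_g = 0,
                         total_sugar_g = 0, fibre_g = 0, protein_g = 0,
                         sodium_mg = 0, ...) {
  tibble::tibble(product_code = product_code, category = category,
                 brand = brand, serving_size = serving_size,
                 serving_unit = serving_unit, energy_kj = energy_kj,
                 total_fat_g = total_fat_g, saturated_fat_g = saturated_fat_g,
                 total_sugar_g = total_sugar_g, fibre_g = fibre_g,
                 protein_g = protein_g, sodium_mg = sodium_mg, ...)
}

# random products spanning all tier branches (default/small-RA/mixed-dish),
# g and mL categories, nutrient amounts straddling the thresholds
random_products <- function(n, scheme = default_scheme(),
                            with_exemption_attr = TRUE) {
  ra <- scheme$reference_amounts
  cats <- sample(ra$category, n, replace = TRUE)
  idx <- match(cats, ra$category)
  serving <- round(ra$amount[idx] * stats::runif(n, 0.5, 1.6), 1)
  out <- tibble::tibble(
    product_code = sprintf("R%05d", seq_len(n)),
    category = cats,
    brand = "Rnd",
    serving_size = serving,
    serving_unit = ra$unit[idx],
    energy_kj = stats::runif(n, 100, 2000),
    total_fat_g = stats::runif(n, 0, 25),
    saturated_fat_g = stats::runif(n, 0, 9),
    total_sugar_g = stats::runif(n, 0, 35),
    fibre_g = stats::runif(n, 0, 5),
    protein_g = stats::runif(n, 0, 20),
    sodium_mg = stats::runif(n, 0, 900)
  )
  if (with_exemption_attr) {
    out$exemption_calcium_pct_dv <- stats::runif(n, 0, 30)
  }
  out
}
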