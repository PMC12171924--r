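#' Run the full surveillance pipeline
#'
#' Orchestrates merge -> classify -> summarise -> simulate -> render and
#' collects the four report products: availability and market coverage per
#' category (table1), the sales-weighted nutritional portrait per serving
#' (table2), the distribution of products over 0/1/2/3 flagged nutrients
#' (fig1, as data), and the reformulation prevalence grid (table3). The
#' pipeline is a pure function of its inputs: identical inputs reproduce
#' every output exactly. All outputs are computed first and written only
#' after every stage has succeeded, so a failing stage leaves no partial
#' files.
#'
#' @param products products tibble (from [load_products()] or
#'   [generate_supply()]).
#' @param sales sales tibble.
#' @param scheme a [fop_scheme()] (default [default_scheme()]).
#' @param nutrients,reductions the reformulation grid (defaults: all three
#'   nutrients at 5/10/15 %).
#' @param out_dir optional directory; when given, `table1.csv`, `table2.csv`,
#'   `fig1_data.csv`, `table3.csv`, `fig1.png` and `run_metadata.yaml` are
#'   written there.
#' @param render_chart draw `fig1.png` (requires `out_dir`).
#' @param missing_policy passed to the classifier.
#' @return An object of class `fop_report_bundle`: list with `table1`,
#'   `table2`, `fig1`, `table3`, `coverage_overall`, `verdicts`, `supply`
#'   and `metadata`.
#' @export
run_pipeline <- function(products, sales, scheme = default_scheme(),
                         nutrients = fop_nutrients(),
                         reductions = c(0.05, 0.10, 0.15),
                         out_dir = NULL, render_chart = !is.null(out_dir),
                         missing_policy = "lenient") {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  supply <- stage("merge", merge_by_code(products, sales))
  coverage <- stage("coverage", market_coverage(supply, scheme = scheme))
  verdicts <- stage("classify",
                    classify_supply(supply, scheme, missing_policy = missing_policy))
  table2 <- stage("summarize", category_summary(supply))
  prev <- stage("summarize", prevalence_table(verdicts))
  table3 <- stage("simulate",
                  run_scenario_grid(supply, scheme, nutrients = nutrients,
                                    reductions = reductions,
                                    missing_policy = missing_policy))

  table1 <- coverage$by_category
  fig1 <- prev |>
    tidyr::pivot_longer(dplyr::all_of(paste0("p_flagged_", 0:3)),
                        names_to = "n_flagged", names_prefix = "p_flagged_",
                        values_to = "fraction") |>
    dplyr::select("category", "n_flagged", "fraction")

  bundle <- structure(
    list(table1 = table1, table2 = table2, fig1 = fig1, table3 = table3,
         prevalence = prev,
         coverage_overall = coverage$overall,
         verdicts = verdicts, supply = supply,
         metadata = list(scheme_hash = rlang::hash(unclass(scheme)),
                         n_label_products = nrow(supply$matched) +
                           nrow(supply$unmatched_products),
                         n_matched = nrow(supply$matched),
                         package_version = as.character(utils::packageVersion("fopscan")))),
    class = "fop_report_bundle")

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    readr::write_csv(table1, file.path(out_dir, "table1.csv"), progress = FALSE)
    readr::write_csv(table2, file.path(out_dir, "table2.csv"), progress = FALSE)
    readr::write_csv(fig1, file.path(out_dir, "fig1_data.csv"), progress = FALSE)
    readr::write_csv(table3, file.path(out_dir, "table3.csv"), progress = FALSE)
    yaml::write_yaml(bundle$metadata, file.path(out_dir, "run_metadata.yaml"))
    if (render_chart) {
      render_fig1(fig1, path = file.path(out_dir, "fig1.png"))
    }
  }
  bundle
}

#' @export
print.fop_report_bundle <- function(x, ...) {
  cat("<fop_report_bundle>\n")
  cat(sprintf("  %d matched products across %d categories; coverage %.0f %%\n",
              x$metadata$n_matched, nrow(x$table1), 100 * x$coverage_overall))
  ov <- x$prevalence[x$prevalence$category == "(overall)", ]
  cat(sprintf("  symbol prevalence: any %.0f %% | Na %.0f %% | sat fat %.0f %% | sugar %.0f %%\n",
              100 * ov$any_symbol, 100 * ov$sodium,
              100 * ov$saturated_fat, 100 * ov$total_sugar))
  invisible(x)
}

#' Stacked-bar chart of the flagged-nutrient distribution
#'
#' One bar per category (the `"(overall)"` bar included), four segments for
#' 0/1/2/3 flagged nutrients; segment heights equal the input fractions. If
#' `path` is given the chart is written (PNG/SVG by extension) together with
#' a `*_data.csv` sidecar holding exactly the plotted numbers, so every
#' graphical claim stays testable.
#'
#' @param fig1_data tibble with columns `category`, `n_flagged`, `fraction`
#'   (fractions summing to 1 within each category).
#' @param path optional output file.
#' @return The ggplot object, invisibly.
#' @export
render_fig1 <- function(fig1_data, path = NULL) {
  sums <- tapply(fig1_data$fraction, fig1_data$category, sum)
  if (any(abs(sums - 1) > 1e-6)) {
    stop("fig1 fractions must sum to 1 within each category", call. = FALSE)
  }
  p <- ggplot2::ggplot(fig1_data,
                       ggplot2::aes(x = .data$category, y = .data$fraction,
                                    fill = factor(.data$n_flagged, levels = 3:0))) +
    ggplot2::geom_col(position = "stack", width = 0.8) +
    ggplot2::scale_y_continuous(labels = function(x) paste0(100 * x, " %")) +
    ggplot2::scale_fill_brewer(palette = "OrRd", direction = -1,
                               name = "Flagged\nnutrients") +
    ggplot2::labs(x = NULL, y = "Share of products",
                  title = "Products requiring the 'high in' symbol") +
    ggplot2::coord_flip() +
    ggplot2::theme_minimal()
  if (!is.null(path)) {
    ggplot2::ggsave(path, p, width = 8, height = 6, dpi = 150)
    sidecar <- sub("\\.[A-Za-z]+$", "_data.csv", path)
    readr::write_csv(fig1_data, sidecar, progress = FALSE)
  }
  invisible(p)
}
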