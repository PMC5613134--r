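#' Published MET reference tables
#'
#' Per-environment REML variance components (with the proportions printed
#' alongside them) and mean test-set predictive abilities reported for a
#' 9-environment sunflower hybrid seed-oil MET (36 maintainer x 36 restorer
#' incomplete factorial). Bundled so the package's table arithmetic —
#' parts of variance, relative model improvements — can be recomputed and
#' checked against the printed values.
#'
#' @return `reference_variance_components()`: tibble with `model`
#'   (GCA/FM/FMI), `term`, `environment`, `component` (squared oil %) and
#'   `reported_share` (printed proportion, `NA` for residual rows).
#'   `reference_predictive_ability()`: tibble with `scheme`
#'   (`random_hybrids` = any-hybrid test sets, `by_parents` = T0/T1 test
#'   sets), `model`, `environment` (`"MET"` = across-environment average)
#'   and `mean_ability`.
#' @export
reference_variance_components <- function() {
  readr::read_csv(system.file("extdata", "met_variance_components.csv",
                              package = "hybridgs"),
                  show_col_types = FALSE)
}

#' @rdname reference_variance_components
#' @export
reference_predictive_ability <- function() {
  readr::read_csv(system.file("extdata", "met_predictive_ability.csv",
                              package = "hybridgs"),
                  show_col_types = FALSE)
}
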