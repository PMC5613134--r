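#' Adjust raw plot phenotypes within an environment
#'
#' Per-environment spatial adjustment of plot-level records before genomic
#' modeling: oil is regressed on field row and column (unordered factors,
#' sum-coded), the repetition when more than one is present, and the
#' genotype status (check variety vs hybrid) as fixed effects, with an
#' independent random genotype effect fitted by REML through the package's
#' mixed-model engine. The adjusted phenotype of a hybrid is
#' `mu + status(hybrid) + genotype BLUP`; check varieties are excluded from
#' the output. Row/column factors are a deliberate simplification of richer
#' spatial models (no smooth surface, no autocorrelated error).
#'
#' @param plots data frame with columns `environment`, `row`, `col`, `rep`,
#'   `genotype`, `status` (`"check"` or `"hybrid"`), `oil` (% seed oil).
#' @return tibble with `environment`, `hybrid_id`, `value` (adjusted oil %),
#'   one row per hybrid per environment.
#' @export
adjust_phenotypes <- function(plots) {
  plots <- tibble::as_tibble(plots)
  need <- c("environment", "row", "col", "rep", "genotype", "status", "oil")
  assert_that(all(need %in% names(plots)),
              paste("plots needs columns:", paste(need, collapse = ", ")))
  assert_that(all(plots$oil > 0 & plots$oil < 100),
              "oil must be within (0, 100)")
  assert_that(!any(duplicated(plots[c("environment", "row", "col", "rep")])),
              "duplicate (environment, row, col, rep) plot positions")
  assert_that(all(plots$status %in% c("check", "hybrid")),
              "status must be 'check' or 'hybrid'")
  out <- plots |>
    dplyr::group_split(.data$environment) |>
    purrr::map(adjust_one_environment) |>
    dplyr::bind_rows()
  out
}

adjust_one_environment <- function(pl) {
  env <- pl$environment[1]
  assert_that(dplyr::n_distinct(pl$row) >= 2 && dplyr::n_distinct(pl$col) >= 2,
              sprintf("environment %s: need >= 2 rows and >= 2 columns", env))
  d <- data.frame(
    value = pl$oil,
    row = factor(pl$row), col = factor(pl$col), rep = factor(pl$rep),
    status = factor(pl$status, levels = c("check", "hybrid")),
    genotype = as.character(pl$genotype)
  )
  stats::contrasts(d$row) <- stats::contr.sum(nlevels(d$row))
  stats::contrasts(d$col) <- stats::contr.sum(nlevels(d$col))
  fx <- "~ row + col"
  if (nlevels(d$rep) > 1) {
    stats::contrasts(d$rep) <- stats::contr.sum(nlevels(d$rep))
    fx <- paste(fx, "+ rep")
  }
  has_checks <- nlevels(droplevels(d$status)) > 1
  if (has_checks) fx <- paste(fx, "+ status")

  # a fixed level carried by a single plot is aliased with that plot's
  # genotype; the rank-deficiency drop is reported
  X0 <- stats::model.matrix(stats::as.formula(fx), d)
  if (qr(X0)$rank < ncol(X0))
    warning(sprintf("environment %s: confounded field layout, %d aliased fixed column(s) dropped",
                    env, ncol(X0) - qr(X0)$rank))

  fit <- reml_fit(
    d,
    list(random_term("genotype", "genotype", levels = unique(d$genotype))),
    response = "value", fixed = stats::as.formula(fx))

  status_coef <- if (has_checks && "statushybrid" %in% names(fit$beta))
    fit$beta[["statushybrid"]] else 0
  hyb <- unique(d$genotype[d$status == "hybrid"])
  tibble::tibble(
    environment = env,
    hybrid_id = hyb,
    value = fit$mu + status_coef + fit$blup$genotype[hyb]
  )
}
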