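#' Test-set plan: random hybrids
#'
#' Draws `n_sets` independent test sets, each a without-replacement sample of
#' `round(fraction x n_observed)` of the hybrids observed at least once in
#' the trial (round half up). This scheme evaluates completion of the
#' factorial: test hybrids have parents with other phenotyped descendants in
#' training.
#'
#' @param design a [factorial_design()].
#' @param fraction test fraction (default 0.10).
#' @param n_sets number of test sets (default 100).
#' @param seed root seed; each set uses a derived substream so earlier sets
#'   are unchanged when `n_sets` grows.
#' @return object of class `cv_plan`.
#' @export
sample_random_hybrids <- function(design, fraction = 0.10, n_sets = 100,
                                  seed = 1) {
  assert_that(fraction > 0 && fraction < 1, "fraction must be in (0, 1)")
  obs <- observed_any(design)
  size <- round_half_up(fraction * nrow(obs))
  if (size < 1) stop("test fraction yields empty test sets", call. = FALSE)
  sets <- lapply(seq_len(n_sets), function(s) {
    set.seed(substream_seed(seed, s))
    tibble::tibble(hybrid_id = sample(obs$hybrid_id, size), tier = "T2")
  })
  new_cv_plan("random_hybrids", fraction, n_sets, seed, sets,
              sampled_parents = NULL)
}

#' Test-set plan: held-out parents (T0/T1 hybrids)
#'
#' Per set, `round(fraction x n_parents)` parents are drawn from the pooled
#' female + male lines (unstratified by default); the test set is every
#' observed hybrid with at least one sampled parent, so no sampled parent
#' has any descendant left in training. Hybrids with both parents sampled
#' are labeled T0, with one parent sampled T1.
#'
#' @inheritParams sample_random_hybrids
#' @param stratified when TRUE, half of the parents are drawn from each sex
#'   (rounded); default FALSE, pooled sampling.
#' @return object of class `cv_plan`; each set carries its `tier` labels and
#'   the plan records the sampled parents.
#' @export
sample_by_parents <- function(design, fraction = 0.10, n_sets = 100,
                              seed = 1, stratified = FALSE) {
  assert_that(fraction > 0 && fraction < 1, "fraction must be in (0, 1)")
  obs <- observed_any(design)
  females <- unique(design$female_id)
  males <- unique(design$male_id)
  pool <- c(females, males)
  n_par <- round_half_up(fraction * length(pool))
  if (n_par < 1) stop("test fraction yields no sampled parents", call. = FALSE)
  sets <- vector("list", n_sets)
  parents <- vector("list", n_sets)
  for (s in seq_len(n_sets)) {
    set.seed(substream_seed(seed, s))
    for (try in 1:100) {
      sel <- if (stratified) {
        c(sample(females, round_half_up(n_par / 2)),
          sample(males, n_par - round_half_up(n_par / 2)))
      } else sample(pool, n_par)
      f_in <- obs$female_id %in% sel
      m_in <- obs$male_id %in% sel
      test <- f_in | m_in
      if (any(test) && !all(test)) break
      message(sprintf("set %d: degenerate parent draw, resampling", s))
    }
    if (all(test) || !any(test))
      stop("could not draw a parent set leaving both test and training hybrids",
           call. = FALSE)
    sets[[s]] <- tibble::tibble(
      hybrid_id = obs$hybrid_id[test],
      tier = ifelse(f_in[test] & m_in[test], "T0", "T1"))
    parents[[s]] <- sel
  }
  new_cv_plan("by_parents", fraction, n_sets, seed, sets, parents)
}

observed_any <- function(design) {
  envs <- design_environments(design)
  d <- tibble::as_tibble(design)
  obs <- if (length(envs)) rowSums(as.matrix(d[envs])) > 0 else rep(TRUE, nrow(d))
  d[obs, c("hybrid_id", "female_id", "male_id")]
}

new_cv_plan <- function(scheme, fraction, n_sets, seed, sets, sampled_parents) {
  structure(list(scheme = scheme, fraction = fraction, n_sets = n_sets,
                 seed = seed, sets = sets, sampled_parents = sampled_parents),
            class = "cv_plan")
}

#' @export
print.cv_plan <- function(x, ...) {
  sz <- vapply(x$sets, nrow, 0L)
  cat(sprintf("<cv_plan> scheme %s: %d sets of %d-%d test hybrids (fraction %.2f, seed %d)\n",
              x$scheme, x$n_sets, min(sz), max(sz), x$fraction, x$seed))
  invisible(x)
}

#' Tidy a cross-validation plan
#' @param x a `cv_plan`.
#' @param ... unused.
#' @return tibble with `set`, `hybrid_id`, `tier`.
#' @method tidy cv_plan
#' @export
tidy.cv_plan <- function(x, ...) {
  dplyr::bind_rows(x$sets, .id = "set") |>
    dplyr::mutate(set = as.integer(.data$set))
}

#' Predictive ability
#'
#' Pearson correlation between observed (adjusted) phenotypes and predicted
#' genetic values of test hybrids. Returns `NaN` with a warning when either
#' side has zero variance; callers exclude such sets from means.
#'
#' @param observed,predicted paired numeric vectors.
#' @return Pearson correlation in `[-1, 1]`, or `NaN`.
#' @export
predictive_ability <- function(observed, predicted) {
  assert_that(length(observed) == length(predicted), "length mismatch")
  keep <- stats::complete.cases(observed, predicted)
  observed <- observed[keep]; predicted <- predicted[keep]
  if (length(observed) < 3)
    stop("need at least 3 paired values", call. = FALSE)
  if (stats::sd(observed) == 0 || stats::sd(predicted) == 0) {
    warning("zero variance in observed or predicted values; ability undefined")
    return(NaN)
  }
  stats::cor(observed, predicted)
}

#' Run the cross-validation loop
#'
#' For every test set of the plan and every environment: variance components
#' are re-estimated by REML on the training hybrids only, test hybrids are
#' predicted (their parents enter only through marker kinship, never through
#' phenotypes), and the predictive ability is scored. All models are
#' evaluated on the same sets, so per-set model differences are paired; a
#' set on which any model fails to fit is skipped for all models.
#'
#' @param adjusted tibble of adjusted phenotypes: `environment`, `hybrid_id`,
#'   `value`.
#' @param design a [factorial_design()].
#' @param models character vector of model kinds (see [assemble_model()]).
#' @param plan a `cv_plan`.
#' @param kernels named kernel list passed to [assemble_model()].
#' @param environments environments to evaluate (default: all in `adjusted`).
#' @return object of class `hybridgs_cv` with per-set abilities, per
#'   environment summaries, and the MET (unweighted across-environment)
#'   average per model.
#' @export
run_cv <- function(adjusted, design, models, plan, kernels = list(),
                   environments = NULL) {
  adjusted <- tibble::as_tibble(adjusted)
  environments <- environments %||% unique(adjusted$environment)
  crosses <- tibble::as_tibble(design)[, c("hybrid_id", "female_id", "male_id")]
  adjusted <- dplyr::inner_join(adjusted, crosses, by = "hybrid_id")
  female_ids <- unique(design$female_id)
  male_ids <- unique(design$male_id)
  term_sets <- lapply(stats::setNames(models, models), assemble_model,
                      kernels = kernels, female_ids = female_ids,
                      male_ids = male_ids)
  rows <- list()
  for (env in environments) {
    d_env <- adjusted[adjusted$environment == env, ]
    for (s in seq_len(plan$n_sets)) {
      test_ids <- plan$sets[[s]]$hybrid_id
      train <- d_env[!d_env$hybrid_id %in% test_ids, ]
      test <- d_env[d_env$hybrid_id %in% test_ids, ]
      if (nrow(test) < 3 || nrow(train) < 10) next
      res <- tryCatch(
        lapply(term_sets, function(tm) {
          fit <- reml_fit(train, tm)
          pr <- predict_hybrids(fit, test)
          predictive_ability(test$value, pr$predicted)
        }),
        error = function(e) {
          message(sprintf("environment %s set %d skipped: %s", env, s,
                          conditionMessage(e)))
          NULL
        })
      if (is.null(res)) next
      rows[[length(rows) + 1]] <- tibble::tibble(
        environment = env, set = s, model = names(res),
        ability = unlist(res), n_test = nrow(test))
    }
  }
  per_set <- dplyr::bind_rows(rows)
  assert_that(nrow(per_set) > 0, "no test set could be evaluated")
  summary <- per_set |>
    dplyr::filter(is.finite(.data$ability)) |>
    dplyr::group_by(.data$environment, .data$model) |>
    dplyr::summarise(mean_ability = mean(.data$ability),
                     var_ability = stats::var(.data$ability),
                     n_sets = dplyr::n(), .groups = "drop")
  met <- summary |>
    dplyr::group_by(.data$model) |>
    dplyr::summarise(mean_ability = mean(.data$mean_ability),
                     n_environments = dplyr::n(), .groups = "drop")
  structure(list(per_set = per_set, summary = summary, met = met,
                 scheme = plan$scheme),
            class = "hybridgs_cv")
}

#' @export
print.hybridgs_cv <- function(x, ...) {
  cat(sprintf("<hybridgs_cv> scheme %s\n", x$scheme))
  print(x$summary, n = 20)
  cat("MET averages:\n")
  print(x$met)
  invisible(x)
}

#' Per-set cross-validation abilities
#' @param x a `hybridgs_cv`.
#' @param ... unused.
#' @return tibble `environment`, `set`, `model`, `ability`, `n_test`.
#' @method tidy hybridgs_cv
#' @export
tidy.hybridgs_cv <- function(x, ...) x$per_set

#' MET-level cross-validation summary
#' @param x a `hybridgs_cv`.
#' @param ... unused.
#' @return tibble `model`, `mean_ability`, `n_environments`.
#' @method glance hybridgs_cv
#' @export
glance.hybridgs_cv <- function(x, ...) x$met

#' Boxplot of per-set predictive abilities
#' @param object a `hybridgs_cv`.
#' @param ... unused.
#' @return a ggplot object.
#' @method autoplot hybridgs_cv
#' @export
autoplot.hybridgs_cv <- function(object, ...) {
  ggplot2::ggplot(object$per_set,
                  ggplot2::aes(x = .data$model, y = .data$ability,
                               fill = .data$model)) +
    ggplot2::geom_boxplot(show.legend = FALSE) +
    ggplot2::facet_wrap(~environment) +
    ggplot2::labs(x = NULL, y = "predictive ability (Pearson r)",
                  title = sprintf("Test-set accuracy, scheme: %s",
                                  object$scheme)) +
    ggplot2::theme_minimal()
}
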