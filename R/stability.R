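#' Hybrid MET performance matrix
#'
#' Assembles the complete hybrids x environments matrix of predicted
#' performances (`mu + BLUP` per environment) from per-environment fitted
#' models; predictions exist for every cross, observed or not, which is what
#' makes stability screening possible on the full factorial.
#'
#' @param fits named list of `hybridgs_fit` objects, one per environment.
#' @param crosses data frame with `hybrid_id`, `female_id`, `male_id`.
#' @return tibble `hybrid_id`, `environment`, `predicted`.
#' @export
met_performance <- function(fits, crosses) {
  assert_that(!is.null(names(fits)), "fits must be named by environment")
  purrr::imap(fits, function(f, env) {
    dplyr::mutate(predict_hybrids(f, crosses), environment = env)
  }) |>
    dplyr::bind_rows() |>
    dplyr::select("hybrid_id", "environment", "predicted")
}

#' Wricke's ecovalence stability screen
#'
#' A hybrid's ecovalence is its contribution to the genotype x environment
#' interaction sum of squares of the performance matrix:
#' `W_i = sum_e (p_ie - pbar_i. - pbar_.e + pbar_..)^2`. Small values mean
#' the hybrid's relative performance is stable across environments. The sum
#' of all `W_i` equals the interaction sum of squares of the double-centered
#' matrix.
#'
#' @param performance long tibble (`hybrid_id`, `environment`, `predicted`)
#'   or a complete hybrids x environments matrix. Missing cells are an
#'   error: predict every cross first (see [met_performance()]).
#' @param threshold stability cutoff on `W` (default 5, units: squared trait
#'   scale — data dependent, tune per trait).
#' @return object of class `hybridgs_stability`: tibble with `hybrid_id`,
#'   `met_mean`, `ecovalence`, `stable`.
#' @export
wricke_ecovalence <- function(performance, threshold = 5) {
  if (!is.matrix(performance)) {
    performance <- tibble::as_tibble(performance)
    wide <- tidyr::pivot_wider(
      performance[, c("hybrid_id", "environment", "predicted")],
      names_from = "environment", values_from = "predicted")
    m <- as.matrix(wide[, -1])
    rownames(m) <- wide$hybrid_id
  } else m <- performance
  if (anyNA(m))
    stop("performance matrix has missing cells; predictions must be complete",
         call. = FALSE)
  assert_that(nrow(m) >= 2 && ncol(m) >= 2,
              "need >= 2 hybrids and >= 2 environments")
  centered <- sweep(sweep(m, 1, rowMeans(m)), 2, colMeans(m)) + mean(m)
  w <- rowSums(centered^2)
  out <- tibble::tibble(
    hybrid_id = rownames(m) %||% as.character(seq_len(nrow(m))),
    met_mean = unname(rowMeans(m)),
    ecovalence = unname(w),
    stable = unname(w < threshold))
  structure(out, class = c("hybridgs_stability", class(out)),
            threshold = threshold, interaction_ss = sum(w))
}

#' Mean performance vs ecovalence plot
#' @param object a `hybridgs_stability` result.
#' @param ... unused.
#' @return a ggplot object.
#' @method autoplot hybridgs_stability
#' @export
autoplot.hybridgs_stability <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$met_mean, y = .data$ecovalence,
                               colour = .data$stable)) +
    ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = attr(object, "threshold"),
                        linetype = "dashed") +
    ggplot2::labs(x = "MET mean predicted performance",
                  y = "Wricke ecovalence",
                  colour = sprintf("W < %s", attr(object, "threshold"))) +
    ggplot2::theme_minimal()
}
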