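#' Incomplete factorial cross design
#'
#' Records which female x male crosses were made and, per environment, which
#' crosses were observed for the trait. The design must be connected: the
#' bipartite graph with parents as vertices and crosses as edges has a single
#' connected component, otherwise parental effects are not comparable across
#' components.
#'
#' @param crosses data frame with columns `hybrid_id`, `female_id`, `male_id`
#'   plus one logical column per environment flagging observation.
#' @param environments optional character vector naming the environment
#'   columns; defaults to every column after the three id columns.
#' @return An object of class `factorial_design`: tibble of crosses with an
#'   `environments` attribute.
#' @export
factorial_design <- function(crosses, environments = NULL) {
  crosses <- tibble::as_tibble(crosses)
  assert_that(all(c("hybrid_id", "female_id", "male_id") %in% names(crosses)),
              "crosses needs hybrid_id, female_id, male_id columns")
  environments <- environments %||%
    setdiff(names(crosses), c("hybrid_id", "female_id", "male_id"))
  for (e in environments) crosses[[e]] <- as.logical(crosses[[e]])
  assert_that(!any(duplicated(crosses[c("female_id", "male_id")])),
              "duplicated crosses in design")
  g <- igraph::graph_from_edgelist(
    cbind(paste0("F:", crosses$female_id), paste0("M:", crosses$male_id)),
    directed = FALSE)
  if (igraph::count_components(g) > 1L)
    stop("factorial design is not connected", call. = FALSE)
  structure(crosses, class = c("factorial_design", class(crosses)),
            environments = environments)
}

#' @export
print.factorial_design <- function(x, ...) {
  cat(sprintf(
    "<factorial_design> %d crosses: %d females x %d males, %d environment(s)\n",
    nrow(x), dplyr::n_distinct(x$female_id), dplyr::n_distinct(x$male_id),
    length(design_environments(x))))
  NextMethod()
}

#' Environment names of a design
#' @param design a [factorial_design()].
#' @return character vector.
#' @export
design_environments <- function(design) attr(design, "environments")

#' Observed crosses of one environment
#' @param design a [factorial_design()].
#' @param environment environment name.
#' @return tibble of crosses observed in that environment.
#' @export
observed_crosses <- function(design, environment) {
  assert_that(environment %in% design_environments(design),
              paste("unknown environment", environment))
  tibble::as_tibble(design)[which(design[[environment]]),
                            c("hybrid_id", "female_id", "male_id")]
}

#' Read a cross design from CSV
#'
#' Expected columns: `hybrid_id`, `female_id`, `male_id`, then one
#' TRUE/FALSE (or 0/1) column per environment.
#'
#' @param path CSV file.
#' @return a [factorial_design()].
#' @export
read_design_csv <- function(path) {
  factorial_design(readr::read_csv(path, show_col_types = FALSE))
}

#' Write a cross design to CSV
#' @param design a [factorial_design()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_design_csv <- function(design, path) {
  readr::write_csv(tibble::as_tibble(design), path)
  invisible(path)
}

check_design_parents <- function(design, females, males) {
  miss_f <- setdiff(design$female_id, parent_ids(females))
  miss_m <- setdiff(design$male_id, parent_ids(males))
  if (length(miss_f) || length(miss_m))
    stop("design references unknown parents: ",
         paste(c(miss_f, miss_m), collapse = ", "), call. = FALSE)
  invisible(TRUE)
}
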