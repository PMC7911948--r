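#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy match-statistic results
#'
#' Broom-style one-row summaries of result objects, so batch runs bind
#' naturally into tables.
#'
#' @param x A result object.
#' @param ... Unused.
#' @return A tibble.
#' @name mitograph-tidiers
NULL

#' @rdname mitograph-tidiers
#' @method tidy rmne_result
#' @export
tidy.rmne_result <- function(x, ...) {
  tibble(
    population = x$population,
    n_consistent = x$n_consistent,
    n = x$n,
    p_rmne = x$p_rmne,
    p_rmne_upper = x$p_rmne_upper,
    conf = x$conf
  )
}

#' @rdname mitograph-tidiers
#' @method tidy gbc_result
#' @export
tidy.gbc_result <- function(x, ...) {
  tibble(
    n_explaining = x$n_explaining,
    denominator = x$denominator,
    proportion = x$proportion,
    upper_bound = x$upper_bound,
    u = x$u,
    n = x$n,
    conf = x$conf
  )
}

#' @rdname mitograph-tidiers
#' @method tidy total_likelihood_result
#' @export
tidy.total_likelihood_result <- function(x, ...) {
  tibble(
    likelihood = x$likelihood,
    n_sets = x$n_sets,
    empty_T = x$empty_T,
    u = x$u
  )
}

#' @rdname mitograph-tidiers
#' @method tidy mixture_profile
#' @export
tidy.mixture_profile <- function(x, ...) {
  dplyr::mutate(x$calls,
                alleles = purrr::map_chr(.data$alleles, paste, collapse = "/"))
}

#' Node and edge tables of a variation graph
#'
#' `tidy()` returns the node table; `as_tibble()` likewise. The edge table
#' is available via `graph_edges()`.
#'
#' @param x A `variant_graph`.
#' @param ... Unused.
#' @return A tibble.
#' @method tidy variant_graph
#' @export
tidy.variant_graph <- function(x, ...) {
  tibble(id = x$nodes$id, kind = x$nodes$kind, label = x$nodes$label)
}

#' @rdname tidy.variant_graph
#' @param graph A `variant_graph`.
#' @export
graph_edges <- function(graph) {
  tibble(from = graph$edges$from, to = graph$edges$to)
}

#' @rdname tidy.variant_graph
#' @method as_tibble variant_graph
#' @export
as_tibble.variant_graph <- function(x, ...) tidy.variant_graph(x, ...)

#' @rdname mitograph-tidiers
#' @method glance mito_study
#' @export
glance.mito_study <- function(x, ...) {
  tibble(
    n_mixtures = nrow(x),
    modal_explaining_pairs =
      as.integer(names(which.max(table(x$n_explaining_pairs)))),
    mean_consistent = mean(x$n_consistent),
    median_consistent = stats::median(x$n_consistent),
    frac_unique_pair = mean(x$n_explaining_pairs == 1L),
    frac_generating_pair_explains = mean(x$generating_pair_explains),
    n_rejected = sum(attr(x, "rejections"))
  )
}
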