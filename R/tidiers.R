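#' @importFrom generics tidy glance
NULL

#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a pharmacology network into an edge table
#'
#' @param x A [netpharm_network()].
#' @param ... Unused.
#' @return A tibble of edges with the endpoint roles joined on.
#' @export
tidy.netpharm_network <- function(x, ...) {
  x$edges |>
    left_join(rename(x$nodes, from_role = "role"), by = c(from = "id")) |>
    left_join(rename(x$nodes, to_role = "role"), by = c(to = "id"))
}

#' One-row composition summary of a network
#'
#' @param x A [netpharm_network()].
#' @param ... Unused.
#' @return The [summarize_network()] row.
#' @export
glance.netpharm_network <- function(x, ...) summarize_network(x)

#' Tidy a module result into long membership form
#'
#' @param x A [find_complexes()] result.
#' @param ... Unused.
#' @return A tibble with one row per (module, member) pair.
#' @export
tidy.netpharm_modules <- function(x, ...) {
  if (nrow(x) == 0) {
    return(tibble(rank = integer(), seed = character(), node = character(),
                  seed_flag = logical()))
  }
  tidyr::unnest(select(as_tibble(x), "rank", "seed", "members"),
                "members") |>
    rename(node = "members") |>
    mutate(seed_flag = .data$node == .data$seed)
}

#' One-row summary of a module detection run
#'
#' @param x A [find_complexes()] result.
#' @param ... Unused.
#' @return A tibble with the module count, total membership and top score.
#' @export
glance.netpharm_modules <- function(x, ...) {
  tibble(n_modules = nrow(x),
         n_members = if (nrow(x)) length(unique(unlist(x$members))) else 0L,
         top_score = if (nrow(x)) max(x$score) else NA_real_)
}

#' Centrality medians and screen summary
#'
#' @param x A [compute_centralities()] table.
#' @param ... Unused.
#' @return A one-row tibble with the three medians and the default-screen
#'   hub count.
#' @export
glance.netpharm_centrality <- function(x, ...) {
  med <- centrality_medians(x)
  tibble(n_nodes = nrow(x),
         median_degree = med[["degree"]],
         median_betweenness = med[["betweenness"]],
         median_closeness = med[["closeness"]],
         n_pass = sum(x$pass))
}

#' One-row summary of an enrichment run
#'
#' @param x An [enrich()] result.
#' @param ... Unused.
#' @return A tibble with term counts and the minimum p-value.
#' @export
glance.netpharm_enrichment <- function(x, ...) {
  tibble(n_terms = nrow(x),
         n_passing = sum(x$passes),
         min_p = if (nrow(x)) min(x$p_value) else NA_real_)
}
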