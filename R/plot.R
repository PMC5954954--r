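#' @importFrom ggplot2 ggplot aes autoplot geom_point geom_segment geom_col
#'   scale_size_continuous labs theme_minimal facet_wrap
NULL

#' @export
ggplot2::autoplot

#' Plot a pharmacology network
#'
#' Draws the network with a deterministic Kamada-Kawai layout, colouring
#' nodes by role (the conventional compound / compound-target /
#' disease-target / shared / other scheme) and distinguishing
#' compound-target from protein-protein edges by linetype.
#'
#' @param object A [netpharm_network()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.netpharm_network <- function(object, ...) {
  g <- as_igraph(object)
  xy <- igraph::layout_with_kk(g)
  nodes <- mutate(object$nodes, x = xy[, 1], y = xy[, 2])
  edges <- object$edges |>
    left_join(select(nodes, "id", x1 = "x", y1 = "y"),
              by = c(from = "id")) |>
    left_join(select(nodes, "id", x2 = "x", y2 = "y"),
              by = c(to = "id"))
  ggplot() +
    geom_segment(data = edges,
                 aes(x = .data$x1, y = .data$y1, xend = .data$x2,
                     yend = .data$y2, linetype = .data$kind),
                 colour = "grey60", linewidth = 0.3) +
    geom_point(data = nodes,
               aes(x = .data$x, y = .data$y, colour = .data$role),
               size = 2) +
    labs(x = NULL, y = NULL, colour = "role", linetype = "edge kind") +
    theme_minimal()
}

#' Plot a centrality table
#'
#' Degree against betweenness (log-scaled betweenness axis suppressed to
#' keep zeros visible), point size mapped to closeness, hub-screen passes
#' highlighted. The dashed lines mark the metric medians used by the
#' screen.
#'
#' @param object A [compute_centralities()] table.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.netpharm_centrality <- function(object, ...) {
  med <- centrality_medians(object)
  ggplot(as_tibble(object),
         aes(x = .data$degree, y = .data$betweenness,
             size = .data$closeness, colour = .data$pass)) +
    geom_point(alpha = 0.7) +
    ggplot2::geom_vline(xintercept = med[["degree"]], linetype = "dashed") +
    ggplot2::geom_hline(yintercept = med[["betweenness"]],
                        linetype = "dashed") +
    labs(colour = "above all medians") +
    theme_minimal()
}

#' Plot detected module scores
#'
#' @param object A [find_complexes()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.netpharm_modules <- function(object, ...) {
  ggplot(as_tibble(object),
         aes(x = factor(.data$rank), y = .data$score)) +
    geom_col(fill = "steelblue") +
    labs(x = "module rank", y = "score (density x size)") +
    theme_minimal()
}

#' Enrichment dot plot across modules
#'
#' The conventional module-by-term dot plot: one column per module, one row
#' per significantly enriched term, dot size showing the rich factor (the
#' fraction of a term's annotated genes hit by the module) and colour the
#' FDR.
#'
#' @param enrichment_list Named list of [enrich()] results, one per module.
#' @param passing_only Show only terms passing the thresholds
#'   (default `TRUE`).
#' @return A ggplot object.
#' @export
plot_enrichment_dotplot <- function(enrichment_list, passing_only = TRUE) {
  long <- purrr::imap_dfr(enrichment_list, function(res, nm) {
    mutate(as_tibble(res), module = nm)
  })
  if (passing_only) long <- filter(long, .data$passes)
  if (nrow(long) == 0) {
    return(ggplot() + theme_minimal() +
             labs(title = "no terms pass the enrichment thresholds"))
  }
  ggplot(long, aes(x = .data$module, y = .data$term_name,
                   size = .data$rich_factor, colour = .data$fdr)) +
    geom_point() +
    scale_size_continuous(limits = c(0, 1)) +
    facet_wrap(~ .data$category, scales = "free_y") +
    labs(x = "module", y = NULL, size = "rich factor", colour = "FDR") +
    theme_minimal()
}
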