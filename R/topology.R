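#' Compute degree, betweenness and closeness centralities
#'
#' The three topological indices used for hub screening. Degree is the
#' number of incident edges. Betweenness is the fraction of shortest paths
#' between other node pairs that pass through the node, normalised to
#' `[0, 1]` by `(n-1)(n-2)/2` for an undirected graph of `n` nodes.
#' Closeness is distance-based reachability, computed within each connected
#' component:
#'
#' * `"normalized"` (default): `(n_comp - 1) / sum(d)` where `d` are the
#'   distances to the other members of the node's component — 1 for the
#'   centre of a star, in `(0, 1]` on any connected graph. This is the
#'   convention graph viewers report and the scale on which published
#'   closeness medians around 0.4-0.5 live.
#' * `"raw_inverse_sum"`: the literal reciprocal of the distance sum,
#'   `1 / sum(d)`.
#'
#' Medians of the three metrics over all table rows are attached as the
#' `"medians"` attribute and a `pass` flag records the default hub screen
#' (all three values strictly above their median; see
#' [screen_by_median()]).
#'
#' @param network A [netpharm_network()] with at least one edge.
#' @param closeness_convention `"normalized"` or `"raw_inverse_sum"`.
#' @return A tibble of class `netpharm_centrality` with columns `node`,
#'   `role`, `degree`, `betweenness`, `closeness`, `pass`.
#' @export
compute_centralities <- function(network,
                                 closeness_convention = c("normalized",
                                                          "raw_inverse_sum")) {
  stopifnot(is_netpharm_network(network))
  closeness_convention <- match.arg(closeness_convention)
  if (nrow(network$edges) == 0) {
    abort("network has no edges; centralities are undefined.")
  }
  g <- as_igraph(network)
  n <- igraph::vcount(g)
  ids <- igraph::V(g)$name

  deg <- igraph::degree(g)
  btw <- igraph::betweenness(g, directed = FALSE, weights = NA)
  btw <- if (n > 2) btw / ((n - 1) * (n - 2) / 2) else rep(0, n)

  comp <- igraph::components(g)
  clo <- numeric(n)
  for (ci in seq_len(comp$no)) {
    members <- which(comp$membership == ci)
    if (length(members) < 2) { clo[members] <- 0; next }
    d <- igraph::distances(g, v = members, to = members, weights = NA)
    s <- rowSums(d)
    clo[members] <- if (closeness_convention == "normalized") {
      (length(members) - 1) / s
    } else {
      1 / s
    }
  }

  out <- tibble(
    node = ids,
    role = network$nodes$role[match(ids, network$nodes$id)],
    degree = as.integer(deg),
    betweenness = as.numeric(btw),
    closeness = clo
  )
  med <- c(degree = stats::median(out$degree),
           betweenness = stats::median(out$betweenness),
           closeness = stats::median(out$closeness))
  out$pass <- out$degree > med[["degree"]] &
    out$betweenness > med[["betweenness"]] &
    out$closeness > med[["closeness"]]
  attr(out, "medians") <- med
  attr(out, "closeness_convention") <- closeness_convention
  class(out) <- c("netpharm_centrality", class(out))
  out
}

#' Median metric values of a centrality table
#'
#' @param table A table from [compute_centralities()].
#' @return Named numeric vector with `degree`, `betweenness`, `closeness`.
#' @export
centrality_medians <- function(table) {
  m <- attr(table, "medians")
  m %||% c(degree = stats::median(table$degree),
           betweenness = stats::median(table$betweenness),
           closeness = stats::median(table$closeness))
}

#' Screen hub nodes against median centralities
#'
#' A node is a hub when, for every metric, its value exceeds
#' `multiplier * median(metric)`. Multipliers of 1 reproduce the usual
#' "above all three medians" rule; a degree multiplier of 2 reproduces the
#' stricter "degree above twice the median" variant sometimes applied to
#' larger networks. The comparison is strict (`>`) by default, so a value
#' exactly equal to its threshold does not pass.
#'
#' @param table Centrality table from [compute_centralities()].
#' @param multipliers Named numeric vector with entries `degree`,
#'   `betweenness`, `closeness` (missing entries default to 1); or a single
#'   number recycled over all three.
#' @param strict Use strict `>` (default) or inclusive `>=`.
#' @return Character vector of hub node ids, sorted by degree descending
#'   with ties broken lexicographically.
#' @examples
#' net <- netpharm_network(
#'   nodes = data.frame(id = LETTERS[1:4], role = "other"),
#'   edges = data.frame(from = c("A", "A", "A"), to = c("B", "C", "D"))
#' )
#' screen_by_median(compute_centralities(net))
#' @export
screen_by_median <- function(table, multipliers = 1, strict = TRUE) {
  if (length(multipliers) == 1 && is.null(names(multipliers))) {
    multipliers <- c(degree = multipliers, betweenness = multipliers,
                     closeness = multipliers)
  }
  mult <- c(degree = 1, betweenness = 1, closeness = 1)
  mult[names(multipliers)] <- multipliers
  if (any(mult <= 0)) abort("multipliers must be positive.")
  med <- centrality_medians(table)
  cmp <- if (strict) `>` else `>=`
  pass <- cmp(table$degree, mult[["degree"]] * med[["degree"]]) &
    cmp(table$betweenness, mult[["betweenness"]] * med[["betweenness"]]) &
    cmp(table$closeness, mult[["closeness"]] * med[["closeness"]])
  hubs <- table[pass, ]
  hubs <- hubs[order(-hubs$degree, hubs$node, method = "radix"), ]
  hubs$node
}
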