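#' @importFrom rlang %||% abort warn .data
#' @importFrom dplyr filter mutate select arrange left_join distinct bind_rows
#'   group_by summarise ungroup pull rename count n desc across all_of row_number
#' @importFrom tibble tibble as_tibble
NULL

NODE_ROLES <- c("compound", "compound_target", "disease_target",
                "shared_target", "other")

#' Annotated pharmacology network
#'
#' A light container for the node-and-edge graphs used throughout the
#' pipeline: a tibble of nodes, each carrying a role label, and a tibble of
#' undirected edges, each carrying an interaction kind (`"ct"` for
#' compound-target, `"pp"` for protein-protein) and an optional confidence
#' score. Edges are stored with canonically ordered endpoints
#' (`from <= to`) and duplicate unordered pairs are collapsed, keeping the
#' maximum score.
#'
#' Node roles follow the conventional colouring of compound-target figures:
#' `compound` (a chemical ingredient), `compound_target` (protein targeted
#' by a compound only), `disease_target` (protein in the disease gene set
#' only), `shared_target` (both), and `other` (interactor pulled in from
#' the PPI).
#'
#' @param nodes Data frame with columns `id` and `role`; `role` must be one
#'   of `"compound"`, `"compound_target"`, `"disease_target"`,
#'   `"shared_target"`, `"other"`.
#' @param edges Data frame with columns `from`, `to`, and optionally `kind`
#'   (default `"pp"`) and `score` (default `NA`).
#' @return An object of class `netpharm_network`: a list with tibbles
#'   `$nodes` and `$edges`.
#' @examples
#' net <- netpharm_network(
#'   nodes = data.frame(id = c("A", "B", "C"), role = "other"),
#'   edges = data.frame(from = c("A", "B"), to = c("B", "C"))
#' )
#' net
#' @export
netpharm_network <- function(nodes, edges) {
  nodes <- as_tibble(nodes)
  if (!all(c("id", "role") %in% names(nodes))) {
    abort("`nodes` must have columns `id` and `role`.")
  }
  nodes <- nodes[, c("id", "role")]
  nodes$id <- as.character(nodes$id)
  nodes$role <- as.character(nodes$role)
  if (anyDuplicated(nodes$id)) abort("duplicate node ids in `nodes`.")
  bad <- setdiff(unique(nodes$role), NODE_ROLES)
  if (length(bad)) {
    abort(paste0("unknown node role(s): ", paste(bad, collapse = ", ")))
  }

  edges <- as_tibble(edges)
  if (nrow(edges) == 0) {
    edges <- tibble(from = character(), to = character(),
                    kind = character(), score = double())
  }
  if (!all(c("from", "to") %in% names(edges))) {
    abort("`edges` must have columns `from` and `to`.")
  }
  if (!"kind" %in% names(edges)) edges$kind <- "pp"
  if (!"score" %in% names(edges)) edges$score <- NA_real_
  edges <- edges[, c("from", "to", "kind", "score")]
  edges$from <- as.character(edges$from)
  edges$to <- as.character(edges$to)
  edges$score <- as.numeric(edges$score)
  if (any(edges$from == edges$to)) abort("self-loops are not allowed.")
  missing_ep <- setdiff(c(edges$from, edges$to), nodes$id)
  if (length(missing_ep)) {
    abort(paste0("edge endpoint(s) not in node set: ",
                 paste(utils::head(missing_ep, 5), collapse = ", ")))
  }
  edges <- canonicalize_edges(edges)

  structure(list(nodes = nodes, edges = edges), class = "netpharm_network")
}

# Order endpoints, collapse duplicate unordered pairs to the max score
# (first kind wins), preserve first-appearance order.
canonicalize_edges <- function(edges) {
  if (nrow(edges) == 0) return(edges)
  a <- pmin(edges$from, edges$to)
  b <- pmax(edges$from, edges$to)
  edges$from <- a
  edges$to <- b
  edges |>
    group_by(.data$from, .data$to) |>
    summarise(
      kind = .data$kind[1],
      score = if (all(is.na(.data$score))) NA_real_ else
        max(.data$score, na.rm = TRUE),
      .order = min(row_number()),
      .groups = "drop"
    ) |>
    arrange(.data$.order) |>
    select(-".order")
}

#' @export
print.netpharm_network <- function(x, ...) {
  cat("<netpharm_network> ", nrow(x$nodes), " nodes, ",
      nrow(x$edges), " edges\n", sep = "")
  rc <- table(factor(x$nodes$role, levels = NODE_ROLES))
  rc <- rc[rc > 0]
  if (length(rc)) {
    cat("  roles: ", paste(names(rc), rc, sep = "=", collapse = ", "), "\n",
        sep = "")
  }
  kc <- table(x$edges$kind)
  if (length(kc)) {
    cat("  edges: ", paste(names(kc), kc, sep = "=", collapse = ", "), "\n",
        sep = "")
  }
  invisible(x)
}

#' @export
format.netpharm_network <- function(x, ...) {
  paste0("<netpharm_network> ", nrow(x$nodes), " nodes, ",
         nrow(x$edges), " edges")
}

is_netpharm_network <- function(x) inherits(x, "netpharm_network")

#' Convert a pharmacology network to an igraph graph
#'
#' @param network A [netpharm_network()].
#' @return An undirected `igraph` graph with vertex attribute `role` and
#'   edge attributes `kind` and `score`.
#' @export
as_igraph <- function(network) {
  stopifnot(is_netpharm_network(network))
  igraph::graph_from_data_frame(
    d = network$edges,
    directed = FALSE,
    vertices = network$nodes
  )
}

#' Drop isolated nodes from a network
#'
#' Nodes with no incident edge are removed; network figures and counts in
#' this package always refer to the connected part.
#'
#' @param network A [netpharm_network()].
#' @return The network without degree-zero nodes.
#' @export
drop_isolated <- function(network) {
  stopifnot(is_netpharm_network(network))
  keep <- network$nodes$id %in% c(network$edges$from, network$edges$to)
  network$nodes <- network$nodes[keep, ]
  network
}

#' Summarise network composition
#'
#' Counts nodes per role plus node and edge totals, the bookkeeping printed
#' alongside every network in a network-pharmacology report. The role
#' counts always sum to the node total.
#'
#' @param network A [netpharm_network()].
#' @return A one-row tibble with columns `n_nodes`, `n_edges`, one count per
#'   role (`n_compound`, `n_compound_target`, `n_disease_target`,
#'   `n_shared_target`, `n_other`).
#' @examples
#' net <- netpharm_network(
#'   nodes = data.frame(id = c("c1", "T1"), role = c("compound", "compound_target")),
#'   edges = data.frame(from = "c1", to = "T1", kind = "ct")
#' )
#' summarize_network(net)
#' @export
summarize_network <- function(network) {
  stopifnot(is_netpharm_network(network))
  rc <- table(factor(network$nodes$role, levels = NODE_ROLES))
  out <- tibble(
    n_nodes = nrow(network$nodes),
    n_edges = nrow(network$edges)
  )
  for (r in NODE_ROLES) out[[paste0("n_", r)]] <- as.integer(rc[[r]])
  out
}
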