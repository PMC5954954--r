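#' Export a network for external graph tools
#'
#' Writes a [netpharm_network()] in one of three formats plus a companion
#' node-attribute TSV (columns `node`, `role`) so that role colouring
#' survives the trip into a graph viewer:
#'
#' * `"sif"` — simple interaction format, one `source <TAB> relation <TAB>
#'   target` line per edge; relation is the edge kind (`pp` or `ct`).
#'   Isolated nodes are written as single-field lines. SIF carries no
#'   scores.
#' * `"graphml"` — GraphML via igraph, with `role`, `kind` and `score`
#'   attributes; fully round-trippable.
#' * `"edge_tsv"` — plain `from to kind score` TSV; round-trippable
#'   together with the node-attribute file.
#'
#' @param network A [netpharm_network()].
#' @param path Output path.
#' @param format One of `"sif"`, `"graphml"`, `"edge_tsv"`.
#' @param node_attr_path Path for the node-attribute TSV; default replaces
#'   the extension of `path` with `_nodes.tsv`.
#' @return `path`, invisibly.
#' @seealso [read_network()]
#' @export
write_network <- function(network, path,
                          format = c("sif", "graphml", "edge_tsv"),
                          node_attr_path = NULL) {
  stopifnot(is_netpharm_network(network))
  format <- match.arg(format)
  node_attr_path <- node_attr_path %||% default_node_attr_path(path)

  if (format == "sif") {
    e <- network$edges
    lines <- paste(e$from, e$kind, e$to, sep = "\t")
    iso <- setdiff(network$nodes$id, c(e$from, e$to))
    writeLines(c(lines, iso), path)
  } else if (format == "edge_tsv") {
    readr::write_tsv(network$edges, path, progress = FALSE)
  } else {
    g <- as_igraph(network)
    # GraphML has no NA; NaN survives igraph's writer/reader.
    if (igraph::ecount(g) > 0) {
      sc <- igraph::E(g)$score
      sc[is.na(sc)] <- NaN
      igraph::E(g)$score <- sc
    }
    igraph::write_graph(g, path, format = "graphml")
  }
  readr::write_tsv(
    tibble(node = network$nodes$id, role = network$nodes$role),
    node_attr_path, progress = FALSE
  )
  invisible(path)
}

default_node_attr_path <- function(path) {
  paste0(tools::file_path_sans_ext(path), "_nodes.tsv")
}

#' Read a network written by [write_network()]
#'
#' Reconstructs the network from any of the three export formats and the
#' companion node-attribute TSV. Nodes present only in the attribute file
#' are restored as isolated nodes; nodes missing from it default to role
#' `"other"`.
#'
#' @param path Path to the network file.
#' @param format One of `"sif"`, `"graphml"`, `"edge_tsv"`.
#' @param node_attr_path Companion node-attribute TSV; default as in
#'   [write_network()]. Ignored for GraphML, which embeds roles.
#' @return A [netpharm_network()].
#' @export
read_network <- function(path, format = c("sif", "graphml", "edge_tsv"),
                         node_attr_path = NULL) {
  format <- match.arg(format)
  node_attr_path <- node_attr_path %||% default_node_attr_path(path)

  if (format == "graphml") {
    g <- igraph::read_graph(path, format = "graphml")
    nodes <- tibble(id = igraph::V(g)$name,
                    role = igraph::V(g)$role %||% "other")
    if (igraph::ecount(g) > 0) {
      el <- igraph::as_edgelist(g, names = TRUE)
      score <- igraph::E(g)$score %||% rep(NA_real_, nrow(el))
      score[is.nan(score)] <- NA_real_
      edges <- tibble(from = el[, 1], to = el[, 2],
                      kind = igraph::E(g)$kind %||% "pp", score = score)
    } else {
      edges <- tibble(from = character(), to = character())
    }
    return(netpharm_network(nodes, edges))
  }

  if (format == "sif") {
    lines <- readLines(path)
    lines <- lines[nzchar(trimws(lines))]
    parts <- strsplit(lines, "\t", fixed = TRUE)
    iso <- vapply(parts, length, 1L) == 1L
    ep <- parts[!iso]
    edges <- tibble(
      from = purrr::map_chr(ep, 1, .default = NA_character_),
      kind = purrr::map_chr(ep, 2, .default = NA_character_),
      to = purrr::map_chr(ep, 3, .default = NA_character_)
    )
    edges$score <- NA_real_
    node_ids <- unique(c(edges$from, edges$to,
                         purrr::map_chr(parts[iso], 1)))
  } else {
    edges <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
    node_ids <- unique(c(edges$from, edges$to))
  }

  roles <- tibble(id = node_ids, role = "other")
  if (file.exists(node_attr_path)) {
    attrs <- readr::read_tsv(node_attr_path, show_col_types = FALSE,
                             progress = FALSE)
    roles <- tibble(id = as.character(attrs$node),
                    role = as.character(attrs$role))
    extra <- setdiff(node_ids, roles$id)
    if (length(extra)) roles <- bind_rows(roles, tibble(id = extra,
                                                        role = "other"))
  }
  netpharm_network(roles, edges)
}
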