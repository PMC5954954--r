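# Role of a protein node given membership in the compound-target and
# disease-target gene sets.
protein_role <- function(ids, compound_targets, disease_targets) {
  in_c <- ids %in% compound_targets
  in_d <- ids %in% disease_targets
  dplyr::case_when(
    in_c & in_d ~ "shared_target",
    in_c ~ "compound_target",
    in_d ~ "disease_target",
    .default = "other"
  )
}

#' Build the compound-target bipartite network
#'
#' Connects each compound to its targets with `ct` edges. Targets that are
#' also disease targets get role `shared_target`; the rest get
#' `compound_target`. No target-target edges are created.
#'
#' @param records Compound-target tibble (columns `compound_id`, `target`),
#'   as from [read_compound_targets()].
#' @param disease_targets Character vector of disease gene symbols
#'   (default none).
#' @return A [netpharm_network()] with `compound` nodes on one side and
#'   target nodes on the other.
#' @export
build_bipartite_network <- function(records, disease_targets = character()) {
  records <- as_tibble(records)
  if (nrow(records) == 0) {
    abort("no compound-target records; cannot build a bipartite network.")
  }
  records <- distinct(records, .data$compound_id, .data$target)
  disease_targets <- toupper(disease_targets)
  compounds <- unique(records$compound_id)
  targets <- unique(records$target)
  clash <- intersect(compounds, targets)
  if (length(clash)) {
    abort(paste0("compound ids collide with target symbols: ",
                 paste(utils::head(clash, 3), collapse = ", ")))
  }
  nodes <- bind_rows(
    tibble(id = compounds, role = "compound"),
    tibble(id = targets,
           role = ifelse(targets %in% disease_targets,
                         "shared_target", "compound_target"))
  )
  edges <- tibble(from = records$compound_id, to = records$target,
                  kind = "ct", score = NA_real_)
  netpharm_network(nodes, edges)
}

#' Expand a seed gene set into its PPI neighbourhood
#'
#' Builds the PPI network "of" a seed set: the seeds that occur in the
#' filtered interaction data plus every other protein adjacent to at least
#' `min_seed_links` seeds, with **all** interactions among the retained
#' proteins (the induced subgraph). Seeds that end up with no edge are
#' dropped.
#'
#' Non-seed interactors get role `other`. Role labels for the retained
#' proteins can be refined by passing the compound-target and
#' disease-target gene sets, which assigns `compound_target` /
#' `disease_target` / `shared_target` by membership; otherwise seeds get
#' `seed_role`.
#'
#' @param ppi_edges Tibble from [read_ppi_edges()] (already score-filtered).
#' @param seeds Character vector of seed gene symbols.
#' @param min_seed_links Minimum number of seed neighbours a non-seed
#'   protein needs to be pulled in (default 2).
#' @param compound_targets,disease_targets Optional gene sets for role
#'   labelling.
#' @param seed_role Role given to seeds when no gene sets are supplied.
#' @return A [netpharm_network()] of `pp` edges.
#' @export
expand_with_interactors <- function(ppi_edges, seeds, min_seed_links = 2,
                                    compound_targets = NULL,
                                    disease_targets = NULL,
                                    seed_role = "compound_target") {
  ppi_edges <- as_tibble(ppi_edges)
  seeds <- unique(toupper(seeds))
  if (length(seeds) == 0) abort("empty seed set.")
  if (min_seed_links < 1) abort("`min_seed_links` must be >= 1.")

  ppi_nodes <- unique(c(ppi_edges$protein_a, ppi_edges$protein_b))
  seeds_in <- intersect(seeds, ppi_nodes)

  # Count, for every non-seed protein, how many distinct seeds it touches.
  touch <- bind_rows(
    tibble(node = ppi_edges$protein_a, other = ppi_edges$protein_b),
    tibble(node = ppi_edges$protein_b, other = ppi_edges$protein_a)
  ) |>
    filter(!(.data$node %in% seeds_in), .data$other %in% seeds_in) |>
    distinct(.data$node, .data$other) |>
    count(.data$node, name = "n_seed_links")
  neighbours <- touch$node[touch$n_seed_links >= min_seed_links]

  keep <- c(seeds_in, neighbours)
  edges <- filter(ppi_edges,
                  .data$protein_a %in% keep & .data$protein_b %in% keep)

  connected <- unique(c(edges$protein_a, edges$protein_b))
  keep <- keep[keep %in% connected]
  if (length(keep) == 0) {
    warn("expansion produced an empty network (no connected seeds).")
  }
  if (is.null(compound_targets) && is.null(disease_targets)) {
    roles <- ifelse(keep %in% seeds_in, seed_role, "other")
  } else {
    roles <- protein_role(keep,
                          toupper(compound_targets %||% character()),
                          toupper(disease_targets %||% character()))
  }
  netpharm_network(
    nodes = tibble(id = keep, role = roles),
    edges = tibble(from = edges$protein_a, to = edges$protein_b,
                   kind = "pp", score = edges$score)
  )
}

# Merge two role labels on the shared-membership lattice.
merge_roles <- function(r1, r2) {
  as_bits <- function(r) cbind(
    compound = r %in% c("compound_target", "shared_target"),
    disease = r %in% c("disease_target", "shared_target")
  )
  b <- as_bits(r1) | as_bits(r2)
  dplyr::case_when(
    b[, 1] & b[, 2] ~ "shared_target",
    b[, 1] ~ "compound_target",
    b[, 2] ~ "disease_target",
    .default = "other"
  )
}

#' Intersect two PPI networks
#'
#' The network of targets shared between two PPI expansions (for example
#' the compound-target expansion and the disease-target expansion): nodes
#' present in both parents, edges present in both parents, isolated
#' survivors dropped. A surviving node's role merges its parent roles —
#' a node that is a compound target in one parent and a disease target in
#' the other becomes a `shared_target`.
#'
#' @param net_a,net_b [netpharm_network()] objects with `pp` edges only.
#' @return A [netpharm_network()].
#' @export
intersect_networks <- function(net_a, net_b) {
  stopifnot(is_netpharm_network(net_a), is_netpharm_network(net_b))
  if (any(net_a$edges$kind != "pp") || any(net_b$edges$kind != "pp")) {
    abort("intersect_networks() expects pp-edge networks.")
  }
  node_ids <- intersect(net_a$nodes$id, net_b$nodes$id)
  if (length(node_ids) == 0) {
    warn("networks share no nodes; intersection is empty.")
  }
  key <- function(e) paste(e$from, e$to)
  eb_keys <- key(net_b$edges)
  edges <- net_a$edges[key(net_a$edges) %in% eb_keys, ]
  edges <- edges[edges$from %in% node_ids & edges$to %in% node_ids, ]
  # score: the two parents may carry different scores for the same pair;
  # keep the maximum, consistent with duplicate collapsing elsewhere.
  eb <- net_b$edges
  m <- match(key(edges), eb_keys)
  edges$score <- pmax(edges$score, eb$score[m], na.rm = TRUE)

  connected <- unique(c(edges$from, edges$to))
  keep <- node_ids[node_ids %in% connected]
  ra <- net_a$nodes$role[match(keep, net_a$nodes$id)]
  rb <- net_b$nodes$role[match(keep, net_b$nodes$id)]
  netpharm_network(
    nodes = tibble(id = keep, role = merge_roles(ra, rb)),
    edges = edges
  )
}
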