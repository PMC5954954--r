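#' MCODE parameter set
#'
#' Parameters of the molecular-complex-detection algorithm. The defaults
#' mirror the widely used Cytoscape plugin: vertices of degree below
#' `degree_cutoff` are ignored during weighting; expansion from a seed
#' admits vertices whose weight exceeds `(1 - node_score_cutoff)` times the
#' seed weight; predicted complexes must contain a `k_core`-core; the
#' haircut removes singly connected members; fluff (off by default) grows a
#' complex with neighbours whose neighbourhood density exceeds
#' `fluff_density_cutoff`.
#'
#' @param degree_cutoff Integer >= 1 (default 2).
#' @param node_score_cutoff Vertex weight percentage in `[0, 1)`
#'   (default 0.2).
#' @param k_core Integer >= 2 (default 2).
#' @param haircut Logical (default `TRUE`).
#' @param fluff Logical (default `FALSE`).
#' @param fluff_density_cutoff Real in `[0, 1]` (default 0.1).
#' @param max_depth Maximum expansion depth from the seed (default 100).
#' @return A list of class `mcode_params`.
#' @export
mcode_params <- function(degree_cutoff = 2, node_score_cutoff = 0.2,
                         k_core = 2, haircut = TRUE, fluff = FALSE,
                         fluff_density_cutoff = 0.1, max_depth = 100) {
  stopifnot(degree_cutoff >= 1,
            node_score_cutoff >= 0, node_score_cutoff < 1,
            k_core >= 2,
            is.logical(haircut), is.logical(fluff),
            fluff_density_cutoff >= 0, fluff_density_cutoff <= 1,
            max_depth >= 1)
  structure(list(degree_cutoff = as.integer(degree_cutoff),
                 node_score_cutoff = node_score_cutoff,
                 k_core = as.integer(k_core),
                 haircut = haircut, fluff = fluff,
                 fluff_density_cutoff = fluff_density_cutoff,
                 max_depth = as.integer(max_depth)),
            class = "mcode_params")
}

# density = 2E / (V(V-1)), loops excluded; 0 for fewer than 2 vertices.
graph_density_simple <- function(n_vertices, n_edges) {
  if (n_vertices < 2) return(0)
  2 * n_edges / (n_vertices * (n_vertices - 1))
}

# Induced-subgraph edge count from an adjacency list of integer indices.
count_edges_within <- function(adj, members) {
  if (length(members) < 2) return(0L)
  inset <- logical(length(adj))
  inset[members] <- TRUE
  sum(vapply(members, function(v) sum(inset[adj[[v]]]), 1L)) %/% 2L
}

# k-coreness of an induced subgraph given integer-index adjacency.
coreness_within <- function(adj, members) {
  inset <- logical(length(adj))
  inset[members] <- TRUE
  deg <- vapply(members, function(v) sum(inset[adj[[v]]]), 1L)
  names(deg) <- members
  core <- integer(length(members))
  names(core) <- members
  alive <- rep(TRUE, length(members))
  k <- 0L
  while (any(alive)) {
    repeat {
      low <- which(alive & deg <= k)
      if (!length(low)) break
      core[low] <- k
      alive[low] <- FALSE
      for (i in low) {
        nb <- adj[[members[i]]]
        idx <- match(nb, members)
        idx <- idx[!is.na(idx)]
        idx <- idx[alive[idx]]
        deg[idx] <- deg[idx] - 1L
      }
    }
    k <- k + 1L
  }
  core
}

#' MCODE vertex weighting
#'
#' Weights each vertex by the density of the most cohesive region around
#' it: the weight of `v` is the highest core number `k_max` of the
#' subgraph induced by the closed neighbourhood `N[v]`, multiplied by the
#' density of that highest k-core. Vertices whose degree is below
#' `degree_cutoff` get weight 0.
#'
#' @param network A [netpharm_network()] (treated as a simple undirected
#'   graph; only `pp` edges are meaningful here).
#' @param params An [mcode_params()] object.
#' @return A tibble with columns `node` and `weight`.
#' @export
mcode_vertex_weights <- function(network, params = mcode_params()) {
  stopifnot(is_netpharm_network(network), inherits(params, "mcode_params"))
  ids <- network$nodes$id
  adj <- adjacency_index(network, ids)
  w <- vapply(seq_along(ids), function(v) {
    if (length(adj[[v]]) < params$degree_cutoff) return(0)
    nbhd <- c(v, adj[[v]])
    core <- coreness_within(adj, nbhd)
    kmax <- max(core)
    if (kmax == 0) return(0)
    core_vs <- nbhd[core == kmax]
    e <- count_edges_within(adj, core_vs)
    kmax * graph_density_simple(length(core_vs), e)
  }, numeric(1))
  tibble(node = ids, weight = w)
}

# integer-index adjacency list in the order of `ids`
adjacency_index <- function(network, ids) {
  n <- length(ids)
  adj <- vector("list", n)
  for (i in seq_len(n)) adj[[i]] <- integer(0)
  if (nrow(network$edges)) {
    fi <- match(network$edges$from, ids)
    ti <- match(network$edges$to, ids)
    for (k in seq_along(fi)) {
      adj[[fi[k]]] <- c(adj[[fi[k]]], ti[k])
      adj[[ti[k]]] <- c(adj[[ti[k]]], fi[k])
    }
  }
  adj
}

#' Detect molecular complexes (MCODE)
#'
#' Seeded greedy complex prediction over a vertex-weighted graph. The
#' highest-weight unexamined vertex seeds a complex; breadth-first
#' expansion admits a neighbour when its weight exceeds
#' `seed_weight * (1 - node_score_cutoff)` — always compared against the
#' *original* seed's weight — up to `max_depth` steps from the seed. Each
#' vertex belongs to at most one complex. Post-processing drops complexes
#' lacking a `k_core`-core, optionally fluffs the boundary, applies the
#' haircut (restriction to the 2-core of the complex), and discards
#' complexes smaller than 2. Ties in seed selection are broken by
#' lexicographic node id, making the result independent of input order.
#' When the haircut removes the original seed itself, the highest-weight
#' surviving member is reported as the seed, so the seed is always a
#' member.
#'
#' Each complex is scored by `density * size`, where density is
#' `2E / (V(V-1))` within the complex.
#'
#' @param network A [netpharm_network()].
#' @param params An [mcode_params()] object.
#' @param weights Optional precomputed tibble from
#'   [mcode_vertex_weights()].
#' @return A tibble of class `netpharm_modules` with columns `rank`,
#'   `seed`, `size`, `density`, `score`, and list-column `members`, ranked
#'   by descending score.
#' @examples
#' # two disjoint triangles
#' edges <- data.frame(from = c("A", "B", "C", "X", "Y", "Z"),
#'                     to   = c("B", "C", "A", "Y", "Z", "X"))
#' nodes <- data.frame(id = unique(c(edges$from, edges$to)), role = "other")
#' find_complexes(netpharm_network(nodes, edges))
#' @export
find_complexes <- function(network, params = mcode_params(), weights = NULL) {
  stopifnot(is_netpharm_network(network), inherits(params, "mcode_params"))
  ids <- network$nodes$id
  n <- length(ids)
  if (n == 0 || nrow(network$edges) == 0) {
    return(empty_modules())
  }
  adj <- adjacency_index(network, ids)
  if (is.null(weights)) weights <- mcode_vertex_weights(network, params)
  w <- weights$weight[match(ids, weights$node)]

  in_complex <- logical(n)
  seeded <- logical(n)
  complexes <- list()

  # deterministic seed order: weight desc, then id asc (C collation)
  seed_order <- order(-w, ids, method = "radix")

  for (s in seed_order) {
    if (seeded[s] || in_complex[s]) next
    seeded[s] <- TRUE
    if (w[s] <= 0) next
    threshold <- w[s] * (1 - params$node_score_cutoff)
    members <- s
    in_complex[s] <- TRUE
    frontier <- s
    depth <- 0L
    while (length(frontier) && depth < params$max_depth) {
      nxt <- integer(0)
      for (v in frontier) {
        for (u in adj[[v]]) {
          if (!in_complex[u] && w[u] > threshold) {
            in_complex[u] <- TRUE
            members <- c(members, u)
            nxt <- c(nxt, u)
          }
        }
      }
      frontier <- nxt
      depth <- depth + 1L
    }

    if (length(members) < 2) { in_complex[members] <- FALSE; next }

    # must contain a k_core-core
    core <- coreness_within(adj, members)
    if (max(core) < params$k_core) { in_complex[members] <- FALSE; next }

    if (params$fluff) {
      boundary <- unique(unlist(adj[members]))
      boundary <- boundary[!in_complex[boundary]]
      for (u in sort(boundary)) {
        nbhd <- c(u, adj[[u]])
        e <- count_edges_within(adj, nbhd)
        if (graph_density_simple(length(nbhd), e) >
            params$fluff_density_cutoff) {
          in_complex[u] <- TRUE
          members <- c(members, u)
        }
      }
    }

    if (params$haircut) {
      core <- coreness_within(adj, members)
      dropped <- members[core < 2]
      members <- members[core >= 2]
      in_complex[dropped] <- FALSE
    }

    if (length(members) < 2) { in_complex[members] <- FALSE; next }
    # the haircut may shave the seed itself; report the highest-weight
    # surviving member as the complex seed so the seed is always a member
    rep_seed <- if (s %in% members) s else
      members[order(-w[members], ids[members], method = "radix")][1]
    complexes[[length(complexes) + 1]] <- list(seed = rep_seed,
                                               members = members)
  }

  if (!length(complexes)) return(empty_modules())
  out <- purrr::map_dfr(complexes, function(cx) {
    size <- length(cx$members)
    e <- count_edges_within(adj, cx$members)
    dens <- graph_density_simple(size, e)
    tibble(seed = ids[cx$seed], size = size, density = dens,
           score = dens * size,
           members = list(sort(ids[cx$members])))
  })
  out <- out[order(-out$score, -out$size, out$seed, method = "radix"), ]
  out <- mutate(out, rank = row_number(), .before = 1)
  class(out) <- c("netpharm_modules", class(out))
  out
}

empty_modules <- function() {
  out <- tibble(rank = integer(), seed = character(), size = integer(),
                density = double(), score = double(), members = list())
  class(out) <- c("netpharm_modules", class(out))
  out
}

#' Score a candidate complex
#'
#' The MCODE complex score: subgraph density (`2E / (V(V-1))`, loops
#' excluded) times the number of members. A k-clique scores exactly k.
#'
#' @param network A [netpharm_network()].
#' @param members Character vector of at least two node ids, all present in
#'   the network.
#' @return A single number in `[0, |members|]`.
#' @export
complex_score <- function(network, members) {
  stopifnot(is_netpharm_network(network))
  members <- unique(members)
  if (length(members) < 2) abort("a complex needs at least 2 members.")
  missing <- setdiff(members, network$nodes$id)
  if (length(missing)) {
    abort(paste0("member(s) not in network: ",
                 paste(utils::head(missing, 5), collapse = ", ")))
  }
  e <- network$edges
  inset <- e$from %in% members & e$to %in% members
  graph_density_simple(length(members), sum(inset)) * length(members)
}
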