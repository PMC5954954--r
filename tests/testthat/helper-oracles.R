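# Test helpers: small network builders and brute-force oracles that are
# independent of the package's (igraph-backed) implementations.

# quick network from paired endpoint vectors
make_net <- function(from, to, roles = NULL, kind = "pp", score = NA_real_) {
  ids <- sort(unique(c(from, to)))
  roles <- roles %||% stats::setNames(rep("other", length(ids)), ids)
  netpharm_network(
    nodes = tibble::tibble(id = ids, role = unname(roles[ids])),
    edges = tibble::tibble(from = from, to = to, kind = kind, score = score)
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

k_clique_edges <- function(ids) {
  cmb <- utils::combn(ids, 2)
  list(from = cmb[1, ], to = cmb[2, ])
}

random_edge_df <- function(n, p) {
  ids <- sprintf("N%02d", seq_len(n))
  cmb <- utils::combn(ids, 2)
  keep <- stats::runif(ncol(cmb)) < p
  data.frame(from = cmb[1, keep], to = cmb[2, keep])
}

# adjacency matrix in node order of `net$nodes$id`
adj_matrix <- function(net) {
  ids <- net$nodes$id
  A <- matrix(0L, length(ids), length(ids), dimnames = list(ids, ids))
  for (i in seq_len(nrow(net$edges))) {
    a <- net$edges$from[i]; b <- net$edges$to[i]
    A[a, b] <- 1L; A[b, a] <- 1L
  }
  A
}

# all-pairs shortest-path distances by repeated neighbourhood expansion on
# the adjacency matrix (no graph library involved)
dist_matrix_oracle <- function(A) {
  n <- nrow(A)
  D <- matrix(Inf, n, n, dimnames = dimnames(A))
  diag(D) <- 0
  reach <- diag(n) == 1
  step <- A > 0
  k <- 1
  frontier <- step
  while (any(frontier & !reach)) {
    D[frontier & !reach] <- k
    reach <- reach | frontier
    frontier <- (frontier %*% A) > 0
    k <- k + 1
    if (k > n) break
  }
  D
}

# shortest-path counts sigma[s, t] by dynamic programming over distance
# layers (independent of Brandes-style accumulation)
sigma_counts_oracle <- function(A, D) {
  n <- nrow(A)
  sigma <- matrix(0, n, n, dimnames = dimnames(A))
  diag(sigma) <- 1
  for (s in seq_len(n)) {
    ord <- order(D[s, ])
    for (t in ord) {
      if (t == s || !is.finite(D[s, t])) next
      preds <- which(A[, t] > 0 & D[s, ] == D[s, t] - 1)
      sigma[s, t] <- sum(sigma[s, preds])
    }
  }
  sigma
}

# normalised betweenness, closeness (both conventions) and degree,
# computed from first principles
oracle_centralities <- function(net,
                                closeness_convention = "normalized") {
  A <- adj_matrix(net)
  n <- nrow(A)
  D <- dist_matrix_oracle(A)
  sigma <- sigma_counts_oracle(A, D)
  btw <- numeric(n)
  for (v in seq_len(n)) {
    acc <- 0
    for (s in seq_len(n)) {
      if (s == v) next
      for (t in seq_len(n)) {
        if (t <= s || t == v) next
        if (!is.finite(D[s, t]) || sigma[s, t] == 0) next
        if (D[s, v] + D[v, t] == D[s, t]) {
          acc <- acc + sigma[s, v] * sigma[v, t] / sigma[s, t]
        }
      }
    }
    btw[v] <- acc
  }
  if (n > 2) btw <- btw / ((n - 1) * (n - 2) / 2)
  clo <- numeric(n)
  for (v in seq_len(n)) {
    comp <- which(is.finite(D[v, ]))
    if (length(comp) < 2) { clo[v] <- 0; next }
    s <- sum(D[v, setdiff(comp, v)])
    clo[v] <- if (closeness_convention == "normalized") {
      (length(comp) - 1) / s
    } else 1 / s
  }
  tibble::tibble(node = rownames(A), degree = as.integer(rowSums(A)),
                 betweenness = btw, closeness = clo)
}

# direct hypergeometric upper tail by summing the combinatorial mass
hyper_tail_oracle <- function(k, K, n, N) {
  ks <- seq(k, min(K, n))
  sum(choose(K, ks) * choose(N - K, n - ks)) / choose(N, n)
}
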