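ct_records <- function(compounds, targets) {
  tibble::tibble(compound_id = compounds, target = targets)
}

test_that("bipartite network assigns roles and contains only ct edges", {
  recs <- ct_records(c("c1", "c1", "c1", "c2", "c2"),
                     c("T1", "T2", "T3", "T4", "T5"))
  net <- build_bipartite_network(recs)
  expect_equal(nrow(net$nodes), 7L)
  expect_equal(sum(net$nodes$role == "compound"), 2L)
  expect_equal(sum(net$nodes$role == "compound_target"), 5L)
  expect_true(all(net$edges$kind == "ct"))

  # disease membership flips targets to shared_target
  net2 <- build_bipartite_network(recs, disease_targets = c("T2", "T9"))
  s <- summarize_network(net2)
  expect_equal(s$n_shared_target, 1L)
  expect_equal(s$n_compound + s$n_compound_target + s$n_shared_target,
               s$n_nodes)

  # input order does not matter
  shuffled <- recs[c(4, 2, 5, 1, 3), ]
  net3 <- build_bipartite_network(shuffled, disease_targets = "T2")
  expect_setequal(paste(net3$edges$from, net3$edges$to),
                  paste(net2$edges$from, net2$edges$to))
  expect_equal(
    net3$nodes$role[match(net2$nodes$id, net3$nodes$id)],
    net2$nodes$role)

  expect_error(build_bipartite_network(recs[0, ]), "no compound-target")
})

test_that("PPI expansion keeps the induced subgraph over seeds and linked neighbours", {
  # star + closing edge: seed A, edges A-B, A-C, B-C
  ppi <- tibble::tibble(protein_a = c("A", "A", "B"),
                        protein_b = c("B", "C", "C"),
                        score = 0.9)
  net1 <- expand_with_interactors(ppi, "A", min_seed_links = 1)
  expect_setequal(net1$nodes$id, c("A", "B", "C"))
  expect_equal(nrow(net1$edges), 3L)  # B-C included by induction

  # with min_seed_links = 2, B and C each touch one seed; A alone is
  # isolated and dropped
  expect_warning(net2 <- expand_with_interactors(ppi, "A",
                                                 min_seed_links = 2),
                 "empty")
  expect_equal(nrow(net2$nodes), 0L)

  expect_error(expand_with_interactors(ppi, character()), "empty seed")
})

test_that("expansion matches a naive two-pass construction on a random PPI", {
  withr::with_seed(23, {
    ids <- sprintf("P%03d", 1:200)
    cmb <- utils::combn(ids, 2)
    keep <- stats::runif(ncol(cmb)) < 0.03
    ppi <- tibble::tibble(protein_a = cmb[1, keep], protein_b = cmb[2, keep],
                          score = 0.9)
    seeds <- sample(ids, 30)
    for (msl in 1:3) {
      net <- expand_with_interactors(ppi, seeds, min_seed_links = msl)

      # oracle: explicit double loop over candidate nodes and edges
      present <- unique(c(ppi$protein_a, ppi$protein_b))
      nb_seeds <- function(v) {
        sum(vapply(seq_len(nrow(ppi)), function(i) {
          (ppi$protein_a[i] == v && ppi$protein_b[i] %in% seeds) ||
            (ppi$protein_b[i] == v && ppi$protein_a[i] %in% seeds)
        }, logical(1)))
      }
      keep_nodes <- union(
        intersect(seeds, present),
        present[!(present %in% seeds) &
                  vapply(present, nb_seeds, 1) >= msl])
      in_keep <- ppi$protein_a %in% keep_nodes & ppi$protein_b %in% keep_nodes
      connected <- unique(c(ppi$protein_a[in_keep], ppi$protein_b[in_keep]))
      expect_setequal(net$nodes$id, intersect(keep_nodes, connected))
      expect_equal(nrow(net$edges), sum(in_keep))
      # always an induced subgraph of the input PPI
      expect_true(all(paste(net$edges$from, net$edges$to) %in%
                        paste(ppi$protein_a, ppi$protein_b)))
    }
  })
})

test_that("network intersection is idempotent, commutative and exact", {
  tri <- make_net(c("A", "B", "C", "A", "X"), c("B", "C", "A", "D", "Y"))
  self <- intersect_networks(tri, tri)
  expect_setequal(self$nodes$id, tri$nodes$id)  # no isolates in tri
  expect_equal(nrow(self$edges), nrow(tri$edges))

  # parents share a triangle; each has private extra nodes
  pa <- make_net(c("A", "B", "C", "A"), c("B", "C", "A", "P"))
  pb <- make_net(c("A", "B", "C", "B"), c("B", "C", "A", "Q"))
  inter <- intersect_networks(pa, pb)
  expect_setequal(inter$nodes$id, c("A", "B", "C"))
  expect_equal(nrow(inter$edges), 3L)

  swapped <- intersect_networks(pb, pa)
  expect_setequal(swapped$nodes$id, inter$nodes$id)
  expect_setequal(paste(swapped$edges$from, swapped$edges$to),
                  paste(inter$edges$from, inter$edges$to))

  disjoint <- make_net("U", "V")
  expect_warning(e <- intersect_networks(pa, disjoint), "no nodes")
  expect_equal(nrow(e$nodes), 0L)
})

test_that("intersection merges parent roles on the membership lattice", {
  roles_a <- c(A = "compound_target", B = "compound_target",
               C = "other", D = "shared_target")
  roles_b <- c(A = "disease_target", B = "compound_target",
               C = "other", D = "shared_target")
  pa <- make_net(c("A", "B", "C"), c("B", "C", "D"), roles = roles_a)
  pb <- make_net(c("A", "B", "C"), c("B", "C", "D"), roles = roles_b)
  inter <- intersect_networks(pa, pb)
  got <- stats::setNames(inter$nodes$role, inter$nodes$id)
  expect_equal(got[["A"]], "shared_target")  # compound in a, disease in b
  expect_equal(got[["B"]], "compound_target")
  expect_equal(got[["C"]], "other")
  expect_equal(got[["D"]], "shared_target")
})

test_that("network summaries add role counts up to the node total", {
  st <- simulate_study(seed = 9)
  d <- withr::local_tempdir()
  paths <- write_study(st, d)
  ppi <- read_ppi_edges(paths$ppi)
  ct_genes <- unique(st$compound_targets$target)
  dis <- st$truth$disease_union
  for (net in list(
    build_bipartite_network(st$compound_targets, dis),
    expand_with_interactors(ppi, ct_genes, compound_targets = ct_genes,
                            disease_targets = dis),
    expand_with_interactors(ppi, dis, compound_targets = ct_genes,
                            disease_targets = dis)
  )) {
    s <- summarize_network(net)
    expect_equal(s$n_compound + s$n_compound_target + s$n_disease_target +
                   s$n_shared_target + s$n_other, s$n_nodes)
  }
})
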