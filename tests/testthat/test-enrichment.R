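test_that("hypergeometric tail matches hand-computed and boundary cases", {
  # C(5,4)C(5,0)/C(10,4) = 5/210
  expect_equal(hypergeom_tail(4, 5, 4, 10), 5 / 210)
  expect_equal(hypergeom_tail(0, 5, 4, 10), 1.0)
  # EASE decrement: k = 1 behaves like plain k = 0
  expect_equal(hypergeom_tail(1, 5, 4, 10, ease = TRUE), 1.0)
  expect_equal(hypergeom_tail(3, 5, 4, 10, ease = TRUE),
               hypergeom_tail(2, 5, 4, 10))
  expect_error(hypergeom_tail(5, 4, 5, 10), "inconsistent")
  expect_error(hypergeom_tail(2, 11, 4, 10), "inconsistent")
})

test_that("tail equals direct combinatorial summation on a dense scan", {
  for (N in c(5, 12, 25)) {
    for (K in seq_len(N)) {
      for (n in seq_len(N)) {
        ks <- 0:min(K, n)
        got <- hypergeom_tail(ks, K, n, N)
        want <- vapply(ks, hyper_tail_oracle, 1, K = K, n = n, N = N)
        expect_equal(got, want, tolerance = 1e-12)
      }
    }
  }
})

test_that("BH adjustment reproduces hand-worked values and its bounds", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_fdr(0.05), 0.05)
  expect_equal(bh_fdr(numeric(0)), numeric(0))
  withr::with_seed(13, {
    p <- stats::runif(50)
    q <- bh_fdr(p)
    expect_true(all(q >= p & q <= 1))
    # invariant under permutation after mapping back
    perm <- sample(50)
    expect_equal(bh_fdr(p[perm]), q[perm])
  })
  expect_error(bh_fdr(c(0.5, 0)), "\\(0, 1\\]")
})

make_annotation <- function(terms, universe = NULL) {
  ann <- tibble::tibble(
    term_id = names(terms),
    term_name = names(terms),
    category = "GO",
    class = NA_character_,
    genes = unname(terms)
  )
  attr(ann, "universe") <- universe %||% unique(unlist(terms))
  class(ann) <- c("netpharm_annotation", class(ann))
  ann
}

test_that("a fully covered term ranks first and passes the screen", {
  withr::with_seed(19, {
    universe <- sprintf("U%03d", 1:200)
    terms <- purrr::map(1:20, ~ universe[((.x - 1) * 10 + 1):(.x * 10)])
    names(terms) <- sprintf("T%02d", 1:20)
    ann <- make_annotation(terms, universe)
    res <- enrich(terms$T05, ann)
    expect_equal(res$term_id[1], "T05")
    expect_true(res$passes[1])
    expect_equal(res$k[1], 10L)
    expect_equal(res$rich_factor[1], 1.0)
    expect_equal(res$N[1], 200L)
    # p-value equals the direct tail at (k = 10, K = 10, n = 10, N = 200)
    expect_equal(res$p_value[1], hyper_tail_oracle(10, 10, 10, 200))
    # terms with zero overlap are not reported
    expect_true(all(res$k >= 1))
  })
})

test_that("rich factor is overlap over term size", {
  ann <- make_annotation(list(T1 = sprintf("A%02d", 1:20)),
                         universe = sprintf("A%02d", 1:60))
  res <- enrich(sprintf("A%02d", 1:5), ann)
  expect_equal(res$k, 5L)
  expect_equal(res$K, 20L)
  expect_equal(res$rich_factor, 0.25)
})

test_that("FDR is computed within annotation category", {
  ann <- tibble::tibble(
    term_id = c("G1", "G2", "K1"),
    term_name = c("G1", "G2", "K1"),
    category = c("GO", "GO", "KEGG"),
    class = NA_character_,
    genes = list(c("A", "B"), c("A", "C"), c("A", "B"))
  )
  attr(ann, "universe") <- c("A", "B", "C", "D", "E", "F")
  class(ann) <- c("netpharm_annotation", class(ann))
  res <- enrich(c("A", "B"), ann, p_cutoff = 1, fdr_cutoff = 1)
  # the KEGG family has one test, so its fdr equals its p-value; the GO
  # family adjusts over two tests
  k1 <- res[res$term_id == "K1", ]
  expect_equal(k1$fdr, k1$p_value)
  go <- res[res$category == "GO", ]
  expect_equal(sort(go$fdr), sort(bh_fdr(go$p_value)))
})

test_that("enrich rejects a query disjoint from the background", {
  ann <- make_annotation(list(T1 = c("A", "B")))
  expect_error(enrich("Z", ann), "no genes")
})

test_that("category tallies count passing pathways and sum to the total", {
  res <- tibble::tibble(
    term_id = paste0("P", 1:6),
    category = "KEGG",
    class = c("human diseases", "human diseases", "cellular processes",
              "organismal systems", NA, "cellular processes"),
    passes = c(TRUE, TRUE, TRUE, FALSE, TRUE, TRUE)
  )
  expect_warning(tally <- classify_categories(res), "unassigned")
  expect_equal(attr(tally, "total"), 5L)
  expect_equal(sum(tally$n_pathways), 5L)
  expect_equal(tally$n_pathways[tally$class == "cellular processes"], 2L)

  empty <- classify_categories(res[res$passes & !is.na(res$class), ][0, ])
  expect_equal(nrow(empty), 0L)
  expect_equal(attr(empty, "total"), 0L)

  # explicit map overrides the class column
  map <- stats::setNames(rep("genetic information processing", 6),
                         paste0("P", 1:6))
  t2 <- classify_categories(res, category_map = map)
  expect_equal(t2$n_pathways, 5L)
})

test_that("a planted fully loaded term attains the minimum p-value", {
  withr::with_seed(29, {
    universe <- sprintf("U%03d", 1:300)
    module <- sample(universe, 12)
    sim <- simulate_annotations(universe, n_terms = 30,
                                enriched = list(list(genes = module,
                                                     fraction = 1.0,
                                                     category = "GO")),
                                seed = 8)
    res <- enrich(module, sim$annotation)
    expect_equal(res$term_id[1], sim$truth$enriched_terms)
    expect_equal(res$p_value[1], min(res$p_value))
  })
})
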