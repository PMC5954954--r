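write_lines_tmp <- function(lines, ext = ".tsv") {
  tf <- tempfile(fileext = ext)
  writeLines(lines, tf)
  tf
}

test_that("compound-target reader validates, uppercases and de-duplicates", {
  tf <- write_lines_tmp(c("compound\ttarget", "c1\ttp53", "c1\tTP53",
                          "c2\tcdk2"))
  ct <- read_compound_targets(tf)
  expect_equal(nrow(ct), 2L)
  expect_equal(ct$target, c("TP53", "CDK2"))

  csv <- write_lines_tmp(c("compound,target,source", "c1,EGFR,db"),
                         ext = ".csv")
  expect_equal(read_compound_targets(csv)$source, "db")

  blank <- write_lines_tmp(c("compound\ttarget", "c1\tTP53", "c2\tCDK2",
                             "c3\t"))
  expect_error(read_compound_targets(blank), "row 3")

  nocol <- write_lines_tmp(c("compound\tprotein", "c1\tTP53"))
  expect_error(read_compound_targets(nocol), "target")

  empty <- write_lines_tmp("compound\ttarget")
  expect_warning(res <- read_compound_targets(empty), "no data rows")
  expect_equal(nrow(res), 0L)
})

test_that("PPI reader applies scale, strict threshold and max-collapse", {
  # per-mille: 700 normalises to 0.700 and is dropped by the strict > 0.7 cut
  tf <- write_lines_tmp(c("protein1 protein2 combined_score",
                          "A B 700", "A C 701"), ext = ".txt")
  e <- read_ppi_edges(tf, score_scale = "permille")
  expect_equal(nrow(e), 1L)
  expect_equal(e$protein_b, "C")
  expect_equal(e$score, 0.701)

  # unit scale boundary: 0.71 kept
  tf2 <- write_lines_tmp(c("protein1 protein2 combined_score", "A B 0.71"),
                         ext = ".txt")
  expect_equal(read_ppi_edges(tf2, score_scale = "unit")$score, 0.71)

  # duplicate unordered pair collapses to the max score
  tf3 <- write_lines_tmp(c("protein1 protein2 combined_score",
                           "A B 0.8", "B A 0.9"), ext = ".txt")
  e3 <- read_ppi_edges(tf3, score_scale = "unit")
  expect_equal(nrow(e3), 1L)
  expect_equal(e3$score, 0.9)
  expect_equal(c(e3$protein_a, e3$protein_b), c("A", "B"))

  # self-loops dropped; auto-detection picks per-mille when scores exceed 1
  tf4 <- write_lines_tmp(c("protein1 protein2 combined_score",
                           "A A 999", "A B 950"), ext = ".txt")
  e4 <- read_ppi_edges(tf4)
  expect_equal(nrow(e4), 1L)
  expect_equal(e4$score, 0.95)

  # declared per-mille but all scores <= 1 is ambiguous
  expect_error(read_ppi_edges(tf2, score_scale = "permille"), "ambiguous")
  # score outside declared scale
  tf5 <- write_lines_tmp(c("protein1 protein2 combined_score", "A B 1200"),
                         ext = ".txt")
  expect_error(read_ppi_edges(tf5, score_scale = "permille"), "999")
  expect_error(read_ppi_edges(tf4, score_scale = "unit"), "\\[0, 1\\]")
})

test_that("per-mille and equivalent unit-scale input yield identical edges", {
  scores <- c(710, 850, 999, 701)
  pm <- write_lines_tmp(c("protein1 protein2 combined_score",
                          paste("A", c("B", "C", "D", "E"), scores)),
                        ext = ".txt")
  un <- write_lines_tmp(c("protein1 protein2 combined_score",
                          paste("A", c("B", "C", "D", "E"), scores / 1000)),
                        ext = ".txt")
  expect_equal(read_ppi_edges(pm, "permille"), read_ppi_edges(un, "unit"))
})

test_that("GMT reader computes the member union as universe", {
  tf <- write_lines_tmp(c(
    "T1\tfirst term|category=GO\tA\tB\tC\tD\tE",
    "T2\tsecond term|category=KEGG|class=human diseases\tD\tE\tF\tG\tH"
  ), ext = ".gmt")
  ann <- read_gene_sets(tf)
  expect_equal(nrow(ann), 2L)
  # 5 + 5 - 2 shared
  expect_length(annotation_universe(ann), 8L)
  expect_equal(ann$category, c("GO", "KEGG"))
  expect_equal(ann$class, c(NA, "human diseases"))
  expect_equal(ann$term_name[1], "first term")

  one <- write_lines_tmp("T1\tdesc\tA\tB\tC\tD\tE", ext = ".gmt")
  a1 <- read_gene_sets(one)
  expect_equal(nrow(a1), 1L)
  expect_length(annotation_universe(a1), 5L)
  expect_equal(a1$category, "unassigned")

  short <- write_lines_tmp(c("T1\tdesc\tA", "T2\tdesc"), ext = ".gmt")
  expect_error(read_gene_sets(short), "line 2")
})

test_that("GMT files round-trip through writer and reader", {
  tf <- write_lines_tmp(c(
    "T1\tfirst|category=GO\tA\tB\tC",
    "T2\tsecond|category=KEGG|class=cellular processes\tB\tD"
  ), ext = ".gmt")
  ann <- read_gene_sets(tf)
  out <- tempfile(fileext = ".gmt")
  write_gene_sets(ann, out)
  back <- read_gene_sets(out)
  expect_equal(as.data.frame(back), as.data.frame(ann))
  expect_setequal(annotation_universe(back), annotation_universe(ann))
})

test_that("network exports round-trip on nodes, edges, scores and roles", {
  withr::with_seed(7, {
    for (rep in 1:5) {
      ed <- random_edge_df(10, 0.3)
      if (nrow(ed) == 0) next
      roles <- stats::setNames(
        sample(c("compound_target", "disease_target", "shared_target",
                 "other"), 10, replace = TRUE),
        sprintf("N%02d", 1:10))
      net <- make_net(ed$from, ed$to, roles = roles,
                      score = round(stats::runif(nrow(ed)), 6))
      for (fmt in c("sif", "graphml", "edge_tsv")) {
        path <- tempfile(fileext = paste0(".", fmt))
        write_network(net, path, format = fmt)
        back <- read_network(path, format = fmt)
        expect_setequal(back$nodes$id, net$nodes$id)
        expect_equal(
          back$nodes$role[match(net$nodes$id, back$nodes$id)],
          net$nodes$role)
        key <- function(n) sort(paste(n$edges$from, n$edges$to))
        expect_equal(key(back), key(net))
        if (fmt != "sif") {
          m <- match(paste(net$edges$from, net$edges$to),
                     paste(back$edges$from, back$edges$to))
          expect_equal(back$edges$score[m], net$edges$score,
                       tolerance = 1e-9)
          expect_equal(back$edges$kind[m], net$edges$kind)
        }
      }
    }
  })
})

test_that("SIF export writes relations by edge kind and a node table", {
  net <- netpharm_network(
    nodes = tibble::tibble(id = c("c1", "c2", "T1", "T2", "T3"),
                           role = c("compound", "compound",
                                    rep("compound_target", 3))),
    edges = tibble::tibble(from = c("c1", "c1", "c2"),
                           to = c("T1", "T2", "T3"), kind = "ct")
  )
  path <- tempfile(fileext = ".sif")
  write_network(net, path, format = "sif")
  lines <- readLines(path)
  expect_length(lines, 3L)
  expect_true(all(grepl("\tct\t", lines)))
  attrs <- readr::read_tsv(paste0(tools::file_path_sans_ext(path),
                                  "_nodes.tsv"), show_col_types = FALSE)
  expect_equal(nrow(attrs), 5L)
  expect_equal(sum(attrs$role == "compound"), 2L)

  # a 3-node path gives 2 SIF lines
  p3 <- make_net(c("A", "B"), c("B", "C"))
  path2 <- tempfile(fileext = ".sif")
  write_network(p3, path2, format = "sif")
  expect_length(readLines(path2), 2L)

  expect_error(write_network(p3, path2, format = "dot"))
})
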