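# Run `code` under a fixed, version-stable RNG state without disturbing the
# caller's random stream.
with_rng <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed, kind = "Mersenne-Twister", normal.kind = "Inversion",
           sample.kind = "Rejection")
  force(code)
}

# round to the per-mille grid so in-memory scores and STRING-dialect files
# agree exactly
quantize_score <- function(x) round(x, 3)

#' Simulate a compound-target table
#'
#' Draws a bipartite compound-target edge list whose per-compound target
#' counts follow a heavy-tailed (log-normal) law, emulating the typical
#' promiscuity profile of herbal ingredient panels: a couple of hub
#' compounds bind on the order of a hundred proteins while most bind a
#' handful. The defaults are sized to a 32-compound panel averaging about
#' 23 targets each (roughly 730 assertions). With `skew = 0` all compounds
#' get (near-)equal target counts.
#'
#' @param n_compounds Number of compounds (default 32).
#' @param n_targets Size of the target pool (default 353); ignored when
#'   `target_pool` is given.
#' @param mean_degree Average targets per compound (default 22.9).
#' @param skew Log-normal sigma of the compound degree law (default 1.2).
#' @param seed Integer seed.
#' @param target_pool Optional explicit pool of target symbols.
#' @param must_cover Optional gene symbols guaranteed to appear as targets
#'   (swapped into the highest-degree compounds when missed by sampling).
#' @return A list with `records` (tibble `compound_id`, `target`, `source`)
#'   and `truth` (`degrees`, the per-compound target counts).
#' @export
simulate_compound_targets <- function(n_compounds = 32, n_targets = 353,
                                      mean_degree = 22.9, skew = 1.2,
                                      seed = 1, target_pool = NULL,
                                      must_cover = NULL) {
  stopifnot(n_compounds >= 1, mean_degree > 0, skew >= 0)
  target_pool <- target_pool %||% sprintf("T%03d", seq_len(n_targets))
  n_targets <- length(target_pool)
  if (mean_degree > n_targets) {
    abort("`mean_degree` cannot exceed the target pool size.")
  }
  with_rng(seed, {
    w <- exp(skew * stats::rnorm(n_compounds))
    deg <- round(w / sum(w) * n_compounds * mean_degree)
    deg <- pmin(pmax(deg, 1L), n_targets)
    compounds <- sprintf("CMP%02d", seq_len(n_compounds))
    records <- purrr::map_dfr(seq_len(n_compounds), function(i) {
      tibble(compound_id = compounds[i],
             target = sample(target_pool, deg[i]),
             source = "simulated")
    })
    if (!is.null(must_cover)) {
      missing <- setdiff(must_cover, records$target)
      if (length(missing)) {
        # swap missed must-cover genes into the most promiscuous compounds,
        # replacing one of their non-essential targets each
        hubs <- compounds[order(-deg)]
        hi <- 0L
        for (g in missing) {
          repeat {
            hi <- (hi %% n_compounds) + 1L
            already <- records$target[records$compound_id == hubs[hi]]
            rows <- which(records$compound_id == hubs[hi] &
                            !(records$target %in% must_cover))
            if (!(g %in% already) && length(rows)) break
          }
          records$target[rows[1]] <- g
        }
      }
    }
    records <- distinct(records, .data$compound_id, .data$target,
                        .keep_all = TRUE)
    list(records = records,
         truth = list(degrees = stats::setNames(as.integer(deg), compounds)))
  })
}

#' Simulate a scored PPI edge list with planted dense modules
#'
#' Generates an Erdos-Renyi background graph and plants dense blocks
#' (modules) into it, then assigns STRING-style confidence scores: edges
#' inside planted modules always score above the conventional 0.7
#' high-confidence cut, while a configurable fraction of background edges
#' scores below it — so confidence filtering removes background noise but
#' never planted structure. Scores are quantised to the 0.001 grid so the
#' in-memory edge list and its per-mille file serialisation agree exactly.
#'
#' @param n_nodes Number of proteins (default 400); ignored when `genes`
#'   is given.
#' @param background_p Background edge probability (default 0.02).
#' @param modules List of `c(size, intra_p)` pairs (default three modules
#'   of sizes 48, 30, 20 with intra-module edge probability 0.9 — the scale
#'   of large mammalian complexes). Module sizes are deliberately
#'   weight-separated: MCODE admits a vertex when its weight exceeds
#'   `1 - node_score_cutoff` of the seed's, so planted modules whose
#'   realised weight ceilings sit within 20% of each other merge across any
#'   single background edge, and modules below roughly 20 members shed
#'   their low-degree tail. See the methods vignette.
#' @param low_conf_frac Fraction of background edges scored below 0.7
#'   (default 0.4).
#' @param seed Integer seed.
#' @param genes Optional explicit protein symbols.
#' @return A list with `edges` (tibble `protein_a`, `protein_b`, `score`;
#'   unfiltered) and `truth` (`modules`: list of planted member sets;
#'   `low_conf_edges`: count of background edges scored below 0.7).
#' @export
simulate_ppi <- function(n_nodes = 400, background_p = 0.02,
                         modules = list(c(48, 0.9), c(30, 0.9), c(20, 0.9)),
                         low_conf_frac = 0.4, seed = 1, genes = NULL) {
  genes <- genes %||% sprintf("G%03d", seq_len(n_nodes))
  n <- length(genes)
  sizes <- vapply(modules, function(m) as.integer(m[1]), 1L)
  if (sum(sizes) > n) abort("planted module sizes exceed the node count.")
  stopifnot(background_p >= 0, background_p <= 1,
            low_conf_frac >= 0, low_conf_frac <= 1)
  with_rng(seed, {
    member_pool <- sample(genes, sum(sizes))
    starts <- cumsum(c(1L, sizes))
    planted <- purrr::map(seq_along(sizes), function(i) {
      sort(member_pool[starts[i]:(starts[i] + sizes[i] - 1L)])
    })

    idx <- utils::combn(n, 2)
    a <- genes[idx[1, ]]; b <- genes[idx[2, ]]
    mod_of <- integer(n)
    for (i in seq_along(planted)) mod_of[match(planted[[i]], genes)] <- i
    ma <- mod_of[idx[1, ]]; mb <- mod_of[idx[2, ]]
    intra <- ma > 0 & ma == mb
    p_edge <- ifelse(intra,
                     vapply(modules, function(m) m[2], 1)[pmax(ma, 1)],
                     background_p)
    keep <- stats::runif(length(p_edge)) < p_edge

    a <- a[keep]; b <- b[keep]; intra <- intra[keep]
    score <- numeric(length(a))
    score[intra] <- stats::runif(sum(intra), 0.71, 0.999)
    nb <- sum(!intra)
    low <- stats::runif(nb) < low_conf_frac
    sc_bg <- numeric(nb)
    sc_bg[low] <- stats::runif(sum(low), 0.15, 0.7)
    sc_bg[!low] <- stats::runif(sum(!low), 0.701, 0.999)
    score[!intra] <- sc_bg

    edges <- tibble(protein_a = pmin(a, b), protein_b = pmax(a, b),
                    score = quantize_score(score))
    list(edges = edges,
         truth = list(modules = planted,
                      low_conf_edges = sum(edges$score <= 0.7)))
  })
}

#' Simulate multi-source disease-target lists
#'
#' Builds per-source disease gene lists with controlled redundancy: the
#' union of all sources has exactly `union_size` genes (every union gene
#' appears in at least one source; the `sum(sizes) - union_size` surplus
#' slots become cross-source duplicates). The last source additionally
#' carries literature evidence counts, emulating a text-mining source
#' screened at a minimum paper count: its true members get counts at or
#' above `evidence_min`, and `n_decoys` extra genes with sub-threshold
#' counts are appended so the evidence filter has work to do.
#'
#' @param sizes Per-source gene counts (default `c(12, 12, 37, 14)`).
#' @param union_size Size of the de-duplicated union (default 66). Setting
#'   `union_size = sum(sizes)` yields fully disjoint sources (no overlap).
#' @param n_decoys Low-evidence decoy genes appended to the last source
#'   (default 10).
#' @param evidence_min Evidence threshold the true members of the evidence
#'   source are guaranteed to meet (default 20).
#' @param seed Integer seed.
#' @param gene_pool Pool to draw genes from (default synthetic `DG...`
#'   symbols).
#' @param union_genes Optional explicit union gene set (overrides
#'   `union_size`).
#' @param source_names Source labels (default `ttd`, `omim`, `pharmgkb`,
#'   `digsee`-style generic names).
#' @return A list with `sources` (named list of tibbles `gene`,
#'   `evidence_count`) and `truth` (`union`, `evidence_pass`).
#' @export
simulate_disease_sources <- function(sizes = c(12, 12, 37, 14),
                                     union_size = 66, n_decoys = 10,
                                     evidence_min = 20, seed = 1,
                                     gene_pool = NULL, union_genes = NULL,
                                     source_names = NULL) {
  stopifnot(all(sizes >= 1))
  n_src <- length(sizes)
  source_names <- source_names %||% paste0("source", seq_len(n_src))
  with_rng(seed, {
    if (is.null(union_genes)) {
      gene_pool <- gene_pool %||% sprintf("DG%03d", seq_len(2 * union_size))
      union_genes <- sample(gene_pool, union_size)
    } else {
      union_size <- length(union_genes)
      gene_pool <- gene_pool %||% union_genes
    }
    if (union_size > sum(sizes) || union_size < max(sizes)) {
      abort("need max(sizes) <= union_size <= sum(sizes).")
    }

    # first pass: place every union gene once, capacity-proportional
    remaining <- sizes
    assign_src <- integer(union_size)
    for (i in seq_len(union_size)) {
      # keep feasibility: a source must not be starved below the number of
      # genes still to place
      open <- which(remaining > 0)
      assign_src[i] <- if (length(open) == 1) open else
        sample(open, 1, prob = remaining[open])
      remaining[assign_src[i]] <- remaining[assign_src[i]] - 1L
    }
    members <- purrr::map(seq_len(n_src),
                          function(s) union_genes[assign_src == s])
    # second pass: fill surplus slots with duplicates from other sources
    for (s in seq_len(n_src)) {
      if (remaining[s] > 0) {
        candidates <- setdiff(union_genes, members[[s]])
        members[[s]] <- c(members[[s]],
                          sample(candidates, remaining[s]))
      }
      members[[s]] <- sample(members[[s]])  # shuffle presentation order
    }

    ev_src <- n_src
    ev_counts <- evidence_min + stats::rpois(length(members[[ev_src]]), 15)
    decoys <- character(0)
    if (n_decoys > 0) {
      decoy_pool <- setdiff(gene_pool, union_genes)
      if (length(decoy_pool) < n_decoys) {
        decoy_pool <- c(decoy_pool,
                        sprintf("DECOY%02d", seq_len(n_decoys)))
      }
      decoys <- sample(decoy_pool, n_decoys)
    }
    sources <- purrr::map(seq_len(n_src), function(s) {
      if (s == ev_src) {
        tibble(gene = c(members[[s]], decoys),
               source = source_names[s],
               evidence_count = c(ev_counts,
                                  sample(seq_len(evidence_min - 1), n_decoys,
                                         replace = TRUE)))
      } else {
        tibble(gene = members[[s]], source = source_names[s],
               evidence_count = NA_integer_)
      }
    })
    names(sources) <- source_names
    list(sources = sources,
         truth = list(union = union_genes,
                      evidence_pass = members[[ev_src]]))
  })
}

KEGG_TOP_CLASSES <- c("human diseases", "environmental information processing",
                      "organismal systems", "genetic information processing",
                      "cellular processes")

#' Simulate an annotation collection with planted enrichment
#'
#' Draws background gene-set terms uniformly over a gene universe, then
#' loads designated terms with members of given gene sets (typically the
#' planted PPI modules) at a configured fraction, so those terms are
#' genuinely enriched in those modules by construction. Terms are split
#' between a `GO` and a `KEGG` category; KEGG-category terms carry one of
#' the five conventional top-level pathway classes for category tallies.
#' With `enriched = list()` the collection is a pure null — the input for
#' calibration checks.
#'
#' @param universe Character vector of background gene symbols.
#' @param n_terms Number of background terms (default 40).
#' @param size_range Inclusive term-size range (default `c(10, 40)`).
#' @param enriched List of `list(genes =, fraction =, category =)` entries;
#'   each plants one term whose members include `fraction` of `genes`.
#' @param kegg_fraction Fraction of background terms in the KEGG category
#'   (default 0.5).
#' @param seed Integer seed.
#' @return A list with `annotation` (a [read_gene_sets()]-compatible
#'   tibble) and `truth` (`enriched_terms`: term ids planted per entry).
#' @export
simulate_annotations <- function(universe, n_terms = 40,
                                 size_range = c(10, 40), enriched = list(),
                                 kegg_fraction = 0.5, seed = 1) {
  stopifnot(length(universe) >= max(size_range), n_terms >= 1)
  with_rng(seed, {
    categories <- ifelse(seq_len(n_terms) <= round(kegg_fraction * n_terms),
                         "KEGG", "GO")
    rows <- purrr::map_dfr(seq_len(n_terms), function(i) {
      size <- sample(seq(size_range[1], size_range[2]), 1)
      tibble(term_id = sprintf("%s:%04d", categories[i], i),
             term_name = sprintf("synthetic term %d", i),
             category = categories[i],
             class = if (categories[i] == "KEGG")
               sample(KEGG_TOP_CLASSES, 1) else NA_character_,
             genes = list(sort(sample(universe, size))))
    })
    enriched_ids <- character(0)
    if (length(enriched)) {
      erows <- purrr::map_dfr(seq_along(enriched), function(j) {
        e <- enriched[[j]]
        cat_j <- e$category %||% "KEGG"
        frac <- e$fraction %||% 0.9
        core <- sample(e$genes, max(2, ceiling(frac * length(e$genes))))
        size <- max(length(core), sample(seq(size_range[1],
                                             size_range[2]), 1))
        fill <- sample(setdiff(universe, core), size - length(core))
        tibble(term_id = sprintf("%s:E%03d", cat_j, j),
               term_name = sprintf("planted enriched term %d", j),
               category = cat_j,
               class = if (cat_j == "KEGG")
                 sample(KEGG_TOP_CLASSES, 1) else NA_character_,
               genes = list(sort(c(core, fill))))
      })
      enriched_ids <- erows$term_id
      rows <- bind_rows(rows, erows)
    }
    universe <- unique(toupper(universe))
    attr(rows, "universe") <- universe
    class(rows) <- c("netpharm_annotation", class(rows))
    list(annotation = rows,
         truth = list(enriched_terms = enriched_ids))
  })
}

#' Simulate a complete network-pharmacology study
#'
#' Derives per-component seeds from one master seed and generates a
#' coherent synthetic study over a shared gene universe: a scored PPI with
#' planted dense modules, a compound-target table guaranteed to cover the
#' planted modules, four disease-target sources (one evidence-screened)
#' whose union includes half of each planted module — so the planted
#' complexes genuinely sit at the compound-disease interface, as the
#' pipeline assumes — and an annotation collection with one GO and one KEGG
#' term planted per module.
#'
#' @param seed Master integer seed.
#' @param n_genes Gene universe size (default 400).
#' @param n_compounds,mean_degree,skew Passed to
#'   [simulate_compound_targets()].
#' @param modules,background_p,low_conf_frac Passed to [simulate_ppi()].
#' @param source_sizes,union_size,evidence_min Passed to
#'   [simulate_disease_sources()].
#' @param n_terms Background annotation terms (default 40).
#' @param enrichment_fraction Fraction of each module loaded into its
#'   planted terms (default 0.9).
#' @return A list of class `netpharm_study` with elements
#'   `compound_targets`, `ppi_edges`, `sources`, `annotation`, and `truth`
#'   (planted modules, enriched terms per module, disease union, shared
#'   targets, evidence pass set, seed).
#' @export
simulate_study <- function(seed = 1, n_genes = 400, n_compounds = 32,
                           mean_degree = 22.9, skew = 1.2,
                           modules = list(c(48, 0.9), c(30, 0.9), c(20, 0.9)),
                           background_p = 0.02, low_conf_frac = 0.4,
                           source_sizes = c(12, 12, 37, 14), union_size = 66,
                           evidence_min = 20, n_terms = 40,
                           enrichment_fraction = 0.9) {
  sub <- with_rng(seed, sample.int(2^31 - 2, 5))
  genes <- sprintf("G%03d", seq_len(n_genes))

  ppi <- simulate_ppi(background_p = background_p, modules = modules,
                      low_conf_frac = low_conf_frac, seed = sub[1],
                      genes = genes)
  module_genes <- unlist(ppi$truth$modules)

  # disease union: about half of each planted module plus random background
  union_genes <- with_rng(sub[2], {
    half <- unlist(purrr::map(ppi$truth$modules,
                              ~ sample(.x, ceiling(length(.x) / 2))))
    fill <- sample(setdiff(genes, half), union_size - length(half))
    sample(c(half, fill))
  })
  dis <- simulate_disease_sources(sizes = source_sizes,
                                  union_genes = union_genes,
                                  evidence_min = evidence_min,
                                  seed = sub[3], gene_pool = genes,
                                  source_names = c("ttd", "omim", "pharmgkb",
                                                   "digsee")[
                                    seq_along(source_sizes)])

  target_pool <- with_rng(sub[4], {
    unique(c(module_genes,
             sample(setdiff(genes, module_genes),
                    min(353, n_genes) - length(module_genes))))
  })
  ct <- simulate_compound_targets(n_compounds = n_compounds,
                                  mean_degree = mean_degree, skew = skew,
                                  seed = sub[4], target_pool = target_pool,
                                  must_cover = module_genes)

  enriched <- purrr::flatten(purrr::map(ppi$truth$modules, function(m) {
    list(list(genes = m, fraction = enrichment_fraction, category = "GO"),
         list(genes = m, fraction = enrichment_fraction, category = "KEGG"))
  }))
  ann <- simulate_annotations(genes, n_terms = n_terms, enriched = enriched,
                              seed = sub[5])

  shared <- intersect(unique(ct$records$target), union_genes)
  structure(list(
    compound_targets = ct$records,
    ppi_edges = ppi$edges,
    sources = dis$sources,
    annotation = ann$annotation,
    truth = list(
      planted_modules = ppi$truth$modules,
      enriched_terms = split(ann$truth$enriched_terms,
                             rep(seq_along(ppi$truth$modules), each = 2)),
      disease_union = union_genes,
      shared_targets = sort(shared),
      evidence_pass = dis$truth$evidence_pass,
      compound_degrees = ct$truth$degrees,
      seed = seed
    )
  ), class = "netpharm_study")
}

#' Write a simulated study to disk in the pipeline's input dialects
#'
#' Serialises the study exactly as the readers consume it: a
#' compound-target TSV, a STRING-dialect PPI file (space-delimited,
#' per-mille integer scores), one TSV per disease source, a GMT annotation
#' file, and a plain-text `truth.txt` sidecar (`key <TAB>
#' comma-separated-values` lines).
#'
#' @param study A [simulate_study()] result.
#' @param dir Output directory (created if needed).
#' @return Named list of written paths, invisibly.
#' @export
write_study <- function(study, dir) {
  stopifnot(inherits(study, "netpharm_study"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list()

  paths$compound_targets <- file.path(dir, "compound_targets.tsv")
  readr::write_tsv(study$compound_targets, paths$compound_targets,
                   progress = FALSE)

  paths$ppi <- file.path(dir, "ppi_links.txt")
  pm <- as.integer(round(study$ppi_edges$score * 1000))
  writeLines(c("protein1 protein2 combined_score",
               paste(study$ppi_edges$protein_a, study$ppi_edges$protein_b,
                     pm)),
             paths$ppi)

  paths$sources <- character(0)
  for (nm in names(study$sources)) {
    p <- file.path(dir, paste0("disease_", nm, ".tsv"))
    src <- study$sources[[nm]]
    if (all(is.na(src$evidence_count))) {
      readr::write_tsv(src[, "gene"], p, progress = FALSE)
    } else {
      readr::write_tsv(src[, c("gene", "evidence_count")], p,
                       progress = FALSE)
    }
    paths$sources <- c(paths$sources, p)
  }

  paths$annotation <- file.path(dir, "annotations.gmt")
  write_gene_sets(study$annotation, paths$annotation)

  paths$truth <- file.path(dir, "truth.txt")
  tr <- study$truth
  kv <- c(
    paste0("seed\t", tr$seed),
    purrr::imap_chr(tr$planted_modules,
                    ~ paste0("module", .y, "\t", paste(.x, collapse = ","))),
    purrr::imap_chr(tr$enriched_terms,
                    ~ paste0("enriched_terms_module", .y, "\t",
                             paste(.x, collapse = ","))),
    paste0("disease_union\t", paste(tr$disease_union, collapse = ",")),
    paste0("shared_targets\t", paste(tr$shared_targets, collapse = ",")),
    paste0("evidence_pass\t", paste(tr$evidence_pass, collapse = ","))
  )
  writeLines(kv, paths$truth)
  invisible(paths)
}

#' Read a study truth sidecar
#'
#' @param path Path to a `truth.txt` written by [write_study()].
#' @return A list with `planted_modules` (list of gene sets) and the other
#'   recorded truth fields.
#' @export
read_truth <- function(path) {
  lines <- readLines(path)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  keys <- purrr::map_chr(parts, 1)
  vals <- purrr::map(parts, ~ strsplit(.x[2], ",", fixed = TRUE)[[1]])
  names(vals) <- keys
  mod_keys <- grep("^module[0-9]+$", keys, value = TRUE)
  list(
    seed = as.integer(vals$seed),
    planted_modules = unname(vals[mod_keys]),
    enriched_terms = unname(vals[grep("^enriched_terms_module", keys,
                                      value = TRUE)]),
    disease_union = vals$disease_union,
    shared_targets = vals$shared_targets,
    evidence_pass = vals$evidence_pass
  )
}
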