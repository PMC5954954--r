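#' Pipeline run configuration
#'
#' Collects the input paths and every tunable threshold of the full
#' workflow into one validated object, so a run is reproducible from a
#' single serialisable source of truth.
#'
#' @param compound_targets Path to the compound-target TSV/CSV.
#' @param ppi Path to the STRING-dialect PPI edge list.
#' @param sources Character vector of disease-source TSV paths.
#' @param annotations Path to the GMT annotation file.
#' @param out_dir Output directory for tables, networks and the report.
#' @param ppi_min_score Strict lower bound on PPI confidence (default 0.7,
#'   the conventional high-confidence cut).
#' @param min_evidence Inclusive evidence threshold applied to sources that
#'   carry evidence counts (default 20).
#' @param min_seed_links Neighbour-inclusion rule for PPI expansion
#'   (default 2; see [expand_with_interactors()]).
#' @param closeness_convention Passed to [compute_centralities()].
#' @param multipliers,strict Passed to [screen_by_median()].
#' @param mcode Passed to [find_complexes()]; an [mcode_params()] object.
#' @param p_cutoff,fdr_cutoff Enrichment screening thresholds
#'   (defaults 0.01).
#' @param truth Optional path to a [write_study()] truth sidecar; when
#'   given, the report includes a planted-module recovery section.
#' @param score_scale Passed to [read_ppi_edges()].
#' @return A list of class `netpharm_config`.
#' @export
netpharm_config <- function(compound_targets, ppi, sources, annotations,
                            out_dir = NULL,
                            ppi_min_score = 0.7, min_evidence = 20,
                            min_seed_links = 2,
                            closeness_convention = "normalized",
                            multipliers = 1, strict = TRUE,
                            mcode = mcode_params(),
                            p_cutoff = 0.01, fdr_cutoff = 0.01,
                            truth = NULL, score_scale = "auto") {
  stopifnot(ppi_min_score >= 0, ppi_min_score <= 1,
            min_evidence >= 0, min_seed_links >= 1,
            p_cutoff > 0, p_cutoff <= 1, fdr_cutoff > 0, fdr_cutoff <= 1,
            inherits(mcode, "mcode_params"))
  structure(list(
    compound_targets = compound_targets, ppi = ppi, sources = sources,
    annotations = annotations, out_dir = out_dir,
    ppi_min_score = ppi_min_score, min_evidence = min_evidence,
    min_seed_links = min_seed_links,
    closeness_convention = closeness_convention,
    multipliers = multipliers, strict = strict, mcode = mcode,
    p_cutoff = p_cutoff, fdr_cutoff = fdr_cutoff, truth = truth,
    score_scale = score_scale
  ), class = "netpharm_config")
}

stage_abort <- function(stage, parent) {
  abort(paste0("[", stage, "] ", conditionMessage(parent)))
}

run_stage <- function(stage, log_env, expr) {
  log_env$log <- c(log_env$log, paste0("stage: ", stage))
  tryCatch(expr, error = function(e) stage_abort(stage, e))
}

#' Run the full network-pharmacology workflow
#'
#' Executes the complete analysis from one [netpharm_config()]: reads and
#' validates the four input kinds; screens and merges the disease-target
#' sources; builds the compound-target bipartite network, the PPI
#' expansions of the compound targets and of the disease targets, and their
#' intersection; computes centralities and median-screened hubs for the
#' disease network and the intersection network; detects MCODE complexes in
#' the intersection network; runs per-module GO/KEGG over-representation
#' with the configured thresholds and tallies passing KEGG pathways by
#' top-level class. Every applied threshold is echoed into the run log.
#'
#' When `config$out_dir` is set, all tables are written as TSV, the four
#' networks as SIF plus node attributes, and the composition counts as a
#' JSON report.
#'
#' @param config A [netpharm_config()].
#' @return A list of class `netpharm_report`; see Details. Key elements:
#'   `networks` (the four [netpharm_network()] objects), `summary` (one
#'   composition row per network), `disease_targets`, `centralities`,
#'   `hubs`, `modules`, `enrichment` (per-module results), `kegg_classes`,
#'   `recovery` (when truth was supplied), `log`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "netpharm_config"))
  lg <- new.env()
  lg$log <- character(0)
  note <- function(...) lg$log <- c(lg$log, paste0(...))

  ct <- run_stage("read_compound_targets", lg,
                  read_compound_targets(config$compound_targets))

  sources <- run_stage("assemble_disease_targets", lg, {
    purrr::map(config$sources, read_disease_targets)
  })
  names(sources) <- purrr::map_chr(sources, ~ .x$source[1])
  note("min_evidence = ", config$min_evidence,
       " (applied to sources carrying evidence counts)")
  screened <- run_stage("filter_by_evidence", lg, {
    purrr::map(sources, function(src) {
      if (all(is.na(src$evidence_count))) src
      else filter_by_evidence(src, config$min_evidence)
    })
  })
  disease <- run_stage("merge_target_sources", lg,
                       merge_target_sources(screened))

  note("ppi_min_score = ", config$ppi_min_score, " (strict >)")
  ppi <- run_stage("read_ppi_edges", lg,
                   read_ppi_edges(config$ppi,
                                  score_scale = config$score_scale,
                                  min_score = config$ppi_min_score))

  bipartite <- run_stage("build_bipartite_network", lg,
                         build_bipartite_network(ct, disease$gene))

  ct_genes <- unique(ct$target)
  note("min_seed_links = ", config$min_seed_links)
  net_compound <- run_stage("expand_compound_targets", lg,
    expand_with_interactors(ppi, ct_genes,
                            min_seed_links = config$min_seed_links,
                            compound_targets = ct_genes,
                            disease_targets = disease$gene))
  net_disease <- run_stage("expand_disease_targets", lg,
    expand_with_interactors(ppi, disease$gene,
                            min_seed_links = config$min_seed_links,
                            compound_targets = ct_genes,
                            disease_targets = disease$gene))
  net_intersection <- run_stage("intersect_networks", lg,
    intersect_networks(net_compound, net_disease))

  note("closeness_convention = ", config$closeness_convention,
       "; multipliers = ", paste(config$multipliers, collapse = "/"),
       "; strict = ", config$strict)
  centr <- run_stage("compute_centralities", lg, list(
    disease = compute_centralities(net_disease,
                                   config$closeness_convention),
    intersection = compute_centralities(net_intersection,
                                        config$closeness_convention)
  ))
  hubs <- run_stage("screen_by_median", lg, purrr::map(
    centr, screen_by_median,
    multipliers = config$multipliers, strict = config$strict))

  modules <- run_stage("find_complexes", lg,
                       find_complexes(net_intersection, config$mcode))

  note("enrichment thresholds: p < ", config$p_cutoff,
       ", FDR < ", config$fdr_cutoff)
  annotation <- run_stage("read_gene_sets", lg,
                          read_gene_sets(config$annotations))
  enrichment <- run_stage("enrich_modules", lg, {
    purrr::map(seq_len(nrow(modules)), function(i) {
      enrich(modules$members[[i]], annotation,
             p_cutoff = config$p_cutoff, fdr_cutoff = config$fdr_cutoff)
    })
  })
  names(enrichment) <- if (nrow(modules)) paste0("module", modules$rank)
                       else character(0)
  kegg_classes <- run_stage("classify_categories", lg, {
    kegg <- purrr::map_dfr(enrichment, ~ filter(.x, .data$category == "KEGG",
                                                .data$passes)) |>
      distinct(.data$term_id, .keep_all = TRUE)
    classify_categories(kegg, passing_only = FALSE)
  })

  networks <- list(bipartite = bipartite, compound = net_compound,
                   disease = net_disease, intersection = net_intersection)
  summary_tbl <- purrr::imap_dfr(networks, function(n, nm) {
    mutate(summarize_network(n), network = nm, .before = 1)
  })

  recovery <- NULL
  if (!is.null(config$truth)) {
    recovery <- run_stage("module_recovery", lg, {
      truth <- read_truth(config$truth)
      module_recovery(modules, truth$planted_modules)
    })
  }

  report <- structure(list(
    networks = networks, summary = summary_tbl,
    disease_targets = disease, centralities = centr, hubs = hubs,
    modules = modules, enrichment = enrichment,
    kegg_classes = kegg_classes, recovery = recovery,
    config = config, log = lg$log
  ), class = "netpharm_report")

  if (!is.null(config$out_dir)) write_report(report, config$out_dir)
  report
}

#' Best-Jaccard recovery of planted modules
#'
#' For each planted module, the best Jaccard similarity between its member
#' set and any detected complex.
#'
#' @param modules A [find_complexes()] result.
#' @param planted_modules List of character vectors (ground-truth member
#'   sets).
#' @return A tibble with columns `planted`, `size`, `best_jaccard`,
#'   `matched_rank`.
#' @export
module_recovery <- function(modules, planted_modules) {
  purrr::imap_dfr(planted_modules, function(truth, i) {
    truth <- unique(truth)
    if (nrow(modules) == 0) {
      return(tibble(planted = i, size = length(truth),
                    best_jaccard = 0, matched_rank = NA_integer_))
    }
    jac <- purrr::map_dbl(modules$members, function(m) {
      length(intersect(m, truth)) / length(union(m, truth))
    })
    tibble(planted = i, size = length(truth),
           best_jaccard = max(jac),
           matched_rank = modules$rank[which.max(jac)])
  })
}

# Write every report table and network under `dir`; deterministic bytes for
# identical inputs.
write_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_tsv(report$summary, file.path(dir, "network_summary.tsv"),
                   progress = FALSE)
  for (nm in names(report$networks)) {
    write_network(report$networks[[nm]],
                  file.path(dir, paste0("network_", nm, ".sif")),
                  format = "sif")
  }
  dt <- mutate(report$disease_targets,
               sources = purrr::map_chr(.data$sources, paste,
                                        collapse = ","))
  readr::write_tsv(dt, file.path(dir, "disease_targets.tsv"),
                   progress = FALSE)
  for (nm in names(report$centralities)) {
    readr::write_tsv(as_tibble(report$centralities[[nm]]),
                     file.path(dir, paste0("centrality_", nm, ".tsv")),
                     progress = FALSE)
    writeLines(report$hubs[[nm]], file.path(dir, paste0("hubs_", nm, ".txt")))
  }
  mods <- report$modules
  if (nrow(mods)) {
    membership <- tidyr::unnest(
      select(mods, "rank", "seed", "members"), "members") |>
      rename(node = "members") |>
      mutate(seed_flag = .data$node == .data$seed)
    readr::write_tsv(membership, file.path(dir, "module_members.tsv"),
                     progress = FALSE)
  }
  readr::write_tsv(select(as_tibble(mods), -"members"),
                   file.path(dir, "module_summary.tsv"), progress = FALSE)
  for (nm in names(report$enrichment)) {
    readr::write_tsv(as_tibble(report$enrichment[[nm]]),
                     file.path(dir, paste0("enrichment_", nm, ".tsv")),
                     progress = FALSE)
  }
  readr::write_tsv(report$kegg_classes,
                   file.path(dir, "kegg_classes.tsv"), progress = FALSE)
  if (!is.null(report$recovery)) {
    readr::write_tsv(report$recovery,
                     file.path(dir, "module_recovery.tsv"), progress = FALSE)
  }
  writeLines(report$log, file.path(dir, "run_log.txt"))
  jsonlite::write_json(
    list(summary = report$summary,
         n_hubs = purrr::map_int(report$hubs, length),
         n_modules = nrow(report$modules),
         kegg_classes = report$kegg_classes),
    file.path(dir, "report.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  invisible(dir)
}

#' @export
print.netpharm_report <- function(x, ...) {
  cat("<netpharm_report>\n")
  cat("networks:\n")
  print(as.data.frame(x$summary), row.names = FALSE)
  cat("hubs: ",
      paste(names(x$hubs), purrr::map_int(x$hubs, length),
            sep = "=", collapse = ", "), "\n", sep = "")
  cat("modules: ", nrow(x$modules), "\n", sep = "")
  if (nrow(x$kegg_classes)) {
    cat("passing KEGG pathways by class:\n")
    print(as.data.frame(x$kegg_classes), row.names = FALSE)
  }
  if (!is.null(x$recovery)) {
    cat("planted-module recovery:\n")
    print(as.data.frame(x$recovery), row.names = FALSE)
  }
  invisible(x)
}
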