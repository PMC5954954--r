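#' Filter disease-target records by literature evidence
#'
#' Some disease-gene sources report how many papers support each
#' gene-disease association; keeping only well-supported genes (for example
#' those reported by at least 20 papers) is a standard credibility screen
#' before merging sources. The comparison is inclusive: a record passes
#' when `evidence_count >= min_evidence`. Records without an evidence count
#' are kept only when `min_evidence` is 0, i.e. when no screening is asked
#' for.
#'
#' @param records Tibble with columns `gene` and optionally
#'   `evidence_count` (as from [read_disease_targets()]).
#' @param min_evidence Non-negative inclusive threshold (default 20).
#' @return The filtered tibble, row order preserved.
#' @examples
#' recs <- tibble::tibble(gene = c("A", "B", "C"),
#'                        evidence_count = c(19L, 20L, 21L))
#' filter_by_evidence(recs, 20)
#' @export
filter_by_evidence <- function(records, min_evidence = 20) {
  records <- as_tibble(records)
  if (!is.numeric(min_evidence) || length(min_evidence) != 1 ||
      is.na(min_evidence) || min_evidence < 0) {
    abort("`min_evidence` must be a single non-negative number.")
  }
  if (!"evidence_count" %in% names(records)) {
    records$evidence_count <- NA_integer_
  }
  ec <- records$evidence_count
  keep <- ifelse(is.na(ec), min_evidence == 0, ec >= min_evidence)
  records[keep, ]
}

#' Merge disease-target sources into a redundancy-free set
#'
#' Takes per-source gene lists, removes redundancy, and records which
#' sources contributed each gene. Presentation order is first appearance
#' across sources in the given source order, so the result is deterministic;
#' the gene *set* does not depend on source order.
#'
#' @param per_source Named list; each element either a character vector of
#'   gene symbols or a tibble with a `gene` column (as from
#'   [read_disease_targets()]). Unnamed elements are labelled
#'   `source1`, `source2`, ...
#' @return A tibble with columns `gene`, `n_sources` and list-column
#'   `sources` (the contributing source labels per gene).
#' @examples
#' merge_target_sources(list(ttd = c("TP53", "CDK2"), omim = c("CDK2", "EGFR")))
#' @export
merge_target_sources <- function(per_source) {
  if (!is.list(per_source) || length(per_source) == 0) {
    abort("`per_source` must be a non-empty list of source gene lists.")
  }
  labels <- names(per_source) %||% rep("", length(per_source))
  labels[!nzchar(labels)] <- paste0("source", which(!nzchar(labels)))
  long <- purrr::map2_dfr(per_source, labels, function(x, lab) {
    genes <- if (is.data.frame(x)) as.character(x$gene) else as.character(x)
    tibble(gene = toupper(trimws(genes)), source = lab)
  })
  long <- long[nzchar(long$gene), ]
  if (nrow(long) == 0) {
    warn("union of disease-target sources is empty.")
    return(tibble(gene = character(), n_sources = integer(),
                  sources = list()))
  }
  long |>
    mutate(.ord = row_number()) |>
    group_by(.data$gene) |>
    summarise(
      n_sources = dplyr::n_distinct(.data$source),
      sources = list(unique(.data$source)),
      .ord = min(.data$.ord),
      .groups = "drop"
    ) |>
    arrange(.data$.ord) |>
    select(-".ord")
}
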