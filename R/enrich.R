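#' Hypergeometric upper-tail probability
#'
#' The over-representation p-value: the probability of observing at least
#' `k` annotated genes in a random draw of `n` genes from a background of
#' `N` genes of which `K` carry the annotation, `P(X >= k)` for
#' `X ~ Hypergeometric(N, K, n)`. With `ease = TRUE` the overlap is
#' decremented by one (floored at zero) before computing the tail, the
#' conservative convention popularised by the DAVID/EASE tools.
#'
#' @param k Observed overlap(s), `0 <= k <= min(K, n)`.
#' @param K Annotated genes in the background.
#' @param n Query genes in the background.
#' @param N Background size.
#' @param ease Apply the EASE decrement (default `FALSE`).
#' @return Upper-tail probability in `(0, 1]`, vectorised over the inputs.
#' @examples
#' hypergeom_tail(4, 5, 4, 10)  # 5/210
#' @export
hypergeom_tail <- function(k, K, n, N, ease = FALSE) {
  m <- max(length(k), length(K), length(n), length(N))
  k <- rep_len(as.numeric(k), m); K <- rep_len(as.numeric(K), m)
  n <- rep_len(as.numeric(n), m); N <- rep_len(as.numeric(N), m)
  if (any(k < 0 | K < 0 | n < 0 | N < 0) ||
      any(k > pmin(K, n)) || any(K > N) || any(n > N)) {
    abort("inconsistent counts: need 0 <= k <= min(K, n) and K, n <= N.")
  }
  if (ease) k <- pmax(k - 1, 0)
  stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false-discovery-rate adjustment with monotonicity enforcement,
#' mapped back to the input order (a thin wrapper over
#' [stats::p.adjust()]).
#'
#' @param p_values Numeric vector of p-values in `(0, 1]`.
#' @return Adjusted values, same length and order as the input.
#' @export
bh_fdr <- function(p_values) {
  if (length(p_values) == 0) return(numeric(0))
  if (any(is.na(p_values)) || any(p_values <= 0 | p_values > 1)) {
    abort("p-values must lie in (0, 1].")
  }
  stats::p.adjust(p_values, method = "BH")
}

#' Over-representation analysis of a gene list
#'
#' Tests each annotation term for enrichment in `query_genes` with the
#' hypergeometric upper tail ([hypergeom_tail()]). The background is the
#' annotation universe unless overridden. Query and term member sets are
#' intersected with the background before counting. Terms with zero overlap
#' are not reported (they carry p = 1 and only dilute the FDR). FDR is
#' Benjamini-Hochberg, applied within each annotation category separately
#' (GO terms and KEGG pathways are distinct testing families). A term
#' passes when `p_value < p_cutoff` and `fdr < fdr_cutoff`; the defaults
#' reproduce the common stringent screen p < 0.01 and FDR < 0.01. The rich
#' factor `k / K` — the fraction of a term's annotated genes hit by the
#' query — is reported for dot plots.
#'
#' @param query_genes Character vector of gene symbols.
#' @param annotation Annotation tibble from [read_gene_sets()].
#' @param background Optional explicit background gene universe.
#' @param p_cutoff,fdr_cutoff Significance thresholds (defaults 0.01).
#' @param ease Use the EASE-decremented tail (default `FALSE`).
#' @return A tibble of class `netpharm_enrichment`, one row per term with
#'   `k >= 1`, columns `term_id`, `term_name`, `category`, `class`, `N`,
#'   `K`, `n`, `k`, `p_value`, `fdr`, `rich_factor`, `passes`; sorted by
#'   `p_value` then `term_id`.
#' @export
enrich <- function(query_genes, annotation, background = NULL,
                   p_cutoff = 0.01, fdr_cutoff = 0.01, ease = FALSE) {
  background <- unique(toupper(background %||%
                                 annotation_universe(annotation)))
  query <- intersect(unique(toupper(query_genes)), background)
  if (length(query) == 0) {
    abort("query shares no genes with the background universe.")
  }
  N <- length(background)
  n <- length(query)

  rows <- purrr::map_dfr(seq_len(nrow(annotation)), function(i) {
    members <- intersect(annotation$genes[[i]], background)
    K <- length(members)
    k <- length(intersect(query, members))
    if (k < 1) return(NULL)
    tibble(term_id = annotation$term_id[i],
           term_name = annotation$term_name[i],
           category = annotation$category[i],
           class = if ("class" %in% names(annotation))
             annotation$class[i] else NA_character_,
           N = N, K = K, n = n, k = k)
  })
  if (nrow(rows) == 0) {
    out <- tibble(term_id = character(), term_name = character(),
                  category = character(), class = character(),
                  N = integer(), K = integer(), n = integer(), k = integer(),
                  p_value = double(), fdr = double(),
                  rich_factor = double(), passes = logical())
    class(out) <- c("netpharm_enrichment", class(out))
    return(out)
  }
  rows$p_value <- hypergeom_tail(rows$k, rows$K, rows$n, rows$N, ease = ease)
  rows <- rows |>
    group_by(.data$category) |>
    mutate(fdr = bh_fdr(.data$p_value)) |>
    ungroup() |>
    mutate(rich_factor = .data$k / .data$K,
           passes = .data$p_value < p_cutoff & .data$fdr < fdr_cutoff) |>
    arrange(.data$p_value, .data$term_id)
  class(rows) <- c("netpharm_enrichment", class(rows))
  rows
}

#' Tally passing pathways by top-level category
#'
#' Groups the significant pathways of an enrichment result into top-level
#' classes (for KEGG: human diseases, environmental information processing,
#' organismal systems, genetic information processing, cellular processes)
#' and counts pathways per class. Pathways without a mapping are tallied
#' under `"unassigned"` with a warning. Class counts always sum to the
#' number of passing pathways.
#'
#' @param results Enrichment tibble from [enrich()].
#' @param category_map Named character vector mapping `term_id` to a
#'   top-level class, or `NULL` to use the `class` column carried by the
#'   annotation.
#' @param passing_only Tally only terms with `passes == TRUE`
#'   (default `TRUE`).
#' @return A tibble with columns `class` and `n_pathways`, sorted by count
#'   descending then class name, with the grand total in attribute
#'   `"total"`.
#' @export
classify_categories <- function(results, category_map = NULL,
                                passing_only = TRUE) {
  rows <- if (passing_only) filter(results, .data$passes) else results
  if (nrow(rows) == 0) {
    out <- tibble(class = character(), n_pathways = integer())
    attr(out, "total") <- 0L
    return(out)
  }
  cls <- if (!is.null(category_map)) {
    unname(category_map[rows$term_id])
  } else if ("class" %in% names(rows)) {
    rows$class
  } else {
    rep(NA_character_, nrow(rows))
  }
  if (anyNA(cls)) {
    warn(paste0(sum(is.na(cls)),
                " pathway(s) had no top-level class; tallied as 'unassigned'."))
    cls[is.na(cls)] <- "unassigned"
  }
  out <- tibble(class = cls) |>
    count(.data$class, name = "n_pathways") |>
    arrange(desc(.data$n_pathways), .data$class)
  attr(out, "total") <- sum(out$n_pathways)
  out
}
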