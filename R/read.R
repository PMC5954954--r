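#' Read a compound-target table
#'
#' Reads the tabular output of a compound target-prediction step: one row
#' per compound-to-protein assertion. The file must have a header naming a
#' compound column and a target column (matched case-insensitively against
#' `compound` and `target`, or supplied explicitly). Gene symbols are
#' upper-cased at read time because public sources mix symbol styles; exact
#' duplicate (compound, target) pairs are dropped, keeping first appearance.
#'
#' @param path Path to a TSV or CSV file (delimiter sniffed from the header
#'   line unless `delim` is given).
#' @param compound_col,target_col Optional explicit column names.
#' @param delim Optional field delimiter; default sniffs `","` vs tab.
#' @return A tibble with columns `compound_id`, `target` and `source`
#'   (`NA` when the file carries no provenance column).
#' @examples
#' tf <- tempfile(fileext = ".tsv")
#' writeLines(c("compound\ttarget", "c1\ttp53", "c1\tTP53", "c2\tCDK2"), tf)
#' read_compound_targets(tf)
#' @export
read_compound_targets <- function(path, compound_col = NULL,
                                  target_col = NULL, delim = NULL) {
  raw <- read_delim_sniffed(path, delim)
  nm <- tolower(names(raw))
  pick <- function(given, pattern, what) {
    if (!is.null(given)) {
      if (!given %in% names(raw)) {
        abort(paste0("compound-target file is missing column `", given, "`."))
      }
      return(given)
    }
    hit <- which(grepl(pattern, nm))
    if (!length(hit)) {
      abort(paste0("compound-target file is missing a ", what,
                   " column (no header matches '", pattern, "')."))
    }
    names(raw)[hit[1]]
  }
  ccol <- pick(compound_col, "compound", "compound")
  tcol <- pick(target_col, "target", "target")
  scol <- names(raw)[grepl("source|provenance", nm)][1]

  if (nrow(raw) == 0) {
    warn(paste0("compound-target file '", path, "' has no data rows."))
    return(tibble(compound_id = character(), target = character(),
                  source = character()))
  }

  out <- tibble(
    compound_id = as.character(raw[[ccol]]),
    target = toupper(trimws(as.character(raw[[tcol]]))),
    source = if (!is.na(scol)) as.character(raw[[scol]]) else NA_character_
  )
  bad <- which(is.na(out$compound_id) | out$compound_id == "" |
                 is.na(out$target) | out$target == "")
  if (length(bad)) {
    abort(paste0("empty compound or target field on data row ", bad[1],
                 " of '", path, "'."))
  }
  ws <- which(grepl("\\s", out$target))
  if (length(ws)) {
    abort(paste0("target symbol contains whitespace on data row ", ws[1],
                 " of '", path, "'."))
  }
  distinct(out, .data$compound_id, .data$target, .keep_all = TRUE)
}

# Sniff comma vs whitespace/tab from the header line.
read_delim_sniffed <- function(path, delim = NULL) {
  header <- readLines(path, n = 1L)
  if (is.null(delim)) {
    delim <- if (grepl(",", header) && !grepl("\t", header)) "," else "\t"
  }
  if (delim == ",") {
    readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  } else {
    readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  }
}

#' Read a scored protein interaction edge list
#'
#' Reads STRING-style `protein1 protein2 combined_score` files
#' (whitespace- or tab-delimited, header required). STRING distributes
#' combined scores as integers on a 0-999 per-mille scale; normalised
#' scores in `[0, 1]` are also accepted. With `score_scale = "auto"` the
#' scale is inferred: any score above 1 implies per-mille. Per-mille scores
#' are divided by 1000, so 700 maps to 0.700.
#'
#' Self-loops are dropped, duplicate unordered pairs are collapsed to their
#' maximum score, and only edges with score strictly greater than
#' `min_score` are kept — the conventional "high confidence" cut keeps
#' combined scores > 0.7.
#'
#' @param path Path to the edge-list file.
#' @param score_scale One of `"auto"`, `"unit"`, `"permille"`.
#' @param min_score Strict lower bound on the normalised score
#'   (default `0.7`); use `0` to keep every positive-score edge.
#' @return A tibble with columns `protein_a`, `protein_b` (canonically
#'   ordered, upper-cased) and `score` in `[0, 1]`.
#' @examples
#' tf <- tempfile(fileext = ".txt")
#' writeLines(c("protein1 protein2 combined_score", "TP53 MDM2 962",
#'              "CDK2 CCNA2 700"), tf)
#' read_ppi_edges(tf)  # the 0.700 edge is dropped by the strict > 0.7 cut
#' @export
read_ppi_edges <- function(path,
                           score_scale = c("auto", "unit", "permille"),
                           min_score = 0.7) {
  score_scale <- match.arg(score_scale)
  raw <- utils::read.table(path, header = TRUE, stringsAsFactors = FALSE)
  nm <- tolower(names(raw))
  need <- c("protein1", "protein2", "combined_score")
  if (!all(need %in% nm)) {
    abort(paste0("PPI file must have columns protein1/protein2/combined_score; ",
                 "found: ", paste(names(raw), collapse = ", ")))
  }
  names(raw) <- nm
  score <- as.numeric(raw$combined_score)
  if (anyNA(score)) abort("non-numeric combined_score value in PPI file.")

  if (score_scale == "auto") {
    score_scale <- if (length(score) && max(score) > 1) "permille" else "unit"
  } else if (score_scale == "permille" && length(score) && all(score <= 1)) {
    abort(paste0("score scale declared per-mille but all scores are <= 1; ",
                 "ambiguous; declare `unit` or `auto`."))
  }
  if (score_scale == "permille") {
    if (any(score < 0 | score > 999) || any(score != round(score))) {
      abort("per-mille scores must be integers in [0, 999].")
    }
    score <- score / 1000
  } else {
    if (any(score < 0 | score > 1)) {
      abort("unit-scale scores must lie in [0, 1].")
    }
  }

  a <- toupper(trimws(as.character(raw$protein1)))
  b <- toupper(trimws(as.character(raw$protein2)))
  keep <- a != b
  edges <- tibble(
    protein_a = pmin(a[keep], b[keep]),
    protein_b = pmax(a[keep], b[keep]),
    score = score[keep]
  )
  edges <- edges |>
    group_by(.data$protein_a, .data$protein_b) |>
    summarise(score = max(.data$score), .order = min(row_number()),
              .groups = "drop") |>
    arrange(.data$.order) |>
    select(-".order")
  filter(edges, .data$score > min_score)
}

#' Read gene sets from a GMT file
#'
#' Parses the tab-delimited GMT gene-set format: one term per line as
#' `term_id <TAB> description <TAB> gene1 <TAB> gene2 ...`. An annotation
#' category (for example `GO` or `KEGG`) is read from a `category=<x>`
#' token in the description, and an optional top-level class (used for
#' pathway tallies) from a `class=<x>` token; tokens are separated by `|`.
#' Remaining description text becomes the term name.
#'
#' @param path Path to a GMT file.
#' @param universe Optional explicit background gene universe; defaults to
#'   the union of all member sets.
#' @return A tibble with columns `term_id`, `term_name`, `category`,
#'   `class` and list-column `genes`, carrying the gene universe in
#'   attribute `"universe"` (see [annotation_universe()]).
#' @export
read_gene_sets <- function(path, universe = NULL) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(lengths(parts) < 3)
  if (length(short)) {
    abort(paste0("GMT line ", short[1], " has fewer than 3 fields."))
  }
  recs <- purrr::map(parts, function(p) {
    desc <- p[2]
    toks <- strsplit(desc, "|", fixed = TRUE)[[1]]
    grab <- function(key) {
      hit <- grep(paste0("^", key, "="), toks, value = TRUE)
      if (length(hit)) sub(paste0("^", key, "="), "", hit[1]) else NA_character_
    }
    name_toks <- toks[!grepl("^(category|class)=", toks)]
    genes <- toupper(trimws(p[-(1:2)]))
    genes <- unique(genes[nzchar(genes)])
    list(term_id = p[1],
         term_name = if (length(name_toks)) paste(name_toks, collapse = "|")
                     else p[1],
         category = grab("category") %||% NA_character_,
         class = grab("class"),
         genes = genes)
  })
  empty <- which(purrr::map_int(recs, ~ length(.x$genes)) == 0)
  if (length(empty)) {
    abort(paste0("GMT line ", empty[1], " has an empty gene list."))
  }
  out <- tibble(
    term_id = purrr::map_chr(recs, "term_id"),
    term_name = purrr::map_chr(recs, "term_name"),
    category = dplyr::coalesce(purrr::map_chr(recs, "category"), "unassigned"),
    class = purrr::map_chr(recs, "class"),
    genes = purrr::map(recs, "genes")
  )
  if (anyDuplicated(out$term_id)) abort("duplicate term_id in GMT file.")
  members <- unique(unlist(out$genes))
  if (is.null(universe)) {
    universe <- members
  } else {
    universe <- unique(toupper(universe))
    if (!all(members %in% universe)) {
      abort("explicit universe does not contain every term member.")
    }
  }
  attr(out, "universe") <- universe
  class(out) <- c("netpharm_annotation", class(out))
  out
}

#' Background universe of an annotation collection
#'
#' @param annotation An annotation tibble from [read_gene_sets()].
#' @return Character vector of background gene symbols.
#' @export
annotation_universe <- function(annotation) {
  u <- attr(annotation, "universe")
  u %||% unique(unlist(annotation$genes))
}

#' Write gene sets to a GMT file
#'
#' Inverse of [read_gene_sets()]: category and class are encoded as
#' `category=` / `class=` tokens in the description field.
#'
#' @param annotation Annotation tibble (columns `term_id`, `term_name`,
#'   `category`, optional `class`, list-column `genes`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gene_sets <- function(annotation, path) {
  desc <- paste0(annotation$term_name, "|category=", annotation$category)
  if ("class" %in% names(annotation)) {
    has_class <- !is.na(annotation$class)
    desc[has_class] <- paste0(desc[has_class], "|class=",
                              annotation$class[has_class])
  }
  lines <- vapply(seq_len(nrow(annotation)), function(i) {
    paste(c(annotation$term_id[i], desc[i], annotation$genes[[i]]),
          collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read one disease-target source file
#'
#' Each disease-gene source (a therapeutic-target database, a genetic
#' disease catalogue, a text-mining engine, ...) contributes one TSV with a
#' `gene` column and, where the source quantifies literature support, an
#' `evidence_count` column.
#'
#' @param path Path to the TSV.
#' @param source Source label; defaults to the file name without extension.
#' @return A tibble with columns `gene`, `source`, `evidence_count`
#'   (`NA` when the file has no evidence column).
#' @export
read_disease_targets <- function(path, source = NULL) {
  source <- source %||% tools::file_path_sans_ext(basename(path))
  raw <- read_delim_sniffed(path)
  nm <- tolower(names(raw))
  gcol <- which(nm == "gene")
  if (!length(gcol)) abort(paste0("'", path, "' has no `gene` column."))
  ecol <- which(nm == "evidence_count")
  out <- tibble(
    gene = toupper(trimws(as.character(raw[[gcol[1]]]))),
    source = source,
    evidence_count = if (length(ecol)) as.integer(raw[[ecol[1]]]) else
      NA_integer_
  )
  if (any(!nzchar(out$gene) | is.na(out$gene))) {
    abort(paste0("empty gene field in '", path, "'."))
  }
  if (any(!is.na(out$evidence_count) & out$evidence_count < 0)) {
    abort(paste0("negative evidence_count in '", path, "'."))
  }
  out
}
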