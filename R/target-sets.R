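#' Normalise gene symbols
#'
#' Trims whitespace and uppercases, drops empties and duplicates. Gene identity
#' throughout the package is the uppercase HGNC-style symbol string; no alias
#' resolution is attempted.
#'
#' @param genes Character vector.
#' @return Unique, uppercase, whitespace-free symbols (input order of first
#'   occurrence preserved).
#' @export
normalize_symbols <- function(genes) {
  genes <- toupper(trimws(as.character(genes)))
  unique(genes[nzchar(genes) & !is.na(genes)])
}

#' Union of predicted targets over compounds
#'
#' Deduplicated union of the target genes of the listed compounds in a
#' compound-target map.
#'
#' @param map Data frame with columns `compound_id` and `gene` (an optional
#'   `score` column is ignored here; see [read_compound_targets()] for
#'   score-based filtering).
#' @param compounds Compound ids to pool over; default all compounds in `map`.
#' @return Sorted character vector of unique gene symbols.
#' @export
union_targets <- function(map, compounds = NULL) {
  map <- as_tibble(map)
  for (col in c("compound_id", "gene")) {
    if (!col %in% names(map)) abort(sprintf("Map lacks column '%s'.", col))
  }
  if (is.null(compounds)) {
    compounds <- unique(map$compound_id)
  } else {
    unknown <- setdiff(compounds, map$compound_id)
    if (length(unknown)) {
      abort(sprintf("Unknown compound id(s): %s.",
                    paste(unknown, collapse = ", ")))
    }
  }
  sort(normalize_symbols(map$gene[map$compound_id %in% compounds]))
}

#' Intersect two gene sets
#'
#' Symbols are normalised on ingest, so case/whitespace variants collapse.
#' An empty intersection is a valid result and is reported with a warning.
#'
#' @param a,b Character vectors of gene symbols.
#' @return Sorted character vector `a` intersect `b`.
#' @export
intersect_targets <- function(a, b) {
  out <- sort(intersect(normalize_symbols(a), normalize_symbols(b)))
  if (length(out) == 0L) {
    warn("Empty intersection between the two target sets.")
  }
  out
}

#' Venn counts for two gene sets
#'
#' @param a,b Character vectors of gene symbols.
#' @return A tibble with one row: `a_only`, `b_only`, `shared`. The three
#'   counts sum to the size of the union.
#' @export
venn_counts <- function(a, b) {
  a <- normalize_symbols(a)
  b <- normalize_symbols(b)
  shared <- length(intersect(a, b))
  tibble(
    a_only = length(a) - shared,
    b_only = length(b) - shared,
    shared = shared
  )
}

#' Read a compound-to-target map
#'
#' Tab-separated file with columns `compound_id`, `gene` and optionally
#' `score`. Pairs with score below `score_min` are dropped (the configurable
#' stand-in for upstream "false-positive target" removal); pairs are
#' deduplicated and symbols normalised.
#'
#' @param path TSV path.
#' @param score_min Minimum score to keep when a `score` column is present;
#'   default 0 (keep all).
#' @return Tibble with columns `compound_id`, `gene` (plus `score` if present).
#' @export
read_compound_targets <- function(path, score_min = 0) {
  if (!file.exists(path)) abort(sprintf("Target map not found: '%s'.", path))
  map <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  for (col in c("compound_id", "gene")) {
    if (!col %in% names(map)) abort(sprintf("Map lacks column '%s'.", col))
  }
  map$gene <- toupper(trimws(map$gene))
  map <- map[nzchar(map$gene), ]
  if ("score" %in% names(map) && score_min > 0) {
    map <- map[map$score >= score_min, ]
  }
  dplyr::distinct(map, .data$compound_id, .data$gene, .keep_all = TRUE)
}

#' Read a gene set
#'
#' Plain text, one symbol per line; lines starting with `#` are ignored.
#'
#' @param path File path.
#' @return Normalised character vector of symbols.
#' @export
read_gene_list <- function(path) {
  if (!file.exists(path)) abort(sprintf("Gene list not found: '%s'.", path))
  lines <- readr::read_lines(path, progress = FALSE)
  lines <- lines[!startsWith(trimws(lines), "#")]
  normalize_symbols(lines)
}

#' Read a GMT annotation collection
#'
#' Standard GMT: one term per line, `term_id <tab> description <tab> genes...`.
#'
#' @param path GMT file path.
#' @return Long tibble with columns `term_id`, `term_name`, `gene`.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) abort(sprintf("GMT file not found: '%s'.", path))
  lines <- readr::read_lines(path, progress = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  rows <- purrr::map(lines, function(line) {
    parts <- strsplit(line, "\t", fixed = TRUE)[[1]]
    if (length(parts) < 3L) {
      abort(sprintf("Malformed GMT line (need id, name, >=1 gene): '%s'.",
                    substr(line, 1, 60)))
    }
    tibble(term_id = parts[[1]], term_name = parts[[2]],
           gene = normalize_symbols(parts[-(1:2)]))
  })
  dplyr::bind_rows(rows)
}

#' Write a GMT annotation collection
#'
#' @param terms Long tibble with `term_id`, `term_name`, `gene` columns.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(terms, path) {
  terms <- as_tibble(terms)
  split_terms <- split(terms, terms$term_id)
  lines <- purrr::map_chr(split_terms, function(tt) {
    paste(c(tt$term_id[[1]], tt$term_name[[1]], sort(unique(tt$gene))),
          collapse = "\t")
  })
  readr::write_lines(lines[order(names(split_terms))], path)
  invisible(path)
}
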