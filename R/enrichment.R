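check_hyper_args <- function(k, n, K, N) {
  if (any(c(k, n, K, N) < 0)) abort("Counts must be non-negative.")
  if (any(k > n)) abort("Inconsistent counts: k > n.")
  if (any(k > K)) abort("Inconsistent counts: k > K.")
  if (any(n > N)) abort("Inconsistent counts: n > N.")
  if (any(K > N)) abort("Inconsistent counts: K > N.")
}

#' Hypergeometric upper-tail probability
#'
#' Probability of drawing at least `k` annotated genes when drawing `n` genes
#' without replacement from a universe of `N` genes of which `K` are annotated:
#' `P(X >= k)` for `X ~ Hypergeometric(N, K, n)`. Evaluated via the stable
#' log-space routine in `stats::phyper`. Vectorised.
#'
#' @param k Overlap count (query genes in the term).
#' @param n Query size.
#' @param K Term size.
#' @param N Universe size.
#' @return p-value in (0, 1].
#' @examples
#' hypergeom_upper_tail(2, 2, 2, 4) # 1/6
#' @export
hypergeom_upper_tail <- function(k, n, K, N) {
  check_hyper_args(k, n, K, N)
  phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' EASE-score p-value
#'
#' DAVID's conservative over-representation variant: the hypergeometric upper
#' tail with the overlap count reduced by one (`max(k - 1, 0)`), so
#' single-gene overlaps are never significant. Always >= the plain
#' hypergeometric p for the same counts.
#'
#' @inheritParams hypergeom_upper_tail
#' @return p-value in (0, 1].
#' @export
ease_p <- function(k, n, K, N) {
  check_hyper_args(k, n, K, N)
  hypergeom_upper_tail(pmax(k - 1, 0), n, K, N)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment (via `stats::p.adjust`), with input
#' validation. Order-preserving with respect to input positions.
#'
#' @param p Numeric vector of raw p-values in \[0, 1\].
#' @return Adjusted p-values, same length and order.
#' @export
bh_adjust <- function(p) {
  if (length(p) == 0L) return(numeric(0))
  if (anyNA(p) || any(p < 0 | p > 1)) {
    abort("p-values must lie in [0, 1] with no missing values.")
  }
  p.adjust(p, method = "BH")
}

as_annotation <- function(collection) {
  if (is.character(collection) && length(collection) == 1L) {
    collection <- read_gmt(collection)
  }
  collection <- as_tibble(collection)
  for (col in c("term_id", "term_name", "gene")) {
    if (!col %in% names(collection)) {
      abort(sprintf("Annotation collection lacks column '%s'.", col))
    }
  }
  if (!"category" %in% names(collection)) collection$category <- NA_character_
  collection$gene <- toupper(trimws(collection$gene))
  dplyr::distinct(collection, .data$term_id, .data$gene, .keep_all = TRUE)
}

#' Over-representation analysis of a gene list
#'
#' DAVID-style enrichment of a query gene set against an annotation
#' collection. For every term overlapping the query, computes the overlap
#' count `k`, term size `K`, effective query size `n` (query genes present in
#' the universe), the EASE or plain hypergeometric p-value, the BH-adjusted
#' p-value (over all overlapping terms, before truncation), and the gene ratio
#' `k / n`. Rows are sorted by ascending p-value, ties broken by descending
#' `k` then by term id, and truncated to `top_k`.
#'
#' @param query Character vector of gene symbols.
#' @param collection Long annotation tibble (`term_id`, `term_name`, `gene`,
#'   optional `category`) or a GMT path.
#' @param stat `"ease"` (DAVID's default, used here too) or `"hypergeom"`.
#' @param top_k Keep the `top_k` most significant terms; default 20.
#' @param universe Background gene set; default all genes appearing in the
#'   collection.
#' @return Tibble of class `np_enrich` with columns `term_id`, `term_name`,
#'   `category`, `k`, `n`, `K`, `N`, `gene_ratio`, `p_value`, `p_adjusted`,
#'   `overlap_genes` (list column).
#' @export
enrich <- function(query, collection, stat = c("ease", "hypergeom"),
                   top_k = 20, universe = NULL) {
  stat <- match.arg(stat)
  if (!is.numeric(top_k) || top_k < 1) abort("`top_k` must be >= 1.")
  collection <- as_annotation(collection)
  query <- normalize_symbols(query)
  universe <- if (is.null(universe)) unique(collection$gene) else
    normalize_symbols(universe)
  N <- length(universe)
  q <- intersect(query, universe)
  n <- length(q)
  if (n == 0L) {
    abort(paste("Query and universe are disjoint; check that the annotation",
                "collection (or supplied universe) covers the query genes."))
  }
  terms <- split(collection, collection$term_id)
  rows <- purrr::map(terms, function(tt) {
    members <- intersect(unique(tt$gene), universe)
    ov <- sort(intersect(q, members))
    if (length(ov) == 0L) return(NULL)
    tibble(
      term_id = tt$term_id[[1]], term_name = tt$term_name[[1]],
      category = tt$category[[1]],
      k = length(ov), n = n, K = length(members), N = N,
      overlap_genes = list(ov)
    )
  })
  res <- dplyr::bind_rows(rows)
  if (nrow(res) == 0L) {
    res <- tibble(term_id = character(0), term_name = character(0),
                  category = character(0), k = integer(0), n = integer(0),
                  K = integer(0), N = integer(0),
                  overlap_genes = list(), p_value = double(0),
                  p_adjusted = double(0), gene_ratio = double(0))
  } else {
    res$p_value <- if (stat == "ease") ease_p(res$k, res$n, res$K, res$N) else
      hypergeom_upper_tail(res$k, res$n, res$K, res$N)
    res$p_adjusted <- bh_adjust(res$p_value)
    res$gene_ratio <- res$k / res$n
    res <- dplyr::arrange(res, .data$p_value, dplyr::desc(.data$k),
                          .data$term_id)
    res <- head(res, top_k)
  }
  res <- res[, c("term_id", "term_name", "category", "k", "n", "K", "N",
                 "gene_ratio", "p_value", "p_adjusted", "overlap_genes")]
  attr(res, "stat") <- stat
  attr(res, "query_size") <- n
  attr(res, "universe_size") <- N
  class(res) <- c("np_enrich", class(res))
  res
}

#' @export
glance.np_enrich <- function(x, ...) {
  tibble(
    n_terms = nrow(x),
    n_significant = sum(x$p_adjusted < 0.05),
    query_size = attr(x, "query_size") %||% NA_integer_,
    universe_size = attr(x, "universe_size") %||% NA_integer_,
    statistic = attr(x, "stat") %||% NA_character_
  )
}

#' @export
tidy.np_enrich <- function(x, ...) as_tibble(unclass(x))

#' Write an enrichment table to TSV
#'
#' The `overlap_genes` list column is collapsed to a comma-joined string.
#'
#' @param x An `np_enrich` tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_enrichment <- function(x, path) {
  out <- as_tibble(unclass(x))
  out$overlap_genes <- purrr::map_chr(out$overlap_genes, paste, collapse = ",")
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}
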