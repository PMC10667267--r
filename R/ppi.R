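#' Read a PPI edge list
#'
#' Accepts a 2- or 3-column TSV (`gene_a`, `gene_b`, optional
#' `combined_score`) or SIF (`A <relation> B`, whitespace-delimited). Format is
#' inferred from the extension (`.sif`) unless given.
#'
#' @param path Edge-list path.
#' @param format `"auto"`, `"tsv"` or `"sif"`.
#' @param score_min Drop TSV rows whose score column is below this; default
#'   `NULL` (keep all). Useful for STRING-style confidence filtering.
#' @return Tibble with columns `gene_a`, `gene_b` (plus `score` if present).
#' @export
read_ppi_edges <- function(path, format = c("auto", "tsv", "sif"),
                           score_min = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) abort(sprintf("Edge list not found: '%s'.", path))
  if (format == "auto") {
    format <- if (grepl("\\.sif$", path, ignore.case = TRUE)) "sif" else "tsv"
  }
  lines <- readr::read_lines(path, progress = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (format == "sif") {
    parts <- strsplit(trimws(lines), "[ \t]+")
    bad <- which(lengths(parts) < 3L)
    if (length(bad)) {
      abort(sprintf("Malformed SIF row at line %d: need 'A relation B'.",
                    bad[[1]]))
    }
    edges <- tibble(
      gene_a = purrr::map_chr(parts, 1),
      gene_b = purrr::map_chr(parts, 3)
    )
  } else {
    has_header <- grepl("^\\s*(gene_a|protein1|node1)", lines[[1]],
                        ignore.case = TRUE)
    body <- if (has_header) lines[-1] else lines
    offset <- if (has_header) 1L else 0L
    parts <- strsplit(body, "\t", fixed = TRUE)
    bad <- which(lengths(parts) < 2L)
    if (length(bad)) {
      abort(sprintf("Malformed edge row at line %d: need two tab-separated columns.",
                    bad[[1]] + offset))
    }
    edges <- tibble(
      gene_a = purrr::map_chr(parts, 1),
      gene_b = purrr::map_chr(parts, 2)
    )
    if (any(lengths(parts) >= 3L)) {
      edges$score <- suppressWarnings(as.numeric(purrr::map_chr(
        parts, function(p) if (length(p) >= 3L) p[[3]] else NA_character_
      )))
    }
  }
  if (!is.null(score_min) && "score" %in% names(edges)) {
    edges <- edges[!is.na(edges$score) & edges$score >= score_min, ]
  }
  edges
}

#' Build an undirected simple PPI graph
#'
#' Symbols are normalised, self-loops dropped, duplicate and reversed pairs
#' collapsed. With `restrict_to`, only edges with both endpoints in the set
#' are kept, and members of the set absent from any surviving edge are
#' retained as isolated (degree-0) nodes — matching how a database subnetwork
#' of a fixed query set behaves.
#'
#' @param edges Data frame whose first two columns are interaction partners
#'   (e.g. from [read_ppi_edges()]), or a two-column character matrix.
#' @param restrict_to Optional character vector of gene symbols.
#' @return An `np_graph`: list with `graph` (igraph) plus `nodes`/`edges`
#'   tibbles.
#' @examples
#' g <- build_ppi(tibble::tibble(gene_a = c("A", "B"), gene_b = c("B", "A")))
#' graph_counts(g)
#' @export
build_ppi <- function(edges, restrict_to = NULL) {
  edges <- as.data.frame(edges)
  if (ncol(edges) < 2L) abort("Edge input needs at least two columns.")
  a <- toupper(trimws(as.character(edges[[1]])))
  b <- toupper(trimws(as.character(edges[[2]])))
  bad <- which(!nzchar(a) | !nzchar(b) | is.na(a) | is.na(b))
  if (length(bad)) {
    abort(sprintf("Empty endpoint in edge row %d.", bad[[1]]))
  }
  keep <- a != b                              # drop self-loops
  a <- a[keep]; b <- b[keep]
  lo <- pmin(a, b); hi <- pmax(a, b)          # collapse reversed duplicates
  pair <- !duplicated(paste(lo, hi, sep = "\r"))
  lo <- lo[pair]; hi <- hi[pair]
  if (!is.null(restrict_to)) {
    restrict_to <- normalize_symbols(restrict_to)
    keep <- lo %in% restrict_to & hi %in% restrict_to
    lo <- lo[keep]; hi <- hi[keep]
    nodes <- sort(restrict_to)
  } else {
    nodes <- sort(unique(c(lo, hi)))
  }
  g <- igraph::make_empty_graph(n = 0, directed = FALSE)
  g <- igraph::add_vertices(g, length(nodes), name = nodes)
  if (length(lo)) {
    g <- igraph::add_edges(g, rbind(match(lo, nodes), match(hi, nodes)))
  }
  new_np_graph(g)
}

new_np_graph <- function(g) {
  el <- igraph::as_edgelist(g, names = TRUE)
  structure(
    list(
      graph = g,
      nodes = tibble(gene = igraph::V(g)$name),
      edges = tibble(gene_a = el[, 1], gene_b = el[, 2])
    ),
    class = "np_graph"
  )
}

#' @export
print.np_graph <- function(x, ...) {
  cat(sprintf("<np_graph> %d nodes, %d edges\n",
              igraph::vcount(x$graph), igraph::ecount(x$graph)))
  invisible(x)
}

#' Node and edge counts of a graph
#'
#' @param g An `np_graph`.
#' @return Tibble with `n_nodes`, `n_edges`, `n_components` (counting isolated
#'   nodes as singleton components).
#' @export
graph_counts <- function(g) {
  stopifnot(inherits(g, "np_graph"))
  tibble(
    n_nodes = igraph::vcount(g$graph),
    n_edges = igraph::ecount(g$graph),
    n_components = igraph::components(g$graph)$no
  )
}

#' Node centralities under network-analyzer conventions
#'
#' Computes, per node: degree; betweenness (Brandes) normalised by
#' `(n-1)(n-2)/2` with `n` the full graph's node count (isolated nodes
#' included); and closeness. Closeness follows the component-local convention
#' of Cytoscape's NetworkAnalyzer by default: within each connected component,
#' `(size - 1) / sum(shortest-path distances to co-component nodes)`; isolated
#' nodes get closeness 0 and betweenness 0. The `"wasserman-faust"` convention
#' additionally scales each node's closeness by `(size - 1)/(n - 1)`.
#'
#' @param g An `np_graph` (see [build_ppi()]).
#' @param closeness `"component"` (default) or `"wasserman-faust"`.
#' @return Tibble with columns `gene`, `degree`, `betweenness`, `closeness`,
#'   one row per node, in node-name order.
#' @export
ppi_centralities <- function(g, closeness = c("component", "wasserman-faust")) {
  stopifnot(inherits(g, "np_graph"))
  closeness <- match.arg(closeness)
  gr <- g$graph
  n <- igraph::vcount(gr)
  if (n == 0L) {
    return(tibble(gene = character(0), degree = integer(0),
                  betweenness = double(0), closeness = double(0)))
  }
  deg <- igraph::degree(gr)
  btw_raw <- igraph::betweenness(gr, directed = FALSE, normalized = FALSE)
  btw <- if (n > 2L) btw_raw / ((n - 1) * (n - 2) / 2) else rep(0, n)
  dist <- igraph::distances(gr)
  comp <- igraph::components(gr)$membership
  cc <- vapply(seq_len(n), function(i) {
    members <- which(comp == comp[[i]])
    size <- length(members)
    if (size < 2L) return(0)
    (size - 1) / sum(dist[i, setdiff(members, i)])
  }, numeric(1))
  if (closeness == "wasserman-faust" && n > 1L) {
    sizes <- tabulate(comp)[comp]
    cc <- cc * (sizes - 1) / (n - 1)
  }
  tibble(
    gene = igraph::V(gr)$name,
    degree = as.integer(deg),
    betweenness = unname(btw),
    closeness = unname(cc)
  )
}

#' Select key targets by topological cutoffs
#'
#' Keeps nodes satisfying all three inclusive thresholds: degree,
#' normalised betweenness, normalised closeness. The conventional screening
#' defaults are degree >= 4, betweenness >= 0.01, closeness >= 0.5.
#'
#' @param centrality Tibble from [ppi_centralities()].
#' @param deg_min,bc_min,cc_min Inclusive lower bounds; all must be
#'   non-negative.
#' @return Sorted character vector of key-target symbols.
#' @export
filter_key_targets <- function(centrality, deg_min = 4, bc_min = 0.01,
                               cc_min = 0.5) {
  if (any(c(deg_min, bc_min, cc_min) < 0)) {
    abort("Thresholds must be non-negative.")
  }
  need <- c("gene", "degree", "betweenness", "closeness")
  missing <- setdiff(need, names(centrality))
  if (length(missing)) {
    abort(sprintf("Centrality table lacks column(s): %s.",
                  paste(missing, collapse = ", ")))
  }
  keep <- centrality$degree >= deg_min &
    centrality$betweenness >= bc_min &
    centrality$closeness >= cc_min
  sort(centrality$gene[keep])
}

#' Induced subgraph
#'
#' Subgraph on `keep`: nodes in `keep`, edges with both endpoints in `keep`.
#' Centralities of the result must be recomputed — betweenness and closeness
#' are not restriction-invariant.
#'
#' @param g An `np_graph`.
#' @param keep Character vector of node names; all must exist in `g`.
#' @return An `np_graph`.
#' @export
ppi_subgraph <- function(g, keep) {
  stopifnot(inherits(g, "np_graph"))
  keep <- normalize_symbols(keep)
  unknown <- setdiff(keep, igraph::V(g$graph)$name)
  if (length(unknown)) {
    abort(sprintf("Node(s) not in graph: %s.", paste(unknown, collapse = ", ")))
  }
  new_np_graph(igraph::induced_subgraph(g$graph, keep))
}

#' Analyse a PPI network end to end
#'
#' Convenience wrapper: build the (optionally restricted) graph, compute
#' centralities, flag key targets, and return everything as one object with
#' [tidy()], [glance()] and [autoplot()] methods.
#'
#' @inheritParams build_ppi
#' @inheritParams filter_key_targets
#' @inheritParams ppi_centralities
#' @return An object of class `np_ppi`.
#' @export
ppi_analyze <- function(edges, restrict_to = NULL, deg_min = 4, bc_min = 0.01,
                        cc_min = 0.5,
                        closeness = c("component", "wasserman-faust")) {
  closeness <- match.arg(closeness)
  g <- build_ppi(edges, restrict_to = restrict_to)
  cent <- ppi_centralities(g, closeness = closeness)
  key <- filter_key_targets(cent, deg_min, bc_min, cc_min)
  cent$is_key <- cent$gene %in% key
  structure(
    list(graph = g, centrality = cent, key_targets = key,
         key_graph = if (length(key)) ppi_subgraph(g, key) else NULL,
         thresholds = c(deg_min = deg_min, bc_min = bc_min, cc_min = cc_min)),
    class = "np_ppi"
  )
}

#' @export
print.np_ppi <- function(x, ...) {
  cnt <- graph_counts(x$graph)
  cat(sprintf("<np_ppi> %d nodes, %d edges; %d key target(s)\n",
              cnt$n_nodes, cnt$n_edges, length(x$key_targets)))
  invisible(x)
}

#' @export
tidy.np_ppi <- function(x, ...) x$centrality

#' @export
glance.np_ppi <- function(x, ...) {
  cnt <- graph_counts(x$graph)
  kcnt <- if (!is.null(x$key_graph)) graph_counts(x$key_graph) else
    tibble(n_nodes = 0L, n_edges = 0L)
  tibble(
    n_nodes = cnt$n_nodes, n_edges = cnt$n_edges,
    n_components = cnt$n_components,
    n_key_targets = length(x$key_targets),
    key_subgraph_nodes = kcnt$n_nodes, key_subgraph_edges = kcnt$n_edges
  )
}

#' Export a graph to GraphML
#'
#' @param g An `np_graph` or `np_ppi` (key flags exported as a node attribute).
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_ppi_graphml <- function(g, path) {
  if (inherits(g, "np_ppi")) {
    gr <- g$graph$graph
    idx <- match(igraph::V(gr)$name, g$centrality$gene)
    igraph::V(gr)$degree <- g$centrality$degree[idx]
    igraph::V(gr)$betweenness <- g$centrality$betweenness[idx]
    igraph::V(gr)$closeness <- g$centrality$closeness[idx]
    igraph::V(gr)$is_key <- g$centrality$is_key[idx]
  } else if (inherits(g, "np_graph")) {
    gr <- g$graph
  } else {
    abort("`g` must be an np_graph or np_ppi.")
  }
  igraph::write_graph(gr, path, format = "graphml")
  invisible(path)
}
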