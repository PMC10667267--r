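#' Build the integrated compound-target-pathway network
#'
#' Tripartite network merging the expected active compounds (EAC), the key
#' targets, and the enriched pathways. Compound-target edges are the
#' compound-target map restricted to `eac x key` (optionally widened to all
#' mapped targets of the EAC); target-pathway edges link each key target to
#' every enriched pathway whose overlap genes contain it. Compounds and
#' pathways are linked only transitively through targets — the network never
#' contains intra-layer or compound-pathway edges. Compounds and pathways
#' left without any edge are retained as isolated nodes and flagged.
#'
#' @param eac Character vector of EAC compound ids.
#' @param key Character vector of key-target gene symbols.
#' @param pathways Enrichment rows (an `np_enrich` tibble, or any data frame
#'   with `term_id` and `overlap_genes` as a list column or comma-joined
#'   string).
#' @param map Compound-target map (`compound_id`, `gene`).
#' @param restrict_to_key Keep only compound-target edges whose target is a
#'   key target (default `TRUE`, matching a merge of EAC, key targets and
#'   pathways); `FALSE` keeps every mapped target of the EAC as a target-layer
#'   node.
#' @return An object of class `np_ctp` with `nodes` (node, layer, degree,
#'   isolated), `ct_edges`, `tp_edges`.
#' @export
build_ctp <- function(eac, key, pathways, map, restrict_to_key = TRUE) {
  map <- as_tibble(map)
  for (col in c("compound_id", "gene")) {
    if (!col %in% names(map)) abort(sprintf("Map lacks column '%s'.", col))
  }
  eac <- unique(as.character(eac))
  key <- normalize_symbols(key)
  pathways <- as_tibble(pathways)
  if (!all(c("term_id", "overlap_genes") %in% names(pathways))) {
    abort("`pathways` needs `term_id` and `overlap_genes` columns.")
  }
  overlap <- pathways$overlap_genes
  if (!is.list(overlap)) overlap <- strsplit(as.character(overlap), ",[ ]?")
  overlap <- purrr::map(overlap, normalize_symbols)

  map$gene <- toupper(trimws(map$gene))
  ct <- dplyr::distinct(map[map$compound_id %in% eac, c("compound_id", "gene")])
  target_nodes <- if (restrict_to_key) key else
    sort(unique(c(key, ct$gene)))
  ct <- ct[ct$gene %in% target_nodes, ]
  ct <- dplyr::arrange(ct, .data$compound_id, .data$gene)

  tp <- purrr::map2(pathways$term_id, overlap, function(id, genes) {
    hits <- sort(intersect(genes, key))
    if (length(hits)) tibble(gene = hits, term_id = id) else NULL
  })
  tp <- dplyr::bind_rows(tp)
  if (nrow(tp) == 0L) tp <- tibble(gene = character(0), term_id = character(0))
  tp <- dplyr::arrange(dplyr::distinct(tp), .data$gene, .data$term_id)

  orphan_key <- setdiff(key, c(ct$gene, tp$gene))
  if (length(orphan_key)) {
    warn(sprintf(
      "Key target(s) absent from every compound map entry and pathway: %s.",
      paste(orphan_key, collapse = ", ")
    ))
  }

  all_nodes <- tibble(
    node = c(eac, target_nodes, unique(pathways$term_id)),
    layer = c(rep("compound", length(eac)),
              rep("target", length(target_nodes)),
              rep("pathway", length(unique(pathways$term_id))))
  )
  if (anyDuplicated(all_nodes$node)) {
    dup <- unique(all_nodes$node[duplicated(all_nodes$node)])
    abort(sprintf("Node label(s) shared across layers: %s.",
                  paste(dup, collapse = ", ")))
  }
  incidence <- c(ct$compound_id, ct$gene, tp$gene, tp$term_id)
  all_nodes$degree <- as.integer(
    vapply(all_nodes$node, function(v) sum(incidence == v), integer(1))
  )
  all_nodes$isolated <- all_nodes$degree == 0L

  structure(
    list(nodes = all_nodes, ct_edges = ct,
         tp_edges = tp[, c("gene", "term_id")]),
    class = "np_ctp"
  )
}

#' @export
print.np_ctp <- function(x, ...) {
  n <- table(factor(x$nodes$layer, c("compound", "target", "pathway")))
  cat(sprintf(
    "<np_ctp> %d compounds, %d targets, %d pathways; %d C-T + %d T-P edges\n",
    n[["compound"]], n[["target"]], n[["pathway"]],
    nrow(x$ct_edges), nrow(x$tp_edges)
  ))
  invisible(x)
}

#' Ranked degree table of a tripartite network
#'
#' @param net An `np_ctp`.
#' @return Tibble (`node`, `layer`, `degree`, `isolated`) sorted by layer
#'   (compound, target, pathway) then descending degree, ties by node name.
#' @export
degree_table <- function(net) {
  stopifnot(inherits(net, "np_ctp"))
  nodes <- net$nodes
  nodes$layer <- factor(nodes$layer, c("compound", "target", "pathway"))
  dplyr::arrange(nodes, .data$layer, dplyr::desc(.data$degree), .data$node)
}

#' @export
tidy.np_ctp <- function(x, ...) degree_table(x)

#' @export
glance.np_ctp <- function(x, ...) {
  n <- table(factor(x$nodes$layer, c("compound", "target", "pathway")))
  tibble(
    n_compounds = as.integer(n[["compound"]]),
    n_targets = as.integer(n[["target"]]),
    n_pathways = as.integer(n[["pathway"]]),
    n_ct_edges = nrow(x$ct_edges),
    n_tp_edges = nrow(x$tp_edges),
    n_isolated = sum(x$nodes$isolated)
  )
}

#' Export a tripartite network to GraphML
#'
#' Node attributes: `layer`, `degree`, `isolated`. Deterministic: identical
#' networks give byte-identical files.
#'
#' @param net An `np_ctp`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ctp_graphml <- function(net, path) {
  stopifnot(inherits(net, "np_ctp"))
  nodes <- net$nodes
  g <- igraph::make_empty_graph(n = 0, directed = FALSE)
  g <- igraph::add_vertices(g, nrow(nodes), name = nodes$node,
                            layer = nodes$layer,
                            degree = nodes$degree,
                            isolated = nodes$isolated)
  edges <- rbind(
    cbind(net$ct_edges$compound_id, net$ct_edges$gene),
    cbind(net$tp_edges$gene, net$tp_edges$term_id)
  )
  if (nrow(edges)) {
    g <- igraph::add_edges(g, rbind(match(edges[, 1], nodes$node),
                                    match(edges[, 2], nodes$node)))
  }
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}
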