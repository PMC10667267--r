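test_that("graph building deduplicates, drops loops and keeps isolated query nodes", {
  g <- build_ppi(tibble::tibble(gene_a = c("A", "B", "A"),
                                gene_b = c("B", "A", "A")))
  cnt <- graph_counts(g)
  expect_equal(cnt$n_nodes, 2L)
  expect_equal(cnt$n_edges, 1L)

  g2 <- build_ppi(tibble::tibble(gene_a = c("A", "C"), gene_b = c("B", "D")),
                  restrict_to = c("A", "B", "C"))
  expect_equal(sort(g2$nodes$gene), c("A", "B", "C"))
  expect_equal(nrow(g2$edges), 1L)
  cent <- ppi_centralities(g2)
  expect_equal(cent$degree[cent$gene == "C"], 0L)
  expect_equal(cent$closeness[cent$gene == "C"], 0)
  expect_equal(cent$betweenness[cent$gene == "C"], 0)
})

test_that("edge-list parsing reports malformed rows with their line number", {
  tsv <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("gene_a\tgene_b\tscore", "A\tB\t900", "C", "D\tE\t100"), tsv)
  expect_error(read_ppi_edges(tsv), "line 3")

  writeLines(c("A\tB\t900", "D\tE\t100"), tsv)
  expect_equal(nrow(read_ppi_edges(tsv)), 2L)
  expect_equal(nrow(read_ppi_edges(tsv, score_min = 500)), 1L)

  sif <- withr::local_tempfile(fileext = ".sif")
  writeLines(c("A pp B", "B pp C"), sif)
  edges <- read_ppi_edges(sif)
  expect_equal(edges$gene_a, c("A", "B"))
  expect_equal(edges$gene_b, c("B", "C"))
  writeLines(c("A pp B", "C pp"), sif)
  expect_error(read_ppi_edges(sif), "line 2")
})

test_that("restriction matches a brute-force filter of the raw rows", {
  set.seed(99)
  rows <- tibble::tibble(
    gene_a = sample(sprintf("G%02d", 1:40), 200, replace = TRUE),
    gene_b = sample(sprintf("G%02d", 1:40), 200, replace = TRUE)
  )
  keep <- sprintf("G%02d", 1:24)
  g <- build_ppi(rows, restrict_to = keep)
  # oracle: unordered distinct non-loop pairs with both ends in the set
  pairs <- unique(paste(pmin(rows$gene_a, rows$gene_b),
                        pmax(rows$gene_a, rows$gene_b)))
  pairs <- pairs[sapply(strsplit(pairs, " "), function(p)
    p[1] != p[2] && all(p %in% keep))]
  expect_equal(graph_counts(g)$n_nodes, 24L)
  expect_equal(graph_counts(g)$n_edges, length(pairs))
})

test_that("path and star graphs have their textbook centralities", {
  path <- build_ppi(tibble::tibble(gene_a = c("A", "B"), gene_b = c("B", "C")))
  cent <- ppi_centralities(path)
  expect_equal(cent$betweenness[cent$gene == "B"], 1)
  expect_equal(cent$closeness[cent$gene == "B"], 1)
  expect_equal(cent$closeness[cent$gene == "A"], 2 / 3)

  star <- build_ppi(tibble::tibble(gene_a = rep("HUB", 4),
                                   gene_b = c("L1", "L2", "L3", "L4")))
  cent <- ppi_centralities(star)
  hub <- cent[cent$gene == "HUB", ]
  expect_equal(hub$degree, 4L)
  expect_equal(hub$betweenness, 1)
  expect_equal(hub$closeness, 1)

  # complete graph: betweenness 0, closeness 1 everywhere
  k5 <- t(utils::combn(sprintf("N%d", 1:5), 2))
  cent <- ppi_centralities(build_ppi(tibble::tibble(gene_a = k5[, 1],
                                                    gene_b = k5[, 2])))
  expect_equal(cent$betweenness, rep(0, 5))
  expect_equal(cent$closeness, rep(1, 5))
})

test_that("centralities match the exhaustive path-enumeration oracle on random graphs", {
  set.seed(2024)
  for (i in 1:25) {
    n <- sample(4:8, 1)
    adj <- random_adjacency(n, runif(1, 0.2, 0.7))  # connected or not
    got <- package_centralities(adj)
    want <- oracle_centralities(adj)
    expect_equal(got$degree, as.integer(want$degree))
    expect_equal(got$betweenness, want$betweenness, tolerance = 1e-12)
    expect_equal(got$closeness, want$closeness, tolerance = 1e-12)
    expect_equal(sum(got$degree), 2 * sum(adj) / 2)  # handshake identity
  }
})

test_that("Wasserman-Faust closeness rescales by component coverage", {
  # two components: an edge A-B and an isolated pair C-D plus singleton E
  g <- build_ppi(tibble::tibble(gene_a = c("A", "C"), gene_b = c("B", "D")),
                 restrict_to = c("A", "B", "C", "D", "E"))
  comp <- ppi_centralities(g, closeness = "component")
  wf <- ppi_centralities(g, closeness = "wasserman-faust")
  expect_equal(comp$closeness[comp$gene == "A"], 1)
  expect_equal(wf$closeness[wf$gene == "A"], 1 * (2 - 1) / (5 - 1))
  expect_equal(wf$closeness[wf$gene == "E"], 0)
})

test_that("key-target filtering is inclusive at the thresholds and monotone", {
  cent <- tibble::tibble(
    gene = c("AT", "BELOW", "ISO"),
    degree = c(4L, 3L, 0L),
    betweenness = c(0.01, 0.2, 0),
    closeness = c(0.5, 0.8, 0)
  )
  expect_equal(filter_key_targets(cent), "AT")      # exact boundary included
  expect_error(filter_key_targets(cent, deg_min = -1), "non-negative")

  # monotone in each threshold
  base <- filter_key_targets(cent, 0, 0, 0)
  expect_true(all(filter_key_targets(cent, 1, 0, 0) %in% base))
  expect_true(all(filter_key_targets(cent, 0, 0.01, 0) %in% base))
  expect_true(all(filter_key_targets(cent, 0, 0, 0.5) %in% base))
  # zero thresholds return everything, isolated nodes included iff cc_min = 0
  expect_equal(base, sort(cent$gene))
  expect_equal(filter_key_targets(cent, 0, 0, 1e-9), c("AT", "BELOW"))
})

test_that("induced subgraphs recompute rather than inherit centralities", {
  ring <- tibble::tibble(gene_a = c("A", "B", "C", "D"),
                         gene_b = c("B", "C", "D", "A"))
  g <- build_ppi(ring)
  expect_equal(graph_counts(ppi_subgraph(g, c("A", "B", "C", "D")))$n_edges, 4L)
  expect_equal(graph_counts(ppi_subgraph(g, "A"))$n_edges, 0L)
  expect_error(ppi_subgraph(g, "Z"), "Z")

  # closeness of A in the induced path B-A-... differs from the ring's
  sub <- ppi_subgraph(g, c("A", "B", "C"))
  cc_sub <- ppi_centralities(sub)
  cc_full <- ppi_centralities(g)
  expect_false(isTRUE(all.equal(
    cc_sub$closeness[cc_sub$gene == "B"],
    cc_full$closeness[cc_full$gene == "B"]
  )))

  # random keep-set: edge count equals a brute-force pair scan
  set.seed(5)
  adj <- random_adjacency(9, 0.4)
  nm <- oracle_node_names(9)
  g9 <- build_ppi(adj_to_edges(adj), restrict_to = nm)
  keep <- sample(nm, 5)
  idx <- match(keep, nm)
  expected_edges <- sum(adj[idx, idx]) / 2
  expect_equal(graph_counts(ppi_subgraph(g9, keep))$n_edges, expected_edges)
})

test_that("ppi_analyze bundles graph, centralities and key targets", {
  sim <- simulate_study(sim_config(seed = 3))
  ppi <- ppi_analyze(sim$ppi_edges, restrict_to = sim$truth$overlap)
  expect_s3_class(ppi, "np_ppi")
  expect_equal(ppi$key_targets, sim$truth$hubs)
  expect_equal(sum(tidy(ppi)$is_key), 9L)
  g <- glance(ppi)
  expect_equal(g$n_nodes, 24L)
  expect_equal(g$n_key_targets, 9L)

  gml <- withr::local_tempfile(fileext = ".graphml")
  write_ppi_graphml(ppi, gml)
  expect_true(file.exists(gml) && file.size(gml) > 0)
  expect_s3_class(autoplot(ppi), "ggplot")
})
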