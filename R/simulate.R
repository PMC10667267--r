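#' Configuration for the synthetic study generator
#'
#' Defaults emulate the scale of a single-herb network-pharmacology screen:
#' 43 isolates of which 28 are drug-like, a 447-gene predicted-target pool, a
#' 265-gene disease set sharing a planted 24-gene overlap with the pool, a
#' 24-node interactome with a planted 9-hub core, and a 66-term pathway
#' collection with one planted over-represented term.
#'
#' @param seed Integer seed; every generator stream is derived from it in a
#'   fixed order, so outputs are fully deterministic and adding a downstream
#'   generator never perturbs an earlier stream.
#' @param n_compounds Number of compounds (default 43).
#' @param frac_druglike Fraction of compounds planted as drug-like
#'   (QED >= 0.3 and Veber pass); the planted count is
#'   `round(frac_druglike * n_compounds)` (default 28/43).
#' @param universe_size Size of the gene-symbol universe (default 3000).
#' @param n_predicted_pool Size of the predicted-target pool, i.e. the union
#'   of compound targets (default 447).
#' @param n_disease_genes Disease gene-set size (default 265).
#' @param n_overlap Planted intersection size between the predicted pool and
#'   the disease set (default 24).
#' @param compound_target_rate Per-gene probability that a compound targets a
#'   pool gene (default 0.05).
#' @param n_hubs Planted hub count in the interactome (default 9).
#' @param hub_edge_prob Edge probability within the hub core (>= 0.9 so the
#'   core is clique-like; default 0.95).
#' @param background_edge_prob Edge probability for non-core pairs
#'   (<= 0.05; default 0.02).
#' @param n_pathways Number of annotation terms (default 66).
#' @param planted_term_coverage Fraction of key genes included in the planted
#'   term (default 0.8).
#' @param annotation_bg_rate Background membership rate of non-planted terms
#'   (default 0.05).
#' @param annotation_pool_size Gene pool from which annotation members are
#'   drawn, in addition to the key genes (default 600).
#' @param max_retries Bounded resampling budget wherever a planted property is
#'   verified post hoc (default 50).
#' @return A validated list of class `np_sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_compounds = 43L,
                       frac_druglike = 28 / 43,
                       universe_size = 3000L,
                       n_predicted_pool = 447L,
                       n_disease_genes = 265L,
                       n_overlap = 24L,
                       compound_target_rate = 0.05,
                       n_hubs = 9L,
                       hub_edge_prob = 0.95,
                       background_edge_prob = 0.02,
                       n_pathways = 66L,
                       planted_term_coverage = 0.8,
                       annotation_bg_rate = 0.05,
                       annotation_pool_size = 600L,
                       max_retries = 50L) {
  cfg <- list(
    seed = as.integer(seed), n_compounds = as.integer(n_compounds),
    frac_druglike = frac_druglike, universe_size = as.integer(universe_size),
    n_predicted_pool = as.integer(n_predicted_pool),
    n_disease_genes = as.integer(n_disease_genes),
    n_overlap = as.integer(n_overlap),
    compound_target_rate = compound_target_rate,
    n_hubs = as.integer(n_hubs), hub_edge_prob = hub_edge_prob,
    background_edge_prob = background_edge_prob,
    n_pathways = as.integer(n_pathways),
    planted_term_coverage = planted_term_coverage,
    annotation_bg_rate = annotation_bg_rate,
    annotation_pool_size = as.integer(annotation_pool_size),
    max_retries = as.integer(max_retries)
  )
  probs <- c("frac_druglike", "compound_target_rate", "hub_edge_prob",
             "background_edge_prob", "planted_term_coverage",
             "annotation_bg_rate")
  for (p in probs) {
    if (cfg[[p]] < 0 || cfg[[p]] > 1) {
      abort(sprintf("`%s` must lie in [0, 1].", p))
    }
  }
  if (cfg$hub_edge_prob <= cfg$background_edge_prob) {
    abort("`hub_edge_prob` must exceed `background_edge_prob`.")
  }
  if (cfg$n_overlap > min(cfg$n_predicted_pool, cfg$n_disease_genes)) {
    abort("`n_overlap` cannot exceed the predicted pool or the disease set.")
  }
  if (cfg$n_predicted_pool + (cfg$n_disease_genes - cfg$n_overlap) >
      cfg$universe_size) {
    abort("Universe too small for the requested pool and disease-set sizes.")
  }
  if (cfg$n_hubs > cfg$n_overlap) {
    abort("`n_hubs` cannot exceed the planted overlap (the interactome nodes).")
  }
  structure(cfg, class = "np_sim_config")
}

# fixed-order stream seeds derived from the master seed; stream indices:
# 1 compounds, 2 target layers, 3 interactome, 4 annotations
stream_seed <- function(cfg, stream) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()) else
            suppressWarnings(rm(".Random.seed", envir = globalenv())))
  set.seed(cfg$seed)
  sample.int(.Machine$integer.max, 8L)[[stream]]
}

with_stream <- function(cfg, stream, code) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()) else
            suppressWarnings(rm(".Random.seed", envir = globalenv())))
  set.seed(stream_seed(cfg, stream))
  force(code)
}

gene_universe <- function(cfg) sprintf("G%04d", seq_len(cfg$universe_size))

#' Generate a synthetic compound descriptor table
#'
#' Descriptors are sampled stratified by the planted verdict: drug-like
#' compounds draw from drug-like ranges (MW 250-450, ALOGP 1-3.5, HBA 2-6,
#' HBD 0-3, TPSA 40-120, ROTB 0-8, AROM 1-3, ALERTS 0); non-drug-like
#' compounds violate at least one criterion by construction (rotatable bonds
#' 11-20, TPSA 141-200, or a bulky high-alert profile pushing QED below 0.3).
#' Each compound's computed verdict is checked against its planted one and
#' resampled (bounded) on mismatch, so the planted drug-like count —
#' `round(frac_druglike * n_compounds)` — is recovered exactly by
#' [screen_compounds()] for every seed.
#'
#' @param cfg An `np_sim_config`.
#' @return Tibble with `compound_id`, `name`, the eight descriptor columns,
#'   and the planted verdict in `planted_druglike`.
#' @export
gen_compounds <- function(cfg) {
  stopifnot(inherits(cfg, "np_sim_config"))
  with_stream(cfg, 1L, {
    n <- cfg$n_compounds
    n_dl <- round(cfg$frac_druglike * n)
    planted <- sample(rep(c(TRUE, FALSE), c(n_dl, n - n_dl)))
    draw_one <- function(druglike) {
      for (i in seq_len(cfg$max_retries)) {
        d <- if (druglike) {
          tibble(MW = runif(1, 250, 450), ALOGP = runif(1, 1, 3.5),
                 HBA = sample(2:6, 1), HBD = sample(0:3, 1),
                 TPSA = runif(1, 40, 120), ROTB = sample(0:8, 1),
                 AROM = sample(1:3, 1), ALERTS = 0L)
        } else {
          mode <- sample(c("rotb", "tpsa", "bulky"), 1)
          switch(mode,
            rotb = tibble(MW = runif(1, 250, 450), ALOGP = runif(1, 1, 3.5),
                          HBA = sample(2:6, 1), HBD = sample(0:3, 1),
                          TPSA = runif(1, 40, 120), ROTB = sample(11:20, 1),
                          AROM = sample(1:3, 1), ALERTS = 0L),
            tpsa = tibble(MW = runif(1, 250, 450), ALOGP = runif(1, 1, 3.5),
                          HBA = sample(6:12, 1), HBD = sample(2:6, 1),
                          TPSA = runif(1, 141, 200), ROTB = sample(0:8, 1),
                          AROM = sample(1:3, 1), ALERTS = 0L),
            bulky = tibble(MW = runif(1, 650, 900), ALOGP = runif(1, 5.5, 7.5),
                           HBA = sample(10:14, 1), HBD = sample(6:9, 1),
                           TPSA = runif(1, 80, 140), ROTB = sample(0:10, 1),
                           AROM = sample(5:7, 1), ALERTS = sample(3:6, 1))
          )
        }
        verdict <- qed_score(d$MW, d$ALOGP, d$HBA, d$HBD, d$TPSA, d$ROTB,
                             d$AROM, d$ALERTS) >= 0.3 &&
          veber_pass(d$ROTB, d$TPSA)
        if (verdict == druglike) return(d)
      }
      abort("Could not realise the planted screening verdict within the retry budget.")
    }
    rows <- dplyr::bind_rows(lapply(planted, draw_one))
    dplyr::bind_cols(
      tibble(compound_id = sprintf("CPD%03d", seq_len(n)),
             name = sprintf("synthetic-compound-%03d", seq_len(n))),
      rows,
      tibble(planted_druglike = planted)
    )
  })
}

#' Generate compound-target map and disease gene set with a planted overlap
#'
#' Compound targets are drawn per compound from a fixed predicted pool at
#' `compound_target_rate`; coverage is topped up through the planted drug-like
#' compounds so the union of their targets equals the full pool. The disease
#' set takes `n_overlap` genes from the pool and the remainder from outside
#' it, so the intersection of the drug-like compounds' target union with the
#' disease set is exactly the planted overlap.
#'
#' @param cfg An `np_sim_config`.
#' @param compounds Output of [gen_compounds()] (needs `compound_id` and
#'   `planted_druglike`).
#' @return List with `map` (tibble `compound_id`, `gene`), `disease`
#'   (character), `overlap` (character, the planted intersection), `pool`
#'   (character).
#' @export
gen_target_layers <- function(cfg, compounds) {
  stopifnot(inherits(cfg, "np_sim_config"))
  for (col in c("compound_id", "planted_druglike")) {
    if (!col %in% names(compounds)) {
      abort(sprintf("`compounds` lacks column '%s'.", col))
    }
  }
  with_stream(cfg, 2L, {
    universe <- gene_universe(cfg)
    pool <- sort(sample(universe, cfg$n_predicted_pool))
    ids <- compounds$compound_id
    eac_ids <- ids[compounds$planted_druglike]
    per_compound <- lapply(ids, function(id) {
      hits <- pool[runif(length(pool)) < cfg$compound_target_rate]
      if (!length(hits)) hits <- sample(pool, 1)
      tibble(compound_id = id, gene = hits)
    })
    map <- dplyr::bind_rows(per_compound)
    if (length(eac_ids)) {
      covered <- unique(map$gene[map$compound_id %in% eac_ids])
      gaps <- setdiff(pool, covered)
      if (length(gaps)) {
        map <- dplyr::bind_rows(map, tibble(
          compound_id = sample(eac_ids, length(gaps), replace = TRUE),
          gene = gaps
        ))
      }
    }
    map <- dplyr::arrange(dplyr::distinct(map), .data$compound_id, .data$gene)
    overlap <- sort(sample(pool, cfg$n_overlap))
    outside <- setdiff(universe, pool)
    disease <- sort(c(overlap,
                      sample(outside, cfg$n_disease_genes - cfg$n_overlap)))
    list(map = map, disease = disease, overlap = overlap, pool = pool)
  })
}

#' Generate an interactome with a planted hub module
#'
#' The first `n_hubs` of the potential-target genes (randomly chosen) form a
#' clique-like core (pairwise edge probability `hub_edge_prob`); every
#' non-hub is pinned to one home hub (round-robin) and further background
#' edges among non-core pairs appear at `background_edge_prob`. The planted
#' separation — exactly the hubs satisfy degree >= 4, betweenness >= 0.01 and
#' closeness >= 0.5 — is verified post hoc and the instance resampled
#' (bounded by `max_retries`) until it holds, because the centrality
#' thresholds are global properties no local rule can guarantee.
#'
#' @param cfg An `np_sim_config`.
#' @param potential Character vector of node gene symbols (the potential
#'   targets).
#' @return List with `edges` (tibble `gene_a`, `gene_b`) and `hubs`
#'   (character).
#' @export
gen_interactome <- function(cfg, potential) {
  stopifnot(inherits(cfg, "np_sim_config"))
  potential <- normalize_symbols(potential)
  if (cfg$n_hubs < 1L) abort("`n_hubs` must be at least 1 to plant a module.")
  if (cfg$n_hubs > length(potential)) {
    abort("`n_hubs` exceeds the number of potential targets.")
  }
  with_stream(cfg, 3L, {
    hubs <- sort(sample(potential, cfg$n_hubs))
    sats <- setdiff(potential, hubs)
    for (attempt in seq_len(cfg$max_retries)) {
      edges <- list()
      if (length(hubs) >= 2L) {
        hp <- t(utils::combn(hubs, 2))
        keep <- runif(nrow(hp)) < cfg$hub_edge_prob
        edges$core <- tibble(gene_a = hp[keep, 1], gene_b = hp[keep, 2])
      }
      if (length(sats)) {
        home <- rep_len(hubs, length(sats))
        edges$spokes <- tibble(gene_a = sats, gene_b = home)
        # background noise among satellite-satellite / satellite-non-home-hub
        others <- t(utils::combn(potential, 2))
        is_core <- others[, 1] %in% hubs & others[, 2] %in% hubs
        is_spoke <- paste(pmin(others[, 1], others[, 2]),
                          pmax(others[, 1], others[, 2])) %in%
          paste(pmin(sats, home), pmax(sats, home))
        cand <- others[!is_core & !is_spoke, , drop = FALSE]
        keep <- runif(nrow(cand)) < cfg$background_edge_prob
        edges$background <- tibble(gene_a = cand[keep, 1],
                                   gene_b = cand[keep, 2])
      }
      edge_tbl <- dplyr::bind_rows(edges)
      g <- build_ppi(edge_tbl, restrict_to = potential)
      if (length(sats) == 0L) {
        # no non-hubs: the separation contract is vacuous; all nodes are hubs
        return(list(edges = g$edges, hubs = hubs))
      }
      found <- filter_key_targets(ppi_centralities(g))
      if (identical(found, hubs)) {
        return(list(edges = g$edges, hubs = hubs))
      }
    }
    abort(sprintf(
      paste("Planted hub separation not achieved in %d attempts;",
            "last attempt recovered %d of %d hubs (plus %d false positives).",
            "Consider a denser core or sparser background."),
      cfg$max_retries, length(intersect(found, hubs)), length(hubs),
      length(setdiff(found, hubs))
    ))
  })
}

#' Generate an annotation collection with one planted enriched term
#'
#' One planted term contains `ceiling(planted_term_coverage * |key|)` key
#' genes plus background members; the remaining terms draw members at
#' `annotation_bg_rate` from a gene pool that includes the key genes, so
#' chance overlaps occur at a realistic rate. [enrich()] ranks the planted
#' term first with high probability at the defaults.
#'
#' @param cfg An `np_sim_config`.
#' @param key Character vector of key-target gene symbols.
#' @return List with `terms` (long tibble `term_id`, `term_name`, `category`,
#'   `gene`) and `planted_term` (the planted term id).
#' @export
gen_annotations <- function(cfg, key) {
  stopifnot(inherits(cfg, "np_sim_config"))
  key <- normalize_symbols(key)
  k_plant <- ceiling(cfg$planted_term_coverage * length(key))
  if (k_plant < 2L) {
    abort("`planted_term_coverage` times the key-set size must be >= 2.")
  }
  with_stream(cfg, 4L, {
    universe <- gene_universe(cfg)
    bg_pool <- sort(unique(c(key, sample(universe, cfg$annotation_pool_size))))
    ids <- sprintf("PW%04d", seq_len(cfg$n_pathways))
    planted_id <- sample(ids, 1)
    rows <- lapply(ids, function(id) {
      if (id == planted_id) {
        members <- c(sample(key, k_plant),
                     sample(setdiff(bg_pool, key),
                            max(1L, round(cfg$annotation_bg_rate *
                                            cfg$annotation_pool_size))))
      } else {
        members <- bg_pool[runif(length(bg_pool)) < cfg$annotation_bg_rate]
        if (!length(members)) members <- sample(bg_pool, 1)
      }
      tibble(term_id = id,
             term_name = if (id == planted_id) "planted signaling pathway" else
               sprintf("background pathway %s", sub("PW", "", id)),
             category = "KEGG",
             gene = sort(unique(members)))
    })
    list(terms = dplyr::bind_rows(rows), planted_term = planted_id)
  })
}

#' Generate a complete synthetic study
#'
#' Runs all four generators in order and, when `dir` is given, writes the five
#' pipeline inputs (`compounds.tsv`, `compound_targets.tsv`,
#' `disease_genes.txt`, `ppi_edges.tsv`, `pathways.gmt`) plus `truth.json`
#' recording the planted EAC ids, overlap genes, hub genes and planted term.
#' Fully deterministic: the same config (including seed) yields byte-identical
#' files.
#'
#' @param cfg An `np_sim_config`; default `sim_config()`.
#' @param dir Optional output directory (created if missing).
#' @return List with `compounds`, `map`, `disease`, `ppi_edges`, `annotations`
#'   (long tibble), and `truth` (list of planted structures); `paths` is added
#'   when `dir` is given.
#' @export
simulate_study <- function(cfg = sim_config(), dir = NULL) {
  stopifnot(inherits(cfg, "np_sim_config"))
  compounds <- gen_compounds(cfg)
  layers <- gen_target_layers(cfg, compounds)
  interactome <- gen_interactome(cfg, layers$overlap)
  annotations <- gen_annotations(cfg, interactome$hubs)
  truth <- list(
    eac = compounds$compound_id[compounds$planted_druglike],
    overlap = layers$overlap,
    hubs = interactome$hubs,
    planted_term = annotations$planted_term
  )
  out <- list(
    compounds = compounds, map = layers$map, disease = layers$disease,
    ppi_edges = interactome$edges, annotations = annotations$terms,
    truth = truth
  )
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    paths <- list(
      compounds = file.path(dir, "compounds.tsv"),
      compound_targets = file.path(dir, "compound_targets.tsv"),
      disease_genes = file.path(dir, "disease_genes.txt"),
      ppi_edges = file.path(dir, "ppi_edges.tsv"),
      pathways = file.path(dir, "pathways.gmt"),
      truth = file.path(dir, "truth.json")
    )
    readr::write_tsv(compounds[setdiff(names(compounds), "planted_druglike")],
                     paths$compounds, progress = FALSE)
    readr::write_tsv(layers$map, paths$compound_targets, progress = FALSE)
    readr::write_lines(layers$disease, paths$disease_genes)
    readr::write_tsv(interactome$edges, paths$ppi_edges, progress = FALSE)
    write_gmt(annotations$terms, paths$pathways)
    jsonlite::write_json(truth, paths$truth, auto_unbox = FALSE, pretty = TRUE)
    out$paths <- paths
  }
  out
}
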