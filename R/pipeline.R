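#' Run the full screening pipeline
#'
#' Executes the stages in order — compound screening, target union and
#' intersection, PPI topology and key-target selection, pathway
#' over-representation, integrated compound-target-pathway network — writing
#' every stage's table to `out_dir` plus a `manifest.json` recording the
#' configuration, input checksums, per-stage row counts and output checksums.
#' The pipeline is a pure function of (inputs, config): re-running on
#' identical inputs reproduces identical outputs (verifiable through the
#' manifest checksums).
#'
#' @param config A named list, or path to a YAML/JSON file, with fields:
#'   `compounds`, `compound_targets`, `disease_genes`, `ppi_edges`,
#'   `pathways` (input paths); `out_dir`; and optional overrides `qed_cutoff`
#'   (0.3), `qed_mode` ("weighted"), `score_min` (0, compound-target map),
#'   `ppi_score_min` (NULL), `deg_min` (4), `bc_min` (0.01), `cc_min` (0.5),
#'   `stat` ("ease"), `top_k` (20).
#' @param ... Individual fields overriding `config` entries.
#' @return The manifest, invisibly, with the stage results attached as
#'   `results`.
#' @examples
#' \donttest{
#' sim <- simulate_study(sim_config(seed = 7), dir = tempfile("sim"))
#' manifest <- run_pipeline(c(sim$paths[1:5], out_dir = tempfile("run")))
#' manifest$stages$ppi
#' }
#' @export
run_pipeline <- function(config = list(), ...) {
  if (is.character(config) && length(config) == 1L) {
    config <- read_run_config(config)
  }
  config <- utils::modifyList(as.list(config), list(...))
  defaults <- list(qed_cutoff = 0.3, qed_mode = "weighted", score_min = 0,
                   ppi_score_min = NULL, deg_min = 4, bc_min = 0.01,
                   cc_min = 0.5, stat = "ease", top_k = 20)
  config <- utils::modifyList(defaults, config)
  for (field in c("compounds", "compound_targets", "disease_genes",
                  "ppi_edges", "pathways", "out_dir")) {
    if (is.null(config[[field]])) {
      abort(sprintf("Pipeline config lacks required field '%s'.", field))
    }
  }
  out_dir <- config$out_dir
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(sprintf("Pipeline stage '%s' failed: %s", name,
                    conditionMessage(e)))
    })
  }
  results <- list()
  counts <- list()

  # 1. screening
  results$screen <- stage("screen", {
    screened <- screen_compounds(read_compounds(config$compounds),
                                 qed_cutoff = config$qed_cutoff,
                                 qed_mode = config$qed_mode)
    readr::write_tsv(tidy(screened), file.path(out_dir, "screened_compounds.tsv"),
                     progress = FALSE)
    screened
  })
  eac <- results$screen$compound_id[results$screen$is_eac]
  counts$screen <- list(n_compounds = nrow(results$screen),
                        n_eac = length(eac))
  message(sprintf("[screen] %d compounds in, %d EAC selected",
                  nrow(results$screen), length(eac)))

  # 2. target intersection
  results$targets <- stage("intersect", {
    map <- read_compound_targets(config$compound_targets,
                                 score_min = config$score_min)
    disease <- read_gene_list(config$disease_genes)
    predicted <- union_targets(map, intersect(eac, unique(map$compound_id)))
    potential <- suppressWarnings(intersect_targets(predicted, disease))
    venn <- venn_counts(predicted, disease)
    readr::write_lines(potential, file.path(out_dir, "potential_targets.txt"))
    jsonlite::write_json(as.list(venn), file.path(out_dir, "venn_counts.json"),
                         auto_unbox = TRUE)
    list(map = map, predicted = predicted, disease = disease,
         potential = potential, venn = venn)
  })
  counts$intersect <- list(n_predicted = length(results$targets$predicted),
                           n_disease = length(results$targets$disease),
                           n_potential = length(results$targets$potential))
  message(sprintf("[intersect] %d predicted vs %d disease genes -> %d potential",
                  length(results$targets$predicted),
                  length(results$targets$disease),
                  length(results$targets$potential)))

  # 3. PPI topology
  results$ppi <- stage("ppi", {
    edges <- read_ppi_edges(config$ppi_edges,
                            score_min = config$ppi_score_min)
    ppi <- ppi_analyze(edges, restrict_to = results$targets$potential,
                       deg_min = config$deg_min, bc_min = config$bc_min,
                       cc_min = config$cc_min)
    readr::write_tsv(tidy(ppi), file.path(out_dir, "ppi_nodes.tsv"),
                     progress = FALSE)
    readr::write_lines(ppi$key_targets, file.path(out_dir, "key_targets.txt"))
    write_ppi_graphml(ppi, file.path(out_dir, "ppi.graphml"))
    ppi
  })
  gsum <- glance(results$ppi)
  counts$ppi <- as.list(gsum)
  message(sprintf("[ppi] %d nodes, %d edges; %d key targets (%d nodes/%d edges)",
                  gsum$n_nodes, gsum$n_edges, gsum$n_key_targets,
                  gsum$key_subgraph_nodes, gsum$key_subgraph_edges))

  # 4. enrichment
  results$enrichment <- stage("enrich", {
    enr <- enrich(results$ppi$key_targets, config$pathways,
                  stat = config$stat, top_k = config$top_k)
    write_enrichment(enr, file.path(out_dir, "enrichment.tsv"))
    enr
  })
  counts$enrich <- list(n_terms = nrow(results$enrichment))
  message(sprintf("[enrich] %d terms reported (top %d, %s statistic)",
                  nrow(results$enrichment), config$top_k, config$stat))

  # 5. integrated network
  results$ctp <- stage("ctp", {
    net <- build_ctp(eac, results$ppi$key_targets, results$enrichment,
                     results$targets$map)
    readr::write_tsv(degree_table(net), file.path(out_dir, "ctp_degree.tsv"),
                     progress = FALSE)
    write_ctp_graphml(net, file.path(out_dir, "ctp.graphml"))
    net
  })
  counts$ctp <- as.list(glance(results$ctp))
  message(sprintf("[ctp] %d C-T and %d T-P edges",
                  nrow(results$ctp$ct_edges), nrow(results$ctp$tp_edges)))

  inputs <- unlist(config[c("compounds", "compound_targets", "disease_genes",
                            "ppi_edges", "pathways")])
  outputs <- list.files(out_dir, full.names = TRUE)
  outputs <- outputs[basename(outputs) != "manifest.json"]
  manifest <- list(
    tool = "netpharm",
    version = as.character(utils::packageVersion("netpharm")),
    config = config[setdiff(names(config), "out_dir")],
    input_md5 = as.list(tools::md5sum(inputs)),
    output_md5 = as.list(tools::md5sum(sort(outputs))),
    stages = counts
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, null = "null")
  manifest$results <- results
  invisible(manifest)
}

read_run_config <- function(path) {
  if (!file.exists(path)) abort(sprintf("Config file not found: '%s'.", path))
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
}
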