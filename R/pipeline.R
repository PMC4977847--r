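# End-to-end orchestration: hybridize -> screen -> (validate) -> network ->
# enrich -> (tissues), with per-stage TSV outputs, a run log and a
# machine-readable summary. Outputs are deterministic for a fixed
# configuration: rerunning the same config gives byte-identical files.

stage_wrap <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    stop("stage ", stage, ": ", conditionMessage(e), call. = FALSE)
  })
}

#' Run the full analysis pipeline
#'
#' Executes every stage in order, writing per-stage TSVs, `config.yaml`,
#' `run_log.txt` and `summary.json` into `out_dir`.
#'
#' @param cfg A [pipeline_config()].
#' @param out_dir Output directory (created if missing).
#' @return The summary as a named list, invisibly; side effect: the run
#'   directory.
#' @export
run_pipeline <- function(cfg, out_dir) {
  stopifnot(inherits(cfg, "pipeline_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_lines <- character(0)
  say <- function(...) log_lines <<- c(log_lines, paste0(...))

  must_exist <- function(stage, path) {
    if (!is.null(path) && !file.exists(path)) {
      stop("stage ", stage, ": input file not found: ", path, call. = FALSE)
    }
  }
  must_exist("hybridize", cfg$mirnas)
  must_exist("hybridize", cfg$targets)
  must_exist("network", cfg$edges)
  must_exist("enrich", cfg$ontology)
  must_exist("enrich", cfg$annotations)
  must_exist("enrich", cfg$slim)
  must_exist("tissues", cfg$expression)
  must_exist("validate", cfg$validated)

  model <- energy_model()
  prof <- filter_profile(cfg$profile, mfe_max = cfg$mfe_max,
                         p_max = cfg$p_max)

  # -- hybridize ------------------------------------------------------------
  hyb <- stage_wrap("hybridize", {
    mirnas <- read_fasta(cfg$mirnas)[, c("id", "seq")]
    targets <- read_fasta(cfg$targets, default_region = "UTR3")
    regions <- tibble(gene_id = targets$id, accession = targets$id,
                      region = targets$region, seq = targets$seq)
    hits <- predict_targets(mirnas, regions, model,
                            width = cfg$width, stride = cfg$stride)
    calibs <- calibrate_nulls(mirnas, regions, model,
                              n_shuffles = cfg$n_shuffles, seed = cfg$seed,
                              width = cfg$width,
                              windows_per_shuffle = cfg$windows_per_shuffle)
    hits <- add_pvalues(hits, calibs)
    list(mirnas = mirnas, regions = regions, hits = hits, calibs = calibs)
  })
  write_tsv_dot(hyb$hits, file.path(out_dir, "primary_hits.tsv"))
  say("hybridize: ", nrow(hyb$hits), " primary hits from ",
      nrow(hyb$mirnas), " miRNAs x ", nrow(hyb$regions), " regions")

  # -- screen ---------------------------------------------------------------
  refined <- stage_wrap("screen", {
    rank_targets(apply_filters(hyb$hits, prof))
  })
  write_tsv_dot(refined, file.path(out_dir, "refined_hits.tsv"))
  say("screen: ", nrow(refined), " refined hits (profile ", prof$species, ")")

  # -- validate -------------------------------------------------------------
  val_summary <- NULL
  if (!is.null(cfg$validated)) {
    records <- stage_wrap("validate", {
      validated <- read_tsv_dot(cfg$validated)
      validate_three_level(validated, hyb$regions, hyb$hits, refined)
    })
    write_tsv_dot(records, file.path(out_dir, "validation.tsv"))
    val_summary <- validation_summary(records)
    say("validate: ", val_summary$n_validated, " validated targets, ",
        val_summary$n_in_top50, " in per-miRNA top 50")
  }

  # -- network --------------------------------------------------------------
  net <- stage_wrap("network", {
    graph <- build_graph(cfg$edges)
    weights <- pagerank_weights(graph, mode = cfg$mode, tol = cfg$tol)
    bridges <- select_bridges(weights, graph, k = cfg$k_bridges)
    modules <- decompose_modules(graph, bridges)
    list(graph = graph, weights = weights, bridges = bridges,
         modules = modules)
  })
  write_tsv_dot(tidy(net$weights), file.path(out_dir, "node_weights.tsv"))
  write_tsv_dot(module_membership(net$modules),
                file.path(out_dir, "modules.tsv"))
  gl <- glance(net$weights)
  say("network: ", igraph::vcount(net$graph), " nodes, ",
      igraph::ecount(net$graph), " edges; weights converged in ",
      gl$iteration_count, " iterations (perturbation ",
      signif(gl$final_perturbation, 3), "); ",
      length(net$bridges), " bridges -> ", nrow(net$modules), " modules")

  # -- enrich ---------------------------------------------------------------
  enr <- stage_wrap("enrich", {
    terms <- read_ontology(cfg$ontology)
    ann <- go_annotation(terms, read_annotations(cfg$annotations))
    background <- igraph::V(net$graph)$name
    res <- enrich_modules(net$modules, ann, background,
                          alpha = cfg$alpha, propagate = cfg$propagate)
    slim_list <- if (!is.null(cfg$slim)) readLines(cfg$slim) else character(0)
    slim_map <- if (length(slim_list) > 0 && nrow(res) > 0) {
      map_to_slim(unique(res$term_id), slim_list, ann)
    } else {
      tibble(term_id = character(), slim_id = character())
    }
    sim <- NULL
    if (nrow(res) > 0 && length(slim_list) > 0) {
      cats <- dplyr::left_join(res[, c("module_id", "term_id")], slim_map,
                               by = "term_id")
      by_mod <- split(cats$slim_id, cats$module_id)
      ids <- names(by_mod)
      if (length(ids) >= 2) {
        combo <- utils::combn(ids, 2)
        sim <- purrr::map_dfr(seq_len(ncol(combo)), function(j) {
          dplyr::bind_cols(
            tibble(module_a = as.integer(combo[1, j]),
                   module_b = as.integer(combo[2, j])),
            functional_similarity(by_mod[[combo[1, j]]],
                                  by_mod[[combo[2, j]]])
          )
        })
      }
    }
    list(results = res, slim_map = slim_map, similarity = sim)
  })
  write_tsv_dot(enr$results, file.path(out_dir, "enrichment.tsv"))
  write_tsv_dot(enr$slim_map, file.path(out_dir, "slim_mapping.tsv"))
  if (!is.null(enr$similarity)) {
    write_tsv_dot(enr$similarity, file.path(out_dir, "module_similarity.tsv"))
  }
  say("enrich: ", nrow(enr$results), " enriched terms at adjusted-p < ",
      cfg$alpha, " across ", nrow(net$modules), " modules")

  # -- tissues --------------------------------------------------------------
  tissues <- NULL
  if (!is.null(cfg$expression)) {
    tissues <- stage_wrap("tissues", {
      classify_tissue_levels(read_tsv_dot(cfg$expression))
    })
    write_tsv_dot(tissues, file.path(out_dir, "tissue_levels.tsv"))
    say("tissues: ", sum(tissues$level == "ubiquitous"), " ubiquitous, ",
        sum(tissues$level == "highly_expressed"), " highly expressed, ",
        sum(tissues$level == "tissue_specific"), " tissue-specific genes")
  }

  # -- provenance + summary -------------------------------------------------
  yaml::write_yaml(unclass(cfg), file.path(out_dir, "config.yaml"))
  summary <- list(
    n_mirnas = nrow(hyb$mirnas),
    n_regions = nrow(hyb$regions),
    n_primary_hits = nrow(hyb$hits),
    n_refined_hits = nrow(refined),
    n_nodes = igraph::vcount(net$graph),
    n_edges = igraph::ecount(net$graph),
    n_bridges = length(net$bridges),
    n_modules = nrow(net$modules),
    n_module_genes = sum(net$modules$size),
    n_enriched_terms = nrow(enr$results)
  )
  if (!is.null(val_summary)) {
    summary$n_validated <- val_summary$n_validated
    summary$n_in_top50 <- val_summary$n_in_top50
    summary$frac_top50 <- val_summary$frac_top50
  }
  if (!is.null(tissues)) {
    summary$n_ubiquitous <- sum(tissues$level == "ubiquitous")
    summary$n_highly_expressed <- sum(tissues$level == "highly_expressed")
    summary$n_tissue_specific <- sum(tissues$level == "tissue_specific")
  }
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  writeLines(log_lines, file.path(out_dir, "run_log.txt"))
  invisible(summary)
}

#' Write a complete synthetic input set to disk
#'
#' Generates every pipeline input (miRNA FASTA, tagged transcript FASTA,
#' edge list, flat ontology, annotations, slim list, expression matrix, a
#' validated-target list derived from the clean planted sites) plus the
#' truth tables for scoring.
#'
#' @param cfg A [synth_config()].
#' @param out_dir Output directory (created if missing).
#' @return Named list of file paths (inputs and truth tables), invisibly.
#' @export
synth_all <- function(cfg, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(out_dir, f)

  mirnas <- gen_mirnas(cfg)
  tr <- gen_transcripts_with_sites(cfg, mirnas)
  net <- gen_network(cfg)
  ann <- gen_annotations(cfg, net)
  genes <- c(net$truth$gene, net$bridges)
  ex <- gen_expression(cfg, genes)

  write_fasta(mirnas, p("mirnas.fa"))
  write_fasta(tr$regions[, c("gene_id", "region", "seq")] |>
                dplyr::rename(id = "gene_id"), p("transcripts.fa"))
  write_tsv_dot(tr$truth, p("truth_sites.tsv"))
  clean <- tr$truth[tr$truth$corruption == "none", ]
  write_tsv_dot(clean[, c("mirna_id", "gene_id", "region")],
                p("validated.tsv"))
  write_tsv_dot(net$edges, p("edges.tsv"))
  write_tsv_dot(tibble(gene = c(net$truth$gene, net$bridges),
                       module = c(net$truth$module,
                                  rep(NA_integer_, length(net$bridges))),
                       is_bridge = c(rep(FALSE, nrow(net$truth)),
                                     rep(TRUE, length(net$bridges)))),
                p("truth_network.tsv"))
  write_ontology(ann$annotation$terms, p("ontology.tsv"))
  write_tsv_dot(ann$annotation$mapping, p("annotations.tsv"))
  writeLines(ann$slim, p("slim.txt"))
  write_tsv_dot(ann$truth, p("truth_terms.tsv"))
  write_tsv_dot(ex$expr, p("expression.tsv"))
  write_tsv_dot(ex$truth, p("truth_expression.tsv"))

  invisible(list(
    mirnas = p("mirnas.fa"), targets = p("transcripts.fa"),
    edges = p("edges.tsv"), ontology = p("ontology.tsv"),
    annotations = p("annotations.tsv"), slim = p("slim.txt"),
    expression = p("expression.tsv"), validated = p("validated.tsv"),
    truth_sites = p("truth_sites.tsv"),
    truth_network = p("truth_network.tsv"),
    truth_terms = p("truth_terms.tsv"),
    truth_expression = p("truth_expression.tsv")
  ))
}
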