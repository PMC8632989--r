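# Config-driven end-to-end runner: reads (or generates) the inputs, builds
# both networks, computes phenotypic and molecular diversity, and runs the
# comparative statistics in sequence, logging counts per stage and
# collecting everything into a results bundle with provenance.

#' Validate a pipeline configuration
#'
#' Accepts a YAML/JSON file path or a list. Either `synthetic: true` (with
#' optional `synthetic_config` fields) or explicit input paths
#' (`associations`, `term_mapping`, `cluster_records`, `interactome`;
#' optionally `drug_targets`, `gene_sets`, `categories`, `drop_list`,
#' `disease_associations`). All validation problems are reported at once.
#'
#' @param config path to a config file, or a list.
#' @return validated config list (class `pipeline_config`) with defaults
#'   filled in.
#' @export
validate_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    config <- yaml::read_yaml(config)
  }
  stopifnot(is.list(config))
  defaults <- list(synthetic = FALSE, score_threshold = 700,
                   include_chief = TRUE, n_perm = 1000, seed = 1,
                   p_threshold = 0.05, min_cooccurrence = 15,
                   high_value_threshold = 250, semantic_type = "T184",
                   focal_symptom = NULL, output_dir = NULL,
                   n_row_clusters = 5, n_col_clusters = 8)
  for (nm in names(defaults)) {
    if (is.null(config[[nm]])) config[[nm]] <- defaults[[nm]]
  }
  problems <- character(0)
  if (isTRUE(config$synthetic)) {
    sc_args <- config$synthetic_config %||% list()
    sc_args$seed <- sc_args$seed %||% config$seed
    config$synthetic_config <- tryCatch(
      do.call(synthetic_config, sc_args),
      error = function(e) { problems <<- c(problems, conditionMessage(e)); NULL })
  } else {
    required <- c("associations", "term_mapping", "cluster_records",
                  "interactome")
    for (nm in required) {
      if (is.null(config[[nm]])) {
        problems <- c(problems, sprintf("missing required input path: %s", nm))
      }
    }
    for (nm in c(required, "drug_targets", "gene_sets", "categories",
                 "drop_list", "disease_associations")) {
      p <- config[[nm]]
      if (!is.null(p) && !file.exists(p)) {
        problems <- c(problems, sprintf("input path does not exist: %s = %s",
                                        nm, p))
      }
    }
  }
  if (config$n_perm < 1) problems <- c(problems, "n_perm must be >= 1")
  if (config$p_threshold <= 0 || config$p_threshold > 1) {
    problems <- c(problems, "p_threshold must lie in (0, 1]")
  }
  if (length(problems)) {
    stop(paste(c("invalid pipeline config:", paste(" -", problems)),
               collapse = "\n"), call. = FALSE)
  }
  class(config) <- "pipeline_config"
  config
}

run_stage <- function(bundle, name, expr) {
  res <- tryCatch(list(status = "ok", value = expr),
                  error = function(e) {
                    message(sprintf("stage %s FAILED: %s", name,
                                    conditionMessage(e)))
                    list(status = paste("failed:", conditionMessage(e)),
                         value = NULL)
                  })
  bundle$stages[[name]] <- res$status
  bundle[[name]] <- res$value
  bundle
}

#' Run the full network-diversity pipeline
#'
#' Executes, in order: input reading/filtering, term mapping, symptom
#' co-occurrence network construction, phenotypic diversity (PD/PE),
#' interactome construction and diversity, molecular diversity (MGD/MGE)
#' per symptom, diversity correlations, shared-gene pair enumeration and
#' the degree-preserving randomization test, pair-versus-single
#' comparisons with high-value proportions, an optional second phenotype
#' class (disease) comparison, drug-target proximity and its
#' correlations, and the focal-symptom case study (pair selection,
#' enrichment, overlap, clustering, subnetwork). Stages with missing
#' optional inputs are marked skipped; a failing stage is recorded and
#' later independent stages still run.
#'
#' @param config a [validate_config()]-acceptable config.
#' @return object of class `symdiv_bundle`: list of stage outputs plus a
#'   `provenance` block (config, hash, seed, package version, timestamp)
#'   and a `stages` status list.
#' @export
run_pipeline <- function(config) {
  cfg <- validate_config(config)
  bundle <- structure(list(stages = list()), class = "symdiv_bundle")

  # ---- inputs -------------------------------------------------------------
  if (isTRUE(cfg$synthetic)) {
    syn_dir <- cfg$output_dir %||% tempfile("symdiv_syn_")
    syn <- generate_synthetic_inputs(cfg$synthetic_config,
                                     file.path(syn_dir, "synthetic_inputs"))
    cfg$associations <- syn$paths[["associations"]]
    cfg$term_mapping <- syn$paths[["term_mapping"]]
    cfg$cluster_records <- syn$paths[["cluster_records"]]
    cfg$interactome <- syn$paths[["interactome"]]
    cfg$drug_targets <- syn$paths[["drug_targets"]]
    cfg$gene_sets <- syn$paths[["gene_sets"]]
    cfg$categories <- syn$paths[["categories"]]
    cfg$drop_list <- syn$paths[["drop_list"]]
  }
  drop_list <- if (!is.null(cfg$drop_list)) {
    readLines(cfg$drop_list, encoding = "UTF-8", warn = FALSE)
  } else NULL

  raw_assoc <- read_associations(cfg$associations,
                                 semantic_type_filter = cfg$semantic_type,
                                 drop_list = drop_list)
  mapping <- read_term_mapping(cfg$term_mapping)
  assoc <- apply_term_mapping(raw_assoc, mapping)
  message(sprintf("associations: %d records -> %d mapped terms, %d genes",
                  nrow(raw_assoc$records), length(assoc$index),
                  length(assoc$reverse_index)))
  bundle <- run_stage(bundle, "association_summary",
                      summarize_associations(assoc))

  records <- read_cluster_records(cfg$cluster_records)

  # ---- networks and diversity --------------------------------------------
  scn <- build_cooccurrence_network(records,
                                    include_chief = cfg$include_chief)
  message(sprintf("SCN: %d nodes, %d links", igraph::vcount(scn),
                  igraph::ecount(scn)))
  bundle$scn <- scn
  pd <- all_node_diversity(scn)
  names(pd) <- c("phenotype", "PE", "PD", "rank")
  bundle <- run_stage(bundle, "phenotypic_diversity", pd)

  ppi_edges <- read_interactome(cfg$interactome,
                                score_threshold = cfg$score_threshold)
  ppi <- build_interactome_graph(ppi_edges)
  message(sprintf("PPI: %d nodes, %d edges", igraph::vcount(ppi),
                  igraph::ecount(ppi)))
  bundle$ppi <- ppi
  ppi_div <- all_node_diversity(ppi)
  bundle$ppi_diversity <- ppi_div

  md <- molecular_diversity(ppi_div, assoc)
  bundle <- run_stage(bundle, "molecular_diversity", md)

  # ---- correlations -------------------------------------------------------
  bundle <- run_stage(bundle, "diversity_correlations", {
    merged <- merge(pd, md, by = "phenotype")
    merged <- merged[!is.na(merged$MGD), , drop = FALSE]
    rbind(
      data.frame(x = "PD", y = "MGD",
                 as.data.frame(pearson_correlation(merged$PD, merged$MGD))),
      data.frame(x = "PE", y = "MGE",
                 as.data.frame(pearson_correlation(merged$PE, merged$MGE))))
  })

  # ---- shared-gene pairs and randomization -------------------------------
  pairs <- suppressMessages(enumerate_shared_gene_pairs(scn, assoc, ppi_div))
  message(sprintf("shared-gene pairs: %d", nrow(pairs)))
  bundle$pair_table <- pairs
  bundle <- run_stage(bundle, "randomization",
                      shared_pair_randomization(assoc, scn,
                                                n_perm = cfg$n_perm,
                                                seed = cfg$seed))

  bundle <- run_stage(bundle, "pair_vs_single", {
    single <- bundle$molecular_diversity
    single <- single[!is.na(single$MGD), , drop = FALSE]
    pr <- pairs[!is.na(pairs$MGD), , drop = FALSE]
    thr <- cfg$high_value_threshold
    list(
      MGD = rank_sum_compare(pr$MGD, single$MGD),
      MGE = rank_sum_compare(pr$MGE, single$MGE),
      high_value_threshold = thr,
      prop_MGD_pairs = proportion_ge(pr$MGD, thr),
      prop_MGD_single = proportion_ge(single$MGD, thr),
      prop_MGE_pairs = proportion_ge(pr$MGE, thr),
      prop_MGE_single = proportion_ge(single$MGE, thr))
  })

  # ---- optional second phenotype class (e.g., diseases) ------------------
  if (!is.null(cfg$disease_associations)) {
    bundle <- run_stage(bundle, "disease_comparison", {
      dis <- read_associations(cfg$disease_associations)
      dis_md <- molecular_diversity(ppi_div, dis)
      dis_md <- dis_md[!is.na(dis_md$MGD), , drop = FALSE]
      sym_md <- bundle$molecular_diversity
      sym_md <- sym_md[!is.na(sym_md$MGD), , drop = FALSE]
      list(MGD = rank_sum_compare(dis_md$MGD, sym_md$MGD),
           MGE = rank_sum_compare(dis_md$MGE, sym_md$MGE),
           disease_table = dis_md)
    })
  } else {
    bundle$stages[["disease_comparison"]] <- "skipped: no input"
  }

  # ---- drug proximity -----------------------------------------------------
  if (!is.null(cfg$drug_targets)) {
    bundle <- run_stage(bundle, "drug_proximity", {
      drugs <- read_drug_targets(cfg$drug_targets)
      prox <- proximity_table(ppi, assoc, drugs)
      div <- merge(pd[, c("phenotype", "PD")],
                   bundle$molecular_diversity[, c("phenotype", "MGD")],
                   by = "phenotype")
      list(proximity = prox,
           correlations = proximity_diversity_correlations(prox, div))
    })
  } else {
    bundle$stages[["drug_proximity"]] <- "skipped: no input"
  }

  # ---- case study ---------------------------------------------------------
  focal <- cfg$focal_symptom
  if (is.null(focal) && nrow(pairs)) {
    # default focal symptom: the one involved in most shared-gene pairs
    tab <- sort(table(c(pairs$symptom_a, pairs$symptom_b)), decreasing = TRUE)
    focal <- names(tab)[1L]
  }
  if (!is.null(cfg$gene_sets) && !is.null(focal)) {
    bundle <- run_stage(bundle, "case_study", {
      collection <- read_gene_sets(cfg$gene_sets)
      fp <- pairs[pairs$symptom_a == focal | pairs$symptom_b == focal, ,
                  drop = FALSE]
      sel <- select_case_pairs(fp, cfg$min_cooccurrence)
      message(sprintf("case study '%s': %d pairs, %d at co-occurrence >= %d",
                      focal, nrow(fp), nrow(sel), cfg$min_cooccurrence))
      focal_genes <- assoc$index[[focal]]
      focal_enr <- enrich(focal_genes, collection,
                          p_threshold = cfg$p_threshold)
      partners <- setdiff(unique(c(sel$symptom_a, sel$symptom_b)), focal)
      partner_enr <- lapply(setNames(partners, partners), function(p) {
        enrich(assoc$index[[p]], collection, p_threshold = cfg$p_threshold)
      })
      overlaps <- lapply(partner_enr, overlap_enriched, b = focal_enr)
      overlap_table <- do.call(rbind, lapply(partners, function(p) {
        co <- pair_cooccurrence(records, p, focal,
                                include_chief = cfg$include_chief)
        data.frame(symptom = p, cooccurrence_n = co$n, occurrence_N = co$N,
                   cooccurrence_pct = co$percent,
                   overlap_n = overlaps[[p]]$n_overlap,
                   enriched_N = overlaps[[p]]$n_total,
                   overlap_pct = overlaps[[p]]$percent,
                   stringsAsFactors = FALSE)
      }))
      if (!is.null(overlap_table)) {
        overlap_table <-
          overlap_table[order(-overlap_table$cooccurrence_n), , drop = FALSE]
        rownames(overlap_table) <- NULL
      }
      emat <- enrichment_matrix(c(list(focal = focal_enr), partner_enr))
      clust <- if (ncol(emat) >= 1 && nrow(emat) >= 2) {
        cluster_pathway_matrix(emat, n_row_clusters = cfg$n_row_clusters,
                               n_col_clusters = cfg$n_col_clusters)
      } else NULL
      gene_sets_for_sub <- c(setNames(list(focal_genes), focal),
                             lapply(setNames(partners, partners),
                                    function(p) assoc$index[[p]]))
      subnet <- suppressWarnings(extract_subnetwork(ppi, gene_sets_for_sub))
      list(focal = focal, selected_pairs = sel,
           overlap_table = overlap_table, enrichment_matrix = emat,
           clustering = clust, subnetwork = subnet)
    })
  } else {
    bundle$stages[["case_study"]] <- "skipped: no input"
  }

  bundle$provenance <- list(config = cfg[setdiff(names(cfg), "synthetic_config")],
                            config_hash = config_hash(cfg),
                            seed = cfg$seed,
                            package_version = as.character(packageVersion("symdiv")),
                            timestamp = format(Sys.time(), tz = "UTC"))

  # ---- optional file outputs ---------------------------------------------
  if (!is.null(cfg$output_dir)) {
    write_bundle(bundle, cfg$output_dir)
  }
  bundle
}

#' Write a results bundle to disk
#'
#' TSV for tables, GraphML for networks, JSON for statistics; every file
#' name is prefixed by nothing but lives under `dir`, and the provenance
#' block (with the config hash) is written alongside.
#'
#' @param bundle a `symdiv_bundle`.
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_bundle <- function(bundle, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  if (!is.null(bundle$phenotypic_diversity)) {
    pd_out <- bundle$phenotypic_diversity
    names(pd_out) <- c("node", "degree", "diversity", "rank")
    write_diversity_table(pd_out, file.path(dir, "phenotypic_diversity.tsv"))
  }
  if (!is.null(bundle$molecular_diversity)) {
    write_tsv(bundle$molecular_diversity,
              file.path(dir, "molecular_diversity.tsv"))
  }
  if (!is.null(bundle$pair_table)) {
    write_tsv(bundle$pair_table, file.path(dir, "shared_gene_pairs.tsv"))
  }
  if (!is.null(bundle$scn)) {
    export_graphml(bundle$scn, file.path(dir, "scn.graphml"))
  }
  if (!is.null(bundle$drug_proximity)) {
    write_tsv(bundle$drug_proximity$proximity,
              file.path(dir, "drug_proximity.tsv"))
  }
  stats_block <- list(
    diversity_correlations = bundle$diversity_correlations,
    randomization = if (!is.null(bundle$randomization))
      unclass(bundle$randomization),
    pair_vs_single = bundle$pair_vs_single,
    drug_correlations = if (!is.null(bundle$drug_proximity))
      bundle$drug_proximity$correlations,
    stages = bundle$stages,
    provenance = bundle$provenance)
  jsonlite::write_json(stats_block, file.path(dir, "results.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null", force = TRUE)
  invisible(dir)
}

#' @export
print.symdiv_bundle <- function(x, ...) {
  cat("Symptom network-diversity results bundle\n")
  if (!is.null(x$scn)) {
    cat(sprintf("  SCN: %d nodes, %d links\n", igraph::vcount(x$scn),
                igraph::ecount(x$scn)))
  }
  if (!is.null(x$ppi)) {
    cat(sprintf("  PPI: %d nodes, %d edges\n", igraph::vcount(x$ppi),
                igraph::ecount(x$ppi)))
  }
  if (!is.null(x$diversity_correlations)) {
    dc <- x$diversity_correlations
    for (i in seq_len(nrow(dc))) {
      cat(sprintf("  %s-%s: PCC = %.3f (n = %d, p = %.3g)\n", dc$x[i],
                  dc$y[i], dc$pcc[i], dc$n[i], dc$p_value[i]))
    }
  }
  if (!is.null(x$randomization)) {
    cat(sprintf("  shared-gene pairs: %d observed vs null mean %.1f (empirical p = %.3g)\n",
                x$randomization$observed, mean(x$randomization$null_counts),
                x$randomization$empirical_p))
  }
  cat("  stages:\n")
  for (nm in names(x$stages)) {
    cat(sprintf("    %-24s %s\n", nm, x$stages[[nm]]))
  }
  invisible(x)
}
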