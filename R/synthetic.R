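# Synthetic inputs with the statistical structure the analysis assumes:
# a heavy-tailed interactome, power-law symptom-gene association degrees,
# body-system category structure (which both drives record co-occurrence
# and plants gene sharing on co-occurring pairs), a tunable coupling
# between a symptom's clinical breadth and the interactome diversity of
# its genes, and drug targets optionally placed near symptom genes.
# Every generator is bit-reproducible from the config seed; each component
# uses its own fixed offset of the seed so it can be regenerated alone.

#' Configuration for the synthetic-data generator
#'
#' Defaults are desk-scale counterparts of the study inputs: 300 symptoms,
#' 2,000 genes with ~16,000 preferential-attachment interactome edges,
#' 2,000 cluster records of mean size 6, 120 drugs with drug targets
#' covering ~8% of proteins, and 14 body-system categories.
#'
#' @param seed integer seed; every generated artifact derives from it.
#' @param n_symptoms,n_genes,n_records,n_drugs scale of the generated data.
#' @param ppi_model interactome model: preferential attachment (default;
#'   heavy-tailed degrees), configuration (degree-matched null) or random
#'   (Erdos-Renyi).
#' @param ppi_edges_per_node attachment parameter m (edges per added node).
#' @param decoy_edge_frac fraction of extra sub-threshold (score < 700)
#'   edges added to the emitted edge file to exercise score filtering.
#' @param assoc_degree_exponent exponent of the discrete power law for
#'   symptom gene-set sizes.
#' @param assoc_min_genes,assoc_max_genes gene-set size bounds.
#' @param diversity_coupling probability in [0, 1] that a broad symptom
#'   draws its genes biased toward high-diversity interactome nodes; the
#'   planted strength of the clinical-molecular diversity association.
#' @param drug_proximity_bias probability in [0, 1] that a drug target is
#'   placed within distance 1 of a symptom gene rather than uniformly.
#' @param record_size_min,record_size_mean symptom-cluster record size:
#'   `min + Poisson(mean - min)` terms per record.
#' @param n_categories number of body-system categories.
#' @param category_fidelity probability mass a record places on its own
#'   category when sampling member symptoms.
#' @param broad_fraction fraction of symptoms designated broad
#'   (high-occurrence).
#' @param broad_weight record-inclusion weight of broad symptoms relative
#'   to narrow ones.
#' @param n_pathways,pathway_size_mean,pathway_noise pathway collection:
#'   number of sets, mean size, fraction of members replaced by uniform
#'   noise genes.
#' @param targets_per_drug_mean mean targets per drug (1 + Poisson).
#' @param cui_per_symptom_max each symptom's associations are split over
#'   1..max source identifiers, exercising many-to-one term mapping.
#' @return object of class `synthetic_config` (a validated list).
#' @export
synthetic_config <- function(seed = 1L,
                             n_symptoms = 300L, n_genes = 2000L,
                             n_records = 2000L, n_drugs = 120L,
                             ppi_model = c("preferential-attachment",
                                           "configuration", "random"),
                             ppi_edges_per_node = 8L,
                             decoy_edge_frac = 0.3,
                             assoc_degree_exponent = 2.0,
                             assoc_min_genes = 3L, assoc_max_genes = 200L,
                             diversity_coupling = 1.0,
                             drug_proximity_bias = 1.0,
                             record_size_min = 2L, record_size_mean = 6,
                             n_categories = 14L, category_fidelity = 0.8,
                             broad_fraction = 0.3, broad_weight = 6,
                             n_pathways = 80L, pathway_size_mean = 30,
                             pathway_noise = 0.2,
                             targets_per_drug_mean = 1.4,
                             cui_per_symptom_max = 3L) {
  cfg <- list(seed = as.integer(seed), n_symptoms = as.integer(n_symptoms),
              n_genes = as.integer(n_genes), n_records = as.integer(n_records),
              n_drugs = as.integer(n_drugs),
              ppi_model = match.arg(ppi_model),
              ppi_edges_per_node = as.integer(ppi_edges_per_node),
              decoy_edge_frac = decoy_edge_frac,
              assoc_degree_exponent = assoc_degree_exponent,
              assoc_min_genes = as.integer(assoc_min_genes),
              assoc_max_genes = as.integer(assoc_max_genes),
              diversity_coupling = diversity_coupling,
              drug_proximity_bias = drug_proximity_bias,
              record_size_min = as.integer(record_size_min),
              record_size_mean = record_size_mean,
              n_categories = as.integer(n_categories),
              category_fidelity = category_fidelity,
              broad_fraction = broad_fraction, broad_weight = broad_weight,
              n_pathways = as.integer(n_pathways),
              pathway_size_mean = pathway_size_mean,
              pathway_noise = pathway_noise,
              targets_per_drug_mean = targets_per_drug_mean,
              cui_per_symptom_max = as.integer(cui_per_symptom_max))
  counts <- c("n_symptoms", "n_genes", "n_records", "n_drugs",
              "ppi_edges_per_node", "n_categories", "n_pathways")
  for (f in counts) {
    if (cfg[[f]] < 1L) stop(sprintf("synthetic_config: %s must be positive", f),
                            call. = FALSE)
  }
  for (f in c("diversity_coupling", "drug_proximity_bias",
              "category_fidelity", "broad_fraction")) {
    if (cfg[[f]] < 0 || cfg[[f]] > 1) {
      stop(sprintf("synthetic_config: %s must lie in [0, 1]", f),
           call. = FALSE)
    }
  }
  if (cfg$assoc_min_genes > cfg$assoc_max_genes ||
      cfg$assoc_max_genes > cfg$n_genes) {
    stop("synthetic_config: need assoc_min_genes <= assoc_max_genes <= n_genes",
         call. = FALSE)
  }
  if (cfg$record_size_min < 1L || cfg$record_size_mean < cfg$record_size_min) {
    stop("synthetic_config: invalid record size distribution", call. = FALSE)
  }
  structure(cfg, class = "synthetic_config")
}

gene_names <- function(n) sprintf("G%04d", seq_len(n))
symptom_names <- function(n) sprintf("sym%03d", seq_len(n))

#' Generate a synthetic interactome
#'
#' The true network is drawn from the configured model (preferential
#' attachment by default, so degrees are heavy-tailed); the emitted edge
#' list carries uniform scores in 700-1000 for true edges plus a
#' configurable fraction of decoy non-edges scored below 700, so that
#' score-filtering at the standard threshold recovers exactly the true
#' graph.
#'
#' @param cfg a [synthetic_config()].
#' @return list with `edges` (data frame `protein_a`, `protein_b`,
#'   `score`, as written to file) and `graph` (the true igraph).
#' @export
generate_interactome <- function(cfg) {
  stopifnot(inherits(cfg, "synthetic_config"))
  set.seed(cfg$seed + 1L)
  n <- cfg$n_genes
  m <- cfg$ppi_edges_per_node
  g <- switch(cfg$ppi_model,
    "preferential-attachment" =
      igraph::sample_pa(n, power = 1, m = m, directed = FALSE),
    "configuration" = {
      ref <- igraph::sample_pa(n, power = 1, m = m, directed = FALSE)
      igraph::sample_degseq(igraph::degree(ref),
                            method = "fast.heur.simple")
    },
    "random" = igraph::sample_gnm(n, m * n - choose(m + 1, 2)))
  g <- igraph::simplify(g)
  igraph::V(g)$name <- gene_names(n)
  ends <- igraph::as_data_frame(g, what = "edges")
  true_edges <- data.frame(protein_a = pmin(ends$from, ends$to),
                           protein_b = pmax(ends$from, ends$to),
                           score = sample(700:1000, nrow(ends), replace = TRUE),
                           stringsAsFactors = FALSE)
  n_decoy <- round(cfg$decoy_edge_frac * nrow(true_edges))
  decoys <- data.frame(protein_a = sample(gene_names(n), n_decoy, replace = TRUE),
                       protein_b = sample(gene_names(n), n_decoy, replace = TRUE),
                       score = sample(150:699, n_decoy, replace = TRUE),
                       stringsAsFactors = FALSE)
  decoys <- decoys[decoys$protein_a != decoys$protein_b, , drop = FALSE]
  edges <- rbind(true_edges, decoys)
  edges <- edges[sample.int(nrow(edges)), , drop = FALSE]
  rownames(edges) <- NULL
  g$kind <- "molecular"
  list(edges = edges, graph = g)
}

#' Generate synthetic symptom-gene associations
#'
#' Gene-set sizes follow a discrete power law. Symptoms carry a body-system
#' category and a broad/narrow label; broad symptoms, with probability
#' `diversity_coupling`, draw genes weighted toward high-diversity
#' interactome nodes (the planted clinical-molecular association),
#' otherwise uniformly from their category's gene pool. Category pools
#' overlap across symptoms, planting gene sharing among co-occurring
#' (same-category) symptoms. Each symptom's associations are split over
#' 1..`cui_per_symptom_max` CUI-like source identifiers, and decoy rows of
#' a different semantic type plus a drop list of review-removed phenotypes
#' are added to the raw rows to exercise filtering.
#'
#' @param cfg a [synthetic_config()].
#' @param ppi_diversity interactome diversity table
#'   ([all_node_diversity()] of the true graph).
#' @return list with `assoc` (ground-truth [association_table()] keyed by
#'   clinical term), `raw` (data frame as written to file, CUI-level, with
#'   `semantic_type`), `mapping` (named vector CUI -> term), `drop_list`,
#'   and `labels` (per-symptom ground truth: term, category, broad,
#'   biased, weight, n_genes).
#' @export
generate_associations <- function(cfg, ppi_diversity) {
  stopifnot(inherits(cfg, "synthetic_config"))
  set.seed(cfg$seed + 2L)
  terms <- symptom_names(cfg$n_symptoms)
  genes <- gene_names(cfg$n_genes)
  phi <- setNames(ppi_diversity$diversity, ppi_diversity$node)[genes]
  phi[is.na(phi)] <- 0

  category <- sample.int(cfg$n_categories, cfg$n_symptoms, replace = TRUE)
  pool_size <- min(cfg$n_genes, ceiling(2 * cfg$n_genes / cfg$n_categories))
  pools <- lapply(seq_len(cfg$n_categories),
                  function(i) sample(genes, pool_size))
  broad <- runif(cfg$n_symptoms) < cfg$broad_fraction
  biased <- broad & (runif(cfg$n_symptoms) < cfg$diversity_coupling)

  ks <- cfg$assoc_min_genes:cfg$assoc_max_genes
  sizes <- sample(ks, cfg$n_symptoms, replace = TRUE,
                  prob = ks^(-cfg$assoc_degree_exponent))
  sizes <- pmin(sizes, pool_size)

  sets <- lapply(seq_len(cfg$n_symptoms), function(s) {
    pool <- pools[[category[s]]]
    w <- if (biased[s]) (phi[pool] + 1)^2 else rep(1, length(pool))
    sample(pool, sizes[s], prob = w)
  })

  # split each symptom's genes over 1..max CUI codes (many-to-one mapping)
  cui_counter <- 0L
  raw_rows <- vector("list", cfg$n_symptoms)
  map_src <- character(0)
  map_tgt <- character(0)
  for (s in seq_len(cfg$n_symptoms)) {
    gs <- sets[[s]]
    n_cui <- sample.int(min(cfg$cui_per_symptom_max, length(gs)), 1L)
    cuis <- sprintf("C%07d", cui_counter + seq_len(n_cui))
    cui_counter <- cui_counter + n_cui
    assign_to <- sample(rep_len(seq_len(n_cui), length(gs)))
    raw_rows[[s]] <- data.frame(
      phenotype_id = cuis[assign_to],
      phenotype_label = sprintf("%s_en%d", terms[s], assign_to),
      gene = gs, semantic_type = "T184", stringsAsFactors = FALSE)
    map_src <- c(map_src, cuis)
    map_tgt <- c(map_tgt, rep(terms[s], n_cui))
  }
  raw <- do.call(rbind, raw_rows)

  # decoy rows of a non-symptom semantic type (removed by the T184 filter)
  n_decoy <- max(5L, round(0.08 * nrow(raw)))
  decoy <- data.frame(
    phenotype_id = sprintf("C9%06d", sample.int(cfg$n_symptoms, n_decoy,
                                                replace = TRUE)),
    phenotype_label = "non_symptom_concept",
    gene = sample(genes, n_decoy, replace = TRUE),
    semantic_type = "T047", stringsAsFactors = FALSE)

  # review-removed phenotypes: extra T184 rows whose CUIs sit on the drop list
  n_drop <- max(2L, round(0.02 * cfg$n_symptoms))
  drop_cuis <- sprintf("C8%06d", seq_len(n_drop))
  dropped <- do.call(rbind, lapply(seq_len(n_drop), function(i) {
    data.frame(phenotype_id = drop_cuis[i],
               phenotype_label = sprintf("reviewed_out_%02d", i),
               gene = sample(genes, 3L), stringsAsFactors = FALSE,
               semantic_type = "T184")
  }))

  raw_all <- rbind(raw, decoy, dropped)
  raw_all <- raw_all[sample.int(nrow(raw_all)), , drop = FALSE]
  rownames(raw_all) <- NULL

  truth <- association_table(data.frame(
    phenotype_id = rep(terms, lengths(sets)),
    phenotype_label = rep(terms, lengths(sets)),
    gene = unlist(sets, use.names = FALSE), stringsAsFactors = FALSE))

  labels <- data.frame(term = terms,
                       category = sprintf("SYS%02d", category),
                       broad = broad, biased = biased,
                       weight = ifelse(broad, cfg$broad_weight, 1),
                       n_genes = lengths(sets), stringsAsFactors = FALSE)
  list(assoc = truth, raw = raw_all,
       mapping = setNames(map_tgt, map_src),
       drop_list = drop_cuis, labels = labels)
}

#' Generate synthetic symptom-cluster records
#'
#' Record sizes are `record_size_min + Poisson(mean - min)`. Each record
#' picks a category (probability proportional to the category's total
#' symptom weight) and samples distinct member symptoms with probability
#' mass `category_fidelity` on its own category, weighted by the broadness
#' weight, so broad symptoms occur in more records (elevating their SCN
#' degree and phenotypic diversity) and co-occurring symptoms tend to
#' share a category (hence genes). The first sampled member acts as the
#' record's chief symptom.
#'
#' @param cfg a [synthetic_config()].
#' @param labels per-symptom ground truth from [generate_associations()].
#' @return a [cluster_records()] object.
#' @export
generate_cluster_records <- function(cfg, labels) {
  stopifnot(inherits(cfg, "synthetic_config"))
  set.seed(cfg$seed + 3L)
  w <- labels$weight
  cat_of <- labels$category
  cats <- sort(unique(cat_of))
  cat_w <- vapply(cats, function(cc) sum(w[cat_of == cc]), 0)
  sizes <- cfg$record_size_min +
    rpois(cfg$n_records, cfg$record_size_mean - cfg$record_size_min)
  sizes <- pmin(pmax(sizes, 1L), nrow(labels))
  records <- vector("list", cfg$n_records)
  chiefs <- character(cfg$n_records)
  for (r in seq_len(cfg$n_records)) {
    cc <- sample(cats, 1L, prob = cat_w)
    in_cat <- cat_of == cc
    v <- (1 - cfg$category_fidelity) * w / sum(w)
    v[in_cat] <- v[in_cat] +
      cfg$category_fidelity * w[in_cat] / sum(w[in_cat])
    members <- labels$term[sample.int(nrow(labels), sizes[r], prob = v)]
    chiefs[r] <- members[1L]
    records[[r]] <- members[-1L]
  }
  cluster_records(records, chiefs)
}

#' Generate synthetic drug-target associations
#'
#' Each drug owns `1 + Poisson` targets. With probability
#' `drug_proximity_bias` a target is placed within distance 1 of a symptom
#' gene (the gene itself or one of its interactome neighbors), otherwise
#' uniformly over interactome nodes. Placement labels are kept as ground
#' truth.
#'
#' @param cfg a [synthetic_config()].
#' @param assoc ground-truth [association_table()] (symptom gene sets).
#' @param ppi true interactome igraph.
#' @return list with `pairs` (data frame `drug_id`, `target_gene`,
#'   deduplicated) and `placed_near` (logical ground truth per pair).
#' @export
generate_drug_targets <- function(cfg, assoc, ppi) {
  stopifnot(inherits(cfg, "synthetic_config"), inherits(assoc, "assoc_table"))
  set.seed(cfg$seed + 4L)
  nodes <- igraph::V(ppi)$name
  sym_genes <- intersect(unique(unlist(assoc$index, use.names = FALSE)), nodes)
  if (!length(sym_genes)) stop("generate_drug_targets: no symptom gene in ppi",
                               call. = FALSE)
  n_t <- 1L + rpois(cfg$n_drugs, cfg$targets_per_drug_mean - 1)
  drug_id <- rep(sprintf("DB%05d", seq_len(cfg$n_drugs)), n_t)
  total <- sum(n_t)
  near <- runif(total) < cfg$drug_proximity_bias
  target <- character(total)
  for (i in seq_len(total)) {
    if (near[i]) {
      gp <- sample(sym_genes, 1L)
      nb <- igraph::V(ppi)$name[unlist(igraph::adjacent_vertices(ppi, gp))]
      target[i] <- if (length(nb) && runif(1) < 0.5) sample(nb, 1L) else gp
    } else {
      target[i] <- sample(nodes, 1L)
    }
  }
  pairs <- data.frame(drug_id = drug_id, target_gene = target,
                      stringsAsFactors = FALSE)
  keep <- !duplicated(pairs)
  list(pairs = pairs[keep, , drop = FALSE], placed_near = near[keep])
}

#' Generate a synthetic pathway collection
#'
#' Each pathway is a connected interactome neighborhood (breadth-first
#' from a random seed node) with a fraction of members replaced by uniform
#' noise genes; written/consumed as GMT.
#'
#' @param cfg a [synthetic_config()].
#' @param ppi true interactome igraph.
#' @return a [gene_set_collection()].
#' @export
generate_gene_sets <- function(cfg, ppi) {
  stopifnot(inherits(cfg, "synthetic_config"))
  set.seed(cfg$seed + 5L)
  nodes <- igraph::V(ppi)$name
  sets <- lapply(seq_len(cfg$n_pathways), function(i) {
    size <- max(5L, rpois(1L, cfg$pathway_size_mean))
    root <- sample(nodes, 1L)
    ord <- igraph::bfs(ppi, root = root, unreachable = FALSE,
                       dist = FALSE)$order
    ord <- ord[!is.na(ord)]
    members <- nodes[as.integer(ord)[seq_len(min(size, length(ord)))]]
    n_noise <- round(cfg$pathway_noise * length(members))
    if (n_noise > 0) {
      members <- unique(c(members[seq_len(length(members) - n_noise)],
                          sample(nodes, n_noise)))
    }
    members
  })
  names(sets) <- sprintf("PW%03d", seq_len(cfg$n_pathways))
  gene_set_collection(sets, rep("synthetic pathway", cfg$n_pathways))
}

#' Generate and write the full synthetic input bundle
#'
#' Runs every generator in dependency order and writes all standard input
#' files (TSV/GMT/plain text) plus a manifest JSON with the full config,
#' its hash and the ground-truth file paths.
#'
#' @param cfg a [synthetic_config()].
#' @param dir output directory (created if needed).
#' @return (invisibly) list with all in-memory objects (`interactome`,
#'   `ppi_diversity`, `associations`, `records`, `drugs`, `pathways`) and
#'   `paths` (named file paths).
#' @export
generate_synthetic_inputs <- function(cfg, dir) {
  stopifnot(inherits(cfg, "synthetic_config"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  inter <- generate_interactome(cfg)
  ppi_div <- all_node_diversity(inter$graph)
  asc <- generate_associations(cfg, ppi_div)
  recs <- generate_cluster_records(cfg, asc$labels)
  drugs <- generate_drug_targets(cfg, asc$assoc, inter$graph)
  paths_ok <- function(f) file.path(dir, f)
  pw <- generate_gene_sets(cfg, inter$graph)

  paths <- c(interactome = paths_ok("interactome.tsv"),
             associations = paths_ok("associations.tsv"),
             term_mapping = paths_ok("term_mapping.tsv"),
             cluster_records = paths_ok("cluster_records.tsv"),
             drug_targets = paths_ok("drug_targets.tsv"),
             gene_sets = paths_ok("pathways.gmt"),
             categories = paths_ok("categories.tsv"),
             drop_list = paths_ok("drop_list.txt"),
             labels = paths_ok("ground_truth_labels.tsv"),
             manifest = paths_ok("manifest.json"))
  write_tsv(inter$edges, paths[["interactome"]])
  write_tsv(asc$raw, paths[["associations"]])
  write_tsv(data.frame(source = names(asc$mapping),
                       target = unname(asc$mapping),
                       stringsAsFactors = FALSE), paths[["term_mapping"]])
  write_cluster_records(recs, paths[["cluster_records"]])
  write_tsv(drugs$pairs, paths[["drug_targets"]])
  write_gene_sets(pw, paths[["gene_sets"]])
  write_tsv(data.frame(term = asc$labels$term,
                       category = asc$labels$category,
                       stringsAsFactors = FALSE), paths[["categories"]])
  writeLines(asc$drop_list, paths[["drop_list"]])
  write_tsv(asc$labels, paths[["labels"]])
  jsonlite::write_json(list(config = unclass(cfg),
                            config_hash = config_hash(cfg),
                            paths = as.list(paths)),
                       paths[["manifest"]], auto_unbox = TRUE, pretty = TRUE)
  invisible(list(interactome = inter, ppi_diversity = ppi_div,
                 associations = asc, records = recs, drugs = drugs,
                 pathways = pw, paths = paths))
}

#' Fingerprint of a configuration
#'
#' FNV-1a hash of the canonical JSON form; stamped into every output for
#' provenance.
#'
#' @param cfg a config list.
#' @return 8-hex-digit string.
#' @export
config_hash <- function(cfg) {
  fnv1a_hash(jsonlite::toJSON(unclass(cfg), auto_unbox = TRUE, digits = NA,
                              force = TRUE, null = "null"))
}
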