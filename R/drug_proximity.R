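# Shortest-path proximity between drug targets and symptom genes in the
# interactome. The thresholded interactome is unweighted, so the Dijkstra
# computation specializes to breadth-first search; "first order" means
# distance <= 1, counting a target that is itself a symptom gene
# (distance 0) or a direct interactome neighbor of one (distance 1).

#' Multi-source shortest-path lengths from a gene set
#'
#' BFS distances over unit-weight edges from the nearest source; nodes
#' unreachable from every source are absent from the result. Sources not
#' present in the graph are logged and skipped.
#'
#' @param ppi interactome igraph.
#' @param sources character vector of source genes.
#' @return named numeric vector: gene -> distance to the nearest source.
#' @export
shortest_path_lengths <- function(ppi, sources) {
  sources <- unique(as.character(sources))
  present <- intersect(sources, igraph::V(ppi)$name)
  if (!length(present)) {
    stop("shortest_path_lengths: no source gene present in the graph",
         call. = FALSE)
  }
  if (length(present) < length(sources)) {
    message(sprintf("shortest_path_lengths: %d source(s) absent from graph, skipped",
                    length(sources) - length(present)))
  }
  d <- igraph::distances(ppi, v = present, weights = NA)
  dist <- apply(d, 2L, min)
  dist[is.finite(dist)]
}

#' First-order drug targets of a phenotype gene set
#'
#' A drug target counts when it lies at distance <= 1 from the phenotype's
#' gene set: it is itself a phenotype gene, or a direct interactome
#' neighbor of one. Targets shared by several drugs are counted once
#' (DTN deduplicates targets); `n_drugs` counts distinct drugs owning at
#' least one counted target.
#'
#' @param ppi interactome igraph.
#' @param phenotype_genes character vector of the phenotype's genes.
#' @param drug_targets data frame with columns `drug_id`, `target_gene`
#'   ([read_drug_targets()]).
#' @param phenotype optional phenotype term carried into the result.
#' @return one-row data frame `phenotype`, `DTN`, `n_drugs`,
#'   `genes_in_network`.
#' @export
first_order_targets <- function(ppi, phenotype_genes, drug_targets,
                                phenotype = NA_character_) {
  phenotype_genes <- unique(as.character(phenotype_genes))
  in_net <- intersect(phenotype_genes, igraph::V(ppi)$name)
  neighborhood <- if (length(in_net)) {
    nb_idx <- unique(unlist(igraph::adjacent_vertices(ppi, in_net)))
    unique(c(in_net, igraph::V(ppi)$name[nb_idx]))
  } else character()
  # distance 0 also covers phenotype genes outside the network: the target
  # coincides with a symptom gene whether or not that gene is wired in
  zone <- union(phenotype_genes, neighborhood)
  counted <- drug_targets$target_gene %in% zone
  data.frame(phenotype = phenotype,
             DTN = length(unique(drug_targets$target_gene[counted])),
             n_drugs = length(unique(drug_targets$drug_id[counted])),
             genes_in_network = length(in_net),
             stringsAsFactors = FALSE)
}

#' First-order drug-target counts for every phenotype
#'
#' @param ppi interactome igraph.
#' @param assoc an [association_table()].
#' @param drug_targets drug-target data frame.
#' @return data frame, one row per phenotype, as in
#'   [first_order_targets()].
#' @export
proximity_table <- function(ppi, assoc, drug_targets) {
  stopifnot(inherits(assoc, "assoc_table"))
  out <- do.call(rbind, lapply(names(assoc$index), function(p) {
    first_order_targets(ppi, assoc$index[[p]], drug_targets, phenotype = p)
  }))
  rownames(out) <- NULL
  out
}

#' Correlations between drug-target counts and diversity
#'
#' Pearson correlations of DTN and n_drugs against the phenotypic (PD) and
#' molecular (MGD) diversity of the same phenotypes.
#'
#' @param proximity data frame from [proximity_table()].
#' @param diversity data frame with columns `phenotype`, and any of `PD`,
#'   `MGD` (rows matched by phenotype).
#' @return data frame `x`, `y`, `n`, `pcc`, `p_value`, one row per
#'   available combination.
#' @export
proximity_diversity_correlations <- function(proximity, diversity) {
  merged <- merge(proximity, diversity, by = "phenotype")
  if (nrow(merged) < 3) {
    stop("proximity_diversity_correlations: need >= 3 phenotypes with both quantities",
         call. = FALSE)
  }
  combos <- expand.grid(x = c("DTN", "n_drugs"),
                        y = intersect(c("MGD", "PD"), names(merged)),
                        stringsAsFactors = FALSE)
  out <- do.call(rbind, lapply(seq_len(nrow(combos)), function(i) {
    res <- pearson_correlation(merged[[combos$x[i]]], merged[[combos$y[i]]])
    data.frame(x = combos$x[i], y = combos$y[i], n = res$n, pcc = res$pcc,
               p_value = res$p_value, stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
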