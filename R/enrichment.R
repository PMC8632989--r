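# Hypergeometric over-representation of a gene set against a pathway
# collection, enriched-pathway overlap for symptom pairs, and
# agglomerative clustering of the binary pair x pathway matrix.

#' Hypergeometric over-representation test
#'
#' For each set in the collection, the upper-tail hypergeometric
#' probability of observing at least the seen overlap between the query
#' and the set, drawing without replacement from the gene universe. The
#' query is restricted to the universe before testing. Raw p-values are
#' compared against `p_threshold` (no multiple-testing correction by
#' default, matching the common enrichment-service convention);
#' Benjamini-Hochberg adjustment is available behind `adjust`.
#'
#' @param genes query gene set.
#' @param collection a [gene_set_collection()].
#' @param universe gene universe; default the collection's universe.
#' @param p_threshold significance cutoff for the `enriched` flag.
#' @param adjust if TRUE, flag on BH-adjusted p-values (reported in
#'   `p_adjusted`).
#' @return object of class `enrichment_result`: data frame `set`,
#'   `overlap`, `query_size`, `set_size`, `universe_size`, `p_value`,
#'   (`p_adjusted`), `enriched`, with attributes `query` and `threshold`.
#' @export
enrich <- function(genes, collection, universe = NULL, p_threshold = 0.05,
                   adjust = FALSE) {
  stopifnot(inherits(collection, "gene_set_collection"))
  universe <- unique(universe %||% collection$universe)
  genes <- intersect(unique(as.character(genes)), universe)
  if (!length(genes)) {
    stop("enrich: query empty after restriction to the universe",
         call. = FALSE)
  }
  N <- length(universe)
  q <- length(genes)
  rows <- lapply(names(collection$sets), function(nm) {
    s <- intersect(collection$sets[[nm]], universe)
    k <- length(intersect(genes, s))
    m <- length(s)
    p <- phyper(k - 1, m, N - m, q, lower.tail = FALSE)
    data.frame(set = nm, overlap = k, query_size = q, set_size = m,
               universe_size = N, p_value = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (adjust) {
    out$p_adjusted <- stats::p.adjust(out$p_value, method = "BH")
    out$enriched <- out$p_adjusted < p_threshold
  } else {
    out$enriched <- out$p_value < p_threshold
  }
  rownames(out) <- NULL
  attr(out, "query") <- genes
  attr(out, "threshold") <- p_threshold
  attr(out, "collection_sets") <- names(collection$sets)
  class(out) <- c("enrichment_result", "data.frame")
  out
}

#' Overlap of enriched sets between two enrichment results
#'
#' Intersection of the enriched set names of `a` and `b`, reported with the
#' n/N (%) convention of the case-study tables: N is `a`'s enriched count
#' (the partner symptom's total), n the number of names enriched in both.
#'
#' @param a enrichment result of the partner symptom.
#' @param b enrichment result of the focal symptom.
#' @return list with `overlapped` (set names), `n_overlap`, `n_total`,
#'   `percent` (half-up, 2 decimals; NA when `a` has no enriched set).
#' @export
overlap_enriched <- function(a, b) {
  stopifnot(inherits(a, "enrichment_result"), inherits(b, "enrichment_result"))
  if (!identical(attr(a, "collection_sets"), attr(b, "collection_sets"))) {
    stop("overlap_enriched: results come from different collections",
         call. = FALSE)
  }
  ea <- a$set[a$enriched]
  eb <- b$set[b$enriched]
  ov <- intersect(ea, eb)
  list(overlapped = ov, n_overlap = length(ov), n_total = length(ea),
       percent = if (length(ea)) round_half_up(100 * length(ov) / length(ea))
                 else NA_real_)
}

#' Select case-study pairs by co-occurrence
#'
#' Pairs at or above the co-occurrence threshold, sorted by co-occurrence
#' descending.
#'
#' @param pairs pair table from [enumerate_shared_gene_pairs()].
#' @param min_cooccurrence inclusive threshold.
#' @return filtered, sorted pair table.
#' @export
select_case_pairs <- function(pairs, min_cooccurrence) {
  stopifnot("cooccurrence" %in% names(pairs))
  out <- pairs[!is.na(pairs$cooccurrence) &
                 pairs$cooccurrence >= min_cooccurrence, , drop = FALSE]
  out <- out[order(-out$cooccurrence, out$symptom_a, out$symptom_b), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Agglomerative clustering of a binary pathway-membership matrix
#'
#' Clusters both the rows (pairs) and the columns (pathways) of a binary
#' membership matrix with average-linkage agglomerative clustering on
#' Jaccard (binary) distances; deterministic given the matrix and
#' parameters.
#'
#' @param mat binary matrix (rows = pairs/queries, columns = pathways).
#' @param n_row_clusters,n_col_clusters number of clusters to cut to
#'   (either may be NULL to skip labels for that margin).
#' @param method linkage method (default "average").
#' @return list with `row_labels`, `col_labels` (named integer vectors),
#'   `row_hclust`, `col_hclust`.
#' @export
cluster_pathway_matrix <- function(mat, n_row_clusters = NULL,
                                   n_col_clusters = NULL,
                                   method = "average") {
  stopifnot(is.matrix(mat), nrow(mat) >= 1, ncol(mat) >= 1)
  mat <- (mat != 0) * 1
  cluster_margin <- function(m, k) {
    if (nrow(m) == 1L) {
      hc <- NULL
      labels <- setNames(1L, rownames(m) %||% "1")
      return(list(hclust = hc, labels = labels))
    }
    d <- stats::dist(m, method = "binary")   # Jaccard distance on profiles
    d[is.na(d)] <- 0                         # all-zero profiles: identical
    hc <- hclust(d, method = method)
    labels <- if (is.null(k)) NULL else cutree(hc, k = min(k, nrow(m)))
    list(hclust = hc, labels = labels)
  }
  rowc <- cluster_margin(mat, n_row_clusters)
  colc <- cluster_margin(t(mat), n_col_clusters)
  list(row_labels = rowc$labels, col_labels = colc$labels,
       row_hclust = rowc$hclust, col_hclust = colc$hclust)
}

#' Build the binary pair x pathway enrichment matrix
#'
#' Rows are queries (for instance focal-symptom pairs), columns the union
#' of their enriched set names; cell = 1 when the set is enriched for the
#' query.
#'
#' @param results named list of enrichment results.
#' @return binary matrix (possibly 0 columns when nothing is enriched).
#' @export
enrichment_matrix <- function(results) {
  stopifnot(length(results) > 0, !is.null(names(results)))
  enriched <- lapply(results, function(r) r$set[r$enriched])
  cols <- sort(unique(unlist(enriched, use.names = FALSE)))
  mat <- matrix(0L, nrow = length(results), ncol = length(cols),
                dimnames = list(names(results), cols))
  for (i in seq_along(results)) {
    mat[i, enriched[[i]]] <- 1L
  }
  mat
}

#' Write an enrichment result as TSV
#' @param result an enrichment result.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_enrichment <- function(result, path) {
  write_tsv(as.data.frame(result), path)
}
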