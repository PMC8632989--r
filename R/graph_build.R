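# Construction of the symptom co-occurrence network (SCN) and the
# interactome graph, subnetwork extraction, and pair co-occurrence counts.
# Both networks are igraph objects; the SCN carries an edge attribute
# `weight` (co-occurrence count) and a vertex attribute `occurrence`
# (number of records containing the term).

#' Build the symptom co-occurrence network
#'
#' Every symptom-cluster record contributes one co-occurrence to each
#' unordered pair of distinct terms it contains (the chief symptom is part
#' of its record when `include_chief` is on, reflecting the reading of a
#' differential-diagnosis record as chief symptom plus accompanying
#' cluster). Edge weight is the number of records containing both terms;
#' singleton records create isolated nodes.
#'
#' @param records a [cluster_records()] object.
#' @param include_chief include each record's chief symptom as a member of
#'   the record (default TRUE; ignored when records carry no chief).
#' @return undirected igraph; edge attribute `weight`, vertex attribute
#'   `occurrence`, graph attribute `kind = "phenotype"`.
#' @export
build_cooccurrence_network <- function(records, include_chief = TRUE) {
  stopifnot(inherits(records, "cluster_records"))
  term_sets <- lapply(seq_along(records$records), function(i) {
    terms <- records$records[[i]]
    if (include_chief && !is.null(records$chief)) {
      terms <- c(records$chief[i], terms)
    }
    unique(terms)
  })
  occ <- table(unlist(term_sets, use.names = FALSE))
  pair_list <- lapply(term_sets, function(terms) {
    if (length(terms) < 2L) return(NULL)
    terms <- sort(terms)
    cmb <- utils::combn(terms, 2L)
    paste(cmb[1L, ], cmb[2L, ], sep = "\r")
  })
  pairs <- unlist(pair_list, use.names = FALSE)
  nodes <- names(occ)
  if (is.null(pairs)) {
    g <- igraph::make_empty_graph(n = 0, directed = FALSE)
    g <- igraph::add_vertices(g, length(nodes), name = nodes)
  } else {
    w <- table(pairs)
    ends <- do.call(rbind, strsplit(names(w), "\r", fixed = TRUE))
    g <- igraph::graph_from_data_frame(
      data.frame(from = ends[, 1L], to = ends[, 2L],
                 weight = as.integer(w), stringsAsFactors = FALSE),
      directed = FALSE,
      vertices = data.frame(name = nodes, stringsAsFactors = FALSE))
  }
  igraph::V(g)$occurrence <- as.integer(occ[igraph::V(g)$name])
  g$kind <- "phenotype"
  g
}

#' Build the interactome graph
#'
#' Simple undirected graph from a cleaned, score-filtered edge list (see
#' [read_interactome()]); edges are unweighted after thresholding.
#'
#' @param edges data frame with columns `protein_a`, `protein_b` (an
#'   `interactome_edges` object or equivalent).
#' @return undirected igraph with graph attribute `kind = "molecular"`.
#' @export
build_interactome_graph <- function(edges) {
  require_columns(edges, c("protein_a", "protein_b"), "build_interactome_graph")
  if (!nrow(edges)) {
    g <- igraph::make_empty_graph(n = 0, directed = FALSE)
  } else {
    g <- igraph::graph_from_data_frame(
      edges[, c("protein_a", "protein_b")], directed = FALSE)
    g <- igraph::simplify(g)
  }
  g$kind <- "molecular"
  g
}

#' Extract the induced subnetwork of named gene sets
#'
#' Induced subgraph on the union of the given sets intersected with the
#' graph's nodes; each retained node is labeled with the names of the sets
#' containing it (vertex attribute `sets`, pipe-separated).
#'
#' @param graph an igraph.
#' @param gene_sets named list of character vectors.
#' @return igraph subnetwork with vertex attribute `sets`.
#' @export
extract_subnetwork <- function(graph, gene_sets) {
  stopifnot(is.list(gene_sets), !is.null(names(gene_sets)),
            all(lengths(gene_sets) > 0))
  wanted <- unique(unlist(gene_sets, use.names = FALSE))
  present <- intersect(wanted, igraph::V(graph)$name)
  if (!length(present)) {
    warning("extract_subnetwork: no set member present in the graph",
            call. = FALSE)
  }
  sub <- igraph::induced_subgraph(graph, present)
  labels <- vapply(igraph::V(sub)$name, function(v) {
    paste(names(gene_sets)[vapply(gene_sets, function(s) v %in% s, TRUE)],
          collapse = "|")
  }, "")
  igraph::V(sub)$sets <- unname(labels)
  sub
}

#' Pair co-occurrence count for two symptom terms
#'
#' Counts records containing both terms (n), records containing the first
#' term (N), and reports the percentage n/N to 2 decimals -- the convention
#' used in the case-study tables where the partner symptom's total
#' occurrence is the denominator.
#'
#' @param records a [cluster_records()] object.
#' @param s1,s2 symptom terms.
#' @param include_chief include chief symptoms as record members.
#' @return list with `n`, `N`, `percent` (NA with a warning when N = 0).
#' @export
pair_cooccurrence <- function(records, s1, s2, include_chief = TRUE) {
  stopifnot(inherits(records, "cluster_records"))
  term_sets <- lapply(seq_along(records$records), function(i) {
    terms <- records$records[[i]]
    if (include_chief && !is.null(records$chief)) {
      terms <- c(records$chief[i], terms)
    }
    terms
  })
  has1 <- vapply(term_sets, function(t) s1 %in% t, TRUE)
  has2 <- vapply(term_sets, function(t) s2 %in% t, TRUE)
  n <- sum(has1 & has2)
  N <- sum(has1)
  if (N == 0L) {
    warning(sprintf("pair_cooccurrence: '%s' never occurs; percentage undefined",
                    s1), call. = FALSE)
    pct <- NA_real_
  } else {
    pct <- round_half_up(100 * n / N)
  }
  list(n = n, N = N, percent = pct)
}

#' Export a network as GraphML
#'
#' Writes the graph with whatever node attributes it carries (occurrence,
#' degree, diversity, category, set labels) and the `weight` edge
#' attribute; the machine-readable stand-in for an interactive network
#' rendering.
#'
#' @param graph an igraph.
#' @param path output path.
#' @param diversity optional diversity table (as from
#'   [all_node_diversity()]) whose `diversity` and `degree` columns are
#'   attached to matching nodes.
#' @param category optional named character vector term -> category.
#' @return `path`, invisibly.
#' @export
export_graphml <- function(graph, path, diversity = NULL, category = NULL) {
  if (!is.null(diversity)) {
    idx <- match(igraph::V(graph)$name, diversity$node)
    igraph::V(graph)$diversity <- diversity$diversity[idx]
    igraph::V(graph)$degree <- diversity$degree[idx]
  }
  if (!is.null(category)) {
    igraph::V(graph)$category <-
      unname(category[igraph::V(graph)$name])
  }
  igraph::write_graph(graph, path, format = "graphml")
  invisible(path)
}

#' Export a network as an edge-list TSV
#' @param graph an igraph.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
export_edgelist <- function(graph, path) {
  df <- igraph::as_data_frame(graph, what = "edges")
  write_tsv(df, path)
}
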