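# Node diversity phi: the bridging-coefficient-based statistic at the core
# of the analysis. For a focal node j,
#
#   phi(j) = sum over neighbors i with k(i) >= 2 of delta_j(i) / (k(i) - 1)
#
# where delta_j(i) is the number of edges from neighbor i to nodes outside
# the closed neighborhood N(j) u {j} of the focal node, equivalently
# k(i) - 1 - |N(i) n N(j)|. Each term lies in [0, 1], so 0 <= phi <= degree:
# phi is large for nodes whose many neighbors themselves reach outside.
# Degree-1 neighbors contribute 0 (the denominator is otherwise undefined).
# phi is computed on unweighted topology; edge weights are ignored.

# normalize graph input to a (named) adjacency list of integer indices
as_adjlist_internal <- function(graph) {
  if (igraph::is_igraph(graph)) {
    if (igraph::any_multiple(graph) || any(igraph::which_loop(graph))) {
      stop("node diversity requires a simple graph", call. = FALSE)
    }
    adj <- lapply(igraph::as_adj_list(graph, mode = "all"), as.integer)
    nm <- igraph::V(graph)$name %||% as.character(seq_along(adj))
  } else if (is.matrix(graph)) {
    if (!isSymmetric(unname(graph) * 1) || any(diag(graph) != 0)) {
      stop("adjacency matrix must be symmetric with a zero diagonal",
           call. = FALSE)
    }
    adj <- apply(graph != 0, 1L, which, simplify = FALSE)
    nm <- rownames(graph) %||% as.character(seq_len(nrow(graph)))
  } else {
    stop("graph must be an igraph object or an adjacency matrix",
         call. = FALSE)
  }
  list(adj = adj, names = nm)
}

phi_from_adjlist <- function(adj) {
  deg <- lengths(adj)
  vapply(seq_along(adj), function(j) {
    nj <- adj[[j]]
    s <- 0
    for (i in nj) {
      ki <- deg[[i]]
      if (ki >= 2L) {
        common <- sum(adj[[i]] %in% nj)
        s <- s + (ki - 1L - common) / (ki - 1L)
      }
    }
    s
  }, 0)
}

#' Node diversity of one or more nodes
#'
#' Computes the node-diversity statistic phi (see the package vignette for
#' the formula and its reading) on any simple undirected graph, given as an
#' igraph object or an adjacency matrix.
#'
#' @param graph igraph object or symmetric 0/1 adjacency matrix.
#' @param nodes node names (or indices for unnamed graphs); default all.
#' @return named numeric vector of phi values.
#' @export
node_diversity <- function(graph, nodes = NULL) {
  al <- as_adjlist_internal(graph)
  if (is.matrix(graph)) {
    # matrix route: closed-form via common-neighbor counts, a second,
    # algebraic derivation of the same statistic
    A <- (unname(graph) != 0) * 1
    k <- rowSums(A)
    cn <- A %*% A                       # cn[i, j] = |N(i) n N(j)|
    term <- matrix(0, nrow(A), ncol(A))
    ok <- k >= 2
    if (any(ok)) {
      term[ok, ] <- A[ok, , drop = FALSE] *
        ((k[ok] - 1 - cn[ok, , drop = FALSE]) / (k[ok] - 1))
    }
    phi <- colSums(term)
  } else {
    phi <- phi_from_adjlist(al$adj)
  }
  names(phi) <- al$names
  if (!is.null(nodes)) {
    nodes <- as.character(nodes)
    missing <- setdiff(nodes, al$names)
    if (length(missing)) {
      stop(sprintf("node_diversity: node(s) not in graph: %s",
                   paste(missing, collapse = ", ")), call. = FALSE)
    }
    phi <- phi[nodes]
  }
  phi
}

#' Diversity table for every node of a graph
#'
#' One row per node with its degree and diversity, sorted by diversity
#' descending (ties broken by node name for determinism) with a dense rank
#' column; the per-network table behind both the phenotypic (PD/PE) and the
#' molecular (gene-level) diversity results.
#'
#' @param graph igraph object or adjacency matrix.
#' @return data frame with columns `node`, `degree`, `diversity`, `rank`.
#' @export
all_node_diversity <- function(graph) {
  al <- as_adjlist_internal(graph)
  if (!length(al$adj)) {
    return(data.frame(node = character(), degree = integer(),
                      diversity = numeric(), rank = integer()))
  }
  phi <- phi_from_adjlist(al$adj)
  out <- data.frame(node = al$names, degree = lengths(al$adj),
                    diversity = phi, stringsAsFactors = FALSE)
  out <- out[order(-out$diversity, out$node), , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

#' Molecular diversity of a phenotype's gene set
#'
#' The phenotype's molecular network diversity: the maximum node diversity
#' (MGD) and maximum degree (MGE) over its associated genes present in the
#' interactome. Genes absent from the interactome are excluded and
#' counted; ties for the maximum-diversity gene are broken
#' lexicographically.
#'
#' @param ppi_diversity diversity table of the interactome, as returned by
#'   [all_node_diversity()].
#' @param phenotype phenotype term (carried into the result).
#' @param genes character vector of associated genes (non-empty).
#' @return one-row data frame `phenotype`, `genes_total`,
#'   `genes_in_network`, `MGD`, `MGE`, `argmax_gene`, `unmapped`; MGD/MGE
#'   are NA and `unmapped` TRUE when no gene is in the network.
#' @export
gene_set_diversity <- function(ppi_diversity, phenotype, genes) {
  stopifnot(length(genes) > 0)
  genes <- unique(as.character(genes))
  hit <- ppi_diversity[ppi_diversity$node %in% genes, , drop = FALSE]
  if (!nrow(hit)) {
    return(data.frame(phenotype = phenotype, genes_total = length(genes),
                      genes_in_network = 0L, MGD = NA_real_, MGE = NA_real_,
                      argmax_gene = NA_character_, unmapped = TRUE,
                      stringsAsFactors = FALSE))
  }
  hit <- hit[order(hit$node), , drop = FALSE]   # lexicographic tie-break
  best <- which.max(hit$diversity)
  data.frame(phenotype = phenotype, genes_total = length(genes),
             genes_in_network = nrow(hit),
             MGD = hit$diversity[best], MGE = max(hit$degree),
             argmax_gene = hit$node[best], unmapped = FALSE,
             stringsAsFactors = FALSE)
}

#' Molecular diversity for every phenotype of an association table
#'
#' @param ppi_diversity interactome diversity table
#'   ([all_node_diversity()]).
#' @param assoc an [association_table()] (typically after term mapping).
#' @return data frame, one row per phenotype, as in
#'   [gene_set_diversity()].
#' @export
molecular_diversity <- function(ppi_diversity, assoc) {
  stopifnot(inherits(assoc, "assoc_table"))
  out <- do.call(rbind, lapply(names(assoc$index), function(p) {
    gene_set_diversity(ppi_diversity, p, assoc$index[[p]])
  }))
  rownames(out) <- NULL
  out
}

#' Enumerate shared-gene symptom pairs on the co-occurrence network
#'
#' For every SCN edge whose two endpoint symptoms both carry gene sets, a
#' pair record is emitted when the gene-set intersection is non-empty; the
#' pair's MGD/MGE are taken over the shared genes only (so pair MGD can
#' never exceed either single-symptom MGD).
#'
#' @param scn phenotype co-occurrence network
#'   ([build_cooccurrence_network()]).
#' @param assoc an [association_table()] keyed by SCN terms.
#' @param ppi_diversity interactome diversity table; when NULL, MGD/MGE
#'   columns are NA.
#' @return data frame `symptom_a`, `symptom_b`, `n_shared`,
#'   `shared_genes` (comma-separated), `MGD`, `MGE`, `cooccurrence`.
#' @export
enumerate_shared_gene_pairs <- function(scn, assoc, ppi_diversity = NULL) {
  stopifnot(inherits(assoc, "assoc_table"))
  ed <- igraph::as_data_frame(scn, what = "edges")
  if (!nrow(ed)) {
    return(data.frame(symptom_a = character(), symptom_b = character(),
                      n_shared = integer(), shared_genes = character(),
                      MGD = numeric(), MGE = numeric(),
                      cooccurrence = integer()))
  }
  if (is.null(ed$weight)) ed$weight <- NA_integer_
  rows <- lapply(seq_len(nrow(ed)), function(r) {
    a <- ed$from[r]; b <- ed$to[r]
    ga <- assoc$index[[a]]; gb <- assoc$index[[b]]
    if (is.null(ga) || is.null(gb)) return(NULL)
    shared <- intersect(ga, gb)
    if (!length(shared)) return(NULL)
    if (is.null(ppi_diversity)) {
      mgd <- NA_real_; mge <- NA_real_
    } else {
      gd <- gene_set_diversity(ppi_diversity, a, shared)
      mgd <- gd$MGD; mge <- gd$MGE
    }
    lohi <- sort(c(a, b))
    data.frame(symptom_a = lohi[1L], symptom_b = lohi[2L],
               n_shared = length(shared),
               shared_genes = paste(sort(shared), collapse = ","),
               MGD = mgd, MGE = mge,
               cooccurrence = as.integer(ed$weight[r]),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(symptom_a = character(), symptom_b = character(),
                      n_shared = integer(), shared_genes = character(),
                      MGD = numeric(), MGE = numeric(),
                      cooccurrence = integer())
  }
  message(sprintf("enumerate_shared_gene_pairs: %d shared-gene pairs from %d edges",
                  nrow(out), nrow(ed)))
  rownames(out) <- NULL
  out
}

#' Write a diversity table as TSV
#' @param diversity table from [all_node_diversity()].
#' @param path output path.
#' @param digits decimals for the reported diversity (half-up; default 2).
#' @return `path`, invisibly.
#' @export
write_diversity_table <- function(diversity, path, digits = 2) {
  out <- diversity
  out$diversity <- round_half_up(out$diversity, digits)
  write_tsv(out, path)
}
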