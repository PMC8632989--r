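test_that("node diversity has its closed-form values on stars, cliques and paths", {
  star <- igraph::make_star(6, mode = "undirected")  # center + 5 leaves
  phi <- node_diversity(star)
  expect_equal(unname(phi[1]), 0)       # center: every leaf edge returns inward
  expect_true(all(phi[-1] == 1))        # each leaf sees the hub reaching out

  for (n in 3:8) {
    phi <- node_diversity(igraph::make_full_graph(n))
    expect_true(all(phi == 0))          # cliques have no outward-leaving links
  }

  path <- igraph::make_graph(~ a - b, b - c)
  tab <- all_node_diversity(path)
  expect_equal(setNames(tab$diversity, tab$node)[c("a", "b", "c")],
               c(a = 1, b = 0, c = 1))
  expect_equal(setNames(tab$degree, tab$node)[c("a", "b", "c")],
               c(a = 1, b = 2, c = 1))
})

test_that("node diversity agrees with the edge-enumeration oracle on random graphs", {
  set.seed(53)
  for (rep in 1:30) {
    n <- sample(3:8, 1)
    A <- rand_adj(n, runif(1, 0.2, 0.8))
    g <- igraph::graph_from_adjacency_matrix(A, mode = "undirected")
    expect_equal(unname(node_diversity(g)), oracle_phi_all(A),
                 tolerance = 1e-12)
    # matrix and igraph routes agree (two independent implementations)
    expect_equal(unname(node_diversity(A)), unname(node_diversity(g)),
                 tolerance = 1e-12)
  }
})

test_that("node diversity is bounded by degree and invariant under relabeling", {
  set.seed(59)
  for (rep in 1:15) {
    A <- rand_adj(20, 0.2)
    phi <- node_diversity(A)
    deg <- rowSums(A)
    expect_true(all(phi >= -1e-12 & phi <= deg + 1e-12))
    perm <- sample.int(20)
    expect_equal(unname(node_diversity(A[perm, perm])), unname(phi)[perm],
                 tolerance = 1e-12)
  }
})

test_that("diversity tables are deterministic, ranked, and self-consistent", {
  expect_equal(nrow(all_node_diversity(igraph::make_empty_graph(0,
                                                                directed = FALSE))),
               0L)
  set.seed(61)
  g <- igraph::sample_gnp(300, 0.02)
  igraph::V(g)$name <- sprintf("n%03d", 1:300)
  tab <- all_node_diversity(g)
  expect_equal(tab$rank, seq_len(300))
  expect_true(all(diff(tab$diversity) <= 1e-12))
  phi <- node_diversity(g)
  # per-node agreement with single-node queries
  pick <- sample(tab$node, 25)
  expect_equal(setNames(tab$diversity, tab$node)[pick], phi[pick])
  expect_error(node_diversity(g, "absent_node"), "not in graph")
})

test_that("gene-set diversity is the maximum over mapped genes with deterministic ties", {
  set.seed(67)
  g <- igraph::sample_gnp(60, 0.1)
  igraph::V(g)$name <- sprintf("G%02d", 1:60)
  div <- all_node_diversity(g)
  phi <- setNames(div$diversity, div$node)
  deg <- setNames(div$degree, div$node)

  one <- gene_set_diversity(div, "p", "G05")
  expect_equal(one$MGD, unname(phi["G05"]))
  expect_equal(one$MGE, unname(deg["G05"]))

  part <- gene_set_diversity(div, "p", c("G05", "NOT_A_GENE"))
  expect_equal(part$genes_in_network, 1L)
  expect_equal(part$genes_total, 2L)

  none <- gene_set_diversity(div, "p", "NOPE")
  expect_true(none$unmapped)
  expect_true(is.na(none$MGD))

  for (rep in 1:20) {
    genes <- sample(names(phi), sample(2:10, 1))
    gd <- gene_set_diversity(div, "p", genes)
    expect_equal(gd$MGD, max(phi[genes]))      # brute-force max oracle
    expect_equal(gd$MGE, max(deg[genes]))
    best <- genes[phi[genes] == max(phi[genes])]
    expect_equal(gd$argmax_gene, min(best))    # lexicographic tie-break
  }
})

test_that("shared-gene pair enumeration matches the double-loop oracle", {
  scn <- igraph::graph_from_data_frame(
    data.frame(from = c("a", "a", "b"), to = c("b", "c", "c"),
               weight = c(3L, 1L, 2L)), directed = FALSE)
  at <- association_table(data.frame(
    phenotype_id = c("a", "a", "b", "b", "c"),
    phenotype_label = "x",
    gene = c("X", "Y", "Y", "Z", "Q")))
  pairs <- suppressMessages(enumerate_shared_gene_pairs(scn, at))
  expect_equal(nrow(pairs), 1L)                 # only (a,b) share {Y}
  expect_equal(pairs$shared_genes, "Y")
  expect_equal(pairs$cooccurrence, 3L)

  set.seed(71)
  terms <- sprintf("t%02d", 1:20)
  g <- igraph::sample_gnp(20, 0.3)
  igraph::V(g)$name <- terms
  igraph::E(g)$weight <- sample(1:5, igraph::ecount(g), TRUE)
  at <- association_table(do.call(rbind, lapply(terms[1:15], function(p) {
    data.frame(phenotype_id = p, phenotype_label = p,
               gene = sample(sprintf("g%02d", 1:30), sample(1:5, 1)))
  })))
  pairs <- suppressMessages(enumerate_shared_gene_pairs(g, at))
  ed <- igraph::as_data_frame(g)
  oracle <- 0L
  for (r in seq_len(nrow(ed))) {
    ga <- at$index[[ed$from[r]]]
    gb <- at$index[[ed$to[r]]]
    if (!is.null(ga) && !is.null(gb) && length(intersect(ga, gb))) {
      oracle <- oracle + 1L
    }
  }
  expect_equal(nrow(pairs), oracle)
  # every reported intersection is correct
  for (r in seq_len(nrow(pairs))) {
    expect_setequal(strsplit(pairs$shared_genes[r], ",")[[1]],
                    intersect(at$index[[pairs$symptom_a[r]]],
                              at$index[[pairs$symptom_b[r]]]))
  }
})

test_that("pair diversity never exceeds either single-symptom diversity", {
  set.seed(73)
  ppi <- igraph::sample_pa(150, m = 3, directed = FALSE)
  igraph::V(ppi)$name <- sprintf("G%03d", 1:150)
  div <- all_node_diversity(ppi)
  terms <- sprintf("t%02d", 1:15)
  at <- association_table(do.call(rbind, lapply(terms, function(p) {
    data.frame(phenotype_id = p, phenotype_label = p,
               gene = sample(sprintf("G%03d", 1:150), sample(3:12, 1)))
  })))
  scn <- igraph::sample_gnp(15, 0.5)
  igraph::V(scn)$name <- terms
  igraph::E(scn)$weight <- 1L
  pairs <- suppressMessages(enumerate_shared_gene_pairs(scn, at, div))
  md <- molecular_diversity(div, at)
  single <- setNames(md$MGD, md$phenotype)
  expect_gt(nrow(pairs), 0)
  expect_true(all(pairs$MGD <= pmin(single[pairs$symptom_a],
                                    single[pairs$symptom_b]) + 1e-12))
})
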