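make_collection <- function(n_sets = 6, universe_size = 40, seed = 1) {
  set.seed(seed)
  genes <- sprintf("g%02d", seq_len(universe_size))
  sets <- lapply(seq_len(n_sets), function(i) sample(genes, sample(3:12, 1)))
  names(sets) <- sprintf("S%02d", seq_len(n_sets))
  gene_set_collection(sets, universe = genes)
}

test_that("hypergeometric enrichment has its closed forms and oracle agreement", {
  genes <- sprintf("g%02d", 1:40)
  coll <- gene_set_collection(list(inset = genes[1:10], offset = genes[11:15]),
                              universe = genes)
  # single-gene query inside a set of size m: p = m/N exactly
  res <- enrich(genes[1], coll)
  expect_equal(res$p_value[res$set == "inset"], 10 / 40)
  # query disjoint from a set: p = 1
  expect_equal(res$p_value[res$set == "offset"], 1)

  # invariant to gene ordering
  q <- genes[c(3, 7, 12, 20)]
  expect_equal(enrich(q, coll)$p_value, enrich(rev(q), coll)$p_value)

  # monotone decreasing in overlap at fixed sizes
  ps <- vapply(0:5, function(k) {
    q <- c(genes[seq_len(k)], genes[30:(34 - k)])[1:5]
    enrich(q, coll)$p_value[1]
  }, 0)
  expect_true(all(diff(ps) <= 1e-12))

  expect_error(enrich("not_in_universe", coll), "empty")

  # tail-sum oracle on random configurations
  set.seed(127)
  for (rep in 1:25) {
    coll <- make_collection(seed = rep)
    q <- sample(coll$universe, sample(2:10, 1))
    res <- enrich(q, coll)
    for (r in seq_len(nrow(res))) {
      expect_equal(res$p_value[r],
                   oracle_hyper_tail(res$overlap[r], res$set_size[r],
                                     res$universe_size[r], res$query_size[r]),
                   tolerance = 1e-12)
    }
  }
})

test_that("BH adjustment flag changes the enriched call, not the raw p", {
  coll <- make_collection(seed = 5)
  q <- sample(coll$universe, 8)
  raw <- enrich(q, coll)
  adj <- enrich(q, coll, adjust = TRUE)
  expect_equal(raw$p_value, adj$p_value)
  expect_equal(adj$p_adjusted,
               stats::p.adjust(raw$p_value, method = "BH"))
})

test_that("enriched-pathway overlap follows the n/N convention", {
  coll <- make_collection(seed = 7)
  q1 <- sample(coll$universe, 8)
  a <- enrich(q1, coll, p_threshold = 0.8)   # high threshold: several enriched
  b <- enrich(q1, coll, p_threshold = 0.8)
  ov <- overlap_enriched(a, b)
  expect_setequal(ov$overlapped, a$set[a$enriched])   # identical results
  expect_equal(ov$percent, if (ov$n_total) 100 else NA_real_)

  lowa <- enrich(q1, coll, p_threshold = 1e-9)
  ov0 <- overlap_enriched(lowa, b)
  expect_equal(ov0$n_overlap, 0L)

  other <- make_collection(n_sets = 3, seed = 9)
  expect_error(overlap_enriched(a, enrich(other$universe[1:5], other)),
               "different collections")

  # brute-force name-intersection oracle with distinct thresholds
  a <- enrich(sample(coll$universe, 10), coll, p_threshold = 0.5)
  b <- enrich(sample(coll$universe, 6), coll, p_threshold = 0.5)
  ov <- overlap_enriched(a, b)
  expect_setequal(ov$overlapped,
                  intersect(a$set[a$enriched], b$set[b$enriched]))
  expect_equal(ov$n_total, sum(a$enriched))
})

test_that("case-pair selection applies an inclusive threshold and recounts", {
  pairs <- data.frame(symptom_a = c("a", "b", "c"), symptom_b = "z",
                      n_shared = 1L, shared_genes = "g", MGD = 1, MGE = 1,
                      cooccurrence = c(14L, 15L, 16L))
  sel <- select_case_pairs(pairs, 15)
  expect_equal(nrow(sel), 2L)
  expect_equal(sel$cooccurrence, c(16L, 15L))
  expect_equal(nrow(select_case_pairs(pairs, 0)), 3L)

  set.seed(131)
  pairs <- data.frame(symptom_a = sprintf("s%02d", 1:50), symptom_b = "z",
                      n_shared = 1L, shared_genes = "g", MGD = 1, MGE = 1,
                      cooccurrence = sample(0:30, 50, TRUE))
  thr <- 12
  expect_equal(nrow(select_case_pairs(pairs, thr)),
               sum(pairs$cooccurrence >= thr))
})

test_that("pathway-matrix clustering recovers structure deterministically", {
  # identical rows co-cluster; an orthogonal row separates
  m <- rbind(r1 = c(1, 1, 0, 0), r2 = c(1, 1, 0, 0), r3 = c(0, 0, 1, 1))
  cl <- cluster_pathway_matrix(m, n_row_clusters = 2)
  expect_equal(cl$row_labels[["r1"]], cl$row_labels[["r2"]])
  expect_false(cl$row_labels[["r1"]] == cl$row_labels[["r3"]])

  ident <- diag(5)
  rownames(ident) <- colnames(ident) <- sprintf("x%d", 1:5)
  cl <- cluster_pathway_matrix(ident, n_row_clusters = 5)
  expect_equal(length(unique(cl$row_labels)), 5L)

  one <- matrix(1, 1, 3, dimnames = list("only", NULL))
  expect_equal(unname(cluster_pathway_matrix(one, 1)$row_labels), 1L)

  # planted two-block matrix with 5% bit flips: block recovery
  set.seed(137)
  block <- rbind(matrix(rep(c(1, 0), c(10, 10)), 20, 20, byrow = TRUE),
                 matrix(rep(c(0, 1), c(10, 10)), 20, 20, byrow = TRUE))
  truth <- rep(1:2, each = 20)
  flips <- matrix(runif(length(block)) < 0.05, nrow(block))
  noisy <- abs(block - flips)
  rownames(noisy) <- sprintf("p%02d", 1:40)
  cl <- cluster_pathway_matrix(noisy, n_row_clusters = 2)
  expect_gt(ari(cl$row_labels, truth), 0.9)

  # invariant under row permutation (same partition up to relabeling)
  perm <- sample.int(40)
  cl2 <- cluster_pathway_matrix(noisy[perm, ], n_row_clusters = 2)
  expect_equal(ari(cl2$row_labels[rownames(noisy)], cl$row_labels), 1)
})

test_that("the enrichment matrix marks exactly the enriched sets", {
  coll <- make_collection(seed = 17)
  rs <- list(q1 = enrich(sample(coll$universe, 8), coll, p_threshold = 0.5),
             q2 = enrich(sample(coll$universe, 5), coll, p_threshold = 0.5))
  m <- enrichment_matrix(rs)
  expect_setequal(colnames(m),
                  union(rs$q1$set[rs$q1$enriched], rs$q2$set[rs$q2$enriched]))
  for (q in rownames(m)) {
    expect_setequal(colnames(m)[m[q, ] == 1], rs[[q]]$set[rs[[q]]$enriched])
  }
})
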